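#' The five annotation indicator columns, in scoring order
#' @export
INDICATOR_COLS <- c("missense", "cis_eqtl", "kegg", "ppi", "ko_mice")

#' Assemble five-category annotation profiles
#'
#' Combines the two variant-level indicators (missense, whole-blood
#' cis-eQTL) with the three enrichment-derived category flags into one
#' 0/1 profile per universe gene and recomputes the total score as their
#' sum. Genes absent from a flag mapping default to 0 in that category;
#' a flag naming a symbol outside the universe is a consistency error.
#'
#' @param gene_facts data frame from [collapse_to_genes()].
#' @param kegg_flags,ppi_flags,ko_flags named logical vectors keyed by
#'   gene symbol, e.g. from [member_flags()]. `ppi_flags` carries the
#'   gene-ontology biological-process category (the field's "PPI"
#'   annotation point); `ko_flags` the knockout-mouse phenotype
#'   category.
#' @return data frame of class `gene_profiles`: `gene_id`,
#'   `gene_symbol`, the five indicator columns, `total_score` (0-5).
#' @export
build_profiles <- function(gene_facts, kegg_flags = logical(),
                           ppi_flags = logical(), ko_flags = logical()) {
  universe <- gene_universe(gene_facts)
  flag_col <- function(flags, what) {
    if (!length(flags)) return(integer(nrow(universe)))
    names(flags) <- norm_symbol(names(flags))
    stray <- setdiff(names(flags)[flags], universe$gene_symbol)
    if (length(stray)) {
      stop_data(what, " flag(s) for symbol(s) outside the universe: ",
                paste(head(stray, 5L), collapse = ", "))
    }
    as.integer(flags[universe$gene_symbol] %in% TRUE)
  }
  out <- data.frame(
    gene_id     = universe$gene_id,
    gene_symbol = universe$gene_symbol,
    missense    = as.integer(gene_facts$has_missense[
      match(universe$gene_id, gene_facts$gene_id)] %in% TRUE),
    cis_eqtl    = as.integer(gene_facts$has_eqtl[
      match(universe$gene_id, gene_facts$gene_id)] %in% TRUE),
    kegg        = flag_col(kegg_flags, "KEGG"),
    ppi         = flag_col(ppi_flags, "PPI"),
    ko_mice     = flag_col(ko_flags, "KO-mice"),
    stringsAsFactors = FALSE
  )
  out$total_score <- rowSums(out[INDICATOR_COLS])
  class(out) <- c("gene_profiles", "data.frame")
  out
}

#' Construct profiles from an already-tabulated indicator matrix
#'
#' For data that arrive as a finished indicator table (such as the
#' packaged reference table), rather than from the ingest/enrichment
#' stages. Totals are always recomputed from the indicators.
#'
#' @param tab data frame with `gene_id`, `gene_symbol` and the five
#'   indicator columns `missense`, `cis_eqtl`, `kegg`, `ppi`, `ko_mice`.
#' @return data frame of class `gene_profiles`.
#' @export
as_gene_profiles <- function(tab) {
  need <- c("gene_id", "gene_symbol", INDICATOR_COLS)
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_data("indicator table missing column(s): ",
              paste(missing, collapse = ", "))
  }
  out <- tab[, need]
  for (cl in INDICATOR_COLS) {
    v <- out[[cl]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- "0"  # blank cell = 0
    v <- as.integer(v)
    if (any(is.na(v) | !v %in% 0:1)) {
      stop_data("indicator column '", cl, "' is not 0/1")
    }
    out[[cl]] <- v
  }
  out$gene_symbol <- norm_symbol(out$gene_symbol)
  out$total_score <- rowSums(out[INDICATOR_COLS])
  rownames(out) <- NULL
  class(out) <- c("gene_profiles", "data.frame")
  out
}

#' Call risk genes at a score threshold
#'
#' A gene is a risk gene when its total annotation score reaches the
#' threshold (default 2 of 5 categories). Output is ranked by
#' descending score with a configurable tie-break.
#'
#' @param profiles `gene_profiles` data frame.
#' @param threshold minimum total score, default 2.
#' @param tie_break secondary sort key within a score: `"symbol"`
#'   (lexicographic, default) or `"gene_id"`.
#' @return the profiles ranked, with a logical `is_risk_gene` column.
#' @export
call_risk_genes <- function(profiles, threshold = 2,
                            tie_break = c("symbol", "gene_id")) {
  if (threshold < 0) stop_data("threshold must be >= 0")
  tie_break <- match.arg(tie_break)
  key <- if (tie_break == "symbol") profiles$gene_symbol else profiles$gene_id
  out <- profiles[order(-profiles$total_score, key), ]
  out$is_risk_gene <- out$total_score >= threshold
  rownames(out) <- NULL
  out
}

#' Risk-gene symbols of a profile table
#'
#' @param profiles `gene_profiles` data frame.
#' @param threshold minimum total score, default 2.
#' @return character vector of risk-gene symbols.
#' @export
risk_genes <- function(profiles, threshold = 2) {
  calls <- call_risk_genes(profiles, threshold)
  calls$gene_symbol[calls$is_risk_gene]
}

#' Distribution of total annotation scores
#'
#' @param profiles `gene_profiles` data frame.
#' @return named integer vector of gene counts for scores "0" .. "5";
#'   counts sum to `nrow(profiles)`.
#' @export
score_histogram <- function(profiles) {
  counts <- table(factor(profiles$total_score, levels = 0:5))
  setNames(as.integer(counts), names(counts))
}

#' Regression check of recomputed scores against a printed table
#'
#' Joins computed profiles to a reference indicator table by gene id and
#' reports every gene whose recomputed total disagrees with the printed
#' total, plus genes present on only one side. An empty report means
#' the profiles reproduce the reference exactly.
#'
#' @param profiles `gene_profiles` data frame.
#' @param printed reference table with `gene_id`, `gene_symbol`,
#'   indicator columns and a printed `total_score`.
#' @return data frame with one row per discrepancy: `gene_id`,
#'   `gene_symbol`, `computed_total`, `printed_total`, `note`.
#' @export
compare_profiles <- function(profiles, printed) {
  ref <- as_gene_profiles(printed)  # recomputes totals from indicators
  ref$printed_total <- as.integer(printed$total_score %||% ref$total_score)
  m <- match(ref$gene_id, profiles$gene_id)
  rows <- list()
  add <- function(id, sym, comp, prt, note) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = id, gene_symbol = sym, computed_total = comp,
      printed_total = prt, note = note, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ref))) {
    if (ref$total_score[i] != ref$printed_total[i]) {
      add(ref$gene_id[i], ref$gene_symbol[i], ref$total_score[i],
          ref$printed_total[i], "printed indicators do not sum to total")
    } else if (is.na(m[i])) {
      add(ref$gene_id[i], ref$gene_symbol[i], NA_integer_,
          ref$printed_total[i], "missing from computed profiles")
    } else if (profiles$total_score[m[i]] != ref$printed_total[i]) {
      add(ref$gene_id[i], ref$gene_symbol[i],
          profiles$total_score[m[i]], ref$printed_total[i],
          "total score differs")
    }
  }
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(gene_id = character(), gene_symbol = character(),
               computed_total = integer(), printed_total = integer(),
               note = character(), stringsAsFactors = FALSE)
  }
}

#' Write gene profiles as TSV
#'
#' Mirrors the reference table's column layout (id, symbol, five
#' indicators, total score).
#'
#' @param profiles `gene_profiles` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  write.table(as.data.frame(profiles), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
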