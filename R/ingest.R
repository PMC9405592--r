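#' SNP consequence vocabulary
#'
#' Controlled vocabulary for the functional consequence of a SNP record.
#' Consequences outside this set are coerced to `"other"` at read time.
#'
#' @export
SNP_CONSEQUENCES <- c("missense", "nonsense", "synonymous",
                      "intronic", "intergenic", "other")

#' Default column mapping for SNP annotation snapshots
#'
#' Maps the fields of a SNP record to the column names of a tab-separated
#' annotation snapshot (the reference dialect used by the packaged
#' fixtures and the synthetic generator). Real exports from annotation
#' browsers can be adapted by overriding individual entries.
#'
#' @export
default_snp_columns <- function() {
  list(snp_id      = "snp_id",
       gene_id     = "gene_id",
       gene_symbol = "gene_symbol",
       consequence = "consequence",
       eqtl_tissue = "eqtl_tissue")
}

#' Read a SNP-level annotation snapshot
#'
#' Parses a tab-separated table of SNP-to-gene annotations (one row per
#' SNP-gene pair) into a typed data frame. A SNP overlapping several
#' genes appears on several rows and contributes to every mapped gene.
#'
#' @param path path to a TSV file with a header row.
#' @param columns named list mapping record fields to file column names;
#'   see [default_snp_columns()]. Entries other than `eqtl_tissue` are
#'   required to be present in the header.
#' @return a data frame with columns `snp_id`, `gene_id`, `gene_symbol`,
#'   `consequence` (one of [SNP_CONSEQUENCES]) and `eqtl_tissue` (empty
#'   string when the SNP is not an eQTL). Row order follows the file.
#' @export
read_snp_table <- function(path, columns = default_snp_columns()) {
  if (!file.exists(path)) stop_data("SNP table not found: ", path)
  columns <- utils::modifyList(default_snp_columns(), as.list(columns))
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  required <- unlist(columns[c("snp_id", "gene_id", "gene_symbol",
                               "consequence")])
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop_data("SNP table is missing mapped column(s): ",
              paste(missing, collapse = ", "))
  }
  eqtl <- if (columns$eqtl_tissue %in% names(raw)) {
    raw[[columns$eqtl_tissue]]
  } else {
    rep("", nrow(raw))
  }
  cons <- tolower(trimws(raw[[columns$consequence]]))
  cons[!cons %in% SNP_CONSEQUENCES] <- "other"
  out <- data.frame(
    snp_id      = trimws(raw[[columns$snp_id]]),
    gene_id     = trimws(raw[[columns$gene_id]]),
    gene_symbol = norm_symbol(raw[[columns$gene_symbol]]),
    consequence = cons,
    eqtl_tissue = trimws(eqtl),
    stringsAsFactors = FALSE
  )
  if (nrow(out) && any(out$snp_id == "")) stop_data("empty snp_id in SNP table")
  out
}

#' Collapse SNP records to per-gene annotation facts
#'
#' Reduces SNP-level records to one row per gene carrying the two
#' variant-level annotation indicators: whether any SNP of the gene is a
#' missense variant, and whether any SNP is a cis-eQTL in the filter
#' tissue. Each indicator is worth one point in the downstream score.
#'
#' @param records data frame from [read_snp_table()].
#' @param eqtl_tissue tissue label an eQTL must match (case- and
#'   underscore/space-insensitive). Default `"Whole_Blood"`.
#' @param count_nonsense also count nonsense variants toward the
#'   missense indicator. Default `FALSE`: the scored criterion is
#'   missense presence.
#' @return a data frame with one row per distinct `gene_id`, columns
#'   `gene_id`, `gene_symbol`, `has_missense`, `has_eqtl`, ordered by
#'   `gene_id`.
#' @export
collapse_to_genes <- function(records, eqtl_tissue = "Whole_Blood",
                              count_nonsense = FALSE) {
  if (!nrow(records)) {
    return(data.frame(gene_id = character(), gene_symbol = character(),
                      has_missense = logical(), has_eqtl = logical(),
                      stringsAsFactors = FALSE))
  }
  sym_by_id <- tapply(records$gene_symbol, records$gene_id,
                      function(s) unique(s))
  conflicts <- names(sym_by_id)[lengths(sym_by_id) > 1L]
  if (length(conflicts)) {
    stop_data("conflicting gene_symbol for gene_id(s): ",
              paste(conflicts, collapse = ", "))
  }
  mis_cons <- if (count_nonsense) c("missense", "nonsense") else "missense"
  is_mis <- records$consequence %in% mis_cons
  is_eqtl <- norm_tissue(records$eqtl_tissue) == norm_tissue(eqtl_tissue) &
    records$eqtl_tissue != ""
  ids <- sort(unique(records$gene_id))
  out <- data.frame(
    gene_id      = ids,
    gene_symbol  = vapply(sym_by_id[ids], identity, character(1)),
    has_missense = as.logical(tapply(is_mis, records$gene_id, any)[ids]),
    has_eqtl     = as.logical(tapply(is_eqtl, records$gene_id, any)[ids]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Gene universe of an annotation snapshot
#'
#' The set of distinct (gene_id, gene_symbol) pairs covered by the SNP
#' records; this is the background for all enrichment-derived scoring.
#'
#' @param gene_facts data frame from [collapse_to_genes()] (or any data
#'   frame with `gene_id` and `gene_symbol` columns).
#' @return a data frame with columns `gene_id`, `gene_symbol`.
#' @export
gene_universe <- function(gene_facts) {
  u <- unique(gene_facts[, c("gene_id", "gene_symbol")])
  if (anyDuplicated(u$gene_id)) stop_data("duplicate gene_id in universe")
  rownames(u) <- NULL
  u
}
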