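#' Read a drug-target table
#'
#' Tab-separated snapshot with one row per drug-target association:
#' `drug_name`, `gene_symbol`, `original_indication` (column names
#' adaptable). Rows duplicated after normalization are collapsed.
#'
#' @param path path to a TSV file with header.
#' @param columns named list mapping the three fields to column names.
#' @param strip_salts treat salt forms as the same drug (off by
#'   default; "atracurium besylate" stays distinct from "atracurium").
#' @return data frame with `drug_name`, `gene_symbol`,
#'   `original_indication`, and the normalized join key `drug_key`.
#' @export
read_drug_targets <- function(path,
                              columns = list(
                                drug_name = "drug_name",
                                gene_symbol = "gene_symbol",
                                original_indication = "original_indication"),
                              strip_salts = FALSE) {
  if (!file.exists(path)) stop_data("drug-target table not found: ", path)
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  missing <- setdiff(unlist(columns), names(raw))
  if (length(missing)) {
    stop_data("drug-target table missing column(s): ",
              paste(missing, collapse = ", "))
  }
  drug_target_table(raw[[columns$drug_name]], raw[[columns$gene_symbol]],
                    raw[[columns$original_indication]],
                    strip_salts = strip_salts)
}

#' Construct a normalized drug-target table
#'
#' @param drug_name,gene_symbol,original_indication character vectors of
#'   equal length (one element per association).
#' @param strip_salts see [read_drug_targets()].
#' @return data frame with unique (drug, gene) associations.
#' @export
drug_target_table <- function(drug_name, gene_symbol,
                              original_indication = "", strip_salts = FALSE) {
  if (any(!nzchar(trimws(drug_name)))) stop_data("empty drug_name")
  out <- data.frame(
    drug_name = trimws(drug_name),
    gene_symbol = norm_symbol(gene_symbol),
    original_indication = rep_len(trimws(original_indication),
                                  length(drug_name)),
    stringsAsFactors = FALSE
  )
  out$drug_key <- norm_drug(out$drug_name, strip_salts = strip_salts)
  out <- out[!duplicated(out[, c("drug_key", "gene_symbol")]), ]
  rownames(out) <- NULL
  out
}

#' Overlap target genes with a drug-target table
#'
#' A target gene is druggable when at least one drug in the table lists
#' it as a target. Candidate drugs are the distinct drugs hitting at
#' least one target gene; a drug may target several genes.
#'
#' @param targets a `target_gene_set` from [expand_seeds()] or a
#'   character vector of gene symbols.
#' @param drug_table data frame from [read_drug_targets()] /
#'   [drug_target_table()].
#' @return object of class `druggability_report`: list with
#'   `druggable_genes`, `undruggable_genes` (partition of the targets),
#'   `candidate_drugs` (data frame `drug_name`, `drug_key`, `n_genes`,
#'   `genes` comma-joined) and `associations` (the matching drug-gene
#'   rows).
#' @export
map_drugs <- function(targets, drug_table) {
  stopifnot(is.data.frame(drug_table))  # zero rows allowed: nothing druggable
  target_syms <- if (inherits(targets, "target_gene_set")) targets$all
                 else unique(norm_symbol(targets))
  assoc <- drug_table[drug_table$gene_symbol %in% target_syms, ]
  rownames(assoc) <- NULL
  druggable <- sort(unique(assoc$gene_symbol))
  by_drug <- split(assoc$gene_symbol, assoc$drug_key)
  first <- assoc[!duplicated(assoc$drug_key), ]
  drugs <- data.frame(
    drug_name = first$drug_name,
    drug_key = first$drug_key,
    n_genes = lengths(by_drug)[first$drug_key],
    genes = vapply(by_drug[first$drug_key],
                   function(g) paste(sort(unique(g)), collapse = ","),
                   character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  drugs <- drugs[order(drugs$drug_key), ]
  rownames(drugs) <- NULL
  structure(list(
    druggable_genes = druggable,
    undruggable_genes = sort(setdiff(target_syms, druggable)),
    candidate_drugs = drugs,
    associations = assoc
  ), class = "druggability_report")
}

#' @export
print.druggability_report <- function(x, ...) {
  cat(sprintf(paste0("<druggability_report: %d of %d target genes druggable, ",
                     "%d candidate drugs (%d associations)>\n"),
              length(x$druggable_genes),
              length(x$druggable_genes) + length(x$undruggable_genes),
              nrow(x$candidate_drugs), nrow(x$associations)))
  invisible(x)
}
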