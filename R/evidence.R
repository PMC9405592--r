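EVIDENCE_SOURCES <- c("clinical", "preclinical")

#' Read an evidence snapshot
#'
#' Tab-separated snapshot of registry / literature search results, one
#' row per evidence record: `drug_name`, `source` (`clinical` for trial
#' registry hits, `preclinical` for literature hits), `identifier`
#' (NCT accession or PubMed id).
#'
#' @param path path to a TSV file with header.
#' @return data frame with `drug_name`, `source`, `identifier` and the
#'   normalized join key `drug_key`.
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) stop_data("evidence table not found: ", path)
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  missing <- setdiff(c("drug_name", "source", "identifier"), names(raw))
  if (length(missing)) {
    stop_data("evidence table missing column(s): ",
              paste(missing, collapse = ", "))
  }
  evidence_table(raw$drug_name, raw$source, raw$identifier)
}

#' Construct a normalized evidence table
#'
#' @param drug_name,source,identifier character vectors of equal length.
#' @return data frame with `drug_name`, `source`, `identifier`,
#'   `drug_key`.
#' @export
evidence_table <- function(drug_name, source, identifier) {
  source <- tolower(trimws(source))
  if (any(!source %in% EVIDENCE_SOURCES)) {
    stop_data("evidence source must be one of: ",
              paste(EVIDENCE_SOURCES, collapse = ", "))
  }
  identifier <- trimws(identifier)
  if (any(!nzchar(identifier))) stop_data("empty evidence identifier")
  data.frame(drug_name = trimws(drug_name), source = source,
             identifier = identifier, drug_key = norm_drug(drug_name),
             stringsAsFactors = FALSE)
}

#' Expand a truncated trial accession to full NCT form
#'
#' Registry accessions are sometimes printed with the "NCT" prefix and
#' leading zeros dropped; this zero-pads bare digit strings to the
#' 8-digit NCT format. Strings that are not bare digits are returned
#' unchanged (PubMed ids keep their printed form).
#'
#' @param x character vector of identifiers.
#' @return character vector with clinical accessions in NCT form.
#' @export
normalize_nct <- function(x) {
  bare <- grepl("^[0-9]{1,8}$", x)
  x[bare] <- sprintf("NCT%08d", as.integer(x[bare]))
  x
}

#' Classify candidate drug-target pairs by development evidence
#'
#' Each drug-target association of the druggability report is classified
#' as `in_development` when the drug has at least one clinical or
#' preclinical evidence record, else `novel_candidate`. Candidates are
#' tallied at drug-target-pair granularity — the granularity of
#' drug-target snapshots, where one drug hitting two genes counts as two
#' development records; drug-level summaries are available through
#' [candidate_drugs()]. Each pair carries its target gene's annotation
#' score (NA when the gene has no profile, e.g. a network-added target).
#'
#' @param report `druggability_report` from [map_drugs()].
#' @param evidence data frame from [read_evidence()] /
#'   [evidence_table()]; may be empty (zero rows) for none.
#' @param profiles `gene_profiles` data frame used to look up gene
#'   scores.
#' @return data frame of class `candidate_classification`, one row per
#'   drug-target pair: `drug_name`, `drug_key`, `gene_symbol`,
#'   `original_indication`, `gene_score`, `status`, `evidence_sources`,
#'   `evidence_ids` (comma-joined, empty for novel candidates). Rows
#'   are ranked in-development first, then by descending score and drug
#'   name.
#' @export
classify_candidates <- function(report, evidence, profiles) {
  stopifnot(inherits(report, "druggability_report"))
  assoc <- report$associations
  ev <- evidence
  known <- unique(assoc$drug_key)
  stray <- setdiff(unique(ev$drug_key), known)
  if (length(stray)) {
    warning("evidence for drug(s) absent from candidates: ",
            paste(stray, collapse = ", "), call. = FALSE)
  }
  ev_by_drug <- split(ev, ev$drug_key)
  score_of <- setNames(profiles$total_score, profiles$gene_symbol)
  out <- assoc
  out$gene_score <- unname(score_of[out$gene_symbol])
  has_ev <- out$drug_key %in% names(ev_by_drug)
  out$status <- ifelse(has_ev, "in_development", "novel_candidate")
  out$evidence_sources <- vapply(out$drug_key, function(k) {
    e <- ev_by_drug[[k]]
    if (is.null(e)) "" else paste(sort(unique(e$source)), collapse = ",")
  }, character(1))
  out$evidence_ids <- vapply(out$drug_key, function(k) {
    e <- ev_by_drug[[k]]
    if (is.null(e)) "" else paste(unique(e$identifier), collapse = ",")
  }, character(1))
  ord <- order(out$status != "in_development",
               -ifelse(is.na(out$gene_score), -1L, out$gene_score),
               out$drug_key, out$gene_symbol)
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("candidate_classification", "data.frame")
  out
}

#' Drug-level view of a candidate classification
#'
#' Collapses drug-target pairs to one row per distinct drug, keeping
#' the union of its target genes, the maximum gene score over them, and
#' the drug's status.
#'
#' @param classifications `candidate_classification` data frame.
#' @return data frame with `drug_name`, `drug_key`, `status`,
#'   `target_genes` (comma-joined), `gene_score` (max over targets,
#'   NA-removed unless all NA).
#' @export
candidate_drugs <- function(classifications) {
  by_drug <- split(seq_len(nrow(classifications)),
                   classifications$drug_key)
  rows <- lapply(by_drug, function(ix) {
    cl <- classifications[ix, ]
    sc <- cl$gene_score[!is.na(cl$gene_score)]
    data.frame(
      drug_name = cl$drug_name[1], drug_key = cl$drug_key[1],
      status = cl$status[1],
      target_genes = paste(sort(unique(cl$gene_symbol)), collapse = ","),
      gene_score = if (length(sc)) max(sc) else NA_integer_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$status != "in_development",
                   -ifelse(is.na(out$gene_score), -1, out$gene_score),
                   out$drug_key), ]
  rownames(out) <- NULL
  out
}

#' Evidence-backed target genes
#'
#' The union of target genes over all in-development candidates — the
#' genes whose druggability is already supported by clinical or
#' preclinical depression evidence, and hence the "most promising"
#' targets for repurposing.
#'
#' @param classifications `candidate_classification` data frame.
#' @return sorted character vector of gene symbols.
#' @export
promising_genes <- function(classifications) {
  sort(unique(
    classifications$gene_symbol[classifications$status == "in_development"]))
}

#' Shortlist novel candidates hitting promising genes
#'
#' Novel (evidence-free) candidates whose target gene is among the
#' promising genes, ranked by descending gene score then drug name —
#' the repurposing shortlist.
#'
#' @param classifications `candidate_classification` data frame.
#' @param promising character vector of promising gene symbols,
#'   defaulting to [promising_genes()] of the same classification.
#' @return `candidate_classification` rows for the shortlist.
#' @export
shortlist_candidates <- function(classifications,
                                 promising = promising_genes(classifications)) {
  keep <- classifications$status == "novel_candidate" &
    classifications$gene_symbol %in% promising
  out <- classifications[keep, ]
  ord <- order(-ifelse(is.na(out$gene_score), -1, out$gene_score),
               out$drug_key)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
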