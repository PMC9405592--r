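#' Read a weighted protein-protein interaction edge list
#'
#' Accepts the common two-protein-plus-score TSV dialect
#' (`protein1`, `protein2`, `combined_score`); alternative column names
#' can be mapped. Scores on the 0-1000 integer scale are normalized to
#' `[0, 1]` at read time. Edges are undirected: endpoints are put in
#' canonical (lexicographic) order, self-loops rejected, and duplicate
#' edges collapsed keeping the highest confidence.
#'
#' @param path path to a TSV edge list with header.
#' @param columns named list mapping `gene_a`, `gene_b`, `confidence`
#'   to file column names.
#' @return data frame of class `ppi_edges`: `gene_a`, `gene_b`
#'   (normalized symbols, `gene_a < gene_b`), `confidence` in `[0, 1]`.
#' @export
read_ppi_edges <- function(path,
                           columns = list(gene_a = "protein1",
                                          gene_b = "protein2",
                                          confidence = "combined_score")) {
  if (!file.exists(path)) stop_data("edge list not found: ", path)
  raw <- read.delim(path, check.names = FALSE, na.strings = NULL)
  missing <- setdiff(unlist(columns), names(raw))
  if (length(missing)) {
    stop_data("edge list missing column(s): ",
              paste(missing, collapse = ", "))
  }
  ppi_edges(raw[[columns$gene_a]], raw[[columns$gene_b]],
            as.numeric(raw[[columns$confidence]]))
}

#' Construct a canonical undirected edge table
#'
#' @param gene_a,gene_b endpoint gene symbols.
#' @param confidence interaction confidence; values above 1 are taken to
#'   be on the 0-1000 scale and divided by 1000.
#' @return data frame of class `ppi_edges`.
#' @export
ppi_edges <- function(gene_a, gene_b, confidence) {
  a <- norm_symbol(gene_a); b <- norm_symbol(gene_b)
  if (any(a == b)) stop_data("self-loop edge(s) not allowed")
  conf <- as.numeric(confidence)
  if (any(!is.finite(conf) | conf < 0)) stop_data("bad confidence value(s)")
  if (any(conf > 1)) conf <- conf / 1000
  assert_prob(conf, "confidence")
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- data.frame(gene_a = lo, gene_b = hi, confidence = conf,
                    stringsAsFactors = FALSE)
  # collapse duplicates, keeping the strongest evidence for the pair
  out <- out[order(out$gene_a, out$gene_b, -out$confidence), ]
  out <- out[!duplicated(out[, c("gene_a", "gene_b")]), ]
  rownames(out) <- NULL
  class(out) <- c("ppi_edges", "data.frame")
  out
}

#' Expand seed genes through their strongest interactions
#'
#' Selects the `k` highest-confidence edges with at least one endpoint
#' in the seed set (expansion radius 1) and unions the non-seed
#' endpoints of the selected edges into the target set. Ties in
#' confidence are broken by canonical edge order (`gene_a`, then
#' `gene_b`), so the result is deterministic and invariant to the edge
#' list's row order. If fewer than `k` incident edges exist, all are
#' taken and the shortfall is messaged.
#'
#' @param seeds character vector of seed (risk) gene symbols.
#' @param edges `ppi_edges` data frame.
#' @param k number of interactions to select, default 50.
#' @param min_confidence drop incident edges below this confidence
#'   before selection. Default 0 (keep all).
#' @return object of class `target_gene_set`: a list with `seeds`,
#'   `added`, `all` (symbol vectors), the `selected` edge table, and
#'   the selection rule recorded in `meta`.
#' @export
expand_seeds <- function(seeds, edges, k = 50, min_confidence = 0) {
  if (k < 0) stop_data("k must be >= 0")
  stopifnot(is.data.frame(edges))
  seeds <- sort(unique(norm_symbol(seeds)))
  incident <- edges[(edges$gene_a %in% seeds | edges$gene_b %in% seeds) &
                      edges$confidence >= min_confidence, ]
  incident <- incident[order(-incident$confidence, incident$gene_a,
                             incident$gene_b), ]
  if (nrow(incident) < k) {
    message("only ", nrow(incident), " incident edge(s) available for k = ", k)
  }
  selected <- head(incident, k)
  added <- sort(setdiff(unique(c(selected$gene_a, selected$gene_b)), seeds))
  structure(list(
    seeds = seeds,
    added = added,
    all = sort(unique(c(seeds, added))),
    selected = `rownames<-`(selected, NULL),
    meta = list(rule = "top-k confidence among seed-incident edges",
                k = k, min_confidence = min_confidence,
                n_incident = nrow(incident))
  ), class = "target_gene_set")
}

#' @export
print.target_gene_set <- function(x, ...) {
  cat(sprintf(paste0("<target_gene_set: %d seeds + %d added = %d targets ",
                     "(%d of %d incident edges selected)>\n"),
              length(x$seeds), length(x$added), length(x$all),
              nrow(x$selected), x$meta$n_incident))
  invisible(x)
}
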