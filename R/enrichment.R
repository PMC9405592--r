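#' Upper-tail hypergeometric over-representation probability
#'
#' Probability of drawing at least `overlap` members of a gene set when
#' `query_size` genes are sampled without replacement from a background
#' of `background_size` genes of which `set_size` belong to the set:
#' `P(X >= overlap)` with `X ~ Hypergeometric(background_size, set_size,
#' query_size)`. This one-sided tail is the classical over-representation
#' test (Fisher's exact test, alternative "greater").
#'
#' @param overlap observed overlap count (vectorized).
#' @param query_size number of query genes.
#' @param set_size number of background genes in the set.
#' @param background_size total background size.
#' @return upper-tail probability in `[0, 1]`.
#' @examples
#' hypergeom_test(5, 5, 5, 10)   # 1 / choose(10, 5)
#' hypergeom_test(0, 10, 4, 50)  # P(X >= 0) is always 1
#' @export
hypergeom_test <- function(overlap, query_size, set_size, background_size) {
  n <- max(length(overlap), length(query_size), length(set_size),
           length(background_size))
  overlap <- rep_len(overlap, n); query_size <- rep_len(query_size, n)
  set_size <- rep_len(set_size, n)
  background_size <- rep_len(background_size, n)
  if (any(background_size < pmax(query_size, set_size))) {
    stop_data("background_size must be >= max(query_size, set_size)")
  }
  if (any(overlap < 0) || any(overlap > pmin(query_size, set_size))) {
    stop_data("overlap must lie in [0, min(query_size, set_size)]")
  }
  phyper(overlap - 1L, set_size, background_size - set_size, query_size,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate q-values for a vector of p-values, aligned to
#' the input order. Thin wrapper over [stats::p.adjust()] with domain
#' checking; kept as a named operation because every significance call
#' in the pipeline flows through it.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  assert_prob(p_values, "p-values")
  p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene list against a collection
#'
#' Tests every set of the collection for enrichment in the query with
#' the upper-tail hypergeometric test, adjusts across the collection
#' with Benjamini-Hochberg, and flags sets with `q < alpha` (strict
#' inequality). The background is the collection's explicit background
#' if set, otherwise the annotation universe: the union of the query and
#' all set members. Query symbols outside the background are dropped
#' with a warning.
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param alpha FDR significance level, default 0.05.
#' @return data frame of class `enrichment_result` with one row per set:
#'   `set_id`, `overlap`, `set_size`, `query_size`, `background_size`,
#'   `p_value`, `q_value`, `significant`. The genes behind each overlap
#'   are kept in `attr(, "overlap_genes")`.
#' @export
enrich <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop_data("alpha must be a single value in [0, 1]")
  }
  query <- unique(norm_symbol(query))
  background <- collection$background %||%
    unique(c(query, unlist(collection$sets, use.names = FALSE)))
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query symbol(s) outside background dropped",
            call. = FALSE)
    query <- intersect(query, background)
  }
  sets <- lapply(collection$sets, intersect, y = background)
  overlap_genes <- lapply(sets, intersect, y = query)
  overlap <- lengths(overlap_genes)
  set_size <- lengths(sets)
  res <- data.frame(
    set_id = names(sets),
    overlap = overlap,
    set_size = set_size,
    query_size = length(query),
    background_size = length(background),
    row.names = NULL, stringsAsFactors = FALSE
  )
  # a set emptied by background restriction cannot be tested; p = 1
  res$p_value <- ifelse(
    set_size == 0L, 1,
    hypergeom_test(overlap, length(query), pmax(set_size, 1L),
                   length(background))
  )
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < alpha
  attr(res, "overlap_genes") <- overlap_genes
  attr(res, "collection_id") <- collection$collection_id
  attr(res, "alpha") <- alpha
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Per-gene membership flags for one annotation category
#'
#' A query gene earns the category's point if it belongs to at least one
#' significant set — the flag is boolean, never a count, so a gene in
#' many significant sets still contributes at most one point to its
#' total score.
#'
#' @param results `enrichment_result` from [enrich()].
#' @param collection the [gene_set_collection()] the results came from.
#' @param query character vector of gene symbols (the enrichment query).
#' @return named logical vector over the query symbols.
#' @export
member_flags <- function(results, collection, query) {
  stopifnot(inherits(results, "enrichment_result"))
  query <- unique(norm_symbol(query))
  sig_sets <- results$set_id[results$significant]
  hit <- unique(unlist(collection$sets[sig_sets], use.names = FALSE))
  setNames(query %in% hit, query)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment of %d genes against %d sets ('%s'), alpha = %g\n",
              x$query_size[1] %||% NA, nrow(x),
              attr(x, "collection_id") %||% "?", attr(x, "alpha") %||% NA))
  cat(sprintf("  significant sets: %d\n", sum(x$significant)))
  NextMethod()
}

#' Write enrichment results as TSV
#'
#' @param results `enrichment_result` from [enrich()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
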