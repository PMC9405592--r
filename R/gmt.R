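#' Read a GMT gene-set file
#'
#' GMT is the conventional one-set-per-line format: set id, TAB,
#' description, TAB, then one gene symbol per remaining field. Empty
#' trailing fields are dropped; symbols are normalized with the same
#' rule as every other join in the package.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (unique symbols per set),
#'   with the per-set descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_data("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop_data("GMT line(s) with fewer than 3 fields: ",
              paste(bad, collapse = ", "))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop_data("duplicate set ids in GMT: ", path)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) {
    g <- norm_symbol(p[-(1:2)])
    unique(g[nzchar(g)])
  })
  names(sets) <- ids
  attr(sets, "description") <- setNames(desc, ids)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional named character vector of descriptions;
#'   defaults to the set id.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  description <- description %||% attr(sets, "description") %||%
    setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, unname(description[[id]]), sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Bundle gene sets into a collection for enrichment
#'
#' A collection ties gene sets to the background universe against which
#' over-representation is judged. When no explicit background is given
#' it defaults, at test time, to the union of the query and all set
#' members (the annotation universe); see [enrich()].
#'
#' @param sets named list of character vectors, e.g. from [read_gmt()].
#' @param collection_id label for the collection, conventionally one of
#'   `"KEGG"`, `"GO_BP"`, `"MP"`.
#' @param background optional character vector of background symbols.
#' @param strict require every set member to belong to `background`.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, collection_id = "custom",
                                background = NULL, strict = FALSE) {
  if (!length(sets)) stop_data("empty gene-set collection")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_data("all gene sets must be named")
  }
  sets <- lapply(sets, function(s) unique(norm_symbol(s)))
  if (any(lengths(sets) == 0L)) stop_data("empty gene set in collection")
  if (!is.null(background)) {
    background <- unique(norm_symbol(background))
    if (strict) {
      stray <- setdiff(unique(unlist(sets, use.names = FALSE)), background)
      if (length(stray)) {
        stop_data("set member(s) outside background: ",
                  paste(head(stray, 5L), collapse = ", "),
                  if (length(stray) > 5L) ", ...")
      }
    }
  }
  structure(list(collection_id = collection_id, sets = sets,
                 background = background),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection '%s': %d sets, background %s>\n",
              x$collection_id, length(x$sets),
              if (is.null(x$background)) "implicit"
              else length(x$background)))
  invisible(x)
}

#' Check gene-set symbols against a gene universe
#'
#' Reports which set members are absent from the universe — useful for
#' spotting symbol-dialect mismatches between an annotation snapshot and
#' a gene-set download before running enrichment.
#'
#' @param collection a [gene_set_collection()].
#' @param universe data frame from [gene_universe()] or a character
#'   vector of symbols.
#' @return data frame with columns `set_id`, `n_members`, `n_in_universe`.
#' @export
validate_collection <- function(collection, universe) {
  syms <- if (is.data.frame(universe)) universe$gene_symbol else universe
  syms <- norm_symbol(syms)
  data.frame(
    set_id = names(collection$sets),
    n_members = lengths(collection$sets),
    n_in_universe = vapply(collection$sets,
                           function(s) sum(s %in% syms), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
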