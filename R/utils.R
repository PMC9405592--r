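`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a gene symbol
#'
#' Upper-cases and trims whitespace. HGNC symbols are case-insensitive in
#' practice across database exports; all joins in the package go through
#' this normalization.
#'
#' @param x character vector of symbols.
#' @return normalized character vector.
#' @keywords internal
norm_symbol <- function(x) toupper(trimws(x))

#' Normalize a drug name
#'
#' Case-folds and collapses internal whitespace. Salt suffixes are kept:
#' "atracurium besylate" stays distinct from "atracurium" unless
#' `strip_salts = TRUE`.
#'
#' @param x character vector of drug names.
#' @param strip_salts drop a trailing salt/ester qualifier word
#'   (besylate, iodide, citrate, ...) before comparison. Default `FALSE`.
#' @return normalized character vector.
#' @keywords internal
norm_drug <- function(x, strip_salts = FALSE) {
  out <- tolower(gsub("\\s+", " ", trimws(x)))
  if (strip_salts) {
    salts <- c("besylate", "iodide", "citrate", "chloride", "bromide",
               "sulfate", "mesylate", "hydrochloride", "tartrate")
    out <- sub(paste0("\\s+(", paste(salts, collapse = "|"), ")$"), "", out)
  }
  out
}

# Tissue labels match after case-folding and underscore/space unification,
# so "Whole_Blood", "whole blood" and "WHOLE_BLOOD" are one tissue.
norm_tissue <- function(x) gsub("[ _]+", "_", tolower(trimws(x)))

stop_data <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    stop_data(what, " must lie in [0, 1]")
  }
  invisible(x)
}
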