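# Frozen checksums of the packaged reference tables; load_fixture()
# refuses silently corrupted copies.
FIXTURE_MD5 <- c(
  table1 = "c09cfaf9a80530d98a8019b26af654e8",
  table2 = "d1145ebbb2902c9726d22ef28187b949",
  table3 = "4e4b1e068f9def60291b5ba56b7af8fd"
)

#' Load a packaged reference table
#'
#' The package ships three curated tables from a published depression
#' drug-repurposing case study:
#' \describe{
#'   \item{table1}{the 65 risk genes with their five annotation
#'     indicators and total score (blank cells mean 0);}
#'   \item{table2}{the 20 drug-target development records with their
#'     clinical (trial registry) or preclinical (literature) evidence
#'     identifiers;}
#'   \item{table3}{the 15 shortlisted novel repurposing candidates with
#'     their target gene's score.}
#' }
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`.
#' @return a typed data frame; for `table1` a `gene_profiles` object
#'   with an extra `printed_total` column, for `table2`/`table3` the
#'   drug rows with a normalized `drug_key`.
#' @export
load_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "snp2drug")
  if (!nzchar(path)) stop_data("fixture not installed: ", name)
  sum <- unname(md5sum(path))
  if (!identical(sum, unname(FIXTURE_MD5[[name]]))) {
    stop_data("fixture integrity check failed for ", name,
              " (md5 ", sum, ")")
  }
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  switch(name,
    table1 = {
      printed <- as.integer(raw$total_score)
      names(raw)[names(raw) == "gencode_id"] <- "gene_id"
      names(raw)[names(raw) == "gencode_name"] <- "gene_symbol"
      out <- as_gene_profiles(raw)
      out$printed_total <- printed
      out
    },
    table2 = {
      out <- raw
      out$gene_symbol <- norm_symbol(out$gene_symbol)
      out$source <- tolower(out$source)
      out$drug_key <- norm_drug(out$drug_name)
      out
    },
    table3 = {
      out <- raw
      out$score <- as.integer(out$score)
      out$gene_symbol <- norm_symbol(out$gene_symbol)
      out$drug_key <- norm_drug(out$drug_name)
      out
    }
  )
}
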