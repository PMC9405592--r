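# Independent oracles, kept free of the implementation paths they check.

# Exact upper-tail hypergeometric probability by brute-force enumeration
# of every possible query draw (feasible for background <= 15): the
# fraction of size-q subsets of the background sharing >= k members
# with the set.
hyper_oracle_enum <- function(overlap, query_size, set_size,
                              background_size) {
  draws <- utils::combn(background_size, query_size)
  in_set <- colSums(draws <= set_size)  # wlog the set is genes 1..set_size
  mean(in_set >= overlap)
}

# Closed-form upper tail as an exact sum of binomial-coefficient terms,
# for backgrounds too large to enumerate.
hyper_oracle_sum <- function(overlap, query_size, set_size,
                             background_size) {
  k <- overlap:min(query_size, set_size)
  sum(exp(lchoose(set_size, k) +
            lchoose(background_size - set_size, query_size - k) -
            lchoose(background_size, query_size)))
}

# Hand-rolled Benjamini-Hochberg step-up: sort, scale by m/rank, then
# enforce monotonicity by a cumulative minimum from the largest rank.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(scaled)))
  pmin(q_sorted, 1)[order(o)]
}

# Write a small SNP annotation TSV and return its path.
write_snp_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "snp_id\tgene_id\tgene_symbol\tconsequence\teqtl_tissue"
  writeLines(c(header, rows), path)
  path
}

# Deterministic 20-SNP / 8-gene table; exactly genes g2, g5, g7 carry a
# missense SNP and exactly g1, g4 carry a whole-blood eQTL (counted by
# hand when the fixture was written).
snp_fixture_20 <- function() {
  genes <- sprintf("G%d", 1:8)
  ids <- sprintf("ENSG%011d", 1:8)
  rows <- c(
    sprintf("rs%03d\t%s\t%s\tintronic\t", 1:8, ids, genes),
    sprintf("rs%03d\t%s\t%s\tmissense\t", 9:11, ids[c(2, 5, 7)],
            genes[c(2, 5, 7)]),
    sprintf("rs%03d\t%s\t%s\tintronic\tWhole_Blood", 12:13, ids[c(1, 4)],
            genes[c(1, 4)]),
    sprintf("rs%03d\t%s\t%s\tsynonymous\t", 14:17, ids[c(1, 3, 6, 8)],
            genes[c(1, 3, 6, 8)]),
    sprintf("rs%03d\t%s\t%s\tintergenic\tBrain_Cortex", 18:20,
            ids[c(2, 4, 6)], genes[c(2, 4, 6)])
  )
  write_snp_fixture(rows)
}

# Tiny five-gene annotation world used by the scoring tests.
tiny_gene_facts <- function() {
  data.frame(
    gene_id = sprintf("ENSG%011d", 1:5),
    gene_symbol = c("IL6R", "STAT6", "AAA1", "BBB2", "CCC3"),
    has_missense = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    has_eqtl = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}
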