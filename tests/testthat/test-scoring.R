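test_that("profiles assemble the five indicators and recompute totals", {
  facts <- tiny_gene_facts()
  prof <- build_profiles(
    facts,
    kegg_flags = c(STAT6 = TRUE),
    ppi_flags = c(IL6R = TRUE, STAT6 = TRUE, AAA1 = TRUE),
    ko_flags = c(IL6R = TRUE, STAT6 = TRUE))
  il6r <- prof[prof$gene_symbol == "IL6R", ]
  expect_equal(unlist(il6r[INDICATOR_COLS]),
               c(missense = 1, cis_eqtl = 1, kegg = 0, ppi = 1, ko_mice = 1))
  expect_equal(il6r$total_score, 4)
  expect_equal(prof$total_score[prof$gene_symbol == "STAT6"], 4)
  expect_equal(prof$total_score[prof$gene_symbol == "CCC3"], 0)
  expect_true(all(prof$total_score == rowSums(prof[INDICATOR_COLS])))
  expect_true(all(prof$total_score >= 0 & prof$total_score <= 5))
})

test_that("a flag for a symbol outside the universe is a consistency error", {
  expect_error(
    build_profiles(tiny_gene_facts(), kegg_flags = c(NOTAGENE = TRUE)),
    "outside the universe")
})

test_that("risk calling ranks by score and is monotone in the threshold", {
  facts <- tiny_gene_facts()
  prof <- build_profiles(facts, ko_flags = c(IL6R = TRUE, AAA1 = TRUE))
  calls <- call_risk_genes(prof, threshold = 2)
  expect_equal(calls$is_risk_gene, calls$total_score >= 2)
  expect_true(all(diff(calls$total_score) <= 0))
  # within one score stratum, symbols are lexicographic
  for (s in unique(calls$total_score)) {
    expect_false(is.unsorted(calls$gene_symbol[calls$total_score == s]))
  }
  expect_true(all(call_risk_genes(prof, threshold = 0)$is_risk_gene))
  n_at <- vapply(0:5, function(th) sum(call_risk_genes(prof, th)$is_risk_gene),
                 integer(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("score histograms recount the profile table", {
  prof <- build_profiles(tiny_gene_facts())
  h <- score_histogram(prof)
  expect_named(h, as.character(0:5))
  expect_equal(sum(h), nrow(prof))
  expect_equal(sum(score_histogram(prof[0, ])), 0L)

  set.seed(11)
  big <- data.frame(
    gene_id = sprintf("E%03d", 1:100), gene_symbol = sprintf("S%03d", 1:100),
    missense = rbinom(100, 1, .3), cis_eqtl = rbinom(100, 1, .4),
    kegg = rbinom(100, 1, .2), ppi = rbinom(100, 1, .6),
    ko_mice = rbinom(100, 1, .7))
  bigp <- as_gene_profiles(big)
  h2 <- score_histogram(bigp)
  recount <- vapply(0:5, function(s) sum(bigp$total_score == s), integer(1))
  expect_equal(unname(h2), recount)
})

test_that("the packaged risk-gene table reproduces its printed totals", {
  t1 <- load_fixture("table1")
  expect_equal(nrow(t1), 65L)
  expect_equal(t1$total_score, t1$printed_total)
  expect_equal(sum(t1$total_score == 4), 7L)
  expect_setequal(t1$gene_symbol[t1$total_score == 4],
                  c("IL4", "IL18R1", "IL6R", "STAT6", "SMAD3", "IL13", "TLR1"))
  expect_equal(sum(t1$total_score >= 2), 65L)
  expect_equal(sum(call_risk_genes(t1, threshold = 5)$is_risk_gene), 0L)
  il6r <- t1[t1$gene_symbol == "IL6R", ]
  expect_equal(il6r$gene_id, "ENSG00000160712")
  expect_equal(unlist(il6r[INDICATOR_COLS]),
               c(missense = 1, cis_eqtl = 1, kegg = 0, ppi = 1, ko_mice = 1))
  stat6 <- t1[t1$gene_symbol == "STAT6", ]
  expect_equal(unname(unlist(stat6[INDICATOR_COLS])), c(0, 1, 1, 1, 1))
})

test_that("golden-table comparison flags corrupted fixtures", {
  t1 <- load_fixture("table1")
  expect_equal(nrow(compare_profiles(t1, t1)), 0L)

  corrupt <- t1
  corrupt$kegg[3] <- 1 - corrupt$kegg[3]
  rep1 <- compare_profiles(t1, transform(corrupt, total_score = printed_total))
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$gene_id, t1$gene_id[3])

  # swapping two indicator columns breaks every gene where they differ
  swapped <- t1
  swapped$missense <- t1$ppi
  swapped$ppi <- t1$missense
  swapped$total_score <- t1$printed_total
  affected <- sum(t1$missense != t1$ppi)
  rep2 <- compare_profiles(t1, swapped)
  expect_equal(nrow(rep2), 0L)  # totals unchanged by a swap
  swapped2 <- t1
  swapped2$ppi <- t1$kegg       # overwrite instead of swap
  swapped2$total_score <- t1$printed_total
  rep3 <- compare_profiles(t1, swapped2)
  expect_equal(nrow(rep3), sum(t1$ppi != t1$kegg))
})

test_that("blank indicator cells parse as zero", {
  tab <- data.frame(gene_id = c("E1", "E2"), gene_symbol = c("A", "B"),
                    missense = c("1", ""), cis_eqtl = c("", "1"),
                    kegg = "0", ppi = c("1", ""), ko_mice = c("", "1"),
                    stringsAsFactors = FALSE)
  prof <- as_gene_profiles(tab)
  expect_equal(prof$total_score, c(2, 2))
  bad <- transform(tab, kegg = "2")
  expect_error(as_gene_profiles(bad), "not 0/1")
})
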