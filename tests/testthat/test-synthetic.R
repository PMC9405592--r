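small_config <- function(seed = 1L, ...) {
  generator_config(seed = seed, n_genes = 120L, n_snps = 600L,
                   n_risk_genes = 20L, n_filler_genes = 400L,
                   n_noise_sets = 10L, n_ppi_neighbors = 12L,
                   n_ppi_noise_edges = 80L, ...)
}

noise_free_rates <- function(on = c("missense", "cis_eqtl", "kegg", "ppi",
                                    "ko_mice")) {
  r <- setNames(rep(0, 5), c("missense", "cis_eqtl", "kegg", "ppi",
                             "ko_mice"))
  r[on] <- 1
  r
}

test_that("generation is deterministic for a fixed seed", {
  b1 <- generate_bundle(small_config(seed = 9))
  b2 <- generate_bundle(small_config(seed = 9))
  expect_identical(b1$snp_table, b2$snp_table)
  expect_identical(b1$collections$KEGG$sets, b2$collections$KEGG$sets)
  expect_identical(b1$ppi, b2$ppi)
  expect_identical(b1$drug_targets, b2$drug_targets)
  expect_identical(b1$ground_truth, b2$ground_truth)
  b3 <- generate_bundle(small_config(seed = 10))
  expect_false(identical(b1$ground_truth$planted, b3$ground_truth$planted))
})

test_that("component streams are independent of downstream settings", {
  b1 <- generate_bundle(small_config(seed = 5))
  b2 <- generate_bundle(small_config(seed = 5, evidence_frac = 0.9,
                                     druggable_frac = 0.6))
  expect_identical(b1$snp_table, b2$snp_table)
  expect_identical(b1$collections$MP$sets, b2$collections$MP$sets)
  expect_identical(b1$ppi, b2$ppi)
  expect_false(identical(b1$drug_targets, b2$drug_targets))
})

test_that("degenerate rates give planted genes exactly the planted score", {
  cfg <- small_config(seed = 2,
                      planted_rates = noise_free_rates(c("missense",
                                                         "cis_eqtl", "ppi")),
                      background_rates = noise_free_rates(character()))
  b <- generate_bundle(cfg)
  gt <- b$ground_truth
  planted_rows <- gt$profiles[gt$profiles$gene_symbol %in% gt$planted, ]
  expect_true(all(planted_rows$total_score == 3))
  other <- gt$profiles[!gt$profiles$gene_symbol %in% gt$planted, ]
  expect_true(all(other$total_score == 0))
  expect_setequal(gt$risk_genes, gt$planted)
})

test_that("generated tables respect their structural bounds", {
  cfg <- small_config(seed = 3)
  b <- generate_bundle(cfg)
  facts <- collapse_to_genes(b$snp_table)
  expect_equal(nrow(facts), cfg$n_genes)
  expect_equal(nrow(b$snp_table), cfg$n_snps)
  expect_true(all(b$ppi$confidence >= 0 & b$ppi$confidence <= 1))
  for (cl in b$collections) {
    noise <- cl$sets[grepl("_NOISE_", names(cl$sets))]
    expect_true(all(lengths(noise) >= cfg$noise_set_size[1] &
                      lengths(noise) <= cfg$noise_set_size[2]))
    expect_true(all(lengths(cl$sets) > 0))
  }
  # drawn indicators match the SNP materialization exactly
  gt <- b$ground_truth$profiles
  m <- match(facts$gene_symbol, gt$gene_symbol)
  expect_equal(as.integer(facts$has_missense), gt$missense[m])
  expect_equal(as.integer(facts$has_eqtl), gt$cis_eqtl[m])
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(n_genes = 10, n_risk_genes = 20),
               "exceed")
  expect_error(generator_config(n_genes = 100, n_snps = 50),
               "one SNP per gene")
  expect_error(generator_config(planted_rates = c(missense = 2)),
               "named|\\[0, 1\\]")
})

test_that("bundles round-trip through the standard file formats", {
  b <- generate_bundle(small_config(seed = 6))
  dir <- tempfile("bundle")
  paths <- write_bundle(b, dir)
  expect_true(all(file.exists(paths)))
  snp2 <- read_snp_table(paths[["snps"]])
  expect_equal(snp2, b$snp_table)
  kegg2 <- read_gmt(paths[["KEGG"]])
  expect_equal(unname(lapply(kegg2, sort)),
               unname(lapply(b$collections$KEGG$sets, sort)))
  ppi2 <- read_ppi_edges(paths[["ppi"]])
  expect_equal(ppi2$confidence, round(b$ppi$confidence * 1000) / 1000)
  gt <- jsonlite::read_json(paths[["ground_truth"]], simplifyVector = TRUE)
  expect_equal(gt$risk_genes, b$ground_truth$risk_genes)
})

test_that("packaged reference tables load with their printed shape", {
  t1 <- load_fixture("table1")
  expect_equal(nrow(t1), 65L)
  t2 <- load_fixture("table2")
  expect_equal(nrow(t2), 20L)
  expect_equal(sum(t2$source == "clinical"), 12L)
  expect_equal(sum(t2$source == "preclinical"), 8L)
  t3 <- load_fixture("table3")
  expect_equal(nrow(t3), 15L)
  expect_equal(sum(t3$score == 4), 2L)
  expect_false("SFTL" %in% t3$gene_symbol)  # printed typo normalized
})
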