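test_that("hypergeometric tail matches brute-force enumeration exactly", {
  for (N in c(6L, 10L, 13L, 15L)) {
    for (K in c(2L, N %/% 2, N - 1L)) {
      for (q in c(1L, N %/% 3, N %/% 2)) {
        for (k in 0:min(K, q)) {
          expect_equal(hypergeom_test(k, q, K, N),
                       hyper_oracle_enum(k, q, K, N),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d q=%d k=%d", N, K, q, k))
        }
      }
    }
  }
})

test_that("hypergeometric boundary cases and worked examples hold", {
  expect_equal(hypergeom_test(0, 10, 4, 50), 1)
  expect_equal(hypergeom_test(0, 3, 3, 6), 1)
  # drawing all 5 set members in 5 draws from 10: one draw in C(10,5)
  expect_equal(hypergeom_test(5, 5, 5, 10), 1 / 252, tolerance = 1e-15)
  expect_equal(hypergeom_test(2, 4, 5, 12), hyper_oracle_enum(2, 4, 5, 12),
               tolerance = 1e-12)
})

test_that("impossible counts are domain errors", {
  expect_error(hypergeom_test(6, 5, 5, 10), "overlap")
  expect_error(hypergeom_test(-1, 5, 5, 10), "overlap")
  expect_error(hypergeom_test(2, 8, 5, 7), "background_size")
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.005, 0.03, 0.04)), c(0.015, 0.04, 0.04))
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH agrees with an independent step-up and is permutation-stable", {
  set.seed(42)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("enrich handles the degenerate and disjoint collections", {
  bg <- sprintf("G%02d", 1:40)
  query <- bg[1:15]
  whole <- gene_set_collection(list(all = bg), background = bg)
  res <- enrich(query, whole)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  disjoint <- gene_set_collection(
    list(s1 = bg[16:25], s2 = bg[26:40]), background = bg)
  res2 <- enrich(query, disjoint)
  expect_true(all(res2$p_value == 1))
  expect_false(any(res2$significant))
})

test_that("a planted set inside the query is flagged significant", {
  set.seed(7)
  bg <- sprintf("G%03d", 1:500)
  query <- bg[1:20]
  planted <- bg[1:10]          # fully contained in the query
  sets <- c(list(planted = planted),
            setNames(replicate(30, sample(bg, 25), simplify = FALSE),
                     sprintf("noise%02d", 1:30)))
  coll <- gene_set_collection(sets, background = bg)
  # independent closed-form check of the raw tail before adjustment
  expect_lt(hyper_oracle_sum(10, 20, 10, 500), 1e-6)
  res <- enrich(query, coll)
  expect_true(res$significant[res$set_id == "planted"])
  expect_equal(res$q_value, bh_oracle(res$p_value), tolerance = 1e-12)
})

test_that("alpha endpoints behave as strict-inequality thresholds", {
  bg <- sprintf("G%02d", 1:30)
  coll <- gene_set_collection(list(a = bg[1:5], b = bg[20:30]),
                              background = bg)
  expect_false(any(enrich(bg[1:8], coll, alpha = 0)$significant))
  res1 <- enrich(bg[1:8], coll, alpha = 1)
  expect_equal(res1$significant, res1$p_value < 1)
})

test_that("query symbols outside the background are dropped with a warning", {
  bg <- sprintf("G%02d", 1:20)
  coll <- gene_set_collection(list(a = bg[1:5]), background = bg)
  expect_warning(res <- enrich(c(bg[1:5], "ZZZ"), coll), "dropped")
  expect_equal(res$query_size, 5L)
})

test_that("membership flags are boolean and bounded by the query", {
  bg <- sprintf("G%02d", 1:60)
  query <- bg[1:20]
  coll <- gene_set_collection(
    list(hit1 = bg[1:6], hit2 = bg[4:9], miss = bg[40:60]),
    background = bg)
  res <- enrich(query, coll)
  flags <- member_flags(res, coll, query)
  expect_type(flags, "logical")
  expect_named(flags, query)
  expect_lte(sum(flags), length(query))
  if (any(res$significant)) {
    hit <- unique(unlist(coll$sets[res$set_id[res$significant]]))
    expect_setequal(names(flags)[flags], intersect(query, hit))
  }
  # no significant sets -> all flags false
  none <- enrich(query, coll, alpha = 0)
  expect_false(any(member_flags(none, coll, query)))
})

test_that("empty or anonymous collections are configuration errors", {
  expect_error(gene_set_collection(list()), "empty")
  expect_error(gene_set_collection(list(c("A", "B"))), "named")
  expect_error(gene_set_collection(list(s = character())), "empty")
  expect_error(
    gene_set_collection(list(s = c("A", "ZZ")), background = c("A", "B"),
                        strict = TRUE),
    "outside background")
})
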