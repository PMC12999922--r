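test_that("cosine similarity matches hand computations", {
  v <- c(1, 1, rep(0, 94))
  w <- c(1, 0, rep(0, 94))
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(w, c(0, 1, rep(0, 94))), 0)
  expect_equal(cosine_similarity(v, w), 1 / sqrt(2), tolerance = 1e-12)
  expect_error(cosine_similarity(v, rep(0, 96)), "zero")
})

test_that("reconstruction is the exposure-weighted catalog combination", {
  cat3 <- toy_signature_catalog(3)
  one <- reconstruct_profile(c("SBS-A" = 1), cat3, total = 250)
  expect_equal(unname(one), 250 * unname(unclass(cat3)[, "SBS-A"]),
               tolerance = 1e-12)
  fr <- c("SBS-A" = 0.3, "SBS-C" = 0.7)
  rec <- reconstruct_profile(fr, cat3, total = 1000)
  manual <- 1000 * (0.3 * unclass(cat3)[, "SBS-A"] +
                      0.7 * unclass(cat3)[, "SBS-C"])
  expect_equal(unname(rec), unname(manual), tolerance = 1e-9)
  expect_equal(sum(rec), 1000, tolerance = 1e-6)
  expect_error(reconstruct_profile(c(X = 1), cat3, 10), "missing")
})

test_that("Signature Score and SE match closed-form arithmetic", {
  pv <- toy_prevalence(c("A", "B"), c(0.8, 0.4), n = 100L)
  sc <- signature_score(c(A = 0.5, B = 0.5), pv, "lung", cs = 0.9)
  expect_equal(sc$ss, 0.9 * (0.5 * 0.8 + 0.5 * 0.4), tolerance = 1e-12)

  pv1 <- toy_prevalence("A", 0.5, n = 100L)
  sc1 <- signature_score(c(A = 1), pv1, "lung", cs = 1)
  expect_equal(sc1$se, sqrt(0.25 / 100), tolerance = 1e-12)

  # degenerate frequency of 1: perfect score, zero error
  pv2 <- toy_prevalence("A", 1, n = 50L)
  sc2 <- signature_score(c(A = 1), pv2, "lung", cs = 1)
  expect_equal(sc2$ss, 1)
  expect_equal(sc2$se, 0)

  # absent signatures contribute frequency 0 to both sums
  sc3 <- signature_score(c(A = 0.5, Z = 0.5), pv1, "lung", cs = 1)
  expect_equal(sc3$ss, 0.5 * 0.5)
})

test_that("score invariants: ss <= cs, monotone in f, se vanishes with N", {
  set.seed(61)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    s <- runif(k); s <- s / sum(s); names(s) <- paste0("S", 1:k)
    f <- runif(k)
    cs <- runif(1)
    pv <- toy_prevalence(names(s), f, n = 200L)
    sc <- signature_score(s, pv, "lung", cs)
    expect_lte(sc$ss, cs + 1e-12)
    expect_gte(sc$se, 0)
    # raising one frequency cannot lower the score
    f2 <- pmin(f + 0.1, 1)
    sc2 <- signature_score(s, toy_prevalence(names(s), f2, 200L), "lung", cs)
    expect_gte(sc2$ss, sc$ss - 1e-12)
    # larger cohorts shrink the SE
    sc_big <- signature_score(s, toy_prevalence(names(s), f, 20000L),
                              "lung", cs)
    expect_lt(sc_big$se, sc$se + 1e-15)
  }
  # f in {0,1} everywhere -> zero SE
  pv01 <- toy_prevalence(c("A", "B"), c(1, 0), 100L)
  expect_equal(signature_score(c(A = 0.6, B = 0.4), pv01, "lung", 0.9)$se, 0)
})

test_that("dominant signature uses the strict >0.5 rule with catalog-order ties", {
  d <- dominant_signature(c(SBS4 = 0.62, SBS2 = 0.2, SBS1 = 0.18))
  expect_identical(d$signature_id, "SBS4")
  expect_equal(d$fraction, 0.62)
  expect_true(d$is_dominant)

  d2 <- dominant_signature(c(A = 0.4, B = 0.35, C = 0.25))
  expect_identical(d2$signature_id, "A")
  expect_false(d2$is_dominant)

  d3 <- dominant_signature(c(A = 0.5, B = 0.5))
  expect_identical(d3$signature_id, "A")
  expect_false(d3$is_dominant)
})

test_that("top-k selection matches a full-sort oracle", {
  fr <- c(A = 0.62, B = 0.25, C = 0.13)
  expect_identical(names(top_k_signatures(fr, 2)), c("A", "B"))
  expect_identical(names(top_k_signatures(fr, 10)), c("A", "B", "C"))
  set.seed(62)
  for (rep in 1:10) {
    x <- runif(6); names(x) <- paste0("S", 1:6)
    k <- sample(1:6, 1)
    oracle <- names(sort(x, decreasing = TRUE))[1:k]
    expect_identical(names(top_k_signatures(x, k)), oracle)
  }
})

test_that("score comparisons standardize by pooled SE with a normal reference", {
  a <- list(ss = 0.6, se = 0.05)
  b <- list(ss = 0.4, se = 0.05)
  cmp <- compare_scores(a, b)
  expect_equal(cmp$z, 0.2 / sqrt(0.005), tolerance = 1e-9)
  expect_equal(cmp$p_value, 2 * pnorm(-0.2 / sqrt(0.005)), tolerance = 1e-9)
  expect_equal(cmp$p_value, 0.00468, tolerance = 1e-3)

  same <- compare_scores(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  flip <- compare_scores(b, a)
  expect_equal(flip$z, -cmp$z)
  expect_equal(flip$p_value, cmp$p_value)

  deg <- compare_scores(list(ss = 0.3, se = 0), list(ss = 0.1, se = 0))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
  expect_match(deg$note, "underestimated")
})
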