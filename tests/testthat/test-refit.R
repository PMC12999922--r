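cat4 <- toy_signature_catalog(4)
pv4 <- toy_prevalence(colnames(cat4), c(0.8, 0.6, 0.5, 0.4))
map1 <- c(Lung = "lung")

test_that("NNLS recovers pure and noiseless mixed sources exactly", {
  pure <- exact_mixture_profile(cat4, c("SBS-A" = 1), total = 1000)
  fr <- nnls_fit(pure, cat4, "SBS-A")
  expect_equal(unname(fr), 1, tolerance = 1e-6)

  mix <- exact_mixture_profile(cat4, c("SBS-A" = 0.6, "SBS-B" = 0.4))
  fr2 <- nnls_fit(mix, cat4, c("SBS-A", "SBS-B"))
  expect_equal(unname(fr2), c(0.6, 0.4), tolerance = 1e-6)

  # oracle: the noiseless two-signature problem solved as an exact linear
  # system on two independent channels
  A <- unclass(cat4)[, c("SBS-A", "SBS-B")]
  p <- mix$counts / mix$total
  rows <- c(which.max(A[, 1]), which.max(A[, 2]))
  direct <- solve(A[rows, ], p[rows])
  expect_equal(unname(fr2), unname(direct / sum(direct)), tolerance = 1e-8)
})

test_that("fitting all signatures is no worse than any exhaustive 2-subset fit", {
  set.seed(51)
  mix <- exact_mixture_profile(cat4, c("SBS-B" = 0.5, "SBS-C" = 0.5))
  mix$counts <- mix$counts + runif(96, 0, 2)  # mild perturbation
  resid_of <- function(subset) {
    fr <- nnls_fit(mix, cat4, subset)
    est <- as.numeric(unclass(cat4)[, subset, drop = FALSE] %*% fr)
    p <- as.numeric(mix$counts) / sum(mix$counts)
    scale <- sum(p * est) / sum(est^2)  # best conic rescale
    sum((p - scale * est)^2)
  }
  full <- resid_of(colnames(cat4))
  pairs <- combn(colnames(cat4), 2, simplify = FALSE)
  expect_true(all(vapply(pairs, resid_of, numeric(1)) >= full - 1e-12))
})

test_that("site-prioritized refit recovers an allowed pure signature without rescue", {
  pure <- exact_mixture_profile(cat4, c("SBS-A" = 1), total = 2000)
  fit <- refit_signatures(pure, cat4, pv4, map1, "Lung")
  expect_s3_class(fit, "sigfit")
  expect_gte(coef(fit)[["SBS-A"]], 0.99)
  expect_false(fit$rescue_used)
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-6)
})

test_that("rescue admits an out-of-site signature when allowed ones fit poorly", {
  # only SBS-A and SBS-B are expected at the site; the profile is pure SBS-D
  pv_narrow <- toy_prevalence(c("SBS-A", "SBS-B"), c(0.8, 0.5))
  pure_d <- exact_mixture_profile(cat4, c("SBS-D" = 1), total = 2000)
  # construct check: no allowed signature is close to the target
  cs_allowed <- vapply(c("SBS-A", "SBS-B"), function(id) {
    cosine_similarity(pure_d$counts, unclass(cat4)[, id])
  }, numeric(1))
  expect_true(all(cs_allowed < 0.8))
  fit <- refit_signatures(pure_d, cat4, pv_narrow, map1, "Lung")
  expect_true(fit$rescue_used)
  expect_identical(fit$dominant$signature_id, "SBS-D")
  expect_gte(fit$cs, 0.99)
  # without rescue an empty expected set is an error
  pv_none <- toy_prevalence("SBS-A", 0)
  expect_error(refit_signatures(pure_d, cat4, pv_none, map1, "Lung",
                                rescue = FALSE), "rescue")
})

test_that("tiny raw fractions are pruned and survivors renormalized", {
  mix <- exact_mixture_profile(cat4, c("SBS-A" = 0.7, "SBS-B" = 0.296,
                                       "SBS-C" = 0.004))
  fit <- refit_signatures(mix, cat4, pv4, map1, "Lung")
  expect_false("SBS-C" %in% names(coef(fit)))
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-9)
  # matches a direct re-solve on the surviving pair
  resolved <- nnls_fit(mix, cat4, c("SBS-A", "SBS-B"))
  expect_equal(coef(fit)[c("SBS-A", "SBS-B")], resolved, tolerance = 1e-9)
})

test_that("noiseless mixtures of up to three allowed signatures are exactly recovered", {
  mixtures <- list(c("SBS-A" = 1),
                   c("SBS-A" = 0.6, "SBS-B" = 0.4),
                   c("SBS-A" = 0.5, "SBS-B" = 0.3, "SBS-C" = 0.2))
  for (mx in mixtures) {
    prof <- exact_mixture_profile(cat4, mx)
    fit <- refit_signatures(prof, cat4, pv4, map1, "Lung")
    expect_equal(coef(fit)[names(mx)], mx, tolerance = 1e-6)
  }
})

test_that("stage-1 fits never include sub-threshold-prevalence signatures unless rescued", {
  set.seed(52)
  for (rep in 1:10) {
    w <- runif(3); w <- w / sum(w)
    names(w) <- c("SBS-A", "SBS-B", "SBS-C")
    prof <- exact_mixture_profile(cat4, w)
    prof$counts <- prof$counts * (1 + runif(96, -0.05, 0.05))
    fit <- refit_signatures(prof, cat4, pv4, map1, "Lung", min_freq = 0.5)
    if (!fit$rescue_used) {
      expect_true(all(names(coef(fit)) %in%
                        allowed_signatures("Lung", map1, pv4, cat4,
                                           min_freq = 0.5)))
    }
    expect_true(all(coef(fit) >= 0))
    expect_equal(sum(coef(fit)), 1, tolerance = 1e-6)
  }
})

test_that("sigfit accessor methods are mutually consistent", {
  mix <- exact_mixture_profile(cat4, c("SBS-A" = 0.6, "SBS-B" = 0.4),
                               total = 1000)
  fit <- refit_signatures(mix, cat4, pv4, map1, "Lung")
  expect_equal(sum(fitted(fit)), mix$total, tolerance = 1e-6)
  expect_equal(residuals(fit), mix$counts - fitted(fit))
  expect_equal(predict(fit, total = 500), fitted(fit) / 2, tolerance = 1e-9)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.sigfit")
  expect_equal(sm$table$fraction[1], fit$dominant$fraction)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(96L, 3L))
  expect_true(all(colSums(sims) == mix$total))
  expect_output(print(fit), "Site-prioritized")
})
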