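# The study-size setting used throughout: 35,476/46,839 cases/controls in
# the discovery study, 9,747/14,278 in the target, sharing 500 cases and
# 9,200 controls.
paper_spec <- function()
  overlap_spec(35476, 46839, 9747, 14278, 500, 9200)

test_that("estimate_inflation is the mean squared z", {
  expect_equal(suppressWarnings(estimate_inflation(rep(0, 10))), 0)
  expect_equal(suppressWarnings(estimate_inflation(c(1, -1, 1, -1))), 1)
  expect_error(estimate_inflation(numeric(0)), "empty")
  expect_warning(estimate_inflation(rnorm(50)), "fewer than 100")
  set.seed(31)
  z <- rnorm(1e5, sd = sqrt(1.82))
  expect_lt(abs(estimate_inflation(z) - 1.82), 0.03)
})

test_that("overlap covariance is 0 with no sharing and 1 for identical studies", {
  none <- overlap_spec(100, 200, 300, 400, 0, 0)
  expect_equal(theoretical_overlap_cov(none), 0)
  full <- overlap_spec(120, 240, 120, 240, 120, 240)
  expect_equal(theoretical_overlap_cov(full), 1)
})

test_that("the overlap covariance formula reproduces 0.1644", {
  cc <- theoretical_overlap_cov(paper_spec())
  expect_equal(round(cc, 4), 0.1644)
})

test_that("overlap covariance is symmetric in the two studies", {
  s <- paper_spec()
  swapped <- overlap_spec(s$n2_case, s$n2_control, s$n1_case,
                          s$n1_control, s$ns_case, s$ns_control)
  expect_equal(theoretical_overlap_cov(s),
               theoretical_overlap_cov(swapped), tolerance = 1e-14)
})

test_that("degenerate overlap specs are rejected", {
  expect_error(overlap_spec(100, 100, 100, 100, 150, 0), "ns_case")
  expect_error(
    theoretical_overlap_cov(
      structure(list(n1_case = 0, n1_control = 10, n2_case = 10,
                     n2_control = 10, ns_case = 0, ns_control = 0),
                class = "overlap_spec")),
    "positive")
})

test_that("build_null derives the correlation and checks feasibility", {
  m <- build_null(1.82, 1.24, theoretical_overlap_cov(paper_spec()))
  expect_equal(round(m$corr, 3), 0.109)
  expect_equal(build_null(1, 1, 0)$corr, 0)
  expect_equal(build_null(4, 1, 1)$corr, 0.5)
  expect_error(build_null(1, 1, 1.5), "exceeds 1")
  expect_error(build_null(-1, 1, 0), "positive")
})

test_that("empirical covariance recovers the truth on simulated pairs", {
  set.seed(32)
  n <- 1e5
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  expect_equal(empirical_overlap_cov(z1, z2), 0, tolerance = 0.01)
  cc <- 0.1644
  S <- matrix(c(1.82, cc, cc, 1.24), 2)
  L <- chol(S)
  Z <- matrix(rnorm(2 * n), n) %*% L
  expect_lt(abs(empirical_overlap_cov(Z[, 1], Z[, 2]) - cc), 0.02)
  expect_error(empirical_overlap_cov(z1, z2[-1]), "equal length")
})

test_that("the LDSC-intercept estimator separates overlap from LD signal", {
  # per-SNP E[z1 z2] = a + b * ld: the intercept must recover a
  set.seed(33)
  n <- 5e4
  ld <- rexp(n, rate = 1 / 50)
  a <- 0.1644; b <- 0.002
  cov_j <- a + b * ld
  z1 <- rnorm(n)
  z2 <- cov_j * z1 + rnorm(n, sd = sqrt(pmax(0.2, 1 - cov_j^2)))
  est <- empirical_overlap_cov(z1, z2, ld_scores = ld)
  expect_lt(abs(as.numeric(est) - a), 2 * attr(est, "se"))
  expect_error(empirical_overlap_cov(z1, z2, ld_scores = ld[-1]),
               "length")
})

test_that("conditional transform reduces to the identity without overlap", {
  m <- build_null(1, 1, 0)
  ct <- conditional_transform(c(3, -1), c(1.3, 0.4), m)
  expect_equal(ct$z_corrected, c(1.3, 0.4))
  expect_equal(ct$p_corrected, 2 * pnorm(-abs(c(1.3, 0.4))))
})

test_that("the conditional residual standardizes by tau", {
  m <- build_null(1.82, 1.24, 0.1644)
  tau <- sqrt(1.24 - 0.1644^2 / 1.82)   # independent arithmetic
  ct <- conditional_transform(0, 1.10687, m)
  expect_equal(ct$z_corrected, 1.10687 / tau, tolerance = 1e-12)
  expect_equal(ct$z_corrected, 1.0, tolerance = 1e-4)
  # z2 exactly at the conditional mean maps to 0 with p = 1
  z1 <- 2.5
  mu <- (0.1644 / 1.82) * z1
  at_mean <- conditional_transform(z1, mu, m)
  expect_equal(at_mean$z_corrected, 0)
  expect_equal(at_mean$p_corrected, 1)
})

test_that("the transform is monotone in z2 and linear given z1", {
  m <- build_null(1.82, 1.24, 0.1644)
  z2 <- seq(-3, 3, length.out = 21)
  zc <- conditional_transform(rep(1, 21), z2, m)$z_corrected
  expect_true(all(diff(zc) > 0))
  # conditional on z1 = 0 the transform is division by tau
  tau <- sqrt(1.24 - 0.1644^2 / 1.82)
  expect_equal(conditional_transform(rep(0, 21), z2, m)$z_corrected,
               z2 / tau, tolerance = 1e-12)
})

test_that("corrected z is standard normal on exact model draws", {
  set.seed(34)
  m <- build_null(1.82, 1.24, 0.1644)
  n <- 1e5
  S <- matrix(c(m$var1, m$cov, m$cov, m$var2), 2)
  Z <- matrix(rnorm(2 * n), n) %*% chol(S)
  ct <- conditional_transform(Z[, 1], Z[, 2], m)
  ks <- suppressWarnings(ks.test(ct$z_corrected, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(ct$p_corrected < 0.05), 0.05, tolerance = 0.005 / 0.05)
})

test_that("unit variance mode is anti-conservative relative to marginal", {
  m <- build_null(1.82, 1.24, 0.1644)
  marg <- conditional_transform(1, 2, m, variance_mode = "marginal")
  unit <- conditional_transform(1, 2, m, variance_mode = "unit")
  expect_gt(abs(unit$z_corrected), abs(marg$z_corrected))
})

test_that("swap_null exchanges the two studies' roles", {
  m <- build_null(1.82, 1.24, 0.1644)
  s <- swap_null(m)
  expect_equal(s$var1, 1.24)
  expect_equal(s$var2, 1.82)
  expect_equal(s$corr, m$corr)
})
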