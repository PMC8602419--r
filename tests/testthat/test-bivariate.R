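test_that("quadrivariate expected covariance has the Cholesky block form", {
  A <- matrix(c(0.7, 0, 0, 0.6), 2, 2)   # a21 = 0
  E <- matrix(c(0.7, 0, 0, 0.8), 2, 2)
  S <- expected_quad_covariance(A, E, "MZ")
  expect_equal(S[1, 2], 0)               # no cross-trait covariance anywhere
  expect_equal(S[1, 4], 0)
  expect_equal(S[2, 3], 0)

  A <- matrix(c(0.8, 0.5, 0, 0.4), 2, 2)
  E <- matrix(c(0.6, -0.2, 0, 0.5), 2, 2)
  S <- expected_quad_covariance(A, E, "MZ")
  # MZ cross-twin cross-trait covariance is exactly a11 * a21
  expect_equal(S[1, 4], 0.8 * 0.5)
  expect_equal(S[3, 2], 0.8 * 0.5)
  Sdz <- expected_quad_covariance(A, E, "DZss")
  expect_equal(Sdz[1, 4], 0.5 * 0.8 * 0.5)
  expect_true(isSymmetric(S))
})

test_that("expected covariance matches latent-factor simulation moments", {
  A <- matrix(c(0.9, -0.4, 0, 0.55), 2, 2)
  E <- matrix(c(0.7, 0.25, 0, 0.6), 2, 2)
  n <- 200000
  set.seed(61)
  for (zyg in c("MZ", "DZss")) {
    k <- if (zyg == "MZ") 1 else 0.5
    # independent oracle: build pairs directly from correlated factor draws
    FA1 <- matrix(rnorm(2 * n), n, 2)
    FA2 <- k * FA1 + sqrt(1 - k^2) * matrix(rnorm(2 * n), n, 2)
    y1 <- FA1 %*% t(A) + matrix(rnorm(2 * n), n, 2) %*% t(E)
    y2 <- FA2 %*% t(A) + matrix(rnorm(2 * n), n, 2) %*% t(E)
    emp <- cov(cbind(y1, y2))
    theo <- expected_quad_covariance(A, E, zyg)
    for (i in 1:4) for (j in 1:4) {
      se <- sqrt((theo[i, i] * theo[j, j] + theo[i, j]^2) / n)
      expect_lt(abs(emp[i, j] - theo[i, j]), 3 * se)
    }
  }
})

test_that("genetic correlation from paths", {
  expect_equal(genetic_correlation_from_paths(1, 0.5, 0), 1)
  expect_equal(genetic_correlation_from_paths(1, 0, 0.8), 0)
  # oracle: correlation assembled from the full A %*% t(A) matrix
  A <- matrix(c(1, 0.6, 0, 0.8), 2, 2)
  VA <- A %*% t(A)
  expect_equal(genetic_correlation_from_paths(1, 0.6, 0.8),
               VA[1, 2] / sqrt(VA[1, 1] * VA[2, 2]))
  expect_equal(genetic_correlation_from_paths(1, 0.6, 0.8), 0.6)
  expect_error(genetic_correlation_from_paths(0, 0.5, 0.5), "trait 1")
  expect_error(genetic_correlation_from_paths(1, 0, 0), "trait 2")
})

test_that("correlation decomposition identities and edge cases", {
  # pure genetic overlap: A explains everything
  d <- decompose_trait_correlation(0.5, 0.5, 0.5, 0.5, rA = 0.8, rE = 0)
  expect_equal(d$fracA, 1)
  expect_equal(d$fracE, 0)

  # no correlation at all: fractions undefined
  expect_warning(
    d0 <- decompose_trait_correlation(0.5, 0.5, 0.5, 0.5, 0, 0), "undefined")
  expect_equal(d0$r, 0)
  expect_true(is.na(d0$fracA))

  expect_error(decompose_trait_correlation(0.7, 0.5, 0.5, 0.5, 0.5, 0.5),
               "sum to 1")
  expect_error(decompose_trait_correlation(0.5, 0.5, 0.5, 0.5, 1.2, 0),
               "\\[-1, 1\\]")

  # opposite-signed components can push fractions outside [0, 1]
  dmix <- decompose_trait_correlation(0.6, 0.6, 0.4, 0.4, rA = -0.17,
                                      rE = 0.05)
  expect_equal(dmix$fracA + dmix$fracE, 1, tolerance = 1e-8)
  expect_gt(dmix$fracA, 1)
  expect_lt(dmix$fracE, 0)
})

test_that("shared variance fraction is even and exact", {
  expect_equal(shared_variance_fraction(0), 0)
  expect_equal(shared_variance_fraction(-0.6), shared_variance_fraction(0.6))
  expect_equal(shared_variance_pct(-0.82), 67)
  expect_error(shared_variance_fraction(1.2), "\\[-1, 1\\]")
})

test_that("bivariate fit recovers the decomposition and its identity", {
  cfg <- simulation_config(1200, 1200, 0,
                           traits = list(sim_trait("t1", a2 = 0.5),
                                         sim_trait("t2", a2 = 0.6)),
                           rA = -0.8, rE = -0.4)
  co <- simulate_cohort(cfg, seed = 70)
  fit <- fit_bivariate(co, "t1", "t2", ci = FALSE)
  d <- fit$decomposition$pooled
  expect_lt(abs(d$rA - (-0.8)), 0.07)
  expect_lt(abs(d$rE - (-0.4)), 0.07)
  expect_lt(abs(d$h2[[1]] - 0.5), 0.07)
  # reconstruction identity holds exactly at the fitted values
  expect_equal(d$r,
               d$rA * sqrt(d$h2[1] * d$h2[2]) + d$rE * sqrt(d$e2[1] * d$e2[2]),
               tolerance = 1e-8)
  expect_equal(d$fracA + d$fracE, 1, tolerance = 1e-8)

  # symmetry: swapping the traits leaves the derived quantities unchanged
  swp <- fit_bivariate(co, "t2", "t1", ci = FALSE)
  expect_lt(abs(swp$decomposition$pooled$r - d$r), 1e-6)
  expect_lt(abs(swp$decomposition$pooled$rA - d$rA), 1e-6)
  expect_lt(abs(swp$decomposition$pooled$rE - d$rE), 1e-6)
})

test_that("a duplicated trait collapses to perfect correlations", {
  cfg <- simulation_config(150, 150, 0, traits = sim_trait("t1", a2 = 0.5))
  co <- as.data.frame(simulate_cohort(cfg, seed = 71))
  co$t2 <- co$t1
  fit <- fit_bivariate(twin_cohort(co), "t1", "t2", ci = FALSE)
  d <- fit$decomposition$pooled
  expect_lt(abs(d$r - 1), 1e-3)
  expect_lt(abs(d$rA - 1), 1e-3)
  expect_lt(abs(d$rE - 1), 1e-3)
})

test_that("rA profile interval covers zero for independent traits", {
  cfg <- simulation_config(250, 250, 0,
                           traits = list(sim_trait("t1", a2 = 0.5),
                                         sim_trait("t2", a2 = 0.5)),
                           rA = 0, rE = 0)
  cover <- vapply(1:40, function(i) {
    co <- simulate_cohort(cfg, seed = 40000 + i)
    fit <- fit_bivariate(co, "t1", "t2", ci = FALSE)
    ci <- twinvar:::biv_profile_ci(fit, "pooled", "A")
    ci$lower <= 0 && 0 <= ci$upper
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})
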