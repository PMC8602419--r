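test_that("AE maximum likelihood recovers the generating heritability", {
  cfg <- simulation_config(4000, 4000, 0, traits = sim_trait("y", a2 = 0.5))
  co <- simulate_cohort(cfg, seed = 17)
  fit <- fit_univariate(co, "y", "AE", "pooled")
  expect_lt(abs(fit$proportions$pooled[["a2"]] - 0.5), 0.03)
  expect_true(fit$convergence$converged)
})

test_that("E-only fit equals the closed-form ML variance", {
  co <- rand_cohort(11, n_mz = 50, n_dz = 50)
  fit <- fit_univariate(co, "y", "E", "pooled")
  d <- as.data.frame(complete_pairs(co, "y"))
  mu <- mean(d$y)
  ml_var <- mean((d$y - mu)^2)
  expect_equal(fit$components$pooled[["e2"]], ml_var, tolerance = 1e-6)
  expect_equal(fit$means[["pooled"]], mu, tolerance = 1e-6)
})

test_that("identification requires both MZ and DZ pairs", {
  cfg <- simulation_config(100, 0, 0, traits = sim_trait("y", a2 = 0.5))
  co <- simulate_cohort(cfg, seed = 4)
  expect_error(fit_univariate(co, "y", "AE", "pooled"), "not identified")
  # E-only needs no zygosity contrast
  expect_s3_class(fit_univariate(co, "y", "E", "pooled"), "univariate_fit")
})

test_that("likelihood-ratio bookkeeping and nesting rules", {
  co <- rand_cohort(12, n_mz = 60, n_dz = 60)
  ace <- fit_univariate(co, "y", "ACE", "pooled")
  ade <- fit_univariate(co, "y", "ADE", "pooled")
  ae <- fit_univariate(co, "y", "AE", "pooled")

  same <- compare_models(ae, ae)
  expect_equal(same$chi2, 0)
  expect_equal(same$df, 0)
  expect_equal(same$p, 1)

  cc <- compare_models(ace, ae)
  expect_equal(cc$chi2, max(0, ae$minus2LL - ace$minus2LL))
  expect_equal(cc$df, 1)
  expect_equal(cc$p, pchisq(cc$chi2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(cc$p_mixture, 0.5 * cc$p, tolerance = 1e-12)

  expect_error(compare_models(ace, ade), "not nested")
})

test_that("selection sequence keeps AE under an AE generator", {
  # under a true AE model the AE restriction should rarely be rejected
  cfg <- simulation_config(250, 250, 0, traits = sim_trait("y", a2 = 0.4))
  keep <- vapply(1:40, function(i) {
    co <- simulate_cohort(cfg, seed = 30000 + i)
    sel <- selection_sequence(co, "y", sex = "pooled")
    sel$comparisons$p[sel$comparisons$full == sel$best &
                        sel$comparisons$nested == "AE"] > 0.05
  }, logical(1))
  expect_gte(mean(keep), 0.85)
})

test_that("shared-environment signal steers selection toward ACE", {
  cfg <- simulation_config(5000, 5000, 0,
                           traits = sim_trait("y", a2 = 0.3, c2 = 0.3))
  co <- simulate_cohort(cfg, seed = 88)
  sel <- selection_sequence(co, "y", sex = "pooled")
  expect_lt(sel$fits$ACE$minus2LL, sel$fits$ADE$minus2LL)
  expect_equal(sel$best, "ACE")
  expect_equal(nrow(sel$comparisons), 4)
})

test_that("bonferroni threshold", {
  expect_equal(round(bonferroni_threshold(0.05, 11), 4), 0.0045)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.5, 3), "alpha")
})

test_that("profile_interval matches the Wald interval for a quadratic", {
  # -2lnL exactly quadratic: profile and Wald intervals coincide
  t0 <- 0.42; v <- 0.003
  f <- function(t) 100 + (t - t0)^2 / v
  res <- profile_interval(f, t0, 100, qchisq(0.95, 1), lower = 0, upper = 1,
                          tol = 1e-6)
  half <- qnorm(0.975) * sqrt(v)
  expect_equal(res$lower, t0 - half, tolerance = 1e-4)
  expect_equal(res$upper, t0 + half, tolerance = 1e-4)
  expect_false(res$lower_at_bound || res$upper_at_bound)
})

test_that("profile CI brackets the estimate and flags boundary pins", {
  cfg <- simulation_config(300, 300, 0, traits = sim_trait("y", a2 = 0.4))
  co <- simulate_cohort(cfg, seed = 55)
  fit <- fit_univariate(co, "y", "AE", "pooled")
  ci <- profile_ci(fit, "a2")
  expect_lte(ci$lower, ci$estimate)
  expect_gte(ci$upper, ci$estimate)
  expect_gte(ci$lower, 0); expect_lte(ci$upper, 1)

  # a2 = 0 generator: lower limit clipped to 0 and flagged
  cfg0 <- simulation_config(150, 150, 0, traits = sim_trait("y", a2 = 0))
  co0 <- simulate_cohort(cfg0, seed = 56)
  fit0 <- fit_univariate(co0, "y", "AE", "pooled")
  ci0 <- profile_ci(fit0, "a2")
  expect_equal(ci0$lower, 0)
  expect_true(ci0$lower_at_bound)
})

test_that("fits are deterministic and invariant to pair order", {
  co <- rand_cohort(13, n_mz = 60, n_dz = 60)
  f1 <- fit_univariate(co, "y", "AE", "pooled")
  set.seed(999)
  perm <- as.data.frame(co)[sample(nrow(co)), ]
  f2 <- fit_univariate(twin_cohort(perm), "y", "AE", "pooled")
  expect_equal(f1$minus2LL, f2$minus2LL, tolerance = 1e-8)
  expect_equal(f1$proportions$pooled, f2$proportions$pooled, tolerance = 1e-6)
})

test_that("sex-limitation fit recovers sex-specific heritabilities and rg", {
  cfg <- simulation_config(2000, 2000, 2000,
                           traits = sim_trait("y", a2 = c(0.3, 0.6)),
                           rg_os = 1)
  co <- simulate_cohort(cfg, seed = 21)
  fit <- fit_univariate(co, "y", "AE", "sexlim")
  expect_lt(abs(fit$proportions$M[["a2"]] - 0.3), 0.05)
  expect_lt(abs(fit$proportions$F[["a2"]] - 0.6), 0.05)
  # freeing rg under rg = 1 truth should not move the fit much
  free <- fit_univariate(co, "y", "AE", "sexlim", rg = "free")
  expect_lte(free$minus2LL, fit$minus2LL + 1e-6)
  expect_equal(free$n_parameters, fit$n_parameters + 1)
  lrt <- compare_models(free, fit)
  expect_gte(lrt$p, 0)
})
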