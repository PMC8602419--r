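test_that("trait and config validation rejects impossible structures", {
  expect_error(sim_trait("y", a2 = -0.1, e2 = 1.1), "negative")
  expect_error(sim_trait("y", a2 = 0.5, e2 = 0.6), "sum to 1")
  expect_error(sim_trait("y", a2 = 0.3, c2 = 0.2, d2 = 0.2, e2 = 0.3),
               "both be positive")
  expect_error(simulation_config(0, 0, 0, traits = sim_trait("y", a2 = 0.5)),
               "nonempty")
  expect_error(simulation_config(10, 0, 0, traits = sim_trait("y", a2 = 0.5),
                                 rg_os = 1.5), "rg_os")
})

test_that("identical config and seed give bitwise-identical cohorts", {
  cfg <- simulation_config(50, 40, 30, n_singletons = 10,
                           traits = sim_trait("y", a2 = c(0.3, 0.5)))
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("degenerate and independent variance structures behave exactly", {
  # a2 = 1: the trait is the shared additive factor, MZ co-twins equal
  co <- simulate_cohort(simulation_config(200, 0, 0,
                                          traits = sim_trait("y", a2 = 1)),
                        seed = 1)
  d <- as.data.frame(co); d <- d[order(d$pair_id, d$member), ]
  i1 <- seq(1, nrow(d), 2)
  expect_equal(d$y[i1], d$y[i1 + 1])

  # a2 = 0: co-twins independent in every group
  co0 <- simulate_cohort(simulation_config(5000, 5000, 5000,
                                           traits = sim_trait("y", a2 = 0)),
                         seed = 2)
  d <- as.data.frame(co0); d <- d[order(d$pair_id, d$member), ]
  i1 <- seq(1, nrow(d), 2)
  for (z in c("MZ", "DZss", "DZos")) {
    sel <- d$zygosity[i1] == z
    expect_lt(abs(cor(d$y[i1][sel], d$y[i1 + 1][sel])), 0.05)
  }
})

test_that("cross-twin correlations match the closed-form structure", {
  co <- simulate_cohort(simulation_config(20000, 20000, 0,
                                          traits = sim_trait("y", a2 = 0.6)),
                        seed = 3)
  d <- as.data.frame(co); d <- d[order(d$pair_id, d$member), ]
  i1 <- seq(1, nrow(d), 2)
  mz <- d$zygosity[i1] == "MZ"
  expect_lt(abs(cor(d$y[i1][mz], d$y[i1 + 1][mz]) - 0.60), 0.01)
  expect_lt(abs(cor(d$y[i1][!mz], d$y[i1 + 1][!mz]) - 0.30), 0.01)
})

test_that("within-group covariances and margins match theory across configs", {
  cases <- list(
    list(tr = sim_trait("y", a2 = 0.4, c2 = 0.2, mean = 10, sd = 2), rg = 1),
    list(tr = sim_trait("y", a2 = 0.3, d2 = 0.3), rg = 1),
    list(tr = sim_trait("y", a2 = c(0.5, 0.6)), rg = 0.5)
  )
  n <- 4000
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    tr <- cs$tr
    co <- simulate_cohort(simulation_config(n, n, n, traits = tr,
                                            rg_os = cs$rg), seed = 40 + i)
    d <- as.data.frame(co); d <- d[order(d$pair_id, d$member), ]
    i1 <- seq(1, nrow(d), 2)
    z1 <- (d$y[i1] - tr$mean[d$sex[i1]]) / tr$sd[d$sex[i1]]
    z2 <- (d$y[i1 + 1] - tr$mean[d$sex[i1 + 1]]) / tr$sd[d$sex[i1 + 1]]
    theo <- c(MZ = mean(tr$a2 + tr$c2 + tr$d2),
              DZss = mean(0.5 * tr$a2 + tr$c2 + 0.25 * tr$d2),
              DZos = unname(0.5 * cs$rg * sqrt(tr$a2[["M"]] * tr$a2[["F"]]) +
                            sqrt(tr$c2[["M"]] * tr$c2[["F"]]) +
                            0.25 * sqrt(tr$d2[["M"]] * tr$d2[["F"]])))
    for (z in names(theo)) {
      sel <- d$zygosity[i1] == z
      obs <- cov(z1[sel], z2[sel])
      se <- sqrt((1 + theo[[z]]^2) / sum(sel))
      expect_lt(abs(obs - theo[[z]]), 3 * se)
    }
    # marginal calibration per sex
    for (s in c("M", "F")) {
      ys <- d$y[d$sex == s]
      expect_lt(abs(mean(ys) - tr$mean[s]), 3 * tr$sd[s] / sqrt(length(ys)))
      expect_equal(sd(ys), tr$sd[[s]], tolerance = 0.05 * tr$sd[[s]])
    }
  }
})

test_that("attach_pgs calibrates variance explained and genetic sharing", {
  cfg <- simulation_config(12500, 12500, 0, traits = sim_trait("y", a2 = 0.5))
  co <- simulate_cohort(cfg, seed = 7)

  # null score: independent of the trait
  co0 <- attach_pgs(co, "y", 0, seed = 8)
  expect_lt(cor(co0$y, co0$pgs_y)^2, 0.005)

  # calibrated score: sample R2 near the target at n = 50 000
  co5 <- attach_pgs(co, "y", 0.05, seed = 9)
  r2 <- cor(co5$y, co5$pgs_y)^2
  expect_gt(r2, 0.04); expect_lt(r2, 0.06)

  # MZ co-twins share the full genetic score exactly
  mz <- as.data.frame(co5[co5$zygosity == "MZ", ])
  mz <- mz[order(mz$pair_id, mz$member), ]
  i1 <- seq(1, nrow(mz), 2)
  expect_equal(cor(mz$pgs_y[i1], mz$pgs_y[i1 + 1]), 1)
  # ... and DZ co-twins about half of it
  dz <- as.data.frame(co5[co5$zygosity == "DZss", ])
  dz <- dz[order(dz$pair_id, dz$member), ]
  i1 <- seq(1, nrow(dz), 2)
  expect_lt(abs(cor(dz$pgs_y[i1], dz$pgs_y[i1 + 1]) - 0.5), 0.03)

  # existing columns are untouched
  expect_identical(co5$y, co$y)
  expect_identical(co5$pair_id, co$pair_id)

  # a genetic score cannot out-explain the heritability
  expect_error(attach_pgs(co, "y", 0.6, seed = 1), "heritability")
})
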