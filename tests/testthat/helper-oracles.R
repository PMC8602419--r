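# Independent brute-force oracles and small fixture builders.

# -2 log-likelihood of rows of x under N(mu, S), summed pair by pair with
# generic matrix algebra (solve / determinant); independent of the package's
# closed-form evaluation.
brute_mvn_n2ll <- function(x, mu, S) {
  x <- as.matrix(x)
  Sinv <- solve(S)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  tot <- 0
  for (i in seq_len(nrow(x))) {
    d <- as.numeric(x[i, ]) - mu
    tot <- tot + length(mu) * log(2 * pi) + ld + sum(d * (Sinv %*% d))
  }
  tot
}

# hand-rolled Stata-convention cluster sandwich for y ~ x with intercept:
# G/(G-1) * (N-1)/(N-k) * (X'X)^-1 (sum_g u_g u_g') (X'X)^-1
stata_cluster_vcov <- function(y, x, cl) {
  X <- cbind(1, x)
  n <- length(y); k <- ncol(X)
  XtXinv <- solve(crossprod(X))
  b <- XtXinv %*% crossprod(X, y)
  e <- as.numeric(y - X %*% b)
  ug <- rowsum(X * e, cl)
  G <- nrow(ug)
  (G / (G - 1)) * ((n - 1) / (n - k)) * XtXinv %*% crossprod(ug) %*% XtXinv
}

# tiny cohort built by hand: one row per entry of values (list of length-2
# numeric vectors, one per pair; NA allowed; length-1 vectors = singletons)
toy_cohort <- function(values, zygosity = "MZ", sex = NULL, trait = "y") {
  np <- length(values)
  zyg <- rep(zygosity, length.out = np)
  rows <- list()
  for (i in seq_len(np)) {
    v <- values[[i]]
    sx <- if (is.null(sex)) {
      if (zyg[i] == "DZos") c("M", "F") else c("F", "F")
    } else rep(sex[[min(i, length(sex))]], length.out = 2)
    for (m in seq_along(v)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sprintf("p%03d", i), member = m, zygosity = zyg[i],
        sex = sx[m], stringsAsFactors = FALSE)
      rows[[length(rows)]][[trait]] <- v[m]
    }
  }
  twin_cohort(do.call(rbind, rows))
}

# random small cohort with a random AE/ACE/ADE structure, for likelihood and
# nesting property tests
rand_cohort <- function(seed, n_mz = 40, n_dz = 40) {
  set.seed(seed)
  a2 <- runif(1, 0.15, 0.6)
  extra <- runif(1, 0, min(0.25, 0.95 - a2))
  kind <- sample(c("none", "c", "d"), 1)
  tr <- switch(kind,
    none = sim_trait("y", a2 = a2, mean = runif(1, -5, 5), sd = runif(1, 0.5, 3)),
    c = sim_trait("y", a2 = a2, c2 = extra, mean = runif(1, -5, 5), sd = runif(1, 0.5, 3)),
    d = sim_trait("y", a2 = a2, d2 = extra, mean = runif(1, -5, 5), sd = runif(1, 0.5, 3)))
  simulate_cohort(simulation_config(n_mz, n_dz, 0, traits = tr),
                  seed = seed + 10000)
}
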