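#' Expected covariance of a twin pair measured on two traits
#'
#' Covariance matrix of the quadrivariate observation
#' `(trait1-twin1, trait2-twin1, trait1-twin2, trait2-twin2)` implied by
#' lower-triangular additive-genetic (`A`) and unique-environment (`E`)
#' Cholesky path matrices. Within-person blocks are `A A' + E E'`; the
#' cross-twin block is `k A A'` with `k = 1` for MZ and `k = 0.5` for DZ
#' pairs. For opposite-sex DZ pairs twin 1 carries the male paths (`A`,
#' `E`) and twin 2 the female paths (`A2`, `E2`), with cross-twin block
#' `0.5 * rg * A A2'`.
#'
#' @param A,E 2x2 lower-triangular path matrices for twin 1.
#' @param zygosity `"MZ"`, `"DZss"` or `"DZos"`.
#' @param A2,E2 Path matrices for twin 2 (default: same as twin 1).
#' @param rg Cross-sex additive-genetic correlation (DZos only).
#' @return A 4x4 covariance matrix.
#' @export
expected_quad_covariance <- function(A, E, zygosity, A2 = A, E2 = E, rg = 1) {
  zygosity <- match.arg(zygosity, c("MZ", "DZss", "DZos"))
  k <- switch(zygosity, MZ = 1, DZss = 0.5, DZos = 0.5 * rg)
  W1 <- A %*% t(A) + E %*% t(E)
  W2 <- A2 %*% t(A2) + E2 %*% t(E2)
  C <- k * (A %*% t(A2))
  rbind(cbind(W1, C), cbind(t(C), W2))
}

#' Genetic correlation from Cholesky paths
#'
#' The additive-genetic correlation between two traits implied by the
#' lower-triangular A-paths `a11`, `a21`, `a22`: the A-covariance
#' `a11 * a21` divided by the geometric mean of the A-variances `a11^2` and
#' `a21^2 + a22^2`.
#'
#' @param a11,a21,a22 Cholesky path coefficients.
#' @return The genetic correlation `rA` in `[-1, 1]`.
#' @export
genetic_correlation_from_paths <- function(a11, a21, a22) {
  if (a11 == 0) stop("trait 1 has zero genetic variance; rA undefined")
  v2 <- a21^2 + a22^2
  if (v2 <= 0) stop("trait 2 has zero genetic variance; rA undefined")
  (a11 * a21) / (abs(a11) * sqrt(v2))
}

#' Decompose a phenotypic correlation into genetic and environmental parts
#'
#' Under the AE model the phenotypic correlation between two traits is
#' `r = rA * sqrt(h1_2 * h2_2) + rE * sqrt(e1_2 * e2_2)`, where `h*_2` and
#' `e*_2` are the standardized additive-genetic and unique-environment
#' proportions of each trait. The fraction explained by genetic factors is
#' the genetic term over `r`; the fractions sum to 1 and may individually
#' exceed 1 when `rA` and `rE` have opposite signs (they are deliberately
#' not clamped).
#'
#' @param h1_2,h2_2 Heritabilities (standardized A proportions) of the two
#'   traits.
#' @param e1_2,e2_2 Standardized unique-environment proportions; each
#'   trait's proportions must sum to 1.
#' @param rA,rE Genetic and unique-environment correlations, in `[-1, 1]`.
#' @return List: `r`, `fracA`, `fracE` (`NA` fractions, with a warning, when
#'   `r` is 0).
#' @export
decompose_trait_correlation <- function(h1_2, h2_2, e1_2, e2_2, rA, rE) {
  if (abs(h1_2 + e1_2 - 1) > 0.02 || abs(h2_2 + e2_2 - 1) > 0.02) {
    stop("standardized components of each trait must sum to 1")
  }
  if (abs(rA) > 1 || abs(rE) > 1) stop("correlations must lie in [-1, 1]")
  gen <- rA * sqrt(h1_2 * h2_2)
  env <- rE * sqrt(e1_2 * e2_2)
  r <- gen + env
  if (r == 0) {
    warning("phenotypic correlation is 0; explained fractions are undefined")
    return(list(r = 0, fracA = NA_real_, fracE = NA_real_))
  }
  list(r = r, fracA = gen / r, fracE = env / r)
}

#' Fraction of genetic variance shared between two traits
#'
#' `rA^2`: the proportion of one trait's additive-genetic variance that is
#' shared with the other. Report layers express it as an integer-rounded
#' percentage (see `shared_variance_pct`).
#'
#' @param rA Genetic correlation in `[-1, 1]`.
#' @return `rA^2`.
#' @export
shared_variance_fraction <- function(rA) {
  if (any(abs(rA) > 1)) stop("rA must lie in [-1, 1]")
  rA^2
}

#' @rdname shared_variance_fraction
#' @export
shared_variance_pct <- function(rA) {
  round(100 * shared_variance_fraction(rA))
}

# ---- bivariate pair layout and likelihood ---------------------------------

# complete pairs on both traits -> per-group list with 4-col data
# (t1w1, t2w1, t1w2, t2w2) and sufficient statistics
quad_layout <- function(cohort, trait1, trait2, stratify) {
  cc <- complete_pairs(cohort, traits = c(trait1, trait2))
  if (!nrow(cc)) stop("no complete pairs observed on both traits")
  d <- as.data.frame(cc)
  d <- d[order(as.character(d$pair_id), d$member), ]
  i1 <- seq(1, nrow(d), by = 2)
  x <- cbind(d[[trait1]][i1], d[[trait2]][i1],
             d[[trait1]][i1 + 1], d[[trait2]][i1 + 1])
  zyg <- d$zygosity[i1]
  s1 <- d$sex[i1]
  swap <- zyg == "DZos" & s1 == "F"
  x[swap, ] <- x[swap, c(3, 4, 1, 2)]
  lab <- if (!stratify) {
    ifelse(zyg == "MZ", "MZ", "DZ")
  } else {
    ifelse(zyg == "DZos", "DZOS", paste0(ifelse(zyg == "MZ", "MZ", "DZ"), s1))
  }
  groups <- lapply(split(seq_along(lab), lab), function(idx) {
    xi <- x[idx, , drop = FALSE]
    list(x = xi, n = nrow(xi), Sx = colSums(xi), Sxx = crossprod(xi))
  })
  attr(groups, "n_pairs") <- length(lab)
  groups
}

n2ll_quad_stats <- function(g, mu, S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  logdet <- 2 * sum(log(diag(ch)))
  M <- g$Sxx - outer(g$Sx, mu) - outer(mu, g$Sx) + g$n * outer(mu, mu)
  q <- sum(chol2inv(ch) * M)
  g$n * (4 * log(2 * pi) + logdet) + q
}

lower2 <- function(p) matrix(c(p[1], p[2], 0, p[3]), 2, 2)

derive_biv <- function(A, E) {
  VA <- A %*% t(A); VE <- E %*% t(E)
  tot <- diag(VA) + diag(VE)
  h2 <- diag(VA) / tot
  e2 <- diag(VE) / tot
  rA <- if (VA[1, 1] > 0 && VA[2, 2] > 0)
    VA[1, 2] / sqrt(VA[1, 1] * VA[2, 2]) else NA_real_
  rE <- if (VE[1, 1] > 0 && VE[2, 2] > 0)
    VE[1, 2] / sqrt(VE[1, 1] * VE[2, 2]) else NA_real_
  r <- (VA[1, 2] + VE[1, 2]) / sqrt(tot[1] * tot[2])
  gen <- rA * sqrt(h2[1] * h2[2])
  list(h2 = h2, e2 = e2, rA = rA, rE = rE, r = r,
       fracA = if (!is.na(r) && r != 0) gen / r else NA_real_,
       fracE = if (!is.na(r) && r != 0) 1 - gen / r else NA_real_)
}

#' Bivariate AE Cholesky twin model
#'
#' Maximum-likelihood fit of the bivariate additive-genetic /
#' unique-environment Cholesky decomposition to complete twin pairs observed
#' on two traits: each pair contributes a 4-variate normal density with
#' covariance [expected_quad_covariance()]. Returns the path estimates and
#' the derived decomposition: per-trait standardized components, the
#' genetic correlation `rA`, the unique-environment correlation `rE`, the
#' model-implied phenotypic correlation `r` and the fractions of `r`
#' explained by A and by E, with profile-likelihood CIs on `rA` and `rE`
#' (profiled directly on the correlation via a reparameterization of the
#' second trait's paths) and a Fisher-z CI on `r`. The leading paths `a11`
#' and `e11` are reported positive to fix the reflection invariance of the
#' Cholesky factor.
#'
#' With `stratify_sex = TRUE` male and female path sets are estimated from
#' same-sex groups, and opposite-sex DZ pairs contribute through sex-specific
#' expected covariances with cross-sex genetic correlation `rg` (fixed at 1).
#'
#' @param cohort A [twin_cohort()].
#' @param trait1,trait2 Trait columns.
#' @param stratify_sex Fit sex-specific paths?
#' @param ci Compute profile CIs for `rA`/`rE`?
#' @param level Confidence level.
#' @return A `bivariate_fit`: `paths` (per sex: `A`, `E` matrices),
#'   `decomposition` (per sex), `minus2LL`, `n_parameters`, `n_pairs`.
#' @export
fit_bivariate <- function(cohort, trait1, trait2, stratify_sex = FALSE,
                          ci = TRUE, level = 0.95) {
  groups <- quad_layout(cohort, trait1, trait2, stratify_sex)
  sexes <- if (stratify_sex) c("M", "F") else "pooled"
  nsx <- length(sexes)
  npar <- nsx * 8L  # 2 means + 6 paths per sex

  unpack <- function(theta) {
    out <- list()
    off <- 0
    for (s in sexes) {
      out[[s]] <- list(mu = theta[off + 1:2],
                       A = lower2(theta[off + 3:5]),
                       E = lower2(theta[off + 6:8]))
      off <- off + 8
    }
    out
  }

  group_n2ll <- function(par, g, lab) {
    if (lab %in% c("MZ", "DZ")) {
      p <- par[["pooled"]]
      S <- expected_quad_covariance(p$A, p$E, if (lab == "MZ") "MZ" else "DZss")
      mu <- rep(p$mu, 2)
    } else if (lab == "DZOS") {
      S <- expected_quad_covariance(par$M$A, par$M$E, "DZos",
                                    A2 = par$F$A, E2 = par$F$E)
      mu <- c(par$M$mu, par$F$mu)
    } else {
      s <- substr(lab, 3, 3)
      zyg <- if (substr(lab, 1, 2) == "MZ") "MZ" else "DZss"
      S <- expected_quad_covariance(par[[s]]$A, par[[s]]$E, zyg)
      mu <- rep(par[[s]]$mu, 2)
    }
    n2ll_quad_stats(g, mu, S)
  }

  objective <- function(theta) {
    par <- unpack(theta)
    tot <- 0
    for (lab in names(groups)) {
      tot <- tot + group_n2ll(par, groups[[lab]], lab)
      if (!is.finite(tot)) return(1e12)
    }
    tot
  }

  # moment-based start: split the phenotypic covariance half A / half E,
  # plus A-heavy and E-heavy alternatives
  allx <- do.call(rbind, lapply(groups, `[[`, "x"))
  pheno <- rbind(allx[, 1:2], allx[, 3:4])
  mu0 <- colMeans(pheno)
  Tcov <- stats::cov(pheno)
  start_for <- function(wA) {
    CA <- tryCatch(t(chol(wA * Tcov)), error = function(e) lower2(sqrt(wA) * sqrt(diag(Tcov))[c(1, 2, 2)] * c(1, 0, 1)))
    CE <- tryCatch(t(chol((1 - wA) * Tcov)), error = function(e) lower2(sqrt(1 - wA) * sqrt(diag(Tcov))[c(1, 2, 2)] * c(1, 0, 1)))
    rep(c(mu0, CA[c(1, 2, 4)], CE[c(1, 2, 4)]), nsx)
  }
  starts <- lapply(c(0.5, 0.8, 0.2), start_for)

  best <- NULL; objs <- c()
  for (st in starts) {
    opt <- stats::optim(st, objective, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-12))
    opt <- stats::optim(opt$par, objective, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-12,
                                       ndeps = rep(1e-6, length(opt$par))))
    objs <- c(objs, opt$value)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  par <- unpack(best$par)
  # fix reflection: leading and diagonal paths nonnegative
  for (s in sexes) {
    for (m in c("A", "E")) {
      L <- par[[s]][[m]]
      if (L[1, 1] < 0) { L[1, 1] <- -L[1, 1]; L[2, 1] <- -L[2, 1] }
      if (L[2, 2] < 0) L[2, 2] <- -L[2, 2]
      par[[s]][[m]] <- L
    }
  }

  decomp <- lapply(par, function(p) derive_biv(p$A, p$E))

  fit <- structure(list(trait1 = trait1, trait2 = trait2,
                        stratify_sex = stratify_sex,
                        paths = par, decomposition = decomp,
                        minus2LL = best$value, n_parameters = npar,
                        n_pairs = attr(groups, "n_pairs"),
                        layout = groups,
                        convergence = list(objectives = objs)),
                   class = "bivariate_fit")
  if (ci) {
    n_ind <- 2 * fit$n_pairs
    for (s in sexes) {
      fit$decomposition[[s]]$rA_ci <-
        biv_profile_ci(fit, s, "A", level)
      fit$decomposition[[s]]$rE_ci <-
        biv_profile_ci(fit, s, "E", level)
      fit$decomposition[[s]]$r_ci <-
        fisher_z_ci(fit$decomposition[[s]]$r, n_ind, level)
    }
  }
  fit
}

fisher_z_ci <- function(r, n, level = 0.95) {
  if (is.na(r) || abs(r) >= 1 || n < 4) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

# profile -2lnL over rA (or rE) by reparameterizing the second trait's
# paths for the target matrix as (rho, total SD): l21 = rho * s,
# l22 = sqrt(1 - rho^2) * s with s > 0 free; everything else free.
biv_profile_ci <- function(fit, sexlab, which = c("A", "E"), level = 0.95,
                           tol = 1e-4) {
  which <- match.arg(which)
  groups <- fit$layout
  sexes <- names(fit$paths)
  rho_hat <- if (which == "A") fit$decomposition[[sexlab]]$rA
             else fit$decomposition[[sexlab]]$rE
  if (is.na(rho_hat)) return(list(estimate = NA_real_, lower = NA_real_,
                                  upper = NA_real_))

  # nuisance: per sex 8 params, except the target (sexlab, which) matrix
  # uses (l11, log s) in place of (l11, l21, l22)
  pack0 <- function() {
    nu <- c()
    for (s in sexes) {
      p <- fit$paths[[s]]
      nu <- c(nu, p$mu)
      for (m in c("A", "E")) {
        L <- p[[m]]
        if (s == sexlab && m == which) {
          s2 <- sqrt(L[2, 1]^2 + L[2, 2]^2)
          nu <- c(nu, L[1, 1], log(max(s2, 1e-8)))
        } else {
          nu <- c(nu, L[1, 1], L[2, 1], L[2, 2])
        }
      }
    }
    nu
  }
  unpack_nu <- function(nu, rho) {
    out <- list(); off <- 0
    for (s in sexes) {
      mu <- nu[off + 1:2]; off <- off + 2
      mats <- list()
      for (m in c("A", "E")) {
        if (s == sexlab && m == which) {
          l11 <- nu[off + 1]; s2 <- exp(nu[off + 2]); off <- off + 2
          mats[[m]] <- lower2(c(l11, rho * s2, sqrt(max(0, 1 - rho^2)) * s2))
        } else {
          mats[[m]] <- lower2(nu[off + 1:3]); off <- off + 3
        }
      }
      out[[s]] <- list(mu = mu, A = mats$A, E = mats$E)
    }
    out
  }
  group_n2ll <- function(par, g, lab) {
    if (lab %in% c("MZ", "DZ")) {
      p <- par[["pooled"]]
      S <- expected_quad_covariance(p$A, p$E, if (lab == "MZ") "MZ" else "DZss")
      mu <- rep(p$mu, 2)
    } else if (lab == "DZOS") {
      S <- expected_quad_covariance(par$M$A, par$M$E, "DZos",
                                    A2 = par$F$A, E2 = par$F$E)
      mu <- c(par$M$mu, par$F$mu)
    } else {
      s <- substr(lab, 3, 3)
      zyg <- if (substr(lab, 1, 2) == "MZ") "MZ" else "DZss"
      S <- expected_quad_covariance(par[[s]]$A, par[[s]]$E, zyg)
      mu <- rep(par[[s]]$mu, 2)
    }
    n2ll_quad_stats(g, mu, S)
  }
  nuis0 <- pack0()
  nuis_cur <- nuis0  # warm start across bisection steps
  prof <- function(rho) {
    rho <- min(max(rho, -1), 1)
    f <- function(nu) {
      par <- unpack_nu(nu, rho)
      tot <- 0
      for (lab in names(groups)) {
        tot <- tot + group_n2ll(par, groups[[lab]], lab)
        if (!is.finite(tot)) return(1e12)
      }
      tot
    }
    # the warm start can be stale after a jump across the minimum; fall back
    # to the fit's own parameter values whenever they score better
    start <- if (f(nuis_cur) <= f(nuis0)) nuis_cur else nuis0
    opt <- stats::optim(start, f, method = "BFGS",
                        control = list(maxit = 400, reltol = 1e-11))
    if (opt$value < 1e11) nuis_cur <<- opt$par
    opt$value
  }
  crit <- stats::qchisq(level, 1)
  res <- profile_interval(prof, rho_hat, fit$minus2LL, crit,
                          lower = -1, upper = 1, tol = tol)
  list(estimate = rho_hat, lower = res$lower, upper = res$upper,
       lower_at_bound = res$lower_at_bound,
       upper_at_bound = res$upper_at_bound, level = level)
}

#' @export
print.bivariate_fit <- function(x, digits = 3, ...) {
  cat("<bivariate_fit> ", x$trait1, " ~ ", x$trait2,
      if (x$stratify_sex) " (sex-stratified)" else " (pooled)",
      ", pairs=", x$n_pairs, ", -2lnL=", format(x$minus2LL, digits = 10),
      "\n", sep = "")
  for (s in names(x$decomposition)) {
    d <- x$decomposition[[s]]
    cat("  ", s, ": r=", round(d$r, digits), " rA=", round(d$rA, digits),
        " rE=", round(d$rE, digits), " fracA=", round(d$fracA, digits),
        " h2=(", paste(round(d$h2, digits), collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}
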