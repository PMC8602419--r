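model_components <- function(model) {
  switch(model,
         ACE = c("a", "c", "e"),
         ADE = c("a", "d", "e"),
         AE  = c("a", "e"),
         E   = "e",
         stop("unknown model: ", model))
}

# squares of a path vector, named a2/c2/d2/e2
paths_to_comps <- function(paths) {
  stats::setNames(paths^2, paste0(names(paths), "2"))
}

#' Fit a univariate twin model by maximum likelihood
#'
#' Fits ACE, ADE, AE or E variance-component models to complete twin pairs
#' by minimizing the -2 log-likelihood ([neg2_loglik()]) over raw path
#' coefficients (variances enter as squares, so no bound constraints are
#' needed). Optimization is quasi-Newton (BFGS) from three fixed starting
#' points (equal split, A-heavy, E-heavy), keeping the best converged
#' solution, so fits are deterministic.
#'
#' Sex handling: `"pooled"` fits one parameter set to MZ and DZ pairs (DZos
#' included as DZ); `"stratified"` fits separate male and female parameters
#' to same-sex groups; `"sexlim"` additionally models opposite-sex DZ pairs,
#' whose additive cross-twin covariance is `0.5 * rg * a_m * a_f` with the
#' cross-sex genetic correlation `rg` either fixed (default 1) or estimated.
#'
#' @param cohort A [twin_cohort()].
#' @param trait Trait column.
#' @param model `"ACE"`, `"ADE"`, `"AE"` or `"E"`.
#' @param sex `"pooled"`, `"stratified"` or `"sexlim"`.
#' @param rg `"fixed"` (at `rg_value`) or `"free"` (sexlim only).
#' @param rg_value Fixed value of the cross-sex genetic correlation.
#' @return A `univariate_fit`: path coefficients, variance components and
#'   standardized proportions per sex, means, `minus2LL`, `n_parameters`,
#'   `n_pairs` and convergence information.
#' @export
fit_univariate <- function(cohort, trait, model = c("AE", "ACE", "ADE", "E"),
                           sex = c("pooled", "stratified", "sexlim"),
                           rg = c("fixed", "free"), rg_value = 1) {
  model <- match.arg(model)
  sex <- match.arg(sex)
  rg <- match.arg(rg)
  comps <- model_components(model)
  groups <- pair_layout(cohort, trait, sex)
  has_mz <- any(grepl("^MZ", names(groups)))
  has_dz <- any(grepl("^DZ", names(groups)))
  if (length(comps) >= 2 && (!has_mz || !has_dz)) {
    stop("model ", model, " is not identified without both MZ and DZ pairs",
         call. = FALSE)
  }
  rg_free <- sex == "sexlim" && rg == "free"

  sexes <- if (sex == "pooled") "pooled" else c("M", "F")
  npath <- length(comps)
  nmean <- length(sexes)
  npar <- nmean + npath * length(sexes) + as.integer(rg_free)

  unpack <- function(theta) {
    mu <- theta[seq_len(nmean)]
    names(mu) <- sexes
    paths <- list()
    off <- nmean
    for (s in sexes) {
      paths[[s]] <- stats::setNames(theta[off + seq_len(npath)], comps)
      off <- off + npath
    }
    rg_cur <- if (rg_free) stats::plogis(theta[off + 1]) else rg_value
    list(mu = mu, paths = paths, rg = rg_cur)
  }

  group_moments <- function(par) {
    lapply(stats::setNames(names(groups), names(groups)), function(lab) {
      if (lab %in% c("MZ", "DZ")) {
        cm <- paths_to_comps(par$paths[["pooled"]])
        list(mu = rep(par$mu[["pooled"]], 2),
             S = expected_pair_covariance(cm, if (lab == "MZ") "MZ" else "DZss"))
      } else if (lab == "DZOS") {
        list(mu = c(par$mu[["M"]], par$mu[["F"]]),
             S = expected_pair_covariance(paths_to_comps(par$paths[["M"]]),
                                          "DZos",
                                          paths_to_comps(par$paths[["F"]]),
                                          rg = par$rg))
      } else {
        s <- substr(lab, 3, 3)
        zyg <- if (substr(lab, 1, 2) == "MZ") "MZ" else "DZss"
        list(mu = rep(par$mu[[s]], 2),
             S = expected_pair_covariance(paths_to_comps(par$paths[[s]]), zyg))
      }
    })
  }

  objective <- function(theta) {
    par <- unpack(theta)
    mo <- group_moments(par)
    tot <- 0
    for (lab in names(groups)) {
      tot <- tot + n2ll_group_stats(groups[[lab]], mo[[lab]]$mu, mo[[lab]]$S)
      if (!is.finite(tot)) return(1e12)
    }
    tot
  }

  # deterministic starts from the pooled moments
  allx <- do.call(rbind, lapply(groups, `[[`, "x"))
  v <- stats::var(as.vector(allx))
  mu0 <- mean(allx)
  splits <- list(equal = rep(1 / npath, npath),
                 A_heavy = if (npath == 1) 1 else
                   c(0.8, rep(0.2 / (npath - 1), npath - 1)),
                 E_heavy = if (npath == 1) 1 else
                   c(rep(0.1 / (npath - 1), npath - 1), 0.9))
  starts <- lapply(splits, function(w) {
    p <- sqrt(w * v)
    c(rep(mu0, nmean), rep(p, length(sexes)), if (rg_free) 2)
  })

  best <- NULL
  objs <- c()
  for (st in starts) {
    opt <- stats::optim(st, objective, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    opt <- stats::optim(opt$par, objective, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12,
                                       ndeps = rep(1e-6, length(opt$par))))
    objs <- c(objs, opt$value)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  grad <- num_grad(objective, best$par)
  converged <- max(abs(grad)) < 1e-4 * (1 + abs(best$value)) &&
    (max(objs) - min(objs)) < 1e-4
  if (!is.finite(best$value) || best$value >= 1e11) {
    stop("optimization failed for model ", model, " on trait ", trait)
  }

  par <- unpack(best$par)
  components <- lapply(par$paths, paths_to_comps)
  proportions <- lapply(components, function(cm) {
    pr <- cm / sum(cm)
    full <- stats::setNames(numeric(4), c("a2", "c2", "d2", "e2"))
    full[names(pr)] <- pr
    full
  })
  structure(list(model = model, sex = sex, trait = trait,
                 paths = lapply(par$paths, abs),
                 components = components, proportions = proportions,
                 means = par$mu, rg = if (sex == "sexlim") par$rg else NULL,
                 rg_free = rg_free,
                 minus2LL = best$value, n_parameters = npar,
                 n_pairs = attr(groups, "n_pairs"),
                 layout = groups,
                 convergence = list(converged = converged,
                                    grad_norm = max(abs(grad)),
                                    objectives = objs)),
            class = "univariate_fit")
}

num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

#' Likelihood-ratio comparison of nested twin models
#'
#' Chi-square difference test: `chi2 = minus2LL(nested) - minus2LL(full)`
#' (clamped at 0), `df` = difference in free parameters, p from the upper
#' chi-square tail. Model nesting must follow the chain
#' E < AE < ACE|ADE < saturated; comparing ACE with ADE (not nested) is an
#' error. For single-df tests of a variance component the 50:50
#' chi-square-mixture p-value, which accounts for the boundary null, is
#' reported alongside as `p_mixture`.
#'
#' @param full,nested `univariate_fit` objects on the same data.
#' @return A `model_comparison` list: `chi2`, `df`, `p`, `p_mixture`.
#' @export
compare_models <- function(full, nested) {
  stopifnot(inherits(full, "univariate_fit"), inherits(nested, "univariate_fit"))
  if (!identical(full$trait, nested$trait) ||
      full$n_pairs != nested$n_pairs) {
    stop("models were not fitted to the same data")
  }
  rank <- c(E = 1, AE = 2, ACE = 3, ADE = 3, sat = 4)
  chain_ok <- function(nst, fl) {
    if (nst == fl) return(TRUE)
    if (fl == "sat") return(TRUE)
    if (nst == "E") return(fl %in% c("AE", "ACE", "ADE"))
    if (nst == "AE") return(fl %in% c("ACE", "ADE"))
    FALSE
  }
  if (!chain_ok(nested$model, full$model)) {
    stop("'", nested$model, "' is not nested in '", full$model, "'")
  }
  df <- full$n_parameters - nested$n_parameters
  if (df < 0) stop("nested model has more parameters than the full model")
  chi2 <- max(0, nested$minus2LL - full$minus2LL)
  p <- if (df == 0) {
    if (chi2 < 1e-8) 1 else 0
  } else {
    stats::pchisq(chi2, df, lower.tail = FALSE)
  }
  p_mix <- if (df == 1) {
    if (chi2 < 1e-12) 1 else 0.5 * stats::pchisq(chi2, 1, lower.tail = FALSE)
  } else NA_real_
  structure(list(full = full$model, nested = nested$model,
                 chi2 = chi2, df = df, p = p, p_mixture = p_mix),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("LRT ", x$nested, " vs ", x$full, ": chi2 = ", round(x$chi2, 3),
      ", df = ", x$df, ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Model-selection sequence for a trait
#'
#' Runs the standard twin-model workflow: fit the saturated, ACE, ADE, AE
#' and E models; choose the better of ACE/ADE by lower -2lnL (ties resolved
#' to ACE, with a message); then test AE against the chosen full model, AE
#' against the saturated model (the twin-modeling assumption check) and E
#' against AE. Emits a model-fit table shaped like a supplementary
#' model-comparison table.
#'
#' @param cohort A [twin_cohort()].
#' @param trait Trait column.
#' @param sex Sex handling, as in [fit_univariate()].
#' @return A list: `fits` (named list of `univariate_fit`s), `best` (name of
#'   the better of ACE/ADE), `comparisons` (data frame with one row per
#'   likelihood-ratio test).
#' @export
selection_sequence <- function(cohort, trait,
                               sex = c("pooled", "stratified", "sexlim")) {
  sex <- match.arg(sex)
  # the saturated reference needs >= 2 pairs per group; on very small
  # cohorts it may be unavailable, in which case its comparisons are skipped
  sat <- tryCatch(saturated_model(cohort, trait, sex), error = function(e) {
    warning("saturated model unavailable: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
  fits <- list(
    sat = sat,
    ACE = fit_univariate(cohort, trait, "ACE", sex),
    ADE = fit_univariate(cohort, trait, "ADE", sex),
    AE  = fit_univariate(cohort, trait, "AE", sex),
    E   = fit_univariate(cohort, trait, "E", sex)
  )
  best <- if (fits$ADE$minus2LL < fits$ACE$minus2LL) "ADE" else "ACE"
  if (abs(fits$ADE$minus2LL - fits$ACE$minus2LL) < 1e-9) {
    message("ACE and ADE fit equally well (-2lnL tie); keeping ACE")
    best <- "ACE"
  }
  cmps <- list(
    c(full = "sat", nested = best),
    c(full = best, nested = "AE"),
    c(full = "sat", nested = "AE"),
    c(full = "AE", nested = "E")
  )
  if (is.null(sat)) {
    cmps <- Filter(function(cm) cm[["full"]] != "sat", cmps)
    fits$sat <- NULL
  }
  rows <- lapply(cmps, function(cm) {
    # on degenerate data (e.g. saturated groups dropped) a comparison can be
    # ill-posed; flag it with NAs instead of aborting the whole sequence
    cc <- tryCatch(compare_models(fits[[cm["full"]]], fits[[cm["nested"]]]),
                   error = function(e) {
                     warning("comparison ", cm[["nested"]], " vs ",
                             cm[["full"]], " not available: ",
                             conditionMessage(e), call. = FALSE)
                     list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                          p_mixture = NA_real_)
                   })
    data.frame(full = cm[["full"]], nested = cm[["nested"]],
               minus2LL_full = fits[[cm["full"]]]$minus2LL,
               minus2LL_nested = fits[[cm["nested"]]]$minus2LL,
               chi2 = cc$chi2, df = cc$df, p = cc$p,
               p_mixture = cc$p_mixture, stringsAsFactors = FALSE)
  })
  list(fits = fits, best = best, comparisons = do.call(rbind, rows))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level, in (0, 1).
#' @param k Number of tests, a positive integer.
#' @return `alpha / k` (report layers round to 4 decimals).
#' @examples
#' bonferroni_threshold(0.05, 11)  # 0.004545...
#' @export
bonferroni_threshold <- function(alpha, k) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (!is.numeric(k) || k < 1) stop("k must be a positive integer")
  alpha / k
}

#' Profile-likelihood interval for a monotone profile objective
#'
#' Generic bisection utility: given a profiled objective `f(t)` (minimized
#' over nuisance parameters), its minimizer `t_hat` and minimum `f_min`,
#' finds on each side of `t_hat` the value of `t` where `f` crosses
#' `f_min + crit`, assuming `f` is monotone on each side. Endpoints where
#' `f` never reaches the cutoff are returned as the bound itself and flagged.
#'
#' @param f Function of a scalar `t` returning the profiled objective.
#' @param t_hat Location of the minimum.
#' @param f_min Minimum objective value.
#' @param crit Cutoff above the minimum (e.g. `qchisq(0.95, 1)`).
#' @param lower,upper Search bounds.
#' @param tol Absolute tolerance on `t`.
#' @return List: `lower`, `upper`, `lower_at_bound`, `upper_at_bound`.
#' @export
profile_interval <- function(f, t_hat, f_min, crit, lower = 0, upper = 1,
                             tol = 1e-5) {
  threshold <- f_min + crit
  side <- function(a, b, increasing_away) {
    # f(b_away) is the far end; bisect for the crossing
    far <- if (increasing_away) a else b
    fv <- f(far)
    if (fv <= threshold) return(list(t = far, at_bound = TRUE))
    lo <- a; hi <- b
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      above <- f(mid) > threshold
      if (increasing_away) {
        if (above) lo <- mid else hi <- mid
      } else {
        if (above) hi <- mid else lo <- mid
      }
    }
    list(t = (lo + hi) / 2, at_bound = FALSE)
  }
  left <- if (t_hat - lower < tol) list(t = lower, at_bound = TRUE)
          else side(lower, t_hat, increasing_away = TRUE)
  right <- if (upper - t_hat < tol) list(t = upper, at_bound = TRUE)
           else side(t_hat, upper, increasing_away = FALSE)
  list(lower = left$t, upper = right$t,
       lower_at_bound = left$at_bound, upper_at_bound = right$at_bound)
}

#' Profile-likelihood confidence interval for a standardized proportion
#'
#' Likelihood-based interval for one standardized variance proportion (e.g.
#' `a2`) of a fitted univariate model: the set of values whose profiled
#' -2 log-likelihood (all other parameters re-optimized) lies within the
#' chi-square(1) quantile of the minimum, clipped to `[0, 1]`. Estimates
#' pinned at a boundary yield a one-sided interval with the corresponding
#' `*_at_bound` flag set.
#'
#' @param fit A `univariate_fit` from [fit_univariate()].
#' @param component `"a2"`, `"c2"`, `"d2"` or `"e2"` (must be in the model).
#' @param sex For stratified fits, `"M"` or `"F"`; ignored for pooled fits.
#' @param level Confidence level.
#' @param tol Bisection tolerance on the proportion scale.
#' @return List: `estimate`, `lower`, `upper`, boundary flags and `level`.
#' @export
profile_ci <- function(fit, component = "a2", sex = NULL, level = 0.95,
                       tol = 1e-5) {
  stopifnot(inherits(fit, "univariate_fit"))
  if (fit$model == "sat") stop("profile CIs apply to parametric models only")
  comps <- model_components(fit$model)
  target <- sub("2$", "", component)
  if (!target %in% comps) {
    stop("component ", component, " is not in model ", fit$model)
  }
  sx <- if (fit$sex == "pooled") "pooled" else match.arg(sex, c("M", "F"))
  others <- setdiff(comps, target)
  groups <- fit$layout
  sexes <- if (fit$sex == "pooled") "pooled" else c("M", "F")

  # nuisance vector: per sex, mean; for sx: logV (+ logit split if 2 others);
  # for the other sex (stratified): raw paths; rg param if free.
  build <- function(t, nuis) {
    mu <- stats::setNames(nuis[seq_along(sexes)], sexes)
    off <- length(sexes)
    paths <- list()
    for (s in sexes) {
      if (s == sx) {
        V <- exp(nuis[off + 1]); off <- off + 1
        vv <- stats::setNames(numeric(length(comps)), comps)
        vv[target] <- t * V
        if (length(others) == 1) {
          vv[others] <- (1 - t) * V
        } else {
          sh <- stats::plogis(nuis[off + 1]); off <- off + 1
          vv[others[1]] <- sh * (1 - t) * V
          vv[others[2]] <- (1 - sh) * (1 - t) * V
        }
        paths[[s]] <- sqrt(vv)
      } else {
        paths[[s]] <- stats::setNames(nuis[off + seq_along(comps)], comps)
        off <- off + length(comps)
      }
    }
    rg_cur <- if (isTRUE(fit$rg_free)) stats::plogis(nuis[off + 1])
              else if (!is.null(fit$rg)) fit$rg else 1
    list(mu = mu, paths = paths, rg = rg_cur)
  }

  obj_at <- function(t, nuis) {
    par <- build(t, nuis)
    tot <- 0
    for (lab in names(groups)) {
      m <- if (lab %in% c("MZ", "DZ")) {
        list(mu = rep(par$mu[["pooled"]], 2),
             S = expected_pair_covariance(paths_to_comps(par$paths[["pooled"]]),
                                          if (lab == "MZ") "MZ" else "DZss"))
      } else if (lab == "DZOS") {
        list(mu = c(par$mu[["M"]], par$mu[["F"]]),
             S = expected_pair_covariance(paths_to_comps(par$paths[["M"]]),
                                          "DZos",
                                          paths_to_comps(par$paths[["F"]]),
                                          rg = par$rg))
      } else {
        s <- substr(lab, 3, 3)
        zyg <- if (substr(lab, 1, 2) == "MZ") "MZ" else "DZss"
        list(mu = rep(par$mu[[s]], 2),
             S = expected_pair_covariance(paths_to_comps(par$paths[[s]]), zyg))
      }
      tot <- tot + n2ll_group_stats(groups[[lab]], m$mu, m$S)
      if (!is.finite(tot)) return(1e12)
    }
    tot
  }

  # starting nuisance values from the fit
  nuis0 <- unname(fit$means[sexes])
  Vhat <- sum(fit$components[[sx]])
  nuis0 <- c(nuis0, log(Vhat))
  if (length(others) == 2) {
    o1 <- fit$components[[sx]][paste0(others[1], "2")]
    o2 <- fit$components[[sx]][paste0(others[2], "2")]
    sh <- if (o1 + o2 > 0) o1 / (o1 + o2) else 0.5
    nuis0 <- c(nuis0, stats::qlogis(min(max(sh, 1e-6), 1 - 1e-6)))
  }
  for (s in setdiff(sexes, sx)) {
    nuis0 <- c(nuis0, unname(fit$paths[[s]]))
  }
  if (isTRUE(fit$rg_free)) {
    nuis0 <- c(nuis0, stats::qlogis(min(max(fit$rg, 1e-6), 1 - 1e-6)))
  }

  nuis_cur <- nuis0  # warm start across bisection steps
  prof <- function(t) {
    t <- min(max(t, 0), 1)
    f <- function(nu) obj_at(t, nu)
    start <- if (f(nuis_cur) <= f(nuis0)) nuis_cur else nuis0
    opt <- stats::optim(start, f, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-11))
    if (opt$value < 1e11) nuis_cur <<- opt$par
    opt$value
  }

  t_hat <- unname(fit$proportions[[sx]][paste0(target, "2")] /
                    sum(fit$proportions[[sx]][paste0(comps, "2")]))
  crit <- stats::qchisq(level, 1)
  res <- profile_interval(prof, t_hat, fit$minus2LL, crit,
                          lower = 0, upper = 1, tol = tol)
  list(estimate = t_hat, lower = res$lower, upper = res$upper,
       lower_at_bound = res$lower_at_bound,
       upper_at_bound = res$upper_at_bound, level = level)
}
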