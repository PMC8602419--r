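#' Expected within-pair covariance matrix of a twin model
#'
#' The 2x2 covariance matrix of a trait measured on both members of a twin
#' pair, implied by (unstandardized) variance components. The diagonal is
#' `a2 + c2 + d2 + e2`; the off-diagonal follows the classical cross-twin
#' factor correlations: additive genetic 1 (MZ) / 0.5 (DZ), dominance 1
#' (MZ) / 0.25 (DZ), shared environment 1 in both. For opposite-sex DZ pairs
#' the members may carry sex-specific components (`comp1` = male twin,
#' `comp2` = female twin) and the additive cross-term is
#' `0.5 * rg * sqrt(a2_m * a2_f)` with `rg` the cross-sex additive-genetic
#' correlation.
#'
#' @param comp1 Named numeric vector with elements `a2`, `c2`, `d2`, `e2`
#'   (missing elements default to 0) for twin 1.
#' @param zygosity `"MZ"`, `"DZss"` or `"DZos"`.
#' @param comp2 Components for twin 2; defaults to `comp1`.
#' @param rg Cross-sex additive-genetic correlation (used for `"DZos"`).
#' @return A 2x2 covariance matrix.
#' @examples
#' expected_pair_covariance(c(a2 = 0.5, e2 = 0.5), "MZ")
#' @export
expected_pair_covariance <- function(comp1, zygosity, comp2 = comp1, rg = 1) {
  zygosity <- match.arg(zygosity, c("MZ", "DZss", "DZos"))
  g <- function(x, nm) if (nm %in% names(x)) unname(x[nm]) else 0
  a1 <- g(comp1, "a2"); c1 <- g(comp1, "c2"); d1 <- g(comp1, "d2"); e1 <- g(comp1, "e2")
  a2 <- g(comp2, "a2"); c2 <- g(comp2, "c2"); d2 <- g(comp2, "d2"); e2 <- g(comp2, "e2")
  kA <- switch(zygosity, MZ = 1, DZss = 0.5, DZos = 0.5 * rg)
  kD <- switch(zygosity, MZ = 1, DZss = 0.25, DZos = 0.25)
  off <- kA * sqrt(a1 * a2) + sqrt(c1 * c2) + kD * sqrt(d1 * d2)
  matrix(c(a1 + c1 + d1 + e1, off, off, a2 + c2 + d2 + e2), 2, 2)
}

# ---- internal pair layout -------------------------------------------------

# Arrange complete pairs for one trait into per-group n x 2 matrices.
# sex modes: "pooled"     -> groups MZ, DZ (DZss + DZos)
#            "stratified" -> MZM, MZF, DZM, DZF (DZos excluded)
#            "sexlim"     -> MZM, MZF, DZM, DZF, DZOS (male member first)
pair_layout <- function(cohort, trait, sex = c("pooled", "stratified", "sexlim")) {
  sex <- match.arg(sex)
  cc <- complete_pairs(cohort, traits = trait)
  if (!nrow(cc)) stop("no complete pairs with non-missing '", trait, "'")
  d <- as.data.frame(cc)
  d <- d[order(as.character(d$pair_id), d$member), ]
  i1 <- seq(1, nrow(d), by = 2)
  y1 <- d[[trait]][i1]; y2 <- d[[trait]][i1 + 1]
  zyg <- d$zygosity[i1]
  s1 <- d$sex[i1]; s2 <- d$sex[i1 + 1]
  # DZos: order so that the male member is first
  swap <- zyg == "DZos" & s1 == "F"
  tmp <- y1[swap]; y1[swap] <- y2[swap]; y2[swap] <- tmp
  lab <- switch(sex,
    pooled     = ifelse(zyg == "MZ", "MZ", "DZ"),
    stratified = ifelse(zyg == "DZos", NA,
                        paste0(ifelse(zyg == "MZ", "MZ", "DZ"), s1)),
    sexlim     = ifelse(zyg == "DZos", "DZOS",
                        paste0(ifelse(zyg == "MZ", "MZ", "DZ"),
                               ifelse(zyg == "MZ", s1, s1))))
  keep <- !is.na(lab)
  x <- unname(cbind(y1, y2))[keep, , drop = FALSE]
  lab <- lab[keep]
  groups <- lapply(split(seq_along(lab), lab), function(idx) {
    xi <- x[idx, , drop = FALSE]
    list(x = xi, n = nrow(xi),
         Sx = colSums(xi), Sxx = crossprod(xi))
  })
  attr(groups, "n_pairs") <- length(lab)
  attr(groups, "n_removed") <- attr(cc, "n_removed")
  groups
}

# -2 log likelihood contribution of one group, from raw pair values.
# Vectorized bivariate-normal density; non-PD covariance -> Inf.
n2ll_group_raw <- function(x, mu, S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (!is.finite(det) || det <= 0 || S[1, 1] <= 0) return(Inf)
  d1 <- x[, 1] - mu[1]; d2 <- x[, 2] - mu[2]
  q <- (S[2, 2] * d1^2 - 2 * S[1, 2] * d1 * d2 + S[1, 1] * d2^2) / det
  nrow(x) * (2 * log(2 * pi) + log(det)) + sum(q)
}

# same quantity from sufficient statistics (identical algebra, O(1) per call)
n2ll_group_stats <- function(g, mu, S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (!is.finite(det) || det <= 0 || S[1, 1] <= 0) return(Inf)
  M <- g$Sxx - outer(g$Sx, mu) - outer(mu, g$Sx) + g$n * outer(mu, mu)
  q <- (S[2, 2] * M[1, 1] - 2 * S[1, 2] * M[1, 2] + S[1, 1] * M[2, 2]) / det
  g$n * (2 * log(2 * pi) + log(det)) + q
}

#' Twin-pair normal likelihood
#'
#' Minus twice the log-likelihood of complete twin pairs under group-specific
#' bivariate-normal distributions: the sum over pairs of the bivariate normal
#' log density with the group's mean vector and covariance matrix, times -2.
#' Additive over pairs; a non-positive-definite covariance yields `Inf`
#' rather than an error so optimizers can reject it.
#'
#' @param cohort A [twin_cohort()].
#' @param trait Trait column.
#' @param means Named list of length-2 mean vectors (scalars are recycled),
#'   one per group label.
#' @param covs Named list of 2x2 covariance matrices, one per group label.
#' @param sex Grouping mode: `"pooled"` (groups `MZ`, `DZ`), `"stratified"`
#'   (`MZM`, `MZF`, `DZM`, `DZF`; opposite-sex pairs excluded) or `"sexlim"`
#'   (adds `DZOS`, male member first).
#' @return Scalar -2 log-likelihood.
#' @export
neg2_loglik <- function(cohort, trait, means, covs,
                        sex = c("pooled", "stratified", "sexlim")) {
  groups <- pair_layout(cohort, trait, match.arg(sex))
  total <- 0
  for (lab in names(groups)) {
    if (!lab %in% names(means) || !lab %in% names(covs)) {
      stop("means/covs must be supplied for group ", lab)
    }
    mu <- rep(as.numeric(means[[lab]]), length.out = 2)
    total <- total + n2ll_group_raw(groups[[lab]]$x, mu,
                                    as.matrix(covs[[lab]]))
  }
  total
}

#' Saturated twin model
#'
#' Reference model with free means per group and birth order and a free 2x2
#' covariance matrix per group, estimated by maximum likelihood (means =
#' sample means, covariance = ML covariance with denominator n). Used to
#' test the twin-model assumptions of equal means and variances across birth
#' order and zygosity. Groups with a singular sample covariance are dropped
#' with a warning.
#'
#' @param cohort A [twin_cohort()].
#' @param trait Trait column.
#' @param sex Grouping mode, as in [neg2_loglik()].
#' @return A `univariate_fit` with per-group estimates, `minus2LL` and
#'   `n_parameters` (5 per group).
#' @export
saturated_model <- function(cohort, trait,
                            sex = c("pooled", "stratified", "sexlim")) {
  sex <- match.arg(sex)
  groups <- pair_layout(cohort, trait, sex)
  est <- list(); m2ll <- 0; npar <- 0L
  for (lab in names(groups)) {
    g <- groups[[lab]]
    if (g$n < 2) {
      warning("group ", lab, " has fewer than 2 pairs; dropped")
      next
    }
    mu <- g$Sx / g$n
    S <- g$Sxx / g$n - outer(mu, mu)
    det <- S[1, 1] * S[2, 2] - S[1, 2]^2
    if (det <= 0) {
      warning("group ", lab, " has singular sample covariance; dropped")
      next
    }
    m2ll <- m2ll + n2ll_group_raw(g$x, mu, S)
    npar <- npar + 5L
    est[[lab]] <- list(mean = mu, cov = S, n = g$n)
  }
  if (!length(est)) stop("no usable groups for the saturated model")
  structure(list(model = "sat", sex = sex, trait = trait,
                 groups = est, minus2LL = m2ll, n_parameters = npar,
                 n_pairs = attr(groups, "n_pairs"),
                 convergence = list(converged = TRUE, method = "closed form")),
            class = "univariate_fit")
}

#' @export
print.univariate_fit <- function(x, digits = 3, ...) {
  cat("<univariate_fit> model=", x$model, " (", x$sex, "), trait=", x$trait,
      ", pairs=", x$n_pairs, "\n", sep = "")
  cat("  -2lnL = ", format(x$minus2LL, digits = 10),
      ", parameters = ", x$n_parameters, "\n", sep = "")
  if (!is.null(x$proportions)) {
    for (s in names(x$proportions)) {
      p <- x$proportions[[s]]
      cat("  ", s, ": ",
          paste(names(p), round(p, digits), sep = "=", collapse = "  "),
          "\n", sep = "")
    }
  }
  invisible(x)
}
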