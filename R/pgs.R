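#' Standardize a score to mean 0, SD 1
#'
#' @param values Numeric vector with at least 2 distinct non-missing values.
#' @return The values centered and scaled by the sample SD (denominator
#'   n - 1); affine transforms of the input give identical output.
#' @export
standardize_score <- function(values) {
  x <- as.numeric(values)
  ok <- !is.na(x)
  if (length(unique(x[ok])) < 2) {
    stop("score is constant (or has fewer than 2 distinct values); ",
         "cannot standardize")
  }
  (x - mean(x[ok])) / stats::sd(x[ok])
}

# Stata-convention cluster-robust covariance: sandwich with cluster-summed
# score contributions and small-sample factor G/(G-1) * (N-1)/(N-k),
# i.e. sandwich::vcovCL(type = "HC1", cadjust = TRUE).
cluster_vcov <- function(model, cluster) {
  sandwich::vcovCL(model, cluster = cluster, type = "HC1", cadjust = TRUE)
}

#' Polygenic-score regression with pair-clustered standard errors
#'
#' Ordinary-least-squares regression of a trait on a standardized score
#' (slope = change in trait units per 1 SD of score), with the slope's
#' variance estimated by the cluster-sandwich estimator over twin pairs
#' (cluster-summed score-residual products with the standard small-sample
#' correction `G/(G-1) * (N-1)/(N-k)`) and a confidence interval from the
#' t distribution with G - 1 degrees of freedom, G = number of clusters.
#' `R2` is the squared sample correlation between trait and score. With
#' singleton clusters the estimator reduces exactly to the
#' heteroskedasticity-robust (HC1) standard error.
#'
#' @param trait Numeric response vector.
#' @param score Numeric score vector (standardized internally unless
#'   `standardize = FALSE`).
#' @param cluster Cluster (pair) identifiers, same length.
#' @param standardize Standardize the score before regressing?
#' @param standardize_trait Also z-score the trait (fully standardized
#'   coefficients)? Default `FALSE`: trait stays in raw units.
#' @param level Confidence level.
#' @return A `pgs_association` list: `beta`, `se`, `ci`, `R2`, `n`,
#'   `n_clusters`, `p`.
#' @export
pgs_regression_clustered <- function(trait, score, cluster,
                                     standardize = TRUE,
                                     standardize_trait = FALSE,
                                     level = 0.95) {
  if (length(trait) != length(score) || length(trait) != length(cluster)) {
    stop("trait, score and cluster must have equal length")
  }
  ok <- !is.na(trait) & !is.na(score)
  y <- trait[ok]; x <- score[ok]; cl <- as.character(cluster[ok])
  if (length(unique(x)) < 2) stop("score is constant")
  G <- length(unique(cl))
  if (G < 2) stop("at least 2 clusters are required")
  if (standardize) x <- standardize_score(x)
  if (standardize_trait) y <- standardize_score(y)
  m <- stats::lm(y ~ x)
  V <- cluster_vcov(m, cl)
  beta <- unname(stats::coef(m)[2])
  se <- sqrt(V[2, 2])
  q <- stats::qt(1 - (1 - level) / 2, df = G - 1)
  p <- 2 * stats::pt(-abs(beta / se), df = G - 1)
  structure(list(beta = beta, se = se,
                 ci = c(beta - q * se, beta + q * se),
                 R2 = stats::cor(y, x)^2,
                 n = length(y), n_clusters = G, p = unname(p),
                 level = level),
            class = "pgs_association")
}

#' @export
print.pgs_association <- function(x, digits = 3, ...) {
  cat("beta = ", round(x$beta, digits), " (", x$level * 100, "% CI ",
      round(x$ci[1], digits), ", ", round(x$ci[2], digits), "), R2 = ",
      round(x$R2, digits), ", n = ", x$n, " in ", x$n_clusters,
      " clusters\n", sep = "")
  invisible(x)
}

#' Sex-interaction test for a polygenic-score association
#'
#' Pooled regression of the trait on sex, standardized score and their
#' interaction; the interaction coefficient is tested with a cluster-robust
#' Wald statistic (same estimator as [pgs_regression_clustered()]) against
#' t(G - 1).
#'
#' @param trait,score Numeric vectors.
#' @param sex Factor-like vector with both levels present.
#' @param cluster Cluster (pair) identifiers.
#' @return List: `p`, `estimate`, `se`, `n_clusters`.
#' @export
sex_interaction_test <- function(trait, score, sex, cluster) {
  ok <- !is.na(trait) & !is.na(score)
  y <- trait[ok]; x <- score[ok]; sx <- as.factor(sex[ok])
  cl <- as.character(cluster[ok])
  if (nlevels(droplevels(sx)) < 2) {
    stop("both sexes must be present for an interaction test")
  }
  x <- standardize_score(x)
  m <- stats::lm(y ~ sx * x)
  V <- cluster_vcov(m, cl)
  k <- length(stats::coef(m))
  est <- unname(stats::coef(m)[k])
  se <- sqrt(V[k, k])
  G <- length(unique(cl))
  p <- 2 * stats::pt(-abs(est / se), df = G - 1)
  list(p = unname(p), estimate = est, se = se, n_clusters = G)
}

#' Polygenic-score association table
#'
#' Per-score associations with a trait, stratified by sex (scores are
#' standardized within stratum) plus the pooled sex-interaction p-value,
#' shaped like a per-score report table.
#'
#' @param cohort A [twin_cohort()].
#' @param trait Trait column.
#' @param scores Character vector of score columns.
#' @param stratify_sex Report per-sex rows (default) or a single pooled row.
#' @return Data frame: `score`, `sex`, `beta`, `LL`, `UL`, `R2`,
#'   `interaction_p` (repeated across the score's rows).
#' @export
pgs_table <- function(cohort, trait, scores, stratify_sex = TRUE) {
  stopifnot(inherits(cohort, "twin_cohort"))
  rows <- list()
  for (sc in scores) {
    if (!sc %in% names(cohort)) stop("unknown score column: ", sc)
    ip <- tryCatch(
      sex_interaction_test(cohort[[trait]], cohort[[sc]], cohort$sex,
                           cohort$pair_id)$p,
      error = function(e) NA_real_)
    strata <- if (stratify_sex) c("M", "F") else "pooled"
    for (s in strata) {
      rowsel <- if (s == "pooled") rep(TRUE, nrow(cohort)) else cohort$sex == s
      fit <- pgs_regression_clustered(cohort[[trait]][rowsel],
                                      cohort[[sc]][rowsel],
                                      cohort$pair_id[rowsel])
      rows[[length(rows) + 1L]] <- data.frame(
        score = sc, sex = s, beta = fit$beta, LL = fit$ci[1], UL = fit$ci[2],
        R2 = fit$R2, interaction_p = ip, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
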