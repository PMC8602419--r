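#' Descriptive statistics by sex with a pair-clustered difference test
#'
#' Per-sex n, mean and sample SD (denominator n - 1) for one trait, plus a
#' sex-difference p-value from a linear model of the trait on a sex
#' indicator with standard errors clustered on twin pairs (same estimator
#' and t(G - 1) reference as [pgs_regression_clustered()], G = number of
#' pairs).
#'
#' @param cohort A [twin_cohort()].
#' @param trait Trait column name.
#' @return A one-row data frame: `trait`, `n_men`, `mean_men`, `sd_men`,
#'   `n_women`, `mean_women`, `sd_women`, `p_sexdiff`.
#' @export
describe_by_sex <- function(cohort, trait) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (!trait %in% names(cohort)) stop("unknown trait: ", trait)
  y <- cohort[[trait]]
  ok <- !is.na(y)
  if (!any(ok)) stop("trait '", trait, "' is entirely missing")
  y <- y[ok]
  sex <- cohort$sex[ok]
  id <- as.character(cohort$pair_id)[ok]
  nm <- sum(sex == "M"); nf <- sum(sex == "F")
  if (nm < 2 || nf < 2) {
    stop("trait '", trait, "' needs at least 2 non-missing values per sex")
  }
  fit <- stats::lm(y ~ sex)
  V <- cluster_vcov(fit, id)
  tval <- stats::coef(fit)[2] / sqrt(V[2, 2])
  G <- length(unique(id))
  p <- 2 * stats::pt(-abs(tval), df = G - 1)
  data.frame(trait = trait,
             n_men = nm, mean_men = mean(y[sex == "M"]),
             sd_men = stats::sd(y[sex == "M"]),
             n_women = nf, mean_women = mean(y[sex == "F"]),
             sd_women = stats::sd(y[sex == "F"]),
             p_sexdiff = unname(p),
             stringsAsFactors = FALSE)
}

#' Descriptive table over several traits
#'
#' @param cohort A [twin_cohort()].
#' @param traits Character vector of trait columns (defaults to all).
#' @return A data frame with one [describe_by_sex()] row per trait.
#' @export
describe_table <- function(cohort, traits = trait_names(cohort)) {
  do.call(rbind, lapply(traits, function(tr) describe_by_sex(cohort, tr)))
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sum))` for a
#' matrix of individuals by items. Rows with missing entries are dropped
#' (listwise deletion). Alpha can be negative for negatively correlated
#' items and is not clamped.
#'
#' @param item_matrix Numeric matrix or data frame, individuals x items.
#' @return Alpha (scalar, at most 1).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (!is.numeric(m)) stop("item matrix must be numeric")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2) stop("at least 2 items are required")
  if (nrow(m) < 3) stop("at least 3 complete individuals are required")
  vt <- stats::var(rowSums(m))
  if (vt <= 0) stop("total-score variance is zero; alpha is undefined")
  vi <- sum(apply(m, 2, stats::var))
  (k / (k - 1)) * (1 - vi / vt)
}

#' Pairwise trait correlations, optionally sex-adjusted
#'
#' Pearson correlations between trait columns over individuals with complete
#' observations per trait pair. With `adjust_for_sex = TRUE` each trait is
#' first centered within sex, which is equivalent to partialling out a
#' binary sex indicator.
#'
#' @param cohort A [twin_cohort()].
#' @param traits Character vector of at least two trait columns.
#' @param adjust_for_sex Center traits within sex before correlating?
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
trait_correlations <- function(cohort, traits, adjust_for_sex = TRUE) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (length(traits) < 2) stop("at least 2 traits are required")
  bad <- setdiff(traits, names(cohort))
  if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "))
  X <- as.matrix(as.data.frame(cohort)[, traits, drop = FALSE])
  if (adjust_for_sex) {
    for (s in unique(cohort$sex)) {
      rows <- cohort$sex == s
      X[rows, ] <- sweep(X[rows, , drop = FALSE], 2,
                         colMeans(X[rows, , drop = FALSE], na.rm = TRUE))
    }
  }
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(sds)) || any(sds == 0)) {
    stop("constant trait(s): ",
         paste(traits[is.na(sds) | sds == 0], collapse = ", "),
         "; correlation undefined")
  }
  r <- stats::cor(X, use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}
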