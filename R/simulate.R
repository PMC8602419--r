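#' Specify a simulated quantitative trait
#'
#' Defines one trait of a simulated twin cohort on a standardized latent
#' scale: the variance proportions `a2` (additive genetic), `c2` (shared
#' environment), `d2` (dominance genetic) and `e2` (unique environment) must
#' be nonnegative and sum to 1 per sex, and `c2` and `d2` may not both be
#' positive (twins reared together cannot separate them). Values may be a
#' single number or a length-2 vector `c(M, F)` for sex-specific structure.
#' The latent trait is mapped affinely to the configured `mean` and `sd`.
#'
#' @param name Trait column name.
#' @param a2,c2,d2,e2 Standardized variance proportions, scalar or `c(M, F)`.
#'   `e2 = NULL` fills the remainder to 1.
#' @param mean,sd Observed-scale mean and total SD, scalar or `c(M, F)`.
#' @return A `sim_trait` specification list.
#' @export
sim_trait <- function(name, a2, c2 = 0, d2 = 0, e2 = NULL, mean = 0, sd = 1) {
  per_sex <- function(x) {
    x <- as.numeric(x)
    if (length(x) == 1L) x <- c(x, x)
    if (length(x) != 2L) stop("per-sex values must have length 1 or 2")
    names(x) <- c("M", "F")
    x
  }
  a2 <- per_sex(a2); c2 <- per_sex(c2); d2 <- per_sex(d2)
  mean <- per_sex(mean); sd <- per_sex(sd)
  e2 <- if (is.null(e2)) 1 - a2 - c2 - d2 else per_sex(e2)
  for (s in c("M", "F")) {
    p <- c(a2[s], c2[s], d2[s], e2[s])
    if (any(p < -1e-12)) {
      stop("trait '", name, "', sex ", s, ": negative variance proportion",
           call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop("trait '", name, "', sex ", s,
           ": variance proportions must sum to 1 (got ", sum(p), ")",
           call. = FALSE)
    }
    if (c2[s] > 0 && d2[s] > 0) {
      stop("trait '", name, "', sex ", s,
           ": c2 and d2 cannot both be positive", call. = FALSE)
    }
    if (sd[s] <= 0) stop("trait '", name, "': sd must be positive", call. = FALSE)
  }
  structure(list(name = name, a2 = pmax(a2, 0), c2 = pmax(c2, 0),
                 d2 = pmax(d2, 0), e2 = pmax(e2, 0), mean = mean, sd = sd),
            class = "sim_trait")
}

#' Configure a simulated twin cohort
#'
#' Group sizes are counts of complete pairs by zygosity; `n_singletons`
#' individuals are additionally generated as pairs with one member deleted,
#' so [complete_pairs()] has genuine work to do downstream. When `rA`/`rE`
#' are supplied, the first two traits are generated jointly under a bivariate
#' additive-genetic / unique-environment (AE) Cholesky structure with the
#' given additive-genetic and unique-environmental correlations (scalar or
#' `c(M, F)`); those traits must then be pure AE. `rg_os` is the cross-sex
#' additive-genetic correlation within opposite-sex DZ pairs (1 = no
#' sex-specific genetic factors).
#'
#' @param n_mz,n_dzss,n_dzos Numbers of complete pairs per zygosity group.
#' @param traits List of [sim_trait()] specifications.
#' @param n_singletons Number of singleton twins.
#' @param rA,rE Optional cross-trait correlations for the first two traits.
#' @param rg_os Cross-sex additive-genetic correlation in DZos pairs, in
#'   `[0, 1]`.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_mz, n_dzss, n_dzos, traits,
                              n_singletons = 0, rA = NULL, rE = NULL,
                              rg_os = 1) {
  stopifnot(n_mz >= 0, n_dzss >= 0, n_dzos >= 0, n_singletons >= 0)
  if (n_mz + n_dzss + n_dzos + n_singletons == 0) {
    stop("at least one pair group must be nonempty")
  }
  if (!length(traits)) stop("at least one trait must be specified")
  if (inherits(traits, "sim_trait")) traits <- list(traits)
  for (tr in traits) stopifnot(inherits(tr, "sim_trait"))
  nm <- vapply(traits, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicated trait names")
  names(traits) <- nm
  if (!is.null(rA) || !is.null(rE)) {
    if (length(traits) < 2) stop("cross-trait structure needs two traits")
    if (is.null(rA)) rA <- 0
    if (is.null(rE)) rE <- 0
    rA <- if (length(rA) == 1) c(M = rA, F = rA) else stats::setNames(rA, c("M", "F"))
    rE <- if (length(rE) == 1) c(M = rE, F = rE) else stats::setNames(rE, c("M", "F"))
    stopifnot(all(abs(rA) <= 1), all(abs(rE) <= 1))
    for (i in 1:2) {
      if (any(traits[[i]]$c2 > 0) || any(traits[[i]]$d2 > 0)) {
        stop("cross-trait (Cholesky) traits must be AE-only")
      }
    }
  }
  if (rg_os < 0 || rg_os > 1) stop("rg_os must be in [0, 1]")
  structure(list(n_mz = as.integer(n_mz), n_dzss = as.integer(n_dzss),
                 n_dzos = as.integer(n_dzos),
                 n_singletons = as.integer(n_singletons),
                 traits = traits, rA = rA, rE = rE, rg_os = rg_os),
            class = "simulation_config")
}

#' Default cohort configuration
#'
#' Mirrors the design of a young-adult Finnish twin cohort: 254 MZ, 176
#' same-sex DZ and 156 opposite-sex DZ complete pairs plus 121 singleton
#' twins, with a sense-of-coherence (SOC) score and a depressive-symptoms
#' score carrying AE-dominated, sex-specific variance structure
#' (heritabilities 0.30/0.51 and 0.37/0.63 for men/women) and strong negative
#' genetic overlap (rA about -0.8).
#'
#' @return A [simulation_config()].
#' @export
default_config <- function() {
  simulation_config(
    n_mz = 254, n_dzss = 176, n_dzos = 156, n_singletons = 121,
    traits = list(
      sim_trait("soc", a2 = c(0.30, 0.51),
                mean = c(64.1, 61.7), sd = c(10.00, 10.63)),
      sim_trait("depression", a2 = c(0.37, 0.63),
                mean = c(13.6, 15.3), sd = c(4.10, 4.94))
    ),
    rA = c(-0.82, -0.84), rE = c(-0.46, -0.43)
  )
}

#' Simulate a twin cohort with known variance-component structure
#'
#' Latent factors are drawn directly from the classical twin-design
#' correlation structure: additive-genetic factors correlate 1 within MZ and
#' 0.5 within DZ pairs (0.5 * `rg_os` in opposite-sex pairs), dominance
#' factors 1 (MZ) and 0.25 (DZ), shared-environment factors 1 in all pairs
#' and unique-environment factors 0. Each trait is a path-weighted sum of its
#' factors, so on the standardized scale the within-pair covariance is
#' exactly `a2 + c2 + d2` (MZ), `0.5 a2 + c2 + 0.25 d2` (DZss) and
#' `0.5 rg aM aF + c2` (DZos). Sexes of same-sex pairs are assigned at
#' random with equal probability.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; identical `(config, seed)` give identical
#'   cohorts.
#' @return A [twin_cohort()] carrying a `"sim"` attribute with the config,
#'   seed and per-individual standardized additive-genetic factor scores
#'   (used by [attach_pgs()]).
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  # singleton twins are generated as extra pairs, one member dropped later
  extra <- config$n_singletons
  zyg_extra <- rep(c("MZ", "DZss", "DZos"), length.out = extra)
  zyg <- c(rep("MZ", config$n_mz), rep("DZss", config$n_dzss),
           rep("DZos", config$n_dzos), zyg_extra)
  np <- length(zyg)
  pair_id <- sprintf("P%05d", seq_len(np))
  same_sex <- zyg %in% c("MZ", "DZss")
  sex1 <- ifelse(same_sex, ifelse(stats::runif(np) < 0.5, "M", "F"), "M")
  sex2 <- ifelse(same_sex, sex1, "F")

  kA <- ifelse(zyg == "MZ", 1, ifelse(zyg == "DZss", 0.5, 0.5 * config$rg_os))
  kD <- ifelse(zyg == "MZ", 1, 0.25)

  tr_names <- names(config$traits)
  ntr <- length(tr_names)
  Y1 <- matrix(NA_real_, np, ntr, dimnames = list(NULL, tr_names))
  Y2 <- Y1
  A1 <- Y1  # standardized additive factor per individual, kept for attach_pgs
  A2 <- Y1

  joint <- !is.null(config$rA)
  for (j in seq_len(ntr)) {
    if (joint && j <= 2) next
    tr <- config$traits[[j]]
    FA <- draw_mixed_factors(np, kA, zyg)
    FD <- draw_mixed_factors(np, kD, zyg)
    FC <- stats::rnorm(np)
    E1 <- stats::rnorm(np); E2 <- stats::rnorm(np)
    p1 <- path_of(tr, sex1); p2 <- path_of(tr, sex2)
    Y1[, j] <- p1$a * FA[, 1] + p1$c * FC + p1$d * FD[, 1] + p1$e * E1
    Y2[, j] <- p2$a * FA[, 2] + p2$c * FC + p2$d * FD[, 2] + p2$e * E2
    A1[, j] <- FA[, 1]; A2[, j] <- FA[, 2]
  }
  if (joint) {
    # bivariate AE Cholesky: 2 additive and 2 unique factor dimensions
    FA_1 <- draw_mixed_factors(np, kA, zyg)  # factor dim 1, both twins
    FA_2 <- draw_mixed_factors(np, kA, zyg)  # factor dim 2
    for (tw in 1:2) {
      sx <- if (tw == 1) sex1 else sex2
      FA <- cbind(if (tw == 1) FA_1[, 1] else FA_1[, 2],
                  if (tw == 1) FA_2[, 1] else FA_2[, 2])
      FE <- cbind(stats::rnorm(np), stats::rnorm(np))
      for (s in c("M", "F")) {
        rows <- which(sx == s)
        if (!length(rows)) next
        L <- biv_paths(config, s)
        y <- FA[rows, , drop = FALSE] %*% t(L$A) +
             FE[rows, , drop = FALSE] %*% t(L$E)
        a_std <- FA[rows, , drop = FALSE] %*% t(L$A)
        h <- sqrt(diag(L$A %*% t(L$A)))
        a_std <- sweep(a_std, 2, ifelse(h > 0, h, 1), "/")
        if (tw == 1) {
          Y1[rows, 1:2] <- y; A1[rows, 1:2] <- a_std
        } else {
          Y2[rows, 1:2] <- y; A2[rows, 1:2] <- a_std
        }
      }
    }
  }

  # affine map to observed scale, by sex
  for (j in seq_len(ntr)) {
    tr <- config$traits[[j]]
    Y1[, j] <- tr$mean[sex1] + tr$sd[sex1] * Y1[, j]
    Y2[, j] <- tr$mean[sex2] + tr$sd[sex2] * Y2[, j]
  }

  d1 <- data.frame(pair_id = pair_id, member = 1L, zygosity = zyg, sex = sex1,
                   stringsAsFactors = FALSE)
  d2 <- data.frame(pair_id = pair_id, member = 2L, zygosity = zyg, sex = sex2,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ntr)) {
    d1[[tr_names[j]]] <- Y1[, j]
    d2[[tr_names[j]]] <- Y2[, j]
  }
  out <- rbind(d1, d2)
  ord <- order(out$pair_id, out$member)
  out <- out[ord, , drop = FALSE]
  Afac <- rbind(A1, A2)[ord, , drop = FALSE]

  # delete member 2 of the trailing 'extra' pairs to create singletons
  if (extra > 0) {
    singleton_ids <- pair_id[np - extra + seq_len(extra)]
    drop <- out$pair_id %in% singleton_ids & out$member == 2L
    out <- out[!drop, , drop = FALSE]
    Afac <- Afac[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out <- twin_cohort(out)
  attr(out, "sim") <- list(config = config, seed = as.integer(seed), A = Afac)
  out
}

# per-pair factor draws where the within-pair correlation varies by row
draw_mixed_factors <- function(np, k, zyg) {
  f <- matrix(stats::rnorm(2 * np), np, 2)
  out <- f
  out[, 2] <- k * f[, 1] + sqrt(pmax(0, 1 - k^2)) * f[, 2]
  exact <- k >= 1
  out[exact, 2] <- f[exact, 1]
  out
}

path_of <- function(tr, sex) {
  list(a = sqrt(tr$a2[sex]), c = sqrt(tr$c2[sex]),
       d = sqrt(tr$d2[sex]), e = sqrt(tr$e2[sex]))
}

# lower-triangular AE Cholesky path matrices implied by (h2_1, h2_2, rA, rE)
biv_paths <- function(config, sex) {
  t1 <- config$traits[[1]]; t2 <- config$traits[[2]]
  h1 <- t1$a2[sex]; h2 <- t2$a2[sex]
  e1 <- t1$e2[sex]; e2 <- t2$e2[sex]
  rA <- config$rA[sex]; rE <- config$rE[sex]
  list(A = chol2_lower(h1, h2, rA), E = chol2_lower(e1, e2, rE))
}

# lower Cholesky factor of [[v1, r*sqrt(v1 v2)], [., v2]]
chol2_lower <- function(v1, v2, r) {
  l11 <- sqrt(v1)
  l21 <- if (l11 > 0) r * sqrt(v2) else 0
  l22 <- sqrt(pmax(0, v2 - l21^2))
  matrix(c(l11, l21, 0, l22), 2, 2, byrow = FALSE)
}

#' Attach a calibrated polygenic score to a simulated cohort
#'
#' Builds a standardized score from each individual's additive-genetic factor
#' for `trait` plus an independent *genetic* component (sharing the twin
#' correlation structure: 1 within MZ, 0.5 within DZ pairs), weighted so the
#' population squared correlation between score and trait equals `pgs_R2`.
#' Because both components are genetic, MZ co-twins receive exactly equal
#' scores. A score cannot explain more trait variance than the trait's
#' additive-genetic share, so `pgs_R2` must not exceed the simulated
#' heritability in either sex.
#'
#' @param cohort A cohort produced by [simulate_cohort()].
#' @param trait Trait the score targets.
#' @param pgs_R2 Population variance share the score explains, in `[0, 1)`.
#' @param name Column name for the score (default `pgs_<trait>`).
#' @param seed Integer seed for the independent genetic component.
#' @return The cohort with one added standardized score column; all existing
#'   columns are untouched.
#' @export
attach_pgs <- function(cohort, trait, pgs_R2, name = paste0("pgs_", trait),
                       seed) {
  stopifnot(inherits(cohort, "twin_cohort"))
  sim <- attr(cohort, "sim")
  if (is.null(sim)) stop("attach_pgs needs a cohort from simulate_cohort()")
  if (!trait %in% colnames(sim$A)) stop("unknown trait: ", trait)
  if (pgs_R2 < 0 || pgs_R2 >= 1) stop("pgs_R2 must be in [0, 1)")
  a2 <- sim$config$traits[[trait]]$a2
  if (any(pgs_R2 > a2 + 1e-12)) {
    stop("pgs_R2 (", pgs_R2, ") exceeds the simulated heritability of '",
         trait, "' (", min(a2), "); a genetic score cannot explain more ",
         "than the additive-genetic share", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  # independent genetic factor with the usual twin correlation structure
  ids <- as.character(cohort$pair_id)
  upairs <- unique(ids)
  zyg <- cohort$zygosity[match(upairs, ids)]
  k <- ifelse(zyg == "MZ", 1,
              ifelse(zyg == "DZss", 0.5, 0.5 * sim$config$rg_os))
  G <- draw_mixed_factors(length(upairs), k, zyg)
  gi <- G[cbind(match(ids, upairs), cohort$member)]

  w <- pgs_R2 / a2          # per-sex weight on the trait's own A factor
  w[a2 == 0] <- 0
  ws <- w[cohort$sex]
  score <- sqrt(ws) * sim$A[, trait] + sqrt(1 - ws) * gi
  cohort[[name]] <- as.numeric(score)
  sim$A <- sim$A  # unchanged; scores are not re-usable as factors
  attr(cohort, "sim") <- sim
  cohort
}
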