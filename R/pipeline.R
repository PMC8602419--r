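#' Run the full twin-analysis pipeline from one configuration
#'
#' Orchestrates simulate/load -> descriptives -> univariate variance
#' decomposition -> bivariate Cholesky -> polygenic-score association, and
#' writes report-style tables to `out_dir`:
#'
#' * `table1.csv` - per-trait descriptives by sex with clustered
#'   sex-difference p-values;
#' * `table2.csv` - standardized a2/e2 with profile CIs per sex (AE model);
#' * `table3.csv` - phenotypic, genetic and environmental correlations of
#'   the focal trait with each other trait, with explained fractions;
#' * `table4.csv` - polygenic-score betas, CIs and R2 per sex;
#' * `modelfit.csv` - likelihood-ratio model-comparison rows per trait;
#' * `log.txt` - seed, package version and per-stage pair counts (including
#'   singletons removed).
#'
#' Human-readable tables are rounded to report precision (proportions and
#' correlations 2 dp, p-values 4 dp or `<0.001`); full-precision copies are
#' written alongside with suffix `_full`. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config A list with either `input` (path to a cohort CSV) or
#'   `simulation` (a [simulation_config()]), and optionally: `focal_trait`
#'   (default: first trait), `traits` (default: all numeric non-score
#'   columns), `scores` (PGS columns or, for simulated input, a named list
#'   `list(name = R2)` of scores to attach), `alpha` (default 0.05),
#'   `n_tests` (Bonferroni count, default: number of traits), `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed tables and fits.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!is.null(config$input) && !is.null(config$simulation)) {
    stop("config must contain exactly one of 'input' or 'simulation'")
  }
  if (is.null(config$input) && is.null(config$simulation)) {
    stop("config must contain one of 'input' or 'simulation'")
  }
  alpha <- config$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("twinvar pipeline log",
                 paste0("package version: ",
                        as.character(utils::packageVersion("twinvar"))),
                 paste0("seed: ", seed))

  stage <- "load"
  result <- tryCatch({
    if (!is.null(config$input)) {
      cohort <- read_cohort(config$input)
      log_lines <- c(log_lines, paste0("input: ", config$input))
    } else {
      cohort <- simulate_cohort(config$simulation, seed = seed)
      log_lines <- c(log_lines, "input: simulated cohort")
      if (!is.null(config$scores) && is.list(config$scores)) {
        for (i in seq_along(config$scores)) {
          nm <- names(config$scores)[i]
          tr0 <- config$focal_trait %||% names(config$simulation$traits)[1]
          cohort <- attach_pgs(cohort, tr0, config$scores[[i]],
                               name = nm, seed = seed + i)
        }
      }
    }
    score_cols <- if (is.list(config$scores)) names(config$scores)
                  else config$scores
    traits <- config$traits %||% setdiff(trait_names(cohort), score_cols)
    focal <- config$focal_trait %||% traits[1]
    n_tests <- config$n_tests %||% length(traits)
    log_lines <- c(log_lines,
                   paste0("individuals: ", nrow(cohort)),
                   paste0("traits: ", paste(traits, collapse = ", ")),
                   paste0("bonferroni threshold (alpha=", alpha, ", k=",
                          n_tests, "): ",
                          sprintf("%.4f", bonferroni_threshold(alpha, n_tests))))

    stage <- "descriptives"
    tab1 <- describe_table(cohort, traits)

    stage <- "complete-pairs"
    cp <- complete_pairs(cohort)
    log_lines <- c(log_lines,
                   paste0("individuals without a co-twin removed: ",
                          attr(cp, "n_removed")),
                   paste0("complete pairs: ", nrow(cp) / 2))

    stage <- "univariate"
    tab2_rows <- list(); fit_rows <- list(); uni_fits <- list()
    for (tr in traits) {
      sel <- selection_sequence(cohort, tr, sex = "stratified")
      fit_rows[[tr]] <- cbind(trait = tr, sel$comparisons)
      fit <- sel$fits$AE
      uni_fits[[tr]] <- fit
      for (s in c("M", "F")) {
        ci_a <- profile_ci(fit, "a2", sex = s)
        tab2_rows[[paste(tr, s)]] <- data.frame(
          trait = tr, sex = s,
          a2 = fit$proportions[[s]][["a2"]],
          a2_LL = ci_a$lower, a2_UL = ci_a$upper,
          e2 = fit$proportions[[s]][["e2"]],
          e2_LL = 1 - ci_a$upper, e2_UL = 1 - ci_a$lower,
          stringsAsFactors = FALSE)
      }
      log_lines <- c(log_lines, paste0("univariate [", tr, "]: pairs used ",
                                       fit$n_pairs))
    }
    tab2 <- do.call(rbind, tab2_rows)
    modelfit <- do.call(rbind, fit_rows)

    stage <- "bivariate"
    tab3_rows <- list(); biv_fits <- list()
    for (tr in setdiff(traits, focal)) {
      bf <- fit_bivariate(cohort, focal, tr, stratify_sex = TRUE)
      biv_fits[[tr]] <- bf
      for (s in c("M", "F")) {
        d <- bf$decomposition[[s]]
        tab3_rows[[paste(tr, s)]] <- data.frame(
          trait = tr, sex = s,
          r = d$r, r_LL = d$r_ci[1], r_UL = d$r_ci[2],
          rA = d$rA, rA_LL = d$rA_ci$lower, rA_UL = d$rA_ci$upper,
          pct_A = d$fracA,
          rE = d$rE, rE_LL = d$rE_ci$lower, rE_UL = d$rE_ci$upper,
          pct_E = d$fracE,
          shared_genetic_pct = shared_variance_pct(d$rA),
          stringsAsFactors = FALSE)
      }
      log_lines <- c(log_lines, paste0("bivariate [", focal, "-", tr,
                                       "]: pairs used ", bf$n_pairs))
    }
    tab3 <- if (length(tab3_rows)) do.call(rbind, tab3_rows) else NULL

    stage <- "pgs"
    tab4 <- NULL
    if (length(score_cols)) {
      tab4 <- pgs_table(cohort, focal, score_cols, stratify_sex = TRUE)
    }

    stage <- "write"
    wr <- function(tab, name, round_cols = NULL, p_cols = NULL) {
      if (is.null(tab)) return(invisible(NULL))
      rownames(tab) <- NULL
      utils::write.csv(tab, file.path(out_dir, paste0(name, "_full.csv")),
                       row.names = FALSE)
      h <- tab
      for (cc in names(h)) {
        if (!is.numeric(h[[cc]])) next
        if (cc %in% p_cols) {
          h[[cc]] <- ifelse(h[[cc]] < 0.001, "<0.001", sprintf("%.4f", h[[cc]]))
        } else if (is.null(round_cols) || cc %in% round_cols) {
          h[[cc]] <- sprintf("%.2f", h[[cc]])
        }
      }
      utils::write.csv(h, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
    wr(tab1, "table1", p_cols = "p_sexdiff")
    wr(tab2, "table2")
    wr(tab3, "table3")
    wr(tab4, "table4", p_cols = "interaction_p")
    wr(modelfit, "modelfit", p_cols = c("p", "p_mixture"))
    writeLines(log_lines, file.path(out_dir, "log.txt"))
    list(table1 = tab1, table2 = tab2, table3 = tab3, table4 = tab4,
         modelfit = modelfit, univariate = uni_fits, bivariate = biv_fits,
         cohort = cohort)
  }, error = function(e) {
    writeLines(c(log_lines, paste0("FAILED at stage: ", stage),
                 conditionMessage(e)),
               file.path(out_dir, "log.txt"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' Maps a structured text file onto the `config` list accepted by
#' [run_pipeline()]; a `simulation:` block mirrors the
#' [simulation_config()] fields with a `traits:` list of per-trait
#' `a2`/`c2`/`d2`/`e2`/`mean`/`sd` entries (scalar or `[M, F]`).
#'
#' @param path Path to a YAML file.
#' @return A config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    s <- raw$simulation
    traits <- lapply(names(s$traits), function(nm) {
      tr <- s$traits[[nm]]
      sim_trait(nm,
                a2 = unlist(tr$a2 %||% 0), c2 = unlist(tr$c2 %||% 0),
                d2 = unlist(tr$d2 %||% 0),
                e2 = if (is.null(tr$e2)) NULL else unlist(tr$e2),
                mean = unlist(tr$mean %||% 0), sd = unlist(tr$sd %||% 1))
    })
    raw$simulation <- simulation_config(
      n_mz = s$n_mz %||% 0, n_dzss = s$n_dzss %||% 0,
      n_dzos = s$n_dzos %||% 0, n_singletons = s$n_singletons %||% 0,
      traits = traits,
      rA = if (is.null(s$rA)) NULL else unlist(s$rA),
      rE = if (is.null(s$rE)) NULL else unlist(s$rE),
      rg_os = s$rg_os %||% 1)
  }
  raw
}
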