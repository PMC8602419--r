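#' Twin cohort container
#'
#' A `twin_cohort` is a data frame with one row per twin individual and the
#' mandatory columns `pair_id` (pair identifier), `member` (1 or 2 within the
#' pair), `zygosity` (`"MZ"`, `"DZss"` or `"DZos"`) and `sex` (`"M"` or
#' `"F"`). Any further numeric columns are quantitative traits or polygenic
#' scores; missing values are coded `NA`, never as sentinels.
#'
#' Structural invariants enforced on construction: a `pair_id` occurs at most
#' twice and with distinct `member` indices; both members of a pair carry the
#' same zygosity; MZ and same-sex DZ (DZss) pairs are sex-concordant while
#' opposite-sex DZ (DZos) pairs are sex-discordant.
#'
#' @param data A data frame with the columns described above.
#' @return An object of class `twin_cohort` (also a `data.frame`).
#' @examples
#' d <- data.frame(pair_id = c(1, 1), member = c(1, 2),
#'                 zygosity = "MZ", sex = "F", y = c(0.1, -0.2))
#' twin_cohort(d)
#' @export
twin_cohort <- function(data) {
  data <- as.data.frame(data)
  validate_cohort(data)
  class(data) <- c("twin_cohort", "data.frame")
  data
}

validate_cohort <- function(data) {
  required <- c("pair_id", "member", "zygosity", "sex")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(data$member %in% c(1L, 2L))) {
    stop("'member' must be 1 or 2", call. = FALSE)
  }
  if (!all(data$zygosity %in% c("MZ", "DZss", "DZos"))) {
    stop("'zygosity' must be one of MZ, DZss, DZos", call. = FALSE)
  }
  if (!all(data$sex %in% c("M", "F"))) {
    stop("'sex' must be M or F", call. = FALSE)
  }
  trait_cols <- setdiff(names(data), required)
  for (tc in trait_cols) {
    if (!is.numeric(data[[tc]])) {
      stop("trait column '", tc, "' is not numeric", call. = FALSE)
    }
  }
  if (nrow(data)) {
    id <- as.character(data$pair_id)
    tab <- table(id)
    if (any(tab > 2)) {
      stop("pair_id occurs more than twice: ",
           paste(names(tab)[tab > 2], collapse = ", "), call. = FALSE)
    }
    sp <- split(seq_len(nrow(data)), id)
    for (idx in sp) {
      if (length(idx) == 2L) {
        if (data$member[idx[1]] == data$member[idx[2]]) {
          stop("pair ", id[idx[1]], " has duplicated member index", call. = FALSE)
        }
        if (data$zygosity[idx[1]] != data$zygosity[idx[2]]) {
          stop("pair ", id[idx[1]], " has discordant zygosity", call. = FALSE)
        }
        same_sex <- data$sex[idx[1]] == data$sex[idx[2]]
        zyg <- data$zygosity[idx[1]]
        if (zyg %in% c("MZ", "DZss") && !same_sex) {
          stop("pair ", id[idx[1]], " is ", zyg, " but sex-discordant", call. = FALSE)
        }
        if (zyg == "DZos" && same_sex) {
          stop("pair ", id[idx[1]], " is DZos but sex-concordant", call. = FALSE)
        }
      }
    }
  }
  invisible(data)
}

#' Trait columns of a cohort
#'
#' @param cohort A [twin_cohort()].
#' @return Character vector of non-structural (trait / score) column names.
#' @export
trait_names <- function(cohort) {
  setdiff(names(cohort), c("pair_id", "member", "zygosity", "sex"))
}

#' Restrict a cohort to complete pairs
#'
#' Keeps only individuals whose co-twin is present and, when `traits` is
#' given, whose pair has non-missing values on all requested traits for both
#' members. Singleton twins (pairs with one member) are removed. The number
#' of individuals dropped is recorded in the `"n_removed"` attribute.
#'
#' @param cohort A [twin_cohort()].
#' @param traits Optional character vector of trait columns that must be
#'   observed for both pair members.
#' @return A `twin_cohort` of complete pairs; `attr(, "n_removed")` holds the
#'   number of individuals removed.
#' @export
complete_pairs <- function(cohort, traits = NULL) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (!is.null(traits)) {
    bad <- setdiff(traits, names(cohort))
    if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "))
  }
  id <- as.character(cohort$pair_id)
  ok_row <- rep(TRUE, nrow(cohort))
  if (!is.null(traits)) {
    for (tr in traits) ok_row <- ok_row & !is.na(cohort[[tr]])
  }
  # a pair survives iff it contributes exactly two rows, both individually ok
  n_ok <- tapply(ok_row, id, function(z) sum(z) * (length(z) == 2L))
  keep_pair <- names(n_ok)[!is.na(n_ok) & n_ok == 2L]
  keep <- id %in% keep_pair & ok_row
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  att <- attributes(cohort)
  for (a in setdiff(names(att), c("names", "row.names", "class"))) {
    if (a == "sim") {
      sim <- att[[a]]
      if (!is.null(sim$A)) {
        # rows added after simulation make the latent factors stale
        if (nrow(sim$A) != length(keep)) next
        sim$A <- sim$A[keep, , drop = FALSE]
      }
      attr(out, a) <- sim
    } else {
      attr(out, a) <- att[[a]]
    }
  }
  attr(out, "n_removed") <- nrow(cohort) - nrow(out)
  out
}

#' Read / write a twin cohort as CSV
#'
#' The on-disk layout is a plain CSV with header columns `pair_id`, `member`,
#' `zygosity`, `sex` followed by trait and score columns; missing values are
#' empty fields.
#'
#' @param path File path.
#' @return `read_cohort` returns a [twin_cohort()]; `write_cohort` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path) {
  # sex/zygosity must stay character ("F" would otherwise parse as FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"),
                       colClasses = c(pair_id = "character",
                                      member = "integer",
                                      zygosity = "character",
                                      sex = "character"))
  twin_cohort(d)
}

#' @rdname read_cohort
#' @param cohort A [twin_cohort()].
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "twin_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.twin_cohort <- function(x, ...) {
  id <- as.character(x$pair_id)
  npair <- sum(table(id) == 2L)
  cat("<twin_cohort> ", nrow(x), " individuals, ", npair, " complete pairs (",
      paste(names(table(x$zygosity)), as.integer(table(x$zygosity)),
            sep = ":", collapse = " "), ")\n", sep = "")
  cat("traits: ", paste(trait_names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}
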