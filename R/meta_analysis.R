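#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' Combines per-cohort association estimates METAL-style: weights are
#' inverse squared standard errors, the combined z is referred to the normal
#' distribution, Cochran's Q and I2 quantify between-cohort heterogeneity
#' (I2 >= 75% conventionally read as considerable), and a direction string
#' records each cohort's sign in a fixed configured order.
#'
#' @name meta_analysis
NULL

#' IVW fixed-effects combination
#'
#' @param Bs Numeric vector of per-cohort effects.
#' @param SEs Matching standard errors, all > 0.
#' @return List with combined `B`, `SE`, `z`, two-sided normal `p`, and `k`.
#' @export
ivw_fixed <- function(Bs, SEs) {
  stopifnot(length(Bs) == length(SEs), length(Bs) >= 1L)
  if (any(!is.finite(SEs)) || any(SEs <= 0)) {
    stop("ivw_fixed: standard errors must be positive")
  }
  w <- 1 / SEs^2
  B <- sum(w * Bs) / sum(w)
  SE <- 1 / sqrt(sum(w))
  z <- B / SE
  list(B = B, SE = SE, z = z,
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       k = length(Bs))
}

#' Cochran's Q and I-squared
#'
#' @inheritParams ivw_fixed
#' @return List with `Q` and `I2` (percent in [0, 100]); both `NA` when
#'   fewer than two estimates are supplied.
#' @export
heterogeneity <- function(Bs, SEs) {
  k <- length(Bs)
  if (k < 2L) return(list(Q = NA_real_, I2 = NA_real_))
  w <- 1 / SEs^2
  B <- sum(w * Bs) / sum(w)
  Q <- sum(w * (Bs - B)^2)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  list(Q = Q, I2 = I2)
}

#' Per-cohort sign string
#'
#' One character per configured cohort: `+` for a positive effect, `-` for
#' negative, `?` where the cohort contributed no estimate (or a zero/flagged
#' one).
#'
#' @param Bs Named numeric vector of effects (names = cohorts present).
#' @param cohort_order Character vector fixing the cohort order.
#' @return Single string of length `length(cohort_order)`.
#' @export
direction_string <- function(Bs, cohort_order) {
  chars <- vapply(cohort_order, function(co) {
    b <- if (co %in% names(Bs)) Bs[[co]] else NA_real_
    if (is.na(b) || b == 0) "?" else if (b > 0) "+" else "-"
  }, character(1))
  paste(chars, collapse = "")
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise alpha in (0, 1).
#' @param n_tests Number of tests, >= 1.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Weighted average
#'
#' Sample-size-weighted averaging, used e.g. to combine per-cohort adjusted
#' R-squared values into one reported number.
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights, not all zero.
#' @return `sum(w * v) / sum(w)`.
#' @export
weighted_average <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weighted_average: weights must be non-negative and not all zero")
  }
  sum(weights * values) / sum(weights)
}

#' Meta-analyze per-cohort scan tables
#'
#' Joins per-cohort association records on (snp, cpg) -- or cpg alone for the
#' Emodel -- and combines every record reported by at least one cohort
#' (METAL behaviour; `k` records how many contributed, so downstream
#' filtering to all-cohort records is possible). Flagged cohort records
#' (monomorphic, collinear, zero variance) contribute `?` to the direction
#' string and no weight.
#'
#' @param tables Named list of per-cohort scan `data.frame`s (as returned by
#'   the scan functions). Names define the cohorts.
#' @param cohort_order Cohort order for the direction string (default:
#'   `names(tables)`).
#' @return `data.frame` with `snp` (NA for Emodel records), `cpg`, combined
#'   `B`, `SE`, `z`, `p`, `Q`, `I2` (percent), `direction`, `k`, pooled `n`,
#'   and sample-size-weighted `delta_adj_r2`.
#' @export
meta_analyze <- function(tables, cohort_order = names(tables)) {
  stopifnot(length(tables) >= 1L, !is.null(names(tables)))
  dt <- data.table::rbindlist(
    lapply(names(tables), function(co) {
      d <- data.table::as.data.table(tables[[co]])
      if (!"snp" %in% names(d)) d[, snp := NA_character_]
      d[, cohort := co]
      d
    }), use.names = TRUE, fill = TRUE)
  ok <- dt[flag == "ok" & !is.na(SE) & SE > 0]

  meta_one <- function(B, SE, n, dr2, cohort) {
    m <- ivw_fixed(B, SE)
    h <- heterogeneity(B, SE)
    dirs <- direction_string(stats::setNames(B, cohort), cohort_order)
    data.table::data.table(
      B = m$B, SE = m$SE, z = m$z, p = m$p, Q = h$Q, I2 = h$I2,
      direction = dirs, k = m$k, n = sum(n),
      delta_adj_r2 = weighted_average(dr2, n))
  }
  out <- ok[, meta_one(B, SE, n, delta_adj_r2, cohort), by = .(snp, cpg)]
  out <- as.data.frame(out)
  rownames(out) <- NULL
  out
}
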