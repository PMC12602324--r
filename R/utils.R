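# data.table is used via :: but its [ methods must see this package as aware
.datatable.aware <- TRUE

#' Winsorize values at quantile-derived bounds
#'
#' Clips values outside `[Q1 - multiplier * IQR, Q3 + multiplier * IQR]` to
#' those bounds, the outlier rule applied to both the cumulative stress score
#' and (per probe) to methylation beta values. Quantiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param x Numeric vector, length >= 4, NAs not allowed.
#' @param multiplier IQR multiplier defining the clip bounds (default 3).
#' @return `x` with out-of-range values set to the nearer bound. Idempotent:
#'   applying twice equals applying once.
#' @export
winsorize_iqr <- function(x, multiplier = 3) {
  if (anyNA(x)) stop("winsorize_iqr: missing values not allowed")
  if (length(x) < 4L) stop("winsorize_iqr: need at least 4 values")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  lo <- q[1L] - multiplier * iqr
  hi <- q[2L] + multiplier * iqr
  pmin(pmax(x, lo), hi)
}

#' Fan a global seed out to reproducible child seeds
#'
#' Derives independent per-component seeds from one integer so that each
#' simulation component (genotypes, stress, methylation, mediators, each
#' cohort) is reproducible in isolation. Children stay below 2^31.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` child seeds.
#' @export
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  # LCG hop (Numerical Recipes constants) keeps children decorrelated without
  # touching the global RNG stream
  s <- as.double(seed) %% 2147483647
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (1664525 * s + 1013904223) %% 2147483647
    out[i] <- s
  }
  as.integer(out)
}

# Internal: check a probability-like scalar/vector
.check_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what))
  }
  invisible(p)
}

# Internal: drop collinear columns of a design matrix by pivoted QR,
# tolerance relative to the leading diagonal element
.drop_collinear <- function(Z, tol = 1e-8) {
  qrz <- qr(Z, tol = tol)
  keep <- sort(qrz$pivot[seq_len(qrz$rank)])
  if (length(keep) < ncol(Z)) {
    dropped <- colnames(Z)[setdiff(seq_len(ncol(Z)), keep)]
    attr(Z, "dropped") <- dropped
    Z <- Z[, keep, drop = FALSE]
  }
  Z
}

# Internal: build a full-rank nuisance design (intercept + covariates),
# expanding factors/characters to treatment-coded indicators
.build_nuisance <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  # single-level factors (e.g. one cohort, one batch) carry no information
  keep <- vapply(covariates, function(x) {
    !((is.factor(x) || is.character(x)) && length(unique(x)) < 2L)
  }, logical(1))
  covariates <- covariates[, keep, drop = FALSE]
  if (!ncol(covariates)) {
    return(matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- droplevels(covariates)
  mm <- stats::model.matrix(~ ., data = covariates)
  .drop_collinear(mm)
}
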