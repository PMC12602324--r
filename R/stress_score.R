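#' Cumulative prenatal stress scoring
#'
#' Functions that turn a raw table of ~50 pregnancy stress items into the
#' cumulative prenatal stress score: dichotomize each item into no-risk (0) /
#' risk (1), exclude subjects missing more than half the items, impute the
#' rest by predictive mean matching, average items within the four stress
#' domains (life events, contextual risk, personal stress, interpersonal
#' stress), sum the domain scores into a total in [0, 4], standardize within
#' cohort and winsorize at 3 IQR.
#'
#' @name stress_score
NULL

#' Dichotomize raw stress items into risk indicators
#'
#' Applies a per-item rule to convert raw (possibly continuous) items into
#' binary risk indicators: 0 = no risk, 1 = risk, NA propagates.
#'
#' @param raw Data frame of raw item values (subjects x items). Row order is
#'   preserved.
#' @param rules Named list, one entry per column of `raw`. Each entry is
#'   either the string `"identity"` (item already 0/1) or a list with
#'   `threshold` (numeric) and `direction` (`"ge"` risk iff value >= threshold,
#'   `"le"` risk iff value <= threshold).
#' @return Data frame of the same shape with values in {0, 1, NA}.
#' @export
dichotomize <- function(raw, rules) {
  raw <- as.data.frame(raw)
  missing_rules <- setdiff(names(raw), names(rules))
  if (length(missing_rules)) {
    stop("dichotomize: no rule for item(s): ",
         paste(missing_rules, collapse = ", "))
  }
  out <- raw
  for (item in names(raw)) {
    rule <- rules[[item]]
    x <- raw[[item]]
    if (identical(rule, "identity")) {
      bad <- !is.na(x) & !(x %in% c(0, 1))
      if (any(bad)) {
        stop(sprintf("dichotomize: item '%s' marked identity but non-binary",
                     item))
      }
      out[[item]] <- x
    } else {
      if (is.null(rule$threshold) || is.null(rule$direction)) {
        stop(sprintf("dichotomize: malformed rule for item '%s'", item))
      }
      out[[item]] <- switch(rule$direction,
        ge = as.numeric(x >= rule$threshold),
        le = as.numeric(x <= rule$threshold),
        stop(sprintf("dichotomize: unknown direction '%s' for item '%s'",
                     rule$direction, item))
      )
    }
  }
  out
}

#' Exclude subjects with high item missingness
#'
#' Removes subjects whose fraction of missing items is strictly greater than
#' `threshold` (default: more than 50% missing). A subject missing exactly
#' half the items is retained.
#'
#' @param items Data frame of dichotomized items in {0, 1, NA}.
#' @param threshold Maximum tolerated missing fraction (default 0.5).
#' @return List with `items` (retained rows, order preserved), `retained`
#'   (logical vector over input rows) and `n_excluded`.
#' @export
exclude_high_missingness <- function(items, threshold = 0.5) {
  items <- as.data.frame(items)
  frac <- rowMeans(is.na(items))
  keep <- frac <= threshold
  list(items = items[keep, , drop = FALSE],
       retained = keep,
       n_excluded = sum(!keep))
}

#' Impute missing items by predictive mean matching
#'
#' Single imputation by chained equations with predictive mean matching:
#' missing cells are initialized from observed values of the same item, then
#' for `n_iter` cycles each incomplete item is regressed (OLS) on all other
#' items, and each missing cell receives the observed value of one of the
#' `k_donors` donors whose predicted means are nearest to the missing cell's
#' prediction. Donor candidate ties are broken by lowest subject index; the
#' donor draw itself is seeded, so the result is deterministic given `seed`.
#' Because donors contribute observed values, imputed binary items stay
#' binary.
#'
#' @param items Data frame of items in {0, 1, NA} (subjects already past the
#'   missingness exclusion).
#' @param k_donors Number of nearest donors to draw from (default 5).
#' @param n_iter Number of chained-equation cycles (default 60).
#' @param seed Integer seed for donor draws.
#' @return Data frame with no missing values.
#' @export
impute_pmm <- function(items, k_donors = 5, n_iter = 60, seed = 1L) {
  items <- as.data.frame(items)
  X <- as.matrix(items)
  n <- nrow(X)
  all_missing <- colSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    stop("impute_pmm: item(s) 100% missing: ",
         paste(colnames(X)[all_missing], collapse = ", "))
  }
  few_donors <- colSums(!is.na(X)) < k_donors
  if (any(few_donors)) {
    stop("impute_pmm: fewer than k_donors observed values for item(s): ",
         paste(colnames(X)[few_donors], collapse = ", "))
  }
  miss <- is.na(X)
  if (!any(miss)) return(items)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  # initialize missing cells by sampling observed values of the same item
  for (j in which(colSums(miss) > 0L)) {
    obs <- X[!miss[, j], j]
    X[miss[, j], j] <- sample(obs, sum(miss[, j]), replace = TRUE)
  }

  incomplete <- which(colSums(miss) > 0L)
  for (iter in seq_len(n_iter)) {
    for (j in incomplete) {
      mis_j <- miss[, j]
      obs_j <- !mis_j
      Zj <- cbind(1, X[, -j, drop = FALSE])
      fit <- stats::lm.fit(Zj[obs_j, , drop = FALSE], X[obs_j, j])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred <- drop(Zj %*% beta)
      pred_obs <- pred[obs_j]
      obs_idx <- which(obs_j)
      for (i in which(mis_j)) {
        d <- abs(pred_obs - pred[i])
        # k nearest donors; ties broken by lowest subject index
        ord <- order(d, obs_idx)
        donors <- obs_idx[ord[seq_len(min(k_donors, length(ord)))]]
        X[i, j] <- X[donors[sample.int(length(donors), 1L)], j]
      }
    }
  }
  out <- as.data.frame(X)
  rownames(out) <- rownames(items)
  out
}

#' Domain scores and cumulative total
#'
#' Averages complete binary items within each of the four stress domains and
#' sums the four domain means into the cumulative total (range 0 to 4).
#'
#' @param items Complete data frame of binary items.
#' @param mapping Named character vector: item name -> domain. Domains must be
#'   among `life_events`, `contextual`, `personal`, `interpersonal`.
#' @return Data frame with the four domain scores (each in [0, 1]) and
#'   `total` in [0, 4], one row per subject.
#' @export
domain_and_total <- function(items, mapping) {
  items <- as.data.frame(items)
  domains <- c("life_events", "contextual", "personal", "interpersonal")
  if (anyNA(items)) stop("domain_and_total: items must be complete")
  unknown <- setdiff(unique(mapping), domains)
  if (length(unknown)) {
    stop("domain_and_total: unknown domain(s): ",
         paste(unknown, collapse = ", "))
  }
  unmapped <- setdiff(names(items), names(mapping))
  if (length(unmapped)) {
    stop("domain_and_total: unmapped item(s): ",
         paste(unmapped, collapse = ", "))
  }
  out <- lapply(domains, function(d) {
    cols <- names(mapping)[mapping == d]
    cols <- intersect(cols, names(items))
    if (!length(cols)) stop(sprintf("domain_and_total: empty domain '%s'", d))
    rowMeans(items[, cols, drop = FALSE])
  })
  names(out) <- domains
  out <- as.data.frame(out)
  out$total <- rowSums(out)
  rownames(out) <- rownames(items)
  out
}

#' Standardize a score within cohorts
#'
#' Centers and scales to unit variance (denominator n - 1) separately within
#' each cohort.
#'
#' @param values Numeric vector.
#' @param cohort Cohort labels, same length as `values`.
#' @return Numeric vector of z-values; each cohort has mean 0 and SD 1.
#' @export
standardize_within_cohort <- function(values, cohort) {
  stopifnot(length(values) == length(cohort))
  out <- numeric(length(values))
  for (g in unique(cohort)) {
    idx <- cohort == g
    v <- values[idx]
    if (sum(idx) < 2L) {
      stop(sprintf("standardize_within_cohort: cohort '%s' has < 2 values", g))
    }
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("standardize_within_cohort: zero variance in cohort '%s'", g))
    }
    out[idx] <- (v - mean(v)) / s
  }
  out
}

#' Full stress-score construction for one cohort
#'
#' Convenience wrapper running the fixed order of operations: dichotomize,
#' exclude > 50% missing, impute (PMM), domain/total, then (optionally, when
#' `standardize = TRUE`) within-cohort standardization and 3-IQR
#' winsorization of the total.
#'
#' @param raw Raw item table (subjects x items).
#' @param rules Dichotomization rules (see [dichotomize()]).
#' @param mapping Item -> domain mapping (see [domain_and_total()]).
#' @param seed Seed for the imputation donor draws.
#' @param standardize Standardize + winsorize the total (default TRUE).
#' @return Data frame of domain scores, `total`, and (if requested) `z`
#'   (standardized total) and `z_winsorized`; rows are the retained subjects.
#' @export
build_stress_score <- function(raw, rules, mapping, seed = 1L,
                               standardize = TRUE) {
  items <- dichotomize(raw, rules)
  kept <- exclude_high_missingness(items)
  complete <- impute_pmm(kept$items, seed = seed)
  score <- domain_and_total(complete, mapping)
  if (standardize) {
    score$z <- standardize_within_cohort(score$total,
                                         rep("all", nrow(score)))
    score$z_winsorized <- winsorize_iqr(score$z)
  }
  attr(score, "n_excluded") <- kept$n_excluded
  score
}
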