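#' Follow-up analyses: stress-domain decomposition and mediation
#'
#' For CpGs significant in the main scans: (1) refit with the four stress
#' domains (life events, contextual risk, personal stress, interpersonal
#' stress) entered jointly -- plus their genotype interactions when a SNP is
#' supplied -- to isolate the unique contribution of each domain; (2) test
#' mediation of the stress effect on methylation by candidate mediators
#' (prenatal smoking, alcohol, gestational age, birth weight), each modeled
#' separately, by the product of coefficients with a Bonferroni threshold of
#' 0.0125 (0.05 / 4 mediators).
#'
#' @name followup
NULL

#' Stress-domain decomposition of one CpG
#'
#' Without genotype: fits `y ~ d1 + d2 + d3 + d4 + C` and reports each
#' domain's coefficient. With genotype `g` (dominant-coded): fits
#' `y ~ g + d1 + ... + d4 + g:d1 + ... + g:d4 + C` and reports each domain's
#' interaction coefficient. A domain is flagged as contributing uniquely
#' when its p-value is below `alpha` (default 0.05).
#'
#' @param y Methylation vector for one CpG.
#' @param domains Data frame of the four domain scores.
#' @param g Optional dominant-coded genotype vector; switches to
#'   interaction mode.
#' @param covariates Optional covariate data frame.
#' @param alpha Flag threshold (default 0.05).
#' @return Data frame with one row per domain: `domain`, `term` (`"main"` or
#'   `"interaction"`), `B`, `SE`, `t`, `p`, `unique_contribution`.
#' @export
domain_decomposition <- function(y, domains, g = NULL, covariates = NULL,
                                 alpha = 0.05) {
  domains <- as.data.frame(domains)
  stopifnot(ncol(domains) == 4L, nrow(domains) == length(y))
  cc <- stats::cor(domains)
  if (any(abs(cc[upper.tri(cc)]) >= 1 - 1e-12)) {
    stop("domain_decomposition: perfectly collinear domain scores")
  }
  n <- length(y)
  Z <- .build_nuisance(covariates, n)
  D <- as.matrix(domains)
  if (is.null(g)) {
    X <- cbind(Z, D)
    terms <- ncol(Z) + seq_len(4L)
    kind <- "main"
  } else {
    stopifnot(length(g) == n)
    X <- cbind(Z, g = g, D, D * g)
    colnames(X)[(ncol(Z) + 6L):(ncol(Z) + 9L)] <-
      paste0(colnames(domains), ":g")
    terms <- ncol(Z) + 5L + seq_len(4L)
    kind <- "interaction"
  }
  out <- lapply(seq_len(4L), function(i) {
    o <- naive_ols_oracle(y, X, terms[i])
    data.frame(domain = colnames(domains)[i], term = kind,
               B = o$B, SE = o$SE, t = o$t, p = o$p,
               unique_contribution = o$p < alpha)
  })
  do.call(rbind, out)
}

#' Product-of-coefficients mediation
#'
#' Two linear regressions on complete cases: `mediator ~ X + C` gives the
#' a-path, `Y ~ X + mediator + C` gives the b-path and the direct effect.
#' The indirect effect is `a * b` with a first-order delta-method standard
#' error `sqrt(a^2 SE_b^2 + b^2 SE_a^2)` and a normal two-sided p (the Sobel
#' test); an optional percentile bootstrap replaces the delta interval. For
#' complete-data linear models the total effect from `Y ~ X + C` equals
#' direct + indirect exactly.
#'
#' @param X Exposure vector (e.g. standardized cumulative stress; for GxE
#'   hits, the centered G-by-E product with G and E supplied as covariates).
#' @param mediator Mediator vector (non-constant).
#' @param Y Outcome vector (methylation at one CpG).
#' @param covariates Optional covariate data frame.
#' @param bootstrap_reps Number of bootstrap replicates (0 = delta method
#'   only).
#' @param seed Seed for the bootstrap.
#' @param alpha_mediation Significance threshold on p(ab) (default 0.0125,
#'   Bonferroni for 4 mediators).
#' @return List with `a`, `se_a`, `b`, `se_b`, `indirect`, `se_indirect`,
#'   `p_indirect`, `ci_low`, `ci_high`, `direct`, `total`, `significant`,
#'   `n`.
#' @export
mediate <- function(X, mediator, Y, covariates = NULL, bootstrap_reps = 0,
                    seed = 1L, alpha_mediation = 0.0125) {
  n <- length(Y)
  stopifnot(length(X) == n, length(mediator) == n)
  if (anyNA(X) || anyNA(mediator) || anyNA(Y)) {
    stop("mediate: complete cases required")
  }
  if (stats::sd(mediator) == 0) stop("mediate: mediator is constant")
  Z <- .build_nuisance(covariates, n)

  Xa <- cbind(Z, X = X)
  oa <- naive_ols_oracle(mediator, Xa, ncol(Xa))
  Xb <- cbind(Z, X = X, mediator = mediator)
  ob <- naive_ols_oracle(Y, Xb, ncol(Xb))          # b path
  od <- naive_ols_oracle(Y, Xb, ncol(Xb) - 1L)     # direct effect of X
  ot <- naive_ols_oracle(Y, Xa, ncol(Xa))          # total effect of X

  a <- oa$B; b <- ob$B
  ab <- a * b
  se_ab <- sqrt(a^2 * ob$SE^2 + b^2 * oa$SE^2)
  p_ab <- 2 * stats::pnorm(abs(ab / se_ab), lower.tail = FALSE)
  ci <- ab + c(-1, 1) * stats::qnorm(0.975) * se_ab

  if (bootstrap_reps > 0) {
    set.seed(as.integer(seed))
    boots <- vapply(seq_len(bootstrap_reps), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      fa <- stats::lm.fit(Xa[idx, , drop = FALSE], mediator[idx])
      fb <- stats::lm.fit(Xb[idx, , drop = FALSE], Y[idx])
      fa$coefficients[["X"]] * fb$coefficients[["mediator"]]
    }, numeric(1))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
    attr(ci, "bootstrap_se") <- stats::sd(boots)
  }

  list(a = a, se_a = oa$SE, b = b, se_b = ob$SE,
       indirect = ab, se_indirect = se_ab, p_indirect = p_ab,
       ci_low = ci[1L], ci_high = ci[2L],
       direct = od$B, total = ot$B,
       significant = p_ab < alpha_mediation, n = n,
       bootstrap_se = attr(ci, "bootstrap_se"))
}
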