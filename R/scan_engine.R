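#' Fast association scans (Emodel, Gmodel, GxEmodel)
#'
#' Ordinary-least-squares scans of DNA methylation (outcome, winsorized beta
#' values) on cumulative prenatal stress (Emodel), dominant-coded genotype
#' (Gmodel), or their interaction (GxEmodel), adjusted for covariates.
#' Speed comes from the Frisch-Waugh-Lovell decomposition: outcomes and the
#' tested term are projected off the nuisance design once (per genotype
#' missingness pattern), after which each per-pair fit reduces to a handful
#' of inner products. Every statistic equals the naive per-pair regression
#' (see [naive_ols_oracle()]) to numerical precision.
#'
#' Models fitted per CpG k (and SNP j where applicable):
#' \itemize{
#'   \item Emodel:   M_k ~ 1 + E + C, testing E
#'   \item Gmodel:   M_k ~ 1 + G_j + C, testing G_j
#'   \item GxEmodel: M_k ~ 1 + G_j + E + G_j:E + C, testing G_j:E
#' }
#' Missing genotypes are handled by per-SNP complete-case analysis; the
#' nuisance projection is recomputed per missingness pattern and cached.
#'
#' @name scan_engine
NULL

#' Project a matrix off a nuisance design
#'
#' Returns the OLS residuals of each column of `Y` on `Z`. The result is
#' orthogonal to every column of `Z`.
#'
#' @param Y Numeric matrix (or vector), n x K.
#' @param Z Nuisance design matrix, n x q, full column rank.
#' @return Residual matrix of the same shape as `Y`.
#' @export
residualize <- function(Y, Z) {
  Y <- as.matrix(Y)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    dep <- colnames(Z)[qz$pivot[-seq_len(qz$rank)]]
    stop("residualize: nuisance design rank-deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  Y - qr.fitted(qz, Y)
}

#' Naive per-pair OLS reference
#'
#' Textbook single-outcome least squares via QR: coefficient, standard
#' error, t, two-sided p for one term, plus the adjusted R-squared of the
#' full model and of the model with the term removed. This is the exact
#' reference every scan is tested against.
#'
#' @param y Outcome vector.
#' @param X Design matrix including the intercept, full rank, n > ncol + 1.
#' @param term Column index of the tested term.
#' @return List with `B`, `SE`, `t`, `p`, `adj_r2_full`, `adj_r2_reduced`,
#'   `delta_adj_r2`, `n`.
#' @export
naive_ols_oracle <- function(y, X, term) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("naive_ols_oracle: n must exceed ncol(X) + 1")
  qx <- qr(X)
  if (qx$rank < p) stop("naive_ols_oracle: design is rank deficient")
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  XtX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta[term] / se[term]
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  adj_full <- 1 - (rss / (n - p)) / (tss / (n - 1))
  Xr <- X[, -term, drop = FALSE]
  rss_red <- sum(qr.resid(qr(Xr), y)^2)
  adj_red <- 1 - (rss_red / (n - ncol(Xr))) / (tss / (n - 1))
  list(B = unname(beta[term]), SE = unname(se[term]), t = unname(tval),
       p = unname(pval), adj_r2_full = adj_full, adj_r2_reduced = adj_red,
       delta_adj_r2 = adj_full - adj_red, n = n)
}

# Internal: FWL statistics for one tested term across all outcome columns.
#   Mres: outcomes residualized on the reduced design (n x K)
#   x:    tested term residualized on the same design (n vector)
#   tss:  per-outcome total SS about the mean (K)
#   p_full: columns in the full design (reduced + 1)
# Returns a data.frame of per-outcome statistics.
.fwl_stats <- function(Mres, x, tss, p_full, n) {
  xtx <- sum(x^2)
  rss_red <- colSums(Mres^2)
  b <- drop(crossprod(x, Mres)) / xtx
  rss_full <- pmax(rss_red - b^2 * xtx, 0)
  df <- n - p_full
  se <- sqrt(rss_full / df / xtx)
  tval <- b / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  adj_full <- 1 - (rss_full / df) / (tss / (n - 1))
  adj_red <- 1 - (rss_red / (df + 1)) / (tss / (n - 1))
  data.frame(B = b, SE = se, t = tval, p = pval, n = n,
             delta_adj_r2 = adj_full - adj_red)
}

# Internal: validate subject alignment and basic design sanity
.check_design <- function(M, E = NULL, G = NULL, covariates = NULL,
                          need_E = FALSE) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (anyNA(M)) stop("scan: methylation matrix must be complete")
  if (need_E) {
    stopifnot(length(E) == n)
    if (anyNA(E)) stop("scan: exposure must be complete")
    if (stats::sd(E) == 0) stop("scan: exposure has zero variance")
  }
  if (!is.null(G)) stopifnot(nrow(G) == n)
  if (!is.null(covariates)) stopifnot(nrow(as.data.frame(covariates)) == n)
  M
}

#' Epigenome-wide scan of stress on methylation (Emodel)
#'
#' Fits `M_k ~ 1 + E + C` for every CpG and reports the stress coefficient.
#'
#' @param M Methylation matrix, subjects x CpGs (complete, winsorized betas).
#' @param E Standardized, winsorized cumulative stress vector.
#' @param covariates Optional covariate data frame (sex, genetic PCs, cell
#'   proportions, batch); factors are expanded and collinear columns dropped.
#' @return `data.frame` with one row per CpG: `cpg`, `B`, `SE`, `t`, `p`,
#'   `n`, `delta_adj_r2`, `flag` (`"ok"` or `"zero_variance"`).
#' @export
emodel_scan <- function(M, E, covariates = NULL) {
  M <- .check_design(M, E = E, covariates = covariates, need_E = TRUE)
  n <- nrow(M)
  Z <- .build_nuisance(covariates, n)
  ok <- apply(M, 2L, stats::sd) > 0
  Mres <- residualize(M, Z)
  e_res <- drop(residualize(E, Z))
  tss <- colSums(scale(M, scale = FALSE)^2)
  st <- .fwl_stats(Mres, e_res, tss, p_full = ncol(Z) + 1L, n = n)
  out <- cbind(data.frame(model = "E", cpg = colnames(M)), st)
  out$flag <- ifelse(ok, "ok", "zero_variance")
  out[!ok, c("B", "SE", "t", "p", "delta_adj_r2")] <- NA_real_
  rownames(out) <- NULL
  out
}

# Internal: group SNP columns by missingness pattern; returns list of
# (snp index vector, subject index vector) pairs
.missingness_patterns <- function(G) {
  keys <- apply(is.na(G), 2L, function(m) paste(which(m), collapse = ","))
  split(seq_len(ncol(G)), keys)
}

# Internal shared driver for the pair-level scans. For each missingness
# pattern, builds the reduced design (nuisance, plus E and G_j for the GxE
# model), projects outcomes once, and sweeps the SNPs of the pattern.
.pair_scan <- function(M, G, E = NULL, covariates = NULL,
                       interaction = FALSE, chunk_size = Inf,
                       emit_p_max = 1) {
  M <- .check_design(M, E = E, G = G, covariates = covariates,
                     need_E = interaction)
  n <- nrow(M)
  K <- ncol(M)
  snp_ids <- colnames(G)
  cpg_ids <- colnames(M)
  chunks <- split(seq_len(K),
                  ceiling(seq_len(K) / min(chunk_size, K)))
  patterns <- .missingness_patterns(G)
  res <- vector("list", length(patterns) * length(chunks))
  ri <- 1L
  model_tag <- if (interaction) "GxE" else "G"

  for (pat in patterns) {
    idx <- which(!is.na(G[, pat[1L]]))
    n_s <- length(idx)
    Cs <- if (is.null(covariates)) NULL else
      as.data.frame(covariates)[idx, , drop = FALSE]
    Z0 <- .build_nuisance(Cs, n_s)
    if (interaction) Z0 <- cbind(Z0, E = E[idx])
    q0 <- qr(Z0)
    if (q0$rank < ncol(Z0)) {
      dep <- colnames(Z0)[q0$pivot[-seq_len(q0$rank)]]
      stop("scan: nuisance design rank-deficient on a missingness subset; ",
           "dependent column(s): ", paste(dep, collapse = ", "))
    }
    for (ch in chunks) {
      Ms <- M[idx, ch, drop = FALSE]
      M0 <- Ms - qr.fitted(q0, Ms)
      tss <- colSums(scale(Ms, scale = FALSE)^2)
      for (j in pat) {
        g <- G[idx, j]
        if (length(unique(g)) < 2L) {
          res[[ri]] <- data.frame(
            model = model_tag, snp = snp_ids[j], cpg = cpg_ids[ch],
            B = NA_real_, SE = NA_real_, t = NA_real_, p = NA_real_,
            n = n_s, delta_adj_r2 = NA_real_, flag = "monomorphic")
          ri <- ri + 1L
          next
        }
        g0 <- g - qr.fitted(q0, g)
        if (sum(g0^2) < 1e-10 * sum(g^2)) {
          res[[ri]] <- data.frame(
            model = model_tag, snp = snp_ids[j], cpg = cpg_ids[ch],
            B = NA_real_, SE = NA_real_, t = NA_real_, p = NA_real_,
            n = n_s, delta_adj_r2 = NA_real_, flag = "collinear")
          ri <- ri + 1L
          next
        }
        if (interaction) {
          # reduced design for the interaction test: Z0 + G_j
          gg <- sum(g0^2)
          M1 <- M0 - g0 %*% (crossprod(g0, M0) / gg)
          x <- g * E[idx]
          x0 <- x - qr.fitted(q0, x)
          x1 <- x0 - g0 * (sum(g0 * x0) / gg)
          if (sum(x1^2) < 1e-10 * max(sum(x^2), 1)) {
            res[[ri]] <- data.frame(
              model = model_tag, snp = snp_ids[j], cpg = cpg_ids[ch],
              B = NA_real_, SE = NA_real_, t = NA_real_, p = NA_real_,
              n = n_s, delta_adj_r2 = NA_real_, flag = "collinear")
            ri <- ri + 1L
            next
          }
          st <- .fwl_stats(M1, x1, tss, p_full = ncol(Z0) + 2L, n = n_s)
        } else {
          st <- .fwl_stats(M0, g0, tss, p_full = ncol(Z0) + 1L, n = n_s)
        }
        keep <- !is.na(st$p) & st$p <= emit_p_max
        if (!any(keep)) { next }
        res[[ri]] <- cbind(
          data.frame(model = model_tag, snp = snp_ids[j],
                     cpg = cpg_ids[ch][keep]),
          st[keep, , drop = FALSE],
          data.frame(flag = "ok"))
        ri <- ri + 1L
      }
    }
  }
  out <- data.table::rbindlist(res[!vapply(res, is.null, logical(1))])
  out <- as.data.frame(out)
  # stable order: snp then cpg in input order
  out <- out[order(match(out$snp, snp_ids), match(out$cpg, cpg_ids)), ]
  rownames(out) <- NULL
  out
}

#' Genome-wide by epigenome-wide meQTL scan (Gmodel)
#'
#' Fits `M_k ~ 1 + G_j + C` for every SNP-CpG pair and reports the genotype
#' coefficient. SNPs monomorphic after per-SNP complete-case restriction are
#' flagged and skipped.
#'
#' @inheritParams emodel_scan
#' @param G Dominant-coded genotype matrix, subjects x SNPs, values in
#'   {0, 1, NA}.
#' @param chunk_size CpGs per processing chunk; results are identical for
#'   any chunk size.
#' @param emit_p_max Emit only pairs with p <= this bound (default 1, emit
#'   all). Monomorphic/collinear flags are always emitted.
#' @return `data.frame` of per-pair association records.
#' @export
gmodel_scan <- function(M, G, covariates = NULL, chunk_size = Inf,
                        emit_p_max = 1) {
  .pair_scan(M, G, covariates = covariates, interaction = FALSE,
             chunk_size = chunk_size, emit_p_max = emit_p_max)
}

#' Genotype-by-stress interaction scan (GxEmodel)
#'
#' Fits `M_k ~ 1 + G_j + E + G_j:E + C` for every SNP-CpG pair and reports
#' the interaction coefficient. Main effects of G and E are always included
#' alongside the tested interaction.
#'
#' @inheritParams gmodel_scan
#' @param E Standardized, winsorized cumulative stress vector.
#' @return `data.frame` of per-pair association records for the interaction
#'   term.
#' @export
gxe_scan <- function(M, G, E, covariates = NULL, chunk_size = Inf,
                     emit_p_max = 1) {
  .pair_scan(M, G, E = E, covariates = covariates, interaction = TRUE,
             chunk_size = chunk_size, emit_p_max = emit_p_max)
}
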