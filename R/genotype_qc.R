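#' Genotype quality control
#'
#' SNP-level filters (call rate, exact Hardy-Weinberg test, minor allele
#' frequency, imputation info score), sample-level relatedness exclusion,
#' VIF-based LD pruning with the PLINK-style (window 50, step 5, VIF 2)
#' parameters, and dominant recoding of hard calls with cross-cohort allele
#' harmonization.
#'
#' Genotype matrices are subjects x SNPs integer matrices with calls in
#' {0, 1, 2, NA} counting copies of `allele1`, accompanied by a SNP metadata
#' data frame (`snp`, `chr`, `pos`, `allele1`, `allele2`, optionally `info`).
#'
#' @name genotype_qc
NULL

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts: conditional on the observed
#' allele counts, the probabilities of every attainable heterozygote count
#' are computed and those no larger than the observed count's probability are
#' summed. Log-gamma arithmetic keeps the enumeration stable at large n.
#'
#' @param n_AA,n_Aa,n_aa Non-negative integer genotype counts.
#' @return Exact two-sided p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("hwe_exact_test: counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("hwe_exact_test: no observations")
  n_a <- n_Aa + 2L * n_aa            # minor-ish allele count (label-free)
  # attainable heterozygote counts share n_a's parity
  hets <- seq.int(n_a %% 2L, min(n_a, 2L * n - n_a), by = 2L)
  # log P(het = h | n, n_a) up to a shared constant:
  # P ~ n! / (nAA! nAa! naa!) * 2^h, with nAa = h
  logp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    AA <- n - h - aa
    h * log(2) - lgamma(h + 1) - lgamma(aa + 1) - lgamma(AA + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_Aa, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Per-SNP summary statistics
#'
#' Call rate, minor allele frequency (of the rarer allele among non-missing
#' calls) and HWE exact p for every column of a call matrix.
#'
#' @param calls Integer matrix, subjects x SNPs, values in {0, 1, 2, NA}.
#' @return Data frame with `call_rate`, `maf`, `hwe_p` per SNP.
#' @export
snp_stats <- function(calls) {
  n_obs <- colSums(!is.na(calls))
  call_rate <- n_obs / nrow(calls)
  n2 <- colSums(calls == 2, na.rm = TRUE)
  n1 <- colSums(calls == 1, na.rm = TRUE)
  n0 <- colSums(calls == 0, na.rm = TRUE)
  af1 <- (2 * n2 + n1) / (2 * pmax(n_obs, 1L))
  maf <- pmin(af1, 1 - af1)
  hwe_p <- vapply(seq_len(ncol(calls)), function(j) {
    if (n_obs[j] == 0L) return(NA_real_)
    hwe_exact_test(n0[j], n1[j], n2[j])
  }, numeric(1))
  data.frame(snp = colnames(calls), call_rate = call_rate, maf = maf,
             hwe_p = hwe_p, row.names = NULL)
}

#' SNP-level filtering
#'
#' Applies the QC filters in a fixed order -- call rate, HWE, MAF, info
#' score -- logging the number of SNPs dropped at each step. MAF and HWE are
#' computed on the non-missing calls of the supplied (post sample exclusion)
#' matrix.
#'
#' @param calls Call matrix (subjects x SNPs).
#' @param snp_info Optional numeric vector of per-SNP imputation info scores.
#' @param thresholds List with `call_rate_min` (default 0.95), `hwe_p_min`
#'   (1e-7), `maf_min` (0.05), `info_min` (0, i.e. off unless set).
#' @return List with `keep` (character vector of retained SNP ids), `drops`
#'   (named integer vector of per-filter drop counts) and `reasons` (first
#'   firing filter per dropped SNP).
#' @export
snp_filter <- function(calls, snp_info = NULL,
                       thresholds = list()) {
  th <- utils::modifyList(
    list(call_rate_min = 0.95, hwe_p_min = 1e-7, maf_min = 0.05,
         info_min = 0), thresholds)
  st <- snp_stats(calls)
  alive <- rep(TRUE, ncol(calls))
  reasons <- setNames(rep(NA_character_, ncol(calls)), colnames(calls))
  drops <- c(call_rate = 0L, hwe = 0L, maf = 0L, info = 0L)

  fire <- function(bad, label) {
    bad <- bad & alive
    reasons[bad] <<- label
    drops[label] <<- sum(bad)
    alive <<- alive & !bad
  }
  fire(st$call_rate < th$call_rate_min, "call_rate")
  fire(!is.na(st$hwe_p) & st$hwe_p < th$hwe_p_min, "hwe")
  fire(st$maf < th$maf_min, "maf")
  if (!is.null(snp_info)) fire(snp_info < th$info_min, "info")

  list(keep = colnames(calls)[alive], drops = drops,
       reasons = reasons[!is.na(reasons)])
}

#' Exclude one member of each cryptically related pair
#'
#' Greedy exclusion over pairs with IBD above the threshold: pairs are
#' visited in decreasing IBD order and, where both members are still
#' retained, the member with less non-missing data is dropped (ties broken by
#' a seeded random draw). The result contains no retained pair above the
#' threshold.
#'
#' @param subjects Character vector of subject ids.
#' @param ibd_pairs Data frame with columns `id1`, `id2`, `ibd`.
#' @param data_completeness Named numeric vector: non-missing data count per
#'   subject (higher = kept preferentially).
#' @param ibd_max Exclusion threshold (default 0.15; pairs with IBD strictly
#'   greater are split).
#' @param seed Seed for tie breaks.
#' @return Character vector of retained subject ids, input order preserved.
#' @export
relatedness_exclude <- function(subjects, ibd_pairs, data_completeness,
                                ibd_max = 0.15, seed = 1L) {
  flagged <- ibd_pairs[ibd_pairs$ibd > ibd_max, , drop = FALSE]
  missing_ids <- setdiff(unique(c(flagged$id1, flagged$id2)), subjects)
  if (length(missing_ids)) {
    stop("relatedness_exclude: pair subject(s) absent from data: ",
         paste(missing_ids, collapse = ", "))
  }
  retained <- rep(TRUE, length(subjects))
  names(retained) <- subjects
  if (nrow(flagged)) {
    set.seed(as.integer(seed))
    flagged <- flagged[order(-flagged$ibd), , drop = FALSE]
    for (r in seq_len(nrow(flagged))) {
      a <- flagged$id1[r]; b <- flagged$id2[r]
      if (!retained[a] || !retained[b]) next
      ca <- data_completeness[[a]]; cb <- data_completeness[[b]]
      drop_id <- if (ca > cb) b else if (cb > ca) a else sample(c(a, b), 1L)
      retained[drop_id] <- FALSE
    }
  }
  subjects[retained]
}

# Internal: VIFs of a set of dosage columns (regress each on the others).
# Perfect collinearity yields Inf.
.window_vifs <- function(G) {
  p <- ncol(G)
  if (p < 2L) return(rep(1, p))
  vapply(seq_len(p), function(j) {
    y <- G[, j]
    vy <- stats::var(y)
    if (vy == 0) return(1)
    X <- cbind(1, G[, -j, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    r2 <- 1 - sum(fit$residuals^2) / (vy * (length(y) - 1))
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' LD pruning by variance inflation factor
#'
#' Slides a window of `window` SNPs advancing by `step` along each
#' chromosome (SNPs must be position-sorted within chromosome) and, within
#' each window, iteratively removes the SNP with the highest VIF until every
#' remaining SNP's VIF (from regressing its additive dosage on the other
#' retained SNPs in the window) is at most `vif_max`.
#'
#' @param calls Additive call matrix (subjects x SNPs), pre-dominant-coding.
#' @param snps Data frame with `snp`, `chr`, `pos` matching the columns.
#' @param window Window size in SNPs (default 50).
#' @param step Step size in SNPs (default 5).
#' @param vif_max VIF cap (default 2).
#' @return Character vector of retained SNP ids.
#' @export
vif_prune <- function(calls, snps, window = 50, step = 5, vif_max = 2) {
  stopifnot(ncol(calls) == nrow(snps))
  for (ch in unique(snps$chr)) {
    pos <- snps$pos[snps$chr == ch]
    if (is.unsorted(pos)) {
      stop(sprintf("vif_prune: SNPs not position-sorted on chromosome %s", ch))
    }
  }
  keep <- rep(TRUE, ncol(calls))
  for (ch in unique(snps$chr)) {
    idx <- which(snps$chr == ch)
    start <- 1L
    repeat {
      win <- idx[seq.int(start, min(start + window - 1L, length(idx)))]
      alive <- win[keep[win]]
      while (length(alive) >= 2L) {
        vifs <- .window_vifs(calls[, alive, drop = FALSE])
        worst <- which.max(vifs)
        if (vifs[worst] <= vif_max) break
        keep[alive[worst]] <- FALSE
        alive <- alive[-worst]
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  colnames(calls)[keep]
}

#' Harmonize allele labels against a reference cohort
#'
#' Aligns a cohort's calls to the reference cohort's allele1/allele2
#' orientation by id: where the labels are swapped the calls are flipped
#' (x -> 2 - x); strand-ambiguous A/T and C/G SNPs cannot be harmonized by
#' label matching and are dropped with a warning; any other label mismatch is
#' an error naming the SNP.
#'
#' @param calls Call matrix of the cohort to harmonize.
#' @param snps Cohort SNP metadata (`snp`, `allele1`, `allele2`).
#' @param ref_snps Reference cohort SNP metadata (same columns).
#' @return List with harmonized `calls` and `snps` (ambiguous SNPs removed).
#' @export
harmonize_alleles <- function(calls, snps, ref_snps) {
  m <- match(snps$snp, ref_snps$snp)
  if (anyNA(m)) {
    stop("harmonize_alleles: SNP(s) absent from reference: ",
         paste(snps$snp[is.na(m)], collapse = ", "))
  }
  ref <- ref_snps[m, ]
  ambiguous <- (pmin(snps$allele1, snps$allele2) == "A" &
                pmax(snps$allele1, snps$allele2) == "T") |
               (pmin(snps$allele1, snps$allele2) == "C" &
                pmax(snps$allele1, snps$allele2) == "G")
  same <- snps$allele1 == ref$allele1 & snps$allele2 == ref$allele2
  swapped <- snps$allele1 == ref$allele2 & snps$allele2 == ref$allele1
  bad <- !same & !swapped & !ambiguous
  if (any(bad)) {
    stop("harmonize_alleles: irreconcilable alleles for SNP(s): ",
         paste(snps$snp[bad], collapse = ", "))
  }
  if (any(ambiguous)) {
    warning("harmonize_alleles: dropping strand-ambiguous SNP(s): ",
            paste(snps$snp[ambiguous], collapse = ", "))
  }
  flip <- swapped & !ambiguous
  calls[, flip] <- 2L - calls[, flip]
  snps$allele1[flip] <- ref$allele1[flip]
  snps$allele2[flip] <- ref$allele2[flip]
  keep <- !ambiguous
  list(calls = calls[, keep, drop = FALSE], snps = snps[keep, , drop = FALSE])
}

#' Dominant genotype coding
#'
#' Contrasts carriers of at least one minor allele (1) against homozygous
#' major genotypes (0). The minor allele is defined in a designated reference
#' cohort (its allele frequency is passed in), so coding is consistent across
#' cohorts after allele harmonization.
#'
#' @param calls Call matrix counting copies of allele1.
#' @param maf_reference Numeric vector: allele1 frequency per SNP in the
#'   reference cohort. Where > 0.5, allele1 is the major allele and the
#'   contrast is inverted accordingly.
#' @return Integer matrix in {0, 1, NA}; SNPs monomorphic after coding carry
#'   attribute `monomorphic_after_coding` (character vector of ids).
#' @export
dominant_code <- function(calls, maf_reference) {
  stopifnot(length(maf_reference) == ncol(calls))
  out <- matrix(NA_integer_, nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  a1_minor <- maf_reference <= 0.5
  for (j in seq_len(ncol(calls))) {
    x <- calls[, j]
    out[, j] <- if (a1_minor[j]) as.integer(x >= 1L) else as.integer(x <= 1L)
  }
  rng <- apply(out, 2L, function(x) length(unique(x[!is.na(x)])))
  mono <- colnames(out)[rng <= 1L]
  attr(out, "monomorphic_after_coding") <- mono
  out
}
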