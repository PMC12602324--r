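test_that("HWE exact test matches enumeration on hand cases", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-7)
  expect_equal(hwe_exact_test(1, 2, 1), oracle_hwe_p(1, 2, 1),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 2, 1), "non-negative")
})

test_that("HWE exact test equals the factorial oracle for all n <= 50", {
  for (n in c(1:20, 35, 50)) {
    for (n_aa in 0:n) {
      for (n_Aa in 0:(n - n_aa)) {
        n_AA <- n - n_aa - n_Aa
        expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa),
                     oracle_hwe_p(n_AA, n_Aa, n_aa),
                     tolerance = 1e-12,
                     info = sprintf("(%d,%d,%d)", n_AA, n_Aa, n_aa))
      }
    }
  }
})

make_calls <- function(n, mafs, seed = 1) {
  set.seed(seed)
  calls <- sapply(mafs, function(f) rbinom(n, 2, f))
  colnames(calls) <- paste0("snp", seq_along(mafs))
  calls
}

test_that("snp_filter drops by call rate, HWE and MAF in order", {
  n <- 200
  calls <- make_calls(n, c(0.3, 0.3, 0.04, 0.25), seed = 2)
  calls[1:13, 2] <- NA                        # 93.5% call rate
  hwe_bad <- c(rep(0, 100), rep(2, 100))       # no hets
  calls <- cbind(calls, snp5 = hwe_bad)
  out <- snp_filter(calls)
  expect_false("snp2" %in% out$keep)
  expect_equal(unname(out$reasons["snp2"]), "call_rate")
  expect_false("snp3" %in% out$keep)
  expect_equal(unname(out$reasons["snp3"]), "maf")
  expect_equal(unname(out$reasons["snp5"]), "hwe")
  expect_true(all(c("snp1", "snp4") %in% out$keep))
  expect_equal(sum(out$drops), 3L)

  clean <- make_calls(500, runif(10, 0.15, 0.5), seed = 3)
  out2 <- snp_filter(clean)
  expect_equal(sum(out2$drops), 0L)
  # re-running on the retained set drops nothing further
  out3 <- snp_filter(clean[, out2$keep, drop = FALSE])
  expect_equal(out3$keep, out2$keep)
})

test_that("relatedness exclusion keeps the more complete member", {
  subj <- c("A", "B", "C", "D")
  comp <- c(A = 40, B = 50, C = 45, D = 48)
  pairs <- data.frame(id1 = "A", id2 = "B", ibd = 0.5)
  kept <- relatedness_exclude(subj, pairs, comp)
  expect_true("B" %in% kept)
  expect_false("A" %in% kept)
  expect_equal(kept, c("B", "C", "D"))  # order preserved

  none <- relatedness_exclude(subj, data.frame(id1 = "A", id2 = "B",
                                               ibd = 0.1), comp)
  expect_equal(none, subj)

  # chain A-B, B-C: greedy removal must leave no flagged pair
  chain <- data.frame(id1 = c("A", "B"), id2 = c("B", "C"),
                      ibd = c(0.3, 0.25))
  for (seed in 1:5) {
    kept <- relatedness_exclude(subj, chain, comp, seed = seed)
    for (r in seq_len(nrow(chain))) {
      expect_false(chain$id1[r] %in% kept && chain$id2[r] %in% kept)
    }
  }
  expect_error(relatedness_exclude(subj,
                                   data.frame(id1 = "A", id2 = "Z",
                                              ibd = 0.4), comp),
               "absent")
})

test_that("VIF pruning removes duplicated columns and keeps independent ones", {
  set.seed(4)
  n <- 300
  base <- make_calls(n, rep(0.3, 6), seed = 4)
  calls <- cbind(base, dup = base[, 1])
  snps <- data.frame(snp = colnames(calls), chr = 1,
                     pos = seq_len(ncol(calls)) * 1000)
  kept <- vif_prune(calls, snps, window = 10, step = 5)
  expect_equal(length(kept), ncol(calls) - 1L)
  expect_equal(sum(c("snp1", "dup") %in% kept), 1L)

  indep <- make_calls(n, runif(8, 0.2, 0.5), seed = 5)
  snps2 <- data.frame(snp = colnames(indep), chr = 1,
                      pos = seq_len(8) * 1000)
  expect_equal(vif_prune(indep, snps2, window = 8, step = 4),
               colnames(indep))
  snps_bad <- snps2
  snps_bad$pos <- rev(snps_bad$pos)
  expect_error(vif_prune(indep, snps_bad), "sorted")
})

test_that("VIF pruning agrees with exhaustive subset search on a toy window", {
  set.seed(6)
  n <- 400
  G <- make_calls(n, runif(7, 0.2, 0.5), seed = 6)
  # create two correlated clusters
  G <- cbind(G,
             c1 = ifelse(runif(n) < 0.9, G[, 1], rbinom(n, 2, 0.3)),
             c2 = ifelse(runif(n) < 0.9, G[, 2], rbinom(n, 2, 0.3)))
  G <- G[, sample(ncol(G))]
  snps <- data.frame(snp = colnames(G), chr = 1,
                     pos = seq_len(ncol(G)) * 500)
  kept <- vif_prune(G, snps, window = ncol(G), step = ncol(G), vif_max = 2)
  best <- colnames(G)[oracle_vif_subset(G, 2)]
  # the retained set is as large as the brute-force maximum and itself
  # satisfies the VIF cap
  expect_equal(length(kept), length(best))
  Gk <- G[, kept, drop = FALSE]
  for (j in seq_along(kept)) {
    fit <- lm.fit(cbind(1, Gk[, -j, drop = FALSE]), Gk[, j])
    r2 <- 1 - sum(fit$residuals^2) / (var(Gk[, j]) * (nrow(Gk) - 1))
    expect_lte(1 / (1 - r2), 2 + 1e-8)
  }
})

test_that("dominant coding contrasts carriers against homozygous major", {
  calls <- matrix(c(0L, 1L, 2L, NA), 4, 2,
                  dimnames = list(NULL, c("a", "b")))
  out <- dominant_code(calls, maf_reference = c(0.2, 0.2))  # allele1 minor
  expect_equal(out[, "a"], c(0L, 1L, 1L, NA))
  # allele1 major: carriers of allele2 are 0/1 calls
  out2 <- dominant_code(calls, maf_reference = c(0.8, 0.8))
  expect_equal(out2[, "a"], c(1L, 1L, 0L, NA))
  expect_true(all(out[!is.na(out)] %in% c(0L, 1L)))

  mono <- matrix(0L, 5, 1, dimnames = list(NULL, "m"))
  coded <- dominant_code(mono, 0.1)
  expect_equal(unname(coded[, 1]), rep(0L, 5))
  expect_equal(attr(coded, "monomorphic_after_coding"), "m")
})

test_that("allele harmonization makes swapped-label cohorts identical", {
  set.seed(8)
  calls <- make_calls(100, c(0.3, 0.4), seed = 8)
  ref <- data.frame(snp = c("snp1", "snp2"),
                    allele1 = c("A", "C"), allele2 = c("G", "T"))
  snps_sw <- data.frame(snp = c("snp1", "snp2"),
                        allele1 = c("G", "C"), allele2 = c("A", "T"))
  flipped <- calls
  flipped[, 1] <- 2L - flipped[, 1]
  h <- harmonize_alleles(flipped, snps_sw, ref)
  expect_equal(h$calls, calls)
  expect_equal(h$snps$allele1, ref$allele1)
  # dominant coding after harmonization matches the reference cohort's
  maf_ref <- colMeans(calls) / 2
  expect_equal(dominant_code(h$calls, maf_ref),
               dominant_code(calls, maf_ref))

  amb <- data.frame(snp = "snp1", allele1 = "A", allele2 = "T")
  ref_amb <- data.frame(snp = "snp1", allele1 = "T", allele2 = "A")
  expect_warning(
    h2 <- harmonize_alleles(calls[, 1, drop = FALSE], amb, ref_amb),
    "ambiguous")
  expect_equal(ncol(h2$calls), 0L)
})
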