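test_that("residualize projects exactly off the nuisance space", {
  set.seed(1)
  Z <- cbind(1, matrix(rnorm(150), 50, 3))
  Y <- matrix(rnorm(100), 50, 2)
  R <- residualize(Y, Z)
  expect_lt(max(abs(crossprod(Z, R))), 1e-8 * max(abs(Y)))
  # Y in span(Z) -> zero matrix
  expect_lt(max(abs(residualize(Z %*% rbind(1, 2, -1, 0.5), Z))), 1e-10)
  # column-wise equality with lm residuals
  for (k in 1:2) {
    expect_equal(R[, k], unname(resid(lm(Y[, k] ~ Z - 1))),
                 tolerance = 1e-10)
  }
  expect_error(residualize(Y, cbind(Z, Z[, 2])), "rank-deficient")
})

test_that("naive OLS oracle agrees with lm and nails exact fits", {
  set.seed(2)
  n <- 60
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4), rnorm(n))
  y <- drop(X %*% c(0.3, 0.2, -0.1, 0)) + rnorm(n, 0, 0.5)
  for (term in 2:4) {
    o <- naive_ols_oracle(y, X, term)
    l <- oracle_lm(y, X, term)
    expect_equal(o$B, l$B, tolerance = 1e-10)
    expect_equal(o$SE, l$SE, tolerance = 1e-10)
    expect_equal(o$p, l$p, tolerance = 1e-10)
  }
  # exact linear relation: recovered coefficient, vanishing p
  y2 <- drop(X %*% c(1, 2, 3, 4))
  o2 <- naive_ols_oracle(y2, X, 2)
  expect_equal(o2$B, 2, tolerance = 1e-8)
  expect_lt(o2$p, 1e-100)
  # null model adjusted R2 is zero by construction
  o3 <- naive_ols_oracle(y, cbind(1, rnorm(n)), 2)
  expect_equal(o3$adj_r2_reduced, 0, tolerance = 1e-12)
})

test_that("all three scans equal the per-pair oracle on random designs", {
  worst <- 0
  for (seed in 1:30) {
    d <- random_design(n = sample(30:60, 1), n_snps = 4, n_cpgs = 3,
                       miss = ifelse(seed %% 2, 0.1, 0), seed = seed)
    Z <- model.matrix(~ ., d$C)

    sE <- emodel_scan(d$M, d$E, d$C)
    for (k in seq_len(ncol(d$M))) {
      o <- naive_ols_oracle(d$M[, k], cbind(Z, E = d$E), ncol(Z) + 1)
      r <- sE[sE$cpg == colnames(d$M)[k], ]
      expect_equal(r$B, o$B, tolerance = 1e-8)
      expect_equal(r$SE, o$SE, tolerance = 1e-8)
      expect_equal(r$p, o$p, tolerance = 1e-8)
      expect_equal(r$delta_adj_r2, o$delta_adj_r2, tolerance = 1e-8)
    }

    sG <- gmodel_scan(d$M, d$G, d$C)
    sGxE <- gxe_scan(d$M, d$G, d$E, d$C)
    for (j in seq_len(ncol(d$G))) {
      ok <- !is.na(d$G[, j])
      if (length(unique(d$G[ok, j])) < 2) {
        expect_true(all(sG$flag[sG$snp == colnames(d$G)[j]] == "monomorphic"))
        next
      }
      Zs <- model.matrix(~ ., d$C[ok, , drop = FALSE])
      for (k in seq_len(ncol(d$M))) {
        Xg <- cbind(Zs, g = d$G[ok, j])
        og <- naive_ols_oracle(d$M[ok, k], Xg, ncol(Xg))
        rg <- sG[sG$snp == colnames(d$G)[j] & sG$cpg == colnames(d$M)[k], ]
        expect_equal(rg$B, og$B, tolerance = 1e-8)
        expect_equal(rg$p, og$p, tolerance = 1e-8)
        expect_equal(rg$delta_adj_r2, og$delta_adj_r2, tolerance = 1e-8)
        rel <- abs(rg$SE - og$SE) / og$SE
        worst <- max(worst, rel)

        Xi <- cbind(Zs, g = d$G[ok, j], E = d$E[ok],
                    gxe = d$G[ok, j] * d$E[ok])
        oi <- naive_ols_oracle(d$M[ok, k], Xi, ncol(Xi))
        ri <- sGxE[sGxE$snp == colnames(d$G)[j] &
                     sGxE$cpg == colnames(d$M)[k], ]
        expect_equal(ri$B, oi$B, tolerance = 1e-8)
        expect_equal(ri$SE, oi$SE, tolerance = 1e-8)
        expect_equal(ri$p, oi$p, tolerance = 1e-8)
        expect_equal(ri$delta_adj_r2, oi$delta_adj_r2, tolerance = 1e-8)
        expect_equal(ri$n, oi$n)
      }
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("scans are invariant to chunk size and duplicated SNPs", {
  d <- random_design(n = 50, n_snps = 5, n_cpgs = 7, miss = 0.05, seed = 99)
  full <- gxe_scan(d$M, d$G, d$E, d$C)
  for (cs in c(1, 7)) {
    expect_equal(gxe_scan(d$M, d$G, d$E, d$C, chunk_size = cs), full)
  }
  G2 <- cbind(d$G, s1copy = d$G[, "s1"])
  dup <- gmodel_scan(d$M, G2, d$C)
  a <- dup[dup$snp == "s1", -2]
  b <- dup[dup$snp == "s1copy", -2]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("dominant relabeling of genotype classes does not change results", {
  d <- random_design(n = 45, n_snps = 3, n_cpgs = 3, miss = 0, seed = 12)
  Graw <- matrix(rbinom(45 * 3, 2, 0.35), 45, 3,
                 dimnames = list(NULL, paste0("s", 1:3)))
  Gdom <- (Graw >= 1) * 1L
  Grelab <- Graw
  Grelab[Grelab == 2] <- 1L
  expect_equal(gxe_scan(d$M, Gdom, d$E, d$C),
               gxe_scan(d$M, Grelab, d$E, d$C))
})

test_that("degenerate designs are flagged or rejected", {
  d <- random_design(n = 40, n_snps = 2, n_cpgs = 2, miss = 0, seed = 5)
  expect_error(gxe_scan(d$M, d$G, rep(1, 40), d$C), "zero variance")
  M2 <- d$M
  M2[, 1] <- 0.5
  sE <- emodel_scan(M2, d$E, d$C)
  expect_equal(sE$flag[1], "zero_variance")
  expect_true(is.na(sE$B[1]))
  Gmono <- matrix(c(rep(1L, 40), rbinom(40, 1, 0.5)), 40, 2,
                  dimnames = list(NULL, c("mono", "ok")))
  sG <- gmodel_scan(d$M, Gmono, d$C)
  expect_true(all(sG$flag[sG$snp == "mono"] == "monomorphic"))
  expect_true(all(sG$flag[sG$snp == "ok"] == "ok"))
})

test_that("under the null the scan's p-values are uniform", {
  set.seed(21)
  n <- 400
  M <- matrix(runif(n * 25, 0.3, 0.7), n, 25,
              dimnames = list(NULL, paste0("c", 1:25)))
  E <- rnorm(n)
  C <- data.frame(sex = rbinom(n, 1, 0.5), pc = rnorm(n))
  s <- emodel_scan(M, E, C)
  expect_gt(ks.test(s$p, "punif")$p.value, 0.01)
  rate <- mean(s$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 25) + 0.05)
})
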