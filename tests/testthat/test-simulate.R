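small_cfg <- function(...) {
  sim_config(n_cohorts = 1, n_subjects = 300, n_snps = 30, n_cpgs = 20,
             stress_means = 0.4, seed = 1, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_snps = 0), "positive")
  expect_error(sim_config(domain_sizes = c(10, 10, 10, 10)), "sum")
  expect_error(sim_config(ld_copy_prob = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(maf_range = c(0.2, 0.7)), "maf_range")
  expect_error(sim_config(stress_means = c(5, 5, 5)), "stress_means")
})

test_that("genotypes honor the LD copy mechanism at its extremes", {
  cfg <- small_cfg(ld_block_size = 5, ld_copy_prob = 1)
  meta <- data.frame(snp = paste0("s", 1:5), chr = 1,
                     pos = 1:5 * 1000, block = rep(1, 5),
                     maf = runif(5, 0.2, 0.5))
  G <- simulate_genotypes(cfg, 100, meta, seed = 2)
  for (j in 2:5) expect_equal(unname(G[, j]), unname(G[, 1]))

  cfg0 <- small_cfg(ld_copy_prob = 0)
  meta$maf <- rep(0.4, 5)
  G0 <- simulate_genotypes(cfg0, 2000, meta, seed = 3)
  cors <- cor(G0)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.1)
})

test_that("genotype frequencies are consistent with HWE at the drawn MAF", {
  cfg <- small_cfg()
  meta <- data.frame(snp = paste0("s", 1:20), chr = 1, pos = 1:20 * 1000,
                     block = 1:20, maf = runif(20, 0.1, 0.5))
  G <- simulate_genotypes(cfg, 2000, meta, seed = 4)
  expect_true(all(G %in% 0:2))
  emp_maf <- colMeans(G) / 2
  expect_lt(max(abs(emp_maf - meta$maf)), 4 * sqrt(0.25 / (2 * 2000)) + 0.02)
  hwe_p <- snp_stats(G)$hwe_p
  expect_gt(min(hwe_p), 1e-5)

  meta5 <- meta[1:2, ]
  meta5$maf <- 0.5
  G5 <- simulate_genotypes(cfg, 4000, meta5, seed = 5)
  expect_equal(unname(colMeans(G5) / 2), c(0.5, 0.5), tolerance = 0.03)
})

test_that("stress items hit cohort mean targets and missingness settings", {
  cfg <- sim_config(n_subjects = c(1000, 1000, 1000), seed = 2)
  for (cix in 1:3) {
    s <- simulate_stress_items(cfg, 1000, cfg$stress_means[cix],
                               seed = 10 + cix)
    expect_lt(abs(mean(s$total_true) - cfg$stress_means[cix]), 0.05)
    expect_lt(abs(mean(is.na(unlist(s$items))) - cfg$missing_rate_items),
              0.01)
  }
  cfg0 <- small_cfg(missing_rate_items = 0)
  s0 <- simulate_stress_items(cfg0, 200, 0.4, seed = 1)
  expect_false(anyNA(s0$items))
  z <- simulate_stress_items(cfg0, 100, 0, seed = 1)
  expect_true(all(z$total_true == 0))
  expect_error(simulate_stress_items(cfg0, 50, 5, seed = 1), "unreachable")
})

test_that("mediators sit on or off the stress pathway as configured", {
  cfg <- small_cfg(med_a = 0.5)
  set.seed(2)
  z <- rnorm(2000)
  med <- simulate_mediators(cfg, z, seed = 6)
  expect_equal(cor(med$smoking, z), 0.5, tolerance = 0.06)
  expect_lt(abs(cor(med$alcohol, z)), 0.08)
  expect_lt(abs(cor(med$gestational_age, z)), 0.08)
  # constant stress -> smoking independent of it by construction
  medc <- simulate_mediators(cfg, rep(1, 500), seed = 7)
  expect_equal(sd(medc$smoking), 1, tolerance = 0.15)
  # null a path
  cfg0 <- small_cfg(med_a = 0)
  med0 <- simulate_mediators(cfg0, z, seed = 8)
  expect_lt(abs(cor(med0$smoking, z)), 0.08)
})

test_that("betas are bounded and planted-free CpGs carry no signal", {
  cfg <- small_cfg(effect_sizes = c(g = 0, e = 0, gxe = 0, mediated = 0))
  sim <- simulate_cohorts(cfg)
  co <- sim$cohorts[[1]]
  expect_true(all(co$betas > 0 & co$betas < 1))
  expect_equal(nrow(sim$registry$planted_gxe), 0L)
  s <- emodel_scan(co$betas, co$stress_z, co$covariates)
  expect_gt(ks.test(s$p, "punif")$p.value, 0.01)
})

test_that("same seed reproduces byte-identical data, different seeds differ", {
  cfg <- small_cfg()
  a <- simulate_cohorts(cfg)
  b <- simulate_cohorts(cfg)
  expect_identical(a, b)
  cfg2 <- small_cfg()
  cfg2$seed <- 2L
  c2 <- simulate_cohorts(cfg2)
  expect_false(identical(a$cohorts[[1]]$betas, c2$cohorts[[1]]$betas))
})

test_that("planted interaction magnitudes are recovered in rank order", {
  n <- 3000
  n_eff <- 22
  cfg <- sim_config(n_cohorts = 1, n_subjects = n, n_snps = n_eff,
                    n_cpgs = n_eff, stress_means = 0.4, seed = 5)
  meta <- data.frame(snp = sprintf("s%02d", 1:n_eff), chr = 1,
                     pos = 1:n_eff * 1e4, block = 1:n_eff,
                     maf = runif(n_eff, 0.25, 0.5))
  set.seed(5)
  G <- simulate_genotypes(cfg, n, meta, seed = 51)
  Gd <- dominant_code(G, meta$maf)
  E <- rnorm(n)
  covs <- simulate_covariates(n, seed = 52)
  probe_meta <- data.frame(cpg = sprintf("c%02d", 1:n_eff), chr = 2,
                           pos = 1:n_eff * 1e4, cross_reactive = FALSE,
                           baseline = 0)  # flat baselines: no differential
                                          # squashing across CpGs
  registry <- list(
    planted_g = data.frame(snp = character(), cpg = character(),
                           beta = numeric()),
    planted_e = data.frame(cpg = character(), beta = numeric()),
    planted_gxe = data.frame(snp = meta$snp, cpg = probe_meta$cpg,
                             beta = seq(0.02, 0.4, length.out = n_eff) *
                               rep_len(c(-1, 1), n_eff)),
    planted_mediated = data.frame(cpg = character(), a = numeric(),
                                  b = numeric()))
  betas <- simulate_methylation(cfg, Gd, E, covs, mediators = NULL,
                                registry = registry,
                                probe_meta = probe_meta, seed = 53)
  sc <- gxe_scan(betas, Gd, E, covs)
  got <- sc[match(paste(registry$planted_gxe$snp, registry$planted_gxe$cpg),
                  paste(sc$snp, sc$cpg)), ]
  rho <- cor(got$B, registry$planted_gxe$beta, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("cohort heterogeneity multipliers scale planted effects", {
  cfg <- sim_config(n_cohorts = 2, n_subjects = c(2000, 2000),
                    stress_means = c(0.4, 0.4), n_snps = 40, n_cpgs = 30,
                    missing_rate_items = 0,
                    effect_sizes = c(g = 0, e = 3, gxe = 0, mediated = 0),
                    cohort_multiplier = c(1, 0), seed = 6)
  sim <- simulate_cohorts(cfg)
  reg <- sim$registry$planted_e
  s1 <- emodel_scan(sim$cohorts[[1]]$betas[, reg$cpg, drop = FALSE],
                    sim$cohorts[[1]]$stress_z)
  s2 <- emodel_scan(sim$cohorts[[2]]$betas[, reg$cpg, drop = FALSE],
                    sim$cohorts[[2]]$stress_z)
  expect_lt(min(s1$p), 1e-8)
  expect_gt(min(s2$p), 1e-4)
})
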