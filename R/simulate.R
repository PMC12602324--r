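#' Synthetic multi-cohort data with planted effects
#'
#' Generates multi-cohort genotype / stress-item / methylation / mediator
#' data with the statistical structure the analysis pipeline assumes:
#' genotypes in Hardy-Weinberg equilibrium with tunable LD blocks
#' (Li-Stephens-style copy-with-probability down a block), ~50 binary stress
#' items in four domains with domain-shared latent liability and
#' cohort-specific mean total scores, beta-scale methylation built by
#' logistic squashing of a Gaussian latent with planted G-only, E-only, GxE
#' and smoking-mediated effects of configurable adjusted-R-squared
#' increment, and mediator tables (smoking on the stress pathway; alcohol,
#' gestational age, birth weight as null paths). A truth registry records
#' every planted effect for recovery testing.
#'
#' @name synthetic_cohorts
NULL

#' Simulation configuration
#'
#' Defaults describe the emulated study: three sub-cohorts of 1224, 949 and
#' 790 newborns, 50 dichotomous prenatal stress items split 13/13/12/12 over
#' the four domains, cohort mean total stress scores 0.36 / 0.44 / 0.51,
#' common SNPs with MAF in [0.05, 0.5] in 5-SNP LD blocks, and planted
#' effects sized to an adjusted-R-squared increment of 0.02.
#'
#' @param n_cohorts Number of sub-cohorts.
#' @param n_subjects Per-cohort subject counts.
#' @param n_snps,n_cpgs Marker panel sizes.
#' @param n_items Number of stress items.
#' @param domain_sizes Items per domain (must sum to `n_items`).
#' @param maf_range Minor-allele-frequency interval, within [0.05, 0.5].
#' @param ld_block_size SNPs per LD block.
#' @param ld_copy_prob Per-haplotype probability of copying the previous
#'   SNP's allele within a block.
#' @param stress_means Per-cohort target mean of the total stress score
#'   (scale 0-4).
#' @param missing_rate_items MCAR missingness rate injected into items.
#' @param effect_sizes Named counts of planted effects:
#'   `g`, `e`, `gxe`, `mediated`.
#' @param effect_r2 Target adjusted-R-squared increment per planted effect.
#' @param noise_sd Residual SD of the methylation latent (logit scale).
#' @param med_a Standardized stress -> smoking path for mediated effects.
#' @param cohort_multiplier Optional per-cohort multiplier on planted
#'   effects (heterogeneity knob; default all 1).
#' @param seed Master seed, fanned out to per-component child seeds.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 3,
                       n_subjects = c(1224, 949, 790),
                       n_snps = 500,
                       n_cpgs = 300,
                       n_items = 50,
                       domain_sizes = c(13, 13, 12, 12),
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 5,
                       ld_copy_prob = 0.8,
                       stress_means = c(0.36, 0.44, 0.51),
                       missing_rate_items = 0.05,
                       effect_sizes = c(g = 5, e = 3, gxe = 5, mediated = 3),
                       effect_r2 = 0.02,
                       noise_sd = 0.4,
                       med_a = 0.5,
                       cohort_multiplier = NULL,
                       seed = 1L) {
  cfg <- list(n_cohorts = n_cohorts, n_subjects = n_subjects,
              n_snps = n_snps, n_cpgs = n_cpgs, n_items = n_items,
              domain_sizes = domain_sizes, maf_range = maf_range,
              ld_block_size = ld_block_size, ld_copy_prob = ld_copy_prob,
              stress_means = stress_means,
              missing_rate_items = missing_rate_items,
              effect_sizes = effect_sizes, effect_r2 = effect_r2,
              noise_sd = noise_sd, med_a = med_a,
              cohort_multiplier = cohort_multiplier %||% rep(1, n_cohorts),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname sim_config
#' @param cfg A `sim_config` list.
#' @export
validate_sim_config <- function(cfg) {
  if (cfg$n_cohorts < 1 || cfg$n_snps < 1 || cfg$n_cpgs < 1 ||
      any(cfg$n_subjects < 1)) {
    stop("sim_config: dimensions must be positive")
  }
  if (length(cfg$n_subjects) != cfg$n_cohorts ||
      length(cfg$stress_means) != cfg$n_cohorts) {
    stop("sim_config: per-cohort vectors must have length n_cohorts")
  }
  if (sum(cfg$domain_sizes) != cfg$n_items) {
    stop("sim_config: domain_sizes must sum to n_items")
  }
  .check_prob(cfg$ld_copy_prob, "ld_copy_prob")
  .check_prob(cfg$missing_rate_items, "missing_rate_items")
  if (cfg$maf_range[1] < 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("sim_config: maf_range must be an interval within [0, 0.5]")
  }
  if (any(cfg$stress_means < 0) || any(cfg$stress_means > 4)) {
    stop("sim_config: stress_means must lie in [0, 4]")
  }
  if (cfg$effect_r2 <= 0 || cfg$effect_r2 >= 1) {
    stop("sim_config: effect_r2 must lie in (0, 1)")
  }
  invisible(cfg)
}

# Internal: shared SNP metadata (identical ids/positions across cohorts)
.sim_snp_meta <- function(cfg) {
  s <- cfg$n_snps
  n_blocks <- ceiling(s / cfg$ld_block_size)
  block <- rep(seq_len(n_blocks), each = cfg$ld_block_size)[seq_len(s)]
  chr <- ((block - 1L) %% 22L) + 1L
  pos <- integer(s)
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    pos[idx] <- seq(1e5, by = 5000L, length.out = length(idx))
  }
  pairs <- c("A/G", "A/C", "T/G", "T/C", "G/A", "C/A", "G/T", "C/T")
  al <- matrix(unlist(strsplit(sample(pairs, s, replace = TRUE), "/")),
               ncol = 2L, byrow = TRUE)
  data.frame(snp = sprintf("rs%06d", seq_len(s)), chr = chr, pos = pos,
             allele1 = al[, 1L], allele2 = al[, 2L], block = block,
             stringsAsFactors = FALSE)
}

#' Simulate genotype hard calls for one cohort
#'
#' Draws per-SNP allele frequencies once (shared across cohorts via the
#' metadata), then builds 2n haplotypes per cohort: within an LD block each
#' haplotype copies its previous SNP's allele with probability
#' `ld_copy_prob`, otherwise draws a fresh Bernoulli(MAF) allele. Genotypes
#' are haplotype sums, hence in HWE at the drawn frequency.
#'
#' @param cfg A [sim_config()].
#' @param n Number of subjects.
#' @param snp_meta SNP metadata from the master generator (id, chr, pos,
#'   block, maf).
#' @param seed Component seed.
#' @return Integer matrix n x n_snps with values in {0, 1, 2}.
#' @export
simulate_genotypes <- function(cfg, n, snp_meta, seed) {
  set.seed(as.integer(seed))
  s <- nrow(snp_meta)
  H <- matrix(0L, 2L * n, s)
  for (j in seq_len(s)) {
    fresh <- stats::rbinom(2L * n, 1L, snp_meta$maf[j])
    if (j > 1L && snp_meta$block[j] == snp_meta$block[j - 1L]) {
      copy <- stats::runif(2L * n) < cfg$ld_copy_prob
      H[, j] <- ifelse(copy, H[, j - 1L], fresh)
    } else {
      H[, j] <- fresh
    }
  }
  G <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
  colnames(G) <- snp_meta$snp
  storage.mode(G) <- "integer"
  G
}

#' Simulate binary stress items for one cohort
#'
#' Items share a per-domain latent liability: subject i's items in domain d
#' are Bernoulli(plogis(alpha + lambda * u_id)) with u_id standard normal
#' and alpha calibrated (by numerical root finding on the Gaussian-mixed
#' logistic prevalence) so the expected total score matches the cohort
#' target. MCAR missingness is injected at `missing_rate_items`.
#'
#' @param cfg A [sim_config()].
#' @param n Subjects.
#' @param target_mean Target mean total score (0-4 scale).
#' @param seed Component seed.
#' @param lambda Latent liability loading (default 0.8).
#' @return List with `items` (data frame in {0,1,NA}), `items_complete`
#'   (pre-masking), `mapping` (item -> domain), `total_true` (complete-data
#'   total score).
#' @export
simulate_stress_items <- function(cfg, n, target_mean, seed, lambda = 0.8) {
  prev <- target_mean / 4
  if (prev < 0 || prev > 1) {
    stop("simulate_stress_items: target mean unreachable")
  }
  set.seed(as.integer(seed))
  domains <- c("life_events", "contextual", "personal", "interpersonal")
  # alpha with E_phi[plogis(alpha + lambda u)] = prev
  alpha <- if (prev == 0) -Inf else if (prev == 1) Inf else {
    stats::uniroot(function(a) {
      stats::integrate(function(u) stats::plogis(a + lambda * u) *
                         stats::dnorm(u), -8, 8)$value - prev
    }, c(-30, 30))$root
  }
  mapping <- stats::setNames(
    rep(domains, times = cfg$domain_sizes),
    sprintf("item%02d", seq_len(cfg$n_items)))
  items <- matrix(0L, n, cfg$n_items,
                  dimnames = list(NULL, names(mapping)))
  for (d in seq_along(domains)) {
    u <- stats::rnorm(n)
    cols <- which(mapping == domains[d])
    p <- stats::plogis(alpha + lambda * u)
    for (j in cols) items[, j] <- stats::rbinom(n, 1L, p)
  }
  complete <- as.data.frame(items)
  masked <- complete
  if (cfg$missing_rate_items > 0) {
    mask <- matrix(stats::runif(n * cfg$n_items) < cfg$missing_rate_items,
                   n, cfg$n_items)
    masked[mask] <- NA
  }
  total_true <- domain_and_total(complete, mapping)$total
  list(items = masked, items_complete = complete, mapping = mapping,
       total_true = total_true)
}

#' Simulate covariates for one cohort
#'
#' Sex (0/1), five genetic principal components (standard normal), seven
#' cell-type proportions (Dirichlet, summing to one) and a cohort-specific
#' batch factor.
#'
#' @param n Subjects.
#' @param n_batches Number of batch levels for this cohort.
#' @param seed Component seed.
#' @return Data frame of covariates.
#' @export
simulate_covariates <- function(n, n_batches = 3, seed = 1L) {
  set.seed(as.integer(seed))
  pcs <- matrix(stats::rnorm(n * 5L), n, 5L,
                dimnames = list(NULL, paste0("pc", 1:5)))
  g <- matrix(stats::rgamma(n * 7L, shape = c(8, 3, 2, 2, 1.5, 1, 0.5)),
              n, 7L, byrow = TRUE)
  cells <- g / rowSums(g)
  colnames(cells) <- paste0("cell", 1:7)
  data.frame(sex = stats::rbinom(n, 1L, 0.5), pcs, cells,
             batch = factor(sample(paste0("b", seq_len(n_batches)), n,
                                   replace = TRUE)))
}

#' Simulate mediators for one cohort
#'
#' Smoking is generated on the stress pathway: standardized smoking =
#' `med_a` * standardized stress + noise. Alcohol, gestational age and
#' birth weight are generated as null paths (independent of stress) unless
#' nonzero paths are configured.
#'
#' @param cfg A [sim_config()].
#' @param stress_z Standardized total stress score.
#' @param seed Component seed.
#' @return Data frame with `smoking`, `alcohol`, `gestational_age`,
#'   `birth_weight`.
#' @export
simulate_mediators <- function(cfg, stress_z, seed) {
  set.seed(as.integer(seed))
  n <- length(stress_z)
  a <- cfg$med_a
  sz <- stats::sd(stress_z)
  zs <- if (is.finite(sz) && sz > 0) (stress_z - mean(stress_z)) / sz else
    rep(0, n)
  smoking <- a * zs + sqrt(max(1 - a^2, 0)) * stats::rnorm(n)
  data.frame(
    smoking = smoking,
    alcohol = stats::rnorm(n),
    gestational_age = stats::rnorm(n, 40, 1.5),
    birth_weight = stats::rnorm(n, 3530, 500))
}

# Internal: solve for the latent-scale coefficient b that yields the target
# R-squared on the *observed* (logistic-squashed) beta scale, given samples
# of the predictor x and latent noise z: the linear regression of
# plogis(mu + b x + s z) on x explains coef^2 var(x) of var(beta).
.solve_latent_effect <- function(target_r2, mu, s, x, z) {
  r2_of <- function(b) {
    y <- stats::plogis(mu + b * x + s * z)
    cxy <- stats::cov(y, x)
    (cxy^2 / stats::var(x)) / stats::var(y)
  }
  upper <- 10 * s / stats::sd(x)
  if (r2_of(upper) < target_r2) {
    stop("simulate_methylation: effect_r2 exceeds the residual variance ",
         "budget")
  }
  stats::uniroot(function(b) r2_of(b) - target_r2, c(1e-8, upper),
                 tol = 1e-10)$root
}

# Internal: pick planted SNP/CpG ids and effect coefficients
.sim_registry <- function(cfg, snp_meta, probe_meta, p_carrier, seed) {
  set.seed(as.integer(seed))
  cpg_ids <- probe_meta$cpg
  sizes <- cfg$effect_sizes
  need <- sum(sizes)
  if (need > length(cpg_ids)) {
    stop("simulate_methylation: more planted effects than CpGs")
  }
  r2 <- cfg$effect_r2
  # Monte-Carlo quadrature samples (calibration only). The tested term in
  # each scan is the *partial* predictor -- for the interaction, G*E with
  # the G and E main effects projected out, which for centered unit E and
  # carrier probability q leaves G*E - q*E -- so calibration uses the
  # partialled predictor.
  nq <- 20000L
  zq <- stats::rnorm(nq)
  eq <- stats::rnorm(nq)
  xfor <- function(kind, q) {
    switch(kind,
      g = stats::rbinom(nq, 1L, q),
      e = eq,
      gxe = (stats::rbinom(nq, 1L, q) - q) * eq,
      mediated = stats::rnorm(nq))
  }
  bfor <- function(kind, cpg, q = NA_real_) {
    mu <- probe_meta$baseline[match(cpg, cpg_ids)]
    vapply(seq_along(mu), function(i) {
      .solve_latent_effect(r2, mu[i], cfg$noise_sd,
                           xfor(kind, if (is.na(q[i])) p_carrier else q[i]),
                           zq)
    }, numeric(1))
  }
  common <- snp_meta$snp[snp_meta$maf >= 0.2]
  if (length(common) < sizes[["g"]] + sizes[["gxe"]]) {
    common <- snp_meta$snp
  }
  picked_snps <- sample(common, sizes[["g"]] + sizes[["gxe"]])
  cpg_pool <- sample(cpg_ids, need)
  take <- function(k) {
    if (k == 0L) return(character(0))
    out <- cpg_pool[seq_len(k)]
    cpg_pool <<- cpg_pool[-seq_len(k)]
    out
  }
  cpg_g <- take(sizes[["g"]])
  cpg_e <- take(sizes[["e"]])
  cpg_gxe <- take(sizes[["gxe"]])
  cpg_med <- take(sizes[["mediated"]])
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  q_of <- function(ids) {
    maf <- snp_meta$maf[match(ids, snp_meta$snp)]
    1 - (1 - maf)^2
  }
  snps_g <- picked_snps[seq_len(sizes[["g"]])]
  snps_gxe <- picked_snps[sizes[["g"]] + seq_len(sizes[["gxe"]])]
  list(
    planted_g = data.frame(
      snp = snps_g, cpg = cpg_g,
      beta = bfor("g", cpg_g, q_of(snps_g)) * sgn(sizes[["g"]])),
    planted_e = data.frame(
      cpg = cpg_e,
      beta = bfor("e", cpg_e) * sgn(sizes[["e"]])),
    planted_gxe = data.frame(
      snp = snps_gxe, cpg = cpg_gxe,
      beta = bfor("gxe", cpg_gxe, q_of(snps_gxe)) * sgn(sizes[["gxe"]])),
    planted_mediated = data.frame(
      cpg = cpg_med,
      a = rep(cfg$med_a, sizes[["mediated"]]),
      b = bfor("mediated", cpg_med) * sgn(sizes[["mediated"]])))
}

#' Simulate methylation for one cohort given planted effects
#'
#' Each CpG's latent value is baseline + small covariate loadings + any
#' planted effect terms + Gaussian noise, squashed through the inverse
#' logit so betas stay in [0, 1] without truncation. Planted terms use the
#' dominant-coded genotype, the standardized stress score, their product,
#' or the smoking mediator, with coefficients from the truth registry
#' (optionally scaled by the cohort's heterogeneity multiplier).
#'
#' @param cfg A [sim_config()].
#' @param G_dom Dominant-coded genotype matrix for this cohort.
#' @param stress_z Standardized total stress.
#' @param covariates Covariate data frame.
#' @param mediators Mediator data frame (for mediated effects).
#' @param registry Truth registry (see [simulate_cohorts()]).
#' @param probe_meta Probe metadata with `cpg` and `baseline` (logit-scale).
#' @param multiplier Cohort effect multiplier.
#' @param seed Component seed.
#' @return Numeric matrix n x n_cpgs of beta values in (0, 1).
#' @export
simulate_methylation <- function(cfg, G_dom, stress_z, covariates,
                                 mediators, registry, probe_meta,
                                 multiplier = 1, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(stress_z)
  K <- nrow(probe_meta)
  X <- cbind(sex = covariates$sex,
             as.matrix(covariates[, paste0("pc", 1:5)]),
             as.matrix(covariates[, paste0("cell", 1:7)]))
  # small, CpG-specific covariate loadings
  B <- matrix(stats::rnorm(ncol(X) * K, 0, 0.05), ncol(X), K)
  batch_eff <- stats::rnorm(nlevels(covariates$batch), 0, 0.05)
  L <- matrix(rep(probe_meta$baseline, each = n), n, K) +
    X %*% B + batch_eff[as.integer(covariates$batch)] +
    matrix(stats::rnorm(n * K, 0, cfg$noise_sd), n, K)
  colnames(L) <- probe_meta$cpg

  add <- function(cpg, term) {
    L[, cpg] <<- L[, cpg] + term
  }
  for (r in seq_len(nrow(registry$planted_g))) {
    with(registry$planted_g[r, ], add(cpg, multiplier * beta * G_dom[, snp]))
  }
  for (r in seq_len(nrow(registry$planted_e))) {
    with(registry$planted_e[r, ], add(cpg, multiplier * beta * stress_z))
  }
  for (r in seq_len(nrow(registry$planted_gxe))) {
    with(registry$planted_gxe[r, ],
         add(cpg, multiplier * beta * G_dom[, snp] * stress_z))
  }
  for (r in seq_len(nrow(registry$planted_mediated))) {
    with(registry$planted_mediated[r, ],
         add(cpg, multiplier * b * mediators$smoking))
  }
  stats::plogis(L)
}

#' Generate a full multi-cohort dataset with truth registry
#'
#' Master generator: shared SNP and probe metadata, then per cohort
#' genotypes, stress items (with missingness), covariates, mediators and
#' methylation with planted effects. One global seed is fanned out to
#' per-component child seeds so any component is reproducible in isolation.
#'
#' @param cfg A [sim_config()].
#' @return List with `cohorts` (per cohort: `genotypes`, `snps`, `items`,
#'   `items_complete`, `mapping`, `stress_z` (true complete-data
#'   standardized score), `covariates`, `mediators`, `betas`, `probes`) and
#'   `registry` (planted G / E / GxE / mediated effects).
#' @export
simulate_cohorts <- function(cfg) {
  validate_sim_config(cfg)
  seeds <- child_seeds(cfg$seed, 4L + 6L * cfg$n_cohorts)
  set.seed(seeds[1L])
  snp_meta <- .sim_snp_meta(cfg)
  snp_meta$maf <- stats::runif(cfg$n_snps, cfg$maf_range[1],
                               cfg$maf_range[2])
  set.seed(seeds[2L])
  probe_meta <- data.frame(
    cpg = sprintf("cg%07d", seq_len(cfg$n_cpgs)),
    chr = sample(1:22, cfg$n_cpgs, replace = TRUE),
    pos = sample.int(2e8, cfg$n_cpgs),
    cross_reactive = FALSE,
    baseline = stats::runif(cfg$n_cpgs, -1.5, 1.5))

  # effect calibration needs the dominant-coded carrier probability at the
  # average MAF (HWE)
  p_car <- mean(1 - (1 - snp_meta$maf)^2)
  registry <- .sim_registry(cfg, snp_meta, probe_meta, p_carrier = p_car,
                            seed = seeds[3L])

  cohorts <- vector("list", cfg$n_cohorts)
  names(cohorts) <- paste0("cohort", seq_len(cfg$n_cohorts))
  for (cix in seq_len(cfg$n_cohorts)) {
    s <- seeds[4L + 6L * (cix - 1L) + 1:6]
    n <- cfg$n_subjects[cix]
    G <- simulate_genotypes(cfg, n, snp_meta, seed = s[1L])
    stress <- simulate_stress_items(cfg, n, cfg$stress_means[cix],
                                    seed = s[2L])
    covs <- simulate_covariates(n, n_batches = 2L + cix, seed = s[3L])
    stress_z <- standardize_within_cohort(stress$total_true,
                                          rep("all", n))
    meds <- simulate_mediators(cfg, stress_z, seed = s[4L])
    G_dom <- dominant_code(G, snp_meta$maf)
    betas <- simulate_methylation(
      cfg, G_dom, stress_z, covs, meds, registry, probe_meta,
      multiplier = cfg$cohort_multiplier[cix], seed = s[5L])
    rownames(betas) <- NULL
    cohorts[[cix]] <- list(
      genotypes = G, snps = snp_meta, items = stress$items,
      items_complete = stress$items_complete, mapping = stress$mapping,
      stress_z = stress_z, covariates = covs, mediators = meds,
      betas = betas, probes = probe_meta)
  }
  list(cohorts = cohorts, registry = registry, config = cfg)
}
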