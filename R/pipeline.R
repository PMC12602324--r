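#' Pipeline orchestration
#'
#' End-to-end drivers: [run_cohort()] takes one cohort's raw inputs through
#' stress scoring, genotype QC, methylation preparation and the three
#' association scans; [run_meta_and_followup()] combines per-cohort scan
#' tables by IVW fixed-effects meta-analysis, applies Bonferroni and
#' suggestive thresholds, annotates cis/trans, runs the cross-model overlap
#' enrichment, and follows up significant hits with stress-domain
#' decomposition and mediation. All stages are deterministic given the
#' config seed; tables are returned in memory and, when `out_dir` is set,
#' also written as TSV (one directory per cohort plus one meta directory).
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' @param out_dir Output directory (NULL = in-memory only).
#' @param seed Master seed.
#' @param alpha Family-wise alpha for Bonferroni thresholds (default 0.05).
#' @param suggestive_g,suggestive_e Suggestive p thresholds for the
#'   pair-level (G / GxE, default 5e-8) and CpG-level (E, default 1e-5)
#'   models.
#' @param emit_p_max Per-model emission thresholds for scan records; the
#'   defaults emit every CpG-level record and pair-level records with
#'   p below 1e-4.
#' @param qc SNP QC thresholds (see [snp_filter()]).
#' @param do_vif_prune Run VIF-based LD pruning (default TRUE).
#' @param vif Window/step/cap for [vif_prune()].
#' @param chunk_size CpG chunk size for the pair-level scans.
#' @param mediation_alpha Mediation significance threshold (default 0.0125).
#' @return Nested list of settings.
#' @export
pipeline_config <- function(out_dir = NULL, seed = 1L, alpha = 0.05,
                            suggestive_g = 5e-8, suggestive_e = 1e-5,
                            emit_p_max = list(E = 1, G = 1e-4, GxE = 1e-4),
                            qc = list(call_rate_min = 0.95,
                                      hwe_p_min = 1e-7, maf_min = 0.05,
                                      info_min = 0),
                            do_vif_prune = TRUE,
                            vif = list(window = 50, step = 5, vif_max = 2),
                            chunk_size = Inf,
                            mediation_alpha = 0.0125) {
  list(out_dir = out_dir, seed = as.integer(seed), alpha = alpha,
       suggestive_g = suggestive_g, suggestive_e = suggestive_e,
       emit_p_max = emit_p_max, qc = qc, do_vif_prune = do_vif_prune,
       vif = vif, chunk_size = chunk_size,
       mediation_alpha = mediation_alpha)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config Configuration list from [pipeline_config()].
#' @return `read_pipeline_config` returns the configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[intersect(names(raw),
                                                names(formals(pipeline_config)))])
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Internal: write a TSV with a comment header recording provenance
.write_tsv <- function(df, dir, name, seed = NULL) {
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, name)
  header <- sprintf("# gxescan %s | seed=%s | %s rows",
                    as.character(utils::packageVersion("gxescan")),
                    seed %||% "NA", nrow(df))
  writeLines(header, path)
  suppressWarnings(utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the full per-cohort analysis
#'
#' Stages, in order: stress-score construction (dichotomize -> exclude >50%
#' missing -> PMM imputation -> domain/total -> within-cohort
#' standardization -> 3-IQR winsorization), SNP QC (call rate, HWE, MAF,
#' info; optional VIF pruning; dominant coding), probe filtering and beta
#' winsorization, then the Emodel, Gmodel and GxEmodel scans with
#' covariate adjustment. Subjects excluded by the stress-score missingness
#' rule are dropped from every matrix.
#'
#' @param cohort One cohort's data: a list with `items`, `mapping`,
#'   `genotypes`, `snps`, `betas`, `probes`, `covariates` (and optionally
#'   `mediators`, `rules`, `ibd_pairs`), as produced by [simulate_cohorts()]
#'   or assembled from files.
#' @param config A [pipeline_config()].
#' @param name Cohort name (used for the output subdirectory).
#' @return List with `scores`, `E` (final exposure), `G_dom`, `betas`
#'   (prepped), `covariates`, `scans` (named list of the three scan
#'   tables), `qc` (drop logs), `subjects` (retained row indices).
#' @export
run_cohort <- function(cohort, config = pipeline_config(), name = "cohort") {
  seeds <- child_seeds(config$seed + 100L, 3L)
  rules <- cohort$rules %||%
    stats::setNames(rep(list("identity"), ncol(cohort$items)),
                    colnames(cohort$items))

  # -- stress score ---------------------------------------------------------
  items <- dichotomize(cohort$items, rules)
  kept <- exclude_high_missingness(items)
  idx <- which(kept$retained)
  if (length(idx) < 4L) stop("run_cohort [stress]: too few subjects retained")
  complete <- impute_pmm(kept$items, seed = seeds[1L])
  scores <- domain_and_total(complete, cohort$mapping)
  scores$z <- standardize_within_cohort(scores$total,
                                        rep("all", nrow(scores)))
  scores$z_winsorized <- winsorize_iqr(scores$z)
  E <- scores$z_winsorized

  # optional relatedness exclusion
  if (!is.null(cohort$ibd_pairs) && nrow(cohort$ibd_pairs)) {
    ids <- as.character(seq_len(nrow(cohort$items)))[idx]
    completeness <- stats::setNames(rowSums(!is.na(items))[idx], ids)
    keep_ids <- relatedness_exclude(ids, cohort$ibd_pairs, completeness,
                                    seed = seeds[2L])
    sel <- ids %in% keep_ids
    idx <- idx[sel]
    scores <- scores[sel, , drop = FALSE]
    E <- E[sel]
  }

  G <- cohort$genotypes[idx, , drop = FALSE]
  M <- cohort$betas[idx, , drop = FALSE]
  covs <- cohort$covariates[idx, , drop = FALSE]

  # -- genotype QC ----------------------------------------------------------
  filt <- snp_filter(G, snp_info = cohort$snps$info,
                     thresholds = config$qc)
  G <- G[, filt$keep, drop = FALSE]
  snps <- cohort$snps[match(filt$keep, cohort$snps$snp), , drop = FALSE]
  if (config$do_vif_prune) {
    kept_snps <- vif_prune(G, snps, window = config$vif$window,
                           step = config$vif$step,
                           vif_max = config$vif$vif_max)
    G <- G[, kept_snps, drop = FALSE]
    snps <- snps[match(kept_snps, snps$snp), , drop = FALSE]
  }
  af1 <- colMeans(G, na.rm = TRUE) / 2
  G_dom <- dominant_code(G, af1)

  # -- methylation prep -----------------------------------------------------
  cross <- cohort$probes$cpg[cohort$probes$cross_reactive %in% TRUE]
  pf <- probe_filter(M, cross_reactive = cross)
  M <- M[, pf$keep, drop = FALSE]
  M <- winsorize_betas(M)

  # -- scans ----------------------------------------------------------------
  scans <- list(
    E = emodel_scan(M, E, covariates = covs),
    G = gmodel_scan(M, G_dom, covariates = covs,
                    chunk_size = config$chunk_size,
                    emit_p_max = config$emit_p_max$G),
    GxE = gxe_scan(M, G_dom, E, covariates = covs,
                   chunk_size = config$chunk_size,
                   emit_p_max = config$emit_p_max$GxE))
  scans$E <- scans$E[scans$E$p <= config$emit_p_max$E |
                       is.na(scans$E$p), , drop = FALSE]

  if (!is.null(config$out_dir)) {
    dir <- file.path(config$out_dir, name)
    .write_tsv(scores, dir, "stress_scores.tsv", config$seed)
    for (m in names(scans)) {
      .write_tsv(scans[[m]], dir, sprintf("scan_%s.tsv", m), config$seed)
    }
    .write_tsv(data.frame(filter = names(filt$drops),
                          dropped = as.integer(filt$drops)),
               dir, "snp_qc_log.tsv", config$seed)
    .write_tsv(data.frame(step = names(pf$drops),
                          dropped = as.integer(pf$drops)),
               dir, "probe_qc_log.tsv", config$seed)
  }

  list(scores = scores, E = E, G_dom = G_dom, betas = M,
       covariates = covs, snps = snps, scans = scans,
       qc = list(snp_drops = filt$drops, probe_drops = pf$drops,
                 n_excluded_stress = kept$n_excluded),
       subjects = idx)
}

#' Meta-analysis and follow-up across cohorts
#'
#' Meta-analyzes the three models across cohorts, flags Bonferroni-
#' significant and suggestive records, annotates SNP-CpG distance and
#' cis/trans status, tests suggestive-set overlap between the Gmodel (or
#' Emodel) and the GxEmodel, and -- for significant hits -- runs the
#' stress-domain decomposition and the four-mediator mediation battery on
#' the pooled subject-level data (cohort entered as a covariate).
#'
#' @param results Named list of [run_cohort()] results (one per cohort).
#' @param data The [simulate_cohorts()] structure (or equivalent) holding
#'   subject-level inputs for follow-up, SNP and probe metadata.
#' @param config A [pipeline_config()].
#' @return List with `meta` (per model), `thresholds`, `annotated_gxe`,
#'   `overlap` (Fisher tests), `domain_decomposition`, `mediation`.
#' @export
run_meta_and_followup <- function(results, data,
                                  config = pipeline_config()) {
  cohort_order <- names(results)
  missing_co <- setdiff(cohort_order, names(data$cohorts))
  if (length(missing_co)) {
    stop("run_meta_and_followup: cohort(s) absent from data: ",
         paste(missing_co, collapse = ", "))
  }
  meta <- lapply(c(E = "E", G = "G", GxE = "GxE"), function(m) {
    meta_analyze(lapply(results, function(r) r$scans[[m]]), cohort_order)
  })

  snp_meta <- data$cohorts[[1L]]$snps
  probe_meta <- data$cohorts[[1L]]$probes
  n_snps <- length(unique(meta$G$snp))
  n_cpgs <- length(unique(meta$E$cpg))
  thresholds <- list(
    pairwise_tests = n_snps * n_cpgs,
    gxe = bonferroni_threshold(config$alpha, max(n_snps * n_cpgs, 1)),
    e = bonferroni_threshold(config$alpha, max(n_cpgs, 1)))

  for (m in names(meta)) {
    thr <- if (m == "E") thresholds$e else thresholds$gxe
    sug <- if (m == "E") config$suggestive_e else config$suggestive_g
    meta[[m]]$significant <- meta[[m]]$p < thr
    meta[[m]]$suggestive <- meta[[m]]$p < sug
  }

  annotate <- function(tab) {
    si <- match(tab$snp, snp_meta$snp)
    pi <- match(tab$cpg, probe_meta$cpg)
    ct <- classify_cis_trans(snp_meta$chr[si], snp_meta$pos[si],
                             probe_meta$chr[pi], probe_meta$pos[pi])
    cbind(tab, ct)
  }
  annotated_gxe <- annotate(meta$GxE)
  annotated_g <- annotate(meta$G)

  overlap <- list(
    snp_g_vs_gxe = suggestive_overlap_test(
      unique(meta$G$snp),
      unique(meta$G$snp[meta$G$suggestive]),
      intersect(unique(meta$GxE$snp[meta$GxE$suggestive]),
                unique(meta$G$snp))),
    cpg_g_vs_gxe = suggestive_overlap_test(
      unique(meta$G$cpg),
      unique(meta$G$cpg[meta$G$suggestive]),
      intersect(unique(meta$GxE$cpg[meta$GxE$suggestive]),
                unique(meta$G$cpg))))

  # pooled subject-level data for follow-up
  pool <- function(get) do.call(rbind, lapply(cohort_order, get))
  E_all <- unlist(lapply(results, function(r) r$E))
  covs_all <- pool(function(co) {
    cbind(results[[co]]$covariates, cohort = co)
  })
  covs_all$batch <- interaction(covs_all$cohort, covs_all$batch, drop = TRUE)

  hits_gxe <- meta$GxE[which(meta$GxE$significant), , drop = FALSE]
  hits_e <- meta$E[which(meta$E$significant), , drop = FALSE]

  # per-cohort QC can drop a SNP or probe in one cohort only; absent
  # columns contribute NA and fall out of the complete-case follow-up
  get_col <- function(field, id) {
    unlist(lapply(cohort_order, function(co) {
      m <- results[[co]][[field]]
      if (id %in% colnames(m)) m[, id] else rep(NA_real_, nrow(m))
    }))
  }
  domains_all <- pool(function(co) {
    results[[co]]$scores[, c("life_events", "contextual", "personal",
                             "interpersonal"), drop = FALSE]
  })
  meds_all <- pool(function(co) {
    data$cohorts[[co]]$mediators[results[[co]]$subjects, , drop = FALSE]
  })

  dd <- list(); med <- list()
  all_hits <- rbind(
    if (nrow(hits_gxe)) cbind(hits_gxe[, c("snp", "cpg")], model = "GxE"),
    if (nrow(hits_e)) data.frame(snp = NA, cpg = hits_e$cpg, model = "E"))
  if (!is.null(all_hits) && nrow(all_hits)) {
    for (h in seq_len(nrow(all_hits))) {
      cpg <- all_hits$cpg[h]
      y <- get_col("betas", cpg)
      is_gxe <- all_hits$model[h] == "GxE"
      g <- NULL
      if (is_gxe) {
        g <- get_col("G_dom", all_hits$snp[h])
        ok <- !is.na(g) & !is.na(y)
      } else ok <- !is.na(y)
      if (sum(ok) < 20L) next
      key <- paste0(all_hits$model[h], ":",
                    ifelse(is_gxe, paste0(all_hits$snp[h], ":"), ""), cpg)
      dd[[key]] <- domain_decomposition(
        y[ok], domains_all[ok, , drop = FALSE],
        g = if (is_gxe) g[ok] else NULL,
        covariates = covs_all[ok, , drop = FALSE])
      X <- if (is_gxe) {
        gx <- g[ok] * E_all[ok]
        gx - mean(gx)
      } else E_all[ok]
      extra <- if (is_gxe) {
        cbind(covs_all[ok, , drop = FALSE], G = g[ok], E = E_all[ok])
      } else covs_all[ok, , drop = FALSE]
      med[[key]] <- lapply(
        c(smoking = "smoking", alcohol = "alcohol",
          gestational_age = "gestational_age",
          birth_weight = "birth_weight"),
        function(mname) {
          mediate(X, meds_all[ok, mname], y[ok], covariates = extra,
                  alpha_mediation = config$mediation_alpha)
        })
    }
  }

  out <- list(meta = meta, thresholds = thresholds,
              annotated_gxe = annotated_gxe, annotated_g = annotated_g,
              overlap = overlap, domain_decomposition = dd,
              mediation = med)
  if (!is.null(config$out_dir)) {
    dir <- file.path(config$out_dir, "meta")
    for (m in names(meta)) {
      .write_tsv(meta[[m]], dir, sprintf("meta_%s.tsv", m), config$seed)
    }
    .write_tsv(annotated_gxe, dir, "meta_GxE_annotated.tsv", config$seed)
    med_rows <- if (length(med)) {
      do.call(rbind, lapply(names(med), function(k) {
        do.call(rbind, lapply(names(med[[k]]), function(mn) {
          r <- med[[k]][[mn]]
          data.frame(hit = k, mediator = mn, indirect = r$indirect,
                     se = r$se_indirect, p = r$p_indirect,
                     significant = r$significant)
        }))
      }))
    } else {
      data.frame(hit = character(), mediator = character(),
                 indirect = numeric(), se = numeric(), p = numeric(),
                 significant = logical())
    }
    .write_tsv(med_rows, dir, "mediation.tsv", config$seed)
  }
  out
}
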