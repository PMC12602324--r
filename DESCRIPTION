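Package: gxescan
Title: Genome-Wide by Epigenome-Wide Scans for Genotype by Prenatal
    Stress Interactions on DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-cohort pipeline for testing genotype (G), cumulative
    prenatal stress (E) and genotype-by-stress interaction (GxE) effects on
    cord-blood DNA methylation. Builds a cumulative psychosocial stress score
    from dichotomized questionnaire items (exclusion, predictive-mean-matching
    imputation, domain averaging, within-cohort standardization, IQR
    winsorization), applies SNP- and probe-level quality control (exact
    Hardy-Weinberg test, call-rate/MAF/info filters, VIF-based LD pruning,
    relatedness exclusion, dominant genotype coding, MAD-based probe
    selection), runs fast ordinary-least-squares association scans over all
    SNP-CpG pairs via Frisch-Waugh-Lovell covariate projection, combines
    sub-cohorts by inverse-variance-weighted fixed-effects meta-analysis with
    Cochran's Q and I2, classifies hits as cis or trans, tests enrichment
    (Fisher 2x2 overlap, hypergeometric gene sets with resampling FWER), and
    follows up hits with stress-domain decomposition and product-of-
    coefficients mediation. Includes a synthetic multi-cohort generator with
    planted G, E, GxE and mediated effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    rtracklayer,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
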