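# gxescan

Genome-wide-by-epigenome-wide scans for genotype-by-prenatal-stress
interaction effects on DNA methylation at birth.

## What this is for

Prenatal psychosocial stress leaves detectable marks on the newborn
epigenome, but whether a child's genotype modulates that imprint requires
testing an interaction for every SNP against every methylation probe — on
the order of 10^10 model fits across several sub-cohorts. `gxescan` packages
that analysis for epigenetics groups working with birth-cohort data: it
builds the exposure (a cumulative prenatal stress score from ~50
questionnaire items), applies genotype and probe quality control, runs three
association scans per cohort, meta-analyzes them, and follows up the hits.

The three models, fitted by OLS with methylation beta values $M_k \in [0,1]$
as the outcome and covariates $C$ (child sex, 5 genetic PCs, 7 cell-type
proportions, batch):

| model | fit per | tested term |
|---|---|---|
| Emodel | CpG | $M_k = \alpha + \beta_E E + \gamma'C + \varepsilon$ |
| Gmodel | SNP x CpG | $M_k = \alpha + \beta_G G_j + \gamma'C + \varepsilon$ |
| GxEmodel | SNP x CpG | $M_k = \alpha + \beta_G G_j + \beta_E E + \beta_{GE} G_j E + \gamma'C + \varepsilon$ |

$E$ is the standardized, 3-IQR-winsorized cumulative stress score (items
dichotomized to risk/no-risk, >50%-missing subjects excluded, predictive
mean matching imputation, domain means summed over the four domains: life
events, contextual, personal, interpersonal). $G_j$ is dominant-coded
(minor-allele carrier vs homozygous major). Scans run via
Frisch-Waugh-Lovell covariate projection, exactly equal to per-pair
regression but orders of magnitude faster; per-cohort results are combined
by inverse-variance-weighted fixed-effects meta-analysis with Cochran's Q,
I², per-cohort direction strings, and Bonferroni/suggestive thresholds.
Follow-up includes cis/trans annotation, Fisher overlap enrichment,
hypergeometric gene-set enrichment with resampling FWER, stress-domain
decomposition, and Sobel/bootstrap mediation through prenatal smoking,
alcohol, gestational age and birth weight.

Because individual-level birth-cohort data are access-restricted, the
package ships a first-class synthetic multi-cohort generator
(`simulate_cohorts()`) with planted G / E / GxE / mediated effects and a
truth registry, used by the test suite for end-to-end recovery validation.
See the methods vignette (`vignettes/gxescan-methods.Rmd`) for the model,
generator design, and every numerical convention.

## Worked example

Three synthetic sub-cohorts, a planted-interaction recovery run:

```r
library(gxescan)

cfg <- sim_config(n_subjects = c(400, 350, 300), n_snps = 60, n_cpgs = 50,
                  seed = 42)
sim <- simulate_cohorts(cfg)
pc  <- pipeline_config(seed = 42, emit_p_max = list(E = 1, G = 1, GxE = 1))
res <- lapply(names(sim$cohorts), function(co)
  run_cohort(sim$cohorts[[co]], pc, name = co))
names(res) <- names(sim$cohorts)
mf  <- run_meta_and_followup(res, sim, pc)

gxe <- mf$meta$GxE[order(mf$meta$GxE$p), ]
head(gxe[, c("snp", "cpg", "B", "SE", "p", "I2", "direction", "k")], 3)
#>           snp       cpg       B      SE        p    I2 direction k
#> 1247 rs000060 cg0000047 -0.0228 0.00493 3.84e-06 48.44       --- 3
#> 710  rs000035 cg0000010  0.0225 0.00527 1.92e-05  6.72       +++ 3
#> 829  rs000040 cg0000029  0.0265 0.00644 3.83e-05  0.00       +++ 3

sim$registry$planted_gxe
#>        snp       cpg   beta
#> 1 rs000041 cg0000033 -0.130
#> 2 rs000033 cg0000032  0.136
#> 3 rs000038 cg0000029  0.125
#> 4 rs000035 cg0000010  0.122
#> 5 rs000060 cg0000047 -0.131
```

The top meta-analysis interaction hit (`rs000060` x `cg0000047`,
B = -0.023 beta-value units per unit stress among carriers, combined over
k = 3 cohorts with direction `---`) is a planted pair; so is the runner-up,
and the third is a same-LD-block proxy of planted `rs000038 x cg0000029`.
At this panel size (26 QC-surviving SNPs x 50 CpGs = 1300 pairwise tests)
the Bonferroni threshold `mf$thresholds$gxe` is 3.85e-05, so the first two
hits are study-wide significant. `mf$mediation` and
`mf$domain_decomposition` hold the follow-up fits for every significant
hit, and setting `out_dir` in `pipeline_config()` writes each stage as TSV
(one directory per cohort plus one meta directory).

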