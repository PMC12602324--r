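---
title: "Methods: scanning for genotype-by-prenatal-stress effects on DNA methylation"
author: "gxescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning for genotype-by-prenatal-stress effects on DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxescan)
```

# The analysis

`gxescan` implements a genome-wide-by-epigenome-wide interaction analysis:
for every SNP $j$ and every CpG $k$ assayed on a methylation array, it asks
whether the association between cumulative prenatal stress and DNA
methylation at birth depends on genotype. Methylation is the outcome
throughout, on the beta-value scale (methylated signal over total signal,
in $[0,1]$). Three nested linear models are fitted per (sub-)cohort:

* **Emodel** (per CpG): $M_k = \alpha + \beta_E E + \gamma' C + \varepsilon$
* **Gmodel** (per SNP-CpG pair): $M_k = \alpha + \beta_G G_j + \gamma' C + \varepsilon$
* **GxEmodel** (per SNP-CpG pair):
  $M_k = \alpha + \beta_G G_j + \beta_E E + \beta_{GE}\, G_j E + \gamma' C + \varepsilon$

where $E$ is the standardized, winsorized cumulative prenatal stress score,
$G_j$ a dominant-coded genotype (carrier of at least one minor allele vs
homozygous major — robust to sparse minor-homozygote cells), and $C$ the
covariates: child sex, five genetic principal components, seven estimated
cell-type proportions, and methylation batch indicators. The GxEmodel always
contains both main effects next to the tested interaction; an interaction
test without its mains is not interpretable, and this matches the convention
of matrix-based EWAS interaction software.

Per-cohort estimates are combined by inverse-variance-weighted (IVW)
fixed-effects meta-analysis: $\hat\beta = \sum w_i b_i / \sum w_i$ with
$w_i = SE_i^{-2}$, $SE = (\sum w_i)^{-1/2}$, p-values from the normal
distribution (METAL semantics). Heterogeneity is quantified by Cochran's
$Q$ and $I^2 = \max(0, (Q - (k-1))/Q) \cdot 100$, with $I^2 \ge 75\%$ read
as considerable. A record is combined over however many cohorts report it;
the cohort count `k` is kept so downstream filtering can demand
all-cohort support.

Significance is Bonferroni-corrected for the number of tests actually run
($\alpha / (n_{SNPs} \times n_{CpGs})$ for the pair-level models,
$\alpha / n_{CpGs}$ for the Emodel). Suggestive thresholds default to
$5\times10^{-8}$ (pair-level) and $1\times10^{-5}$ (CpG-level).

# The cumulative stress score

Roughly 50 questionnaire items collected during pregnancy are reduced to one
score per subject in a fixed order:

1. **Dichotomize** each item to 0 = no risk / 1 = risk via a per-item
   config rule (threshold + direction, or identity for binary items).
   Harmonization rules are data, not code: the item list and cutoffs load
   from configuration.
2. **Exclude** subjects missing strictly more than 50% of items.
3. **Impute** the remainder by single-imputation predictive mean matching:
   chained equations, linear predictor over all other items, the 5 donors
   nearest in predicted value (ties to the lowest subject index), 60 cycles.
   Donors contribute observed values, so imputed items stay binary. We read
   "iterations" as chained-equation cycles, the usual meaning in `mice`-style
   imputation.
4. **Average** items within the four domains — life events, contextual
   risk, personal stress, interpersonal stress — giving domain scores in
   $[0,1]$; **sum** the four into a total in $[0,4]$.
5. **Standardize** within cohort (mean 0, SD 1, denominator $n-1$) and
6. **Winsorize** at $[Q_1 - 3\,IQR,\ Q_3 + 3\,IQR]$. Standardization comes
   first because the winsorization bounds are defined on the standardized
   score's quantiles. Quantiles use linear interpolation between order
   statistics (type 7), the most common default; the rule is idempotent and
   rank-preserving among unclipped values.

# Quality control

**SNPs** are filtered in a fixed, audited order: call rate $\ge 95\%$,
Hardy-Weinberg exact $p \ge 10^{-7}$, MAF $\ge 5\%$, then an imputation
info-score floor where scores are supplied. The HWE test is the exact
conditional test: given the allele-count margins, all attainable
heterozygote counts are enumerated and those no more probable than the
observed one are summed (log-gamma arithmetic, stable to large n). MAF and
HWE are computed after sample exclusions, on the analysis sample.
Cryptic relatedness (pairwise IBD > 0.15, estimates supplied externally) is
resolved greedily from the highest-IBD pair down, keeping the member with
more non-missing data (ties broken by a seeded draw); a post-condition
guarantees no retained pair stays above threshold. LD pruning follows the
PLINK `--indep` parameterization (window 50 SNPs, step 5, VIF cap 2) on
additive dosages, iteratively dropping the highest-VIF SNP within each
window. Dominant coding defines the minor allele in a designated reference
cohort and harmonizes other cohorts by allele-label matching; A/T and C/G
strand-ambiguous SNPs cannot be resolved by labels and are dropped with a
warning.

**Probes**: cross-reactive probes are removed from a supplied list;
variability filtering is a configurable rule (MAD threshold or top-K by
MAD) because the original epigenome-wide-variability probe list is an
external artifact; an optional shared-probe list restricts to probes valid
on both array generations. Beta values are then winsorized per probe with
the same 3-IQR rule. Filtering precedes winsorization so that clip bounds
are computed on the analysis set.

# The fast scan and its oracle

Fitting $>10^{10}$ small regressions naively is infeasible, so the scans
use the Frisch-Waugh-Lovell decomposition: project the outcome matrix and
the tested term off the nuisance design once, then every pair reduces to a
few inner products. Per genotype missingness pattern (per-SNP complete
cases; exactness over speed), the nuisance design is rebuilt, factored by
QR, and cached. Collinear covariate columns are dropped by pivoted rank
detection at a tolerance of $10^{-8}$ relative to the leading diagonal.
Degrees of freedom are $n - p$ with $p$ the number of estimated
coefficients; two-sided p-values come from the t distribution. The reported
effect-size increment $\Delta adjR^2$ is the adjusted-$R^2$ of the full
model minus that of the model without the tested term.

Interactions can be exactly collinear with the main effects (for example a
lone non-carrier makes $G_jE$ a linear combination of $1, E, G_j$); such
pairs are flagged `collinear` and skipped, as are SNPs monomorphic on their
complete-case subset.

`naive_ols_oracle()` is the package's own textbook QR-based per-pair
regression. Every scan statistic is tested against it (and it against
`lm()`) to $10^{-8}$ relative error on random designs with and without
missing genotypes, and results are invariant to CpG chunk size by
construction — chunking only batches the projections.

# Annotation, enrichment and follow-up

SNP-CpG distance is $|pos_{CpG} - pos_{SNP}|$ computed from raw positions
even across chromosomes — a reporting convention for tabulated pair
distances — while the *cis* call additionally requires the same chromosome
and distance $\le$ 1 Mb. Nearest genes minimize the distance to the
interval (0 inside), ties to the lower start coordinate; BED input is
converted from 0-based half-open to 1-based inclusive coordinates. These
tie/boundary conventions are stated, not claimed identical to any external
annotator.

Fisher 2x2 tests (e.g. suggestive status in one model versus another, over
the shared SNP or CpG universe) use the exact two-sided rule — sum all
tables with the observed margins whose probability does not exceed the
observed table's — with the odds ratio as the sample cross-product ratio
(Haldane +0.5 on zero cells; Woolf log-OR CI). The conditional-MLE OR that
some software reports differs; the cross-product form is documented here.
Gene-set enrichment is a per-set hypergeometric over-representation test
with a resampling FWER: the adjusted p of a set is the fraction of seeded
random candidate sets (same size, drawn from the universe) whose minimum
raw p beats the observed one, floored at the raw p.

For significant hits, **stress-domain decomposition** refits the model with
all four domain scores (and, for interaction hits, all four G-by-domain
terms) entered jointly; a domain contributing at $p < 0.05$ over and above
the co-occurring domains is flagged as unique. **Mediation** uses the
product of coefficients: $a$ from mediator $\sim X + C$, $b$ and the direct
effect from $Y \sim X + \text{mediator} + C$, indirect $= ab$ with the
first-order delta SE $\sqrt{a^2 SE_b^2 + b^2 SE_a^2}$ (Sobel test; optional
percentile bootstrap), threshold $0.0125 = 0.05/4$ mediators, each mediator
modeled separately. For linear complete-data models the two-regression
estimates coincide with joint ML estimation, and total = direct + indirect
holds as an identity. For interaction hits the mediation exposure is the
centered $G \times E$ product with $G$ and $E$ retained as covariates — the
natural choice, since the moderated effect is the quantity whose pathway is
being probed. Follow-up models run on the pooled subject-level data with
cohort entered as a covariate (and batch nested within cohort).

# The synthetic multi-cohort generator

Real birth-cohort genotype and methylation data cannot be redistributed, so
validation runs end-to-end on synthetic cohorts whose defaults mirror the
emulated study design:

* **3 sub-cohorts** of 1224, 949 and 790 subjects with distinct batch
  structure (3, 4, 5 batch levels).
* **Stress items**: 50 binary items split 13/13/12/12 over the four
  domains, sharing a per-domain Gaussian liability (loading 0.8) so items
  cluster realistically; the item intercept is solved numerically so the
  expected total score matches the per-cohort targets 0.36 / 0.44 / 0.51
  (on the 0-4 scale). Item missingness is MCAR at 5%. Item prevalence
  profiles and score reliability are not published quantities, so they are
  exposed as free parameters rather than guessed; all items share one
  prevalence within a cohort.
* **Genotypes**: per-SNP MAF uniform on $[0.05, 0.5]$; haplotypes built by
  a Li-Stephens-style copy mechanism — within a 5-SNP LD block each
  haplotype copies its previous allele with probability 0.8, else draws
  fresh — giving Hardy-Weinberg genotypes with tunable block LD. SNP ids
  and positions are shared across cohorts.
* **Methylation**: each CpG has a latent Gaussian value (baseline uniform
  on logit $[-1.5, 1.5]$, small random covariate and batch loadings,
  residual SD 0.4) squashed through the inverse logit, keeping betas in
  $(0,1)$ without truncation artifacts.
* **Planted effects**: disjoint CpG sets receive G-only, E-only, GxE and
  smoking-mediated effects. Coefficients are calibrated per CpG, by
  root-finding on a Monte-Carlo quadrature, so that the *observed-scale*
  adjusted-$R^2$ increment of the tested (partialled) term hits the target,
  default 0.02 — the logistic squashing otherwise attenuates a
  latent-scale target by up to a factor of three, and the interaction
  predictor loses variance to its main effects ($var(GE - qE) = q(1-q)$
  for carrier probability $q$). An optional per-cohort multiplier scales
  planted effects to exercise the $I^2$ machinery.
* **Mediators**: standardized smoking $= 0.5 \cdot$ stress + noise;
  alcohol, gestational age (40 ± 1.5 weeks) and birth weight (3530 ± 500 g)
  are null paths.
* One master seed fans out to per-component child seeds (an LCG hop), so
  any component is reproducible in isolation and the whole dataset is
  byte-identical under a fixed seed.

What the generator does **not** emulate: realistic chromatin or annotation
structure, genuine LD decay curves, population stratification beyond the
supplied PCs, non-random missingness, array batch artifacts beyond additive
batch shifts, and the heavy-tailed per-probe variance structure of real
arrays. Passing recovery tests therefore demonstrates correctness of the
statistical machinery under the assumed generative model, not robustness to
everything real data can do.

# Problem sizes and numerical choices

The validation suite exercises: exact-test equivalence against brute-force
enumeration (all HWE tables to $n = 50$; all Fisher tables with row margins
$\le 30$); scan-oracle equivalence on over 100 random designs of 30-60
subjects with missing genotypes; a null interaction scan of 200 SNPs x 200
CpGs at $n = 1000$ (type-I rate within 3 binomial SDs of 5%, KS uniformity
on $10^4$ p-values); and a 3-cohort recovery run at $n = 1000$ per cohort
with 150 SNPs x 120 CpGs, in which the top meta-analysis interaction hit
must be a planted pair (or its same-block LD proxy — block neighbours carry
the same signal, as correlated SNP clusters do in real data), the IVW meta
p must track the pooled-analysis p within 10% on the $\log_{10}$ scale, and
smoking mediation must be detected for planted mediated CpGs (and no null
mediator flagged) in at least 90% of 20 replicates at the pooled sample
size. These dimensions keep the full suite in a few minutes while leaving
every per-test sample size at or above the scale the corresponding
statistical claim needs.

Numerical conventions collected in one place: quantile type 7 everywhere;
rank tolerance $10^{-8}$ of the leading singular value; VIF cap applied
with perfect collinearity treated as infinite VIF; heterozygote-count
enumeration in log space; Fisher tie comparison at relative slack
$1+10^{-7}$ (the conventional guard against floating-point ties); PMM donor
ties to the lowest subject index; meta-analysis p from the normal, scan p
from the t; direction characters `+`, `-`, `?` with zero effects mapped to
`?`.

# Limitations

Single imputation understates imputation uncertainty (no pooling across
multiple imputations). The fast scan assumes homoscedastic Gaussian errors
within each fit; no robust/sandwich errors or mixed models are offered.
The FWER resampling for gene sets treats sets as flat (no ontology graph
propagation). Mediation is the classic product-of-coefficients under
linearity and no unmeasured confounding; it is not a causal sensitivity
analysis.
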