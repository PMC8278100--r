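---
title: "Methods: miRNA regulators of immune pathways and the IAMIPS risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA regulators of immune pathways and the IAMIPS risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ImmuMiR)
```

# The problem

MicroRNAs tune immune activity in solid tumours, but inferring which miRNA
regulates which immune program from bulk expression is confounded by tumour
purity: both miRNA and mRNA abundances co-vary with the malignant-cell
fraction of a biopsy, so naive miRNA–gene correlations partly measure
composition, not regulation. ImmuMiR implements a scan that (i) removes the
purity component from every miRNA–gene correlation, (ii) summarizes each
miRNA's genome-wide association profile as a ranked gene list, and (iii)
asks, per immune pathway, whether the pathway's genes crowd the top or
bottom of that list. Downstream, a fixed three-miRNA prognostic signature
(IAMIPS) converts standardized miRNA expression into a risk score with a
survival-optimal cutpoint, and a drug screen relates the score to imputed
IC50 profiles.

# The scan, step by step

**Purity-adjusted association.** For miRNA $M$, gene $G$ and purity $P$
over $n$ patients, the first-order partial correlation is

$$\mathrm{PCC} = \frac{R_{MG} - R_{MP}R_{GP}}
  {\sqrt{1-R_{MP}^2}\sqrt{1-R_{GP}^2}},$$

with plain Pearson correlations on the right. Its two-sided p-value uses
the standard transform $t = \mathrm{PCC}\sqrt{(n-3)/(1-\mathrm{PCC}^2)}$ on
$n-3$ degrees of freedom (one covariate partialled out). The test is not
prescribed by the score's definition; the $t$ form is the textbook choice
for a first-order partial correlation, and the suite verifies its
calibration under an independent Gaussian null. $|\mathrm{PCC}|$ is clipped
to $1-10^{-12}$ before the transform so collinear inputs stay finite.

**Rank score.** Genes are ordered by
$\mathrm{RS} = -\log_{10}(p)\cdot\mathrm{sign}(\mathrm{PCC})$, descending,
with ties broken by gene id so the ordering is reproducible. $p$ is floored
at $10^{-300}$; RS is only used for ordering and as an enrichment weight,
so the floor has no practical effect beyond keeping values finite. Raw
(not multiplicity-adjusted) p-values feed RS: adjustment is monotone within
one miRNA and would not change the ordering, only the weights.

**Enrichment.** Each pathway is scored by the weighted
Kolmogorov–Smirnov running sum: walking the ranked list, hits advance by
$|\mathrm{RS}|^w / \sum_{hits}|\mathrm{RS}|^w$ and misses retreat by
$1/(N-N_{hit})$; the enrichment score (ES) is the deviation of maximal
absolute value. The default $w=1$ weights hits by association strength;
$w=0$ recovers the classic KS statistic (both are tested against naive
reimplementations and against an independent GSEA implementation).

**Permutation null and miRES.** The null is gene-set permutation:
`nPerm` random same-size sets drawn from the ranked universe, rescoring
each. The p-value conditions on the observed sign,

$$p = \frac{1 + \#\{|ES_0| \ge |ES|,\ \mathrm{sign}(ES_0)=\mathrm{sign}(ES)\}}
  {1 + \#\{\mathrm{sign}(ES_0)=\mathrm{sign}(ES)\}},$$

so that the signed combination
$\mathrm{miRES} = 1-2p$ (ES > 0) or $2p-1$ (ES < 0) keeps a coherent sign
interpretation near significance. miRES runs from $-1$ (strong depletion)
to $+1$ (strong enrichment), with $p=0.5$ mapping to 0. A pair is called
significant when $|\mathrm{miRES}| > 0.995$ — equivalently $p < 0.0025$ —
*and* its BH FDR, pooled across all miRNA × pathway pairs of the scan, is
below 0.05. Note that for non-significant pairs ($p > 0.5$) miRES crosses
zero and takes the opposite sign of ES; that regime never passes the dual
filter, because large $p$ forces large FDR.

**Permutation resolution.** The pseudocount bounds the smallest attainable
p at $1/(1+\#\mathrm{same\ sign}) \approx 2/\mathrm{nPerm}$, so the
smallest attainable BH-adjusted p in a scan of $m$ pairs is about
$2m/\mathrm{nPerm}$. The default `nPerm = 1000` (the conventional figure
for gene-set permutation) therefore resolves FDR at the 0.05 level only
for scans of up to ~25 pairs; the recovery analyses in this package scan
$50 \times 5 = 250$ pairs and run at `nPerm = 20000`
($2m/\mathrm{nPerm} = 0.025$). When planning a scan, pick
$\mathrm{nPerm} \gtrsim 40\,m$ if the pooled FDR filter matters. The
permutation kernel is compiled (hit positions are sampled in R under the
session seed; the running-sum extrema are computed in C++), so large
`nPerm` is cheap.

**Determinism.** One integer seed in `scanConfig()` drives every draw;
pathways with equal effective size share one null per miRNA (random sets
depend only on the list and the set size), and record order is fixed, so
repeated runs are byte-identical.

# Preprocessing conventions

- Counts are library-size normalized to reads per million (RPM, miRNA) or
  length-corrected transcripts per million (TPM, mRNA; gene lengths in kb
  are caller-supplied since no annotation is bundled). RPM is the CLI
  default for both matrices.
- The log transform is $\log_2(x+1)$: normalized expression contains exact
  zeros, and the +1 offset pins them at zero. The offset is a package
  choice; any fixed offset gives rank-identical downstream results for a
  cohort.
- Features with zero counts in *strictly more than* half the samples are
  dropped before normalization, so a feature at exactly 50% zeros
  survives.
- Risk scoring requires per-cohort z-scored expression (`zscoreRows`, n−1
  denominator); standardizing per cohort is what makes the packaged
  coefficients transferable across data sets. Constant rows become zero
  with a warning rather than an error, since single-feature degeneracy
  should not abort a cohort.
- Inputs are aligned on the intersection of sample ids, with the dropped
  count reported.

# The IAMIPS signature, cutpoint and drug screen

The packaged signature is the published three-miRNA LASSO-Cox fit:
risk = $0.015\,z(\text{miR-216a-5p}) - 0.035\,z(\text{miR-194-3p})
- 0.124\,z(\text{miR-3677-3p})$, cutoff 0.05. Refitting (univariate Cox
screening, 10-fold CV LASSO) is out of scope: those are standard
estimators whose training cohort is not bundled; the scoring method is the
tool's job. Patients with score strictly above the cutoff are high-risk;
the boundary case goes to low risk (a convention — the source formula is
silent, and the choice only matters for exact ties).

`optimalCutpoint()` is the maximally selected log-rank statistic:
candidates are midpoints of adjacent sorted unique scores, each side must
hold at least `minprop` (default 0.1) of subjects — the usual constraint
that keeps the statistic away from unstable extreme splits — and ties go
to the smaller cutpoint for determinism. The maximally selected statistic
is biased as a *test* (it maximizes over cutpoints); here it only selects
an operating threshold, and group comparison p-values should be read with
that in mind.

The drug screen intersects two drug-level criteria, each BH-corrected
across drugs only: |Pearson r| with the risk score > 0.3 at FDR < 0.05,
and |log2 fold change| of IC50 (high − low risk) > 0.5 at FDR < 0.05,
using Welch's t-test (variances are not assumed equal; the plain t-test is
a special case). Constant IC50 rows have undefined correlation and are
excluded with a warning.

# The synthetic cohort generator

`generateCohort()` produces the study conditions every statistical claim
in the test suite is evaluated under. Defaults: 200 patients, 50 miRNAs,
2000 genes, five disjoint 40-gene pathways, one planted regulation
(`mir001` up-regulating `pathway1` with effect 0.8 on 60% of its genes).

- Purity is Uniform(0.3, 0.9) — the realistic range for resected
  carcinoma samples.
- Latent log expression is baseline + (feature-specific purity slope ×
  purity) + Gaussian noise (sd 0.5); purity slopes are N(0, 1) on both the
  miRNA and gene side, which makes purity a genuine confounder of the
  naive correlation (the suite demonstrates that plain Pearson inflates
  |r| > 0.3 calls relative to the adjusted PCC on null cohorts).
- A planted pair adds `direction × effect × z(miRNA latent)` to its target
  genes' log expression before noise.
- Observed counts are Poisson(exp(latent)), so the zero filter and
  normalization run on genuine counts.
- Survival: Weibull event times (shape 1.2, scale 40 time units) whose
  hazard is multiplied by `hazardRatio` (default 3) for patients whose
  true score — a linear combination (1, −1, 0.5) of the first three
  standardized latent miRNAs — exceeds the true cutpoint (default 0);
  censoring is independent exponential (mean 60). The step-at-cutpoint
  hazard was chosen over a log-linear one so that the recorded cutpoint is
  an identifiable target for the cutpoint search rather than a label.

What the generator does *not* emulate: negative binomial overdispersion,
library-size variation, miRNA-family correlation structure, measurement
batch effects, and realistic censoring patterns. Passing tests show the
algorithms are correct and calibrated under the stated generative model;
they do not certify performance on real cohorts, where purity estimates
are themselves noisy and effect sizes are smaller.

A side effect of planting a regulation worth knowing: the planted program
makes the target pathway's genes mutually correlated, and under gene-set
permutation such inter-gene correlation can lift *other* miRNAs'
enrichment on that pathway above the random-set null. This is a recognized
property of gene-set-permutation GSEA, not an artifact of this
implementation; the false-positive calibration is therefore assessed on
null cohorts.

# Numerical and degenerate-case choices

- Partial correlation requires $n \ge 4$, non-constant vectors, and
  $|R_{MP}|, |R_{GP}| < 1$; absent purity falls back to plain Pearson
  with a warning.
- miRES is undefined at ES = 0 (a measure-zero event with continuous
  weights); the scalar function errors, the scan records NA and never
  flags such a pair.
- If every hit weight is zero at $w > 0$ (all member p-values exactly 1),
  the ES falls back to unweighted steps with a warning.
- Ties in the running sum between equal positive and negative deviations
  resolve to the positive value; the naive oracle in the tests encodes the
  same rule.
- ssGSEA (`ssgseaScores`) uses ascending-rank weights $r^{\alpha}$ with
  $\alpha = 0.25$ and reports raw scores; min–max rescaling across samples
  sits behind a flag since both conventions are in circulation. Sets with
  no measured gene score 0 with a warning.

# Problem sizes used by the test suite

The suite's simulation-based checks use: 2000 replicates at $n=50$ for
partial-correlation calibration; 500 replicates at $n=200$ for log-rank
calibration; 20 null cohorts at the generator defaults (`nPerm` 1000) for
scan false-positive control; 20 planted cohorts at the defaults
(`nPerm` 20000) for regulator recovery; 20 replicates at $n=300$,
hazard ratio 3, for cutpoint recovery; and 20 replicates of a 22-drug
table (2 planted) for the screen. These sizes make each claim's sampling
error small relative to its acceptance margin while keeping the full
suite in the minutes range on one core.

# Known limitations

- The permutation scheme is gene-set permutation only; phenotype
  permutation (which preserves inter-gene correlation) is out of scope.
- The FDR pool is all pairs of one scan; scans run in batches are not
  jointly corrected.
- No leading-edge gene reporting, no moderated or robust correlation
  variants, and a single covariate (purity) only.
- qRT-PCR-scale inputs are not supported for the signature: the published
  qRT-PCR validation used a different cutoff on a U6-normalized scale
  whose transform to z-scores is not specified, so only
  sequencing/array-style matrices are scored here.
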