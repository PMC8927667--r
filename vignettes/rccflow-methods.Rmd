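---
title: "Count processing and outcome association for targeted nCounter panels"
author: "rccflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count processing and outcome association for targeted nCounter panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rccflow)
```

## Scope

rccflow processes digital expression counts from targeted NanoString
nCounter panels and relates gene expression to clinical outcome in small
oncology cohorts. The motivating setting is a custom panel of 221
stroma- and growth-factor-signaling genes measured in high-grade serous
ovarian cancer, where the clinical question is which genes separate
patients who relapse within six months of completing platinum-based
chemotherapy ("resistant") from those with an ongoing response, and which
genes carry prognostic weight for overall (OS) and recurrence-free (RFS)
survival.

The package covers five layers: lane-file input/output (the plain-text RCC
format), control-based quality checks, a two-stage normalization with
background-noise gene exclusion, a gene-wise outcome-association battery
(Cox regression, Kaplan–Meier, normality-gated two-group tests, bootstrap
ROC, FDR), and hypergeometric gene-set overrepresentation. A synthetic
cohort generator with planted effects makes every layer testable by
parameter recovery.

## The count-processing model

An nCounter lane reports one integer count per probe. Four probe classes
matter:

* **negative controls** (8 by default): probes with no human target; their
  counts estimate non-specific binding.
* **positive controls** (6): spiked synthetic RNAs on a known 4-fold
  titration (128, 32, 8, 2, 0.5, 0.125 fM by default), giving each lane an
  internal standard curve.
* **reference (housekeeping) genes** (9, in three expression tiers):
  anchors for between-sample normalization.
* **endogenous targets** (221): the biology.

### Technical normalization

For sample $s$, the background threshold is

$$b_s = \bar{x}^{neg}_s + 2\,\mathrm{sd}(x^{neg}_s),$$

with the sample standard deviation on the $n-1$ denominator. Every
endogenous and housekeeping count is reduced by $b_s$ and floored at zero
(counts cannot be negative; control probes pass through untouched so the
audit trail stays complete). Note the deliberate conservatism: the
threshold over-subtracts the expected background by two standard
deviations, so counts near background are compressed toward zero rather
than unbiasedly corrected. This is the intended behavior of the
procedure, not an estimation target.

### Biological normalization

Let $g_s$ be the geometric mean of the (background-subtracted) reference
genes in sample $s$, and $G = (\prod_s g_s)^{1/n}$ their grand geometric
mean. The normalization factor is $f_s = G / g_s$; all target counts are
multiplied by $f_s$ and then rounded **half away from zero** to integers
(2.5 becomes 3 — commercial rounding, not R's round-half-to-even; this is
asserted in the tests). Before rounding, the reference-gene geometric mean
is exactly equal across samples; after rounding it agrees within 0.5
counts per gene.

Two numerical choices guard degenerate input: reference counts of zero
after subtraction are replaced by 1 (with a warning) so the geometric
means stay defined, and a sample whose reference geometric mean is still
non-positive is a hard error naming the sample.

A subtlety worth stating: multiplying every count of one sample by $c$
rescales $g_s$ by $c$ but also drifts the grand mean $G$ by $c^{1/n}$, so
normalized counts are invariant up to that shared $c^{1/n}$ shift, which
vanishes as $n$ grows. The test suite checks the exact form of this
invariance rather than the idealized one.

### Background-noise gene exclusion

After normalization, each endogenous gene is tested against the pooled raw
negative-control counts of all samples with a one-sided two-sample test
(alternative: the gene exceeds background). The default is Welch's
unequal-variance $t$; a one-sided Wilcoxon rank-sum variant sits behind
`noise_test = "wilcoxon"`. Genes with $p \ge \alpha$ (default 0.05) are
excluded from all downstream analysis but recorded with their p-values.
When a gene's counts are identically equal to a constant background the
tie rule applies ($p = 1$).

The exclusion defaults to running after biological normalization; a config
switch (`noise_on = "subtracted"`) runs it directly on the
background-subtracted counts, and both orders are exercised in tests. The
test is cohort-level (each gene's per-sample counts against the pooled
negatives), which is the reading we adopt of "not relevantly expressed
across the cohort"; a per-sample exclusion variant would drop different
genes per lane and break the rectangular count matrix, so it is not
offered.

## Outcome association

**Outcome label.** `derive_outcome()` labels a patient resistant iff the
recurrence event was observed and RFS is below 6 months after therapy
completion. Patients censored before 6 months cannot be classified
reliably; they keep the ongoing-response label but carry an explicit
caveat flag. Records with missing survival get `NA` and are excluded from
all survival fits (their count is logged and reported in the manifest —
never silently dropped).

**Survival scan.** Per retained gene, a single-covariate Cox
proportional-hazards fit on standardized $\log_2(\text{count}+1)$
expression (Efron tie handling — months are heavily tied; the covariate
scale is our choice, as count scales make hazard ratios uninterpretable
across genes). The hazard ratio, 95% Wald interval, and all three
standard tests (likelihood ratio, Wald, score/logrank) are reported; the
score test feeds the forest-plot table by convention, and BH-FDR is
applied within each endpoint family (OS or RFS). Complete separation or
monotone likelihood is flagged as non-convergence rather than reported as
a silent estimate. `km_estimate()` adds product-limit curves, median
survival (smallest $t$ with $S(t) \le 0.5$, `NA` when never reached) and
step-function lookups of $S(t)$. `dichotomize_expression()` median-splits
a gene for high/low group comparisons, sending values equal to the median
to "low".

**Differential expression.** Per gene, Shapiro–Wilk at
$\alpha_{norm} = 0.05$ gates each outcome group: both Gaussian-compatible
means Welch's $t$ (we prefer the unequal-variance form over the pooled
Student's $t$ because group variances in 12-vs-12 cohorts are
unverifiable; a documented, switchable deviation), otherwise Wilcoxon
rank-sum (exact for $n \le 25$ without ties, normal approximation with
continuity correction beyond). Fold changes are
$-\log_2(\mathrm{loc}(A)/\mathrm{loc}(B))$ with location = mean on the
parametric branch and median otherwise, a $+1$ pseudocount throughout,
and orientation $A$ = ongoing response, $B$ = resistant, so genes higher
in resistant patients get positive values; the orientation is recorded in
the result's metadata because it is a convention, not a finding.

**ROC.** AUC uses the Mann–Whitney pair-counting identity with midranks
(ties count one half). The 95% interval is a percentile bootstrap over
1000 class-stratified resamples (stratification avoids degenerate
one-class draws), and the operating point maximizes Youden's $J$ with
ties broken toward the lower cutpoint. Fixed seed implies bit-identical
output.

**Overrepresentation.** Gene sets load from GMT; enrichment is the
upper-tail hypergeometric probability of the observed overlap, BH-FDR
across sets. The universe is the retained (noise-excluded) panel genes,
not the genome: the panel is targeted, and a genome universe would
inflate every p-value. Sets with fewer than 3 mapped members are skipped.
Permutation-based running-score enrichment and external web toolkits are
deliberately out of scope; the per-pathway signed fold-change table is
exported for external map coloring instead.

## The synthetic-data generator

`sim_config()` describes a cohort in the image of the motivating study:
24 patients, 221 endogenous genes, 8 negative controls, 6 titrated
positive controls, 9 reference genes in tiers of three
(high/medium/low, 2000/500/125 expected counts, spanning the panel's
dynamic range), and 5 of 24 patients with missing survival when
`missing_survival_fraction = 5/24`.

Counts are negative-binomial with mean
$\mu = \text{lane factor} \times \text{baseline} \times \text{fold change}
+ \text{background}$ and variance $\mu + \phi\mu^2$ (dispersion
$\phi = 0.05$ by default, $\phi = 0$ degenerates to Poisson); negative
controls are Poisson at the background mean; positive controls are
Poisson at lane factor × 8 counts/fM × nominal concentration. Endogenous
baselines are log-normal (median 300 counts, log-sd 1) unless
`target_baselines` pins them explicitly. RFS is exponential with rate
$\lambda_0 \exp(\sum_g \beta_g z_g)$, where $z_g$ is the standardized
log2 expression of planted hazard genes and $\lambda_0 = \ln 2 / 9$ per
month (median 9 months); OS is RFS plus an independent exponential
post-recurrence time; censoring is uniform on $[0, 60]$ months; missing
survival is an explicit marker, never a zero time.

The generator emulates the *structure* real lanes have — class layout,
titration, lane-scale effects, overdispersed counts, outcome coupling —
but not FFPE RNA degradation, probe chemistry, batch drift across
cartridges, or the unknown true distribution of the original counts (no
raw data are public). Passing the recovery tests therefore demonstrates
that the pipeline's arithmetic and inference behave as specified under a
plausible generative law, not that any particular biological result is
reproduced.

## Validation design and problem sizes

The automated checks validate each stage against an oracle that is
independent of the implementation path: spreadsheet-style hand arithmetic
for thresholds, factors and rounding; closed forms (exponential median
$\ln 2/\lambda$, hypergeometric and Fisher enumeration, BH step-up by
hand); brute-force pair enumeration for AUC on exhaustive small grids;
and Monte-Carlo parameter recovery for the Cox and DE layers. Sizes were
chosen to make Monte-Carlo error small relative to the assertion bands:
50 seeds for the reference-equalization invariant, 180 samples for
lane-effect removal under Poisson noise with equal baselines of 300
(isolating the scale effect from background bias, which the subtraction
oracle covers separately), 100 seeds × 100 genes for noise-exclusion
accuracy, 500 null cohorts of 221 genes (12 vs 12) for type-I error —
judged against the 95% binomial band of a single 221-gene scan — 200
cohorts of $n=200$ for CI coverage, and $n=10{,}000$ for the
Kaplan–Meier closed form. The end-to-end pipeline is additionally run at
the 303-sample scale of a typical public validation cohort and checked
for byte-identical reruns under a fixed seed.

## Known limitations

* The over-subtraction built into the mean + 2 SD threshold biases
  low-expression genes downward; ratios of group means for genes near
  background reflect the bias. This is inherent to the procedure.
* The noise-exclusion test treats pooled negative controls as a reference
  distribution, ignoring lane-to-lane background correlation; with eight
  negatives per lane this is mild but real.
* Cox fits carry no proportional-hazards diagnostics beyond a
  non-convergence flag; with 19 usable patients in the motivating design,
  gene-wise models are screening tools, not final inference.
* The generator's negative-binomial law is a configurable stand-in; no
  distributional claim is made about real FFPE nCounter counts.
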