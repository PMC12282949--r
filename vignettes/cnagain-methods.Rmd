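---
title: "Methods: low-amplitude copy-number-gain analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-amplitude copy-number-gain analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnagain)
```

This vignette is the package's own account of its models and of the design
choices made where the methodology was genuinely open. The numbers quoted
as *defaults* are configuration values; every empirical statement below is
one that the test suite or `scripts/acceptance.R` computes.

## Copy-number model and binning geometry

Inputs are segmented profiles: per sample, disjoint genomic intervals with
a ploidy-normalized log2 copy-number ratio. Because values are divided by
sample ploidy, every call the package makes is *relative to ploidy* — a
"gain" in a tetraploid genome means more copies than four. Internally all
coordinates are 0-based, half-open; SEG input is treated as 1-based
inclusive by default with a dialect flag, because interval arithmetic with
half-open intervals is unambiguous.

`build_bins()` tiles each chromosome from 0 in `bin_size` steps and inserts
both centromere boundaries, so no bin spans two arms. We chose global
tiling with centromere splits rather than restarting the tiling at each arm
(both are available, `per_arm = TRUE`) because it keeps bin boundaries
comparable across samples and datasets regardless of centromere placement.
The centromere-interior bin is retained rather than dropped; on real
platforms it is simply missing-valued, and carrying it makes the bin union
an exact partition of the chromosome, which in turn makes the geometry
testable by exhaustive oracle.

The bin copy number is the overlap-length-weighted mean of segment values,
with the covered fraction carried alongside. No minimum covered fraction is
imposed for reporting a value — callers filter on `covered_fraction`
instead, because any hard-coded floor would be invisible downstream.
Two properties pin the implementation down: an interval fully covered by a
single segment returns that segment's value exactly, and refining a
segmentation (splitting any segment internally) changes nothing.

## Discrete calling

All thresholds are strict inequalities; a value exactly at a threshold
falls into the lower category. This matches the "higher than" phrasing of
the calling rules and makes ties deterministic. Defaults: `t_gain = +0.1`,
`t_loss = −0.1` on the ploidy-normalized log2 scale — roughly a single-copy
gain in a diploid background after typical shrinkage — and both are
per-dataset configuration, since appropriate cutoffs depend on platform
noise.

An arm is gained when the length with cn above `t_gain`, divided by the
*covered* length of the arm (not the full arm length), exceeds 0.8. Using
covered length keeps the rule meaningful for sparsely covered arms; an arm
with no data is flagged missing rather than not-gained.

Amplification is sample-relative: a gene is amplified when its copy number
strictly exceeds the highest whole-arm-gain copy number in the same sample.
The intuition is that anything clearly above the sample's own single-copy
arm-gain level must be a multi-copy event. For samples with no gained arm
the rule is undefined, so a fixed fallback (`amp_fallback = +0.9`, about
2 extra copies on the log2 scale) applies.

Five-way gene status uses the precedence `amplification ≻ arm_gain ≻
focal_gain ≻ loss ≻ neutral`. A gene *below* `t_gain` on a gained arm stays
`neutral`: status describes the gene's own copy number, and letting genes
inherit arm calls would blur exactly the arm-versus-focal distinction the
analysis needs.

Cohort gain/loss frequencies are standardized to z-scores across bins
within one cohort. This is a cohort-internal standardization (each bin
against the distribution over all bins), adequate for ranking recurrently
gained regions; it is documented as an approximation rather than a
calibrated significance measure.

## Dependency associations

The contrast of interest is low-amplitude gain (arm-level and focal gain
combined; an arm-only switch exists) versus neutral. "Student's t-test" is
implemented as the unequal-variance Welch test — the default two-sample test
in this statistical environment — with a pooled-variance switch. Groups
below 2 observations yield missing statistics rather than being silently
dropped.

Multiple testing uses Storey q-values: the null proportion is estimated by
the smoother over a lambda grid and caps at 1, so q-values never exceed
plain Benjamini–Hochberg. With fewer than 100 p-values, or when the
smoother is unstable, the estimate falls back to 1 (exact BH). q-values are
monotone in p by construction.

Ranking for enrichment uses sign(Δ)·(−log10 q), ties broken by |Δ| then
label so the order is reproducible; q = 0 is clamped to the smallest
positive double. The preranked GSEA statistic is the weighted
Kolmogorov–Smirnov running sum with weight |metric|. Significance comes
from gene-label permutations (default 1000, seeded): sample-level
permutation is impossible once only a ranked list exists. The p-value is
the rank of |ES| among the permuted |ES| values with add-one smoothing,
giving a floor of 1/(n_perm + 1) and a uniform null — the observed score is
exchangeable with the permuted ones under the null, so the magnitude rank
is pivotal. NES divides ES by the mean |null ES| of the same sign.

Candidate drivers require q < 0.3 *and* Δ < −0.05 in at least 2 of 3
datasets; all three constants are configuration. The lenient per-dataset q
is deliberately paired with the cross-dataset replication requirement.
Mutation co-occurrence uses Fisher's exact test (no test is canonical
here, and margins are small for rare events); expression upregulation uses
a one-sided test because the claim being checked is directional.

## Drug-response associations

AUC is oriented higher-is-more-resistant (the GDSC/CTRP convention) and the
orientation is asserted at load time rather than guessed. The no-gain group
is neutral-or-loss; amplified lines belong to neither group, since the
question is specifically about low-amplitude gain. Multi-target compounds
yield one record per (compound, target) pair. The on-target flag is a
conjunction — Pearson r > 0.3 *and* correlation p < 1e−10 — and correlation
operations require at least 30 shared cell lines; below that the record is
flagged untestable instead of reported.

## Elastic-net biomarker selection

Predictors are binary indicators (mutations; per-bin gain, loss and
amplification, encoded independently rather than exclusively; one-hot type
and subtype). They are left unstandardized so a coefficient reads directly
as an AUC shift per indicator; the response is centred. The alpha grid is
{0.1, 0.5, 0.9} with the CV-best alpha chosen per fit.

The lambda rule defaults to `one_se` (the largest lambda within one
standard error of the CV minimum). The minimizing lambda (`cv_min`,
available as a switch) systematically admits a handful of spurious features
on pure-noise responses, while `one_se` returns empty sets on noise and
still recovers planted effects — the selection here feeds a reported
biomarker list, so parsimony under the null is the priority. Replicates
(default 3) differ only in CV fold assignment; only features selected in
all replicates are reported, features whose coefficient sign flips are
dropped, and type/subtype covariates stay in the model but out of the
report. Each surviving feature is re-tested by linear-model ANOVA with
cancer type and subtype as the only covariates; features collinear with
those covariates are untestable.

## Survival

Per bin, a univariate proportional-hazards model is fitted separately on
the gain indicator and the loss indicator (Efron ties). No clinical
covariates are included by default because the per-bin scan is a screen,
not a prognostic model; adjustment hooks exist in the fitting call. The
signed survival score is HR for HR ≥ 1 and −1/HR for HR < 1, with HR = 1
assigned to the positive branch; it makes protective and harmful effects
symmetric around ±1. Bins need at least 3 samples per indicator group and
10 events overall; constant indicators are untestable.

## The synthetic cohort

The generator is the package's study design, not a tuning knob. Defaults:
4 chromosomes of 120 Mb with centromeres at 58–62 Mb (large enough to
separate arm-level from focal events at both 25-Mb and 1-Mb binning, small
enough for exhaustive oracles); per-arm gain/loss probabilities 0.15/0.10;
one focal gain per sample on average (2–20 Mb); amplifications in 5% of
samples (0.5–3 Mb at log2 level 1.2); single-copy levels ±0.3/−0.35;
Gaussian segment noise with sd 0.1. Breakpoints live on a 10-kb lattice,
which defines the coordinate granularity at which brute-force per-base
oracles operate. Event times are exponential with hazards multiplied by
planted per-bin hazard ratios and independent exponential censoring tuned
to an approximate 40% event rate.

What the generator emulates: segment-level profiles with arm/focal/
amplification structure, status-linked mean shifts in dependency and
expression, target-gain AUC shifts, planted mutation odds ratios, and
planted hazards — each recorded once in a truth ledger that recovery tests
consume. What it does not emulate: realistic breakpoint processes,
whole-genome doubling, wave/GC artefacts, heavy-tailed screen noise, or
correlated gene effects. Passing recovery tests therefore demonstrates that
the pipeline's inference machinery is correct under its stated model, not
that thresholds are optimal for any particular real platform.

One deliberate consequence of the defaults: segment noise (sd 0.1) equals
the call threshold (0.1), so a visible fraction of truly neutral arms is
called gained and planted dependency deltas attenuate at cohort scale —
the analysis drivers under `analysis/` show this honestly. The recovery
experiments that check estimation accuracy plant effects on the status
groups directly, so accuracy and call-noise robustness are assessed
separately.

## Problem sizes and reproducibility

The simulation-study battery uses: 1000 random profiles for the geometry
oracle and 1000 random arms for the arm rule; 20 cohorts of 100 lines per
status group (score sd 0.3) for the dependency ladder (−0.64/−0.44/−0.28);
20 pure-null cohorts of 2000 genes for false-discovery control; 10
replicates of the 3×500-gene candidate experiment; 1000 permutations and
100 null re-draws for enrichment; a 200-compound, 400-line screen with 20
planted ±0.12 AUC effects; 200 lines × ~320 features with three planted
effects for elastic-net stability; and 300-patient cohorts with a planted
hazard ratio of 2.6. All random draws derive from a single integer seed
through R's default Mersenne–Twister generator; equal-seed pipeline runs
are byte-identical, which the suite verifies by checksum.

## Known limitations

The z-score track is a cohort-internal standardization; per-dataset calling
thresholds must come from the user (the defaults suit the synthetic
cohort); confounder filtering consumes an externally supplied importance
table rather than refitting a dependency-prediction model; GSEA uses
gene-label permutations, which ignore inter-gene correlation; and the
elastic net does not model interactions or nonlinearities. Segmentation of
raw data, liftover, allele-specific copy number and peak-detection methods
in the GISTIC family are out of scope.
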