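---
title: "Methods: from differential lncRNA expression to cis-target prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from differential lncRNA expression to cis-target prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cncnet)
```

# The analysis chain

`cncnet` models a common two-group transcriptome design: bulk expression of
lncRNA and mRNA probes in a case group (labelled PDC by default) and a
control group (BC), already normalized to the log2 scale. The package's
question is which lncRNAs change between groups and which coding genes they
plausibly regulate. Five stages answer it, each behind its own function so
that any stage can be run, tested or replaced in isolation.

## Differential expression

The effect size is the difference of group means on the log2 scale,
reported alongside a signed linear fold change whose sign carries direction
and whose magnitude is `2^|log2fc|` (so the value is never inside (-1, 1)).
A zero difference reports `+1`.

The test statistic is a moderated t: the per-probe pooled residual variance
`s^2` (on `d = n1 + n2 - 2` df) is shrunk toward a prior variance `s0^2`
carrying `d0` prior degrees of freedom,

```
s2_post = (d0 * s0^2 + d * s^2) / (d0 + d)
t       = log2fc / (s_post * sqrt(1/n1 + 1/n2)),  df = d + d0.
```

The hyperparameters are estimated from all probes by the standard
empirical-Bayes method of moments: under the working model
`s^2 ~ s0^2 * F(d, d0)`, the mean and variance of `log(s^2)` are linear in
digamma/trigamma terms, and the trigamma equation for `d0` is inverted with
a Newton iteration. Two boundary conventions matter:

* when the observed dispersion of log variances does not exceed the
  chi-square sampling floor, there is no evidence of between-probe
  heterogeneity: `d0 = Inf` and `s0^2` is the mean variance (this makes the
  constant-variance input return exactly that constant);
* `d0 = Inf` is kept explicit and enters the t reference distribution
  through a large-df cap of 10^6, which is the normal limit to numerical
  precision, avoiding a special-cased distribution;
* `d0 = 0` is allowed as the shrinkage-free limit and reproduces the
  ordinary pooled-variance t exactly — a property the tests assert to
  1e-10.

The screening filter is the conventional array rule: `|FC| >= 1.5` on the
linear scale (equivalently `|log2fc| >= log2(1.5)`, non-strict, following
the ">=" convention that rule is usually written with) and raw `P < 0.05`
(strict). The filter deliberately uses raw P, which is how such screens are
habitually applied to arrays of this size; BH-adjusted FDR is always
computed and reported for modern use but does not gate the call. Fold
change is interpreted as a difference of log2 means rather than a ratio of
linear means — the standard choice for log2-normalized arrays, and the two
only coincide in the noise-free limit.

Welch's t (per probe), an exact-small-sample Mann–Whitney U and a paired t
are provided as the companion tests for designs where the pooled-variance
model is inappropriate. Mann–Whitney switches from exact enumeration to
the tie- and continuity-corrected normal approximation above a combined
sample size of 12.

## Coexpression network

Every DE-lncRNA x DE-mRNA pair is scored with the Pearson correlation
across **all** samples, cases and controls pooled. The sample set is a
genuine modelling choice: pooling maximizes n (22 in the default design)
and matches how coding–noncoding coexpression networks are usually built,
but it means a strong group effect on both members contributes to the
correlation. The `samples` argument exposes within-group correlation for
users who want the group-adjusted relationship instead.

Edge significance uses the exact null of the product-moment correlation
under bivariate normality, `t = r * sqrt(n-2) / sqrt(1-r^2)` on `n-2` df —
the tests verify this analytic P against a 10^5-shuffle permutation null at
n = 22. Both edge thresholds are strict (`|pcc| > 0.7`, `p < 0.05`),
following the ">" symbol such filters are stated with; the fold-change
filter above is non-strict for the same reason. Nodes with no passing edge
are not part of the network, so the node count is data-dependent and
smaller than the DE count. Edge P values are not multiplicity-adjusted for
the filter (none is conventionally applied at this stage); BH across all
candidate pairs is reported in an `fdr` column.

Hubs are nodes with raw degree (edge count) strictly greater than 60 —
degree centrality is left unnormalized because a threshold of 60 is only
meaningful for raw counts. The top-k edge list (default 30) is sorted by
ascending P with ties broken by larger `|pcc|`, then lexicographically by
ids so the output is deterministic.

## Cis-target prediction

A coding gene is a candidate cis target of a lncRNA when both lie on the
same chromosome within a 300 kb window and the pair is also a CNC edge.
Distance is the minimum gap between the two gene spans in bp (0 for
overlap), computed on 0-based half-open BED coordinates. Two conventions
were genuinely open and are resolved as follows:

* window measured from gene boundaries (span gap), not TSS-to-TSS — the
  window is described as "upstream and downstream" of the lncRNA without a
  TSS anchor, and span gap is symmetric and strand-agnostic;
* the boundary is inclusive (`<= 300000`), reading "within 300 kb" as
  non-strict;
* strand is recorded (`same_strand`) but never filters the window, since
  the window covers both sides regardless of orientation.

Queries run on the GenomicRanges interval index; the test suite proves the
result identical to an exhaustive quadratic scan on ~1,000 random loci,
including planted exact-boundary and overlap cases.

## Over-representation analysis

Gene-set enrichment of the up- and downregulated DE mRNAs (separately,
since opposite-direction signals dilute each other) uses the
hypergeometric upper tail `P[X >= k]` for an overlap of `k` between a
query of size `n` and a set of size `K` in a universe of size `N`. The
universe defaults to all mRNA gene symbols on the array — the standard ORA
background for array studies — and is overridable. `k = 0` gives `P = 1`
exactly (the upper tail at zero carries all mass). Raw `P < 0.05` flags
significance, with BH FDR reported alongside. Gene identity is the
annotation's gene-symbol column when provided, else the probe id, matched
case-sensitively; no identifier mapping is ever inferred.

## qPCR validation

Relative expression follows the single-reference 2^-ddCt method:
`dCt = Ct(target) - Ct(reference)` per sample, `ddCt` baselined on the
arithmetic mean control dCt per gene (equivalently the geometric mean
fold), `fold = 2^-ddCt`. Consequences asserted by the tests: any constant
added to all wells of a sample cancels; the control-group geometric mean
fold is 1 by construction; a noise-free planted 2-fold change is recovered
exactly. Group comparisons run on dCt — the log-abundance scale, where
normality is a far better approximation than on folds — while the reported
direction comes from the fold means, so "up" always means higher relative
expression in cases. Welch's t is the default; the exact Mann–Whitney is
available for small or skewed cohorts. Efficiency correction and
multi-reference normalization are out of scope.

# The synthetic-data generator

`synthetic_config()` fixes the emulated study conditions; the generator is
the package's ground-truth instrument, not a tuning knob.

* **Design.** 13 case vs 9 control arrays, and a 9 vs 12 validation cohort
  for qPCR — the smaller follow-up cohort such validation experiments
  typically recruit.
* **Scale.** The emulated array carries 22,621 lncRNA and 31,860 mRNA
  probes; the default config runs at one-tenth scale (2,262 / 3,186) so a
  full run stays interactive, with the full counts one argument away.
* **Signal.** Planted DE probes (defaults 40 lncRNA, 44 mRNA — the
  one-tenth-scale analogue of a few-hundred-probe screen hit) shift the
  case mean by 1.5 log2 units; the within-group noise SD defaults to 0.5
  log2 units, a typical residual scale for normalized two-color arrays.
  The variance structure of real arrays is not knowable from summary
  statistics alone, so `noise_sd` is an explicit, documented modelling
  choice exposed in the config.
* **Coexpression.** Linked pairs draw from a bivariate normal with
  correlation 0.85 across all samples *first*; group shifts are added
  afterwards. The planted correlation is therefore a within-population
  correlation, not an artifact of shared group effects. Linked pairs are
  assigned to planted-DE probes first, with concordant DE directions —
  positively correlated genes co-shift, as cis co-regulation predicts — so
  the pooled correlation survives the group effect; surplus linked pairs
  fall on null probes, which is how pure-correlation recovery is measured
  unconfounded (set `n_de_* = 0`).
* **Baseline.** Constant 8.0 log2 units; every statistic in the chain is
  location-invariant, so the value is arbitrary.
* **Annotation.** Each probe gets a 1 kb interval. Placement units are laid
  left to right with gaps strictly larger than the cis window, so no two
  units are within the window of each other; a designated cis pair is one
  unit whose members sit a uniform 0..300,000 bp apart (boundary
  inclusive). Hence the truth table's cis labels agree exactly with any
  correct distance computation, non-cis linked pairs are never within the
  window, and loci never overlap unless a zero gap is drawn.
* **qPCR.** Reference gene at Ct 15, targets at Ct 25, a shared per-sample
  loading offset (cancelled by dCt), and a case-group Ct shift of
  `-planted_log2fc * direction` for planted targets. The Ct noise SD is a
  separate argument so the exact-arithmetic (zero-noise) contracts can be
  exercised.
* **Determinism.** One RNG stream per generator, seeded at `seed`,
  `seed + 1` (annotation), `seed + 2` (qPCR), `seed + 3` (bundle gene
  sets), each consumed in a fixed documented order — identical config and
  seed give byte-identical files.

What the generator does **not** emulate: dye effects, probe-level
background, normalization artifacts, correlated noise across probes beyond
the planted pairs, outlier samples, or realistic genomic clustering of
genes. Passing recovery tests therefore demonstrate the *inferential*
correctness of the chain under its own assumptions, not robustness to the
failure modes of real microarray data.

# Numerical and problem-size choices

* Trigamma inversion uses Newton iteration with asymptotic guards
  (`1/sqrt(y)` for very large `y`, `1/y` for very small), converging to a
  relative 1e-10; the finite-d0 fit agrees with the reference
  empirical-Bayes implementation in the test suite to 1e-9.
* P values are two-sided throughout; BH ties are resolved by probe-id
  order so outputs are deterministic.
* Calibration and recovery checks run at 10,000 probes (the scale where a
  +/-0.01 band around a 0.05 type-I rate is a ~4-sigma statement), edge
  recovery at a 200 x 200 pair grid, the permutation oracle at 10^5
  shuffles, and the end-to-end recovery on a ~300-probe bundle — sizes
  chosen so the whole suite gives tight statistical statements while
  completing in well under a minute per check.
* The pipeline validates every input path before any stage runs, aborts
  with the failing stage's name, and records per-stage row counts and the
  applied thresholds in a JSON manifest, mirroring how each filtering step
  of such an analysis is conventionally reported.

# Known limitations

* Correlation edges are association, not mechanism; the cis window adds
  positional plausibility but no causal evidence.
* The pooled-correlation default inflates edges between strongly DE genes;
  use `samples = "case"`/`"control"` when that is a concern.
* The moderated test assumes a shared residual df across probes (complete
  matrices, two groups, no covariates); missing values are rejected rather
  than imputed.
* ORA inherits all the usual background-sensitivity of hypergeometric
  enrichment; the universe default (all array mRNAs) is a convention, not
  a recommendation for every design.
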