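---
title: "Quality assessment of degraded-sample expression arrays: methods and design"
author: "ffpeqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment of degraded-sample expression arrays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpeqc)
```

## The problem

Expression arrays run on formalin-fixed, paraffin-embedded (FFPE) tissue sit
at the opposite end of the quality spectrum from fresh-frozen material. RNA
degradation and formalin cross-linking leave many probes producing no signal
above background ("dead probes"), and the severity varies continuously from
array to array: in large archival cohorts a substantial minority of arrays —
on the order of 15% — show compressed or heavily skewed intensity
distributions. This breaks the working assumption behind most normalization
routines, namely that every array's marginal intensity distribution is
essentially the same and corrections are numerically small. Two questions
follow: does a badly degraded array distort the normalization target for
everyone else, and can such arrays be identified with thresholds that travel
across studies?

`ffpeqc` answers both with a pair of per-array statistics tied to the
additive log2 model

$$Y_{ij} = \mu_{ij} + S_{ij} + \varepsilon_{ij},$$

where $Y$ is the background-corrected log2 intensity of feature $i$ on array
$j$, $\mu$ the true relative abundance, $S$ a systematic bias removed by
normalization, and $\varepsilon$ mean-zero noise whose variance is
feature-specific. Background correction is upstream of this package: the
input contract is a features-by-samples matrix of background-corrected
intensities (log2, or transformed at ingestion). Normalization produces
$Y'_{ij} = Y_{ij} - S_{ij}$ together with the realized shift matrix $S$.

## The metrics

**Stress.** $\mathrm{Stress}_j = 2^{\,\mathrm{median}_i\,|S_{ij} -
\bar S_{j}|}$ summarizes the deformation array $j$ suffers during
normalization, on the fold-change scale. Subtracting the array mean
$\bar S_j$ first makes the metric blind to constant offsets — a scanner
running 50% brighter is not a quality problem, and the package tests this
invariance explicitly through the whole quantile-normalization path. The
absolute value treats up- and down-corrections symmetrically. A Stress of 2
reads directly: half of the features had to be adjusted two-fold or more,
which is the same order as the effect sizes most studies hope to detect —
hence the default removal cutoff of 1.5.

**dfArray.** After normalization, each cell is standardized against the
remaining arrays' estimate of its feature:
$$\mathrm{dfArray}_{ij} = \frac{Y'_{ij} - \hat\mu_{i(-j)}}{\mathrm{sd}\,\hat\mu_{i(-j)}},$$
in the spirit of case-deletion diagnostics in regression. The exact
leave-one-out mean and standard deviation are available
(`mode = "exact_loo"`, computed in one pass from row sums and sums of
squares), but the default is the robust one-shot approximation: the
across-array median in place of the leave-one-out mean and
$1.4826 \times \mathrm{MAD}$ in place of the standard deviation. The grid is
stored signed; the per-array summary takes the 0.75 quantile of the
magnitudes, since deviations above and below the consensus are equivalent
errors. An array whose summary reaches 2 has a quarter of its features more
than two standard deviations from the consensus — the default "investigate"
cutoff, expressed in units any analyst can reason about.

**The comparison panel.** RLE (per-feature median subtracted from $Y'$,
summarized by per-array median and IQR), NUSE (per-cell standard errors
scaled by the feature's median SE, requiring a user-supplied SE matrix; a
per-feature reference denominator can be supplied where an archive exists),
the distance-to-average-array rule (feature-standardized profiles against a
median target, Euclidean or $1 - r$ dissimilarity, flagged beyond
$Th \times \mathrm{median}$ distance), and the raw-distribution quadrant
classification: $\mathrm{IQR} = Q_3 - Q_1$ and
$\mathrm{skew} = (Q_2 - Q_1)/\mathrm{IQR}$, which is $0.5$ for symmetric
distributions and collapses toward $0$ when the lower half of the
distribution piles up at background. The skew definition uses $Q_2 - Q_1$ in
the numerator; the alternative sometimes written with $Q_3 - Q_1$ is
degenerate (always 1) and cannot yield 0.5 for symmetric distributions, so
the package treats it as a typographical variant and does not implement it.

## Normalization

Quantile normalization is the default throughout: the target distribution is
the per-rank mean of the column order statistics, each cell is replaced by
the target value at its within-column rank, and ties receive the mean of the
target values over the tied ranks. The tie rule matters for FFPE data — the
dead-probe floor creates large tie groups — and this rule is deterministic
and invariant to sample order. The mean (not median) of order statistics is
the standard convention and is used here.

`feature_target_normalize()` provides the probe-specific alternative: each
feature's across-array median is the target, and each array's deviations
from the target are smoothed along the target-ordered feature axis with a
running median (window $\max(3,\ \mathrm{round}(\mathrm{span}\cdot p))$,
odd-ized; default span 0.3) and subtracted. A running median was chosen over
local regression because it has a single tunable and is unmoved by the
dead-probe floor; within any window where the deviation curve is monotone
the smoother is exact, so RLE after this normalization sits at zero
essentially by construction — which the acceptance checks verify on
noiseless monotone-distorted fixtures.

Every pipeline renormalizes from the *raw* matrix of survivors after each
removal stage; normalized data are never renormalized.

## Two-stage workflows

`run_mahoney()`: quantile-normalize everything, compute Stress (and dfArray
as a stage-1 diagnostic only), remove arrays with Stress ≥ 1.5,
renormalize the survivors from raw, compute dfArray, flag arrays at or above
2, and — only if `remove_stage2 = TRUE` — drop them before the final
normalization. Stage 2 defaults to advisory ("investigate") rather than
removal, because a large dfArray can also mean a genuine biological subclass
rather than a technical failure; the choice is the caller's.

`run_chow()`: the distance-outlier rule applied to raw log2 data (stage 1),
then to the renormalized survivors (stage 2), removing at both stages. The
stage-1 application to un-normalized data follows the published workflow
even though the metric is scale-sensitive there.

Both abort if fewer than 3 arrays would survive a stage (the leave-one-out
denominator and the distance target both need at least 3). All threshold
comparisons are inclusive (`>=`). `concordance()` cross-tabulates two
pipelines' suspect sets with the four disjoint id sets attached.

## Numerical choices

- Quantiles and quartiles everywhere use the type-7 linear-interpolation
  rule (the R default), fixed and documented for cross-implementation
  determinism.
- MAD is scaled by 1.4826 so the robust dfArray denominator estimates the
  standard deviation under normality, keeping the "two standard deviations"
  reading of the default cutoff literal.
- Zero-spread guard: where a dfArray denominator is 0 (common under
  dead-probe floors), the cell is 0 when the numerator is also 0, and
  otherwise excluded from that array's summary and counted per sample. The
  same policy governs zero-sd features in the distance metric's
  standardization, which are dropped and counted.
- A zero-IQR array has undefined skew: reported `NA`, quadrant forced to R4,
  with a warning.
- Ingestion floor-imputes cells that are empty, `NA`, or (when a log2
  transform is requested) nonpositive, using the matrix-wide minimum
  positive value, and reports the per-sample count in the QC table. Dropping
  such rows would desynchronize companion matrices; imputing to the floor
  mimics how dead probes actually present.
- Matrix TSVs are written at full double precision; the QC report TSV is
  rounded to 6 significant digits for readability, with the JSON report
  keeping full precision (so JSON round-trips exactly and TSV to about
  1e-6 relative).

## The synthetic-data generator

No public dataset reproduces the heterogeneity of a large FFPE cohort, so
the package ships a generator that does, with ground truth attached.
Features draw true abundances from a two-component mixture: a fraction
`frac_expressed` (default 0.7) around `baseline_mean = 10` (sd 2.5) and the
rest pinned at `background_level = 5`, all in log2 units; feature noise is
`noise_sd = 0.3` scaled by a per-feature lognormal factor, plus a small
per-array offset (sd 0.05). These defaults put a clean array's IQR near 6
and skew near 0.6 — the well-behaved R1 quadrant — and are what the
package's property tests run under.

Five degradation operators each target one failure mode one specific metric
claims to catch, making per-metric attribution testable: `dead_collapse`
(a severity-fraction of expressed features falls to background; crushes IQR,
caught by Stress), `range_compression` (spread shrinks about the median),
`skewed_degradation` (the lower half compresses toward background, driving
the skew statistic down), `profile_discordant` (a fraction of features swap
true abundances — the marginal distribution is preserved, so Stress and the
quadrant view are blind, but dfArray and the distance metric are not), and
`constant_shift` (a pure additive offset that no metric should flag). A
mixed run with roughly 15% degraded arrays mirrors the poor-quality fraction
typical of archival cohorts.

What the generator does *not* emulate: bead-level replicate structure,
probe-sequence effects, batch/plate spatial artifacts, and correlated
biological subclasses. Passing recovery tests on this generator therefore
demonstrates that the metrics detect the modeled failure modes at the
modeled severities — not that real FFPE cohorts will separate as cleanly,
and the severity scale should not be read as calibrated to any real assay.

`generate_monotone_distortion_set()` is a separate noiseless fixture: one
latent target profile and strictly increasing cubic distortions per array
(derivative bounded away from zero by construction), used to exercise the
feature-target normalization path.

## Impact of keeping questionable arrays

`evaluate_impact()` makes the cost of lax QC concrete: normalize a clean
reference set alone, record per-feature means and variances; normalize the
reference plus the added (questionable) arrays from raw; recompute; report
the per-feature variance ratio and mean difference, binned into 20
equal-count bins by reference-mean percentile and smoothed by the per-bin
median, with the 25th/50th/75th reference intensity percentiles carried as
markers. Moments of the expanded set are computed over all its columns by
default — the straightforward reading of "recalculate after adding" — with
`scope = "reference_only"` exposing the variant restricted to the reference
columns after joint renormalization. Features with zero reference variance
are excluded and counted. On simulated data, adding good arrays leaves
ratios within sampling noise of 1 and bias near 0; adding collapsed arrays
inflates the variance ratio across bins and introduces nonzero bias, the
qualitative signature that motivates removing such arrays before
normalization.

## Problem sizes and tolerances in the test suite

The suite checks exact analytic cases (Stress of a hand-built shift column,
skew of a symmetric distribution) to machine precision; algebraic
postconditions (sorted-column equality, $Y' + S = Y$, idempotence) to
1e-12 at $p = 10^4, n = 100$; the exact leave-one-out implementation against
a naive $O(pn^2)$ brute force on 10×6 instances to 1e-10; robust-versus-exact
dfArray agreement on heteroscedastic Gaussian data at $p = 2000, n = 20$;
and outlier recovery (10 dead-collapse at severity 0.7 plus 5
profile-discordant at severity 0.4 among 96 arrays, $p = 5000$) averaged
over 10 seeds, at sensitivity ≥ 0.9 and specificity ≥ 0.95. These sizes were
chosen as the smallest at which the distributional statements are stable;
the generator makes larger replications a one-line change.

## Known limitations

- Stress and dfArray are defined relative to the current cohort; a batch
  composed mostly of degraded arrays shifts the consensus itself, and no
  within-batch metric fully escapes that (the same caveat applies more
  strongly to the batch-median distance rule).
- NUSE requires per-cell standard errors the upstream platform must supply;
  without multiple probes or bead replicates per feature it is undefined,
  which is precisely why Stress/dfArray exist.
- The robust dfArray denominator underestimates spread for features with
  more than half their mass on the dead-probe floor; the zero-spread guard
  bounds, but does not remove, this effect.
- Floor imputation at ingestion is a pragmatic policy, not an inference; if
  the upstream pipeline encodes dead probes differently, transform before
  ingestion and pass `log2_transform = FALSE`.
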