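---
title: "Resampling statistics for peri-event photometry: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resampling statistics for peri-event photometry: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periboot)
```

## The data model and its assumptions

`periboot` operates on peri-event matrices: one matrix per group or
condition, rows indexed by peri-event time, columns by animal or trial.
Three assumptions are load-bearing:

1. **The signal is already normalized.** Baselines are assumed
   z-scored (or otherwise centred) upstream, so that 0 is the null for
   "no deviation from baseline". `baseline_significance()` does *not*
   re-centre traces on the baseline window; if your baseline period or
   normalization changes, the y-scale — and therefore which CIs exclude
   0 — changes with it.
2. **The animal/trial is the exchangeable unit.** Both the bootstrap
   and the permutation test resample whole columns, never individual
   timepoint cells. A bootstrap iteration draws the n column indices
   once and reuses them at every timepoint, which preserves the
   temporal coherence of the resampled waveforms; the per-timepoint
   marginal distribution is identical to independent per-timepoint
   resampling, but resampled traces remain plausible waveforms and the
   computation vectorizes to one matrix product.
3. **Complete rectangular data.** Any blank or non-numeric cell inside
   the data rectangle is an error, not an NA to be tolerated: column
   resampling and paired subtraction have no principled treatment of
   holes.

## Bootstrapped CIs and the narrowness adjustment

Per timepoint, the CI is the percentile interval of B bootstrap means
(default B = 1,000; more resamples stabilize the quantiles but do not
narrow the interval), with linear-interpolation empirical quantiles
(the default quantile definition in R, deterministic and standard).
Percentile intervals from small n are systematically too narrow, so the
interval is widened about the bootstrap mean by

$$f = \sqrt{\tfrac{n}{n-1}},$$

the usual first-order correction for the bootstrap's use of the
biased (divisor-n) variance. The form is isolated in one function
(`periboot:::narrowness_factor`) because it is the one genuinely
contestable numerical choice in the package; alternatives of the same
family (n/(n−1), or resampling n−1 of n columns) differ only in how
much they widen.

**What the adjustment does and does not fix.** For Gaussian data at
n = 7 the adjusted interval is still anticonservative: the percentile
interval behaves roughly like $\bar x \pm z_{\alpha/2}\, s\sqrt{(n-1)/n}/\sqrt n$,
and matching nominal coverage would need the *t*-quantile ratio
(≈ 1.35 at n = 7), not ≈ 1.08. Run `scripts/acceptance.R` to see the
measured coverage and per-timepoint flag rates on synthetic data. This
is inherent to percentile bootstrap CIs at photometry-typical group
sizes and is precisely why the consecutive threshold exists: per-point
error control is left mildly liberal, and family-wise control comes
from requiring temporally extended significance.

The null decision is strict: a CI endpoint exactly equal to 0 counts as
containing the null (flag 0). This only matters for degenerate
(constant) data and breaks ties conservatively.

For the between-subjects design the difference distribution is
`samplesA − samplesB` row-wise and the adjustment uses n = min(nA, nB),
a conservative choice since no single n describes a difference of
unequal groups. The within-subjects design bootstraps the paired
difference matrix, so its n is the number of pairs.

## Consecutive threshold

`apply_consecutive_threshold()` zeroes every maximal run of 1s shorter
than k samples. k = 0 and k = 1 are both identity: any run of length
≥ 1 is a significant point. Thresholding is monotone (larger k never
adds significance) and idempotent. The recommender converts durations
to samples with round-half-up and floors at 1 sample:

```{r}
recommend_consecutive_threshold(rise_s = 0.08, half_decay_s = 0.33,
                                sampling_hz = 10)   # kinetics: 0.41 s
recommend_consecutive_threshold(0, 0, low_pass_hz = 6,
                                sampling_hz = 10)   # 1/6 s rule
```

Thresholds are in samples, so they must be rescaled after
downsampling: 10 samples at 10 Hz is the same duration as 1 sample at
1 Hz.

## Permutation tests

Each animal is reduced to its window mean before permuting — the test
compares groups of animals, not pools of timepoints. The statistic is
the absolute difference of group means (two-sided; the output also
reports the signed observed difference). Between-subjects exchanges
group labels; within-subjects flips the signs of paired differences,
the standard exchangeability-preserving scheme for paired data. The p
value is `count / n_permutations` without the +1 continuity
correction, matching output that can legitimately display p = 0.000
(meaning < 1/N); users needing finer resolution should raise N rather
than reinterpret zeros. `exact_permutation_p()` enumerates all
$\binom{n_A+n_B}{n_A}$ assignments or $2^n$ sign patterns (capped at
$10^6$) and anchors the Monte-Carlo tests in the package's suite.

The consecutive threshold is irrelevant to window p values: with a
fixed seed they are bit-identical across thresholds, and without one
they differ only by Monte-Carlo jitter.

## Downsampler and time bins

The downsampler partitions rows into consecutive blocks of `factor`
rows and averages each block. A trailing partial block is averaged and
**kept** — dropping it would discard the end of the comparison window;
the cost is that the final point averages fewer samples and is
correspondingly noisier. Output length is `ceiling(n/factor)`, e.g.
813 rows at factor 10 → 82. When `factor` divides the row count,
grand means are conserved exactly and downsampling composes
(`factor a` then `b` equals `a*b`).

Time bins are arbitrary 0-based inclusive `(start, end)` row pairs.
They may overlap or leave gaps deliberately: the interface collects
whatever windows the analyst considers meaningful and only checks
bounds.

## Workbook conventions

Row indices in every interface are 0-based and inclusive (row 0 is the
first data row, maximum index is `n_timepoints − 1`). The first row of
an input sheet is treated as data when every cell parses as a number
and as column labels otherwise; this tolerates both layouts
deterministically, at the price that a fully numeric label row would
be misread as data — output files therefore always write non-numeric
`trial_*` labels. Output naming: `<stem>_downsampled_<factor>.xlsx`,
`<stem>_time_bin_means.xlsx`, `<stem>_results.xlsx`; existing files
are overwritten with a warning. Every output workbook embeds a
settings sheet echoing the exact parameters used. P values are
rendered to three decimals in the results sheet; the in-memory
`results_bundle` keeps full precision. Numeric cells are written with
17 significant digits, so write/read round trips are exact.

## Seeding and determinism

All resampling accepts an optional integer seed. `run_pairwise_suite()`
derives one substream seed per task (each baseline map, each pairwise
map, each window test) from the master seed in a fixed order, so
results are bit-identical across runs and do not depend on evaluation
order or degree of parallelism; the CLI's `--workers` flag exists for
interface parity and cannot change output. An absent seed falls back
to the session RNG (CLI: an entropy-drawn seed, logged and recorded in
the settings sheet).

## The synthetic generator

`generate_event_dataset()` emulates the structure the statistics
assume: i.i.d. Gaussian noise per cell plus, from the event row
onward, a peak-normalized difference-of-exponentials transient
$(1-e^{-t/\tau_{rise}})\,e^{-t/\tau_{decay}}$ scaled by group amplitude
plus a per-subject offset (shared across groups when `paired = TRUE`,
which creates the column correlation a within-subjects analysis
exploits). Defaults mirror a typical fast-sensor experiment: 3 groups
× 7 subjects × 813 rows at 10 Hz with the event at row 213 (−20 s …
+60 s), unit noise SD on the z-scale, rise 0.08 s and decay constant
0.48 s (≈ 0.33 s half-decay). It deliberately omits pink noise,
photobleaching drift, motion artifacts, and autocorrelated baselines —
so passing tests demonstrate correctness of the statistics under clean
exchangeability, not robustness to every pathology of real recordings.
Test problem sizes in the suite (e.g. 25–40 replicates of the
813-row layout, 1,000 resamples) were chosen as the smallest sizes at
which the Monte-Carlo bands in the tests are meaningful.

## Known limitations

- No hierarchical (trials-within-animal) bootstrap; choose the unit of
  analysis before reshaping the workbook.
- No BCa/studentized intervals and no cluster-mass permutation
  correction; the consecutive threshold is the only family-wise
  control.
- Per-point CI calibration at small n is liberal (see above); treat
  un-thresholded maps as descriptive.
- Permutation p values are window-level, one per group pair per
  window, not per-timepoint.
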