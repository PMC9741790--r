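---
title: "Methods: Sample Entropy of treadmill gait signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Sample Entropy of treadmill gait signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsampen)
```

## What the package computes

Treadmill walking produces long, quasi-periodic recordings of the centre of
pressure (fore-aft COPap and lateral COPml, in mm) and the resultant
vertical ground reaction force (vGRF, in N), typically sampled at 100 Hz.
Sample Entropy (SampEn) quantifies how *regular* such a series is: it is
the negative log of the conditional probability that two m-sample
subsequences that match within a tolerance `r` (Chebyshev distance) still
match when extended by one sample. The package computes SampEn exactly in
the Richman–Moorman convention — both the m- and the (m+1)-length template
pairs are counted over the common start-index range `1..N-m` with
self-matches excluded, which guarantees `A <= B` and a non-negative value —
and exposes the raw match counts `A` and `B` so any value can be audited.

SampEn is famously sensitive to its inputs, so the package is built around
a *sensitivity analysis*: the same recording is analysed as four signal
preparations (`WHOLE`, `SEGM`, `NORM`, `ZERO`) crossed with a grid of
template lengths (`m = 2, 4, 6, 8, 10`) and tolerance factors (default
`r = 0.2 × SD`, sweeps typically 0.1–0.3), for two walking conditions
(preferred speed `Vpref` and maximum tolerated speed `Vmax`).

## The synthetic generator

Real centre-of-pressure recordings are not required: `generate_recording()`
synthesises signals with the statistical structure the analysis assumes.
Its defaults are the package's fixed description of the study conditions:

* `sampling_rate = 100` Hz and `mean_stride_time = 1.06` s — typical of
  comfortable treadmill walking around 0.8 m/s;
* `stride_time_cv = 0.02` — a 2% stride-time coefficient of variation, the
  order healthy adults show on a treadmill; stride durations are drawn from
  a normal distribution truncated at ±3 SD so no stride degenerates;
* `copap_amplitude = 60` mm, `copml_amplitude = 25` mm, `body_weight =
  800` N — plausible magnitudes for the per-stride COP excursion and the
  mean resultant force of an ~80 kg adult;
* `waveform_noise_sd = (0.5, 0.5, 4)` — white measurement noise per
  channel (mm, mm, N), i.e. about 1% of each channel's scale;
* `within_cycle_shape_jitter` — the strength of a smooth random deformation
  (three low-order sine harmonics, vanishing at the cycle ends so the
  concatenated signal stays continuous) drawn independently per stride.
  This is the generator's notion of *intra-stride motor variability* and
  the quantity the entropy should react to;
* `drift_rate` (mm/s) — a linear positional drift on both COP channels,
  the slow treadmill wander that the `ZERO` preparation is designed to
  remove.

Within a stride (phase φ ∈ [0,1)) the templates are: an asymmetric
fore-aft excursion made of two half-sine lobes peaking at 60% of the
stride (COPap); one full sinusoid per stride (COPml); and, for the vGRF,
the sum of two M-shaped per-foot stance profiles
`sin(πu) + β sin(3πu)` offset by half a stride, with stance occupying 70%
of the stride and the two feet given slightly different midstance-valley
depths (β = 0.30 vs 0.24). Two deliberate conventions are worth noting:

* **Phase anchor.** Stride phase 0 is placed at the anchor foot's
  midstance valley of the resultant force. The resultant of the two offset
  stance profiles then has exactly two local minima per stride (the two
  midstance valleys) and no spurious dips at the stance transitions — that
  is why the stance fraction is 0.7 — so a valley detector can recover the
  generator's ground-truth boundaries exactly on clean data.
* **Leg asymmetry.** The slightly deeper valley of the anchor foot makes
  the two alternating valley series distinguishable, mirroring the mild
  left–right asymmetry of real gait and making "every second event, same
  leg" a well-posed selection.

The generator does **not** attempt musculoskeletal realism: noise is white
(the spectra of real force-plate noise are not modelled), drift is linear,
the waveform templates are stylised, and there is no per-foot COP
decomposition. Passing tests therefore demonstrate that the *machinery* —
segmentation, preprocessing, entropy, statistics — behaves correctly on
signals of this structure, not that any biological conclusion transfers to
real data.

## Stride segmentation

`segment_strides()` uses only the vGRF. The signal is smoothed with a
moving average of `sampling_rate / 20` samples (50 ms), local minima are
taken as midstance landmarks, a refractory rule discards minima closer
than 0.4× the median landmark spacing (keeping the deeper one), each
landmark is then relocalised as the vertex of a least-squares parabola
fitted over ±0.1 s of the smoothed force (which averages away most of the
noise-induced wander of the raw argmin), and finally every second landmark
is kept so consecutive boundaries span one full stride. Of the two
alternating landmark series the detector keeps the one with the lower mean
force value (the deeper-valley leg); with perfectly symmetric legs the
first landmark wins. Cycles are half-open `[b_i, b_{i+1})` so
concatenation never duplicates a boundary sample.

Under the package's reference noise condition (2% stride-time CV, white
noise at 1% of body weight) the detector places more than 95% of
boundaries within ±3 samples of the generator's ground truth, and is exact
to ±2 samples on clean signals.

## The four preparations

* `WHOLE` — first `n_points` samples (default 2200) of the trimmed
  recording, no amplitude or time-base change. The common length exists so
  every subject contributes equally; when a run's shortest recording is
  shorter, the run lowers the length to that minimum and logs it.
* `SEGM` — each cycle resampled to `samples_per_cycle = 100` points by
  piecewise-linear interpolation on a uniform grid including both
  endpoints. Linear interpolation is shape-preserving and exactly
  reproduces conforming and affine cycles, which the tests exploit.
* `NORM` — per-cycle affine rescale of each COP cycle to exactly [0, 1]:
  the excursion as a fraction of that stride's own range ("stride length"
  fore-aft, "stride width" laterally). An externally measured stride
  length would be an alternative reading; the per-cycle range is the one
  consistent with unit-interval traces and is the package's choice. A
  zero-range cycle is an error naming the cycle index.
* `ZERO` — every (COPap, COPml) cycle translated to start at (0, 0).
  First differences are untouched (preserved to 1e-12 in tests), so all
  absolute within-cycle distances survive; only the across-stride drift is
  removed. One caveat the package documents rather than hides: zeroing
  removes each cycle's *starting offset*, not the within-cycle ramp a
  linear drift adds, so for a drifted signal the zeroed cycles all carry
  one and the same residual ramp. The entropy consequence of that residual
  is far smaller than the drift's effect on `SEGM`, which is the operative
  property and is what the tests assert.
* The vGRF is never spatially normalised or zeroed; attempting it is an
  error.

## Entropy implementation and numerical choices

The counting kernel (C++) computes, for every template-start pair, the
maximal prefix length over which the two windows stay within `r`, and
feeds every `m` up to `m_max` in a single O(N²) pass — so a full m-grid
costs one pass per tolerance. Counts are unordered pairs; the A/B ratio is
unchanged. The kernel is validated against full pairwise enumeration
(`embed()` plus base R's Chebyshev `dist()`) over hundreds of random
series, exactly, count for count.

Conventions fixed for reproducibility:

* tolerance `r = r_factor × SD` with the *population* SD of the analysed
  series (an alternative per-cycle-averaged SD is available via
  `samples_per_cycle` in `compute_r()`, not the default);
* `A = 0` or `B = 0` is reported as an undefined entropy with a reason
  code (`sampen_grid()` keeps such cells as missing rather than
  substituting a ceiling, which would bias grids);
* a value of exactly 0 (all m-matches extend) is normalised to +0.

## Spectral support for choosing m

`power_spectrum()` is a mean-removed periodogram normalised so total power
equals the population variance (exact Parseval for the rectangular
window; a Hann window is available). The summary frequency is the
smallest frequency below which 99% of the power lies — the threshold is a
configurable, conservative stand-in for "the highest frequency present",
which no standard criterion pins down. Two helpers turn this into a
template-length argument: `min_neuromotor_interval(f)` = `1/f` and
`template_time_span(m, stride, points)` = `m × stride / points`, both
rounded *half-up* to 3 decimals (half-up, not banker's rounding, so
`1/16 = 0.0625` prints as the conventional 0.063). At 16 Hz and a 1.06 s
stride resampled to 100 points, `m = 6` spans 0.064 s — the shortest
template longer than the fastest neuromotor time scale.

## Statistical design

Per condition and variable, a balanced fixed-effects two-way ANOVA tests
processing type and template length with subjects as replicates; with 4
types, 5 m-levels and 23 subjects the dfs are (3, 440), (4, 440),
(12, 440). The velocity comparison at a fixed `m` is a split-plot mixed
ANOVA: walking condition within subjects, processing type between — each
subject × type series is one experimental unit measured in both
conditions, giving (1, 88) for velocity and (3, 88) for type at 23
subjects. Treating type as between-subjects even though all types derive
from the same subjects is a caveat of this conventional layout; the
package reproduces the design as stated and documents the caveat. Both
models are fitted with `stats::aov` (including the `Error()` stratum for
the split plot) and are verified in tests against hand-written
sums-of-squares oracles to 1e-8; effects with numerically zero
between-group variance report `F = 0, p = 1` rather than 0/0. Balance and
pairing are preconditions, checked with explicit errors; in the pipeline a
subject contributing an undefined entropy cell is dropped from the
affected ANOVA (logged) to preserve balance. Sphericity corrections and
post-hoc procedures are left to standard routines and are not part of this
package's surface.

## The experiment pipeline

`run_experiment()` ties the stages together deterministically from one
seed (subject *i* uses `seed + 2(i-1)`; the Vmax member of a pair uses the
subject seed + 1). The default condition parameterisation expresses the
speed manipulation: `Vpref` with 1.06 s strides and shape jitter
(0.15, 0.10, 0.10) for (COPap, COPml, vGRF); `Vmax` with 0.85 s strides
and jitter (0.05, 0.20, 0.04) — tighter fore-aft and force waveforms,
looser lateral waveform — plus 1 mm/s of COP drift in both. Those defaults
encode the qualitative finding the discrimination check exercises: COPap
and vGRF become *more* regular at maximum speed while COPml becomes *less*
regular; the pipeline's velocity-comparison table reproduces those
directions in ≥ 90% of seeded replicates. This validates the machinery's
sensitivity, not the biology. Summary tables report subject means with
0.95 t-based confidence intervals.

## Problem sizes used in the tests

The suite keeps its own scale choices explicit: oracle equivalence runs
200 random series up to N = 400; the ANOVA-structure check runs the full
23-subject design on shortened recordings (12/15 strides, 800-point raw
window), which exercises the identical design matrix at a fraction of the
cost; the discrimination check runs 20 replicates of a 3-subject
experiment at `m = 6`; segmentation recovery uses 20 seeds of 30-stride
recordings. These sizes are the package's chosen test conditions, stated
here so they can be scaled up by anyone wanting tighter Monte-Carlo bands.

## Known limitations

* The generator's noise is white and its drift linear — by decision, not
  evidence; the `ZERO` preparation is designed exactly for that structure.
* Valley-based segmentation assumes a double-bump resultant force; it is
  not a general gait-event detector and will mislocate events on signals
  without midstance valleys.
* SampEn values depend on `samples_per_cycle` and the common series
  length; comparisons are only meaningful within a fixed configuration.
* The mixed ANOVA reproduces the conventional (type-as-between) design;
  a fully within-subject treatment of type would need a different error
  structure and is out of scope.
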