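---
title: "Methods: validating pressure insoles against force plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating pressure insoles against force plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insoleval)
```

## The measurement model

A pressure insole reports, at each frame, the pressure `p_i` (kPa) on
each of its sensels — small sensing elements of known area `A_i` (cm²)
at known planar coordinates `(x_i, z_i)` (cm; `x` medial–lateral, `z`
anterior–posterior). The package derives three outcome channels per
frame:

* **vGRF**: the summed sensel load, `F = Σ_i 0.1 p_i A_i` newtons.
* **peak pressure**: `max_i p_i`.
* **COP**: the load-weighted mean of the sensel coordinates.

Weighting COP by *load* (pressure × area) rather than raw pressure is a
deliberate choice: the two coincide exactly on uniform-area grids (the
common case, including the default grid here) but only load-weighting
remains the physical centre of force when areas differ. Vendor software
that pressure-weights may therefore disagree on non-uniform grids; the
difference is zero for the grids this package ships.

**Load floor.** At zero load the COP is undefined (0/0), and at a few
newtons it is numerically meaningless. COP samples are flagged
undefined whenever total load is at or below `load_floor_n` (default
10 N per foot — roughly the weight of the shoe itself, and comfortably
above sensor noise). Flagged samples are *excluded*, never
interpolated: every downstream stage (filtering, resampling,
normalization, range extraction) carries the gaps through explicitly.

**Foot mirroring.** Grids are stored in the device frame. At channel
derivation, left-foot COP-ML is reflected about the grid's ML midline
so that "+ML" means the same physical direction for both feet; this is
what makes left/right averaging and per-foot comparisons coherent.

**Saturation.** Pressures above the device ceiling (883 kPa) are
clamped with a warning rather than rejected: an occasional saturated
heel-strike sample should not void a trial, but must be visible in the
log.

## Preprocessing

All channels are low-pass filtered with a zero-phase (forward–backward)
second-order Butterworth filter, cutoff 6 Hz. The cutoff is a
biomechanics convention that accommodates both slow (squat) and
impact-rich (jump, stairs) tasks with one setting. The forward–backward
scheme removes phase lag — essential, since cycle boundaries are read
off the filtered signal — at the price of squaring the magnitude
response, so the effective attenuation at a frequency `f` is
`|H(f)|² = (1 + (f/f_c)^4)^(-1)`. `butterworth_gain()` returns this
response, exactly (bilinear-warped) when the sampling rate is supplied.

Zero-phase IIR filtering is sensitive to edge transients. The
implementation pads each end with an odd reflection of the data,
extended by constant fill when the series is shorter than the pad,
sized at five cutoff periods (≈30 pole time constants) so the
zero-state transient decays below numerical noise before the retained
samples begin. A constant series therefore filters to itself to within
~1e-8.

Insole channels are resampled up to the plate rate with polyphase FIR
rational resampling (`signal::resample`). COP channels, which may carry
undefined spans, are instead resampled by linear interpolation with gap
propagation (an output sample is undefined if either bracketing input
sample is), because band-limited interpolation across a flight-phase
gap would manufacture data. Passband ripple of the FIR design bounds
constant-signal reproduction at ~1e-3 relative, well below any effect
of interest here.

Synchronization mirrors a timestamp-matching protocol: the
free-running insole stream is cropped to start/end anchors (closed
interval), with nearest-timestamp matching within a 50 ms tolerance and
a hard error beyond it — recordings with broken timestamps are excluded
loudly, not shifted silently. A plate recording whose duration differs
from the anchor window by more than 5% fails synchronization.

## Cycle segmentation

Movement cycles are delimited by local extrema of the filtered vGRF:

* **squat** — the load dips below quiet standing; boundaries are the
  *maxima* flanking each dip;
* **jump, sit-to-stand, walking, stairs** — the load rises from a low
  baseline; boundaries are the *minima* flanking each load peak.

The extremum detector returns strictly interior extrema passing a
prominence threshold (default 10% of the signal range) and a minimum
separation (default 0.4 s, well below any plausible cycle duration).
Plateaus — exact ties, common after clipping a filtered signal at
zero — resolve to the plateau midpoint, which is also what keeps
detected boundaries centred in zero-load swing/flight spans. A valid
cycle must contain exactly one opposite-polarity extremum; a candidate
cycle with none is merged with its successor, one with several is
accepted with the most prominent treated as defining (both repairs are
logged). Adjacent cycles share their boundary sample.

The first and last detected cycles are discarded (movement initiation
and termination), each retained cycle is linearly interpolated onto an
inclusive 101-point 0–100% grid, and each channel is summarized by its
per-cycle range (max − min over the 101 points), averaged across
cycles. Ranges are computed on the normalized cycle, not the raw
segment — for the linear interpolation used here the difference is
bounded by the interpolation error. Undefined COP samples propagate
through normalization; a cycle whose undefined fraction exceeds
`max_gap_fraction` is excluded from that channel's aggregation. The
default budget is 20%; for walking and stairs, where the swing phase
legitimately unloads the foot for about a third of the cycle, the
pipelines raise it to 45% (`segmentation_params()`), so the COP range
is taken over the loaded portion of the cycle rather than discarding
gait COP wholesale.

## Agreement statistics

Per activity and channel, per-participant range values (feet averaged
when both are present) are compared as insole − plate. The
Bland–Altman report branches on a normality check of the differences:

* normal: mean difference ± 1.96 SD;
* non-normal: median difference ± 1.45 IQR, with type-7
  (linear-interpolation) quartiles — the multiplier is only meaningful
  relative to a stated quantile rule, so the rule is part of the
  report's provenance.

The normality check is Kolmogorov–Smirnov with the Lilliefors
correction by default, since the null parameters are estimated from
the sample; the uncorrected test is available for strict replication
of software that ignores the estimation effect (and is used
automatically at n = 4, below the Lilliefors tables). A paired t-test
against zero is always reported as the fixed-bias check. When the two
systems agree exactly the result degenerates to a zero-width interval
and the tests are reported as `NA` rather than fabricating a p-value.

## Reliability statistics

Test–retest reliability uses the two-way random-effects *consistency*
ICC, single measures, from the subjects × sessions ANOVA without
replication:

`ICC(C,1) = (MS_rows − MS_error) / (MS_rows + (k−1) MS_error)`.

Consistency (rather than absolute agreement) is the defining choice: a
uniform session offset — a learning or donning effect that shifts every
subject equally — moves `MS_cols` only and leaves the ICC unchanged,
which the tests verify directly. The 95% CI is the exact F-based
interval on `F = MS_rows/MS_error` with `(n−1, (n−1)(k−1))` degrees of
freedom. Negative estimates (noise exceeding between-subject variance)
are reported as computed, with a warning, rather than truncated.

Qualitative bands: ≥ 0.75 excellent, 0.4–0.74 fair-to-high, < 0.4
poor. The published bands leave (0.39, 0.40) unassigned; the boundary
is placed at 0.4 so both printed boundary cases keep their labels.

`SEM = SD·√(1 − ICC)`, with SD taken over subjects of each subject's
across-session mean — absolute reliability in the outcome's own unit.

`reliability_sample_size()` implements the Walter–Eliasziw–Donner
variance approximation with a one-sided `z_α` (the hypothesis ρ > p0
is directional). For α = 0.05, β = 0.2, k = 3, p0 = 0.4, p1 = 0.7 it
gives n = 21. Published reliability studies using these same design
values sometimes quote smaller numbers (e.g. 16); such differences are
consistent with a different approximation variant, sidedness, or table
interpolation, which is why the function records its formula variant
and exact (unrounded) n in the result metadata instead of presenting
the count as canonical.

## The synthetic-data generator

No public corpus of paired insole/force-plate recordings exists at the
frame level, so the generator is a first-class module: it constructs a
noise-free ground-truth waveform per activity at a 2000 Hz master rate
(above both device rates, so each rendering is a downsampling and
neither system is privileged) and renders it twice.

Waveform shapes encode each activity's defining features, per foot:

* **squat**: load dips below standing, `BW/2·(1 − 0.5 sin²(πft))`;
* **sit-to-stand**: seated low load (10% BW) rising to 45% BW;
* **jump**: `sin²` stance bumps (peak 0.8 BW) separated by
  exact-zero flight spans (15% of the cycle);
* **walking/stairs**: double-bump stance profiles
  (`sin(πτ) + c₂ sin(3πτ)`, stance 65–70% of the cycle) separated by
  zero-load swing.

Stance profiles are symmetric about mid-stance so that cycle
boundaries (swing/flight midpoints) are preserved exactly under
zero-phase filtering; the second-bump coefficient is kept small
(`c₂ ≤ 0.08`) so the mid-stance valley stays below the 10% prominence
threshold and never splits a cycle. The waveform runs from the first
boundary through the last plus a half-cycle margin: every boundary
except the very first is then a detectable interior extremum, so an
ideal detector finds `n_cycles − 1` cycles and edge trimming retains
`n_cycles − 3` — the bookkeeping the segmentation tests assert. COP
trajectories are smooth curves centred on the grid (AP excursions of
6–12 cm, ML of 1–3 cm depending on activity), undefined wherever the
foot is unloaded.

The plate rendering decimates truth to 1000 Hz and adds white noise
(default 2 N on vGRF, 0.05 cm on COP). The insole rendering samples
truth at 60 Hz and deposits, per frame, a bivariate-Gaussian pressure
footprint on the sensel grid, scaled so the summed sensel load equals
the truth vGRF times `vgrf_scale_bias` *exactly* — conservation holds
by construction — and centred at the truth COP with ML excursions
shrunk about the grid midline by `cop_ml_shrink`. The default biases
(vGRF × 0.85, COP-ML × 0.6) emulate the characteristic insole errors
the pipeline is designed to detect: under-read force and a compressed
medial–lateral picture. The footprint SD defaults to 1.2 cm: pressure
under a foot concentrates beneath the heel and metatarsal heads, and a
much wider footprint is visibly truncated at the insole edge, which
biases the recovered COP toward the midline (with 1.2 cm the
noise-free round trip recovers COP within 0.1 cm RMS everywhere; at
2 cm the truncation bias alone reaches several tenths of a cm for
realistic ML excursions).

The default grid is a deterministic foot-shaped lattice of 235 sensels
(9 × 9 mm on a 9.5 mm pitch) — a stand-in built from published device
characteristics (sensel count, pitch, pressure range), since real
sensel coordinates are not published. Geometry always travels with the
data (grid object or CSV); nothing in the computation assumes a
particular layout.

What the generator does *not* model: sensor creep and temperature
drift, shear forces, inter-sensel crosstalk, footwear deformation,
clock drift between devices, or biofidelic inter-cycle waveform
variability (cycles differ only through noise and amplitude scaling).
Passing tests therefore demonstrate that the pipeline's computations
are correct and that its statistics recover known structure — not that
a physical insole meets any agreement or reliability threshold.

## Study-scale choices in the tests

Cohort-level tests run at deliberately modest sizes chosen to keep the
statistical assertions sound: the end-to-end agreement experiment uses
20 subjects × 3 activities × 2 feet with 5 cycles per trial; ICC
parameter recovery uses n = 200 subjects × 2 sessions × 100 seeds per
true ρ ∈ {0.2, 0.5, 0.8, 0.95}; the ICC-versus-oracle equivalence uses
200 random matrices (n ∈ [5, 20], k ∈ [2, 4]); boundary recovery runs
every activity at 5, 8 and 12 cycles. These sizes are properties of
the test design, stated here so that reruns and extensions scale them
knowingly.

## Known limitations

* The per-cycle repair rules (merge on zero opposite extrema, accept
  on several) are deterministic and logged, but heavily corrupted
  signals will still segment; the exclusion log, not the range table,
  is the place to catch that.
* COP agreement between systems inherits the insole's load floor:
  near-floor samples exist on one system and not the other, so COP
  ranges are not computed over exactly the same support. This mirrors
  the real measurement situation and is documented rather than
  hidden.
* The Lilliefors p-value is itself approximate for small n; at n = 4
  the branch decision rests on the plain KS test.
* `simulate_reliability_study()` controls the *amplitude* variance
  structure; derived COP ranges inherit the target ICC only
  approximately (rendering noise adds a small within-session
  component).
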