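---
title: "Models, thresholds, and design choices in spineglia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, thresholds, and design choices in spineglia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineglia)
```

spineglia packages five analysis chains that are usually re-implemented ad
hoc in every lab studying microglia–neuron interactions and adult-born
granule cell (abGC) physiology: microglia–spine contact scoring with an
image-offset chance null, ΔF/F~σ~ odor-response extraction, tuning and
event statistics, spine morphometry, and voltage-clamp summaries, tied
together with a two-level hierarchical bootstrap. This vignette explains
the models behind each chain, the parameters that matter, the numerical
choices made where the methods literature leaves the design open, and what
the synthetic-data module does and does not establish about real data.

## Microglia–spine interactions and the offset null

The primitive observable is the **coverage fraction**: the proportion of a
spine-head ROI's pixels overlapped by the binary microglia mask in one
frame. A pixel belongs to the ROI when its center falls inside the polygon
(even-odd rule); `coverage_fraction()` is tested against an independent
point-in-polygon oracle on random polygons, so the rasterization is exact,
not approximate. A frame counts as an **interaction** when coverage reaches
the criterion, 5% of the head area. The methods convention is stated both
as "greater than 0.05" and as "at least 5%"; we adopt the inclusive
`>= 0.05` reading and expose `strict = TRUE` for the other. Runs of
consecutive qualifying frames form one interaction whose length is the run
length times the frame interval (3 min by default); frames flagged invalid
(too dim to segment) break runs, because the interaction state during them
is unknowable.

Chance is modeled by **circularly translating the microglia channel**
relative to the spine ROIs: horizontal, vertical, and diagonal (dx = dy)
shifts, starting at the maximum spine width (32 px, so no offset overlaps
the true alignment) and stepping by the mean spine width (10 px, so
successive offsets decorrelate). For an 800 px field this yields 77
magnitudes per mode, 231 offsets. Circular wrap-around is the only reading
under which that printed count is reproducible for an 800 px field, and it
keeps every offset's mask statistically identical to the original whenever
the mask process is stationary. Offsets that move a microglial soma onto a
spine are *not* excluded; as noted where the method was introduced, this
makes the null conservative. The one-tailed permutation p uses the add-one
convention `p = (1 + #{null >= obs})/(N + 1)`, which cannot return 0 and
matches the granularity of published values at 231 offsets (11/232 ≈
0.047).

**Discreteness and the calibration experiment.** Count-based summaries
(interactions per 10 min, proportion of spines with an interaction) take
few distinct values on a single dendrite-sized movie, so many offsets tie
with the observation; since ties count against the observation, the
permutation test is conservative for those statistics at desk scale. The
dendrite summary therefore also carries `mean_coverage` — the mean
per-spine coverage fraction, the continuous statistic underlying the
criterion — which is effectively tie-free. The calibration suite runs 200
bias-free movies in a 224 px field: that field size gives 60 offsets, so
the attainable rejection level at p < 0.05 is 3/61 ≈ 0.049, i.e. the
discrete test's level sits essentially at the nominal 5% being checked.
Both choices are consequences of the test's discreteness, decided at design
time, not fits to data.

**What the movie generator emulates.** Microglial processes are disks whose
centers start uniformly over the (toroidal) field and follow a wrapped
random walk (default step 4 px/frame); the process density default
(7.5 × 10⁻⁴ per px², ~38 processes in a 224 px field) was set so bias-free
movies reproduce the published scale of contact statistics — roughly 36% of
mushroom spines with at least one interaction and ~0.13 interactions per
10 min over a 48 min session. Uniform initial positions on a torus make the
mask translation-invariant, which is exactly the condition under which the
offset null is exchangeable with the real alignment — the property the
calibration test verifies. The dendrite is a randomly oriented line of
spines; with a fixed (say horizontal) orientation, the offset mode parallel
to the dendrite re-samples overlapping mask bands and correlates with the
observation, which measurably depresses the rejection rate. With
`bias > 0`, a fraction `bias/(bias + 5)` of process positions is re-drawn
each frame at a mushroom spine head with 1.5 px jitter; `bias = 5` is a
deliberately strong implanted effect used for power checks. The generator
does **not** emulate photoreceptor noise, segmentation errors, soma
morphology, z-drift, or registration failure — so passing tests establish
the statistics' behavior under a clean, stationary null and a strong
implanted alternative, not robustness to segmentation artifacts.

## ΔF/F~σ~ responses and quality control

Traces are normalized as `(F − F₀)/F_σ` with `F_σ` the baseline SD —
appropriate when baseline fluorescence is too dim to estimate ΔF/F₀
reliably — and the response is the mean over the 5 s after odor onset
(windows are half-open in frames; dropped frames are omitted from the mean,
not interpolated). The QC chain mirrors the field's rules exactly:

* **Frames**: discarded when the cosine similarity to the reference
  projection deviates by more than 25% (anesthetized) / 30% (awake) from
  the best-trial mean, or 20% / 15% from that trial's baseline mean.
  "Differs by more than X%" is read as relative absolute deviation.
* **Trials**: discarded when mean brightness falls below half the mean of
  the first three trials, when the baseline–odor brightness difference
  exceeds 3 first-trial SDs, or when fewer than 75% of frames survive in
  the baseline *or* analysis window (the two windows are checked
  separately).
* **ROIs**: removed when `F_σ > 0.30 ×` mean baseline fluorescence.

**Baseline drift.** `F₀` is normally the plain baseline mean. When the mean
of the last 2.5 s of the baseline exceeds 1.1× the mean of the first 2.5 s,
a single exponential `a·exp(b·t) + c` is fitted (Levenberg–Marquardt) and
its value at the end of the baseline is used instead. As printed, this rule
triggers on *rising* baselines — the opposite of photobleaching; we
implement it verbatim and expose `direction = "falling"` to reverse it,
flagging the ambiguity rather than silently "fixing" it. A failed fit falls
back to the plain mean with a warning. `F₀` is estimated per trial (whether
the original analysis did so per trial or per session is not stated;
per-trial is the more conservative choice under drift).

## Thresholds, sparseness, events, temporal dynamics

The ROC threshold is the lowest candidate (pooled observed values) whose
blank-trial false-positive rate does not exceed the 10% design target,
with responses from all groups pooled before selection; "responds" is
strictly greater than the threshold. With n blank trials the achieved rate
is exact to one order statistic, which is what the acceptance check
asserts. Lifetime sparseness uses the standard ratio form on thresholded
responses with sub-threshold entries zeroed (one of two defensible readings
of "after applying a threshold"; zeroing is the one that makes the
all-sub-threshold rule LS = 0 continuous with the formula). Its analytic
anchors — LS = 1 for uniform vectors, 1/m for single responders, 0 for
silent cells — are asserted exactly; note 1/15 ≈ 0.067 is also the analytic
value of a single-responder dendrite on a 15-odor panel.

Event detection scans for runs of at least `n_min` consecutive frames at or
above `k` baseline SDs, within the response period. The `(n_min, k)` pair
is grid-searched to bring the blank-trial event rate closest to 10%, ties
broken toward the more conservative pair (larger `n_min`, then larger `k`).
The default `k` grid runs 1–5 SD in 0.25 steps: integer-only thresholds
leave a gap (on Gaussian blanks the feasible rates jump from ~7% to ~37%)
that makes a ±2-point landing on the target impossible. Event frames are
unioned across repeats, the repeat-mean trace is evaluated in a 1 s window
centered on its peak (clipped to the response period, restricted to event
frames), and latency averages onset delays over repeats with events.

For temporal dynamics, each group's trace matrix (trials × timepoints over
the analysis window) is column-centered and its first three principal axes
taken by SVD. The test statistic is the **largest principal angle** between
the two 3-dimensional subspaces — the usual single-number "angle between
subspaces"; the original description says only "the angle", so all three
principal angles are returned as well. The null shuffles whole traces
between groups, preserving group sizes; p uses the add-one convention. The
angle is symmetric in group order and invariant to a common orthogonal
rotation — both asserted as properties.

## Morphometry and electrophysiology

Spines are **filopodial** when the maximum head diameter is below 1.5× the
mean neck diameter, else **mushroom** (the ratio is the only input, so the
rule is scale-free; the 1.5 cutoff was originally chosen to reproduce a
published mushroom:filopodial ratio, and the generator's synthetic tables
are built around that ~0.37 mushroom share). Only protrusions shorter than
10 µm count as spines. Density divides *terminal points* by dendrite
length — branched spines count once per head — over dendrites at least
40 µm long, averaged per cell without weighting.

Passive properties come from the repetition-averaged test pulse
(−10 mV, 20 ms, 50 reps, 20 kHz): Rs from the capacitive peak, Rm from the
steady state over the last 20% of the pulse, Cm from the 20–80% decay fit
via `Cm = τ/(Rs‖Rm)` (the single-compartment relation; validated by
parameter recovery against the generating circuit). Two numerical choices
matter. First, the peak is taken from the decay fit extrapolated back to
the step onset — at 20 kHz the true instantaneous peak falls between
samples whenever τ is a few hundred µs, and the raw sample maximum would
bias Rs upward. Second, when no transient rises above 4× the baseline noise
the pure-resistor limit is returned (τ = 0, Cm = 0) instead of a degenerate
fit; a genuinely non-monotone decay segment is an error, not a silent fit.
The estimator needs the decay resolved by at least ~3 samples between its
80% and 20% points; at 20 kHz this bounds usable cells to τ over roughly
0.1 ms, which all realistic Rs‖Rm·Cm combinations satisfy. Sweep QC and the
<3 ms doublet rule follow the stated post-filters exactly, including the
sequential reading under which `{0, 2, 4}` ms keeps 0 and 4. Event
*detection* kernels are out of scope by design: the module consumes event
lists and implements only the published post-filters and summaries.
Band-stop conditioning cascades zero-phase Butterworth notches at 60 Hz and
four harmonics (±2 Hz), filtered around the running mean to avoid
zero-initial-condition edge transients; its contract — ≥20 dB at the
harmonics, <1 dB at 30 Hz and 1 kHz — is measured, not assumed.

## Hierarchical bootstrap

Each iteration resamples upper units with replacement (as many as
observed), then `n_lower` values with replacement within each drawn unit,
and evaluates the statistic on the pooled draw. Fixed `n_lower` (100 for
dendrites/spines, 5000 for synaptic events) represents each unit equally
regardless of how many raw observations it contributed. The directional
p is the paired-iteration probability that group A's statistic exceeds
group B's, with ties credited ½ so `p(A,B) + p(B,A) = 1` exactly (tie
handling is not specified in the original prose; ½ is the symmetric
choice). Callers report `p` or `1 − p` depending on the direction of
interest. The method is approximately — not exactly — calibrated: on
matched two-level Gaussian groups the one-tailed type-I rate at 0.05 runs
around 6%, and the acceptance suite allows up to ~7% plus binomial error,
the tolerance long associated with this resampling scheme.

## Problem sizes and determinism

The test and calibration suites run at sizes chosen to make the Monte-Carlo
assertions sharp while staying desk-scale: 200 bias-free movies (20 spines,
16 frames, 224 px) plus 25 biased movies for the contact calibration; 500
replicate pairs (5 units × 20 values, n_boot = 200) for the bootstrap
type-I rate and 100 for power; 200 replicates at 200 permutations for the
subspace calibration; 1000 random polygon/mask pairs for the rasterization
oracle. Every generator draws from one seeded stream per dataset (no global
RNG state is disturbed), identical seed + configuration is byte-identical
by construction, and the pipeline driver writes a manifest with checksums
so reruns can be verified bit for bit.

## Limitations

* The contact null's validity rests on stationarity of the microglia
  channel; real fields with a soma parked beside the dendrite violate it in
  the conservative direction (as in the original design).
* Count statistics on single short movies leave the permutation test
  conservative; calibration statements use the continuous coverage
  statistic.
* Registration, segmentation, and ROI drawing are upstream of this package:
  inputs are assumed registered, and the microglia channel is assumed
  binary (a plain threshold segmentation is provided for convenience, not
  as a trainable-segmentation replacement).
* The synthetic calcium model injects one kernel shape per responsive pair;
  it does not model adaptation across repeats, correlated noise, or neuropil
  contamination.
* Trace interchange is long-format CSV; no HDF5 reader is bundled.
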