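---
title: "Methods: bouton activity and structure analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bouton activity and structure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutonpipe)
```

`boutonpipe` analyzes trace-level data from longitudinal two-photon
imaging of corticostriatal axonal boutons in mice performing a cued
lever-pushing task. This vignette documents the models and procedures the
package implements, the parameters that matter, the numerical choices
made where a definition leaves latitude, and what the synthetic-data
generator does and does not emulate.

## Task and movement analysis

The lever trace is sampled at the imaging frame rate. A movement bout is
a contiguous run above a rest threshold: the onset is the first crossing,
the offset the first sample back below it (half-open interval, seconds),
and bouts separated by less than 500 ms are merged into one continuous
movement. A bout is a **rewarded movement (RM)** when its peak
displacement reaches the push threshold (1.5 mm by default) and its onset
falls inside a cue-initiated task period (10 s); all other pushes —
sub-threshold in the task period, or un-cued — are **un-rewarded
movements (UM)**. Because the reward terminates a trial, only the first
supra-threshold bout per cue window is RM; later bouts inside the nominal
window are treated as un-cued. Whether a push that starts just before the
cue but crosses threshold inside the window should count as rewarded is
genuinely ambiguous; we require the *onset* to fall inside the window.

Bouts preceded by any other movement offset within the prior 3 s are
excluded, guaranteeing a clean pre-movement baseline for trial-aligned
averaging.

When no explicit rest threshold is given it is estimated as
mean + k·sd of the putative rest period (samples below the session
median). We default to `k_rest = 8`: a small multiplier (2–3) sits at the
noise floor and crosses at chance on every rest period, which the 500-ms
merging rule then chains into spurious long bouts; 8 sd is still an order
of magnitude below genuine push amplitudes. The multiplier is
configurable for noisier sensors.

Movement-trajectory correlations between trials are Pearson correlations
of lever snippets aligned −0.5…+1.5 s around onset and linearly resampled
to a common length (64 points); the alignment window is a package choice,
as no canonical value exists.

## ΔF/F, z-scoring, event detection

The baseline F₀ at each frame is the 30th percentile of the raw trace in
a centered 30-s sliding window; ΔF/F = (F − F₀)/F₀. Two numerical
dialects are fixed deliberately: the window is *centered with edge
truncation* (it shrinks near the segment boundaries rather than lagging
them), and the percentile *interpolates linearly between order
statistics* (the type-7 convention), because percentile definitions
differ across software. The ratio form makes ΔF/F exactly invariant under
positive rescaling of raw fluorescence, which the tests assert.

z-scoring is per continuous imaged segment — the same convention the
segment-level PCA uses — so an event's z value is relative to that
segment's overall variability.

A calcium event is a local maximum of ΔF/F satisfying **both** criteria:
z-scored ΔF/F above 1 sd and raw ΔF/F above 0.08. A local maximum is a
sample strictly greater than both neighbors; plateaus count once, at
their first sample; peaks closer than 3 frames (configurable) are reduced
to the largest, since peak-finder defaults are not standardized. The
1-sd criterion applies to the peak's z value, not its prominence.

## Trial alignment and outcome classification

Activity is aligned −1 s (baseline) to +3 s around each movement onset on
the native frame grid; trials whose window does not fit in the segment
are dropped and reported. A bouton is *responsive* to a trial type when
the peak of its trial-averaged trace, searched −0.2…3 s relative to
onset, minus the 5th percentile of that averaged trace, strictly exceeds
90% of the bouton's session standard deviation. Two details are package
decisions: the reference sd is the sd of the bouton's ΔF/F over the full
imaged segment (the same quantity z-scoring uses), and the 5th percentile
is taken over the full aligned window rather than the baseline only — the
baseline-only alternative changes little on simulated data but is noted
for users comparing conventions. Classification requires at least 5
trials of each type (a package addition; below it the bouton is flagged
and classed `none`).

Axons use the same peak-minus-5th-percentile statistic but a
population-derived threshold: histograms of the per-axon peak values in
RM and UM trials (bin width 0.1 sd, spanning from 0, mode ties broken
toward the lower bin — deterministic and conservative), threshold = the
mean of the two mode-bin centers, capped at 1 sd.

Classes are exhaustive and exclusive: RM-only, UM-only, both, none, with
RM-responsive = RM-only ∪ both when a grouped view is needed. Transition
matrices between learning stages are row-conditional distributions over
the same tracked boutons. In the two-stage pipeline the early stage is
training days 1–3 and the late stage day ≥ 8.

## Population geometry and the selectivity index

Two PCA views are computed. For the *bouton embedding*, each bouton's
trial-averaged RM and UM traces are concatenated into a 2M × N matrix
(M frames per window, N boutons); each bouton's column is mean-centered
(no variance scaling — conventional for ΔF/F) and the SVD taken across
time points, so every bouton is a dot in PC space. For *population time
courses*, PCA runs on the boutons × frames matrix of one continuous
segment, giving the first three PCs as time series. Component signs are
fixed so each loading vector's largest-magnitude element is positive, for
reproducibility; rank-deficient inputs return the reduced rank with a
warning.

Single-trial trajectories are the first three PCs aligned −1…+3 s around
each onset. For an RM trial the selectivity index at each frame is
(d_UM − d_RM)/(d_RM + d_UM), with d the Euclidean distance to the mean
UM (RM) trajectory at that frame; for UM trials the roles swap. The
index is +1 when the trial coincides with its own type's mean and −1 on
the opposite mean. Frames where both distances are zero are undefined
and *excluded* rather than set to 0 — zero would fabricate neutrality.
Mean trajectories include the trial under evaluation (no leave-one-out;
none is implied by the definition), which biases single-trial indices
slightly toward +1 when trial counts are low — a caveat for small
sessions. Per-trial means, per-frame values and labels are all exported
so any aggregation level can be compared.

## Same-axon heterogeneity

Events of two boutons match when they occur within 670 ms of each other;
matching is one-to-one, greedy over the first train's events in time
order, each taking its nearest unmatched partner. For trains whose
within-train spacing exceeds twice the tolerance, greedy matching equals
the maximum-cardinality bipartite matching (asserted against a
brute-force oracle); differences are confined to pathological spacings.
The same-peak fraction of a pair is 2m/(nᵢ + nⱼ) — a matched pair counts
once in each bouton's tally. The defining phrase ("same peaks over total
peaks per bouton pair") is ambiguous between this and m/max(nᵢ, nⱼ); the
symmetric convention is the default and the components (m, nᵢ, nⱼ) are
reported so the alternative can be recomputed. Fractions aggregate
hierarchically: per bouton over its pairs, per axon over boutons, per
mouse over axons; axons with fewer than two boutons carry no pairs.

A peak is RM- (UM-) related when it falls 330 ms before to 670 ms after
an RM (UM) onset; when windows of both outcomes cover a peak, the nearest
onset wins (the definitions are silent on overlap). Axon heterogeneity is
the minority fraction among the RM-only and UM-only boutons of one axon
(0 = uniform, 0.5 = maximally mixed); `both`-class boutons are excluded
because they carry no preference — counting them toward both classes is
the documented alternative.

"Activated in a trial" — needed for the ensemble-difference statistic
|a − b|/(0.5(a + b)) — has no canonical operational definition; the
package counts a responsive bouton as activated when it has at least one
detected event in the −0.33…+0.67 s outcome window around the trial
onset, reusing the outcome-association window. Pair statistics are binned
by movement correlation into −0.2…0, 0…0.2, …, 0.8…1 (half-open bins,
the last closed; pairs below −0.2 excluded) and, in the pipeline,
averaged per mouse before stages are compared.

## Structural dynamics

Boutons are tracked as presence/absence per imaging day (0, 2, …, 10 by
default) at a 1-D position along the axon; along-axon distance is the
difference of stored positions (no 3-D path reconstruction). Between
adjacent sessions every bouton is exactly one of persistent / formed /
eliminated / absent. A presence gap (present → absent → present) is an
elimination followed by a formation; the definitions do not address
re-appearance, and this treatment keeps the bookkeeping identity
present(d) = present(d−2) − eliminated + formed exact, which the tests
assert. Formation and elimination percentages are normalized to the
boutons present at the *earlier* session of each pair. Density is
boutons per µm of axon; normalized density divides by the first imaged
day. Survival of the day-4-formed cohort is the fraction still present on
days 6, 8, 10.

## The synthetic-data generator

The generator is the package's test bed and defines its study
conditions; defaults are chosen once to be realistic for this
preparation:

- **Behavior**: 15-Hz sampling, 10-s task period, 4-s ITI (doubled after
  an un-cued push, as a timeout), 1.5-mm threshold, raised-cosine pushes
  of 0.4–0.8 s. `p_success` (default 0.7) and `p_iti_push` (0.3) set the
  outcome mix; ITI pushes are placed late in the interval so they retain
  a clean 3-s baseline.
- **Fluorescence**: GCaMP6s-like difference-of-exponentials kernel
  (rise 0.2 s, decay 1.0 s) normalized to unit peak; a constant positive
  per-bouton baseline (uniform in 50–150 a.u.) keeps ΔF/F well defined;
  additive Gaussian noise `noise_sd` (0.05 ΔF/F). Each axon carries a
  shared spontaneous train (0.08 Hz); each bouton realizes a shared event
  with probability `p_shared` (0.8) and adds unique events (0.02 Hz).
  Outcome-tuned boutons (`frac_rm_only` = 0.3, `frac_um_only` = 0.2,
  `frac_both` = 0.2) receive a transient of amplitude `response_gain`
  (0.6 ΔF/F) at each preferred onset. Events within one bouton are kept
  at least `min_event_gap` = 1 s apart so the 670-ms matching rule is
  unambiguous; no public SNR or amplitude statistics exist for this
  preparation, so these are free parameters, not literature values.
- **Structure**: 60-µm axons at 0.35 boutons/µm; per-interval formation
  (0.08) and elimination (0.06) probabilities relative to the boutons
  present; finite `cluster_scale_um` places new boutons a Gaussian offset
  from an existing or co-formed bouton (reflected into the axon),
  `Inf` places them uniformly.

A single master seed is expanded into per-stream substreams (behavior,
fluorescence, structure) so stages can be regenerated independently;
identical config and seed give bit-identical output.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: no pixel-level imaging, motion artifacts or
neuropil contamination (simulation is at ROI-trace level); no baseline
drift or bleaching (the constant baseline makes the sliding-percentile
baseline an easy case); no biophysical spike-to-calcium nonlinearity,
amplitude adaptation or indicator saturation; lever noise is white and
Gaussian; and structural turnover is memoryless per interval, with no
activity coupling unless programmed explicitly.

## Problem sizes and runtime choices

The shipped tests run the generator at deliberately modest scales — a few
hundred to a few thousand frames, tens of boutons — except where a check
is about sampling error: classification recovery uses 500 boutons over a
6000-frame session with `response_gain` well above the noise sd (the
misclassifications that remain are false positives of the 0.9-sd
criterion on non-responsive boutons, i.e. its nominal false-positive
rate); structural rate recovery uses ~500–600 boutons over six sessions;
the greedy-vs-optimal matching equivalence is checked on 1000 random
train pairs. Event-recovery checks use `min_event_gap` = 2 s, because at
1-s spacing a transient riding the previous decay tail can shift the
detected peak beyond the ±2-frame bound — a superposition property of the
kernel, not a detector failure.

## Known limitations

- The trial-pair "activity pattern" and the activated-ensemble rule are
  documented stand-ins where no operational definition exists.
- The selectivity index inherits a small own-type bias from including
  the evaluated trial in its mean trajectory.
- Greedy peak matching can differ from optimal matching on trains with
  spacing below twice the tolerance; the simulator avoids this regime by
  construction, real data may not.
- Structural analysis assumes positions are comparable across days
  (registration and manual tracking are upstream of this package).
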