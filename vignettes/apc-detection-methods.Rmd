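---
title: "Detecting attempted prey captures from head-mounted accelerometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting attempted prey captures from head-mounted accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcr)
```

## The problem

Free-ranging pinnipeds cannot be watched while they forage. Head-mounted
tri-axial accelerometers offer an indirect window: when a seal lunges at,
grabs, and handles a prey item, its head moves in fast jerks that are
spectrally distinct from the slow, rhythmic movements of swimming and
searching. `apcr` implements a complete, testable pipeline for turning
head-acceleration and time-depth records into counts of individual
*attempted prey captures* (APC — lunges at a single prey item, whether or
not the capture succeeds), and for validating those counts against
annotated animal-borne video.

The pipeline has five stages, each an independently usable module:

1. **Signal I/O and alignment** — read 20 Hz tri-axial acceleration (g,
   clipped at ±3 g) and 1 Hz depth (m), apply user-supplied clock offsets,
   linearly upsample depth to the accelerometer rate, and trim both streams
   to a common time vector.
2. **Dive segmentation** — zero-offset correct the depth record, find dives
   (excursions deeper than 15 m, delimited by 2 m surface crossings), and
   split each into descent/bottom/ascent by changes in depth slope.
3. **APC detection** — per dive and per axis: 3 Hz zero-phase high-pass,
   moving 1.5 s sample variance, supra-threshold variance peaks, and a
   minimum-interval rule merging nearby peaks into single events.
4. **Validation** — match detections to video event windows; count TP, FP
   (including multiple matches), FN, and dive-level TN; compute detection
   rate, FP rate, and precision, averaged per animal.
5. **Optimisation** — a random dive-level 50/50 holdout; grid search of the
   variance threshold and minimum interval on the training dives; a 2%
   detection tie rule resolved by precision.

A synthetic-deployment generator closes the loop: every stage is exercised
end to end without any field data.

## The detector

Let $a(t)$ be one acceleration axis sampled at $f_s = 20$ Hz. The detector
computes:

1. $\tilde a = \mathrm{HP}_{3\,\mathrm{Hz}}(a)$, a 4th-order Butterworth
   high-pass applied forward and backward (`signal::filtfilt`). Stroking
   (~1.2 Hz) and the quasi-static gravity orientation sit below the cutoff;
   prey-capture jerks carry most of their power above it. The zero-phase
   realization matters: matching to video happens at second-level
   precision, and a causal filter would delay every event by a
   data-dependent lag. The whole trace is filtered once and dives are cut
   out afterwards, so filter edge transients occur only at the deployment's
   ends (at the surface), never at dive boundaries. The filter itself
   reflect-pads the series after removing its mean; without padding, a
   forward-backward pass leaves large transients on any signal with a DC
   offset.
2. $v_i = \mathrm{Var}(\tilde a_{i-14}, \ldots, \tilde a_{i+15})$, the
   centred moving sample variance ($n-1$ denominator) over 1.5 s = 30
   samples, stride 1. Positions whose window would leave the dive are
   excluded, as are samples shallower than 2 m.
3. Peaks: strict local maxima of $v$ above the variance threshold
   (plateaus count once, at their first sample). Fur-seal variance traces
   are sharply peaked, so the strict-maximum semantics is stable; a
   brute-force scan pins it exactly in the tests.
4. Grouping: consecutive peaks no more than `min_interval` seconds apart
   chain into one APC; a larger gap starts a new APC. One APC therefore
   spans at most one prey item's chase-capture-handling sequence, whose
   internal head movements recur every few seconds.
5. Features per APC: time of the first peak (the event time used for
   matching), number of peaks, duration (first to last supra-threshold
   sample over the group's supra-threshold extents), and the cumulative
   integral of the variance curve over those extents.

### Tunable parameters

| parameter            | default | units | role |
|----------------------|---------|-------|------|
| `cutoff`             | 3       | Hz    | separates head jerks from stroking/orientation |
| `variance_window`    | 1.5     | s     | smoothing scale of the variance envelope |
| `variance_threshold` | 0.1     | g²    | sensitivity; grid 0.1/0.2/0.4/0.8 (heave 0.1/0.2/0.4) |
| `min_interval`       | 5       | s     | event-merging scale; grid 5/10/20 |

The threshold/interval defaults are the *generic* parameters — one setting
shared by all animals, the most sensitive point of the grid. *Animal-specific*
parameters are chosen per animal on its training dives: take all grid points
with detection within 2 percentage points of the maximum, pick the one with
the highest precision, and break residual ties toward the lower threshold,
then the shorter interval (the most sensitive candidate).

### The integral's units

The per-event integral is reported, by default, as a time integral of the
variance curve (trapezoidal rule, units g²·s). Field reports sometimes
quote this quantity in plain g², which corresponds to summing the variance
samples instead; `detector_params(integral_mode = "sum")` selects that
convention. The default is the time integral because it is invariant to
resampling.

### Variance on the filtered signal

The moving variance is computed on the *filtered* signal, not the raw one.
On raw acceleration the slow orientation drift inflates every window's
variance and the stroke oscillation contributes a constant pedestal;
filtering first makes the threshold comparable across dives and animals.

## Matching and error metrics

A detection matches a video event when its first-peak time falls inside the
event's annotated window (chase start to end of handling for captures,
chase start to chase end for misses). Per event, the earliest matching
detection is the TP; further matches are "multiple-match" FPs — the
detector claimed two captures where the video shows one. Detections covered
by no window are FPs; unmatched events are FNs. A dive with no events and
no detections contributes exactly one dive-level TN, and TN can never
exceed one per dive. Chases that ended with the seal resuming search
swimming are excluded from matching altogether and count as prey-absent
context. Two bookkeeping identities hold by construction and are enforced
in the tests: TP + FN = number of events, TP + FP = number of detections.

The metrics, in percent:

$$\mathrm{detection} = 100\,\frac{TP}{TP+FN}, \qquad
  \mathrm{FP\ rate} = 100\,\frac{FP}{FP+TP}, \qquad
  \mathrm{precision} = 100 - \mathrm{FP\ rate}.$$

Note the FP rate here is the complement of precision (the fraction of
*detections* that are spurious), not the specificity-based rate — the
dive-level TN is too interpretation-laden to normalise by. Precision is
computed literally as `100 - fp_rate` so the complement identity is exact
in floating point. Undefined denominators (no events; no detections)
produce an explicit `NA` with a reason, never a silent zero. Per-animal
aggregation is counts-first: pool each animal's confusion counts over its
dives, compute one metric per animal, then average with equal weight per
animal — so a well-sampled animal does not dominate the cohort mean.

A dive-level summary is also provided: a *foraging dive* is any dive with
at least one APC, and the foraging-dive identification error is the signed
relative difference `100·(video − accel)/video` between the two sources'
foraging-dive counts.

## The synthetic generator

`sim_config()` / `generate_deployment()` emulate the study conditions of a
benthic-foraging fur seal on a shallow shelf:

* benthic dives with maximum depths drawn uniformly from 61–86 m,
  trapezoidal depth profiles (1.5 m/s transit), 40 s surface intervals;
* 1–7 APC per foraging dive, a rounded normal (mean 2.6, SD 1.6) truncated
  to that range — the printed mean/SD/range constrain the draw without
  asserting a distribution;
* 93% of APC successful; successful durations a truncated normal
  4.1 ± 2.7 s, unsuccessful 2.7 ± 1.2 s; prey mostly fish, with small
  cephalopod/stingray fractions and ~15% unknown;
* APC bursts as Hanning-enveloped 8 Hz sinusoid packets (well above the
  3 Hz cutoff); successful events contain 1–8 contiguous sub-bursts
  (handling), unsuccessful events one. Sub-burst intensity follows a
  unimodal profile across the event — handling intensity builds and ebbs —
  so within-event variance peaks rise toward the event's middle;
* a 1.2 Hz stroke oscillation (0.3 g), a slowly drifting orientation
  offset (period ~3 min), Gaussian noise (0.05 g), and hard clipping at
  ±3 g;
* optional non-feeding head-movement distractors (Poisson per dive), never
  overlapping true events;
* annotated event windows open 1 s before the burst (`chase_lead`): video
  annotators see the chase begin before the head strike reaches the
  accelerometer. This also absorbs the ≤ 0.75 s left-smear of the centred
  variance window.

Identical configurations (including the seed) give byte-identical output.
Events are laid out in each dive's bottom phase with at least `event_gap`
(default 10 s) between bursts, and the bottom phase is sized to fit them; a
user-supplied total duration that cannot accommodate the requested dives is
an explicit error, never a silent truncation.

What the generator does **not** emulate: amplitude variation of real APC
(burst amplitude is a free parameter, not an estimate — no published
amplitude distribution exists to calibrate it), hydrodynamic noise,
sensor-axis cross-talk, clock drift (only constant offsets), duty-cycled
video coverage, and prey-type-dependent signal differences (the validation
study found none). Perfect detection on clean synthetic data therefore
shows the pipeline's *internal* consistency — that the detector recovers
exactly what the model injects — not the field error rates, which are
dominated by head movements the model does not generate.

## Numerical and design choices

* **ZOC**: rolling-minimum baseline over a 600 s window subtracted and
  floored at 0. The window must exceed the longest dive so every window
  sees true surface; 600 s is double the longest default dive. Recovery of
  a known injected offset is the test.
* **Phase boundaries**: descent ends when downward speed first drops below
  10% of the dive's peak vertical speed; ascent symmetric from the end;
  V-dives collapse to a zero-length bottom. The fraction is configurable
  because absolute-versus-relative slope conventions differ between
  analysts.
* **Dive edges**: start/end at the 2 m surface-exclusion crossings, so the
  dive window includes the descent/ascent but the variance analysis skips
  near-surface samples.
* **Even variance windows**: a 30-sample window is centred half a sample
  left of its midpoint; the convention is frozen by the brute-force oracle.
* **Degenerate inputs**: dives shorter than the variance window yield zero
  APC with a notice; series shorter than the window yield all-`NA`
  variance; empty peak sets yield empty groups.
* **Holdout split**: a seeded *balanced* draw (`round(n/2)` dives into
  training) rather than an independent coin per dive. Realized training
  proportions then sit within 48–53% at field cohort sizes (32–77 dives),
  which is the regime the selection rule was designed for; an unbalanced
  split of 32 dives would regularly land outside it.
* **Overlapping event windows**: a detection inside two windows goes to
  the event with the nearest start (tie: earlier event), deterministically.

### Monotonicity of the APC count

For a fixed peak set, the total APC count is non-increasing in the minimum
interval — merging can only coarsen as the interval grows. In the variance
threshold the analogous statement is *not* an identity of the chain rule:
raising the threshold can delete a mid-chain peak and split one group into
two (e.g. peaks at 0 s, 12 s, 24 s with a 20 s interval form one group;
remove the middle one and two groups remain). In practice the count still
falls with the threshold whenever distinct events are separated by more
than the tested interval and within-event peak heights are unimodal — then
any threshold keeps a contiguous run of each event's peaks. The generator
satisfies both conditions by construction, and the property suite verifies
monotonicity over the full 12-point surge/sway and 9-point heave grids on
deployments whose event spacing exceeds the largest tested interval.

## Problem sizes in the tests

The test and validation runs use cohorts of 2–4 animals with 5–8 dives each
(roughly 15–25 minutes of 20 Hz data per animal) and 1000+ randomized
fixtures for the brute-force oracle comparisons; these sizes exercise every
code path while keeping the default suite fast.

## Known limitations

* Only constant clock offsets are modelled; deployments with drifting
  clocks must be pre-corrected or excluded, as in field practice.
* The detector works per axis; combined-axis indices (ODBA, vector norms)
  are out of scope.
* Success/failure and prey type are carried through the truth tables but
  the detector makes no attempt to discriminate them — the validation study
  found the acceleration features uninformative for that purpose.
* The dive-level TN depends strongly on how many prey-absent dives a
  deployment happens to contain; metrics that normalise by TN (accuracy,
  specificity) are deliberately not reported.
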