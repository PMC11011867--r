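---
title: "Calcium responsiveness profiling of pituitary adenoma recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcium responsiveness profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pitflux` turns raw multi-cell fluorescence recordings of acutely resected
pituitary adenoma tissue into per-cell secretagogue-response phenotypes and
tumor-level responsiveness fingerprints, and applies a threshold rule
linking those fingerprints to tumor recurrence. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
accompanying synthetic-data validation does and does not establish.

```{r setup, message = FALSE}
library(pitflux)
```

## The recording model

A recording is a cells × frames matrix of arbitrary-unit fluorescence
`F(t)` acquired at 5 Hz (0.2 s frames) under a fixed stimulation protocol:
a 3-minute unstimulated baseline; for each applied secretagogue (CRH, GHRH,
GnRH, TRH, TRH+dopamine) a 30-s pulse followed by a 15-minute wash; and a
terminal 30-s high-potassium pulse that depolarizes every live excitable
cell. `build_protocol()` encodes this timing as an epoch table; all epoch
boundaries are snapped down to the frame grid. The TRH+DA channel is a
distinct stimulus: it separates lactotroph-like cells (TRH receptor plus
dopamine receptor, inhibited by DA) from pure TRH responders, and the
mono/multi counting treats it as its own axis by default
(`collapse_trh = TRUE` collapses the two).

We model the measured signal per cell as

```
F(t) = F0 · b(t) · (1 + s(t) + ε(t)),
```

where `b(t) = (1 − depth) + depth · exp(−t/τ)` is multiplicative
mono-exponential photobleaching, `s(t)` is the calcium signal in ΔF/F
units, and `ε` is white Gaussian noise. The multiplicative form is the
standard epifluorescence bleaching model and makes the correction exactly
invertible; it is also why the ΔF/Fmin normalization is invariant to the
overall trace scale.

## Trace processing

**Photobleach correction** fits `A·exp(−t/τ) + C` to a running lower
envelope of each trace — the rolling 10th percentile over a window of 5% of
frames, evaluated on a strided grid — and divides the fitted curve out,
preserving the initial scale. Three refinements matter in practice:

1. *Quantile position.* On a decaying baseline the 10th-percentile of a
   window is attained near the window's 90% position, not its center;
   envelope points are assigned to that time, removing a systematic lag of
   about 0.4 window lengths.
2. *One-sided robustness.* Calcium events only ever push the envelope up,
   so the fit residual scale is estimated from the lower side and elevated
   envelope points are shed iteratively (with a peeling step for dense
   contamination).
3. *Shared decay constant.* Bleaching kinetics are a property of the
   fluorophore and illumination, shared across a field of view. A first
   pass of free per-cell fits yields the cross-cell median τ; the final
   per-cell fit masks event-carrying frames (sustained excursions above
   2σ, padded by 5 s before and 20 s after) and refits only amplitude and
   offset with τ pinned. Without this, a cell responding to all five
   secretagogues with prolonged transients has most of its trace elevated
   and a free three-parameter fit is unidentifiable — in synthetic
   recordings such cells showed ΔF/F reconstruction errors above 0.25,
   versus < 0.005 with the shared-τ refit.

Cells whose nonlinear fit fails fall back to a linear envelope detrend and
are flagged in the per-cell QC table.

**ΔF/Fmin.** Fmin is the 5th percentile of the corrected trace over the
baseline epoch, computed as an attained order statistic (inverse-ECDF
quantile), so ΔF/F is exactly zero at the frame attaining Fmin. A low
percentile rather than the global minimum keeps Fmin robust to noise
undershoot; restricting it to the baseline epoch keeps it independent of
stimulus responses. The processing order is fixed — correct, then
normalize — and recorded in the output metadata.

Because Fmin is a low percentile, the *resting ΔF/F level* of a pure-noise
trace sits about 1.6σ above zero. All detection and gating thresholds are
therefore expressed as excursions above the per-cell resting level (the
baseline-epoch median of ΔF/F), not above zero; a zero-referenced "k·σ"
threshold would in effect be a 2σ threshold and drown the detector in false
events.

**Viability.** A cell is viable iff its ΔF/F excursion in the high-K window
(pulse start to pulse end + 10 s) exceeds `max(k_K·σ, 0.05)` with
`k_K = 5`, where σ is the robust baseline noise SD, estimated as
`1.4826 · MAD(diff(baseline ΔF/F)) / √2` — first-differencing makes the
estimate insensitive to the sparse events themselves. Viable cells are
"100% of analyzed cells": every downstream proportion uses them as the
denominator, mirroring how ROIs are selected in the original assay. On
synthetic tissue with 10% non-viable cells (n = 500), gate sensitivity and
specificity are both 1.00 at default settings.

## Event detection

A baseline event is a calcium excursion exceeding the detection threshold
(resting level + 3.5σ, floored at 0.02 ΔF/F) for at least 0.6 s (three
frames). Event boundaries use hysteresis: an event begins when the trace
leaves the re-arm level (resting level + 1σ) and ends when it returns
there, with interruptions shorter than 0.4 s bridged. Two properties follow
by construction:

* the excursion segmentation does not depend on the detection threshold, so
  raising the threshold can only remove events — the detected count is
  monotone non-increasing in `threshold_k` (for thresholds above the
  re-arm level, i.e. `threshold_k` ≥ ~2);
* with merging disabled (`merge_gap_s = 0`) the detector reduces exactly to
  maximal threshold-crossing runs, which is what the exported brute-force
  oracle `detect_runs_naive()` computes frame by frame; the equivalence is
  exercised on hundreds of random traces in the test suite.

Events lasting ≥ 10 s are classed *prolonged*, shorter ones *fast*. The
cutoff, the threshold multiplier, the minimum duration and the merge gap
are all exposed in the configuration; none is prescribed by the assay
itself, so they were chosen once to separate the two transient morphologies
the synthetic generator produces (below) and left alone. Event rates are
reported per minute of baseline; a cell is *spontaneously active* iff it
has at least one baseline event.

## Response classification

A cell responds to a secretagogue iff an event *onset* falls inside the
response window: pulse start to pulse end + 30 s. Requiring the onset (not
merely elevated fluorescence) inside the window prevents decaying baseline
or wash activity from being scored as a response; an excursion already in
progress at the window start is attributed to earlier activity. The 30-s
post-window is a design choice — the assay does not state how long after
the pulse a rise still counts — and is configurable. Counting positive
calls maps each viable cell to non- (0), mono- (1) or multi-responsive
(≥ 2); the spontaneous flag is carried independently, so a spontaneously
active but stimulus-silent cell is non-responsive with
`spontaneous = TRUE`. Category percentages per tumor partition 100% exactly.

## Tumor profiling and the recurrence rule

`build_feature_table()` assembles per-tumor fingerprints — spontaneous and
category percentages, the five per-stimulus percentages, and maximum tumor
diameter — and standardizes each feature to zero mean and unit variance,
dropping constants with a report. PCA is computed by SVD of the centered
matrix (equivalent to the covariance eigendecomposition, against which it
is tested); component signs are fixed so each loading vector's
largest-magnitude entry is positive, making scores reproducible across
platforms. Tumors are clustered agglomeratively on correlation distance
(1 − Pearson r between fingerprint rows) with complete linkage — the
distance used by proportion-heatmap association analyses; the linkage is a
package choice, as only the plotting tool is specified by the assay.

The recurrence rule is the conjunction of three configurable clauses:

> predicted recurrent ⇔ `pct_spontaneous > 0` and `pct_multi > 20` and
> `pct_non < 50`.

It is monotone in each input, returns a per-clause trace, and reproduces
the observed recurrence status of the three reference fingerprints in the
cohort (tumors 2, 4 and 8). The rule is *reproduced, not validated*: with
13 tumors there is no claim of out-of-sample predictive performance.

## The synthetic generator

`simulate_recording()` exists so that every stage has ground truth. Its
defaults are the study conditions: 0.2-s frames, the full protocol
(optionally with washes compressed by an integer factor for desk-scale
runs — pulse timing and response windows are untouched), F0 = 100 a.u.,
noise SD 0.05 ΔF/F, bleach depth 0.3 with τ = 300 s, spontaneous event
amplitude 0.6 ΔF/F, response amplitude 1.0, high-K amplitude 2.0, each
jittered ±20% per cell. The assay does not state response amplitudes
relative to spontaneous events, so both are free parameters; the defaults
put the smallest transients at ~10σ, the regime the assay's clear example
traces display.

Population composition is *exact by construction*: viability, spontaneity
and category counts are largest-remainder allocations of the requested
fractions (ties broken by category position), so recovery experiments are
limited by detection error only, not label sampling error. Spontaneous
cells draw 1–12 baseline events uniformly; multi-responsive cells draw 2–5
distinct stimuli weighted by configurable per-stimulus weights.

Transients are difference-of-exponentials kernels with two shape classes
mirroring the two morphologies seen in adenoma cells: *fast* (rise 0.3 s,
decay 1.2 s; a few seconds wide) and *prolonged* (rise 4 s, decay 25 s;
FWHM ≈ 29 s). A cell's prolonged shape is used where a single event must
fit its window (a single spontaneous event, or a stimulus response);
multi-event baseline trains always use the fast kernel, since twelve
prolonged events cannot fit a 3-minute baseline. Spontaneous onsets are
stratified into equal slots across the baseline with uniform jitter —
random but non-overlapping, so ground-truth event counts are recoverable;
fully independent uniform placement would make exact count recovery
impossible at high event numbers and would test collision behavior rather
than the detector. Responses start uniformly within 5 s of pulse onset.
Every transient is clipped at its epoch boundary (baseline events end
before the first stimulus; responses before the next stimulus), and every
clipping is tallied, never silent.

What the generator does **not** emulate: optical crosstalk between ROIs,
movement, non-exponential or illumination-varying bleaching, cell–cell
coupling or network events, dye saturation, and baseline drift other than
bleaching. Passing the recovery experiments therefore shows the pipeline
is correct *under the stated noise model*, not that it is robust to every
artifact of real tissue recordings.

## Problem sizes and determinism

The packaged validation uses 500-viable-cell recordings with 10×-compressed
washes (≈ 810 s, 4050 frames) for the scenario-recovery experiments and the
viability-gate characterization, and smaller populations (4–40 cells) for
structural and property tests; these sizes give sub-percentage-point
recovery of the generator fractions while keeping a full suite run in a few
minutes. All randomness flows from a single integer seed: the population
draw uses the seed itself, event placement and noise use seed + 1, and
identical configurations produce byte-identical stage tables (checked by
MD5 in the test suite). Every written table carries the configuration hash
in a comment header.

## Known limitations

* Fingerprint percentages from few viable cells are coarse
  (1 cell = 0.2% at n = 500, but 5% at n = 20); the package does not
  propagate counting uncertainty into the recurrence rule.
* The shared-τ bleaching refit assumes one dominant bleaching timescale per
  recording; fields mixing fluorophores with very different kinetics would
  need per-cell free fits (`pass-1` behavior).
* The event detector reports fluorescence-level events only; it does not
  deconvolve spike trains or estimate calcium concentration.
* The recurrence thresholds (20% multi, 50% non, any spontaneous activity)
  come from a 13-tumor series; they are configurable and should be treated
  as hypotheses, not validated cutoffs.
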