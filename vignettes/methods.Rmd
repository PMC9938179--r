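---
title: "Detecting and quantifying NREM sleep oscillations with somnoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying NREM sleep oscillations with somnoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnoscope)
```

somnoscope analyses rodent polysomnography: local field potentials (LFP)
from prelimbic cortex (PrL) and dorsal hippocampal CA1, an EMG channel, an
epoch-wise hypnogram, and sorted single-unit spike trains. Its target
questions are pharmacological: how does a drug given mid-recording change
the cardinal oscillations of non-REM sleep — cortical slow-waves,
thalamocortical spindles and hippocampal ripples — their temporal
coordination, and the underlying spiking? This vignette describes the
models and procedures, the tunable parameters and their defaults, the
synthetic-data generator used for validation, and the numerical choices
made where the design was genuinely open.

## Event detection

All three detectors operate on a band-pass filtered, z-scored trace.

**Filtering.** Band-pass filtering is zero-phase: an order-2 Butterworth
filter applied forward and backward (`signal::filtfilt`), giving effective
order 4 and no phase distortion — essential because trough times anchor
both the peri-event spike analyses and the phase-amplitude coupling. An
FIR design was considered and rejected: at 0.5–4 Hz relative to a 1–2 kHz
sampling rate an FIR kernel needs thousands of taps, and higher-order IIR
designs are numerically unstable at these narrow relative bands. The
chosen filter attenuates a 50 Hz tone by more than 90 dB when configured
for the slow-wave band. z-scoring uses the mean and SD of the whole
submitted trace; an option excludes artifact-labelled epochs from the
scaling statistics. Baseline and post-drug windows are always analysed
independently, each with its own scaling.

**Slow-waves** (0.5–4 Hz, PrL). Candidate waves are delimited by
zero-crossings of the filtered z trace: a positive lobe followed by a
negative lobe. A wave qualifies when its extremum exceeds ±3.5 SD in
either direction. Amplitude is the initial positive peak (marking onset)
minus the maximal negative trough, in microvolts of the filtered trace;
waves whose trough negativity does not exceed 50 µV are rejected. The
intrinsic frequency is the reciprocal of the wave period,
1/(end − start), and the trough is the event's anchor (`peak_time`). Two
open points were resolved as follows: the 50 µV criterion is applied to
the *filtered* trace (the raw trace mixes in broadband power the rule
cannot have been meant to count), and a threshold crossing of either
polarity qualifies a wave (the amplitude and negativity rules are
unchanged). If no positive sample precedes the trough within the wave the
amplitude falls back to |trough| and the event is flagged.

**Spindles and ripples** (8–16 Hz on PrL; 125–220 Hz on CA1). The
rectified z trace is enveloped by a cubic spline through its local maxima
(ends held at the first/last maximum). An event is seeded where the
envelope crosses 3.5 SD and extended outward to the edge-threshold
crossings (1.5 SD for spindles, 2 SD for ripples). Events closer than the
merge gap (0.5 s spindles, 50 ms ripples) are merged *first*; the
duration bounds (0.35–4 s spindles, 50–500 ms ripples) are applied
*afterwards*. This ordering is deliberate: applying duration bounds
before merging would reject short excursions that are really fragments of
one longer event, which is exactly the situation the merge rule exists
for. Amplitude is the peak envelope rescaled to µV by the scaling SD;
intrinsic frequency is (number of local maxima of the filtered trace
within the event − 1)/duration — for a band-limited trace, local maxima
recur at the carrier rate, so this cycle count estimates the oscillation
frequency, reading up to one cycle per event low when the detected extent
out-spans the oscillation; `peak_time` is the envelope maximum.

Detection is never restricted to NREM: events are detected everywhere and
tagged afterwards with the state of the epoch containing their anchor
(`attribute_state()`), so state fractions are themselves an analysis
output.

## Spectra and phase-amplitude coupling

Power spectra are Welch averages of non-overlapping 4 s Hamming-tapered
periodograms (0.25 Hz bins, density-normalised to µV²/Hz). The SWA time
course averages 0.5–4 Hz power per 4 s window and then across 5-min bins;
empty bins are reported missing, never zero.

Coupling between the slow-oscillation phase and spindle-band amplitude is
quantified by the normalised-entropy modulation index: instantaneous
phase and amplitude come from analytic signals of the two band-filtered
traces, mean amplitude is accumulated in 18 phase bins of 20° (the
canonical binning for this index; coarser bins blur the coupled phase,
finer bins starve on data), normalised to a distribution P, and
MI = (log N − H(P))/log N ∈ [0, 1]. The comodulogram evaluates MI on a
grid of phase bands (0.5 Hz wide, stepped 0.5 Hz across 0.5–4 Hz) and
amplitude bands (2 Hz wide, stepped 1 Hz across 8–20 Hz): resolution
sufficient to isolate the 0.5–1.5 Hz × 10–16 Hz extraction window while
staying cheap. Three numerical choices matter:

* PAC is estimated on NREM samples only, from runs of at least 8 s,
  trimmed by one cycle of the lowest phase frequency at run edges —
  coupling is an NREM phenomenon and shorter fragments carry unusable
  phase estimates.
* The trace is decimated to 100 Hz by boxcar averaging before filtering:
  every analysis band sits at or below 20 Hz, the boxcar's spectral null
  falls at the new sampling rate, and the narrow analysis bands reject
  the residual alias energy (estimated at well under 1% of in-band power
  for 1/f-like input).
* The drug effect on coupling is the difference of the maximal in-window
  MI, post − pre, reported in raw MI units. Absolute MI values for
  slow-wave/spindle coupling are small (order 10⁻³–10⁻²) because spindles
  occupy a few percent of NREM time; any presentation scaling is left to
  the caller.

## Single units

Putative pyramidal cells have spike width > 200 µs and mean rate < 5 Hz.
Rate analyses include units above 0.15 Hz over the whole recording;
cross-correlation analyses require more than 200 spikes in *each* 20-min
analysis window. The bursting index is the fraction of inter-spike
intervals strictly below 20 ms. Peri-event time histograms are formed
around slow-wave troughs (±500 ms, 5 ms bins) or ripple maxima (±250 ms,
2 ms bins), converted to rates and z-scored across the bins of the unit's
own PETH — the only reference distribution available without an external
baseline; the statistic window (±250 ms slow-waves, ±40 ms ripples) is
*not* excluded from its own normalisation. Cross-correlograms count
spike-time differences in 2 ms bins over ±500 ms (the 5 ms variant used
for display in some figures is available via `bin_len`), z-scored across
lag bins; the peak statistic averages z over ±100 ms for within-region
pairs and 0–200 ms for PrL→CA1 pairs. With a state restriction, a
difference contributes only when both spikes fall in epochs of that
state. Changes are computed per unit within session (post − baseline);
units are assumed stable across the session — no re-matching is
attempted.

## Vigilance scoring

The rule-based scorer emulates manual scoring from the two features
scorers actually use: the theta/SWA power ratio of the LFP (high in wake
and REM, low in NREM) and the EMG RMS (high in wake, intermediate in
NREM, very low in REM), per 4 s epoch. Scoring is hierarchical, as in
standard rodent auto-scorers: wake is split off first by muscle tone,
then REM by its very low tone, falling back to the theta/SWA ratio when
the EMG clusters are too close to trust (under 0.5 log units apart). All
thresholds are per-recording — deterministic k-means splits on the log
features initialised at extreme quantiles, so small wake or REM fractions
still seed their own cluster. A fixed quantile rule (`method =
"quantile"`) is retained for comparison. A quantile- or median-based NREM
split was tried first and abandoned: with realistic state proportions
(NREM 40–75% of a session) any fixed-quantile split mislabels whatever
fraction the recording deviates from that quantile. Epochs containing
samples at or beyond the clipping limit (default 5 mV) are artifacts.
Externally scored hypnograms can be supplied everywhere a hypnogram is
accepted. Sleep-onset latency is the start time of the first NREM epoch.

## Group statistics

Changes from baseline (difference, or % of baseline where the baseline is
nonzero) are compared across conditions with a distribution-driven tree:
Shapiro–Wilk normality per group and Bartlett equality of variances (both
at α = 0.05) route the data either to one-way ANOVA with Bonferroni
pairwise comparisons against saline, or to Kruskal–Wallis with Dunn's
rank-sum post-hoc using Šidák adjustment ("Dunn–Šidák" being the closest
standard reading of the procedure's name). Groups with constant values
cannot pass a normality test and route to the rank path; fully degenerate
data (all values identical) short-circuit to p = 1 with no flags. PAC
changes are the stated exception: one-sample t against zero and Welch
two-sample t against saline, because PAC-change variances are unequal by
construction. Per-frequency-bin spectral comparisons apply the same tree
independently at every 0.25 Hz bin and report raw and
Bonferroni-corrected significance plus contiguous significant runs. The
sampling unit is the subject for LFP-level metrics and the unit or pair
for cellular metrics.

## The synthetic generator

No recordings ship with the package, so every stage is validated against
`simulate_session()`, which produces paired PrL/CA1 signals, EMG, a
hypnogram, ground-truth events and spike trains from one parameter object
(`gen_params()`). What it emulates, and the defaults:

* **State schedule**: alternating wake → NREM → REM bouts with
  exponential lengths (means 45/90/30 s), quantised to 4 s epochs. Only
  the NREM fraction matters downstream.
* **Background**: 1/f noise (exponent 1), RMS 30 µV, plus a 7 Hz, 12 µV
  theta during wake and REM so the theta/SWA ratio is informative. The
  theta envelope is ramped by a smoothed state indicator; switching it
  abruptly produces broadband transients that register as spurious
  spindles.
* **Events**: densities per NREM minute (slow-waves 6, spindles 2.5,
  ripples 15 — typical for adult rat NREM), placed without same-kind
  overlap, with 5% of events "leaking" outside NREM. Slow-waves are
  one-cycle biphasic raised-cosine pulses (positive lobe over the first
  40% of the period, then the trough), 170 ± 20 µV peak-to-trough over
  1.0 ± 0.15 s; spindles and ripples are hann-windowed sinusoids at 12 Hz
  (55 ± 8 µV, 1.0 ± 0.2 s) and 160 Hz (48 ± 8 µV, 0.14 ± 0.02 s).
  Amplitudes were calibrated once against the default background so that
  filtered slow-wave troughs sit near 8 SD and spindle/ripple peaks near
  6–8 SD of their bands — the regime a well-targeted electrode delivers —
  and the ripple duration so that its extent above the 2 SD edge
  threshold (~55% of nominal) lands at the ~75 ms of typical CA1 ripples.
* **Coupling**: each spindle is, with probability 0.7, anchored to a
  random slow-wave at onset trough + 0.25 periods, jittered uniformly by
  ±half a period scaled by (1 − depth); depth 1 is an exact lock, depth 0
  uniform phase. Spindle–ripple coupling is exposed nowhere: the source
  analyses quantify only slow-wave/spindle coupling, so the generator
  defaults it off.
* **Spikes**: inhomogeneous Poisson by thinning; rate × (1 − 0.8) within
  ±125 ms of slow-wave troughs, × (1 + 2) inside ripples for CA1 units;
  pairwise correlation from a per-region mother process (common fraction
  0.2, shared spikes jittered ~3 ms); burstiness by appending 3–15 ms
  doublets after a fraction of spikes, with the append probability
  corrected for chance short ISIs so the realised bursting index equals
  the configured fraction; 90% of units get pyramidal waveform widths.
* **Drug effects** are parameter transforms (`apply_drug_effect()`):
  multiplicative/additive changes addressed by dotted parameter paths,
  fraction-valued parameters clipped to [0, 1], provenance recorded.

The default sampling rate is 1000 Hz — comfortably above twice the
highest carrier (220 Hz) while keeping simulation light; readers ingest
2 kHz recordings unchanged.

**What the generator does not emulate** — and therefore what passing
validation does and does not show: real LFPs have non-stationary
backgrounds, movement and chewing artifacts, volume-conducted events,
spindles with chirping frequency, ripples riding sharp waves, and EMG
whose state-dependence is far noisier than the generator's clean
per-state RMS levels (the scorer's near-perfect agreement on synthetic
sessions is an upper bound, not a field estimate). Spike trains are
Poisson-based: no refractoriness beyond de-duplication, no true burst
dynamics, no behaviour-locked rate drift. Validation against this
generator demonstrates that the *analysis chain* is correct — thresholds,
rules, windows, statistics — not that detection performance on any given
recording will match.

## Validation harness and problem sizes

`assess_*()` functions regenerate ground truth and measure each stage;
`scripts/acceptance.R` runs them all and writes the results as JSON. The
problem sizes are the package's own choices: 20 ten-minute sessions for
detector fidelity; 1000 random candidate sets for rule conformance; 20
seeds per amplitude transform for recovery; 30-minute sessions for
coupling (the modulation index needs generous NREM for a stable
estimate); 100 simulated pairs for the correlogram comparison; 1000 null
datasets per regime for the type-I check. Slow-wave amplitude recovery
shows a small systematic shrinkage (1–3 percentage points at ×1.1–×1.5):
detection thresholds select the upper amplitude tail more aggressively at
baseline than post-transform, a selection effect real threshold detectors
share.

## Known limitations

* The EDF writer quantises to 16 bits over each channel's observed range;
  round-trips are exact only to that step. Record duration is fixed at
  1 s and sampling rates must be integers (CSV/binary formats carry
  arbitrary rates).
* The spline envelope needs at least 4 rectified maxima; sub-second
  inputs are rejected rather than guessed at.
* `filtfilt` edge transients are not specially treated; the first and
  last ~2 filter time-constants of a window are less trustworthy, which
  is immaterial for 10+ minute windows but argues against feeding the
  detectors very short snippets.
* The per-bin spectral comparison treats bins independently; its
  Bonferroni correction is conservative for smooth spectra.
* No artifact *detection* beyond clipping: artifact epochs must come from
  the hypnogram.
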