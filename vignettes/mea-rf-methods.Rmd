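---
title: "Methods: MEA phase metrics and thermometric dosimetry in mearf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA phase metrics and thermometric dosimetry in mearf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mearf)
```

This vignette is the package's account of its methods: the models and
algorithms it implements, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical choices made where
the published descriptions of these methods leave room.

## The experimental design the pipeline assumes

Recordings follow a five-phase protocol: two 15-min baselines (S1, S2), a
15-min exposure phase (E), and two 15-min post-exposure phases (P1, P2) —
75 min in total. `phase_protocol()` encodes this as five contiguous
half-open intervals `[start, end)`; a spike or burst sitting exactly on a
boundary belongs to the later phase, so the binning of events is
unambiguous. The protocol is fully configurable (labels and durations), and
the test suite makes extensive use of shortened 5 × 60 s protocols: every
algorithm is scale-free in the phase duration except where rates are
explicitly per-second or per-minute.

## Spike detection

Spikes are detected on raw voltages by a peak-to-peak threshold: within a
sliding 2-ms window, an excursion qualifies when max − min exceeds
`threshold_factor` (default 8) times the channel's noise SD. Design points:

- **Noise estimator.** The published contract says "SD of the biological
  noise", without excluding spikes from the estimation window. We use the
  median absolute deviation scaled to the Gaussian SD (MAD × 1.4826) over
  the reference window (default: the S1 phase). The MAD is essentially
  unaffected by sparse large spikes, so channels with vigorous activity do
  not inflate their own thresholds; tests verify a ±1 % recovery of the
  true SD with 0.2 % of samples replaced by 100-µV spikes.
- **Timestamp.** The spike time is the negative peak of the qualifying
  excursion (extracellular spikes are trough-dominated). Whether the
  original analysis stamped threshold crossings or peaks is not documented;
  the peak choice makes timestamps invariant to the threshold factor.
- **Refractory merge.** Detections closer than 1 ms are merged, keeping
  the deeper trough (earlier one on ties). This resolves double counting
  when one biphasic transient produces two overlapping qualifying windows.
- **Degenerate channels.** A constant channel has SD 0; it is flagged and
  skipped rather than producing division-free infinite sensitivity.

The detector is deterministic, scale-equivariant (multiplying signal and
noise SD by the same constant changes nothing), and on synthesized
recordings at peak-to-peak SNR 10 recovers ≥ 95 % of injected spikes within
±0.5 ms with ≤ 5 % false detections — measured against the generator's
ground-truth spike times, which is the strongest oracle available without
paired intracellular data.

## Burst and network-burst detection

Per electrode, the histogram of log10(ISI in ms) is built at 0.1-decade
bins, smoothed with a 3-bin moving average (partial windows at the edges).
Bursty electrodes show two modes: intra-burst ISIs (~10 ms) and the
between-burst/tonic mode (hundreds of ms to seconds). The adaptive
threshold is the leftmost minimum between the first and second peaks,
provided the first peak sits below 100 ms; otherwise a fixed 100-ms
fallback applies. Electrodes with fewer than 10 ISIs get no threshold and
no bursts.

Numerical choices worth recording:

- **Peak prominence.** A candidate peak must reach 10 % of the histogram
  maximum (`min_peak_frac`). Without this, a single pair of nearly
  coincident spikes creates a one-count "peak" at sub-millisecond ISIs,
  which would silently become the intra-burst peak and collapse the
  threshold. The canonical logISI methods likewise only consider
  substantial peaks.
- **Tie-breaks.** Plateau peaks resolve to their leftmost bin; the valley
  is the leftmost minimum between the peaks. Both choices are arbitrary
  but deterministic.
- **Burst definition.** Maximal runs of ≥ `min_spikes` (default 3)
  consecutive spikes with ISIs ≤ threshold. The resulting partition of
  spikes into in-burst and outside-burst is exhaustive and exclusive, a
  conservation law asserted property-style in the tests.

Network bursts pool burst onsets across electrodes, derive a grouping
threshold from the histogram of log inter-onset intervals (same valley
algorithm), and report groups in which the distinct participating
electrodes reach 20 % of the active set. The denominator set is the
bursting-active set of S1, consistent with the metric denominators below.
Network bursts are reported for inspection; no downstream metric consumes
them, because the four phase metrics are defined per electrode.

## Phase metrics and normalization

With per-electrode, per-phase firing rate FR (Hz), burst rate BR
(bursts/min), mean burst duration BD (s) and outside-burst firing rate
OBFR (Hz):

- MFR = ΣFR / N_S(S1), summed over the S1 spiking-active set
  (FR(S1) ≥ 0.1 Hz, boundary inclusive);
- MBR = ΣBR / N_B(S1), over the S1 bursting-active set
  (burst rate ≥ 0.04 Hz, i.e. 36 bursts in a 900-s phase);
- MBD = ΣBD / N_B, where BD is each electrode's mean burst duration;
- M_OB_FR = ΣOBFR / N_B(S1).

The active sets are computed once from S1 and reused for every phase;
activity appearing later in the recording cannot change a denominator.
Sums run over the same sets as the denominators — anything else would make
the S1 = 100 % normalization meaningless. The published form of the MBD
denominator is written N_B without an explicit "(S1)"; the package
defaults to the S1 set and exposes `mbd_denominator = "per_phase"` for the
other reading (the per-phase count of bursting electrodes). A phase in
which no active electrode bursts has MBD missing, not zero — zero would
fabricate a duration.

Normalization divides each culture's metric by its S1 value (× 100). It is
idempotent, S1 is exactly 100 by construction, and a culture whose S1 value
is 0 for some metric has that metric undefined rather than infinite.
Cultures with empty active sets are flagged unusable and excluded, with a
warning naming them.

The per-minute MBR time course bins burst starts (60-s bins by default) on
the S1 bursting-active set, normalizes each culture to its S1-bin mean, and
aggregates as mean ± SEM across cultures — the descriptive view of onset
and recovery dynamics.

## Statistics

Phases are compared per metric with the Kruskal–Wallis omnibus (base R's
`kruskal.test`, tie-corrected) followed by Conover–Iman all-pairs
comparisons computed from the same pooled ranks:

t_ij = (R̄_i − R̄_j) / sqrt(S² · (N − 1 − H)/(N − k) · (1/n_i + 1/n_j)),

with S² the tie-corrected rank variance and N − k degrees of freedom,
two-sided p-values, Holm-adjusted over the 10 phase pairs. The adjustment
method is recorded in the report and configurable; Holm was chosen because
it is conservative, exact under any dependence, and deterministic. The four
metrics are treated as separate families (no cross-metric correction),
matching the per-metric presentation of such analyses. Effect sizes are
reported as median percent changes between phases,
100 · (med_a − med_b)/med_b, on normalized values.

## The synthetic generator

`generate_scenario()` draws from a doubly stochastic model chosen to
reproduce exactly the structure the detection chain assumes:

- network-burst events arrive as a Poisson process at `network_burst_rate`
  (default 10 events/min — mid-range for mature dissociated cortical
  cultures in their synchronized-bursting stage);
- each event recruits each active electrode with `participation_prob`
  (default 0.6), so events are visible as network bursts;
- a recruited electrode emits 1 + Poisson(7) spikes (mean 8) at
  gamma-distributed intra-burst ISIs (mean 10 ms, shape 4), its onset
  jittered by N(0, 15 ms) around the event time;
- tonic spikes arrive independently per electrode at `tonic_rate`
  (default 0.5 Hz), and 15 % of electrodes are "inactive" (0.02 Hz, no
  burst participation), mimicking the silent-electrode fraction of real
  arrays.

The absolute rates are stated here as package defaults because published
work of this kind reports normalized values only; nothing downstream
depends on them beyond the activity thresholds being comfortably cleared.

Exposure effects enter as per-phase multipliers with three tracks: burst
initiation rate (reversible, RF-like — consistent with stable burst
duration and outside-burst firing under RF), tonic rate, and per-spike
retention probability (uniform thinning; persistent from E onward for the
heat-like scenario, whose firing suppression does not reverse). Transitions
are instantaneous by default; `onset_tau`/`recovery_tau` switch to
exponential relaxation for gradual-onset studies. The generator returns its
ground truth (event times, burst intervals, per-phase event counts), which
is what the recovery tests measure against.

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate about real data: electrode-to-electrode rate
heterogeneity beyond the active/inactive split, development or drift of
activity within a recording, burst-internal rate profiles
(acceleration/adaptation), propagation delays across the array, correlated
noise or stimulation artifacts in the waveforms, and any biophysics of the
exposure itself. The pipeline's validation is parameter recovery under its
own generative assumptions plus exact worked examples; it is not a
re-analysis of laboratory data.

## Dosimetry

The thermometric SAR estimate is SAR = C · ∂T/∂t at exposure onset, with
C = 4196.8 J/(kg·K) for culture medium. The initial slope comes from
fitting ΔT(t) = A(1 − e^(−t/τ)) to the first 5 min of exposure (the window
is configurable; 5 min constrains τ ≈ 120 s well while staying dominated
by the initial rise) and evaluating A/τ. Numerically, the fit is profiled
least squares: for fixed τ the model is linear in A, so A(τ) has a closed
form and the remaining one-dimensional problem in log τ is solved by
golden-section search. This has no starting-value failure mode, unlike a
generic nonlinear fit when early noisy samples cross zero. A linear fit
over the first 30 s is available behind `linear_fallback` for degenerate
traces; flat traces are rejected as non-heating. The noiseless round trip
simulate → fit → SAR is exact to < 0.1 %; with 0.02 °C measurement noise
at 1 Hz the estimate stays well inside the ±4 W/kg experimental
uncertainty at 28 W/kg.

Power bookkeeping converts a target SAR through the calibration
(W/kg per W) to watts and then dBm, reported to 0.1 dBm:
1, 3 and 28 W/kg at a 28 (W/kg)/W calibration require 15.5, 20.3 and
30.0 dBm.

## Problem sizes and reproducibility

The package-level checks run the three exposure-recovery scenarios at
16, 14 and 13 cultures of 60 electrodes over the full 75-min protocol
(the sizes of the experimental groups they mirror), a 19-culture sham run,
and a 1000-replicate null simulation for the omnibus test's type-I error —
about two minutes in total on one CPU. Unit tests use 5 × 60 s protocols
and 12-electrode cultures, which preserve every algorithmic property at a
fraction of the cost. Every stochastic step takes an explicit seed;
`simulate_cultures()` derives per-culture seeds as base + i − 1, and
identical configuration plus seed reproduces outputs byte for byte
(`run_analysis()` writes a manifest recording both).

## Known limitations

- The peak-to-peak detector does no spike sorting; multi-unit electrodes
  are treated as one spike source, as in the analysis it reproduces.
- The exact sub-variant of the published peak-to-peak detection algorithm
  (its "peak lifetime" bookkeeping) is not restated in the sources this
  package follows; the implemented contract — 8 × SD peak-to-peak in 2 ms,
  negative-peak timestamp, refractory merge — is the testable surface.
- The logISI histogram parameters (bin width, smoothing, minimum spikes
  per burst) follow the canonical defaults of the cited method and are all
  exposed in the API; published analyses rarely state them.
- MBD's denominator ambiguity is handled by a switch, not resolved.
- The heating model is single-compartment; it represents heat loss only
  through the exponential saturation and cannot capture convection-driven
  asymmetries between heating and cooling.
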