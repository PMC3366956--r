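---
title: "Methods: ripple detection, theta phase coding and place-field analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ripple detection, theta phase coding and place-field analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippocode)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, the choices we made where the standard
methodology leaves room, and what the synthetic-data tests do and do not
establish about real recordings.

## The data model

A `recording_session` binds one or more LFP channels (regularly sampled
voltage, typically decimated to 1 kHz), curated single units (sorted spike
times plus a mean waveform), a 25 Hz video position track, and a trial
table (rest / open-field / zigzag epochs). All times are seconds from
session start; intervals are half-open `[start, end)` so that a spike at a
boundary belongs to exactly one epoch. The original acquisition rate of
tetrode systems (tens of kHz) matters only for waveforms; the ripple band
(≤ 250 Hz) is fully represented at 1 kHz, which is the default rate of the
synthetic generator and keeps every analysis desk-scale.

Tracking dropouts up to 0.4 s (a few lost video frames) are linearly
interpolated before speed computation; longer gaps remain invalid. Running
speed is a central difference of boxcar-smoothed coordinates (window 0.2 s
— wide enough to suppress 25 Hz tracker jitter, short enough not to blur
run/stop transitions).

## Sharp wave/ripple detection

The detection chain is: zero-phase band-pass 125–250 Hz → RMS power in
20 ms windows stepped by 10 ms → a window above mean + 7 SD seeds an
epoch → the epoch extends in both directions to the last window at or
above mean + 2.5 SD. Candidates whose seed windows coincide (±1 window)
with a 7 SD excursion of the reference channel's ripple-band power are
discarded as muscle artifacts. Overlapping or nearly touching epochs
(< 10 ms apart) merge, and epochs shorter than one window (20 ms) are
dropped — sub-window detections are unresolvable at this windowing.

Two choices deserve explanation:

* **Filter realization.** No filter family is canonical here, but zero
  phase is mandatory because ripple and theta phase are *defined* by
  zero-crossings of the filtered trace. We use an order-4 Butterworth
  applied forward-backward. Very narrow normalized bands (delta at a 1 kHz
  rate) push an order-4 realization's poles marginally outside the unit
  circle; `bandpass()` checks pole radii and steps the order down until
  the realization is stable, which preserves zero phase and in-band unity
  gain.

* **Baseline statistics.** The mean and SD that the 7/2.5 thresholds refer
  to must describe the *noise floor*, not the events being detected. At
  realistic event rates the ripple windows themselves inflate the RMS SD
  by a third or more, silently costing sensitivity. `detect_swr()`
  therefore re-estimates the baseline iteratively, excluding windows more
  than 5 SD above the running mean (disable with
  `baseline_clip_sd = Inf`). Because ripples occur principally during
  immobility, the baseline is best computed over rest-trial windows
  (`baseline_epochs`); run periods would otherwise inflate it further.

Epoch characterization takes the peak-power time (center of the maximal
RMS window), the ripple cycles (descending zero-crossings of the filtered
trace), the amplitude (half the peak-to-trough swing within one cycle of
the power peak; the envelope-peak alternative is a config switch away in
spirit — we chose peak-to-trough because it is what a cursor measures on a
trace), and the peak frequency of the epoch's band-passed spectrum. For
the per-epoch spectrum we use a *single* Slepian taper: with 50–100 ms
epochs, the conventional NW = 3 / 5-taper smoother has a ±40 Hz
concentration band and cannot localize a ripple carrier to the ±5 Hz the
recovery tests demand; one taper of NW = 1 resolves it to ~2 Hz.
Session-level spectra (longer segments) keep the standard NW = 3, K = 5.

## Theta epochs and oscillation phase

Theta epochs are contiguous 500 ms windows whose theta (6–10 Hz) to delta
(2–4 Hz) RMS ratio exceeds 2. Within epochs the raw trace is filtered at
5–14 Hz; each positive-to-negative zero-crossing is phase 0°, and phase
interpolates linearly to 360° across the cycle. This cycle-by-cycle
convention absorbs the frequency wander of real theta, unlike a Hilbert
phase on a fixed narrow band. Epochs with fewer than two crossings are
marked invalid; spikes in invalid segments are excluded from all phase
analyses and counted per unit.

Spike phase statistics are the mean resultant length
$R = |\sum e^{i\theta}|/n$, the circular mean, and the Rayleigh test with
the standard finite-$n$ correction
$p = e^{-Z}\,(1 + (2Z - Z^2)/(4n))$, $Z = nR^2$. Group comparisons of
phase distributions use Watson's two-sample U² with its asymptotic tail
probability and the 0.187 / 0.268 critical values at 0.05 / 0.01.

Speed-resolved theta spectra cut the theta epochs into 500 ms segments,
assign each to a speed bin (lower edges 3, 8, 13, 18, 23 cm/s; the last
bin open) by the mean running speed, and average multitaper spectra per
bin.

## Unit classification

Three features per unit: log₁₀ mean session rate (cluster separation
between cell classes is multiplicative in rate, so log units make the
template covariance honest), the first moment of the spike-time
autocorrelation over lags (0, 25] ms in 0.5 ms bins (bursty pyramidal
cells are short-lag-heavy; tonic units approach the uniform-lag mean of
12.5 ms), and the spike duration at 25% of peak amplitude with linear
interpolation at the crossings. The pyramidal template is the mean and
sample covariance of these features over reference cells — spatially
selective units with open-field information > 0.5 — with a tiny diagonal
regularization (10⁻⁶ × trace/3) if the covariance is near-singular.
Mahalanobis distance below 20 labels a unit pyramidal, above 40
interneuron, and the band between (boundaries included) stays
unclassified. A documented discrepancy exists in the field between a 25 ms
and a 50 ms autocorrelation window for this feature; we use 25 ms and
expose the window as an argument.

Isolation distance is the n-th smallest Mahalanobis distance of
non-cluster spikes from the cluster's own mean and covariance (n = cluster
size); it is infinite (with a warning) when fewer noise than cluster
spikes exist.

## Spatial maps and selectivity

Occupancy uses 2 × 2 cm bins, a 3 cm-SD Gaussian kernel truncated at 3 SD,
and the 3 cm/s speed gate. Smoothing is *mass-conserving*: each source
bin's kernel is renormalized over its in-arena support, so no occupancy
leaks off the edges (total smoothed time equals total raw time to
floating-point precision). Rate maps divide the smoothed spike-count map
by the smoothed occupancy — smoothing numerator and denominator separately
with the same kernel is numerically stable where occupancy is thin,
whereas smoothing the ratio amplifies low-occupancy noise. Bins with raw
occupancy under 0.05 s count as unvisited and carry no rate. Cells firing
fewer than 300 spikes in a trial are excluded from selectivity analyses
(the gate scales with trial length in scaled-down runs).

Field detection is iterative: take the highest unassigned bin above 5 Hz,
flood-fill its 4-connected neighborhood down to 20% of that peak, accept
components of ≥ 10 bins (40 cm²), remove them, repeat. 4-connectivity is
the conservative choice (fewer spurious merges across diagonal saddle
points), and removing assigned bins guarantees termination with disjoint
fields. The 1-D variant extends from the peak until the rate drops below
20%, with no minimum length.

The zigzag maze (five 7 cm × 65 cm alleys, 58 cm dividing walls) is
linearized onto a skeleton of alley centerlines joined by half-turns of
radius 3.5 cm — half the alley width, the only radius consistent with the
7 cm turning gaps; total skeleton length 341 cm. Samples project to the
nearest skeleton point; runs split at visits to the two maze ends, and
northbound/southbound maps are built separately because in-field phase
behavior is direction-specific.

## Theta phase precession

For spikes inside a linear field, the model is
$\theta \approx 360^\circ\, a\, x + \theta_0$ with $x$ the relative
position in the field and $a$ in cycles/field. The slope maximizes the
mean resultant length of $\theta - 360 a x$ over $a \in [-2, 2]$ (dense
grid then golden-section refinement; final precision well under 10⁻³).
The signed correlation is the *pairwise* Fisher–Lee circular–circular
correlation between observed and fitted phases, signed like the slope. We
use the pairwise form deliberately: the mean-based form references sample
circular means, which are arbitrary directions when phases span the full
cycle (exactly the situation under strong precession), making it unstable;
the pairwise form needs no reference direction. Significance comes from
permuting positions against phases (1000 shuffles by default), with the
maximal grid resultant as the test statistic for both the observed data
and the null — the permutations reuse one complex basis matrix, so the
whole test is a single matrix product. A field counts as precessing when
r < 0 and p < 0.05; theta modulation of a unit is called at Rayleigh
p < 0.01. No multiple-testing correction is applied anywhere, matching
standard practice for these per-cell summaries; consumers comparing many
metrics should correct downstream.

Field-segment analysis divides each field into 4 equal segments and
reports per-segment firing rate by phase bin (12 bins of 30°), normalized
per theta cycle and converted to Hz by the time a phase bin occupies in a
mean cycle. Spatio-temporal maps histogram spikes over (relative position,
phase), normalize by positional occupancy, and smooth with a 1-bin-SD
Gaussian.

## The synthetic session generator

The generator emulates the statistical structure the analyses assume,
with every parameter recorded as ground truth:

* **Trajectories** — open field: Ornstein–Uhlenbeck velocity (correlation
  time 0.7 s, mean speed ~12 cm/s) with reflecting walls, covering ≥ 90%
  of the arena in 20 min; zigzag: end-to-end runs at 12–18 cm/s with 2–4 s
  pauses at the ends; rest: sub-cm tracker jitter.
* **LFP** — 1/f background noise, a speed-gated 6–10 Hz theta (amplitude
  1.5 × background SD, enough to clear the theta/delta ratio of 2 during
  running while rest stays below), and ripple bursts: Gaussian envelope of
  SD 10 ms, carrier uniform in 130–180 Hz, amplitude exactly 8 × the
  ripple-band SD of the background, injected at Poisson times (0.3 /s)
  during immobility with a 250 ms refractory gap. The 8 × amplitude puts
  the 7 SD threshold on the shoulder of the operating curve: detection is
  a meaningful test rather than a formality. The reference channel has its
  own background, optional shared artifacts, and no ripples.
* **Spike trains** — inhomogeneous Poisson by exact thinning. Place cells:
  Gaussian spatial envelope × unit-mean von Mises theta modulation whose
  preferred phase shifts linearly with in-field position at the configured
  precession slope × an SWR gain inside ripple epochs. Interneurons:
  15–40 Hz baseline with theta and ripple-phase von Mises coupling.
  Feature populations for classification draw the two clusters so that
  interneurons sit ~100 Mahalanobis units from a tight pyramidal template
  — the regime the 20/40 thresholds describe, where template cells are a
  selected homogeneous subpopulation.
* **Sessions** — the nine-trial rest/forage alternation (ABAB over open
  field and zigzag), 20 min per trial by default; tests scale trials down
  to 1–2 min and relax the 300-spike gate proportionally.

Everything is a pure function of (parameters, seed): sessions serialize
byte-identically across repeated generation, and the full pipeline is
deterministic given a session, a config, and the permutation seed.

**What the synthetic tests do not show.** The generator's ripples are
clean tones on stationary 1/f noise; real SWRs ride on sharp waves, vary
in envelope shape, and co-occur with population bursts. Its theta has a
slowly wandering frequency but no sawtooth asymmetry, phase–amplitude
coupling, or running-speed frequency shifts. Place fields are isotropic
Gaussians without rate remapping, head-direction tuning, or overdispersion
(real spike trains are super-Poisson). Passing the recovery suite
therefore certifies the *estimators* — that each stage recovers what was
injected under its own assumptions at realistic SNR — not that those
assumptions capture every property of mouse CA1.

## Problem sizes in the shipped tests

The test suite runs the SWR recovery on one 10-minute rest LFP
(~150–170 events), the Rayleigh calibration on 10⁴ uniform samples of
n = 50, the vector-length recovery as a mean over 30 draws of n = 1000
per κ ∈ {0.5, 1, 2} (a single draw has sampling SD ~0.02 — larger than
the 0.03 acceptance band it is checked against, so averaging is needed to
test the estimator rather than one realization), the precession recovery
on 100 generated fields of ~250 spikes (1000 permutations each) plus 100
null fields, the classification recovery on 100 populations of 50 units,
and the determinism check on a nine-trial session scaled to 2-minute
trials. Oracle-equivalence checks use ≥ 100 random small instances per
statistic against brute-force reimplementations kept in the test helpers.
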