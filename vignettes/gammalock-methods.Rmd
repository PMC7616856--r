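---
title: "Methods: phase-locking, decoding and connectivity in gammalock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-locking, decoding and connectivity in gammalock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators, parameter choices and
known limitations of the package, in the spirit of a methods section a
maintainer can audit.

## The analysis problem

Two visual areas are recorded simultaneously with laminar probes: a
*sender* whose stimulus-induced gamma rhythm (30–80 Hz, session-specific
peak) propagates feedforward, and a *receiver* whose units may or may not
lock to that rhythm depending on cell class (narrow-waveform, NW,
putative fast-spiking interneurons vs. broad-waveform, BW, putative
excitatory cells) and cortical layer (granular input layer vs.
superficial/deep). A trial structure contrasts attention directed toward
vs. away from the driven stimulus. The package quantifies (i) how
strongly spikes and fields lock to gamma, (ii) how reliably each signal
class encodes the attention condition, (iii) where attention effects
arise in the laminar circuit and when, and (iv) the direction of
interareal influence.

## Estimators

### Pairwise phase consistency

PPC is the mean cosine of all pairwise differences among phase
observations. It is computed via the algebraic identity
`(|Σu|² − n)/(n(n−1))` with `u = exp(iφ)`, which is exactly the all-pairs
average (the test suite checks this against an O(n²) brute force).
PPC1 restricts pairs to spikes from different trials:
with per-trial resultants `R_t = Σ_{spikes in t} u`,

    PPC1 = (|Σ_t R_t|² − Σ_t |R_t|²) / (N² − Σ_t n_t²).

This removes the estimator's sensitivity to within-trial spike counts
and to common within-trial phase noise, which is why thinning half the
spikes at random leaves its expectation unchanged (a property the
acceptance suite verifies). For a von Mises coupling of concentration κ,
the population value is `(I₁(κ)/I₀(κ))²`; this closed form is the
calibration oracle at κ ∈ {0, 0.5, 1, 2}.

Spike phases are estimated two ways, matching two analysis traditions:

* **spike-triggered windowed Fourier**: a window of 9 cycles of the
  target frequency (9/f s) centred on each spike, Hann-tapered, one
  complex coefficient per frequency. The "9 cycles" reading of the
  window rule makes spectral resolution proportional to frequency and
  matches the taper "of corresponding length"; the length is
  configurable because the rule is stated ambiguously in the source
  literature. Mouse mode uses a fixed 250 ms window instead. Edge
  spikes are dropped, not padded — padding biases the phase. The
  in-bounds rule uses the *largest* window across the evaluated
  frequencies so the spike set is identical at every frequency.
* **band-passed analytic signal**: order-12 two-way (zero-phase)
  Butterworth, then the Hilbert transform; per spike, the circular mean
  of the phase across the supplied channels at the spike sample.

LFP–LFP PPC uses multitaper coefficients (0.5 s epochs, seven unit-energy
DPSS tapers, time–bandwidth 4) with each (epoch, taper) pair as one
phase observation; a flag averages tapers within an epoch first, since
either pooling convention is found in practice.

### Decoding

Per-trial features are modelled per signal and condition by Poisson
(spike counts), Gaussian (phase-locking strengths) or von Mises
(angles) likelihoods, multiplied across signals in log space with a
flat prior, and evaluated leave-one-trial-out. Feature construction
follows the decoding-methods convention: the spike-phase modality is
*per unit* (trial mean phase per unit–LFP pair, combined by the
population product), while the trial-wise spike–field PPC pools spikes
across simultaneously recorded units. A unit silent in a trial
contributes no evidence for that trial. Degenerate fits are guarded: κ
capped at 10³, σ floored at 10⁻⁶ of the feature scale, Poisson λ = 0
gives mass 1 to zero counts and −∞ otherwise; posterior ties break by a
seeded coin flip so symmetric nulls stay at 50 % accuracy.

### Granger causality

Multi-unit count series (1 ms bins) in 0.5 s Hann-tapered windows give a
cross-spectral density on a 2 Hz grid. Wilson's iterative factorization
finds the minimum-phase factor; the plus operator keeps lags 0…n/2 with
the lag-0 coefficient halved and its strictly-lower triangle zeroed
(fixing the square root's normalization), initialized from the upper
Cholesky factor of the lag-0 covariance. The implementation was
validated against an analytic bivariate AR(2) oracle: on a dense grid it
recovers the transfer function to ~10⁻¹³ and the Geweke spectrum
exactly; on coarse grids the residual floor reflects lag truncation and
is reported through the `converged` flag and `residual` diagnostic
(default tolerance 10⁻⁹ relative, 100 iterations, ridge 10⁻⁸·trace for
singular grids). Only the bivariate (pairwise) case is implemented, as
directed influences are reported between compartment pairs. A
time-reversal control distinguishes genuine directionality (which flips)
from noise-asymmetry artifacts (which do not).

### Randomization inference

All tests are two-sided, nonparametric, defaulting to 1000 seeded
randomizations. For spectra/time courses, family-wise error across bins
is controlled by the max-statistic rule (97.5th percentile of
per-randomization maxima, 2.5th of minima). For scalars, the historical
recipe — rectify the difference standardized by the null SD, take the
standard normal CDF, subtract from 1, halve — is reported as `p_zcdf`;
because that formula returns 0.25 for a null-central difference, the
conventional empirical-quantile two-sided p (`p_empirical`, add-one
corrected) is returned alongside and is what the package's own
significance decisions use. Which distribution the original recipe
intends is ambiguous; both values are always surfaced rather than
silently choosing.

## The synthetic session generator

The generator produces the study conditions every test runs under; its
defaults are fixed and are not tuning knobs.

**Gamma process.** A stochastic oscillator with a *smooth* instantaneous
phase: the instantaneous frequency wanders around the condition's peak
(Ornstein–Uhlenbeck, correlation time 75 ms, SD set so the spectral FWHM
matches the configured bandwidth) under a slow log-normal amplitude
envelope. A driven AR(2) resonator was considered and rejected: its
Hilbert phase carries ~0.2 rad of sample-to-sample jitter that no
band-limited estimator can track, so spike coupling generated against it
is systematically attenuated in every downstream PPC measurement. With
the smooth-phase oscillator, Hilbert-phase PPC1 recovers the Bessel
closed form within estimator noise and the 9-cycle windowed estimator
comes within ~10 %.

**Structure and timing.** Behavioural delays are drawn from the task's
uniform ranges (pre-stimulus 614 ms; cue delay 618–1131 ms; change delay
1162–2133 ms). Two 16-contact shanks at 150 µm spacing span the cortex
(outside / superficial / granular / deep / white matter in the
proportions of a full penetration; granular anchor at contact 8).
Receiver LFP is a 3 ms-lagged, layer-weighted copy of the sender gamma.
Per-channel gamma gains vary log-normally (SD 0.35) around the laminar
profile so bipolar derivation retains gamma, and most background noise
(85 %) is shank-common so re-referencing/bipolar derivation removes it —
the two properties that make those preprocessing steps meaningful.
A stimulus-evoked laminar transient with its curvature extremum at the
anchor supports CSD-based layer assignment, and per-channel spike-sign
counts implement the outside/gray/white log-ratio rule.

**Spiking.** Inhomogeneous Poisson by exact thinning, with intensity
`rate(t) · exp(κ cos(φ(t) − φ₀)) / I₀(κ)` — unit mean over a uniform
phase, so rate and coupling are independently calibrated (both
verified). Attention multiplies rates by a layer-specific gain
(superficial 1.4, granular 1.25, deep 1.15 — strongest superficial)
ramping on sigmoidally (50 ms width, avoiding convolution artifacts in
latency analyses) at per-compartment latencies (earliest, 150 ms, in
receiver superficial). A slow shared log-normal gain (OU, 200 ms
correlation time; SD 0.20 away vs. 0.10 toward) induces the
noise correlations that chunked correlation analysis targets.

**Coupling map.** Sender units lock to the gamma with
class-and-layer-specific κ (NW ≫ BW, granular strongest; BW flat at
0.25). Two calibrations deserve emphasis because they were set from the
reported phenomenology, not convenience:

* the *attentional κ increment* for NW cells (a free parameter — no
  source value exists) defaults to +0.12, i.e. a PPC increase of ~0.03
  at the gamma peak: the order of magnitude of reported
  cell-type-specific attention effects. Much larger increments make the
  attention condition genuinely decodable from spike phases, which
  contradicts the central chance-level-decoding observation the suite
  checks; at the calibrated value, both the NW-only locking increase and
  chance-level spike-phase decoding are emergent.
* `receiver_kappa_scale` (default 0.45) scales the whole map for
  receiver units, encoding the reported asymmetry that interareal
  spike-to-sender-gamma locking is much weaker than local sender
  locking.

Receiver units' preferred phase is offset by 1.51 rad from the sender's,
the recovery target for the phase-difference analysis.

**Mouse extras.** An LGN population (12 units, gamma-locked) for the
surrogate-LFP path; pupil and running-speed traces for state detection;
10 ms opto pulses after the task period with tagged units responding at
~4 ms latency.

**What the generator does not emulate** — and hence what green tests do
not show about real data: no biophysics (no conductances, no spike
waveform/LFP coupling), no eye movements or microsaccades, no
burst/refractory spike-train structure, no nonstationarities beyond the
attention ramp and the slow shared gain, Gaussian 1/f backgrounds
without line noise or artifacts, and a single dipole for the evoked
response. Estimator robustness to those features must be judged on real
recordings.

## Numerical choices

* Phase convention: radians in (−π, π]; epochs half-open `[t0, t1)`;
  spike exactly at the right edge excluded.
* Bipolar orientation: deeper minus shallower contact, derived channel
  at the midpoint depth (the source convention is unstated; this one is
  fixed here for sign-consistency with the CSD).
* Gaussian PETH smoothing uses reflected-edge padding; zero-spike trials
  get all-zero z-traces and are flagged rather than dropped, keeping
  condition trial counts aligned.
* The final incomplete chunk (< 10 trials) of the chunked noise
  correlation is discarded.
* FFT work on arbitrary-length sessions pads to 5-smooth lengths (R's
  mixed-radix FFT is quadratic at prime lengths) and truncates; the
  analytic signal reflects the tail before padding.
* All randomness flows through explicit integer seeds; a temporary-seed
  helper restores the caller's RNG state, and identical configurations
  yield bit-identical sessions.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so
every stochastic check has comfortable statistical margin: the
study-conditions session uses 120 trials and 12 units per area
(~1000 spikes per unit-condition, PPC1 estimator SD ≈ 0.004); the
closed-form calibration uses 50 s of rhythm at 30 Hz firing (~1500
spikes per κ); the family-wise-error simulation uses 500 (tests) or 200
(script) null experiments of 60 bins at 1000 randomizations; the
Granger oracle uses a 512-point grid (analytic) and 400 half-second
windows (simulated); latency analyses use 20-unit populations over
10–30 seeded runs.

## Known limitations

* PPC2 (phase–rate dependence correction) and magnitude-weighted
  coherence are intentionally out of scope.
* The exact t-SNE used for waveform embedding is O(n²); adequate for the
  few hundred units of a session bank, not for atlas-scale inputs.
* The windowed spike-phase estimator retains a small (<10 %) attenuation
  from frequency wander inside the 9-cycle window; the analytic-signal
  path is preferred where absolute PPC levels matter.
* The Wilson factorization is bivariate; conditional (multivariate) GC
  is not provided.
* Layer assignment automates the published rules (log-ratio bands, sink
  anchoring) but real penetrations warrant the manual-override fields it
  exposes.
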