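# gammalock

Analysis toolkit for laminar multi-area extracellular recordings during
selective-attention tasks: spike–field and field–field gamma
phase-locking, maximum-likelihood decoding of the attentional state,
laminar and cell-type assignment, firing-rate modulation and latency
metrics, chunked noise correlations, and nonparametric spectral Granger
causality — together with a seeded synthetic two-area laminar session
generator that carries full ground truth, so every stage can be
validated by parameter recovery.

## Who this is for

Systems neuroscientists analysing simultaneous laminar-probe recordings
from a sender and a receiver visual area (e.g. V1 and V4 in the macaque,
or LGN/V1/higher visual areas in the mouse) with single-unit spike
trains, local field potentials (LFPs) and a trial structure contrasting
two attention conditions ("toward" vs. "away").

## The statistics at the core

**Pairwise phase consistency (PPC).** For phase observations
φ<sub>1</sub>…φ<sub>n</sub>, PPC is the average cosine of all pairwise
phase differences,

    PPC = 2/(n(n-1)) · Σ_{j<k} cos(φ_j − φ_k) ,

computed in O(n) through the identity `(|Σ e^{iφ}|² − n) / (n(n−1))`. Its
expectation does not depend on n (unlike squared resultant length).
**PPC1** restricts the average to pairs of spikes from *different*
trials, removing the dependence of the estimate on within-trial spike
counts (firing-rate bias). For spikes coupled to an oscillation with a
von Mises concentration κ, the population PPC equals
`(I₁(κ)/I₀(κ))²` — the closed form used throughout the test suite
(≈ 0.199 at κ = 1).

**Spike phases** come either from Hann-tapered Fourier coefficients of
LFP windows centred on each spike (9 cycles of the target frequency, or
a fixed 250 ms window in mouse mode), or from the analytic signal of an
order-12 two-way Butterworth band-passed LFP.

**Attentional-state decoding.** Per-trial features (spike counts,
LFP–LFP phase-locking value, relative phase, trial-wise spike–field PPC,
per-unit spike phase) are modelled per signal and condition with
Poisson, Gaussian or von Mises likelihoods, combined across signals as a
product with a flat prior (naive Bayes, in log space), and scored by
leave-one-trial-out jackknife.

**Nonparametric spectral Granger causality.** Hann-tapered 0.5 s windows
give a cross-spectral density on a 2 Hz grid (4–200 Hz analysed); Wilson
spectral matrix factorization yields a minimum-phase transfer function H
and innovation covariance Σ with S = HΣH\*, from which Geweke's
frequency-resolved directed influence is computed, with a time-reversal
control against noise-asymmetry artifacts.

**Inference** is nonparametric throughout: 1000 label-exchange
randomizations, max-statistic control of the family-wise error across
frequency/time bins (97.5th percentile of per-randomization maxima /
2.5th percentile of minima), and shuffle tests for correlations.

## Worked example

```r
library(gammalock)

cfg <- synth_config(n_trials = 40L, n_units_per_area = 8L, seed = 42L)
gen <- gen_session(cfg)
gen$session
#> <synth_session> 32 LFP channels x 148195 samples @ 1000 Hz, 16 units, 40 trials

res <- run_pipeline(gen$session, min_spikes = 100L, seed = 1L)

res$spectral$gamma_peak          # session gamma peak of LFP-LFP locking
#> [1] 62

res$decode$summary
#>      modality accuracy n_trials
#>          rate    0.825       40
#>       lfp_plv    0.625       40
#>  lfp_relphase    0.500       40
#>     spike_ppc    0.525       40
#>   spike_phase    0.400       40
```

Spike counts decode the attention condition far better than any
phase-based measure, whose accuracies sit at chance (0.5) within the
binomial confidence interval for 40 trials — the qualitative pattern the
pipeline is designed to expose.

```r
ra <- res$rates$per_unit
round(tapply(ra$ami[ra$area == "receiver"],
             ra$layer[ra$area == "receiver"], mean), 3)
#>        deep    granular superficial
#>       0.155       0.134       0.214

fw <- res$connectivity$forward
c(peak = max(fw$gc_xy), at_hz = fw$freqs[which.max(fw$gc_xy)],
  reverse = max(fw$gc_yx))
#>   peak  at_hz reverse
#>  0.113 58.000   0.067

res$cellclass$layers$anchor      # granular anchor from the evoked CSD
#> [1] 8
```

The attentional modulation index (AMI = (FR_tow − FR_away)/(FR_tow +
FR_away)) is strongest in superficial layers; directed influence in
multi-unit activity runs sender → receiver with a gamma-band peak; and
the current-source-density profile anchors the granular compartment at
the channel where the generator injected the sink.

## Scope notes

The package analyses sessions in its own in-memory layout (see
`gen_session()` for the structure); loaders for specific public deposits
are left as extension points. Spike sorting, receptive-field mapping and
the internals of the ZETA test (pluggable in `optotag()`) are out of
scope.
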