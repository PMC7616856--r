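Package: gammalock
Title: Spike-Field Gamma Phase-Locking, Attentional-State Decoding and
    Laminar Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for laminar multi-area extracellular
    recordings (local field potentials plus single-unit spike trains)
    during selective-attention tasks.  Implements multitaper spectral
    estimation with pairwise phase consistency (PPC) for LFP-LFP and
    spike-LFP phase locking (including the rate-bias-free PPC1
    estimator), von Mises / Poisson / Gaussian naive-Bayes
    maximum-likelihood decoding of attentional state, current-source-
    density laminar assignment, waveform-based cell classification,
    firing-rate modulation metrics, chunked noise correlations,
    nonparametric spectral Granger causality via Wilson spectral matrix
    factorization, latency analyses, and a max-statistic randomization
    inference framework.  A seeded synthetic two-area laminar session
    generator with full ground truth supports parameter-recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
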