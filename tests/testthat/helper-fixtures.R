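# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

## Small two-area session for module-level integration tests.
small_session <- function() {
  if (is.null(fixture_env$small)) {
    cfg <- synth_config(n_trials = 24L, n_units_per_area = 8L, seed = 11L)
    fixture_env$small <- gen_session(cfg)
  }
  fixture_env$small
}

## Full-scale study-conditions session for the acceptance suite
## (generator defaults are the study preset).
paperlike_session <- function() {
  if (is.null(fixture_env$paper)) {
    fixture_env$paper <- gen_session(synth_config(seed = 101L))
  }
  fixture_env$paper
}

paperlike_pipeline <- function() {
  if (is.null(fixture_env$paper_res)) {
    g <- paperlike_session()
    fixture_env$paper_res <- suppressWarnings(  # 24-unit bank: perplexity
      run_pipeline(g$session, seed = 101L, n_rand = 500L))
  }
  fixture_env$paper_res
}

## Clean narrow-band gamma rhythm with ground-truth phase.
gamma_fixture <- function(duration = 40, f = 60, bw = 6, fs = 1000,
                          seed = 5L) {
  key <- paste("gam", duration, f, bw, fs, seed, sep = "_")
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- gammalock:::with_seed(
      seed, gammalock:::gamma_oscillation(round(duration * fs), f, bw, fs))
  }
  fixture_env[[key]]
}

## Single-shank laminar geometry.
grid_geometry <- function(n_ch = 8L, shank = "s1", area = "A") {
  data.frame(channel = paste0(shank, "_c", seq_len(n_ch)), area = area,
             shank = shank, depth_index = seq_len(n_ch),
             depth_um = (seq_len(n_ch) - 1L) * 150,
             stringsAsFactors = FALSE)
}

## Hand-built spectral_coeffs object holding given per-epoch phases at a
## single frequency (unit amplitude), for PPC arithmetic tests.
coeffs_from_phases <- function(phases, freqs = 10) {
  coef <- array(complex(real = 0),
                dim = c(length(phases), 1L, length(freqs)))
  for (f in seq_along(freqs)) coef[, 1L, f] <- exp(1i * phases)
  structure(list(coef = coef, freqs = freqs, fs = 1000, epoch_len = 0.5,
                 n_tapers = 1L, n_epochs = length(phases)),
            class = "spectral_coeffs")
}

## Brute-force all-pairs PPC oracle.
ppc_brute <- function(phases) {
  n <- length(phases)
  s <- 0
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) s <- s + cos(phases[j] - phases[k])
  }
  s / (n * (n - 1L) / 2)
}

## Reference bivariate AR(2) model with unidirectional x -> y coupling
## resonant near 25 Hz at fs = 200.
ar_fixture <- list(
  A1 = matrix(c(0.55, 0, 0.4, 0.25), 2L, 2L, byrow = TRUE),
  A2 = matrix(c(-0.8, 0, 0, -0.5), 2L, 2L, byrow = TRUE),
  Sig = diag(c(1, 0.7))
)

## Analytic spectral matrix and transfer function of a bivariate AR(2)
## model on an FFT frequency grid (the parametric oracle).
ar_truth <- function(A1, A2, Sig, fs, n_fft) {
  n_f <- n_fft %/% 2L + 1L
  freqs <- (seq_len(n_f) - 1L) * fs / n_fft
  S <- array(complex(real = 0), dim = c(2L, 2L, n_f))
  H <- array(complex(real = 0), dim = c(2L, 2L, n_f))
  for (k in seq_len(n_f)) {
    z <- exp(-2i * pi * freqs[k] / fs)
    Hk <- solve(diag(2) - A1 * z - A2 * z^2)
    H[, , k] <- Hk
    S[, , k] <- Hk %*% Sig %*% Conj(t(Hk))
  }
  list(freqs = freqs, S = S, H = H)
}

## Parametric Geweke GC of the bivariate model on the analysis band.
ar_parametric_gc <- function(tr, Sig, band_idx) {
  s2_xy <- Sig[1, 1] - Sig[1, 2]^2 / Sig[2, 2]
  s2_yx <- Sig[2, 2] - Sig[1, 2]^2 / Sig[1, 1]
  list(
    gc_xy = log(Re(tr$S[2, 2, band_idx]) /
                  (Re(tr$S[2, 2, band_idx]) -
                     s2_xy * Mod(tr$H[2, 1, band_idx])^2)),
    gc_yx = log(Re(tr$S[1, 1, band_idx]) /
                  (Re(tr$S[1, 1, band_idx]) -
                     s2_yx * Mod(tr$H[1, 2, band_idx])^2)))
}

## Simulate the bivariate AR process (burn-in discarded).
ar_sim <- function(A1, A2, Sig, n, seed) {
  with_seed(seed, {
    e <- cbind(rnorm(n + 200, 0, sqrt(Sig[1, 1])),
               rnorm(n + 200, 0, sqrt(Sig[2, 2])))
    x <- matrix(0, n + 200, 2L)
    for (t in 3:(n + 200)) {
      x[t, ] <- A1 %*% x[t - 1, ] + A2 %*% x[t - 2, ] + e[t, ]
    }
    x[-(1:200), ]
  })
}

## Cut a vector into consecutive equal windows (rows).
segment_windows <- function(v, width) {
  n_w <- length(v) %/% width
  t(vapply(seq_len(n_w), function(w) {
    v[((w - 1L) * width + 1L):(w * width)]
  }, numeric(width)))
}

## Brute-force cross-trial PPC oracle.
ppc1_brute <- function(phases, trial_id) {
  n <- length(phases)
  s <- 0; m <- 0L
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      if (trial_id[j] != trial_id[k]) {
        s <- s + cos(phases[j] - phases[k]); m <- m + 1L
      }
    }
  }
  s / m
}
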