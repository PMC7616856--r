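# Multitaper spectral estimation and LFP-LFP phase locking.
#
# Spectra are estimated on 0.5 s epochs multiplied with seven Slepian
# (DPSS) tapers followed by an FFT; phase locking between channel pairs is
# quantified with the pairwise phase consistency (PPC), an estimator whose
# expectation does not depend on the number of epochs.

#' Multitaper Fourier coefficients of LFP epochs
#'
#' Multiplies each epoch with `n_tapers` unit-energy DPSS tapers and
#' Fourier-transforms the products. Coefficients are returned unaveraged so
#' downstream estimators (power, PPC) can choose their own pooling.
#'
#' @param epochs Epochs x samples matrix (one channel), or a list of such
#'   matrices for several channels.
#' @param fs Sampling rate in Hz.
#' @param epoch_len Epoch length in seconds (default 0.5); `epoch_len * fs`
#'   must match the epoch sample count.
#' @param n_tapers Number of Slepian tapers (default 7).
#' @param nw Time-bandwidth product (default 4).
#' @return A `spectral_coeffs` object: complex array
#'   `(epoch, taper, frequency)`, with `freqs` (Hz), `fs`, `epoch_len`,
#'   `n_tapers` attached. For a list input, a list of such objects.
#' @export
multitaper_coeffs <- function(epochs, fs, epoch_len = 0.5, n_tapers = 7L,
                              nw = 4) {
  if (is.list(epochs) && !is.matrix(epochs)) {
    return(lapply(epochs, multitaper_coeffs, fs = fs, epoch_len = epoch_len,
                  n_tapers = n_tapers, nw = nw))
  }
  stopifnot(is.matrix(epochs))
  n_samp <- round(epoch_len * fs)
  if (abs(epoch_len * fs - n_samp) > 1e-9) {
    stop("epoch_len * fs must be an integer sample count")
  }
  if (ncol(epochs) < n_samp) stop("epochs are shorter than epoch_len")
  if (ncol(epochs) > n_samp) epochs <- epochs[, seq_len(n_samp), drop = FALSE]
  n_ep <- nrow(epochs)
  tapers <- dpss_tapers(n_samp, k = n_tapers, nw = nw)
  n_freq <- floor(n_samp / 2) + 1L
  freqs <- (seq_len(n_freq) - 1L) * fs / n_samp
  coef <- array(complex(real = 0), dim = c(n_ep, n_tapers, n_freq))
  for (k in seq_len(n_tapers)) {
    tapered <- sweep(epochs, 2L, tapers[, k], `*`)
    ft <- t(apply(tapered, 1L, stats::fft))
    if (n_ep == 1L) ft <- matrix(ft, nrow = 1L)
    coef[, k, ] <- ft[, seq_len(n_freq), drop = FALSE]
  }
  structure(list(coef = coef, freqs = freqs, fs = fs, epoch_len = epoch_len,
                 n_tapers = n_tapers, n_epochs = n_ep),
            class = "spectral_coeffs")
}

#' Tile non-overlapping epochs from a continuous series
#'
#' Cuts `[t_start, t_end)` into consecutive non-overlapping windows of
#' `epoch_len` seconds (partial final window discarded).
#'
#' @param x Numeric vector, one channel.
#' @param fs Sampling rate (Hz).
#' @param t_start,t_end Analysis-period bounds in seconds relative to the
#'   first sample.
#' @param epoch_len Window length in seconds.
#' @return Epochs x samples matrix (possibly 0 rows).
#' @export
tile_epochs <- function(x, fs, t_start, t_end, epoch_len = 0.5) {
  n_samp <- round(epoch_len * fs)
  i0 <- floor(t_start * fs) + 1L
  i1 <- floor(t_end * fs)
  n_ep <- max(0L, (i1 - i0 + 1L) %/% n_samp)
  if (n_ep == 0L) return(matrix(numeric(0), nrow = 0L, ncol = n_samp))
  t(vapply(seq_len(n_ep), function(e) {
    x[(i0 + (e - 1L) * n_samp):(i0 + e * n_samp - 1L)]
  }, numeric(n_samp)))
}

#' Multitaper power spectrum
#'
#' Mean squared magnitude of the Fourier coefficients over epochs and
#' tapers. Optionally multiplies each bin by its squared frequency, which
#' flattens the 1/f^2 background and emphasizes gamma-band structure.
#'
#' @param coeffs A `spectral_coeffs` object.
#' @param f2_scale Multiply power by frequency squared (default `FALSE`).
#' @return List with `freqs` and `power`.
#' @export
power_spectrum <- function(coeffs, f2_scale = FALSE) {
  stopifnot(inherits(coeffs, "spectral_coeffs"))
  p <- apply(Mod(coeffs$coef)^2, 3L, mean)
  if (f2_scale) p <- p * coeffs$freqs^2
  list(freqs = coeffs$freqs, power = p)
}

## Pairwise phase consistency of a set of unit phasors, via the algebraic
## identity (|sum u|^2 - n) / (n (n - 1)), exactly equal to the mean over
## all unordered pairs of cos(phi_j - phi_k).
ppc_from_phasors <- function(u) {
  n <- length(u)
  if (n < 2L) return(NA_real_)
  (Mod(sum(u))^2 - n) / (n * (n - 1))
}

#' LFP-LFP pairwise phase consistency spectrum
#'
#' For each frequency, the relative phase between the two channels is
#' extracted per epoch (and taper), normalized to a unit vector, and the
#' PPC — the average over all unordered pairs of observations of the cosine
#' of their phase difference — is computed together with the circular mean
#' relative phase.
#'
#' @param coeffs_a,coeffs_b `spectral_coeffs` of the two channels, on
#'   identical epoch/taper/frequency grids.
#' @param average_tapers If `TRUE`, taper coefficients are averaged within
#'   an epoch before phase extraction, making each epoch one observation;
#'   if `FALSE` (default) each (epoch, taper) pair is one observation.
#' @return A `phase_spectrum` object: `freqs`, `ppc`, `mean_phase`
#'   (relative phase A minus B), `n_obs`.
#' @export
lfp_lfp_ppc <- function(coeffs_a, coeffs_b, average_tapers = FALSE) {
  stopifnot(inherits(coeffs_a, "spectral_coeffs"),
            inherits(coeffs_b, "spectral_coeffs"),
            identical(dim(coeffs_a$coef), dim(coeffs_b$coef)))
  if (coeffs_a$n_epochs < 2L) stop("at least 2 epochs are required for PPC")
  rel <- coeffs_a$coef * Conj(coeffs_b$coef)
  if (average_tapers) {
    rel <- apply(rel, c(1L, 3L), mean)       # epochs x freqs
    dim(rel) <- c(dim(rel)[1L], 1L, dim(rel)[2L])
  }
  n_freq <- dim(rel)[3L]
  ppc <- numeric(n_freq); mph <- numeric(n_freq)
  for (f in seq_len(n_freq)) {
    u <- as.vector(rel[, , f])
    m <- Mod(u)
    ok <- m > 0
    u <- u[ok] / m[ok]
    ppc[f] <- ppc_from_phasors(u)
    mph[f] <- if (length(u)) Arg(sum(u)) else NA_real_
  }
  structure(list(freqs = coeffs_a$freqs, ppc = ppc, mean_phase = mph,
                 n_obs = sum(Mod(rel[, , 1]) >= 0)),
            class = "phase_spectrum")
}

#' Align spectra to each session's gamma peak
#'
#' Finds each session's gamma peak (local maximum of its spectrum inside
#' `search_band`), re-indexes every spectrum to frequency offsets relative
#' to its own peak, and averages the sessions on the common offset grid.
#' Sessions without a local maximum inside the band are flagged and
#' excluded from the aligned mean.
#'
#' @param spectra List of lists with `freqs` and a `values` vector (use
#'   `ppc` or `power` upstream); all on the same frequency grid.
#' @param search_band Length-2 Hz band searched for the peak (default
#'   `c(20, 100)`).
#' @return List with `offsets` (Hz grid relative to peak), `mean` (aligned
#'   group mean), `aligned` (matrix sessions x offsets), `peaks` (per
#'   session, NA if flagged), `excluded` (logical).
#' @export
align_to_gamma_peak <- function(spectra, search_band = c(20, 100)) {
  stopifnot(length(spectra) >= 1L)
  freqs <- spectra[[1L]]$freqs
  df <- diff(freqs[1:2])
  vals <- t(vapply(spectra, function(s) s$values, numeric(length(freqs))))
  peaks <- vapply(seq_along(spectra), function(i) {
    find_local_peak(freqs, vals[i, ], search_band)
  }, numeric(1))
  excluded <- is.na(peaks)
  if (all(excluded)) {
    stop("no session has a local spectral maximum inside the search band")
  }
  keep <- which(!excluded)
  # common offset grid spanning all kept sessions
  pk_idx <- vapply(peaks[keep], function(p) which.min(abs(freqs - p)), integer(1))
  lo <- max(1L - pk_idx)            # most negative representable offset
  hi <- min(length(freqs) - pk_idx)
  offs <- seq(lo, hi) * df
  aligned <- t(vapply(seq_along(keep), function(j) {
    vals[keep[j], pk_idx[j] + seq(lo, hi)]
  }, numeric(length(offs))))
  list(offsets = offs, mean = colMeans(aligned), aligned = aligned,
       peaks = peaks, excluded = excluded)
}

## Local maximum of y inside band; NA when the maximum sits on the band
## edge or the spectrum is flat there.
find_local_peak <- function(freqs, y, band) {
  idx <- which(freqs >= band[1] & freqs <= band[2])
  if (length(idx) < 3L) return(NA_real_)
  yb <- y[idx]
  k <- which.max(yb)
  if (k == 1L || k == length(yb)) return(NA_real_)
  if (yb[k] <= yb[k - 1L] || yb[k] <= yb[k + 1L]) return(NA_real_)
  freqs[idx[k]]
}

#' Time-resolved LFP-LFP phase locking
#'
#' Slides a Hann window of +/- 2.5 cycles per frequency over each trial in
#' steps of `step` seconds; at each (time, frequency) the windowed Fourier
#' phase difference between the two channels is computed per trial and the
#' PPC across trials is returned. Time bins whose window exceeds the trial
#' edges are left `NA`.
#'
#' @param trials_a,trials_b Lists of equal-length numeric vectors: the two
#'   channels' raw traces per trial, aligned to a common event.
#' @param fs Sampling rate (Hz).
#' @param freqs Frequencies to evaluate (Hz).
#' @param step Slide step in seconds (default 0.001).
#' @param band_average Optional length-2 Hz band; if given, a `band_mean`
#'   time course averaged over frequencies inside the band is included.
#' @return List with `times` (s, relative to trial start), `freqs`, `ppc`
#'   (times x freqs matrix), and optionally `band_mean`.
#' @export
tf_lfp_ppc <- function(trials_a, trials_b, fs, freqs, step = 0.001,
                       band_average = NULL) {
  stopifnot(length(trials_a) == length(trials_b), length(trials_a) >= 2L)
  n_samp <- length(trials_a[[1L]])
  step_samp <- max(1L, round(step * fs))
  centers <- seq(1L, n_samp, by = step_samp)
  times <- (centers - 1L) / fs
  ppc <- matrix(NA_real_, length(centers), length(freqs))
  n_tr <- length(trials_a)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    half <- round(2.5 / f * fs)          # +/- 2.5 cycles
    win <- hann_window(2L * half + 1L)
    kern <- win * exp(-2i * pi * f * seq(-half, half) / fs)
    ok <- centers > half & centers <= n_samp - half
    if (!any(ok)) next
    # windowed Fourier coefficient per trial via direct products
    u <- matrix(complex(real = 0), n_tr, sum(ok))
    cs <- centers[ok]
    for (tr in seq_len(n_tr)) {
      a <- trials_a[[tr]]; b <- trials_b[[tr]]
      ca <- vapply(cs, function(c0) sum(a[(c0 - half):(c0 + half)] * kern),
                   complex(1))
      cb <- vapply(cs, function(c0) sum(b[(c0 - half):(c0 + half)] * kern),
                   complex(1))
      rel <- ca * Conj(cb)
      m <- Mod(rel)
      u[tr, ] <- ifelse(m > 0, rel / m, complex(real = NA_real_))
    }
    ppc[ok, fi] <- apply(u, 2L, function(col) ppc_from_phasors(col[!is.na(col)]))
  }
  out <- list(times = times, freqs = freqs, ppc = ppc)
  if (!is.null(band_average)) {
    sel <- freqs >= band_average[1] & freqs <= band_average[2]
    out$band_mean <- rowMeans(ppc[, sel, drop = FALSE])
  }
  out
}

#' @export
print.phase_spectrum <- function(x, ...) {
  pk <- x$freqs[which.max(x$ppc)]
  cat("<phase_spectrum> ", length(x$freqs), " frequency bins, PPC peak ",
      round(max(x$ppc), 4), " at ", pk, " Hz\n", sep = "")
  invisible(x)
}
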