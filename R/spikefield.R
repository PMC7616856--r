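# Spike-LFP phase locking.
#
# Per-spike phases are obtained from Hann-tapered Fourier coefficients of
# LFP windows centred on each spike (window length 9 cycles of the target
# frequency in macaque mode, fixed 250 ms in mouse mode), or from the
# analytic signal of a band-passed LFP. Locking strength is quantified
# with PPC: the average cosine of phase differences over spike pairs,
# either over all pairs (PPC0) or restricted to pairs of spikes from
# different trials (PPC1), which removes the dependence of the estimate's
# bias on the within-trial spike count.

#' Spike-triggered windowed Fourier phases
#'
#' For each spike and frequency `f`, collects the LFP segment centred on
#' the spike (length `9 / f` seconds in `"macaque"` mode, a fixed
#' `fixed_window` in `"mouse"` mode), multiplies it with a Hann taper, and
#' takes the phase of its Fourier coefficient at `f`. Spikes whose window
#' extends beyond the recording are dropped and counted.
#'
#' @param lfp Numeric vector: one (typically bipolar-derived) LFP channel.
#' @param fs Sampling rate, Hz.
#' @param spikes Spike times in seconds (relative to the first LFP sample).
#' @param freqs Frequencies to evaluate, Hz.
#' @param trial_id Optional integer vector assigning each spike to a
#'   trial (required downstream by [ppc1()]).
#' @param mode `"macaque"` (9-cycle windows) or `"mouse"` (fixed window).
#' @param fixed_window Mouse-mode window length in seconds (default 0.25).
#' @return A `spike_phase_set`: list with `phases` (spikes x freqs matrix,
#'   radians), `freqs`, `trial_id`, `n_spikes`, `n_dropped`.
#' @export
spike_triggered_coeffs <- function(lfp, fs, spikes, freqs, trial_id = NULL,
                                   mode = c("macaque", "mouse"),
                                   fixed_window = 0.25) {
  mode <- match.arg(mode)
  stopifnot(all(freqs > 0), all(freqs < fs / 2))
  n <- length(lfp)
  if (!is.null(trial_id)) stopifnot(length(trial_id) == length(spikes))
  # largest window decides which spikes are in-bounds for every frequency,
  # keeping the spike set identical across the spectrum
  max_half <- if (mode == "macaque") {
    floor(9 / min(freqs) * fs / 2)
  } else {
    floor(fixed_window * fs / 2)
  }
  centre <- round(spikes * fs) + 1L
  ok <- centre - max_half >= 1L & centre + max_half <= n
  n_dropped <- sum(!ok)
  centre <- centre[ok]
  if (!is.null(trial_id)) trial_id <- trial_id[ok]
  n_sp <- length(centre)
  phases <- matrix(NA_real_, n_sp, length(freqs))
  if (n_sp > 0L) {
    for (fi in seq_along(freqs)) {
      f <- freqs[fi]
      half <- if (mode == "macaque") floor(9 / f * fs / 2) else
        floor(fixed_window * fs / 2)
      len <- 2L * half + 1L
      offs <- seq(-half, half)
      kern <- hann_window(len) * exp(-2i * pi * f * offs / fs)
      seg <- matrix(lfp[rep(centre, each = len) + rep(offs, times = n_sp)],
                    nrow = len)
      phases[, fi] <- Arg(as.vector(crossprod(seg, kern)))
    }
  }
  structure(list(phases = phases, freqs = freqs, trial_id = trial_id,
                 n_spikes = n_sp, n_dropped = n_dropped),
            class = "spike_phase_set")
}

#' PPC over all spike pairs (PPC0)
#'
#' Mean cosine of the phase difference over all unordered spike pairs,
#' computed per frequency through the algebraic identity
#' `(|sum(exp(i phi))|^2 - n) / (n (n - 1))`.
#'
#' @param phase_set A `spike_phase_set`, or a numeric vector/matrix of
#'   phases (spikes x frequencies).
#' @return List with `freqs` (if known), `ppc` per frequency, `n_spikes`.
#' @export
ppc0 <- function(phase_set) {
  ph <- as_phase_matrix(phase_set)
  if (nrow(ph) < 2L) stop("PPC requires at least 2 spikes")
  u <- exp(1i * ph)
  vals <- apply(u, 2L, ppc_from_phasors)
  list(freqs = attr(ph, "freqs"), ppc = vals, n_spikes = nrow(ph))
}

#' Rate-bias-free PPC over cross-trial spike pairs (PPC1)
#'
#' Restricts the pair average to spikes from different trials, removing
#' the sensitivity of the estimate to within-trial spike-count (rate)
#' differences and to within-trial phase dependencies. Units with fewer
#' than `min_spikes` spikes are excluded (the analysis inclusion rule;
#' set `min_spikes = 0` to disable).
#'
#' @inheritParams ppc0
#' @param trial_id Integer trial label per spike (taken from the
#'   `spike_phase_set` when present).
#' @param min_spikes Minimum spike count required (default 200).
#' @return List with `freqs`, `ppc`, `n_spikes`, `n_trials`; or an object
#'   with `excluded = TRUE` and a `reason` when below `min_spikes`.
#' @export
ppc1 <- function(phase_set, trial_id = NULL, min_spikes = 200L) {
  ph <- as_phase_matrix(phase_set)
  if (is.null(trial_id) && inherits(phase_set, "spike_phase_set")) {
    trial_id <- phase_set$trial_id
  }
  if (is.null(trial_id)) stop("ppc1 requires per-spike trial labels")
  stopifnot(length(trial_id) == nrow(ph))
  n_sp <- nrow(ph)
  if (n_sp < min_spikes) {
    return(list(excluded = TRUE,
                reason = sprintf("only %d spikes (< %d required)",
                                 n_sp, min_spikes),
                n_spikes = n_sp))
  }
  trials <- unique(trial_id)
  if (length(trials) < 2L) stop("ppc1 undefined with all spikes in one trial")
  u <- exp(1i * ph)
  n_t <- as.numeric(table(factor(trial_id, levels = trials)))
  denom <- n_sp^2 - sum(n_t^2)           # number of ordered cross-trial pairs
  vals <- vapply(seq_len(ncol(ph)), function(fi) {
    s_tot <- sum(u[, fi])
    s_within <- vapply(trials, function(tr) {
      Mod(sum(u[trial_id == tr, fi]))^2
    }, numeric(1))
    (Mod(s_tot)^2 - sum(s_within)) / denom
  }, numeric(1))
  list(freqs = attr(ph, "freqs"), ppc = vals, n_spikes = n_sp,
       n_trials = length(trials), excluded = FALSE)
}

## Accept spike_phase_set, vector, or matrix.
as_phase_matrix <- function(x) {
  if (inherits(x, "spike_phase_set")) {
    m <- x$phases
    attr(m, "freqs") <- x$freqs
    return(m)
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  x
}

#' Spike-count-weighted group PPC spectrum
#'
#' Averages per-unit PPC spectra with weights equal to the ratio of each
#' unit's spike count to a reference mean count: the mean count of units
#' in the same cell class (`scheme = "class_mean"`, for between-class
#' comparisons) or the mean total count across all included units
#' (`scheme = "condition_total"`, for between-condition comparisons).
#'
#' @param spectra List of per-unit PPC results (each with `ppc` and
#'   `n_spikes`).
#' @param class_labels Cell class per unit (required for `class_mean`).
#' @param scheme Weighting scheme.
#' @param counts Optional explicit spike counts overriding `n_spikes`.
#' @param total_counts For `condition_total`: per-unit total (across-
#'   condition) counts whose mean forms the denominator; defaults to
#'   `counts`.
#' @return List with `ppc` (weighted group mean spectrum), `weights`,
#'   `n_units`.
#' @export
weight_spectra <- function(spectra, class_labels = NULL,
                           scheme = c("class_mean", "condition_total"),
                           counts = NULL, total_counts = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(counts)) {
    counts <- vapply(spectra, function(s) s$n_spikes, numeric(1))
  }
  mat <- do.call(rbind, lapply(spectra, function(s) as.numeric(s$ppc)))
  if (scheme == "class_mean") {
    if (is.null(class_labels)) stop("class_mean weighting needs class labels")
    w <- numeric(length(counts))
    for (cl in unique(class_labels)) {
      idx <- class_labels == cl
      m <- mean(counts[idx])
      if (m <= 0) stop("zero mean spike count in class '", cl, "'")
      w[idx] <- counts[idx] / m
    }
  } else {
    if (is.null(total_counts)) total_counts <- counts
    m <- mean(total_counts)
    if (m <= 0) stop("zero mean total spike count")
    w <- counts / m
  }
  list(ppc = colMeans(mat * w), weights = w, n_units = nrow(mat))
}

#' Per-spike phase from band-passed analytic signals
#'
#' Returns, for every spike, the circular mean across channels of the
#' analytic-signal phase at the spike sample, plus the per-unit circular
#' mean over spikes. Spikes outside the signal span are dropped and
#' counted.
#'
#' @param analytic An `analytic_signal` (from [bandpass_hilbert()]).
#' @param spikes Spike times, seconds relative to the first sample.
#' @param t0 Time of the first sample (default 0).
#' @return List with `spike_phases` (radians, one per retained spike),
#'   `mean_phase`, `n_dropped`.
#' @export
spike_phase_hilbert <- function(analytic, spikes, t0 = 0) {
  stopifnot(inherits(analytic, "analytic_signal"))
  n <- ncol(analytic$values)
  idx <- round((spikes - t0) * analytic$fs) + 1L
  ok <- idx >= 1L & idx <= n
  idx <- idx[ok]
  ph <- vapply(idx, function(i) {
    Arg(sum(exp(1i * Arg(analytic$values[, i]))))
  }, numeric(1))
  list(spike_phases = ph, mean_phase = circ_mean(ph), n_dropped = sum(!ok))
}

#' Circular mean difference between two phase samples
#'
#' Computes the circular mean of each group and the wrapped difference
#' (A minus B), with a label-exchange randomization p-value on the
#' absolute wrapped difference.
#'
#' @param phases_a,phases_b Angles in radians.
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Integer seed.
#' @return List with `mean_a`, `mean_b`, `diff` in `(-pi, pi]`,
#'   `p_empirical`.
#' @export
circ_mean_diff <- function(phases_a, phases_b, n_rand = 1000L, seed = 1L) {
  if (length(phases_a) < 1L || length(phases_b) < 1L) {
    stop("both phase groups must be non-empty")
  }
  obs <- wrap_phase(circ_mean(phases_a) - circ_mean(phases_b))
  pooled <- c(phases_a, phases_b)
  n_a <- length(phases_a)
  null <- with_seed(seed, {
    vapply(seq_len(n_rand), function(r) {
      idx <- sample.int(length(pooled))
      abs(wrap_phase(circ_mean(pooled[idx[seq_len(n_a)]]) -
                       circ_mean(pooled[idx[-seq_len(n_a)]])))
    }, numeric(1))
  })
  p <- (1 + sum(null >= abs(obs))) / (n_rand + 1)
  list(mean_a = circ_mean(phases_a), mean_b = circ_mean(phases_b),
       diff = obs, p_empirical = p, n_rand = n_rand, seed = seed)
}
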