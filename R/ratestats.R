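# Firing-rate metrics: smoothed z-scored PETHs, attentional modulation
# index, drivenness, chunked noise correlations, attention-latency
# difference time courses with cross-correlation asymmetry, and the
# multi-linear AMI regression.

#' Peri-event time histogram
#'
#' Per trial: spikes are binned at 1 ms over the full trial window,
#' convolved with a Gaussian kernel (default length 50 ms, SD 8 ms,
#' reflected-edge padding), z-scored within the trial, then the requested
#' epoch is cut out and averaged across trials. Trials without spikes get
#' an all-zero z-trace and are flagged.
#'
#' @param spikes Spike times of one unit, seconds.
#' @param events Per-trial alignment event times, seconds.
#' @param window_full Length-2 window (s, relative to event) over which
#'   binning, smoothing and z-scoring are done ("the full trial").
#' @param window_epoch Optional sub-window retained after z-scoring
#'   (defaults to `window_full`).
#' @param kernel_len Kernel length, seconds (default 0.05).
#' @param kernel_sd Kernel SD, seconds (default 0.008).
#' @param bin Bin width, seconds (default 0.001).
#' @return A `peth` object: `time` (epoch grid, s), `mean` (trial-averaged
#'   z-trace), `trials` (trials x time matrix), `counts` (unsmoothed
#'   per-trial counts over the full window), `empty_trials`.
#' @export
peth <- function(spikes, events, window_full, window_epoch = NULL,
                 kernel_len = 0.05, kernel_sd = 0.008, bin = 0.001) {
  stopifnot(length(events) >= 1L, length(window_full) == 2L)
  if (is.null(window_epoch)) window_epoch <- window_full
  n_bins <- round((window_full[2] - window_full[1]) / bin)
  edges0 <- window_full[1] + bin * (0:n_bins)
  mids <- edges0[-1] - bin / 2
  n_tr <- length(events)
  counts <- matrix(0L, n_tr, n_bins)
  ztr <- matrix(0, n_tr, n_bins)
  empty <- logical(n_tr)
  for (i in seq_len(n_tr)) {
    s <- select_epoch(spikes, events[i], window_full, type = "spikes")
    if (length(s)) {
      counts[i, ] <- tabulate(pmin(n_bins, floor((s - window_full[1]) / bin) + 1L),
                              nbins = n_bins)
    }
    sm <- gauss_smooth(counts[i, ], len = round(kernel_len / bin),
                       sd = kernel_sd / bin)
    sdv <- stats::sd(sm)
    if (!is.finite(sdv) || sdv == 0) {
      empty[i] <- TRUE
      ztr[i, ] <- 0
    } else {
      ztr[i, ] <- (sm - mean(sm)) / sdv
    }
  }
  keep <- mids >= window_epoch[1] & mids < window_epoch[2]
  structure(list(time = mids[keep], mean = colMeans(ztr[, keep, drop = FALSE]),
                 trials = ztr[, keep, drop = FALSE],
                 counts = counts, bin = bin, empty_trials = empty),
            class = "peth")
}

## Mean spike count of one unit in an event-aligned window, per trial.
counts_in_window <- function(spikes, events, window) {
  vapply(events, function(e) {
    sum(spikes >= e + window[1] & spikes < e + window[2])
  }, numeric(1))
}

## Bounded contrast index (a - b) / (a + b); NA when both are zero.
contrast_index <- function(a, b) {
  if (a + b == 0) return(NA_real_)
  (a - b) / (a + b)
}

#' Attentional modulation index
#'
#' `AMI = (FR_toward - FR_away) / (FR_toward + FR_away)` on the mean spike
#' counts in a window (by default the 1 s before the first luminance
#' change of each trial).
#'
#' @param spikes Spike times of one unit, seconds.
#' @param trials Trial table with `change_onset` and `condition` columns.
#' @param window Window relative to the alignment event (default
#'   `c(-1, 0)` before the change).
#' @param event_col Column holding the alignment event (default
#'   `"change_onset"`).
#' @return List with `ami`, `fr_toward`, `fr_away`, `n_toward`, `n_away`.
#' @export
ami <- function(spikes, trials, window = c(-1, 0),
                event_col = "change_onset") {
  tow <- trials[[event_col]][trials$condition == "toward"]
  awy <- trials[[event_col]][trials$condition == "away"]
  if (!length(tow) || !length(awy)) stop("both conditions must be represented")
  fr_t <- mean(counts_in_window(spikes, tow, window))
  fr_a <- mean(counts_in_window(spikes, awy, window))
  list(ami = contrast_index(fr_t, fr_a), fr_toward = fr_t, fr_away = fr_a,
       n_toward = length(tow), n_away = length(awy))
}

#' Stimulus drivenness index
#'
#' `dr = (FR_stim - FR_base) / (FR_stim + FR_base)` with the stimulus
#' window 0.05-0.25 s after stimulus onset and the baseline the 0.2 s
#' before stimulus onset.
#'
#' @inheritParams ami
#' @param stim_window,base_window Windows relative to stimulus onset.
#' @return List with `dr`, `fr_stim`, `fr_base`.
#' @export
drivenness <- function(spikes, trials, stim_window = c(0.05, 0.25),
                       base_window = c(-0.2, 0)) {
  ev <- trials$stim_onset
  fr_s <- mean(counts_in_window(spikes, ev, stim_window))
  fr_b <- mean(counts_in_window(spikes, ev, base_window))
  list(dr = contrast_index(fr_s, fr_b), fr_stim = fr_s, fr_base = fr_b)
}

#' Chunked noise correlations between multi-unit count series
#'
#' Pearson correlation of per-trial spike counts between channel pairs,
#' computed separately within chunks of `chunk` adjacent trials and then
#' averaged, which removes the inflation caused by slow session-wide rate
#' drifts. Time-resolved mode counts spikes in +/-40 ms windows slid
#' every 10 ms and correlates the concatenated within-trial time series;
#' window mode uses one fixed window (default the 0.5 s ending at the
#' alignment event).
#'
#' @param spike_list List of spike-time vectors (channels/units).
#' @param events Per-trial alignment times, seconds.
#' @param mode `"window"` or `"timeresolved"`.
#' @param window Fixed-window bounds for `"window"` mode (default
#'   `c(-0.5, 0)`).
#' @param span Trial span for `"timeresolved"` mode (default `c(-0.5, 0)`).
#' @param half_width,step Sliding count parameters (defaults 0.04 and
#'   0.01 s).
#' @param chunk Trials per chunk (default 10; incomplete final chunk is
#'   dropped).
#' @return List with `pairs` (data frame: i, j, r, n_chunks) and `r_mean`.
#' @export
noise_corr <- function(spike_list, events, mode = c("window", "timeresolved"),
                       window = c(-0.5, 0), span = c(-0.5, 0),
                       half_width = 0.04, step = 0.01, chunk = 10L) {
  mode <- match.arg(mode)
  n_tr <- length(events)
  n_chunks <- n_tr %/% chunk
  if (n_chunks < 1L) stop("need at least one full chunk of ", chunk, " trials")
  n_ch <- length(spike_list)
  # feature matrix per trial: scalar count (window mode) or sliding counts
  feats <- lapply(spike_list, function(sp) {
    if (mode == "window") {
      matrix(counts_in_window(sp, events, window), ncol = 1L)
    } else {
      centers <- seq(span[1] + half_width, span[2] - half_width, by = step)
      t(vapply(events, function(e) {
        vapply(centers, function(c0) {
          sum(sp >= e + c0 - half_width & sp < e + c0 + half_width)
        }, numeric(1))
      }, numeric(length(centers))))
    }
  })
  pair_idx <- utils::combn(n_ch, 2L)
  res <- apply(pair_idx, 2L, function(pr) {
    rs <- numeric(0)
    for (ck in seq_len(n_chunks)) {
      tr <- ((ck - 1L) * chunk + 1L):(ck * chunk)
      a <- as.vector(t(feats[[pr[1]]][tr, , drop = FALSE]))
      b <- as.vector(t(feats[[pr[2]]][tr, , drop = FALSE]))
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      rs <- c(rs, stats::cor(a, b))
    }
    c(i = pr[1], j = pr[2], r = if (length(rs)) mean(rs) else NA_real_,
      n_chunks = length(rs))
  })
  pairs <- as.data.frame(t(res))
  list(pairs = pairs, r_mean = mean(pairs$r, na.rm = TRUE))
}

#' Whole-session (unchunked) noise correlation
#'
#' Companion to [noise_corr()] for quantifying how much slow drift
#' inflates the correlation when chunking is disabled.
#'
#' @inheritParams noise_corr
#' @return List with `pairs` and `r_mean`.
#' @export
noise_corr_session <- function(spike_list, events, window = c(-0.5, 0)) {
  noise_corr(spike_list, events, mode = "window", window = window,
             chunk = length(events))
}

#' Attentional difference time courses with population significance
#'
#' For each unit, the smoothed difference between its attend-toward and
#' attend-away peri-cue z-scored PETHs (default window -0.1 to +0.5 s
#' around cue onset, Gaussian smoothing of length 80 and SD 13 samples on
#' the 1 ms grid). Population-level per-bin significance uses the paired
#' condition-label-exchange null with max-statistic control.
#'
#' @param peth_toward,peth_away Units x time matrices of condition PETHs
#'   on a common 1 ms grid.
#' @param smooth_len,smooth_sd Smoothing parameters in samples (defaults
#'   80 and 13).
#' @param n_rand,seed,alpha Randomization parameters.
#' @return List with `diff` (units x time, smoothed), `mean`, `mask`
#'   (significant bins), `onset_bin` (first significant bin or NA).
#' @export
attn_difference_timecourse <- function(peth_toward, peth_away,
                                       smooth_len = 80L, smooth_sd = 13,
                                       n_rand = 1000L, seed = 1L,
                                       alpha = 0.05) {
  stopifnot(identical(dim(peth_toward), dim(peth_away)))
  d <- peth_toward - peth_away
  d <- t(apply(d, 1L, gauss_smooth, len = smooth_len, sd = smooth_sd))
  rt <- rand_test(d, paired = TRUE, n_rand = n_rand, seed = seed,
                  alpha = alpha)
  onset <- if (any(rt$mask)) which(rt$mask)[1L] else NA_integer_
  list(diff = d, mean = colMeans(d), mask = rt$mask, onset_bin = onset,
       upper = rt$upper, lower = rt$lower)
}

## Unbiased cross-correlation: r(l) = sum_t a(t) b(t + l) / (n - |l|).
xcorr_unbiased <- function(a, b, max_lag) {
  n <- length(a)
  lags <- -max_lag:max_lag
  vapply(lags, function(l) {
    if (l >= 0) {
      sum(a[1:(n - l)] * b[(1 + l):n]) / (n - l)
    } else {
      sum(a[(1 - l):n] * b[1:(n + l)]) / (n + l)
    }
  }, numeric(1))
}

#' Cross-correlation asymmetry between two difference time courses
#'
#' Cross-correlates the population-mean attentional difference traces of
#' two unit populations over an analysis period (default 0.05-0.5 s after
#' cue onset) with the bias-corrected normalization, and summarizes lead/
#' lag as `asymmetry = integral(r, -0.2..0) - integral(r, 0..0.2)`. With
#' the convention `r(l) = <A(t) B(t+l)>`, a positive asymmetry means B
#' leads A (B's modulation rises earlier). Significance comes from
#' pseudorandomly reassigning units between the two populations.
#'
#' @param units_a,units_b Units x time matrices of per-unit difference
#'   traces on a common grid covering the analysis period.
#' @param fs Sampling rate of the traces, Hz.
#' @param max_lag Maximum lag, seconds (default 0.2).
#' @param n_rand,seed Randomization parameters (default 1000).
#' @return List with `lags` (s), `xcorr`, `asymmetry`, `p_empirical`.
#' @export
xcorr_asymmetry <- function(units_a, units_b, fs, max_lag = 0.2,
                            n_rand = 1000L, seed = 1L) {
  stopifnot(ncol(units_a) == ncol(units_b))
  max_l <- round(max_lag * fs)
  if (ncol(units_a) <= max_l) stop("traces shorter than the maximum lag")
  asym_of <- function(ma, mb) {
    r <- xcorr_unbiased(colMeans(ma), colMeans(mb), max_l)
    lags <- (-max_l:max_l) / fs
    sum(r[lags >= -max_lag & lags <= 0]) / fs -
      sum(r[lags >= 0 & lags <= max_lag]) / fs
  }
  obs_r <- xcorr_unbiased(colMeans(units_a), colMeans(units_b), max_l)
  obs <- asym_of(units_a, units_b)
  pooled <- rbind(units_a, units_b)
  n_a <- nrow(units_a)
  null <- with_seed(seed, {
    vapply(seq_len(n_rand), function(i) {
      idx <- sample.int(nrow(pooled))
      asym_of(pooled[idx[seq_len(n_a)], , drop = FALSE],
              pooled[idx[-seq_len(n_a)], , drop = FALSE])
    }, numeric(1))
  })
  p <- (1 + sum(abs(null - mean(null)) >= abs(obs - mean(null)))) / (n_rand + 1)
  list(lags = (-max_l:max_l) / fs, xcorr = obs_r, asymmetry = obs,
       p_empirical = min(1, p), n_rand = n_rand, seed = seed)
}

#' Multi-linear regression of AMI on baseline rate and layer
#'
#' Least-squares fit of `AMI ~ rate + layer + rate:layer` with the layer
#' coded as a categorical factor.
#'
#' @param ami_values AMI per unit.
#' @param baseline_rate Baseline firing rate per unit, Hz.
#' @param layer Laminar compartment per unit (factor/character).
#' @return List with `coefficients`, `r_squared`, `residuals`, `fit` (the
#'   underlying `lm`).
#' @export
ami_regression <- function(ami_values, baseline_rate, layer) {
  layer <- factor(layer)
  if (nlevels(layer) < 2L) stop("at least 2 layers must be represented")
  df <- data.frame(ami = ami_values, rate = baseline_rate, layer = layer)
  fit <- stats::lm(ami ~ rate * layer, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  list(coefficients = stats::coef(fit),
       r_squared = summary(fit)$r.squared,
       residuals = stats::residuals(fit), fit = fit)
}
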