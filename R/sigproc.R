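# Continuous-signal preprocessing: shank re-referencing, bipolar
# derivation, zero-phase band-pass + analytic signal, current source
# density, surrogate LFP from population spiking, and epoch selection.
#
# Conventions: LFP matrices are channels x samples; `geometry` is a
# data.frame with one row per channel and columns `channel`, `area`,
# `shank`, `depth_index` (increasing with depth), `depth_um`. All times are
# in seconds; epochs are half-open [t0, t1).

#' Subtract the per-shank average LFP
#'
#' Removes common-mode (reference and headstage) signal by subtracting, at
#' every sample, the mean across the channels of each shank from every
#' channel of that shank.
#'
#' @param lfp Channels x samples matrix.
#' @param geometry Channel geometry data.frame (see package conventions).
#' @return Re-referenced LFP matrix of the same shape.
#' @export
shank_rereference <- function(lfp, geometry) {
  check_geometry(lfp, geometry)
  for (sh in unique(geometry$shank)) {
    idx <- which(geometry$shank == sh)
    if (length(idx) < 2L) {
      stop("shank '", sh, "' has fewer than 2 channels; cannot re-reference")
    }
    mu <- colMeans(lfp[idx, , drop = FALSE])
    lfp[idx, ] <- sweep(lfp[idx, , drop = FALSE], 2L, mu)
  }
  lfp
}

#' Bipolar derivation along each shank
#'
#' Differences adjacent contacts within each shank, deeper minus shallower,
#' attenuating volume-conducted common signal. The derived channel inherits
#' the midpoint depth of its parent contacts.
#'
#' @inheritParams shank_rereference
#' @return List with `lfp` ((channels - shanks) x samples matrix) and the
#'   derived `geometry`.
#' @export
bipolar_derive <- function(lfp, geometry) {
  check_geometry(lfp, geometry)
  out <- list(); geo <- list()
  for (sh in unique(geometry$shank)) {
    idx <- which(geometry$shank == sh)
    d <- geometry$depth_index[idx]
    if (is.unsorted(d, strictly = TRUE)) {
      stop("channels of shank '", sh, "' are not ordered by increasing depth")
    }
    if (length(idx) < 2L) stop("shank '", sh, "' has fewer than 2 channels")
    deep <- idx[-1L]; shallow <- idx[-length(idx)]
    out[[as.character(sh)]] <- lfp[deep, , drop = FALSE] - lfp[shallow, , drop = FALSE]
    geo[[as.character(sh)]] <- data.frame(
      channel = paste0(geometry$channel[deep], "-", geometry$channel[shallow]),
      area = geometry$area[deep],
      shank = sh,
      depth_index = (geometry$depth_index[deep] + geometry$depth_index[shallow]) / 2,
      depth_um = (geometry$depth_um[deep] + geometry$depth_um[shallow]) / 2,
      stringsAsFactors = FALSE
    )
  }
  list(lfp = do.call(rbind, out), geometry = do.call(rbind, c(geo, make.row.names = FALSE)))
}

#' Zero-phase band-pass filter plus analytic signal
#'
#' Applies a two-way (forward-backward, hence zero-phase) Butterworth
#' band-pass of the given overall order to every channel, then takes the
#' Hilbert transform to obtain the analytic signal, from which
#' instantaneous phase and amplitude are defined at every sample. Intended
#' to be applied to complete trials before any epoch selection.
#'
#' @param lfp Channels x samples matrix or a single numeric vector.
#' @param band Length-2 numeric, pass band in Hz (e.g. `c(40, 90)`).
#' @param fs Sampling rate in Hz.
#' @param order Overall filter order (default 12; must be even).
#' @return An `analytic_signal` object: list with complex `values`
#'   (channels x samples), `band`, `order`, `fs`.
#' @export
bandpass_hilbert <- function(lfp, band, fs, order = 12L) {
  if (is.null(dim(lfp))) lfp <- matrix(lfp, nrow = 1L)
  stopifnot(length(band) == 2L, band[1] < band[2])
  if (band[1] <= 0 || band[2] >= fs / 2) {
    stop("band must lie strictly inside (0, fs/2)")
  }
  if (order %% 2 != 0) stop("'order' must be even for a band-pass design")
  bf <- signal::butter(order / 2, band * 2 / fs, type = "pass")
  filt <- t(apply(lfp, 1L, function(ch) signal::filtfilt(bf, ch)))
  z <- analytic_signal(filt)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  structure(list(values = z, band = band, order = order, fs = fs),
            class = "analytic_signal")
}

#' Current source density from a laminar LFP profile
#'
#' Second discrete spatial derivative across equally spaced contacts of one
#' shank: `CSD_i = (V_{i-1} - 2 V_i + V_{i+1}) / h^2`. Channels flagged as
#' bad are replaced by the linear interpolation of their neighbours before
#' differencing.
#'
#' @param evoked_lfp Channels x time matrix for a single shank, ordered by
#'   depth.
#' @param spacing Contact spacing h in micrometers.
#' @param bad_channels Integer indices of low-SNR channels to interpolate;
#'   must not include the first or last contact.
#' @return A `csd_profile` object: `values` ((channels - 2) x time matrix),
#'   `channels` (the interior contact indices), `spacing`,
#'   `interpolated` (logical per input channel).
#' @export
compute_csd <- function(evoked_lfp, spacing, bad_channels = integer(0)) {
  stopifnot(is.matrix(evoked_lfp), nrow(evoked_lfp) >= 3L, spacing > 0)
  n <- nrow(evoked_lfp)
  bad_channels <- as.integer(bad_channels)
  if (any(bad_channels %in% c(1L, n))) {
    stop("bad channels at the shank edge cannot be interpolated")
  }
  interp <- rep(FALSE, n)
  for (b in sort(bad_channels)) {
    lo <- max(which(!(seq_len(n) %in% bad_channels) & seq_len(n) < b))
    hi <- min(which(!(seq_len(n) %in% bad_channels) & seq_len(n) > b))
    w <- (b - lo) / (hi - lo)
    evoked_lfp[b, ] <- (1 - w) * evoked_lfp[lo, ] + w * evoked_lfp[hi, ]
    interp[b] <- TRUE
  }
  i <- 2:(n - 1L)
  vals <- (evoked_lfp[i - 1L, , drop = FALSE] - 2 * evoked_lfp[i, , drop = FALSE] +
             evoked_lfp[i + 1L, , drop = FALSE]) / spacing^2
  structure(list(values = vals, channels = i, spacing = spacing,
                 interpolated = interp),
            class = "csd_profile")
}

#' Surrogate LFP from population spiking
#'
#' For structures without a laminar LFP (e.g. LGN), sums the spikes of all
#' isolated units into a 1 ms binned population rate and band-passes the
#' result (default 1-100 Hz, zero-phase Butterworth). At least 10 units are
#' required, mirroring the session-inclusion rule, unless `override = TRUE`.
#'
#' @param spike_trains List of numeric spike-time vectors (seconds), one
#'   per unit.
#' @param fs Output sampling rate in Hz (spike binning rate; default 1000).
#' @param band Pass band in Hz (default `c(1, 100)`).
#' @param duration Recording span in seconds (defaults to the latest spike).
#' @param override Allow fewer than 10 units.
#' @return Numeric vector: the surrogate LFP sampled at `fs`.
#' @export
surrogate_lfp <- function(spike_trains, fs = 1000, band = c(1, 100),
                          duration = NULL, override = FALSE) {
  n_units <- length(spike_trains)
  if (n_units < 10L && !override) {
    stop("surrogate LFP requires >= 10 units; got ", n_units)
  }
  all_spikes <- unlist(spike_trains, use.names = FALSE)
  if (is.null(duration)) {
    duration <- if (length(all_spikes)) max(all_spikes) + 1 / fs else 1
  }
  n <- max(2L, ceiling(duration * fs))
  counts <- numeric(n)
  if (length(all_spikes)) {
    idx <- floor(all_spikes * fs) + 1L
    idx <- idx[idx >= 1L & idx <= n]
    tab <- tabulate(idx, nbins = n)
    counts <- as.numeric(tab)
  }
  if (all(counts == 0)) return(counts)
  bf <- signal::butter(2, band * 2 / fs, type = "pass")
  as.numeric(signal::filtfilt(bf, counts))
}

#' Select an event-aligned epoch
#'
#' Extracts the half-open interval `[event + w0, event + w1)`. For spike
#' trains the spikes are returned re-referenced to the event; for sampled
#' series the corresponding sample range is returned.
#'
#' @param x Numeric spike-time vector (`type = "spikes"`) or sampled series
#'   (vector/matrix, `type = "series"`).
#' @param event Event time in seconds.
#' @param window Length-2 numeric, window relative to the event in seconds.
#' @param fs Sampling rate (required for series).
#' @param t0 Time of the first sample of a series (default 0).
#' @param type `"spikes"` or `"series"`.
#' @return Re-referenced spike times, or the series segment.
#' @export
select_epoch <- function(x, event, window, fs = NULL, t0 = 0,
                         type = c("spikes", "series")) {
  type <- match.arg(type)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  if (type == "spikes") {
    keep <- x >= event + window[1] & x < event + window[2]
    return(x[keep] - event)
  }
  stopifnot(!is.null(fs))
  n <- if (is.matrix(x)) ncol(x) else length(x)
  i0 <- floor((event + window[1] - t0) * fs) + 1L
  i1 <- floor((event + window[2] - t0) * fs)
  if (i0 < 1L || i1 > n) stop("epoch window exceeds the recording span")
  if (i1 < i0) {
    return(if (is.matrix(x)) x[, 0, drop = FALSE] else x[0])
  }
  if (is.matrix(x)) x[, i0:i1, drop = FALSE] else x[i0:i1]
}

## Shared geometry validation.
check_geometry <- function(lfp, geometry) {
  stopifnot(is.matrix(lfp), is.data.frame(geometry))
  need <- c("channel", "shank", "depth_index")
  if (!all(need %in% names(geometry))) {
    stop("geometry must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(geometry) != nrow(lfp)) {
    stop("geometry rows (", nrow(geometry), ") must match LFP channels (",
         nrow(lfp), ")")
  }
  invisible(TRUE)
}

#' @export
print.analytic_signal <- function(x, ...) {
  cat("<analytic_signal> ", nrow(x$values), " channel(s) x ",
      ncol(x$values), " samples, band ", x$band[1], "-", x$band[2],
      " Hz, order ", x$order, ", fs ", x$fs, " Hz\n", sep = "")
  invisible(x)
}
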