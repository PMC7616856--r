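# Seeded synthetic two-area laminar session generator with ground truth.
#
# The generator emulates the statistical structure that the analysis
# modules assume: a sender area ("V1") carrying a stimulus-induced
# narrow-band gamma rhythm (damped AR(2) oscillator on top of 1/f
# background noise), a receiver area ("V4") receiving a lagged,
# layer-weighted copy of that rhythm, units whose spiking is
# inhomogeneous-Poisson with von Mises phase coupling to the sender gamma
# (concentration depending on cell class, layer and attention condition),
# multiplicative attentional rate gains switching on at per-compartment
# latencies after cue onset, and a slow shared gain fluctuation that
# induces noise correlations. Mouse mode adds an LGN unit population for
# surrogate-LFP analyses, pupil and running-speed traces, and
# opto-pulse-locked responses in tagged units.

LAYERS <- c("superficial", "granular", "deep")
CLASSES <- c("NW", "BW")
CONDITIONS <- c("toward", "away")

#' Configuration for the synthetic session generator
#'
#' All defaults constitute the "paper-like" preset: a macaque-style
#' two-area laminar session with 16-contact shanks at 150 um spacing,
#' behavioural timing drawn from the attention-task delay ranges, gamma
#' peak slightly higher in frequency and power with attention, NW-only
#' attentional increase in phase coupling, attentional rate gain strongest
#' in superficial layers and earliest in the receiver superficial
#' compartment, and weaker shared rate co-fluctuations with attention.
#'
#' @param n_trials Number of trials (conditions balanced).
#' @param fs LFP sampling rate, Hz.
#' @param n_channels_per_shank Contacts per shank (default 16).
#' @param channel_spacing Contact spacing, um (default 150).
#' @param n_units_per_area Single units per area.
#' @param gamma_peak Named numeric: sender gamma peak frequency (Hz) per
#'   condition.
#' @param gamma_bandwidth Gamma spectral half-width, Hz.
#' @param gamma_power Named numeric: gamma variance (a.u.) per condition.
#' @param feedforward_lag Sender-to-receiver lag, seconds.
#' @param receiver_gamma_gain Amplitude of the lagged gamma copy in the
#'   receiver relative to the sender.
#' @param coupling_kappa Named list `[[class]][[layer]]` of length-2 named
#'   vectors (toward, away): von Mises concentration of spike coupling.
#' @param receiver_kappa_scale Multiplier applied to the coupling map for
#'   receiver-area units (default 0.45): interareal spike-to-sender-gamma
#'   locking is substantially weaker than local sender locking.
#' @param preferred_phase Named numeric `c(sender=, receiver=)`: preferred
#'   sender-gamma phase of spiking per area, radians.
#' @param base_rate Mean stimulus-period firing rate, Hz (per-unit rates
#'   are drawn log-normally around this).
#' @param baseline_rate_frac Pre-stimulus rate as a fraction of the
#'   stimulus-period rate.
#' @param attention_gain Named numeric per layer: multiplicative rate gain
#'   in attend-toward trials.
#' @param attention_latency Named numeric per compartment
#'   (`area.layer`, e.g. `receiver.superficial`): seconds after cue onset
#'   at which the gain ramps on.
#' @param ramp_width Width of the sigmoidal gain ramp, seconds.
#' @param shared_gain_sd Named numeric per condition: SD of the slow
#'   shared log-gain driving noise correlations.
#' @param shared_gain_tau Autocorrelation time of the shared gain, s.
#' @param trial_timing List with `pre_stim` (s), `cue_delay` (range, s),
#'   `change_delay` (range, s), `post_change` (s), `gap` (s).
#' @param noise_sd LFP background (1/f) noise SD, uV.
#' @param evoked_amplitude Amplitude of the stimulus-evoked laminar
#'   transient used for CSD, uV.
#' @param mouse Add mouse-mode extras (LGN units, pupil/speed, opto).
#' @param n_lgn_units LGN population size (mouse mode).
#' @param n_opto_pulses Number of 10 ms opto pulses appended after the
#'   task period (mouse mode).
#' @param seed Integer seed; the session is a deterministic function of
#'   the full configuration.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_trials = 120L,
                         fs = 1000,
                         n_channels_per_shank = 16L,
                         channel_spacing = 150,
                         n_units_per_area = 12L,
                         gamma_peak = c(toward = 61, away = 58),
                         gamma_bandwidth = 10,
                         gamma_power = c(toward = 1.25, away = 1),
                         feedforward_lag = 0.003,
                         receiver_gamma_gain = 0.6,
                         coupling_kappa = NULL,
                         receiver_kappa_scale = 0.45,
                         preferred_phase = c(sender = 0, receiver = 1.51),
                         base_rate = 8,
                         baseline_rate_frac = 0.5,
                         attention_gain = c(superficial = 1.4, granular = 1.25,
                                            deep = 1.15),
                         attention_latency = c(receiver.superficial = 0.15,
                                               receiver.granular = 0.25,
                                               receiver.deep = 0.30,
                                               sender.superficial = 0.35,
                                               sender.granular = 0.35,
                                               sender.deep = 0.35),
                         ramp_width = 0.05,
                         shared_gain_sd = c(toward = 0.10, away = 0.20),
                         shared_gain_tau = 0.2,
                         trial_timing = list(pre_stim = 0.614,
                                             cue_delay = c(0.618, 1.131),
                                             change_delay = c(1.162, 2.133),
                                             post_change = 0.3,
                                             gap = 0.2),
                         noise_sd = 1,
                         evoked_amplitude = 40,
                         mouse = FALSE,
                         n_lgn_units = 12L,
                         n_opto_pulses = 50L,
                         seed = 1L) {
  if (is.null(coupling_kappa)) {
    # NW attentional increments give a PPC increase of ~0.03 at the
    # gamma peak, the order of magnitude of the reported cell-type-
    # specific attention effect; BW locking is weak and unmodulated
    coupling_kappa <- list(
      NW = list(superficial = c(toward = 0.92, away = 0.8),
                granular   = c(toward = 1.32, away = 1.2),
                deep       = c(toward = 0.72, away = 0.6)),
      BW = list(superficial = c(toward = 0.25, away = 0.25),
                granular   = c(toward = 0.25, away = 0.25),
                deep       = c(toward = 0.25, away = 0.25))
    )
  }
  cfg <- list(n_trials = as.integer(n_trials), fs = fs,
              n_channels_per_shank = as.integer(n_channels_per_shank),
              channel_spacing = channel_spacing,
              n_units_per_area = as.integer(n_units_per_area),
              gamma_peak = gamma_peak, gamma_bandwidth = gamma_bandwidth,
              gamma_power = gamma_power, feedforward_lag = feedforward_lag,
              receiver_gamma_gain = receiver_gamma_gain,
              coupling_kappa = coupling_kappa,
              receiver_kappa_scale = receiver_kappa_scale,
              preferred_phase = preferred_phase,
              base_rate = base_rate, baseline_rate_frac = baseline_rate_frac,
              attention_gain = attention_gain,
              attention_latency = attention_latency,
              ramp_width = ramp_width,
              shared_gain_sd = shared_gain_sd,
              shared_gain_tau = shared_gain_tau,
              trial_timing = trial_timing,
              noise_sd = noise_sd, evoked_amplitude = evoked_amplitude,
              mouse = mouse, n_lgn_units = as.integer(n_lgn_units),
              n_opto_pulses = as.integer(n_opto_pulses),
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_trials >= 2L, cfg$fs > 0, cfg$n_channels_per_shank >= 8L,
            cfg$base_rate >= 0, cfg$baseline_rate_frac >= 0,
            cfg$gamma_bandwidth > 0)
  if (any(cfg$gamma_peak >= cfg$fs / 2)) {
    stop("gamma peak frequency must be below the Nyquist frequency")
  }
  if (!all(CONDITIONS %in% names(cfg$gamma_peak)) ||
      !all(CONDITIONS %in% names(cfg$gamma_power)) ||
      !all(CONDITIONS %in% names(cfg$shared_gain_sd))) {
    stop("condition-keyed parameters need names 'toward' and 'away'")
  }
  for (cl in names(cfg$coupling_kappa)) {
    if (!cl %in% CLASSES) stop("unknown cell class in coupling_kappa: '", cl, "'")
    for (ly in names(cfg$coupling_kappa[[cl]])) {
      if (!ly %in% LAYERS) stop("unknown layer in coupling_kappa: '", ly, "'")
      k <- cfg$coupling_kappa[[cl]][[ly]]
      if (any(k < 0)) stop("coupling kappa must be >= 0")
    }
  }
  if (!all(names(cfg$attention_gain) %in% LAYERS)) {
    stop("unknown layer in attention_gain: '",
         setdiff(names(cfg$attention_gain), LAYERS)[1], "'")
  }
  if (any(cfg$attention_gain <= 0)) stop("attention gains must be > 0")
  tt <- cfg$trial_timing
  if (tt$pre_stim <= 0 || any(tt$cue_delay <= 0) || any(tt$change_delay <= 0) ||
      tt$cue_delay[1] > tt$cue_delay[2] ||
      tt$change_delay[1] > tt$change_delay[2]) {
    stop("trial timing ranges must be positive and ordered")
  }
  invisible(cfg)
}

## Unit-variance stochastic gamma oscillation with a smooth instantaneous
## phase: the instantaneous frequency wanders around f as a slow OU
## process (FWHM of the spectral bump ~ bw) and the amplitude is a slow
## log-normal modulation. Returns both the signal and its ground-truth
## phase, which - unlike the instantaneous phase of a driven AR(2)
## process - is smooth enough to be recoverable by band-limited phase
## estimators. Uses the current RNG stream.
gamma_oscillation <- function(n, f, bw, fs, freq_tau = 0.075,
                              amp_tau = 0.15, amp_sd = 0.4) {
  df <- ou_process(n, fs, freq_tau) * (bw / 2.355)
  theta <- cumsum(2 * pi * (f + df) / fs)
  amp <- exp(amp_sd * ou_process(n, fs, amp_tau))
  x <- amp * cos(theta)
  list(x = x / stats::sd(x), phase = wrap_phase(theta))
}

## 1/f-amplitude background noise with unit variance (FFT colouring).
## Computed at a highly composite padded length (R's FFT is O(n^2) for
## prime n) and truncated.
one_over_f_noise <- function(n, exponent = 1) {
  m <- stats::nextn(n, c(2, 3, 5))
  wn <- stats::rnorm(m)
  f <- stats::fft(wn)
  k <- c(1, seq_len(m - 1))
  k <- pmin(k, m - k + 1)                 # symmetric frequency index
  amp <- 1 / (k^(exponent / 2))
  amp[1] <- 0
  x <- Re(stats::fft(f * amp, inverse = TRUE) / m)[seq_len(n)]
  x / stats::sd(x)
}

## Ornstein-Uhlenbeck process, unit stationary variance, correlation time
## tau seconds.
ou_process <- function(n, fs, tau) {
  a <- exp(-1 / (fs * tau))
  x <- stats::filter(stats::rnorm(n) * sqrt(1 - a^2), a, method = "recursive")
  as.numeric(x)
}

## Phase unwrapping (cumulative wrapped first differences).
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- wrap_phase(d)
  cumsum(c(p[1], d))
}

#' Generate a narrow-band stochastic gamma oscillation plus 1/f background
#'
#' The oscillation has a smoothly wandering instantaneous frequency
#' (slow Ornstein-Uhlenbeck modulation around `f_peak`, giving a broad,
#' session-realistic spectral bump of width about `bandwidth`) and a slow
#' log-normal amplitude envelope, superimposed on 1/f background noise of
#' unit variance. With `power = 0` only the background is returned.
#'
#' @param f_peak Peak frequency, Hz (must be below Nyquist).
#' @param bandwidth Spectral half-width, Hz.
#' @param power Variance of the oscillatory component (a.u.).
#' @param duration Signal duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed (deterministic output).
#' @return Numeric vector of `duration * fs` samples.
#' @export
gen_lfp_oscillation <- function(f_peak, bandwidth, power, duration, fs,
                                seed = 1L) {
  if (f_peak <= 0 || f_peak >= fs / 2) {
    stop("f_peak must lie strictly inside (0, fs/2)")
  }
  stopifnot(bandwidth > 0, power >= 0, duration > 0)
  n <- round(duration * fs)
  with_seed(seed, {
    bg <- one_over_f_noise(n)
    if (power > 0) {
      bg + sqrt(power) * gamma_oscillation(n, f_peak, bandwidth, fs)$x
    } else {
      bg
    }
  })
}

#' Inhomogeneous-Poisson spikes phase-locked to an oscillation
#'
#' Spike intensity is `lambda(t) = mean_rate * exp(kappa * cos(phi(t) -
#' pref_phase)) / I0(kappa)`, so that for a phase uniformly distributed
#' over time the time-averaged rate equals `mean_rate` and the spike-phase
#' distribution is von Mises with concentration `kappa`. Sampling uses
#' exact Poisson thinning with the phase linearly interpolated (after
#' unwrapping) at candidate spike times.
#'
#' @param phase Instantaneous oscillation phase, radians, sampled at `fs`.
#' @param fs Sampling rate of `phase`, Hz.
#' @param mean_rate Time-averaged firing rate, Hz (>= 0).
#' @param kappa von Mises concentration (>= 0).
#' @param pref_phase Preferred phase, radians.
#' @param seed Integer seed.
#' @param t0 Time of the first phase sample, seconds.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
gen_spikes_phase_locked <- function(phase, fs, mean_rate, kappa,
                                    pref_phase = 0, seed = 1L, t0 = 0) {
  stopifnot(mean_rate >= 0, kappa >= 0)
  n <- length(phase)
  if (mean_rate == 0 || n < 2L) return(numeric(0))
  dur <- n / fs
  i0k <- besselI(kappa, 0, expon.scaled = TRUE)  # I0(k) * exp(-k)
  lambda_max <- mean_rate / i0k                  # = rate * exp(k)/I0(k)
  up <- unwrap_phase(phase)
  tgrid <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    n_cand <- stats::rpois(1L, lambda_max * dur)
    if (n_cand == 0L) return(numeric(0))
    tc <- sort(stats::runif(n_cand, 0, dur))
    pc <- stats::approx(tgrid, up, xout = tc, rule = 2)$y
    lam <- mean_rate * exp(kappa * (cos(pc - pref_phase) - 1)) / i0k
    keep <- stats::runif(n_cand) * lambda_max < lam
    t0 + tc[keep]
  })
}

## Compartment layer of a channel depth index on a 16-style shank; the
## map scales with shank length. Returns one of outside/superficial/
## granular/deep/white_matter, and the granular anchor index.
shank_layer_map <- function(n_ch) {
  # proportions modelled on a 16-contact penetration spanning the cortex
  cuts <- round(n_ch * c(0.125, 0.40, 0.5625, 0.8125))
  lab <- character(n_ch)
  lab[seq_len(cuts[1])] <- "outside"
  lab[(cuts[1] + 1):cuts[2]] <- "superficial"
  lab[(cuts[2] + 1):cuts[3]] <- "granular"
  lab[(cuts[3] + 1):cuts[4]] <- "deep"
  lab[(cuts[4] + 1):n_ch] <- "white_matter"
  list(labels = lab, anchor = cuts[2] + ceiling((cuts[3] - cuts[2]) / 2))
}

## Biphasic waveform template bank; trough-to-peak 0.2 ms (NW) vs 0.5 ms
## (BW) at 30 kHz over 1.6 ms. `variant` adds the contaminant families
## used by the exclusion tests.
waveform_template <- function(class = c("NW", "BW", "triphasic", "dc"),
                              fs_wave = 30000, n_samp = 48L) {
  class <- match.arg(class)
  t <- (seq_len(n_samp) - 1L) / fs_wave * 1000   # ms
  t_trough <- 0.5
  tp <- switch(class, NW = 0.2, BW = 0.5, triphasic = 0.35, dc = 0.35)
  w <- -exp(-(t - t_trough)^2 / (2 * 0.06^2)) +
    0.45 * exp(-(t - t_trough - tp)^2 / (2 * (0.08 + 0.25 * tp)^2))
  if (class == "triphasic") {
    w <- w + 0.9 * exp(-(t - t_trough + 0.25)^2 / (2 * 0.07^2))
  }
  if (class == "dc") {
    w <- w + 0.4 * (t / max(t))
  }
  w
}

## Sigmoid attention ramp: 0 before latency, 1 after, width w seconds.
att_ramp <- function(t, latency, w) {
  1 / (1 + exp(-(t - latency) / (w / 4)))
}

#' Generate a synthetic two-area laminar session with ground truth
#'
#' Builds the full session described in the package overview: trial table
#' with stimulus/cue/change events and balanced attention conditions,
#' laminar LFPs for a sender and a receiver shank (gamma in the sender,
#' lagged layer-weighted copy in the receiver, stimulus-evoked laminar
#' transient for CSD), phase-locked unit spiking with class/layer/
#' condition-dependent coupling and rates, waveform templates, per-channel
#' spike-sign counts, and (in mouse mode) an LGN population, pupil and
#' running-speed traces and opto-tagged responses.
#'
#' @param config A [synth_config()] object.
#' @return List with `session` and `truth`. See the package vignette for
#'   the layout of both.
#' @export
gen_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  cfg <- config
  fs <- cfg$fs
  with_seed(cfg$seed, {
    ## ---- trial table -------------------------------------------------
    tt <- cfg$trial_timing
    n_tr <- cfg$n_trials
    cond <- sample(rep(CONDITIONS, length.out = n_tr))
    pre <- rep(tt$pre_stim, n_tr)
    cue_d <- stats::runif(n_tr, tt$cue_delay[1], tt$cue_delay[2])
    chg_d <- stats::runif(n_tr, tt$change_delay[1], tt$change_delay[2])
    t_start <- numeric(n_tr)
    cur <- 0.5
    for (i in seq_len(n_tr)) {
      t_start[i] <- cur
      cur <- cur + pre[i] + cue_d[i] + chg_d[i] + tt$post_change + tt$gap
    }
    stim_onset <- t_start + pre
    cue_onset <- stim_onset + cue_d
    change_onset <- cue_onset + chg_d
    trial_end <- change_onset + tt$post_change
    trials <- data.frame(trial = seq_len(n_tr), t_start = t_start,
                         stim_onset = stim_onset, cue_onset = cue_onset,
                         change_onset = change_onset, t_end = trial_end,
                         condition = cond, valid = TRUE,
                         stringsAsFactors = FALSE)
    task_end <- trial_end[n_tr] + 0.5
    n_task <- ceiling(task_end * fs)

    ## ---- gamma drive and its phase ----------------------------------
    gamma <- numeric(n_task)
    phase <- rep(NA_real_, n_task)
    lag_samp <- round(cfg$feedforward_lag * fs)
    for (i in seq_len(n_tr)) {
      i0 <- floor(stim_onset[i] * fs) + 1L
      i1 <- min(n_task, floor(trial_end[i] * fs))
      seg_n <- i1 - i0 + 1L
      osc <- gamma_oscillation(seg_n, cfg$gamma_peak[cond[i]],
                               cfg$gamma_bandwidth, fs)
      g <- osc$x * sqrt(cfg$gamma_power[cond[i]])
      edge <- min(seg_n %/% 4L, round(0.05 * fs))
      if (edge > 0) {
        ramp <- seq(0, 1, length.out = edge)
        g[seq_len(edge)] <- g[seq_len(edge)] * ramp
        g[seg_n - edge + seq_len(edge) - 0L] <-
          g[seg_n - edge + seq_len(edge) - 0L] * rev(ramp)
      }
      gamma[i0:i1] <- g
      phase[i0:i1] <- osc$phase
    }
    gamma_lag <- c(numeric(lag_samp), gamma[seq_len(n_task - lag_samp)])

    ## ---- geometry and laminar weights -------------------------------
    n_ch <- cfg$n_channels_per_shank
    lmap <- shank_layer_map(n_ch)
    geometry <- do.call(rbind, lapply(c("sender", "receiver"), function(a) {
      data.frame(channel = paste0(a, "_ch", seq_len(n_ch)), area = a,
                 shank = a, depth_index = seq_len(n_ch),
                 depth_um = (seq_len(n_ch) - 1L) * cfg$channel_spacing,
                 layer = lmap$labels, stringsAsFactors = FALSE)
    }))
    w_layer <- c(outside = 0.1, superficial = 0.7, granular = 1,
                 deep = 0.5, white_matter = 0.05)

    ## ---- evoked laminar transient (for CSD) -------------------------
    ev_len <- round(0.1 * fs)
    ev_t <- seq_len(ev_len) / fs
    ev_time <- sin(2 * pi * ev_t / 0.1) * exp(-ev_t / 0.03)
    ev_profile <- -exp(-(seq_len(n_ch) - lmap$anchor)^2 / (2 * 1.2^2))
    evoked <- matrix(0, n_ch, n_task)
    for (i in seq_len(n_tr)) {
      i0 <- floor(stim_onset[i] * fs) + 1L
      idx <- i0:(i0 + ev_len - 1L)
      evoked[, idx] <- evoked[, idx] +
        cfg$evoked_amplitude * outer(ev_profile, ev_time)
    }

    ## ---- LFP matrices -----------------------------------------------
    ## Per-channel gamma gains vary around the laminar profile so that
    ## bipolar derivation retains gamma; part of the 1/f background is
    ## common to a shank (reference/headstage noise) and removed by
    ## re-referencing/bipolar derivation, the rest is channel-private.
    gain_s <- w_layer[lmap$labels] * exp(stats::rnorm(n_ch, 0, 0.35))
    gain_r <- w_layer[lmap$labels] * exp(stats::rnorm(n_ch, 0, 0.35))
    common_s <- one_over_f_noise(n_task)
    common_r <- one_over_f_noise(n_task)
    lfp <- matrix(0, 2L * n_ch, n_task)
    for (ch in seq_len(n_ch)) {
      lfp[ch, ] <- gain_s[ch] * gamma +
        cfg$noise_sd * (0.85 * common_s + 0.45 * one_over_f_noise(n_task)) +
        evoked[ch, ]
      lfp[n_ch + ch, ] <- gain_r[ch] * cfg$receiver_gamma_gain * gamma_lag +
        cfg$noise_sd * (0.85 * common_r + 0.45 * one_over_f_noise(n_task)) +
        0.8 * evoked[ch, ]
    }

    ## ---- spike-sign counts per channel (for layer assignment) -------
    base_n <- 2000
    log_ratio_true <- c(outside = 0, superficial = -2, granular = -2,
                        deep = -2, white_matter = 1)
    pos <- neg <- integer(2L * n_ch)
    for (r in seq_len(2L * n_ch)) {
      lr <- log_ratio_true[geometry$layer[r]] + stats::rnorm(1, 0, 0.05)
      neg[r] <- stats::rpois(1, base_n)
      pos[r] <- stats::rpois(1, base_n * exp(lr))
    }
    spike_sign_counts <- data.frame(channel = geometry$channel,
                                    positive = pos, negative = neg,
                                    stringsAsFactors = FALSE)

    ## ---- shared slow gain -------------------------------------------
    ou <- ou_process(n_task, fs, cfg$shared_gain_tau)
    sd_by_samp <- numeric(n_task)
    for (i in seq_len(n_tr)) {
      i0 <- floor(t_start[i] * fs) + 1L
      i1 <- min(n_task, floor(trial_end[i] * fs))
      sd_by_samp[i0:i1] <- cfg$shared_gain_sd[cond[i]]
    }
    shared_gain <- exp(sd_by_samp * ou - sd_by_samp^2 / 2)

    ## ---- units -------------------------------------------------------
    n_u <- cfg$n_units_per_area
    mk_units <- function(area) {
      cls <- rep(CLASSES, length.out = n_u)
      lay <- rep(rep(LAYERS, each = 2L), length.out = n_u)
      data.frame(unit = paste0(area, "_u", seq_len(n_u)), area = area,
                 class = cls, layer = lay, stringsAsFactors = FALSE)
    }
    units <- rbind(mk_units("sender"), mk_units("receiver"))
    # channel in matching layer of own shank
    units$channel <- vapply(seq_len(nrow(units)), function(j) {
      cand <- geometry$channel[geometry$area == units$area[j] &
                                 geometry$layer == units$layer[j]]
      cand[1L + (j %% length(cand))]
    }, character(1))
    units$base_rate <- cfg$base_rate * exp(stats::rnorm(nrow(units), 0, 0.3))
    units$pref_phase <- wrap_phase(
      cfg$preferred_phase[units$area] + stats::rnorm(nrow(units), 0, 0.1))
    kap <- function(cl, ly, cd, area) {
      k <- cfg$coupling_kappa[[cl]]
      if (is.null(k) || is.null(k[[ly]])) return(0)
      sc <- if (area == "receiver") cfg$receiver_kappa_scale else 1
      unname(k[[ly]][cd]) * sc
    }
    units$kappa_toward <- mapply(kap, units$class, units$layer, "toward",
                                 units$area)
    units$kappa_away <- mapply(kap, units$class, units$layer, "away",
                               units$area)
    g_lay <- function(ly) unname(cfg$attention_gain[ly])
    units$rate_toward <- units$base_rate * vapply(units$layer, g_lay, numeric(1))
    units$rate_away <- units$base_rate
    units$opto_tagged <- FALSE

    ## waveforms
    waveforms <- t(vapply(seq_len(nrow(units)), function(j) {
      waveform_template(units$class[j]) + stats::rnorm(48L, 0, 0.03)
    }, numeric(48L)))
    rownames(waveforms) <- units$unit

    ## ---- spiking ------------------------------------------------------
    tgrid <- (seq_len(n_task) - 1L) / fs
    lat_of <- function(area, layer) {
      key <- paste(area, layer, sep = ".")
      if (key %in% names(cfg$attention_latency)) {
        unname(cfg$attention_latency[key])
      } else 0.3
    }
    spikes <- vector("list", nrow(units))
    names(spikes) <- units$unit
    up_all <- unwrap_phase(ifelse(is.na(phase), 0, phase))
    for (j in seq_len(nrow(units))) {
      uj <- units[j, ]
      rate <- rep(cfg$baseline_rate_frac * uj$base_rate, n_task)
      kappa_samp <- numeric(n_task)
      for (i in seq_len(n_tr)) {
        i0 <- floor(stim_onset[i] * fs) + 1L
        i1 <- min(n_task, floor(trial_end[i] * fs))
        seg_t <- tgrid[i0:i1]
        r <- rep(uj$base_rate, length(seg_t))
        if (cond[i] == "toward") {
          ramp <- att_ramp(seg_t - cue_onset[i], lat_of(uj$area, uj$layer),
                           cfg$ramp_width)
          r <- r * (1 + (g_lay(uj$layer) - 1) * ramp)
          kappa_samp[i0:i1] <- uj$kappa_toward
        } else {
          kappa_samp[i0:i1] <- uj$kappa_away
        }
        rate[i0:i1] <- r
      }
      rate <- rate * shared_gain
      kmax <- max(uj$kappa_toward, uj$kappa_away)
      i0k <- besselI(kmax, 0, expon.scaled = TRUE)
      lambda_max <- max(rate) / i0k * 1.0001
      n_cand <- stats::rpois(1L, lambda_max * task_end)
      if (n_cand == 0L) { spikes[[j]] <- numeric(0); next }
      tc <- sort(stats::runif(n_cand, 0, task_end))
      idx <- pmin(n_task, pmax(1L, floor(tc * fs) + 1L))
      k_c <- kappa_samp[idx]
      r_c <- stats::approx(tgrid, rate, xout = tc, rule = 2)$y
      p_c <- stats::approx(tgrid, up_all, xout = tc, rule = 2)$y
      coupled <- k_c > 0 & !is.na(phase[idx])
      mod <- rep(1, n_cand)
      i0k_c <- besselI(k_c[coupled], 0, expon.scaled = TRUE)
      mod[coupled] <- exp(k_c[coupled] *
                            (cos(p_c[coupled] - uj$pref_phase) - 1)) / i0k_c
      lam <- r_c * mod
      keep <- stats::runif(n_cand) * lambda_max < lam
      spikes[[j]] <- tc[keep]
    }

    session <- list(lfp = lfp, fs = fs, geometry = geometry[, 1:5],
                    spikes = spikes, units = units[, c("unit", "area",
                                                       "channel", "class",
                                                       "layer")],
                    waveforms = waveforms, trials = trials,
                    spike_sign_counts = spike_sign_counts,
                    duration = n_task / fs, mouse = cfg$mouse)
    class(session) <- "synth_session"

    ## ---- mouse extras ------------------------------------------------
    duration_total <- n_task / fs
    if (cfg$mouse) {
      lgn_spikes <- vector("list", cfg$n_lgn_units)
      for (j in seq_len(cfg$n_lgn_units)) {
        lgn_spikes[[j]] <- gen_spikes_phase_locked(
          ifelse(is.na(phase), 0, phase), fs, mean_rate = 10,
          kappa = 0.8, pref_phase = 0,
          seed = child_seed(cfg$seed, paste0("lgn", j)))
      }
      names(lgn_spikes) <- paste0("lgn_u", seq_len(cfg$n_lgn_units))
      pupil <- pmin(1, pmax(0.05, 0.6 + 0.25 * ou_process(n_task, fs, 5)))
      speed <- pmax(0, 6 * (ou_process(n_task, fs, 10) > 0.3) +
                      stats::rnorm(n_task, 0, 0.2))
      pulse_start <- duration_total + 1
      opto_pulses <- pulse_start + (seq_len(cfg$n_opto_pulses) - 1L) * 0.25
      tagged <- units$class == "NW" & units$area == "receiver"
      units$opto_tagged <- tagged
      session$units$opto_tagged <- tagged
      for (j in which(tagged)) {
        resp <- rep(opto_pulses, each = 3L) +
          stats::rnorm(3L * length(opto_pulses), 0.004, 0.001)
        resp <- resp[resp > rep(opto_pulses, each = 3L) + 0.0015]
        session$spikes[[j]] <- sort(c(session$spikes[[j]], resp))
      }
      session$lgn_spikes <- lgn_spikes
      session$pupil <- pupil
      session$speed <- speed
      session$opto_pulses <- opto_pulses
      session$duration <- max(opto_pulses) + 0.5
    }

    truth <- list(
      units = units[, c("unit", "area", "channel", "class", "layer",
                        "base_rate", "rate_toward", "rate_away",
                        "kappa_toward", "kappa_away", "pref_phase",
                        "opto_tagged")],
      gamma_peak = cfg$gamma_peak,
      gamma_power = cfg$gamma_power,
      feedforward_lag = cfg$feedforward_lag,
      preferred_phase = cfg$preferred_phase,
      granular_anchor = lmap$anchor,
      layer_labels = lmap$labels,
      attention_gain = cfg$attention_gain,
      attention_latency = cfg$attention_latency,
      shared_gain_sd = cfg$shared_gain_sd,
      config = cfg
    )
    list(session = session, truth = truth)
  })
}

#' @export
print.synth_session <- function(x, ...) {
  cat("<synth_session> ", nrow(x$lfp), " LFP channels x ", ncol(x$lfp),
      " samples @ ", x$fs, " Hz, ", length(x$spikes), " units, ",
      nrow(x$trials), " trials", if (isTRUE(x$mouse)) ", mouse mode", "\n",
      sep = "")
  invisible(x)
}

#' Export a session's trial table to CSV
#'
#' @param session A `synth_session`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trial_table <- function(session, path) {
  utils::write.csv(session$trials, path, row.names = FALSE)
  invisible(path)
}
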