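# Synthetic session generator: determinism, calibration, validation.

test_that("configurations are validated with informative errors", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(gamma_peak = c(toward = 600, away = 58)),
               "Nyquist")
  expect_error(synth_config(coupling_kappa = list(
    XX = list(granular = c(toward = 1, away = 1)))), "unknown cell class")
  expect_error(synth_config(coupling_kappa = list(
    NW = list(l9 = c(toward = 1, away = 1)))), "unknown layer")
  expect_error(synth_config(coupling_kappa = list(
    NW = list(granular = c(toward = -1, away = 1)))), ">= 0")
  expect_error(synth_config(attention_gain = c(superficial = 0)), "> 0")
  expect_error(synth_config(trial_timing = list(
    pre_stim = 0.6, cue_delay = c(1.2, 0.6), change_delay = c(1.2, 2.1),
    post_change = 0.3, gap = 0.2)), "ordered")
})

test_that("the oscillation generator peaks where configured", {
  fs <- 1000
  x <- gen_lfp_oscillation(60, 10, 4, 20, fs, seed = 6L)
  pw <- power_spectrum(multitaper_coeffs(tile_epochs(x, fs, 0, 20), fs))
  band <- pw$freqs >= 20 & pw$freqs <= 150
  expect_equal(pw$freqs[band][which.max(pw$power[band])], 60, tolerance = 5)
  # power = 0: no bump; gamma-band power comparable to neighbours
  x0 <- gen_lfp_oscillation(60, 10, 0, 20, fs, seed = 6L)
  p0 <- power_spectrum(multitaper_coeffs(tile_epochs(x0, fs, 0, 20), fs))
  g <- p0$freqs >= 55 & p0$freqs <= 65
  lo <- p0$freqs >= 35 & p0$freqs <= 45
  expect_lt(mean(p0$power[g]) / mean(p0$power[lo]), 1.5)
  expect_identical(gen_lfp_oscillation(60, 10, 1, 2, fs, seed = 9L),
                   gen_lfp_oscillation(60, 10, 1, 2, fs, seed = 9L))
  expect_error(gen_lfp_oscillation(500, 10, 1, 1, fs), "fs/2")
})

test_that("phase-locked spiking hits the configured rate and coupling", {
  fs <- 1000
  osc <- gamma_fixture(duration = 60)
  # kappa = 0: homogeneous Poisson at mean_rate, uniform spike phases
  sp0 <- gen_spikes_phase_locked(osc$phase, fs, 12, 0, 0, seed = 41L)
  expect_equal(length(sp0) / 60, 12, tolerance = 3 * sqrt(12 * 60) / 60)
  up <- gammalock:::unwrap_phase(osc$phase)
  ph0 <- wrap_phase(stats::approx((seq_along(osc$phase) - 1) / fs, up,
                                  xout = sp0, rule = 2)$y)
  expect_lt(Mod(mean(exp(1i * ph0)))^2, 0.01)
  # kappa large: phases concentrate at the preferred phase, PPC -> 1
  sp50 <- gen_spikes_phase_locked(osc$phase, fs, 12, 50, 0.7, seed = 42L)
  ph50 <- wrap_phase(stats::approx((seq_along(osc$phase) - 1) / fs, up,
                                   xout = sp50, rule = 2)$y)
  expect_equal(circ_mean(ph50), 0.7, tolerance = 0.05)
  expect_gt(ppc0(ph50)$ppc, 0.9)
  # rate preserved under coupling
  sp2 <- gen_spikes_phase_locked(osc$phase, fs, 12, 2, 0.7, seed = 43L)
  expect_equal(length(sp2) / 60, 12, tolerance = 3 * sqrt(12 * 60) / 60)
  expect_length(gen_spikes_phase_locked(osc$phase, fs, 0, 1, 0), 0L)
})

test_that("sessions are bit-identical given the same configuration", {
  g <- small_session()
  g2 <- gen_session(synth_config(n_trials = 24L, n_units_per_area = 8L,
                                 seed = 11L))
  expect_identical(g$session$lfp, g2$session$lfp)
  expect_identical(g$session$spikes, g2$session$spikes)
  expect_identical(g$truth$units, g2$truth$units)
})

test_that("session structure satisfies its invariants", {
  s <- small_session()$session
  expect_true(all(is.finite(s$lfp)))
  expect_true(all(s$units$channel %in% s$geometry$channel))
  spans <- range(unlist(s$spikes))
  expect_gte(spans[1], 0)
  expect_lte(spans[2], s$duration)
  tr <- s$trials
  expect_true(all(tr$stim_onset < tr$cue_onset))
  expect_true(all(tr$cue_onset < tr$change_onset))
  expect_true(all(tr$condition %in% c("toward", "away")))
  expect_equal(sum(tr$condition == "toward"), nrow(tr) / 2)
  # delay draws stay inside the configured behavioural ranges
  expect_true(all(tr$cue_onset - tr$stim_onset >= 0.618 &
                    tr$cue_onset - tr$stim_onset <= 1.131))
  expect_true(all(tr$change_onset - tr$cue_onset >= 1.162 &
                    tr$change_onset - tr$cue_onset <= 2.133))
  # ground truth has one record per unit with the configured values
  tru <- small_session()$truth
  expect_equal(nrow(tru$units), length(s$spikes))
  expect_true(all(tru$units$kappa_toward >= 0))
})

test_that("unit firing rates match ground truth within sampling error", {
  g <- small_session()
  s <- g$session
  tr <- s$trials[s$trials$condition == "away", ]
  dur <- sum(tr$change_onset - tr$stim_onset)
  for (j in c(1L, 5L, 12L)) {
    u <- g$truth$units[j, ]
    cnt <- sum(vapply(seq_len(nrow(tr)), function(i) {
      sum(s$spikes[[u$unit]] >= tr$stim_onset[i] &
            s$spikes[[u$unit]] < tr$change_onset[i])
    }, numeric(1)))
    se <- sqrt(cnt) / dur
    expect_lt(abs(cnt / dur - u$rate_away), 3.5 * se + 0.1 * u$rate_away)
  }
})

test_that("the receiver gamma lags the sender by the configured delay", {
  g <- small_session()
  s <- g$session
  fs <- s$fs
  geo <- s$geometry
  pick <- function(a) which(geo$area == a &
                              geo$depth_index == g$truth$granular_anchor)
  az <- bandpass_hilbert(s$lfp[c(pick("sender"), pick("receiver")), ],
                         c(40, 90), fs)
  env <- Mod(az$values)
  # restrict to stimulus periods where gamma is present
  keep <- logical(ncol(env))
  for (i in seq_len(nrow(s$trials))) {
    keep[floor(s$trials$stim_onset[i] * fs):floor(s$trials$change_onset[i] * fs)] <- TRUE
  }
  cc <- stats::ccf(env[2, keep], env[1, keep], lag.max = 15, plot = FALSE)
  best <- cc$lag[which.max(cc$acf)]
  expect_equal(best, round(g$truth$feedforward_lag * fs), tolerance = 1)
})

test_that("mouse mode adds LGN units, state traces and opto responses", {
  cfg <- synth_config(n_trials = 10L, n_units_per_area = 6L, mouse = TRUE,
                      n_lgn_units = 11L, n_opto_pulses = 40L, seed = 13L)
  g <- gen_session(cfg)
  s <- g$session
  expect_length(s$lgn_spikes, 11L)
  expect_length(s$pupil, ncol(s$lfp))
  expect_true(all(s$pupil > 0 & s$pupil <= 1))
  expect_length(s$opto_pulses, 40L)
  tagged <- g$truth$units$opto_tagged
  expect_true(any(tagged) && !all(tagged))
  # tagged units respond within 10 ms of pulses; untagged do not
  resp_frac <- function(u) {
    sp <- s$spikes[[u]]
    mean(vapply(s$opto_pulses, function(p) {
      any(sp > p & sp <= p + 0.01)
    }, logical(1)))
  }
  expect_gt(min(vapply(g$truth$units$unit[tagged], resp_frac, numeric(1))),
            0.8)
  expect_lt(max(vapply(g$truth$units$unit[!tagged], resp_frac, numeric(1))),
            0.3)
})
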