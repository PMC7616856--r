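# PETHs, modulation indices, chunked noise correlations, latency
# analyses, AMI regression.

test_that("PETH pipeline bins, smooths, z-scores and averages", {
  events <- seq(5, 100, by = 5)
  # constant-rate unit: averaged z-trace stays near 0
  sp <- with_seed(61L, sort(runif(2000, 0, 105)))
  p <- peth(sp, events, window_full = c(-1, 1))
  expect_equal(diff(p$time[1:2]), 0.001)
  expect_lt(mean(abs(p$mean)), 0.3)       # no systematic structure
  # per-trial z-scoring: mean ~ 0, sd ~ 1
  expect_lt(max(abs(rowMeans(p$trials))), 1e-6)
  expect_equal(unname(apply(p$trials, 1, stats::sd)),
               rep(1, length(events)), tolerance = 0.01)
  # single spike at fixed latency: averaged trace peaks there with the
  # kernel shape
  sp1 <- events + 0.25
  p1 <- peth(sp1, events, window_full = c(-1, 1))
  expect_equal(p1$time[which.max(p1$mean)], 0.25, tolerance = 0.01)
  # empty trains are flagged, not errors
  p0 <- peth(numeric(0), events, window_full = c(-1, 1))
  expect_true(all(p0$empty_trials))
  expect_equal(p0$mean, rep(0, length(p0$time)))
})

test_that("PETH counts are additive across merged spike trains", {
  events <- c(10, 20, 30)
  a <- with_seed(62L, sort(runif(300, 0, 35)))
  b <- with_seed(63L, sort(runif(300, 0, 35)))
  pa <- peth(a, events, c(-1, 1))
  pb <- peth(b, events, c(-1, 1))
  pm <- peth(sort(c(a, b)), events, c(-1, 1))
  expect_equal(pm$counts, pa$counts + pb$counts)
})

test_that("AMI and drivenness are the stated bounded contrasts", {
  # deterministic spike trains: 6 vs 2 spikes in the 1 s window
  trials <- data.frame(trial = 1:2, stim_onset = c(1, 11),
                       cue_onset = c(2, 12), change_onset = c(4, 14),
                       condition = c("toward", "away"))
  sp <- c(3 + (1:6) / 10, 13 + (1:2) / 10)
  a <- ami(sp, trials)
  expect_equal(a$ami, 0.5)
  # swapping the conditions flips the sign
  trials2 <- trials; trials2$condition <- rev(trials2$condition)
  expect_equal(ami(sp, trials2)$ami, -0.5)
  expect_true(is.na(ami(numeric(0), trials)$ami))
  # drivenness windows: 0.05-0.25 s post-stim vs 0.2 s pre-stim baseline
  sp_dr <- c(1 - 0.2 + (1:2) / 20, 1.05 + (1:3) / 25)  # 2 base, 3 stim
  d <- drivenness(sp_dr, trials[1, ])
  expect_equal(d$dr, (3 - 2) / 5)
  sp_silent <- 1.06 + (1:4) / 30
  expect_equal(drivenness(sp_silent, trials[1, ])$dr, 1)
  expect_equal(drivenness(c(0.9, 1.1), trials[1, ])$dr, 0)
})

test_that("chunked correlations remove slow drift, plain ones do not", {
  n_tr <- 100L
  events <- seq(2, by = 4, length.out = n_tr)
  with_seed(64L, {
    # common monotone drift in rate plus independent noise
    drift <- seq(2, 22, length.out = n_tr)
    ca <- rpois(n_tr, drift); cb <- rpois(n_tr, drift)
    sp_a <- unlist(lapply(seq_len(n_tr), function(i)
      events[i] - runif(ca[i], 0, 0.5)))
    sp_b <- unlist(lapply(seq_len(n_tr), function(i)
      events[i] - runif(cb[i], 0, 0.5)))
  })
  chunked <- noise_corr(list(sp_a, sp_b), events)$r_mean
  whole <- noise_corr_session(list(sp_a, sp_b), events)$r_mean
  expect_gt(whole - chunked, 0.1)
  # identical and anti-varying count series
  sp_c <- unlist(lapply(seq_len(n_tr), function(i)
    events[i] - seq_len(ifelse(i %% 2 == 0, 10, 2)) / 30))
  sp_d <- unlist(lapply(seq_len(n_tr), function(i)
    events[i] - seq_len(ifelse(i %% 2 == 0, 2, 10)) / 30))
  expect_equal(noise_corr(list(sp_c, sp_c), events)$r_mean, 1)
  expect_equal(noise_corr(list(sp_c, sp_d), events)$r_mean, -1)
  # independent units: near-zero mean r
  with_seed(65L, {
    sp_e <- unlist(lapply(seq_len(n_tr), function(i)
      events[i] - runif(rpois(1, 8), 0, 0.5)))
    sp_f <- unlist(lapply(seq_len(n_tr), function(i)
      events[i] - runif(rpois(1, 8), 0, 0.5)))
  })
  expect_lt(abs(noise_corr(list(sp_e, sp_f), events)$r_mean), 0.12)
  expect_error(noise_corr(list(sp_a, sp_b), events[1:5]), "full chunk")
})

test_that("attentional difference time courses flag real gain changes", {
  n_units <- 24L
  n_time <- 600L
  tgrid <- seq_len(n_time) / 1000 - 0.1
  with_seed(66L, {
    base_t <- matrix(rnorm(n_units * n_time, 0, 0.4), n_units)
    base_a <- matrix(rnorm(n_units * n_time, 0, 0.4), n_units)
  })
  # identical conditions: no significant bins
  r0 <- attn_difference_timecourse(base_t, base_a, n_rand = 400L, seed = 3L)
  expect_false(any(r0$mask))
  # gain from 150 ms after the event
  eff <- outer(rep(1, n_units), as.numeric(tgrid > 0.15))
  r1 <- attn_difference_timecourse(base_t + 0.8 * eff, base_a,
                                   n_rand = 400L, seed = 3L)
  expect_true(any(r1$mask))
  onset_1 <- tgrid[r1$onset_bin]
  expect_equal(onset_1, 0.15, tolerance = 0.08)
  # a later onset yields later first significant bins
  eff2 <- outer(rep(1, n_units), as.numeric(tgrid > 0.35))
  r2 <- attn_difference_timecourse(base_t + 0.8 * eff2, base_a,
                                   n_rand = 400L, seed = 3L)
  expect_gt(tgrid[r2$onset_bin], onset_1 + 0.1)
})

test_that("cross-correlation asymmetry detects a 50 ms lead", {
  fs <- 1000
  tgrid <- seq(0.05, 0.5, by = 1 / fs)
  ramp <- function(t0) 1 / (1 + exp(-(tgrid - t0) / 0.02))
  with_seed(67L, {
    early <- t(vapply(1:20, function(i)
      ramp(0.15) + rnorm(length(tgrid), 0, 0.3), numeric(length(tgrid))))
    late <- t(vapply(1:20, function(i)
      ramp(0.20) + rnorm(length(tgrid), 0, 0.3), numeric(length(tgrid))))
    same <- t(vapply(1:20, function(i)
      ramp(0.18) + rnorm(length(tgrid), 0, 0.3), numeric(length(tgrid))))
  })
  # identical populations: zero asymmetry by construction
  r_eq <- xcorr_asymmetry(early, early, fs, n_rand = 200L, seed = 4L)
  expect_equal(r_eq$asymmetry, 0, tolerance = 1e-10)
  # B = A delayed: with r(l) = <A(t) B(t+l)>, mass shifts to positive
  # lags, so the (negative-lag minus positive-lag) asymmetry is negative
  r_lead <- xcorr_asymmetry(early, late, fs, n_rand = 300L, seed = 4L)
  expect_lt(r_lead$asymmetry, 0)
  expect_lt(r_lead$p_empirical, 0.05)
  r_same <- xcorr_asymmetry(early, same, fs, n_rand = 300L, seed = 4L)
  expect_lt(abs(r_same$asymmetry), abs(r_lead$asymmetry))
  expect_error(xcorr_asymmetry(early[, 1:100], late[, 1:100], fs),
               "maximum lag")
})

test_that("AMI regression recovers exact linear structure", {
  with_seed(68L, {
    rate <- runif(30, 2, 20)
    layer <- rep(c("superficial", "granular", "deep"), 10)
  })
  flat <- suppressWarnings(ami_regression(rep(0.2, 30), rate, layer))
  expect_equal(unname(flat$coefficients["rate"]), 0, tolerance = 1e-10)
  expect_equal(unname(flat$coefficients["(Intercept)"]), 0.2)
  exact <- suppressWarnings(ami_regression(0.1 * rate, rate, layer))
  expect_equal(unname(exact$coefficients["rate"]), 0.1, tolerance = 1e-10)
  expect_equal(exact$r_squared, 1)
  # layer offsets are recovered through the contrasts
  offs <- c(deep = 0, granular = 0.1, superficial = 0.25)
  fit <- suppressWarnings(ami_regression(0.02 * rate + offs[layer], rate, layer))
  expect_equal(unname(fit$coefficients["layergranular"]), 0.1,
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["layersuperficial"]), 0.25,
               tolerance = 1e-10)
  expect_error(ami_regression(rep(0.1, 5), runif(5), rep("deep", 5)),
               "2 layers")
})
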