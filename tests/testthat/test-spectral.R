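# Multitaper estimation, LFP-LFP PPC, gamma-peak alignment, time-resolved
# PPC.

test_that("multitaper coefficients localize a grid-frequency tone", {
  fs <- 1000
  tone <- cos(2 * pi * 24 * (0:3999) / fs)
  ep <- tile_epochs(tone, fs, 0, 4)
  expect_equal(nrow(ep), 8L)
  co <- multitaper_coeffs(ep, fs)
  expect_equal(diff(co$freqs[1:2]), 2)           # 0.5 s -> 2 Hz resolution
  # the first (most concentrated) taper localizes the tone at its bin;
  # the multitaper average concentrates within the nw/T = 8 Hz band
  expect_equal(co$freqs[which.max(Mod(co$coef[1, 1, ]))], 24)
  mt <- apply(Mod(co$coef)^2, 3L, mean)
  expect_equal(co$freqs[which.max(mt)], 24, tolerance = 2)
  inband <- abs(co$freqs - 24) <= 8
  expect_gt(sum(mt[inband]) / sum(mt), 0.95)
  expect_error(multitaper_coeffs(ep[, 1:400, drop = FALSE], fs), "shorter")
})

test_that("power spectra scale quadratically and f^2 flattens 1/f^2", {
  fs <- 1000
  x <- with_seed(3L, rnorm(20000))
  ep <- tile_epochs(x, fs, 0, 20)
  p1 <- power_spectrum(multitaper_coeffs(ep, fs))
  p2 <- power_spectrum(multitaper_coeffs(2 * ep, fs))
  expect_equal(p2$power, 4 * p1$power, tolerance = 1e-12)
  expect_equal(power_spectrum(multitaper_coeffs(0 * ep, fs))$power,
               rep(0, length(p1$power)))
  # Brownian noise has a 1/f^2 spectrum; f^2 scaling flattens it
  br <- with_seed(4L, gammalock:::one_over_f_noise(60000L, exponent = 2))
  pb <- power_spectrum(multitaper_coeffs(tile_epochs(br, fs, 0, 60), fs),
                       f2_scale = TRUE)
  mid <- pb$freqs >= 20 & pb$freqs <= 200
  expect_lt(stats::sd(log10(pb$power[mid])), 0.25)
})

test_that("LFP-LFP PPC matches pair-average arithmetic", {
  # constant relative phase pi/2 -> PPC 1, mean phase pi/2
  ca <- coeffs_from_phases(rep(pi / 2, 5))
  cb <- coeffs_from_phases(rep(0, 5))
  r <- lfp_lfp_ppc(ca, cb)
  expect_equal(r$ppc, 1)
  expect_equal(r$mean_phase, pi / 2)
  # antipodal pair -> -1
  r2 <- lfp_lfp_ppc(coeffs_from_phases(c(0, pi)), coeffs_from_phases(c(0, 0)))
  expect_equal(r2$ppc, -1)
  # {0, 0, pi, pi} -> mean over the 6 pairs = -1/3
  r3 <- lfp_lfp_ppc(coeffs_from_phases(c(0, 0, pi, pi)),
                    coeffs_from_phases(rep(0, 4)))
  expect_equal(r3$ppc, -1 / 3)
  expect_error(lfp_lfp_ppc(coeffs_from_phases(0.3), coeffs_from_phases(0)),
               "2 epochs")
})

test_that("the O(n) PPC identity equals the brute-force pair average", {
  ph <- with_seed(8L, runif(60, -pi, pi))
  expect_equal(lfp_lfp_ppc(coeffs_from_phases(ph),
                           coeffs_from_phases(rep(0, 60)))$ppc,
               ppc_brute(ph), tolerance = 1e-12)
})

test_that("PPC of phase-shifted copies is 1; independent phases give ~0", {
  fs <- 1000
  x <- gamma_fixture(duration = 6)$x + 0.3 * with_seed(2L, rnorm(6000))
  ep <- tile_epochs(x, fs, 0, 6)
  co_a <- multitaper_coeffs(ep, fs)
  # a pure time shift is a per-frequency phase shift
  shift <- 5L
  ep_b <- tile_epochs(c(x[-seq_len(shift)], numeric(shift)), fs, 0, 6)
  co_b <- multitaper_coeffs(ep_b, fs)
  r <- lfp_lfp_ppc(co_a, co_b)
  powered <- co_a$freqs >= 54 & co_a$freqs <= 66   # where the rhythm has power
  expect_true(all(r$ppc[powered] > 0.9))
  # unbiasedness under independence: mean PPC over 200 null draws ~ 0,
  # while the squared resultant length stays positive-biased
  nulls <- with_seed(9L, vapply(1:200, function(i) {
    ph_a <- runif(12, -pi, pi); ph_b <- runif(12, -pi, pi)
    u <- exp(1i * (ph_a - ph_b))
    c(ppc = gammalock:::ppc_from_phasors(u), r2 = Mod(mean(u))^2)
  }, numeric(2)))
  expect_lt(abs(mean(nulls["ppc", ])), 0.01)
  expect_gt(mean(nulls["r2", ]), 0.05)
})

test_that("gamma-peak alignment superimposes session peaks at offset 0", {
  freqs <- seq(0, 200, by = 2)
  mk <- function(pk) list(freqs = freqs,
                          values = exp(-(freqs - pk)^2 / (2 * 16)))
  al <- align_to_gamma_peak(list(mk(44), mk(60)), search_band = c(20, 100))
  expect_equal(al$peaks, c(44, 60))
  expect_equal(al$offsets[apply(al$aligned, 1L, which.max)], c(0, 0))
  # single session: aligned peak at 0
  al1 <- align_to_gamma_peak(list(mk(52)))
  expect_equal(al1$offsets[which.max(al1$mean)], 0)
  # flat spectrum is flagged and excluded
  flat <- list(freqs = freqs, values = rep(1, length(freqs)))
  al2 <- align_to_gamma_peak(list(mk(60), flat))
  expect_true(al2$excluded[2])
  expect_error(align_to_gamma_peak(list(flat)), "no session")
})

test_that("time-resolved PPC tracks a coupling step within a window", {
  fs <- 1000
  n_tr <- 30L
  n_samp <- 1200L
  t0 <- 0.6                       # coupling switches on at 600 ms
  trials_a <- list(); trials_b <- list()
  with_seed(21L, {
    for (i in seq_len(n_tr)) {
      osc <- gammalock:::gamma_oscillation(n_samp, 60, 6, fs)
      pre <- gammalock:::gamma_oscillation(n_samp, 60, 6, fs)$x
      b <- c(pre[seq_len(t0 * fs)], osc$x[(t0 * fs + 1L):n_samp])
      trials_a[[i]] <- osc$x + 0.2 * rnorm(n_samp)
      trials_b[[i]] <- b + 0.2 * rnorm(n_samp)
    }
  })
  tf <- tf_lfp_ppc(trials_a, trials_b, fs, freqs = 60, step = 0.02)
  # +-2.5 cycles at 60 Hz ~ 42 ms half window: edges are masked
  expect_true(is.na(tf$ppc[1, 1]))
  pre_bins <- tf$times > 0.1 & tf$times < t0 - 0.06
  post_bins <- tf$times > t0 + 0.06 & tf$times < 1.1
  expect_lt(mean(tf$ppc[pre_bins, 1]), 0.2)
  expect_gt(mean(tf$ppc[post_bins, 1]), 0.6)
  # stationary coupled pair: flat high PPC
  tf2 <- tf_lfp_ppc(trials_b, trials_b, fs, freqs = 60, step = 0.05)
  ok <- !is.na(tf2$ppc[, 1])
  expect_true(all(tf2$ppc[ok, 1] > 0.99))
})
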