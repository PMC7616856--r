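# Referencing, bipolar derivation, band-pass + analytic phase, CSD,
# surrogate LFP, epoch selection.

test_that("shank re-referencing removes the common mode exactly", {
  geo <- grid_geometry(4L)
  n <- 200L
  common <- matrix(rep(sin(seq_len(n) / 10), each = 4L), 4L)
  expect_equal(shank_rereference(common, geo), matrix(0, 4L, n))
  # one channel carries signal s: it keeps 3/4 s, the others get -s/4
  s <- cos(seq_len(n) / 5)
  lfp <- rbind(s, matrix(0, 3L, n))
  out <- shank_rereference(lfp, geo)
  expect_equal(out[1, ], 0.75 * s)
  expect_equal(out[3, ], -0.25 * s)
  # idempotence
  expect_equal(shank_rereference(out, geo), out)
  expect_error(shank_rereference(matrix(0, 1L, 10L), grid_geometry(1L)),
               "fewer than 2")
})

test_that("bipolar derivation is deep-minus-shallow with n-1 channels", {
  geo <- grid_geometry(16L)
  n <- 100L
  common <- matrix(rep(rnorm(n), each = 16L), 16L)
  out <- bipolar_derive(common, geo)
  expect_equal(nrow(out$lfp), 15L)
  expect_equal(out$lfp, matrix(0, 15L, n))
  # linear depth gradient g per contact -> constant g
  grad <- outer(seq_len(16L) * 2.5, rep(1, n))
  expect_equal(bipolar_derive(grad, geo)$lfp, matrix(2.5, 15L, n))
  # derived channel inherits midpoint depth
  expect_equal(bipolar_derive(grad, geo)$geometry$depth_index[1], 1.5)
  bad <- geo; bad$depth_index <- rev(bad$depth_index)
  expect_error(bipolar_derive(grad, bad), "ordered")
})

test_that("re-reference then bipolar equals bipolar alone", {
  g <- small_session()$session
  geo <- g$geometry[g$geometry$area == "sender", ]
  lfp <- g$lfp[seq_len(nrow(geo)), 1:4000]
  direct <- bipolar_derive(lfp, geo)$lfp
  via_ref <- bipolar_derive(shank_rereference(lfp, geo), geo)$lfp
  expect_equal(via_ref, direct, tolerance = 1e-10)
})

test_that("band-pass + Hilbert gives zero-phase in-band analytic signals", {
  fs <- 1000
  t <- (0:9999) / fs
  tone <- cos(2 * pi * 60 * t)
  az <- bandpass_hilbert(tone, c(40, 90), fs)
  mid <- 1000:9000
  expect_equal(Mod(az$values[1, mid]), rep(1, length(mid)), tolerance = 0.01)
  dphi <- wrap_phase(diff(Arg(az$values[1, mid])))
  expect_equal(mean(dphi), 2 * pi * 60 / fs, tolerance = 1e-4)
  # zero group delay: in-band input and output peak-correlate at lag 0
  cc <- stats::ccf(Re(az$values[1, mid]), tone[mid], lag.max = 20,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # out-of-band attenuation > 20 dB
  slow <- cos(2 * pi * 5 * t)
  az5 <- bandpass_hilbert(slow, c(40, 90), fs)
  atten <- 20 * log10(stats::sd(Re(az5$values[1, mid])) / stats::sd(slow[mid]))
  expect_lt(atten, -20)
  expect_equal(bandpass_hilbert(numeric(100), c(40, 90), fs)$values,
               matrix(complex(real = 0), 1L, 100L), tolerance = 1e-12)
  expect_error(bandpass_hilbert(tone, c(40, 600), fs), "inside")
})

test_that("CSD is the second spatial difference with interpolation", {
  h <- 150
  depth <- (0:7) * h
  n_t <- 5L
  linear <- outer(3 + 0.01 * depth, rep(1, n_t))
  expect_equal(compute_csd(linear, h)$values, matrix(0, 6L, n_t))
  quad <- outer(2e-4 * depth^2, rep(1, n_t))
  expect_equal(compute_csd(quad, h)$values,
               matrix(2 * 2e-4, 6L, n_t))
  # Gaussian bump centred on channel 5 -> CSD extremum at channel 5
  bump <- outer(-exp(-((1:8) - 5)^2 / 2), rep(1, n_t))
  csd <- compute_csd(bump, h)
  expect_equal(csd$channels[which.max(abs(csd$values[, 1]))], 5L)
  # linearity
  a <- matrix(rnorm(8 * n_t), 8L); b <- matrix(rnorm(8 * n_t), 8L)
  expect_equal(compute_csd(a + 2 * b, h)$values,
               compute_csd(a, h)$values + 2 * compute_csd(b, h)$values)
  # bad-channel interpolation replaces the row before differencing
  bad <- linear; bad[4, ] <- 99
  fixed <- compute_csd(bad, h, bad_channels = 4L)
  expect_equal(fixed$values, matrix(0, 6L, n_t), tolerance = 1e-12)
  expect_true(fixed$interpolated[4])
  expect_error(compute_csd(bad, h, bad_channels = 1L), "edge")
})

test_that("surrogate LFP enforces the unit-count rule and carries rhythm", {
  expect_error(surrogate_lfp(rep(list(c(0.1, 0.2)), 9L)), ">= 10 units")
  expect_silent(surrogate_lfp(rep(list(c(0.1, 0.2)), 9L), override = TRUE))
  expect_equal(surrogate_lfp(rep(list(numeric(0)), 12L), duration = 1),
               numeric(1000))
  # population spiking modulated at 60 Hz -> sLFP spectrum peaks at 60 Hz
  fs <- 1000
  osc <- gamma_fixture(duration = 20)
  trains <- lapply(1:12, function(j) {
    gen_spikes_phase_locked(osc$phase, fs, 8, 1.5, 0, seed = 100L + j)
  })
  slfp <- surrogate_lfp(trains, fs = fs, duration = 20)
  ep <- tile_epochs(slfp, fs, 0.5, 19.5)
  pw <- power_spectrum(multitaper_coeffs(ep, fs))
  band <- pw$freqs >= 30 & pw$freqs <= 100
  expect_equal(pw$freqs[band][which.max(pw$power[band])], 60, tolerance = 5)
})

test_that("epoch selection is half-open and event-relative", {
  expect_equal(select_epoch(c(9.2, 9.8, 10.3), 10, c(-1, 0)),
               c(-0.8, -0.2))
  expect_length(select_epoch(c(1, 2), 1.5, c(0, 0)), 0L)
  # spike exactly at event + w1 is excluded
  expect_equal(select_epoch(c(2.0), 1.0, c(0, 1)), numeric(0))
  expect_equal(select_epoch(c(1.999), 1.0, c(0, 1)), 0.999)
  x <- seq_len(1000)
  seg <- select_epoch(x, 0.5, c(0, 0.2), fs = 1000, type = "series")
  expect_length(seg, 200L)
  expect_equal(seg[1], x[501])
  expect_error(select_epoch(x, 0.95, c(0, 0.2), fs = 1000, type = "series"),
               "exceeds")
})
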