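# Trial features, likelihood fitting, naive-Bayes decoding, jackknife
# accuracy, population curves, error correlations.

test_that("trial PLV and relative phase follow their closed forms", {
  n <- 1000
  t <- seq_len(n)
  z <- exp(1i * (0.3 + 2 * pi * 0.06 * t))
  expect_equal(trial_plv(z, z), 1)
  expect_equal(trial_plv(z * exp(1i * pi / 2), z), 1)   # fixed offset
  expect_equal(trial_relphase(z * exp(1i * pi / 3), z), pi / 3)
  # alternating +-delta offsets cancel
  off <- rep(c(0.4, -0.4), n / 2)
  expect_equal(trial_relphase(z * exp(1i * off), z), 0, tolerance = 1e-10)
  # offset drifting linearly 0 -> pi at constant amplitude: the averaged
  # phasor is (1/pi) * integral of exp(i theta) = 2i/pi, angle pi/2
  drift <- seq(0, pi, length.out = n)
  expect_equal(trial_relphase(z * exp(1i * drift), z), pi / 2,
               tolerance = 0.01)
  # independent random-walk phases decorrelate: PLV well below 1
  with_seed(51L, {
    za <- exp(1i * cumsum(rnorm(n, 0, 0.3)))
    zb <- exp(1i * cumsum(rnorm(n, 0, 0.3)))
  })
  expect_lt(trial_plv(za, zb), 0.5)
  expect_error(trial_plv(complex(0), complex(0)), "empty")
})

test_that("trial spike-field PPC handles degenerate spike sets", {
  fs <- 1000
  az <- bandpass_hilbert(cos(2 * pi * 60 * (0:1999) / fs), c(40, 90), fs)
  period <- 1 / 60
  locked <- 0.5 + period * (0:20)
  expect_gt(trial_spikefield_ppc(az, locked), 0.95)
  expect_true(is.na(trial_spikefield_ppc(az, 0.5)))
  anti <- c(0.5, 0.5 + period / 2)
  expect_lt(trial_spikefield_ppc(az, anti), -0.9)
  unif <- with_seed(52L, runif(100, 0.3, 1.7))
  expect_lt(abs(trial_spikefield_ppc(az, unif)), 0.1)
})

test_that("likelihood families are fitted as stated", {
  expect_equal(fit_likelihood(c(4, 6, 5, 5), "poisson")$lambda, 5)
  vm <- fit_likelihood(rep(0.8, 10), "vonmises")
  expect_equal(vm$mu, 0.8)
  expect_equal(vm$kappa, 1e3)            # degenerate concentration capped
  expect_true(vm$degenerate)
  gs <- fit_likelihood(c(1, 1, 1), "gaussian")
  expect_true(gs$degenerate)
  expect_gt(gs$sigma, 0)
  # von Mises ML on a real sample recovers mu and kappa
  ph <- with_seed(53L, gammalock:::rvonmises(4000, 0.5, 2))
  vm2 <- fit_likelihood(ph, "vonmises")
  expect_equal(vm2$mu, 0.5, tolerance = 0.05)
  expect_equal(vm2$kappa, 2, tolerance = 0.15)
  expect_error(fit_likelihood(3, "poisson"), "2 training values")
})

test_that("per-trial posteriors are normalized, order-invariant and sane", {
  mk <- function(lam) list(lambda = lam, family = "poisson",
                           degenerate = FALSE)
  model <- list(toward = list(mk(8), mk(6)), away = list(mk(4), mk(3)))
  d <- decode_trial(model, c(8, 6))
  expect_equal(sum(d$posterior), 1, tolerance = 1e-12)
  expect_gt(d$posterior["toward"], 0.5)
  expect_equal(d$predicted, "toward")
  # signal order does not change the posterior
  model_r <- list(toward = list(mk(6), mk(8)), away = list(mk(3), mk(4)))
  expect_equal(decode_trial(model_r, c(6, 8))$posterior, d$posterior)
  # identical parameters: uniform posterior
  model_e <- list(toward = list(mk(5)), away = list(mk(5)))
  expect_equal(unname(decode_trial(model_e, 5)$posterior), c(0.5, 0.5))
  # angular symmetry
  vmm <- function(mu) list(mu = mu, kappa = 2, family = "vonmises",
                           degenerate = FALSE)
  mv <- list(toward = list(vmm(0)), away = list(vmm(pi)))
  expect_equal(decode_trial(mv, 0)$predicted, "toward")
})

test_that("jackknife accuracy separates what is separable", {
  feats <- c(0, 1, 0, 1, 20, 21, 20, 21)
  labels <- rep(c("away", "toward"), each = 4L)
  expect_equal(loo_accuracy(feats, labels, "poisson")$accuracy, 1)
  expect_error(loo_accuracy(feats[1:5], labels[1:5], "poisson"),
               "at least 2 trials")
  # label-independent features decode at chance (within binomial CI)
  with_seed(54L, {
    f <- rpois(200, 6)
    l <- rep(c("toward", "away"), 100)
  })
  acc <- loo_accuracy(f, l, "poisson", seed = 3L)$accuracy
  expect_gt(acc, 0.5 - 1.96 * sqrt(0.25 / 200))
  expect_lt(acc, 0.5 + 1.96 * sqrt(0.25 / 200))
})

test_that("population curves interpolate between single-cell and full", {
  with_seed(55L, {
    n_tr <- 120L
    labels <- rep(c("toward", "away"), n_tr / 2)
    lam <- ifelse(labels == "toward", 8, 5)
    feats <- vapply(1:4, function(j) rpois(n_tr, lam), numeric(n_tr))
  })
  curve <- accuracy_vs_ncells(feats, labels, n_range = c(1L, 4L),
                              n_subsamples = 4L, seed = 5L)
  full <- loo_accuracy(feats, labels, seed = gammalock:::child_seed(5L, 1L))
  expect_equal(curve$accuracy[curve$n == 4], full$accuracy)
  expect_gte(curve$accuracy[curve$n == 4], curve$accuracy[curve$n == 1])
  expect_warning(
    accuracy_vs_ncells(feats, labels, n_range = c(2L, 9L),
                       n_subsamples = 2L, seed = 5L), "skipping")
})

test_that("decoding-error correlations behave at the extremes", {
  e1 <- c(0, 1, 0, 1, 1, 0, 0, 1, 1, 0)
  r <- trial_error_correlation(e1, e1, seed = 6L)
  expect_equal(r$rho, 1)
  expect_lt(r$p_empirical, 0.05)
  expect_equal(trial_error_correlation(e1, 1 - e1, seed = 6L)$rho, -1)
  with_seed(56L, {
    a <- rbinom(500, 1, 0.5); b <- rbinom(500, 1, 0.5)
  })
  rn <- trial_error_correlation(a, b, seed = 7L)
  expect_lt(abs(rn$rho), 1.96 / sqrt(500) * 1.5)
  expect_error(trial_error_correlation(rep(0, 5), e1[1:5]), "constant")
})
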