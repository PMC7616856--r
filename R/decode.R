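# Maximum-likelihood (naive Bayes) decoding of the attention condition.
#
# Per-trial features (spike counts, LFP-LFP phase-locking value, LFP-LFP
# relative phase, within-trial spike-field PPC, or spike phase) are
# modelled per signal and condition with a Poisson (counts), Gaussian
# (non-angular) or von Mises (angular) likelihood, combined across signals
# as a product with a flat prior, and evaluated in a leave-one-trial-out
# jackknife. The decoding epoch in the task analyses is the 1 s preceding
# the first luminance-change event.

#' Trial-wise phase-locking value between two analytic signals
#'
#' `PLV = |mean(exp(i (phi_a - phi_b)))|` over the samples of the epoch;
#' invariant to a fixed phase offset.
#'
#' @param za,zb Complex vectors (analytic-signal samples of the epoch).
#' @return PLV in `[0, 1]`.
#' @export
trial_plv <- function(za, zb) {
  stopifnot(length(za) == length(zb))
  if (length(za) == 0L) stop("empty epoch")
  Mod(mean(exp(1i * (Arg(za) - Arg(zb)))))
}

#' Trial-wise relative phase between two analytic signals
#'
#' Angle of the time-averaged conjugate product `mean(za * Conj(zb))`.
#'
#' @inheritParams trial_plv
#' @return Relative phase in `(-pi, pi]`; `NA` (with a warning) if the
#'   averaged product has zero amplitude.
#' @export
trial_relphase <- function(za, zb) {
  stopifnot(length(za) == length(zb))
  if (length(za) == 0L) stop("empty epoch")
  m <- mean(za * Conj(zb))
  if (Mod(m) < .Machine$double.eps) {
    warning("zero-amplitude epoch: relative phase undefined")
    return(NA_real_)
  }
  Arg(m)
}

#' Trial-wise spike-field PPC of pooled spikes
#'
#' All-pairs PPC of the analytic phases of an LFP at the spike times
#' occurring within one trial epoch, with spikes pooled across
#' simultaneously recorded units.
#'
#' @param analytic An `analytic_signal` (single channel used: row 1).
#' @param spikes Pooled spike times (s, relative to the first sample).
#' @param t0 Time of the first sample.
#' @return PPC value, or `NA` when fewer than 2 spikes fall in range.
#' @export
trial_spikefield_ppc <- function(analytic, spikes, t0 = 0) {
  stopifnot(inherits(analytic, "analytic_signal"))
  idx <- round((spikes - t0) * analytic$fs) + 1L
  idx <- idx[idx >= 1L & idx <= ncol(analytic$values)]
  if (length(idx) < 2L) return(NA_real_)
  u <- exp(1i * Arg(analytic$values[1L, idx]))
  ppc_from_phasors(u)
}

#' Fit a per-condition likelihood family
#'
#' @param values Training feature values of one signal and condition.
#' @param family `"poisson"` (spike counts: lambda = sample mean),
#'   `"gaussian"` (non-angular: mean and SD), or `"vonmises"` (angular:
#'   circular mean and ML concentration).
#' @param sigma_floor Lower bound on the Gaussian SD, as a fraction of
#'   `max(1, |mu|)` (default 1e-6).
#' @param kappa_max Concentration cap for degenerate angular samples.
#' @return List of parameters (`lambda`, or `mu`/`sigma`, or `mu`/`kappa`)
#'   plus `family` and a `degenerate` flag.
#' @export
fit_likelihood <- function(values, family = c("poisson", "gaussian", "vonmises"),
                           sigma_floor = 1e-6, kappa_max = 1e3) {
  family <- match.arg(family)
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("at least 2 training values are required")
  degenerate <- FALSE
  out <- switch(family,
    poisson = {
      if (any(values < 0)) stop("Poisson features must be non-negative")
      list(lambda = mean(values))
    },
    gaussian = {
      mu <- mean(values); s <- stats::sd(values)
      floor_s <- sigma_floor * max(1, abs(mu))
      if (!is.finite(s) || s < floor_s) { s <- floor_s; degenerate <- TRUE }
      list(mu = mu, sigma = s)
    },
    vonmises = {
      r <- circ_r(values)
      k <- vm_kappa_from_r(r, kappa_max = kappa_max)
      if (k >= kappa_max) degenerate <- TRUE
      mu <- circ_mean(values)
      if (is.na(mu)) { mu <- 0; k <- 0 }
      list(mu = mu, kappa = k)
    })
  c(out, list(family = family, degenerate = degenerate))
}

## Log-likelihood of observations under a fitted family.
loglik_value <- function(x, fit) {
  switch(fit$family,
    poisson = {
      if (fit$lambda <= 0) {
        ifelse(x == 0, 0, -Inf)
      } else {
        stats::dpois(round(x), fit$lambda, log = TRUE)
      }
    },
    gaussian = stats::dnorm(x, fit$mu, fit$sigma, log = TRUE),
    vonmises = {
      fit$kappa * cos(x - fit$mu) - log(2 * pi) -
        (log(besselI(fit$kappa, 0, expon.scaled = TRUE)) + fit$kappa)
    })
}

#' Posterior over conditions for one trial
#'
#' Combines per-signal likelihoods as a product (sum of log-likelihoods)
#' with a flat prior and normalizes. Ties in the posterior are broken by a
#' seeded coin flip.
#'
#' @param model List: per condition, a list of per-signal fitted
#'   likelihoods (from [fit_likelihood()]).
#' @param features Numeric vector, one value per signal.
#' @param tie_seed Seed for tie-breaking.
#' @return List with `posterior` (named, sums to 1), `predicted`,
#'   `uninformative` flag (all likelihoods vanished).
#' @export
decode_trial <- function(model, features, tie_seed = 1L) {
  conds <- names(model)
  ll <- vapply(conds, function(cd) {
    fits <- model[[cd]]
    sum(vapply(seq_along(fits), function(i) {
      if (!is.finite(features[i])) return(0)  # missing signal: no evidence
      loglik_value(features[i], fits[[i]])
    }, numeric(1)))
  }, numeric(1))
  uninformative <- all(!is.finite(ll))
  if (uninformative) {
    post <- rep(1 / length(conds), length(conds))
  } else {
    ll[!is.finite(ll)] <- -Inf
    m <- max(ll)
    post <- exp(ll - m)
    post <- post / sum(post)
  }
  names(post) <- conds
  pred <- if (abs(post[1] - post[2]) < 1e-12) {
    with_seed(tie_seed, sample(conds, 1L))
  } else {
    conds[which.max(post)]
  }
  list(posterior = post, predicted = pred, uninformative = uninformative)
}

## Fit the per-condition, per-signal model on a training subset.
fit_decoder <- function(features, labels, family, rows) {
  conds <- levels(factor(labels))
  stats::setNames(lapply(conds, function(cd) {
    idx <- rows[labels[rows] == cd]
    lapply(seq_len(ncol(features)), function(j) {
      fit_likelihood(features[idx, j], family = family)
    })
  }), conds)
}

#' Leave-one-trial-out jackknife decoding accuracy
#'
#' For every trial the decoder is refit on all other trials and the held
#' out trial is decoded; accuracy is the fraction of correct predictions.
#'
#' @param features Trials x signals numeric matrix (or vector for one
#'   signal).
#' @param labels Condition label per trial (two levels).
#' @param family Likelihood family passed to [fit_likelihood()].
#' @param seed Seed for posterior tie-breaking.
#' @return List with `accuracy`, per-trial `errors` (0/1), `predicted`,
#'   and `posteriors` (trials x conditions).
#' @export
loo_accuracy <- function(features, labels, family = "poisson", seed = 1L) {
  if (is.null(dim(features))) features <- matrix(features, ncol = 1L)
  labels <- as.character(labels)
  conds <- levels(factor(labels))
  if (length(conds) != 2L) stop("two condition labels are required")
  if (any(table(labels) < 2L)) stop("each condition needs at least 2 trials")
  n_tr <- nrow(features)
  post <- matrix(NA_real_, n_tr, 2L, dimnames = list(NULL, conds))
  pred <- character(n_tr)
  for (t in seq_len(n_tr)) {
    rows <- setdiff(seq_len(n_tr), t)
    model <- fit_decoder(features, labels, family, rows)
    dec <- decode_trial(model, features[t, ],
                        tie_seed = child_seed(seed, t))
    post[t, ] <- dec$posterior
    pred[t] <- dec$predicted
  }
  errors <- as.integer(pred != labels)
  list(accuracy = 1 - mean(errors), errors = errors, predicted = pred,
       posteriors = post, n_trials = n_tr)
}

#' Decoding accuracy as a function of population size
#'
#' For each `n` in `n_range`, draws `n_subsamples` random subsets of `n`
#' signals, decodes with the product-of-posteriors population rule, and
#' averages the jackknife accuracies.
#'
#' @inheritParams loo_accuracy
#' @param n_range Population sizes to evaluate.
#' @param n_subsamples Random subsets per size (default 50).
#' @param seed Integer seed for subsampling and tie-breaking.
#' @return Data frame with `n`, `accuracy` (mean over subsets), `sd`.
#' @export
accuracy_vs_ncells <- function(features, labels, family = "poisson",
                               n_range = NULL, n_subsamples = 50L,
                               seed = 1L) {
  if (is.null(dim(features))) features <- matrix(features, ncol = 1L)
  n_sig <- ncol(features)
  if (is.null(n_range)) n_range <- seq_len(n_sig)
  n_range <- n_range[n_range >= 1L]
  skipped <- n_range[n_range > n_sig]
  if (length(skipped)) {
    warning("skipping n > population size: ", paste(skipped, collapse = ", "))
    n_range <- n_range[n_range <= n_sig]
  }
  res <- lapply(seq_along(n_range), function(k) {
    n <- n_range[k]
    subs <- with_seed(child_seed(seed, paste0("sub", n)), {
      lapply(seq_len(if (n == n_sig) 1L else n_subsamples),
             function(r) sort(sample.int(n_sig, n)))
    })
    acc <- vapply(seq_along(subs), function(r) {
      loo_accuracy(features[, subs[[r]], drop = FALSE], labels,
                   family = family, seed = child_seed(seed, r))$accuracy
    }, numeric(1))
    data.frame(n = n, accuracy = mean(acc), sd = stats::sd(acc))
  })
  do.call(rbind, res)
}

#' Trial-wise co-fluctuation of decoding errors
#'
#' Spearman correlation between a single-signal error sequence and a
#' population-level error sequence over shared trials, with a shuffle
#' test for significance.
#'
#' @param su_errors,population_errors Binary (0/1) error vectors on a
#'   shared trial index.
#' @param n_rand,seed Shuffle-test parameters.
#' @return [shuffle_correlation_test()] result.
#' @export
trial_error_correlation <- function(su_errors, population_errors,
                                    n_rand = 1000L, seed = 1L) {
  stopifnot(length(su_errors) == length(population_errors))
  if (stats::sd(su_errors) == 0 || stats::sd(population_errors) == 0) {
    stop("decoding-error sequence is constant; correlation undefined")
  }
  shuffle_correlation_test(su_errors, population_errors,
                           n_rand = n_rand, seed = seed)
}
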