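# Waveform normalization and exclusion, broad/narrow-waveform (BW/NW)
# classification via a 2-D t-SNE embedding followed by fuzzy c-means,
# laminar compartment assignment from CSD + spike-sign log-ratios,
# opto-tag latency classification, and behavioural-state detection.

#' Normalize a mean spike waveform
#'
#' Subtracts the offset (median of the pooled first 10 and last 10
#' samples) and scales to unit energy (L2 norm), making downstream
#' classification invariant to amplitude and DC offset.
#'
#' @param trace Numeric voltage trace (>= 20 samples).
#' @return Normalized trace.
#' @export
normalize_waveform <- function(trace) {
  if (length(trace) < 20L) stop("waveform must have at least 20 samples")
  off <- stats::median(c(utils::head(trace, 10L), utils::tail(trace, 10L)))
  w <- trace - off
  e <- sqrt(sum(w^2))
  if (e == 0) stop("all-zero waveform cannot be normalized")
  w / e
}

#' Exclude contaminated waveforms
#'
#' Discards triphasic waveforms (a stronger positive peak before than
#' after the trough) and waveforms with a DC difference between their
#' beginning and end segments.
#'
#' @param traces Units x samples matrix of normalized waveforms.
#' @param dc_tol DC threshold on `|mean(first 10) - mean(last 10)|`;
#'   `NULL` (default) uses 3x the population SD of that difference.
#' @return List with `keep` (logical), `reason` (character, `""` if
#'   kept), `dc_tol`.
#' @export
exclude_waveforms <- function(traces, dc_tol = NULL) {
  stopifnot(is.matrix(traces))
  n <- ncol(traces)
  dc <- apply(traces, 1L, function(w) {
    mean(w[seq_len(10L)]) - mean(w[(n - 9L):n])
  })
  if (is.null(dc_tol)) dc_tol <- 3 * stats::sd(dc)
  reason <- rep("", nrow(traces))
  for (i in seq_len(nrow(traces))) {
    w <- traces[i, ]
    trough <- which.min(w)
    pre_peak <- if (trough > 1L) max(w[seq_len(trough - 1L)], 0) else 0
    post_peak <- if (trough < n) max(w[(trough + 1L):n], 0) else 0
    if (pre_peak > post_peak && pre_peak > 0) {
      reason[i] <- "triphasic"
    } else if (abs(dc[i]) > dc_tol) {
      reason[i] <- "DC"
    }
  }
  list(keep = reason == "", reason = reason, dc_tol = dc_tol)
}

#' Trough-to-peak duration of a waveform
#'
#' Time from the global trough to the subsequent positive peak.
#'
#' @param trace Waveform samples.
#' @param fs_wave Waveform sampling rate, Hz (default 30000).
#' @return Duration in milliseconds (`NA` if no post-trough peak).
#' @export
trough_to_peak <- function(trace, fs_wave = 30000) {
  trough <- which.min(trace)
  if (trough >= length(trace)) return(NA_real_)
  post <- trace[(trough + 1L):length(trace)]
  (which.max(post)) / fs_wave * 1000
}

## Minimal exact t-SNE (O(n^2)), sufficient for waveform banks of a few
## hundred units. Deterministic given the seed.
tsne_embed <- function(x, perplexity = 30, n_iter = 500L, seed = 1L) {
  n <- nrow(x)
  if (n < 4L) stop("too few points for a t-SNE embedding")
  if (3 * perplexity > n - 1) {
    perplexity <- max(2, floor((n - 1) / 3))
    warning("perplexity reduced to ", perplexity, " for ", n, " points")
  }
  d2 <- as.matrix(stats::dist(x))^2
  if (max(d2) == 0) stop("degenerate embedding: all points identical")
  # per-point precision by binary search on the target entropy
  P <- matrix(0, n, n)
  target <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { beta <- beta / 2; next }
      p <- p / sp
      h <- -sum(ifelse(p > 0, p * log(p), 0))
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2L)
    vel <- matrix(0, n, 2L)
    eta <- 100
    for (it in seq_len(n_iter)) {
      ex <- if (it <= 100L) 4 else 1           # early exaggeration
      momentum <- if (it <= 250L) 0.5 else 0.8
      yd2 <- as.matrix(stats::dist(y))^2
      num <- 1 / (1 + yd2); diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (ex * P - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% y
      vel <- momentum * vel - eta * grad
      y <- y + vel
      y <- sweep(y, 2L, colMeans(y))
    }
    y
  })
}

#' Classify units into broad- and narrow-waveform classes
#'
#' Embeds the normalized waveforms in two dimensions with t-SNE
#' (perplexity 30) and clusters the embedding with fuzzy c-means
#' (2 clusters, fuzzifier 2, Euclidean distance, tolerance 1e-10). Hard
#' labels are the maximal-membership cluster; cluster identity is mapped
#' to NW/BW by mean trough-to-peak duration (shorter = NW).
#'
#' @param traces Units x samples matrix of normalized waveforms.
#' @param perplexity t-SNE perplexity (default 30; auto-reduced with a
#'   warning for small banks).
#' @param fuzzifier Fuzzy c-means fuzzifier m (default 2).
#' @param tol Fuzzy c-means convergence tolerance (default 1e-10).
#' @param fs_wave Waveform sampling rate, Hz.
#' @param seed Integer seed (embedding init and clustering are seeded).
#' @return List with `class` (per unit: "NW"/"BW"), `membership`
#'   (units x 2, rows sum to 1, columns named), `embedding` (units x 2),
#'   `trough_to_peak_ms`, `separated` (bimodality sanity flag).
#' @export
classify_bw_nw <- function(traces, perplexity = 30, fuzzifier = 2,
                           tol = 1e-10, fs_wave = 30000, seed = 1L) {
  stopifnot(is.matrix(traces))
  emb <- tsne_embed(traces, perplexity = perplexity, seed = seed)
  cm <- with_seed(child_seed(seed, "cmeans"), {
    e1071::cmeans(emb, centers = 2L, m = fuzzifier,
                  dist = "euclidean", method = "cmeans",
                  control = list(reltol = tol))
  })
  hard <- apply(cm$membership, 1L, which.max)
  ttp <- apply(traces, 1L, trough_to_peak, fs_wave = fs_wave)
  mean_ttp <- vapply(1:2, function(k) mean(ttp[hard == k]), numeric(1))
  nw_cluster <- which.min(mean_ttp)
  cls <- ifelse(hard == nw_cluster, "NW", "BW")
  membership <- cm$membership[, c(nw_cluster, setdiff(1:2, nw_cluster))]
  colnames(membership) <- c("NW", "BW")
  # separation sanity check: the clusters must be apart in the embedding
  # AND differ in trough-to-peak duration beyond the within-cluster
  # spread, otherwise a unimodal bank has merely been split in half
  ctr <- cm$centers
  spread <- mean(vapply(1:2, function(k) {
    mean(sqrt(rowSums(sweep(emb[hard == k, , drop = FALSE], 2L, ctr[k, ])^2)))
  }, numeric(1)))
  sep <- sqrt(sum((ctr[1, ] - ctr[2, ])^2)) / max(spread, 1e-12)
  ttp_sd <- sqrt(mean(vapply(1:2, function(k) {
    stats::var(ttp[hard == k])
  }, numeric(1))))
  ttp_gap <- abs(diff(mean_ttp)) / max(ttp_sd, 1e-9)
  list(class = cls, membership = membership, embedding = emb,
       trough_to_peak_ms = ttp, separated = sep > 2 && ttp_gap > 3,
       separation = sep, ttp_gap = ttp_gap)
}

#' Assign laminar compartments from CSD and spike-sign log-ratios
#'
#' Contacts are first split by the log-ratio of positive to negative
#' spike counts: near zero = outside the brain, positive = white matter,
#' negative = gray matter. Within gray matter, the contact with the
#' strongest early current sink anchors the granular compartment;
#' contacts above the granular block are superficial, below it deep.
#'
#' @param csd A `csd_profile` for the shank (from [compute_csd()]).
#' @param spike_sign_counts Data frame with `positive` and `negative`
#'   counts, one row per contact of the shank (same order as the CSD
#'   input LFP).
#' @param log_ratio_tol Half-width of the "outside" band on the
#'   log-ratio (default 0.5).
#' @param sink_window Column range of `csd$values` searched for the sink
#'   (default all).
#' @param granular_halfwidth Contacts on each side of the anchor included
#'   in the granular compartment (default 1).
#' @return List with `compartment` (per contact), `anchor` (granular
#'   anchor contact index), `log_ratio`, `thresholds`.
#' @export
assign_layers <- function(csd, spike_sign_counts, log_ratio_tol = 0.5,
                          sink_window = NULL, granular_halfwidth = 1L) {
  stopifnot(inherits(csd, "csd_profile"))
  n_ch <- length(csd$interpolated)
  stopifnot(nrow(spike_sign_counts) == n_ch)
  lr <- log((spike_sign_counts$positive + 0.5) /
              (spike_sign_counts$negative + 0.5))
  comp <- rep(NA_character_, n_ch)
  comp[abs(lr) <= log_ratio_tol] <- "outside"
  comp[lr > log_ratio_tol] <- "white_matter"
  gray <- which(lr < -log_ratio_tol)
  vals <- csd$values
  if (!is.null(sink_window)) vals <- vals[, sink_window, drop = FALSE]
  # sink = most negative CSD among gray-matter interior contacts
  interior_gray <- csd$channels %in% gray
  if (!any(interior_gray)) {
    warning("no gray-matter contact available for sink detection")
    return(list(compartment = comp, anchor = NA_integer_, log_ratio = lr,
                thresholds = log_ratio_tol))
  }
  # strongest evoked CSD extremum (the sink, up to the sign convention of
  # the plain second spatial derivative)
  sink_strength <- apply(abs(vals), 1L, max)
  cand <- which(interior_gray)
  anchor <- csd$channels[cand[which.max(sink_strength[cand])]]
  gran <- intersect(gray, (anchor - granular_halfwidth):(anchor + granular_halfwidth))
  comp[gran] <- "granular"
  comp[setdiff(gray[gray < min(gran)], gran)] <- "superficial"
  comp[setdiff(gray[gray > max(gran)], gran)] <- "deep"
  list(compartment = comp, anchor = anchor, log_ratio = lr,
       thresholds = log_ratio_tol)
}

## Default significance test for opto responses: two-sided Poisson rate
## test of the post-pulse count against the pre-pulse baseline
## expectation. Windows are kept shorter than typical pulse spacing so
## neighbouring pulses do not contaminate the baseline; a ZETA-style
## test over the full 0.5 s window can be plugged in instead.
default_opto_test <- function(spikes, pulses, response_window = 0.1,
                              baseline_window = c(-0.1, 0)) {
  n_resp <- sum(vapply(pulses, function(p) {
    sum(spikes >= p & spikes < p + response_window)
  }, numeric(1)))
  base_counts <- vapply(pulses, function(p) {
    sum(spikes >= p + baseline_window[1] & spikes < p + baseline_window[2])
  }, numeric(1))
  base_rate <- sum(base_counts) / (length(pulses) * diff(baseline_window))
  expected <- max(base_rate * response_window * length(pulses), 1e-6)
  stats::poisson.test(n_resp, T = 1, r = expected)$p.value
}

#' Opto-tag classification by response latency
#'
#' A unit is tagged when (1) the pluggable significance test finds its
#' firing significantly modulated in the 0.5 s window after pulse onset
#' and (2) its peak latency falls within the 10 ms stimulation pulse.
#' Units with peaks earlier than 1 ms are discarded as light artifacts.
#'
#' @param spikes Spike times, seconds.
#' @param pulses Pulse onset times, seconds.
#' @param sig_test Function `(spikes, pulses) -> p-value` (default: a
#'   Poisson rate test on the 10 ms response window vs. baseline).
#' @param alpha Significance level (default 0.05).
#' @param latency_bin Peak-latency histogram bin width, s (default 2.5e-4).
#' @return List with `tagged`, `significant`, `peak_latency` (s),
#'   `artifact` (peak < 1 ms), `p_value`.
#' @export
optotag <- function(spikes, pulses, sig_test = NULL, alpha = 0.05,
                    latency_bin = 2.5e-4) {
  if (!length(pulses)) stop("no optogenetic pulses supplied")
  if (is.null(sig_test)) sig_test <- default_opto_test
  p <- sig_test(spikes, pulses)
  # instantaneous peak latency from the pulse-aligned histogram (0-20 ms)
  rel <- unlist(lapply(pulses, function(pu) {
    s <- spikes[spikes >= pu & spikes < pu + 0.02] - pu
  }))
  if (!length(rel)) {
    return(list(tagged = FALSE, significant = p < alpha,
                peak_latency = NA_real_, artifact = FALSE, p_value = p))
  }
  h <- tabulate(floor(rel / latency_bin) + 1L, nbins = ceiling(0.02 / latency_bin))
  peak <- (which.max(h) - 0.5) * latency_bin
  artifact <- peak <= 0.001
  tagged <- (p < alpha) && !artifact && peak <= 0.010
  list(tagged = tagged, significant = p < alpha, peak_latency = peak,
       artifact = artifact, p_value = p)
}

#' Behavioural-state labels from pupil and running speed
#'
#' Pupil diameter is normalized by its session maximum; samples with
#' values in (0.65, 0.95) are labelled high arousal and in (0.3, 0.55)
#' low arousal. Locomotion is high above 5 cm/s and low below 1 cm/s.
#' Samples between bands stay unlabelled (`NA`).
#'
#' @param pupil Pupil diameter trace (arbitrary units, positive max).
#' @param speed Running speed trace, cm/s.
#' @param arousal_high,arousal_low Normalized-pupil bands.
#' @param speed_high,speed_low Speed thresholds, cm/s.
#' @return List with `arousal` and `locomotion` label vectors
#'   (`"high"`/`"low"`/`NA`), and `pupil_norm`.
#' @export
detect_state <- function(pupil, speed,
                         arousal_high = c(0.65, 0.95),
                         arousal_low = c(0.3, 0.55),
                         speed_high = 5, speed_low = 1) {
  mx <- max(pupil, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("pupil maximum must be positive")
  pn <- pupil / mx
  arousal <- rep(NA_character_, length(pupil))
  arousal[pn >= arousal_high[1] & pn <= arousal_high[2]] <- "high"
  arousal[pn >= arousal_low[1] & pn <= arousal_low[2]] <- "low"
  locomotion <- rep(NA_character_, length(speed))
  locomotion[speed > speed_high] <- "high"
  locomotion[speed < speed_low] <- "low"
  list(arousal = arousal, locomotion = locomotion, pupil_norm = pn)
}
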