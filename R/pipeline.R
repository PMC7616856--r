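# End-to-end orchestration: run the analysis stages on a session
# (synthetic or user-supplied in the same layout), collect tidy result
# tables, optionally write them as CSV plus a JSON run log.

#' Run the full analysis pipeline on a session
#'
#' Executes the requested stages and returns their results in one list.
#' Stages: `"cellclass"` (waveform classification + laminar assignment),
#' `"spectral"` (multitaper power and LFP-LFP PPC with gamma peak),
#' `"spikefield"` (per-unit PPC1 spectra by condition, class summaries),
#' `"rates"` (AMI, drivenness), `"decode"` (per-modality jackknife
#' accuracies), `"connectivity"` (sender/receiver Granger causality with
#' time-reversal control). Stages whose inputs are missing are skipped
#' with a reason in the log.
#'
#' @param session A session list (see [gen_session()]).
#' @param stages Character vector of stages to run.
#' @param gamma_band Band for phase extraction, Hz (default `c(40, 90)`).
#' @param freqs Spike-field/LFP PPC frequency grid, Hz.
#' @param min_spikes PPC1 inclusion threshold per condition (default 200).
#' @param decode_epoch Decoding window relative to the first change
#'   (default `c(-1, 0)`).
#' @param n_rand Randomizations for inferential stages.
#' @param seed Integer seed propagated to all stochastic stages.
#' @param out_dir Optional output directory for CSV tables and the run
#'   log.
#' @return A `pipeline_result` list with one element per executed stage
#'   plus `log` (parameters, seed, skipped stages).
#' @export
run_pipeline <- function(session,
                         stages = c("cellclass", "spectral", "spikefield",
                                    "rates", "decode", "connectivity"),
                         gamma_band = c(40, 90),
                         freqs = seq(20, 100, by = 4),
                         min_spikes = 200L,
                         decode_epoch = c(-1, 0),
                         n_rand = 1000L,
                         seed = 1L,
                         out_dir = NULL) {
  t_begin <- Sys.time()
  res <- list()
  log <- list(stages_requested = stages, seed = seed,
              gamma_band = gamma_band, min_spikes = min_spikes,
              skipped = list())
  fs <- session$fs
  geo <- session$geometry
  trials <- session$trials

  lfp_ref <- shank_rereference(session$lfp, geo)
  bip <- bipolar_derive(lfp_ref, geo)
  pick_granular <- function(geometry, area) {
    idx <- which(geometry$area == area)
    mid <- stats::median(geometry$depth_index[idx])
    # contact nearest mid-depth: a granular-layer proxy when no layer
    # labels are available
    idx[which.min(abs(geometry$depth_index[idx] - mid))]
  }
  sender_ch <- pick_granular(bip$geometry, "sender")
  receiver_ch <- pick_granular(bip$geometry, "receiver")

  for (stage in stages) {
    out <- tryCatch(switch(stage,
      cellclass = stage_cellclass(session, lfp_ref, seed),
      spectral = stage_spectral(session, bip, sender_ch, receiver_ch),
      spikefield = stage_spikefield(session, bip, sender_ch, freqs,
                                    min_spikes, n_rand, seed),
      rates = stage_rates(session, n_rand, seed),
      decode = stage_decode(session, lfp_ref, gamma_band, decode_epoch,
                            seed),
      connectivity = stage_connectivity(session, seed),
      stop("unknown stage '", stage, "'")),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "stage_skipped"))
    if (inherits(out, "stage_skipped")) {
      log$skipped[[stage]] <- out$message
    } else {
      res[[stage]] <- out
    }
  }
  log$elapsed_s <- as.numeric(difftime(Sys.time(), t_begin, units = "secs"))
  res$log <- log
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

## ---- individual stages ---------------------------------------------------

stage_spectral <- function(session, bip, sender_ch, receiver_ch) {
  fs <- session$fs
  trials <- session$trials
  ep_a <- list(); ep_b <- list()
  for (i in seq_len(nrow(trials))) {
    ea <- tile_epochs(bip$lfp[sender_ch, ], fs,
                      trials$stim_onset[i] + 0.25, trials$change_onset[i])
    eb <- tile_epochs(bip$lfp[receiver_ch, ], fs,
                      trials$stim_onset[i] + 0.25, trials$change_onset[i])
    if (nrow(ea)) { ep_a[[length(ep_a) + 1L]] <- ea; ep_b[[length(ep_b) + 1L]] <- eb }
  }
  ea <- do.call(rbind, ep_a); eb <- do.call(rbind, ep_b)
  ca <- multitaper_coeffs(ea, fs)
  cb <- multitaper_coeffs(eb, fs)
  pow <- power_spectrum(ca)
  ppc <- lfp_lfp_ppc(ca, cb)
  peak <- find_local_peak(ppc$freqs, ppc$ppc, c(20, 100))
  list(power = pow, lfp_ppc = ppc, gamma_peak = peak,
       n_epochs = nrow(ea))
}

stage_spikefield <- function(session, bip, sender_ch, freqs, min_spikes,
                             n_rand, seed) {
  fs <- session$fs
  trials <- session$trials
  units <- session$units
  lfp <- bip$lfp[sender_ch, ]
  per_unit <- list()
  for (j in seq_len(nrow(units))) {
    sp <- session$spikes[[units$unit[j]]]
    for (cond in c("toward", "away")) {
      tr <- trials[trials$condition == cond, ]
      keep <- rep(NA_integer_, length(sp))
      for (i in seq_len(nrow(tr))) {
        inb <- sp >= tr$stim_onset[i] & sp < tr$change_onset[i]
        keep[inb] <- tr$trial[i]
      }
      sel <- !is.na(keep)
      ph <- spike_triggered_coeffs(lfp, fs, sp[sel], freqs,
                                   trial_id = keep[sel])
      p1 <- ppc1(ph, min_spikes = min_spikes)
      per_unit[[paste(units$unit[j], cond, sep = ".")]] <-
        c(p1, list(unit = units$unit[j], condition = cond,
                   class = units$class[j], layer = units$layer[j],
                   area = units$area[j]))
    }
  }
  included <- Filter(function(u) !isTRUE(u$excluded), per_unit)
  tab <- do.call(rbind, lapply(included, function(u) {
    data.frame(unit = u$unit, condition = u$condition, class = u$class,
               layer = u$layer, area = u$area, n_spikes = u$n_spikes,
               peak_ppc = max(u$ppc), stringsAsFactors = FALSE)
  }))
  list(per_unit = per_unit, summary = tab, freqs = freqs,
       n_included = length(included),
       n_excluded = length(per_unit) - length(included))
}

stage_rates <- function(session, n_rand, seed) {
  units <- session$units
  trials <- session$trials
  tab <- do.call(rbind, lapply(seq_len(nrow(units)), function(j) {
    sp <- session$spikes[[units$unit[j]]]
    a <- ami(sp, trials)
    d <- drivenness(sp, trials)
    data.frame(unit = units$unit[j], area = units$area[j],
               class = units$class[j], layer = units$layer[j],
               ami = a$ami, fr_toward = a$fr_toward, fr_away = a$fr_away,
               dr = d$dr, stringsAsFactors = FALSE)
  }))
  reg <- tryCatch(ami_regression(tab$ami, (tab$fr_toward + tab$fr_away) / 2,
                                 tab$layer),
                  error = function(e) NULL)
  list(per_unit = tab, ami_regression = reg)
}

stage_decode <- function(session, lfp_ref, gamma_band, decode_epoch, seed) {
  fs <- session$fs
  trials <- session$trials
  labels <- trials$condition
  units <- session$units
  geo <- session$geometry
  sender_idx <- which(geo$area == "sender")
  receiver_idx <- which(geo$area == "receiver")
  mid_of <- function(idx) idx[which.min(abs(geo$depth_index[idx] -
                                              stats::median(geo$depth_index[idx])))]
  ch_a <- mid_of(sender_idx); ch_b <- mid_of(receiver_idx)
  az <- bandpass_hilbert(lfp_ref[c(ch_a, ch_b), ], gamma_band, fs)
  receiver_units <- units$unit[units$area == "receiver"]

  n_tr <- nrow(trials)
  rate_feat <- matrix(0, n_tr, length(receiver_units))
  # one spike-phase signal per receiver unit (per-unit trial mean phase);
  # the spike-field PPC pools spikes across simultaneously recorded units
  sphase_feat <- matrix(NA_real_, n_tr, length(receiver_units))
  plv_feat <- relph_feat <- sfppc_feat <- numeric(n_tr)
  pooled <- sort(unlist(session$spikes[receiver_units], use.names = FALSE))
  spike_idx <- function(sp, ev) {
    sp <- sp[sp >= ev + decode_epoch[1] & sp < ev + decode_epoch[2]]
    idx <- round(sp * fs) + 1L
    idx[idx >= 1L & idx <= ncol(az$values)]
  }
  for (i in seq_len(n_tr)) {
    ev <- trials$change_onset[i]
    for (u in seq_along(receiver_units)) {
      sp_u <- session$spikes[[receiver_units[u]]]
      rate_feat[i, u] <- sum(counts_in_window(sp_u, ev, decode_epoch))
      idx_u <- spike_idx(sp_u, ev)
      if (length(idx_u) >= 1L) {
        sphase_feat[i, u] <- Arg(sum(exp(1i * Arg(az$values[1L, idx_u]))))
      }
    }
    i0 <- floor((ev + decode_epoch[1]) * fs) + 1L
    i1 <- floor((ev + decode_epoch[2]) * fs)
    za <- az$values[1L, i0:i1]; zb <- az$values[2L, i0:i1]
    plv_feat[i] <- trial_plv(za, zb)
    relph_feat[i] <- trial_relphase(za, zb)
    idx <- spike_idx(pooled, ev)
    sfppc_feat[i] <- if (length(idx) >= 2L) {
      ppc_from_phasors(exp(1i * Arg(az$values[1L, idx])))
    } else NA_real_
  }
  safe_loo <- function(f, fam) {
    # matrices may hold NA for signals silent in a trial; decode_trial
    # treats those as contributing no evidence
    ok <- if (is.matrix(f)) rowSums(is.finite(f)) > 0 else is.finite(f)
    if (sum(ok) < 8L) return(NULL)
    loo_accuracy(if (is.matrix(f)) f[ok, , drop = FALSE] else f[ok],
                 labels[ok], family = fam, seed = seed)
  }
  acc <- list(
    rate = safe_loo(rate_feat, "poisson"),
    lfp_plv = safe_loo(plv_feat, "gaussian"),
    lfp_relphase = safe_loo(relph_feat, "vonmises"),
    spike_ppc = safe_loo(sfppc_feat, "gaussian"),
    spike_phase = safe_loo(sphase_feat, "vonmises")
  )
  summary <- data.frame(
    modality = names(acc),
    accuracy = vapply(acc, function(a) if (is.null(a)) NA_real_ else a$accuracy,
                      numeric(1)),
    n_trials = vapply(acc, function(a) if (is.null(a)) NA_integer_ else a$n_trials,
                      integer(1)))
  list(results = acc, summary = summary, n_trials = n_tr)
}

stage_connectivity <- function(session, seed) {
  fs <- session$fs
  trials <- session$trials
  units <- session$units
  eq <- equalize_trials(which(trials$condition == "toward"),
                        which(trials$condition == "away"), seed = seed)
  use_trials <- sort(c(eq$a, eq$b))
  win <- round(0.5 * fs)
  mu_series <- function(area) {
    sp <- sort(unlist(session$spikes[units$unit[units$area == area]],
                      use.names = FALSE))
    t(vapply(use_trials, function(i) {
      ev <- trials$change_onset[i]
      bin_spikes(sp, fs, ev - 0.5, ev)[seq_len(win)]
    }, numeric(win)))
  }
  x <- mu_series("sender"); y <- mu_series("receiver")
  ctrl <- time_reversal_control(x, y, fs, band = c(4, min(200, fs / 2 - 2)))
  list(forward = ctrl$forward, reversed = ctrl$reversed,
       dominance_flipped = ctrl$dominance_flipped,
       n_trials_used = length(use_trials))
}

stage_cellclass <- function(session, lfp_ref, seed) {
  fs <- session$fs
  wf <- t(apply(session$waveforms, 1L, normalize_waveform))
  excl <- exclude_waveforms(wf)
  cls <- classify_bw_nw(wf[excl$keep, , drop = FALSE], seed = seed)
  # laminar assignment on the sender shank from the trial-averaged
  # stimulus-evoked LFP
  geo <- session$geometry
  sidx <- which(geo$area == "sender")
  ev_len <- round(0.1 * fs)
  evoked <- matrix(0, length(sidx), ev_len)
  for (i in seq_len(nrow(session$trials))) {
    i0 <- floor(session$trials$stim_onset[i] * fs) + 1L
    evoked <- evoked + session$lfp[sidx, i0:(i0 + ev_len - 1L)]
  }
  evoked <- evoked / nrow(session$trials)
  csd <- compute_csd(evoked, spacing = diff(geo$depth_um[sidx])[1])
  lay <- assign_layers(csd, session$spike_sign_counts[sidx, ])
  list(keep = excl$keep, exclusion_reason = excl$reason, class = cls,
       csd = csd, layers = lay)
}

## ---- output writing ------------------------------------------------------

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(res$spectral)) {
    wr(data.frame(frequency = res$spectral$lfp_ppc$freqs,
                  ppc = res$spectral$lfp_ppc$ppc,
                  power = res$spectral$power$power), "lfp_spectra")
  }
  if (!is.null(res$spikefield) && !is.null(res$spikefield$summary)) {
    wr(res$spikefield$summary, "spikefield_summary")
  }
  if (!is.null(res$rates)) wr(res$rates$per_unit, "rates_per_unit")
  if (!is.null(res$decode)) wr(res$decode$summary, "decoding_accuracy")
  if (!is.null(res$connectivity)) {
    fw <- res$connectivity$forward
    wr(data.frame(frequency = fw$freqs, gc_sender_to_receiver = fw$gc_xy,
                  gc_receiver_to_sender = fw$gc_yx), "granger_spectra")
  }
  jsonlite::write_json(res$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  ran <- setdiff(names(x), "log")
  cat("<pipeline_result> stages run: ", paste(ran, collapse = ", "), "\n",
      sep = "")
  if (length(x$log$skipped)) {
    cat("  skipped: ", paste(names(x$log$skipped), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
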