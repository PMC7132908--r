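# Per-unit descriptive statistics: count windows, response probability,
# responsive fraction, orientation tuning with jackknife errors, waveform
# classes and arousal-state splits.

#' Extract spike counts in an onset-aligned window
#'
#' Counts spikes per unit and presentation in the half-open interval
#' `[onset + window_start, onset + window_end)`. A warning reports how many
#' consecutive-trial windows overlap the following stimulus onset.
#'
#' @param bundle a `spike_bundle`.
#' @param window_start_ms,window_end_ms window relative to stimulus onset.
#' @return a [spike_count_matrix()].
#' @export
count_spikes_in_window <- function(bundle, window_start_ms = 0,
                                   window_end_ms = 500) {
  if (window_end_ms <= window_start_ms)
    stop_sc("window_end_ms must exceed window_start_ms")
  pres <- bundle$presentations
  ord <- order(pres$onset_time_s)
  onset_sorted <- pres$onset_time_s[ord]
  n_overlap <- sum(utils::head(onset_sorted, -1) + window_end_ms / 1000 >
                     utils::tail(onset_sorted, -1))
  if (n_overlap > 0)
    warning(sprintf("%d count window(s) overlap the next stimulus onset",
                    n_overlap), call. = FALSE)
  lo <- pres$onset_time_s + window_start_ms / 1000
  hi <- pres$onset_time_s + window_end_ms / 1000
  unit_ids <- bundle$units$unit_id
  counts <- matrix(0L, length(unit_ids), nrow(pres))
  ev_by_unit <- split(bundle$events$spike_time_s, bundle$events$unit_id)
  for (i in seq_along(unit_ids)) {
    st <- ev_by_unit[[unit_ids[i]]]
    if (is.null(st) || length(st) == 0L) next
    st <- sort(st)
    counts[i, ] <- findInterval(hi, st, left.open = TRUE) -
      findInterval(lo, st, left.open = TRUE)
  }
  cond_cols <- intersect(c("orientation_label", "orientation_deg",
                           "contrast", "duration_ms", "trial_index",
                           "onset_time_s"), names(pres))
  spike_count_matrix(counts, unit_ids, pres[cond_cols],
                     window_start_ms, window_end_ms)
}

#' Per-unit, per-condition response probability
#'
#' The fraction of trials on which a unit fired at least one spike, grouped
#' by stimulus condition. Pass counts extracted in the window spanning the
#' stimulus presentation plus 100 ms (e.g. `window_rule =
#' "stimulus_plus_100"` in the generator) to reproduce the spike-probability
#' measure.
#'
#' @param scm a [spike_count_matrix()].
#' @return data frame with `unit_id`, condition columns, `n_trials`, `prob`.
#' @export
response_probability <- function(scm) {
  key <- condition_key(scm$conditions, include_orientation = TRUE)
  groups <- split(seq_len(ncol(scm$counts)), key)
  out <- do.call(rbind, lapply(names(groups), function(k) {
    idx <- groups[[k]]
    data.frame(unit_id = scm$unit_ids,
               orientation_label = scm$conditions$orientation_label[idx[1]],
               contrast = scm$conditions$contrast[idx[1]],
               duration_ms = scm$conditions$duration_ms[idx[1]],
               n_trials = length(idx),
               prob = rowMeans(scm$counts[, idx, drop = FALSE] >= 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of simultaneously recorded units active per trial
#'
#' For each trial, the fraction of units with at least one spike in the
#' count window; the session summary is the mean and SD across trials.
#'
#' @param scm a [spike_count_matrix()].
#' @return list with `fraction` (per-trial vector), `mean`, `sd`.
#' @export
responsive_fraction <- function(scm) {
  if (nrow(scm$counts) < 1L) stop_sc("need >= 1 unit")
  frac <- colMeans(scm$counts >= 1)
  list(fraction = frac, mean = mean(frac), sd = stats::sd(frac))
}

#' Orientation selectivity and preferred orientation by vector sum
#'
#' The selectivity index is the resultant length of the doubled-angle
#' vector sum, `OSI = |sum_k R_k exp(2 i theta_k)| / sum_k R_k` (one minus
#' the circular variance), and the preferred orientation is half the
#' resultant angle mapped to \[0, 180). The ratio form
#' `(R_pref - R_orth) / (R_pref + R_orth)` is available via
#' `method = "ratio"`.
#'
#' @param orientations_deg stimulus orientations (>= 4 distinct values).
#' @param mean_rates mean response per orientation (>= 0).
#' @param method "vector" (default) or "ratio".
#' @return list with `osi`, `pref_orientation_deg`, `orientations_deg`,
#'   `mean_rates`; all-zero rates give `osi = NA` with an error flag.
#' @export
osi_and_pref <- function(orientations_deg, mean_rates,
                         method = c("vector", "ratio")) {
  method <- match.arg(method)
  if (length(orientations_deg) < 4L) stop_sc("need >= 4 orientations")
  if (any(mean_rates < 0)) stop_sc("rates must be >= 0")
  total <- sum(mean_rates)
  if (total == 0)
    return(list(osi = NA_real_, pref_orientation_deg = NA_real_,
                orientations_deg = orientations_deg,
                mean_rates = mean_rates, error = "all rates zero"))
  z <- sum(mean_rates * exp(2i * orientations_deg * pi / 180))
  pref <- (Arg(z) / 2 * 180 / pi) %% 180
  osi <- if (method == "vector") {
    Mod(z) / total
  } else {
    # circular distance in orientation space (period 180 deg)
    circ_dist <- function(a, b) {
      d <- abs(a - b) %% 180
      pmin(d, 180 - d)
    }
    rp <- mean_rates[which.min(circ_dist(orientations_deg, pref))]
    ro <- mean_rates[which.min(circ_dist(orientations_deg,
                                         (pref + 90) %% 180))]
    if (rp + ro == 0) NA_real_ else (rp - ro) / (rp + ro)
  }
  list(osi = osi, pref_orientation_deg = pref,
       orientations_deg = orientations_deg, mean_rates = mean_rates,
       error = NULL)
}

#' Jackknife errors for tuning statistics
#'
#' Leave-one-trial-out replicates of the vector-sum tuning statistic. The
#' reported errors are jackknife standard errors: the SD of the replicates
#' inflated by `sqrt((n - 1)^2 / n)`, which for a linear statistic matches
#' the analytic standard error. The preferred-orientation error uses the
#' circular SD in doubled-angle space.
#'
#' @param trial_orientations_deg orientation shown on each trial.
#' @param trial_rates response of the unit on each trial (>= 3 trials per
#'   orientation).
#' @return list with `sd_osi` and `sd_pref_deg`.
#' @export
jackknife_errors <- function(trial_orientations_deg, trial_rates) {
  n <- length(trial_rates)
  tab <- table(trial_orientations_deg)
  if (any(tab < 3L)) stop_sc("need >= 3 trials per orientation")
  stat <- function(keep) {
    agg <- tapply(trial_rates[keep], trial_orientations_deg[keep], mean)
    osi_and_pref(as.numeric(names(agg)), as.numeric(agg))
  }
  reps <- lapply(seq_len(n), function(i) stat(setdiff(seq_len(n), i)))
  osis <- vapply(reps, `[[`, 0, "osi")
  prefs <- vapply(reps, `[[`, 0, "pref_orientation_deg")
  infl <- sqrt((n - 1)^2 / n)
  # circular SD of the doubled angles, halved back to orientation degrees
  zbar <- mean(exp(2i * prefs * pi / 180))
  circ_sd_deg <- if (Mod(zbar) >= 1) 0 else
    sqrt(-2 * log(Mod(zbar))) / 2 * 180 / pi
  list(sd_osi = stats::sd(osis) * infl,
       sd_pref_deg = circ_sd_deg * infl)
}

#' Classify units into fast- and regular-spiking by k-means
#'
#' Clusters units on standardised (spike width, log firing rate) with
#' k-means (50 restarts). The cluster with the smaller mean spike width is
#' labelled "fast". Labels are invariant to unit ordering and reproducible
#' under a fixed seed.
#'
#' @param units unit table with `spike_width_ms` and `mean_rate_hz`.
#' @param k number of clusters (2).
#' @param seed integer seed.
#' @return list with `labels` ("fast"/"regular" per unit), `centers`
#'   (cluster means on the original scale), `degenerate` flag.
#' @export
classify_waveforms <- function(units, k = 2, seed = NULL) {
  if (nrow(units) < k) stop_sc("need >= k units")
  width <- units$spike_width_ms
  rate <- log(pmax(units$mean_rate_hz, 1e-3))
  feats <- cbind(width, rate)
  if (all(apply(feats, 2, stats::sd) == 0)) {
    return(list(labels = rep("regular", nrow(units)), centers = NULL,
                degenerate = TRUE))
  }
  z <- scale(feats)
  z[, apply(feats, 2, stats::sd) == 0] <- 0
  km <- with_seed(seed, stats::kmeans(z, centers = k, nstart = 50))
  mean_width <- tapply(width, km$cluster, mean)
  fast_cluster <- as.integer(names(which.min(mean_width)))
  labels <- ifelse(km$cluster == fast_cluster, "fast", "regular")
  centers <- do.call(rbind, lapply(split(seq_len(nrow(units)), labels),
                                   function(i) c(
                                     spike_width_ms = mean(width[i]),
                                     mean_rate_hz = mean(units$mean_rate_hz[i]))))
  list(labels = labels, centers = centers, degenerate = FALSE)
}

#' Split trials by arousal state from a pupil trace
#'
#' The pupil trace is smoothed with a 1-s median filter and z-scored over
#' the session; a trial is labelled high-arousal when the mean z within its
#' count window exceeds 0 (ties, e.g. a constant trace with z identically
#' 0, go to low arousal). Trials with no trace samples in their window are
#' labelled missing. Running speed, when present, is ignored: pupil size is
#' the sole arousal measure.
#'
#' @param trace arousal trace data frame (`time_s`, `pupil_size`).
#' @param presentations presentation table with `onset_time_s`.
#' @param window_start_ms,window_end_ms trial window used for the mean z.
#' @param filter_window_s median filter width in seconds (default 1).
#' @return list with `trial_labels` ("high"/"low"/"missing"), `z_trace`,
#'   `filter_window_s`.
#' @export
arousal_split <- function(trace, presentations, window_start_ms = 0,
                          window_end_ms = 500, filter_window_s = 1.0) {
  if (nrow(trace) < 3L) stop_sc("arousal trace too short")
  dt <- stats::median(diff(trace$time_s))
  if (!is.finite(dt) || dt <= 0) stop_sc("arousal trace sampling invalid")
  k <- max(3L, round(filter_window_s / dt))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, nrow(trace) - (1 - nrow(trace) %% 2))
  smoothed <- stats::runmed(trace$pupil_size, k)
  sdv <- stats::sd(smoothed)
  z <- if (sdv == 0) rep(0, length(smoothed)) else
    (smoothed - mean(smoothed)) / sdv
  lo <- presentations$onset_time_s + window_start_ms / 1000
  hi <- presentations$onset_time_s + window_end_ms / 1000
  labels <- vapply(seq_along(lo), function(t) {
    sel <- trace$time_s >= lo[t] & trace$time_s < hi[t]
    if (!any(sel)) return("missing")
    if (mean(z[sel]) > 0) "high" else "low"
  }, "")
  n_missing <- sum(labels == "missing")
  if (n_missing > 0)
    sc_log("arousal_split: %d trial(s) without trace coverage", n_missing)
  list(trial_labels = labels, z_trace = z, filter_window_s = filter_window_s)
}
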