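# Virtual-population simulation: performance versus number of pooled
# units, required population size against behavioural targets, shuffle
# controls and sensory/cognitive noise models.
#
# Virtual sessions resample units with replacement from a pool of decoded
# units. Each virtual trial draws every unit's spike count from that
# unit's empirical response multiset for the simulated stimulus condition,
# and combines units as independent regressors: the total log-odds is the
# sum of the per-unit logistic intercepts and slope terms, and the
# prediction is its sign (ties to "left").

#' Tabulate per-unit responses by stimulus condition
#'
#' @param scm a [spike_count_matrix()].
#' @return list (one element per unit) of lists mapping condition keys
#'   (orientation|contrast|duration) to integer count vectors.
#' @export
response_table <- function(scm) {
  key <- condition_key(scm$conditions, include_orientation = TRUE)
  lapply(seq_len(nrow(scm$counts)), function(i)
    split(scm$counts[i, ], key))
}

rt_key <- function(orientation_label, contrast, duration_ms) {
  paste(orientation_label, sprintf("%g", contrast),
        sprintf("%g", duration_ms), sep = "|")
}

#' Build a pool of units for virtual-population simulation
#'
#' Combines decoded sessions into one pool of units carrying their
#' condition-indexed response multisets and their single-unit logistic
#' coefficients. By default only consistent predictors enter the pool.
#' Units lacking responses for a requested condition are excluded at
#' sampling time with a warning.
#'
#' @param sessions list of lists with elements `scm` and `decode` (the
#'   result of [decode_session()]).
#' @param consistent_only keep only consistent predictors (default TRUE).
#' @return an object of class `virtual_pool`: list with `tables`,
#'   `intercepts`, `coefs`, `unit_ids`, `n_units`.
#' @export
virtual_pool <- function(sessions, consistent_only = TRUE) {
  tables <- list(); intercepts <- numeric(0); coefs <- numeric(0)
  ids <- character(0)
  for (s in sessions) {
    tabs <- response_table(s$scm)
    res <- s$decode$results
    for (i in seq_along(res)) {
      if (consistent_only && !res[[i]]$consistent) next
      tables[[length(tables) + 1L]] <- tabs[[i]]
      intercepts <- c(intercepts, res[[i]]$intercept_mean)
      coefs <- c(coefs, res[[i]]$coefficient_mean)
      ids <- c(ids, names(res)[i])
    }
  }
  if (length(tables) == 0L) stop_sc("virtual pool is empty")
  structure(list(tables = tables, intercepts = intercepts, coefs = coefs,
                 unit_ids = ids, n_units = length(tables)),
            class = "virtual_pool")
}

#' @export
print.virtual_pool <- function(x, ...) {
  cat(sprintf("<virtual_pool> %d units\n", x$n_units))
  invisible(x)
}

#' Simulate one virtual session of a given population size
#'
#' Samples `n_units` units from the pool with replacement (each unit
#' equally likely), simulates balanced left/right trials of one stimulus
#' condition by drawing each unit's count from its own response multiset
#' for that condition, and predicts the label from the summed per-unit
#' log-odds.
#'
#' @param pool a [virtual_pool()].
#' @param n_units virtual population size N.
#' @param condition list with `contrast` and `duration_ms`.
#' @param n_trials simulated trials (half left, half right).
#' @param combine "logodds" (sum of per-unit intercept + slope terms,
#'   default) or "vote" (per-unit majority vote).
#' @param seed integer seed.
#' @return list with `accuracy`, `predicted`, `labels`, `unit_idx`.
#' @export
build_virtual_session <- function(pool, n_units, condition,
                                  n_trials = 200,
                                  combine = c("logodds", "vote"),
                                  seed = NULL) {
  combine <- match.arg(combine)
  keys <- c(rt_key("left", condition$contrast, condition$duration_ms),
            rt_key("right", condition$contrast, condition$duration_ms))
  if (condition$contrast == 0)
    keys <- rep(rt_key("none", condition$contrast, condition$duration_ms),
                2)
  has_cond <- vapply(pool$tables, function(tab)
    all(keys %in% names(tab)) &&
      all(vapply(tab[unique(keys)], length, 1L) > 0L), TRUE)
  if (!any(has_cond))
    stop_sc("no pool unit has responses for this condition")
  if (!all(has_cond))
    warning(sprintf("%d pool unit(s) lack responses for this condition",
                    sum(!has_cond)), call. = FALSE)
  eligible <- which(has_cond)
  with_seed(seed, {
    pick <- eligible[sample.int(length(eligible), n_units, replace = TRUE)]
    n_right <- floor(n_trials / 2)
    labels <- rep(c("left", "right"), c(n_trials - n_right, n_right))
    key_per_trial <- ifelse(labels == "right", keys[2], keys[1])
    scores <- matrix(0, n_units, n_trials)
    for (j in seq_len(n_units)) {
      tab <- pool$tables[[pick[j]]]
      x <- numeric(n_trials)
      for (kk in unique(keys)) {
        sel <- key_per_trial == kk
        x[sel] <- tab[[kk]][sample.int(length(tab[[kk]]), sum(sel),
                                       replace = TRUE)]
      }
      scores[j, ] <- if (combine == "logodds") {
        pool$intercepts[pick[j]] + pool$coefs[pick[j]] * x
      } else sign(pool$intercepts[pick[j]] + pool$coefs[pick[j]] * x)
    }
    total <- colSums(scores)
    predicted <- ifelse(total > 0, "right", "left")
    list(accuracy = mean(predicted == labels), predicted = predicted,
         labels = labels, unit_idx = pick)
  })
}

#' Performance versus population size
#'
#' For each population size, simulates `n_resamples` independent virtual
#' sessions and records their accuracies; the curve reports the median and
#' the 2.5/97.5 percentiles across resamples.
#'
#' @param pool a [virtual_pool()].
#' @param sizes increasing vector of population sizes.
#' @param condition list with `contrast` and `duration_ms`.
#' @param n_resamples virtual sessions per size (1000 by default).
#' @param n_trials trials per virtual session.
#' @param combine evidence combination rule (see
#'   [build_virtual_session()]).
#' @param seed integer seed.
#' @return an object of class `population_curve`: `sizes`,
#'   `median_performance`, `pct2_5`, `pct97_5`, `accuracy` (sizes x
#'   resamples matrix), `condition`, `n_resamples`.
#' @export
population_curve <- function(pool, sizes, condition, n_resamples = 1000,
                             n_trials = 200, combine = "logodds",
                             seed = NULL) {
  if (is.unsorted(sizes)) stop_sc("sizes must be sorted increasing")
  seed <- seed %||% 1L
  acc <- matrix(NA_real_, length(sizes), n_resamples)
  for (si in seq_along(sizes)) {
    for (r in seq_len(n_resamples)) {
      acc[si, r] <- build_virtual_session(
        pool, sizes[si], condition, n_trials, combine,
        seed = sub_seed(seed, si * 100003 + r))$accuracy
    }
  }
  structure(list(sizes = sizes,
                 median_performance = apply(acc, 1, stats::median),
                 pct2_5 = apply(acc, 1, stats::quantile, 0.025),
                 pct97_5 = apply(acc, 1, stats::quantile, 0.975),
                 accuracy = acc, condition = condition,
                 n_resamples = n_resamples, n_trials = n_trials),
            class = "population_curve")
}

#' @export
print.population_curve <- function(x, ...) {
  cat(sprintf(
    "<population_curve> N in [%d, %d], median performance %.3f-%.3f (%d resamples)\n",
    min(x$sizes), max(x$sizes), min(x$median_performance),
    max(x$median_performance), x$n_resamples))
  invisible(x)
}

#' Population size required to reach a behavioural target
#'
#' On the median curve, the smallest size whose median performance reaches
#' the target. The uncertainty interval comes from the resample level: for
#' each resample column of the accuracy matrix, the smallest size reaching
#' the target, summarised by its 2.5/97.5 percentiles.
#'
#' @param curve a [population_curve()].
#' @param behavioral_target target proportion correct in (0.5, 1).
#' @return list with `n_required` (NA with `unreachable = TRUE` when the
#'   curve never attains the target), `interval`, `unreachable`.
#' @export
required_population_size <- function(curve, behavioral_target) {
  if (behavioral_target <= 0.5 || behavioral_target >= 1)
    stop_sc("behavioral_target must lie in (0.5, 1)")
  hit <- which(curve$median_performance >= behavioral_target)
  if (length(hit) == 0L)
    return(list(n_required = NA_integer_, interval = c(NA, NA),
                unreachable = TRUE))
  per_resample <- apply(curve$accuracy, 2, function(a) {
    h <- which(a >= behavioral_target)
    if (length(h) == 0L) NA_real_ else curve$sizes[min(h)]
  })
  interval <- stats::quantile(per_resample, c(0.025, 0.975), na.rm = TRUE)
  list(n_required = curve$sizes[min(hit)], interval = interval,
       unreachable = FALSE)
}

#' Shuffle spike counts within stimulus conditions
#'
#' Permutes, independently for every unit, the counts among trials sharing
#' identical (orientation, contrast, duration). Per-unit per-condition
#' count distributions are unchanged; across-unit trial-to-trial
#' correlations (noise correlations) are destroyed.
#'
#' @param scm a [spike_count_matrix()].
#' @param seed integer seed.
#' @return a new [spike_count_matrix()].
#' @export
shuffle_within_condition <- function(scm, seed = NULL) {
  key <- condition_key(scm$conditions, include_orientation = TRUE)
  groups <- split(seq_len(ncol(scm$counts)), key)
  counts <- scm$counts
  with_seed(seed, {
    for (i in seq_len(nrow(counts))) {
      for (idx in groups) {
        if (length(idx) > 1L)
          counts[i, idx] <- counts[i, idx[sample.int(length(idx))]]
      }
    }
  })
  spike_count_matrix(counts, scm$unit_ids, scm$conditions,
                     scm$window_start_ms, scm$window_end_ms)
}

#' Required population size under sensory or cognitive noise models
#'
#' Under the sensory model, behavioural lapses reflect limited sensory
#' evidence and the decoder must match raw behavioural performance. Under
#' the cognitive model, a random fraction of trials (the lapse rate) is
#' corrupted post-sensorily and answered at chance, so the decoder must
#' reach the higher target `(behavioral - lapse/2) / (1 - lapse)` on the
#' uncorrupted trials.
#'
#' @param curve a [population_curve()].
#' @param behavioral_performance observed proportion correct in (0.5, 1).
#' @param lapse lapse rate in \[0, 0.5).
#' @param mode "sensory" or "cognitive".
#' @return list with `decoder_target`, `requirement` (from
#'   [required_population_size()]), `mode`, `infeasible` flag.
#' @export
noise_model_requirement <- function(curve, behavioral_performance, lapse,
                                    mode = c("sensory", "cognitive")) {
  mode <- match.arg(mode)
  if (behavioral_performance <= 0.5 || behavioral_performance >= 1)
    stop_sc("behavioral_performance must lie in (0.5, 1)")
  if (lapse < 0 || lapse >= 0.5) stop_sc("lapse must lie in [0, 0.5)")
  target <- if (mode == "sensory") behavioral_performance else
    (behavioral_performance - 0.5 * lapse) / (1 - lapse)
  if (target >= 1)
    return(list(decoder_target = target, requirement = NULL,
                mode = mode, infeasible = TRUE))
  list(decoder_target = target,
       requirement = required_population_size(curve, target),
       mode = mode, infeasible = FALSE)
}
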