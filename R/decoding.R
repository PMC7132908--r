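# Single-unit and population logistic decoding with the repeated-split
# consistency criterion.
#
# Spike counts are regressed on the left/right stimulus label with a
# binary logistic model. Trials are split 70/30 into training and test
# sets, stratified by stimulus condition, and the split is repeated 100
# times. A unit is a consistent predictor when its slope is significant
# (two-sided Wald p < 0.05) with a stable sign in at least 70 of the 100
# splits. Zero-contrast trials carry no correct orientation: they are
# excluded from training and from the accuracy, and the decoder's
# prediction split on them is reported separately as a diagnostic.

#' Repeated-split protocol
#'
#' @param train_fraction fraction of stimulus trials used for training.
#' @param n_splits number of random splits.
#' @param min_consistent number of qualifying splits required for the
#'   consistency flag; defaults to 70% of `n_splits` (70 of 100).
#' @param seed integer seed controlling the split assignments.
#' @return a `split_protocol` list.
#' @export
split_protocol <- function(train_fraction = 0.7, n_splits = 100,
                           min_consistent = NULL, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_sc("train_fraction must lie in (0, 1)")
  min_consistent <- min_consistent %||% ceiling(0.7 * n_splits)
  structure(list(train_fraction = train_fraction,
                 n_splits = as.integer(n_splits),
                 min_consistent = as.integer(min_consistent), seed = seed),
            class = "split_protocol")
}

# logistic fit y ~ 1 + X via stats::glm.fit, with a small-ridge IRLS
# fallback when the unpenalised fit separates or is rank deficient
logit_fit <- function(X, y, ridge = FALSE, lambda = 1e-4) {
  Xd <- cbind(1, X)
  if (!ridge) {
    fit <- suppressWarnings(
      stats::glm.fit(Xd, y, family = stats::binomial()))
    coefs <- fit$coefficients
    # deviance ~ 0 means a perfect (separated) fit whose Wald p collapses
    separated <- !fit$converged || any(!is.finite(coefs)) ||
      any(abs(coefs[-1]) > 15) || fit$deviance < 1e-6
    if (!separated) {
      R <- fit$qr$qr[seq_len(ncol(Xd)), , drop = FALSE]
      R[lower.tri(R)] <- 0
      cov <- try(chol2inv(R), silent = TRUE)
      if (!inherits(cov, "try-error") && all(is.finite(diag(cov)))) {
        se <- sqrt(diag(cov))
        z <- coefs / se
        return(list(coef = coefs,
                    p = 2 * stats::pnorm(-abs(z)), flagged = FALSE))
      }
    }
  }
  # ridge-penalised IRLS (penalty on all coefficients but the intercept)
  p <- ncol(Xd)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  for (it in 1:50) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd * w, Xd) + pen
    g <- crossprod(Xd, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- drop(Xd %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  cov <- solve(crossprod(Xd * w, Xd) + pen)
  se <- sqrt(diag(cov))
  p_wald <- 2 * stats::pnorm(-abs(drop(beta) / se))
  if (ncol(Xd) == 2L) {
    # Wald p is unreliable under separation (Hauck-Donner); use the
    # likelihood-ratio test against the intercept-only model instead
    loglik <- sum(y * log(pmax(mu, 1e-12)) +
                    (1 - y) * log(pmax(1 - mu, 1e-12)))
    p0 <- mean(y)
    loglik0 <- sum(y * log(max(p0, 1e-12)) +
                     (1 - y) * log(max(1 - p0, 1e-12)))
    p_wald[2] <- stats::pchisq(2 * (loglik - loglik0), df = 1,
                               lower.tail = FALSE)
  }
  list(coef = drop(beta), p = p_wald, flagged = TRUE)
}

# prediction from a logistic fit; ties at probability 0.5 go to "left"
logit_predict <- function(coef, X) {
  eta <- drop(cbind(1, X) %*% coef)
  ifelse(eta > 0, "right", "left")
}

# stratified train/test index split; every stratum with >= 2 trials
# appears in both sets
stratified_split <- function(strata, train_fraction) {
  train <- logical(length(strata))
  groups <- split(seq_along(strata), strata)
  # iterate strata by first trial index so the split (and the RNG stream)
  # is invariant to how the strata happen to be labelled
  groups <- groups[order(vapply(groups, min, 1L))]
  for (idx in groups) {
    n <- length(idx)
    n_train <- round(train_fraction * n)
    if (n >= 2L) n_train <- min(max(n_train, 1L), n - 1L)
    train[sample(idx, n_train)] <- TRUE
  }
  train
}

#' Fit the repeated-split single-unit decoder
#'
#' @param counts integer spike counts, one per trial.
#' @param labels left/right stimulus label per trial ("none" allowed for
#'   zero-contrast trials).
#' @param conditions optional per-trial condition data frame used for
#'   stratified splitting; when `NULL`, splits are stratified on the label
#'   only.
#' @param protocol a [split_protocol()].
#' @param zero_contrast_mask logical mask of no-stimulus trials; defaults
#'   to `conditions$contrast == 0` (or labels == "none").
#' @return an object of class `unit_decoder_result`: coefficient and
#'   intercept means, per-split table (coef, p_value, test_accuracy),
#'   `performance` (mean test accuracy), `consistent`, `n_qualifying`,
#'   `majority_sign`, `zero_contrast_right_fraction`, `n_flagged_fits`.
#' @export
fit_single_unit_decoder <- function(counts, labels, conditions = NULL,
                                    protocol = split_protocol(),
                                    zero_contrast_mask = NULL) {
  labels <- as.character(labels)
  zero_contrast_mask <- zero_contrast_mask %||%
    (if (!is.null(conditions)) conditions$contrast == 0 else
       labels == "none")
  stim <- which(!zero_contrast_mask)
  y_all <- ifelse(labels == "right", 1L, 0L)
  if (length(unique(labels[stim])) < 2L)
    stop_sc("single-class data: need both left and right stimulus trials")
  if (min(table(labels[stim])) < 10L)
    stop_sc("need >= 10 stimulus trials per class")
  strata <- if (!is.null(conditions)) {
    condition_key(conditions[stim, , drop = FALSE])
  } else labels[stim]
  x_stim <- counts[stim]
  y_stim <- y_all[stim]
  n_splits <- protocol$n_splits
  per_split <- matrix(NA_real_, n_splits, 4,
                      dimnames = list(NULL, c("coef", "intercept",
                                              "p_value", "test_accuracy")))
  n_flagged <- 0L
  with_seed(protocol$seed, {
    for (sp in seq_len(n_splits)) {
      tr <- stratified_split(strata, protocol$train_fraction)
      fit <- logit_fit(x_stim[tr], y_stim[tr])
      if (fit$flagged) n_flagged <- n_flagged + 1L
      pred <- logit_predict(fit$coef, x_stim[!tr])
      acc <- mean(pred == labels[stim][!tr])
      per_split[sp, ] <- c(fit$coef[2], fit$coef[1], fit$p[2], acc)
    }
  })
  sig <- per_split[, "p_value"] < 0.05
  signs <- sign(per_split[, "coef"])
  majority <- if (any(sig)) {
    s <- sum(signs[sig])
    if (s >= 0) 1 else -1
  } else NA_real_
  n_qual <- if (is.na(majority)) 0L else
    sum(sig & signs == majority)
  zc_right <- if (any(zero_contrast_mask)) {
    mean_coef <- colMeans(per_split[, c("intercept", "coef")])
    mean(logit_predict(mean_coef, counts[zero_contrast_mask]) == "right")
  } else NA_real_
  structure(list(
    coefficient_mean = mean(per_split[, "coef"]),
    intercept_mean = mean(per_split[, "intercept"]),
    per_split = as.data.frame(per_split),
    performance = mean(per_split[, "test_accuracy"]),
    consistent = n_qual >= protocol$min_consistent,
    n_qualifying = n_qual, majority_sign = majority,
    zero_contrast_right_fraction = zc_right,
    n_flagged_fits = n_flagged, protocol = protocol),
    class = "unit_decoder_result")
}

#' @export
print.unit_decoder_result <- function(x, ...) {
  cat(sprintf(
    "<unit_decoder_result> performance %.3f, %sconsistent (%d/%d qualifying)\n",
    x$performance, if (x$consistent) "" else "not ",
    x$n_qualifying, x$protocol$n_splits))
  invisible(x)
}

#' Decode every unit of a session
#'
#' Runs [fit_single_unit_decoder()] for each row of a spike-count matrix,
#' reusing the same split protocol (each unit gets its own derived split
#' seed).
#'
#' @param scm a [spike_count_matrix()].
#' @param protocol a [split_protocol()].
#' @return list with `results` (one `unit_decoder_result` per unit) and
#'   `summary` (from [consistency_summary()]).
#' @export
decode_session <- function(scm, protocol = split_protocol()) {
  labels <- scm$conditions$orientation_label
  results <- lapply(seq_len(nrow(scm$counts)), function(i) {
    proto_i <- protocol
    proto_i$seed <- if (is.null(protocol$seed)) NULL else
      sub_seed(protocol$seed, i)
    fit_single_unit_decoder(scm$counts[i, ], labels, scm$conditions,
                            proto_i)
  })
  names(results) <- scm$unit_ids
  list(results = results, summary = consistency_summary(results))
}

#' Sweep the spike-count window for decoding
#'
#' Extracts counts for each window `(0, t)` and reruns the single-unit
#' decoding, reporting the population mean performance and the number of
#' consistent predictors per window.
#'
#' @param bundle a `spike_bundle` with events and presentations.
#' @param windows_ms vector of window end points (shared onset 0).
#' @param protocol a [split_protocol()].
#' @return data frame with `window_end_ms`, `mean_performance`,
#'   `n_consistent`.
#' @export
window_sweep <- function(bundle, windows_ms = seq(100, 1000, by = 100),
                         protocol = split_protocol()) {
  out <- lapply(windows_ms, function(w) {
    scm <- suppressWarnings(count_spikes_in_window(bundle, 0, w))
    dec <- decode_session(scm, protocol)
    data.frame(window_end_ms = w,
               mean_performance = dec$summary$mean_performance_all,
               n_consistent = dec$summary$n_consistent)
  })
  do.call(rbind, out)
}

#' Fit the population (multivariate) decoder
#'
#' Uses the spike counts of all simultaneously recorded units as features
#' of one logistic regression, under the same repeated-split protocol.
#' When the training set is too small relative to the number of units
#' (`n_trials <= n_units + 10`) or the unpenalised fit separates, a small
#' ridge penalty is applied and the result flagged.
#'
#' @param scm a [spike_count_matrix()].
#' @param protocol a [split_protocol()].
#' @return an object of class `population_decoder_result` with
#'   `coefficients` (split-mean, one per unit), `intercept`, `performance`,
#'   `per_split`, `n_units`, `n_flagged_fits`.
#' @export
fit_population_decoder <- function(scm, protocol = split_protocol()) {
  labels <- scm$conditions$orientation_label
  zero <- scm$conditions$contrast == 0
  stim <- which(!zero)
  if (length(unique(labels[stim])) < 2L)
    stop_sc("single-class data: need both left and right stimulus trials")
  X <- t(scm$counts[, stim, drop = FALSE])
  y <- ifelse(labels[stim] == "right", 1L, 0L)
  strata <- condition_key(scm$conditions[stim, , drop = FALSE])
  force_ridge <- nrow(X) <= ncol(X) + 10L
  if (force_ridge)
    sc_log("fit_population_decoder: n_trials <= n_units + 10, ridge path")
  n_splits <- protocol$n_splits
  acc <- numeric(n_splits)
  coefs <- matrix(NA_real_, n_splits, ncol(X) + 1L)
  n_flagged <- 0L
  with_seed(protocol$seed, {
    for (sp in seq_len(n_splits)) {
      tr <- stratified_split(strata, protocol$train_fraction)
      fit <- logit_fit(X[tr, , drop = FALSE], y[tr], ridge = force_ridge)
      if (fit$flagged) n_flagged <- n_flagged + 1L
      pred <- logit_predict(fit$coef, X[!tr, , drop = FALSE])
      acc[sp] <- mean(pred == labels[stim][!tr])
      coefs[sp, ] <- fit$coef
    }
  })
  structure(list(session_id = scm$conditions$session_id[1] %||% NA,
                 intercept = mean(coefs[, 1]),
                 coefficients = colMeans(coefs[, -1, drop = FALSE]),
                 performance = mean(acc),
                 per_split = data.frame(test_accuracy = acc),
                 n_units = nrow(scm$counts),
                 n_flagged_fits = n_flagged),
            class = "population_decoder_result")
}

#' Summarise consistency across unit decoders
#'
#' @param results list of `unit_decoder_result` objects.
#' @return one-row data frame: `n_units`, `n_consistent`,
#'   `fraction_consistent` with its Clopper-Pearson 95% CI,
#'   `mean_performance_all`, `mean_performance_consistent`.
#' @export
consistency_summary <- function(results) {
  if (length(results) == 0L)
    return(data.frame(n_units = 0L, n_consistent = 0L,
                      fraction_consistent = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      mean_performance_all = NA_real_,
                      mean_performance_consistent = NA_real_))
  perf <- vapply(results, `[[`, 0, "performance")
  cons <- vapply(results, `[[`, TRUE, "consistent")
  ci <- clopper_pearson(sum(cons), length(cons))
  data.frame(n_units = length(results), n_consistent = sum(cons),
             fraction_consistent = mean(cons),
             ci_lower = ci["lower"], ci_upper = ci["upper"],
             mean_performance_all = mean(perf),
             mean_performance_consistent =
               if (any(cons)) mean(perf[cons]) else NA_real_,
             row.names = NULL)
}
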