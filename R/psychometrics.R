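# Psychometric model fitting for 2AFC behaviour.
#
# Performance as a function of stimulus strength s is modelled as
#   P(s) = gamma + (1 - lambda - gamma) / (1 + exp(-(s - m) / omega))
# with gamma the guessing rate (fixed at 0.5 for 2AFC), lambda the lapse
# rate, m the stimulus strength at half-maximum performance and omega the
# width of the psychometric function. On the duration axis the fitted m is
# the threshold integration time tau; on the contrast axis it is the
# threshold contrast upsilon.

#' Construct a psychometric model
#'
#' @param m stimulus strength at half-maximum performance (units of the
#'   swept axis: ms for duration, unitless for contrast).
#' @param omega width of the psychometric function (> 0, same units as `m`).
#' @param lapse lapse rate lambda in \[0, 0.5).
#' @param guess guessing rate gamma; 0.5 for a 2AFC task.
#' @return an object of class `psychometric_model`.
#' @export
psychometric_model <- function(m, omega, lapse = 0, guess = 0.5) {
  if (!is.finite(omega) || omega <= 0) stop_sc("omega must be > 0")
  if (lapse < 0 || lapse >= 0.5) stop_sc("lapse must lie in [0, 0.5)")
  if (lapse + guess >= 1) stop_sc("lapse + guess must be < 1")
  structure(list(m = m, omega = omega, lapse = lapse, guess = guess),
            class = "psychometric_model")
}

#' Predicted 2AFC performance at a stimulus strength
#'
#' Evaluates the logistic-with-lapse psychometric function. The lower
#' asymptote is the guessing rate and the upper asymptote is `1 - lapse`.
#'
#' @param model a `psychometric_model` (or list with m, omega, lapse, guess).
#' @param s numeric vector of stimulus strengths.
#' @return predicted proportion correct, in \[guess, 1 - lapse\].
#' @export
predict_performance <- function(model, s) {
  if (!is.finite(model$omega) || model$omega <= 0)
    stop_sc("omega must be > 0")
  g <- model$guess %||% 0.5
  g + (1 - model$lapse - g) * stats::plogis((s - model$m) / model$omega)
}

#' Filter trials on reaction time
#'
#' Removes implausibly fast trials (completed in under 50 ms, which would
#' require unattainable motor speeds) and very slow trials (over 5 s,
#' indicating low motivation). Boundaries are inclusive: reaction times in
#' `[0.05, 5]` s are kept.
#'
#' @param trials trial table with `reaction_time_s`.
#' @return list with `trials` (kept rows) and `report` (a one-row data
#'   frame: n_input, n_fast_excluded, n_slow_excluded, n_kept).
#' @export
filter_trials <- function(trials) {
  rt <- trials$reaction_time_s
  fast <- rt < 0.05
  slow <- rt > 5
  keep <- !fast & !slow
  report <- data.frame(n_input = length(rt), n_fast_excluded = sum(fast),
                       n_slow_excluded = sum(slow), n_kept = sum(keep))
  sc_log("filter_trials: %d in, %d fast (<50 ms) and %d slow (>5 s) excluded, %d kept",
         report$n_input, report$n_fast_excluded, report$n_slow_excluded,
         report$n_kept)
  list(trials = trials[keep, , drop = FALSE], report = report)
}

# Aggregate trials to binomial counts per stimulus level on the chosen axis.
# Zero-contrast trials on the duration axis carry no stimulus information
# and are excluded from the level table.
aggregate_levels <- function(trials, axis) {
  s <- switch(axis, duration = trials$duration_ms, contrast = trials$contrast,
              stop_sc("axis must be 'duration' or 'contrast'"))
  if (axis == "duration") {
    keep <- trials$contrast > 0
    s <- s[keep]
    correct <- trials$correct[keep]
  } else correct <- trials$correct
  if (length(s) == 0L)
    return(data.frame(s = numeric(0), k = integer(0), n = integer(0)))
  agg <- stats::aggregate(cbind(k = correct, n = 1L) ~ s,
                          data = data.frame(s = s, correct = correct),
                          FUN = sum)
  agg[order(agg$s), ]
}

# Log posterior of (m, omega, lambda) given binomial counts per level.
# Flat priors on m and omega inside their boxes; Beta(1.2, 12) prior on the
# lapse rate, truncated to [0, 0.5).
make_logpost <- function(levels, bounds) {
  s <- levels$s; k <- levels$k; n <- levels$n
  function(theta) {
    m <- theta[1]; om <- theta[2]; la <- theta[3]
    # large finite penalty rather than -Inf: box-constrained optimisers
    # probe finite-difference points marginally outside the box
    if (m < bounds$m[1] || m > bounds$m[2] ||
        om < bounds$omega[1] || om > bounds$omega[2] ||
        la < 0 || la >= 0.5) return(-1e10)
    p <- 0.5 + (0.5 - la) * stats::plogis((s - m) / om)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(k * log(p) + (n - k) * log1p(-p)) +
      stats::dbeta(la, 1.2, 12, log = TRUE)
  }
}

default_bounds <- function(levels) {
  rng <- range(levels$s)
  span <- diff(rng)
  if (span <= 0) stop_sc("need >= 2 distinct stimulus levels")
  list(m = rng, omega = c(1e-3 * span, span))
}

map_fit <- function(logpost, bounds, starts) {
  lower <- c(bounds$m[1], bounds$omega[1], 1e-8)
  upper <- c(bounds$m[2], bounds$omega[2], 0.5 - 1e-8)
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, function(t) -logpost(t), method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop_sc("MAP optimisation failed from all starts")
  unname(best$par)
}

# Adaptive random-walk Metropolis, one chain. Warm-up runs componentwise
# proposals tuned toward ~35% acceptance and records the visited states;
# sampling then uses joint multivariate-normal proposals whose covariance
# is the warm-up posterior covariance scaled by 2.38^2/d (the classic
# adaptive-Metropolis rule), which mixes far better when the parameters
# are correlated, as m, omega and the lapse rate are here.
mh_chain <- function(logpost, init, n_warmup, n_draws, scales) {
  d <- length(init)
  cur <- init
  cur_lp <- logpost(cur)
  warm <- matrix(NA_real_, n_warmup, d)
  acc <- integer(d)
  tries <- integer(d)
  for (it in seq_len(n_warmup)) {
    for (j in seq_len(d)) {
      prop <- cur
      prop[j] <- cur[j] + stats::rnorm(1, 0, scales[j])
      lp <- logpost(prop)
      tries[j] <- tries[j] + 1L
      if (is.finite(lp) && lp > -1e9 &&
          log(stats::runif(1)) < lp - cur_lp) {
        cur <- prop; cur_lp <- lp; acc[j] <- acc[j] + 1L
      }
    }
    if (it %% 50L == 0L) {
      rate <- acc / pmax(tries, 1L)
      scales <- scales * exp(1.2 * (rate - 0.35))
      acc[] <- 0L; tries[] <- 0L
    }
    warm[it, ] <- cur
  }
  late <- warm[seq(floor(n_warmup / 2), n_warmup), , drop = FALSE]
  S <- stats::cov(late)
  if (!all(is.finite(S)) || any(diag(S) <= 0))
    S <- diag(pmax(scales, 1e-8)^2, d)
  S <- S + diag(1e-10, d)
  L <- t(chol(2.38^2 / d * S))
  draws <- matrix(NA_real_, n_draws, d)
  for (it in seq_len(n_draws)) {
    prop <- cur + drop(L %*% stats::rnorm(d))
    lp <- logpost(prop)
    if (is.finite(lp) && lp > -1e9 &&
        log(stats::runif(1)) < lp - cur_lp) {
      cur <- prop; cur_lp <- lp
    }
    draws[it, ] <- cur
  }
  draws
}

# Split-Rhat convergence diagnostic (each chain halved, rank-classical).
split_rhat <- function(chains) {
  halves <- do.call(cbind, lapply(chains, function(x) {
    n <- floor(length(x) / 2)
    cbind(x[seq_len(n)], x[(length(x) - n + 1):length(x)])
  }))
  n <- nrow(halves); m <- ncol(halves)
  mu <- colMeans(halves)
  B <- n * stats::var(mu)
  W <- mean(apply(halves, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the logistic-with-lapse psychometric function
#'
#' Fits (m, omega, lambda) to a 2AFC trial table by constrained maximum a
#' posteriori estimation, then samples the posterior by adaptive
#' random-walk Metropolis MCMC. The likelihood is binomial per stimulus
#' level; the guessing rate is fixed at 0.5; the lapse rate carries a
#' Beta(1.2, 12) prior and m and omega flat priors over the observed
#' stimulus range (omega bounded below at 1e-3 of the range to avoid
#' step-function degeneracy). Credible intervals are the 2.5/97.5
#' percentiles of the marginal posteriors.
#'
#' @param trials trial table (already reaction-time filtered if desired).
#' @param axis "duration" (threshold = tau, ms) or "contrast" (threshold =
#'   upsilon). On the duration axis zero-contrast trials are dropped.
#' @param priors optional list overriding `m` and/or `omega` bounds, e.g.
#'   `list(m = c(0, 600))`.
#' @param mcmc list of sampler settings: `n_chains` (4), `n_warmup` (1000),
#'   `n_draws` (5000 per chain).
#' @param seed integer seed for the sampler.
#' @return an object of class `psychometric_fit` with elements `map`
#'   (a `psychometric_model`), `samples` (data frame of m, omega, lapse),
#'   `ci95`, `threshold`, `total_integration_time_T` (duration axis),
#'   `rhat`, `degenerate`, `converged`, `n_trials_used`, `axis`, `levels`.
#' @export
fit_psychometric <- function(trials, axis = c("duration", "contrast"),
                             priors = NULL, mcmc = NULL, seed = NULL) {
  axis <- match.arg(axis)
  levels <- aggregate_levels(trials, axis)
  degenerate <- FALSE
  if (nrow(levels) < 2L) {
    degenerate <- TRUE
  } else if (all(levels$k == levels$n) || all(levels$k == 0L)) {
    degenerate <- TRUE
  }
  if (degenerate) {
    sc_log("fit_psychometric: degenerate data (no usable stimulus dependence)")
    return(structure(list(map = NULL, samples = NULL, ci95 = NULL,
                          threshold = NA_real_,
                          total_integration_time_T = NA_real_,
                          rhat = NULL, degenerate = TRUE, converged = FALSE,
                          n_trials_used = sum(levels$n), axis = axis,
                          levels = levels),
                     class = "psychometric_fit"))
  }
  bounds <- default_bounds(levels)
  if (!is.null(priors$m)) bounds$m <- priors$m
  if (!is.null(priors$omega)) bounds$omega <- priors$omega
  mcmc <- utils::modifyList(list(n_chains = 4L, n_warmup = 1000L,
                                 n_draws = 5000L), mcmc %||% list())
  logpost <- make_logpost(levels, bounds)
  span <- diff(bounds$m)
  with_seed(seed, {
    starts <- list(
      c(mean(bounds$m), diff(range(levels$s)) / 4, 0.05),
      c(stats::quantile(levels$s, 0.25), diff(range(levels$s)) / 8, 0.1),
      c(stats::quantile(levels$s, 0.6), diff(range(levels$s)) / 2, 0.2))
    map <- map_fit(logpost, bounds, starts)
    scales0 <- c(span / 20, diff(bounds$omega) / 20, 0.02)
    chains <- lapply(seq_len(mcmc$n_chains), function(ch) {
      init <- map * stats::runif(3, 0.95, 1.05)
      init[3] <- min(max(map[3] + stats::runif(1, -0.02, 0.02), 1e-4), 0.45)
      init[1] <- min(max(init[1], bounds$m[1]), bounds$m[2])
      init[2] <- min(max(init[2], bounds$omega[1]), bounds$omega[2])
      mh_chain(logpost, init, mcmc$n_warmup, mcmc$n_draws, scales0)
    })
  })
  samples <- as.data.frame(do.call(rbind, chains))
  names(samples) <- c("m", "omega", "lapse")
  rhat <- vapply(1:3, function(j)
    split_rhat(lapply(chains, function(c) c[, j])), 0)
  names(rhat) <- names(samples)
  converged <- all(rhat < 1.05)
  if (!converged)
    sc_log("fit_psychometric: split-Rhat > 1.05 (%s); fit flagged",
           paste(sprintf("%s=%.3f", names(rhat), rhat), collapse = ", "))
  ci95 <- vapply(samples, stats::quantile, numeric(2),
                 probs = c(0.025, 0.975))
  rownames(ci95) <- c("2.5%", "97.5%")
  model <- psychometric_model(map[1], map[2], map[3], 0.5)
  fit <- structure(list(map = model, samples = samples, ci95 = ci95,
                        threshold = map[1],
                        total_integration_time_T = NA_real_,
                        rhat = rhat, degenerate = FALSE,
                        converged = converged,
                        n_trials_used = sum(levels$n), axis = axis,
                        levels = levels),
                   class = "psychometric_fit")
  if (axis == "duration")
    fit$total_integration_time_T <- total_integration_time(fit)
  fit
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<psychometric_fit> degenerate (no stimulus dependence)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<psychometric_fit> axis=%s  m=%.3g  omega=%.3g  lapse=%.3g  (n=%d)\n",
    x$axis, x$map$m, x$map$omega, x$map$lapse, x$n_trials_used))
  if (x$axis == "duration")
    cat(sprintf("  threshold tau = %.3g ms, total integration time T = %.3g ms\n",
                x$threshold, x$total_integration_time_T))
  invisible(x)
}

#' Total integration time from a duration-axis fit
#'
#' The smallest duration T at which performance reaches 90% of its maximum.
#' "Maximum" is measured relative to the above-chance dynamic range by
#' default, i.e. T solves `P(T) - gamma = 0.9 (P(Inf) - gamma)`, which has
#' the lapse-invariant closed form `T = m + omega log 9`. The absolute
#' convention `P(T) = 0.9 P(Inf)` is available via `relative = FALSE` and
#' is solved numerically.
#'
#' @param fit a `psychometric_fit` on the duration axis, or a
#'   `psychometric_model`.
#' @param relative measure the 90% point relative to the above-chance range
#'   (default) or on the absolute performance scale.
#' @return T in the units of the swept axis (ms).
#' @export
total_integration_time <- function(fit, relative = TRUE) {
  model <- if (inherits(fit, "psychometric_fit")) {
    if (fit$degenerate) stop_sc("total integration time undefined for a degenerate fit")
    if (fit$axis != "duration")
      stop_sc("total integration time is defined on the duration axis")
    fit$map
  } else fit
  if (relative) return(model$m + model$omega * log(9))
  g <- model$guess
  target <- 0.9 * (1 - model$lapse)
  if (target <= g)
    stop_sc("absolute 90%% criterion lies below the guessing rate")
  q <- (target - g) / (1 - model$lapse - g)
  if (q >= 1) stop_sc("absolute 90%% criterion is unreachable")
  model$m + model$omega * stats::qlogis(q)
}

#' Balanced average-subject estimates
#'
#' Different subjects contribute different numbers of trials. To give each
#' animal equal weight, each resample draws the minimum per-subject trial
#' count from every subject without replacement (randomly across stimulus
#' conditions), concatenates them into a pseudo-subject, and computes MAP
#' psychometric estimates. The resampling is repeated `n_resamples` times
#' and the mean of the MAP estimates across resamples is reported.
#'
#' @param per_subject_trials list of >= 2 trial tables, one per subject.
#' @param axis "duration" or "contrast".
#' @param n_resamples number of balanced resamples (1000 by default).
#' @param seed integer seed.
#' @param priors optional prior bounds passed to the fit.
#' @return list with `estimates` (data frame of per-resample MAP m, omega,
#'   lapse), `mean`, `sd`, and `n_per_subject`.
#' @export
average_subject <- function(per_subject_trials, axis = "duration",
                            n_resamples = 1000, seed = NULL, priors = NULL) {
  if (length(per_subject_trials) < 2L) stop_sc("need >= 2 subjects")
  ns <- vapply(per_subject_trials, nrow, 1L)
  if (any(ns == 0L)) stop_sc("subject with zero trials")
  n_draw <- min(ns)
  pooled0 <- do.call(rbind, per_subject_trials)
  levels_all <- aggregate_levels(pooled0, axis)
  bounds <- default_bounds(levels_all)
  if (!is.null(priors$m)) bounds$m <- priors$m
  if (!is.null(priors$omega)) bounds$omega <- priors$omega
  est <- with_seed(seed, {
    t(vapply(seq_len(n_resamples), function(r) {
      pooled <- do.call(rbind, lapply(per_subject_trials, function(tr) {
        tr[sample.int(nrow(tr), n_draw), , drop = FALSE]
      }))
      levels <- aggregate_levels(pooled, axis)
      logpost <- make_logpost(levels, bounds)
      map_fit(logpost, bounds, list(
        c(mean(bounds$m), diff(range(levels$s)) / 4, 0.05)))
    }, numeric(3)))
  })
  est <- as.data.frame(est)
  names(est) <- c("m", "omega", "lapse")
  list(estimates = est, mean = colMeans(est),
       sd = vapply(est, stats::sd, 0), n_per_subject = n_draw)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval obtained by inverting the binomial test, computed
#' from Beta quantiles. The lower bound is 0 when `k = 0` and the upper
#' bound is 1 when `k = n`.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (> 0).
#' @param alpha two-sided error level (default 0.05).
#' @return named numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (n <= 0 || k < 0 || k > n) stop_sc("need 0 <= k <= n with n > 0")
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Agresti-Caffo interval for a difference of binomial proportions
#'
#' Adds one success and one failure to each arm (p-tilde = (k+1)/(n+2)) and
#' forms the Wald interval on the adjusted difference. The difference is
#' declared significant when the interval excludes 0.
#'
#' @param k1,n1 successes and trials in arm 1.
#' @param k2,n2 successes and trials in arm 2.
#' @param alpha two-sided error level.
#' @return list with `estimate` (p1 - p2, unadjusted), `interval`,
#'   `significant`.
#' @export
agresti_caffo <- function(k1, n1, k2, n2, alpha = 0.05) {
  if (n1 <= 0 || n2 <= 0) stop_sc("n1 and n2 must be > 0")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop_sc("need 0 <= k <= n in both arms")
  p1 <- (k1 + 1) / (n1 + 2)
  p2 <- (k2 + 1) / (n2 + 2)
  se <- sqrt(p1 * (1 - p1) / (n1 + 2) + p2 * (1 - p2) / (n2 + 2))
  z <- stats::qnorm(1 - alpha / 2)
  interval <- c(lower = (p1 - p2) - z * se, upper = (p1 - p2) + z * se)
  list(estimate = k1 / n1 - k2 / n2, interval = interval,
       significant = interval[1] > 0 || interval[2] < 0)
}
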