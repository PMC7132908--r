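# Synthetic behavioural and V1 population data.
#
# The generator emulates the statistical structure the downstream analyses
# assume: Bernoulli 2AFC responses from a logistic-with-lapse observer, and
# sparse orientation-tuned spike counts that are Poisson conditional on a
# per-trial gain (doubly stochastic), giving over-dispersion and tunable
# noise correlations through a single shared-gain parameter.
#
# Ongoing (stimulus-independent) activity is piecewise-constant in time: a
# low tonic rate plus an elevated late component (default 300-600 ms after
# trial onset) standing in for recurrent network activity that outlasts the
# stimulus. This late component is what lets a unit be silent in short
# stimulus-locked windows on most trials while still contributing to the
# much higher fraction of units with at least one spike over a full 500 ms
# window, a combination a time-homogeneous Poisson process cannot produce.

#' Specify a synthetic 2AFC observer
#'
#' @param m stimulus strength at half-maximum performance (swept-axis units).
#' @param omega psychometric width (> 0).
#' @param lapse lapse rate in \[0, 0.5).
#' @param guess guessing rate (0.5 for 2AFC).
#' @param rt_median_s,rt_sigma lognormal reaction-time parameters.
#' @param fast_rate,slow_rate rates at which implausibly fast (< 50 ms) and
#'   slow (> 5 s) reaction-time outliers are injected, to exercise the
#'   reaction-time filters.
#' @return an `observer_spec` list.
#' @export
observer_spec <- function(m, omega, lapse = 0.1, guess = 0.5,
                          rt_median_s = 1.0, rt_sigma = 0.5,
                          fast_rate = 0.001, slow_rate = 0.0118) {
  if (omega <= 0) stop_sc("omega must be > 0")
  if (lapse < 0 || lapse >= 0.5) stop_sc("lapse must lie in [0, 0.5)")
  if (lapse + guess >= 1) stop_sc("lapse + guess must be < 1")
  structure(list(m = m, omega = omega, lapse = lapse, guess = guess,
                 rt_median_s = rt_median_s, rt_sigma = rt_sigma,
                 fast_rate = fast_rate, slow_rate = slow_rate),
            class = "observer_spec")
}

#' Specify a synthetic V1 population
#'
#' Each unit has a tonic baseline rate, an evoked amplitude, a preferred
#' orientation and a tuning concentration. Counts for a window \[0, w\] are
#' Poisson with mean `g_t * (baseline * eff(w) + amplitude *
#' contrast_gain(c) * tuning(theta) * evoked_overlap(w, d))`, where `eff`
#' integrates the piecewise-constant ongoing intensity, the evoked interval
#' runs from `latency_s` to `latency_s + duration + evoked_tail_s`, and
#' `g_t` is a per-trial lognormal shared gain (times `arousal_gain` on
#' high-arousal trials when arousal is simulated).
#'
#' Only units flagged informative respond to brief flashed discriminanda in
#' an orientation-dependent way; the rest respond with an untuned transient
#' of matched mean drive. All units express their tuning for long
#' characterisation gratings (duration >= 500 ms).
#'
#' @param n_units units per simulated session.
#' @param baseline_meanlog,baseline_sdlog lognormal tonic rate (Hz) of
#'   regular-spiking units; rates are clipped to `rate_range_hz`.
#' @param fast_fraction fraction of narrow-waveform fast-spiking units.
#' @param fast_rate_mult multiplicative rate factor for fast units.
#' @param rate_range_hz allowed session rate range (Hz).
#' @param amp_meanlog,amp_sdlog lognormal evoked amplitude (Hz).
#' @param k_meanlog,k_sdlog lognormal tuning concentration (doubled-angle
#'   von Mises kappa); kappa ~ 0.65 gives a vector-sum OSI near 0.31.
#' @param cardinal_bias probability a preferred orientation is drawn near a
#'   cardinal (0/90 deg) axis rather than uniformly.
#' @param contrast_c50,contrast_n Hill contrast gain, normalised to 1 at
#'   full contrast; c50 defaults to the behavioural threshold contrast 0.15.
#' @param informative_fraction fraction of units whose flash response
#'   depends on the left/right (+/-45 deg) label.
#' @param amp_informative_meanlog,amp_informative_sdlog lognormal evoked
#'   amplitude (Hz) of informative units, drawn separately from the
#'   untuned population.
#' @param informative_pref_sd SD (deg) of informative units' preferred
#'   orientations around the discriminanda; consistent predictors in vivo
#'   are enriched in preferences near the discriminated stimuli.
#' @param discriminanda_deg the two discriminated orientations.
#' @param shared_gain_sd SD of the log shared per-trial gain (0 =
#'   independent units).
#' @param arousal_gain firing-rate gain applied on high-arousal trials.
#' @param latency_s response latency; `evoked_tail_s` response tail beyond
#'   stimulus offset.
#' @param late_start_s,late_end_s,late_gain window and gain of the late
#'   ongoing (recurrent) component.
#' @return a `population_spec` list.
#' @export
population_spec <- function(n_units = 30,
                            baseline_meanlog = log(0.5),
                            baseline_sdlog = 1.1,
                            fast_fraction = 0.25,
                            fast_rate_mult = 2.7,
                            rate_range_hz = c(0.2, 80),
                            amp_meanlog = log(1.0), amp_sdlog = 0.9,
                            k_meanlog = log(0.65), k_sdlog = 0.6,
                            cardinal_bias = 0.4,
                            contrast_c50 = 0.15, contrast_n = 1.2,
                            informative_fraction = 0.35,
                            amp_informative_meanlog = log(2.0),
                            amp_informative_sdlog = 0.5,
                            informative_pref_sd = 15,
                            discriminanda_deg = c(45, 135),
                            shared_gain_sd = 0.15,
                            arousal_gain = 1.25,
                            latency_s = 0.05, evoked_tail_s = 0.1,
                            late_start_s = 0.3, late_end_s = 0.6,
                            late_gain = 3.5) {
  if (informative_fraction < 0 || informative_fraction > 1)
    stop_sc("informative_fraction must lie in [0, 1]")
  if (shared_gain_sd < 0) stop_sc("shared_gain_sd must be >= 0")
  if (arousal_gain < 1) stop_sc("arousal_gain must be >= 1")
  structure(as.list(environment()), class = "population_spec")
}

#' Simulate 2AFC behaviour from a logistic-with-lapse observer
#'
#' Per trial, `correct ~ Bernoulli(P(s))` with `s` the swept stimulus
#' strength; the response is derived from the correct flag and the true
#' left/right label. Zero-contrast trials are rewarded at random
#' (performance at chance). Reaction times are lognormal with configurable
#' fast/slow outlier injection.
#'
#' @param observer an `observer_spec`.
#' @param schedule data frame with columns `contrast`, `duration_ms`,
#'   `n_trials`.
#' @param axis which stimulus feature is being swept: "duration" or
#'   "contrast".
#' @param subject_id subject identifier stored in the trial table.
#' @param seed integer seed.
#' @return a validated trial table (one row per trial).
#' @export
simulate_behavior <- function(observer, schedule, axis = "duration",
                              subject_id = "sim01", seed = NULL) {
  if (nrow(schedule) == 0L) stop_sc("schedule must be non-empty")
  check_columns(schedule, c("contrast", "duration_ms", "n_trials"),
                "behaviour schedule")
  with_seed(seed, {
    rows <- schedule[rep(seq_len(nrow(schedule)), schedule$n_trials), ,
                     drop = FALSE]
    n <- nrow(rows)
    s <- switch(axis, duration = rows$duration_ms,
                contrast = rows$contrast,
                stop_sc("axis must be 'duration' or 'contrast'"))
    p <- predict_performance(observer, s)
    if (any(p < 0 | p > 1)) stop_sc("observer predicts P(s) outside [0, 1]")
    p[rows$contrast == 0] <- 0.5
    label <- ifelse(rows$contrast == 0, "none",
                    sample(c("left", "right"), n, replace = TRUE))
    correct <- stats::runif(n) < p
    response <- ifelse(label == "none",
                       sample(c("left", "right"), n, replace = TRUE),
                       ifelse(correct, label,
                              ifelse(label == "left", "right", "left")))
    deg <- ifelse(label == "left", 45, ifelse(label == "right", 135,
                                              NA_real_))
    rt <- stats::rlnorm(n, log(observer$rt_median_s), observer$rt_sigma)
    u <- stats::runif(n)
    rt[u < observer$fast_rate] <- stats::runif(sum(u < observer$fast_rate),
                                               0.005, 0.045)
    sl <- u >= observer$fast_rate &
      u < observer$fast_rate + observer$slow_rate
    rt[sl] <- stats::runif(sum(sl), 5.5, 20)
    validate_trials(data.frame(
      subject_id = subject_id, trial_index = seq_len(n),
      orientation_label = label, orientation_deg = deg,
      contrast = rows$contrast, duration_ms = rows$duration_ms,
      response = response, correct = correct, reaction_time_s = rt,
      stringsAsFactors = FALSE))
  })
}

#' Condition grid used for the short-stimulus physiology
#'
#' @param contrasts,durations_ms grids; defaults are the study values.
#' @param n_per_cell trials per condition cell.
#' @return schedule data frame with `orientation_label`, `orientation_deg`,
#'   `contrast`, `duration_ms`, `n_trials`.
#' @export
study_grid <- function(contrasts = c(0, 0.15, 1),
                       durations_ms = c(50, 100, 150, 200),
                       n_per_cell = 30) {
  cells <- expand.grid(orientation_label = c("left", "right"),
                       contrast = contrasts, duration_ms = durations_ms,
                       stringsAsFactors = FALSE)
  zero <- cells$contrast == 0
  if (any(zero)) {
    none <- unique(transform(cells[zero, ], orientation_label = "none"))
    cells <- rbind(none, cells[!zero, ])
  }
  cells$orientation_deg <- ifelse(cells$orientation_label == "left", 45,
                                  ifelse(cells$orientation_label == "right",
                                         135, NA_real_))
  cells$n_trials <- n_per_cell
  rownames(cells) <- NULL
  cells[c("orientation_label", "orientation_deg", "contrast",
          "duration_ms", "n_trials")]
}

# normalised Hill contrast gain: 0 at c=0, 1 at c=1
contrast_gain <- function(contrast, c50, n) {
  num <- contrast^n / (contrast^n + c50^n)
  num / (1 / (1 + c50^n))
}

# integrated ongoing intensity (effective seconds) for a window [0, w]
ongoing_eff_seconds <- function(w, pop) {
  pmin(w, pop$late_start_s) +
    pop$late_gain * pmax(0, pmin(w, pop$late_end_s) - pop$late_start_s) +
    pmax(0, w - pop$late_end_s)
}

# overlap (seconds) of the evoked interval with the window [0, w]
evoked_overlap_seconds <- function(w, duration_ms, pop) {
  end <- pop$latency_s + duration_ms / 1000 + pop$evoked_tail_s
  pmax(0, pmin(w, end) - pop$latency_s)
}

# doubled-angle von Mises tuning, peak 1 at the preferred orientation
tuning_value <- function(theta_deg, pref_deg, kappa) {
  exp(kappa * (cos(2 * (theta_deg - pref_deg) * pi / 180) - 1))
}

# circular mean of the tuning curve: drive of an untuned transient matched
# to the tuned units' average
tuning_flat <- function(kappa) exp(-kappa) * besselI(kappa, 0)

draw_units <- function(pop, session_id, day = 1L) {
  n <- pop$n_units
  fast <- stats::runif(n) < pop$fast_fraction
  b <- stats::rlnorm(n, pop$baseline_meanlog, pop$baseline_sdlog)
  b[fast] <- b[fast] * pop$fast_rate_mult
  # session-average rate exceeds the tonic rate because of the late ongoing
  # component; clip so session rates stay inside rate_range_hz
  sess_factor <- (1.5 - (pop$late_end_s - pop$late_start_s) +
                    pop$late_gain * (pop$late_end_s - pop$late_start_s)) / 1.5
  b <- pmin(pmax(b, pop$rate_range_hz[1] / sess_factor),
            pop$rate_range_hz[2] / sess_factor)
  amp <- stats::rlnorm(n, pop$amp_meanlog, pop$amp_sdlog)
  kappa <- stats::rlnorm(n, pop$k_meanlog, pop$k_sdlog)
  cardinal <- stats::runif(n) < pop$cardinal_bias
  pref <- ifelse(cardinal,
                 (sample(c(0, 90), n, replace = TRUE) +
                    stats::rnorm(n, 0, 10)) %% 180,
                 stats::runif(n, 0, 180))
  n_inf <- round(pop$informative_fraction * n)
  informative <- logical(n)
  if (n_inf > 0) informative[sample.int(n, n_inf)] <- TRUE
  # informative units: stronger evoked drive, preferences clustered near
  # the discriminanda (as observed for consistent predictors)
  amp[informative] <- stats::rlnorm(n_inf, pop$amp_informative_meanlog,
                                    pop$amp_informative_sdlog)
  if (n_inf > 0)
    pref[informative] <- (sample(pop$discriminanda_deg, n_inf,
                                 replace = TRUE) +
                            stats::rnorm(n_inf, 0, pop$informative_pref_sd)) %% 180
  width <- ifelse(fast, stats::rnorm(n, 0.26, 0.04),
                  stats::rnorm(n, 0.54, 0.07))
  width <- pmax(width, 0.07)
  depth <- stats::runif(n, 100, 800)
  tt <- seq(0, 1.6, by = 0.05)
  waveform <- lapply(seq_len(n), function(i) {
    -exp(-((tt - 0.4) / (width[i] / 2))^2) +
      0.45 * exp(-((tt - 0.4 - width[i]) / (width[i]))^2)
  })
  isi <- lapply(seq_len(n), function(i) {
    edges <- seq(0, 0.5, by = 0.02)
    diff(stats::pexp(edges, rate = max(b[i], 0.1)))
  })
  data.frame(unit_id = sprintf("%s_u%02d", session_id, seq_len(n)),
             session_id = session_id, day = day,
             electrode = sprintf("e%02d", seq_len(n)),
             depth_um = depth, layer = assign_layer(depth),
             spike_width_ms = width, mean_rate_hz = b * sess_factor,
             is_single_unit = stats::runif(n) < 0.45,
             baseline_hz = b, amplitude_hz = amp, kappa = kappa,
             pref_deg = pref, informative = informative,
             waveform = I(waveform), isi_histogram = I(isi),
             stringsAsFactors = FALSE)
}

# per unit x trial expected spike count (before the shared gain)
expected_mass <- function(units, cond, window_s, pop) {
  n_units <- nrow(units)
  n_trials <- nrow(cond)
  eff <- ongoing_eff_seconds(window_s, pop)        # per trial (scalar or vec)
  ong <- outer(units$baseline_hz, rep(1, n_trials)) *
    matrix(eff, n_units, n_trials, byrow = TRUE)
  cg <- contrast_gain(cond$contrast, pop$contrast_c50, pop$contrast_n)
  ov <- evoked_overlap_seconds(window_s, cond$duration_ms, pop)
  grating <- cond$duration_ms >= 500
  tune <- matrix(0, n_units, n_trials)
  for (i in seq_len(n_units)) {
    tuned <- grating | units$informative[i]
    tv <- ifelse(is.na(cond$orientation_deg), 0,
                 ifelse(tuned,
                        tuning_value(cond$orientation_deg,
                                     units$pref_deg[i], units$kappa[i]),
                        tuning_flat(units$kappa[i])))
    tune[i, ] <- tv
  }
  evoked <- (units$amplitude_hz * tune) *
    matrix(cg * ov, n_units, n_trials, byrow = TRUE)
  ong + evoked
}

#' Simulate a session of sparse V1 spike counts
#'
#' Generates one session: a unit table, a presentation table, a spike-count
#' matrix for the requested window, and optionally a spike-event table and
#' an arousal trace. With a fixed seed all outputs are bit-identical across
#' runs.
#'
#' @param pop a `population_spec`.
#' @param schedule condition schedule as from [study_grid()].
#' @param window_end_ms end of the count window (onset-aligned), used when
#'   `window_rule = "fixed"`.
#' @param window_rule "fixed" (0 to `window_end_ms` for every trial) or
#'   "stimulus_plus_100" (0 to stimulus duration + 100 ms per trial).
#' @param events also generate a spike-event table (Poisson event times
#'   consistent with the piecewise-constant intensities).
#' @param arousal simulate a two-state slow arousal process driving pupil
#'   size and firing gain.
#' @param session_id session identifier.
#' @param seed integer seed.
#' @return an object of class `sim_session`: list with `scm` (a
#'   [spike_count_matrix()]), `units`, `presentations`, and optionally
#'   `bundle` (a `spike_bundle`) and `arousal` (trace data frame plus
#'   per-trial `arousal_state`).
#' @export
simulate_population <- function(pop, schedule = study_grid(),
                                window_end_ms = 500,
                                window_rule = c("fixed",
                                                "stimulus_plus_100"),
                                events = FALSE, arousal = FALSE,
                                session_id = "s01", seed = NULL) {
  window_rule <- match.arg(window_rule)
  check_columns(schedule, c("orientation_label", "orientation_deg",
                            "contrast", "duration_ms", "n_trials"),
                "population schedule")
  with_seed(seed, {
    units <- draw_units(pop, session_id)
    cond <- schedule[rep(seq_len(nrow(schedule)), schedule$n_trials),
                     c("orientation_label", "orientation_deg", "contrast",
                       "duration_ms"), drop = FALSE]
    cond <- cond[sample.int(nrow(cond)), , drop = FALSE]
    rownames(cond) <- NULL
    n_trials <- nrow(cond)
    cond$trial_index <- seq_len(n_trials)
    iti_s <- 1.5
    cond$onset_time_s <- (cond$trial_index - 1) * iti_s +
      stats::runif(n_trials, 0, 0.2)
    # arousal: slow two-state process (dwell times of seconds)
    ar <- NULL
    state_per_trial <- rep(FALSE, n_trials)
    if (arousal) {
      dt <- 0.05
      t_grid <- seq(0, max(cond$onset_time_s) + 2, by = dt)
      state <- logical(length(t_grid))
      cur <- stats::runif(1) < 0.5
      i <- 1L
      while (i <= length(t_grid)) {
        dwell <- max(stats::rexp(1, 1 / 12), 2)   # mean 12 s, min 2 s
        j <- min(length(t_grid), i + round(dwell / dt))
        state[i:j] <- cur
        cur <- !cur
        i <- j + 1L
      }
      pupil <- 2 + state * 1 + stats::rnorm(length(t_grid), 0, 0.25)
      ar <- data.frame(time_s = t_grid, pupil_size = pupil,
                       running_speed = state * 8 +
                         abs(stats::rnorm(length(t_grid), 0, 1)))
      state_per_trial <- state[findInterval(cond$onset_time_s, t_grid)]
    }
    window_s <- if (window_rule == "fixed") {
      rep(window_end_ms / 1000, n_trials)
    } else (cond$duration_ms + 100) / 1000
    mass <- expected_mass(units, cond, window_s, pop)
    gain <- exp(stats::rnorm(n_trials, 0, pop$shared_gain_sd) -
                  pop$shared_gain_sd^2 / 2)
    if (arousal) gain <- gain * ifelse(state_per_trial, pop$arousal_gain, 1)
    lambda <- sweep(mass, 2, gain, `*`)
    n_clipped <- sum(lambda < 0)
    if (n_clipped > 0) {
      warning(sprintf("%d negative rates clipped to 0", n_clipped),
              call. = FALSE)
      lambda[lambda < 0] <- 0
    }
    counts <- matrix(stats::rpois(length(lambda), lambda),
                     nrow(lambda), ncol(lambda))
    scm <- spike_count_matrix(counts, units$unit_id, cond,
                              window_start_ms = 0,
                              window_end_ms = if (window_rule == "fixed")
                                window_end_ms else NA_real_)
    bundle <- NULL
    if (events) {
      # event times: within-window events uniform over intensity segments
      ev <- vector("list", nrow(units))
      horizon <- max(1.0, window_end_ms / 1000)
      for (i in seq_len(nrow(units))) {
        segs <- segment_table(units[i, ], cond, pop, horizon)
        lam <- segs$rate * segs$len *
          gain[segs$trial]
        k <- stats::rpois(length(lam), lam)
        if (sum(k) == 0) { ev[[i]] <- numeric(0); next }
        idx <- rep(seq_along(k), k)
        times <- segs$start[idx] + stats::runif(sum(k)) * segs$len[idx] +
          cond$onset_time_s[segs$trial[idx]]
        ev[[i]] <- sort(times)
      }
      events_df <- data.frame(
        unit_id = rep(units$unit_id, lengths(ev)),
        spike_time_s = unlist(ev))
      pres <- cond[c("trial_index", "onset_time_s", "orientation_label",
                     "orientation_deg", "contrast", "duration_ms")]
      bundle <- spike_bundle(events_df, pres, units)
      # counts re-derived from events so both views agree exactly
      scm <- count_spikes_in_window(bundle, 0, window_end_ms)
    }
    structure(list(scm = scm, units = units, presentations = cond,
                   bundle = bundle, arousal = ar,
                   arousal_state = state_per_trial,
                   n_clipped = n_clipped, pop = pop,
                   session_id = session_id),
              class = "sim_session")
  })
}

# piecewise-constant intensity segments for one unit across all trials
segment_table <- function(unit, cond, pop, horizon) {
  n_trials <- nrow(cond)
  b <- unit$baseline_hz
  # ongoing: three segments per trial
  on_start <- c(0, pop$late_start_s, pop$late_end_s)
  on_end <- c(pop$late_start_s, pop$late_end_s, horizon)
  on_rate <- c(b, b * pop$late_gain, b)
  grating <- cond$duration_ms >= 500
  tuned <- grating | unit$informative
  tv <- ifelse(is.na(cond$orientation_deg), 0,
               ifelse(tuned,
                      tuning_value(cond$orientation_deg, unit$pref_deg,
                                   unit$kappa),
                      tuning_flat(unit$kappa)))
  cg <- contrast_gain(cond$contrast, pop$contrast_c50, pop$contrast_n)
  ev_rate <- unit$amplitude_hz * cg * tv
  ev_start <- rep(pop$latency_s, n_trials)
  ev_end <- pmin(pop$latency_s + cond$duration_ms / 1000 +
                   pop$evoked_tail_s, horizon)
  trial <- c(rep(seq_len(n_trials), each = 3L), seq_len(n_trials))
  start <- c(rep(on_start, n_trials), ev_start)
  end <- c(rep(on_end, n_trials), ev_end)
  rate <- c(rep(on_rate, times = n_trials), ev_rate)
  data.frame(trial = trial, start = start, len = pmax(end - start, 0),
             rate = rate)
}

#' Calibration summary of a population spec
#'
#' Passes simulated sessions through the measurement pipeline and reports
#' the population statistics the generator is calibrated against: the
#' responsive fraction in the 0-500 ms window, the per-trial spike
#' probability at the strongest condition (stimulus + 100 ms window), and
#' the fraction and mean decoding performance of consistent predictors.
#' Monte-Carlo standard errors accompany each estimate.
#'
#' @param pop a `population_spec`.
#' @param n_sessions sessions to simulate.
#' @param n_splits decoding splits per unit.
#' @param seed integer seed.
#' @return data frame with columns `statistic`, `value`, `mc_se`.
#' @export
calibration_report <- function(pop, n_sessions = 8, n_splits = 100,
                               seed = NULL) {
  seed <- seed %||% 1L
  rf <- numeric(0)
  spike_prob <- numeric(0)
  perf <- numeric(0)
  consistent <- logical(0)
  for (s in seq_len(n_sessions)) {
    sim <- simulate_population(pop, session_id = sprintf("s%02d", s),
                               seed = sub_seed(seed, s))
    rf <- c(rf, responsive_fraction(sim$scm)$fraction)
    sim100 <- simulate_population(pop, window_rule = "stimulus_plus_100",
                                  session_id = sprintf("s%02d", s),
                                  seed = sub_seed(seed, s))
    rp <- response_probability(sim100$scm)
    strongest <- rp[rp$contrast == 1 & rp$duration_ms == 200, ]
    spike_prob <- c(spike_prob,
                    tapply(strongest$prob, strongest$unit_id, mean))
    dec <- decode_session(sim$scm,
                          split_protocol(n_splits = n_splits,
                                         seed = sub_seed(seed, 1000 + s)))
    perf <- c(perf, vapply(dec$results, `[[`, 0, "performance"))
    consistent <- c(consistent,
                    vapply(dec$results, `[[`, TRUE, "consistent"))
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  data.frame(
    statistic = c("responsive_fraction_0_500",
                  "spike_prob_c1_d200_stim100",
                  "consistent_fraction",
                  "consistent_mean_performance"),
    value = c(mean(rf), mean(spike_prob), mean(consistent),
              mean(perf[consistent])),
    mc_se = c(se(rf), se(spike_prob),
              sqrt(mean(consistent) * (1 - mean(consistent)) /
                     length(consistent)),
              se(perf[consistent])))
}
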