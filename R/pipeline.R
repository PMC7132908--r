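# End-to-end pipeline: simulate -> filter/fit psychometrics ->
# characterise units -> decode -> population curves -> required-N
# estimates, with all stage outputs written as CSV and a consolidated
# summary assembled from the stage files (the report layer recomputes
# nothing).

default_pipeline_config <- function() {
  list(
    preset = "v1_default",
    seed = NULL,                      # mandatory, must be supplied
    out_dir = "sparsecode_out",
    n_subjects = 3L,
    behavior_trials_per_level = 150L,
    n_sessions = 4L,
    window_ms = c(0, 500),
    n_splits = 100L,
    train_fraction = 0.7,
    curve_sizes = c(1, 2, 5, 10, 20, 40, 80, 160, 300),
    n_resamples = 200L,
    n_virtual_trials = 200L,
    curve_condition = list(contrast = 0.15, duration_ms = 100),
    n_resamples_avg_subject = 200L,
    mcmc = list(n_chains = 4L, n_warmup = 500L, n_draws = 1500L),
    shuffle_check = TRUE)
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (or takes a list) and merges it over the pipeline
#' defaults. Command-line style overrides win over the file.
#'
#' @param config path to a YAML file, a list, or `NULL` for defaults.
#' @param overrides named list applied last.
#' @return the merged configuration list.
#' @export
pipeline_config <- function(config = NULL, overrides = list()) {
  base <- default_pipeline_config()
  if (is.character(config)) {
    if (!file.exists(config)) stop_sc("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(base, config %||% list())
  cfg <- utils::modifyList(cfg, overrides)
  if (is.null(cfg$seed)) stop_sc("pipeline config: seed is mandatory")
  cfg
}

write_stage <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  write_delim_table(as.data.frame(df), path)
  path
}

#' Run the full analysis pipeline on synthetic (or supplied) data
#'
#' Executes every stage in sequence and writes one CSV per stage plus a
#' consolidated `summary.csv` into the output directory. The configuration
#' actually used is copied to `config_used.yaml` for provenance. A stage
#' failure raises an error naming the stage; outputs of completed stages
#' are retained.
#'
#' @param config as accepted by [pipeline_config()].
#' @param overrides named list of config overrides.
#' @return invisibly, a list with the summary data frame and stage file
#'   paths.
#' @export
run_pipeline <- function(config = NULL, overrides = list()) {
  cfg <- pipeline_config(config, overrides)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config_used.yaml"))
  ps <- preset(cfg$preset)
  files <- list()
  summary_rows <- list()
  add <- function(stat, value) {
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(statistic = stat, value = value)
  }
  stage <- function(name, expr) {
    sc_log("pipeline stage: %s", name)
    tryCatch(expr, error = function(e)
      stop_sc("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ## 1. behaviour -------------------------------------------------------
  trials_by_subject <- list()
  stage("simulate_behavior", {
    sched <- expand.grid(contrast = c(0.15, 1),
                         duration_ms = ps$behavior_durations_ms)
    sched$n_trials <- cfg$behavior_trials_per_level
    for (i in seq_len(cfg$n_subjects)) {
      jit <- with_seed(sub_seed(cfg$seed, 9000 + i),
                       stats::runif(2, 0.9, 1.1))
      trials <- rbind(
        simulate_behavior(
          observer_spec(ps$observer$high$m * jit[1],
                        ps$observer$high$omega * jit[2],
                        ps$observer$high$lapse),
          sched[sched$contrast == 1, ], axis = "duration",
          subject_id = sprintf("m%02d", i),
          seed = sub_seed(cfg$seed, 100 + i)),
        simulate_behavior(
          observer_spec(ps$observer$low$m * jit[1],
                        ps$observer$low$omega * jit[2],
                        ps$observer$low$lapse),
          sched[sched$contrast == 0.15, ], axis = "duration",
          subject_id = sprintf("m%02d", i),
          seed = sub_seed(cfg$seed, 200 + i)))
      trials_by_subject[[i]] <- trials
    }
    files$trials <- write_stage(do.call(rbind, trials_by_subject),
                                cfg$out_dir, "trials")
  })

  ## 2. psychometrics ---------------------------------------------------
  fits <- list()
  stage("fit_psychometrics", {
    rows <- list()
    for (ctr in c(1, 0.15)) {
      sub_trials <- lapply(trials_by_subject, function(tr) {
        flt <- filter_trials(tr[tr$contrast == ctr, ])
        flt$trials
      })
      fit <- fit_psychometric(do.call(rbind, sub_trials), "duration",
                              mcmc = cfg$mcmc,
                              seed = sub_seed(cfg$seed, 300 + ctr * 100))
      avg <- average_subject(sub_trials, "duration",
                             n_resamples = cfg$n_resamples_avg_subject,
                             seed = sub_seed(cfg$seed, 400 + ctr * 100))
      fits[[as.character(ctr)]] <- list(fit = fit, avg = avg)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = ctr,
        tau_ms = fit$threshold,
        tau_ci_lo = fit$ci95["2.5%", "m"],
        tau_ci_hi = fit$ci95["97.5%", "m"],
        omega = fit$map$omega, lapse = fit$map$lapse,
        total_integration_time_ms = fit$total_integration_time_T,
        avg_subject_tau_ms = avg$mean["m"],
        rhat_max = max(fit$rhat), converged = fit$converged)
    }
    psych <- do.call(rbind, rows)
    files$psychometrics <- write_stage(psych, cfg$out_dir, "psychometrics")
    add("tau_high_contrast_ms", psych$tau_ms[psych$contrast == 1])
    add("tau_low_contrast_ms", psych$tau_ms[psych$contrast == 0.15])
    add("T_high_contrast_ms",
        psych$total_integration_time_ms[psych$contrast == 1])
    add("T_low_contrast_ms",
        psych$total_integration_time_ms[psych$contrast == 0.15])
  })

  ## 3. physiology: simulate + characterise + decode --------------------
  sessions <- list()
  stage("simulate_and_decode", {
    unit_rows <- list(); trial_rows <- list()
    for (s in seq_len(cfg$n_sessions)) {
      sim <- simulate_population(ps$population, ps$schedule,
                                 window_end_ms = cfg$window_ms[2],
                                 arousal = TRUE,
                                 session_id = sprintf("s%02d", s),
                                 seed = sub_seed(cfg$seed, 500 + s))
      dec <- decode_session(sim$scm,
                            split_protocol(cfg$train_fraction,
                                           cfg$n_splits,
                                           seed = sub_seed(cfg$seed,
                                                           600 + s)))
      popdec <- fit_population_decoder(
        sim$scm, split_protocol(cfg$train_fraction, cfg$n_splits,
                                seed = sub_seed(cfg$seed, 700 + s)))
      cls <- classify_waveforms(sim$units,
                                seed = sub_seed(cfg$seed, 800 + s))
      spl <- arousal_split(sim$arousal, sim$presentations,
                           cfg$window_ms[1], cfg$window_ms[2])
      rf <- responsive_fraction(sim$scm)
      sessions[[s]] <- list(scm = sim$scm, decode = dec,
                            population = popdec)
      unit_rows[[s]] <- data.frame(
        unit_id = sim$units$unit_id, session_id = sim$units$session_id,
        depth_um = sim$units$depth_um, layer = sim$units$layer,
        spike_width_ms = sim$units$spike_width_ms,
        mean_rate_hz = sim$units$mean_rate_hz,
        waveform_class = cls$labels,
        performance = vapply(dec$results, `[[`, 0, "performance"),
        consistent = vapply(dec$results, `[[`, TRUE, "consistent"))
      trial_rows[[s]] <- data.frame(
        session_id = sim$session_id,
        trial_index = sim$presentations$trial_index,
        responsive_fraction = rf$fraction,
        arousal = spl$trial_labels)
    }
    units_df <- do.call(rbind, unit_rows)
    files$units <- write_stage(units_df, cfg$out_dir, "units")
    files$trial_stats <- write_stage(do.call(rbind, trial_rows),
                                     cfg$out_dir, "trial_stats")
    all_results <- unlist(lapply(sessions, function(s) s$decode$results),
                          recursive = FALSE)
    consum <- consistency_summary(all_results)
    files$decoding <- write_stage(consum, cfg$out_dir, "decoding_summary")
    add("responsive_fraction_mean",
        mean(do.call(rbind, trial_rows)$responsive_fraction))
    add("fraction_consistent", consum$fraction_consistent)
    add("mean_performance_all", consum$mean_performance_all)
    add("mean_performance_consistent",
        consum$mean_performance_consistent)
    add("population_decoder_mean_performance",
        mean(vapply(sessions, function(s) s$population$performance, 0)))
  })

  ## 4. virtual populations --------------------------------------------
  stage("population_model", {
    pool <- virtual_pool(sessions, consistent_only = TRUE)
    curve <- population_curve(pool, cfg$curve_sizes, cfg$curve_condition,
                              n_resamples = cfg$n_resamples,
                              n_trials = cfg$n_virtual_trials,
                              seed = sub_seed(cfg$seed, 900))
    curve_df <- data.frame(size = curve$sizes,
                           median = curve$median_performance,
                           pct2_5 = curve$pct2_5, pct97_5 = curve$pct97_5)
    files$curve <- write_stage(curve_df, cfg$out_dir, "population_curve")
    # behavioural target at the curve condition from the fitted observer
    obs <- if (cfg$curve_condition$contrast >= 1) fits[["1"]] else
      fits[["0.15"]]
    target <- predict_performance(obs$fit$map,
                                  cfg$curve_condition$duration_ms)
    target <- min(max(target, 0.55), 0.95)
    req <- required_population_size(curve, target)
    lapse <- obs$fit$map$lapse
    sens <- noise_model_requirement(curve, target, lapse, "sensory")
    cogn <- noise_model_requirement(curve, target, lapse, "cognitive")
    req_df <- data.frame(
      behavioral_target = target,
      n_required = req$n_required %||% NA,
      n_lo = req$interval[1], n_hi = req$interval[2],
      unreachable = req$unreachable,
      n_required_sensory = if (sens$infeasible) NA else
        sens$requirement$n_required,
      n_required_cognitive = if (cogn$infeasible) NA else
        cogn$requirement$n_required)
    files$requirement <- write_stage(req_df, cfg$out_dir,
                                     "population_requirement")
    add("behavioral_target", target)
    add("n_required", req_df$n_required)
    add("n_required_sensory", req_df$n_required_sensory)
    add("n_required_cognitive", req_df$n_required_cognitive)
    if (isTRUE(cfg$shuffle_check)) {
      scm1 <- sessions[[1]]$scm
      shuf <- shuffle_within_condition(scm1,
                                       seed = sub_seed(cfg$seed, 950))
      perf_orig <- sessions[[1]]$population$performance
      perf_shuf <- fit_population_decoder(
        shuf, split_protocol(cfg$train_fraction, cfg$n_splits,
                             seed = sub_seed(cfg$seed, 700 + 1)))$performance
      files$shuffle <- write_stage(
        data.frame(performance_original = perf_orig,
                   performance_shuffled = perf_shuf),
        cfg$out_dir, "shuffle_check")
      add("shuffle_performance_delta", perf_shuf - perf_orig)
    }
  })

  summary_df <- do.call(rbind, summary_rows)
  files$summary <- write_stage(summary_df, cfg$out_dir, "summary")
  sc_log("pipeline complete: %s", cfg$out_dir)
  invisible(list(summary = summary_df, files = files, config = cfg))
}
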