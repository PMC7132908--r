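# Frozen presets. The v1_default population parameters were calibrated
# once against the published population statistics (responsive fraction,
# spike-probability bound, consistent-predictor prevalence and
# performance) and are version-pinned; do not retune them casually, since
# downstream calibration-consistency checks assume these exact values.

PRESET_VERSION <- "1.0"

#' Retrieve a named preset
#'
#' A preset bundles a behavioural observer pair (high/low contrast, swept
#' over stimulus duration), a V1 population spec and the trial schedule
#' used to exercise the full pipeline.
#'
#' The `v1_default` observers use the average-subject psychometric
#' parameters: threshold integration times of 12 ms (high contrast) and
#' 45 ms (low contrast) with total integration times of 98 and 107 ms and
#' plateau performance of 0.80 / 0.74.
#'
#' @param name preset name; only "v1_default" ships with the package.
#' @return a list with `name`, `version`, `observer` (list `high`, `low`),
#'   `population`, `schedule` (short-stimulus condition grid),
#'   `behavior_durations_ms`, `n_sessions`.
#' @export
preset <- function(name = "v1_default") {
  if (name != "v1_default") stop_sc("unknown preset: %s", name)
  list(
    name = "v1_default",
    version = PRESET_VERSION,
    observer = list(
      high = observer_spec(m = 12, omega = (98 - 12) / log(9), lapse = 0.20),
      low = observer_spec(m = 45, omega = (107 - 45) / log(9), lapse = 0.26)),
    population = v1_default_population(),
    schedule = study_grid(n_per_cell = 50),
    behavior_durations_ms = c(16, 25, 50, 75, 100, 150, 250, 500),
    n_sessions = 20L)
}

# Calibrated population parameters (frozen).
v1_default_population <- function() {
  population_spec(
    n_units = 30,
    baseline_meanlog = log(0.18),
    baseline_sdlog = 0.8,
    fast_fraction = 0.25,
    fast_rate_mult = 2.7,
    rate_range_hz = c(0.2, 80),
    amp_meanlog = log(0.3), amp_sdlog = 0.9,
    k_meanlog = log(0.65), k_sdlog = 0.6,
    cardinal_bias = 0.4,
    contrast_c50 = 0.15, contrast_n = 1.2,
    informative_fraction = 0.25,
    amp_informative_meanlog = log(1.0),
    amp_informative_sdlog = 0.35,
    informative_pref_sd = 15,
    discriminanda_deg = c(45, 135),
    shared_gain_sd = 0.15,
    arousal_gain = 1.25,
    latency_s = 0.05, evoked_tail_s = 0.1,
    late_start_s = 0.3, late_end_s = 0.6, late_gain = 8)
}
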