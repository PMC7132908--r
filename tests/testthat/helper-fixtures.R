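# Shared fixtures, built in code at test time.

options(sparsecode.quiet = TRUE)

make_trials <- function(n = 6, contrast = 1, duration_ms = 100,
                        rt = 1, subject_id = "m01") {
  label <- rep(c("left", "right"), length.out = n)
  data.frame(
    subject_id = rep(subject_id, n), trial_index = seq_len(n),
    orientation_label = label,
    orientation_deg = ifelse(label == "left", 45, 135),
    contrast = rep(contrast, length.out = n),
    duration_ms = rep(duration_ms, length.out = n),
    response = label, correct = rep(TRUE, n),
    reaction_time_s = rep(rt, length.out = n),
    stringsAsFactors = FALSE)
}

make_units <- function(n = 2, session_id = "s01", day = 1L) {
  data.frame(unit_id = sprintf("%s_u%02d", session_id, seq_len(n)),
             session_id = session_id, day = day,
             electrode = sprintf("e%02d", seq_len(n)),
             depth_um = seq(150, by = 120, length.out = n),
             spike_width_ms = 0.5, mean_rate_hz = 2,
             is_single_unit = TRUE, stringsAsFactors = FALSE)
}

make_bundle <- function(spike_times = list(c(0.1, 0.3, 0.6), numeric(0)),
                        n_presentations = 4, iti = 1.5) {
  units <- make_units(length(spike_times))
  onsets <- (seq_len(n_presentations) - 1) * iti
  label <- rep(c("left", "right"), length.out = n_presentations)
  pres <- data.frame(trial_index = seq_len(n_presentations),
                     onset_time_s = onsets,
                     orientation_label = label,
                     orientation_deg = ifelse(label == "left", 45, 135),
                     contrast = 1, duration_ms = 100,
                     stringsAsFactors = FALSE)
  # spike_times are offsets from the first onset for unit i
  events <- data.frame(
    unit_id = rep(units$unit_id, lengths(spike_times)),
    spike_time_s = unlist(spike_times))
  spike_bundle(events, pres, units)
}

# tiny deterministic spike-count matrix: unit 1 informative, unit 2 not
make_scm <- function(n_per_class = 30, seed = 1) {
  withr::local_seed(seed)
  label <- rep(c("left", "right"), each = n_per_class)
  counts <- rbind(ifelse(label == "right", 5L, 0L),
                  rpois(2 * n_per_class, 1))
  cond <- data.frame(orientation_label = label,
                     orientation_deg = ifelse(label == "left", 45, 135),
                     contrast = 1, duration_ms = 100)
  spike_count_matrix(counts, c("u1", "u2"), cond, 0, 500)
}

expect_seed_identical <- function(expr, seed) {
  a <- eval.parent(substitute(expr))
  b <- eval.parent(substitute(expr))
  expect_identical(a, b)
}
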