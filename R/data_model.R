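# Core domain tables, delimited-text I/O and unit bookkeeping.
#
# All tables are plain delimited text (comma by default, tab accepted) with
# required named headers. Units of measure are fixed per column: times in
# seconds, stimulus durations in milliseconds, electrode depths in
# micrometres. Vector-valued fields (waveforms, ISI histograms) are stored
# in a single column as ";"-joined numbers.

TRIAL_COLUMNS <- c("subject_id", "trial_index", "orientation_label",
                   "orientation_deg", "contrast", "duration_ms",
                   "response", "correct", "reaction_time_s")

UNIT_COLUMNS <- c("unit_id", "session_id", "day", "electrode", "depth_um",
                  "spike_width_ms", "mean_rate_hz", "is_single_unit")

#' Detect the field delimiter of a delimited text file
#' @param path file path.
#' @return "," or "\t".
#' @keywords internal
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) return(",")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop_sc("file not found: %s", path)
  delim <- delim %||% detect_delim(path)
  utils::read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

write_delim_table <- function(df, path, delim = ",") {
  out <- df
  for (j in seq_along(out)) out[[j]] <- format_full(out[[j]])
  utils::write.table(out, path, sep = delim, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a 2AFC behavioural trial table
#'
#' Reads one row per trial with the stimulus condition, the subject's
#' response and its reaction time. Categorical fields are validated and
#' bound violations are reported with their row numbers.
#'
#' Required columns: `subject_id`, `trial_index`, `orientation_label`
#' (left/right/none), `orientation_deg` (degrees in \[0,180), `NA` for
#' zero-contrast trials), `contrast` (in \[0,1\]), `duration_ms` (> 0),
#' `response` (left/right), `correct` (logical/0-1), `reaction_time_s`.
#'
#' @param path path to a CSV/TSV file.
#' @param delim field delimiter; autodetected from the header when `NULL`.
#' @return a `data.frame` of validated trial records.
#' @export
read_trials <- function(path, delim = NULL) {
  df <- read_delim_table(path, delim)
  check_columns(df, TRIAL_COLUMNS, "trial table")
  if (nrow(df) == 0L) {
    warning("trial table has a header but no rows", call. = FALSE)
    return(validate_trials(df))
  }
  validate_trials(df)
}

#' Validate an in-memory trial table
#' @param df data frame with the trial-table columns.
#' @return the validated (type-coerced) data frame.
#' @export
validate_trials <- function(df) {
  check_columns(df, TRIAL_COLUMNS, "trial table")
  df$correct <- as.logical(df$correct)
  for (col in c("orientation_deg", "contrast", "duration_ms",
                "reaction_time_s")) df[[col]] <- as.numeric(df[[col]])
  df$trial_index <- as.integer(df$trial_index)
  bad_row <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0L)
      stop_sc("trial table: %s in row(s) %s", what,
              paste(utils::head(bad, 10L), collapse = ", "))
  }
  bad_row(df$orientation_label %in% c("left", "right", "none"),
          "orientation_label not one of left/right/none")
  bad_row(df$response %in% c("left", "right"),
          "response not one of left/right")
  bad_row(is.finite(df$contrast) & df$contrast >= 0 & df$contrast <= 1,
          "contrast outside [0, 1]")
  bad_row(is.finite(df$duration_ms) & df$duration_ms > 0,
          "non-positive duration_ms")
  bad_row(is.finite(df$reaction_time_s) & df$reaction_time_s >= 0,
          "negative or non-finite reaction_time_s")
  # contrast 0 carries no orientation: label must be "none"
  bad_row(df$contrast > 0 | df$orientation_label == "none",
          "zero-contrast trial with an orientation label")
  df
}

#' Write a trial table to delimited text
#'
#' Numeric columns are written at full double precision so that
#' write-then-read round-trips reproduce values exactly.
#'
#' @param df trial table.
#' @param path output path.
#' @param delim field delimiter.
#' @return the path, invisibly.
#' @export
write_trials <- function(df, path, delim = ",") {
  check_columns(df, TRIAL_COLUMNS, "trial table")
  write_delim_table(df[TRIAL_COLUMNS], path, delim)
}

parse_vector_field <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

join_vector_field <- function(v) {
  vapply(v, function(x) paste(sprintf("%.17g", x), collapse = ";"), "")
}

#' Read spike events, stimulus presentations and unit metadata
#'
#' Reads three cross-referenced delimited files and joins them into an
#' in-memory bundle. Spikes referencing unknown units are counted, logged
#' and dropped. Duplicated presentation `trial_index` values and
#' non-monotone per-unit spike times are errors.
#'
#' @param events_path CSV/TSV with columns `unit_id`, `spike_time_s`.
#' @param presentations_path CSV/TSV with `trial_index`, `onset_time_s` and
#'   the stimulus condition columns `orientation_label`, `orientation_deg`,
#'   `contrast`, `duration_ms`.
#' @param units_path CSV/TSV of unit metadata (see `UNIT_COLUMNS`); the
#'   optional `waveform` and `isi_histogram` columns hold ";"-joined
#'   numbers.
#' @param delim field delimiter; autodetected when `NULL`.
#' @return an object of class `spike_bundle`: a list with `events`,
#'   `presentations`, `units` and `n_orphan_spikes`.
#' @export
read_spikes <- function(events_path, presentations_path, units_path,
                        delim = NULL) {
  events <- read_delim_table(events_path, delim)
  check_columns(events, c("unit_id", "spike_time_s"), "spike events")
  pres <- read_delim_table(presentations_path, delim)
  check_columns(pres, c("trial_index", "onset_time_s", "orientation_label",
                        "orientation_deg", "contrast", "duration_ms"),
                "presentations")
  units <- read_delim_table(units_path, delim)
  check_columns(units, UNIT_COLUMNS, "unit table")
  for (col in c("waveform", "isi_histogram"))
    if (col %in% names(units)) units[[col]] <- parse_vector_field(units[[col]])
  spike_bundle(events, pres, units)
}

#' Assemble a spike bundle from in-memory tables
#' @param events data frame of (unit_id, spike_time_s).
#' @param presentations data frame of presentations with condition columns.
#' @param units unit metadata table.
#' @return a `spike_bundle` object.
#' @export
spike_bundle <- function(events, presentations, units) {
  if (anyDuplicated(presentations$trial_index))
    stop_sc("presentations: duplicated trial_index")
  known <- events$unit_id %in% units$unit_id
  n_orphan <- sum(!known)
  if (n_orphan > 0L) {
    sc_log("read_spikes: dropped %d orphan spike(s) with unknown unit_id",
           n_orphan)
    events <- events[known, , drop = FALSE]
  }
  events$spike_time_s <- as.numeric(events$spike_time_s)
  for (uid in unique(events$unit_id)) {
    st <- events$spike_time_s[events$unit_id == uid]
    if (is.unsorted(st))
      stop_sc("spike events: non-monotone spike times for unit %s", uid)
  }
  units$depth_um <- as.numeric(units$depth_um)
  if (any(units$depth_um < 0, na.rm = TRUE))
    stop_sc("unit table: negative depth_um")
  units$layer <- assign_layer(units$depth_um)
  structure(list(events = events, presentations = presentations,
                 units = units, n_orphan_spikes = n_orphan),
            class = "spike_bundle")
}

#' @export
print.spike_bundle <- function(x, ...) {
  cat(sprintf("<spike_bundle> %d units, %d spikes, %d presentations\n",
              nrow(x$units), nrow(x$events), nrow(x$presentations)))
  invisible(x)
}

#' Write a spike bundle back to delimited text
#' @param bundle a `spike_bundle`.
#' @param events_path,presentations_path,units_path output paths.
#' @param delim field delimiter.
#' @return invisibly, the three paths.
#' @export
write_spikes <- function(bundle, events_path, presentations_path, units_path,
                         delim = ",") {
  write_delim_table(bundle$events, events_path, delim)
  write_delim_table(bundle$presentations, presentations_path, delim)
  units <- bundle$units
  for (col in c("waveform", "isi_histogram"))
    if (col %in% names(units)) units[[col]] <- join_vector_field(units[[col]])
  units$layer <- NULL
  write_delim_table(units, units_path, delim)
  invisible(c(events_path, presentations_path, units_path))
}

#' Assign a cortical layer label from recording depth
#'
#' Depths shallower than 400 um are superficial (L2/3), deeper than 450 um
#' are deep (L5/6). Depths falling in the 400-450 um gap between the two
#' definitions are labelled `ambiguous` and excluded from layer contrasts.
#'
#' @param depth_um numeric vector of electrode depths (micrometres, >= 0).
#' @return character vector: "superficial", "deep" or "ambiguous".
#' @export
assign_layer <- function(depth_um) {
  if (any(depth_um < 0, na.rm = TRUE)) stop_sc("negative depth_um")
  out <- rep("ambiguous", length(depth_um))
  out[depth_um < 400] <- "superficial"
  out[depth_um > 450] <- "deep"
  out[is.na(depth_um)] <- NA_character_
  out
}

#' Detect duplicate units recorded across days
#'
#' Chronically implanted probes can pick up the same cell on consecutive
#' days. Units recorded on the same electrode at the same depth on
#' consecutive days whose mean waveforms and ISI histograms both correlate
#' with Pearson r > 0.95 are grouped (transitively across days), and only
#' the earliest-day unit of each group is retained for analysis. Waveforms
#' are correlated as stored (no normalisation). Zero-variance vectors make
#' the correlation undefined and are treated as non-duplicates with a
#' warning.
#'
#' @param units unit table with list-columns `waveform` and
#'   `isi_histogram` plus `electrode`, `depth_um`, `day`.
#' @param r_threshold Pearson correlation threshold (default 0.95).
#' @return a list with `keep` (unit ids retained), `drop` (ids removed) and
#'   `groups` (data frame mapping each kept unit to its dropped
#'   duplicates, ";"-joined).
#' @export
detect_duplicate_units <- function(units, r_threshold = 0.95) {
  check_columns(units, c("unit_id", "electrode", "depth_um", "day"),
                "unit table")
  stopifnot(is.list(units$waveform), is.list(units$isi_histogram))
  n <- nrow(units)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  safe_cor <- function(a, b) {
    if (length(a) != length(b) || length(a) < 2L) return(NA_real_)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance waveform/ISI vector; treated as non-duplicate",
              call. = FALSE)
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  key <- paste(units$electrode, units$depth_um, sep = "@")
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    idx <- idx[order(units$day[idx])]
    for (a in seq_len(length(idx) - 1L)) {
      i <- idx[a]; j <- idx[a + 1L]
      if (units$day[j] - units$day[i] != 1L) next  # consecutive days only
      rw <- safe_cor(units$waveform[[i]], units$waveform[[j]])
      ri <- safe_cor(units$isi_histogram[[i]], units$isi_histogram[[j]])
      if (!is.na(rw) && !is.na(ri) && rw > r_threshold && ri > r_threshold)
        union_(i, j)
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  keep_idx <- vapply(split(seq_len(n), root), function(g) {
    g[which.min(units$day[g])]
  }, 1L)
  keep <- units$unit_id[sort(keep_idx)]
  drop <- setdiff(units$unit_id, keep)
  groups <- do.call(rbind, lapply(split(seq_len(n), root), function(g) {
    first <- g[which.min(units$day[g])]
    data.frame(kept_unit = units$unit_id[first],
               dropped_units = paste(units$unit_id[setdiff(g, first)],
                                     collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  sc_log("detect_duplicate_units: %d unit(s) in, %d kept, %d dropped",
         n, length(keep), length(drop))
  list(keep = keep, drop = drop, groups = groups)
}

#' Construct a spike-count matrix
#'
#' Container for integer spike counts (units x trials) extracted in a fixed
#' post-onset window, together with the per-trial stimulus conditions.
#'
#' @param counts integer matrix, units in rows, trials in columns.
#' @param unit_ids character vector, one per row.
#' @param conditions data frame with one row per trial: `orientation_label`,
#'   `orientation_deg`, `contrast`, `duration_ms` (plus optional extras such
#'   as `trial_index` or `session_id`).
#' @param window_start_ms,window_end_ms count window relative to stimulus
#'   onset, `window_end_ms > window_start_ms`.
#' @return an object of class `spike_count_matrix`.
#' @export
spike_count_matrix <- function(counts, unit_ids, conditions,
                               window_start_ms = 0, window_end_ms = 500) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_sc("counts must be non-negative integers")
  if (!is.na(window_end_ms) && window_end_ms <= window_start_ms)
    stop_sc("window_end_ms must exceed window_start_ms")
  stopifnot(length(unit_ids) == nrow(counts),
            nrow(conditions) == ncol(counts))
  storage.mode(counts) <- "integer"
  rownames(counts) <- unit_ids
  structure(list(counts = counts, unit_ids = unit_ids,
                 conditions = conditions, window_start_ms = window_start_ms,
                 window_end_ms = window_end_ms),
            class = "spike_count_matrix")
}

#' @export
print.spike_count_matrix <- function(x, ...) {
  cat(sprintf(
    "<spike_count_matrix> %d units x %d trials, window %g-%g ms\n",
    nrow(x$counts), ncol(x$counts), x$window_start_ms, x$window_end_ms))
  invisible(x)
}

#' Condition key strings for a set of trials
#'
#' Collapses the stimulus condition columns into one label per trial, used
#' for stratified splitting, response tabulation and within-condition
#' shuffling.
#'
#' @param conditions per-trial condition data frame.
#' @param include_orientation include the left/right label in the key.
#' @return character vector of keys.
#' @export
condition_key <- function(conditions, include_orientation = TRUE) {
  base <- paste(sprintf("%g", conditions$contrast),
                sprintf("%g", conditions$duration_ms), sep = "|")
  if (include_orientation)
    base <- paste(conditions$orientation_label, base, sep = "|")
  base
}

#' Read an arousal trace (pupil size, optional running speed)
#' @param path CSV/TSV with columns `time_s`, `pupil_size` and optionally
#'   `running_speed`.
#' @param delim field delimiter; autodetected when `NULL`.
#' @return data frame with non-decreasing `time_s`.
#' @export
read_arousal <- function(path, delim = NULL) {
  df <- read_delim_table(path, delim)
  check_columns(df, c("time_s", "pupil_size"), "arousal trace")
  if (is.unsorted(df$time_s)) stop_sc("arousal trace: time_s not sorted")
  df
}
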