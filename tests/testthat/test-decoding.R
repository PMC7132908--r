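test_that("perfectly separable counts decode perfectly and consistently", {
  scm <- make_scm(n_per_class = 30)
  res <- fit_single_unit_decoder(scm$counts[1, ],
                                 scm$conditions$orientation_label,
                                 scm$conditions,
                                 split_protocol(n_splits = 40, seed = 1))
  expect_equal(res$performance, 1)
  expect_true(res$consistent)
  # separation is handled by the penalised path, and flagged
  expect_gt(res$n_flagged_fits, 0)
})

test_that("uninformative counts decode at chance", {
  withr::local_seed(2)
  n <- 400
  label <- rep(c("left", "right"), each = n / 2)
  counts <- rpois(n, 2)
  res <- fit_single_unit_decoder(counts, label,
                                 protocol = split_protocol(n_splits = 50,
                                                           seed = 3))
  expect_lt(abs(res$performance - 0.5), 0.06)
  expect_false(res$consistent)
})

test_that("performance is symmetric under label exchange", {
  withr::local_seed(4)
  n <- 300
  label <- rep(c("left", "right"), each = n / 2)
  counts <- rpois(n, ifelse(label == "right", 3, 1.5))
  res <- fit_single_unit_decoder(counts, label,
                                 protocol = split_protocol(n_splits = 40,
                                                           seed = 5))
  flipped <- ifelse(label == "left", "right", "left")
  res2 <- fit_single_unit_decoder(counts, flipped,
                                  protocol = split_protocol(n_splits = 40,
                                                            seed = 5))
  expect_equal(res$performance, res2$performance, tolerance = 1e-12)
  expect_equal(res$coefficient_mean, -res2$coefficient_mean,
               tolerance = 1e-8)
})

test_that("decoder accuracy approaches but does not beat the Bayes bound", {
  # enumeration oracle for Poisson(1) vs Poisson(3)
  ks <- 0:60
  bayes <- 0.5 * sum(pmax(dpois(ks, 1), dpois(ks, 3)))
  expect_equal(bayes, 0.768, tolerance = 0.001)
  withr::local_seed(6)
  n <- 5000
  label <- rep(c("left", "right"), each = n / 2)
  counts <- rpois(n, ifelse(label == "right", 3, 1))
  res <- fit_single_unit_decoder(counts, label,
                                 protocol = split_protocol(n_splits = 50,
                                                           seed = 7))
  expect_lt(abs(res$performance - bayes), 0.02)
  expect_lt(res$performance, bayes + 0.02)
  expect_true(res$consistent)
})

test_that("splits are stratified, seeded and cover every condition", {
  strata <- rep(c("a", "b", "c"), times = c(40, 6, 2))
  withr::local_seed(8)
  for (i in 1:20) {
    tr <- sparsecode:::stratified_split(strata, 0.7)
    for (s in unique(strata)) {
      expect_true(any(tr[strata == s]))
      expect_true(any(!tr[strata == s]))
    }
  }
  scm <- make_scm(40)
  r1 <- fit_single_unit_decoder(scm$counts[2, ],
                                scm$conditions$orientation_label,
                                scm$conditions,
                                split_protocol(n_splits = 20, seed = 9))
  r2 <- fit_single_unit_decoder(scm$counts[2, ],
                                scm$conditions$orientation_label,
                                scm$conditions,
                                split_protocol(n_splits = 20, seed = 9))
  expect_identical(r1$per_split, r2$per_split)
})

test_that("zero-contrast trials are excluded but reported as a diagnostic", {
  withr::local_seed(10)
  n <- 200
  label <- c(rep(c("left", "right"), each = n / 2), rep("none", 60))
  counts <- c(rpois(n, ifelse(rep(c("left", "right"), each = n / 2) ==
                                "right", 4, 1)), rpois(60, 1))
  cond <- data.frame(orientation_label = label,
                     orientation_deg = NA, contrast = c(rep(1, n),
                                                        rep(0, 60)),
                     duration_ms = 100)
  res <- fit_single_unit_decoder(counts, label, cond,
                                 split_protocol(n_splits = 30, seed = 11))
  expect_false(is.na(res$zero_contrast_right_fraction))
  # low counts at zero contrast lean toward the "left" (low-count) class
  expect_lt(res$zero_contrast_right_fraction, 0.5)
  # single-class data error
  expect_error(
    fit_single_unit_decoder(rpois(40, 1), rep("left", 40),
                            protocol = split_protocol(n_splits = 5)),
    "single-class")
})

test_that("the population decoder reduces to the unit decoder and pools gains", {
  # single-unit session: population fit equals the unit fit up to split noise
  withr::local_seed(12)
  n <- 400
  label <- rep(c("left", "right"), each = n / 2)
  counts <- matrix(rpois(n, ifelse(label == "right", 2.5, 1.5)), 1)
  cond <- data.frame(orientation_label = label, orientation_deg = NA,
                     contrast = 1, duration_ms = 100)
  scm <- spike_count_matrix(counts, "u1", cond)
  pop_res <- fit_population_decoder(scm, split_protocol(n_splits = 40,
                                                        seed = 13))
  unit_res <- fit_single_unit_decoder(counts[1, ], label, cond,
                                      split_protocol(n_splits = 40,
                                                     seed = 13))
  expect_lt(abs(pop_res$performance - unit_res$performance), 0.03)
  # many weakly informative independent units beat the best single unit
  m <- 20
  counts_m <- t(vapply(seq_len(m), function(i)
    rpois(n, ifelse(label == "right", 1.5, 1.0)), numeric(n)))
  scm_m <- spike_count_matrix(counts_m, sprintf("u%02d", 1:m), cond)
  pop_m <- fit_population_decoder(scm_m, split_protocol(n_splits = 30,
                                                        seed = 14))
  dec_m <- decode_session(scm_m, split_protocol(n_splits = 30, seed = 15))
  best_single <- max(vapply(dec_m$results, `[[`, 0, "performance"))
  expect_gt(pop_m$performance, best_single)
  # uninformative session stays at chance
  counts_0 <- matrix(rpois(10 * n, 1.5), 10)
  scm_0 <- spike_count_matrix(counts_0, sprintf("z%02d", 1:10), cond)
  pop_0 <- fit_population_decoder(scm_0, split_protocol(n_splits = 30,
                                                        seed = 16))
  expect_lt(abs(pop_0$performance - 0.5), 0.05)
})

test_that("a single-window sweep equals calling the decoder directly", {
  pop <- population_spec(n_units = 4, baseline_meanlog = log(1.5),
                         informative_fraction = 0.5)
  sim <- simulate_population(pop, study_grid(n_per_cell = 15),
                             events = TRUE, seed = 17)
  sw <- suppressWarnings(
    window_sweep(sim$bundle, windows_ms = 500,
                 protocol = split_protocol(n_splits = 20, seed = 18)))
  direct <- decode_session(
    suppressWarnings(count_spikes_in_window(sim$bundle, 0, 500)),
    split_protocol(n_splits = 20, seed = 18))
  expect_equal(sw$mean_performance, direct$summary$mean_performance_all)
  expect_equal(sw$n_consistent, direct$summary$n_consistent)
})

test_that("decoding performance grows with windows that add signal, not noise", {
  # signal confined to early time: performance should not keep rising for
  # windows far beyond the response
  pop <- population_spec(n_units = 8, informative_fraction = 1,
                         amp_informative_meanlog = log(10),
                         amp_informative_sdlog = 0.2,
                         informative_pref_sd = 5,
                         k_meanlog = log(2), k_sdlog = 0.1,
                         baseline_meanlog = log(0.5),
                         late_gain = 1, shared_gain_sd = 0)
  sched <- study_grid(contrasts = 1, durations_ms = 200, n_per_cell = 80)
  sim <- simulate_population(pop, sched, events = TRUE, seed = 19)
  sw <- suppressWarnings(
    window_sweep(sim$bundle, windows_ms = c(100, 400, 1000),
                 protocol = split_protocol(n_splits = 20, seed = 20)))
  # evoked interval ends at 350 ms: the 400 ms window captures it all
  expect_gt(sw$mean_performance[2], sw$mean_performance[1] - 0.02)
  expect_lt(sw$mean_performance[3], sw$mean_performance[2] + 0.02)
})

test_that("consistency summaries aggregate correctly", {
  expect_equal(consistency_summary(list())$n_units, 0L)
  scm <- make_scm(30)
  dec <- decode_session(scm, split_protocol(n_splits = 30, seed = 21))
  expect_equal(dec$summary$n_units, 2L)
  expect_equal(dec$summary$mean_performance_all,
               mean(vapply(dec$results, `[[`, 0, "performance")))
  expect_true(dec$summary$ci_lower <= dec$summary$fraction_consistent)
})
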