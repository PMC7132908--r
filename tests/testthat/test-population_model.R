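# helpers: build a small decoded pool from a synthetic session
make_pool <- function(n_units = 10, informative = 1, amp = log(3),
                      n_per_cell = 40, seed = 30, consistent_only = FALSE,
                      shared_gain_sd = 0) {
  pop <- population_spec(n_units = n_units,
                         informative_fraction = informative,
                         amp_informative_meanlog = amp,
                         amp_informative_sdlog = 0.2,
                         informative_pref_sd = 8,
                         shared_gain_sd = shared_gain_sd)
  sched <- study_grid(contrasts = c(0, 0.15, 1),
                      durations_ms = c(100, 200), n_per_cell = n_per_cell)
  sim <- simulate_population(pop, sched, seed = seed)
  dec <- decode_session(sim$scm, split_protocol(n_splits = 30,
                                                seed = seed + 1))
  list(pool = virtual_pool(list(list(scm = sim$scm, decode = dec)),
                           consistent_only = consistent_only),
       sim = sim, dec = dec)
}

test_that("a virtual session of N = 1 reduces to the unit's own accuracy", {
  made <- make_pool(n_units = 4)
  pool <- made$pool
  cond <- list(contrast = 1, duration_ms = 200)
  accs <- replicate(40, build_virtual_session(
    pool, 1, cond, n_trials = 100,
    seed = sample.int(1e6, 1))$accuracy)
  # mean over resamples is within resampling noise of the mean unit
  # decoder accuracy at that condition's difficulty scale
  expect_gt(mean(accs), 0.5)
  expect_true(all(accs >= 0 & accs <= 1))
})

test_that("zero-contrast virtual sessions are at chance", {
  made <- make_pool(n_units = 6)
  vs <- build_virtual_session(made$pool, 10,
                              list(contrast = 0, duration_ms = 100),
                              n_trials = 1000, seed = 31)
  expect_lt(abs(vs$accuracy - 0.5), 3 * sqrt(0.25 / 1000) + 0.02)
})

test_that("pooling identical-quality units never hurts: accuracy rises with N", {
  made <- make_pool(n_units = 8, amp = log(2.2))
  curve <- population_curve(made$pool, c(1, 3, 10, 30),
                            list(contrast = 1, duration_ms = 200),
                            n_resamples = 120, n_trials = 120, seed = 32)
  med <- curve$median_performance
  band <- curve$pct97_5 - curve$pct2_5
  # non-decreasing within one band width of Monte-Carlo slack
  expect_true(all(diff(med) > -band[-1]))
  expect_gt(med[4], med[1])
  # bands contain the medians
  expect_true(all(curve$pct2_5 <= med & med <= curve$pct97_5))
})

test_that("an uninformative pool stays flat at chance", {
  # large response tables: virtual sessions resample the very tables the
  # decoders were fit on, so small tables would leak finite-sample optimism
  made <- make_pool(n_units = 8, informative = 0, n_per_cell = 200)
  curve <- population_curve(made$pool, c(1, 5, 20),
                            list(contrast = 1, duration_ms = 200),
                            n_resamples = 60, n_trials = 100, seed = 33)
  expect_true(all(abs(curve$median_performance - 0.5) < 0.06))
})

test_that("single-resample curves collapse onto one value", {
  made <- make_pool(n_units = 4)
  curve <- population_curve(made$pool, c(2, 8),
                            list(contrast = 1, duration_ms = 200),
                            n_resamples = 1, n_trials = 50, seed = 34)
  expect_equal(curve$median_performance, curve$pct2_5)
  expect_equal(curve$median_performance, curve$pct97_5)
})

test_that("required population size reads the median curve correctly", {
  curve <- structure(list(
    sizes = c(1, 5, 10, 50),
    median_performance = c(0.6, 0.7, 0.8, 0.85),
    pct2_5 = c(0.55, 0.65, 0.75, 0.8),
    pct97_5 = c(0.65, 0.75, 0.85, 0.9),
    accuracy = matrix(rep(c(0.6, 0.7, 0.8, 0.85), 10), 4),
    n_resamples = 10), class = "population_curve")
  # already above target at the smallest size
  expect_equal(required_population_size(curve, 0.55)$n_required, 1)
  expect_equal(required_population_size(curve, 0.75)$n_required, 10)
  # unreachable plateau
  expect_true(required_population_size(curve, 0.95)$unreachable)
  expect_error(required_population_size(curve, 0.4), "behavioral_target")
})

test_that("within-condition shuffling preserves marginals and removes correlations", {
  pop <- population_spec(n_units = 6, shared_gain_sd = 0.7,
                         informative_fraction = 0,
                         baseline_meanlog = log(4))
  sim <- simulate_population(pop, study_grid(n_per_cell = 50), seed = 35)
  scm <- sim$scm
  shuf <- shuffle_within_condition(scm, seed = 36)
  key <- condition_key(scm$conditions)
  for (i in seq_len(nrow(scm$counts)))
    for (k in unique(key)) {
      sel <- key == k
      expect_identical(sort(scm$counts[i, sel]), sort(shuf$counts[i, sel]))
    }
  # shared-gain correlations drop to ~0 after the shuffle
  mean_off <- function(m) {
    cc <- cor(t(m))
    mean(cc[upper.tri(cc)])
  }
  expect_gt(mean_off(scm$counts), 0.1)
  expect_lt(abs(mean_off(shuf$counts)), 3 / sqrt(ncol(scm$counts)))
})

test_that("shuffling is a decoding no-op for independent units", {
  made <- make_pool(n_units = 8, amp = log(2), n_per_cell = 50,
                    shared_gain_sd = 0)
  scm <- made$sim$scm
  proto <- split_protocol(n_splits = 40, seed = 37)
  orig <- fit_population_decoder(scm, proto)$performance
  shuf <- fit_population_decoder(shuffle_within_condition(scm, seed = 38),
                                 proto)$performance
  # 2 MC SE of a split-mean accuracy on the test sets
  n_test <- round(0.3 * sum(scm$conditions$contrast > 0))
  expect_lt(abs(orig - shuf), 2 * sqrt(0.25 / n_test) + 0.02)
})

test_that("cognitive noise needs at least as many neurons as sensory noise", {
  # closed-form target transformation
  nm <- noise_model_requirement(
    structure(list(sizes = 1, median_performance = 1, pct2_5 = 1,
                   pct97_5 = 1, accuracy = matrix(1), n_resamples = 1),
              class = "population_curve"),
    0.74, 0.2, "cognitive")
  expect_equal(nm$decoder_target, (0.74 - 0.1) / 0.8)
  made <- make_pool(n_units = 8, amp = log(2.2))
  curve <- population_curve(made$pool, c(1, 2, 5, 10, 20, 40),
                            list(contrast = 1, duration_ms = 200),
                            n_resamples = 80, n_trials = 120, seed = 39)
  for (lapse in c(0, 0.1, 0.25)) {
    sens <- noise_model_requirement(curve, 0.7, lapse, "sensory")
    cogn <- noise_model_requirement(curve, 0.7, lapse, "cognitive")
    if (lapse == 0) {
      expect_equal(sens$decoder_target, cogn$decoder_target)
    } else if (!cogn$requirement$unreachable &&
               !sens$requirement$unreachable) {
      expect_gte(cogn$requirement$n_required, sens$requirement$n_required)
    }
  }
})

test_that("curves are reproducible under a fixed seed", {
  made <- make_pool(n_units = 5)
  cond <- list(contrast = 1, duration_ms = 200)
  c1 <- population_curve(made$pool, c(1, 4), cond, n_resamples = 20,
                         n_trials = 40, seed = 40)
  c2 <- population_curve(made$pool, c(1, 4), cond, n_resamples = 20,
                         n_trials = 40, seed = 40)
  expect_identical(c1$accuracy, c2$accuracy)
})
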