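test_that("the psychometric function hits its asymptotes and midpoints", {
  m0 <- psychometric_model(m = 45, omega = 15, lapse = 0)
  # lower asymptote: far below threshold performance is the guessing rate
  expect_equal(predict_performance(m0, 45 - 40 * 15), 0.5, tolerance = 1e-9)
  # at s = m, performance is halfway up the dynamic range
  expect_equal(predict_performance(m0, 45), 0.75)
  m1 <- psychometric_model(45, 15, lapse = 0.2)
  # logistic(log 9) = 0.9 exactly
  expect_equal(predict_performance(m1, 45 + 15 * log(9)),
               0.5 + 0.3 * 0.9, tolerance = 1e-12)
  expect_error(predict_performance(list(m = 1, omega = -1, lapse = 0,
                                        guess = 0.5), 1), "omega")
})

test_that("predicted performance is monotone non-decreasing in s", {
  withr::local_seed(11)
  for (i in 1:25) {
    mod <- psychometric_model(runif(1, -50, 200), runif(1, 0.5, 80),
                              runif(1, 0, 0.49))
    s <- sort(runif(50, -500, 800))
    p <- predict_performance(mod, s)
    expect_true(all(diff(p) >= -1e-12))
    expect_true(all(p >= 0.5 - 1e-12 & p <= 1 - mod$lapse + 1e-12))
  }
})

test_that("reaction-time filtering keeps [0.05, 5] s inclusive", {
  tr <- make_trials(3, rt = c(0.04, 1.0, 6.0))
  out <- filter_trials(tr)
  expect_equal(out$trials$reaction_time_s, 1.0)
  expect_equal(out$report$n_fast_excluded, 1L)
  expect_equal(out$report$n_slow_excluded, 1L)
  expect_equal(out$report$n_input,
               out$report$n_kept + out$report$n_fast_excluded +
                 out$report$n_slow_excluded)
  # boundaries are inclusive
  tr2 <- make_trials(2, rt = c(0.05, 5))
  expect_equal(filter_trials(tr2)$report$n_kept, 2L)
  # empty input
  empty <- filter_trials(make_trials(0))
  expect_equal(empty$report$n_input, 0L)
  expect_equal(nrow(empty$trials), 0L)
})

test_that("total integration time has the closed form m + omega log 9", {
  expect_equal(total_integration_time(psychometric_model(45, 20, 0.1)),
               45 + 20 * log(9))
  # step-function limit: T -> m as omega -> 0
  expect_equal(total_integration_time(psychometric_model(45, 1e-6, 0.1)),
               45, tolerance = 1e-4)
  # closed form agrees with the numerical root of the defining equation
  mod <- psychometric_model(12, 39.1, 0.2)
  T_closed <- total_integration_time(mod)
  g <- 0.5
  f <- function(T) (predict_performance(mod, T) - g) -
    0.9 * ((1 - mod$lapse) - g)
  T_root <- uniroot(f, c(mod$m, mod$m + 20 * mod$omega), tol = 1e-10)$root
  expect_equal(T_closed, T_root, tolerance = 1e-6)
  # the average-subject-like parameters give T near 98 ms
  expect_equal(T_closed, 97.9, tolerance = 0.01)
  # absolute-scale 90% criterion sits below the range-relative one
  expect_lt(total_integration_time(psychometric_model(45, 15, 0.05),
                                   relative = FALSE),
            total_integration_time(psychometric_model(45, 15, 0.05)))
})

test_that("Clopper-Pearson intervals match closed forms and contain k/n", {
  ci <- clopper_pearson(0, 10)
  expect_equal(ci[["lower"]], 0)
  expect_equal(ci[["upper"]], 1 - 0.025^(1 / 10), tolerance = 1e-12)
  # k = n mirrors k = 0
  ci2 <- clopper_pearson(10, 10)
  expect_equal(ci2[["upper"]], 1)
  expect_equal(ci2[["lower"]], 1 - ci[["upper"]], tolerance = 1e-12)
  withr::local_seed(3)
  for (i in 1:30) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    ci <- clopper_pearson(k, n)
    expect_true(ci[["lower"]] <= k / n + 1e-12 &&
                  ci[["upper"]] >= k / n - 1e-12)
  }
  expect_error(clopper_pearson(11, 10), "k <= n")
})

test_that("Agresti-Caffo flags clear differences and not identical arms", {
  eq <- agresti_caffo(50, 100, 50, 100)
  expect_equal(eq$estimate, 0)
  expect_false(eq$significant)
  diff <- agresti_caffo(90, 100, 50, 100)
  expect_true(diff$significant)
  expect_gt(diff$interval[["lower"]], 0)
  expect_error(agresti_caffo(1, 0, 1, 2), "n1 and n2")
})

test_that("degenerate data are flagged instead of fitted", {
  # zero-contrast-only data carry no stimulus dependence on the duration axis
  tr <- make_trials(40, contrast = 0, duration_ms = 100)
  tr$orientation_label <- "none"
  tr$orientation_deg <- NA_real_
  fit <- fit_psychometric(tr, "duration")
  expect_true(fit$degenerate)
  expect_error(total_integration_time(fit), "degenerate")
})

test_that("MAP fitting recovers generating parameters from rich data", {
  obs <- observer_spec(45, 15, 0.1)
  sched <- data.frame(contrast = 1,
                      duration_ms = c(10, 20, 40, 60, 100, 160, 280, 500),
                      n_trials = 800)
  tr <- simulate_behavior(obs, sched, seed = 21)
  fit <- fit_psychometric(tr, "duration", seed = 22,
                          mcmc = list(n_chains = 2L, n_warmup = 400L,
                                      n_draws = 1200L))
  expect_false(fit$degenerate)
  expect_equal(fit$map$m, 45, tolerance = 0.15)
  expect_equal(fit$map$omega, 15, tolerance = 0.3)
  expect_equal(fit$map$lapse, 0.1, tolerance = 0.5)
  # threshold equals the fitted m and sits inside its own credible interval
  expect_identical(fit$threshold, fit$map$m)
  expect_true(fit$ci95["2.5%", "m"] <= fit$threshold &&
                fit$threshold <= fit$ci95["97.5%", "m"])
  expect_true(all(fit$rhat < 1.05))
})

test_that("MAP matches an independent grid-search oracle", {
  obs <- observer_spec(45, 15, 0.1)
  sched <- data.frame(contrast = 1,
                      duration_ms = c(10, 20, 40, 60, 100, 160, 280, 500),
                      n_trials = 400)
  tr <- simulate_behavior(obs, sched, seed = 31)
  fit <- fit_psychometric(tr, "duration", seed = 32,
                          mcmc = list(n_chains = 2L, n_warmup = 200L,
                                      n_draws = 400L))
  # independent brute-force grid over the same posterior
  agg <- aggregate(cbind(k = correct, n = 1) ~ duration_ms,
                   data = tr[tr$contrast > 0, ], FUN = sum)
  span <- diff(range(agg$duration_ms))
  grid_m <- seq(min(agg$duration_ms), max(agg$duration_ms), length.out = 60)
  grid_om <- seq(1e-3 * span, span, length.out = 60)
  grid_la <- seq(1e-4, 0.4999, length.out = 60)
  best <- c(-Inf, NA, NA, NA)
  for (la in grid_la) {
    lp_prior <- dbeta(la, 1.2, 12, log = TRUE)
    for (om in grid_om) {
      pm <- 0.5 + (0.5 - la) *
        plogis(outer(agg$duration_ms, grid_m, `-`) / om)
      pm <- pmin(pmax(pm, 1e-12), 1 - 1e-12)
      ll <- colSums(agg$k * log(pm) + (agg$n - agg$k) * log1p(-pm)) +
        lp_prior
      j <- which.max(ll)
      if (ll[j] > best[1]) best <- c(ll[j], grid_m[j], om, la)
    }
  }
  expect_equal(fit$map$m, best[2], tolerance = diff(grid_m[1:2]) * 1.5)
  expect_equal(fit$map$omega, best[3], tolerance = diff(grid_om[1:2]) * 1.5)
  expect_equal(fit$map$lapse, best[4], tolerance = diff(grid_la[1:2]) * 1.5)
})

test_that("the average subject weights animals equally and is MC-stable", {
  obs <- observer_spec(45, 15, 0.1)
  sched <- data.frame(contrast = 1,
                      duration_ms = c(20, 50, 100, 200, 400),
                      n_trials = 40)
  big_sched <- transform(sched, n_trials = 400)
  subjects <- list(simulate_behavior(obs, sched, seed = 41),
                   simulate_behavior(obs, big_sched, seed = 42))
  avg <- average_subject(subjects, "duration", n_resamples = 40, seed = 43)
  # every resample draws the minimum subject trial count from each subject
  expect_equal(avg$n_per_subject, sum(sched$n_trials))
  expect_equal(avg$mean[["m"]], 45, tolerance = 10)
  # two seeds agree within Monte-Carlo error of the mean
  avg2 <- average_subject(subjects, "duration", n_resamples = 40, seed = 99)
  se <- avg$sd[["m"]] / sqrt(40)
  expect_lt(abs(avg$mean[["m"]] - avg2$mean[["m"]]), 6 * se + 1)
  expect_error(average_subject(subjects[1]), ">= 2 subjects")
})
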