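test_that("the relative loss matches hand-computed values", {
  prof <- wt_m1_profile(t_r = 10)
  hand <- tibble::tibble(time_hr = c(12, 18, 21), mean = c(10, 5, 2.5),
                         sem = 0, n = 1)
  th0 <- c(rho0 = 10, gamma = 1, epsilon = 0, t_r = 10)
  # exact model: zero loss
  expect_equal(relative_loss(th0, hand, "model1", t_onset = 12), 0)
  # single point 10% high: loss (0.1)^2
  one <- tibble::tibble(time_hr = 18, mean = 5 / 1.1, sem = 0, n = 1)
  expect_equal(relative_loss(th0, one, "model1", t_onset = 12), 0.01,
               tolerance = 1e-12)
  # gamma perturbed to 1.1: value frozen from a direct evaluation of
  # sum(((10 * ((24 - t)/12)^1.1 - d)/d)^2)
  th1 <- c(rho0 = 10, gamma = 1.1, epsilon = 0, t_r = 10)
  expect_equal(relative_loss(th1, hand, "model1", t_onset = 12),
               0.0212417368854601, tolerance = 1e-10)
})

test_that("the loss is invariant to point order and joint rescaling", {
  prof <- wt_m1_profile(t_r = 10)
  tc <- noiseless_timecourse("model1", division_params(9, 1.4, 2), prof,
                             seq(12, 22, 2), 12)
  tc$mean <- tc$mean * 1.07   # deliberate misfit
  th <- c(rho0 = 9, gamma = 1.4, epsilon = 2, t_r = 10)
  l1 <- relative_loss(th, tc, "model1", t_onset = 12)
  shuffled <- tc[sample(nrow(tc)), ]
  expect_equal(relative_loss(th, shuffled, "model1", t_onset = 12), l1)
  th_scaled <- th
  th_scaled["rho0"] <- th["rho0"] * 3
  tc_scaled <- tc
  tc_scaled$mean <- tc$mean * 3
  expect_equal(relative_loss(th_scaled, tc_scaled, "model1", t_onset = 12),
               l1, tolerance = 1e-12)
})

test_that("exclusion rules drop exactly the published points", {
  tc <- tibble::tibble(time_hr = seq(12, 24, 2), mean = 7:1, sem = 0.1, n = 6)
  kept <- apply_exclusions(tc, "cca1_lhy_night")
  expect_equal(kept$time_hr, seq(12, 20, 2))
  expect_equal(attr(kept, "excluded_times"), c(22, 24))
  tc2 <- tibble::tibble(time_hr = seq(8, 24, 2), mean = 9:1, sem = 0.1, n = 6)
  expect_equal(attr(apply_exclusions(tc2, "linear_early"), "excluded_times"),
               c(22, 24))
  expect_equal(attr(apply_exclusions(tc2, "linear_normal"), "excluded_times"),
               24)
  expect_identical(apply_exclusions(tc, "none")$time_hr, tc$time_hr)
  one <- tibble::tibble(time_hr = 24, mean = 1, sem = 0, n = 1)
  expect_error(apply_exclusions(one, "linear_normal"), "every point")
})

test_that("the annealer solves a convex problem and respects its contract", {
  loss <- function(th) (th[["x"]] - 0.37)^2
  cfg <- sa_config(seed = 5, restarts = 1)
  fit <- anneal(loss, list(x = c(0, 1)), cfg)
  expect_lt(abs(fit$theta[["x"]] - 0.37), 1e-3)
  expect_true(fit$theta[["x"]] >= 0 && fit$theta[["x"]] <= 1)
  # best-so-far trace is monotone non-increasing
  expect_true(all(diff(fit$trace) <= 0))
  # reproducible given the seed
  fit2 <- anneal(loss, list(x = c(0, 1)), cfg)
  expect_identical(fit$theta, fit2$theta)
  # non-finite losses are rejected, not propagated
  spiky <- function(th) if (th[["x"]] > 0.9) Inf else (th[["x"]] - 0.37)^2
  fit3 <- anneal(spiky, list(x = c(0, 1)), sa_config(seed = 6, restarts = 1))
  expect_true(is.finite(fit3$loss))
})

test_that("noiseless model-1 data are recovered with a near-zero loss", {
  prof <- wt_m1_profile(t_r = 10)
  pars <- division_params(8, 1.5, 3.0)
  tc <- noiseless_timecourse("model1", pars, prof, seq(12, 22, 2), 12)
  gammas <- vapply(c(2, 9), function(s) {
    fit <- fit_experiment(tc, "model1", 12, config = sa_config(seed = s))
    expect_lt(fit$loss, 1e-6)
    expect_true(all(tidy(fit)$estimate >= tidy(fit)$lower - 1e-9 &
                      tidy(fit)$estimate <= tidy(fit)$upper + 1e-9))
    fit$theta[["gamma"]]
  }, numeric(1))
  expect_true(all(abs(gammas - 1.5) / 1.5 < 0.05))
})

test_that("noiseless model-2 data with a clock phase shift recover t0", {
  prof <- clock_profile("model2", t_r1 = 11.4, t_r2 = 21.4, t0 = -1.3)
  pars <- division_params(5.1, 1.2)
  tc <- noiseless_timecourse("model2", pars, prof, seq(12, 22, 1), 12)
  fit <- fit_experiment(tc, "model2", 12, config = sa_config(seed = 3),
                        free_t0 = TRUE)
  expect_lt(fit$loss, 1e-6)
  expect_lt(abs(fit$theta[["t0"]] - (-1.3)), 0.5)
})

test_that("fit_experiment enforces its preconditions and reports exclusions", {
  tc <- tibble::tibble(time_hr = c(12, 16, 20), mean = c(9, 6, 3),
                       sem = 0, n = 1)
  expect_error(fit_experiment(tc, "model1", 12, config = sa_config(seed = 1)),
               "included points")
  tc7 <- tibble::tibble(time_hr = seq(12, 24, 2), mean = c(7:2, 0.2),
                        sem = 0, n = 1)
  fit <- fit_experiment(tc7, "model1", 12,
                        config = sa_config(seed = 1, restarts = 1,
                                           steps = 20, n_temps = 5,
                                           quench_steps = 0),
                        exclusion_rule = "linear_normal")
  expect_equal(fit$excluded_times, 24)
  expect_equal(glance(fit)$n_points, 6)
})

test_that("sa_config validates its schedule", {
  expect_error(sa_config(cooling = 1.5, seed = 1), "cooling")
  expect_error(sa_config(steps = 0, seed = 1), "steps")
  expect_error(sa_config(), "seed")
})
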