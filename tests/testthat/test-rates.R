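test_that("interval rates follow the two-point formula with propagated SE", {
  r <- interval_rate(c(t = 12, mean = 8.0, sem = 0.2),
                     c(t = 14, mean = 7.0, sem = 0.2))
  expect_equal(r$value, 0.5)
  expect_equal(r$se, sqrt(0.08) / 2)
  r2 <- interval_rate(c(t = 19, mean = 6.0, sem = 0.3),
                      c(t = 21, mean = 4.6, sem = 0.4))
  expect_equal(r2$value, 0.7)
  expect_equal(r2$se, 0.25)
  expect_equal(interval_rate(c(t = 1, mean = 5, sem = 0.1),
                             c(t = 3, mean = 5, sem = 0.1))$value, 0)
  # antisymmetry of the value; se invariant under swap of the two means
  a <- c(t = 12, mean = 9, sem = 0.3)
  b <- c(t = 14, mean = 6, sem = 0.5)
  bb <- a; bb[["mean"]] <- 6; aa <- b; aa[["mean"]] <- 9
  ra <- interval_rate(a, b)
  rb <- interval_rate(bb, aa)
  expect_equal(ra$value, -rb$value)
  expect_equal(ra$se, rb$se)
  expect_error(interval_rate(b, a), "later")
})

test_that("the expected normal-night rate divides by the night length", {
  r <- expected_normal_rate(c(t = 12, mean = 6.0, sem = 0.36))
  expect_equal(r$value, 0.5)
  expect_equal(r$se, 0.03)
  expect_equal(expected_normal_rate(c(t = 12, mean = 12, sem = 0))$value, 1)
  expect_error(expected_normal_rate(c(t = 12, mean = 0, sem = 0.1)),
               "positive")
})

test_that("mean rate differences pool experiments with propagated SEM", {
  eq <- tibble::tibble(value_a = c(0.5, 0.7), se_a = 0.1,
                       value_b = c(0.5, 0.7), se_b = 0.1)
  expect_equal(mean_rate_difference(eq)$value, 0)
  one <- tibble::tibble(value_a = 0.9, se_a = 0.1, value_b = 0.5, se_b = 0.1)
  d <- mean_rate_difference(one)
  expect_equal(d$value, 0.4)
  expect_equal(d$se, sqrt(0.02), tolerance = 1e-12)
  expect_error(mean_rate_difference(one[0, ]), "nrow")
  # simulation with a known rate increase: the pooled delta lands within
  # 2 se of truth
  set.seed(61)
  truth_a <- 1.0; truth_b <- 0.6
  sims <- tibble::tibble(
    value_a = rnorm(3, truth_a, 0.05), se_a = 0.05,
    value_b = rnorm(3, truth_b, 0.05), se_b = 0.05
  )
  ds <- mean_rate_difference(sims)
  expect_lt(abs(ds$value - (truth_a - truth_b)), 2 * ds$se)
})

test_that("the one-tailed test gives textbook normal tail probabilities", {
  expect_equal(one_tailed_test(list(value = 0.2, se = 0.1), null = 0.2), 0.5)
  # frozen from the standard normal upper tail at z = 2.333
  expect_equal(one_tailed_test(list(value = 2.333, se = 1)),
               0.00982407265819648, tolerance = 1e-10)
  expect_equal(one_tailed_test(list(value = 1e6, se = 1)), 0)
  expect_warning(p0 <- one_tailed_test(list(value = 1, se = 0)), "se = 0")
  expect_equal(p0, 0)
  # welch mode defers to a t reference with the Satterthwaite df
  d <- tibble::tibble(value = 0.3, se = 0.1, df_welch = 11)
  expect_equal(one_tailed_test(d, mode = "welch"),
               pt(3, df = 11, lower.tail = FALSE))
})

test_that("night lines recover exact and constant declines", {
  tt <- seq(12, 22, 2)
  exact <- tibble::tibble(time_hr = tt, mean = 10 - 0.8333 * (tt - 12),
                          sem = 0, n = 1)
  f <- fit_night_line(exact, 12)
  expect_equal(f$mu, 0.8333, tolerance = 1e-10)
  expect_equal(f$rho0, 10, tolerance = 1e-10)
  expect_equal(f$se_mu, 0, tolerance = 1e-10)
  const <- tibble::tibble(time_hr = tt, mean = 4, sem = 0, n = 1)
  expect_equal(fit_night_line(const, 12)$mu, 0)
  expect_error(fit_night_line(exact[1:2, ], 12), "3 included")
})

test_that("the OLS slope estimator is unbiased under noise", {
  set.seed(71)
  tt <- seq(12, 22, 2)
  mu_hat <- vapply(1:1000, function(i) {
    tc <- tibble::tibble(time_hr = tt,
                         mean = 10 - 0.8 * (tt - 12) + rnorm(6, 0, 0.3),
                         sem = 0, n = 1)
    fit_night_line(tc, 12)$mu
  }, numeric(1))
  expect_equal(mean(mu_hat), 0.8, tolerance = 0.01)
})

test_that("R equals the night-length ratio on noise-free wild-type data", {
  normal <- linear_night(10, 12, seq(12, 22, 2))
  early <- linear_night(8.5, 8, seq(8, 20, 2))
  r <- ratio_R(fit_night_line(normal, 12), fit_night_line(early, 8))
  expect_equal(r$R, 16 / 12, tolerance = 1e-10)
  # normalization property: invariant to rescaling both nights jointly,
  # and to the two rho0 values separately (the f-fraction argument)
  r2 <- ratio_R(fit_night_line(linear_night(3.1, 12, seq(12, 22, 2)), 12),
                fit_night_line(linear_night(12.4, 8, seq(8, 20, 2)), 8))
  expect_equal(r2$R, 16 / 12, tolerance = 1e-10)
  same <- fit_night_line(normal, 12)
  expect_equal(ratio_R(same, same)$R, 1)
})

test_that("the delta-method se of R matches a parametric bootstrap", {
  set.seed(81)
  tt <- seq(12, 20, 2)
  mk <- function(rho0, onset, sd) {
    tibble::tibble(time_hr = tt - 12 + onset,
                   mean = rho0 * (24 - (tt - 12 + onset)) / (24 - onset) +
                     rnorm(5, 0, sd),
                   sem = sd, n = 6)
  }
  fn <- fit_night_line(mk(10, 12, 0.25), 12)
  fe <- fit_night_line(mk(8.5, 8, 0.25), 8)
  r <- ratio_R(fn, fe)
  # brute-force propagation: redraw (mu, rho0) pairs from the OLS sampling
  # distributions and take the sd of the recomputed ratio
  draw <- function(f, n) {
    ch <- chol(f$cov + diag(1e-12, 2))
    z <- matrix(rnorm(2 * n), ncol = 2) %*% ch
    cbind(mu = f$mu + z[, 1], rho0 = f$rho0 + z[, 2])
  }
  nd <- draw(fn, 1e5)
  ed <- draw(fe, 1e5)
  boot <- (nd[, "mu"] / nd[, "rho0"]) / (ed[, "mu"] / ed[, "rho0"])
  expect_equal(r$se_R, sd(boot), tolerance = 0.05)
})

test_that("the Z-test against the wild-type R reproduces the printed tail", {
  r <- tibble::tibble(R = 1.10, se_R = 0.10)
  p <- z_test_R(r)
  expect_gt(p, 0.0090)
  expect_lt(p, 0.0105)
  expect_equal(z_test_R(tibble::tibble(R = 16 / 12, se_R = 0.1)), 0.5)
  expect_equal(z_test_R(tibble::tibble(R = 1.20, se_R = 0.10)),
               pnorm((1.20 - 16 / 12) / 0.10), tolerance = 1e-12)
})
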