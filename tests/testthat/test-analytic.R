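test_that("analytic solutions equal rho0 at onset and the linear limit", {
  p1 <- wt_m1_profile(t_r = 12)
  pars <- division_params(10, gamma = 1, epsilon = 0)
  # epsilon = 0, gamma = 1: exact linear decline, depleted at expected dawn
  expect_equal(starch_analytic_model1(c(12, 18, 24), 12, pars, p1),
               c(10, 5, 0))
  p2 <- wt_m2_profile(t_r1 = 11, t_r2 = 20)
  # gamma = 1 with onset in the 1/dt window: same linear decline
  expect_equal(starch_analytic_model2(18, 12, division_params(10), p2), 5)
  # identity at t = t_star for generic parameters
  set.seed(21)
  for (m in c("model1", "model2")) {
    d <- draw_params(m)
    ts <- runif(1, 8, 16)
    expect_equal(starch_analytic(ts, ts, d$params, d$profile, model = m),
                 d$params$rho0)
  }
})

test_that("model-2 branch constants integrate the printed linear resets", {
  p <- wt_m2_profile(t_r1 = 10.5, t_r2 = 21)
  taus <- model2_taus(p)
  # u on [0, t_r1] is 1/tau2 - t/tau12; on [t_r2, t_day] it is
  # 1/tau3 - t/tau12: check against the signal itself
  for (t in c(0, 4, 10.5)) {
    expect_equal(1 / taus$tau2 - t / taus$tau12, clock_signal(t, p),
                 tolerance = 1e-12)
  }
  for (t in c(21, 22.5, 24 - 1e-9)) {
    expect_equal(1 / taus$tau3 - t / taus$tau12, clock_signal(t, p),
                 tolerance = 1e-7)
  }
})

test_that("analytic solutions are continuous across branch boundaries", {
  set.seed(31)
  for (i in 1:10) {
    d1 <- draw_params("model1")
    pr <- d1$profile
    # onset before t_r: boundary at t_r (+ t0)
    ts <- pr$t0 + pr$t_r / 2
    b <- pr$t0 + pr$t_r
    expect_lt(abs(starch_analytic_model1(b - 1e-9, ts, d1$params, pr) -
                    starch_analytic_model1(b + 1e-9, ts, d1$params, pr)),
              1e-7)
    # onset after t_r: wrap boundary at t_day (+ t0)
    ts2 <- pr$t0 + pr$t_r + 1
    b2 <- pr$t0 + pr$t_day
    expect_lt(abs(starch_analytic_model1(b2 - 1e-9, ts2, d1$params, pr) -
                    starch_analytic_model1(b2 + 1e-9, ts2, d1$params, pr)),
              1e-7)
    d2 <- draw_params("model2")
    pr2 <- d2$profile
    ts3 <- pr2$t0 + (pr2$t_r1 + pr2$t_r2) / 2
    for (b3 in pr2$t0 + c(pr2$t_r2, pr2$t_day)) {
      expect_lt(abs(starch_analytic_model2(b3 - 1e-9, ts3, d2$params, pr2) -
                      starch_analytic_model2(b3 + 1e-9, ts3, d2$params, pr2)),
                1e-7)
    }
  }
})

test_that("analytic solutions match the ODE integrator on published values", {
  # model1, wild-type normal night best-fit values
  pars <- division_params(rho0 = 11.0, gamma = 1.8, epsilon = 5.0)
  prof <- wt_m1_profile(t_r = 10)
  a <- starch_analytic_model1(21, 12, pars, prof)
  b <- integrate_reduced("model1", pars, prof, 12, 24, grid = 21)$starch
  expect_equal(a, b, tolerance = 1e-6)
  # model2, wild-type normal night best-fit values
  pars2 <- division_params(rho0 = 11.0, gamma = 1.0)
  prof2 <- wt_m2_profile(t_r1 = 12, t_r2 = 20)
  a2 <- starch_analytic_model2(22, 12, pars2, prof2)
  b2 <- integrate_reduced("model2", pars2, prof2, 12, 24, grid = 22)$starch
  expect_equal(a2, b2, tolerance = 1e-6)
  # model2, clock-mutant normal night values with phase shift
  pc <- clock_profile("model2", t_r1 = 11.4, t_r2 = 21.4, t0 = -1.3)
  parc <- division_params(5.1, 1.2)
  tt <- seq(12, 22, 2)
  expect_equal(starch_analytic_model2(tt, 12, parc, pc),
               integrate_reduced("model2", parc, pc, 12, 22,
                                 grid = tt)$starch,
               tolerance = 1e-6)
})

test_that("analytic vs integrator agreement holds across random draws", {
  set.seed(41)
  for (i in 1:8) {
    for (m in c("model1", "model2")) {
      d <- draw_params(m)
      ts <- d$profile$t0 + runif(1, 6, 16)
      tmax <- min(analytic_domain_end(m, d$profile, ts) - 0.5, ts + 18)
      tt <- seq(ts, tmax, length.out = 7)
      a <- starch_analytic(tt, ts, d$params, d$profile, model = m)
      b <- integrate_reduced(m, d$params, d$profile, ts, tmax,
                             grid = tt)$starch
      expect_equal(a, b, tolerance = 1e-6)
    }
  }
})

test_that("evaluation beyond the printed solution domain raises", {
  pars <- division_params(10, 1.5, 2)
  prof <- wt_m1_profile(t_r = 10)
  expect_error(starch_analytic_model1(35, 12, pars, prof), "domain")
  expect_error(starch_analytic_model1(25, 5, pars, prof), "t_day")
  prof2 <- wt_m2_profile()
  expect_error(starch_analytic_model2(36, 12, division_params(10), prof2),
               "domain")
  expect_error(starch_analytic_model1(10, 12, pars, prof), "t_star")
})

test_that("the reduced integrator honors degenerate rates and the division law", {
  prof <- wt_m1_profile(t_r = 10)
  # gamma = 0 is outside division_params validation by design; the zero-rate
  # limit is approximated by a tiny gamma
  tr <- integrate_reduced("model1", division_params(7, 1e-12, 2), prof,
                          12, 24, grid = seq(12, 24, 2))
  expect_equal(tr$starch, rep(7, 7), tolerance = 1e-9)
  # epsilon = 0, gamma = 1: linear decline hitting zero at expected dawn
  tr2 <- integrate_reduced("model1", division_params(10, 1, 0), prof,
                           12, 24, grid = seq(12, 24, 2))
  expect_equal(tr2$starch, 10 * (24 - seq(12, 24, 2)) / 12, tolerance = 1e-8)
  # division property: with k_ST1 [T_C] >> 1 (epsilon << u) the normalized
  # rate -rho'/rho equals gamma/(time to dawn) to 1%
  pars <- division_params(9, 1.4, 0.01)
  tt <- seq(13, 21, 2)
  tr3 <- integrate_reduced("model1", pars, prof, 12, 24,
                           grid = sort(c(tt - 1e-4, tt + 1e-4)))
  for (i in seq_along(tt)) {
    rho_m <- tr3$starch[2 * i - 1]
    rho_p <- tr3$starch[2 * i]
    rate <- -(rho_p - rho_m) / 2e-4 / mean(c(rho_m, rho_p))
    expect_equal(rate, pars$gamma / (24 - tt[i]), tolerance = 0.01)
  }
})

test_that("trajectories are non-increasing in the dark and dated correctly", {
  set.seed(51)
  for (m in c("model1", "model2")) {
    d <- draw_params(m)
    ts <- d$profile$t0 + 12
    tr <- integrate_reduced(m, d$params, d$profile, ts, ts + 10)
    expect_true(all(diff(tr$starch) <= 1e-12))
    expect_true(all(diff(tr$time_hr) > 0))
    expect_true(all(tr$starch >= 0))
  }
})
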