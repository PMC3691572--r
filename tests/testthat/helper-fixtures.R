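# shared fixtures: noiseless time courses generated from the analytic
# solutions, used as ground truth for fitting and rate statistics

wt_m1_profile <- function(t_r = 10, t0 = 0) {
  clock_profile("model1", t_day = 24, t_r = t_r, t0 = t0)
}

wt_m2_profile <- function(t_r1 = 11, t_r2 = 20, t0 = 0) {
  clock_profile("model2", t_day = 24, t_r1 = t_r1, t_r2 = t_r2, t0 = t0)
}

noiseless_timecourse <- function(model, params, profile, times, t_onset) {
  tibble::tibble(
    time_hr = times,
    mean = starch_analytic(times, t_onset, params, profile, model = model),
    sem = 0,
    n = 1
  )
}

# linear wild-type night from the exact gamma=1, epsilon=0 limit:
# rho(t) = rho0 * (t_day - t) / (t_day - t_onset)
linear_night <- function(rho0, t_onset, times, t_day = 24) {
  tibble::tibble(
    time_hr = times,
    mean = rho0 * (t_day - times) / (t_day - t_onset),
    sem = 0,
    n = 1
  )
}

# random in-bounds parameter draw for the oracle-equivalence sweeps
draw_params <- function(model) {
  if (model == "model1") {
    list(
      params = division_params(runif(1, 3, 12), runif(1, 0.7, 3.0),
                               runif(1, 1.5, 5.0)),
      profile = clock_profile("model1", t_r = runif(1, 9, 12),
                              t0 = runif(1, -5, 5))
    )
  } else {
    list(
      params = division_params(runif(1, 3, 12), runif(1, 0.7, 3.0)),
      profile = clock_profile("model2", t_r1 = runif(1, 9, 12),
                              t_r2 = runif(1, 20, 23),
                              t0 = runif(1, -5, 5))
    )
  }
}

# last time covered by the printed analytic branches for an onset ts
analytic_domain_end <- function(model, profile, ts) {
  s <- (ts - profile$t0) %% profile$t_day
  if (model == "model1") {
    if (s <= profile$t_r) ts + (profile$t_day - s)
    else ts + (profile$t_day + profile$t_r - s)
  } else {
    if (s <= profile$t_r1) ts + (profile$t_day - s)
    else if (s <= profile$t_r2) ts + (profile$t_r1 + profile$t_day - s)
    else ts + (profile$t_r2 + profile$t_day - s)
  }
}
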