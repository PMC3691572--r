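#' Exact starch solutions of the reduced division models
#'
#' During darkness the reduced model-1 dynamics are
#' `d rho/dt = -gamma * rho / (epsilon + u(t))` and the model-2 dynamics are
#' `d rho/dt = -gamma * rho * u(t)`, with `u(t) = [T_C](t)/beta` the
#' piecewise clock signal. Because `u` is piecewise linear (model1) or
#' piecewise linear/hyperbolic (model2), the equations integrate in closed
#' form: the solution is a product of branch factors, one per clock segment
#' crossed between the onset of degradation `t_star` and `t`.
#'
#' The printed solution branches cover `t <= t_day` when
#' `t_star` falls in the post-dawn reset window, and wrap once past `t_day`
#' otherwise (to `t_day + t_r` for model1, `t_r2 + t_day` for model2).
#' Evaluation outside the covered domain is an error — the solution is never
#' extrapolated silently (use [integrate_reduced()] with the periodic
#' signal for longer spans).
#'
#' @param t Times in hours after dawn (vector); `t >= t_star`.
#' @param t_star Time at which degradation starts (dark onset), hours.
#' @param params A [division_params()]; `chi` must be 1 here (use
#'   [chi_trajectory()] for `chi < 1`).
#' @param profile A [clock_profile()] of the matching variant.
#' @return Starch content in mg g^-1 FW at each `t`.
#' @seealso [integrate_reduced()], [chi_trajectory()]
#' @examples
#' prof <- clock_profile("model1", t_r = 10)
#' pars <- division_params(rho0 = 10, gamma = 1, epsilon = 0)
#' starch_analytic_model1(c(12, 18, 24), 12, pars, prof)
#' @export
starch_analytic_model1 <- function(t, t_star, params, profile) {
  stopifnot(inherits(params, "division_params"),
            inherits(profile, "clock_profile"),
            profile$variant == "model1")
  analytic1_raw(t, t_star, params$rho0, params$gamma, params$epsilon,
                profile$t_day, profile$t_r, profile$t0)
}

# branch math shared by the validated wrapper and the fitter's fast path
analytic1_raw <- function(t, t_star, rho0, gamma, eps, t_day, t_r, t0) {
  if (any(t < t_star - 1e-12)) stop("t must be >= t_star", call. = FALSE)
  # local clock time: shift by t0 and reduce the onset into [0, t_day)
  s <- (t_star - t0) %% t_day
  tau <- s + (t - t_star)

  slope <- (t_day - t_r) / t_r
  f1 <- function(x, y) ((eps + slope * y) / (eps + slope * x))^(-gamma / slope)
  f2 <- function(x, y) ((eps + t_day - y) / (eps + t_day - x))^gamma

  out <- numeric(length(tau))
  if (s <= t_r) {
    if (any(tau > t_day + 1e-9)) {
      stop("model-1 solution with onset in the reset window covers t <= t_day only",
           call. = FALSE)
    }
    in1 <- tau <= t_r
    out[in1] <- rho0 * f1(s, tau[in1])
    out[!in1] <- rho0 * f1(s, t_r) * f2(t_r, pmin(tau[!in1], t_day))
  } else {
    if (any(tau > t_day + t_r + 1e-9)) {
      stop("model-1 solution domain ends at t_day + t_r past the onset dawn",
           call. = FALSE)
    }
    in1 <- tau <= t_day
    out[in1] <- rho0 * f2(s, tau[in1])
    out[!in1] <- rho0 * f2(s, t_day) * f1(0, tau[!in1] - t_day)
  }
  out
}

#' Model-2 branch time constants
#'
#' The model-2 reset segments are linear in time, `u(t) = 1/tau2 - t/tau12`
#' on `[0, t_r1]` and `u(t) = 1/tau3 - t/tau12` on `[t_r2, t_day]`. The
#' three constants depend only on the profile geometry and are exposed for
#' testing.
#'
#' @param profile A model-2 [clock_profile()].
#' @return Named list with `tau12`, `tau2`, `tau3` (hours).
#' @export
model2_taus <- function(profile) {
  stopifnot(inherits(profile, "clock_profile"), profile$variant == "model2")
  taus_raw(profile$t_day, profile$t_r1, profile$t_r2)
}

taus_raw <- function(t_day, t_r1, t_r2) {
  d <- t_day + t_r1 - t_r2
  inv12 <- (t_r2 - t_r1) / (d * (t_day - t_r1) * (t_day - t_r2))
  inv2 <- ((t_day - t_r2) / (t_day - t_r1) + t_r1 / (t_day - t_r2)) / d
  inv3 <- ((t_day + t_r1) / (t_day - t_r2) - t_r2 / (t_day - t_r1)) / d
  list(tau12 = 1 / inv12, tau2 = 1 / inv2, tau3 = 1 / inv3)
}

#' @rdname starch_analytic_model1
#' @export
starch_analytic_model2 <- function(t, t_star, params, profile) {
  stopifnot(inherits(params, "division_params"),
            inherits(profile, "clock_profile"),
            profile$variant == "model2")
  analytic2_raw(t, t_star, params$rho0, params$gamma,
                profile$t_day, profile$t_r1, profile$t_r2, profile$t0)
}

analytic2_raw <- function(t, t_star, rho0, gamma, t_day, t_r1, t_r2, t0) {
  if (any(t < t_star - 1e-12)) stop("t must be >= t_star", call. = FALSE)
  taus <- taus_raw(t_day, t_r1, t_r2)

  s <- (t_star - t0) %% t_day
  tau <- s + (t - t_star)

  f1 <- function(x, y) exp(-gamma / 2 * (y - x) *
                             (2 / taus$tau2 - (y + x) / taus$tau12))
  f2 <- function(x, y) ((t_day - y) / (t_day - x))^gamma
  f3 <- function(x, y) exp(-gamma / 2 * (y - x) *
                             (2 / taus$tau3 - (y + x) / taus$tau12))

  out <- numeric(length(tau))
  if (s <= t_r1) {
    if (any(tau > t_day + 1e-9)) {
      stop("model-2 solution with onset before t_r1 covers t <= t_day only",
           call. = FALSE)
    }
    b1 <- tau <= t_r1
    b2 <- tau > t_r1 & tau <= t_r2
    b3 <- tau > t_r2
    out[b1] <- rho0 * f1(s, tau[b1])
    out[b2] <- rho0 * f1(s, t_r1) * f2(t_r1, tau[b2])
    out[b3] <- rho0 * f1(s, t_r1) * f2(t_r1, t_r2) * f3(t_r2, tau[b3])
  } else if (s <= t_r2) {
    if (any(tau > t_r1 + t_day + 1e-9)) {
      stop("model-2 solution domain ends at t_r1 + t_day past the onset dawn",
           call. = FALSE)
    }
    b1 <- tau <= t_r2
    b2 <- tau > t_r2 & tau <= t_day
    b3 <- tau > t_day
    out[b1] <- rho0 * f2(s, tau[b1])
    out[b2] <- rho0 * f2(s, t_r2) * f3(t_r2, tau[b2])
    out[b3] <- rho0 * f2(s, t_r2) * f3(t_r2, t_day) * f1(0, tau[b3] - t_day)
  } else {
    if (any(tau > t_r2 + t_day + 1e-9)) {
      stop("model-2 solution domain ends at t_r2 + t_day past the onset dawn",
           call. = FALSE)
    }
    b1 <- tau <= t_day
    b2 <- tau > t_day & tau <= t_r1 + t_day
    b3 <- tau > t_r1 + t_day
    out[b1] <- rho0 * f3(s, tau[b1])
    out[b2] <- rho0 * f3(s, t_day) * f1(0, tau[b2] - t_day)
    out[b3] <- rho0 * f3(s, t_day) * f1(0, t_r1) * f2(t_r1, tau[b3] - t_day)
  }
  out
}

#' Evaluate either analytic solution by model name
#'
#' @param model `"model1"` or `"model2"`.
#' @inheritParams starch_analytic_model1
#' @return Starch content vector.
#' @export
starch_analytic <- function(t, t_star, params, profile,
                            model = profile$variant) {
  if (model == "model1") starch_analytic_model1(t, t_star, params, profile)
  else starch_analytic_model2(t, t_star, params, profile)
}
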