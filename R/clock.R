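#' Clock-controlled T-molecule signal
#'
#' The expected time to dawn is encoded in the stromal concentration of a
#' clock-controlled molecule T. Two signal shapes are supported:
#'
#' * **model1** — `[T_C]` is proportional to the time remaining to expected
#'   dawn, `beta * (t_day - t)`, except during a reset window `[0, t_r]`
#'   after dawn when the signal ramps back up linearly from zero.
#' * **model2** — `[T_C]` is proportional to the *reciprocal* of the time to
#'   dawn, `beta / (t_day - t)`, on `[t_r1, t_r2]`, joined by linear reset
#'   segments on `[0, t_r1]` and `[t_r2, t_day]` that make the signal
#'   continuous and periodic.
#'
#' Both profiles can be rigidly phase-shifted by `t0` hours, in which case
#' dawn is expected at `t_day + t0` hours after the true dawn (the
#' *cca1/lhy* clock-mutant phenotype).
#'
#' @param variant `"model1"` or `"model2"`.
#' @param t_day Period of the light/dark cycle in hours (default 24).
#' @param t_r Model-1 reset time, hours after dawn; required for model1.
#' @param t_r1,t_r2 Model-2 reset window bounds in hours; required for model2.
#' @param t0 Phase shift in hours (may be negative); expected dawn moves to
#'   `t_day + t0`.
#' @param beta Concentration scale of the signal; the reduced dynamics only
#'   depend on `[T_C]/beta`, so `beta` defaults to 1.
#'
#' @return An object of class `clock_profile`.
#' @examples
#' p <- clock_profile("model1", t_day = 24, t_r = 10)
#' clock_signal(c(5, 12, 18), p)
#' @export
clock_profile <- function(variant = c("model1", "model2"), t_day = 24,
                          t_r = NULL, t_r1 = NULL, t_r2 = NULL,
                          t0 = 0, beta = 1) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(t_day), length(t_day) == 1, t_day > 0,
            is.numeric(t0), length(t0) == 1,
            is.numeric(beta), length(beta) == 1, beta > 0)
  if (variant == "model1") {
    if (is.null(t_r)) stop("model1 profile requires `t_r`", call. = FALSE)
    if (!(t_r > 0 && t_r < t_day)) {
      stop("model1 requires 0 < t_r < t_day", call. = FALSE)
    }
  } else {
    if (is.null(t_r1) || is.null(t_r2)) {
      stop("model2 profile requires `t_r1` and `t_r2`", call. = FALSE)
    }
    if (!(t_r1 > 0 && t_r1 < t_r2 && t_r2 < t_day)) {
      stop("model2 requires 0 < t_r1 < t_r2 < t_day", call. = FALSE)
    }
  }
  structure(
    list(variant = variant, t_day = t_day, t_r = t_r,
         t_r1 = t_r1, t_r2 = t_r2, t0 = t0, beta = beta),
    class = "clock_profile"
  )
}

#' @export
print.clock_profile <- function(x, ...) {
  cat("<clock_profile ", x$variant, ">\n", sep = "")
  cat("  t_day = ", x$t_day, " hr,  t0 = ", x$t0, " hr,  beta = ", x$beta, "\n",
      sep = "")
  if (x$variant == "model1") {
    cat("  reset: t_r = ", x$t_r, " hr\n", sep = "")
  } else {
    cat("  1/dt window: [", x$t_r1, ", ", x$t_r2, "] hr\n", sep = "")
  }
  invisible(x)
}

#' Evaluate the normalized clock signal u(t) = [T_C](t)/beta
#'
#' The signal is evaluated on the phase-shifted time axis `t - t0` and
#' extended periodically with period `t_day`, so the same profile drives
#' nights that extend past 24 hr (multi-day darkness, night-time light
#' interruptions).
#'
#' @param t Numeric vector of times in hours after the true dawn.
#' @param profile A [clock_profile()].
#' @return Numeric vector, `[T_C](t)/beta` (dimensionless for model1 in
#'   units of hours; 1/hours for model2).
#' @export
clock_signal <- function(t, profile) {
  stopifnot(inherits(profile, "clock_profile"), is.numeric(t))
  tt <- (t - profile$t0) %% profile$t_day
  t_day <- profile$t_day
  if (profile$variant == "model1") {
    t_r <- profile$t_r
    ifelse(tt <= t_r, (t_day - t_r) / t_r * tt, t_day - tt)
  } else {
    t_r1 <- profile$t_r1
    t_r2 <- profile$t_r2
    d <- t_day + t_r1 - t_r2
    ifelse(tt <= t_r1,
           ((tt + t_day - t_r2) / (t_day - t_r1) +
              (t_r1 - tt) / (t_day - t_r2)) / d,
    ifelse(tt <= t_r2,
           1 / (t_day - tt),
           ((tt - t_r2) / (t_day - t_r1) +
              (t_day + t_r1 - tt) / (t_day - t_r2)) / d))
  }
}

#' Autocatalytic generator of a 1/(time-to-dawn) signal
#'
#' A T molecule that promotes its own production with a quadratic
#' nonlinearity, `d[T]/dt = eta * [T]^2`, has the exact solution
#' `[T](t) = T_init / (1 - eta * (t - t_r1) * T_init)`, which diverges at a
#' finite blow-up time. Choosing `T_init = beta / (t_day - t_r1)` and
#' `eta = 1/beta` places the divergence exactly at expected dawn, so the
#' concentration tracks `beta / (t_day - t)` — the model-2 signal.
#'
#' @param t Times (hours); must lie strictly before the blow-up time.
#' @param t_r1 Time at which the autocatalytic phase starts (hours).
#' @param eta Autocatalytic rate constant.
#' @param T_init Concentration at `t_r1`.
#' @return `[T]` at `t`.
#' @export
autocatalytic_T <- function(t, t_r1, eta, T_init) {
  stopifnot(is.numeric(t), T_init > 0, eta >= 0)
  denom <- 1 - eta * (t - t_r1) * T_init
  if (any(denom <= 0)) {
    stop("autocatalytic_T evaluated at or beyond its blow-up time",
         call. = FALSE)
  }
  T_init / denom
}
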