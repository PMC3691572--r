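#' Numerically integrate the reduced starch dynamics
#'
#' Integrates `d rho/dt = -gamma * rho / (epsilon + u(t))` (model1) or
#' `d rho/dt = -gamma * rho * u(t)` (model2) with the periodic clock signal
#' `u`. The signal is piecewise smooth, so integration proceeds segment by
#' segment between the clock breakpoints — the adaptive integrator never
#' steps across a kink, which preserves its nominal accuracy.
#'
#' This is the numerical oracle for the analytic solutions and, via the
#' periodic extension of `u`, the evaluator for spans the printed analytic
#' branches do not cover.
#'
#' @param model `"model1"` or `"model2"`.
#' @param params A [division_params()].
#' @param profile A [clock_profile()] of the matching variant.
#' @param t_star Onset of degradation, hours after dawn.
#' @param t_end End of integration, hours.
#' @param grid Optional output times within `[t_star, t_end]`; defaults to
#'   a 0.1-hr grid.
#' @param rtol,atol Integrator tolerances (defaults 1e-9, 1e-12).
#' @return A `starch_trajectory` tibble with columns `time_hr`, `starch`.
#' @export
integrate_reduced <- function(model = c("model1", "model2"), params, profile,
                              t_star, t_end, grid = NULL,
                              rtol = 1e-9, atol = 1e-12) {
  model <- match.arg(model)
  stopifnot(inherits(params, "division_params"),
            inherits(profile, "clock_profile"),
            profile$variant == model, t_end >= t_star)
  if (is.null(grid)) grid <- seq(t_star, t_end, by = 0.1)
  if (any(grid < t_star - 1e-12) || any(grid > t_end + 1e-12)) {
    stop("grid must lie within [t_star, t_end]", call. = FALSE)
  }
  grid <- sort(unique(grid))

  deriv <- if (model == "model1") {
    function(t, y, p) {
      list(-params$gamma * y / (params$epsilon + clock_signal(t, profile)))
    }
  } else {
    function(t, y, p) {
      list(-params$gamma * y * clock_signal(t, profile))
    }
  }

  breaks <- clock_breakpoints(profile, t_star, t_end)
  rho <- params$rho0
  out_t <- numeric(0)
  out_y <- numeric(0)
  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]
    b <- breaks[i + 1]
    seg_grid <- grid[grid >= a - 1e-12 & grid <= b + 1e-12]
    times <- sort(unique(c(a, seg_grid, b)))
    sol <- deSolve::ode(y = c(rho = unname(rho)), times = times,
                        func = deriv, parms = NULL, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("reduced-model integration failed (istate ",
           attr(sol, "istate")[1], ")", call. = FALSE)
    }
    keep <- times %in% seg_grid & !(times %in% out_t)
    out_t <- c(out_t, times[keep])
    out_y <- c(out_y, unname(sol[keep, 2]))
    rho <- unname(sol[nrow(sol), 2])
  }
  ord <- order(out_t)
  new_trajectory(out_t[ord], out_y[ord],
                 model = model, params = params, profile = profile)
}

# clock breakpoints (kinks of u) covering [t_star, t_end]
clock_breakpoints <- function(profile, t_star, t_end) {
  base <- if (profile$variant == "model1") {
    c(0, profile$t_r)
  } else {
    c(0, profile$t_r1, profile$t_r2)
  }
  k <- seq(floor((t_star - profile$t0) / profile$t_day) - 1,
           ceiling((t_end - profile$t0) / profile$t_day) + 1)
  pts <- sort(unique(as.vector(outer(k * profile$t_day, base, "+")) +
                       profile$t0))
  pts <- pts[pts > t_star + 1e-12 & pts < t_end - 1e-12]
  c(t_star, pts, t_end)
}

new_trajectory <- function(time_hr, starch, ..., extra = NULL) {
  tb <- tibble::tibble(time_hr = time_hr, starch = starch)
  if (!is.null(extra)) tb <- dplyr::bind_cols(tb, extra)
  attr(tb, "meta") <- list(...)
  class(tb) <- c("starch_trajectory", class(tb))
  tb
}

#' Starch and proxy trajectories under a broken chi normalization
#'
#' When the composite `chi = m_S * f_D2 / (alpha * f_D1)` differs from 1,
#' starch is degraded more slowly than its soluble proxy: the proxy `P(t)`
#' still follows the reduced dynamics (it is depleted at expected dawn for
#' `gamma = 1`), but starch follows
#' `rho(t) = rho0 - chi * (rho0 - P(t))`, so only a fraction `chi` of the
#' onset content is consumed by expected dawn (exactly, when
#' `epsilon = 0`). This is the predicted phenotype of the lsf1, sex4, bam3,
#' bam4 and isa3 starch-excess mutants.
#'
#' @inheritParams integrate_reduced
#' @return A list with tibbles `proxy` and `starch` (both
#'   `starch_trajectory`).
#' @examples
#' prof <- clock_profile("model1", t_r = 10)
#' pars <- division_params(rho0 = 10, gamma = 1, epsilon = 0, chi = 0.3)
#' tr <- chi_trajectory("model1", pars, prof, t_star = 12, t_end = 24)
#' depletion_metrics(tr$starch, t_dawn = 24)
#' @export
chi_trajectory <- function(model = c("model1", "model2"), params, profile,
                           t_star, t_end, grid = NULL, ...) {
  model <- match.arg(model)
  stopifnot(inherits(params, "division_params"))
  proxy_params <- division_params(params$rho0, params$gamma, params$epsilon,
                                  chi = 1)
  proxy <- integrate_reduced(model, proxy_params, profile, t_star, t_end,
                             grid = grid, ...)
  starch <- proxy
  starch$starch <- params$rho0 - params$chi * (params$rho0 - proxy$starch)
  attr(starch, "meta")$chi <- params$chi
  list(proxy = proxy, starch = starch)
}

#' Depletion summaries of a starch trajectory
#'
#' @param traj A `starch_trajectory` (tibble with `time_hr`, `starch`).
#' @param t_dawn Expected dawn in hours; must lie inside the trajectory.
#' @param threshold Optional fraction `q` of the onset content; if given,
#'   `t_below` is the first time starch falls to `q * rho(t_star)`
#'   (linear interpolation between grid points).
#' @return A tibble with `fraction_degraded` and (if requested) `t_below`.
#' @export
depletion_metrics <- function(traj, t_dawn, threshold = NULL) {
  stopifnot(is.data.frame(traj), all(c("time_hr", "starch") %in% names(traj)))
  tmin <- min(traj$time_hr)
  tmax <- max(traj$time_hr)
  if (t_dawn < tmin - 1e-9 || t_dawn > tmax + 1e-9) {
    stop("t_dawn lies outside the trajectory", call. = FALSE)
  }
  rho_start <- traj$starch[which.min(traj$time_hr)]
  rho_dawn <- stats::approx(traj$time_hr, traj$starch, xout = t_dawn,
                            rule = 2)$y
  out <- tibble::tibble(fraction_degraded = (rho_start - rho_dawn) / rho_start)
  if (!is.null(threshold)) {
    target <- threshold * rho_start
    below <- which(traj$starch <= target + 1e-12)
    if (length(below) == 0) {
      out$t_below <- NA_real_
    } else {
      i <- below[1]
      if (i == 1) {
        out$t_below <- traj$time_hr[1]
      } else {
        t1 <- traj$time_hr[i - 1]; t2 <- traj$time_hr[i]
        y1 <- traj$starch[i - 1]; y2 <- traj$starch[i]
        out$t_below <- t1 + (y1 - target) / (y1 - y2) * (t2 - t1)
      }
    }
  }
  out
}
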