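#' Summarize a replicate-form time course
#'
#' Collapses replicate-level starch measurements to per-time-point mean,
#' SEM (`sd/sqrt(n)`) and replicate count.
#'
#' @param data Tibble with columns `time_hr`, `replicate_id`,
#'   `starch_mg_per_g_fw` (replicate form), or already-summary form with
#'   `time_hr`, `mean`, `sem`, `n` (returned unchanged).
#' @return Summary-form tibble (`time_hr`, `mean`, `sem`, `n`) sorted by
#'   time.
#' @export
summarize_timecourse <- function(data) {
  stopifnot(is.data.frame(data))
  if (all(c("mean", "sem", "n") %in% names(data))) {
    if (is.unsorted(data$time_hr)) {
      data <- data[order(data$time_hr), , drop = FALSE]
    }
    return(tibble::as_tibble(data))
  }
  stopifnot(all(c("time_hr", "starch_mg_per_g_fw") %in% names(data)))
  data |>
    dplyr::group_by(.data$time_hr) |>
    dplyr::summarise(
      mean = mean(.data$starch_mg_per_g_fw),
      sem = stats::sd(.data$starch_mg_per_g_fw) /
        sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(sem = ifelse(is.na(.data$sem), 0, .data$sem)) |>
    dplyr::arrange(.data$time_hr)
}

#' Drop the low-starch points excluded from fits
#'
#' Points very close to complete depletion carry large relative errors, so
#' they are excluded before fitting:
#' * `"cca1_lhy_night"` — drop the two points closest in time to 24 hr
#'   (clock-mutant night fits);
#' * `"linear_normal"` — drop the point at t = 24 hr (normal-night linear
#'   fits);
#' * `"linear_early"` — drop the points at t = 22 and 24 hr (early-night
#'   linear fits);
#' * `"none"` — identity.
#'
#' @param data A summary-form time course (see [summarize_timecourse()]).
#' @param rule Exclusion rule.
#' @return Filtered tibble; the dropped times are recorded in the
#'   `"excluded_times"` attribute.
#' @export
apply_exclusions <- function(data, rule = c("none", "cca1_lhy_night",
                                            "linear_normal", "linear_early")) {
  rule <- match.arg(rule)
  data <- summarize_timecourse(data)
  drop_t <- switch(
    rule,
    none = numeric(0),
    cca1_lhy_night = {
      ord <- order(abs(data$time_hr - 24))
      data$time_hr[ord[seq_len(min(2, nrow(data)))]]
    },
    linear_normal = data$time_hr[abs(data$time_hr - 24) < 1e-9],
    linear_early = data$time_hr[abs(data$time_hr - 24) < 1e-9 |
                                  abs(data$time_hr - 22) < 1e-9]
  )
  out <- dplyr::filter(data, !(.data$time_hr %in% drop_t))
  if (nrow(out) == 0) stop("exclusion rule dropped every point", call. = FALSE)
  attr(out, "excluded_times") <- sort(drop_t)
  out
}

#' Relative squared-error loss
#'
#' `L(theta) = sum_i ((rho_theory(t_i, theta) - rho_exp(t_i)) /
#' rho_exp(t_i))^2` over the per-time-point means. Minimizing L gives the
#' maximum-likelihood estimate when measurements scatter around the model
#' curve with a constant *relative* error.
#'
#' @param theta Named parameter vector. Model1: `rho0`, `gamma`, `epsilon`,
#'   `t_r`, optionally `t0`; model2: `rho0`, `gamma`, `t_r1`, `t_r2`,
#'   optionally `t0`.
#' @param data Time course (replicate or summary form); collapsed to means.
#' @param model `"model1"` or `"model2"`.
#' @param t_onset Dark-onset time in hours (the analytic solution's
#'   `t_star`).
#' @param t_day Cycle period in hours.
#' @return The loss (dimensionless, >= 0).
#' @export
relative_loss <- function(theta, data, model = c("model1", "model2"),
                          t_onset, t_day = 24) {
  model <- match.arg(model)
  data <- summarize_timecourse(data)
  if (any(data$mean <= 0)) {
    stop("relative loss needs positive means; apply exclusions first",
         call. = FALSE)
  }
  theory <- theta_curve(theta, data$time_hr, model, t_onset, t_day)
  sum(((theory - data$mean) / data$mean)^2)
}

theta_curve <- function(theta, times, model, t_onset, t_day) {
  # bounds keep theta inside the constructors' validity region, so the
  # raw branch evaluators are called directly (hot path of the annealer)
  t0 <- if ("t0" %in% names(theta)) theta[["t0"]] else 0
  if (model == "model1") {
    analytic1_raw(times, t_onset, theta[["rho0"]], theta[["gamma"]],
                  theta[["epsilon"]], t_day, theta[["t_r"]], t0)
  } else {
    analytic2_raw(times, t_onset, theta[["rho0"]], theta[["gamma"]],
                  t_day, theta[["t_r1"]], theta[["t_r2"]], t0)
  }
}

#' Default fit bounds
#'
#' The published search ranges: `gamma` 0.7–3.0, `epsilon` 1.5–5.0 hr,
#' `t_r` and `t_r1` 9.0–12.0 hr, `t_r2` 20.0–23.0 hr, `t0` -5.0–5.0 hr
#' (fixed at 0 for wild type), and `rho0` within 10% of the measured
#' content at the first included time point.
#'
#' @param data Summary-form time course (used for the `rho0` interval).
#' @param model `"model1"` or `"model2"`.
#' @param free_t0 Should the phase shift be a free parameter?
#' @return Named list of `c(lower, upper)` intervals.
#' @export
fit_bounds <- function(data, model = c("model1", "model2"), free_t0 = FALSE) {
  model <- match.arg(model)
  data <- summarize_timecourse(data)
  rho_meas <- data$mean[1]
  b <- list(rho0 = c(0.9, 1.1) * rho_meas, gamma = c(0.7, 3.0))
  if (model == "model1") {
    b$epsilon <- c(1.5, 5.0)
    b$t_r <- c(9.0, 12.0)
  } else {
    b$t_r1 <- c(9.0, 12.0)
    b$t_r2 <- c(20.0, 23.0)
  }
  if (free_t0) b$t0 <- c(-5.0, 5.0)
  b
}

#' Simulated-annealing configuration
#'
#' @param initial_temp Starting temperature of the Metropolis schedule;
#'   `NULL` (default) sets it adaptively to the loss spread over random
#'   draws from the box, so acceptance starts near 1 regardless of the
#'   loss scale.
#' @param cooling Geometric cooling factor in (0, 1); the default 0.5
#'   over 30 levels takes the temperature ~9 orders of magnitude below
#'   its start, freezing the walk onto the optimum.
#' @param steps Proposals per temperature (>= 1).
#' @param n_temps Number of temperature levels.
#' @param proposal_frac Initial proposal s.d. as a fraction of each bound
#'   width.
#' @param proposal_cooling Geometric shrink factor of the proposal s.d.
#'   per temperature level, so late stages refine locally.
#' @param restarts Independent restarts; the best run wins.
#' @param quench_steps Zero-temperature polishing proposals run from the
#'   best point after the schedule (accept only improvements, step size
#'   halving every 200 proposals).
#' @param seed Mandatory RNG seed.
#' @return An object of class `sa_config`.
#' @export
sa_config <- function(initial_temp = NULL, cooling = 0.5, steps = 150,
                      n_temps = 30, proposal_frac = 0.1,
                      proposal_cooling = 0.75, restarts = 3,
                      quench_steps = 1000, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(cooling > 0, cooling < 1, steps >= 1, n_temps >= 1,
            restarts >= 1, proposal_frac > 0,
            is.null(initial_temp) || initial_temp > 0,
            proposal_cooling > 0, proposal_cooling <= 1, quench_steps >= 0)
  structure(list(initial_temp = initial_temp, cooling = cooling,
                 steps = steps, n_temps = n_temps,
                 proposal_frac = proposal_frac,
                 proposal_cooling = proposal_cooling, restarts = restarts,
                 quench_steps = as.integer(quench_steps),
                 seed = as.integer(seed)),
            class = "sa_config")
}

reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  r <- (x - lo) %% (2 * w)
  lo + ifelse(r > w, 2 * w - r, r)
}

#' Minimize a loss by simulated annealing in a box
#'
#' Metropolis acceptance with a geometric temperature schedule; Gaussian
#' proposals scaled to the bound widths and reflected back into the box;
#' non-finite losses reject the proposal (and are counted) rather than
#' propagating; the best parameter vector ever visited is returned. Fully
#' reproducible given the config seed.
#'
#' @param loss_fn Function of a named parameter vector returning a scalar
#'   loss.
#' @param bounds Named list of `c(lower, upper)` intervals.
#' @param config An [sa_config()].
#' @return An object of class `starch_fit` with elements `theta`, `loss`,
#'   `trace` (best-so-far loss after each accepted move), `seed`,
#'   `converged`, `n_nonfinite`.
#' @export
anneal <- function(loss_fn, bounds, config) {
  stopifnot(inherits(config, "sa_config"), is.list(bounds))
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(hi < lo)) stop("bounds must have lower <= upper", call. = FALSE)
  nm <- names(bounds)
  width <- hi - lo
  fixed <- width == 0

  set.seed(config$seed)
  best_theta <- NULL
  best_loss <- Inf
  trace <- numeric(0)
  n_nonfinite <- 0L

  eval_loss <- function(theta) {
    val <- tryCatch(loss_fn(theta), error = function(e) Inf)
    if (!is.finite(val)) {
      n_nonfinite <<- n_nonfinite + 1L
      Inf
    } else val
  }

  # adaptive starting temperature: spread of the loss over the box
  t0 <- config$initial_temp
  if (is.null(t0)) {
    probe <- replicate(20, {
      th <- lo + stats::runif(length(lo)) * width
      names(th) <- nm
      eval_loss(th)
    })
    probe <- probe[is.finite(probe)]
    t0 <- if (length(probe) >= 2) max(stats::sd(probe), 1e-8) else 1
  }

  for (r in seq_len(config$restarts)) {
    theta <- lo + stats::runif(length(lo)) * width
    names(theta) <- nm
    cur <- eval_loss(theta)
    tries <- 0
    while (!is.finite(cur) && tries < 50) {
      theta <- lo + stats::runif(length(lo)) * width
      names(theta) <- nm
      cur <- eval_loss(theta)
      tries <- tries + 1
    }
    if (!is.finite(cur)) stop("loss not finite at any random start",
                              call. = FALSE)
    if (cur < best_loss) {
      best_loss <- cur
      best_theta <- theta
    }
    temp <- t0
    prop_sd <- config$proposal_frac * width
    for (k in seq_len(config$n_temps)) {
      for (s in seq_len(config$steps)) {
        prop <- theta + stats::rnorm(length(theta), 0, prop_sd)
        prop[fixed] <- lo[fixed]
        prop[!fixed] <- reflect_into(prop[!fixed], lo[!fixed], hi[!fixed])
        names(prop) <- nm
        new <- eval_loss(prop)
        if (is.finite(new) &&
            (new <= cur || stats::runif(1) < exp((cur - new) / temp))) {
          theta <- prop
          cur <- new
          if (cur < best_loss) {
            best_loss <- cur
            best_theta <- theta
          }
          trace <- c(trace, best_loss)
        }
      }
      temp <- temp * config$cooling
      prop_sd <- prop_sd * config$proposal_cooling
    }
  }

  # greedy quench from the best point found by the schedule
  if (config$quench_steps > 0 && !is.null(best_theta)) {
    theta <- best_theta
    cur <- best_loss
    prop_sd <- config$proposal_frac * width * config$proposal_cooling^10
    for (s in seq_len(config$quench_steps)) {
      prop <- theta + stats::rnorm(length(theta), 0, prop_sd)
      prop[fixed] <- lo[fixed]
      prop[!fixed] <- reflect_into(prop[!fixed], lo[!fixed], hi[!fixed])
      names(prop) <- nm
      new <- eval_loss(prop)
      if (is.finite(new) && new < cur) {
        theta <- prop
        cur <- new
        best_theta <- theta
        best_loss <- cur
        trace <- c(trace, best_loss)
      }
      if (s %% 200 == 0) prop_sd <- prop_sd * 0.5
    }
  }
  structure(list(theta = best_theta, loss = best_loss, trace = trace,
                 seed = config$seed, converged = is.finite(best_loss),
                 n_nonfinite = n_nonfinite, bounds = bounds),
            class = "starch_fit")
}

#' Fit a division model to a starch time course
#'
#' Applies the exclusion rule, builds the published bounds (with `rho0`
#' within 10% of the first included measurement), and minimizes the
#' relative squared-error loss by simulated annealing.
#'
#' @param data Time course (replicate or summary form).
#' @param model `"model1"` or `"model2"`.
#' @param t_onset Dark-onset time, hours after dawn.
#' @param config An [sa_config()].
#' @param exclusion_rule Passed to [apply_exclusions()].
#' @param bounds Optional bounds overriding [fit_bounds()].
#' @param free_t0 Fit the clock phase shift `t0` (clock mutants) or pin it
#'   at 0 (wild type).
#' @param t_day Cycle period in hours.
#' @return A `starch_fit` (see [anneal()]) with the data, model and
#'   exclusion report attached.
#' @examples
#' prof <- clock_profile("model1", t_r = 10)
#' pars <- division_params(rho0 = 8, gamma = 1.5, epsilon = 3)
#' tc <- tibble::tibble(
#'   time_hr = seq(12, 22, 2),
#'   mean = starch_analytic_model1(seq(12, 22, 2), 12, pars, prof),
#'   sem = 0, n = 1
#' )
#' fit <- fit_experiment(tc, "model1", t_onset = 12,
#'                       config = sa_config(seed = 1, restarts = 1))
#' tidy(fit)
#' @export
fit_experiment <- function(data, model = c("model1", "model2"), t_onset,
                           config, exclusion_rule = "none", bounds = NULL,
                           free_t0 = FALSE, t_day = 24) {
  model <- match.arg(model)
  kept <- apply_exclusions(data, exclusion_rule)
  if (is.null(bounds)) bounds <- fit_bounds(kept, model, free_t0 = free_t0)
  n_free <- sum(vapply(bounds, function(b) diff(b) > 0, logical(1)))
  if (nrow(kept) < n_free + 1) {
    stop("need at least ", n_free + 1, " included points to fit ", n_free,
         " free parameters", call. = FALSE)
  }
  tv <- kept$time_hr
  mv <- kept$mean
  loss_fn <- function(theta) {
    theory <- theta_curve(theta, tv, model, t_onset, t_day)
    sum(((theory - mv) / mv)^2)
  }
  fit <- anneal(loss_fn, bounds, config)
  fit$model <- model
  fit$t_onset <- t_onset
  fit$t_day <- t_day
  fit$data <- kept
  fit$excluded_times <- attr(kept, "excluded_times")
  fit
}

#' @export
print.starch_fit <- function(x, ...) {
  cat("<starch_fit", if (!is.null(x$model)) paste0(" ", x$model), ">\n",
      sep = "")
  print(round(x$theta, 4))
  cat("loss = ", signif(x$loss, 6), " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Broom-style accessors for fitted objects
#'
#' `tidy()` returns one row per parameter with its search interval;
#' `glance()` returns a one-row model summary.
#'
#' @param x A `starch_fit` or `night_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidiers
#' @export
tidy.starch_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$theta),
    estimate = unname(x$theta),
    lower = vapply(x$bounds, `[`, numeric(1), 1),
    upper = vapply(x$bounds, `[`, numeric(1), 2)
  )
}

#' @rdname tidiers
#' @export
glance.starch_fit <- function(x, ...) {
  tibble::tibble(
    loss = x$loss,
    converged = x$converged,
    seed = x$seed,
    n_points = if (!is.null(x$data)) nrow(x$data) else NA_integer_,
    n_excluded = length(x$excluded_times),
    n_nonfinite = x$n_nonfinite
  )
}
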