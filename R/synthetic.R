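#' Describe a starch-turnover experiment design
#'
#' Encodes the experimental designs the models were tested against:
#' unexpectedly early/normal/late onset of darkness, night-time light
#' interruptions, multi-day recovery after prolonged darkness, and a
#' reduced-daylight day giving a lower onset content. Time is in hours
#' after the first true dawn.
#'
#' Defaults emulate the published growth conditions: 12-hr light/12-hr
#' dark cycles, about 11 mg g^-1 FW of starch at the end of a normal
#' 12-hr light period (hence a day-time accumulation rate of ~0.92
#' mg g^-1 FW hr^-1), measurement noise with a constant relative
#' standard deviation of 0.1, and 6 rosettes per time point (12 for the
#' night-time light-interruption series).
#'
#' @param variant One of `"normal_night"`, `"early_night"`, `"late_night"`,
#'   `"night_light_interruption"`, `"multiday_recovery"`,
#'   `"reduced_daylight"`.
#' @param t_dark_onset Hour of dark onset (single-night designs); defaults
#'   12 (normal), 8 (early), 16 (late).
#' @param light_window `c(start, end)` of the night-time light period in
#'   hours (interruption design; default 14–19).
#' @param sampling_times Hours at which rosettes are harvested; sensible
#'   per-variant defaults.
#' @param n_rosettes Replicate rosettes per time point.
#' @param sigma_rel Relative standard deviation of measurement noise.
#' @param day_accumulation_rate Starch synthesis rate in the light,
#'   mg g^-1 FW hr^-1.
#' @param n_days Number of light/dark cycles (recovery design, default 4).
#' @param seed RNG seed used by [add_noise()].
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(variant = c("normal_night", "early_night",
                                          "late_night",
                                          "night_light_interruption",
                                          "multiday_recovery",
                                          "reduced_daylight"),
                              t_dark_onset = NULL, light_window = NULL,
                              sampling_times = NULL, n_rosettes = NULL,
                              sigma_rel = 0.1,
                              day_accumulation_rate = NULL,
                              n_days = 4, seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(t_dark_onset)) {
    t_dark_onset <- switch(variant, early_night = 8, late_night = 16, 12)
  }
  if (is.null(day_accumulation_rate)) {
    day_accumulation_rate <- if (variant == "reduced_daylight") 0.46 else 0.92
  }
  if (is.null(n_rosettes)) {
    n_rosettes <- if (variant == "night_light_interruption") 12L else 6L
  }
  if (variant == "night_light_interruption" && is.null(light_window)) {
    light_window <- c(14, 19)
  }
  if (is.null(sampling_times)) {
    sampling_times <- switch(
      variant,
      night_light_interruption = c(12, 14, light_window[2],
                                   seq(light_window[2] + 2, 28, by = 2)),
      multiday_recovery = as.vector(outer(c(12, 24), 24 * (0:(n_days - 1)),
                                          "+")),
      seq(t_dark_onset, 24, by = 2)
    )
  }
  if (sigma_rel < 0) stop("sigma_rel must be >= 0", call. = FALSE)
  if (n_rosettes < 1) stop("n_rosettes must be >= 1", call. = FALSE)
  if (!is.null(light_window) && light_window[1] >= light_window[2]) {
    stop("light_window must be an increasing pair", call. = FALSE)
  }
  structure(list(variant = variant, t_dark_onset = t_dark_onset,
                 light_window = light_window,
                 sampling_times = sort(unique(sampling_times)),
                 n_rosettes = as.integer(n_rosettes), sigma_rel = sigma_rel,
                 day_accumulation_rate = day_accumulation_rate,
                 n_days = n_days, seed = as.integer(seed)),
            class = "experiment_design")
}

# light/dark phase table for a design: one row per phase over the full span
design_phases <- function(design, t_end) {
  v <- design$variant
  if (v == "multiday_recovery") {
    k <- seq_len(design$n_days) - 1
    tibble::tibble(
      start = as.vector(rbind(24 * k, 24 * k + 12)),
      end = as.vector(rbind(24 * k + 12, 24 * k + 24)),
      light = rep(c(TRUE, FALSE), design$n_days)
    )
  } else if (v == "night_light_interruption") {
    w <- design$light_window
    on <- design$t_dark_onset
    if (w[1] <= on) stop("light window must start after dark onset",
                         call. = FALSE)
    tibble::tibble(
      start = c(0, on, w[1], w[2]),
      end = c(on, w[1], w[2], t_end),
      light = c(TRUE, FALSE, TRUE, FALSE)
    )
  } else {
    on <- design$t_dark_onset
    tibble::tibble(start = c(0, on), end = c(on, t_end),
                   light = c(TRUE, FALSE))
  }
}

#' Simulate the noise-free starch trajectory of a design
#'
#' Light phases accumulate starch linearly at the design's day rate; dark
#' phases follow the reduced division-model dynamics. At every light-to-
#' dark transition the degradation restarts from the starch level at that
#' moment — the S proxy is re-proportionalized to the current content —
#' which is what makes the degradation rate a *continuously recomputed*
#' division rather than a rate fixed once per night. The clock profile is
#' never re-entrained by night-time light (it keeps free-running with its
#' `t_day` period and phase `t0`).
#'
#' @param design An [experiment_design()].
#' @param model `"model1"` or `"model2"`.
#' @param params A [division_params()] (its `rho0` is overridden by the
#'   running content at each dark onset; `gamma`, `epsilon`, `chi` are
#'   used as given).
#' @param profile A [clock_profile()] of the matching variant.
#' @param rho_start Starch at time 0 (default 0 for the recovery design,
#'   else 0 at dawn of a normal day).
#' @param grid_by Spacing of the dense output grid in hours.
#' @return A `starch_trajectory` tibble covering `[0, max(sampling times)]`.
#' @export
simulate_true_curve <- function(design, model = c("model1", "model2"),
                                params, profile, rho_start = 0,
                                grid_by = 0.05) {
  model <- match.arg(model)
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "division_params"),
            inherits(profile, "clock_profile"))
  t_end <- max(design$sampling_times)
  phases <- design_phases(design, max(t_end, design$t_dark_onset + 1e-6))
  if (t_end > max(phases$end) + 1e-9) {
    stop("sampling times extend beyond the simulated span", call. = FALSE)
  }
  grid <- sort(unique(c(seq(0, t_end, by = grid_by), design$sampling_times,
                        phases$start, phases$end[phases$end <= t_end])))
  rho <- rho_start
  out_t <- numeric(0)
  out_y <- numeric(0)
  for (i in seq_len(nrow(phases))) {
    a <- phases$start[i]
    b <- min(phases$end[i], t_end)
    if (a > t_end) break
    g <- grid[grid >= a - 1e-12 & grid <= b + 1e-12]
    if (phases$light[i]) {
      y <- rho + design$day_accumulation_rate * (g - a)
      rho <- rho + design$day_accumulation_rate * (b - a)
    } else {
      if (rho <= 0) stop("no starch to degrade at dark onset ", a,
                         call. = FALSE)
      night_params <- division_params(rho, params$gamma, params$epsilon,
                                      params$chi)
      tr <- chi_trajectory(model, night_params, profile, t_star = a,
                           t_end = b, grid = g)
      y <- tr$starch$starch
      rho <- y[length(y)]
    }
    keep <- !(g %in% out_t)
    out_t <- c(out_t, g[keep])
    out_y <- c(out_y, y[keep])
  }
  ord <- order(out_t)
  new_trajectory(out_t[ord], pmax(out_y[ord], 0),
                 model = model, params = params, profile = profile,
                 design = design)
}

#' Add replicate-level measurement noise to a true trajectory
#'
#' Each simulated rosette measurement is
#' `true value * (1 + e)`, `e ~ Normal(0, sigma_rel)` — noise with a
#' constant relative error, matching the assumption under which the
#' relative squared-error loss is the maximum-likelihood fit. Draws are
#' truncated at zero (starch content cannot be negative); truncation
#' events are counted in the truth record.
#'
#' @param traj A `starch_trajectory` (the true curve).
#' @param design The [experiment_design()] providing sampling times,
#'   replicate count, noise level and seed (individual fields can be
#'   overridden).
#' @param sampling_times,n_rosettes,sigma_rel,seed Optional overrides.
#' @return An object of class `synthetic_experiment`: list with `truth`
#'   (trajectory), `replicates` (tibble `time_hr`, `replicate_id`,
#'   `starch_mg_per_g_fw`), `summary` (tibble `time_hr`, `mean`, `sem`,
#'   `n`) and `truth_record` (design, seed, truncation count).
#' @export
add_noise <- function(traj, design, sampling_times = design$sampling_times,
                      n_rosettes = design$n_rosettes,
                      sigma_rel = design$sigma_rel, seed = design$seed) {
  stopifnot(is.data.frame(traj), sigma_rel >= 0, n_rosettes >= 1)
  if (any(sampling_times < min(traj$time_hr) - 1e-9) ||
      any(sampling_times > max(traj$time_hr) + 1e-9)) {
    stop("sampling times fall outside the trajectory", call. = FALSE)
  }
  truth <- stats::approx(traj$time_hr, traj$starch, xout = sampling_times)$y
  set.seed(seed)
  eps <- matrix(stats::rnorm(length(sampling_times) * n_rosettes,
                             0, sigma_rel),
                nrow = length(sampling_times))
  vals <- truth * (1 + eps)
  n_trunc <- sum(vals < 0)
  vals <- pmax(vals, 0)
  replicates <- tibble::tibble(
    time_hr = rep(sampling_times, times = n_rosettes),
    replicate_id = rep(seq_len(n_rosettes), each = length(sampling_times)),
    starch_mg_per_g_fw = as.vector(vals)
  ) |> dplyr::arrange(.data$time_hr, .data$replicate_id)
  structure(
    list(truth = traj, replicates = replicates,
         summary = summarize_timecourse(replicates),
         truth_record = list(design = design, seed = seed,
                             sigma_rel = sigma_rel, n_rosettes = n_rosettes,
                             n_truncated = n_trunc,
                             meta = attr(traj, "meta"))),
    class = "synthetic_experiment"
  )
}

#' Fraction of starch degraded during each night of a recovery series
#'
#' For a multi-day recovery experiment, the per-night degraded fraction
#' `(end-of-day - end-of-night) / end-of-day`, computed from the summary
#' means at 12 hr and 24 hr of each cycle. With `chi < 1` this fraction is
#' constant at `chi` night after night while the absolute end-of-night
#' content climbs to the plateau `D * (1 - chi) / chi` (D = starch
#' synthesized per day).
#'
#' @param experiment A `synthetic_experiment` from a `multiday_recovery`
#'   design (or a summary tibble containing the 12/24-hr points of each
#'   cycle).
#' @param n_days Number of cycles; taken from the design when available.
#' @return Tibble with `night`, `end_of_day`, `end_of_night`,
#'   `fraction_degraded`.
#' @export
mutant_recovery_fractions <- function(experiment, n_days = NULL) {
  if (inherits(experiment, "synthetic_experiment")) {
    if (is.null(n_days)) n_days <- experiment$truth_record$design$n_days
    s <- experiment$summary
  } else {
    s <- summarize_timecourse(experiment)
    if (is.null(n_days)) n_days <- floor(max(s$time_hr) / 24)
  }
  get_mean <- function(t) {
    i <- which(abs(s$time_hr - t) < 1e-9)
    if (length(i) != 1) {
      stop("missing sample at t = ", t, " hr", call. = FALSE)
    }
    s$mean[i]
  }
  purrr::map_dfr(seq_len(n_days), function(k) {
    eod <- get_mean(24 * (k - 1) + 12)
    eon <- get_mean(24 * k)
    tibble::tibble(night = k, end_of_day = eod, end_of_night = eon,
                   fraction_degraded = (eod - eon) / eod)
  })
}
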