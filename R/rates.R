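as_point <- function(p) {
  if (is.data.frame(p)) p <- unlist(p[1, , drop = TRUE])
  nm <- names(p)
  if (is.null(nm)) stop("points need named elements t/time_hr, mean, sem",
                        call. = FALSE)
  if ("time_hr" %in% nm) names(p)[nm == "time_hr"] <- "t"
  if (!all(c("t", "mean", "sem") %in% names(p))) {
    stop("points need elements t (or time_hr), mean, sem", call. = FALSE)
  }
  p
}

#' Two-point starch degradation rate with propagated SEM
#'
#' The rate between consecutive sampling times, e.g.
#' `mu_B = (rho(12 hr) - rho(14 hr)) / 2 hr` before a night-time light
#' interruption, with standard error `sqrt(sem1^2 + sem2^2) / (t2 - t1)`.
#'
#' @param p1,p2 Named vectors (or one-row data frames) with `t` (or
#'   `time_hr`), `mean`, `sem`; `p2` is the later point.
#' @return A one-row tibble with `value` (mg g^-1 FW hr^-1) and `se`.
#' @examples
#' interval_rate(c(t = 12, mean = 8, sem = 0.2), c(t = 14, mean = 7, sem = 0.2))
#' @export
interval_rate <- function(p1, p2) {
  p1 <- as_point(p1)
  p2 <- as_point(p2)
  dt <- p2[["t"]] - p1[["t"]]
  if (dt <= 0) stop("p2 must be later than p1", call. = FALSE)
  tibble::tibble(
    value = (p1[["mean"]] - p2[["mean"]]) / dt,
    se = sqrt(p1[["sem"]]^2 + p2[["sem"]]^2) / dt
  )
}

#' Rate expected over a normal night
#'
#' The degradation rate that would have consumed the content measured at
#' the start of a normal night exactly by expected dawn:
#' `mu_normal = rho(12 hr) / 12 hr`.
#'
#' @param p12 Point at the start of the normal night (named vector with
#'   `t`, `mean`, `sem`).
#' @param night_length Length of the normal night in hours (default 12).
#' @return One-row tibble with `value` and `se`.
#' @export
expected_normal_rate <- function(p12, night_length = 12) {
  p12 <- as_point(p12)
  if (p12[["mean"]] <= 0) stop("starch content must be positive",
                               call. = FALSE)
  tibble::tibble(value = p12[["mean"]] / night_length,
                 se = p12[["sem"]] / night_length)
}

#' Mean rate difference across experiments with propagated SEM
#'
#' For paired rate estimates from N independent experiments,
#' `delta = (1/N) * sum(mu_A_i - mu_B_i)`, with
#' `se = sqrt(sum(se_A_i^2 + se_B_i^2)) / N`. A Welch–Satterthwaite
#' effective df over the per-experiment variance components is attached
#' for use with `one_tailed_test(mode = "welch")`.
#'
#' @param rates Tibble with one row per experiment and columns `value_a`,
#'   `se_a`, `value_b`, `se_b` (A = after / treatment, B = before /
#'   reference).
#' @param df Optional per-experiment degrees of freedom of the variance
#'   components (e.g. `n_rosettes - 1`); used for the Satterthwaite df.
#' @return One-row tibble `value`, `se`, `df_welch`.
#' @export
mean_rate_difference <- function(rates, df = NULL) {
  stopifnot(is.data.frame(rates), nrow(rates) >= 1,
            all(c("value_a", "se_a", "value_b", "se_b") %in% names(rates)))
  n <- nrow(rates)
  v <- rates$se_a^2 + rates$se_b^2
  df_i <- if (is.null(df)) rep(Inf, n) else rep_len(df, n)
  df_welch <- if (all(is.infinite(df_i))) Inf else sum(v)^2 / sum(v^2 / df_i)
  tibble::tibble(
    value = mean(rates$value_a - rates$value_b),
    se = sqrt(sum(v)) / n,
    df_welch = df_welch
  )
}

#' One-tailed test of a rate increase
#'
#' Upper-tail probability of the standardized statistic
#' `z = (value - null) / se`. The default reference distribution is the
#' standard normal (the propagated-SE construction has no canonical df);
#' `mode = "welch"` uses a t reference with Welch–Satterthwaite df (taken
#' from the `df_welch` column if present, or the `df` argument).
#'
#' @param delta One-row tibble/list with `value` and `se` (e.g. from
#'   [mean_rate_difference()]).
#' @param null Null value (default 0).
#' @param mode `"z"` (normal reference) or `"welch"` (t reference).
#' @param df Degrees of freedom for `mode = "welch"`.
#' @return The one-tailed p-value.
#' @export
one_tailed_test <- function(delta, null = 0, mode = c("z", "welch"),
                            df = NULL) {
  mode <- match.arg(mode)
  value <- delta$value
  se <- delta$se
  if (se == 0) {
    if (value != null) {
      warning("se = 0 with value != null; p = 0", call. = FALSE)
      return(0)
    }
    return(0.5)
  }
  z <- (value - null) / se
  if (mode == "z") {
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    if (is.null(df)) df <- delta$df_welch
    if (is.null(df) || !is.finite(df)) {
      stats::pnorm(z, lower.tail = FALSE)
    } else {
      stats::pt(z, df = df, lower.tail = FALSE)
    }
  }
}

#' Linear fit of a night's starch decline
#'
#' Ordinary least squares on the per-time-point means,
#' `rho(t) = -mu * (t - t_onset) + rho_0`, with the published low-starch
#' exclusions applied first. The slope is reported as a positive
#' degradation rate `mu`.
#'
#' @param data Time course (replicate or summary form).
#' @param t_onset Dark-onset time in hours (intercept reference).
#' @param exclusion_rule Passed to [apply_exclusions()].
#' @return A `night_fit` object: `mu`, `rho0`, `se_mu`, `se_rho0`, the
#'   2x2 covariance of `(mu, rho0)`, `t_onset`, `n`, and the underlying
#'   `lm` fit.
#' @export
fit_night_line <- function(data, t_onset, exclusion_rule = "none") {
  kept <- apply_exclusions(data, exclusion_rule)
  if (nrow(kept) < 3) stop("need at least 3 included points", call. = FALSE)
  x <- kept$time_hr - t_onset
  if (length(unique(x)) < 2) stop("singular design", call. = FALSE)
  fit <- stats::lm(mean ~ x, data = tibble::tibble(mean = kept$mean, x = x))
  co <- stats::coef(fit)
  # OLS covariance computed directly so an exact (zero-residual) fit gives
  # a clean zero matrix instead of summary.lm warnings
  X <- cbind(1, x)
  s2 <- sum(stats::residuals(fit)^2) / (nrow(kept) - 2)
  vc <- solve(crossprod(X)) * s2
  # mu = -slope, rho0 = intercept; flip the covariance accordingly
  cov_mu_rho0 <- matrix(c(vc[2, 2], -vc[1, 2], -vc[1, 2], vc[1, 1]), 2, 2,
                        dimnames = list(c("mu", "rho0"), c("mu", "rho0")))
  structure(list(mu = -unname(co[2]), rho0 = unname(co[1]),
                 se_mu = sqrt(vc[2, 2]), se_rho0 = sqrt(vc[1, 1]),
                 cov = cov_mu_rho0, t_onset = t_onset, n = nrow(kept),
                 excluded_times = attr(kept, "excluded_times"), lm = fit),
            class = "night_fit")
}

#' @export
print.night_fit <- function(x, ...) {
  cat("<night_fit> mu = ", signif(x$mu, 4), " +/- ", signif(x$se_mu, 3),
      " mg/gFW/hr, rho0 = ", signif(x$rho0, 4), " +/- ",
      signif(x$se_rho0, 3), " (onset ", x$t_onset, " hr, n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.night_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "rho0"),
                 estimate = c(x$mu, x$rho0),
                 std.error = c(x$se_mu, x$se_rho0))
}

#' @rdname tidiers
#' @export
glance.night_fit <- function(x, ...) {
  tibble::tibble(t_onset = x$t_onset, n = x$n,
                 r.squared = summary(x$lm)$r.squared)
}

#' Normalized degradation-rate ratio R
#'
#' `R = (mu_normal / rho_0_normal) / (mu_early / rho_0_early)` — the ratio
#' of the two nights' degradation rates, each normalized by the starch
#' content at its own onset of darkness. For wild-type behaviour (the same
#' fraction degraded by expected dawn in both nights) the expectation is
#' `(t_day - t_early) / (t_day - t_normal) = 16/12 ~ 1.33`. The standard
#' error comes from a first-order delta-method propagation over the two
#' independent OLS fits.
#'
#' @param fit_normal,fit_early `night_fit` objects for the normal and
#'   early night.
#' @return One-row tibble with `R` and `se_R`.
#' @export
ratio_R <- function(fit_normal, fit_early) {
  stopifnot(inherits(fit_normal, "night_fit"), inherits(fit_early, "night_fit"))
  if (fit_normal$rho0 <= 0 || fit_early$rho0 <= 0 ||
      fit_early$mu <= 0 || fit_normal$mu <= 0) {
    stop("ratio_R needs positive slopes and onset contents", call. = FALSE)
  }
  norm_rate <- function(f) {
    m <- f$mu / f$rho0
    g <- c(1 / f$rho0, -f$mu / f$rho0^2)  # d(mu/rho0)/d(mu, rho0)
    list(m = m, var = drop(t(g) %*% f$cov %*% g))
  }
  a <- norm_rate(fit_normal)
  b <- norm_rate(fit_early)
  R <- a$m / b$m
  se_R <- abs(R) * sqrt(a$var / a$m^2 + b$var / b$m^2)
  tibble::tibble(R = R, se_R = se_R)
}

#' One-tailed Z-test of R against the wild-type expectation
#'
#' Lower-tail normal probability of `(R - R0) / se_R`, testing whether the
#' observed ratio falls short of the wild-type value `R0 = 16/12` (the pwd
#' phenotype: failure to adjust the degradation rate to an early night).
#'
#' @param r One-row tibble/list with `R` and `se_R` (from [ratio_R()]).
#' @param R0 Null ratio (default 16/12).
#' @return The one-tailed p-value.
#' @examples
#' z_test_R(tibble::tibble(R = 1.10, se_R = 0.10))  # ~0.01
#' @export
z_test_R <- function(r, R0 = 16 / 12) {
  if (r$se_R == 0) {
    if (r$R != R0) {
      warning("se_R = 0 with R != R0; p = 0", call. = FALSE)
      return(0)
    }
    return(0.5)
  }
  stats::pnorm((r$R - R0) / r$se_R)
}
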