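#' Integrate the full mass-action reaction network
#'
#' The unreduced model tracks, per granule, the stromal S concentration
#' `sC`, the surface-bound pools (`nS` free, `nST` in complex with T), the
#' starch content `rho` and the cumulative number of degraded S molecules
#' `deg`. The clock species `[T_C] = beta * u(t)` is imposed externally —
#' its dynamics are circadian-controlled and independent of starch
#' degradation. In model1, T binding detaches S from the granule
#' (S + T_C -> ST -> S_C + T_C); in model2, the surface ST complex is the
#' degradation-competent species (S + T_C <-> ST; ST -> T_C).
#'
#' Degradation of both S and starch happens over the fixed area `A_d`,
#' giving per-granule fluxes `f_D1 * [pool] * A_d` and a starch flux scaled
#' so that `chi = m_S * f_D2 / (alpha * f_D1)` is the starch:proxy rate
#' ratio (see [reduced_composites()]).
#'
#' This integrator is the oracle for the quasi-steady-state reduction: as
#' `b_S/f_D1` grows and `k_S * A / V_0` shrinks, its starch trajectory
#' converges to [integrate_reduced()].
#'
#' @param micro A [micro_rates()] set (model-1 fields `f_ST1`, `f_ST2` or
#'   model-2 fields `f_ST`, `b_ST` must be present as appropriate).
#' @param profile A [clock_profile()] of the matching variant.
#' @param init Named list of initial values: `rho` (mg g^-1 FW, required),
#'   `sC` (stromal concentration; default puts the whole proxy pool in the
#'   compartment at `rho / (alpha * V_0)`), `nS`, `nST` (default 0).
#' @param t_star,t_end Integration span in hours.
#' @param grid Output times; default 0.1-hr grid.
#' @param rtol,atol Integrator tolerances.
#' @return A `starch_trajectory` tibble with columns `time_hr`, `starch`,
#'   `sC`, `nS`, `nST`, `deg`.
#' @export
integrate_full_network <- function(micro, profile, init, t_star, t_end,
                                   grid = NULL, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(micro, "micro_rates"),
            inherits(profile, "clock_profile"))
  variant <- profile$variant
  if (variant == "model1" && (is.null(micro$f_ST1) || is.null(micro$f_ST2))) {
    stop("model1 network needs f_ST1 and f_ST2", call. = FALSE)
  }
  if (variant == "model2" && (is.null(micro$f_ST) || is.null(micro$b_ST))) {
    stop("model2 network needs f_ST and b_ST", call. = FALSE)
  }
  if (is.null(init$rho)) stop("init$rho is required", call. = FALSE)
  if (is.null(init$sC)) init$sC <- init$rho / (micro$alpha * micro$V_0)
  if (is.null(init$nS)) init$nS <- 0
  if (is.null(init$nST)) init$nST <- 0
  y0 <- c(sC = init$sC, nS = init$nS, nST = init$nST,
          rho = init$rho, deg = 0)
  if (any(y0[1:4] < 0)) {
    stop("initial concentrations must be non-negative", call. = FALSE)
  }
  if (is.null(grid)) grid <- seq(t_star, t_end, by = 0.1)
  grid <- sort(unique(grid))

  chi <- if (micro$f_D1 > 0) {
    micro$m_S * micro$f_D2 / (micro$alpha * micro$f_D1)
  } else NA_real_
  q0 <- init$sC * micro$V_0 + init$nS + init$nST
  alpha_rho <- init$rho / q0
  ad_frac <- micro$A_d / micro$A
  # starch flux per unit degradation-competent pool: chi * alpha_rho * f_D1
  starch_rate <- micro$m_S * micro$f_D2 / micro$alpha * alpha_rho

  deriv <- function(t, y, p) {
    T_C <- profile$beta * clock_signal(t, profile)
    if (variant == "model1") {
      attach <- micro$f_S * y["sC"] * micro$A
      detach <- micro$b_S * y["nS"]
      bindT <- micro$f_ST1 * y["nS"] * T_C
      dissoc <- micro$f_ST2 * y["nST"]
      pool <- y["nS"]
      degS <- micro$f_D1 * pool * ad_frac
      dsC <- (-attach + detach + dissoc) / micro$V_0
      dnS <- attach - detach - bindT - degS
      dnST <- bindT - dissoc
    } else {
      attach <- micro$f_S * y["sC"] * micro$A
      detach <- micro$b_S * y["nS"]
      bindT <- micro$f_ST * y["nS"] * T_C
      dissoc <- micro$b_ST * y["nST"]
      pool <- y["nST"]
      degS <- micro$f_D1 * pool * ad_frac
      dsC <- (-attach + detach) / micro$V_0
      dnS <- attach - detach - bindT + dissoc
      dnST <- bindT - dissoc - degS
    }
    drho <- -starch_rate * pool * ad_frac
    list(c(dsC, dnS, dnST, drho, degS))
  }

  breaks <- clock_breakpoints(profile, t_star, t_end)
  y <- y0
  rows <- list()
  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]
    b <- breaks[i + 1]
    seg_grid <- grid[grid >= a - 1e-12 & grid <= b + 1e-12]
    times <- sort(unique(c(a, seg_grid, b)))
    sol <- deSolve::lsoda(y = y, times = times, func = deriv, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 1e5)
    if (attr(sol, "istate")[1] < 0) {
      stop("full-network integration failed (istate ",
           attr(sol, "istate")[1], ")", call. = FALSE)
    }
    keep <- times %in% seg_grid
    rows[[i]] <- sol[keep, , drop = FALSE]
    y <- sol[nrow(sol), -1]
  }
  m <- do.call(rbind, rows)
  m <- m[!duplicated(m[, "time"]), , drop = FALSE]
  new_trajectory(m[, "time"], m[, "rho"],
                 model = variant, micro = micro, profile = profile,
                 chi = chi, q0 = q0,
                 extra = tibble::tibble(sC = m[, "sC"], nS = m[, "nS"],
                                        nST = m[, "nST"], deg = m[, "deg"]))
}
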