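#' Macroscopic division-model parameters
#'
#' The quasi-steady-state reduction of either reaction network leaves a
#' small set of composite parameters that fully determine the starch
#' trajectory:
#'
#' * `rho0` — starch content at the onset of darkness (mg per g fresh
#'   weight).
#' * `gamma` — dimensionless normalization factor; `gamma = 1` gives a
#'   linear decline that depletes starch exactly at expected dawn.
#' * `epsilon` — model-1 saturation offset `(beta * k_ST1)^-1` in hours;
#'   the effective rate law is `-gamma * rho / (epsilon + u(t))`. Ignored
#'   by model2.
#' * `chi` — ratio of starch degradation to S-proxy degradation,
#'   `m_S * f_D2 / (alpha * f_D1)`. `chi = 1` keeps starch proportional to
#'   its proxy so both run out together; `chi < 1` (the lsf1/sex4-type
#'   mutant phenotype) leaves a fraction `1 - chi` of starch undegraded at
#'   expected dawn.
#'
#' @param rho0 Starch at dark onset, mg g^-1 FW; > 0.
#' @param gamma Normalization factor; > 0.
#' @param epsilon Saturation offset in hours; >= 0 (model1 only).
#' @param chi Starch:proxy degradation ratio in (0, 1].
#' @return An object of class `division_params`.
#' @examples
#' division_params(rho0 = 11, gamma = 1.8, epsilon = 5)
#' @export
division_params <- function(rho0, gamma = 1, epsilon = 0, chi = 1) {
  stopifnot(is.numeric(rho0), length(rho0) == 1,
            is.numeric(gamma), length(gamma) == 1,
            is.numeric(epsilon), length(epsilon) == 1,
            is.numeric(chi), length(chi) == 1)
  if (rho0 <= 0) stop("rho0 must be positive", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (epsilon < 0) stop("epsilon must be non-negative", call. = FALSE)
  if (chi <= 0 || chi > 1) stop("chi must lie in (0, 1]", call. = FALSE)
  structure(list(rho0 = rho0, gamma = gamma, epsilon = epsilon, chi = chi),
            class = "division_params")
}

#' @export
print.division_params <- function(x, ...) {
  cat("<division_params> rho0 = ", x$rho0, " mg/gFW, gamma = ", x$gamma,
      ", epsilon = ", x$epsilon, " hr, chi = ", x$chi, "\n", sep = "")
  invisible(x)
}

#' Microscopic reaction-network rates
#'
#' Rate constants and geometry of the full mass-action network used as the
#' oracle for the quasi-steady-state (QSS) reduction. S molecules exchange
#' between the stromal compartment and the granule surface (`f_S`, `b_S`);
#' in model1 surface-bound S is detached by T binding (`f_ST1`) followed by
#' complex dissociation (`f_ST2`), while in model2 S recruits T to form the
#' degradation-competent ST complex (`f_ST`, `b_ST`). Degradation of the S
#' proxy (`f_D1`) and of starch itself (`f_D2`, `m_S` starch units per
#' event) happens only over a fixed area `A_d` of the granule surface, so
#' the rate does not fall as the granule shrinks.
#'
#' The reduction is valid when surface exchange is fast relative to
#' degradation (`b_S >> f_D1`) and only a small fraction of S is
#' surface-bound (`n * k_S * A << V`, i.e. `k_S * A << V_0`). Both ratios
#' are computed and stored so tests can assert the regime.
#'
#' @param f_S,b_S Surface attach/detach rate parameters.
#' @param f_ST1,f_ST2 Model-1 T-binding and complex-dissociation parameters.
#' @param f_ST,b_ST Model-2 ST association/dissociation parameters.
#' @param f_D1 S-proxy degradation parameter.
#' @param f_D2 Starch degradation parameter.
#' @param m_S Starch degraded per degradation event.
#' @param A_d Fixed degradation area.
#' @param A Granule surface area.
#' @param V_0 Compartment volume per granule (V/n).
#' @param n Number of granules (bookkeeping only; dynamics are per granule).
#' @param alpha Starch-per-S proportionality at dark onset.
#' @return Object of class `micro_rates` with derived ratios `k_S`,
#'   `k_ST1`/`k_ST` and the regime diagnostics `exchange_sep = b_S/f_D1`
#'   and `binding_frac = k_S * A / V_0`.
#' @export
micro_rates <- function(f_S, b_S, f_ST1 = NULL, f_ST2 = NULL,
                        f_ST = NULL, b_ST = NULL,
                        f_D1, f_D2, m_S = 1, A_d = 1, A = 1,
                        V_0 = 1, n = 1, alpha = 1) {
  pos <- c(f_S = f_S, b_S = b_S, m_S = m_S,
           A_d = A_d, A = A, V_0 = V_0, n = n, alpha = alpha)
  if (any(pos <= 0)) stop("rates and geometry must be positive", call. = FALSE)
  if (f_D1 < 0 || f_D2 < 0) {
    stop("degradation rates must be non-negative", call. = FALSE)
  }
  out <- list(f_S = f_S, b_S = b_S, f_ST1 = f_ST1, f_ST2 = f_ST2,
              f_ST = f_ST, b_ST = b_ST, f_D1 = f_D1, f_D2 = f_D2,
              m_S = m_S, A_d = A_d, A = A, V_0 = V_0, n = n, alpha = alpha)
  out$k_S <- f_S / b_S
  if (!is.null(f_ST1)) out$k_ST1 <- f_ST1 / b_S
  if (!is.null(f_ST) && !is.null(b_ST)) out$k_ST <- f_ST / b_ST
  out$exchange_sep <- b_S / f_D1
  out$binding_frac <- out$k_S * A / V_0
  structure(out, class = "micro_rates")
}

#' Composite reduced parameters implied by a microscopic rate set
#'
#' Returns `gamma`, `epsilon` (model1) and `chi` as functions of the
#' microscopic constants: `gamma = f_D1 * A_d * k_S / (k_ST1 * V_0 * beta)`
#' for model1, `gamma = f_D1 * A_d * beta * k_ST * k_S / V_0` for model2,
#' `epsilon = 1 / (beta * k_ST1)`, `chi = m_S * f_D2 / (alpha * f_D1)`.
#'
#' @param micro A [micro_rates()] object.
#' @param variant `"model1"` or `"model2"`.
#' @param beta Clock-signal scale.
#' @return A named list with `gamma`, `epsilon` (model1 only, else 0) and
#'   `chi`.
#' @export
reduced_composites <- function(micro, variant = c("model1", "model2"),
                               beta = 1) {
  stopifnot(inherits(micro, "micro_rates"))
  variant <- match.arg(variant)
  chi <- micro$m_S * micro$f_D2 / (micro$alpha * micro$f_D1)
  if (variant == "model1") {
    if (is.null(micro$k_ST1)) stop("model1 needs f_ST1", call. = FALSE)
    list(
      gamma = micro$f_D1 * micro$A_d * micro$k_S /
        (micro$k_ST1 * micro$V_0 * beta),
      epsilon = 1 / (beta * micro$k_ST1),
      chi = chi
    )
  } else {
    if (is.null(micro$k_ST)) stop("model2 needs f_ST and b_ST", call. = FALSE)
    list(
      gamma = micro$f_D1 * micro$A_d * beta * micro$k_ST * micro$k_S /
        micro$V_0,
      epsilon = 0,
      chi = chi
    )
  }
}
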