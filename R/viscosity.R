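#' Power-law viscosity parameter set for a molten starchy material
#'
#' Container for the parameters of the shear-viscosity model used throughout
#' the package: an Ostwald–de Waele power law \eqn{\eta = K \dot\gamma^{n-1}}
#' whose consistency \eqn{K} depends on absolute temperature, moisture content
#' and cumulative specific mechanical energy (SME) through an
#' Arrhenius/plasticization exponential, and whose flow index \eqn{n} is an
#' empirical polynomial in temperature (°C), moisture and SME.
#'
#' Two dialects of the consistency law are in circulation and both are
#' supported:
#' \describe{
#'   \item{`"referenced"`}{\eqn{K = K_0 \exp[E/R\,(1/T_a - 1/T_0) -
#'     \alpha(MC - MC_0) - \beta(SME - SME_0)]} with reference state
#'     \eqn{T_0 = 353} K, \eqn{MC_0 = 0.10}, \eqn{SME_0 = 350} kJ/kg, so that
#'     \eqn{K = K_0} exactly at the reference state.}
#'   \item{`"absolute"`}{\eqn{K = K_0 \exp[E/R\,(1/T_a) - \alpha\,MC -
#'     \beta\,SME]}; here \eqn{K_0} is not a physically attainable viscosity
#'     but a pre-exponential constant. Wheat-flour/bran parameter sets are
#'     published in this form.}
#' }
#'
#' Moisture content is a wet-basis mass fraction in \[0, 1\] everywhere in
#' this package; coefficients printed for moisture "in percent" must be
#' rescaled before construction. Absent ("-") coefficients are exact zeros.
#'
#' @param K0 consistency at the reference state (Pa·s^n), > 0.
#' @param E_over_R activation temperature E/R (K), >= 0.
#' @param alpha moisture plasticization coefficient (per unit moisture
#'   fraction).
#' @param beta thermomechanical-history coefficient (kg/kJ).
#' @param n0 constant term of the flow-index polynomial.
#' @param a1,a2,a3,a4,a5,a6 flow-index coefficients multiplying T (°C), MC,
#'   SME (kJ/kg), T·MC, T·SME and MC·SME respectively.
#' @param dialect `"referenced"` (default) or `"absolute"`, see Details.
#' @param T0_ref,MC0_ref,SME0_ref reference state (K, fraction, kJ/kg).
#'   Ignored by the `"absolute"` dialect.
#' @return An object of class `"viscosity_params"`.
#' @seealso [consistency_k()], [flow_index()], [apparent_viscosity()],
#'   [fit_viscosity_params()], [convert_dialect()]
#' @examples
#' pf <- viscosity_params(K0 = 8.1e5, E_over_R = 4210, alpha = 11.4, n0 = 0.29)
#' apparent_viscosity(pf, shear_rate = 100, T_C = 79.85, MC = 0.10, SME = 350)
#' @export
viscosity_params <- function(K0, E_over_R, alpha = 0, beta = 0,
                             n0 = 0, a1 = 0, a2 = 0, a3 = 0,
                             a4 = 0, a5 = 0, a6 = 0,
                             dialect = c("referenced", "absolute"),
                             T0_ref = 353, MC0_ref = 0.10, SME0_ref = 350) {
  dialect <- match.arg(dialect)
  check_number(K0, "K0", lower = 0, strict_lower = TRUE)
  check_number(E_over_R, "E_over_R", lower = 0)
  for (nm in c("alpha", "beta", "n0", "a1", "a2", "a3", "a4", "a5", "a6"))
    check_number(get(nm), nm)
  check_number(T0_ref, "T0_ref", lower = 0, strict_lower = TRUE)
  check_number(MC0_ref, "MC0_ref", lower = 0, upper = 1)
  check_number(SME0_ref, "SME0_ref", lower = 0)
  structure(
    list(K0 = K0, E_over_R = E_over_R, alpha = alpha, beta = beta,
         n0 = n0, a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6,
         dialect = dialect,
         T0_ref = T0_ref, MC0_ref = MC0_ref, SME0_ref = SME0_ref),
    class = "viscosity_params")
}

#' @export
print.viscosity_params <- function(x, ...) {
  cat("<viscosity_params> dialect:", x$dialect, "\n")
  cat(sprintf("  K0 = %.4g Pa.s^n, E/R = %.4g K, alpha = %.4g, beta = %.4g\n",
              x$K0, x$E_over_R, x$alpha, x$beta))
  ncf <- unlist(x[c("n0", "a1", "a2", "a3", "a4", "a5", "a6")])
  cat("  flow index:", paste(sprintf("%s = %.4g", names(ncf), ncf),
                             collapse = ", "), "\n")
  if (x$dialect == "referenced")
    cat(sprintf("  reference state: T0 = %g K, MC0 = %g, SME0 = %g kJ/kg\n",
                x$T0_ref, x$MC0_ref, x$SME0_ref))
  invisible(x)
}

validate_melt_state <- function(T_K, MC, SME) {
  check_number(T_K, "T_K", lower = 0, strict_lower = TRUE, allow_vector = TRUE)
  check_number(MC, "MC", lower = 0, upper = 1, strict_lower = TRUE,
               strict_upper = TRUE, allow_vector = TRUE)
  check_number(SME, "SME", lower = 0, allow_vector = TRUE)
}

#' Consistency of the power-law melt at a thermomechanical state
#'
#' Evaluates the consistency \eqn{K} (Pa·s^n) at absolute temperature `T_K`,
#' wet-basis moisture fraction `MC` and cumulative specific mechanical energy
#' `SME` (kJ/kg), honouring the parameter set's dialect. Vectorized over the
#' state arguments.
#'
#' @param params a [viscosity_params()] object.
#' @param T_K absolute temperature (K), > 0. Note the kelvin scale: the flow
#'   index polynomial, by contrast, takes °C ([flow_index()]).
#' @param MC moisture content, wet-basis mass fraction in (0, 1).
#' @param SME cumulative specific mechanical energy (kJ/kg), >= 0.
#' @return Consistency K (Pa·s^n), strictly positive.
#' @export
consistency_k <- function(params, T_K, MC, SME) {
  stopifnot(inherits(params, "viscosity_params"))
  validate_melt_state(T_K, MC, SME)
  if (params$dialect == "referenced") {
    params$K0 * exp(params$E_over_R * (1 / T_K - 1 / params$T0_ref) -
                      params$alpha * (MC - params$MC0_ref) -
                      params$beta * (SME - params$SME0_ref))
  } else {
    params$K0 * exp(params$E_over_R / T_K - params$alpha * MC -
                      params$beta * SME)
  }
}

# hot-path version without argument validation (solver internal)
consistency_k_fast <- function(params, T_K, MC, SME) {
  if (params$dialect == "referenced") {
    params$K0 * exp(params$E_over_R * (1 / T_K - 1 / params$T0_ref) -
                      params$alpha * (MC - params$MC0_ref) -
                      params$beta * (SME - params$SME0_ref))
  } else {
    params$K0 * exp(params$E_over_R / T_K - params$alpha * MC -
                      params$beta * SME)
  }
}

#' Flow index of the power-law melt at a thermomechanical state
#'
#' Evaluates the empirical flow-index polynomial
#' \eqn{n = n_0 + \alpha_1 T + \alpha_2 MC + \alpha_3 SME + \alpha_4 T\,MC +
#' \alpha_5 T\,SME + \alpha_6 MC\,SME} (temperature in °C) and clamps the
#' result to `[n_min, 1]`. The polynomial is a calibration valid only inside
#' its fitting window; the clamp keeps downstream flow computations defined
#' when a solver explores states outside it, and a warning is emitted when it
#' engages.
#'
#' @inheritParams consistency_k
#' @param T_C temperature in °C (the consistency law uses kelvin instead).
#' @param n_min lower clamp for the flow index (default 0.05).
#' @param warn emit a warning when clamping occurs (default TRUE).
#' @return Flow index n in `[n_min, 1]`.
#' @export
flow_index <- function(params, T_C, MC, SME, n_min = 0.05, warn = TRUE) {
  stopifnot(inherits(params, "viscosity_params"))
  validate_melt_state(celsius_to_kelvin(T_C), MC, SME)
  raw <- flow_index_raw(params, T_C, MC, SME)
  if (warn && any(raw < n_min | raw > 1))
    warnf("flow index clamped to [%g, 1] (raw value %s outside the calibration window)",
          n_min, paste(signif(raw[raw < n_min | raw > 1], 3), collapse = ", "))
  pmin(pmax(raw, n_min), 1)
}

flow_index_raw <- function(params, T_C, MC, SME) {
  params$n0 + params$a1 * T_C + params$a2 * MC + params$a3 * SME +
    params$a4 * T_C * MC + params$a5 * T_C * SME + params$a6 * MC * SME
}

flow_index_fast <- function(params, T_C, MC, SME, n_min = 0.05) {
  pmin(pmax(flow_index_raw(params, T_C, MC, SME), n_min), 1)
}

#' Apparent shear viscosity of the melt
#'
#' Power-law viscosity \eqn{\eta = K \dot\gamma^{n-1}} with K and n evaluated
#' at the given thermomechanical state. Shear-thinning (decreasing in shear
#' rate) whenever n < 1.
#'
#' @inheritParams flow_index
#' @param shear_rate shear rate (1/s), > 0.
#' @param warn passed to [flow_index()].
#' @return Apparent viscosity (Pa·s).
#' @export
apparent_viscosity <- function(params, shear_rate, T_C, MC, SME,
                               n_min = 0.05, warn = TRUE) {
  check_number(shear_rate, "shear_rate", lower = 0, strict_lower = TRUE,
               allow_vector = TRUE)
  K <- consistency_k(params, celsius_to_kelvin(T_C), MC, SME)
  n <- flow_index(params, T_C, MC, SME, n_min = n_min, warn = warn)
  K * shear_rate^(n - 1)
}

apparent_viscosity_fast <- function(params, shear_rate, T_C, MC, SME,
                                    n_min = 0.05) {
  K <- consistency_k_fast(params, celsius_to_kelvin(T_C), MC, SME)
  n <- flow_index_fast(params, T_C, MC, SME, n_min = n_min)
  K * shear_rate^(n - 1)
}

#' Convert a viscosity parameter set between dialects
#'
#' The `"referenced"` and `"absolute"` consistency laws describe the same
#' physics; converting the pre-exponential constant makes them evaluate
#' identically at every state:
#' \eqn{K_0^{abs} = K_0^{ref} \exp(-E/R\,/T_0 + \alpha MC_0 + \beta SME_0)}.
#'
#' @param params a [viscosity_params()] object.
#' @param to target dialect.
#' @param T0_ref,MC0_ref,SME0_ref reference state to attach when converting
#'   towards `"referenced"` (defaults: 353 K, 0.10, 350 kJ/kg).
#' @return A [viscosity_params()] object in the target dialect.
#' @export
convert_dialect <- function(params, to = c("referenced", "absolute"),
                            T0_ref = 353, MC0_ref = 0.10, SME0_ref = 350) {
  stopifnot(inherits(params, "viscosity_params"))
  to <- match.arg(to)
  if (params$dialect == to) return(params)
  out <- params
  if (to == "absolute") {
    out$K0 <- params$K0 * exp(-params$E_over_R / params$T0_ref +
                                params$alpha * params$MC0_ref +
                                params$beta * params$SME0_ref)
  } else {
    out$T0_ref <- T0_ref; out$MC0_ref <- MC0_ref; out$SME0_ref <- SME0_ref
    out$K0 <- params$K0 * exp(params$E_over_R / T0_ref -
                                params$alpha * MC0_ref -
                                params$beta * SME0_ref)
  }
  out$dialect <- to
  out
}
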