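#' Fit power-law viscosity parameters from rheometry data
#'
#' Calibrates the consistency/flow-index model from tabulated rheometry
#' points (shear rate, temperature, moisture, SME, apparent viscosity), the
#' way slit-die or pre-shearing capillary datasets are reduced to parameter
#' tables. The model is linear in its unknowns on the log scale:
#' \deqn{\log\eta + \log\dot\gamma = \log K_0 + (E/R) x_T - \alpha x_{MC}
#'       - \beta x_{SME} + n \log\dot\gamma}
#' with \eqn{n} itself linear in T, MC, SME and their pairwise products, so a
#' single least-squares solve recovers every requested coefficient.
#'
#' @param data a data.frame with columns `shear_rate` (1/s), `T_C` (°C),
#'   `MC` (wet-basis fraction), `SME` (kJ/kg) and `eta` (Pa·s), e.g. from
#'   [generate_rheometry()] or read from a CSV with columns
#'   `shear_rate_s-1, T_C, MC_frac, SME_kJkg, eta_Pas`.
#' @param terms character vector naming the coefficients to estimate, a
#'   subset of `c("K0","E_over_R","alpha","beta","n0","a1","a2","a3","a4",
#'   "a5","a6")`. Coefficients not listed are pinned to zero (K0 is always
#'   estimated). Default estimates the four consistency parameters and a
#'   constant flow index.
#' @param dialect dialect of the fitted parameter set.
#' @param T0_ref,MC0_ref,SME0_ref reference state for the `"referenced"`
#'   dialect.
#' @return An object of class `"viscosity_fit"`: a list with `params` (a
#'   [viscosity_params()] object), `coefficients` (estimate/std. error
#'   table), `sigma` (residual standard error on log viscosity), `r_squared`
#'   (on log viscosity), `n_obs`, and `terms`.
#' @examples
#' pf <- viscosity_params(K0 = 8.1e5, E_over_R = 4210, alpha = 11.4, n0 = 0.29)
#' pts <- generate_rheometry(pf,
#'   design = expand.grid(shear_rate = c(10, 100), T_C = c(120, 160),
#'                        MC = c(0.15, 0.25), SME = c(200, 600)),
#'   noise_cv = 0, seed = 1)
#' fit <- fit_viscosity_params(pts, terms = c("K0", "E_over_R", "alpha", "n0"))
#' coef(fit)
#' @export
fit_viscosity_params <- function(data,
                                 terms = c("K0", "E_over_R", "alpha",
                                           "beta", "n0"),
                                 dialect = c("referenced", "absolute"),
                                 T0_ref = 353, MC0_ref = 0.10,
                                 SME0_ref = 350) {
  dialect <- match.arg(dialect)
  req <- c("shear_rate", "T_C", "MC", "SME", "eta")
  if (!is.data.frame(data) || !all(req %in% names(data)))
    stopf("`data` must be a data.frame with columns %s",
          paste(req, collapse = ", "))
  if (any(data$shear_rate <= 0) || any(data$eta <= 0))
    stopf("shear_rate and eta must be strictly positive")
  all_terms <- c("K0", "E_over_R", "alpha", "beta",
                 "n0", "a1", "a2", "a3", "a4", "a5", "a6")
  terms <- union("K0", match.arg(terms, all_terms, several.ok = TRUE))

  lg <- log(data$shear_rate)
  Ta <- celsius_to_kelvin(data$T_C)
  cols <- list(
    K0       = rep(1, nrow(data)),
    E_over_R = if (dialect == "referenced") 1 / Ta - 1 / T0_ref else 1 / Ta,
    alpha    = if (dialect == "referenced") -(data$MC - MC0_ref) else -data$MC,
    beta     = if (dialect == "referenced") -(data$SME - SME0_ref) else -data$SME,
    n0       = lg,
    a1       = data$T_C * lg,
    a2       = data$MC * lg,
    a3       = data$SME * lg,
    a4       = data$T_C * data$MC * lg,
    a5       = data$T_C * data$SME * lg,
    a6       = data$MC * data$SME * lg)
  X <- do.call(cbind, cols[terms])
  colnames(X) <- terms
  y <- log(data$eta) + lg

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stopf(paste0("singular fit: coefficient(s) %s are not identifiable from ",
                 "this design (vary the corresponding factor or drop the ",
                 "term)"), paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  dfree <- nrow(X) - ncol(X)
  sigma <- if (dfree > 0) sqrt(sum(fit$residuals^2) / dfree) else 0
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sigma * sqrt(diag(XtXinv))
  names(se) <- colnames(X)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1

  pv <- as.list(cf)
  pv$K0 <- exp(cf[["K0"]])
  args <- c(pv[setdiff(names(pv), "")],
            list(dialect = dialect, T0_ref = T0_ref, MC0_ref = MC0_ref,
                 SME0_ref = SME0_ref))
  # guard: E_over_R must be >= 0 for the constructor; keep the raw estimate
  eoR <- args$E_over_R %||% 0
  args$E_over_R <- max(eoR, 0)
  params <- do.call(viscosity_params, args)
  if (eoR < 0) params$E_over_R <- eoR  # report the (unphysical) estimate as-is

  ctab <- data.frame(term = names(cf), estimate = unname(cf),
                     std_error = unname(se))
  ctab$estimate[ctab$term == "K0"] <- params$K0
  ctab$std_error[ctab$term == "K0"] <- params$K0 * se[["K0"]]  # delta method

  structure(list(params = params, coefficients = ctab, sigma = sigma,
                 r_squared = r2, n_obs = nrow(data), terms = terms,
                 dialect = dialect),
            class = "viscosity_fit")
}

#' @export
coef.viscosity_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
print.viscosity_fit <- function(x, ...) {
  cat(sprintf("<viscosity_fit> %d observations, dialect %s\n",
              x$n_obs, x$dialect))
  cat(sprintf("  residual SE (log eta) = %.4g, R^2 = %.4f\n",
              x$sigma, x$r_squared))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}
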