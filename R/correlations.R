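#' Construct a product-feature correlation model
#'
#' A two-parameter monotone map from a computed extrusion variable (the
#' predictor: die-exit SME, temperature or viscosity) to a measured product
#' feature. Three families are supported: `linear` \eqn{y = a + b x},
#' `power` \eqn{y = a x^b} and `exponential` \eqn{y = a e^{b x}}.
#' Usually obtained from data via [fit_correlation()] or shipped
#' reconstructed via [feature_fixtures()].
#'
#' @param feature feature name (e.g. `"dVis_pct"`).
#' @param predictor one of `"SME_com"`, `"T_com"`, `"eta_com"`.
#' @param form `"linear"`, `"power"` or `"exponential"`.
#' @param a,b parameters of the form.
#' @param validity length-2 predictor interval over which the model was
#'   calibrated; predictions outside it warn.
#' @param r_squared,sigma,n_obs optional fit diagnostics.
#' @param provenance free text (e.g. `"fitted"`, `"reconstructed"`).
#' @return An object of class `"feature_correlation"`.
#' @export
correlation_model <- function(feature, predictor = c("SME_com", "T_com",
                                                     "eta_com"),
                              form = c("linear", "power", "exponential"),
                              a, b, validity,
                              r_squared = NA_real_, sigma = NA_real_,
                              n_obs = NA_integer_, provenance = "fitted") {
  predictor <- match.arg(predictor)
  form <- match.arg(form)
  check_number(a, "a"); check_number(b, "b")
  if (length(validity) != 2L || validity[1] >= validity[2])
    stopf("`validity` must be an increasing length-2 interval")
  if (form %in% c("power", "exponential") && a <= 0)
    stopf("%s models need a > 0", form)
  if (form == "power" && validity[1] <= 0)
    stopf("power models need a strictly positive validity interval")
  structure(list(feature = feature, predictor = predictor, form = form,
                 a = a, b = b, validity = as.numeric(validity),
                 r_squared = r_squared, sigma = sigma, n_obs = n_obs,
                 provenance = provenance),
            class = "feature_correlation")
}

correlation_eval <- function(m, x) {
  switch(m$form,
         linear = m$a + m$b * x,
         power = m$a * x^m$b,
         exponential = m$a * exp(m$b * x))
}

correlation_inverse <- function(m, y) {
  switch(m$form,
         linear = (y - m$a) / m$b,
         power = (y / m$a)^(1 / m$b),
         exponential = log(y / m$a) / m$b)
}

#' @export
print.feature_correlation <- function(x, ...) {
  f <- switch(x$form, linear = "%s = %.4g + %.4g * %s",
              power = "%s = %.4g * %s^%.4g",
              exponential = "%s = %.4g * exp(%.4g * %s)")
  args <- if (x$form == "power") list(x$feature, x$a, x$predictor, x$b)
          else list(x$feature, x$a, x$b, x$predictor)
  cat("<feature_correlation>", do.call(sprintf, c(f, args)), "\n")
  cat(sprintf("  validity: %s in [%g, %g]  (%s%s)\n", x$predictor,
              x$validity[1], x$validity[2], x$provenance,
              if (is.na(x$r_squared)) ""
              else sprintf(", R^2 = %.3f, n = %d", x$r_squared, x$n_obs)))
  invisible(x)
}

#' @export
coef.feature_correlation <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' Fit a product-feature correlation
#'
#' Least-squares fit of one of the three correlation families. Power and
#' exponential forms are first log-linearized (giving exact recovery on
#' noise-free data) and then refined by nonlinear least squares on the
#' original scale, so the reported parameters minimize the untransformed
#' residual sum of squares.
#'
#' @param x computed-variable samples (predictor).
#' @param y feature samples.
#' @param form `"linear"`, `"power"` or `"exponential"`.
#' @param feature,predictor names recorded in the model.
#' @return A [correlation_model()] with fit diagnostics (`r_squared` on the
#'   original scale, residual `sigma`, `n_obs`) and validity interval
#'   `[min(x), max(x)]`.
#' @export
fit_correlation <- function(x, y, form = c("linear", "power", "exponential"),
                            feature = "feature",
                            predictor = c("SME_com", "T_com", "eta_com")) {
  form <- match.arg(form)
  predictor <- match.arg(predictor)
  if (length(x) != length(y) || length(x) < 3L)
    stopf("need at least 3 (x, y) pairs of equal length")
  if (anyNA(x) || anyNA(y)) stopf("x and y must not contain NA")
  if (form == "power" && any(x <= 0))
    stopf("power form needs strictly positive x")
  if (form %in% c("power", "exponential") && any(y <= 0))
    stopf("%s form needs strictly positive y (log-linearization)", form)

  if (form == "linear") {
    fit <- stats::lm(y ~ x)
    a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  } else {
    lf <- if (form == "power") stats::lm(log(y) ~ log(x))
          else stats::lm(log(y) ~ x)
    a0 <- exp(unname(stats::coef(lf)[1])); b0 <- unname(stats::coef(lf)[2])
    fn <- if (form == "power") y ~ a * x^b else y ~ a * exp(b * x)
    nl <- tryCatch(
      suppressWarnings(
        stats::nls(fn, data = data.frame(x = x, y = y),
                   start = list(a = a0, b = b0),
                   control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(nl) && requireNamespace("minpack.lm", quietly = TRUE))
      nl <- tryCatch(minpack.lm::nlsLM(fn, data = data.frame(x = x, y = y),
                                       start = list(a = a0, b = b0)),
                     error = function(e) NULL)
    if (is.null(nl)) { a <- a0; b <- b0 }
    else { cf <- stats::coef(nl); a <- unname(cf["a"]); b <- unname(cf["b"]) }
  }
  m <- correlation_model(feature, predictor, form, a, b,
                         validity = range(x), provenance = "fitted")
  res <- y - correlation_eval(m, x)
  ss_tot <- sum((y - mean(y))^2)
  m$r_squared <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  m$sigma <- sqrt(sum(res^2) / max(length(x) - 2, 1))
  m$n_obs <- length(x)
  m
}

#' Predict a product feature from a computed variable
#'
#' @param object a [correlation_model()].
#' @param x predictor values; values outside the model's validity interval
#'   trigger a warning (the model is a calibration, not a law).
#' @param ... unused.
#' @return Predicted feature values.
#' @export
predict.feature_correlation <- function(object, x, ...) {
  check_number(x, "x", allow_vector = TRUE)
  out_of <- x < object$validity[1] | x > object$validity[2]
  if (any(out_of))
    warnf("prediction at %s = %s is outside the fitted validity interval [%g, %g]",
          object$predictor,
          paste(signif(x[out_of], 4), collapse = ", "),
          object$validity[1], object$validity[2])
  correlation_eval(object, x)
}

#' Invert a feature target interval onto the predictor
#'
#' Closed-form inverse of a monotone correlation: the feature interval maps
#' to a predictor interval, which is clipped to the model's validity range.
#' Non-monotone models (b = 0) are rejected rather than pseudo-inverted; an
#' empty intersection with the validity interval is reported as infeasible.
#'
#' @param model a [correlation_model()].
#' @param interval closed feature interval `c(lo, hi)`.
#' @return A list of class `"predictor_interval"`: `predictor`, `lo`, `hi`,
#'   `feasible`, `clipped` (TRUE when the validity range truncated the
#'   inverse image).
#' @export
invert_feature <- function(model, interval) {
  stopifnot(inherits(model, "feature_correlation"))
  if (length(interval) != 2L || interval[1] > interval[2])
    stopf("`interval` must be c(lo, hi) with lo <= hi")
  if (model$b == 0)
    stopf("model '%s' is constant (b = 0) and cannot be inverted",
          model$feature)
  if (model$form %in% c("power", "exponential") && any(interval < 0))
    stopf("feature interval must be non-negative for the %s form",
          model$form)
  ends <- correlation_inverse(model, interval)
  lo <- min(ends); hi <- max(ends)
  clo <- max(lo, model$validity[1]); chi <- min(hi, model$validity[2])
  feasible <- clo <= chi
  structure(list(predictor = model$predictor, feature = model$feature,
                 lo = if (feasible) clo else NA_real_,
                 hi = if (feasible) chi else NA_real_,
                 feasible = feasible,
                 clipped = feasible && (clo > lo + 1e-12 || chi < hi - 1e-12)),
            class = "predictor_interval")
}

#' @export
print.predictor_interval <- function(x, ...) {
  if (!x$feasible)
    cat(sprintf("<predictor_interval> %s target for '%s': infeasible (inverse image misses the validity interval)\n",
                x$predictor, x$feature))
  else
    cat(sprintf("<predictor_interval> %s in [%g, %g] for '%s'%s\n",
                x$predictor, x$lo, x$hi, x$feature,
                if (x$clipped) " (clipped to validity)" else ""))
  invisible(x)
}

#' Reconstructed product-feature correlation fixtures
#'
#' The numeric parameters of the published feature correlations are not part
#' of this package's sources; these fixtures are two-parameter monotone
#' models re-anchored to the printed chart landmarks, and are labelled
#' `"reconstructed"` accordingly. They cover:
#' \describe{
#'   \item{`dvis_maize47`}{intrinsic-viscosity drop (%) of 47%-amylose maize
#'     vs SME (kJ/kg); power law through (625, 45) and (875, 55).}
#'   \item{`insoluble_protein_pf`}{SDS+DTE-insoluble proteins (%) of pea
#'     snacks vs die-exit temperature; exponential with cross-linking onset
#'     5% at 155 °C and 10% at 165 °C.}
#'   \item{`density_pea`}{pea-snack density (kg/m^3) vs die-exit
#'     temperature; decreasing exponential through (155, 200) and
#'     (175, 100).}
#'   \item{`ng_potato`}{remnant starch granules per mm^2 of dense potato
#'     extrudates vs SME; decreasing exponential through (500, 300) and
#'     (550, 150).}
#'   \item{`rm_potato`}{residual molar mass (%) vs SME; power law with the
#'     printed sensitivity (fourfold RM drop per 1.5-fold SME) anchored at
#'     (525, 50).}
#'   \item{`wsi_starch_wheat`}{starch water-solubility index (%) vs SME;
#'     linear through (375, 50) and (600, 60).}
#'   \item{`sei_wheat_lb`,`nc_wheat_lb`,`nc_wheat_wf`}{sectional expansion
#'     index and cell density (per cm^3) of wheat snacks (with/without bran)
#'     vs die-exit temperature; exponentials anchored to the printed
#'     onsets, the tenfold cell-density span over 125-195 °C and the
#'     sixfold bran surge at onset.}
#' }
#'
#' @return Named list of [correlation_model()] objects.
#' @export
feature_fixtures <- function() {
  pw2 <- function(x1, y1, x2, y2) {
    b <- log(y2 / y1) / log(x2 / x1)
    list(a = y1 / x1^b, b = b)
  }
  ex2 <- function(x1, y1, x2, y2) {
    b <- log(y2 / y1) / (x2 - x1)
    list(a = y1 / exp(b * x1), b = b)
  }
  dv <- pw2(625, 45, 875, 55)
  ip <- ex2(155, 5, 165, 10)
  de <- ex2(155, 200, 175, 100)
  ng <- ex2(500, 300, 550, 150)
  rm_b <- log(1 / 4) / log(1.5)
  wsi_b <- (60 - 50) / (600 - 375)
  sei <- ex2(125, 8, 195, 3)
  nc_b <- log(10) / (195 - 125)
  list(
    dvis_maize47 = correlation_model(
      "dVis_pct", "SME_com", "power", dv$a, dv$b, c(200, 1000),
      provenance = "reconstructed"),
    insoluble_protein_pf = correlation_model(
      "insoluble_protein_pct", "T_com", "exponential", ip$a, ip$b,
      c(125, 175), provenance = "reconstructed"),
    density_pea = correlation_model(
      "density_kgm3", "T_com", "exponential", de$a, de$b, c(125, 175),
      provenance = "reconstructed"),
    ng_potato = correlation_model(
      "Ng_per_mm2", "SME_com", "exponential", ng$a, ng$b, c(350, 700),
      provenance = "reconstructed"),
    rm_potato = correlation_model(
      "RM_pct", "SME_com", "power", 50 / 525^rm_b, rm_b, c(350, 700),
      provenance = "reconstructed"),
    wsi_starch_wheat = correlation_model(
      "WSI_starch_pct", "SME_com", "linear", 50 - wsi_b * 375, wsi_b,
      c(200, 700), provenance = "reconstructed"),
    sei_wheat_lb = correlation_model(
      "SEI", "T_com", "exponential", sei$a, sei$b, c(125, 195),
      provenance = "reconstructed"),
    nc_wheat_lb = correlation_model(
      "NC_per_cm3", "T_com", "exponential", 600 / exp(nc_b * 160), nc_b,
      c(125, 195), provenance = "reconstructed"),
    nc_wheat_wf = correlation_model(
      "NC_per_cm3", "T_com", "exponential", 100 / exp(nc_b * 155), nc_b,
      c(125, 195), provenance = "reconstructed"))
}

#' Combine feature targets into predictor windows
#'
#' Inverts each feature target through its correlation model and intersects
#' the resulting intervals per predictor (targets sharing a predictor must
#' overlap; an empty intersection is reported as infeasible).
#'
#' @param models named list of [correlation_model()]s, keyed by feature name
#'   (as in [feature_fixtures()], or your own fits).
#' @param targets named list of feature intervals, keys matching the
#'   `feature` field of a model in `models`.
#' @return Named list (by predictor) of `"predictor_interval"` objects.
#' @export
target_window <- function(models, targets) {
  feats <- vapply(models, `[[`, "", "feature")
  out <- list()
  for (nm in names(targets)) {
    idx <- which(feats == nm | names(models) == nm)
    if (!length(idx))
      stopf("no correlation model for feature '%s'", nm)
    iv <- invert_feature(models[[idx[1]]], targets[[nm]])
    p <- iv$predictor
    if (is.null(out[[p]])) out[[p]] <- iv
    else {
      lo <- max(out[[p]]$lo, iv$lo); hi <- min(out[[p]]$hi, iv$hi)
      out[[p]]$feature <- paste(out[[p]]$feature, iv$feature, sep = " & ")
      out[[p]]$feasible <- out[[p]]$feasible && iv$feasible &&
        !is.na(lo) && !is.na(hi) && lo <= hi
      out[[p]]$lo <- if (out[[p]]$feasible) lo else NA_real_
      out[[p]]$hi <- if (out[[p]]$feasible) hi else NA_real_
    }
  }
  out
}

#' Product-design workflow: from feature targets to an operating window
#'
#' The three-step design composition: (1) invert the feature targets through
#' their correlation models into die-exit predictor windows
#' ([target_window()]); (2) sweep the machine over the operating grid
#' ([run_grid()]); (3) extract the grid nodes whose computed die-exit
#' variables fall inside every predictor window and process constraint
#' ([feasible_region()]).
#'
#' @inheritParams run_grid
#' @param models named list of [correlation_model()]s.
#' @param targets named list of feature intervals (see [target_window()]).
#' @param process_constraints optional named list of intervals on chart
#'   response columns (e.g. `list(T_com_C = c(-Inf, 165), P_com_Pa =
#'   c(0, 1e7))`).
#' @return A list of class `"design_window"`: `windows` (predictor
#'   intervals), `chart`, `region`, `feasible`.
#' @export
design_window <- function(extruder, material, op_base, sweep, models,
                          targets, process_constraints = NULL,
                          tb_zones = NULL, control = extrusion_control()) {
  windows <- target_window(models, targets)
  infeasible <- !all(vapply(windows, `[[`, TRUE, "feasible"))
  cols <- c(SME_com = "SME_com_kJkg", T_com = "T_com_C",
            eta_com = "eta_com_Pas")
  constraints <- process_constraints %||% list()
  for (p in names(windows))
    if (windows[[p]]$feasible)
      constraints[[cols[[p]]]] <- c(windows[[p]]$lo, windows[[p]]$hi)
  chart <- NULL; region <- NULL
  if (!infeasible) {
    chart <- run_grid(extruder, material, op_base, sweep,
                      tb_zones = tb_zones, control = control)
    region <- feasible_region(chart, constraints)
  }
  structure(list(windows = windows, chart = chart, region = region,
                 targets = targets,
                 feasible = !infeasible && !is.null(region) &&
                   region$n_feasible > 0),
            class = "design_window")
}

#' @export
print.design_window <- function(x, ...) {
  cat("<design_window>\n  feature targets:\n")
  for (nm in names(x$targets))
    cat(sprintf("    %s in [%g, %g]\n", nm, x$targets[[nm]][1],
                x$targets[[nm]][2]))
  cat("  predictor windows:\n")
  for (w in x$windows)
    if (w$feasible)
      cat(sprintf("    %s in [%.4g, %.4g]  (%s)\n", w$predictor, w$lo, w$hi,
                  w$feature))
    else
      cat(sprintf("    %s: infeasible (%s)\n", w$predictor, w$feature))
  if (!x$feasible)
    cat("  no feasible operating window\n")
  else
    print(x$region)
  invisible(x)
}
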