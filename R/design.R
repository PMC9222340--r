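#' Sweep operating conditions into an operating chart
#'
#' Runs [solve_profile()] over the Cartesian grid of the supplied operating
#' parameter axes and collects the die-exit responses (`T_com`, `SME_com`,
#' `P_com`, `eta_com`, plus `T_max` and mean residence time). Nodes where
#' the solver fails or does not converge are masked (`converged = FALSE`)
#' and reported, not dropped.
#'
#' @param extruder an [extruder()].
#' @param material an [material()] or shipped material name.
#' @param op_base an [operating_point()] supplying every parameter not
#'   swept.
#' @param sweep named list of numeric axes to sweep; names among `N`
#'   (rpm), `Q` (kg/h), `MC` (fraction) and `Tb` (°C; replaces the set
#'   temperature of the zones listed in `tb_zones` and the die).
#' @param tb_zones integer indices of the barrel zones a `Tb` axis controls;
#'   default: the last three zones.
#' @param control an [extrusion_control()].
#' @return An object of class `"operating_chart"`: a data.frame with one row
#'   per grid node (axis columns first, then responses) and attributes
#'   `axes` (the sweep) and `base` (the base operating point).
#' @examples
#' \donttest{
#' chart <- run_grid(extruder_fixture("zsk26_like"), "hb",
#'                   operating_point(N = 500, Q = 20, MC = 0.19,
#'                                   barrel_temps = c(20, 40, 60, 90, 90, 90, 90)),
#'                   sweep = list(N = c(200, 400, 600), Q = c(10, 30, 50)))
#' }
#' @export
run_grid <- function(extruder, material, op_base, sweep,
                     tb_zones = NULL, control = extrusion_control()) {
  stopifnot(inherits(op_base, "operating_point"))
  if (!length(sweep) || is.null(names(sweep)) || any(!nzchar(names(sweep))))
    stopf("`sweep` must be a named list of numeric axes")
  bad <- setdiff(names(sweep), c("N", "Q", "MC", "Tb"))
  if (length(bad))
    stopf("unknown sweep axes: %s (use N, Q, MC, Tb)",
          paste(bad, collapse = ", "))
  if (is.character(material)) material <- material_db(material)
  grid <- do.call(expand.grid,
                  c(sweep, list(KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE)))
  nz <- length(op_base$barrel_temps %||% extruder$barrel_zones$temp)
  tb_zones <- tb_zones %||% seq.int(max(1L, nz - 2L), nz)

  resp <- matrix(NA_real_, nrow(grid), 6,
                 dimnames = list(NULL, c("T_com_C", "SME_com_kJkg", "P_com_Pa",
                                         "eta_com_Pas", "T_max_C",
                                         "residence_s")))
  conv <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    op <- op_base
    if (!is.null(grid$N)) op$N <- grid$N[i]
    if (!is.null(grid$Q)) op$Q <- grid$Q[i]
    if (!is.null(grid$MC)) op$MC <- grid$MC[i]
    if (!is.null(grid$Tb)) {
      tb <- op$barrel_temps %||% extruder$barrel_zones$temp
      tb[tb_zones] <- grid$Tb[i]
      op$barrel_temps <- tb
      op$die_temp <- grid$Tb[i]
    }
    sim <- tryCatch(solve_profile(extruder, material, op, control),
                    error = function(e) NULL)
    if (!is.null(sim) && sim$converged) {
      conv[i] <- TRUE
      resp[i, ] <- c(sim$T_com, sim$SME_com, sim$P_com, sim$eta_com,
                     sim$T_max, sim$mean_residence_time)
    }
  }
  if (any(!conv))
    warnf("%d of %d grid nodes did not converge and are masked",
          sum(!conv), nrow(grid))
  out <- cbind(grid, as.data.frame(resp), converged = conv)
  attr(out, "axes") <- sweep
  attr(out, "base") <- op_base
  attr(out, "machine") <- extruder$name
  attr(out, "material") <- material$name
  class(out) <- c("operating_chart", "data.frame")
  out
}

#' @export
print.operating_chart <- function(x, ...) {
  ax <- attr(x, "axes")
  cat(sprintf("<operating_chart> %s on %s: %s (%d nodes, %d converged)\n",
              attr(x, "material"), attr(x, "machine"),
              paste(sprintf("%s[%d]", names(ax), lengths(ax)),
                    collapse = " x "),
              nrow(x), sum(x$converged)))
  NextMethod()
  invisible(x)
}

#' Extract the feasible region of an operating chart
#'
#' Masks the grid nodes whose responses fall inside every supplied closed
#' interval. An empty region is a legal result and is reported as such. For
#' two-axis charts the constraint boundaries are also returned as contour
#' polylines (in axis coordinates) for plotting.
#'
#' @param chart an [run_grid()] result.
#' @param constraints named list of length-2 numeric intervals (use `-Inf` /
#'   `Inf` for one-sided constraints); names must be response columns of the
#'   chart, e.g. `list(T_com_C = c(-Inf, 165), P_com_Pa = c(0, 1e7))`.
#' @return A list of class `"feasible_region"`: `mask` (logical vector over
#'   grid rows; unconverged nodes are infeasible), `nodes` (the feasible
#'   subset of the chart), `n_feasible`, `boundaries` (list of contour
#'   polylines, 2-axis charts only), `constraints`.
#' @export
feasible_region <- function(chart, constraints) {
  stopifnot(inherits(chart, "operating_chart"))
  if (!length(constraints) || is.null(names(constraints)))
    stopf("`constraints` must be a named list of intervals")
  missing_resp <- setdiff(names(constraints), names(chart))
  if (length(missing_resp))
    stopf("chart has no response column(s): %s",
          paste(missing_resp, collapse = ", "))
  mask <- chart$converged
  for (nm in names(constraints)) {
    iv <- constraints[[nm]]
    if (length(iv) != 2L || iv[1] > iv[2])
      stopf("constraint '%s' must be a non-empty interval c(lo, hi)", nm)
    mask <- mask & chart[[nm]] >= iv[1] & chart[[nm]] <= iv[2]
  }
  mask[is.na(mask)] <- FALSE
  ax <- attr(chart, "axes")
  boundaries <- NULL
  if (length(ax) == 2L && all(lengths(ax) >= 2L) &&
      any(mask) && !all(mask)) {
    a1 <- names(ax)[1]; a2 <- names(ax)[2]
    z <- matrix(NA_real_, length(ax[[1]]), length(ax[[2]]))
    ind <- cbind(match(chart[[a1]], ax[[1]]), match(chart[[a2]], ax[[2]]))
    z[ind] <- as.numeric(mask)
    boundaries <- grDevices::contourLines(ax[[1]], ax[[2]], z, levels = 0.5)
    boundaries <- lapply(boundaries, function(b)
      stats::setNames(data.frame(b$x, b$y), c(a1, a2)))
  }
  structure(list(mask = mask, nodes = chart[mask, , drop = FALSE],
                 n_feasible = sum(mask), boundaries = boundaries,
                 constraints = constraints, axes = names(ax)),
            class = "feasible_region")
}

#' @export
print.feasible_region <- function(x, ...) {
  if (x$n_feasible == 0L) {
    cat("<feasible_region> no feasible window: no grid node satisfies",
        sprintf("all %d constraint(s)\n", length(x$constraints)))
    return(invisible(x))
  }
  cat(sprintf("<feasible_region> %d feasible node(s) under %d constraint(s)\n",
              x$n_feasible, length(x$constraints)))
  for (nm in x$axes)
    cat(sprintf("  %s in [%g, %g]\n", nm, min(x$nodes[[nm]]),
                max(x$nodes[[nm]])))
  invisible(x)
}

#' Contour plot of an operating chart response
#'
#' @param x an `"operating_chart"` with exactly two sweep axes.
#' @param response response column to contour (default `"SME_com_kJkg"`).
#' @param region optional [feasible_region()] whose boundary is overlaid.
#' @param ... passed to [graphics::contour()].
#' @export
plot.operating_chart <- function(x, response = "SME_com_kJkg",
                                 region = NULL, ...) {
  ax <- attr(x, "axes")
  if (length(ax) != 2L)
    stopf("plotting needs a chart with exactly two sweep axes")
  a1 <- names(ax)[1]; a2 <- names(ax)[2]
  z <- matrix(NA_real_, length(ax[[1]]), length(ax[[2]]))
  z[cbind(match(x[[a1]], ax[[1]]), match(x[[a2]], ax[[2]]))] <- x[[response]]
  graphics::filled.contour(
    ax[[1]], ax[[2]], z, xlab = a1, ylab = a2,
    main = sprintf("%s (%s on %s)", response, attr(x, "material"),
                   attr(x, "machine")),
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      if (!is.null(region) && length(region$boundaries))
        for (b in region$boundaries)
          graphics::lines(b[[1]], b[[2]], lwd = 2, lty = 2)
    }, ...)
  invisible(x)
}
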