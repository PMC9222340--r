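#' @export
print.extrusion_sim <- function(x, ...) {
  cat(sprintf("<extrusion_sim> %s on %s: N = %g rpm, Q = %g kg/h, MC = %g\n",
              x$material, x$machine, x$op$N, x$op$Q, x$op$MC))
  cat(sprintf("  T_com = %.1f degC  SME_com = %.0f kJ/kg  P_com = %.2f MPa  eta_com = %.0f Pa.s\n",
              x$T_com, x$SME_com, x$P_com / 1e6, x$eta_com))
  cat(sprintf("  T_max = %.1f degC, melting at %.0f mm from die (T_m = %.1f degC), MRT = %.1f s\n",
              x$T_max, 1e3 * x$melting_position, x$melt_temp,
              x$mean_residence_time))
  cat(sprintf("  converged: %s (%d shooting, %d history iterations)%s\n",
              x$converged, x$iterations, x$sme_iterations,
              if (x$over_fed) " [over-fed configuration]" else ""))
  invisible(x)
}

#' Die-exit summary of a converged simulation
#'
#' Flattens the die-exit state of an [solve_profile()] result into a one-row
#' data.frame (the record exported to CSV/JSON by batch workflows), plus a
#' provenance string identifying machine, material and operating point.
#' Unconverged results are refused.
#'
#' @param object an `"extrusion_sim"` object.
#' @param ... unused.
#' @return A one-row data.frame with columns `T_com_C`, `SME_com_kJkg`,
#'   `P_com_Pa`, `eta_com_Pas`, `T_max_C`, `mean_residence_s`,
#'   `melting_position_m`, `melt_enthalpy_kJkg` and `provenance`.
#' @export
summary.extrusion_sim <- function(object, ...) {
  if (!object$converged)
    stopf("refusing to summarize an unconverged simulation (melting-point residual %.3g degC)",
          object$melt_temp_residual)
  out <- data.frame(
    T_com_C = object$T_com, SME_com_kJkg = object$SME_com,
    P_com_Pa = object$P_com, eta_com_Pas = object$eta_com,
    T_max_C = object$T_max, mean_residence_s = object$mean_residence_time,
    melting_position_m = object$melting_position,
    melt_enthalpy_kJkg = object$melt_enthalpy_kJkg,
    provenance = sprintf("%s|%s|N=%g|Q=%g|MC=%g|Nu=%g",
                         object$machine, object$material, object$op$N,
                         object$op$Q, object$op$MC, object$op$nusselt))
  class(out) <- c("extrusion_summary", "data.frame")
  out
}

#' @export
as.data.frame.extrusion_sim <- function(x, ...) x$states

#' Axial profile plot of a simulation
#'
#' Four stacked panels (temperature, pressure, cumulative SME, viscosity)
#' against axial position measured from the die, with restrictive elements
#' shaded.
#'
#' @param x an `"extrusion_sim"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.extrusion_sim <- function(x, ...) {
  st <- x$states
  pos <- 1e3 * st$position_m
  op_par <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4.2, 0.6, 0.6),
                          oma = c(2, 0, 2, 0), mgp = c(2.4, 0.7, 0))
  on.exit(graphics::par(op_par))
  shade <- function() {
    r <- st$kind != "conveying_rh"
    if (!any(r)) return()
    blocks <- rle(r)
    ends <- cumsum(blocks$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    for (i in which(blocks$values)) {
      u <- graphics::par("usr")
      graphics::rect(pos[ends[i]], u[3], pos[starts[i]], u[4],
                     col = grDevices::adjustcolor("grey60", 0.3), border = NA)
    }
  }
  panel <- function(y, ylab, log = "") {
    graphics::plot(pos, y, type = "l", lwd = 2, xlab = "", ylab = ylab,
                   xlim = rev(range(pos)), log = log, ...)
    shade()
    graphics::lines(pos, y, lwd = 2)
  }
  panel(st$T_C, "T (degC)")
  panel(st$P_Pa / 1e6, "P (MPa)")
  panel(st$SME_kJkg, "SME (kJ/kg)")
  panel(st$eta_Pas, "viscosity (Pa.s)", log = "y")
  graphics::mtext("axial position from die (mm)", side = 1, outer = TRUE,
                  line = 0.5)
  graphics::mtext(sprintf("%s | %s | N = %g rpm, Q = %g kg/h, MC = %g",
                          x$machine, x$material, x$op$N, x$op$Q, x$op$MC),
                  side = 3, outer = TRUE, line = 0.5)
  invisible(x)
}

#' Export an axial profile to CSV
#'
#' @param sim an `"extrusion_sim"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(sim, path) {
  stopifnot(inherits(sim, "extrusion_sim"))
  utils::write.csv(sim$states, path, row.names = FALSE)
  invisible(path)
}
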