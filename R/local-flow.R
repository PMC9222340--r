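#' Define an operating point
#'
#' Screw speed, feed rate, feed moisture and the thermal boundary conditions
#' of one extrusion run.
#'
#' @param N screw speed (rpm), > 0.
#' @param Q total feed rate (kg/h), > 0.
#' @param MC feed moisture content, wet-basis fraction in (0, 0.9).
#' @param barrel_temps set temperatures of the barrel zones (°C); either
#'   NULL (use the machine's zone defaults), one value per zone, or a single
#'   value recycled to all zones. A moisture given as a percentage string
#'   (e.g. `"15%"`) is accepted and divided by 100.
#' @param die_temp die set temperature (°C); default: last barrel zone.
#' @param nusselt Nusselt number of the melt-barrel heat exchange
#'   (default 20).
#' @return An object of class `"operating_point"`.
#' @export
operating_point <- function(N, Q, MC, barrel_temps = NULL, die_temp = NULL,
                            nusselt = 20) {
  if (is.character(MC)) MC <- parse_fraction(MC)
  check_number(N, "N", lower = 0, strict_lower = TRUE)
  check_number(Q, "Q", lower = 0, strict_lower = TRUE)
  check_number(MC, "MC", lower = 0, upper = 0.9, strict_lower = TRUE,
               strict_upper = TRUE)
  check_number(nusselt, "nusselt", lower = 0, strict_lower = TRUE)
  if (!is.null(barrel_temps))
    check_number(barrel_temps, "barrel_temps", allow_vector = TRUE)
  if (!is.null(die_temp)) check_number(die_temp, "die_temp")
  structure(list(N = N, Q = Q, MC = MC, barrel_temps = barrel_temps,
                 die_temp = die_temp, nusselt = nusselt),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> N = %g rpm, Q = %g kg/h, MC = %g (w.b.), Nu = %g\n",
              x$N, x$Q, x$MC, x$nusselt))
  if (!is.null(x$barrel_temps))
    cat("  barrel temps (degC):", paste(x$barrel_temps, collapse = "/"), "\n")
  if (!is.null(x$die_temp)) cat("  die temp (degC):", x$die_temp, "\n")
  invisible(x)
}

#' Pressure change across a screw element (C-chamber law)
#'
#' Rearranges the elementary flow law `Qv = A*Omega + (B/eta) * dP/dtheta`
#' for the pressure change over an element of angular extent `dtheta`:
#' `dP = (Qv - A*Omega) * eta * dtheta / B`, the upstream-minus-downstream
#' pressure difference. A negative value (drag capacity exceeding
#' throughput) means pressure rises toward the die; reverse elements
#' (A < 0) give positive values, i.e. pressure peaking upstream.
#'
#' @param sf shape factors of the element ([shape_factors()]).
#' @param Qv volumetric throughput (m^3/s).
#' @param omega screw speed (rad/s).
#' @param eta local Newtonian-equivalent viscosity (Pa·s), > 0.
#' @param dtheta angular extent (rad); default: the whole element.
#' @return A list with `dP` (Pa, upstream minus downstream) and `filled`
#'   (TRUE when the element must be fully filled for the law to hold, i.e.
#'   when it is pressure-generating or pressure-consuming).
#' @export
pressure_step <- function(sf, Qv, omega, eta, dtheta = sf$dtheta) {
  check_number(eta, "eta", lower = 0, strict_lower = TRUE)
  if (sf$B <= 0) stopf("geometry error: pressure coefficient B must be > 0")
  dP <- (Qv - sf$A * omega) * eta * dtheta / sf$B
  list(dP = dP, filled = sf$A * omega <= Qv)
}

#' Representative shear rates in a screw element
#'
#' The 1D global model linearizes the melt locally as a Newtonian fluid at a
#' representative channel shear rate `pi*D*(N/60)/h`; the flight-gap shear
#' rate `pi*D*(N/60)/gap` is returned as well for the dissipation split.
#'
#' @param element a [screw_element()].
#' @param screw_diameter screw diameter (m).
#' @param N screw speed (rpm), >= 0.
#' @return list with `channel` and `gap` shear rates (1/s).
#' @export
representative_shear_rate <- function(element, screw_diameter, N) {
  check_number(N, "N", lower = 0)
  v <- pi * screw_diameter * N / 60
  list(channel = element$shear_efficiency * v / element$channel_depth,
       gap = v / element$flight_gap)
}

#' Viscous power dissipated in a screw element
#'
#' Evaluates the volume integral of `eta * shear_rate^2` with the
#' channel/flight-gap split: `W = fill * (eta_ch * g_ch^2 * V_ch + eta_gap *
#' g_gap^2 * V_gap)`, viscosities taken from the material model at the
#' element's thermomechanical state. Partially filled chambers dissipate in
#' proportion to the filled volume.
#'
#' @param element a [screw_element()].
#' @param screw_diameter screw diameter (m).
#' @param params a [viscosity_params()] object.
#' @param T_C,MC,SME local melt state (°C, fraction, kJ/kg).
#' @param N screw speed (rpm).
#' @param fill_ratio filled fraction of the element volume, in (0, 1].
#' @return Dissipated power (W), >= 0.
#' @export
dissipated_power <- function(element, screw_diameter, params, T_C, MC, SME,
                             N, fill_ratio = 1) {
  check_number(fill_ratio, "fill_ratio", lower = 0, upper = 1)
  sf <- shape_factors(element, screw_diameter)
  g <- representative_shear_rate(element, screw_diameter, N)
  if (N == 0) return(0)
  eta_ch <- apparent_viscosity_fast(params, g$channel, T_C, MC, SME)
  eta_gap <- apparent_viscosity_fast(params, g$gap, T_C, MC, SME)
  fill_ratio * (eta_ch * g$channel^2 * sf$V_channel +
                  eta_gap * g$gap^2 * sf$V_gap)
}

#' Temperature change of the melt over a screw element
#'
#' Per-unit-mass energy balance between viscous dissipation and conductive
#' exchange with the barrel: `dT = (Ev - Ecd)/Cp` with `Ev = W/(rho*Qv)` and
#' `Ecd = h_t * S * (T - Tb) / (rho*Qv)`, the heat transfer coefficient
#' coming from a Nusselt closure `h_t = Nu * k / h_channel` (characteristic
#' length: channel depth).
#'
#' @param material an [material()] object.
#' @param W_dot dissipated power in the element (W).
#' @param Qv volumetric throughput (m^3/s).
#' @param T_C melt temperature (°C).
#' @param Tb_C barrel set temperature at the element (°C).
#' @param MC moisture content (fraction).
#' @param nusselt Nusselt number (default 20).
#' @param exchange_area barrel-facing exchange surface of the filled
#'   fraction (m^2).
#' @param h_channel channel depth used as the characteristic length of the
#'   Nusselt closure (m).
#' @return Temperature change over the element (°C), sign following
#'   `Ev - Ecd`.
#' @export
energy_step <- function(material, W_dot, Qv, T_C, Tb_C, MC, nusselt = 20,
                        exchange_area, h_channel) {
  rho <- melt_property(material, MC, "rho")
  cp <- melt_property(material, MC, "cp")
  k <- melt_property(material, MC, "k")
  ht <- nusselt * k / h_channel
  Ev <- W_dot / (rho * Qv)
  Ecd <- ht * exchange_area * (T_C - Tb_C) / (rho * Qv)
  (Ev - Ecd) / cp
}
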