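#' Define a screw element
#'
#' One element of the screw profile, hopper-to-die order. Three kinds are
#' supported:
#' \describe{
#'   \item{`conveying_rh`}{right-handed (forward-conveying) screw element.}
#'   \item{`reverse_lh`}{left-handed element; its drag coefficient is
#'     negative, so it impedes conveying and forces full filling and
#'     pressure build-up upstream (a restrictive element).}
#'   \item{`kneading_block`}{a stack of staggered bilobal kneading discs,
#'     modelled as an equivalent conveying element whose pitch is implied by
#'     the stagger angle plus a leakage conductance past the disc tips (also
#'     restrictive). The equivalent pitch is `disc_thickness * 360 /
#'     stagger_angle` (capped at two screw diameters) and the drag efficiency
#'     scales as `1 - stagger_angle/90`, so a 90° (neutral) block conveys
#'     nothing.}
#' }
#'
#' @param kind element kind, see Details.
#' @param length axial length (m), > 0.
#' @param pitch screw pitch (m), > 0 (handedness is carried by `kind`).
#'   Required for conveying and reverse elements; ignored for kneading
#'   blocks.
#' @param channel_depth radial channel depth h (m), > 0.
#' @param flight_count number of parallel flights/channels (bilobal: 2).
#' @param flight_width axial flight-land width (m); default 12% of the
#'   (equivalent) pitch.
#' @param flight_gap radial flight-tip clearance (m), used for the gap
#'   dissipation term.
#' @param stagger_angle disc stagger angle in degrees (kneading blocks only;
#'   typically 45 or 90).
#' @param disc_thickness individual disc thickness (m, kneading blocks only).
#' @param leak_depth_frac restrictive elements: effective depth of the
#'   leakage path past the disc tips (kneading blocks) or through the flight
#'   slots (left-handed elements), as a fraction of `channel_depth`
#'   (default 0.5).
#' @param shear_efficiency scaling of the representative channel shear rate.
#'   Defaults to 1; kneading blocks default to 0.5, reflecting that most of
#'   the inter-disc volume sees far lower shear than the tip region (part of
#'   the equivalent-element closure for staggered discs).
#' @param ht_factor multiplier on the melt-barrel heat-transfer coefficient
#'   over this element (default 1). Useful e.g. to represent the enhanced
#'   wall heat exchange of kneading sections, where the discs continuously
#'   wipe and renew the melt layer at the barrel.
#' @return An object of class `"screw_element"`.
#' @export
screw_element <- function(kind = c("conveying_rh", "reverse_lh",
                                   "kneading_block"),
                          length, pitch = NULL, channel_depth,
                          flight_count = 2L, flight_width = NULL,
                          flight_gap = 1.5e-4,
                          stagger_angle = NULL, disc_thickness = NULL,
                          leak_depth_frac = 0.5, shear_efficiency = NULL,
                          ht_factor = NULL) {
  kind <- match.arg(kind)
  shear_efficiency <- shear_efficiency %||%
    (if (kind == "kneading_block") 0.5 else 1)
  check_number(shear_efficiency, "shear_efficiency", lower = 0, upper = 1,
               strict_lower = TRUE)
  ht_factor <- ht_factor %||% 1
  check_number(ht_factor, "ht_factor", lower = 0, strict_lower = TRUE)
  check_number(length, "length", lower = 0, strict_lower = TRUE)
  check_number(channel_depth, "channel_depth", lower = 0, strict_lower = TRUE)
  check_number(flight_gap, "flight_gap", lower = 0, strict_lower = TRUE)
  if (kind == "kneading_block") {
    if (is.null(stagger_angle) || is.null(disc_thickness))
      stopf("kneading blocks require `stagger_angle` and `disc_thickness`")
    check_number(stagger_angle, "stagger_angle", lower = 0, upper = 90,
                 strict_lower = TRUE)
    check_number(disc_thickness, "disc_thickness", lower = 0,
                 strict_lower = TRUE)
  } else {
    if (is.null(pitch)) stopf("`pitch` is required for %s elements", kind)
    check_number(pitch, "pitch", lower = 0, strict_lower = TRUE)
  }
  structure(
    list(kind = kind, length = length, pitch = pitch,
         channel_depth = channel_depth, flight_count = as.integer(flight_count),
         flight_width = flight_width, flight_gap = flight_gap,
         stagger_angle = stagger_angle, disc_thickness = disc_thickness,
         leak_depth_frac = leak_depth_frac,
         shear_efficiency = shear_efficiency, ht_factor = ht_factor),
    class = "screw_element")
}

is_restrictive <- function(el) el$kind %in% c("reverse_lh", "kneading_block")

#' Define a die element
#'
#' An elementary die channel: a circular capillary or a rectangular slit.
#' Elements sharing a `group` id are in parallel (the flow splits to equalize
#' the pressure drop); groups are traversed in series in list order.
#'
#' @param kind `"circular"` or `"slit"`.
#' @param length channel length (m), > 0.
#' @param radius circular channel radius (m).
#' @param width,height slit width and gap (m).
#' @param group parallel group id (integer); defaults to a singleton group.
#' @return An object of class `"die_element"`.
#' @export
die_element <- function(kind = c("circular", "slit"), length,
                        radius = NULL, width = NULL, height = NULL,
                        group = NULL) {
  kind <- match.arg(kind)
  check_number(length, "length", lower = 0, strict_lower = TRUE)
  if (kind == "circular") {
    if (is.null(radius)) stopf("circular die elements need `radius`")
    check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  } else {
    if (is.null(width) || is.null(height))
      stopf("slit die elements need `width` and `height`")
    check_number(width, "width", lower = 0, strict_lower = TRUE)
    check_number(height, "height", lower = 0, strict_lower = TRUE)
  }
  structure(list(kind = kind, length = length, radius = radius,
                 width = width, height = height, group = group),
            class = "die_element")
}

#' Assemble an extruder
#'
#' The machine: a co-rotating twin-screw defined by its diameter, an ordered
#' screw profile (hopper to die), a die assembly, and barrel temperature
#' zones tiling the screw length. At least one restrictive element
#' (left-handed element or kneading block) is required: the melting section
#' of the flow model is pinned at the first one.
#'
#' @param screw_diameter screw (barrel bore) diameter D (m).
#' @param elements list of [screw_element()]s, hopper -> die order.
#' @param die list of [die_element()]s.
#' @param barrel_zones data.frame with columns `length` (m) and `temp` (°C);
#'   zones tile the screw length in hopper -> die order without overlap.
#' @param total_length total screw length (m); default: sum of element
#'   lengths.
#' @param centerline_distance screw centreline distance (m); default 0.83 D
#'   (typical intermeshing co-rotating geometry). Recorded, not used by the
#'   lumped C-chamber coefficients.
#' @param feed_position axial position of the feed port from the hopper end
#'   (m), default 0.
#' @param name optional machine label.
#' @return An object of class `"extruder"`.
#' @seealso [extruder_fixture()] for shipped machine reconstructions.
#' @export
extruder <- function(screw_diameter, elements, die, barrel_zones,
                     total_length = NULL, centerline_distance = NULL,
                     feed_position = 0, name = "extruder") {
  check_number(screw_diameter, "screw_diameter", lower = 0,
               strict_lower = TRUE)
  if (!length(elements) || !all(vapply(elements, inherits, TRUE,
                                       "screw_element")))
    stopf("`elements` must be a non-empty list of screw_element objects")
  if (!length(die) || !all(vapply(die, inherits, TRUE, "die_element")))
    stopf("`die` must be a non-empty list of die_element objects")
  elen <- vapply(elements, `[[`, 0, "length")
  total_length <- total_length %||% sum(elen)
  if (sum(elen) > total_length + 1e-9)
    stopf("element lengths sum (%.4g m) exceeds total screw length (%.4g m)",
          sum(elen), total_length)
  if (!is.data.frame(barrel_zones) ||
      !all(c("length", "temp") %in% names(barrel_zones)))
    stopf("`barrel_zones` must be a data.frame with columns length, temp")
  if (any(barrel_zones$length <= 0))
    stopf("barrel zone lengths must be positive")
  if (abs(sum(barrel_zones$length) - total_length) > 1e-6 * total_length)
    stopf("barrel zones must tile the screw length (zones sum to %.4g m, screw is %.4g m)",
          sum(barrel_zones$length), total_length)
  hd <- vapply(elements, `[[`, 0, "channel_depth")
  if (any(hd >= screw_diameter / 2))
    stopf("degenerate geometry: channel depth >= D/2")
  restr <- vapply(elements, is_restrictive, TRUE)
  if (!any(restr))
    warnf(paste("the screw profile has no restrictive element (reverse_lh or",
                "kneading_block); the flow solver will refuse it, since the",
                "melting section is pinned at the first restrictive element"))
  structure(
    list(name = name, screw_diameter = screw_diameter,
         centerline_distance = centerline_distance %||% 0.83 * screw_diameter,
         total_length = total_length, elements = elements, die = die,
         barrel_zones = barrel_zones, feed_position = feed_position),
    class = "extruder")
}

#' @export
print.extruder <- function(x, ...) {
  kinds <- vapply(x$elements, `[[`, "", "kind")
  cat(sprintf("<extruder> %s: D = %.3g mm, L = %.3g mm, %d screw elements (%d restrictive), %d die element(s)\n",
              x$name, 1e3 * x$screw_diameter, 1e3 * x$total_length,
              length(x$elements),
              sum(vapply(x$elements, is_restrictive, TRUE)),
              length(x$die)))
  rle_k <- rle(kinds)
  cat("  profile (hopper->die):",
      paste(sprintf("%dx %s", rle_k$lengths, rle_k$values), collapse = " | "),
      "\n")
  cat("  barrel zones (degC):", paste(x$barrel_zones$temp, collapse = "/"),
      "\n")
  invisible(x)
}

#' Geometry-derived flow coefficients of a screw element
#'
#' Computes the drag coefficient A and pressure-flow coefficient B of the
#' C-chamber flow law `Qv = A*Omega + (B/eta)*(dP/dtheta)` from
#' shallow-rectangular-channel lubrication formulas, together with the
#' element's angular extent, free/gap volumes and barrel-facing exchange
#' area. Reverse elements return A < 0; kneading blocks are mapped to an
#' equivalent conveying element (see [screw_element()]) with a leakage
#' conductance added to B.
#'
#' @param element a [screw_element()].
#' @param screw_diameter screw diameter D (m).
#' @return A list with components `A` (m^3), `B` (m^3, per radian of
#'   pressure gradient), `dtheta` (total angular extent, rad), `G`
#'   (axial pressure-flow conductance, m^3: `Q_pressure = G * dP_total /
#'   eta`), `W`, `helix_angle`, `V_channel`, `V_gap`, `S_barrel`,
#'   `channel_depth`, `gap`.
#' @export
shape_factors <- function(element, screw_diameter) {
  stopifnot(inherits(element, "screw_element"))
  D <- screw_diameter
  h <- element$channel_depth
  if (h >= D / 2) stopf("degenerate geometry: channel depth %.4g >= D/2", h)
  drag_eff <- 1
  sgn <- 1
  if (element$kind == "kneading_block") {
    p <- min(element$disc_thickness * 360 / element$stagger_angle, 2 * D)
    drag_eff <- max(1 - element$stagger_angle / 90, 0)
  } else {
    p <- element$pitch
    if (element$kind == "reverse_lh") sgn <- -1
  }
  n_ch <- element$flight_count
  fw <- element$flight_width %||% (0.12 * p)
  phi <- atan(p / (pi * D))
  W <- p * cos(phi) / n_ch - fw
  if (W <= 0)
    stopf("degenerate geometry: channel width <= 0 (pitch %.4g m too small for %d flights)",
          p, n_ch)
  A <- sgn * drag_eff * n_ch * W * h * D * cos(phi) / 4
  L <- element$length
  G <- n_ch * W * h^3 * sin(phi) / (12 * L)
  if (element$kind != "conveying_rh") {
    # leakage past kneading-disc tips / through the slots of left-handed
    # elements: an equivalent annular slit of depth leak_depth_frac * h
    d_leak <- element$leak_depth_frac * h
    G <- G + 0.25 * pi * D * d_leak^3 / (12 * L)
  }
  dtheta <- 2 * pi * L / p
  V_channel <- n_ch * W * h * L / sin(phi)
  V_gap <- n_ch * fw * element$flight_gap * L / sin(phi)
  # barrel-facing surface attributed to the melt (single-bore perimeter)
  S_barrel <- pi * D * L
  list(A = A, B = G * dtheta, dtheta = dtheta, G = G, W = W,
       helix_angle = phi, V_channel = V_channel, V_gap = V_gap,
       S_barrel = S_barrel, channel_depth = h, gap = element$flight_gap,
       flight_width = fw, pitch_eff = p, length = L)
}

# --- die flow ---------------------------------------------------------------

# per-element conductance factor C such that Qv = C * dP^(1/n)
die_flow_factor <- function(el, n, K) {
  if (el$kind == "circular") {
    (pi * el$radius^3 * n / (3 * n + 1)) * (el$radius / (2 * el$length * K))^(1 / n)
  } else {
    (el$width * el$height^2 * n / (2 * (2 * n + 1))) *
      (el$height / (2 * el$length * K))^(1 / n)
  }
}

die_wall_shear <- function(el, Qv, n) {
  if (el$kind == "circular") {
    (3 * n + 1) * Qv / (n * pi * el$radius^3)
  } else {
    2 * (2 * n + 1) * Qv / (n * el$width * el$height^2)
  }
}

#' Pressure drop across a die assembly
#'
#' Power-law Poiseuille flow through each die element (circular capillary or
#' slit), with elements of the same parallel group splitting the flow so
#' their pressure drops equalize, and groups summing in series. The
#' consistency K and flow index n are evaluated once at the supplied
#' thermomechanical state (they do not depend on shear rate); each element's
#' wall shear rate is reported for viscosity evaluation.
#'
#' @param die list of [die_element()]s.
#' @param Qv volumetric flow rate (m^3/s), > 0.
#' @param params a [viscosity_params()] object.
#' @param T_C melt temperature (°C).
#' @param MC moisture content (wet-basis fraction).
#' @param SME cumulative SME (kJ/kg).
#' @param details if TRUE, attach a per-element table (flow split, pressure
#'   drop, wall shear rate) as attribute `"elements"`.
#' @return Total pressure drop (Pa). With `details = TRUE` the attribute
#'   `"elements"` holds a data.frame.
#' @export
die_pressure_drop <- function(die, Qv, params, T_C, MC, SME,
                              details = FALSE) {
  if (!length(die)) stopf("the die has no elements")
  stopifnot(all(vapply(die, inherits, TRUE, "die_element")))
  check_number(Qv, "Qv", lower = 0, strict_lower = TRUE)
  n <- flow_index_fast(params, T_C, MC, SME)
  K <- consistency_k_fast(params, celsius_to_kelvin(T_C), MC, SME)
  groups <- vapply(seq_along(die), function(i) {
    g <- die[[i]]$group
    if (is.null(g)) paste0(".el", i) else as.character(g)
  }, "")
  total <- 0
  rows <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    C <- vapply(die[idx], die_flow_factor, 0, n = n, K = K)
    dP <- (Qv / sum(C))^n
    Qi <- C * dP^(1 / n)
    total <- total + dP
    rows[[g]] <- data.frame(
      element = idx, group = g, Qv = Qi, dP = dP,
      wall_shear = vapply(seq_along(idx), function(j)
        die_wall_shear(die[[idx[j]]], Qi[j], n), 0))
  }
  if (details) {
    out <- total
    attr(out, "elements") <- do.call(rbind, c(rows, make.row.names = FALSE))
    attr(out, "flow_index") <- n
    attr(out, "consistency") <- K
    return(out)
  }
  total
}
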