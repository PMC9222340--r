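#' Generate synthetic rheometry data
#'
#' Draws apparent-viscosity observations lognormally around the power-law
#' viscosity model truth at the requested factor settings — a stand-in for
#' slit-die or pre-shearing capillary rheometer datasets, used to exercise
#' [fit_viscosity_params()]. Deterministic for a fixed seed; the global RNG
#' state is left untouched.
#'
#' @param params a [viscosity_params()] object (the generating truth).
#' @param design data.frame (or named list expanded via [expand.grid()])
#'   with columns/factors `shear_rate`, `T_C`, `MC`, `SME`.
#' @param noise_cv lognormal coefficient of variation of the multiplicative
#'   noise (0 puts every point exactly on the model).
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return data.frame with columns `shear_rate`, `T_C`, `MC`, `SME`, `eta`.
#' @export
generate_rheometry <- function(params, design, noise_cv = 0, seed = NULL) {
  stopifnot(inherits(params, "viscosity_params"))
  check_number(noise_cv, "noise_cv", lower = 0)
  if (!is.data.frame(design))
    design <- do.call(expand.grid,
                      c(design, list(KEEP.OUT.ATTRS = FALSE)))
  req <- c("shear_rate", "T_C", "MC", "SME")
  if (!all(req %in% names(design)))
    stopf("design needs factors %s", paste(req, collapse = ", "))
  eta <- apparent_viscosity(params, design$shear_rate, design$T_C,
                            design$MC, design$SME, warn = FALSE)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    eta <- with_local_seed(seed,
                           eta * exp(stats::rnorm(length(eta), 0, sdlog)))
  }
  cbind(design[req], eta = eta)
}

#' Generate synthetic product-feature data
#'
#' Draws feature observations lognormally around a correlation model truth
#' on a predictor grid — a stand-in for measured product-feature tables,
#' used to exercise [fit_correlation()].
#'
#' @param model a [correlation_model()].
#' @param x predictor values.
#' @param noise_cv lognormal coefficient of variation (0 = exact).
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return data.frame with columns `x` and `y`.
#' @export
generate_feature_data <- function(model, x, noise_cv = 0, seed = NULL) {
  stopifnot(inherits(model, "feature_correlation"))
  check_number(noise_cv, "noise_cv", lower = 0)
  y <- correlation_eval(model, x)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    y <- with_local_seed(seed, y * exp(stats::rnorm(length(y), 0, sdlog)))
  }
  data.frame(x = x, y = y)
}

# --- config I/O -------------------------------------------------------------

mm <- function(x) x * 1e-3

config_errors <- new.env(parent = emptyenv())

collect_error <- function(errs, path, fmt, ...) {
  c(errs, sprintf("%s: %s", path, sprintf(fmt, ...)))
}

known_keys <- list(
  element = c("kind", "length_mm", "pitch_mm", "channel_depth_mm",
              "flight_count", "flight_width_mm", "flight_gap_mm",
              "stagger_angle_deg", "disc_thickness_mm", "leak_depth_frac",
              "shear_efficiency", "ht_factor"),
  die = c("kind", "length_mm", "radius_mm", "width_mm", "height_mm",
          "group"),
  zone = c("length_mm", "from_mm", "to_mm", "temp_C"),
  machine = c("name", "screw_diameter_mm", "centerline_distance_mm",
              "total_length_mm", "feed_position_mm", "elements", "die",
              "barrel_zones"),
  operating = c("screw_speed_rpm", "feed_rate_kg_h", "moisture",
                "barrel_temps_C", "die_temp_C", "nusselt"),
  top = c("machine", "material", "operating"))

check_keys <- function(x, what, path, errs) {
  unknown <- setdiff(names(x), known_keys[[what]])
  if (length(unknown))
    errs <- collect_error(errs, path, "unknown key(s): %s",
                          paste(unknown, collapse = ", "))
  errs
}

#' Read and validate an extrusion configuration file
#'
#' Parses a YAML configuration describing a machine, a material and an
#' operating point into validated package objects. Dimensions carry explicit
#' unit suffixes (`_mm`, `_C`, `_rpm`, `_kg_h`); moisture accepts either a
#' wet-basis fraction or a percentage string (`"15%"`). All validation
#' failures are collected and reported together, each with its location in
#' the file.
#'
#' The `material` entry is either the name of a shipped material
#' ([material_db()]) or the path (relative to the config file) of a material
#' YAML file in the same layout as the shipped database.
#'
#' @param path config file path.
#' @return list with components `machine` ([extruder()]), `material`
#'   ([material()]), `op` ([operating_point()]).
#' @seealso [write_config()] for the inverse; shipped machine files live
#'   under `system.file("extdata", "machines", package = "extrusim")`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  cfg <- yaml::read_yaml(path)
  errs <- character()
  errs <- check_keys(cfg, "top", "<top level>", errs)
  for (sec in c("machine", "operating"))
    if (is.null(cfg[[sec]]))
      errs <- collect_error(errs, "<top level>", "missing section '%s'", sec)
  if (length(errs)) stopf("invalid config:\n  %s",
                          paste(errs, collapse = "\n  "))

  mc <- cfg$machine
  errs <- check_keys(mc, "machine", "machine", errs)
  elements <- list()
  for (i in seq_along(mc$elements)) {
    el <- mc$elements[[i]]
    p <- sprintf("machine$elements[[%d]]", i)
    errs <- check_keys(el, "element", p, errs)
    e <- tryCatch(
      screw_element(kind = el$kind, length = mm(el$length_mm),
                    pitch = if (!is.null(el$pitch_mm)) mm(el$pitch_mm),
                    channel_depth = mm(el$channel_depth_mm),
                    flight_count = el$flight_count %||% 2L,
                    flight_width = if (!is.null(el$flight_width_mm))
                      mm(el$flight_width_mm),
                    flight_gap = mm(el$flight_gap_mm %||% 0.25),
                    stagger_angle = el$stagger_angle_deg,
                    disc_thickness = if (!is.null(el$disc_thickness_mm))
                      mm(el$disc_thickness_mm),
                    leak_depth_frac = el$leak_depth_frac %||% 0.5,
                    shear_efficiency = el$shear_efficiency,
                    ht_factor = el$ht_factor),
      error = function(e) conditionMessage(e))
    if (is.character(e)) errs <- collect_error(errs, p, "%s", e)
    else elements[[i]] <- e
  }
  die <- list()
  for (i in seq_along(mc$die)) {
    d <- mc$die[[i]]
    p <- sprintf("machine$die[[%d]]", i)
    errs <- check_keys(d, "die", p, errs)
    e <- tryCatch(
      die_element(kind = d$kind, length = mm(d$length_mm),
                  radius = if (!is.null(d$radius_mm)) mm(d$radius_mm),
                  width = if (!is.null(d$width_mm)) mm(d$width_mm),
                  height = if (!is.null(d$height_mm)) mm(d$height_mm),
                  group = d$group),
      error = function(e) conditionMessage(e))
    if (is.character(e)) errs <- collect_error(errs, p, "%s", e)
    else die[[i]] <- e
  }
  zones <- data.frame(length = numeric(), temp = numeric())
  zend_prev <- 0
  for (i in seq_along(mc$barrel_zones)) {
    z <- mc$barrel_zones[[i]]
    p <- sprintf("machine$barrel_zones[[%d]]", i)
    errs <- check_keys(z, "zone", p, errs)
    if (!is.null(z$from_mm) || !is.null(z$to_mm)) {
      if (is.null(z$from_mm) || is.null(z$to_mm)) {
        errs <- collect_error(errs, p, "give both from_mm and to_mm")
        next
      }
      if (z$from_mm < zend_prev - 1e-9)
        errs <- collect_error(errs, p,
                              "zone span [%g, %g] mm overlaps the previous zone (ends at %g mm)",
                              z$from_mm, z$to_mm, zend_prev)
      len <- z$to_mm - z$from_mm
      zend_prev <- z$to_mm
    } else {
      len <- z$length_mm
      zend_prev <- zend_prev + (len %||% 0)
    }
    if (is.null(len) || is.null(z$temp_C))
      errs <- collect_error(errs, p, "need length_mm (or from/to) and temp_C")
    else zones <- rbind(zones, data.frame(length = mm(len), temp = z$temp_C))
  }
  if (length(errs)) stopf("invalid config:\n  %s",
                          paste(errs, collapse = "\n  "))
  machine <- extruder(
    screw_diameter = mm(mc$screw_diameter_mm), elements = elements,
    die = die, barrel_zones = zones,
    total_length = if (!is.null(mc$total_length_mm)) mm(mc$total_length_mm),
    centerline_distance = if (!is.null(mc$centerline_distance_mm))
      mm(mc$centerline_distance_mm),
    feed_position = mm(mc$feed_position_mm %||% 0),
    name = mc$name %||% "config")

  mat <- NULL
  if (!is.null(cfg$material)) {
    mat <- if (is.character(cfg$material)) {
      mp <- file.path(dirname(path), cfg$material)
      if (file.exists(mp)) material_from_list(yaml::read_yaml(mp))
      else material_db(cfg$material)
    } else material_from_list(cfg$material, name = cfg$material$name %||% "inline")
  }

  oc <- cfg$operating
  errs <- check_keys(oc, "operating", "operating", errs)
  if (length(errs)) stopf("invalid config:\n  %s",
                          paste(errs, collapse = "\n  "))
  op <- operating_point(N = oc$screw_speed_rpm, Q = oc$feed_rate_kg_h,
                        MC = parse_fraction(oc$moisture),
                        barrel_temps = unlist(oc$barrel_temps_C),
                        die_temp = oc$die_temp_C,
                        nusselt = oc$nusselt %||% 20)
  list(machine = machine, material = mat, op = op)
}

#' Write an extrusion configuration file
#'
#' Serializes a machine + operating point (and optionally a material name)
#' to the YAML layout read by [load_config()]; `load_config(write_config(...))`
#' round-trips.
#'
#' @param machine an [extruder()].
#' @param op an [operating_point()].
#' @param path output file.
#' @param material shipped-material name to record (optional).
#' @return `path`, invisibly.
#' @export
write_config <- function(machine, op, path, material = NULL) {
  stopifnot(inherits(machine, "extruder"), inherits(op, "operating_point"))
  els <- lapply(machine$elements, function(e) {
    out <- list(kind = e$kind, length_mm = 1e3 * e$length,
                channel_depth_mm = 1e3 * e$channel_depth,
                flight_count = e$flight_count,
                flight_width_mm = if (!is.null(e$flight_width))
                  1e3 * e$flight_width,
                flight_gap_mm = 1e3 * e$flight_gap,
                leak_depth_frac = e$leak_depth_frac,
                shear_efficiency = e$shear_efficiency,
                ht_factor = e$ht_factor)
    if (e$kind == "kneading_block") {
      out$stagger_angle_deg <- e$stagger_angle
      out$disc_thickness_mm <- 1e3 * e$disc_thickness
    } else out$pitch_mm <- 1e3 * e$pitch
    out[!vapply(out, is.null, TRUE)]
  })
  dies <- lapply(machine$die, function(d) {
    out <- list(kind = d$kind, length_mm = 1e3 * d$length,
                radius_mm = if (!is.null(d$radius)) 1e3 * d$radius,
                width_mm = if (!is.null(d$width)) 1e3 * d$width,
                height_mm = if (!is.null(d$height)) 1e3 * d$height,
                group = d$group)
    out[!vapply(out, is.null, TRUE)]
  })
  zones <- lapply(seq_len(nrow(machine$barrel_zones)), function(i)
    list(length_mm = 1e3 * machine$barrel_zones$length[i],
         temp_C = machine$barrel_zones$temp[i]))
  cfg <- list(
    machine = list(name = machine$name,
                   screw_diameter_mm = 1e3 * machine$screw_diameter,
                   centerline_distance_mm = 1e3 * machine$centerline_distance,
                   total_length_mm = 1e3 * machine$total_length,
                   elements = els, die = dies, barrel_zones = zones),
    operating = list(
      screw_speed_rpm = op$N, feed_rate_kg_h = op$Q, moisture = op$MC,
      barrel_temps_C = op$barrel_temps, die_temp_C = op$die_temp,
      nusselt = op$nusselt))
  cfg$operating <- cfg$operating[!vapply(cfg$operating, is.null, TRUE)]
  if (!is.null(material)) cfg$material <- material
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}
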