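#' Define an extrusion feed material
#'
#' Bundles everything the flow solver needs to know about one feed recipe:
#' its power-law viscosity parameters, a melting curve (melting temperature
#' versus moisture content), moisture-mixing rules for the thermal/physical
#' properties of the melt, and (optionally) the recipe composition.
#'
#' Melt density, specific heat and conductivity at a given moisture are
#' obtained by a mass-fraction additive rule between the dry molten material
#' and water ([melt_property()]). The melting curve is interpolated piecewise
#' linearly ([melting_temperature()]); it must be strictly decreasing in
#' moisture (water plasticizes the crystallites).
#'
#' @param name identifier (used by [material_db()] lookups).
#' @param viscosity a [viscosity_params()] object.
#' @param melting_curve data.frame with columns `MC` (wet-basis fraction,
#'   strictly increasing) and `T_C` (°C, strictly decreasing).
#' @param composition optional named list of mass fractions (starch, protein,
#'   fiber, lipid, ash, sugar, salt, amylose_of_starch); each in \[0, 1\].
#' @param cp_dry,cp_water specific heat of dry melt / water (J/kg/K).
#' @param rho_dry,rho_water density of dry melt / water (kg/m^3).
#' @param k_dry,k_water thermal conductivity of dry melt / water (W/m/K).
#' @param melting_enthalpy melting enthalpy of the feed (J/kg).
#' @param label,provenance free-text metadata.
#' @return An object of class `"extrusion_material"`.
#' @seealso [material_db()] for the shipped database.
#' @export
material <- function(name, viscosity, melting_curve, composition = NULL,
                     cp_dry = 1500, cp_water = 4186,
                     rho_dry = 1400, rho_water = 1000,
                     k_dry = 0.25, k_water = 0.60,
                     melting_enthalpy = 13000,
                     label = name, provenance = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(viscosity, "viscosity_params"))
  if (!is.data.frame(melting_curve) ||
      !all(c("MC", "T_C") %in% names(melting_curve)) ||
      nrow(melting_curve) < 2L)
    stopf("`melting_curve` must be a data.frame with columns MC, T_C and >= 2 rows")
  mc <- melting_curve[order(melting_curve$MC), c("MC", "T_C")]
  if (any(diff(mc$MC) <= 0))
    stopf("melting_curve MC values must be distinct")
  if (any(diff(mc$T_C) > 0))
    stopf("melting_curve T_C must be non-increasing in MC (water plasticizes)")
  if (!is.null(composition)) {
    fr <- unlist(composition)
    if (any(fr < 0 | fr > 1))
      stopf("composition fractions must lie in [0, 1]")
  }
  for (nm in c("cp_dry", "cp_water", "rho_dry", "rho_water",
               "k_dry", "k_water", "melting_enthalpy"))
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  structure(
    list(name = name, label = label, viscosity = viscosity,
         melting_curve = mc, composition = composition,
         cp_dry = cp_dry, cp_water = cp_water,
         rho_dry = rho_dry, rho_water = rho_water,
         k_dry = k_dry, k_water = k_water,
         melting_enthalpy = melting_enthalpy,
         provenance = provenance),
    class = "extrusion_material")
}

#' @export
print.extrusion_material <- function(x, ...) {
  cat(sprintf("<extrusion_material> %s (%s)\n", x$name, x$label))
  cat(sprintf("  melting curve: %d points, T_m(MC = %.2f) = %.1f degC\n",
              nrow(x$melting_curve), x$melting_curve$MC[1],
              x$melting_curve$T_C[1]))
  cat(sprintf("  viscosity: K0 = %.3g Pa.s^n (%s dialect)\n",
              x$viscosity$K0, x$viscosity$dialect))
  invisible(x)
}

#' Melting temperature at a given moisture content
#'
#' Monotone piecewise-linear interpolation of the material's melting curve.
#' Extrapolation outside the tabulated moisture range is refused: the curve
#' is a calibration, not a law.
#'
#' @param material an [material()] object.
#' @param MC moisture content, wet-basis fraction.
#' @return Melting temperature (°C).
#' @export
melting_temperature <- function(material, MC) {
  stopifnot(inherits(material, "extrusion_material"))
  check_number(MC, "MC", allow_vector = TRUE)
  cv <- material$melting_curve
  if (any(MC < min(cv$MC)) || any(MC > max(cv$MC)))
    stopf("MC = %s outside the tabulated melting-curve range [%g, %g] for '%s'; extrapolation refused",
          paste(signif(MC[MC < min(cv$MC) | MC > max(cv$MC)], 3), collapse = ", "),
          min(cv$MC), max(cv$MC), material$name)
  stats::approx(cv$MC, cv$T_C, xout = MC, method = "linear",
                ties = "ordered")$y
}

#' Melt physical property at a given moisture content
#'
#' Mass-fraction additive rule between dry molten material and water:
#' `prop(MC) = MC * prop_water + (1 - MC) * prop_dry`.
#'
#' @param material an [material()] object.
#' @param MC moisture content, wet-basis fraction in \[0, 1\].
#' @param which one of `"rho"` (kg/m^3), `"cp"` (J/kg/K), `"k"` (W/m/K).
#' @return Property value of the moist melt.
#' @export
melt_property <- function(material, MC, which = c("rho", "cp", "k")) {
  stopifnot(inherits(material, "extrusion_material"))
  which <- match.arg(which)
  check_number(MC, "MC", lower = 0, upper = 1, allow_vector = TRUE)
  dry <- material[[paste0(which, "_dry")]]
  wet <- material[[paste0(which, "_water")]]
  if (is.null(dry) || is.null(wet))
    stopf("material '%s' lacks a %s property", material$name, which)
  MC * wet + (1 - MC) * dry
}

# --- shipped database -------------------------------------------------------

.material_cache <- new.env(parent = emptyenv())

material_from_list <- function(x, name = x$name) {
  v <- x$viscosity
  vp <- viscosity_params(
    K0 = v$K0_Pasn, E_over_R = v$E_over_R_K,
    alpha = v$alpha %||% 0, beta = v$beta %||% 0,
    n0 = v$n0 %||% 0, a1 = v$a1 %||% 0, a2 = v$a2 %||% 0,
    a3 = v$a3 %||% 0, a4 = v$a4 %||% 0, a5 = v$a5 %||% 0, a6 = v$a6 %||% 0,
    dialect = v$dialect %||% "referenced")
  th <- x$thermal %||% list()
  material(
    name = name, viscosity = vp,
    melting_curve = data.frame(MC = x$melting_curve$MC,
                               T_C = x$melting_curve$T_C),
    composition = x$composition,
    cp_dry = th$cp_dry_J_kgK %||% 1500, cp_water = th$cp_water_J_kgK %||% 4186,
    rho_dry = th$rho_dry_kg_m3 %||% 1400, rho_water = th$rho_water_kg_m3 %||% 1000,
    k_dry = th$k_dry_W_mK %||% 0.25, k_water = th$k_water_W_mK %||% 0.60,
    melting_enthalpy = th$melting_enthalpy_J_kg %||% 13000,
    label = x$label %||% name, provenance = x$provenance)
}

#' Built-in material database
#'
#' Loads one of the materials shipped with the package (one YAML file per
#' material under `extdata/materials`). The viscosity parameter sets are
#' published calibration tables for maize starches of several amylose
#' contents (`maize_a` 70%, `maize_b` 47%, `maize_c` 23.5%, `maize_d` 1%),
#' potato starch (`potato1`), two breakfast-cereal recipes (`cb` cacao-based,
#' `hb` honey/malt-based), pea flour (`pf`) and wheat flour with increasing
#' bran content (`wf`, `wf_lb`, `wf_hb`; these use the `"absolute"`
#' consistency dialect). Melting curves and thermal properties are editable
#' reconstructions anchored to published points; see the file comments.
#'
#' @param name material identifier; see [list_materials()].
#' @return An [material()] object.
#' @export
material_db <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(.material_cache[[name]])) return(.material_cache[[name]])
  path <- system.file("extdata", "materials", paste0(name, ".yaml"),
                      package = "extrusim")
  if (!nzchar(path))
    stopf("unknown material '%s'; see list_materials()", name)
  m <- material_from_list(yaml::read_yaml(path), name = name)
  .material_cache[[name]] <- m
  m
}

#' @rdname material_db
#' @export
list_materials <- function() {
  dir <- system.file("extdata", "materials", package = "extrusim")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}
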