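#' Shipped machine reconstructions
#'
#' Ready-made [extruder()] objects for the four machine classes used by the
#' shipped extrusion scenarios. Only screw diameter, screw length and the
#' qualitative profile (conveying / kneading-block / reverse sequence, die
#' type) of these machines are published; element-level geometry (pitches,
#' channel depths, flight widths and clearances, disc thicknesses, zone
#' splits) is reconstructed here from conventional co-rotating twin-screw
#' ratios (channel depth about 0.16 D, pitches 0.5–1 D, bilobal flights) and
#' is deliberately exposed as plain constructor code: every value can be
#' overridden by building your own [extruder()].
#'
#' \describe{
#'   \item{`zsk26_like`}{D = 25.5 mm, L = 740 mm; conveying, three 45°
#'     kneading blocks, three reverse elements, conveying; 3 mm circular die,
#'     15 mm land; 7 barrel zones. Breakfast-cereal and pea-snack class.}
#'   \item{`bc45_like`}{D = 55.5 mm, L = 1000 mm; conveying, one reverse
#'     element, conveying; two parallel circular dies. Expanded-starch
#'     class.}
#'   \item{`process11_like`}{D = 11 mm, L = 269.5 mm; conveying, two 90°
#'     kneading blocks, one reverse element, conveying; 2 mm circular die.
#'     Dense-starch laboratory class.}
#'   \item{`evolum25_like`}{D = 25 mm, L = 400 mm; conveying, one 45°
#'     kneading block, one reverse element, conveying; 3 mm circular die.
#'     Wheat-snack class.}
#' }
#'
#' @param name fixture id.
#' @param reverse_length total axial length of the reverse (left-handed)
#'   section (m); NULL keeps the fixture default. Setting 0 removes the
#'   reverse elements (the kneading blocks then pin the melting section, or
#'   the profile becomes non-restrictive for `bc45_like`).
#' @param barrel_temps default zone set temperatures (°C), recycled;
#'   operating points may override them per run.
#' @return An [extruder()] object.
#' @export
extruder_fixture <- function(name = c("zsk26_like", "bc45_like",
                                      "process11_like", "evolum25_like"),
                             reverse_length = NULL, barrel_temps = NULL) {
  name <- match.arg(name)
  conv <- function(L, pitch, h, fw = 0.08 * pitch)
    screw_element("conveying_rh", length = L, pitch = pitch,
                  channel_depth = h, flight_width = fw, flight_gap = 2.5e-4)
  rev_el <- function(L, pitch, h)
    screw_element("reverse_lh", length = L, pitch = pitch, channel_depth = h,
                  flight_width = 0.08 * pitch, flight_gap = 2.5e-4,
                  leak_depth_frac = 0.6)
  kb <- function(L, stagger, t, h)
    screw_element("kneading_block", length = L, stagger_angle = stagger,
                  disc_thickness = t, channel_depth = h,
                  flight_width = 1e-3, flight_gap = 5e-4,
                  leak_depth_frac = 0.25)
  zones <- function(L, n, temps) {
    temps <- rep(temps, length.out = n)
    data.frame(length = rep(L / n, n), temp = temps)
  }
  switch(name,
    zsk26_like = {
      D <- 25.5e-3; h <- 4e-3
      rl <- reverse_length %||% 45e-3
      revs <- if (rl > 0) rep(list(rev_el(rl / 3, 12.5e-3, h)), 3) else list()
      els <- c(list(conv(420e-3, 25e-3, h)),
               rep(list(kb(20e-3, 45, 5e-3, h)), 3),
               revs,
               list(conv(740e-3 - 420e-3 - 60e-3 - rl, 25e-3, h)))
      extruder(D, els,
               die = list(die_element("circular", length = 15e-3,
                                      radius = 1.5e-3)),
               barrel_zones = zones(740e-3, 7,
                                    barrel_temps %||% c(20, 40, 60, 90, 90, 90, 90)),
               total_length = 740e-3, name = "zsk26_like")
    },
    bc45_like = {
      D <- 55.5e-3; h <- 8.9e-3
      rl <- reverse_length %||% 50e-3
      revs <- if (rl > 0) list(rev_el(rl, 28e-3, h)) else list()
      els <- c(list(conv(1000e-3 - rl - 260e-3, 50e-3, h)), revs,
               list(conv(260e-3, 50e-3, h)))
      suppressWarnings(
        extruder(D, els,
                 die = list(die_element("circular", length = 20e-3,
                                        radius = 2e-3, group = 1),
                            die_element("circular", length = 20e-3,
                                        radius = 2e-3, group = 1)),
                 barrel_zones = zones(1000e-3, 5,
                                      barrel_temps %||% c(20, 60, 90, 120, 120)),
                 total_length = 1000e-3, name = "bc45_like"))
    },
    process11_like = {
      D <- 11e-3; h <- 1.8e-3
      rl <- reverse_length %||% 11e-3
      revs <- if (rl > 0) list(rev_el(rl, 5.5e-3, h)) else list()
      els <- c(list(conv(170e-3, 11e-3, h)),
               rep(list(screw_element("kneading_block", length = 11e-3,
                                      stagger_angle = 90,
                                      disc_thickness = 2.75e-3,
                                      channel_depth = h,
                                      flight_width = 0.08 * 11e-3,
                                      flight_gap = 3e-4)), 2),
               revs,
               list(conv(269.5e-3 - 170e-3 - 22e-3 - rl, 11e-3, h)))
      extruder(D, els,
               die = list(die_element("circular", length = 10e-3,
                                      radius = 1e-3)),
               barrel_zones = zones(269.5e-3, 5,
                                    barrel_temps %||% c(20, 60, 95, 95, 95)),
               total_length = 269.5e-3, name = "process11_like")
    },
    evolum25_like = {
      D <- 25e-3; h <- 4e-3
      rl <- reverse_length %||% 20e-3
      revs <- if (rl > 0) list(rev_el(rl, 12.5e-3, h)) else list()
      els <- c(list(conv(255e-3, 25e-3, h)),
               list(kb(25e-3, 45, 6.25e-3, h)),
               revs,
               list(conv(400e-3 - 255e-3 - 25e-3 - rl, 25e-3, h)))
      extruder(D, els,
               die = list(die_element("circular", length = 15e-3,
                                      radius = 1.5e-3)),
               barrel_zones = zones(400e-3, 4,
                                    barrel_temps %||% c(20, 60, 90, 90)),
               total_length = 400e-3, name = "evolum25_like")
    })
}

#' Shipped extrusion scenarios
#'
#' Machine + material + operating point bundles used by the test-suite and
#' the documentation examples. Each scenario records the qualitative
#' behaviour it is expected to exhibit (profile shape, monotonicity
#' directions) in its `notes`.
#'
#' @param name scenario id; see `scenario_names()`.
#' @return A list with components `machine`, `material`, `op`, `notes`.
#' @export
scenario_fixture <- function(name = scenario_names()) {
  name <- match.arg(name)
  bf_barrel <- c(20, 40, 60, 90, 90, 90, 90)
  sc <- switch(name,
    cb_breakfast = list(
      machine = extruder_fixture("zsk26_like"), material = material_db("cb"),
      op = operating_point(N = 500, Q = 20, MC = 0.15,
                           barrel_temps = bf_barrel),
      notes = "breakfast-cereal reference run, cacao recipe; T steps at restrictive elements, maximum near the last reverse element"),
    hb_breakfast = list(
      machine = extruder_fixture("zsk26_like"), material = material_db("hb"),
      op = operating_point(N = 500, Q = 20, MC = 0.15,
                           barrel_temps = bf_barrel),
      notes = "breakfast-cereal reference run, honey/malt recipe; profile everywhere below the cacao recipe"),
    hb_chart = list(
      machine = extruder_fixture("zsk26_like"), material = material_db("hb"),
      op = operating_point(N = 500, Q = 20, MC = 0.19,
                           barrel_temps = bf_barrel),
      notes = "sensitivity-analysis base point: SME up with N, down with Q and MC; P down with N, up with Q; T_com above the barrel temperature"),
    pf_snack = list(
      machine = extruder_fixture("zsk26_like"), material = material_db("pf"),
      op = operating_point(N = 600, Q = 20, MC = 0.21,
                           barrel_temps = bf_barrel),
      notes = "pea-snack run; die-exit temperature drives protein cross-linking and density"),
    maize_design = list(
      machine = extruder_fixture("bc45_like"), material = material_db("maize_b"),
      op = operating_point(N = 500, Q = 15, MC = 0.20,
                           barrel_temps = c(20, 60, 90, 120, 120)),
      notes = "expanded-starch design run; SME governs intrinsic-viscosity drop"),
    fava_snack = list(
      machine = extruder_fixture("process11_like"),
      material = material_db("pf"),
      op = operating_point(N = 500, Q = 2, MC = 0.25,
                           barrel_temps = c(20, 60, 120, 140, 140)),
      notes = "laboratory-scale legume snack run (pea-flour rheology standing in for fava bean flour, whose shear-viscosity master curves are near-identical)"),
    wheat_snack = list(
      machine = extruder_fixture("evolum25_like"),
      material = material_db("wf_lb"),
      op = operating_point(N = 600, Q = 20, MC = 0.22,
                           barrel_temps = c(20, 60, 90, 140)),
      notes = "bran-enriched wheat snack run; expansion features correlate with T_com and eta_com"))
  sc$name <- name
  sc
}

#' @rdname scenario_fixture
#' @export
scenario_names <- function() {
  c("cb_breakfast", "hb_breakfast", "hb_chart", "pf_snack",
    "maize_design", "fava_snack", "wheat_snack")
}
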