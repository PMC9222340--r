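test_that("shape factors behave like shallow-channel lubrication formulas", {
  D <- 25.5e-3
  el <- function(pitch, kind = "conveying_rh", h = 4e-3)
    screw_element(kind, length = 0.1, pitch = pitch, channel_depth = h,
                  flight_width = 1e-3)
  # drag coefficient vanishes as the pitch (helix angle) closes
  A_seq <- vapply(c(16e-3, 8e-3, 4e-3, 2.5e-3),
                  function(p) shape_factors(el(p), D)$A, 0)
  expect_true(all(diff(A_seq) < 0))
  expect_lt(A_seq[length(A_seq)] / A_seq[1], 0.2)

  # mirrored element: drag flips sign, pressure conductance of the channel
  # is unchanged (the reverse element's slot leakage adds conductance)
  fwd <- shape_factors(el(12.5e-3), D)
  rev <- shape_factors(el(12.5e-3, "reverse_lh"), D)
  expect_equal(rev$A, -fwd$A)
  expect_gte(rev$G, fwd$G)
  rev_noslot <- screw_element("reverse_lh", length = 0.1, pitch = 12.5e-3,
                              channel_depth = 4e-3, flight_width = 1e-3,
                              leak_depth_frac = 1e-6)
  expect_equal(shape_factors(rev_noslot, D)$G, fwd$G, tolerance = 1e-6)

  # regression pin of the drag coefficient against the closed formula
  sf <- shape_factors(screw_element("conveying_rh", length = 0.1,
                                    pitch = 25e-3, channel_depth = 4e-3,
                                    flight_width = 3e-3), D)
  phi <- atan(25e-3 / (pi * D))
  W <- 25e-3 * cos(phi) / 2 - 3e-3
  expect_equal(sf$A, 2 * W * 4e-3 * D * cos(phi) / 4, tolerance = 1e-12)
  expect_equal(sf$G, 2 * W * (4e-3)^3 * sin(phi) / (12 * 0.1),
               tolerance = 1e-12)

  # degenerate geometry is refused
  expect_error(shape_factors(el(25e-3, h = 13e-3), D), "degenerate")
  expect_error(screw_element("kneading_block", length = 0.02,
                             channel_depth = 4e-3),
               "stagger_angle")
})

test_that("Newtonian die pressure drop matches Hagen-Poiseuille exactly", {
  newt <- viscosity_params(K0 = 1000, E_over_R = 0, n0 = 1)
  die <- list(die_element("circular", length = 15e-3, radius = 1.5e-3))
  dp <- die_pressure_drop(die, 4.63e-6, newt, T_C = 79.85, MC = 0.10,
                          SME = 350)
  expect_equal(dp, 8 * 1000 * 0.015 * 4.63e-6 / (pi * 1.5e-3^4),
               tolerance = 1e-9)
  expect_equal(dp, 34933920.5, tolerance = 1e-7)
})

test_that("power-law die flow matches brute-force radial integration", {
  set.seed(11)
  for (i in 1:100) {
    n <- stats::runif(1, 0.15, 1)
    K <- 10^stats::runif(1, 2, 5)
    R <- stats::runif(1, 0.8e-3, 3e-3)
    L <- stats::runif(1, 5e-3, 40e-3)
    Qv <- 10^stats::runif(1, -7, -5.5)
    p <- viscosity_params(K0 = K, E_over_R = 0, n0 = n)
    die <- list(die_element("circular", length = L, radius = R))
    dp <- die_pressure_drop(die, Qv, p, 79.85, 0.10, 350)
    Q_back <- brute_capillary_flow(dp, R, L, K, n)
    expect_lt(abs(Q_back - Qv) / Qv, 0.005)
  }
})

test_that("die assemblies compose in series and parallel", {
  p <- viscosity_params(K0 = 5e3, E_over_R = 0, n0 = 0.4)
  st <- list(T_C = 120, MC = 0.18, SME = 400)
  one <- list(die_element("circular", length = 20e-3, radius = 1.5e-3))
  # splitting a land into two half-lands in series changes nothing
  halves <- list(die_element("circular", length = 10e-3, radius = 1.5e-3),
                 die_element("circular", length = 10e-3, radius = 1.5e-3))
  Qv <- 4e-6
  expect_equal(die_pressure_drop(halves, Qv, p, st$T_C, st$MC, st$SME),
               die_pressure_drop(one, Qv, p, st$T_C, st$MC, st$SME),
               tolerance = 1e-9)
  # two identical dies in parallel: each takes Qv/2 at the single-die drop
  twin <- list(die_element("circular", length = 20e-3, radius = 1.5e-3,
                           group = 1),
               die_element("circular", length = 20e-3, radius = 1.5e-3,
                           group = 1))
  dp_twin <- die_pressure_drop(twin, Qv, p, st$T_C, st$MC, st$SME,
                               details = TRUE)
  expect_equal(as.numeric(dp_twin),
               die_pressure_drop(one, Qv / 2, p, st$T_C, st$MC, st$SME),
               tolerance = 1e-9)
  expect_equal(attr(dp_twin, "elements")$Qv, c(Qv / 2, Qv / 2))

  # slit Newtonian limit: dP = 12 eta L Q / (W h^3)
  newt <- viscosity_params(K0 = 800, E_over_R = 0, n0 = 1)
  slit <- list(die_element("slit", length = 30e-3, width = 20e-3,
                           height = 2e-3))
  expect_equal(die_pressure_drop(slit, Qv, newt, 79.85, 0.1, 350),
               12 * 800 * 0.03 * Qv / (0.02 * (2e-3)^3), tolerance = 1e-9)
  expect_error(die_pressure_drop(list(), Qv, p, 120, 0.2, 300), "no elements")
})

test_that("die pressure drop is monotone in throughput, consistency and radius", {
  set.seed(3)
  for (i in 1:20) {
    n <- stats::runif(1, 0.2, 0.9)
    p <- viscosity_params(K0 = 10^stats::runif(1, 3, 5), E_over_R = 0,
                          n0 = n)
    R <- stats::runif(1, 1e-3, 3e-3)
    die <- function(r) list(die_element("circular", length = 15e-3,
                                        radius = r))
    dpq <- vapply(c(1e-6, 3e-6, 9e-6),
                  function(q) die_pressure_drop(die(R), q, p, 120, 0.2, 300),
                  0)
    expect_true(all(diff(dpq) > 0))
    dpr <- vapply(c(R, 1.3 * R, 1.7 * R),
                  function(r) die_pressure_drop(die(r), 3e-6, p, 120, 0.2, 300),
                  0)
    expect_true(all(diff(dpr) < 0))
  }
})

test_that("extruder assembly enforces zone tiling and geometry invariants", {
  el <- screw_element("conveying_rh", length = 0.3, pitch = 25e-3,
                      channel_depth = 4e-3)
  rv <- screw_element("reverse_lh", length = 0.1, pitch = 12.5e-3,
                      channel_depth = 4e-3)
  die <- list(die_element("circular", length = 15e-3, radius = 1.5e-3))
  zones_ok <- data.frame(length = c(0.2, 0.2), temp = c(60, 90))
  ex <- extruder(25.5e-3, list(el, rv), die, zones_ok)
  expect_s3_class(ex, "extruder")
  expect_error(
    extruder(25.5e-3, list(el, rv), die,
             data.frame(length = c(0.2, 0.3), temp = c(60, 90))),
    "tile")
  expect_warning(
    extruder(25.5e-3, list(el), die,
             data.frame(length = 0.3, temp = 90)),
    "restrictive")
  expect_error(
    extruder(25.5e-3, list(el, rv), die, zones_ok, total_length = 0.35),
    "exceeds")
})
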