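test_that("the melting section is pinned at the first restrictive element", {
  ex <- extruder_fixture("zsk26_like")
  kinds <- vapply(ex$elements, `[[`, "", "kind")
  expect_equal(locate_melting_section(ex), which(kinds == "kneading_block")[1])

  # a reverse element ahead of any kneading block takes precedence
  el <- function(kind, L, p) screw_element(kind, length = L, pitch = p,
                                           channel_depth = 4e-3)
  kb <- screw_element("kneading_block", length = 0.02, stagger_angle = 45,
                      disc_thickness = 5e-3, channel_depth = 4e-3)
  die <- list(die_element("circular", length = 15e-3, radius = 1.5e-3))
  zones <- data.frame(length = 0.62, temp = 90)
  ex2 <- extruder(25.5e-3,
                  list(el("conveying_rh", 0.3, 25e-3),
                       el("reverse_lh", 0.1, 12.5e-3), kb,
                       el("conveying_rh", 0.2, 25e-3)),
                  die, zones)
  expect_equal(locate_melting_section(ex2), 2L)

  ex3 <- suppressWarnings(
    extruder(25.5e-3, list(el("conveying_rh", 0.62, 25e-3)), die, zones))
  expect_error(locate_melting_section(ex3), "restrictive")
})

test_that("reference scenarios converge to the melting-point boundary condition", {
  for (nm in c("cb_breakfast", "hb_breakfast")) {
    sim <- if (nm == "cb_breakfast") cb_reference() else hb_reference()
    expect_true(sim$converged, info = nm)
    expect_lte(sim$iterations, 60)
    expect_lt(abs(sim$melt_temp_residual), 0.1)
    # melting temperature honored at the melting position
    Tm <- melting_temperature(material_db(sub("_.*", "", nm)), 0.15)
    expect_equal(sim$melt_temp, Tm)
  }
})

test_that("the solver is deterministic", {
  s1 <- cb_reference()
  sc <- scenario_fixture("cb_breakfast")
  s2 <- suppressWarnings(solve_profile(sc$machine, sc$material, sc$op))
  expect_identical(s1$T_com, s2$T_com)
  expect_identical(s1$SME_com, s2$SME_com)
  expect_identical(s1$states, s2$states)
})

test_that("axial profiles have the expected physical structure", {
  sim <- cb_reference()
  st <- sim$states
  # pressure is non-negative and positive at the die entrance
  expect_true(all(st$P_Pa >= 0))
  expect_gt(st$P_Pa[1], 0)
  expect_equal(st$P_Pa[1], sim$P_com)
  # SME accumulates monotonically from the melting point to the die
  expect_true(all(diff(rev(st$SME_kJkg)) >= -1e-9))
  # starved conveying between the reverse section and the die-fed section
  mid <- st[st$kind == "conveying_rh" & st$position_m > 0.06 &
              st$position_m < 0.18, ]
  expect_true(all(mid$P_Pa == 0))
  expect_true(all(mid$fill_ratio < 1))
  # fully filled restrictive elements
  expect_true(all(st$fill_ratio[st$kind == "reverse_lh"] == 1))
  # melt temperature stays above the local barrel temperature (90 degC)
  expect_true(all(st$T_C > 90))
  # residence time: filled volume over volumetric throughput
  expect_equal(sim$mean_residence_time,
               sum(st$residence_s) + pi * 1.5e-3^2 * 15e-3 / sim$Qv,
               tolerance = 1e-9)
})

test_that("die-exit summary is consistent and refuses unconverged input", {
  sim <- cb_reference()
  sm <- summary(sim)
  expect_equal(sm$P_com_Pa, sim$P_com)
  expect_equal(sm$T_com_C, sim$T_com)
  # eta_com is the apparent viscosity at the die-wall shear rate
  expect_equal(sm$eta_com_Pas,
               apparent_viscosity(material_db("cb")$viscosity,
                                  sim$die_wall_shear, sim$T_com, 0.15,
                                  sim$SME_com, warn = FALSE))
  broken <- sim
  broken$converged <- FALSE
  expect_error(summary(broken), "unconverged")
})

test_that("discretization refinement leaves the solution essentially unchanged", {
  sc <- scenario_fixture("cb_breakfast")
  coarse <- cb_reference()
  fine <- suppressWarnings(solve_profile(sc$machine, sc$material, sc$op,
                                         extrusion_control(substeps = 12)))
  expect_lt(abs(fine$T_com - coarse$T_com) / coarse$T_com, 0.005)
  expect_lt(abs(fine$SME_com - coarse$SME_com) / coarse$SME_com, 0.02)
})

test_that("melting enthalpy is reported separately and added only on request", {
  sc <- scenario_fixture("hb_breakfast")
  base <- hb_reference()
  withH <- suppressWarnings(solve_profile(sc$machine, sc$material, sc$op,
                                          extrusion_control(include_melt_enthalpy = TRUE)))
  dH <- material_db("hb")$melting_enthalpy / 1000
  expect_equal(base$melt_enthalpy_kJkg, dH)
  expect_equal(withH$SME_com, base$SME_com + dH, tolerance = 1e-6)
})
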