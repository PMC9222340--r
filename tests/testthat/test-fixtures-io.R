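test_that("generators are pure functions of inputs and seed", {
  p <- pf_params()
  des <- list(shear_rate = c(10, 100), T_C = c(120, 160), MC = 0.2,
              SME = c(200, 600))
  exact <- generate_rheometry(p, des, noise_cv = 0)
  expect_equal(exact$eta,
               apparent_viscosity(p, exact$shear_rate, exact$T_C, exact$MC,
                                  exact$SME, warn = FALSE))
  a <- generate_rheometry(p, des, noise_cv = 0.1, seed = 5)
  b <- generate_rheometry(p, des, noise_cv = 0.1, seed = 5)
  expect_identical(a, b)
  c <- generate_rheometry(p, des, noise_cv = 0.1, seed = 6)
  expect_false(identical(a$eta, c$eta))
  # the global RNG stream is not disturbed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_rheometry(p, des, noise_cv = 0.1, seed = 5))
  expect_identical(rnorm(1), before)

  m <- correlation_model("f", "SME_com", "power", 2, 0.5, c(10, 100))
  d0 <- generate_feature_data(m, c(20, 50, 80), noise_cv = 0)
  expect_equal(d0$y, 2 * c(20, 50, 80)^0.5)
  d1 <- generate_feature_data(m, c(20, 50, 80), noise_cv = 0.1, seed = 3)
  expect_identical(d1, generate_feature_data(m, c(20, 50, 80),
                                             noise_cv = 0.1, seed = 3))
})

test_that("config files round-trip through write_config / load_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  mach <- extruder_fixture("zsk26_like")
  op <- operating_point(500, 20, 0.15, barrel_temps = breakfast_barrel)
  write_config(mach, op, path, material = "cb")
  cfg <- load_config(path)
  expect_equal(cfg$machine$screw_diameter, mach$screw_diameter)
  expect_equal(length(cfg$machine$elements), length(mach$elements))
  for (i in seq_along(mach$elements))
    expect_equal(cfg$machine$elements[[i]], mach$elements[[i]],
                 tolerance = 1e-12)
  expect_equal(cfg$machine$barrel_zones, mach$barrel_zones,
               tolerance = 1e-12)
  expect_equal(cfg$op$N, 500)
  expect_equal(cfg$op$MC, 0.15)
  expect_equal(cfg$material$name, "cb")
  # and the loaded machine simulates identically to the in-memory one
  s1 <- suppressWarnings(solve_profile(cfg$machine, cfg$material, cfg$op))
  expect_equal(s1$T_com, cb_reference()$T_com, tolerance = 1e-9)
})

test_that("moisture unit strings are normalized on ingestion", {
  expect_equal(operating_point(500, 20, "15%")$MC, 0.15)
  expect_equal(operating_point(500, 20, "0.22")$MC, 0.22)
  expect_error(operating_point(500, 20, "wet"), "parse")
})

test_that("invalid configs are rejected with located, aggregated errors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("
machine:
  screw_diameter_mm: 25.5
  elements:
    - {kind: conveying_rh, length_mm: 300, pitch_mm: 25, channel_depth_mm: 4,
       bogus_key: 1}
    - {kind: reverse_lh, length_mm: 45, pitch_mm: 12.5, channel_depth_mm: 4}
  die:
    - {kind: circular, length_mm: 15, radius_mm: 1.5}
  barrel_zones:
    - {from_mm: 0, to_mm: 200, temp_C: 60}
    - {from_mm: 150, to_mm: 345, temp_C: 90}
operating:
  screw_speed_rpm: 500
  feed_rate_kg_h: 20
  moisture: 15%
", path)
  err <- tryCatch(load_config(path), error = conditionMessage)
  expect_match(err, "bogus_key")
  expect_match(err, "overlaps")
  expect_match(err, "barrel_zones\\[\\[2\\]\\]")
})

test_that("every shipped machine config loads and validates", {
  dir <- system.file("extdata", "machines", package = "extrusim")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  expect_length(files, 4L)
  for (f in files) {
    cfg <- load_config(f)
    expect_s3_class(cfg$machine, "extruder")
    expect_s3_class(cfg$op, "operating_point")
    expect_s3_class(cfg$material, "extrusion_material")
  }
})

test_that("scenario fixtures are well-formed", {
  for (nm in scenario_names()) {
    sc <- scenario_fixture(nm)
    expect_s3_class(sc$machine, "extruder")
    expect_s3_class(sc$material, "extrusion_material")
    expect_s3_class(sc$op, "operating_point")
    expect_true(nzchar(sc$notes))
  }
})
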