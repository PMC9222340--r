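test_that("a one-point grid reproduces a single simulation", {
  sc <- scenario_fixture("hb_chart")
  chart <- suppressWarnings(
    run_grid(sc$machine, sc$material, sc$op,
             sweep = list(N = 500, Q = 20)))
  sim <- suppressWarnings(solve_profile(sc$machine, sc$material, sc$op))
  expect_equal(nrow(chart), 1L)
  expect_equal(chart$SME_com_kJkg, sim$SME_com)
  expect_equal(chart$T_com_C, sim$T_com)
})

test_that("operating-chart responses move the right way with N and Q", {
  sc <- scenario_fixture("hb_chart")
  # grid kept inside the starved conveying regime (away from flooding)
  chart <- suppressWarnings(
    run_grid(sc$machine, sc$material, sc$op,
             sweep = list(N = c(350, 500, 650), Q = c(12, 26, 40))))
  expect_true(all(chart$converged))
  for (q in unique(chart$Q)) {
    sub <- chart[chart$Q == q, ]
    sub <- sub[order(sub$N), ]
    expect_true(all(diff(sub$SME_com_kJkg) > 0), info = paste("Q =", q))
    expect_true(all(diff(sub$P_com_Pa) < 0), info = paste("Q =", q))
  }
  for (n in unique(chart$N)) {
    sub <- chart[chart$N == n, ]
    sub <- sub[order(sub$Q), ]
    expect_true(all(diff(sub$SME_com_kJkg) < 0), info = paste("N =", n))
    expect_true(all(diff(sub$P_com_Pa) > 0), info = paste("N =", n))
    expect_true(all(diff(sub$eta_com_Pas) < 0), info = paste("N =", n))
  }
  # die-exit melt temperature always above the (90 degC) barrel setpoint
  expect_true(all(chart$T_com_C > 90))
})

test_that("feasible regions honor interval constraints, including empty ones", {
  sc <- scenario_fixture("hb_chart")
  chart <- suppressWarnings(
    run_grid(sc$machine, sc$material, sc$op,
             sweep = list(N = c(250, 450, 650), Q = c(12, 30, 48))))
  all_of_it <- feasible_region(chart, list(SME_com_kJkg = c(0, Inf)))
  expect_equal(all_of_it$n_feasible, nrow(chart))
  nothing <- feasible_region(chart, list(SME_com_kJkg = c(-2, -1)))
  expect_equal(nothing$n_feasible, 0L)
  expect_output(print(nothing), "no feasible window")
  some <- feasible_region(chart, list(T_com_C = c(-Inf, 165),
                                      P_com_Pa = c(0, 1e7)))
  ok <- chart$T_com_C <= 165 & chart$P_com_Pa <= 1e7 & chart$converged
  expect_equal(some$mask, ok)
  expect_error(feasible_region(chart, list(bogus = c(0, 1))), "bogus")
})

test_that("correlation fits recover exact generators in all three forms", {
  x <- seq(200, 900, length.out = 12)
  pw <- fit_correlation(x, 2 * x^0.5, "power")
  expect_equal(unname(coef(pw)), c(2, 0.5), tolerance = 1e-7)
  expect_equal(pw$r_squared, 1, tolerance = 1e-9)
  ex <- fit_correlation(x, 100 * exp(-0.004 * x), "exponential")
  expect_equal(unname(coef(ex)), c(100, -0.004), tolerance = 1e-7)
  ln <- fit_correlation(x, 3 + 0.02 * x, "linear")
  expect_equal(unname(coef(ln)), c(3, 0.02), tolerance = 1e-9)
  expect_error(fit_correlation(c(-1, 2, 3), c(1, 2, 3), "power"),
               "positive")
})

test_that("noisy correlation recovery: power law + 10% noise, n = 12, fixed seed", {
  truth <- correlation_model("dVis_pct", "SME_com", "power", 0.9677,
                             0.5964, c(200, 1000))
  d <- generate_feature_data(truth, seq(250, 950, length.out = 12),
                             noise_cv = 0.10, seed = 99)
  fit <- fit_correlation(d$x, d$y, "power")
  expect_lt(abs(coef(fit)[["b"]] - 0.5964) / 0.5964, 0.20)
})

test_that("predict and invert are mutually inverse on the validity interval", {
  ff <- feature_fixtures()
  for (m in ff) {
    xs <- seq(m$validity[1] + 1e-6, m$validity[2] - 1e-6, length.out = 7)
    ys <- predict(m, xs)
    for (i in c(1, 4, 7)) {
      iv <- invert_feature(m, sort(c(ys[i], ys[i])))
      expect_equal(iv$lo, xs[i], tolerance = 1e-9, info = m$feature)
    }
  }
  # identity-like linear model
  ident <- correlation_model("f", "SME_com", "linear", 0, 1, c(0, 10))
  iv <- invert_feature(ident, c(2, 3))
  expect_equal(c(iv$lo, iv$hi), c(2, 3))
  # decreasing exponential: inverted endpoints swap order
  dec <- correlation_model("f", "T_com", "exponential", 1000, -0.02,
                           c(100, 200))
  iv2 <- invert_feature(dec, predict(dec, c(120, 180))[c(2, 1)])
  expect_equal(c(iv2$lo, iv2$hi), c(120, 180), tolerance = 1e-9)
  # constant models cannot be inverted
  flat <- correlation_model("f", "SME_com", "linear", 5, 0, c(0, 10))
  expect_error(invert_feature(flat, c(4, 6)), "constant")
})

test_that("the intrinsic-viscosity fixture inverts to the published SME window", {
  ff <- feature_fixtures()
  iv <- invert_feature(ff$dvis_maize47, c(45, 55))
  expect_equal(iv$lo, 625, tolerance = 1e-9)
  expect_equal(iv$hi, 875, tolerance = 1e-9)
  # and the model passes through the anchor midpoint
  expect_equal(predict(ff$dvis_maize47, 750), 50.169, tolerance = 1e-4)
})

test_that("feature targets compose into predictor windows; contradictions are reported", {
  ff <- feature_fixtures()
  tw <- target_window(ff, list(density_kgm3 = c(0, 200),
                               insoluble_protein_pct = c(0, 10)))
  expect_equal(c(tw$T_com$lo, tw$T_com$hi), c(155, 165), tolerance = 1e-9)
  # two contradictory targets on the same predictor: very light snacks need
  # high temperature, but low protein cross-linking forbids it
  tw2 <- target_window(ff, list(density_kgm3 = c(0, 120),
                                insoluble_protein_pct = c(0, 6)))
  expect_false(tw2$T_com$feasible)
})

test_that("the design workflow composes inversion, sweep, and region extraction", {
  ff <- feature_fixtures()
  sc <- scenario_fixture("pf_snack")
  dw <- suppressWarnings(design_window(
    sc$machine, sc$material, sc$op,
    sweep = list(N = c(300, 500, 700), Q = 20),
    models = ff,
    targets = list(density_kgm3 = c(0, 200),
                   insoluble_protein_pct = c(0, 10))))
  expect_equal(c(dw$windows$T_com$lo, dw$windows$T_com$hi), c(155, 165),
               tolerance = 1e-9)
  if (dw$feasible) {
    t_feas <- dw$region$nodes$T_com_C
    expect_true(all(t_feas >= 155 & t_feas <= 165))
  }
  # infeasible targets short-circuit before any simulation
  dw2 <- design_window(sc$machine, sc$material, sc$op,
                       sweep = list(N = c(300, 500), Q = 20), models = ff,
                       targets = list(density_kgm3 = c(0, 120),
                                      insoluble_protein_pct = c(0, 6)))
  expect_false(dw2$feasible)
  expect_null(dw2$chart)
})
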