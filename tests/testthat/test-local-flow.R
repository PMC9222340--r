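test_that("the elementary pressure step follows the C-chamber flow law", {
  el <- screw_element("conveying_rh", length = 0.1, pitch = 25e-3,
                      channel_depth = 4e-3, flight_width = 2e-3)
  sf <- shape_factors(el, 25.5e-3)
  omega <- 2 * pi * 500 / 60
  # pure drag flow: no pressure gradient needed
  expect_equal(pressure_step(sf, sf$A * omega, omega, 500)$dP, 0)
  # closed discharge: dP = -A*Omega*eta*dtheta/B
  closed <- pressure_step(sf, 0, omega, 500)
  expect_equal(closed$dP, -sf$A * omega * 500 * sf$dtheta / sf$B)
  expect_lt(closed$dP, 0)
  # linear in viscosity
  expect_equal(pressure_step(sf, 1e-6, omega, 1000)$dP,
               2 * pressure_step(sf, 1e-6, omega, 500)$dP)
  # the filled flag marks elements that need pressure to pass the throughput
  expect_true(pressure_step(sf, sf$A * omega * 1.1, omega, 500)$filled)
  expect_false(pressure_step(sf, sf$A * omega * 0.5, omega, 500)$filled)
})

test_that("representative shear rates scale as tip speed over clearance", {
  el <- screw_element("conveying_rh", length = 0.1, pitch = 25e-3,
                      channel_depth = 4e-3, flight_gap = 1.5e-4)
  g <- representative_shear_rate(el, 25.5e-3, 500)
  expect_equal(g$channel, 166.897, tolerance = 1e-5)
  expect_equal(g$gap, g$channel * 4e-3 / 1.5e-4, tolerance = 1e-9)
  expect_equal(representative_shear_rate(el, 25.5e-3, 0)$channel, 0)
  # halving the channel depth doubles the channel shear rate
  el2 <- screw_element("conveying_rh", length = 0.1, pitch = 25e-3,
                       channel_depth = 2e-3)
  expect_equal(representative_shear_rate(el2, 25.5e-3, 500)$channel,
               2 * g$channel)
})

test_that("dissipated power reduces to eta * gdot^2 * V for a uniform field", {
  el <- screw_element("conveying_rh", length = 0.1, pitch = 25e-3,
                      channel_depth = 4e-3, flight_width = 2e-3)
  sf <- shape_factors(el, 25.5e-3)
  newt <- viscosity_params(K0 = 700, E_over_R = 0, n0 = 1)
  g <- representative_shear_rate(el, 25.5e-3, 500)
  W <- dissipated_power(el, 25.5e-3, newt, 120, 0.2, 300, N = 500)
  expect_equal(W, 700 * g$channel^2 * sf$V_channel +
                    700 * g$gap^2 * sf$V_gap, tolerance = 1e-9)
  expect_equal(dissipated_power(el, 25.5e-3, newt, 120, 0.2, 300, N = 0), 0)
  # partial fill scales linearly
  expect_equal(dissipated_power(el, 25.5e-3, newt, 120, 0.2, 300, N = 500,
                                fill_ratio = 0.25), W / 4)

  # shear-thinning case pinned against a brute-force volume quadrature of
  # eta(gdot) * gdot^2 over the channel and gap regions
  p <- pf_params()
  W2 <- dissipated_power(el, 25.5e-3, p, 120, 0.15, 300, N = 500)
  cells <- 5000
  vol_int <- function(gdot, V) {
    eta <- apparent_viscosity(p, gdot, 120, 0.15, 300, warn = FALSE)
    sum(rep(eta * gdot^2 * V / cells, cells))
  }
  W_brute <- vol_int(g$channel, sf$V_channel) + vol_int(g$gap, sf$V_gap)
  expect_lt(abs(W2 - W_brute) / W_brute, 0.01)
})

test_that("the energy step balances dissipation against barrel exchange", {
  m <- material_db("cb")
  # equilibrium: no dissipation, melt at barrel temperature
  expect_equal(energy_step(m, W_dot = 0, Qv = 4e-6, T_C = 90, Tb_C = 90,
                           MC = 0.15, exchange_area = 1e-3,
                           h_channel = 4e-3), 0)
  # unit balance: Ev = cp gives exactly +1 degC (adiabatic)
  rho <- melt_property(m, 0.15, "rho")
  cp <- melt_property(m, 0.15, "cp")
  Qv <- 4e-6
  expect_equal(energy_step(m, W_dot = cp * rho * Qv, Qv = Qv, T_C = 120,
                           Tb_C = 120, MC = 0.15, exchange_area = 1e-3,
                           h_channel = 4e-3), 1)
  # pure cooling: explicit sub-stepped march matches the closed-form
  # exponential decay within 2%
  k <- melt_property(m, 0.15, "k")
  ht <- 20 * k / 4e-3
  S <- 5e-3
  Tb <- 90; T0 <- 200
  msteps <- 50
  Tn <- T0
  for (i in seq_len(msteps))
    Tn <- Tn + energy_step(m, 0, Qv, Tn, Tb, 0.15,
                           exchange_area = S / msteps, h_channel = 4e-3)
  T_exact <- Tb + (T0 - Tb) * exp(-ht * S / (rho * Qv * cp))
  expect_lt(abs(Tn - T_exact) / (T_exact - Tb), 0.02)
})
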