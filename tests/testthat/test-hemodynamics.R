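# viscosity law, Poiseuille resistance, and the network flow solver
# validated against closed-form series/parallel resistor oracles

test_that("ocular pressures follow p_CRA = 2/3 MAP, p_CRV = IOP", {
  pr <- ocular_pressures(84, 11.1)
  expect_equal(unname(pr), c(56, 11.1, 44.9))
  expect_named(pr, c("p_CRA", "p_CRV", "OPP"))
  expect_error(ocular_pressures(15, 11.1), "non-perfusing")
})

test_that("effective viscosity reproduces the in-vivo law", {
  # documented reference point: D = 10 um, H_D = 0.45 -> ~5.92 cP
  expect_equal(effective_viscosity(10), 5.92, tolerance = 0.01)
  # large-diameter asymptote ~3.2 x plasma viscosity
  expect_equal(effective_viscosity(5000), 3.2, tolerance = 0.01)
  expect_equal(effective_viscosity(5000, mu_plasma = 2),
               2 * effective_viscosity(5000))
  # hematocrit factor is identity at H_D = 0.45, monotone in H_D
  expect_lt(effective_viscosity(10, H_D = 0.30), effective_viscosity(10))
  expect_gt(effective_viscosity(10, H_D = 0.60), effective_viscosity(10))
  expect_error(effective_viscosity(1.0), "1.12")
  expect_error(effective_viscosity(10, H_D = 0))
})

test_that("segment_resistance matches the Poiseuille formula in mixed units", {
  # r = 10 um, l = 1 mm, mu = 1 cP:
  # R_SI = 8 * 1e-3 * 1e-3 / (pi * (1e-5)^4) Pa s / m^3
  R_SI <- 8e-6 / (pi * 1e-20)
  expect_equal(segment_resistance(10, 1, 1), R_SI * 1e-6 / 133.322387415,
               tolerance = 1e-9)
  # scaling laws: ~ l, ~ mu, ~ r^-4
  expect_equal(segment_resistance(10, 2, 1), 2 * segment_resistance(10, 1, 1))
  expect_equal(segment_resistance(10, 1, 3), 3 * segment_resistance(10, 1, 1))
  expect_equal(segment_resistance(20, 1, 1),
               segment_resistance(10, 1, 1) / 16)
  expect_error(segment_resistance(0, 1, 1))
})

test_that("solve_flow matches the series resistor oracle", {
  net <- series_net(r_a = 50, r_v = 60, l_a = 2, l_v = 3)
  hemo <- default_config()$hemo
  sol <- solve_flow(net, 56, 11.1, hemo)
  R1 <- poiseuille_R(50, 2); R2 <- poiseuille_R(60, 3)
  Q_ml_s <- 44.9 / (R1 + R2)              # mL/s
  Q_ul_min <- Q_ml_s * 6e4
  expect_equal(sol$segments$Q, rep(Q_ul_min, 2), tolerance = 1e-10)
  expect_equal(sol$retinal_blood_flow, Q_ul_min, tolerance = 1e-10)
  # interior pressure from the voltage divider
  expect_equal(sol$nodes$pressure[2], 56 - Q_ml_s * R1, tolerance = 1e-10)
  expect_equal(sol$nodes$pressure[c(1, 3)], c(56, 11.1))
  # velocity = Q / (pi r^2), reported in cm/s
  v1 <- (Q_ml_s * 1e-6) / (pi * (50e-6)^2) * 100
  expect_equal(sol$segments$v[1], v1, tolerance = 1e-10)
  expect_lt(sol$kirchhoff_residual, 1e-12)
})

test_that("solve_flow matches the parallel resistor oracle", {
  nodes <- data.frame(id = 1:3, x = c(0, 2, 5), y = 0, z = 0,
                      kind = c("root", "arterial", "root"), plexus = "SVP")
  segs <- data.frame(id = 1:3, from = c(1L, 2L, 2L), to = c(2L, 3L, 3L),
                     radius = c(50, 30, 40), length = c(2, 3, 3),
                     kind = c("artery", "vein", "vein"), plexus = "SVP",
                     is_terminal = FALSE, fixed_resistance = FALSE)
  net <- vascular_network(nodes, segs, validate = FALSE)
  sol <- solve_flow(net, 56, 11.1, default_config()$hemo)
  Ra <- poiseuille_R(50, 2)
  Rv1 <- poiseuille_R(30, 3); Rv2 <- poiseuille_R(40, 3)
  Rpar <- 1 / (1 / Rv1 + 1 / Rv2)
  Q <- 44.9 / (Ra + Rpar)                 # mL/s
  expect_equal(sol$segments$Q[1], Q * 6e4, tolerance = 1e-10)
  # current divider between the two parallel veins
  expect_equal(sol$segments$Q[2], Q * 6e4 * Rpar / Rv1, tolerance = 1e-10)
  expect_equal(sol$segments$Q[3], Q * 6e4 * Rpar / Rv2, tolerance = 1e-10)
  expect_lt(sol$kirchhoff_residual, 1e-12)
})

test_that("artificial segments use the fixed compartment resistance", {
  nodes <- data.frame(id = 1:3, x = c(0, 2, 5), y = 0, z = 0,
                      kind = c("root", "arterial", "root"), plexus = "SVP")
  segs <- data.frame(id = 1:2, from = c(1L, 2L), to = c(2L, 3L),
                     radius = c(50, 10), length = c(2, 1),
                     kind = c("artery", "artificial"), plexus = "SVP",
                     is_terminal = FALSE,
                     fixed_resistance = c(FALSE, TRUE))
  net <- vascular_network(nodes, segs, validate = FALSE)
  hemo <- default_config()$hemo
  hemo$R_compartment <- 2e6
  sol <- solve_flow(net, 56, 11.1, hemo)
  Q <- 44.9 / (poiseuille_R(50, 2) + 2e6)
  expect_equal(sol$retinal_blood_flow, Q * 6e4, tolerance = 1e-10)
})

test_that("flow solution is linear in the applied pressure drop", {
  net <- smoke_net()
  hemo <- smoke_config()$hemo
  s1 <- solve_flow(net, 11.1 + 44.9, 11.1, hemo)
  s2 <- solve_flow(net, 11.1 + 1.2 * 44.9, 11.1, hemo)
  expect_equal(s2$retinal_blood_flow, 1.2 * s1$retinal_blood_flow,
               tolerance = 1e-9)
  expect_equal(s2$macular_flow_fraction, s1$macular_flow_fraction,
               tolerance = 1e-9)
  expect_equal(s2$segments$Q, 1.2 * s1$segments$Q, tolerance = 1e-6)
})

test_that("full network solve satisfies Kirchhoff and reports v_CRA", {
  sol <- smoke_sol()
  net <- smoke_net()
  expect_lt(sol$kirchhoff_residual, 1e-9)
  # velocity consistent with flow through the CRA stub
  cra <- which(net$segments$id == net$meta$cra_segment)
  Q_si <- sol$retinal_blood_flow / 6e10           # m^3/s
  expect_equal(sol$v_CRA, 100 * Q_si / (pi * (81e-6)^2), tolerance = 1e-9)
  # all node pressures within the applied boundary values
  expect_true(all(sol$nodes$pressure <= 56 + 1e-9))
  expect_true(all(sol$nodes$pressure >= 11.1 - 1e-9))
  expect_equal(unname(perfusion_summary(sol)),
               c(sol$retinal_blood_flow, sol$macular_flow_fraction,
                 sol$v_CRA))
})

test_that("solve_flow reports disconnected nodes", {
  nodes <- data.frame(id = 1:4, x = c(0, 2, 5, 9), y = 0, z = 0,
                      kind = c("root", "arterial", "root", "capillary"),
                      plexus = "SVP")
  segs <- data.frame(id = 1:2, from = c(1L, 2L), to = c(2L, 3L),
                     radius = 50, length = c(2, 3),
                     kind = c("artery", "vein"), plexus = "SVP",
                     is_terminal = FALSE, fixed_resistance = FALSE)
  net <- vascular_network(nodes, segs, validate = FALSE)
  expect_error(solve_flow(net, 56, 11.1, default_config()$hemo),
               "disconnected")
})
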