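# constrained-constructive-optimization growth: geometric primitives,
# Murray's-law radii, stage calibration, and the assembled macrovasculature

test_that("min_separation follows l_min = sqrt(nu A / (pi (N + 1)))", {
  expect_equal(min_separation(1, pi * 15^2, 199), sqrt(15^2 / 200))
  expect_equal(min_separation(0.5, 10, 0), sqrt(0.5 * 10 / pi))
  expect_equal(min_separation(0, 10, 5), 0)
  expect_error(min_separation(-1, 10, 5))
  expect_error(min_separation(1, 0, 5))
})

test_that("parent_radius implements Murray's law exactly", {
  expect_equal(parent_radius(3, 4, 3), (27 + 64)^(1 / 3))
  expect_equal(parent_radius(5, 0, 2.85), 5)
  # vectorized and symmetric
  expect_equal(parent_radius(c(1, 2), c(2, 1), 3),
               rev(parent_radius(c(1, 2), c(2, 1), 3)))
  expect_error(parent_radius(1, 1, 0))
})

test_that("bifurcation admissibility combines ratio and angle thresholds", {
  expect_true(bifurcation_admissible(10, 9, theta = 70, delta = 0.8,
                                     theta_min = 60))
  expect_false(bifurcation_admissible(10, 7, theta = 70, delta = 0.8,
                                      theta_min = 60))   # ratio 0.7 <= 0.8
  expect_false(bifurcation_admissible(10, 9, theta = 50, delta = 0.8,
                                      theta_min = 60))   # angle too small
  expect_equal(bifurcation_admissible(c(10, 10), c(9, 7), c(70, 70),
                                      0.8, 60), c(TRUE, FALSE))
})

test_that("terminal sites respect region, FAZ, raphe side and x bound", {
  set.seed(11)
  lognorm <- list(sigma = 4, mu = -0.5, r0 = 0.02)
  reg <- list(r_in = 1.5, r_out = 3)
  for (k in 1:200) {
    p <- sample_terminal_site(reg, lognorm, r_faz = 0.25, side = 1,
                              x_min = -4.5)
    r <- sqrt(sum(p^2))
    expect_true(r >= 1.5 && r <= 3 && r > 0.25)
    expect_gt(p[2], 0)
    expect_gte(p[1], -4.5)
  }
  p <- sample_terminal_site(list(r_in = 0, r_out = 15), lognorm,
                            r_faz = 0.25, side = -1, x_min = -4.5)
  expect_lt(p[2], 0)
  # infeasible region errors instead of hanging
  expect_error(sample_terminal_site(list(r_in = 14.9, r_out = 15),
                                    list(sigma = 0.01, mu = -0.5, r0 = 0.02),
                                    max_reject = 200), "rejections")
})

test_that("grown trees satisfy Murray's law at every bifurcation", {
  cfg <- smoke_config()
  tree <- grown_test_tree()
  Q_root <- 0.063 * pi * (81e-6)^2 / 2          # m^3/s, Table-1 means
  pcra <- 2 / 3 * 84
  bif <- which(tree$c2 >= 0)
  expect_gt(length(bif), 50)
  expect_setequal(unique(tree$gbif[bif]), c(3.0, 2.85))  # frozen per stage
  expect_lt(max(murray_residuals(tree)), 1e-6)
  # continuation segments carry their child's radius unchanged
  cont <- which(tree$c1 >= 0 & tree$c2 < 0)
  expect_equal(tree$radius[cont], tree$radius[tree$c1[cont] + 1])
  # radii never increase from parent to child
  kid <- which(tree$parent >= 0)
  expect_true(all(tree$radius[kid] <=
                  tree$radius[tree$parent[kid] + 1] + 1e-9))

  # calibration: mean root-to-terminal pressure drop of the last stage's
  # terminals equals the stage target at the converged viscosity
  lv <- retinapop:::tree_levels(tree)
  nb <- retinapop:::terminals_below(tree, rev(lv))
  Q <- Q_root * nb / sum(tree$is_term == 1)
  mu <- effective_viscosity(2 * tree$radius)
  dp <- retinapop:::tree_path_dp(tree, tree$radius, mu, Q, lv)
  sel <- tree$is_term == 1 & tree$stage == 3
  target_pa <- (pcra - cfg$stages[[3]]$p_pre_capillary) * 133.322387415
  expect_equal(mean(dp[sel]), target_pa, tolerance = 1e-3)

  # stage-2 terminals were placed in the perifoveal annulus, stage-3 in the
  # parafovea, all on the superior side and temporal of the disc
  for (s in 2:3) {
    reg <- retinapop:::stage_region(cfg, s)
    tip <- which(tree$is_term == 1 & tree$stage == s)
    rad <- sqrt(tree$x1[tip]^2 + tree$y1[tip]^2)
    expect_true(all(rad >= reg$r_in - 1e-9 & rad <= reg$r_out + 1e-9))
  }
  tip <- which(tree$is_term == 1 & tree$stage >= 1)
  expect_true(all(tree$y1[tip] > 0))
  expect_true(all(tree$x1[tip] >= cfg$domain$disc_x))
})

test_that("macrovasculature assembles four trees on CRA/CRV stubs", {
  net <- smoke_macro()
  s <- net$segments; n <- net$nodes
  expect_s3_class(net, "vascular_network")
  expect_equal(sum(n$kind == "root"), 2)
  expect_setequal(unique(s$kind), c("artery", "vein"))
  # CRA stub radius = sampled r_CRA; CRV larger by the configured ratio
  cra <- s[s$id == net$meta$cra_segment, ]
  crv <- s[s$id == net$meta$crv_segment, ]
  expect_equal(cra$radius, 81)
  expect_equal(crv$radius / cra$radius, 1.11)
  expect_equal(cra$length, smoke_config()$population$cra_length)
  # every tree reaches its full terminal complement (per-tree N_terms)
  n_terms_total <- sum(vapply(smoke_config()$stages, `[[`, numeric(1),
                              "N_terms"))
  expect_equal(sum(s$is_terminal & s$kind == "artery"), 2 * n_terms_total)
  expect_equal(sum(s$is_terminal & s$kind == "vein"), 2 * n_terms_total)
  # boundary metadata matches Table-1 means
  expect_equal(net$meta$p_CRA, 56)
  expect_equal(net$meta$p_CRV, 11.1)
  expect_equal(net$meta$OPP, 44.9)
  expect_equal(net$meta$Q_CRA_ul_min, 0.063 * pi * (81e-6)^2 * 6e10,
               tolerance = 1e-10)   # m^3/s -> uL/min is x 6e10
  # creation-time constraint audit: angles and radius ratios admissible
  a <- net$meta$bifurcation_audit
  expect_gt(nrow(a), 100)
  deltas <- vapply(smoke_config()$stages, `[[`, numeric(1), "delta")
  thetas <- vapply(smoke_config()$stages, `[[`, numeric(1), "theta_min")
  expect_true(all(a$ratio > deltas[a$stage]))
  expect_true(all(a$angle_deg > thetas[a$stage]))
})
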