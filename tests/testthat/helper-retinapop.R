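# Shared fixtures for the test suite. Expensive objects (generated networks,
# cohorts) are built once per test run and cached in this environment.

.retinapop_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .retinapop_test_cache))
    assign(key, force(expr), envir = .retinapop_test_cache)
  get(key, envir = .retinapop_test_cache)
}

# population parameters at the distribution means
mean_pop <- function() {
  data.frame(r_CRA = 81, v_CRA = 6.3, MAP = 84, IOP = 11.1,
             OPP = 2 / 3 * 84 - 11.1)
}

# reduced generation scale for structural unit/property tests: small enough
# to generate in a few seconds, large enough to exercise every code path
# (three stages, three plexuses, alpha-wiring, descenders, compartment).
smoke_config <- function() {
  modify_config(default_config(), list(
    stages = list(list(N_terms = 40L), list(N_terms = 30L),
                  list(N_terms = 15L)),
    plexus = list(SVP = list(N_seeds = 600),
                  ICP = list(N_seeds = 1200),
                  DCP = list(N_seeds = 900))))
}

# 50% of the published capillary-seed counts, full tree stages: the scale
# the acceptance runtime target prescribes for cohort statistics.
half_seed_config <- function() {
  modify_config(default_config(), list(
    plexus = list(SVP = list(N_seeds = 2750),
                  ICP = list(N_seeds = 8000),
                  DCP = list(N_seeds = 5250))))
}

# a fitted shape model on the synthetic fixture, shared across files
smoke_shape_model <- function() cached("smoke_shape_model", {
  set.seed(7)
  fit_shape_model(generate_arcade_fixture(8, 20), 5)
})

# smoke-scale macrovasculature only (the four CCO trees + roots)
smoke_macro <- function() cached("smoke_macro", {
  set.seed(7)
  arcades <- sample_arcades(smoke_shape_model(), 3)
  grow_macrovasculature(arcades, as.list(mean_pop()), smoke_config())
})

# one smoke-scale network + flow solution, shared across test files
smoke_net <- function() cached("smoke_net", {
  set.seed(42)
  generate_vasculature(mean_pop(), smoke_config())
})

smoke_sol <- function() cached("smoke_sol", {
  solve_flow(smoke_net(), 2 / 3 * 84, 11.1, smoke_config()$hemo)
})

# further-reduced scale for the >=100-member sign-pattern cohort, so the
# whole suite fits the runtime budget; the correlation signs under test are
# scale-free properties of the generator (see the methods vignette)
sign_config <- function() {
  modify_config(default_config(), list(
    stages = list(list(N_terms = 30L), list(N_terms = 20L),
                  list(N_terms = 10L)),
    plexus = list(SVP = list(N_seeds = 500),
                  ICP = list(N_seeds = 900),
                  DCP = list(N_seeds = 700))))
}

# acceptance cohort: 50 individuals, Table-1 defaults, 50% capillary seeds
acceptance_cohort <- function() cached("acceptance_cohort", {
  cfg <- half_seed_config()
  set.seed(1)
  params <- sample_population(50, cfg)
  run_cohort(params, cfg, base_seed = 1, morphometrics = FALSE,
             raster = FALSE)
})

# sign-pattern cohort: 100 individuals with full morphometrics (FD needs
# the rasterized skeleton)
sign_cohort <- function() cached("sign_cohort", {
  cfg <- sign_config()
  set.seed(2)
  params <- sample_population(100, cfg)
  run_cohort(params, cfg, base_seed = 2, morphometrics = TRUE, raster = TRUE)
})

# one CCO tree grown through all three stages (for Murray-law audits)
grown_test_tree <- function() cached("grown_test_tree", {
  cfg <- smoke_config()
  set.seed(13)
  arcades <- sample_arcades(smoke_shape_model(), 3)
  tree <- retinapop:::make_arcade_tree(c(cfg$domain$disc_x, 0),
                                       arcades$sup_artery)
  Q_root <- 0.063 * pi * (81e-6)^2 / 2
  for (s in 1:3) {
    st <- cfg$stages[[s]]
    tree <- grow_tree(tree, st, retinapop:::stage_region(cfg, s), s,
                      st$N_terms, +1, cfg$terminal_site, Q_root,
                      dp_target = 2 / 3 * 84 - st$p_pre_capillary,
                      domain = cfg$domain, growth = cfg$growth)
  }
  tree
})

# relative Murray-law residuals at every bifurcation of a cco_tree
murray_residuals <- function(tree) {
  bif <- which(tree$c2 >= 0)
  g <- tree$gbif[bif]
  r_p <- tree$radius[bif]
  r_1 <- tree$radius[tree$c1[bif] + 1]
  r_2 <- tree$radius[tree$c2[bif] + 1]
  abs(r_p^g - r_1^g - r_2^g) / r_p^g
}

# hand-built two-segment series network: CRA root -- artery -- mid -- vein
# -- CRV root, for resistor-oracle tests
series_net <- function(r_a = 50, r_v = 60, l_a = 2, l_v = 3) {
  vascular_network(
    nodes = data.frame(
      id = 1:3, x = c(0, 2, 5), y = 0, z = 0,
      kind = c("root", "arterial", "root"), plexus = "SVP"),
    segments = data.frame(
      id = 1:2, from = c(1L, 2L), to = c(2L, 3L),
      radius = c(r_a, r_v), length = c(l_a, l_v),
      kind = c("artery", "vein"), plexus = "SVP",
      is_terminal = FALSE, fixed_resistance = FALSE),
    validate = FALSE)
}

# analytic Poiseuille resistance with the packaged viscosity law, mmHg*s/mL
poiseuille_R <- function(r_um, l_mm, H_D = 0.45, mu_plasma = 1) {
  segment_resistance(r_um, l_mm, effective_viscosity(2 * r_um, H_D, mu_plasma))
}

# Sierpinski carpet occupancy matrix of the given order (3^order pixels/side)
sierpinski_carpet <- function(order) {
  m <- matrix(1L, 1, 1)
  for (k in seq_len(order)) {
    n <- nrow(m)
    big <- matrix(0L, 3 * n, 3 * n)
    for (i in 0:2) for (j in 0:2) {
      if (i == 1 && j == 1) next
      big[i * n + seq_len(n), j * n + seq_len(n)] <- m
    }
    m <- big
  }
  m
}

# Ishigami function and its closed-form Sobol indices (a = 7, b = 0.1)
ishigami <- function(X, a = 7, b = 0.1) {
  sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
}

ishigami_exact <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  V <- V1 + V2 + V13
  list(S1 = c(V1, V2, 0) / V, ST = c(V1 + V13, V2, V13) / V)
}
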