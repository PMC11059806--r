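# Variance-based global sensitivity analysis (Saltelli sampling, Sobol
# first/total-order indices with bootstrap CIs) and the uncertainty-
# quantification scenario grid over the compartment resistance R, OPP
# scaling, and the tree-to-bed connection fraction alpha.

#' Saltelli sample matrix
#'
#' Builds the radial Saltelli design enabling first- and total-order Sobol
#' estimation: two independent stratified-uniform base matrices A and B of
#' `N_base` rows, plus the k matrices AB_i (A with column i from B), stacked
#' as rows `[A; B; AB_1; ...; AB_k]` — `N_base * (k + 2)` rows in total.
#'
#' @param ranges named list of `c(lo, hi)` ranges (one per input).
#' @param N_base base sample size; a power of 2 is recommended for balance.
#' @return numeric matrix with `N_base * (k + 2)` rows and attributes
#'   `N_base`, `k`, `param_names`.
#' @export
saltelli_sample <- function(ranges, N_base) {
  k <- length(ranges)
  stopifnot(k >= 1, N_base >= 2)
  for (r in ranges) if (!(length(r) == 2 && r[1] < r[2]))
    stop("saltelli_sample: each range must be c(lo, hi) with lo < hi")
  if (bitwAnd(N_base, N_base - 1L) != 0)
    warning("N_base is not a power of 2; estimator balance may suffer")
  strat <- function() {
    u <- (sample.int(N_base) - stats::runif(N_base)) / N_base
    u
  }
  A <- sapply(seq_len(k), function(i) strat())
  B <- sapply(seq_len(k), function(i) strat())
  blocks <- vector("list", k + 2)
  blocks[[1]] <- A; blocks[[2]] <- B
  for (i in seq_len(k)) {
    ABi <- A; ABi[, i] <- B[, i]
    blocks[[i + 2]] <- ABi
  }
  X <- do.call(rbind, blocks)
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  X <- sweep(sweep(X, 2, hi - lo, "*"), 2, lo, "+")
  colnames(X) <- names(ranges)
  attr(X, "N_base") <- N_base
  attr(X, "k") <- k
  attr(X, "param_names") <- names(ranges)
  X
}

#' Sobol indices from a Saltelli design
#'
#' First-order indices via the Saltelli (2010) estimator
#' `S_i = mean(yB * (yABi - yA)) / V` and total-order via Jansen's
#' `ST_i = mean((yA - yABi)^2) / (2 V)`, with percentile bootstrap CIs and a
#' convergence trace over nested subsample sizes.
#'
#' @param Y model outputs evaluated row-by-row on [saltelli_sample()] output.
#' @param design the design matrix (for `N_base`, `k` and names), or a list
#'   with those attributes.
#' @param n_boot bootstrap resamples for the CIs.
#' @param conf confidence level.
#' @return object of class `sobol_result`: data.frame `indices` (parameter,
#'   S, S_lo, S_hi, ST, ST_lo, ST_hi) and `convergence` (n_used, parameter,
#'   S, ST).
#' @export
sobol_indices <- function(Y, design, n_boot = 200, conf = 0.95) {
  N <- attr(design, "N_base"); k <- attr(design, "k")
  pn <- attr(design, "param_names")
  if (is.null(pn)) pn <- paste0("x", seq_len(k))
  stopifnot(length(Y) == N * (k + 2))
  yA <- Y[seq_len(N)]
  yB <- Y[N + seq_len(N)]
  yAB <- matrix(Y[-(1:(2 * N))], nrow = N, ncol = k)
  est <- function(idx) {
    a <- yA[idx]; b <- yB[idx]; ab <- yAB[idx, , drop = FALSE]
    V <- stats::var(c(a, b))
    if (V == 0) return(cbind(S = rep(0, k), ST = rep(0, k)))
    S <- colMeans(b * (ab - a)) / V
    ST <- colMeans((a - ab)^2) / (2 * V)
    cbind(S = S, ST = ST)
  }
  point <- est(seq_len(N))
  if (stats::var(c(yA, yB)) == 0)
    warning("sobol_indices: zero output variance; all indices reported 0")
  bs <- array(NA_real_, c(n_boot, k, 2))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(N, replace = TRUE)
    e <- est(idx)
    bs[b, , 1] <- e[, "S"]; bs[b, , 2] <- e[, "ST"]
  }
  a2 <- (1 - conf) / 2
  qs <- apply(bs, c(2, 3), stats::quantile, probs = c(a2, 1 - a2),
              na.rm = TRUE)
  indices <- data.frame(parameter = pn,
                        S = point[, "S"], S_lo = qs[1, , 1],
                        S_hi = qs[2, , 1],
                        ST = point[, "ST"], ST_lo = qs[1, , 2],
                        ST_hi = qs[2, , 2], row.names = NULL)
  sizes <- unique(pmax(2, floor(N * c(0.25, 0.5, 1))))
  conv <- do.call(rbind, lapply(sizes, function(m) {
    e <- est(seq_len(m))
    data.frame(n_used = m, parameter = pn, S = e[, "S"], ST = e[, "ST"],
               row.names = NULL)
  }))
  structure(list(indices = indices, convergence = conv, N_base = N),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("<sobol_result> N_base =", x$N_base, "\n")
  print(x$indices, digits = 3)
  invisible(x)
}

# map one hyperparameter vector (Table-2 names) onto config overrides
apply_hyperparameters <- function(config, hp) {
  st <- config$stages
  if (!is.null(hp[["N_terms_stage2"]])) st[[2]]$N_terms <-
      as.integer(round(hp[["N_terms_stage2"]]))
  if (!is.null(hp[["N_terms_stage3"]])) st[[3]]$N_terms <-
      as.integer(round(hp[["N_terms_stage3"]]))
  for (f in c("l_fr", "delta", "gamma", "nu", "theta_min", "f_n")) {
    if (!is.null(hp[[f]])) for (s in seq_along(st)) st[[s]][[f]] <- hp[[f]]
  }
  config$stages <- st
  if (!is.null(hp[["eta"]])) config$growth$eta <- hp[["eta"]]
  if (!is.null(hp[["N_seeds_SVP"]])) config$plexus$SVP$N_seeds <-
      max(4L, as.integer(round(hp[["N_seeds_SVP"]])))
  validate_config(config)
}

#' Global sensitivity study of the generation hyperparameters
#'
#' Evaluates the structural model over a Saltelli design of the ten
#' generation hyperparameters: for each row, one SVP vasculature is generated
#' (population parameters fixed at their means, structural seed fixed across
#' rows so output variance reflects the hyperparameters) and the SVP
#' morphometrics are computed; Sobol indices are then estimated per metric.
#'
#' @param ranges named ranges (see [sobol_ranges()]).
#' @param N_base Saltelli base sample size.
#' @param config run configuration (use reduced sizes for desk-scale runs).
#' @param struct_seed structural seed held fixed across rows.
#' @param raster include FD/IVD among the metrics.
#' @return list of `sobol_result` per metric, plus `X` (design) and `Y`
#'   (outputs matrix).
#' @export
run_sensitivity_study <- function(ranges, N_base, config = default_config(),
                                  struct_seed = 1, raster = TRUE) {
  X <- saltelli_sample(ranges, N_base)
  pop <- with(config$population, list(
    r_CRA = r_CRA$mean, v_CRA = v_CRA$mean, MAP = MAP$mean, IOP = IOP$mean))
  shape_model <- local({
    set.seed(struct_seed)
    fit_shape_model(generate_arcade_fixture(
      config$shape_model$n_training_eyes, config$shape_model$n_landmarks),
      config$shape_model$n_components)
  })
  mnames <- c("VAD_SVP", "VSD_SVP", "VDI_SVP", "VCI_SVP",
              if (raster) c("FD_SVP", "IVD_SVP"))
  Y <- matrix(NA_real_, nrow(X), length(mnames),
              dimnames = list(NULL, mnames))
  n_fail <- 0
  for (r in seq_len(nrow(X))) {
    cfg <- apply_hyperparameters(config, as.list(X[r, ]))
    val <- tryCatch({
      set.seed(struct_seed)
      net <- generate_vasculature(pop, cfg, shape_model, plexi = "SVP",
                                  orient = FALSE)
      ai <- analytic_indices(net, "SVP",
                             config$morphometrics$fov_diameter / 2)
      v <- c(VAD_SVP = ai$VAD, VSD_SVP = ai$VSD, VDI_SVP = ai$VDI_um,
             VCI_SVP = ai$VCI)
      if (raster) {
        ras <- rasterize_plexus(net, "SVP",
                                config$morphometrics$fov_diameter / 2,
                                config$morphometrics$px_size)
        v <- c(v, FD_SVP = fractal_dimension(ras$skeleton),
               IVD_SVP = intervessel_distance(ras$skeleton,
                                              config$morphometrics$px_size))
      }
      v
    }, error = function(e) NULL)
    if (is.null(val)) n_fail <- n_fail + 1 else Y[r, ] <- val[mnames]
  }
  # impute failed rows by the nearest successful row (count logged)
  if (n_fail) {
    message("run_sensitivity_study: ", n_fail, " failed rows imputed")
    bad <- which(is.na(Y[, 1]))
    good <- which(!is.na(Y[, 1]))
    if (!length(good)) stop("all sensitivity evaluations failed")
    Xs <- scale(X)
    for (b in bad) {
      d2 <- colSums((t(Xs[good, , drop = FALSE]) - Xs[b, ])^2)
      Y[b, ] <- Y[good[which.min(d2)], ]
    }
  }
  res <- lapply(mnames, function(m) sobol_indices(Y[, m], X))
  names(res) <- mnames
  c(res, list(X = X, Y = Y, n_failed = n_fail))
}

# ---- uncertainty quantification --------------------------------------------

#' Uncertainty-quantification scenario grid
#'
#' Re-solves a reduced cohort over the 45-scenario grid: compartment
#' resistance `R` in {5e5, 1e6, 5e6} mmHg*s/mL, OPP at {80%, 100%, 120%} of
#' each individual's baseline, and `alpha` in {0.2, ..., 0.6}. Tree and bed
#' geometry is generated once per individual and reused; changing `alpha`
#' re-wires the SVP connections; changing `R` or OPP only re-solves.
#'
#' @param config run configuration.
#' @param cohort_n individuals in the reduced cohort.
#' @param base_seed seed for population sampling and generation.
#' @param alphas,R_values,opp_scales grid axes.
#' @param progress print progress lines.
#' @return object of class `uq_scenario_table`: `long` (per individual x
#'   scenario: RBF, MFF) and `scenarios` (45-row summary).
#' @export
run_uq_grid <- function(config = default_config(), cohort_n = 10,
                        base_seed = 1,
                        alphas = c(0.2, 0.3, 0.4, 0.5, 0.6),
                        R_values = c(5e5, 1e6, 5e6),
                        opp_scales = c(0.8, 1.0, 1.2),
                        progress = FALSE) {
  set.seed(base_seed %% .Machine$integer.max)
  params <- sample_population(cohort_n, config)
  shape_model <- fit_shape_model(
    generate_arcade_fixture(config$shape_model$n_training_eyes,
                            config$shape_model$n_landmarks),
    config$shape_model$n_components)
  rows <- list()
  for (i in seq_len(cohort_n)) {
    seed_i <- (base_seed + 104729L * i) %% 2147483647L
    set.seed(seed_i)
    pop <- params[i, ]
    arcades <- sample_arcades(shape_model, config$shape_model$clamp_sd)
    macro <- grow_macrovasculature(arcades, as.list(pop), config)
    beds <- list()
    for (nm in c("SVP", "ICP", "DCP"))
      beds[[nm]] <- build_voronoi_bed(config$plexus[[nm]]$N_seeds,
                                      config$domain$r_perifovea,
                                      config$domain$r_FAZ, nm,
                                      config$plexus[[nm]]$z)
    beds$SVP <- prune_capillaries_near_macro(beds$SVP, macro)
    pr <- ocular_pressures(pop$MAP, pop$IOP)
    for (a in alphas) {
      net <- connect_network(macro, beds, a, config$plexus$frac_deep, config)
      net <- assign_and_smooth_diameters(net, config$plexus$SVP$r_capillary)
      for (R in R_values) {
        hemo <- config$hemo; hemo$R_compartment <- R
        for (sc in opp_scales) {
          p_cra <- pr["p_CRV"] + sc * pr["OPP"]
          sol <- solve_flow(net, p_cra, pr["p_CRV"], hemo)
          rows[[length(rows) + 1]] <- data.frame(
            individual = i, alpha = a, R = R, opp_scale = sc,
            OPP = unname(sc * pr["OPP"]),
            RBF = sol$retinal_blood_flow,
            MFF = sol$macular_flow_fraction)
        }
      }
      if (progress) cat(sprintf("individual %d alpha %.1f done\n", i, a))
    }
  }
  long <- do.call(rbind, rows)
  scen <- stats::aggregate(cbind(RBF, MFF) ~ alpha + R + opp_scale,
                           data = long, FUN = mean)
  names(scen)[names(scen) %in% c("RBF", "MFF")] <-
    c("mean_RBF", "mean_MFF")
  structure(list(long = long, scenarios = scen),
            class = "uq_scenario_table")
}

#' @export
print.uq_scenario_table <- function(x, ...) {
  cat("<uq_scenario_table>", nrow(x$scenarios), "scenarios,",
      length(unique(x$long$individual)), "individuals\n")
  invisible(x)
}

#' Linearity diagnostics of the UQ grid
#'
#' Per compartment-resistance stratum (at the baseline `alpha` unless
#' stated): Pearson r^2 between the OPP scaling and (i) total retinal blood
#' flow, computed on per-scale cohort means (the dose-response of the
#' controlled variable), and (ii) macular flow fraction, computed pooled
#' over individuals in the balanced design. Exact network linearity makes
#' (i) equal 1 and (ii) vanish; responses whose variation is below solver
#' round-off (relative sd < 1e-9) report r^2 = 0.
#'
#' @param uq a `uq_scenario_table`.
#' @param alpha_baseline which alpha slice to use (default 0.4).
#' @return data.frame: R, r2_rbf, r2_mff.
#' @export
uq_linearity <- function(uq, alpha_baseline = 0.4) {
  d <- uq$long[abs(uq$long$alpha - alpha_baseline) < 1e-9, ]
  if (!nrow(d)) d <- uq$long[uq$long$alpha == uq$long$alpha[1], ]
  r2_safe <- function(x, y) {
    if (stats::sd(y) < 1e-9 * max(abs(mean(y)), 1e-300)) return(0)
    stats::cor(x, y)^2
  }
  do.call(rbind, lapply(split(d, d$R), function(g) {
    m <- stats::aggregate(RBF ~ opp_scale, data = g, FUN = mean)
    data.frame(R = g$R[1],
               r2_rbf = r2_safe(m$opp_scale, m$RBF),
               r2_mff = r2_safe(g$opp_scale, g$MFF))
  }))
}
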