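# Virtual-cohort generation, batch simulation, and structure-function
# correlation analysis (Spearman with bootstrap confidence intervals).

#' Sample population parameters
#'
#' Independent normal draws of CRA radius (um), CRA velocity (cm/s), MAP and
#' IOP (mmHg) from the configured distributions; individuals with a
#' non-perfusing eye (`OPP <= 0`) or any non-positive parameter are
#' resampled.
#'
#' @param n cohort size.
#' @param config run configuration.
#' @return data.frame with columns r_CRA, v_CRA, MAP, IOP, OPP.
#' @export
sample_population <- function(n, config = default_config()) {
  p <- config$population
  draw <- function() stats::rnorm(4, c(p$r_CRA$mean, p$v_CRA$mean,
                                       p$MAP$mean, p$IOP$mean),
                                  c(p$r_CRA$sd, p$v_CRA$sd,
                                    p$MAP$sd, p$IOP$sd))
  out <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    repeat {
      v <- draw()
      opp <- 2 / 3 * v[3] - v[4]
      if (all(v > 0) && opp > 0) break
    }
    out[i, ] <- v
  }
  df <- as.data.frame(out)
  names(df) <- c("r_CRA", "v_CRA", "MAP", "IOP")
  df$OPP <- 2 / 3 * df$MAP - df$IOP
  df
}

#' Generate one virtual vasculature
#'
#' Full structural pipeline for one individual: arcade sampling from the
#' shape model, staged CCO growth of the four trees, Voronoi capillary beds
#' for the requested plexuses, pruning, wiring (including the compartment
#' closure), diameter smoothing, and flow orientation. Uses the current RNG
#' state; seed externally for reproducibility.
#'
#' @param pop one-row data.frame (or list) of population parameters.
#' @param config run configuration.
#' @param shape_model an `arcade_shape_model`; fitted from a synthetic
#'   fixture when NULL.
#' @param plexi which capillary beds to build.
#' @param orient run the flow-orientation diffusion (not needed for the
#'   linear solve itself; kept for ordering/DAG analyses).
#' @return assembled `vascular_network`.
#' @export
generate_vasculature <- function(pop, config = default_config(),
                                 shape_model = NULL,
                                 plexi = c("SVP", "ICP", "DCP"),
                                 orient = TRUE) {
  if (is.null(shape_model))
    shape_model <- fit_shape_model(
      generate_arcade_fixture(config$shape_model$n_training_eyes,
                              config$shape_model$n_landmarks),
      config$shape_model$n_components)
  arcades <- sample_arcades(shape_model, config$shape_model$clamp_sd)
  macro <- grow_macrovasculature(arcades, as.list(pop), config)
  beds <- list()
  for (nm in intersect(c("SVP", "ICP", "DCP"), plexi)) {
    beds[[nm]] <- build_voronoi_bed(config$plexus[[nm]]$N_seeds,
                                    config$domain$r_perifovea,
                                    config$domain$r_FAZ, nm,
                                    config$plexus[[nm]]$z)
  }
  beds$SVP <- prune_capillaries_near_macro(beds$SVP, macro)
  net <- connect_network(macro, beds, config$plexus$alpha,
                         config$plexus$frac_deep, config)
  net <- assign_and_smooth_diameters(net, config$plexus$SVP$r_capillary)
  if (orient) net <- orient_capillary_flow(net)
  net
}

#' Run a virtual cohort
#'
#' For each individual: generate the vasculature, solve hemodynamics with
#' the individual's OPP (CRA velocity is used only for the growth-stage CRA
#' flow, not in the flow solve), and compute morphometrics and macular
#' diameter ratios. Individual failures are recorded and skipped.
#'
#' @param params data.frame from [sample_population()].
#' @param config run configuration.
#' @param base_seed integer; individual i runs under a seed derived from it.
#' @param morphometrics compute OCTA metrics (needed for correlations).
#' @param raster include FD/IVD (slower).
#' @param keep_networks retain the generated networks (memory-heavy).
#' @param progress print one line per individual.
#' @return object of class `retinapop_cohort`: `results` data.frame (one row
#'   per successful individual), `failures` (list), `networks` (optional).
#' @export
run_cohort <- function(params, config = default_config(), base_seed = 1,
                       morphometrics = TRUE, raster = TRUE,
                       keep_networks = FALSE, progress = FALSE) {
  set.seed(base_seed %% .Machine$integer.max)
  shape_model <- fit_shape_model(
    generate_arcade_fixture(config$shape_model$n_training_eyes,
                            config$shape_model$n_landmarks),
    config$shape_model$n_components)
  rows <- list(); failures <- list(); nets <- list()
  for (i in seq_len(nrow(params))) {
    seed_i <- (base_seed + 7919L * i) %% 2147483647L
    set.seed(seed_i)
    pop <- params[i, ]
    res <- tryCatch({
      net <- generate_vasculature(pop, config, shape_model)
      sol <- solve_flow(net, 2 / 3 * pop$MAP, pop$IOP, config$hemo)
      row <- data.frame(individual = i, seed = seed_i, pop,
                        retinal_blood_flow = sol$retinal_blood_flow,
                        macular_flow_fraction = sol$macular_flow_fraction,
                        v_CRA_model = sol$v_CRA,
                        kirchhoff = sol$kirchhoff_residual)
      dbo <- diameter_by_order(net, region_radius = config$domain$r_perifovea)
      row$av_ratio_all <- attr(dbo, "ratio_all")
      o5 <- dbo$ratio[dbo$order == 5]
      row$av_ratio_order5 <- if (length(o5)) o5 else NA_real_
      row$max_order <- max(dbo$order)
      if (morphometrics) {
        m <- morphometrics_report(net, config$morphometrics$fov_diameter / 2,
                                  config$morphometrics$px_size, raster)
        row <- cbind(row, as.data.frame(m))
      }
      if (keep_networks) nets[[i]] <- net
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(individual = i,
                                               message = conditionMessage(res))
      if (progress) cat(sprintf("[%d/%d] FAILED: %s\n", i, nrow(params),
                                conditionMessage(res)))
    } else {
      rows[[length(rows) + 1]] <- res
      if (progress) cat(sprintf("[%d/%d] RBF %.1f uL/min MFF %.1f%%\n", i,
                                nrow(params), res$retinal_blood_flow,
                                res$macular_flow_fraction))
    }
  }
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r })
  structure(list(results = do.call(rbind, rows), failures = failures,
                 networks = if (keep_networks) nets else NULL,
                 base_seed = base_seed),
            class = "retinapop_cohort")
}

#' @export
print.retinapop_cohort <- function(x, ...) {
  r <- x$results
  cat("<retinapop_cohort> ", nrow(r), " individuals (",
      length(x$failures), " failures)\n", sep = "")
  if (nrow(r))
    cat(sprintf("  RBF %.2f +/- %.2f uL/min | MFF %.2f +/- %.2f %% | ",
                mean(r$retinal_blood_flow), stats::sd(r$retinal_blood_flow),
                mean(r$macular_flow_fraction),
                stats::sd(r$macular_flow_fraction)),
        sprintf("v_CRA %.2f +/- %.2f cm/s\n", mean(r$v_CRA_model),
                stats::sd(r$v_CRA_model)))
  invisible(x)
}

#' Spearman correlation with bootstrap CI
#'
#' Spearman rank correlation with a percentile bootstrap confidence interval
#' (resampling pairs).
#'
#' @param x,y numeric vectors (length >= 3).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @return list `rho`, `ci` (length 2), `n_boot`.
#' @export
spearman_bootstrap <- function(x, y, n_boot = 1000, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman rho undefined")
    return(list(rho = NaN, ci = c(NaN, NaN), n_boot = n_boot))
  }
  rho <- stats::cor(x, y, method = "spearman")
  bs <- replicate(n_boot, {
    i <- sample.int(length(x), replace = TRUE)
    suppressWarnings(stats::cor(x[i], y[i], method = "spearman"))
  })
  a <- (1 - conf) / 2
  list(rho = rho, ci = unname(stats::quantile(bs, c(a, 1 - a), na.rm = TRUE)),
       n_boot = n_boot)
}

#' Structure-function correlation table
#'
#' Spearman correlations (with bootstrap CIs) of each morphological metric
#' against retinal blood flow and macular flow fraction, with qualitative
#' bands (|rho| < 0.25 weak, < 0.5 moderate, else strong).
#'
#' @param cohort a `retinapop_cohort` (>= 10 individuals).
#' @param n_boot bootstrap resamples.
#' @return data.frame: metric, output, rho, ci_lo, ci_hi, strength.
#' @export
correlation_table <- function(cohort, n_boot = 1000) {
  r <- cohort$results
  stopifnot(nrow(r) >= 10)
  metrics <- intersect(c("VAD_SVP", "VSD_SVP", "VDI_SVP", "VCI_SVP",
                         "FD_SVP", "IVD_SVP", "VAD_ICP", "FD_ICP",
                         "VAD_DCP", "FD_DCP", "VAD_ICPDCP", "FD_ICPDCP"),
                       names(r))
  outputs <- c(retinal_blood_flow = "retinal_blood_flow",
               macular_flow_fraction = "macular_flow_fraction")
  out <- list()
  for (m in metrics) for (o in names(outputs)) {
    sb <- spearman_bootstrap(r[[m]], r[[outputs[o]]], n_boot)
    out[[length(out) + 1]] <- data.frame(
      metric = m, output = o, rho = sb$rho,
      ci_lo = sb$ci[1], ci_hi = sb$ci[2],
      strength = if (is.nan(sb$rho)) NA_character_
                 else if (abs(sb$rho) < 0.25) "weak"
                 else if (abs(sb$rho) < 0.5) "moderate" else "strong")
  }
  do.call(rbind, out)
}
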