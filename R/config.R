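#' Default run configuration
#'
#' Loads the packaged baseline configuration: population parameter
#' distributions (CRA radius and velocity, MAP, IOP), the three
#' constructive-optimization growth stages, capillary plexus settings for
#' SVP/ICP/DCP, the hemodynamic closure, and morphometrics conventions.
#' Any field can be overridden with [modify_config()].
#'
#' @return a nested list of class `retinapop_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$stages[[1]]$N_terms
default_config <- function() {
  path <- system.file("extdata", "default_config.yaml", package = "retinapop")
  cfg <- yaml::read_yaml(path)
  cfg <- validate_config(cfg)
  class(cfg) <- c("retinapop_config", "list")
  cfg
}

#' Override configuration fields
#'
#' Recursively merges `overrides` into `config` (same semantics as
#' [utils::modifyList()]), then re-validates.
#'
#' @param config a `retinapop_config` list.
#' @param overrides named list of replacement values, nested as in the config.
#' @return the modified configuration.
#' @export
modify_config <- function(config, overrides) {
  merge_rec <- function(old, new) {
    if (!is.list(old) || !is.list(new)) return(new)
    if (is.null(names(new)) && !is.null(names(old)) == FALSE &&
        is.null(names(old))) {
      # both unnamed (e.g. stages): positional merge
      for (i in seq_along(new))
        if (i <= length(old)) old[[i]] <- merge_rec(old[[i]], new[[i]])
        else old[[i]] <- new[[i]]
      return(old)
    }
    if (is.null(names(new))) return(new)
    for (nm in names(new)) {
      old[[nm]] <- if (nm %in% names(old)) merge_rec(old[[nm]], new[[nm]])
                   else new[[nm]]
    }
    old
  }
  cfg <- merge_rec(config, overrides)
  cfg <- validate_config(cfg)
  class(cfg) <- c("retinapop_config", "list")
  cfg
}

validate_config <- function(cfg) {
  d <- cfg$domain
  stopifnot(d$r_FAZ < d$r_parafovea, d$r_parafovea < d$r_perifovea,
            d$r_perifovea < d$r_retina)
  for (s in cfg$stages) {
    stopifnot(s$delta >= 0, s$delta < 1, s$theta_min >= 0, s$theta_min < 90,
              s$gamma > 0, s$l_fr > 0, s$l_fr < 1, s$N_terms >= 0)
  }
  stopifnot(cfg$plexus$alpha >= 0, cfg$plexus$alpha <= 1,
            cfg$plexus$frac_deep >= 0, cfg$plexus$frac_deep <= 1,
            cfg$hemo$R_compartment > 0,
            cfg$hemo$H_D > 0, cfg$hemo$H_D < 1)
  cfg
}

#' Hyperparameter ranges for sensitivity analysis
#'
#' Ranges over which the ten generation hyperparameters are sampled for the
#' Sobol analysis. The `"as_published"` set is reproduced verbatim from the
#' source table (with a documented warning: some entries look misaligned
#' against the baselines); `"plausible"` reassigns gamma and nu to ranges
#' consistent with their baselines.
#'
#' @param which `"as_published"` or `"plausible"`.
#' @return named list of `c(lo, hi)` ranges.
#' @export
sobol_ranges <- function(which = c("as_published", "plausible")) {
  which <- match.arg(which)
  path <- system.file("extdata", "sobol_ranges.yaml", package = "retinapop")
  r <- yaml::read_yaml(path)[[which]]
  if (which == "as_published")
    warning("'as_published' ranges include entries inconsistent with the ",
            "baseline values (gamma, nu); see ?sobol_ranges", call. = FALSE)
  lapply(r, as.numeric)
}

# stage region bounds (mm radii) for a given stage index
stage_region <- function(config, stage_idx) {
  d <- config$domain
  reg <- config$stages[[stage_idx]]$region
  switch(reg,
    full = list(r_in = 0, r_out = d$r_retina,
                area = pi * d$r_retina^2),
    annulus = list(r_in = d$r_parafovea, r_out = d$r_perifovea,
                   area = pi * (d$r_perifovea^2 - d$r_parafovea^2)),
    parafovea = list(r_in = 0, r_out = d$r_parafovea,
                     area = pi * d$r_parafovea^2),
    stop("unknown stage region: ", reg))
}
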