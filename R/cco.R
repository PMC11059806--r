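# Staged constrained constructive optimization (CCO) growth of the arterial
# and venous trees over the temporal retina.
#
# A growing tree is a segment-indexed structure (class "cco_tree"): parallel
# vectors x0,y0,x1,y1 (mm; distal end at x1,y1), radius/rbase (um), gbif
# (Murray exponent frozen at the distal bifurcation's creation), parent, c1,
# c2 (0-based indices; c2 == -1 marks a chain node), is_term, stage.
#
# Radii are Murray-consistent by construction: every terminal carries a base
# radius, and each internal segment's radius is (r1^g + r2^g)^(1/g) with its
# own bifurcation exponent. After each stage the base radii of that stage's
# terminals are scaled so that the mean root-to-terminal pressure drop equals
# the stage target under Poiseuille flow with equal terminal flows and the
# diameter-dependent viscosity law (fixed point started at eta).

#' Minimum terminal separation
#'
#' Distance below which a candidate terminal site is rejected, for a domain
#' of given area holding `n_terms` terminals:
#' `l_min = sqrt(nu * area / (pi * (n_terms + 1)))` — each terminal supports
#' a circular patch of area `area / (n_terms + 1)` scaled by the perfusion
#' area factor `nu`.
#'
#' @param nu perfusion-area factor (>= 0).
#' @param domain_area region area, mm^2 (> 0).
#' @param n_terms current number of terminals (>= 0).
#' @return minimum separation in mm.
#' @export
min_separation <- function(nu, domain_area, n_terms) {
  if (nu < 0 || domain_area <= 0 || n_terms < 0)
    stop("min_separation: nu and n_terms must be >= 0, domain_area > 0")
  sqrt(nu * domain_area / (pi * (n_terms + 1)))
}

#' Parent radius under Murray's law
#'
#' `r_p = (r1^gamma + r2^gamma)^(1/gamma)`.
#'
#' @param r1,r2 daughter radii (>= 0).
#' @param gamma Murray exponent (> 0).
#' @return parent radius.
#' @export
parent_radius <- function(r1, r2, gamma) {
  stopifnot(all(r1 >= 0), all(r2 >= 0), gamma > 0)
  (r1^gamma + r2^gamma)^(1 / gamma)
}

#' Bifurcation admissibility
#'
#' A bifurcation is admissible iff the daughter radius symmetry exceeds
#' `delta` and the daughter angle exceeds `theta_min`:
#' `min(r1,r2)/max(r1,r2) > delta` and `theta > theta_min`.
#'
#' @param r1,r2 daughter radii (> 0).
#' @param theta angle between daughters, degrees.
#' @param delta symmetry floor in `[0, 1)`.
#' @param theta_min minimum angle, degrees.
#' @return logical.
#' @export
bifurcation_admissible <- function(r1, r2, theta, delta, theta_min) {
  stopifnot(all(r1 > 0), all(r2 > 0))
  (pmin(r1, r2) / pmax(r1, r2) > delta) & (theta > theta_min)
}

#' Sample a terminal site with foveal bias
#'
#' Radius drawn as `r0 + exp(mu + sigma * Z)`, `Z ~ N(0,1)`; angle uniform on
#' `[0, 2*pi)`. Rejection-resampled until the point lies in the stage region
#' (radial band `[r_in, r_out]`), outside the FAZ, on the requested side of
#' the raphe, and temporal of `x_min`.
#'
#' @param region list with `r_in`, `r_out` (mm).
#' @param lognorm list with `sigma`, `mu`, `r0`.
#' @param r_faz FAZ radius, mm.
#' @param side +1 superior half, -1 inferior half, 0 either.
#' @param x_min temporal bound on x (mm; `-Inf` to disable).
#' @param max_reject error after this many consecutive rejections.
#' @return numeric `c(x, y)` in mm.
#' @export
sample_terminal_site <- function(region, lognorm, r_faz = 0, side = 0,
                                 x_min = -Inf, max_reject = 1e4) {
  for (i in seq_len(max_reject)) {
    r <- lognorm$r0 + exp(lognorm$mu + lognorm$sigma * stats::rnorm(1))
    th <- stats::runif(1, 0, 2 * pi)
    p <- c(r * cos(th), r * sin(th))
    rad <- sqrt(sum(p^2))
    if (rad >= region$r_in && rad <= region$r_out && rad > r_faz &&
        (side == 0 || p[2] * side > 0) && p[1] >= x_min)
      return(p)
  }
  stop("sample_terminal_site: >", max_reject, " consecutive rejections; ",
       "region/parameter mismatch")
}

# ---- tree construction ------------------------------------------------------

# Build an initial cco_tree from a root point and an arcade polyline.
# The chain root->landmark1->...->tip becomes parent-linked segments; the
# distal tip is the tree's initial terminal (stage 1).
make_arcade_tree <- function(root_xy, polyline, rt0 = 10) {
  pts <- rbind(root_xy, polyline)
  n <- nrow(pts) - 1
  tree <- list(
    x0 = pts[seq_len(n), 1], y0 = pts[seq_len(n), 2],
    x1 = pts[-1, 1], y1 = pts[-1, 2],
    radius = rep(rt0, n), rbase = rep(rt0, n), gbif = rep(0, n),
    parent = c(-1L, seq_len(n - 1) - 1L),
    c1 = c(seq_len(n - 1), -1L), c2 = rep(-1L, n),
    is_term = c(rep(0L, n - 1), 1L),
    stage = c(rep(0L, n - 1), 1L))
  class(tree) <- "cco_tree"
  tree
}

tree_depths <- function(tree) {
  n <- length(tree$parent)
  p <- tree$parent + 1L        # 1-based; 0 marks a root
  has_p <- p > 0L
  depth <- integer(n)
  for (it in seq_len(n + 1L)) {   # fixed point reached within max depth steps
    upd <- integer(n)
    upd[has_p] <- depth[p[has_p]] + 1L
    if (all(upd == depth)) return(depth)
    depth <- upd
  }
  stop("tree_depths: parent links contain a cycle")
}

# segment indices grouped by depth, shallow to deep (for level-wise sweeps)
tree_levels <- function(tree) {
  depth <- tree_depths(tree)
  unname(split(seq_along(depth), depth))
}

# number of terminals at/below each segment (levels: deepest first)
terminals_below <- function(tree, levels_desc) {
  nb <- rep(1L, length(tree$parent))
  c1 <- tree$c1 + 1L; c2 <- tree$c2 + 1L
  for (idx in levels_desc) {
    i1 <- idx[c1[idx] > 0L & c2[idx] == 0L]
    if (length(i1)) nb[i1] <- nb[c1[i1]]
    i2 <- idx[c2[idx] > 0L]
    if (length(i2)) nb[i2] <- nb[c1[i2]] + nb[c2[i2]]
  }
  nb
}

# bottom-up Murray radii from terminal base radii (per-bifurcation gamma);
# levels: deepest first, so children are resolved before their parents
recompute_radii <- function(tree, rbase, levels_desc) {
  r <- rbase
  c1 <- tree$c1 + 1L; c2 <- tree$c2 + 1L; g <- tree$gbif
  for (idx in levels_desc) {
    i1 <- idx[c1[idx] > 0L & c2[idx] == 0L]
    if (length(i1)) r[i1] <- r[c1[i1]]
    i2 <- idx[c2[idx] > 0L]
    if (length(i2)) {
      gg <- g[i2]
      r[i2] <- (r[c1[i2]]^gg + r[c2[i2]]^gg)^(1 / gg)
    }
  }
  r
}

tree_seg_lengths <- function(tree) {
  sqrt((tree$x1 - tree$x0)^2 + (tree$y1 - tree$y0)^2)
}

# root-to-distal-end pressure drop per segment (Pa), given radii (um),
# viscosities (cP) and per-segment flow (m^3/s); levels: shallow to deep
tree_path_dp <- function(tree, r_um, mu_cp, Q, levels_asc) {
  l <- mm_to_m(tree_seg_lengths(tree))
  R <- 8 * (mu_cp * 1e-3) * l / (pi * um_to_m(r_um)^4)
  dp <- R * Q
  cum <- dp
  p1 <- tree$parent + 1L
  for (idx in levels_asc) {
    ip <- idx[p1[idx] > 0L]
    if (length(ip)) cum[ip] <- dp[ip] + cum[p1[ip]]
  }
  cum
}

#' Calibrate a stage's terminal radii to the pressure-drop target
#'
#' Scales the base radii of the given stage's terminals so that the mean
#' root-to-terminal pressure drop equals `dp_target`, under equal terminal
#' flows (`Q_root / n_terminals`) and the diameter-dependent effective
#' viscosity law. The viscosity is iterated to its fixed point starting from
#' `eta` (relative change in the scale factor < 1e-6).
#'
#' @param tree a `cco_tree`.
#' @param stage_id stage whose terminals are calibrated.
#' @param Q_root root flow, m^3/s.
#' @param dp_target pressure drop, mmHg.
#' @param eta viscosity iteration start, cP.
#' @param H_D discharge hematocrit.
#' @param mu_plasma plasma viscosity scaling, cP.
#' @return the tree with updated `rbase`/`radius`, and attribute `rt` (the
#'   calibrated base radius of this stage's terminals, um).
#' @keywords internal
calibrate_tree <- function(tree, stage_id, Q_root, dp_target, eta = 0.36,
                           H_D = 0.45, mu_plasma = 1.0) {
  lv_asc <- tree_levels(tree)
  lv_desc <- rev(lv_asc)
  nb <- terminals_below(tree, lv_desc)
  n_term <- sum(tree$is_term == 1)
  Q <- Q_root * nb / n_term
  sel <- which(tree$is_term == 1 & tree$stage == stage_id)
  if (!length(sel)) sel <- which(tree$is_term == 1)
  target_pa <- mmHg_to_Pa(dp_target)
  mu <- rep(eta, length(tree$x0))
  phi <- 1
  for (it in seq_len(50)) {
    f <- function(lphi) {
      rb <- tree$rbase
      rb[sel] <- rb[sel] * exp(lphi)
      r <- recompute_radii(tree, rb, lv_desc)
      mean(tree_path_dp(tree, r, mu, Q, lv_asc)[sel]) - target_pa
    }
    sol <- stats::uniroot(f, c(-8, 8), extendInt = "downX", tol = 1e-10)
    phi_new <- exp(sol$root)
    rb <- tree$rbase
    rb[sel] <- rb[sel] * phi_new
    r <- recompute_radii(tree, rb, lv_desc)
    mu_new <- mu_plasma * relative_viscosity(2 * r, H_D)
    conv <- abs(phi_new - phi) / phi < 1e-6
    mu <- mu_new
    phi <- phi_new
    if (it > 1 && conv) break
  }
  tree$rbase[sel] <- tree$rbase[sel] * phi
  tree$radius <- recompute_radii(tree, tree$rbase, lv_desc)
  attr(tree, "rt") <- stats::median(tree$rbase[sel])
  tree
}

#' Grow one CCO stage on a tree
#'
#' Adds `n_add` terminal vessels by volume-minimizing constrained insertion
#' (see the package vignette for the optimizer), then calibrates the stage's
#' terminal radii to the stage pressure-drop target.
#'
#' @param tree a `cco_tree` (from `make_arcade_tree` or a previous stage).
#' @param stage_cfg stage configuration (one element of `config$stages`,
#'   fields N_terms, p_pre_capillary, delta, theta_min, gamma, l_fr, nu, f_n).
#' @param region list with `r_in`, `r_out`, `area` (see `stage_region`).
#' @param stage_id integer stage label.
#' @param n_add number of terminals to add.
#' @param side +1 superior tree, -1 inferior tree.
#' @param lognorm list(sigma, mu, r0) radial site law.
#' @param Q_root root flow (m^3/s), for calibration.
#' @param dp_target stage pressure-drop target, mmHg.
#' @param domain `config$domain` list (r_FAZ, disc_x).
#' @param growth `config$growth` list (eta, n_candidates, max_attempts).
#' @param H_D,mu_plasma blood model constants for calibration.
#' @param rt_new provisional base radius for the new terminals (um).
#' @return the grown, calibrated tree; audit records appended to
#'   `attr(tree, "audit")` and `attr(tree, "candidate_log")`.
#' @export
grow_tree <- function(tree, stage_cfg, region, stage_id, n_add, side,
                      lognorm, Q_root, dp_target, domain, growth,
                      H_D = 0.45, mu_plasma = 1.0, rt_new = NULL) {
  if (is.null(rt_new)) {
    prev <- attr(tree, "rt")
    rt_new <- if (is.null(prev)) 10 else prev
  }
  pars <- list(
    n_terms = as.integer(n_add), stage_id = as.integer(stage_id),
    r_in = region$r_in, r_out = region$r_out, r_faz = domain$r_FAZ,
    side = as.numeric(side), x_min = domain$disc_x,
    mu = lognorm$mu, sigma = lognorm$sigma, r0 = lognorm$r0,
    delta = stage_cfg$delta, theta_min = stage_cfg$theta_min,
    gamma = stage_cfg$gamma, nu = stage_cfg$nu, f_n = stage_cfg$f_n,
    l_fr = stage_cfg$l_fr, area = region$area, rt_new = rt_new,
    n_candidates = as.integer(growth$n_candidates),
    max_attempts = as.integer(growth$max_attempts))
  old_audit <- attr(tree, "audit")
  old_log <- attr(tree, "candidate_log")
  res <- .cco_grow_stage(unclass(tree)[c("x0", "y0", "x1", "y1", "radius",
                                         "rbase", "gbif", "parent", "c1",
                                         "c2", "is_term", "stage")], pars)
  out <- res[c("x0", "y0", "x1", "y1", "radius", "rbase", "gbif", "parent",
               "c1", "c2", "is_term", "stage")]
  class(out) <- "cco_tree"
  out <- calibrate_tree(out, stage_id, Q_root, dp_target,
                        eta = growth$eta, H_D = H_D, mu_plasma = mu_plasma)
  audit <- as.data.frame(res$audit)
  attr(out, "audit") <- rbind(old_audit, audit)
  clog <- as.data.frame(res$candidate_log)
  attr(out, "candidate_log") <- rbind(old_log, clog)
  out
}

# ---- full macrovasculature --------------------------------------------------

#' Grow the macrovascular network from sampled arcades
#'
#' Runs the three CCO stages for each of the four trees (superior/inferior,
#' arterial/venous), with arterial pressure-drop targets
#' `p_CRA - p_pre_capillary(stage)` and venous targets
#' `p_pre_capillary(stage) - p_CRV`, CRA flow `v_CRA * pi * r_CRA^2` split
#' equally between the two arterial arcades (likewise CRV), and assembles a
#' single [vascular_network()] with CRA/CRV root stubs.
#'
#' @param arcades landmark set in mm (four curves; see [sample_arcades()]).
#' @param pop list with `r_CRA` (um), `v_CRA` (cm/s), `MAP`, `IOP` (mmHg).
#' @param config run configuration ([default_config()]).
#' @param keep_candidate_log retain per-insertion candidate volumes in meta
#'   (for optimality audits; off by default to save memory).
#' @return a `vascular_network` of kinds artery/vein, plexus SVP, with meta
#'   fields `p_CRA`, `p_CRV`, `OPP`, `Q_CRA_ul_min`, `pop`, and the
#'   bifurcation audit table.
#' @export
grow_macrovasculature <- function(arcades, pop, config = default_config(),
                                  keep_candidate_log = FALSE) {
  pr <- ocular_pressures(pop$MAP, pop$IOP)
  Q_cra <- cms_to_ms(pop$v_CRA) * pi * um_to_m(pop$r_CRA)^2   # m^3/s
  disc <- c(config$domain$disc_x, config$domain$disc_y)
  lognorm <- config$terminal_site
  growth <- config$growth
  hemo <- config$hemo

  specs <- list(
    list(label = "sup_artery", kind = "artery", side = +1),
    list(label = "inf_artery", kind = "artery", side = -1),
    list(label = "sup_vein",   kind = "vein",   side = +1),
    list(label = "inf_vein",   kind = "vein",   side = -1))

  trees <- lapply(specs, function(sp) {
    tree <- make_arcade_tree(disc, arcades[[sp$label]])
    for (s in seq_along(config$stages)) {
      st <- config$stages[[s]]
      reg <- stage_region(config, s)
      n_cur <- sum(tree$is_term == 1)
      n_add <- if (s == 1) max(0L, st$N_terms - n_cur) else st$N_terms
      dp <- if (sp$kind == "artery") pr["p_CRA"] - st$p_pre_capillary
            else st$p_pre_capillary - pr["p_CRV"]
      if (dp <= 0) stop("non-positive stage pressure-drop target")
      tree <- grow_tree(tree, st, reg, s, n_add, sp$side, lognorm,
                        Q_root = Q_cra / 2, dp_target = dp,
                        domain = config$domain, growth = growth,
                        H_D = hemo$H_D, mu_plasma = hemo$mu_plasma)
    }
    tree
  })

  # ---- assemble one network --------------------------------------------
  nodes <- list(); segs <- list(); audits <- list()
  next_node <- 0L; next_seg <- 0L
  root_a <- c(disc[1] - 0.5, disc[2]); root_v <- root_a
  # root and disc nodes: ids 1..4
  nodes[[1]] <- data.frame(
    id = 1:4, x = c(root_a[1], disc[1], root_v[1], disc[1]),
    y = c(root_a[2], disc[2], root_v[2], disc[2]), z = 0,
    kind = c("root", "arterial", "root", "venous"), plexus = "SVP")
  r_crv <- config$population$crv_cra_radius_ratio * pop$r_CRA
  l_cra <- config$population$cra_length
  if (is.null(l_cra)) l_cra <- 10
  segs[[1]] <- data.frame(
    id = 1:2, from = c(1L, 3L), to = c(2L, 4L),
    radius = c(pop$r_CRA, r_crv), length = l_cra,
    kind = c("artery", "vein"), plexus = "SVP",
    is_terminal = FALSE, fixed_resistance = FALSE)
  next_node <- 4L; next_seg <- 2L

  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]; sp <- specs[[ti]]
    n <- length(tree$x0)
    disc_node <- if (sp$kind == "artery") 2L else 4L
    # distal node of each segment gets a fresh id
    nid <- next_node + seq_len(n)
    kind_node <- if (sp$kind == "artery") "arterial" else "venous"
    nodes[[length(nodes) + 1]] <- data.frame(
      id = nid, x = tree$x1, y = tree$y1, z = 0,
      kind = kind_node, plexus = "SVP")
    from <- ifelse(tree$parent >= 0, nid[pmax(tree$parent, 0L) + 1L],
                   disc_node)
    segs[[length(segs) + 1]] <- data.frame(
      id = next_seg + seq_len(n), from = from, to = nid,
      radius = tree$radius, length = tree_seg_lengths(tree),
      kind = sp$kind, plexus = "SVP",
      is_terminal = tree$is_term == 1, fixed_resistance = FALSE)
    a <- attr(tree, "audit")
    if (!is.null(a) && nrow(a)) audits[[length(audits) + 1]] <-
        cbind(tree = sp$label, a)
    next_node <- next_node + n
    next_seg <- next_seg + n
  }

  meta <- list(pop = pop, p_CRA = unname(pr["p_CRA"]),
               p_CRV = unname(pr["p_CRV"]), OPP = unname(pr["OPP"]),
               Q_CRA_ul_min = m3s_to_ulmin(Q_cra),
               cra_segment = 1L, crv_segment = 2L,
               bifurcation_audit = do.call(rbind, audits))
  if (keep_candidate_log)
    meta$candidate_log <- lapply(trees, attr, "candidate_log")
  net <- vascular_network(do.call(rbind, nodes), do.call(rbind, segs), meta)
  net
}
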