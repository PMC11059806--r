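# Poiseuille network hemodynamics with diameter-dependent effective blood
# viscosity, Dirichlet pressures at the central retinal artery and vein, and
# an artificial-compartment closure for extramacular terminals.

#' Ocular boundary pressures
#'
#' `p_CRA = (2/3) * MAP`, `p_CRV = IOP`, `OPP = p_CRA - p_CRV`.
#'
#' @param MAP mean arterial pressure, mmHg.
#' @param IOP intraocular pressure, mmHg.
#' @return named vector `c(p_CRA, p_CRV, OPP)` in mmHg.
#' @export
#' @examples
#' ocular_pressures(84, 11.1)   # 56.0, 11.1, 44.9
ocular_pressures <- function(MAP, IOP) {
  stopifnot(MAP >= 0, IOP >= 0)
  p_cra <- 2 / 3 * MAP
  opp <- p_cra - IOP
  if (opp <= 0) stop("non-perfusing eye: OPP = ", signif(opp, 4), " mmHg <= 0")
  c(p_CRA = p_cra, p_CRV = IOP, OPP = opp)
}

# relative in-vivo viscosity (dimensionless multiple of plasma viscosity)
relative_viscosity <- function(D, H_D = 0.45) {
  if (any(D <= 1.12)) stop("effective viscosity undefined for D <= 1.12 um")
  stopifnot(H_D > 0, H_D < 1)
  mu45 <- 6 * exp(-0.085 * D) + 3.2 - 2.44 * exp(-0.06 * D^0.645)
  wall <- (D / (D - 1.12))^2
  if (H_D == 0.45) {
    hfac <- 1
  } else {
    C <- (0.8 + exp(-0.075 * D)) * (-1 + 1 / (1 + 1e-11 * D^12)) +
      1 / (1 + 1e-11 * D^12)
    hfac <- ((1 - H_D)^C - 1) / ((1 - 0.45)^C - 1)
  }
  (1 + (mu45 - 1) * hfac * wall) * wall
}

#' Effective blood viscosity
#'
#' Empirical in-vivo viscosity law accounting for the Fåhræus–Lindqvist
#' effect: diameter- and hematocrit-dependent relative viscosity times the
#' plasma viscosity. At `H_D = 0.45` the hematocrit factor is identically 1;
#' as `D` grows the law tends to `3.2 * mu_plasma`.
#'
#' @param D lumen diameter, um (> 1.12).
#' @param H_D discharge hematocrit in (0, 1).
#' @param mu_plasma plasma viscosity scale, cP.
#' @return viscosity in cP.
#' @export
#' @examples
#' effective_viscosity(10)   # ~5.92
effective_viscosity <- function(D, H_D = 0.45, mu_plasma = 1.0) {
  mu_plasma * relative_viscosity(D, H_D)
}

#' Poiseuille segment resistance
#'
#' `R = 8 * mu * l / (pi * r^4)`, returned in mmHg*s/mL.
#'
#' @param r radius, um.
#' @param l length, mm.
#' @param mu viscosity, cP.
#' @return resistance, mmHg*s/mL.
#' @export
segment_resistance <- function(r, l, mu) {
  stopifnot(all(r > 0), all(l > 0), all(mu > 0))
  R_si <- 8 * (mu * 1e-3) * mm_to_m(l) / (pi * um_to_m(r)^4)
  SI_to_mmHgsml(R_si)
}

# per-segment SI conductance (m^3/s/Pa)
segment_conductance_si <- function(net, hemo) {
  s <- net$segments
  g <- numeric(nrow(s))
  art <- s$fixed_resistance
  if (any(art)) g[art] <- 1 / mmHgsml_to_SI(hemo$R_compartment)
  if (any(!art)) {
    mu <- effective_viscosity(2 * s$radius[!art], hemo$H_D, hemo$mu_plasma)
    R <- 8 * (mu * 1e-3) * mm_to_m(s$length[!art]) /
      (pi * um_to_m(s$radius[!art])^4)
    g[!art] <- 1 / R
  }
  g
}

#' Solve network blood flow
#'
#' Assembles the nodal conductance (weighted Laplacian) system with
#' per-segment Poiseuille conductances (artificial compartment segments use
#' the fixed resistance `hemo$R_compartment`), applies Dirichlet pressures at
#' the CRA and CRV root nodes, and solves the sparse SPD system. Because the
#' discharge hematocrit is constant the viscosity depends on diameter only
#' and the system is linear: one direct solve, no iteration.
#'
#' @param net a `vascular_network` (assembled; see [connect_network()]).
#' @param p_CRA,p_CRV boundary pressures, mmHg.
#' @param hemo hemodynamics configuration (`config$hemo`).
#' @return object of class `hemo_solution`: `nodes` (id, pressure mmHg),
#'   `segments` (id, Q uL/min signed from->to, v cm/s, dp mmHg), and summary
#'   scalars `retinal_blood_flow` (uL/min), `macular_flow_fraction` (%),
#'   `v_CRA` (cm/s), `p_CRA`, `p_CRV`, `OPP`, plus the maximum relative
#'   Kirchhoff residual `kirchhoff_residual`.
#' @export
solve_flow <- function(net, p_CRA, p_CRV, hemo = default_config()$hemo) {
  s <- net$segments; n <- net$nodes
  stopifnot(nrow(s) > 0, p_CRA > p_CRV)
  nid <- n$id
  i <- match(s$from, nid); j <- match(s$to, nid)
  g <- segment_conductance_si(net, hemo)

  root_a <- n$id[n$kind == "root"][1]
  roots <- n$id[n$kind == "root"]
  if (length(roots) < 2) stop("network must contain CRA and CRV root nodes")
  # identify arterial vs venous root by incident segment kind
  rk <- vapply(roots, function(rid) {
    k <- s$kind[s$from == rid | s$to == rid]
    if (any(k == "artery")) "artery" else "vein"
  }, character(1))
  cra_node <- match(roots[rk == "artery"][1], nid)
  crv_node <- match(roots[rk == "vein"][1], nid)

  nn <- nrow(n)
  L <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(-g, -g),
                            dims = c(nn, nn))
  diagv <- -Matrix::rowSums(L)
  L <- L + Matrix::Diagonal(nn, diagv)
  fixed <- c(cra_node, crv_node)
  pfix <- mmHg_to_Pa(c(p_CRA, p_CRV))
  free <- setdiff(seq_len(nn), fixed)
  rhs <- -as.numeric(L[free, fixed, drop = FALSE] %*% pfix)
  Lff <- L[free, free, drop = FALSE]
  ch <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(Lff), LDL = FALSE, perm = TRUE),
    error = function(e) NULL)
  if (is.null(ch)) {
    comp <- igraph::components(igraph::graph_from_edgelist(
      cbind(i, j), directed = FALSE))
    orphan <- nid[comp$membership != comp$membership[cra_node]]
    stop("singular flow system; nodes disconnected from the CRA: ",
         paste(utils::head(orphan, 10), collapse = ", "),
         if (length(orphan) > 10) " ..." else "")
  }
  p <- numeric(nn)
  p[fixed] <- pfix
  p[free] <- as.numeric(Matrix::solve(ch, rhs))
  # one step of iterative refinement tightens the Kirchhoff residual
  res <- numeric(nn)
  res[free] <- rhs - as.numeric(Lff %*% p[free])
  p[free] <- p[free] + as.numeric(Matrix::solve(ch, res[free]))

  Q_si <- g * (p[i] - p[j])                      # signed from -> to
  v_ms <- Q_si / (pi * um_to_m(s$radius)^2)
  # Kirchhoff residual at interior nodes, relative to total inflow
  net_flow <- numeric(nn)
  agg <- rowsum(c(-Q_si, Q_si), c(i, j))
  net_flow[as.integer(rownames(agg))] <- agg[, 1]
  rbf_si <- abs(net_flow[cra_node])
  kirch <- max(abs(net_flow[-fixed])) / rbf_si

  # macular inflow: net arterial flow crossing r_perifovea inward. Summing
  # signed crossings makes arteries that merely pass through the disk (in
  # and back out, e.g. an arcade skirting the macula) cancel out, leaving
  # the arterial flow actually delivered inside the disk.
  rad_from <- sqrt(n$x[i]^2 + n$y[i]^2)
  rad_to <- sqrt(n$x[j]^2 + n$y[j]^2)
  r_peri <- if (!is.null(net$meta$r_perifovea)) net$meta$r_perifovea else 3
  cross <- s$kind == "artery" &
    ((rad_from > r_peri & rad_to <= r_peri) |
     (rad_to > r_peri & rad_from <= r_peri))
  inward <- ifelse(rad_from > rad_to, Q_si, -Q_si)   # + if flowing inward
  mac_in_si <- sum(inward[cross])
  mff <- 100 * mac_in_si / rbf_si

  cra_seg <- net$meta$cra_segment
  r_cra <- if (!is.null(cra_seg)) s$radius[match(cra_seg, s$id)]
           else max(s$radius[s$kind == "artery"])
  v_cra <- ms_to_cms(rbf_si / (pi * um_to_m(r_cra)^2))

  structure(list(
    nodes = data.frame(id = nid, pressure = Pa_to_mmHg(p)),
    segments = data.frame(id = s$id, Q = m3s_to_ulmin(Q_si),
                          v = ms_to_cms(v_ms),
                          dp = Pa_to_mmHg(abs(p[i] - p[j]))),
    retinal_blood_flow = m3s_to_ulmin(rbf_si),
    macular_flow_fraction = mff,
    v_CRA = v_cra,
    p_CRA = p_CRA, p_CRV = p_CRV, OPP = p_CRA - p_CRV,
    kirchhoff_residual = kirch), class = "hemo_solution")
}

#' @export
print.hemo_solution <- function(x, ...) {
  cat(sprintf(paste0("<hemo_solution> RBF %.2f uL/min | macular flow ",
                     "fraction %.2f%% | v_CRA %.2f cm/s | OPP %.1f mmHg\n"),
              x$retinal_blood_flow, x$macular_flow_fraction, x$v_CRA, x$OPP))
  invisible(x)
}

#' Perfusion summary scalars
#'
#' @param solution a `hemo_solution`.
#' @return named vector: retinal blood flow (uL/min), macular flow fraction
#'   (%), CRA velocity (cm/s).
#' @export
perfusion_summary <- function(solution) {
  c(retinal_blood_flow = solution$retinal_blood_flow,
    macular_flow_fraction = solution$macular_flow_fraction,
    v_CRA = solution$v_CRA)
}
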