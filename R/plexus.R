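# Voronoi capillary beds for the three macular plexuses, pruning against the
# macrovasculature, tree-to-bed and interplexus wiring, diameter assignment
# and smoothing, and diffusion-based flow orientation.

#' Build a Voronoi capillary bed
#'
#' Seeds are sampled uniformly in the macular disk; their Delaunay
#' triangulation's triangle centroids generate a second point set whose
#' Voronoi diagram forms the capillary mesh (polygon edges = capillaries).
#' Edges are clipped to the disk, edges intersecting the FAZ disk are
#' removed, and the largest connected component is retained.
#'
#' @param N_seeds number of seed points (>= 4).
#' @param disk_radius bed disk radius, mm.
#' @param r_FAZ foveal avascular zone radius, mm.
#' @param plexus one of "SVP", "ICP", "DCP".
#' @param z plexus depth, um.
#' @return object of class `capillary_bed`: `vertices` (matrix x, y in mm),
#'   `edges` (two-column matrix of vertex indices), `z`, `plexus`.
#' @export
build_voronoi_bed <- function(N_seeds, disk_radius, r_FAZ, plexus = "SVP",
                              z = 0) {
  stopifnot(N_seeds >= 4, disk_radius > 0, r_FAZ >= 0, r_FAZ < disk_radius)
  th <- stats::runif(N_seeds, 0, 2 * pi)
  rr <- disk_radius * sqrt(stats::runif(N_seeds))
  sx <- rr * cos(th); sy <- rr * sin(th)
  tri_of <- function(x, y) {
    for (attempt in 1:3) {
      tm <- tryCatch(interp::tri.mesh(x, y, duplicate = "remove"),
                     error = function(e) NULL)
      if (!is.null(tm)) return(tm)
      message("build_voronoi_bed: degenerate seeds, re-jittering")
      x <- x + stats::rnorm(length(x), 0, 1e-6)
      y <- y + stats::rnorm(length(y), 0, 1e-6)
    }
    stop("build_voronoi_bed: triangulation failed after jitter")
  }
  tm1 <- tri_of(sx, sy)
  t1 <- interp::triangles(tm1)
  cx <- (tm1$x[t1[, "node1"]] + tm1$x[t1[, "node2"]] +
           tm1$x[t1[, "node3"]]) / 3
  cy <- (tm1$y[t1[, "node1"]] + tm1$y[t1[, "node2"]] +
           tm1$y[t1[, "node3"]]) / 3
  tm2 <- tri_of(cx, cy)
  t2 <- interp::triangles(tm2)
  # Voronoi vertices of the centroid set = circumcenters of its Delaunay
  # triangles; Voronoi edges join circumcenters of neighbouring triangles.
  ax <- tm2$x[t2[, "node1"]]; ay <- tm2$y[t2[, "node1"]]
  bx <- tm2$x[t2[, "node2"]]; by <- tm2$y[t2[, "node2"]]
  ccx <- tm2$x[t2[, "node3"]]; ccy <- tm2$y[t2[, "node3"]]
  d <- 2 * (ax * (by - ccy) + bx * (ccy - ay) + ccx * (ay - by))
  d[abs(d) < 1e-14] <- NA
  ux <- ((ax^2 + ay^2) * (by - ccy) + (bx^2 + by^2) * (ccy - ay) +
           (ccx^2 + ccy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (ccx - bx) + (bx^2 + by^2) * (ax - ccx) +
           (ccx^2 + ccy^2) * (bx - ax)) / d
  ntri <- nrow(t2)
  nb <- cbind(t2[, "tr1"], t2[, "tr2"], t2[, "tr3"])
  e1 <- rep(seq_len(ntri), 3); e2 <- as.integer(nb)
  keep <- !is.na(e2) & e2 > e1 & !is.na(ux[e1]) & !is.na(ux[pmax(e2, 1)])
  edges <- cbind(e1[keep], e2[keep])

  verts <- cbind(x = ux, y = uy)
  # drop zero-length edges (cocircular centroids)
  len2 <- (verts[edges[, 1], 1] - verts[edges[, 2], 1])^2 +
    (verts[edges[, 1], 2] - verts[edges[, 2], 2])^2
  edges <- edges[len2 > 1e-18, , drop = FALSE]

  # ---- clip to the disk -------------------------------------------------
  rad2 <- verts[, 1]^2 + verts[, 2]^2
  R2 <- disk_radius^2
  in1 <- rad2[edges[, 1]] <= R2
  in2 <- rad2[edges[, 2]] <= R2
  keep_full <- in1 & in2
  part <- xor(in1, in2)
  if (any(part)) {
    pe <- edges[part, , drop = FALSE]
    pin <- ifelse(in1[part], pe[, 1], pe[, 2])
    pout <- ifelse(in1[part], pe[, 2], pe[, 1])
    p0 <- verts[pin, , drop = FALSE]; p1 <- verts[pout, , drop = FALSE]
    dxy <- p1 - p0
    a <- rowSums(dxy^2)
    b <- 2 * rowSums(p0 * dxy)
    cc <- rowSums(p0^2) - R2
    t <- (-b + sqrt(pmax(b^2 - 4 * a * cc, 0))) / (2 * a)
    newv <- p0 + t * dxy
    newid <- nrow(verts) + seq_len(nrow(newv))
    verts <- rbind(verts, newv)
    edges <- rbind(edges[keep_full, , drop = FALSE], cbind(pin, newid))
  } else {
    edges <- edges[keep_full, , drop = FALSE]
  }

  # ---- FAZ exclusion ----------------------------------------------------
  if (r_FAZ > 0 && nrow(edges)) {
    d_or <- seg_point_dist(verts[edges[, 1], , drop = FALSE],
                           verts[edges[, 2], , drop = FALSE], c(0, 0))
    edges <- edges[d_or >= r_FAZ, , drop = FALSE]
  }

  bed_largest_component(
    structure(list(vertices = verts, edges = edges, z = z, plexus = plexus),
              class = "capillary_bed"))
}

# distance from point p to segments a-b (vectorized over rows)
seg_point_dist <- function(a, b, p) {
  vx <- b[, 1] - a[, 1]; vy <- b[, 2] - a[, 2]
  wx <- p[1] - a[, 1]; wy <- p[2] - a[, 2]
  vv <- vx^2 + vy^2
  t <- ifelse(vv > 0, (wx * vx + wy * vy) / vv, 0)
  t <- pmin(pmax(t, 0), 1)
  sqrt((wx - t * vx)^2 + (wy - t * vy)^2)
}

# keep only the largest connected component; compact vertex indices
bed_largest_component <- function(bed) {
  if (!nrow(bed$edges)) return(bed)
  g <- igraph::graph_from_edgelist(bed$edges, directed = FALSE)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  keepv <- which(comp$membership == big)
  remap <- rep(NA_integer_, nrow(bed$vertices))
  remap[keepv] <- seq_along(keepv)
  ke <- !is.na(remap[bed$edges[, 1]]) & !is.na(remap[bed$edges[, 2]])
  bed$edges <- cbind(remap[bed$edges[ke, 1]], remap[bed$edges[ke, 2]])
  bed$vertices <- bed$vertices[keepv, , drop = FALSE]
  bed
}

#' @export
print.capillary_bed <- function(x, ...) {
  cat("<capillary_bed> ", x$plexus, " z=", x$z, "um: ",
      nrow(x$vertices), " vertices, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Prune capillaries near macrovessels
#'
#' Removes capillary edges that intersect the stadium (segment dilated by
#' its lumen radius) of any macrovascular segment, reproducing the
#' capillary-free region around arterioles. The corridors carved along the
#' macrovessels can split the bed into pockets; all pockets of at least
#' `min_vertices` vertices are kept (each is later wired to the trees by
#' [connect_network()], which drops any pocket left without an attachment).
#'
#' @param bed a `capillary_bed` (SVP).
#' @param macro_net the macrovascular `vascular_network`, or a list with
#'   `coords` (n x 4 matrix x0,y0,x1,y1 in mm) and `radius_mm`.
#' @param min_vertices smallest connected pocket retained.
#' @return the pruned bed.
#' @export
prune_capillaries_near_macro <- function(bed, macro_net, min_vertices = 4) {
  if (inherits(macro_net, "vascular_network")) {
    sel <- macro_net$segments$kind %in% c("artery", "vein")
    coords <- segment_coords(macro_net, macro_net$segments[sel, ])
    rad <- macro_net$segments$radius[sel] / 1000
  } else {
    coords <- macro_net$coords
    rad <- macro_net$radius_mm
  }
  if (is.null(coords) || nrow(coords) == 0 || !nrow(bed$edges)) return(bed)
  q <- cbind(bed$vertices[bed$edges[, 1], 1], bed$vertices[bed$edges[, 1], 2],
             bed$vertices[bed$edges[, 2], 1], bed$vertices[bed$edges[, 2], 2])
  hit <- .segments_hit_stadia(q, coords, rad)
  bed$edges <- bed$edges[!hit, , drop = FALSE]
  bed_drop_small_components(bed, min_vertices)
}

# drop connected pockets smaller than min_vertices; compact vertex indices
bed_drop_small_components <- function(bed, min_vertices) {
  if (!nrow(bed$edges)) return(bed)
  g <- igraph::graph_from_edgelist(bed$edges, directed = FALSE)
  comp <- igraph::components(g)
  keepc <- which(comp$csize >= min_vertices)
  keepv <- which(comp$membership %in% keepc)
  keepv <- keepv[keepv <= nrow(bed$vertices)]
  remap <- rep(NA_integer_, nrow(bed$vertices))
  remap[keepv] <- seq_along(keepv)
  ke <- !is.na(remap[bed$edges[, 1]]) & !is.na(remap[bed$edges[, 2]])
  bed$edges <- cbind(remap[bed$edges[ke, 1]], remap[bed$edges[ke, 2]])
  bed$vertices <- bed$vertices[keepv, , drop = FALSE]
  bed
}

#' Assemble the full network: trees + capillary beds + compartment
#'
#' Wires the macrovasculature to the capillary beds: every macular terminal
#' vessel and a random fraction `alpha` of macular arteriole/venule segments
#' connect to the nearest SVP capillary vertex; a fraction `frac_deep` of
#' macular arterioles and venules gains a midpoint bifurcation descending to
#' the nearest ICP vertex, each such branch immediately continuing to the
#' nearest DCP vertex. Remaining (extramacular) terminal arteries and veins
#' are closed through a compartment node via artificial fixed-resistance
#' segments. Dead-end capillary chains are pruned.
#'
#' @param macro_net macrovascular `vascular_network`.
#' @param beds named list of `capillary_bed`s (`SVP`, `ICP`, `DCP`); `ICP`
#'   and `DCP` may be omitted.
#' @param alpha tree-to-bed connection fraction in the macula.
#' @param frac_deep fraction of macular arterioles/venules bifurcating down.
#' @param config run configuration (domain radii, capillary radius).
#' @return the assembled `vascular_network`.
#' @export
connect_network <- function(macro_net, beds, alpha = 0.4, frac_deep = 0.3,
                            config = default_config()) {
  stopifnot(alpha >= 0, alpha <= 1, frac_deep >= 0, frac_deep <= 1)
  r_peri <- config$domain$r_perifovea
  r_cap <- config$plexus$SVP$r_capillary
  nodes <- macro_net$nodes
  segs <- macro_net$segments
  next_node <- max(nodes$id)
  next_seg <- max(segs$id)

  new_nodes <- list(); new_segs <- list()
  add_nodes <- function(df) new_nodes[[length(new_nodes) + 1]] <<- df
  add_segs <- function(df) new_segs[[length(new_segs) + 1]] <<- df

  # ---- bed nodes/segments ----------------------------------------------
  bed_node_ids <- list()
  for (nm in names(beds)) {
    bed <- beds[[nm]]
    ids <- next_node + seq_len(nrow(bed$vertices))
    bed_node_ids[[nm]] <- ids
    add_nodes(data.frame(id = ids, x = bed$vertices[, 1],
                         y = bed$vertices[, 2], z = bed$z,
                         kind = "capillary", plexus = bed$plexus))
    next_node <- next_node + nrow(bed$vertices)
    if (nrow(bed$edges)) {
      v1 <- bed$edges[, 1]; v2 <- bed$edges[, 2]
      len <- sqrt((bed$vertices[v1, 1] - bed$vertices[v2, 1])^2 +
                    (bed$vertices[v1, 2] - bed$vertices[v2, 2])^2)
      sid <- next_seg + seq_len(nrow(bed$edges))
      add_segs(data.frame(id = sid, from = ids[v1], to = ids[v2],
                          radius = config$plexus[[nm]]$r_capillary,
                          length = len, kind = "capillary",
                          plexus = bed$plexus, is_terminal = FALSE,
                          fixed_resistance = FALSE))
      next_seg <- next_seg + nrow(bed$edges)
    }
  }

  # ---- macular tree segments -------------------------------------------
  # terminals count as macular by their tip (the node that gets wired or
  # closed): a tip inside the disk must never carry a compartment closure,
  # or the artificial path would short-circuit flow across the macular
  # boundary. Non-terminal segments (whose midpoint gains the connection)
  # are classified by that midpoint.
  mid <- segment_midpoints(macro_net)
  is_tree <- segs$kind %in% c("artery", "vein")
  in_mac <- sqrt(mid[, 1]^2 + mid[, 2]^2) <= r_peri
  tipi <- match(segs$to, nodes$id)
  tip_in <- sqrt(nodes$x[tipi]^2 + nodes$y[tipi]^2) <= r_peri
  term_mac <- which(is_tree & tip_in & segs$is_terminal)
  nonterm_mac <- which(is_tree & in_mac & !segs$is_terminal)

  # alpha sample and deep sample, per vessel kind, without replacement
  pick_frac <- function(idx, frac) {
    if (!length(idx) || frac <= 0) return(integer(0))
    k <- round(frac * length(idx))
    if (k == 0) return(integer(0))
    idx[sample.int(length(idx), k)]
  }
  alpha_sel <- c(pick_frac(nonterm_mac[segs$kind[nonterm_mac] == "artery"],
                           alpha),
                 pick_frac(nonterm_mac[segs$kind[nonterm_mac] == "vein"],
                           alpha))
  deep_sel <- c(pick_frac(nonterm_mac[segs$kind[nonterm_mac] == "artery"],
                          frac_deep),
                pick_frac(nonterm_mac[segs$kind[nonterm_mac] == "vein"],
                          frac_deep))

  # ---- midpoint splits for selected segments ----------------------------
  split_sel <- sort(unique(c(alpha_sel, deep_sel)))
  mid_node_of <- integer(nrow(segs))
  if (length(split_sel)) {
    mids <- mid[split_sel, , drop = FALSE]
    ids <- next_node + seq_along(split_sel)
    mid_node_of[split_sel] <- ids
    kindn <- ifelse(segs$kind[split_sel] == "artery", "arterial", "venous")
    add_nodes(data.frame(id = ids, x = mids[, 1], y = mids[, 2], z = 0,
                         kind = kindn, plexus = "SVP"))
    next_node <- next_node + length(split_sel)
    # second halves: midpoint -> original distal node
    sid <- next_seg + seq_along(split_sel)
    add_segs(data.frame(id = sid, from = ids, to = segs$to[split_sel],
                        radius = segs$radius[split_sel],
                        length = segs$length[split_sel] / 2,
                        kind = segs$kind[split_sel], plexus = "SVP",
                        is_terminal = FALSE, fixed_resistance = FALSE))
    next_seg <- next_seg + length(split_sel)
    # first halves: original from -> midpoint (edit in place)
    segs$to[split_sel] <- ids
    segs$length[split_sel] <- segs$length[split_sel] / 2
  }

  # ---- connections to the SVP bed --------------------------------------
  svp_ids <- bed_node_ids$SVP
  svp_xy <- beds$SVP$vertices
  connect_to_svp <- function(node_ids, xy) {
    nn <- FNN::get.knnx(svp_xy, xy, k = 1)
    tgt <- svp_ids[nn$nn.index[, 1]]
    len <- pmax(nn$nn.dist[, 1], 1e-6)
    sid <- next_seg + seq_along(node_ids)
    add_segs(data.frame(id = sid, from = node_ids, to = tgt,
                        radius = 2 * r_cap, length = len,
                        kind = "capillary", plexus = "SVP",
                        is_terminal = FALSE, fixed_resistance = FALSE))
    next_seg <<- next_seg + length(node_ids)
  }
  if (length(term_mac)) {
    tn <- segs$to[term_mac]
    idx <- match(tn, nodes$id)
    connect_to_svp(tn, cbind(nodes$x[idx], nodes$y[idx]))
  }
  if (length(alpha_sel)) {
    ids <- mid_node_of[alpha_sel]
    connect_to_svp(ids, mid[alpha_sel, , drop = FALSE])
  }

  # ---- interplexus descenders (SVP -> ICP -> DCP) -----------------------
  n_desc <- 0L
  if (length(deep_sel) && !is.null(beds$ICP)) {
    ids <- mid_node_of[deep_sel]
    xy <- mid[deep_sel, , drop = FALSE]
    nn_icp <- FNN::get.knnx(beds$ICP$vertices, xy, k = 1)
    icp_tgt <- bed_node_ids$ICP[nn_icp$nn.index[, 1]]
    dz1 <- abs(beds$ICP$z - 0) / 1000          # um -> mm
    sid <- next_seg + seq_along(ids)
    add_segs(data.frame(id = sid, from = ids, to = icp_tgt,
                        radius = 2 * r_cap, length = dz1,
                        kind = "capillary", plexus = "none",
                        is_terminal = FALSE, fixed_resistance = FALSE))
    next_seg <- next_seg + length(ids)
    n_desc <- length(ids)
    if (!is.null(beds$DCP)) {
      icp_xy <- beds$ICP$vertices[nn_icp$nn.index[, 1], , drop = FALSE]
      nn_dcp <- FNN::get.knnx(beds$DCP$vertices, icp_xy, k = 1)
      dcp_tgt <- bed_node_ids$DCP[nn_dcp$nn.index[, 1]]
      dz2 <- abs(beds$DCP$z - beds$ICP$z) / 1000
      sid <- next_seg + seq_along(ids)
      add_segs(data.frame(id = sid, from = icp_tgt, to = dcp_tgt,
                          radius = 2 * r_cap, length = dz2,
                          kind = "capillary", plexus = "none",
                          is_terminal = FALSE, fixed_resistance = FALSE))
      next_seg <- next_seg + length(ids)
    }
  }

  # ---- compartment closure for extramacular terminals -------------------
  all_segs <- rbind(segs, do.call(rbind, new_segs))
  all_nodes <- rbind(nodes, do.call(rbind, new_nodes))
  term_idx <- which(all_segs$is_terminal)
  term_nodes <- all_segs$to[term_idx]
  # a terminal is open if its distal node has no further connections
  deg <- table(c(all_segs$from, all_segs$to))
  open <- term_nodes[deg[as.character(term_nodes)] == 1]
  open_kind <- all_segs$kind[term_idx][deg[as.character(term_nodes)] == 1]
  comp_id <- next_node + 1L
  all_nodes <- rbind(all_nodes, data.frame(
    id = comp_id, x = 0, y = -(config$domain$r_retina + 5), z = 0,
    kind = "compartment", plexus = "none"))
  if (length(open)) {
    sid <- next_seg + seq_along(open)
    all_segs <- rbind(all_segs, data.frame(
      id = sid, from = ifelse(open_kind == "artery", open, comp_id),
      to = ifelse(open_kind == "artery", comp_id, open),
      radius = 10, length = 1, kind = "artificial", plexus = "none",
      is_terminal = FALSE, fixed_resistance = TRUE))
    next_seg <- next_seg + length(open)
  }

  net <- vascular_network(all_nodes, all_segs, macro_net$meta,
                          validate = FALSE)
  net$meta$r_perifovea <- r_peri
  net$meta$alpha <- alpha
  net$meta$frac_deep <- frac_deep
  net$meta$n_alpha_connected <- length(alpha_sel)
  net$meta$n_alpha_eligible <- length(nonterm_mac)
  net$meta$n_descenders <- n_desc
  net <- drop_unfed_capillary_components(net)
  net <- prune_dead_end_capillaries(net)
  validate_network(net)
  net
}

# remove capillary pockets with no path to the trees: any connected component
# of the vessel graph consisting solely of capillary nodes is unperfusable
# (no Dirichlet node reaches it) and is dropped before the flow solve
drop_unfed_capillary_components <- function(net) {
  s <- net$segments[net$segments$kind != "artificial", ]
  if (!nrow(s)) return(net)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(cbind(s$from, s$to)), ncol = 2), directed = FALSE)
  comp <- igraph::components(g)$membership
  vid <- as.integer(igraph::V(g)$name)
  kind <- net$nodes$kind[match(vid, net$nodes$id)]
  fed <- unique(comp[kind != "capillary"])
  drop_nodes <- vid[!(comp %in% fed)]
  if (length(drop_nodes)) {
    keep <- !(net$segments$from %in% drop_nodes |
                net$segments$to %in% drop_nodes)
    net$segments <- net$segments[keep, , drop = FALSE]
    net$nodes <- net$nodes[!net$nodes$id %in% drop_nodes, , drop = FALSE]
  }
  net
}

# iteratively remove degree-1 capillary nodes (dead-end stubs); tree,
# compartment and root nodes are never removed
prune_dead_end_capillaries <- function(net) {
  repeat {
    deg <- table(c(net$segments$from, net$segments$to))
    degv <- integer(max(net$nodes$id))
    degv[as.integer(names(deg))] <- as.integer(deg)
    drop_nodes <- net$nodes$id[net$nodes$kind == "capillary" &
                                 degv[net$nodes$id] <= 1]
    if (!length(drop_nodes)) break
    keep <- !(net$segments$from %in% drop_nodes |
                net$segments$to %in% drop_nodes)
    net$segments <- net$segments[keep, , drop = FALSE]
    net$nodes <- net$nodes[!net$nodes$id %in% drop_nodes, , drop = FALSE]
  }
  net
}

#' Assign and smooth vessel diameters
#'
#' Capillary segments receive radius `r_capillary`, doubled where the
#' segment touches an arteriole or venule; one smoothing pass then replaces
#' every vessel segment's diameter by the mean of its own and its
#' node-adjacent same-kind segments' pre-pass diameters (a contraction: the
#' diameter range can only shrink). Smoothing does not mix vessel kinds:
#' capillary diameters stay at `r_capillary`/`2 r_capillary` even where they
#' plug into a much wider arteriole, and arteriole diameters are smoothed
#' along the tree only. Artificial compartment segments are untouched, and
#' so are the CRA/CRV feeding stubs: their radii are boundary data (the
#' sampled central-vessel calibres), not retinal vessels to be smoothed.
#'
#' @param net assembled `vascular_network`.
#' @param r_capillary baseline capillary radius, um.
#' @return the network with updated radii.
#' @export
assign_and_smooth_diameters <- function(net, r_capillary = 2.5) {
  s <- net$segments
  vessel <- s$kind != "artificial"
  cap <- s$kind == "capillary"
  # nodes touched by arterioles/venules
  tree_nodes <- unique(c(s$from[s$kind %in% c("artery", "vein")],
                         s$to[s$kind %in% c("artery", "vein")]))
  s$radius[cap] <- r_capillary
  touches <- cap & (s$from %in% tree_nodes | s$to %in% tree_nodes)
  s$radius[touches] <- 2 * r_capillary

  d <- 2 * s$radius
  nmax <- max(net$nodes$id)
  newd <- d
  for (kd in c("artery", "vein", "capillary")) {
    grp <- s$kind == kd
    if (!any(grp)) next
    sum_at <- numeric(nmax); cnt_at <- numeric(nmax)
    f <- s$from[grp]; t <- s$to[grp]; dv <- d[grp]
    agg <- rowsum(c(dv, dv), c(f, t))
    sum_at[as.integer(rownames(agg))] <- agg[, 1]
    aggc <- rowsum(rep(1, 2 * length(dv)), c(f, t))
    cnt_at[as.integer(rownames(aggc))] <- aggc[, 1]
    neigh_sum <- sum_at[s$from[grp]] + sum_at[s$to[grp]] - 2 * d[grp]
    neigh_cnt <- cnt_at[s$from[grp]] + cnt_at[s$to[grp]] - 2
    newd[grp] <- (d[grp] + neigh_sum) / (1 + neigh_cnt)
  }
  s$radius <- newd / 2
  # keep the CRA/CRV stub calibres exactly as sampled
  stubs <- c(net$meta$cra_segment, net$meta$crv_segment)
  if (length(stubs)) {
    m <- match(stubs, s$id)
    s$radius[m] <- net$segments$radius[m]
  }
  net$segments <- s
  net
}

#' Orient capillary flow by graph diffusion
#'
#' Solves the clamped Laplace problem on the vessel graph: every arterial
#' node (including the arterial root) is held at potential 1, every venous
#' node at 0, and the capillary node potentials are the fixed point of the
#' nodal diffusion update `u <- u - tau * L u` (solved directly as the
#' discrete Laplace system). Every capillary segment is then directed from
#' higher to lower potential, breaking exact ties by node index so the
#' direction field is induced by a strict total order on nodes; the oriented
#' capillary graph is therefore acyclic, which the function verifies.
#' Capillary nodes unreachable from any clamped node keep the neutral
#' potential 0.5.
#'
#' @param net assembled `vascular_network`.
#' @return the network with capillary segments reordered so `from` is
#'   upstream; node potentials in `net$nodes$potential`; `meta$oriented`
#'   set to TRUE.
#' @export
orient_capillary_flow <- function(net) {
  n <- net$nodes; s <- net$segments
  vessel <- s$kind != "artificial"
  i <- match(s$from[vessel], n$id); j <- match(s$to[vessel], n$id)
  nn <- nrow(n)
  u <- rep(NA_real_, nn)
  u[n$kind == "arterial"] <- 1
  u[n$kind == "venous"] <- 0
  u[n$kind == "compartment"] <- 0
  # roots clamp to their tree's value (identified via the incident segment)
  for (rid in which(n$kind == "root")) {
    k <- s$kind[s$from == n$id[rid] | s$to == n$id[rid]]
    u[rid] <- if (any(k == "vein")) 0 else 1
  }
  fixed <- which(!is.na(u))
  # only solve on components reachable from a clamped node (others: 0.5)
  g0 <- igraph::graph_from_edgelist(cbind(i, j), directed = FALSE)
  if (igraph::vcount(g0) < nn)
    g0 <- igraph::add_vertices(g0, nn - igraph::vcount(g0))
  comp <- igraph::components(g0)$membership
  free <- setdiff(which(comp %in% unique(comp[fixed])), fixed)
  if (length(free)) {
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(nn, nn))
    L <- Matrix::Diagonal(nn, Matrix::rowSums(A)) - A
    rhs <- -as.numeric(L[free, fixed, drop = FALSE] %*% u[fixed])
    sol <- Matrix::solve(Matrix::forceSymmetric(L[free, free, drop = FALSE]),
                         rhs)
    u[free] <- as.numeric(sol)
  }
  u[is.na(u)] <- 0.5
  # direct capillary edges from high to low key, key = (potential, index):
  # a strict total order on nodes, so ties cannot create directed cycles
  cap <- which(s$kind == "capillary")
  ii <- match(s$from[cap], n$id); jj <- match(s$to[cap], n$id)
  ui <- u[ii]; uj <- u[jj]
  swap <- cap[uj > ui | (uj == ui & jj > ii)]
  if (length(swap)) {
    tmp <- s$from[swap]
    s$from[swap] <- s$to[swap]
    s$to[swap] <- tmp
  }
  net$segments <- s
  net$nodes$potential <- u
  net$meta$oriented <- TRUE
  # acyclicity audit on the oriented capillary graph
  sc <- s[s$kind == "capillary", ]
  g <- igraph::graph_from_edgelist(
    matrix(as.character(cbind(sc$from, sc$to)), ncol = 2), directed = TRUE)
  if (!igraph::is_dag(g))
    stop("orient_capillary_flow: residual cycle in oriented capillary graph")
  net
}

#' Node potentials of the orientation diffusion (for audits)
#' @param net oriented network.
#' @return numeric vector aligned with `net$nodes`.
#' @export
capillary_potentials <- function(net) net$nodes$potential
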