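# Voronoi capillary beds, pruning, wiring, diameters, flow orientation

test_that("Voronoi beds are connected meshes clipped to disk and FAZ", {
  set.seed(21)
  bed <- build_voronoi_bed(800, disk_radius = 3, r_FAZ = 0.25,
                           plexus = "SVP", z = 0)
  expect_s3_class(bed, "capillary_bed")
  v <- bed$vertices; e <- bed$edges
  expect_gt(nrow(e), 500)
  expect_true(all(e >= 1 & e <= nrow(v)))
  # vertices inside the disk
  expect_true(all(v[, 1]^2 + v[, 2]^2 <= 3^2 + 1e-9))
  # no edge enters the FAZ
  d_faz <- retinapop:::seg_point_dist(v[e[, 1], , drop = FALSE],
                                      v[e[, 2], , drop = FALSE], c(0, 0))
  expect_true(all(d_faz >= 0.25 - 1e-12))
  # one connected component
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  expect_equal(igraph::count_components(g), 1)
  expect_error(build_voronoi_bed(3, 3, 0.25))
  expect_error(build_voronoi_bed(100, 3, r_FAZ = 5))
})

test_that("pruning removes edges inside macrovessel stadia, keeps pockets", {
  set.seed(22)
  bed <- build_voronoi_bed(1500, 3, 0.25)
  # one thick synthetic macrovessel crossing the bed
  macro <- list(coords = matrix(c(-3, -1, 3, 1), nrow = 1), radius_mm = 0.15)
  pruned <- prune_capillaries_near_macro(bed, macro, min_vertices = 4)
  expect_lt(nrow(pruned$edges), nrow(bed$edges))
  # independent check: sample points along every kept edge; none may lie
  # inside the stadium (distance to the macro segment < its radius)
  v <- pruned$vertices; e <- pruned$edges
  tpar <- seq(0, 1, length.out = 21)
  for (tt in tpar) {
    pts <- cbind(v[e[, 1], 1] * (1 - tt) + v[e[, 2], 1] * tt,
                 v[e[, 1], 2] * (1 - tt) + v[e[, 2], 2] * tt)
    a <- matrix(macro$coords[1, 1:2], nrow(pts), 2, byrow = TRUE)
    b <- matrix(macro$coords[1, 3:4], nrow(pts), 2, byrow = TRUE)
    vx <- b[, 1] - a[, 1]; vy <- b[, 2] - a[, 2]
    tproj <- pmin(pmax(((pts[, 1] - a[, 1]) * vx +
                        (pts[, 2] - a[, 2]) * vy) / (vx^2 + vy^2), 0), 1)
    dd <- sqrt((pts[, 1] - a[, 1] - tproj * vx)^2 +
               (pts[, 2] - a[, 2] - tproj * vy)^2)
    expect_true(all(dd >= macro$radius_mm - 1e-9))
  }
  # every surviving pocket has at least min_vertices vertices
  comp <- igraph::components(igraph::graph_from_edgelist(e, directed = FALSE))
  expect_true(all(comp$csize[unique(comp$membership)] >= 4))
})

test_that("assembled network wires trees, beds, descenders, compartment", {
  net <- smoke_net()
  expect_silent(validate_network(net))
  s <- net$segments; n <- net$nodes
  expect_setequal(unique(s$kind), c("artery", "vein", "capillary",
                                    "artificial"))
  expect_true(all(c("SVP", "ICP", "DCP") %in% s$plexus))
  # exactly one compartment node; artificial segments all touch it and
  # carry the fixed-resistance flag
  comp_id <- n$id[n$kind == "compartment"]
  expect_length(comp_id, 1)
  art <- s[s$kind == "artificial", ]
  expect_gt(nrow(art), 0)
  expect_true(all(art$fixed_resistance))
  expect_true(all(art$from == comp_id | art$to == comp_id))
  expect_true(all(!s$fixed_resistance[s$kind != "artificial"]))
  # interplexus descenders were created
  expect_gt(net$meta$n_descenders, 0)
  # every capillary is fed: its component (excluding artificial segments)
  # contains at least one tree vessel
  vs <- s[s$kind != "artificial", ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(vs$from), to = as.character(vs$to)),
    directed = FALSE)
  comp <- igraph::components(g)$membership
  kind_of <- function(ids) n$kind[match(as.integer(names(comp)[ids]), n$id)]
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    expect_true(any(kind_of(members) %in% c("arterial", "venous", "root")),
                label = sprintf("component %d reachable from a tree", cid))
  }
})

test_that("diameter smoothing stays within same-kind bounds", {
  net <- smoke_net()
  s <- net$segments
  r_cap <- smoke_config()$plexus$SVP$r_capillary
  # capillaries: base radius r_cap, doubled where touching the trees;
  # same-kind smoothing keeps every capillary radius inside [r_cap, 2 r_cap]
  cap_r <- s$radius[s$kind == "capillary"]
  expect_true(all(cap_r >= r_cap - 1e-9 & cap_r <= 2 * r_cap + 1e-9))
  expect_true(any(abs(cap_r - r_cap) < 1e-9))
  # tree radii remain positive and bounded by the CRA stub
  tree_r <- s$radius[s$kind %in% c("artery", "vein")]
  expect_true(all(tree_r > 0))
  expect_lte(max(tree_r), 1.11 * 81 + 1e-9)
})

test_that("orientation clamps potentials and yields a capillary DAG", {
  net <- smoke_net()
  u <- capillary_potentials(net)
  n <- net$nodes; s <- net$segments
  expect_length(u, nrow(n))
  expect_true(all(u[n$kind == "arterial"] == 1))
  expect_true(all(u[n$kind == "venous"] == 0))
  expect_true(all(u >= -1e-9 & u <= 1 + 1e-9))   # maximum principle
  # every capillary segment points from higher to lower potential (exact
  # ties broken by node index, higher first: a strict total order)
  cap <- s[s$kind == "capillary", ]
  ui <- u[match(cap$from, n$id)]; uj <- u[match(cap$to, n$id)]
  expect_true(all(ui > uj | (ui == uj &
                             match(cap$from, n$id) > match(cap$to, n$id))))
  g <- igraph::graph_from_edgelist(
    matrix(as.character(cbind(cap$from, cap$to)), ncol = 2), directed = TRUE)
  expect_true(igraph::is_dag(g))
  expect_true(net$meta$oriented)
})

test_that("orientation potentials solve the Laplace problem (chain oracle)", {
  # arterial -- c1 -- c2 -- c3 -- venous: unweighted Laplace potentials on
  # the free nodes are the linear interpolation 0.75, 0.5, 0.25
  nodes <- data.frame(id = 1:5, x = 0:4, y = 0, z = 0,
                      kind = c("arterial", "capillary", "capillary",
                               "capillary", "venous"),
                      plexus = "SVP")
  segs <- data.frame(id = 1:4, from = c(1L, 3L, 3L, 4L),
                     to = c(2L, 2L, 4L, 5L),   # id-2/3 edge deliberately
                     radius = 2.5, length = 1, # stored "backwards"
                     kind = "capillary", plexus = "SVP",
                     is_terminal = FALSE, fixed_resistance = FALSE)
  net <- vascular_network(nodes, segs)
  out <- orient_capillary_flow(net)
  expect_equal(capillary_potentials(out), c(1, 0.75, 0.5, 0.25, 0),
               tolerance = 1e-8)
  # all edges re-directed downstream (from = higher potential)
  expect_equal(out$segments$from, c(1L, 2L, 3L, 4L))
  expect_equal(out$segments$to, c(2L, 3L, 4L, 5L))
  # a 2D cross: centre node potential is the mean of its neighbours
  nodes2 <- data.frame(id = 1:5, x = c(0, 2, 1, 1, 1), y = c(1, 1, 0, 2, 1),
                       z = 0,
                       kind = c("arterial", "venous", "arterial", "venous",
                                "capillary"),
                       plexus = "SVP")
  segs2 <- data.frame(id = 1:4, from = c(1L, 5L, 3L, 5L),
                      to = c(5L, 2L, 5L, 4L),
                      radius = 2.5, length = 1, kind = "capillary",
                      plexus = "SVP", is_terminal = FALSE,
                      fixed_resistance = FALSE)
  out2 <- orient_capillary_flow(vascular_network(nodes2, segs2))
  expect_equal(capillary_potentials(out2)[5], 0.5, tolerance = 1e-8)
})

test_that("isolated capillary pockets keep the neutral potential", {
  nodes <- data.frame(id = 1:4, x = c(0, 1, 5, 6), y = 0, z = 0,
                      kind = c("arterial", "venous", "capillary",
                               "capillary"),
                      plexus = "SVP")
  segs <- data.frame(id = 1:2, from = c(1L, 3L), to = c(2L, 4L),
                     radius = 2.5, length = 1, kind = "capillary",
                     plexus = "SVP", is_terminal = FALSE,
                     fixed_resistance = FALSE)
  out <- orient_capillary_flow(vascular_network(nodes, segs))
  expect_equal(capillary_potentials(out)[3:4], c(0.5, 0.5))
})
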