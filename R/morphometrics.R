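# OCTA-style structural metrics: analytic vessel indices, rasterization,
# fractal dimension (box counting), intervessel distance (Euclidean distance
# transform), and Horton-Strahler ordering.

# clipped length of segments inside a disk of radius R centred at the origin
clip_length_in_disk <- function(coords, R) {
  p0x <- coords[, 1]; p0y <- coords[, 2]
  p1x <- coords[, 3]; p1y <- coords[, 4]
  dx <- p1x - p0x; dy <- p1y - p0y
  a <- dx^2 + dy^2
  b <- 2 * (p0x * dx + p0y * dy)
  cc <- p0x^2 + p0y^2 - R^2
  disc <- b^2 - 4 * a * cc
  len <- sqrt(a)
  out <- numeric(length(a))
  ok <- disc > 0 & a > 0
  t1 <- pmin(pmax((-b[ok] - sqrt(disc[ok])) / (2 * a[ok]), 0), 1)
  t2 <- pmin(pmax((-b[ok] + sqrt(disc[ok])) / (2 * a[ok]), 0), 1)
  out[ok] <- (t2 - t1) * len[ok]
  # fully inside: both endpoints within R
  inside <- cc <= 0 & (p1x^2 + p1y^2 - R^2) <= 0
  out[inside] <- len[inside]
  out
}

#' Analytic OCTA vessel indices
#'
#' From cumulated vessel length `L = sum(l_i)` and projected lumen area
#' `A = sum(2 r_i l_i)` of a plexus' segments clipped to the analysis disk
#' (field-of-view area `X`):
#' `VAD = A/X`, `VSD = L/X`, `VDI = A/L`, `VCI = (2L)^2 / (4 pi A)`.
#'
#' @param net a `vascular_network`.
#' @param plexus plexus label ("SVP", "ICP", "DCP") or a vector of labels
#'   (e.g. `c("ICP", "DCP")` for the deep complex).
#' @param fov_radius analysis disk radius, mm (default 1.5: 3-mm disk).
#' @return list with `VAD` (dimensionless), `VSD` (1/mm), `VDI_um` (um),
#'   `VCI` (dimensionless), `L_mm`, `A_mm2`, `X_mm2`. With no vessel length
#'   in view, `VDI`/`VCI` are `NaN` (with a warning) and `VAD = VSD = 0`.
#' @export
analytic_indices <- function(net, plexus = "SVP", fov_radius = 1.5) {
  sel <- net$segments$plexus %in% plexus &
    net$segments$kind != "artificial"
  X <- pi * fov_radius^2
  if (!any(sel)) l <- numeric(0)
  else {
    coords <- segment_coords(net, net$segments[sel, ])
    l <- clip_length_in_disk(coords, fov_radius)
  }
  L <- sum(l)
  A <- sum(2 * (net$segments$radius[sel] / 1000) * l)
  if (L == 0) {
    warning("no vessel length in the field of view; VDI/VCI undefined")
    return(list(VAD = 0, VSD = 0, VDI_um = NaN, VCI = NaN,
                L_mm = 0, A_mm2 = 0, X_mm2 = X))
  }
  list(VAD = A / X, VSD = L / X, VDI_um = 1000 * A / L,
       VCI = (2 * L)^2 / (4 * pi * A), L_mm = L, A_mm2 = A, X_mm2 = X)
}

#' Rasterize a plexus to binary images
#'
#' Draws the plexus' segments, clipped to the analysis disk, onto a square
#' canvas: a full-width mask (each segment as a thick line of width equal to
#' its diameter) and a 1-pixel skeleton of centerlines.
#'
#' @param net a `vascular_network`.
#' @param plexus plexus label(s).
#' @param fov_radius analysis disk radius, mm.
#' @param px_size pixel size, um.
#' @return list with integer matrices `mask` and `skeleton`, and `px_size`.
#' @export
rasterize_plexus <- function(net, plexus = "SVP", fov_radius = 1.5,
                             px_size = 10) {
  npx <- ceiling(2 * fov_radius / (px_size / 1000))
  sel <- net$segments$plexus %in% plexus & net$segments$kind != "artificial"
  if (!any(sel)) {
    z <- matrix(0L, npx, npx)
    return(list(mask = z, skeleton = z, px_size = px_size))
  }
  seg <- net$segments[sel, ]
  coords <- segment_coords(net, seg)
  # keep segments near the canvas
  near <- pmin(coords[, 1], coords[, 3]) < fov_radius &
    pmax(coords[, 1], coords[, 3]) > -fov_radius &
    pmin(coords[, 2], coords[, 4]) < fov_radius &
    pmax(coords[, 2], coords[, 4]) > -fov_radius
  ras <- .rasterize_segments(coords[near, , drop = FALSE],
                             seg$radius[near] / 1000, as.integer(npx),
                             fov_radius)
  # apply the circular field of view
  ctr <- ((seq_len(npx) - 0.5) * (2 * fov_radius / npx)) - fov_radius
  in_disk <- outer(ctr^2, ctr^2, "+") <= fov_radius^2
  ras$mask[!in_disk] <- 0L
  ras$skeleton[!in_disk] <- 0L
  list(mask = ras$mask, skeleton = ras$skeleton, px_size = px_size)
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes `N(s)` over box sizes `s` (pixels) and returns the
#' negative least-squares slope of `log N(s)` vs `log s`.
#'
#' @param img binary matrix (skeleton).
#' @param sizes box sizes in pixels (default dyadic 1..64).
#' @return fractal dimension estimate.
#' @export
fractal_dimension <- function(img, sizes = 2^(0:6)) {
  px <- which(img != 0, arr.ind = TRUE)
  if (!nrow(px)) stop("fractal_dimension: empty image")
  counts <- vapply(sizes, function(s) {
    bx <- (px[, 1] - 1) %/% s
    by <- (px[, 2] - 1) %/% s
    length(unique(bx * (max(by) + 2) + by))
  }, numeric(1))
  keep <- counts > 0
  -unname(stats::coef(stats::lm(log(counts[keep]) ~ log(sizes[keep])))[2])
}

#' Intervessel distance
#'
#' Euclidean distance transform of the background (distance of every
#' non-vessel pixel inside the analysis disk to the nearest skeleton pixel);
#' IVD is reported as `factor` times the mean background distance, in um.
#'
#' @param skeleton binary matrix.
#' @param px_size pixel size, um.
#' @param factor normalization factor (default 2).
#' @param disk_only restrict to the inscribed disk.
#' @return IVD in um.
#' @export
intervessel_distance <- function(skeleton, px_size = 10, factor = 2,
                                 disk_only = TRUE) {
  sk <- which(skeleton != 0, arr.ind = TRUE)
  if (!nrow(sk)) stop("intervessel_distance: empty skeleton")
  bg <- which(skeleton == 0, arr.ind = TRUE)
  if (disk_only) {
    n <- nrow(skeleton); c0 <- (n + 1) / 2; r <- n / 2
    bg <- bg[(bg[, 1] - c0)^2 + (bg[, 2] - c0)^2 <= r^2, , drop = FALSE]
  }
  d <- FNN::get.knnx(sk, bg, k = 1)$nn.dist[, 1]
  factor * mean(d) * px_size
}

#' Horton-Strahler stream orders
#'
#' Capillary segments take order 0. Tree vessels are ordered from the
#' capillaries toward the root (upstream for arteries, downstream-to-root
#' for veins): a vessel with one branch of order i (all others lower) takes
#' order i; with two or more branches of the maximal order i it takes i + 1.
#'
#' @param net assembled `vascular_network`.
#' @return integer vector of orders aligned with `net$segments` (NA for
#'   artificial segments).
#' @export
strahler_orders <- function(net) {
  s <- net$segments
  ord <- rep(NA_integer_, nrow(s))
  ord[s$kind == "capillary"] <- 0L
  for (kind in c("artery", "vein")) {
    tsel <- which(s$kind == kind)
    if (!length(tsel)) next
    sub <- s[tsel, ]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(sub$from), to = as.character(sub$to)),
      directed = FALSE)
    if (igraph::ecount(g) != igraph::vcount(g) - igraph::count_components(g))
      stop("strahler_orders: cycle in the ", kind, " tree")
    # depth of each node from the tree's root side
    root_id <- net$nodes$id[net$nodes$kind == "root"]
    root_here <- intersect(as.character(c(sub$from, sub$to)),
                           as.character(root_id))
    if (!length(root_here))
      root_here <- as.character(sub$from[1])
    dists <- igraph::distances(g, v = root_here[1])[1, ]
    nd <- dists[as.character(sub$to)]
    # distal node of each segment = endpoint farther from root
    swapd <- dists[as.character(sub$from)] > nd
    distal <- ifelse(swapd, sub$from, sub$to)
    nd <- pmax(nd, dists[as.character(sub$from)])
    # branches at the distal node: other tree segments + capillaries
    proc <- tsel[order(nd, decreasing = TRUE)]
    # incidence of segments at nodes (tree + capillary kinds)
    vsel <- which(s$kind %in% c("artery", "vein", "capillary"))
    inc <- split(rep(vsel, 2), c(s$from[vsel], s$to[vsel]))
    distal_of <- integer(nrow(s))
    distal_of[tsel] <- distal
    for (si in proc) {
      br <- setdiff(inc[[as.character(distal_of[si])]], si)
      if (!length(br)) { ord[si] <- 0L; next }
      bo <- ord[br]
      if (anyNA(bo)) bo[is.na(bo)] <- 0L
      m <- max(bo)
      ord[si] <- m + as.integer(sum(bo == m) >= 2)
    }
  }
  ord
}

#' Macular diameter-by-order table
#'
#' Per Horton-Strahler order diameter statistics of macular tree vessels,
#' with arteriole and venule means and the arteriole:venule ratio.
#'
#' @param net assembled `vascular_network`.
#' @param orders output of [strahler_orders()] (computed if missing).
#' @param region_radius macular radius, mm.
#' @return data.frame (order, n, mean_d, mean_d_artery, mean_d_vein, ratio)
#'   with an attribute `ratio_all` = mean arteriole diameter / mean venule
#'   diameter over all macular tree vessels.
#' @export
diameter_by_order <- function(net, orders = NULL, region_radius = 3) {
  if (is.null(orders)) orders <- strahler_orders(net)
  s <- net$segments
  mid <- segment_midpoints(net)
  mac <- sqrt(mid[, 1]^2 + mid[, 2]^2) <= region_radius &
    s$kind %in% c("artery", "vein")
  d <- 2 * s$radius
  df <- data.frame(order = orders[mac], d = d[mac], kind = s$kind[mac])
  if (!nrow(df)) {
    out <- data.frame(order = integer(), n = integer(), mean_d = numeric(),
                      mean_d_artery = numeric(), mean_d_vein = numeric(),
                      ratio = numeric())
    attr(out, "ratio_all") <- NaN
    return(out)
  }
  lv <- sort(unique(df$order))
  out <- do.call(rbind, lapply(lv, function(o) {
    x <- df[df$order == o, ]
    ma <- mean(x$d[x$kind == "artery"])
    mv <- mean(x$d[x$kind == "vein"])
    data.frame(order = o, n = nrow(x), mean_d = mean(x$d),
               mean_d_artery = ma, mean_d_vein = mv, ratio = ma / mv)
  }))
  attr(out, "ratio_all") <- mean(df$d[df$kind == "artery"]) /
    mean(df$d[df$kind == "vein"])
  out
}

#' Full morphometrics report for a network
#'
#' Analytic indices per plexus (SVP, ICP, DCP and the ICP-DCP complex) plus
#' fractal dimension and intervessel distance from rasterized images.
#'
#' @param net assembled `vascular_network`.
#' @param fov_radius analysis disk radius, mm.
#' @param px_size raster pixel size, um.
#' @param raster compute FD/IVD (rasterization is the slow part).
#' @return named list of metrics.
#' @export
morphometrics_report <- function(net, fov_radius = 1.5, px_size = 10,
                                 raster = TRUE) {
  out <- list()
  for (px in list("SVP", "ICP", "DCP", c("ICP", "DCP"))) {
    lab <- paste(px, collapse = "")
    ai <- analytic_indices(net, px, fov_radius)
    out[[paste0("VAD_", lab)]] <- ai$VAD
    if (identical(px, "SVP")) {
      out$VSD_SVP <- ai$VSD
      out$VDI_SVP <- ai$VDI_um
      out$VCI_SVP <- ai$VCI
    }
    if (raster) {
      ras <- rasterize_plexus(net, px, fov_radius, px_size)
      if (any(ras$skeleton != 0)) {
        out[[paste0("FD_", lab)]] <- fractal_dimension(ras$skeleton)
        if (identical(px, "SVP"))
          out$IVD_SVP <- intervessel_distance(ras$skeleton, px_size)
      }
    }
  }
  out
}
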