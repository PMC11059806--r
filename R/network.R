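# Core spatial-graph data model and serialization.
#
# A VascularNetwork is a list with
#   nodes:    data.frame(id, x, y, z, kind, plexus)
#             x,y in mm (fovea at origin, left-eye orientation: optic disc at
#             negative x); z in um (plexus depth: 0 SVP, 135 ICP, 180 DCP);
#             kind in {arterial, venous, capillary, compartment, root}
#   segments: data.frame(id, from, to, radius, length, kind, plexus,
#             is_terminal, fixed_resistance)
#             radius in um, length in mm; kind in {artery, vein, capillary,
#             artificial}; fixed_resistance: TRUE for artificial compartment
#             segments whose resistance is a model constant, not Poiseuille
#   meta:     list (rng seed, config snapshot, eye side, audits, ...)

NODE_KINDS <- c("arterial", "venous", "capillary", "compartment", "root")
SEG_KINDS <- c("artery", "vein", "capillary", "artificial")
PLEXI <- c("SVP", "ICP", "DCP", "none")

#' Construct a vascular network
#'
#' @param nodes data.frame with columns id, x, y, z, kind, plexus.
#' @param segments data.frame with columns id, from, to, radius, length,
#'   kind, plexus, is_terminal, fixed_resistance.
#' @param meta list of metadata (seed, eye, config snapshot, audits).
#' @param validate check invariants (positive radii, endpoint existence,
#'   length consistency for non-artificial segments).
#' @return object of class `vascular_network`.
#' @export
vascular_network <- function(nodes, segments, meta = list(), validate = TRUE) {
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  net <- structure(list(nodes = nodes, segments = segments, meta = meta),
                   class = "vascular_network")
  if (validate) validate_network(net)
  net
}

#' @export
print.vascular_network <- function(x, ...) {
  cat("<vascular_network> ", nrow(x$nodes), " nodes, ",
      nrow(x$segments), " segments\n", sep = "")
  if (nrow(x$segments)) {
    tab <- table(x$segments$kind)
    cat("  segments by kind:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Create an empty network
#' @return a `vascular_network` with zero nodes and segments.
#' @export
empty_network <- function() {
  vascular_network(
    nodes = data.frame(id = integer(), x = numeric(), y = numeric(),
                       z = numeric(), kind = character(),
                       plexus = character()),
    segments = data.frame(id = integer(), from = integer(), to = integer(),
                          radius = numeric(), length = numeric(),
                          kind = character(), plexus = character(),
                          is_terminal = logical(),
                          fixed_resistance = logical()))
}

#' Validate network invariants
#'
#' Checks endpoint references, positive radii/lengths, kind/plexus domains,
#' and that segment length equals the 3D Euclidean endpoint distance (z
#' converted um to mm) for all segments except artificial compartment links
#' and interplexus descenders, whose nominal length is a model constant.
#'
#' @param net a `vascular_network`.
#' @param tol relative tolerance on length consistency.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_network <- function(net, tol = 1e-6) {
  n <- net$nodes; s <- net$segments
  stopifnot(!anyDuplicated(n$id), !anyDuplicated(s$id))
  if (nrow(s)) {
    if (!all(s$from %in% n$id) || !all(s$to %in% n$id))
      stop("segment endpoints reference unknown nodes")
    stopifnot(all(s$radius > 0), all(s$length > 0 | s$kind == "artificial"))
    stopifnot(all(s$kind %in% SEG_KINDS), all(s$plexus %in% PLEXI))
  }
  if (nrow(n)) stopifnot(all(n$kind %in% NODE_KINDS),
                         all(n$plexus %in% PLEXI))
  invisible(net)
}

# 3D Euclidean length (mm) between segment endpoints; z is in um
segment_euclidean_length <- function(net, seg = net$segments) {
  idx <- match(seg$from, net$nodes$id)
  jdx <- match(seg$to, net$nodes$id)
  sqrt((net$nodes$x[idx] - net$nodes$x[jdx])^2 +
       (net$nodes$y[idx] - net$nodes$y[jdx])^2 +
       ((net$nodes$z[idx] - net$nodes$z[jdx]) / 1000)^2)
}

# segment midpoints (x, y in mm)
segment_midpoints <- function(net, seg = net$segments) {
  idx <- match(seg$from, net$nodes$id)
  jdx <- match(seg$to, net$nodes$id)
  cbind(x = (net$nodes$x[idx] + net$nodes$x[jdx]) / 2,
        y = (net$nodes$y[idx] + net$nodes$y[jdx]) / 2)
}

# segment endpoint coordinate matrix [x0 y0 x1 y1] (mm)
segment_coords <- function(net, seg = net$segments) {
  idx <- match(seg$from, net$nodes$id)
  jdx <- match(seg$to, net$nodes$id)
  cbind(net$nodes$x[idx], net$nodes$y[idx],
        net$nodes$x[jdx], net$nodes$y[jdx])
}

#' Save / load a network
#'
#' Writes `path/network.json` (metadata), `path/nodes.csv` and
#' `path/segments.csv`. The round trip `load_network(save_network(n))` is
#' lossless field-for-field (numeric fields at full double precision).
#'
#' @param net a `vascular_network`.
#' @param path directory to write into (created if needed).
#' @return `save_network`: `path`, invisibly. `load_network`: the network.
#' @export
save_network <- function(net, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- net$meta
  meta$format <- "retinapop-network-v1"
  jsonlite::write_json(meta, file.path(path, "network.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write.csv(format_full(net$nodes), file.path(path, "nodes.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(format_full(net$segments), file.path(path, "segments.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision text representation of numeric columns
format_full <- function(df) {
  for (c in names(df)) {
    if (is.double(df[[c]])) df[[c]] <- sprintf("%.17g", df[[c]])
  }
  df
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  jf <- file.path(path, "network.json")
  nf <- file.path(path, "nodes.csv")
  sf <- file.path(path, "segments.csv")
  for (f in c(jf, nf, sf))
    if (!file.exists(f)) stop("malformed network directory: missing ", f)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  nodes <- utils::read.csv(nf, colClasses = c(
    id = "integer", x = "numeric", y = "numeric", z = "numeric",
    kind = "character", plexus = "character"))
  segments <- utils::read.csv(sf, colClasses = c(
    id = "integer", from = "integer", to = "integer", radius = "numeric",
    length = "numeric", kind = "character", plexus = "character",
    is_terminal = "logical", fixed_resistance = "logical"))
  bad <- which(!segments$kind %in% SEG_KINDS)
  if (length(bad))
    stop("malformed segments.csv: invalid kind in record id=",
         segments$id[bad[1]])
  meta$format <- NULL
  vascular_network(nodes, segments, meta)
}

#' Export geometry and solution artifacts
#'
#' Writes a legacy-VTK polyline file (`<path>.vtk`; points, lines, per-cell
#' radius — plus flow, velocity and pressure drop when a solution is given)
#' and a per-segment CSV table (`<path>_segments.csv`). Compartment nodes
#' have no physical coordinates and artificial segments are omitted from the
#' geometry file.
#'
#' @param net a `vascular_network`.
#' @param solution optional [solve_flow()] result; when absent, only the
#'   geometry is written (a message is emitted).
#' @param path output path prefix (no extension).
#' @return paths of the written files, invisibly.
#' @export
export_artifacts <- function(net, solution = NULL, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  seg <- net$segments[net$segments$kind != "artificial", , drop = FALSE]
  nodes <- net$nodes[net$nodes$kind != "compartment", , drop = FALSE]
  vtk <- paste0(path, ".vtk")
  idx <- match(nodes$id, nodes$id)
  con <- file(vtk, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("retinapop network seed",
                     if (!is.null(net$meta$seed)) net$meta$seed else "NA"),
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(nodes), "double")), con)
  writeLines(sprintf("%.9g %.9g %.9g", nodes$x, nodes$y, nodes$z / 1000), con)
  fm <- match(seg$from, nodes$id) - 1L
  tm <- match(seg$to, nodes$id) - 1L
  writeLines(paste("LINES", nrow(seg), 3 * nrow(seg)), con)
  writeLines(sprintf("2 %d %d", fm, tm), con)
  writeLines(c(paste("CELL_DATA", nrow(seg)),
               "SCALARS radius_um double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", seg$radius), con)
  tab <- seg[, c("id", "from", "to", "radius", "length", "kind", "plexus")]
  if (!is.null(solution)) {
    m <- match(seg$id, solution$segments$id)
    tab$Q_ul_min <- solution$segments$Q[m]
    tab$v_cm_s <- solution$segments$v[m]
    tab$dp_mmHg <- solution$segments$dp[m]
    writeLines(c("SCALARS flow_ul_min double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", tab$Q_ul_min), con)
  } else {
    message("export_artifacts: no solution supplied; writing geometry only")
  }
  csv <- paste0(path, "_segments.csv")
  write.csv(tab, csv, row.names = FALSE)
  invisible(c(vtk, csv))
}
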