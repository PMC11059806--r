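# OCTA morphometrics: analytic indices, rasterization, fractal dimension,
# intervessel distance, Horton-Strahler ordering

one_segment_net <- function(x0, x1, radius_um, kind = "artery") {
  vascular_network(
    nodes = data.frame(id = 1:2, x = c(x0, x1), y = 0, z = 0,
                       kind = c("arterial", "arterial"), plexus = "SVP"),
    segments = data.frame(id = 1L, from = 1L, to = 2L, radius = radius_um,
                          length = abs(x1 - x0), kind = kind, plexus = "SVP",
                          is_terminal = FALSE, fixed_resistance = FALSE),
    validate = FALSE)
}

test_that("analytic indices match the closed forms on one segment", {
  net <- one_segment_net(-1, 1, radius_um = 50)
  ai <- analytic_indices(net, "SVP", fov_radius = 1.5)
  X <- pi * 1.5^2
  L <- 2; A <- 2 * 0.05 * 2
  expect_equal(ai$L_mm, L)
  expect_equal(ai$A_mm2, A)
  expect_equal(ai$VAD, A / X)
  expect_equal(ai$VSD, L / X)
  expect_equal(ai$VDI_um, 100)              # = lumen diameter
  expect_equal(ai$VCI, (2 * L)^2 / (4 * pi * A))
})

test_that("segments are clipped to the analysis disk", {
  net <- one_segment_net(-3, 3, radius_um = 50)
  ai <- analytic_indices(net, "SVP", fov_radius = 1.5)
  expect_equal(ai$L_mm, 3)                  # chord through the centre
  # segment fully outside contributes nothing
  net2 <- one_segment_net(2, 3, radius_um = 50)
  expect_warning(ai2 <- analytic_indices(net2, "SVP", 1.5), "field of view")
  expect_equal(ai2$VAD, 0)
  expect_true(is.nan(ai2$VDI_um))
  # plexus filter
  expect_warning(analytic_indices(net, "DCP", 1.5), "field of view")
})

test_that("rasterization draws full-width mask and 1-px skeleton", {
  net <- one_segment_net(-1, 1, radius_um = 100)
  ras <- rasterize_plexus(net, "SVP", fov_radius = 1.5, px_size = 10)
  expect_equal(dim(ras$mask), c(300, 300))
  # thickness at mid-chord ~ diameter = 200 um = 20 px (rows index x)
  mid <- 150
  expect_true(sum(ras$mask[mid, ]) %in% 18:23)
  expect_true(sum(ras$skeleton[mid, ]) %in% 1:2)
  # skeleton total ~ chord length 2 mm = 200 px (plus end caps)
  expect_true(sum(ras$skeleton) %in% 195:225)
  # circular field of view applied
  expect_equal(sum(ras$mask[1, ]), 0)
  # empty plexus gives empty canvases
  ras0 <- rasterize_plexus(net, "DCP", 1.5, 10)
  expect_equal(sum(ras0$mask), 0)
})

test_that("fractal dimension recovers line, square and Sierpinski carpet", {
  line <- matrix(0L, 128, 128); line[64, ] <- 1L
  expect_equal(fractal_dimension(line, sizes = 2^(0:5)), 1, tolerance = 0.05)
  square <- matrix(1L, 128, 128)
  expect_equal(fractal_dimension(square, sizes = 2^(0:5)), 2,
               tolerance = 0.05)
  carp <- sierpinski_carpet(5)              # 243 x 243
  expect_equal(fractal_dimension(carp, sizes = 3^(0:5)), log(8) / log(3),
               tolerance = 0.05)
  expect_error(fractal_dimension(matrix(0L, 8, 8)), "empty")
})

test_that("intervessel distance matches a brute-force oracle", {
  n <- 101
  sk <- matrix(0L, n, n); sk[, 51] <- 1L    # vertical line mid-canvas
  got <- intervessel_distance(sk, px_size = 10, factor = 2)
  # nearest skeleton pixel of background (r, c) is (r, 51): distance |c-51|
  c0 <- (n + 1) / 2
  bg <- which(sk == 0, arr.ind = TRUE)
  bg <- bg[(bg[, 1] - c0)^2 + (bg[, 2] - c0)^2 <= (n / 2)^2, , drop = FALSE]
  expect_equal(got, 2 * mean(abs(bg[, 2] - 51)) * 10, tolerance = 1e-12)
  expect_error(intervessel_distance(matrix(0L, 4, 4)), "empty")
})

test_that("Horton-Strahler orders: capillaries 0, merge rule upstream", {
  nodes <- data.frame(id = 1:6,
                      x = c(-2, -1, 0, 0, 1, 1),
                      y = c(0, 0, 1, -1, 1, -1), z = 0,
                      kind = c("root", "arterial", "arterial", "arterial",
                               "capillary", "capillary"),
                      plexus = "SVP")
  segs <- data.frame(id = 1:5,
                     from = c(1L, 2L, 2L, 3L, 4L),
                     to = c(2L, 3L, 4L, 5L, 6L),
                     radius = c(20, 10, 10, 2.5, 2.5),
                     length = 1,
                     kind = c("artery", "artery", "artery", "capillary",
                              "capillary"),
                     plexus = "SVP", is_terminal = FALSE,
                     fixed_resistance = FALSE)
  net <- vascular_network(nodes, segs, validate = FALSE)
  ord <- strahler_orders(net)
  # two order-0 daughters meeting -> parent takes order 1
  expect_equal(ord, c(1L, 0L, 0L, 0L, 0L))
})

test_that("diameter_by_order reports the arteriole:venule ratio", {
  nodes <- data.frame(id = 1:5, x = c(-2, -1, 2, 1, 0), y = 0, z = 0,
                      kind = c("root", "arterial", "root", "venous",
                               "capillary"),
                      plexus = "SVP")
  segs <- data.frame(id = 1:4,
                     from = c(1L, 3L, 2L, 5L),
                     to = c(2L, 4L, 5L, 4L),
                     radius = c(10, 12.5, 2.5, 2.5),
                     length = 1,
                     kind = c("artery", "vein", "capillary", "capillary"),
                     plexus = "SVP", is_terminal = FALSE,
                     fixed_resistance = FALSE)
  net <- vascular_network(nodes, segs, validate = FALSE)
  tab <- diameter_by_order(net, region_radius = 3)
  expect_equal(tab$order, 0L)
  expect_equal(tab$n, 2L)
  expect_equal(tab$mean_d_artery, 20)
  expect_equal(tab$mean_d_vein, 25)
  expect_equal(tab$ratio, 0.8)
  expect_equal(attr(tab, "ratio_all"), 0.8)
})

test_that("full morphometrics report is complete and finite", {
  rep <- morphometrics_report(smoke_net(), fov_radius = 1.5, px_size = 10,
                              raster = TRUE)
  need <- c("VAD_SVP", "VSD_SVP", "VDI_SVP", "VCI_SVP", "VAD_ICP",
            "VAD_DCP", "VAD_ICPDCP", "FD_SVP", "IVD_SVP")
  expect_true(all(need %in% names(rep)))
  for (k in need) expect_true(is.finite(rep[[k]]) && rep[[k]] > 0,
                              label = k)
  expect_true(rep$FD_SVP > 1 && rep$FD_SVP < 2)
})
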