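# Statistical shape model of the four major temporal arcades (two arterial,
# two venous), plus a synthetic landmark fixture generator standing in for
# manually segmented fundus-photograph centerlines.
#
# Landmark sets are lists of four (n_landmarks x 2) matrices named
# sup_artery, sup_vein, inf_artery, inf_vein. Training-space coordinates are
# in degrees of fundus field of view (fovea at origin, left-eye orientation);
# sampled shapes are converted to mm with the fundus rule of thumb
# 10 degrees ~ 5 mm.

ARCADE_LABELS <- c("sup_artery", "sup_vein", "inf_artery", "inf_vein")
MM_PER_DEG <- 0.5  # 10 degrees ~ 5 mm

#' Synthetic temporal-arcade landmark fixture
#'
#' Generates landmark curves emulating manually traced major temporal
#' arcades: noisy parabolic arcs opening temporally from an optic disc at
#' x ~ -9 degrees (-4.5 mm), superior and inferior curves mirrored about the
#' horizontal raphe, veins slightly more arched than arteries, fovea at the
#' origin untouched. Used as training data for [fit_shape_model()] in place
#' of image-derived segmentations.
#'
#' @param n_eyes number of synthetic eyes (>= 2).
#' @param n_landmarks landmarks per curve (arc-length resampled).
#' @return list of `n_eyes` landmark sets (degrees), each a named list of
#'   four `(n_landmarks x 2)` matrices; attribute `units = "deg"`.
#' @export
generate_arcade_fixture <- function(n_eyes, n_landmarks = 20) {
  stopifnot(n_eyes >= 2, n_landmarks >= 4)
  lapply(seq_len(n_eyes), function(e) {
    disc_x <- stats::rnorm(1, -9, 0.4)          # deg
    h_eye <- stats::rnorm(1, 9, 0.8)            # arch height, deg
    xv_eye <- stats::rnorm(1, 1, 0.7)           # arch apex x, deg
    set <- list()
    for (lab in ARCADE_LABELS) {
      sup <- if (grepl("^sup", lab)) 1 else -1
      vein <- grepl("vein", lab)
      h <- h_eye + (if (vein) 0.6 else -0.6) + stats::rnorm(1, 0, 0.3)
      xv <- xv_eye + stats::rnorm(1, 0, 0.3)
      y_disc <- abs(stats::rnorm(1, 0.8, 0.2))
      k <- (h - y_disc) / (disc_x - xv)^2
      # stop where the arc has descended to ~1.5 deg above the raphe
      x_end <- xv + sqrt(max(h - 1.5, 1) / k)
      xs <- seq(disc_x, x_end, length.out = 200)
      ys <- h - k * (xs - xv)^2
      ys <- ys + 0.15 * sin(xs * stats::runif(1, 0.5, 1.5) +
                            stats::runif(1, 0, 2 * pi))   # mild waviness
      # arc-length resample to a fixed landmark count
      dd <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
      tt <- seq(0, dd[length(dd)], length.out = n_landmarks)
      set[[lab]] <- cbind(x = stats::approx(dd, xs, tt)$y,
                          y = sup * stats::approx(dd, ys, tt)$y)
    }
    attr(set, "units") <- "deg"
    set
  })
}

#' Align a landmark set to left-eye orientation
#'
#' Right-eye sets are reflected across the y-axis so that the optic disc lies
#' at negative x; superior/inferior labels are swapped accordingly is not
#' needed because reflection is horizontal.
#'
#' @param set a landmark set (list of four matrices).
#' @param eye `"left"` or `"right"`.
#' @return the aligned landmark set.
#' @export
align_landmarks <- function(set, eye = c("left", "right")) {
  eye <- match.arg(eye)
  if (eye == "right")
    for (lab in names(set)) set[[lab]][, 1] <- -set[[lab]][, 1]
  set
}

# flatten a landmark set to one numeric vector (fixed ordering)
flatten_set <- function(set) {
  unlist(lapply(ARCADE_LABELS, function(l) as.numeric(set[[l]])))
}

unflatten_set <- function(v, n_landmarks) {
  per <- 2 * n_landmarks
  out <- list()
  for (i in seq_along(ARCADE_LABELS)) {
    m <- matrix(v[((i - 1) * per + 1):(i * per)], ncol = 2)
    colnames(m) <- c("x", "y")
    out[[ARCADE_LABELS[i]]] <- m
  }
  out
}

#' Fit the PCA shape model of the temporal arcades
#'
#' Principal-component shape model on flattened landmark vectors (all four
#' curves jointly), fovea-aligned. With all components retained, training
#' shapes are reconstructed exactly.
#'
#' @param landmark_sets list of aligned landmark sets (equal landmark count).
#' @param n_components number of modes to retain (capped at the available
#'   rank, `n_sets - 1`).
#' @return object of class `arcade_shape_model`: mean vector, orthonormal
#'   components (columns), per-mode variances (non-increasing), landmark
#'   count and the degree-to-mm scale rule.
#' @export
fit_shape_model <- function(landmark_sets, n_components = 5) {
  stopifnot(length(landmark_sets) >= 2)
  nl <- vapply(landmark_sets, function(s) nrow(s[[1]]), integer(1))
  if (length(unique(nl)) != 1)
    stop("inconsistent landmark counts across training sets")
  for (s in landmark_sets)
    if (!all(ARCADE_LABELS %in% names(s)))
      stop("landmark set missing one of: ",
           paste(ARCADE_LABELS, collapse = ", "))
  X <- t(vapply(landmark_sets, flatten_set,
                numeric(8 * nl[1])))   # n_sets x (4*2*nl)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation), nrow(X) - 1)
  structure(list(mean = pc$center,
                 components = pc$rotation[, seq_len(k), drop = FALSE],
                 variances = pc$sdev[seq_len(k)]^2,
                 n_landmarks = nl[1],
                 mm_per_deg = MM_PER_DEG),
            class = "arcade_shape_model")
}

#' Sample arcades from the shape model
#'
#' Mode coefficients are drawn from independent zero-mean normals with the
#' model variances, clamped at `clamp_sd` standard deviations, and the
#' resulting shape is converted to mm with the 10-degree ~ 5 mm rule.
#'
#' @param model an `arcade_shape_model`.
#' @param clamp_sd clamp for the per-mode coefficients (default 3; 0 returns
#'   the mean shape exactly).
#' @return landmark set in mm (named list of four matrices), attribute
#'   `units = "mm"`.
#' @export
sample_arcades <- function(model, clamp_sd = 3) {
  sd <- sqrt(model$variances)
  b <- stats::rnorm(length(sd), 0, sd)
  b <- pmax(pmin(b, clamp_sd * sd), -clamp_sd * sd)
  v <- model$mean + as.numeric(model$components %*% b)
  set <- unflatten_set(v * model$mm_per_deg, model$n_landmarks)
  attr(set, "units") <- "mm"
  set
}
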