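#' Configuration for co-registered data augmentation
#'
#' Spatial augmentations (axis flips, small random rotations, elastic
#' deformation) are applied with an identical geometric mapping to the input
#' window and its label window, so supervision stays co-registered; the
#' input is resampled with trilinear interpolation and labels with
#' nearest-neighbour (which never invents codes).  Intensity augmentation
#' divides by `max_intensity`, multiplies by a random scale and adds a random
#' constant; labels are untouched.  Elastic deformation follows the common
#' convention of smoothing a uniform(-1, 1) displacement field with a
#' Gaussian of width `elastic_sigma` and scaling by `elastic_alpha`.
#'
#' When enabled, rotation and elastic deformation are each applied with an
#' independent per-sample probability of 0.5.
#'
#' @param enable_flips,enable_rotation,enable_elastic Toggles per transform.
#' @param rotation_range Maximum absolute rotation per axis, degrees.
#' @param elastic_alpha Length-2 range of deformation magnitudes.
#' @param elastic_sigma Length-2 range of smoothing extents in voxels.
#' @param intensity_scale_range Range of the multiplicative intensity factor.
#' @param intensity_offset_range Range of the additive constant (normalized
#'   units).
#' @param max_intensity Intensity normalization divisor (16-bit: 65535).
#' @return An `augment_config` list.
#' @export
augment_config <- function(enable_flips = TRUE, enable_rotation = FALSE,
                           enable_elastic = FALSE, rotation_range = 15,
                           elastic_alpha = c(0, 200),
                           elastic_sigma = c(9, 13),
                           intensity_scale_range = c(0.8, 1.2),
                           intensity_offset_range = c(-0.05, 0.05),
                           max_intensity = 65535) {
  check_that(max_intensity > 0, "max_intensity must be positive")
  check_that(length(intensity_scale_range) == 2 &&
               diff(intensity_scale_range) >= 0, "bad intensity_scale_range")
  check_that(length(intensity_offset_range) == 2 &&
               diff(intensity_offset_range) >= 0, "bad intensity_offset_range")
  structure(list(enable_flips = enable_flips,
                 enable_rotation = enable_rotation,
                 enable_elastic = enable_elastic,
                 rotation_range = rotation_range,
                 elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma,
                 intensity_scale_range = intensity_scale_range,
                 intensity_offset_range = intensity_offset_range,
                 max_intensity = max_intensity),
            class = "augment_config")
}

flip_array <- function(a, axes) {
  d <- dim(a)
  if (axes[1]) a <- a[rev(seq_len(d[1])), , , drop = FALSE]
  if (axes[2]) a <- a[, rev(seq_len(d[2])), , drop = FALSE]
  if (axes[3]) a <- a[, , rev(seq_len(d[3])), drop = FALSE]
  dim(a) <- d
  a
}

#' Random axis flips of a training sample
#'
#' Each of the three axes is flipped independently with probability 0.5;
#' input and labels are flipped along the same axes so the pair stays
#' co-registered.  Applying the same flip twice restores the original.
#'
#' @param sample A `volume_sample` from [extract_sample()].
#' @param axes Optional logical vector of length 3 forcing the flips
#'   (otherwise drawn at random).
#' @return The flipped sample.
#' @export
random_flip <- function(sample, axes = NULL) {
  if (is.null(axes)) axes <- runif(3) < 0.5
  sample$input <- flip_array(sample$input, axes)
  sample$labels <- flip_array(sample$labels, axes)
  sample$target <- crop_center(sample$labels, sample$margin)
  sample
}

# Separable Gaussian smoothing of a 3D field; rows of the 1D kernel matrix
# are renormalized near the boundary.
gaussian_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  for (axis in 1:3) {
    n <- d[axis]
    i <- seq_len(n)
    K <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
    K <- K / rowSums(K)
    others <- setdiff(1:3, axis)
    ap <- aperm(a, c(axis, others))
    m <- K %*% matrix(ap, n)
    a <- aperm(array(m, dim(ap)), order(c(axis, others)))
  }
  a
}

rotation_matrix <- function(angles) {
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  Rz <- matrix(c(1, 0, 0, 0, cz, sz, 0, -sz, cz), 3)    # about axis 1 (z)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3)    # about axis 2 (y)
  Rx <- matrix(c(cx, sx, 0, -sx, cx, 0, 0, 0, 1), 3)    # about axis 3 (x)
  Rz %*% Ry %*% Rx
}

# Trilinear sampling of vol at real-valued (z,y,x) coordinate arrays.
trilinear_sample <- function(vol, cz, cy, cx, fill) {
  d <- dim(vol)
  eps <- 1e-6   # tolerate fp residue at the domain boundary
  inb <- cz >= 1 - eps & cz <= d[1] + eps & cy >= 1 - eps &
    cy <= d[2] + eps & cx >= 1 - eps & cx <= d[3] + eps
  z0 <- pmin(pmax(floor(cz), 1), d[1] - 1); wz <- cz - z0
  y0 <- pmin(pmax(floor(cy), 1), d[2] - 1); wy <- cy - y0
  x0 <- pmin(pmax(floor(cx), 1), d[3] - 1); wx <- cx - x0
  lin <- function(z, y, x) z + d[1] * (y - 1) + d[1] * d[2] * (x - 1)
  v <- vol[lin(z0,     y0,     x0)]     * (1 - wz) * (1 - wy) * (1 - wx) +
       vol[lin(z0 + 1, y0,     x0)]     * wz       * (1 - wy) * (1 - wx) +
       vol[lin(z0,     y0 + 1, x0)]     * (1 - wz) * wy       * (1 - wx) +
       vol[lin(z0 + 1, y0 + 1, x0)]     * wz       * wy       * (1 - wx) +
       vol[lin(z0,     y0,     x0 + 1)] * (1 - wz) * (1 - wy) * wx +
       vol[lin(z0 + 1, y0,     x0 + 1)] * wz       * (1 - wy) * wx +
       vol[lin(z0,     y0 + 1, x0 + 1)] * (1 - wz) * wy       * wx +
       vol[lin(z0 + 1, y0 + 1, x0 + 1)] * wz       * wy       * wx
  v[!inb] <- fill
  array(v, dim(cz))
}

nearest_sample <- function(vol, cz, cy, cx, fill) {
  d <- dim(vol)
  z <- round(cz); y <- round(cy); x <- round(cx)
  inb <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
  # rounding already absorbs sub-half-voxel fp residue at the boundary
  z <- pmin(pmax(z, 1), d[1]); y <- pmin(pmax(y, 1), d[2])
  x <- pmin(pmax(x, 1), d[3])
  v <- vol[z + d[1] * (y - 1) + d[1] * d[2] * (x - 1)]
  v[!inb] <- fill
  array(v, dim(cz))
}

#' Random rotation and/or elastic deformation of a training sample
#'
#' Builds a single geometric mapping (rotation about the window center
#' composed with a smoothed random displacement field) and applies it
#' identically to the input window and the input-sized label window; the
#' target is then re-cropped from the transformed labels.  The input is
#' resampled trilinearly and filled with its median (a robust background
#' estimate) outside the domain; labels use nearest-neighbour resampling and
#' fill with background (code 1).
#'
#' @param sample A `volume_sample`.
#' @param config An [augment_config()].
#' @param angles Optional fixed rotation angles in degrees, length 3
#'   (overrides the random draw; use `c(0, 0, 0)` with `elastic = list(alpha
#'   = 0, sigma = 1)` for an identity check).
#' @param elastic Optional fixed list `list(alpha =, sigma =)`.
#' @return The transformed sample.
#' @export
spatial_transform <- function(sample, config = augment_config(),
                              angles = NULL, elastic = NULL) {
  if (is.null(angles)) {
    do_rot <- config$enable_rotation && runif(1) < 0.5
    angles <- if (do_rot)
      runif(3, -config$rotation_range, config$rotation_range) else c(0, 0, 0)
  }
  if (is.null(elastic)) {
    do_el <- config$enable_elastic && runif(1) < 0.5
    elastic <- if (do_el)
      list(alpha = runif(1, config$elastic_alpha[1], config$elastic_alpha[2]),
           sigma = runif(1, config$elastic_sigma[1], config$elastic_sigma[2]))
    else list(alpha = 0, sigma = 1)
  }
  d <- dim(sample$input)
  identity_map <- all(angles == 0) && elastic$alpha == 0
  if (identity_map) return(sample)

  ctr <- (d + 1) / 2
  gz <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  gy <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  gx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)

  R <- rotation_matrix(angles * pi / 180)
  # source coordinate for every output voxel (pull-back mapping)
  sz <- ctr[1] + R[1, 1] * (gz - ctr[1]) + R[1, 2] * (gy - ctr[2]) + R[1, 3] * (gx - ctr[3])
  sy <- ctr[2] + R[2, 1] * (gz - ctr[1]) + R[2, 2] * (gy - ctr[2]) + R[2, 3] * (gx - ctr[3])
  sx <- ctr[3] + R[3, 1] * (gz - ctr[1]) + R[3, 2] * (gy - ctr[2]) + R[3, 3] * (gx - ctr[3])
  if (elastic$alpha > 0) {
    sz <- sz + gaussian_smooth3(array(runif(prod(d), -1, 1), d), elastic$sigma) * elastic$alpha
    sy <- sy + gaussian_smooth3(array(runif(prod(d), -1, 1), d), elastic$sigma) * elastic$alpha
    sx <- sx + gaussian_smooth3(array(runif(prod(d), -1, 1), d), elastic$sigma) * elastic$alpha
  }
  fill_int <- stats::median(sample$input)
  sample$input <- trilinear_sample(sample$input, sz, sy, sx, fill_int)
  lab <- nearest_sample(sample$labels, sz, sy, sx,
                        LABEL_CODES[["background"]])
  storage.mode(lab) <- "integer"
  sample$labels <- lab
  sample$target <- crop_center(sample$labels, sample$margin)
  sample
}

#' Normalize and randomly rescale window intensities
#'
#' Output is `input / max_intensity * s + c`, with `s` drawn uniformly from
#' `intensity_scale_range` and `c` from `intensity_offset_range`.  Pass
#' fixed `s = 1, c = 0` for plain normalization (as used at validation and
#' inference time).
#'
#' @param input Intensity window (raw 16-bit scale).
#' @param config An [augment_config()].
#' @param s,c Optional fixed scale and offset overriding the random draw.
#' @return Normalized window.
#' @export
intensity_augment <- function(input, config = augment_config(),
                              s = NULL, c = NULL) {
  if (is.null(s)) s <- runif(1, config$intensity_scale_range[1],
                             config$intensity_scale_range[2])
  if (is.null(c)) c <- runif(1, config$intensity_offset_range[1],
                             config$intensity_offset_range[2])
  input / config$max_intensity * s + c
}
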