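#' Configuration for corner-based training-window sampling
#'
#' Training windows are cubes of edge `input_size` anchored at a random
#' "corner" (the top-left-back voxel); the matching supervision target is the
#' concentric label window of edge `input_size - 2 * margin`.  With
#' probability `oversample_p` the corner is drawn from a list of axon-labeled
#' voxels instead of uniformly, biasing samples toward foreground.
#'
#' @param input_size Edge of the input window in voxels.
#' @param margin Per-side offset between input and target windows.
#' @param oversample_p Probability of drawing a corner from the axon list.
#' @param samples_per_cube Training windows drawn from each cube per epoch.
#' @param seed Optional integer seed for the sampling stream.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(input_size = 64L, margin = 14L,
                           oversample_p = 0.3, samples_per_cube = 100L,
                           seed = NULL) {
  check_that(input_size - 2 * margin > 0,
             "input_size - 2*margin must be positive")
  check_that(oversample_p >= 0 && oversample_p <= 1,
             "oversample_p must lie in [0, 1]")
  check_that(samples_per_cube >= 1, "samples_per_cube must be >= 1")
  structure(list(input_size = as.integer(input_size),
                 margin = as.integer(margin),
                 output_size = as.integer(input_size - 2L * margin),
                 oversample_p = oversample_p,
                 samples_per_cube = as.integer(samples_per_cube),
                 seed = seed),
            class = "sampler_config")
}

#' Valid corner range per axis
#'
#' A window of edge `input_size` anchored at 0-based corner `c` spans
#' `[c, c + input_size)`, so valid corners per axis are `0 ..
#' dim - input_size` inclusive; every window then lies fully inside the cube
#' and no padding is ever needed.
#'
#' @param cube_shape Integer vector of cube dimensions `(z, y, x)`.
#' @param input_size Window edge in voxels.
#' @return List with one `c(0, max)` inclusive range per axis.
#' @export
valid_corner_bounds <- function(cube_shape, input_size) {
  check_that(all(cube_shape >= input_size),
             "cube (%s) is smaller than the %d^3 window",
             paste(cube_shape, collapse = "x"), input_size)
  lapply(as.integer(cube_shape), function(d) c(0L, d - as.integer(input_size)))
}

#' Embed a label cube into padded input-cube coordinates
#'
#' The labeled region sits at the center of the padded input cube; voxels in
#' the padding ring are unlabeled (code 0) and therefore contribute nothing
#' to loss or evaluation.
#'
#' @param labels Label array of edge `cube_edge`.
#' @param pad Padding per side in voxels.
#' @return Label array of edge `cube_edge + 2 * pad`.
#' @export
embed_labels <- function(labels, pad) {
  d <- dim(labels)
  out <- array(LABEL_CODES[["unlabeled"]], d + 2L * pad)
  storage.mode(out) <- "integer"
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- labels
  out
}

#' Enumerate axon-labeled voxels usable as window corners
#'
#' Positions of axon voxels (code 2) in a label volume already embedded in
#' input-cube coordinates, clamped per axis to the valid corner range so that
#' every listed corner yields an in-bounds window; duplicates after clamping
#' are removed.
#'
#' @param labels Embedded label array (same shape as the input cube).
#' @param input_size Window edge in voxels.
#' @return Integer matrix with 0-based columns `z, y, x` (possibly 0 rows).
#' @export
axon_corner_list <- function(labels, input_size) {
  d <- dim(labels)
  idx <- which(labels == LABEL_CODES[["axon"]], arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(matrix(integer(0), ncol = 3, dimnames = list(NULL, c("z", "y", "x"))))
  corners <- idx - 1L  # to 0-based
  for (a in 1:3) corners[, a] <- pmin(corners[, a], d[a] - as.integer(input_size))
  corners <- unique(corners)
  colnames(corners) <- c("z", "y", "x")
  corners
}

#' Draw one training-window corner
#'
#' With probability `oversample_p` the corner is drawn uniformly from
#' `axon_corners` (falling back to the uniform draw when the list is empty);
#' otherwise each coordinate is drawn uniformly over its valid range.
#'
#' @param bounds Per-axis inclusive ranges from [valid_corner_bounds()].
#' @param axon_corners Optional 0-based corner matrix from
#'   [axon_corner_list()].
#' @param oversample_p Probability of the foreground draw.
#' @return Named integer vector `c(z, y, x)` of 0-based corner coordinates.
#' @export
draw_corner <- function(bounds, axon_corners = NULL, oversample_p = 0) {
  if (oversample_p > 0 && !is.null(axon_corners) &&
      nrow(axon_corners) > 0 && runif(1) < oversample_p) {
    out <- axon_corners[sample.int(nrow(axon_corners), 1L), ]
  } else {
    out <- vapply(bounds, function(b) b[1] + sample.int(b[2] - b[1] + 1L, 1L) - 1L,
                  integer(1))
  }
  out <- as.integer(out)
  names(out) <- c("z", "y", "x")
  out
}

#' Extract one input/target training sample
#'
#' The input window of edge `input_size` is anchored at `corner` (0-based,
#' half-open `[corner, corner + input_size)`); the target label window of
#' edge `input_size - 2 * margin` is anchored at `corner + margin` per axis,
#' spatially concentric with the input.  The full-resolution label window is
#' kept alongside the target so that spatial augmentation can transform
#' labels at input resolution before re-cropping the center.
#'
#' @param image Intensity array in input-cube coordinates.
#' @param labels Label array of the same shape (see [embed_labels()]).
#' @param corner 0-based `c(z, y, x)` corner.
#' @param config A [sampler_config()].
#' @return A `volume_sample` list with `input`, `labels` (input-sized label
#'   window), `target` (center-cropped labels), and `margin`.
#' @export
extract_sample <- function(image, labels, corner, config = sampler_config()) {
  stopifnot(all(dim(image) == dim(labels)))
  d <- dim(image)
  s <- config$input_size
  check_that(all(corner >= 0) && all(corner + s <= d),
             "corner (%s) out of bounds for %s cube",
             paste(corner, collapse = ","), paste(d, collapse = "x"))
  iz <- corner[1] + seq_len(s); iy <- corner[2] + seq_len(s)
  ix <- corner[3] + seq_len(s)
  input <- image[iz, iy, ix]
  labwin <- labels[iz, iy, ix]
  structure(list(input = input, labels = labwin,
                 target = crop_center(labwin, config$margin),
                 margin = config$margin),
            class = "volume_sample")
}

#' Center crop of a cubic array
#'
#' @param a 3D array.
#' @param margin Voxels removed per side on every axis.
#' @return The central sub-array.
#' @export
crop_center <- function(a, margin) {
  if (margin == 0) return(a)
  d <- dim(a)
  a[(margin + 1):(d[1] - margin),
    (margin + 1):(d[2] - margin),
    (margin + 1):(d[3] - margin)]
}
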