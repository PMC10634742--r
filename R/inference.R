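#' Offset between input and output windows
#'
#' Predictions exist only for the central region of each input window; the
#' per-side offset is half the difference of the edge lengths (64 and 36
#' give the canonical 14-voxel offset).
#'
#' @param input_size,output_size Window edges in voxels.
#' @return Integer margin per side.
#' @export
window_margin <- function(input_size, output_size) {
  check_that(input_size >= output_size,
             "input_size must be >= output_size")
  check_that((input_size - output_size) %% 2 == 0,
             "input_size - output_size must be even")
  as.integer((input_size - output_size) / 2)
}

#' Sliding-window geometry
#'
#' @param input_size,output_size Window edges in voxels.
#' @param stride Voxels between successive output windows; `NULL` selects
#'   the default at prediction time (abutting windows, or half-overlapping
#'   windows when Gaussian fusion is on).
#' @return A `window_geometry` list with the derived `margin`.
#' @export
window_geometry <- function(input_size = 64L, output_size = 36L,
                            stride = NULL) {
  m <- window_margin(input_size, output_size)
  if (!is.null(stride))
    check_that(stride >= 1 && stride <= output_size,
               "stride must lie in [1, output_size]")
  structure(list(input_size = as.integer(input_size),
                 output_size = as.integer(output_size),
                 margin = m,
                 stride = if (is.null(stride)) NULL else as.integer(stride)),
            class = "window_geometry")
}

#' Gaussian importance map for overlapping-window fusion
#'
#' Weights are `exp(-||v - center||^2 / (2 sigma^2))` over an
#' `output_size`^3 window, so the continuous center carries weight 1 and
#' weights fall off toward the window faces, where predictions have the
#' least surrounding context.
#'
#' @param output_size Window edge in voxels.
#' @param sigma Gaussian width in voxels.
#' @return 3D array of positive weights.
#' @export
gaussian_importance <- function(output_size, sigma) {
  check_that(sigma > 0, "sigma must be positive")
  n <- output_size
  ctr <- (n + 1) / 2
  d2 <- (seq_len(n) - ctr)^2
  w1 <- exp(-d2 / (2 * sigma^2))
  outer(outer(w1, w1), w1)
}

window_starts <- function(total, size, stride) {
  check_that(total >= size, "region smaller than window")
  s <- seq.int(0L, total - size, by = stride)
  if (s[length(s)] != total - size) s <- c(s, total - size)
  as.integer(s)
}

#' Sliding-window whole-volume prediction with overlap fusion
#'
#' Tiles the (already margin-padded) input volume with overlapping windows,
#' predicts each, and fuses overlaps as a weighted mean: each voxel's value
#' is the sum of `weight * prediction` over covering windows divided by the
#' sum of the weights used at that location.  With `gaussian = TRUE` the
#' weights come from [gaussian_importance()] (windows half-overlap by
#' default); otherwise uniform weights and abutting windows are used.
#' Windows at the far faces are shifted inward to end flush with the volume,
#' so every output voxel is covered.  A 188^3 input yields a 160^3
#' prediction with the default geometry.
#'
#' @param model An `axseg_net`, or a function mapping a normalized
#'   `input_size`^3 window to an `output_size`^3 prediction.
#' @param image Intensity volume `(z, y, x)`; every dimension must be at
#'   least `input_size`.
#' @param geometry A [window_geometry()].
#' @param gaussian Use Gaussian importance weighting.
#' @param sigma Gaussian width; default `output_size / 8`.
#' @param stride Overrides the geometry/default stride.
#' @param max_intensity Divisor applied to each window before prediction
#'   (set to 1 if `image` is already normalized).
#' @return Probability volume of edge `dim(image) - 2 * margin`.
#' @export
sliding_window_predict <- function(model, image,
                                   geometry = window_geometry(),
                                   gaussian = TRUE, sigma = NULL,
                                   stride = NULL, max_intensity = 65535) {
  predictor <- if (is.function(model)) model else
    function(win) net_predict(model, win)
  ins <- geometry$input_size
  outs <- geometry$output_size
  m <- geometry$margin
  d <- dim(image)
  check_that(all(d >= ins), "image (%s) smaller than one %d^3 window",
             paste(d, collapse = "x"), ins)
  od <- d - 2L * m
  stride <- stride %||% geometry$stride %||%
    if (gaussian) max(1L, outs %/% 2L) else outs
  check_that(stride >= 1 && stride <= outs,
             "stride must lie in [1, output_size]")
  sigma <- sigma %||% (outs / 8)
  wmap <- if (gaussian) gaussian_importance(outs, sigma) else
    array(1, rep(outs, 3))

  num <- array(0, od)
  den <- array(0, od)
  sz <- window_starts(od[1], outs, stride)
  sy <- window_starts(od[2], outs, stride)
  sx <- window_starts(od[3], outs, stride)
  for (z in sz) for (y in sy) for (x in sx) {
    win <- image[z + seq_len(ins), y + seq_len(ins), x + seq_len(ins)] /
      max_intensity
    p <- predictor(win)
    rz <- z + seq_len(outs); ry <- y + seq_len(outs); rx <- x + seq_len(outs)
    num[rz, ry, rx] <- num[rz, ry, rx] + p * wmap
    den[rz, ry, rx] <- den[rz, ry, rx] + wmap
  }
  num / den
}

#' Threshold a probability volume
#'
#' Voxels strictly above the threshold are positive; a value exactly at the
#' threshold is negative.
#'
#' @param prob Probability volume.
#' @param threshold Scalar threshold.
#' @return Logical mask of the same shape.
#' @export
binarize <- function(prob, threshold = 0.5) {
  prob > threshold
}
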