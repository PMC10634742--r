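#' Configuration for the synthetic tubular phantom generator
#'
#' The phantom emulates the geometry of annotated light-sheet training data:
#' a `cube_edge`^3 labeled region (default 160) embedded at the center of a
#' padded input cube of edge `cube_edge + 2 * pad` (default 188), containing
#' bright tube-like axons on a dim background plus optional bright spheroid
#' artifacts, with additive Gaussian noise on a 16-bit intensity scale.
#'
#' @param cube_edge Edge length in voxels of the labeled region.
#' @param pad Padding in voxels per side of the input cube.
#' @param n_tubes Number of random-walk tubes.
#' @param tube_radius Length-2 integer range of tube radii in voxels.
#' @param axon_intensity_mean Mean intensity of axon voxels (16-bit scale).
#' @param background_intensity_mean Mean background intensity.
#' @param artifact_intensity_mean Mean intensity of artifact blobs.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param n_artifact_blobs Number of bright spheroid artifacts.
#' @param seed Integer seed; identical seeds reproduce identical phantoms
#'   bit for bit.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(cube_edge = 160L, pad = 14L, n_tubes = 6L,
                           tube_radius = c(1L, 3L),
                           axon_intensity_mean = 6000,
                           background_intensity_mean = 800,
                           artifact_intensity_mean = 9000,
                           noise_sd = 300,
                           n_artifact_blobs = 2L,
                           seed = 1L) {
  check_that(cube_edge > 0, "cube_edge must be positive")
  check_that(pad >= 0, "pad must be nonnegative")
  check_that(n_tubes >= 0, "n_tubes must be nonnegative")
  check_that(length(tube_radius) == 2 && all(tube_radius >= 1),
             "tube_radius must be a range of radii >= 1")
  check_that(max(tube_radius) < cube_edge / 2,
             "tube radius must be smaller than cube_edge/2")
  check_that(axon_intensity_mean > background_intensity_mean,
             "axon_intensity_mean must exceed background_intensity_mean")
  check_that(noise_sd >= 0, "noise_sd must be nonnegative")
  structure(list(cube_edge = as.integer(cube_edge), pad = as.integer(pad),
                 n_tubes = as.integer(n_tubes),
                 tube_radius = as.integer(tube_radius),
                 axon_intensity_mean = axon_intensity_mean,
                 background_intensity_mean = background_intensity_mean,
                 artifact_intensity_mean = artifact_intensity_mean,
                 noise_sd = noise_sd,
                 n_artifact_blobs = as.integer(n_artifact_blobs),
                 seed = seed),
            class = "phantom_config")
}

# Integer offsets of a digital ball of the given radius, as an n x 3 matrix.
sphere_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  keep <- g$dz^2 + g$dy^2 + g$dx^2 <= radius^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# Reflect coordinates into [1, n] (mirror boundary).
reflect_into <- function(p, n) {
  if (n == 1) return(rep(1, length(p)))
  period <- 2 * (n - 1)
  q <- (p - 1) %% period
  q <- ifelse(q > (n - 1), period - q, q)
  q + 1
}

# Stamp TRUE into `mask` at points (n x 3 real matrix, (z,y,x) 1-based)
# dilated by the ball of `radius`.
stamp_points <- function(mask, pts, radius) {
  d <- dim(mask)
  off <- sphere_offsets(radius)
  ip <- round(pts)
  nn <- nrow(ip); no <- nrow(off)
  z <- rep(ip[, 1], each = no) + rep(off[, 1], nn)
  y <- rep(ip[, 2], each = no) + rep(off[, 2], nn)
  x <- rep(ip[, 3], each = no) + rep(off[, 3], nn)
  keep <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
  mask[cbind(z[keep], y[keep], x[keep])] <- TRUE
  mask
}

# One random-walk polyline through a cube of edge E, rasterized at sub-voxel
# spacing.  Bounded turning angle gives smoothly curving tubes.
tube_polyline <- function(E, step = 4, turn_sd = 0.35) {
  pos <- runif(3, 1 + 0.1 * E, E - 0.1 * E)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  n_steps <- ceiling(2.2 * E / step)
  pts <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    dir <- dir + rnorm(3, sd = turn_sd)
    dir <- dir / sqrt(sum(dir^2))
    nxt <- pos + dir * step
    t <- seq(0, 1, by = 0.5 / step)
    seg <- cbind(pos[1] + t * (nxt[1] - pos[1]),
                 pos[2] + t * (nxt[2] - pos[2]),
                 pos[3] + t * (nxt[3] - pos[3]))
    seg[, 1] <- reflect_into(seg[, 1], E)
    seg[, 2] <- reflect_into(seg[, 2], E)
    seg[, 3] <- reflect_into(seg[, 3], E)
    pts[[s]] <- seg
    pos <- c(reflect_into(nxt[1], E), reflect_into(nxt[2], E),
             reflect_into(nxt[3], E))
  }
  do.call(rbind, pts)
}

#' Generate a synthetic axon phantom with dense ground-truth labels
#'
#' Produces a padded 16-bit intensity cube of edge `cube_edge + 2 * pad` and a
#' dense categorical label cube of edge `cube_edge` aligned with its center.
#' Axons are random-walk polylines dilated to a per-tube radius; artifacts are
#' bright spheroids; Gaussian noise is added and intensities are clamped to
#' `[0, 65535]` and rounded.  Label codes follow [LABEL_CODES] (no unlabeled
#' and no edge voxels at this stage); axons take precedence where tubes and
#' artifacts overlap.
#'
#' All arrays are indexed `(z, y, x)`.  The same configuration (including
#' `seed`) reproduces identical output bit for bit.
#'
#' @param config A [phantom_config()].
#' @return List with elements `image` (padded intensity array), `labels`
#'   (dense label array of edge `cube_edge`), and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  E <- config$cube_edge + 2L * config$pad
  with_seed(config$seed, {
    axon <- array(FALSE, c(E, E, E))
    art <- array(FALSE, c(E, E, E))
    if (config$n_artifact_blobs > 0) {
      for (i in seq_len(config$n_artifact_blobs)) {
        ctr <- matrix(runif(3, 1 + 3, E - 3), nrow = 1)
        art <- stamp_points(art, ctr, runif(1, 2.5, 5))
      }
    }
    if (config$n_tubes > 0) {
      radii <- config$tube_radius
      for (i in seq_len(config$n_tubes)) {
        r <- if (radii[1] == radii[2]) radii[1] else
          sample(seq(radii[1], radii[2]), 1)
        axon <- stamp_points(axon, tube_polyline(E), r)
      }
    }
    img <- array(config$background_intensity_mean, c(E, E, E))
    img[art] <- config$artifact_intensity_mean
    img[axon] <- config$axon_intensity_mean
    if (config$noise_sd > 0)
      img <- img + rnorm(length(img), sd = config$noise_sd)
    img <- round(pmin(pmax(img, 0), 65535))

    ctr <- (config$pad + 1):(config$pad + config$cube_edge)
    labels <- array(LABEL_CODES[["background"]],
                    rep(config$cube_edge, 3))
    labels[art[ctr, ctr, ctr]] <- LABEL_CODES[["artifact"]]
    labels[axon[ctr, ctr, ctr]] <- LABEL_CODES[["axon"]]
    storage.mode(labels) <- "integer"
    list(image = img, labels = labels, config = config)
  })
}

#' Restrict dense labels to a sparse subset of z-slices
#'
#' Emulates the sparse manual-annotation scheme in which only every
#' `stride`-th z-slice is annotated, starting at 0-based slice index `start`.
#' All other slices are set to code 0 (unlabeled).
#'
#' Slice indices are 0-based: with the defaults (`stride = 20`, `start = 15`)
#' a 160-slice cube retains labels on slices 15, 35, 55, ..., 155.
#'
#' @param dense Dense label array `(z, y, x)`.
#' @param stride Annotation period in slices.
#' @param start 0-based index of the first annotated slice.
#' @return Label array of the same shape with unlabeled slices zeroed.
#' @export
sparsify_labels <- function(dense, stride = 20L, start = 15L) {
  nz <- dim(dense)[1]
  check_that(stride >= 1, "stride must be >= 1")
  check_that(start >= 0 && start < nz,
             "start must be a 0-based slice index within the cube (0..%d)",
             nz - 1L)
  z0 <- seq_len(nz) - 1L
  keep <- z0 >= start & (z0 - start) %% stride == 0
  out <- dense
  out[!keep, , ] <- LABEL_CODES[["unlabeled"]]
  out
}
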