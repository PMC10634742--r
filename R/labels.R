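#' Loss weights per annotation class
#'
#' Dimensionless multipliers applied per voxel in the masked cross-entropy
#' loss: axons are up-weighted, the edge ring is strongly down-weighted so
#' that boundary disagreements of a single voxel are barely penalised, and
#' unlabeled voxels carry weight zero (they are masked out entirely).
#'
#' @param axon,background,artifact,edge,unlabeled Nonnegative weights.
#' @return A `class_weights` list.
#' @export
class_weights <- function(axon = 1.5, background = 0.2, artifact = 0.8,
                          edge = 0.05, unlabeled = 0) {
  w <- c(unlabeled = unlabeled, background = background, axon = axon,
         artifact = artifact, edge = edge)
  check_that(all(w >= 0), "class weights must be nonnegative")
  check_that(unlabeled == 0, "unlabeled weight must be exactly 0")
  structure(as.list(w), class = "class_weights")
}

# Lookup vector ordered by label code 0..4.
weight_lookup <- function(weights) {
  stopifnot(inherits(weights, "class_weights"))
  c(weights$unlabeled, weights$background, weights$axon,
    weights$artifact, weights$edge)
}

# In-plane 8-neighbourhood binary dilation of a logical matrix.
dilate8 <- function(m) {
  d <- dim(m)
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- seq_len(d[1]) + dy
    xs <- seq_len(d[2]) + dx
    okY <- ys >= 1 & ys <= d[1]
    okX <- xs >= 1 & xs <= d[2]
    out[okY, okX] <- out[okY, okX] | m[ys[okY], xs[okX]]
  }
  out
}

#' Derive the edge class around annotated axons
#'
#' On every labeled slice, each background voxel that is 8-adjacent in-plane
#' to an axon voxel is recoded as edge (code 4), yielding the one-voxel
#' boundary ring that absorbs annotator boundary uncertainty.  Axon,
#' artifact, and unlabeled voxels are never modified.  Edges are computed per
#' 2D slice because annotation exists only on a sparse subset of slices, so a
#' 3D boundary is undefined across unlabeled gaps.
#'
#' @param labels Label array `(z, y, x)` containing no edge codes yet.
#' @return Label array with edge voxels added.
#' @export
generate_edges <- function(labels) {
  if (any(labels == LABEL_CODES[["edge"]]))
    stop("labels already contain edge voxels (code 4)", call. = FALSE)
  out <- labels
  for (z in which(labeled_mask(labels))) {
    sl <- labels[z, , ]
    ax <- sl == LABEL_CODES[["axon"]]
    if (!any(ax)) next
    edge <- dilate8(ax) & !ax & sl == LABEL_CODES[["background"]]
    sl[edge] <- LABEL_CODES[["edge"]]
    out[z, , ] <- sl
  }
  out
}

#' Which z-slices carry annotation
#'
#' @param labels Label array `(z, y, x)`.
#' @return Logical vector with one element per slice; element `i` refers to
#'   0-based slice index `i - 1` and is `TRUE` iff the slice contains any
#'   nonzero code.
#' @export
labeled_mask <- function(labels) {
  apply(labels != LABEL_CODES[["unlabeled"]], 1, any)
}
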