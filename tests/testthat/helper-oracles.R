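# Independent brute-force references used to check the vectorized
# implementations on small volumes.

# Edge derivation: per labeled slice, every background voxel with an axon
# voxel among its in-plane 8-neighbours becomes an edge voxel.
edges_oracle <- function(labels) {
  out <- labels
  d <- dim(labels)
  for (z in seq_len(d[1])) {
    if (all(labels[z, , ] == 0)) next
    for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      if (labels[z, y, x] != 1) next
      hit <- FALSE
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        yy <- y + dy; xx <- x + dx
        if (yy >= 1 && yy <= d[2] && xx >= 1 && xx <= d[3] &&
            labels[z, yy, xx] == 2) hit <- TRUE
      }
      if (hit) out[z, y, x] <- 4L
    }
  }
  out
}

# Confusion counting: voxel-by-voxel triple loop over annotated voxels.
confusion_oracle <- function(pred, labels) {
  d <- dim(labels)
  tp <- tn <- fp <- fn <- ea <- 0L
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    code <- labels[z, y, x]
    if (code == 0) next
    p <- isTRUE(pred[z, y, x])
    if (code == 2) {
      if (p) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (p) {
        fp <- fp + 1L
        if (code == 4) ea <- ea + 1L
      } else tn <- tn + 1L
    }
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn, EA = ea)
}

dice_coef <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Small annotated phantom cube prepared for the training pipeline
# (sparse labels with edges, embedded in padded input coordinates).
make_tiny_cube <- function(cube_edge = 32, pad = 4, n_tubes = 2, seed = 3,
                           stride = 10, start = 5) {
  ph <- generate_phantom(phantom_config(cube_edge = cube_edge, pad = pad,
                                        n_tubes = n_tubes, seed = seed))
  sparse <- generate_edges(sparsify_labels(ph$labels, stride, start))
  list(image = ph$image, labels = embed_labels(sparse, pad),
       sparse = sparse, dense = ph$labels, phantom = ph)
}
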