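#' Read a volume from TIFF
#'
#' Accepts either a multipage TIFF or a directory of per-slice 2D TIFFs in
#' lexicographic z-order.  Volumes are returned in `(z, y, x)` order.
#' Images round-trip losslessly at 16 bits (integer counts 0..65535), labels
#' at 8 bits (codes 0..255), and probability volumes as 32-bit float.
#'
#' @param path File or directory path.
#' @param kind One of `"image"` (16-bit), `"labels"` (8-bit), or
#'   `"probability"` (float in `[0, 1]`).
#' @return Numeric or integer array `(z, y, x)`.
#' @export
read_volume <- function(path, kind = c("image", "labels", "probability")) {
  kind <- match.arg(kind)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    check_that(length(files) > 0, "no TIFF slices found in %s", path)
    slices <- lapply(files, tiff::readTIFF)
  } else {
    check_that(file.exists(path), "no such file: %s", path)
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
  }
  dims <- lapply(slices, dim)
  check_that(all(vapply(dims, identical, logical(1), dims[[1]])),
             "slices in %s have inconsistent shapes", path)
  check_that(all(vapply(slices, is.numeric, logical(1))),
             "slices in %s have mixed or unsupported sample types", path)
  nz <- length(slices)
  vol <- array(0, c(nz, dims[[1]]))
  for (z in seq_len(nz)) vol[z, , ] <- slices[[z]]
  switch(kind,
         image = {
           vol <- round(vol * 65535)
           storage.mode(vol) <- "integer"
           vol
         },
         labels = {
           vol <- round(vol * 255)
           storage.mode(vol) <- "integer"
           vol
         },
         probability = vol)
}

#' Write a volume to TIFF
#'
#' The inverse of [read_volume()].  When `path` ends in `.tif`/`.tiff` a
#' multipage TIFF is written atomically (temporary file then rename);
#' otherwise `path` is treated as a directory and one zero-padded
#' `slice_NNNN.tif` per z-slice is written.
#'
#' @param vol Volume array `(z, y, x)`.
#' @param path Destination file or directory.
#' @param kind See [read_volume()]; determines bit depth (16 / 8 / 32
#'   float).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path,
                         kind = c("image", "labels", "probability")) {
  kind <- match.arg(kind)
  bits <- switch(kind, image = 16L, labels = 8L, probability = 32L)
  denom <- switch(kind, image = 65535, labels = 255, probability = 1)
  nz <- dim(vol)[1]
  slices <- lapply(seq_len(nz), function(z) vol[z, , ] / denom)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tmp <- tempfile(tmpdir = dirname(path), fileext = ".tif")
    tiff::writeTIFF(slices, tmp, bits.per.sample = bits)
    file.rename(tmp, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (z in seq_len(nz))
      tiff::writeTIFF(slices[[z]],
                      file.path(path, sprintf("slice_%04d.tif", z - 1L)),
                      bits.per.sample = bits)
  }
  invisible(path)
}
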