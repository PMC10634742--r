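test_that("the input/output offset arithmetic holds", {
  expect_equal(window_margin(64, 36), 14L)
  expect_equal(window_margin(64, 64), 0L)
  expect_equal(window_margin(100, 50), 25L)
  expect_error(window_margin(64, 37), "even")
  expect_error(window_margin(36, 64), ">=")
})

test_that("the Gaussian importance map peaks centrally and is symmetric", {
  w <- gaussian_importance(9, 2)
  expect_equal(dim(w), rep(9, 3))
  expect_true(all(w > 0))
  expect_equal(arrayInd(which.max(w), dim(w)), matrix(c(5L, 5L, 5L), 1))
  expect_equal(w, w[9:1, , ])
  expect_equal(w, w[, 9:1, ])
  expect_equal(w, w[, , 9:1])
  # very wide Gaussian tends to uniform weights
  expect_true(all(abs(gaussian_importance(8, 1e6) - 1) < 1e-9))
  expect_error(gaussian_importance(8, 0), "sigma")
})

test_that("a constant predictor is reproduced exactly under any fusion", {
  geom <- window_geometry(8, 4)
  img <- array(runif(16^3), rep(16, 3))
  for (g in c(TRUE, FALSE)) for (stride in c(1, 2, 4)) {
    out <- sliding_window_predict(function(win) array(0.37, rep(4, 3)),
                                  img, geom, gaussian = g, stride = stride,
                                  max_intensity = 1)
    expect_equal(dim(out), rep(12, 3))
    expect_equal(out, array(0.37, rep(12, 3)), tolerance = 1e-12)
  }
})

test_that("non-overlapping fusion reassembles the window predictions", {
  # the identity predictor (center crop of the window) must reproduce the
  # cropped image exactly, whatever the overlap handling does at flush edges
  geom <- window_geometry(8, 4)
  img <- array(runif(18^3), rep(18, 3))
  for (g in c(TRUE, FALSE)) {
    out <- sliding_window_predict(function(win) crop_center(win, 2),
                                  img, geom, gaussian = g, stride = 4,
                                  max_intensity = 1)
    expect_equal(out, crop_center(img, 2), tolerance = 1e-12)
  }
})

test_that("gaussian and uniform fusion agree on single-coverage voxels", {
  set.seed(3)
  geom <- window_geometry(8, 4)
  img <- array(runif(16^3), rep(16, 3))
  predictor <- function(win) array(mean(win), rep(4, 3))
  # stride = output size: every voxel covered exactly once
  a <- sliding_window_predict(predictor, img, geom, gaussian = TRUE,
                              stride = 4, max_intensity = 1)
  b <- sliding_window_predict(predictor, img, geom, gaussian = FALSE,
                              stride = 4, max_intensity = 1)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("fused values are convex combinations of window predictions", {
  set.seed(9)
  geom <- window_geometry(8, 4)
  img <- array(runif(14^3), rep(14, 3))
  lo <- array(Inf, rep(10, 3))
  hi <- array(-Inf, rep(10, 3))
  predictor <- function(win) array(runif(4^3), rep(4, 3))
  # record per-window extremes with the same deterministic draw sequence
  set.seed(101)
  preds <- list()
  k <- 0
  rec_predictor <- function(win) {
    k <<- k + 1
    preds[[k]] <<- array(runif(4^3), rep(4, 3))
    preds[[k]]
  }
  out <- sliding_window_predict(rec_predictor, img, geom, gaussian = TRUE,
                                stride = 2, max_intensity = 1)
  # rebuild coverage extremes
  starts <- axseg:::window_starts(10, 4, 2)
  k <- 0
  for (z in starts) for (y in starts) for (x in starts) {
    k <- k + 1
    rz <- z + 1:4; ry <- y + 1:4; rx <- x + 1:4
    lo[rz, ry, rx] <- pmin(lo[rz, ry, rx], preds[[k]])
    hi[rz, ry, rx] <- pmax(hi[rz, ry, rx], preds[[k]])
  }
  expect_true(all(out >= lo - 1e-12))
  expect_true(all(out <= hi + 1e-12))
})

test_that("every output voxel is covered for any stride", {
  for (stride in 1:4) {
    s <- axseg:::window_starts(10, 4, stride)
    covered <- rep(FALSE, 10)
    for (st in s) covered[st + 1:4] <- TRUE
    expect_true(all(covered))
    expect_equal(s[length(s)], 6L)
  }
})

test_that("a 188^3 padded cube predicts a 160^3 volume", {
  img <- array(0.5, rep(188, 3))
  geom <- window_geometry(64, 36)
  out <- sliding_window_predict(function(win) crop_center(win, 14), img,
                                geom, gaussian = FALSE, max_intensity = 1)
  expect_equal(dim(out), rep(160, 3))
  expect_true(all(out == 0.5))
})

test_that("images smaller than one window are rejected", {
  expect_error(
    sliding_window_predict(function(w) w, array(0, rep(32, 3)),
                           window_geometry(64, 36)),
    "smaller")
})

test_that("binarization is strictly above-threshold", {
  p <- array(c(0.49, 0.5, 0.51, 0), c(4, 1, 1))
  expect_equal(as.vector(binarize(p)), c(FALSE, FALSE, TRUE, FALSE))
  expect_false(any(binarize(array(0, c(2, 2, 2)))))
})
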