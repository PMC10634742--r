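make_sample <- function(edge = 16, margin = 4, seed = 1) {
  set.seed(seed)
  img <- array(runif(edge^3, 0, 65535), rep(edge, 3))
  lab <- array(sample(c(1L, 1L, 2L, 3L, 4L), edge^3, TRUE), rep(edge, 3))
  extract_sample(img, lab, c(0L, 0L, 0L),
                 sampler_config(input_size = edge, margin = margin))
}

test_that("flipping twice along the same axes restores the sample", {
  smp <- make_sample()
  for (axes in list(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE),
                    c(TRUE, TRUE, TRUE))) {
    once <- random_flip(smp, axes)
    twice <- random_flip(once, axes)
    expect_identical(twice$input, smp$input)
    expect_identical(twice$labels, smp$labels)
    expect_identical(twice$target, smp$target)
  }
})

test_that("a no-flip draw is the identity", {
  smp <- make_sample()
  out <- random_flip(smp, c(FALSE, FALSE, FALSE))
  expect_identical(out, smp)
})

test_that("a tagged voxel and its label move together under flips", {
  edge <- 12
  img <- array(0, rep(edge, 3))
  lab <- array(1L, rep(edge, 3))
  img[3, 5, 7] <- 65535
  lab[3, 5, 7] <- 2L
  smp <- extract_sample(img, lab, c(0L, 0L, 0L),
                        sampler_config(input_size = edge, margin = 0))
  out <- random_flip(smp, c(TRUE, FALSE, TRUE))
  pos <- which(out$input == 65535, arr.ind = TRUE)
  expect_equal(as.integer(pos), c(edge - 3 + 1, 5, edge - 7 + 1))
  expect_equal(out$labels[pos], 2L)
})

test_that("zero rotation and zero elastic magnitude is the exact identity", {
  smp <- make_sample()
  out <- spatial_transform(smp, augment_config(),
                           angles = c(0, 0, 0),
                           elastic = list(alpha = 0, sigma = 1))
  expect_identical(out, smp)
})

test_that("a 90-degree in-plane rotation is an exact index permutation", {
  smp <- make_sample(edge = 16)
  out <- spatial_transform(smp, augment_config(),
                           angles = c(90, 0, 0),
                           elastic = list(alpha = 0, sigma = 1))
  n <- 16
  # pull-back: out[z, y, x] = in[z, n + 1 - x, y]
  ref_in <- smp$input
  ref_lab <- smp$labels
  perm_in <- array(0, dim(ref_in))
  perm_lab <- array(0L, dim(ref_lab))
  for (y in 1:n) for (x in 1:n) {
    perm_in[, y, x] <- ref_in[, n + 1 - x, y]
    perm_lab[, y, x] <- ref_lab[, n + 1 - x, y]
  }
  expect_equal(out$input, perm_in, tolerance = 1e-9)
  expect_identical(out$labels, perm_lab)
})

test_that("labels contain only valid codes after elastic deformation", {
  set.seed(20)
  smp <- make_sample(edge = 16)
  for (i in 1:5) {
    out <- spatial_transform(smp, augment_config(),
                             angles = runif(3, -15, 15),
                             elastic = list(alpha = 120, sigma = 10))
    expect_true(all(out$labels %in% 0:4))
    expect_identical(out$target, crop_center(out$labels, out$margin))
  }
})

test_that("image marker and label stripe stay co-registered", {
  set.seed(30)
  edge <- 32
  img <- array(500, rep(edge, 3))
  lab <- array(1L, rep(edge, 3))
  img[15:18, 10:24, 15:18] <- 60000   # bright bar
  lab[15:18, 10:24, 15:18] <- 2L
  smp <- extract_sample(img, lab, c(0L, 0L, 0L),
                        sampler_config(input_size = edge, margin = 0))
  for (i in 1:5) {
    out <- spatial_transform(smp, augment_config(),
                             angles = runif(3, -15, 15),
                             elastic = list(alpha = runif(1, 0, 200),
                                            sigma = runif(1, 9, 13)))
    marker <- out$input > 30000
    stripe <- out$labels == 2L
    expect_gte(dice_coef(marker, stripe), 0.9)
  }
})

test_that("intensity augmentation implements input/max * s + c", {
  cfg <- augment_config()
  x <- array(runif(5^3, 0, 65535), rep(5, 3))
  expect_equal(intensity_augment(x, cfg, s = 1, c = 0), x / 65535)
  z <- array(0, rep(4, 3))
  expect_true(all(intensity_augment(z, cfg, s = 1.1, c = 0.03) == 0.03))
  # linearity: doubling the input doubles the scaled part
  a <- intensity_augment(x, cfg, s = 0.9, c = 0.02)
  b <- intensity_augment(2 * x, cfg, s = 0.9, c = 0.02)
  expect_equal(b, 2 * (a - 0.02) + 0.02, tolerance = 1e-12)
})

test_that("generator-level augmentation is deterministic under a fixed seed", {
  cube <- make_tiny_cube(cube_edge = 32, pad = 4, n_tubes = 2, seed = 3)
  scfg <- sampler_config(input_size = 16, margin = 4)
  acfg <- augment_config(enable_rotation = TRUE, enable_elastic = TRUE)
  gen <- make_batch_generator(list(cube[c("image", "labels")]), scfg, acfg)
  set.seed(123); b1 <- gen(2)
  set.seed(123); b2 <- gen(2)
  expect_identical(b1, b2)
})
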