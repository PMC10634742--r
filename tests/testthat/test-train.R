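test_that("the weighted loss evaluates the single-voxel hand computation", {
  # one axon voxel predicted at 0.5: 1.5 * (-ln 0.5)
  l <- weighted_loss(array(0.5, c(1, 1, 1)), array(2L, c(1, 1, 1)))
  expect_equal(l, 1.5 * log(2), tolerance = 1e-9)
})

test_that("fully unlabeled targets give zero loss with a warning", {
  expect_warning(
    l <- weighted_loss(array(0.7, c(2, 2, 2)), array(0L, c(2, 2, 2))),
    "nonzero")
  expect_equal(l, 0)
})

test_that("near-perfect predictions drive the loss toward zero", {
  tg <- array(c(2L, 1L, 4L, 3L), c(4, 1, 1))
  p_good <- array(c(1 - 1e-9, 1e-9, 1e-9, 1e-9), c(4, 1, 1))
  expect_lt(weighted_loss(p_good, tg), 1e-5)
})

test_that("the weighted loss matches a per-voxel loop on small windows", {
  set.seed(23)
  w <- class_weights()
  wl <- c(w$unlabeled, w$background, w$axon, w$artifact, w$edge)
  for (i in 1:20) {
    d <- sample(2:5, 3, TRUE)
    tg <- array(sample(0:4, prod(d), TRUE), d)
    p <- array(runif(prod(d), 0.01, 0.99), d)
    acc <- 0; nnz <- 0
    for (v in seq_len(prod(d))) {
      ww <- wl[tg[v] + 1]
      if (ww > 0) nnz <- nnz + 1
      y <- as.numeric(tg[v] == 2)
      acc <- acc + ww * -(y * log(p[v]) + (1 - y) * log(1 - p[v]))
    }
    expected <- if (nnz == 0) 0 else acc / nnz
    if (nnz == 0) next
    expect_equal(weighted_loss(p, tg, w), expected, tolerance = 1e-10)
  }
})

test_that("steps per epoch floor-divide with a minimum of one", {
  expect_equal(steps_per_epoch(700, 6), 116L)
  expect_equal(steps_per_epoch(100, 6), 16L)
  expect_equal(steps_per_epoch(6, 6), 1L)
  expect_equal(steps_per_epoch(3, 6), 1L)
  expect_error(steps_per_epoch(100, 0), "batch_size")
})

test_that("plateau scheduling reduces the rate after the stated patience", {
  lrs <- plateau_schedule(rep(1, 8), lr0 = 1e-4, factor = 0.1, patience = 2)
  expect_equal(lrs[1:3], rep(1e-4, 3))
  expect_equal(lrs[4], 1e-5)
  expect_equal(lrs[7], 1e-6)
  # an improvement resets the wait counter
  lrs2 <- plateau_schedule(c(1, 0.9, 0.95, 0.8, 0.9, 0.95), 1e-4,
                           patience = 2)
  expect_equal(lrs2, c(rep(1e-4, 6)))
  # min_lr clamps the decay
  lrs3 <- plateau_schedule(rep(1, 20), 1e-4, patience = 1, min_lr = 1e-5)
  expect_true(all(lrs3 >= 1e-5))
  expect_equal(lrs3[20], 1e-5)
})

fixed_generators <- function(seed = 31) {
  set.seed(seed)
  s <- 16L; o <- 8L; n <- 4L
  x <- array(runif(s^3 * n, 0, 0.2), c(s, s, s, 1, n))
  tg <- array(1L, c(o, o, o, 1, n))
  for (k in seq_len(n)) {
    blob <- array(FALSE, c(s, s, s))
    blob[6:11, 6:11, 6:11] <- TRUE
    x[, , , 1, k][blob] <- x[, , , 1, k][blob] + 0.6
    tg[2:7, 2:7, 2:7, 1, k] <- 2L
  }
  gen <- function(batch_size) {
    ks <- sample(n, batch_size, replace = TRUE)
    list(x = x[, , , , ks, drop = FALSE], target = tg[, , , , ks, drop = FALSE])
  }
  gen
}

test_that("a tiny training run reduces the loss and tracks the best epoch", {
  gen <- fixed_generators()
  net <- build_network(unet_config(input_size = 16, margin = 4, depth = 2,
                                   base_filters = 2, seed = 9))
  cfg <- train_config(epochs = 5, batch_size = 2, learning_rate = 1e-3,
                      n_train = 4, n_val = 2, seed = 77)
  fit <- train_model(net, gen, gen, cfg)
  h <- fit$history
  expect_equal(nrow(h), 5)
  expect_lt(h$train_loss[5], h$train_loss[1])
  expect_true(all(h$lr == 1e-3))
  expect_equal(fit$checkpoint$val_loss, min(h$val_loss))
  expect_equal(h$val_loss[fit$checkpoint$epoch], fit$checkpoint$val_loss)
})

test_that("a reloaded checkpoint reproduces its recorded validation loss", {
  set.seed(55)
  s <- 16L
  xb <- array(runif(s^3 * 2), c(s, s, s, 1, 2))
  tb <- array(sample(1:2, 8^3 * 2, TRUE), c(8, 8, 8, 1, 2))
  gen <- function(batch_size) list(x = xb, target = tb)
  net <- build_network(unet_config(input_size = 16, margin = 4, depth = 2,
                                   base_filters = 2, seed = 10))
  cfg <- train_config(epochs = 3, batch_size = 2, learning_rate = 1e-3,
                      n_train = 2, n_val = 2, seed = 66)
  fit <- train_model(net, gen, gen, cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit$checkpoint, path)
  ck <- load_checkpoint(path)
  fw <- net_forward(ck$net, xb, training = FALSE)
  expect_equal(weighted_loss(fw$prob, tb, cfg$class_weights),
               ck$val_loss, tolerance = 1e-6)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$epoch, ck$epoch)
})

test_that("non-finite losses abort with a diagnostic", {
  bad_gen <- function(batch_size)
    list(x = array(NaN, c(16, 16, 16, 1, 1)),
         target = array(2L, c(8, 8, 8, 1, 1)))
  net <- build_network(unet_config(input_size = 16, margin = 4, depth = 2,
                                   base_filters = 2, seed = 11))
  cfg <- train_config(epochs = 1, batch_size = 1, n_train = 1, n_val = 1)
  expect_error(train_model(net, bad_gen, bad_gen, cfg), "non-finite")
})

test_that("the plateau scheduler is honoured inside the training loop", {
  gen <- fixed_generators(seed = 40)
  net <- build_network(unet_config(input_size = 16, margin = 4, depth = 2,
                                   base_filters = 2, seed = 12))
  cfg <- train_config(epochs = 6, batch_size = 2, learning_rate = 1e-4,
                      scheduler = list(type = "plateau", factor = 0.1,
                                       patience = 1, min_lr = 1e-7),
                      n_train = 2, n_val = 2, seed = 88)
  fit <- train_model(net, gen, gen, cfg)
  h <- fit$history
  expect_equal(h$lr, plateau_schedule(h$val_loss, 1e-4, 0.1, 1, 1e-7))
})

test_that("invalid training configurations are rejected", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(scheduler = list(type = "plateau", factor = 2)),
               "factor")
  expect_error(train_config(scheduler = list(type = "nope")), "scheduler")
})
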