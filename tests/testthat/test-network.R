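tiny_cfg <- function(...) unet_config(input_size = 16, margin = 4, depth = 2,
                                      base_filters = 2, seed = 1, ...)

test_that("the forward pass realizes the 64^3 to 36^3 spatial contract", {
  net <- build_network(unet_config(input_size = 64, margin = 14, depth = 3,
                                   base_filters = 2, seed = 1))
  x <- array(runif(64^3), c(64, 64, 64, 1, 1))
  p <- net_forward(net, x)$prob
  expect_equal(dim(p), c(36, 36, 36, 1, 1))
  expect_true(all(p > 0 & p < 1))
})

test_that("zero head weights give a constant 0.5 probability map", {
  net <- build_network(tiny_cfg())
  j <- length(net$conv)
  net$conv[[j]]$W[] <- 0
  net$conv[[j]]$b[] <- 0
  x <- array(runif(16^3), c(16, 16, 16, 1, 1))
  expect_true(all(net_forward(net, x)$prob == 0.5))
})

test_that("weight initialization is reproducible by seed", {
  a <- build_network(tiny_cfg())
  b <- build_network(tiny_cfg())
  expect_identical(a$conv, b$conv)
  c <- build_network(unet_config(input_size = 16, margin = 4, depth = 2,
                                 base_filters = 2, seed = 2))
  expect_false(identical(a$conv, c$conv))
})

test_that("spatially unrealizable configurations are rejected", {
  expect_error(unet_config(input_size = 30, margin = 2, depth = 3),
               "divisible")
  expect_error(unet_config(input_size = 16, margin = 8, depth = 2),
               "positive")
})

test_that("layer selection resolves the documented index sets", {
  net <- build_network(unet_config(input_size = 32, margin = 4, depth = 3,
                                   base_filters = 2, seed = 1))
  expect_length(net$conv, 6)
  expect_equal(which(apply_layer_selection(net, "first2")$trainable), 1:2)
  expect_equal(which(apply_layer_selection(net, "middle2")$trainable), 3:4)
  expect_equal(which(apply_layer_selection(net, "last2")$trainable), 5:6)
  expect_equal(which(apply_layer_selection(net, "full")$trainable), 1:6)
  expect_equal(conv_layer_names(net),
               c("enc1", "enc2", "bottleneck", "dec2", "dec1", "head"))
})

test_that("frozen convolutional parameters are bit-identical after training", {
  set.seed(4)
  net <- apply_layer_selection(build_network(tiny_cfg()), "last2")
  before <- net$conv
  x <- array(runif(16^3 * 2), c(16, 16, 16, 1, 2))
  tg <- array(sample(0:4, 8^3 * 2, TRUE), c(8, 8, 8, 1, 2))
  st <- axseg:::adam_init(net)
  for (i in 1:3) {
    fw <- net_forward(net, x, training = TRUE)
    net <- fw$net
    gr <- net_backward(net, fw$cache,
                       axseg:::loss_grad_logits(fw$prob, tg, class_weights()))
    u <- axseg:::adam_step(net, gr, st, 1e-3)
    net <- u$net; st <- u$state
  }
  n <- length(net$conv)
  for (j in seq_len(n - 2))
    expect_identical(net$conv[[j]], before[[j]])
  expect_false(identical(net$conv[[n]], before[[n]]))
  expect_false(identical(net$conv[[n - 1]], before[[n - 1]]))
})

test_that("analytic gradients match finite differences through the network", {
  set.seed(42)
  cfg <- unet_config(input_size = 8, margin = 2, depth = 2, base_filters = 2,
                     seed = 7)
  net <- build_network(cfg)
  x <- array(runif(8^3 * 2), c(8, 8, 8, 1, 2))
  tg <- array(sample(0:4, 4^3 * 2, TRUE), c(4, 4, 4, 1, 2))
  w <- class_weights()
  loss_of <- function(nn) {
    fw <- net_forward(nn, x, training = TRUE)
    weighted_loss(fw$prob, tg, w)
  }
  fw <- net_forward(net, x, training = TRUE)
  gr <- net_backward(fw$net, fw$cache,
                     axseg:::loss_grad_logits(fw$prob, tg, w))
  eps <- 1e-6
  for (j in seq_along(net$conv)) {
    idx <- sample(length(net$conv[[j]]$W),
                  min(3, length(net$conv[[j]]$W)))
    for (i in idx) {
      np <- net; np$conv[[j]]$W[i] <- np$conv[[j]]$W[i] + eps; lp <- loss_of(np)
      nm <- net; nm$conv[[j]]$W[i] <- nm$conv[[j]]$W[i] - eps; lm <- loss_of(nm)
      expect_equal(gr$conv[[j]]$W[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
  for (j in seq_along(net$bn)) {
    if (is.null(net$bn[[j]])) next
    np <- net; np$bn[[j]]$gamma[1] <- np$bn[[j]]$gamma[1] + eps; lp <- loss_of(np)
    nm <- net; nm$bn[[j]]$gamma[1] <- nm$bn[[j]]$gamma[1] - eps; lm <- loss_of(nm)
    expect_equal(gr$bn[[j]]$gamma[1], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("net_predict wraps single windows", {
  net <- build_network(tiny_cfg())
  win <- array(runif(16^3), rep(16, 3))
  p <- net_predict(net, win)
  expect_equal(dim(p), rep(8, 3))
  expect_true(all(p > 0 & p < 1))
})
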