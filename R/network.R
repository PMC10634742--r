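#' Configuration of the 3D encoder-decoder segmentation network
#'
#' A compact U-style network whose spatial contract maps an `input_size`^3
#' window to an `(input_size - 2 * margin)`^3 single-channel axon-probability
#' map: convolutions use "same" padding throughout and the head crops the
#' central region, so predictions exist only where full spatial context is
#' available.  `depth` encoder levels (level `depth` is the bottleneck) give
#' an ordered list of `2 * depth` convolutional layers: `depth` on the
#' contracting path, `depth - 1` on the expanding path, and a final 1x1x1
#' head.
#'
#' @param input_size Input window edge; must be divisible by
#'   `2^(depth - 1)`.
#' @param margin Per-side crop of the head output.
#' @param depth Number of encoder levels (>= 2).
#' @param base_filters Channels at the first level; doubled per level.
#' @param use_batchnorm Insert batch normalization after every convolution
#'   except the head.
#' @param bn_momentum Running-statistics momentum.
#' @param update_frozen_bn_stats Keep updating running statistics of
#'   batch-norm layers attached to frozen convolutions during fine-tuning.
#' @param seed Seed for weight initialization.
#' @return A `unet_config` list (includes derived `output_size`).
#' @export
unet_config <- function(input_size = 64L, margin = 14L, depth = 3L,
                        base_filters = 8L, use_batchnorm = TRUE,
                        bn_momentum = 0.1, update_frozen_bn_stats = TRUE,
                        seed = NULL) {
  output_size <- input_size - 2L * margin
  check_that(output_size > 0, "input_size - 2*margin must be positive")
  check_that(depth >= 2, "depth must be >= 2")
  check_that(margin >= 0, "margin must be nonnegative")
  check_that(input_size %% 2^(depth - 1) == 0,
             "input_size (%d) must be divisible by 2^(depth-1) = %d",
             input_size, 2^(depth - 1))
  structure(list(input_size = as.integer(input_size),
                 margin = as.integer(margin),
                 output_size = as.integer(output_size),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 use_batchnorm = use_batchnorm,
                 bn_momentum = bn_momentum,
                 update_frozen_bn_stats = update_frozen_bn_stats,
                 seed = seed),
            class = "unet_config")
}

# Channel arithmetic for conv layer j in 1..2*depth.
conv_channels <- function(config, j) {
  d <- config$depth; f <- config$base_filters
  if (j <= d) {                       # contracting path (j == d: bottleneck)
    list(inc = if (j == 1) 1L else f * 2^(j - 2),
         out = f * 2^(j - 1), k = 3L)
  } else if (j < 2 * d) {             # expanding path, level l = 2d - j
    l <- 2L * d - j
    list(inc = f * 2^l + f * 2^(l - 1), out = f * 2^(l - 1), k = 3L)
  } else {                            # 1x1x1 head
    list(inc = f, out = 1L, k = 1L)
  }
}

#' Build the segmentation network
#'
#' Weights use He initialization; biases start at zero; batch-norm layers
#' start at identity with zero running mean and unit running variance.  The
#' convolutional layers form a deterministic ordered list (see
#' [conv_layer_names()]), which is what layer-selective fine-tuning indexes
#' into.  Identical seeds give identical initial parameters.
#'
#' @param config A [unet_config()].
#' @return An `axseg_net` object.
#' @export
build_network <- function(config = unet_config()) {
  stopifnot(inherits(config, "unet_config"))
  nconv <- 2L * config$depth
  with_seed(config$seed, {
    conv <- vector("list", nconv)
    bn <- vector("list", nconv)
    for (j in seq_len(nconv)) {
      ch <- conv_channels(config, j)
      fan_in <- ch$k^3 * ch$inc
      conv[[j]] <- list(
        W = array(rnorm(ch$k^3 * ch$inc * ch$out, sd = sqrt(2 / fan_in)),
                  c(ch$k, ch$k, ch$k, ch$inc, ch$out)),
        b = numeric(ch$out))
      if (config$use_batchnorm && j < nconv)
        bn[[j]] <- list(gamma = rep(1, ch$out), beta = numeric(ch$out),
                        rmean = numeric(ch$out), rvar = rep(1, ch$out))
    }
    structure(list(config = config, conv = conv, bn = bn,
                   trainable = rep(TRUE, nconv)),
              class = "axseg_net")
  })
}

#' Names of the ordered convolutional layers
#'
#' @param net An `axseg_net`.
#' @return Character vector, encoder layers first, then decoder, then head.
#' @export
conv_layer_names <- function(net) {
  d <- net$config$depth
  c(paste0("enc", seq_len(d - 1)), "bottleneck",
    paste0("dec", rev(seq_len(d - 1))), "head")
}

#' @export
print.axseg_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("axseg 3D encoder-decoder: %d^3 -> %d^3, depth %d, %d base filters\n",
              cfg$input_size, cfg$output_size, cfg$depth, cfg$base_filters))
  nm <- conv_layer_names(x)
  for (j in seq_along(x$conv)) {
    ch <- conv_channels(cfg, j)
    cat(sprintf("  [%d] %-10s %dx%dx%d conv %3d -> %3d  %s\n", j, nm[j],
                ch$k, ch$k, ch$k, ch$inc, ch$out,
                if (x$trainable[j]) "trainable" else "frozen"))
  }
  invisible(x)
}

#' Select which convolutional layers are trainable
#'
#' `first2`, `middle2`, and `last2` mark exactly two convolutional layers as
#' trainable (the two straddling the midpoint of the ordered layer list for
#' `middle2`); `full` marks all of them.  Batch-normalization layers are
#' always trainable regardless of the selector.  Frozen layer parameters are
#' bit-identical after any number of optimization steps.
#'
#' @param net An `axseg_net`.
#' @param selector One of `"full"`, `"first2"`, `"middle2"`, `"last2"`.
#' @return The network with its `trainable` flags updated.
#' @export
apply_layer_selection <- function(net,
                                  selector = c("full", "first2", "middle2",
                                               "last2")) {
  selector <- match.arg(selector)
  n <- length(net$conv)
  check_that(n >= 2, "network must have at least 2 convolutional layers")
  idx <- switch(selector,
                full = seq_len(n),
                first2 = 1:2,
                middle2 = c(floor(n / 2), floor(n / 2) + 1L),
                last2 = (n - 1L):n)
  net$trainable <- seq_len(n) %in% idx
  net
}

# ---- layer primitives -----------------------------------------------------

# per-channel sums of a (X,Y,Z,C,N) array
chan_sums <- function(x, V, C, N) {
  rowSums(matrix(colSums(matrix(x, V)), C, N))
}

bn_fwd <- function(layer, x, training, update, momentum, eps = 1e-5) {
  d <- dim(x); V <- prod(d[1:3]); C <- d[4]; N <- d[5]
  m <- V * N
  if (training) {
    mu <- chan_sums(x, V, C, N) / m
    xc <- x - rep(mu, each = V)        # recycles over N
    var <- chan_sums(xc * xc, V, C, N) / m
  } else {
    mu <- layer$rmean
    var <- layer$rvar
    xc <- x - rep(mu, each = V)
  }
  invstd <- 1 / sqrt(var + eps)
  xhat <- xc * rep(invstd, each = V)
  y <- xhat * rep(layer$gamma, each = V) + rep(layer$beta, each = V)
  dim(y) <- d
  if (update) {
    layer$rmean <- (1 - momentum) * layer$rmean + momentum * mu
    layer$rvar <- (1 - momentum) * layer$rvar + momentum * var
  }
  list(y = y, layer = layer,
       cache = list(xhat = xhat, invstd = invstd, gamma = layer$gamma,
                    V = V, C = C, N = N, training = training))
}

bn_bwd <- function(cache, gy) {
  V <- cache$V; C <- cache$C; N <- cache$N; m <- V * N
  dbeta <- chan_sums(gy, V, C, N)
  dgamma <- chan_sums(gy * cache$xhat, V, C, N)
  scale <- cache$gamma * cache$invstd
  if (cache$training) {
    dx <- rep(scale, each = V) *
      (gy - rep(dbeta / m, each = V) -
         cache$xhat * rep(dgamma / m, each = V))
  } else {
    dx <- rep(scale, each = V) * gy
  }
  dim(dx) <- dim(gy)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

block_fwd <- function(net, j, x, training) {
  cfg <- net$config
  cv <- conv3d_fwd(x, net$conv[[j]]$W, net$conv[[j]]$b)
  bn_cache <- NULL
  if (!is.null(net$bn[[j]])) {
    upd <- training && (net$trainable[j] || cfg$update_frozen_bn_stats)
    r <- bn_fwd(net$bn[[j]], cv, training, upd, cfg$bn_momentum)
    net$bn[[j]] <- r$layer
    cv <- r$y
    bn_cache <- r$cache
  }
  out <- pmax(cv, 0)
  list(out = out, net = net,
       cache = list(x_in = x, bn_cache = bn_cache, pre_relu = cv))
}

block_bwd <- function(net, j, bcache, gy) {
  g <- gy * (bcache$pre_relu > 0)
  g_bn <- NULL
  if (!is.null(bcache$bn_cache)) {
    r <- bn_bwd(bcache$bn_cache, g)
    g <- r$dx
    g_bn <- list(gamma = r$dgamma, beta = r$dbeta)
  }
  cb <- conv3d_bwd(bcache$x_in, net$conv[[j]]$W, g)
  list(g_conv = list(W = cb$gw, b = cb$gb), g_bn = g_bn, gx = cb$gx)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

crop_center5 <- function(x, m) {
  if (m == 0) return(x)
  d <- dim(x)
  x[(m + 1):(d[1] - m), (m + 1):(d[2] - m), (m + 1):(d[3] - m), , ,
    drop = FALSE]
}

# ---- forward / backward ---------------------------------------------------

#' Forward pass of the network
#'
#' In training mode batch statistics are used for batch normalization (and
#' running statistics updated, subject to the freeze configuration); in
#' evaluation mode running statistics are used.  The returned `net` carries
#' any updated running statistics and must replace the caller's copy during
#' training.
#'
#' @param net An `axseg_net`.
#' @param x Input tensor `(X, Y, Z, 1, N)` of normalized intensities.
#' @param training Logical.
#' @return List with `prob` (cropped sigmoid output, `(O, O, O, 1, N)`),
#'   `cache` (for [net_backward()]), and `net`.
#' @export
net_forward <- function(net, x, training = FALSE) {
  cfg <- net$config
  d <- cfg$depth
  stopifnot(length(dim(x)) == 5)
  blocks <- vector("list", 2L * d)
  pools <- vector("list", d - 1L)
  skips <- vector("list", d - 1L)
  h <- x
  for (i in seq_len(d - 1L)) {
    r <- block_fwd(net, i, h, training)
    net <- r$net; blocks[[i]] <- r$cache; h <- r$out
    skips[[i]] <- h
    mp <- maxpool3d_fwd(h)
    pools[[i]] <- list(argmax = mp$argmax, xdim = dim(h))
    h <- mp$y
  }
  r <- block_fwd(net, d, h, training)
  net <- r$net; blocks[[d]] <- r$cache; h <- r$out
  for (l in rev(seq_len(d - 1L))) {
    j <- 2L * d - l
    up <- upsample3d_fwd(h)
    h <- concat_channels(up, skips[[l]])
    r <- block_fwd(net, j, h, training)
    net <- r$net; blocks[[j]] <- r$cache; h <- r$out
  }
  j <- 2L * d
  logits <- conv3d_fwd(h, net$conv[[j]]$W, net$conv[[j]]$b)
  blocks[[j]] <- list(x_in = h)
  lc <- crop_center5(logits, cfg$margin)
  prob <- 1 / (1 + exp(-lc))
  list(prob = prob,
       cache = list(blocks = blocks, pools = pools,
                    logits_dim = dim(logits)),
       net = net)
}

#' Backward pass of the network
#'
#' @param net The `axseg_net` used in the forward pass.
#' @param cache Cache returned by [net_forward()] (training mode).
#' @param dlogits Gradient of the loss with respect to the cropped logits
#'   (same shape as `prob`).
#' @return List of gradients: `conv[[j]]$W/b` and `bn[[j]]$gamma/beta`.
#' @export
net_backward <- function(net, cache, dlogits) {
  cfg <- net$config
  d <- cfg$depth
  blocks <- cache$blocks
  nconv <- 2L * d
  gconv <- vector("list", nconv)
  gbn <- vector("list", nconv)
  gskips <- vector("list", d - 1L)

  gl <- array(0, cache$logits_dim)
  m <- cfg$margin
  dd <- cache$logits_dim
  if (m == 0) gl[] <- dlogits
  else gl[(m + 1):(dd[1] - m), (m + 1):(dd[2] - m),
          (m + 1):(dd[3] - m), , ] <- dlogits

  j <- nconv
  cb <- conv3d_bwd(blocks[[j]]$x_in, net$conv[[j]]$W, gl)
  gconv[[j]] <- list(W = cb$gw, b = cb$gb)
  g <- cb$gx

  for (l in seq_len(d - 1L)) {
    j <- 2L * d - l
    bb <- block_bwd(net, j, blocks[[j]], g)
    gconv[[j]] <- bb$g_conv; gbn[[j]] <- bb$g_bn
    g <- bb$gx
    cup <- cfg$base_filters * 2^l          # channels of the upsampled part
    ctot <- dim(g)[4]
    gup <- g[, , , seq_len(cup), , drop = FALSE]
    gskips[[l]] <- g[, , , (cup + 1):ctot, , drop = FALSE]
    g <- upsample3d_bwd(gup)
  }

  bb <- block_bwd(net, d, blocks[[d]], g)
  gconv[[d]] <- bb$g_conv; gbn[[d]] <- bb$g_bn
  g <- bb$gx

  for (i in rev(seq_len(d - 1L))) {
    g <- maxpool3d_bwd(g, cache$pools[[i]]$argmax, cache$pools[[i]]$xdim)
    g <- g + gskips[[i]]
    bb <- block_bwd(net, i, blocks[[i]], g)
    gconv[[i]] <- bb$g_conv; gbn[[i]] <- bb$g_bn
    g <- bb$gx
  }
  list(conv = gconv, bn = gbn)
}

#' Predict axon probabilities for one window
#'
#' @param net An `axseg_net`.
#' @param window Normalized 3D intensity window of edge
#'   `config$input_size`.
#' @return 3D probability array of edge `config$output_size`.
#' @export
net_predict <- function(net, window) {
  s <- net$config$input_size
  stopifnot(all(dim(window) == s))
  x <- array(window, c(s, s, s, 1L, 1L))
  p <- net_forward(net, x, training = FALSE)$prob
  array(p, rep(net$config$output_size, 3))
}
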