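#' Masked class-weighted binary cross-entropy
#'
#' Per-voxel binary cross-entropy between the predicted axon probability and
#' the axon indicator (`1` for code 2, `0` for codes 1, 3, 4), multiplied by
#' the class weight of the voxel's label code and averaged over voxels with
#' nonzero weight.  Unlabeled voxels (code 0) carry weight zero and so are
#' masked out entirely; if no voxel has nonzero weight the loss is 0 with a
#' warning.
#'
#' @param prob Predicted probabilities (any shape).
#' @param target Integer label codes, same number of voxels.
#' @param weights A [class_weights()].
#' @param eps Probability clipping bound.
#' @return Scalar loss.
#' @export
weighted_loss <- function(prob, target, weights = class_weights(),
                          eps = 1e-7) {
  stopifnot(length(prob) == length(target))
  wl <- weight_lookup(weights)
  w <- wl[target + 1]
  nnz <- sum(w > 0)
  if (nnz == 0) {
    warning("no voxels with nonzero class weight; loss is 0")
    return(0)
  }
  p <- pmin(pmax(prob, eps), 1 - eps)
  y <- as.numeric(target == LABEL_CODES[["axon"]])
  sum(w * -(y * log(p) + (1 - y) * log(1 - p))) / nnz
}

# Gradient of weighted_loss with respect to the (pre-sigmoid) logits:
# w * (p - y) / n_nonzero.  Computed against the logits for numerical
# stability of the backward pass.
loss_grad_logits <- function(prob, target, weights = class_weights()) {
  wl <- weight_lookup(weights)
  w <- wl[target + 1]
  nnz <- sum(w > 0)
  if (nnz == 0) return(array(0, dim(prob)))
  y <- as.numeric(target == LABEL_CODES[["axon"]])
  g <- w * (as.numeric(prob) - y) / nnz
  array(g, dim(prob))
}

#' Optimization steps per epoch
#'
#' The number of volumes divided by the batch size, floored, with a minimum
#' of one step.
#'
#' @param n_volumes Number of training (or validation) volumes per epoch.
#' @param batch_size Batch size.
#' @return Integer step count.
#' @export
steps_per_epoch <- function(n_volumes, batch_size) {
  check_that(batch_size > 0, "batch_size must be positive")
  check_that(n_volumes > 0, "n_volumes must be positive")
  max(1L, as.integer(n_volumes %/% batch_size))
}

#' Training configuration
#'
#' @param epochs Number of epochs.
#' @param batch_size Volumes per optimization step.
#' @param learning_rate Initial Adam learning rate.
#' @param scheduler Either `list(type = "fixed")` or
#'   `list(type = "plateau", factor = 0.1, patience = 10, min_lr = 1e-6)`:
#'   multiply the learning rate by `factor` after `patience` epochs without
#'   validation-loss improvement.
#' @param class_weights A [class_weights()].
#' @param n_train,n_val Volumes per epoch for the two generators (used for
#'   step accounting).
#' @param seed Optional seed for the training RNG stream.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 6L,
                         learning_rate = 1e-4,
                         scheduler = list(type = "fixed"),
                         class_weights = axseg::class_weights(),
                         n_train = 700L, n_val = 100L, seed = NULL) {
  check_that(epochs >= 1, "epochs must be >= 1")
  check_that(batch_size >= 1, "batch_size must be >= 1")
  check_that(learning_rate > 0, "learning_rate must be positive")
  if (identical(scheduler$type, "plateau")) {
    scheduler$factor <- scheduler$factor %||% 0.1
    scheduler$patience <- scheduler$patience %||% 10L
    scheduler$min_lr <- scheduler$min_lr %||% 1e-6
    check_that(scheduler$factor > 0 && scheduler$factor < 1,
               "plateau factor must lie in (0, 1)")
  } else check_that(identical(scheduler$type, "fixed"),
                    "scheduler type must be 'fixed' or 'plateau'")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, scheduler = scheduler,
                 class_weights = class_weights,
                 n_train = as.integer(n_train), n_val = as.integer(n_val),
                 seed = seed),
            class = "train_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Adam -----------------------------------------------------------------

adam_init <- function(net) {
  st <- list(t = 0L, conv = vector("list", length(net$conv)),
             bn = vector("list", length(net$bn)))
  for (j in seq_along(net$conv))
    st$conv[[j]] <- list(mW = zeros_like(net$conv[[j]]$W),
                         vW = zeros_like(net$conv[[j]]$W),
                         mb = numeric(length(net$conv[[j]]$b)),
                         vb = numeric(length(net$conv[[j]]$b)))
  for (j in seq_along(net$bn))
    if (!is.null(net$bn[[j]]))
      st$bn[[j]] <- list(mg = numeric(length(net$bn[[j]]$gamma)),
                         vg = numeric(length(net$bn[[j]]$gamma)),
                         mb = numeric(length(net$bn[[j]]$beta)),
                         vb = numeric(length(net$bn[[j]]$beta)))
  st
}

adam_apply <- function(param, grad, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  m <- b1 * m + (1 - b1) * grad
  v <- b2 * v + (1 - b2) * grad^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

adam_step <- function(net, grads, state, lr) {
  state$t <- state$t + 1L
  t <- state$t
  for (j in seq_along(net$conv)) {
    if (!net$trainable[j]) next
    g <- grads$conv[[j]]
    u <- adam_apply(net$conv[[j]]$W, g$W, state$conv[[j]]$mW,
                    state$conv[[j]]$vW, lr, t)
    net$conv[[j]]$W <- u$param
    state$conv[[j]]$mW <- u$m; state$conv[[j]]$vW <- u$v
    u <- adam_apply(net$conv[[j]]$b, g$b, state$conv[[j]]$mb,
                    state$conv[[j]]$vb, lr, t)
    net$conv[[j]]$b <- u$param
    state$conv[[j]]$mb <- u$m; state$conv[[j]]$vb <- u$v
  }
  for (j in seq_along(net$bn)) {
    if (is.null(net$bn[[j]]) || is.null(grads$bn[[j]])) next
    g <- grads$bn[[j]]
    u <- adam_apply(net$bn[[j]]$gamma, g$gamma, state$bn[[j]]$mg,
                    state$bn[[j]]$vg, lr, t)
    net$bn[[j]]$gamma <- u$param
    state$bn[[j]]$mg <- u$m; state$bn[[j]]$vg <- u$v
    u <- adam_apply(net$bn[[j]]$beta, g$beta, state$bn[[j]]$mb,
                    state$bn[[j]]$vb, lr, t)
    net$bn[[j]]$beta <- u$param
    state$bn[[j]]$mb <- u$m; state$bn[[j]]$vb <- u$v
  }
  list(net = net, state = state)
}

# ---- learning-rate schedule ----------------------------------------------

plateau_update <- function(st, val_loss, factor, patience, min_lr) {
  if (is.null(st$best) || val_loss < st$best) {
    st$best <- val_loss
    st$wait <- 0L
  } else {
    st$wait <- st$wait + 1L
    if (st$wait >= patience) {
      st$lr <- max(st$lr * factor, min_lr)
      st$wait <- 0L
    }
  }
  st
}

#' Simulate the reduce-on-plateau schedule over a validation-loss trace
#'
#' The learning rate is multiplied by `factor` once `patience` consecutive
#' epochs show no improvement over the best validation loss so far, never
#' dropping below `min_lr`.  Reductions take effect from the following
#' epoch.
#'
#' @param val_losses Per-epoch validation losses.
#' @param lr0 Initial learning rate.
#' @param factor,patience,min_lr Schedule parameters.
#' @return Numeric vector: the learning rate in effect during each epoch.
#' @export
plateau_schedule <- function(val_losses, lr0, factor = 0.1, patience = 10L,
                             min_lr = 1e-6) {
  st <- list(lr = lr0, best = NULL, wait = 0L)
  lrs <- numeric(length(val_losses))
  for (i in seq_along(val_losses)) {
    lrs[i] <- st$lr
    st <- plateau_update(st, val_losses[i], factor, patience, min_lr)
  }
  lrs
}

# ---- training loop --------------------------------------------------------

#' Train (or fine-tune) the segmentation network
#'
#' Runs `epochs * steps_per_epoch(n_train, batch_size)` Adam steps on
#' batches pulled from `train_gen`, evaluating `val_gen` after every epoch.
#' Only the convolutional layers marked trainable (see
#' [apply_layer_selection()]) are updated; batch-norm parameters always are.
#' The checkpoint with the minimum weighted validation loss is retained.  A
#' non-finite loss aborts with a diagnostic.
#'
#' @param net An `axseg_net`.
#' @param train_gen,val_gen Generators: functions of `batch_size` returning
#'   `list(x = (X,Y,Z,1,N) normalized inputs, target = (O,O,O,1,N) label
#'   codes)`.
#' @param config A [train_config()].
#' @return List with `net` (final state), `checkpoint` (`net`, `epoch`,
#'   `val_loss` of the best epoch), and `history` (data.frame of `epoch`,
#'   `train_loss`, `val_loss`, `lr`).
#' @export
train_model <- function(net, train_gen, val_gen, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  steps <- steps_per_epoch(config$n_train, config$batch_size)
  vsteps <- steps_per_epoch(config$n_val, config$batch_size)
  w <- config$class_weights
  sch <- config$scheduler
  pst <- list(lr = config$learning_rate, best = NULL, wait = 0L)
  state <- adam_init(net)
  best <- NULL
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  run <- function() {
    for (epoch in seq_len(config$epochs)) {
      lr_epoch <- pst$lr
      tl <- 0
      for (s in seq_len(steps)) {
        b <- train_gen(config$batch_size)
        fw <- net_forward(net, b$x, training = TRUE)
        net <<- fw$net
        l <- weighted_loss(fw$prob, b$target, w)
        if (!is.finite(l))
          stop(sprintf("non-finite training loss (%g) at epoch %d step %d",
                       l, epoch, s), call. = FALSE)
        gr <- net_backward(net, fw$cache, loss_grad_logits(fw$prob, b$target, w))
        u <- adam_step(net, gr, state, lr_epoch)
        net <<- u$net; state <<- u$state
        tl <- tl + l
      }
      vl <- 0
      for (s in seq_len(vsteps)) {
        vb <- val_gen(config$batch_size)
        fw <- net_forward(net, vb$x, training = FALSE)
        vl <- vl + weighted_loss(fw$prob, vb$target, w)
      }
      val_loss <- vl / vsteps
      if (!is.finite(val_loss))
        stop(sprintf("non-finite validation loss at epoch %d", epoch),
             call. = FALSE)
      history[nrow(history) + 1L, ] <<- list(epoch, tl / steps, val_loss,
                                             lr_epoch)
      if (is.null(best) || val_loss < best$val_loss)
        best <<- list(net = net, epoch = epoch, val_loss = val_loss)
      if (identical(sch$type, "plateau"))
        pst <<- plateau_update(pst, val_loss, sch$factor, sch$patience,
                               sch$min_lr)
    }
  }
  if (is.null(config$seed)) run() else with_seed(config$seed, run())
  list(net = net, checkpoint = best, history = history)
}

#' Save / load a training checkpoint
#'
#' The checkpoint (network parameters plus metadata) is serialized with
#' `saveRDS`; a human-readable JSON sidecar (`<path>.json`) records the
#' network configuration, epoch, and validation loss.
#'
#' @param checkpoint A checkpoint list (`net`, `epoch`, `val_loss`).
#' @param path Destination file (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  side <- list(config = unclass(checkpoint$net$config),
               epoch = checkpoint$epoch, val_loss = checkpoint$val_loss)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# ---- generators -----------------------------------------------------------

#' Build a training or validation batch generator from annotated cubes
#'
#' Each cube is a list with `image` (padded input cube) and `labels` (label
#' volume in the same coordinates, see [embed_labels()]).  Corners are drawn
#' with foreground oversampling (training) or uniformly (validation); cubes
#' are visited round-robin so that `samples_per_cube` draws per cube make up
#' one epoch.  Inputs are normalized by `augment_cfg$max_intensity` and, for
#' training, randomly flipped/rotated/deformed per the augmentation
#' configuration and intensity-jittered.
#'
#' @param cubes List of `list(image =, labels =)` cubes.
#' @param sampler_cfg A [sampler_config()].
#' @param augment_cfg An [augment_config()].
#' @param augment Apply augmentation and oversampling (training) or not
#'   (validation).
#' @return A function of `batch_size` returning `list(x, target)` tensors.
#' @export
make_batch_generator <- function(cubes, sampler_cfg = sampler_config(),
                                 augment_cfg = augment_config(),
                                 augment = TRUE) {
  stopifnot(length(cubes) >= 1)
  prep <- lapply(cubes, function(cb) {
    stopifnot(all(dim(cb$image) == dim(cb$labels)))
    list(image = cb$image, labels = cb$labels,
         bounds = valid_corner_bounds(dim(cb$image), sampler_cfg$input_size),
         corners = axon_corner_list(cb$labels, sampler_cfg$input_size))
  })
  s <- sampler_cfg$input_size
  o <- sampler_cfg$output_size
  cube_i <- 0L
  function(batch_size) {
    x <- array(0, c(s, s, s, 1L, batch_size))
    tg <- array(0L, c(o, o, o, 1L, batch_size))
    for (k in seq_len(batch_size)) {
      cube_i <<- cube_i %% length(prep) + 1L
      cb <- prep[[cube_i]]
      corner <- draw_corner(cb$bounds, cb$corners,
                            if (augment) sampler_cfg$oversample_p else 0)
      smp <- extract_sample(cb$image, cb$labels, corner, sampler_cfg)
      if (augment) {
        if (augment_cfg$enable_flips) smp <- random_flip(smp)
        if (augment_cfg$enable_rotation || augment_cfg$enable_elastic)
          smp <- spatial_transform(smp, augment_cfg)
        xi <- intensity_augment(smp$input, augment_cfg)
      } else {
        xi <- intensity_augment(smp$input, augment_cfg, s = 1, c = 0)
      }
      x[, , , 1L, k] <- xi
      tg[, , , 1L, k] <- smp$target
    }
    list(x = x, target = tg)
  }
}
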