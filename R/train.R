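# Two-stage training schedule: stage 1 trains the decoder (DecoderCup and
# the three branches) with the trunk and Transformer frozen; stage 2
# fine-tunes the whole network. Adam, learning rate dropped by 10x after a
# configurable number of epochs.

#' Training configuration
#'
#' Defaults follow the reference schedule: 50 decoder-only epochs then 100
#' full-network epochs, batch sizes 8 and 4, Adam with learning rate 1e-4
#' reduced to 1e-5 after 25 epochs, and flip / rotation / Gaussian-blur /
#' median-blur augmentation. See [smoke_train_config()] for a desk-scale
#' profile.
#'
#' @param stage1_epochs,stage2_epochs epochs of the two stages.
#' @param batch_sizes integer pair: batch size per stage.
#' @param lr_initial,lr_after learning rates before/after the switch.
#' @param lr_switch_epoch epoch (counted across both stages) after which the
#'   learning rate drops.
#' @param augmentations named logical vector: `flip`, `rotation`,
#'   `gaussian_blur`, `median_blur`.
#' @param seed integer seed controlling shuffling and augmentation draws.
#' @return a `train_config` list.
#' @export
train_config <- function(stage1_epochs = 50L, stage2_epochs = 100L,
                         batch_sizes = c(8L, 4L), lr_initial = 1e-4,
                         lr_after = 1e-5, lr_switch_epoch = 25L,
                         augmentations = c(flip = TRUE, rotation = TRUE,
                                           gaussian_blur = TRUE,
                                           median_blur = TRUE),
                         seed = 1L) {
  stopifnot(stage1_epochs >= 0L, stage2_epochs >= 0L,
            length(batch_sizes) == 2L, all(batch_sizes >= 1L),
            lr_initial > 0, lr_after > 0)
  aug <- c(flip = FALSE, rotation = FALSE, gaussian_blur = FALSE,
           median_blur = FALSE)
  aug[names(augmentations)] <- augmentations
  structure(list(stage1_epochs = as.integer(stage1_epochs),
                 stage2_epochs = as.integer(stage2_epochs),
                 batch_sizes = as.integer(batch_sizes),
                 lr_initial = lr_initial, lr_after = lr_after,
                 lr_switch_epoch = as.integer(lr_switch_epoch),
                 augmentations = aug, seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale smoke-training profile
#'
#' One epoch per stage, batch size 2, otherwise the default schedule.
#' @param ... overrides passed to [train_config()].
#' @return a `train_config`.
#' @export
smoke_train_config <- function(...) {
  args <- list(...)
  defaults <- list(stage1_epochs = 1L, stage2_epochs = 1L, batch_sizes = c(2L, 2L))
  do.call(train_config, utils::modifyList(defaults, args))
}

rot90_mat <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m)[ncol(t(m)):1, , drop = FALSE]
  m
}

augment_scene <- function(image, instances, types, aug) {
  # flips / rotations transform image and label maps together; HV targets are
  # re-encoded from the transformed instance map afterwards, so the distance
  # maps stay exact by construction
  if (aug["flip"] && stats::runif(1) < 0.5) {
    image <- image[, ncol(instances):1, , drop = FALSE]
    instances <- instances[, ncol(instances):1, drop = FALSE]
    types <- types[, ncol(types):1, drop = FALSE]
  }
  if (aug["flip"] && stats::runif(1) < 0.5) {
    image <- image[nrow(instances):1, , , drop = FALSE]
    instances <- instances[nrow(instances):1, , drop = FALSE]
    types <- types[nrow(types):1, , drop = FALSE]
  }
  if (aug["rotation"] && nrow(instances) == ncol(instances)) {
    k <- sample.int(4L, 1L) - 1L
    if (k > 0L) {
      for (ch in 1:3) image[, , ch] <- rot90_mat(image[, , ch], k)
      instances <- rot90_mat(instances, k)
      types <- rot90_mat(types, k)
    }
  }
  if (aug["gaussian_blur"] && stats::runif(1) < 0.5) {
    sg <- stats::runif(1, 0.3, 1.0)
    for (ch in 1:3) image[, , ch] <- gaussian_blur(image[, , ch], sg)
  }
  if (aug["median_blur"] && stats::runif(1) < 0.5) {
    for (ch in 1:3) {
      image[, , ch] <- as.matrix(EBImage::medianFilter(image[, , ch], 1L))
    }
  }
  list(image = image, instances = instances, types = types)
}

center_crop_mat <- function(m, out) {
  r0 <- (nrow(m) - out) %/% 2L
  c0 <- (ncol(m) - out) %/% 2L
  m[r0 + seq_len(out), c0 + seq_len(out), drop = FALSE]
}

scene_batch <- function(scenes, idx, out_size, aug) {
  n <- length(idx)
  h <- nrow(scenes[[idx[1]]]$instances)
  w <- ncol(scenes[[idx[1]]]$instances)
  images <- array(0, dim = c(3L, h, w, n))
  np <- array(0, dim = c(1L, out_size, out_size, n))
  hv <- array(0, dim = c(2L, out_size, out_size, n))
  nc <- array(0, dim = c(1L, out_size, out_size, n))
  for (i in seq_len(n)) {
    sc <- scenes[[idx[i]]]
    a <- augment_scene(sc$image, sc$instances, sc$types, aug)
    tg <- encode_targets(a$instances, a$types)
    images[, , , i] <- aperm(a$image, c(3L, 1L, 2L))
    np[1, , , i] <- center_crop_mat(tg$np, out_size)
    hv[1, , , i] <- center_crop_mat(tg$hv[, , 1], out_size)
    hv[2, , , i] <- center_crop_mat(tg$hv[, , 2], out_size)
    nc[1, , , i] <- center_crop_mat(tg$nc, out_size)
  }
  list(images = images, np = np, hv = hv, nc = nc)
}

#' Run the two-stage training schedule
#'
#' Stage 1 freezes the trunk and Transformer parameters and optimizes the
#' DecoderCup and the three branches; stage 2 unfreezes everything. The
#' learning rate drops from `lr_initial` to `lr_after` after
#' `lr_switch_epoch` epochs (counted across stages). A fresh Adam state is
#' created per stage. Fully deterministic given `cfg$seed`.
#'
#' @param model a `hovseg_model` (modified in place: parameters are
#'   environments).
#' @param scenes nonempty list of `synthetic_scene`s sharing one tile size.
#' @param cfg a [train_config()].
#' @param weights a [loss_weights()].
#' @param sobel_ksize Sobel kernel size for the gradient loss term.
#' @param verbose print per-epoch mean losses?
#' @return a `hovseg_training`: list with `model` and `history` (data.frame:
#'   stage, epoch, step, lr, loss and the six terms).
#' @export
run_training <- function(model, scenes, cfg = smoke_train_config(),
                         weights = loss_weights(), sobel_ksize = 5L,
                         verbose = FALSE) {
  stopifnot(inherits(model, "hovseg_model"), length(scenes) > 0L,
            inherits(cfg, "train_config"))
  if (cfg$stage1_epochs + cfg$stage2_epochs == 0L) {
    stop("both training stages have zero epochs")
  }
  out_size <- model$chain$output
  history <- list()
  global_epoch <- 0L
  withr::with_seed(cfg$seed, {
    for (stage in 1:2) {
      n_epochs <- if (stage == 1L) cfg$stage1_epochs else cfg$stage2_epochs
      if (n_epochs == 0L) next
      bs <- cfg$batch_sizes[stage]
      frozen <- if (stage == 1L) c("trunk.", "transformer.") else character(0)
      set_trainable(model, c("trunk.", "transformer.", "cup.", "np.", "hv.", "nc."),
                    TRUE)
      if (length(frozen) > 0L) set_trainable(model, frozen, FALSE)
      opt <- adam_init(model$params)
      for (ep in seq_len(n_epochs)) {
        global_epoch <- global_epoch + 1L
        lr <- if (global_epoch > cfg$lr_switch_epoch) cfg$lr_after else cfg$lr_initial
        ord <- sample.int(length(scenes))
        steps <- split(ord, ceiling(seq_along(ord) / bs))
        for (si in seq_along(steps)) {
          batch <- scene_batch(scenes, steps[[si]], out_size, cfg$augmentations)
          outputs <- model_forward(model, tg_tensor(batch$images), training = TRUE)
          cl <- composite_loss(outputs, batch[c("np", "hv", "nc")], weights,
                               sobel_ksize)
          tg_zero_grad(model$params)
          tg_backward(cl$total)
          adam_step(opt, model$params, lr = lr)
          history[[length(history) + 1L]] <-
            c(stage = stage, epoch = ep, step = si, lr = lr,
              loss = as.numeric(tg_val(cl$total)), cl$terms)
        }
        if (verbose) {
          hh <- do.call(rbind, history)
          ep_loss <- mean(hh[hh[, "stage"] == stage & hh[, "epoch"] == ep, "loss"])
          message(sprintf("stage %d epoch %d: mean loss %.4f", stage, ep, ep_loss))
        }
      }
    }
  })
  set_trainable(model, c("trunk.", "transformer."), TRUE)
  structure(list(model = model,
                 history = as.data.frame(do.call(rbind, history))),
            class = "hovseg_training")
}

#' @export
print.hovseg_training <- function(x, ...) {
  h <- x$history
  cat("Training run:", nrow(h), "steps\n")
  for (st in unique(h$stage)) {
    hs <- h[h$stage == st, ]
    cat(sprintf("  stage %d: epochs %d, first/last epoch mean loss %.4f -> %.4f\n",
                st, max(hs$epoch),
                mean(hs$loss[hs$epoch == min(hs$epoch)]),
                mean(hs$loss[hs$epoch == max(hs$epoch)])))
  }
  invisible(x)
}

#' Predicted probability stack for one image
#'
#' Runs the network in inference mode and converts the branch outputs to a
#' `prediction_stack` (softmax foreground probability, HV maps, softmax
#' class probabilities) ready for [postprocess_stack()].
#'
#' @param model a `hovseg_model`.
#' @param image `(H, W, 3)` RGB array.
#' @return a `prediction_stack` over the model's output window.
#' @export
predict_stack <- function(model, image) {
  out <- model_forward(model, image, training = FALSE)
  softmax_c_arr <- function(a) {
    m <- matrix(a, dim(a)[1])
    e <- exp(sweep(m, 2L, apply(m, 2L, max)))
    array(sweep(e, 2L, colSums(e), `/`), dim = dim(a))
  }
  npv <- softmax_c_arr(tg_val(out$np))
  ncv <- softmax_c_arr(tg_val(out$nc))
  hvv <- tg_val(out$hv)
  s <- dim(npv)[2:3]
  structure(list(q = matrix(npv[2, , , 1], s[1], s[2]),
                 hv = array(aperm(hvv[, , , 1, drop = FALSE], c(2L, 3L, 1L, 4L)),
                            dim = c(s[1], s[2], 2L)),
                 classes = array(aperm(ncv[, , , 1, drop = FALSE], c(2L, 3L, 1L, 4L)),
                                 dim = c(s[1], s[2], dim(ncv)[1])),
                 n_types = dim(ncv)[1] - 1L),
            class = "prediction_stack")
}
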