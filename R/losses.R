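# Composite training objective: six terms across the three branches,
#   L = la*MSE(HV) + lb*MSE(Sobel grads of HV on foreground)
#     + lc*CE(NP) + ld*Dice(NP) + le*CE(NC) + lf*Dice(NC),
# with default weights (1, 2, 1, 1, 1, 1).

#' Loss weights
#'
#' @param a,b weights of the HV regression terms (map MSE, masked
#'   gradient MSE).
#' @param c,d weights of the NP terms (cross-entropy, Dice).
#' @param e,f weights of the NC terms (cross-entropy, Dice).
#' @return named numeric vector of class `loss_weights`.
#' @export
loss_weights <- function(a = 1, b = 2, c = 1, d = 1, e = 1, f = 1) {
  w <- c(a = a, b = b, c = c, d = d, e = e, f = f)
  stopifnot(all(w >= 0))
  structure(w, class = "loss_weights")
}

DICE_EPS <- 1e-3

# accept (H,W,2) arrays or internal (2,H,W,N) tensors/arrays
as_hv4 <- function(x) {
  if (is_tg(x)) return(x)
  d <- dim(x)
  if (length(d) == 3L && d[3] == 2L) {
    x <- array(aperm(x, c(3L, 1L, 2L)), dim = c(2L, d[1], d[2], 1L))
  }
  stopifnot(length(dim(x)) == 4L)
  tg_tensor(x)
}

as_map4 <- function(x, channels) {
  if (is_tg(x)) return(x)
  d <- dim(x)
  if (length(d) == 2L && channels == 1L) {
    x <- array(x, dim = c(1L, d[1], d[2], 1L))
  } else if (length(d) == 3L && d[3] == channels) {
    x <- array(aperm(x, c(3L, 1L, 2L)), dim = c(channels, d[1], d[2], 1L))
  }
  stopifnot(length(dim(x)) == 4L)
  tg_tensor(x)
}

# fixed (non-learned) depthwise Sobel kernel: channel 1 gets the horizontal
# derivative, channel 2 the vertical one
sobel_pair_kernel <- function(ksize) {
  w <- array(0, dim = c(2L, 2L, ksize, ksize))
  w[1, 1, , ] <- sobel_kernel(ksize, "x")
  w[2, 2, , ] <- sobel_kernel(ksize, "y")
  w
}

#' HV branch losses: map MSE and foreground-masked gradient MSE
#'
#' `l_a` is the mean squared error between predicted and true HV maps over
#' all pixels and both channels. `l_b` is the mean squared error between the
#' Sobel gradients of the predicted and true maps (horizontal derivative of
#' the horizontal map, vertical derivative of the vertical map), restricted
#' to foreground pixels; an empty foreground gives `l_b = 0` by convention.
#'
#' @param pred_hv,true_hv 2-channel HV maps: `(H, W, 2)` arrays or
#'   `(2, H, W, N)` tensors.
#' @param foreground binary nuclear mask `(H, W)` (or `(1, H, W, N)`).
#' @param sobel_ksize Sobel kernel size (shared with the post-processing).
#' @return list `(l_a, l_b)` of scalar tensors (use `$value` for numbers).
#' @export
hv_losses <- function(pred_hv, true_hv, foreground, sobel_ksize = 5L) {
  p <- as_hv4(pred_hv)
  t <- as_hv4(true_hv)
  stopifnot(all(dim(tg_val(p)) == dim(tg_val(t))))
  l_a <- tg_mean(tg_square(tg_sub(p, t)))
  fg <- foreground
  if (length(dim(fg)) == 2L) fg <- array(fg, dim = c(1L, dim(fg), 1L))
  nfg <- sum(fg > 0)
  if (nfg == 0) {
    return(list(l_a = l_a, l_b = tg_tensor(array(0, dim = 1L))))
  }
  kern <- tg_tensor(sobel_pair_kernel(sobel_ksize))   # constant, not learned
  pk <- (sobel_ksize - 1L) %/% 2L
  gp <- tg_conv2d(tg_pad_replicate(p, pk), kern, stride = 1L, pad = "valid")
  gt <- tg_conv2d(tg_pad_replicate(t, pk), kern, stride = 1L, pad = "valid")
  d2 <- tg_mul(tg_square(tg_sub(gp, gt)), (fg > 0) * 1)
  nbatch <- dim(tg_val(p))[4]
  l_b <- tg_scale(tg_sum(d2), 1 / (2 * nfg * max(1L, nbatch / dim(fg)[4])))
  list(l_a = l_a, l_b = l_b)
}

ce_and_dice <- function(pred_logits, true_onehot) {
  # pred_logits, true_onehot: (C, H, W, N); one-hot along channel 1
  ls <- tg_logsoftmax_c(pred_logits)
  npix <- prod(dim(tg_val(pred_logits))[-1])
  ce <- tg_scale(tg_sum(tg_mul(ls, true_onehot)), -1 / npix)
  pr <- tg_softmax_c(pred_logits)
  C <- dim(tg_val(pred_logits))[1]
  dice_terms <- lapply(seq_len(C), function(cl) {
    sel <- array(0, dim = c(C, 1L, 1L, 1L)); sel[cl, 1, 1, 1] <- 1
    pc <- tg_sum(tg_mul(pr, sel))
    tc <- sum(true_onehot[cl, , , ])
    inter <- tg_sum(tg_mul(tg_mul(pr, sel), true_onehot))
    tg_div(tg_add_const(tg_scale(inter, 2), DICE_EPS),
           tg_add_const(tg_add(pc, tg_tensor(array(tc, 1L))), DICE_EPS))
  })
  dice_mean <- tg_scale(Reduce(tg_add, dice_terms), 1 / C)
  dice_loss <- tg_add_const(tg_scale(dice_mean, -1), 1)
  list(ce = ce, dice = dice_loss)
}

onehot_c <- function(classes, C, H, W, N) {
  # classes: (H, W) or (1,H,W,N) integer map with values 0..C-1
  if (length(dim(classes)) == 2L) classes <- array(classes, dim = c(1L, H, W, 1L))
  out <- array(0, dim = c(C, H, W, N))
  for (cl in seq_len(C)) {
    out[cl, , , ] <- (classes[1, , , ] == cl - 1L) * 1
  }
  out
}

#' NP branch losses: cross-entropy and soft Dice
#'
#' `l_c` is the pixel-mean cross-entropy of the 2-class logits against the
#' binary nuclear mask; `l_d` is one minus the soft Dice coefficient,
#' computed per class with smoothing `1e-3` in numerator and denominator and
#' averaged over the two classes.
#'
#' @param pred_logits 2-channel logits: `(H, W, 2)` array or `(2, H, W, N)`
#'   tensor (channel order: background, foreground).
#' @param true_binary binary map `(H, W)` (or `(1, H, W, N)`).
#' @return list `(l_c, l_d)` of scalar tensors.
#' @export
np_losses <- function(pred_logits, true_binary) {
  p <- as_map4(pred_logits, 2L)
  d <- dim(tg_val(p))
  oh <- onehot_c(true_binary, 2L, d[2], d[3], d[4])
  r <- ce_and_dice(p, oh)
  list(l_c = r$ce, l_d = r$dice)
}

#' NC branch losses: cross-entropy and soft Dice over C + 1 classes
#'
#' @param pred_logits `(H, W, C+1)` array or `(C+1, H, W, N)` tensor
#'   (channel 1 = background).
#' @param true_types integer type map `(H, W)` with values `0..C`.
#' @return list `(l_e, l_f)` of scalar tensors.
#' @export
nc_losses <- function(pred_logits, true_types) {
  if (is_tg(pred_logits)) {
    C1 <- dim(tg_val(pred_logits))[1]
  } else {
    C1 <- dim(pred_logits)[length(dim(pred_logits))]
  }
  p <- as_map4(pred_logits, C1)
  d <- dim(tg_val(p))
  tt <- if (length(dim(true_types)) == 2L) true_types else true_types
  if (max(tt) > C1 - 1L) stop("class index ", max(tt), " out of range 0..", C1 - 1L)
  oh <- onehot_c(tt, C1, d[2], d[3], d[4])
  r <- ce_and_dice(p, oh)
  list(l_e = r$ce, l_f = r$dice)
}

#' Weighted composite loss
#'
#' `L = la*l_a + lb*l_b + lc*l_c + ld*l_d + le*l_e + lf*l_f` with the given
#' weights (defaults: `lb = 2`, all others 1).
#'
#' @param terms list or vector of the six loss terms `(l_a .. l_f)`; scalars
#'   or scalar tensors.
#' @param weights a [loss_weights()].
#' @return scalar of the same kind as the inputs (number or tensor).
#' @export
total_loss <- function(terms, weights = loss_weights()) {
  stopifnot(length(terms) == 6L)
  vals <- vapply(terms, function(t) as.numeric(tg_val(t))[1], numeric(1))
  if (any(!is.finite(vals))) stop("non-finite loss term: ",
                                  paste(round(vals, 4), collapse = ", "))
  if (is.list(terms) && any(vapply(terms, is_tg, logical(1)))) {
    Reduce(tg_add, Map(function(t, w) tg_scale(as_tg(t), w), terms,
                       as.numeric(weights)))
  } else {
    sum(vals * as.numeric(weights))
  }
}

#' Composite loss of a model forward pass against encoded targets
#'
#' @param outputs list with tensors `np`, `hv`, `nc` from [model_forward()].
#' @param targets list of target arrays: `np` `(1,H,W,N)` binary, `hv`
#'   `(2,H,W,N)`, `nc` `(1,H,W,N)` integer types.
#' @param weights a [loss_weights()].
#' @param sobel_ksize Sobel kernel size for the gradient loss.
#' @return list with `total` (scalar tensor) and `terms` (named numeric).
#' @export
composite_loss <- function(outputs, targets, weights = loss_weights(),
                           sobel_ksize = 5L) {
  hv <- hv_losses(outputs$hv, tg_tensor(targets$hv), targets$np, sobel_ksize)
  np <- np_losses(outputs$np, targets$np)
  C1 <- dim(tg_val(outputs$nc))[1]
  d <- dim(tg_val(outputs$nc))
  ohnc <- onehot_c(targets$nc, C1, d[2], d[3], d[4])
  ncr <- ce_and_dice(outputs$nc, ohnc)
  terms <- list(hv$l_a, hv$l_b, np$l_c, np$l_d, ncr$ce, ncr$dice)
  tot <- total_loss(terms, weights)
  list(total = tot,
       terms = stats::setNames(vapply(terms, function(t) as.numeric(tg_val(t)),
                                      numeric(1)),
                               c("l_a", "l_b", "l_c", "l_d", "l_e", "l_f")))
}
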