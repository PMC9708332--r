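#' SimAM: parameter-free 3D attention
#'
#' Re-weights every neuron of an activation tensor by a closed-form energy
#' contrasting it with the other neurons of its channel. For a neuron with
#' value `t` in a channel whose remaining neurons have mean `mu` and variance
#' `var` (leave-one-out, computed exactly from channel sums), the minimal
#' energy is
#'
#'   E* = 4 (var + lambda) / ((t - mu)^2 + 2 var + 2 lambda)
#'
#' and the output is `x * sigmoid(1 / E*)`. The module has no learnable
#' parameters and preserves the input shape exactly. Channels with a single
#' spatial element are returned unchanged (the leave-one-out variance is
#' undefined there).
#'
#' @param x activation tensor (or plain array), dim (channels, H, W, batch).
#' @param lambda_reg positive regularizer added to the variance (default
#'   `1e-4`, the value used in the original formulation).
#' @return tensor (or array, matching the input kind) of the same shape.
#' @examples
#' a <- array(c(1, 1, 1, 5), dim = c(1, 2, 2, 1))
#' w <- simam_attend(a) / a  # per-neuron attention weights
#' @export
simam_attend <- function(x, lambda_reg = 1e-4) {
  stopifnot(lambda_reg > 0)
  plain <- !is_tg(x)
  xt <- as_tg(x)
  d <- dim(tg_val(xt))
  stopifnot(length(d) == 4L)
  n <- d[2] * d[3]
  if (n <= 1L) return(if (plain) tg_val(xt) else xt)
  # exact leave-one-out mean/variance from channel sums:
  #   mu_t  = (S - t) / (n - 1)
  #   var_t = (Q - t^2) / (n - 1) - mu_t^2
  S <- tg_sum_hw(xt)
  Q <- tg_sum_hw(tg_square(xt))
  mu <- tg_scale(tg_sub(S, xt), 1 / (n - 1))
  va <- tg_sub(tg_scale(tg_sub(Q, tg_square(xt)), 1 / (n - 1)), tg_square(mu))
  dsq <- tg_square(tg_sub(xt, mu))
  # 1/E* = ((t - mu)^2 + 2 var + 2 lambda) / (4 (var + lambda))
  num <- tg_add_const(tg_add(dsq, tg_scale(va, 2)), 2 * lambda_reg)
  den <- tg_scale(tg_add_const(va, lambda_reg), 4)
  out <- tg_mul(xt, tg_sigmoid(tg_div(num, den)))
  if (plain) tg_val(out) else out
}
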