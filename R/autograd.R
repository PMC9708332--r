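# Minimal reverse-mode automatic differentiation over base-R arrays.
#
# Tensors are environments holding a numeric array (`value`), an optional
# accumulated gradient (`grad`), and — when gradient recording is on — the
# parent tensors and a backward closure mapping the output gradient to
# per-parent gradients.  Convolutions are computed as one BLAS matrix
# multiplication per kernel offset, so all heavy lifting stays in `%*%`.
#
# Array layout conventions:
#   feature maps: dim = (channels, height, width, batch)
#   token matrices: dim = (tokens, embed)
#   kernels: dim = (out_channels, in_channels, kh, kw)

.tg <- new.env(parent = emptyenv())
.tg$grad_on <- TRUE
.tg$id <- 0

#' Create a tensor for the autodiff engine
#'
#' Wraps a numeric array (or scalar/matrix) into the tensor type used by the
#' network code. Gradients accumulate into `$grad` after [tg_backward()].
#'
#' @param value numeric array/matrix/vector.
#' @param requires_grad should gradients be accumulated for this leaf?
#' @return a `tg_tensor` environment with fields `value`, `grad`.
#' @export
tg_tensor <- function(value, requires_grad = FALSE) {
  if (is.null(dim(value))) value <- array(value, dim = length(value))
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  e$ng <- requires_grad        # does anything upstream need this gradient?
  e$parents <- NULL
  e$backfn <- NULL
  .tg$id <- .tg$id + 1
  e$id <- .tg$id
  class(e) <- "tg_tensor"
  e
}

#' @export
print.tg_tensor <- function(x, ...) {
  cat("<tg_tensor> dim:", paste(dim(x$value), collapse = "x"),
      if (isTRUE(x$requires_grad)) "(parameter)" else "", "\n")
  invisible(x)
}

#' Tensor utilities
#'
#' `is_tg` tests for the tensor type, `tg_val` extracts the plain array from
#' a tensor (and passes plain arrays through), `as_tg` wraps a plain array.
#'
#' @param x a `tg_tensor` or plain array.
#' @return `is_tg`: logical; `tg_val`: numeric array; `as_tg`: `tg_tensor`.
#' @export
is_tg <- function(x) inherits(x, "tg_tensor")

#' @rdname is_tg
#' @export
tg_val <- function(x) if (is_tg(x)) x$value else x

#' @rdname is_tg
#' @export
as_tg <- function(x) if (is_tg(x)) x else tg_tensor(x)

# Record an op node. `parents` is a list that may mix tensors and plain
# arrays (constants); backfn(grad) must return a list of gradients aligned
# with `parents` (NULL entries allowed for constants).
tg_op <- function(value, parents, backfn) {
  out <- tg_tensor(value)
  if (.tg$grad_on) {
    needs <- vapply(parents, function(p) is_tg(p) && isTRUE(p$ng), logical(1))
    if (any(needs)) {
      out$parents <- parents
      out$backfn <- backfn
      out$ng <- TRUE
    }
  }
  out
}

#' Evaluate an expression with gradient recording disabled
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
tg_no_grad <- function(expr) {
  old <- .tg$grad_on
  .tg$grad_on <- FALSE
  on.exit(.tg$grad_on <- old)
  expr
}

#' Backpropagate from a scalar tensor
#'
#' Accumulates gradients into every reachable tensor with
#' `requires_grad = TRUE` (fields `$grad`).
#'
#' @param loss scalar `tg_tensor`.
#' @export
tg_backward <- function(loss) {
  stopifnot(is_tg(loss), length(loss$value) == 1L)
  # iterative topological sort (post-order DFS)
  topo <- vector("list", 256L); nt <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, expanded = FALSE))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$expanded) {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- node
      next
    }
    if (!is.null(visited[[key]])) next
    visited[[key]] <- TRUE
    stack[[length(stack) + 1L]] <- list(node = node, expanded = TRUE)
    for (p in node$parents) {
      if (is_tg(p) && isTRUE(p$ng) && is.null(visited[[as.character(p$id)]])) {
        stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
      }
    }
  }
  loss$grad <- array(1, dim = dim(loss$value))
  for (i in seq_len(nt)) {
    node <- topo[[nt - i + 1L]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    gs <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (is_tg(p) && isTRUE(p$ng) && !is.null(gs[[j]])) {
        g <- gs[[j]]
        p$grad <- if (is.null(p$grad)) g else p$grad + g
      }
    }
    if (!isTRUE(node$requires_grad)) node$grad <- NULL  # free intermediate grads
  }
  invisible(loss)
}

# ---- broadcasting helpers ---------------------------------------------------

# expand x (dims equal to `to` or 1) to shape `to`
bc_to <- function(x, to) {
  dx <- dim(x)
  if (identical(dx, to)) return(x)
  stopifnot(length(dx) == length(to), all(dx == to | dx == 1L))
  idx <- lapply(seq_along(to), function(k) if (dx[k] == to[k]) seq_len(to[k]) else rep(1L, to[k]))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# sum gradient g (shape `from`) down to shape `d` (entries equal or 1)
reduce_to <- function(g, d) {
  gd <- dim(g)
  if (identical(gd, d)) return(g)
  red <- which(d == 1L & gd > 1L)
  keep <- setdiff(seq_along(d), red)
  if (length(keep) == 0L) return(array(sum(g), dim = d))
  gp <- aperm(g, c(keep, red))
  m <- matrix(gp, prod(gd[keep]), prod(gd[red]))
  array(rowSums(m), dim = d)
}

bc_shape <- function(da, db) {
  stopifnot(length(da) == length(db), all(da == db | da == 1L | db == 1L))
  pmax(da, db)
}

# ---- elementwise ops --------------------------------------------------------

#' @rdname tg_ops
#' @param a,b tensors or plain arrays (broadcast where dimensions are 1).
#' @export
tg_add <- function(a, b) {
  av <- tg_val(a); bv <- tg_val(b)
  to <- bc_shape(dim(av), dim(bv))
  tg_op(bc_to(av, to) + bc_to(bv, to), list(a, b), function(g) {
    list(if (is_tg(a)) reduce_to(g, dim(av)) else NULL,
         if (is_tg(b)) reduce_to(g, dim(bv)) else NULL)
  })
}

#' @rdname tg_ops
#' @export
tg_sub <- function(a, b) {
  av <- tg_val(a); bv <- tg_val(b)
  to <- bc_shape(dim(av), dim(bv))
  tg_op(bc_to(av, to) - bc_to(bv, to), list(a, b), function(g) {
    list(if (is_tg(a)) reduce_to(g, dim(av)) else NULL,
         if (is_tg(b)) reduce_to(-g, dim(bv)) else NULL)
  })
}

#' @rdname tg_ops
#' @export
tg_mul <- function(a, b) {
  av <- tg_val(a); bv <- tg_val(b)
  to <- bc_shape(dim(av), dim(bv))
  abv <- bc_to(av, to); bbv <- bc_to(bv, to)
  tg_op(abv * bbv, list(a, b), function(g) {
    list(if (is_tg(a)) reduce_to(g * bbv, dim(av)) else NULL,
         if (is_tg(b)) reduce_to(g * abv, dim(bv)) else NULL)
  })
}

#' @rdname tg_ops
#' @export
tg_div <- function(a, b) {
  av <- tg_val(a); bv <- tg_val(b)
  to <- bc_shape(dim(av), dim(bv))
  abv <- bc_to(av, to); bbv <- bc_to(bv, to)
  out <- abv / bbv
  tg_op(out, list(a, b), function(g) {
    list(if (is_tg(a)) reduce_to(g / bbv, dim(av)) else NULL,
         if (is_tg(b)) reduce_to(-g * out / bbv, dim(bv)) else NULL)
  })
}

#' Elementwise and shape ops on autodiff tensors
#'
#' Small algebra of differentiable array operations used to assemble the
#' network: elementwise arithmetic with broadcasting over singleton
#' dimensions, activations, reshapes, reductions.
#'
#' @param x tensor or plain array.
#' @param s plain scalar.
#' @name tg_ops
#' @return a `tg_tensor`.
NULL

#' @rdname tg_ops
#' @export
tg_scale <- function(x, s) {
  tg_op(tg_val(x) * s, list(x), function(g) list(g * s))
}

#' @rdname tg_ops
#' @export
tg_add_const <- function(x, s) {
  tg_op(tg_val(x) + s, list(x), function(g) list(g))
}

#' @rdname tg_ops
#' @export
tg_relu <- function(x) {
  v <- tg_val(x)
  mask <- v > 0
  tg_op(v * mask, list(x), function(g) list(g * mask))
}

#' @rdname tg_ops
#' @export
tg_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-tg_val(x)))
  tg_op(v, list(x), function(g) list(g * v * (1 - v)))
}

#' @rdname tg_ops
#' @export
tg_gelu <- function(x) {
  v <- tg_val(x)
  ph <- stats::pnorm(v)
  tg_op(v * ph, list(x), function(g) list(g * (ph + v * stats::dnorm(v))))
}

#' @rdname tg_ops
#' @export
tg_square <- function(x) {
  v <- tg_val(x)
  tg_op(v * v, list(x), function(g) list(2 * g * v))
}

#' @rdname tg_ops
#' @export
tg_abs <- function(x) {
  v <- tg_val(x)
  s <- sign(v)
  tg_op(abs(v), list(x), function(g) list(g * s))
}

#' @rdname tg_ops
#' @export
tg_log <- function(x) {
  v <- tg_val(x)
  tg_op(log(v), list(x), function(g) list(g / v))
}

# ---- shape ops --------------------------------------------------------------

#' @rdname tg_ops
#' @param d integer vector of target dimensions.
#' @export
tg_reshape <- function(x, d) {
  v <- tg_val(x)
  od <- dim(v)
  stopifnot(prod(od) == prod(d))
  tg_op(array(v, dim = d), list(x), function(g) list(array(g, dim = od)))
}

#' @rdname tg_ops
#' @param perm permutation of dimension indices.
#' @export
tg_aperm <- function(x, perm) {
  v <- tg_val(x)
  inv <- order(perm)
  tg_op(aperm(v, perm), list(x), function(g) list(aperm(g, inv)))
}

#' @rdname tg_ops
#' @export
tg_mean <- function(x) {
  v <- tg_val(x)
  n <- length(v)
  d <- dim(v)
  tg_op(array(mean(v), dim = 1L), list(x),
        function(g) list(array(as.numeric(g) / n, dim = d)))
}

#' @rdname tg_ops
#' @export
tg_sum <- function(x) {
  v <- tg_val(x)
  d <- dim(v)
  tg_op(array(sum(v), dim = 1L), list(x),
        function(g) list(array(as.numeric(g), dim = d)))
}

# sum over height/width of (C,H,W,N) -> (C,1,1,N)
#' @rdname tg_ops
#' @export
tg_sum_hw <- function(x) {
  v <- tg_val(x)
  d <- dim(v)
  stopifnot(length(d) == 4L)
  m <- matrix(aperm(v, c(2L, 3L, 1L, 4L)), d[2] * d[3], d[1] * d[4])
  out <- array(colSums(m), dim = c(d[1], 1L, 1L, d[4]))
  tg_op(out, list(x), function(g) list(bc_to(g, d)))
}

#' @rdname tg_ops
#' @param keep integer vector `(h, w)`: output spatial size after center crop.
#' @export
tg_crop2d <- function(x, keep) {
  v <- tg_val(x)
  d <- dim(v)
  stopifnot(length(d) == 4L, all(keep <= d[2:3]))
  r0 <- (d[2] - keep[1]) %/% 2L
  c0 <- (d[3] - keep[2]) %/% 2L
  rows <- seq_len(keep[1]) + r0
  cols <- seq_len(keep[2]) + c0
  tg_op(v[, rows, cols, , drop = FALSE], list(x), function(g) {
    gx <- array(0, dim = d)
    gx[, rows, cols, ] <- g
    list(gx)
  })
}

#' @rdname tg_ops
#' @export
tg_upsample2 <- function(x) {
  v <- tg_val(x)
  d <- dim(v)
  stopifnot(length(d) == 4L)
  out <- v[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), , drop = FALSE]
  tg_op(out, list(x), function(g) {
    i1 <- seq.int(1L, 2L * d[2], by = 2L)
    j1 <- seq.int(1L, 2L * d[3], by = 2L)
    gh <- g[, i1, , , drop = FALSE] + g[, i1 + 1L, , , drop = FALSE]
    list(gh[, , j1, , drop = FALSE] + gh[, , j1 + 1L, , drop = FALSE])
  })
}

#' @rdname tg_ops
#' @param xs list of tensors to concatenate along the channel dimension.
#' @export
tg_concat_c <- function(xs) {
  vs <- lapply(xs, tg_val)
  ds <- lapply(vs, dim)
  nc <- vapply(ds, `[`, integer(1), 1L)
  rest <- ds[[1]][-1]
  for (d in ds) stopifnot(identical(d[-1], rest))
  out <- array(0, dim = c(sum(nc), rest))
  off <- 0L
  for (k in seq_along(vs)) {
    out[off + seq_len(nc[k]), , , ] <- vs[[k]]
    off <- off + nc[k]
  }
  tg_op(out, xs, function(g) {
    off <- 0L
    lapply(seq_along(xs), function(k) {
      gk <- g[off + seq_len(nc[k]), , , , drop = FALSE]
      off <<- off + nc[k]
      gk
    })
  })
}

# ---- matrix ops -------------------------------------------------------------

#' @rdname tg_ops
#' @export
tg_mm <- function(a, b) {
  av <- tg_val(a); bv <- tg_val(b)
  tg_op(av %*% bv, list(a, b), function(g) {
    list(if (is_tg(a)) g %*% t(bv) else NULL,
         if (is_tg(b)) t(av) %*% g else NULL)
  })
}

#' @rdname tg_ops
#' @param dim1 softmax over rows (`1`) of a matrix.
#' @export
tg_softmax_rows <- function(x) {
  v <- tg_val(x)
  v <- v - apply(v, 1L, max)
  e <- exp(v)
  p <- e / rowSums(e)
  tg_op(p, list(x), function(g) list(p * (g - rowSums(g * p))))
}

#' Row-wise layer normalization of a token matrix
#' @param x (tokens x embed) tensor.
#' @param gamma,beta scale/shift parameter tensors of length embed.
#' @param eps variance floor.
#' @return normalized tensor, same shape.
#' @export
tg_layernorm <- function(x, gamma, beta, eps = 1e-6) {
  v <- tg_val(x)
  D <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gv <- as.numeric(tg_val(gamma)); bv <- as.numeric(tg_val(beta))
  out <- sweep(xhat, 2L, gv, `*`)
  out <- sweep(out, 2L, bv, `+`)
  tg_op(out, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    gxhat <- sweep(g, 2L, gv, `*`)
    dx <- istd * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    list(dx,
         if (is_tg(gamma)) array(dgamma, dim = D) else NULL,
         if (is_tg(beta)) array(dbeta, dim = D) else NULL)
  })
}

# ---- softmax / log-softmax over the channel axis of (C,H,W,N) ---------------

#' @rdname tg_ops
#' @export
tg_logsoftmax_c <- function(x) {
  v <- tg_val(x)
  d <- dim(v)
  m <- matrix(v, d[1])
  mx <- apply(m, 2L, max)
  sh <- sweep(m, 2L, mx)
  ls <- sweep(sh, 2L, log(colSums(exp(sh))))
  p <- exp(ls)
  tg_op(array(ls, dim = d), list(x), function(g) {
    gm <- matrix(g, d[1])
    list(array(gm - sweep(p, 2L, colSums(gm), `*`), dim = d))
  })
}

#' @rdname tg_ops
#' @export
tg_softmax_c <- function(x) {
  v <- tg_val(x)
  d <- dim(v)
  m <- matrix(v, d[1])
  sh <- sweep(m, 2L, apply(m, 2L, max))
  e <- exp(sh)
  p <- sweep(e, 2L, colSums(e), `/`)
  tg_op(array(p, dim = d), list(x), function(g) {
    gm <- matrix(g, d[1])
    list(array(p * sweep(gm, 2L, colSums(gm * p)), dim = d))
  })
}

# ---- convolution ------------------------------------------------------------

pad_hw <- function(x, ph, pw) {
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2] + 2L * ph, d[3] + 2L * pw, d[4]))
  out[, ph + seq_len(d[2]), pw + seq_len(d[3]), ] <- x
  out
}

#' 2D convolution (cross-correlation) with autodiff
#'
#' Computed as one matrix product per kernel offset so the work is done by
#' BLAS. `pad = "valid"` shrinks the output by `k - 1`; `pad = "same"` keeps
#' the spatial size (odd kernels only).
#'
#' @param x input tensor, dim (in_channels, H, W, batch).
#' @param w kernel tensor, dim (out_channels, in_channels, kh, kw).
#' @param b optional bias tensor of length out_channels.
#' @param stride integer stride (both axes).
#' @param pad `"valid"` or `"same"`.
#' @return output tensor, dim (out_channels, H', W', batch).
#' @export
tg_conv2d <- function(x, w, b = NULL, stride = 1L, pad = c("valid", "same")) {
  pad <- match.arg(pad)
  xv <- tg_val(x); wv <- tg_val(w)
  dw <- dim(wv)
  co <- dw[1]; ci <- dw[2]; kh <- dw[3]; kw <- dw[4]
  stopifnot(dim(xv)[1] == ci)
  ph <- 0L; pw <- 0L
  if (pad == "same") {
    stopifnot(kh %% 2L == 1L, kw %% 2L == 1L)
    ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  }
  xp <- if (ph > 0L || pw > 0L) pad_hw(xv, ph, pw) else xv
  d <- dim(xp)
  H <- d[2]; W <- d[3]; N <- d[4]
  if (H < kh || W < kw) {
    stop("conv2d: input ", H, "x", W, " smaller than kernel ", kh, "x", kw)
  }
  Ho <- (H - kh) %/% stride + 1L
  Wo <- (W - kw) %/% stride + 1L
  K <- Ho * Wo * N
  # fast path: 1x1 kernel, stride 1
  if (kh == 1L && kw == 1L && stride == 1L) {
    M <- matrix(wv, co, ci) %*% matrix(xp, ci)
  } else {
    M <- matrix(0, co, K)
    for (i in seq_len(kh)) {
      rows <- seq.int(i, by = stride, length.out = Ho)
      for (j in seq_len(kw)) {
        cols <- seq.int(j, by = stride, length.out = Wo)
        xs <- matrix(xp[, rows, cols, , drop = FALSE], ci, K)
        M <- M + matrix(wv[, , i, j], co, ci) %*% xs
      }
    }
  }
  if (!is.null(b)) M <- M + as.numeric(tg_val(b))
  out <- array(M, dim = c(co, Ho, Wo, N))
  parents <- list(x, w, b)
  tg_op(out, parents, function(g) {
    G <- matrix(g, co, K)
    db <- if (!is.null(b) && is_tg(b)) array(rowSums(G), dim = co) else NULL
    dwv <- if (is_tg(w)) array(0, dim = dw) else NULL
    dxp <- if (is_tg(x) && isTRUE(x$ng)) array(0, dim = d) else NULL
    if (kh == 1L && kw == 1L && stride == 1L) {
      if (!is.null(dwv)) dwv[, , 1L, 1L] <- G %*% t(matrix(xp, ci))
      if (!is.null(dxp)) dxp <- array(t(matrix(wv, co, ci)) %*% G, dim = d)
    } else {
      for (i in seq_len(kh)) {
        rows <- seq.int(i, by = stride, length.out = Ho)
        for (j in seq_len(kw)) {
          cols <- seq.int(j, by = stride, length.out = Wo)
          if (!is.null(dwv)) {
            xs <- matrix(xp[, rows, cols, , drop = FALSE], ci, K)
            dwv[, , i, j] <- G %*% t(xs)
          }
          if (!is.null(dxp)) {
            dxp[, rows, cols, ] <- dxp[, rows, cols, , drop = FALSE] +
              array(t(matrix(wv[, , i, j], co, ci)) %*% G, dim = c(ci, Ho, Wo, N))
          }
        }
      }
    }
    dx <- NULL
    if (!is.null(dxp)) {
      dx <- if (ph > 0L || pw > 0L) {
        dxp[, ph + seq_len(dim(xv)[2]), pw + seq_len(dim(xv)[3]), , drop = FALSE]
      } else dxp
    }
    list(dx, dwv, db)
  })
}

# ---- batch normalization ----------------------------------------------------

#' Per-channel batch normalization for (C,H,W,N) tensors
#'
#' @param x input tensor.
#' @param gamma,beta per-channel scale/shift parameter tensors.
#' @param state environment holding `running_mean`, `running_var`.
#' @param training use batch statistics (and update running ones)?
#' @param momentum running-statistics update rate.
#' @param eps variance floor.
#' @return normalized tensor, same shape.
#' @export
tg_batchnorm2d <- function(x, gamma, beta, state, training = TRUE,
                           momentum = 0.1, eps = 1e-5) {
  v <- tg_val(x)
  d <- dim(v)
  C <- d[1]
  m <- matrix(v, C)
  n <- ncol(m)
  gv <- as.numeric(tg_val(gamma)); bv <- as.numeric(tg_val(beta))
  if (training) {
    mu <- rowMeans(m)
    xc <- m - mu
    va <- rowMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    unb <- if (n > 1L) n / (n - 1L) else 1
    state$running_var <- (1 - momentum) * state$running_var + momentum * va * unb
  } else {
    mu <- state$running_mean
    va <- state$running_var
    xc <- m - mu
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  out <- array(xhat * gv + bv, dim = d)
  tg_op(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, C)
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    gxhat <- gm * gv
    dx <- if (training) {
      istd * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    } else {
      gxhat * istd
    }
    list(array(dx, dim = d),
         if (is_tg(gamma)) array(dgamma, dim = C) else NULL,
         if (is_tg(beta)) array(dbeta, dim = C) else NULL)
  })
}

# ---- optimizer --------------------------------------------------------------

#' Adam optimizer state for a list of parameter tensors
#' @param params named list of `tg_tensor` parameters.
#' @return an environment carrying first/second moment estimates and step count.
#' @export
adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim = dim(p$value)))
  st$v <- lapply(params, function(p) array(0, dim = dim(p$value)))
  st$t <- 0L
  st
}

#' One Adam update over parameters with accumulated gradients
#'
#' Parameters with `requires_grad = FALSE` or no gradient are skipped.
#' Gradients are cleared after the step.
#'
#' @param state environment from [adam_init()].
#' @param params the same named list of parameters.
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical floor.
#' @export
adam_step <- function(state, params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    p <- params[[k]]
    if (!isTRUE(p$requires_grad) || is.null(p$grad)) next
    g <- p$grad
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    p$value <- p$value - lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    p$grad <- NULL
  }
  invisible(state)
}

#' Clear accumulated gradients on a parameter list
#' @param params named list of `tg_tensor`s.
#' @export
tg_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- matrix slicing helpers (used by multi-head attention) ------------------

#' @rdname tg_ops
#' @param idx integer column indices.
#' @export
tg_cols <- function(x, idx) {
  v <- tg_val(x)
  d <- dim(v)
  tg_op(v[, idx, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    gx[, idx] <- g
    list(gx)
  })
}

#' @rdname tg_ops
#' @export
tg_cbind <- function(xs) {
  vs <- lapply(xs, tg_val)
  ks <- vapply(vs, ncol, integer(1))
  tg_op(do.call(cbind, vs), xs, function(g) {
    off <- 0L
    lapply(seq_along(xs), function(k) {
      gk <- g[, off + seq_len(ks[k]), drop = FALSE]
      off <<- off + ks[k]
      gk
    })
  })
}

#' @rdname tg_ops
#' @export
tg_t <- function(x) {
  tg_op(t(tg_val(x)), list(x), function(g) list(t(g)))
}

#' @rdname tg_ops
#' @param n batch index to select (4th dimension, kept as size 1).
#' @export
tg_slice_n <- function(x, n) {
  v <- tg_val(x)
  d <- dim(v)
  tg_op(v[, , , n, drop = FALSE], list(x), function(g) {
    gx <- array(0, dim = d)
    gx[, , , n] <- g
    list(gx)
  })
}

#' @rdname tg_ops
#' @export
tg_concat_n <- function(xs) {
  vs <- lapply(xs, tg_val)
  ds <- lapply(vs, dim)
  nb <- vapply(ds, `[`, integer(1), 4L)
  lead <- ds[[1]][1:3]
  out <- array(0, dim = c(lead, sum(nb)))
  off <- 0L
  for (k in seq_along(vs)) {
    out[, , , off + seq_len(nb[k])] <- vs[[k]]
    off <- off + nb[k]
  }
  tg_op(out, xs, function(g) {
    off <- 0L
    lapply(seq_along(xs), function(k) {
      gk <- g[, , , off + seq_len(nb[k]), drop = FALSE]
      off <<- off + nb[k]
      gk
    })
  })
}

#' @rdname tg_ops
#' @param p replicate-padding width (pixels on each side).
#' @export
tg_pad_replicate <- function(x, p) {
  v <- tg_val(x)
  d <- dim(v)
  stopifnot(length(d) == 4L, p >= 0L)
  if (p == 0L) return(as_tg(x))
  ri <- c(rep(1L, p), seq_len(d[2]), rep(d[2], p))
  ci <- c(rep(1L, p), seq_len(d[3]), rep(d[3], p))
  out <- v[, ri, ci, , drop = FALSE]
  tg_op(out, list(x), function(g) {
    # sum gradient contributions of replicated rows/cols back to their source
    dg <- dim(g)
    gp <- aperm(g, c(2L, 1L, 3L, 4L))
    gr <- rowsum(matrix(gp, dg[2]), ri)
    gr <- aperm(array(gr, dim = c(d[2], dg[1], dg[3], dg[4])), c(2L, 1L, 3L, 4L))
    gp <- aperm(gr, c(3L, 1L, 2L, 4L))
    gc <- rowsum(matrix(gp, dg[3]), ci)
    gc <- aperm(array(gc, dim = c(d[3], dg[1], d[2], dg[4])), c(2L, 3L, 1L, 4L))
    list(gc)
  })
}
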