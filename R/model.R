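# Architecture: pre-activated ResNet-50 trunk (downsampling factor 8) with
# optional SimAM insertions, hybrid Transformer encoder over the trunk's
# feature-map positions, DecoderCup projection, and three structurally
# identical dense-unit decoder branches (NP / HV / NC).

#' Trunk configuration
#'
#' Four pre-activated bottleneck residual blocks with 3, 4, 6 and 3 units at
#' downsampling levels 1, 2, 4 and 8 (total factor 8: the 7x7 stem is
#' stride 1 and there is no max-pool). `width` is the stem width; block
#' channels are `4*width * 2^(d-1)`, so the default 64 gives
#' 256/512/1024/2048.
#'
#' @param block_unit_counts residual units per block.
#' @param width stem width (64 reproduces the reference shapes; smaller
#'   values give proportionally thinner models for CPU-scale runs).
#' @param simam_after_blocks logical flags: insert SimAM after each block.
#' @param input_size expected square input edge in pixels.
#' @return a `trunk_config` list.
#' @export
trunk_config <- function(block_unit_counts = c(3L, 4L, 6L, 3L), width = 64L,
                         simam_after_blocks = rep(TRUE, 4L), input_size = 270L) {
  stopifnot(length(block_unit_counts) == 4L, all(block_unit_counts >= 1L),
            width >= 1L, length(simam_after_blocks) == 4L)
  structure(list(block_unit_counts = as.integer(block_unit_counts),
                 downsample_levels = c(1L, 2L, 4L, 8L),
                 width = as.integer(width),
                 simam_after_blocks = as.logical(simam_after_blocks),
                 input_size = as.integer(input_size)),
            class = "trunk_config")
}

#' Transformer encoder configuration
#'
#' An L-layer pre-norm Transformer (multi-head self-attention + MLP, residual
#' connections around both) consuming one token per spatial position of the
#' trunk's final feature map. Defaults follow the standard base
#' configuration: 12 layers, embedding width 768, 12 heads, MLP width 3072.
#' `patch_edge` is the effective image-to-token downsampling ratio (8 for
#' this trunk).
#'
#' @param n_layers number of encoder layers L (0 = pure projection path).
#' @param embed_dim token embedding width D (divisible by `n_heads`).
#' @param n_heads attention heads.
#' @param mlp_dim hidden width of the per-token MLP.
#' @param patch_edge effective image-to-token ratio.
#' @return a `transformer_config` list.
#' @export
transformer_config <- function(n_layers = 12L, embed_dim = 768L, n_heads = 12L,
                               mlp_dim = 3072L, patch_edge = 8L) {
  stopifnot(n_layers >= 0L, embed_dim >= 1L, n_heads >= 1L,
            embed_dim %% n_heads == 0L, mlp_dim >= 1L)
  structure(list(n_layers = as.integer(n_layers), embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads), mlp_dim = as.integer(mlp_dim),
                 patch_edge = as.integer(patch_edge)),
            class = "transformer_config")
}

#' Decoder branch configuration
#'
#' @param role `"NP"` (nuclear pixel), `"HV"` (horizontal-vertical distance
#'   maps) or `"NC"` (nuclear classification).
#' @param out_channels output channels: 2 for NP and HV, `C + 1` for NC with
#'   C nuclear types.
#' @param dense_unit_counts dense units in the two decoder stages.
#' @param simam_in_branch insert SimAM after each dense block?
#' @return a `branch_config` list.
#' @export
branch_config <- function(role = c("NP", "HV", "NC"), out_channels = NULL,
                          dense_unit_counts = c(8L, 4L), simam_in_branch = TRUE) {
  role <- match.arg(role)
  if (is.null(out_channels)) {
    if (role == "NC") stop("out_channels must be given for the NC branch (C + 1)")
    out_channels <- 2L
  }
  if (role %in% c("NP", "HV") && out_channels != 2L) {
    stop(role, " branch must have out_channels = 2")
  }
  stopifnot(length(dense_unit_counts) == 2L, all(dense_unit_counts >= 1L))
  structure(list(role = role, out_channels = as.integer(out_channels),
                 dense_unit_counts = as.integer(dense_unit_counts),
                 simam_in_branch = isTRUE(simam_in_branch)),
            class = "branch_config")
}

#' Default three-branch configuration
#' @param n_classes number of nuclear types C (NC branch gets C + 1 channels).
#' @param dense_unit_counts dense units per decoder stage.
#' @param simam_in_branch insert SimAM in the branches?
#' @return named list of three `branch_config`s (np, hv, nc).
#' @export
default_branches <- function(n_classes = 4L, dense_unit_counts = c(8L, 4L),
                             simam_in_branch = TRUE) {
  list(np = branch_config("NP", 2L, dense_unit_counts, simam_in_branch),
       hv = branch_config("HV", 2L, dense_unit_counts, simam_in_branch),
       nc = branch_config("NC", n_classes + 1L, dense_unit_counts, simam_in_branch))
}

#' Spatial-size chain of the encoder-decoder for a square input
#'
#' Derives every stage's spatial edge for the valid-convolution chain and
#' errors naming the first stage at which the input becomes too small.
#'
#' @param input_size square input edge (pixels).
#' @param dense_unit_counts dense units in the two decoder stages.
#' @return list with stem/block/decoder sizes and the output edge.
#' @export
hov_shape_chain <- function(input_size, dense_unit_counts = c(8L, 4L)) {
  s <- as.integer(input_size)
  half <- function(v) (v - 1L) %/% 2L + 1L
  s0 <- s - 6L
  if (s0 < 1L) stop("stem conv (7x7 valid): input ", s, " too small")
  s2 <- half(s0); s3 <- half(s2); s4 <- half(s3)
  if (s4 < 1L) stop("residual block 4: input ", s, " too small")
  m1 <- min(2L * s4, s3)
  c1 <- m1 - 4L
  d1 <- c1 - 4L * dense_unit_counts[1]
  if (d1 < 1L) stop("decoder dense block 1 (", dense_unit_counts[1],
                    " valid 5x5 units): input ", s, " too small")
  m2 <- min(2L * d1, s2)
  c2 <- m2 - 4L
  d2 <- c2 - 4L * dense_unit_counts[2]
  if (d2 < 1L) stop("decoder dense block 2 (", dense_unit_counts[2],
                    " valid 5x5 units): input ", s, " too small")
  out <- min(2L * d2, s0)
  list(stem = s0, block1 = s0, block2 = s2, block3 = s3, block4 = s4,
       tokens = s4 * s4, dec1 = d1, dec2 = d2, output = out)
}

# ---- transformer ------------------------------------------------------------

nn_ln_mod <- function(D) {
  D <- as.integer(D)
  gamma <- tg_tensor(array(1, dim = D), requires_grad = TRUE)
  beta <- tg_tensor(array(0, dim = D), requires_grad = TRUE)
  list(params = list(gamma = gamma, beta = beta),
       fwd = function(x, training = TRUE) tg_layernorm(x, gamma, beta))
}

nn_transformer <- function(c_in, n_tokens, cfg) {
  c_in <- as.integer(c_in); n_tokens <- as.integer(n_tokens); force(cfg)
  D <- cfg$embed_dim
  nh <- cfg$n_heads
  dh <- D %/% nh
  embed <- nn_linear(c_in, D)
  pos <- tg_tensor(matrix(stats::rnorm(n_tokens * D, sd = 0.02), n_tokens, D),
                   requires_grad = TRUE)
  params <- c(prefix_params(embed$params, "embed"), list(pos = pos))
  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    ly <- list(ln1 = nn_ln_mod(D), wq = nn_linear(D, D), wk = nn_linear(D, D),
               wv = nn_linear(D, D), wo = nn_linear(D, D), ln2 = nn_ln_mod(D),
               mlp1 = nn_linear(D, cfg$mlp_dim), mlp2 = nn_linear(cfg$mlp_dim, D))
    for (nm in names(ly)) {
      params <- c(params, prefix_params(ly[[nm]]$params, paste0("layer", l, ".", nm)))
    }
    layers[[l]] <- ly
  }
  ln_f <- if (cfg$n_layers > 0L) nn_ln_mod(D) else NULL
  if (!is.null(ln_f)) params <- c(params, prefix_params(ln_f$params, "ln_final"))
  head_cols <- lapply(seq_len(nh), function(h) (h - 1L) * dh + seq_len(dh))
  fwd_tokens <- function(z, training = TRUE) {
    for (ly in layers) {
      h <- ly$ln1$fwd(z, training)
      q <- ly$wq$fwd(h, training)
      k <- ly$wk$fwd(h, training)
      v <- ly$wv$fwd(h, training)
      outs <- lapply(head_cols, function(cols) {
        qh <- tg_cols(q, cols)
        kh <- tg_cols(k, cols)
        vh <- tg_cols(v, cols)
        att <- tg_softmax_rows(tg_scale(tg_mm(qh, tg_t(kh)), 1 / sqrt(dh)))
        tg_mm(att, vh)
      })
      z <- tg_add(z, ly$wo$fwd(tg_cbind(outs), training))
      h2 <- ly$ln2$fwd(z, training)
      z <- tg_add(z, ly$mlp2$fwd(tg_gelu(ly$mlp1$fwd(h2, training)), training))
    }
    if (!is.null(ln_f)) z <- ln_f$fwd(z, training)
    z
  }
  list(params = params, n_tokens = n_tokens, embed_dim = D,
       fwd = function(x, training = TRUE) {
       # x: (C, H', W', N) -> tokens per sample -> (D, H', W', N)
         d <- dim(tg_val(x))
         ntok <- d[2] * d[3]
         if (ntok != n_tokens) {
           stop("token count ", ntok, " inconsistent with position embedding length ",
                n_tokens)
         }
         outs <- lapply(seq_len(d[4]), function(n) {
           xs <- tg_slice_n(x, n)
           tok <- tg_reshape(tg_aperm(xs, c(2L, 3L, 1L, 4L)), c(ntok, d[1]))
           z <- tg_add(embed$fwd(tok, training), pos)
           z <- fwd_tokens(z, training)
           tg_aperm(tg_reshape(z, c(d[2], d[3], D, 1L)), c(3L, 1L, 2L, 4L))
         })
         if (length(outs) == 1L) outs[[1]] else tg_concat_n(outs)
       })
}

#' Transformer encoding of a trunk feature map
#'
#' Flattens a `(C, H', W', N)` feature map to `H'*W'` tokens (row-major over
#' spatial positions), linearly embeds them, adds a learned position
#' embedding, applies `cfg$n_layers` pre-norm self-attention/MLP blocks with
#' residual connections, and reshapes the encoded sequence back to
#' `(D, H', W', N)`. With `n_layers = 0` this reduces to the embedded and
#' reshaped input (pure projection path).
#'
#' @param features 4D tensor or array `(C, H', W', N)`.
#' @param cfg a [transformer_config()].
#' @param module optional pre-built transformer module (from a model); if
#'   omitted, one is initialized from the current RNG state for the given
#'   feature shape.
#' @param training forwarded to layers (no dropout is used, so this only
#'   matters for gradient recording upstream).
#' @return tensor/array `(embed_dim, H', W', N)`, same spatial size as input.
#' @export
transformer_encode <- function(features, cfg = transformer_config(),
                               module = NULL, training = FALSE) {
  plain <- !is_tg(features)
  ft <- as_tg(features)
  d <- dim(tg_val(ft))
  stopifnot(length(d) == 4L)
  if (is.null(module)) {
    module <- nn_transformer(d[1], d[2] * d[3], cfg)
  }
  out <- module$fwd(ft, training)
  if (plain) tg_val(out) else out
}

# ---- model assembly ---------------------------------------------------------

nn_branch <- function(cfg, w, growth, simam_des, simam_lambda) {
  force(cfg); force(w); force(growth); force(simam_des); force(simam_lambda)
  n1 <- cfg$dense_unit_counts[1]
  n2 <- cfg$dense_unit_counts[2]
  conv1 <- nn_conv(16L * w, 4L * w, 5L, pad = "valid", bias = FALSE)
  dense1 <- nn_dense_block(4L * w, n1, 2L * w, growth)
  conv1b <- nn_conv(dense1$out_channels, 8L * w, 1L, bias = FALSE)
  conv2 <- nn_conv(8L * w, 2L * w, 5L, pad = "valid", bias = FALSE)
  dense2 <- nn_dense_block(2L * w, n2, 2L * w, growth)
  conv2b <- nn_conv(dense2$out_channels, 4L * w, 1L, bias = FALSE)
  conv3 <- nn_conv(4L * w, w, 5L, pad = "same", bias = FALSE)
  bn3 <- nn_bn(w)
  head <- nn_conv(w, cfg$out_channels, 1L, bias = TRUE)
  mods <- list(conv1 = conv1, dense1 = dense1, conv1b = conv1b, conv2 = conv2,
               dense2 = dense2, conv2b = conv2b, conv3 = conv3, bn3 = bn3,
               head = head)
  params <- list()
  for (nm in names(mods)) params <- c(params, prefix_params(mods[[nm]]$params, nm))
  use_simam <- isTRUE(cfg$simam_in_branch) && isTRUE(simam_des)
  list(params = params,
       fwd = function(x, skips, training = TRUE) {
         h <- add_cropped(tg_upsample2(x), skips$block3)
         h <- conv1$fwd(h, training)
         h <- dense1$fwd(h, training)
         if (use_simam) h <- simam_attend(h, simam_lambda)
         h <- conv1b$fwd(h, training)
         h <- add_cropped(tg_upsample2(h), skips$block2)
         h <- conv2$fwd(h, training)
         h <- dense2$fwd(h, training)
         if (use_simam) h <- simam_attend(h, simam_lambda)
         h <- conv2b$fwd(h, training)
         h <- add_cropped(tg_upsample2(h), skips$block1)
         h <- conv3$fwd(h, training)
         h <- tg_relu(bn3$fwd(h, training))
         head$fwd(h, training)
       })
}

#' Build the three-branch segmentation/classification network
#'
#' Assembles the full model: 7x7 valid stem, four pre-activated bottleneck
#' residual blocks (strides 1/2/2/2, total downsampling 8) with optional
#' SimAM after each block, an optional Transformer encoder over the final
#' feature-map positions followed by a DecoderCup projection (3x3
#' convolution + batch norm + ReLU back to 16*width channels), and three
#' dense-unit decoder branches with additive center-cropped skip
#' connections. With all flags off the architecture reduces to the plain
#' HoVer-Net-style baseline (no SimAM anywhere, Transformer path replaced by
#' a 1x1 bottleneck convolution).
#'
#' @param trunk a [trunk_config()].
#' @param tf a [transformer_config()].
#' @param branches named list of three [branch_config()]s (np, hv, nc), as
#'   from [default_branches()].
#' @param use_transformer include the Transformer encoder?
#' @param simam_res SimAM after the residual blocks ("Res" placement)?
#' @param simam_des SimAM inside the decoder branches ("Des" placement)?
#' @param simam_lambda SimAM energy regularizer.
#' @param seed integer seed for weight initialization (restored afterwards).
#' @return a `hovseg_model` object; see [model_forward()], [model_summary()].
#' @examples
#' \donttest{
#' m <- build_model(trunk_config(width = 4, input_size = 270),
#'                  transformer_config(n_layers = 1, embed_dim = 16,
#'                                     n_heads = 4, mlp_dim = 32))
#' }
#' @export
build_model <- function(trunk = trunk_config(), tf = transformer_config(),
                        branches = default_branches(4L),
                        use_transformer = TRUE, simam_res = TRUE,
                        simam_des = TRUE, simam_lambda = 1e-4, seed = 1L) {
  stopifnot(inherits(trunk, "trunk_config"), inherits(tf, "transformer_config"),
            length(branches) == 3L)
  roles <- vapply(branches, function(b) b$role, character(1))
  if (!setequal(roles, c("NP", "HV", "NC"))) {
    stop("branches must cover roles NP, HV and NC")
  }
  names(branches) <- tolower(roles)
  duc <- branches[[1]]$dense_unit_counts
  chain <- hov_shape_chain(trunk$input_size, duc)
  w <- trunk$width
  growth <- max(1L, w %/% 2L)
  withr::with_seed(as.integer(seed), {
    conv0 <- nn_conv(3L, w, 7L, pad = "valid", bias = TRUE)
    blocks <- list(
      nn_res_block(w, w, 4L * w, trunk$block_unit_counts[1], stride = 1L),
      nn_res_block(4L * w, 2L * w, 8L * w, trunk$block_unit_counts[2], stride = 2L),
      nn_res_block(8L * w, 4L * w, 16L * w, trunk$block_unit_counts[3], stride = 2L),
      nn_res_block(16L * w, 8L * w, 32L * w, trunk$block_unit_counts[4], stride = 2L))
    if (use_transformer) {
      transformer <- nn_transformer(32L * w, chain$tokens, tf)
      cup_conv <- nn_conv(tf$embed_dim, 16L * w, 3L, pad = "same", bias = FALSE)
      cup_bn <- nn_bn(16L * w)
    } else {
      transformer <- NULL
      cup_conv <- nn_conv(32L * w, 16L * w, 1L, bias = FALSE)
      cup_bn <- nn_bn(16L * w)
    }
    branch_mods <- lapply(branches, nn_branch, w = w, growth = growth,
                          simam_des = simam_des, simam_lambda = simam_lambda)
  })
  params <- c(prefix_params(conv0$params, "trunk.conv0"),
              prefix_params(blocks[[1]]$params, "trunk.block1"),
              prefix_params(blocks[[2]]$params, "trunk.block2"),
              prefix_params(blocks[[3]]$params, "trunk.block3"),
              prefix_params(blocks[[4]]$params, "trunk.block4"),
              if (use_transformer) prefix_params(transformer$params, "transformer"),
              prefix_params(cup_conv$params, "cup.conv"),
              prefix_params(cup_bn$params, "cup.bn"))
  for (nm in names(branch_mods)) {
    params <- c(params, prefix_params(branch_mods[[nm]]$params, nm))
  }
  trace <- new.env(parent = emptyenv())
  simam_trunk <- trunk$simam_after_blocks & isTRUE(simam_res)
  fwd <- function(x, training = TRUE) {
    d <- dim(tg_val(x))
    h <- conv0$fwd(x, training)
    trace$conv0 <- dim(tg_val(h))
    skips <- list()
    for (b in 1:4) {
      h <- blocks[[b]]$fwd(h, training)
      if (simam_trunk[b]) h <- simam_attend(h, simam_lambda)
      trace[[paste0("residual_block_", b)]] <- dim(tg_val(h))
      if (b < 4L) skips[[paste0("block", b)]] <- h
    }
    if (!is.null(transformer)) {
      ds <- dim(tg_val(h))
      trace$transformer_tokens <- c(ds[2] * ds[3], tf$embed_dim)
      h <- transformer$fwd(h, training)
    }
    h <- tg_relu(cup_bn$fwd(cup_conv$fwd(h, training), training))
    trace$decoder_cup <- dim(tg_val(h))
    out <- lapply(branch_mods, function(br) br$fwd(h, skips, training))
    for (nm in names(out)) trace[[nm]] <- dim(tg_val(out[[nm]]))
    out
  }
  structure(list(params = params, fwd = fwd, trace = trace,
                 cfg = list(trunk = trunk, tf = tf, branches = branches,
                            use_transformer = isTRUE(use_transformer),
                            simam_res = isTRUE(simam_res),
                            simam_des = isTRUE(simam_des),
                            simam_lambda = simam_lambda, seed = as.integer(seed)),
                 chain = chain),
            class = "hovseg_model")
}

#' Number of learnable parameters of a model
#' @param model a `hovseg_model`.
#' @return integer count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

#' @export
print.hovseg_model <- function(x, ...) {
  cfg <- x$cfg
  cat("Three-branch nuclear segmentation/classification network\n")
  cat("  trunk width:", cfg$trunk$width,
      " units:", paste(cfg$trunk$block_unit_counts, collapse = "/"), "\n")
  cat("  transformer:", if (cfg$use_transformer) {
    paste0("L=", cfg$tf$n_layers, " D=", cfg$tf$embed_dim)
  } else "off (1x1 bottleneck)", "\n")
  cat("  SimAM: trunk", cfg$simam_res, "| branches", cfg$simam_des, "\n")
  cat("  input size:", cfg$trunk$input_size,
      "-> output", x$chain$output, "x", x$chain$output, "\n")
  cat("  parameters:", format(n_params(x), big.mark = ","), "\n")
  invisible(x)
}

# convert user-facing image input to the internal (3, H, W, N) layout
as_image_batch <- function(images) {
  if (is.list(images)) {
    arrs <- lapply(images, as_image_batch)
    return(do.call(function(...) {
      a <- list(...)
      out <- array(0, dim = c(dim(a[[1]])[1:3], length(a)))
      for (i in seq_along(a)) out[, , , i] <- a[[i]]
      out
    }, arrs))
  }
  d <- dim(images)
  if (length(d) == 3L && d[3] == 3L) {
    images <- array(aperm(images, c(3L, 1L, 2L)), dim = c(3L, d[1], d[2], 1L))
  } else if (length(d) == 4L && d[3] == 3L) {
    images <- aperm(images, c(3L, 1L, 2L, 4L))
  } else if (!(length(d) == 4L && d[1] == 3L)) {
    stop("expected an RGB image (H, W, 3), a batch (H, W, 3, N), ",
         "or an internal (3, H, W, N) array")
  }
  images
}

#' Forward pass of the model
#'
#' @param model a `hovseg_model` from [build_model()].
#' @param images an `(H, W, 3)` RGB array, an `(H, W, 3, N)` batch, a list of
#'   RGB arrays, or an internal `(3, H, W, N)` array/tensor.
#' @param training training mode (batch-norm batch statistics, gradient
#'   recording)? Use `FALSE` for inference.
#' @return list with tensors `np` (2-channel logits), `hv` (2-channel maps),
#'   `nc` (`C + 1`-channel logits), each `(channels, H_out, W_out, N)`.
#' @export
model_forward <- function(model, images, training = FALSE) {
  x <- if (is_tg(images)) images else tg_tensor(as_image_batch(images))
  if (training) model$fwd(x, training = TRUE) else {
    tg_no_grad(model$fwd(x, training = FALSE))
  }
}

#' Per-stage output shapes for a given input size
#'
#' Runs one forward pass on a zero image of the configured input size and
#' reports every recorded stage's output shape (channels, height, width).
#'
#' @param model a `hovseg_model`.
#' @param input_size square input edge; defaults to the configured one.
#' @return data.frame with columns `stage` and `shape`.
#' @export
model_summary <- function(model, input_size = NULL) {
  s <- if (is.null(input_size)) model$cfg$trunk$input_size else as.integer(input_size)
  img <- array(0, dim = c(s, s, 3L))
  invisible(model_forward(model, img, training = FALSE))
  tr <- model$trace
  stages <- c("conv0", paste0("residual_block_", 1:4),
              if (model$cfg$use_transformer) "transformer_tokens",
              "decoder_cup", "np", "hv", "nc")
  data.frame(stage = stages,
             shape = vapply(stages, function(nm) {
               v <- tr[[nm]]
               if (nm != "transformer_tokens") v <- v[-length(v)]
               paste(v, collapse = "x")
             }, character(1)),
             row.names = NULL)
}

#' Set or clear gradient tracking on parameter subtrees
#'
#' @param model a `hovseg_model`.
#' @param prefixes character vector of parameter-name prefixes
#'   (e.g. `c("trunk.", "transformer.")`).
#' @param value `TRUE` to train those parameters, `FALSE` to freeze.
#' @return the model, invisibly.
#' @export
set_trainable <- function(model, prefixes, value) {
  nm <- names(model$params)
  hit <- Reduce(`|`, lapply(prefixes, function(p) startsWith(nm, p)), rep(FALSE, length(nm)))
  for (p in model$params[hit]) {
    p$requires_grad <- value
    p$ng <- value
  }
  invisible(model)
}
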