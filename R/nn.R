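# Layer constructors. A "module" is a plain list:
#   $params : named list of tg_tensor parameters
#   $fwd    : function(x, training) -> tg_tensor
# Parameter names are flattened with dot-separated prefixes so the training
# code can freeze or update whole subtrees by name.

prefix_params <- function(params, pfx) {
  if (length(params) == 0L) return(params)
  stats::setNames(params, paste0(pfx, ".", names(params)))
}

he_init <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

nn_conv <- function(ci, co, k, stride = 1L, pad = "valid", bias = TRUE) {
  ci <- as.integer(ci); co <- as.integer(co); k <- as.integer(k)
  stride <- as.integer(stride); force(pad); force(bias)
  w <- tg_tensor(he_init(ci * k * k, c(co, ci, k, k)), requires_grad = TRUE)
  b <- if (bias) tg_tensor(array(0, dim = co), requires_grad = TRUE) else NULL
  params <- c(list(w = w), if (bias) list(b = b))
  list(params = params,
       fwd = function(x, training = TRUE) tg_conv2d(x, w, b, stride, pad))
}

nn_bn <- function(c) {
  c <- as.integer(c)
  gamma <- tg_tensor(array(1, dim = c), requires_grad = TRUE)
  beta <- tg_tensor(array(0, dim = c), requires_grad = TRUE)
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, c)
  st$running_var <- rep(1, c)
  list(params = list(gamma = gamma, beta = beta), buffers = st,
       fwd = function(x, training = TRUE) {
         tg_batchnorm2d(x, gamma, beta, st, training = training)
       })
}

nn_linear <- function(di, do) {
  di <- as.integer(di); do <- as.integer(do)
  W <- tg_tensor(matrix(stats::rnorm(di * do, sd = sqrt(1 / di)), di, do),
                 requires_grad = TRUE)
  b <- tg_tensor(array(0, dim = c(1L, do)), requires_grad = TRUE)
  list(params = list(W = W, b = b),
       fwd = function(x, training = TRUE) tg_add(tg_mm(x, W), b))
}

# pre-activated bottleneck residual unit (BN-ReLU before each conv)
nn_preact_unit <- function(ci, width, co, stride = 1L) {
  ci <- as.integer(ci); width <- as.integer(width); co <- as.integer(co)
  stride <- as.integer(stride)
  bn1 <- nn_bn(ci)
  conv1 <- nn_conv(ci, width, 1L, bias = FALSE)
  bn2 <- nn_bn(width)
  conv2 <- nn_conv(width, width, 3L, stride = stride, pad = "same", bias = FALSE)
  bn3 <- nn_bn(width)
  conv3 <- nn_conv(width, co, 1L, bias = FALSE)
  project <- (ci != co) || (stride != 1L)
  sc <- if (project) nn_conv(ci, co, 1L, stride = stride, bias = FALSE) else NULL
  params <- c(prefix_params(bn1$params, "bn1"), prefix_params(conv1$params, "conv1"),
              prefix_params(bn2$params, "bn2"), prefix_params(conv2$params, "conv2"),
              prefix_params(bn3$params, "bn3"), prefix_params(conv3$params, "conv3"),
              if (project) prefix_params(sc$params, "shortcut"))
  list(params = params,
       fwd = function(x, training = TRUE) {
         a <- tg_relu(bn1$fwd(x, training))
         h <- conv1$fwd(a, training)
         h <- tg_relu(bn2$fwd(h, training))
         h <- conv2$fwd(h, training)
         h <- tg_relu(bn3$fwd(h, training))
         h <- conv3$fwd(h, training)
         s <- if (project) sc$fwd(a, training) else x
         tg_add(h, s)
       })
}

nn_res_block <- function(ci, width, co, n_units, stride = 1L) {
  force(ci); force(width); force(co); force(n_units); stride <- as.integer(stride)
  units <- vector("list", n_units)
  params <- list()
  for (u in seq_len(n_units)) {
    units[[u]] <- nn_preact_unit(if (u == 1L) ci else co, width, co,
                                 stride = if (u == 1L) stride else 1L)
    params <- c(params, prefix_params(units[[u]]$params, paste0("unit", u)))
  }
  list(params = params,
       fwd = function(x, training = TRUE) {
         for (u in units) x <- u$fwd(x, training)
         x
       })
}

# dense unit: pre-activated 1x1 bottleneck then valid 5x5; concatenation with
# the center-cropped input (each unit shrinks spatial size by 4)
nn_dense_unit <- function(ci, bottleneck, growth) {
  force(ci); force(bottleneck); force(growth)
  bn1 <- nn_bn(ci)
  conv1 <- nn_conv(ci, bottleneck, 1L, bias = FALSE)
  bn2 <- nn_bn(bottleneck)
  conv2 <- nn_conv(bottleneck, growth, 5L, pad = "valid", bias = FALSE)
  params <- c(prefix_params(bn1$params, "bn1"), prefix_params(conv1$params, "conv1"),
              prefix_params(bn2$params, "bn2"), prefix_params(conv2$params, "conv2"))
  list(params = params,
       fwd = function(x, training = TRUE) {
         h <- tg_relu(bn1$fwd(x, training))
         h <- conv1$fwd(h, training)
         h <- tg_relu(bn2$fwd(h, training))
         h <- conv2$fwd(h, training)
         keep <- dim(tg_val(h))[2:3]
         tg_concat_c(list(tg_crop2d(x, keep), h))
       })
}

nn_dense_block <- function(ci, n_units, bottleneck, growth) {
  force(ci); force(n_units); force(bottleneck); force(growth)
  units <- vector("list", n_units)
  params <- list()
  c_in <- ci
  for (u in seq_len(n_units)) {
    units[[u]] <- nn_dense_unit(c_in, bottleneck, growth)
    params <- c(params, prefix_params(units[[u]]$params, paste0("unit", u)))
    c_in <- c_in + growth
  }
  list(params = params, out_channels = c_in,
       fwd = function(x, training = TRUE) {
         for (u in units) x <- u$fwd(x, training)
         x
       })
}

# add two feature maps, center-cropping both to the common spatial size
add_cropped <- function(a, b) {
  da <- dim(tg_val(a))[2:3]
  db <- dim(tg_val(b))[2:3]
  keep <- pmin(da, db)
  if (!all(da == keep)) a <- tg_crop2d(a, keep)
  if (!all(db == keep)) b <- tg_crop2d(b, keep)
  tg_add(a, b)
}
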