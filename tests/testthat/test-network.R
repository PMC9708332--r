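# SimAM, transformer encoding, model assembly and forward contracts,
# exercised on thin configurations (width 4, 1 transformer layer) whose
# spatial chain is identical to the full-width model.

test_that("SimAM weights a constant channel uniformly and preserves shape", {
  x <- array(3, dim = c(2, 4, 5, 1))
  y <- simam_attend(x)
  expect_equal(dim(y), dim(x))
  expect_length(unique(round(as.vector(y), 12)), 1L)
  # all-equal neurons: (t - mu)^2 = 0 everywhere, same weight for all
  expect_true(all(abs(y - y[1]) < 1e-12))
})

test_that("SimAM boosts the outlier neuron per the closed-form energy", {
  x <- array(c(1, 1, 1, 5), dim = c(1, 2, 2, 1))
  w <- as.vector(simam_attend(x)) / as.vector(x)
  # independent hand evaluation of E* for all four neurons
  lam <- 1e-4
  expected <- vapply(1:4, function(i) {
    t <- as.vector(x)[i]
    others <- as.vector(x)[-i]
    mu <- mean(others)
    va <- mean((others - mu)^2)
    inv_e <- ((t - mu)^2 + 2 * va + 2 * lam) / (4 * (va + lam))
    1 / (1 + exp(-inv_e))
  }, numeric(1))
  expect_equal(w, expected, tolerance = 1e-12)
  expect_true(all(w[4] > w[1:3]))
})

test_that("SimAM returns single-element channels unchanged and needs lambda > 0", {
  x <- array(rnorm(6), dim = c(6, 1, 1, 1))
  expect_identical(simam_attend(x), x)
  expect_error(simam_attend(array(1, c(1, 2, 2, 1)), lambda_reg = 0))
})

test_that("SimAM adds zero learnable parameters to the model", {
  m_on <- tiny_model(seed = 3)
  m_off <- build_model(trunk_config(width = 4L, input_size = 198L),
                       transformer_config(1L, 32L, 4L, 64L),
                       default_branches(4L),
                       simam_res = FALSE, simam_des = FALSE, seed = 3)
  expect_equal(n_params(m_on), n_params(m_off))
})

test_that("transformer encoding preserves spatial size and validates token count", {
  set.seed(1)
  x <- array(rnorm(6 * 5 * 7), dim = c(6, 5, 7, 1))
  cfg <- transformer_config(n_layers = 2L, embed_dim = 16L, n_heads = 4L,
                            mlp_dim = 32L)
  y <- transformer_encode(x, cfg)
  expect_equal(dim(y), c(16L, 5L, 7L, 1L))
  mod <- hovseg:::nn_transformer(6L, 35L, cfg)
  bad <- array(rnorm(6 * 4 * 4), dim = c(6, 4, 4, 1))
  expect_error(transformer_encode(bad, cfg, module = mod), "inconsistent")
})

test_that("a 0-layer transformer is the pure projection path", {
  set.seed(2)
  cfg <- transformer_config(n_layers = 0L, embed_dim = 8L, n_heads = 2L,
                            mlp_dim = 16L)
  mod <- hovseg:::nn_transformer(3L, 12L, cfg)
  x <- array(rnorm(3 * 4 * 3), dim = c(3, 4, 3, 1))
  y <- transformer_encode(x, cfg, module = mod)
  # manual projection: tokens (row-major over H, W) x embed W + b + pos
  tok <- matrix(aperm(x, c(2, 3, 1, 4)), 12, 3)
  z <- tok %*% mod$params$embed.W$value
  z <- sweep(z, 2, as.numeric(mod$params$embed.b$value), `+`)
  z <- z + mod$params$pos$value
  expected <- aperm(array(z, dim = c(4, 3, 8, 1)), c(3, 1, 2, 4))
  expect_equal(tg_val(y), expected, tolerance = 1e-12)
})

test_that("model stage shapes follow the derived valid-convolution chain", {
  m <- tiny_model(seed = 7)
  s <- model_summary(m, 198)
  ch <- hov_shape_chain(198)
  expect_equal(s$shape[s$stage == "residual_block_1"], paste0("16x", ch$block1, "x", ch$block1))
  expect_equal(s$shape[s$stage == "residual_block_4"], paste0("128x", ch$block4, "x", ch$block4))
  expect_equal(s$shape[s$stage == "transformer_tokens"], paste0(ch$tokens, "x32"))
  expect_equal(s$shape[s$stage == "decoder_cup"], paste0("64x", ch$block4, "x", ch$block4))
  expect_equal(s$shape[s$stage == "np"], paste0("2x", ch$output, "x", ch$output))
  expect_equal(s$shape[s$stage == "hv"], paste0("2x", ch$output, "x", ch$output))
  expect_equal(s$shape[s$stage == "nc"], paste0("5x", ch$output, "x", ch$output))
})

test_that("the shape chain errors name the first failing stage", {
  expect_error(hov_shape_chain(4), "stem conv")
  expect_error(hov_shape_chain(100), "dense block 1")
  expect_error(build_model(trunk_config(width = 2L, input_size = 100L),
                           transformer_config(1L, 8L, 2L, 16L)),
               "dense block 1")
})

test_that("disabling all attention yields the plain baseline architecture", {
  base <- build_model(trunk_config(width = 4L, input_size = 198L),
                      transformer_config(1L, 32L, 4L, 64L),
                      use_transformer = FALSE, simam_res = FALSE,
                      simam_des = FALSE, seed = 3)
  expect_false(any(grepl("^transformer", names(base$params))))
  full <- tiny_model(seed = 3)
  expect_gt(n_params(full), n_params(base))
  # baseline still honors the spatial contract
  s <- model_summary(base, 198)
  expect_equal(s$shape[s$stage == "np"], "2x8x8")
})

test_that("forward handles batches, rejects non-RGB input, and is deterministic in eval mode", {
  m <- tiny_model(seed = 9)
  img <- array(runif(198 * 198 * 3), dim = c(198, 198, 3))
  batch <- array(0, dim = c(198, 198, 3, 2))
  batch[, , , 1] <- img
  batch[, , , 2] <- img[198:1, , ]
  out <- model_forward(m, batch)
  expect_equal(dim(tg_val(out$np))[4], 2L)
  expect_equal(dim(tg_val(out$hv))[1], 2L)
  expect_equal(dim(tg_val(out$nc))[1], 5L)
  expect_error(model_forward(m, array(0, c(198, 198, 2))), "RGB")
  o1 <- model_forward(m, img)
  o2 <- model_forward(m, img)
  expect_identical(tg_val(o1$np), tg_val(o2$np))
  expect_identical(tg_val(o1$hv), tg_val(o2$hv))
  expect_identical(tg_val(o1$nc), tg_val(o2$nc))
})

test_that("a single optimization step on one batch reduces the composite loss", {
  sc <- generate_scene(198, 198, 10, 4, 0.3, 0.02, seed = 21)
  m <- tiny_model(seed = 13)
  batch <- hovseg:::scene_batch(list(sc), 1L, m$chain$output,
                                c(flip = FALSE, rotation = FALSE,
                                  gaussian_blur = FALSE, median_blur = FALSE))
  loss_of <- function() {
    out <- model_forward(m, tg_tensor(batch$images), training = TRUE)
    composite_loss(out, batch[c("np", "hv", "nc")])
  }
  l0 <- loss_of()
  opt <- adam_init(m$params)
  tg_zero_grad(m$params)
  tg_backward(l0$total)
  adam_step(opt, m$params, lr = 1e-4)
  l1 <- loss_of()
  expect_lt(as.numeric(tg_val(l1$total)), as.numeric(tg_val(l0$total)))
})
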