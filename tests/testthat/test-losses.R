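test_that("HV losses match their closed forms", {
  set.seed(1)
  true_hv <- array(stats::rnorm(12 * 12 * 2), dim = c(12, 12, 2))
  fg <- matrix(1, 12, 12)
  same <- hv_losses(true_hv, true_hv, fg)
  expect_equal(as.numeric(tg_val(same$l_a)), 0)
  expect_equal(as.numeric(tg_val(same$l_b)), 0)
  shifted <- hv_losses(true_hv + 0.1, true_hv, fg)
  expect_equal(as.numeric(tg_val(shifted$l_a)), 0.01, tolerance = 1e-10)
  expect_equal(as.numeric(tg_val(shifted$l_b)), 0, tolerance = 1e-12)
  empty <- hv_losses(true_hv + 1, true_hv, matrix(0, 12, 12))
  expect_equal(as.numeric(tg_val(empty$l_b)), 0)
})

test_that("NP losses: uniform logits give ln 2 cross-entropy; degenerate Dice is 0", {
  truth <- matrix(rbinom(100, 1, 0.4), 10, 10)
  uniform <- np_losses(array(0, c(10, 10, 2)), truth)
  expect_equal(as.numeric(tg_val(uniform$l_c)), log(2), tolerance = 1e-12)
  # near-one-hot prediction: both losses collapse
  logits <- array(0, c(10, 10, 2))
  logits[, , 1] <- ifelse(truth == 0, 40, -40)
  logits[, , 2] <- ifelse(truth == 1, 40, -40)
  perfect <- np_losses(logits, truth)
  expect_lt(as.numeric(tg_val(perfect$l_c)), 1e-6)
  expect_lt(as.numeric(tg_val(perfect$l_d)), 1e-3)
  # all-background truth with hard all-background prediction
  bg_logits <- array(rep(c(40, -40), each = 100), c(10, 10, 2))
  bg <- np_losses(bg_logits, matrix(0, 10, 10))
  expect_equal(as.numeric(tg_val(bg$l_d)), 0, tolerance = 1e-9)
})

test_that("NC losses validate the class range and behave like NP on two classes", {
  truth <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  logits <- array(stats::rnorm(8 * 8 * 4), c(8, 8, 4))
  r <- nc_losses(logits, truth)
  expect_gte(as.numeric(tg_val(r$l_e)), 0)
  expect_gte(as.numeric(tg_val(r$l_f)), -1e-12)
  expect_error(nc_losses(logits, matrix(9L, 8, 8)), "out of range")
})

test_that("the weighted total follows Eq-style pairing with default weights", {
  expect_equal(total_loss(as.list(rep(0, 6))), 0)
  expect_equal(total_loss(as.list(rep(1, 6))), 7)
  expect_equal(total_loss(list(0.5, 0.25, 0, 0, 0, 0)), 1.0)
  expect_equal(total_loss(as.list(1:6), loss_weights(1, 1, 1, 1, 1, 1)), 21)
  expect_error(total_loss(list(NaN, 0, 0, 0, 0, 0)), "non-finite")
})

test_that("loss terms are nonnegative and zero only at matching predictions", {
  set.seed(7)
  truth <- matrix(rbinom(64, 1, 0.5), 8, 8)
  for (i in 1:5) {
    logits <- array(stats::rnorm(128), c(8, 8, 2))
    r <- np_losses(logits, truth)
    expect_gte(as.numeric(tg_val(r$l_c)), 0)
    expect_gte(as.numeric(tg_val(r$l_d)), -1e-9)
    hv <- array(stats::rnorm(128), c(8, 8, 2))
    hv2 <- array(stats::rnorm(128), c(8, 8, 2))
    h <- hv_losses(hv, hv2, truth)
    expect_gte(as.numeric(tg_val(h$l_a)), 0)
    expect_gte(as.numeric(tg_val(h$l_b)), 0)
    expect_gt(as.numeric(tg_val(h$l_a)), 0)
  }
})

test_that("autodiff gradients of the composite loss match finite differences", {
  set.seed(3)
  truth_np <- matrix(rbinom(16, 1, 0.5), 4, 4)
  truth_hv <- array(stats::rnorm(32), c(2, 4, 4, 1))
  truth_nc <- matrix(sample(0:2, 16, replace = TRUE), 4, 4)
  loss_from <- function(v) {
    np_l <- v[1:32]
    hv_l <- v[33:64]
    nc_l <- v[65:112]
    pn <- tg_tensor(array(np_l, c(2, 4, 4, 1)))
    ph <- tg_tensor(array(hv_l, c(2, 4, 4, 1)))
    pc <- tg_tensor(array(nc_l, c(3, 4, 4, 1)))
    hv <- hv_losses(ph, tg_tensor(truth_hv), truth_np)
    np <- np_losses(pn, truth_np)
    nc <- nc_losses(pc, truth_nc)
    total_loss(list(hv$l_a, hv$l_b, np$l_c, np$l_d, nc$l_e, nc$l_f))
  }
  v0 <- stats::rnorm(112)
  pn <- tg_tensor(array(v0[1:32], c(2, 4, 4, 1)), requires_grad = TRUE)
  ph <- tg_tensor(array(v0[33:64], c(2, 4, 4, 1)), requires_grad = TRUE)
  pc <- tg_tensor(array(v0[65:112], c(3, 4, 4, 1)), requires_grad = TRUE)
  hv <- hv_losses(ph, tg_tensor(truth_hv), truth_np)
  np <- np_losses(pn, truth_np)
  nc <- nc_losses(pc, truth_nc)
  L <- total_loss(list(hv$l_a, hv$l_b, np$l_c, np$l_d, nc$l_e, nc$l_f))
  tg_backward(L)
  auto <- c(as.vector(pn$grad), as.vector(ph$grad), as.vector(pc$grad))
  fd <- numeric_grad(function(v) as.numeric(tg_val(loss_from(v))),
                     array(v0, dim = 112))
  expect_lt(max(abs(auto - as.vector(fd))), 1e-4)
})
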