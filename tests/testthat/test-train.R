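# Training schedule contracts on thin models (width 4, 198 px tiles): the
# spatial chain and parameter grouping are identical to the full-width model.

test_that("stage 1 leaves trunk and transformer parameters bit-identical", {
  scenes <- lapply(1:2, function(i) generate_scene(198, 198, 8, 4, 0.2, 0.02,
                                                   seed = 40 + i))
  m <- tiny_model(seed = 17)
  frozen_names <- grep("^(trunk|transformer)\\.", names(m$params), value = TRUE)
  before <- lapply(m$params[frozen_names], function(p) p$value)
  branch_before <- m$params[["np.head.w"]]$value
  run <- run_training(m, scenes,
                      smoke_train_config(stage2_epochs = 0L, seed = 23))
  after <- lapply(m$params[frozen_names], function(p) p$value)
  expect_identical(before, after)
  expect_false(identical(branch_before, m$params[["np.head.w"]]$value))
  expect_equal(unique(run$history$stage), 1)
})

test_that("training with the same seed reproduces the loss history exactly", {
  scenes <- lapply(1:4, function(i) generate_scene(198, 198, 8, 4, 0.2, 0.02,
                                                   seed = 50 + i))
  cfg <- smoke_train_config(stage1_epochs = 1L, stage2_epochs = 0L, seed = 31)
  r1 <- run_training(tiny_model(seed = 19), scenes, cfg)
  r2 <- run_training(tiny_model(seed = 19), scenes, cfg)
  expect_identical(r1$history, r2$history)
})

test_that("a schedule with zero epochs in both stages is rejected", {
  sc <- generate_scene(198, 198, 4, 2, 0, 0, seed = 1)
  m <- tiny_model(seed = 2)
  expect_error(run_training(m, list(sc),
                            smoke_train_config(stage1_epochs = 0L,
                                               stage2_epochs = 0L)),
               "zero epochs")
})

test_that("augmented HV targets equal the encoding of the transformed instance map", {
  # horizontal flip: the augmentation path re-encodes targets from the
  # flipped map; verify this matches the analytic equivariance
  sc <- generate_scene(96, 96, 6, 3, 0.3, 0, seed = 61)
  flipped <- sc$instances[, 96:1]
  hv_direct <- encode_hover(flipped)
  hv_orig <- encode_hover(sc$instances)
  expect_equal(hv_direct[, , 1], -hv_orig[, 96:1, 1])
  expect_equal(hv_direct[, , 2], hv_orig[, 96:1, 2])
  # 90-degree rotation: horizontal and vertical maps exchange roles
  rot <- hovseg:::rot90_mat(sc$instances, 1L)
  hv_rot <- encode_hover(rot)
  expect_equal(sort(unique(round(as.vector(abs(hv_rot)), 6))),
               sort(unique(round(as.vector(abs(hv_orig)), 6))))
})

test_that("predict_stack produces a valid prediction stack over the output window", {
  m <- tiny_model(seed = 29)
  sc <- generate_scene(198, 198, 6, 4, 0.2, 0.02, seed = 71)
  st <- predict_stack(m, sc$image)
  expect_s3_class(st, "prediction_stack")
  out <- m$chain$output
  expect_equal(dim(st$q), c(out, out))
  expect_equal(dim(st$hv), c(out, out, 2L))
  expect_equal(dim(st$classes), c(out, out, 5L))
  expect_true(all(st$q >= 0 & st$q <= 1))
  sums <- apply(st$classes, c(1, 2), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-9)
  # the stack feeds the post-processing without error
  seg <- postprocess_stack(st)
  expect_true(is.matrix(seg$instances))
})
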