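test_that("NP encoding marks exactly the positive labels", {
  expect_identical(encode_np(matrix(0L, 5, 5)), matrix(0, 5, 5))
  m <- matrix(0L, 6, 6)
  m[2:3, 2:6] <- 1L
  m[5, 1:5] <- 2L
  np <- encode_np(m)
  expect_equal(sum(np), 15)
  expect_true(all(np[m > 0] == 1) && all(np[m == 0] == 0))
  expect_error(encode_np(matrix(-1L, 2, 2)), "negative")
  sc <- generate_scene(96, 96, 6, 3, 0.2, 0, seed = 4)
  expect_equal(sum(encode_np(sc$instances)), sum(sc$instances > 0))
})

test_that("HV encoding matches the stated rescaling on a 1x5 bar", {
  m <- matrix(0L, 5, 7)
  m[3, 2:6] <- 1L
  hv <- encode_hover(m)
  expect_equal(hv[3, 2:6, 1], c(-1, -0.5, 0, 0.5, 1))
  expect_true(all(hv[, , 2] == 0))
  # vertical bar: transposed behaviour
  mv <- t(m)
  hvv <- encode_hover(mv)
  expect_equal(hvv[2:6, 3, 2], c(-1, -0.5, 0, 0.5, 1))
  expect_true(all(hvv[, , 1] == 0))
})

test_that("degenerate single-pixel instance encodes to (0, 0)", {
  m <- matrix(0L, 4, 4)
  m[2, 3] <- 1L
  hv <- encode_hover(m)
  expect_equal(hv[2, 3, 1], 0)
  expect_equal(hv[2, 3, 2], 0)
})

test_that("per-instance extremes reach exactly +/-1 and background stays 0", {
  sc <- generate_scene(96, 96, 8, 3, 0.4, 0, seed = 6)
  hv <- encode_hover(sc$instances)
  expect_true(all(hv[, , 1][sc$instances == 0] == 0))
  expect_true(all(hv[, , 2][sc$instances == 0] == 0))
  for (l in seq_len(max(sc$instances))) {
    sel <- sc$instances == l
    cols <- col(sc$instances)[sel]
    if (length(unique(cols)) > 1L) {
      expect_equal(max(abs(hv[, , 1][sel])), 1)
      expect_true(all(abs(hv[, , 1][sel]) <= 1 + 1e-12))
    }
  }
})

test_that("mirroring the instance map negates the horizontal map and mirrors the vertical", {
  sc <- generate_scene(80, 80, 6, 3, 0.3, 0, seed = 8)
  hv <- encode_hover(sc$instances)
  mir <- sc$instances[, ncol(sc$instances):1]
  hv_m <- encode_hover(mir)
  expect_equal(hv_m[, , 1], -hv[, ncol(sc$instances):1, 1])
  expect_equal(hv_m[, , 2], hv[, ncol(sc$instances):1, 2])
})

test_that("the pixel minimizing |h|+|v| lies within 1 px of the brute-force centroid", {
  sc <- generate_scene(96, 96, 7, 3, 0.3, 0, seed = 10)
  hv <- encode_hover(sc$instances)
  score <- abs(hv[, , 1]) + abs(hv[, , 2])
  for (l in seq_len(max(sc$instances))) {
    idx <- which(sc$instances == l)
    best <- idx[which.min(score[idx])]
    rr <- (best - 1) %% 96; cc <- (best - 1) %/% 96
    rows <- (idx - 1) %% 96; cols <- (idx - 1) %/% 96
    expect_lte(max(abs(rr - mean(rows)), abs(cc - mean(cols))), 1 + 1e-9)
  }
})

test_that("NC encoding validates foreground/type agreement", {
  sc <- generate_scene(96, 96, 8, 3, 0.2, 0, seed = 12)
  nc <- encode_nc(sc$instances, sc$types)
  expect_identical(nc, sc$types)
  # per-type pixel histogram matches a brute-force count
  for (cl in 1:3) {
    expect_equal(sum(nc == cl),
                 sum(sc$types[sc$instances > 0] == cl))
  }
  expect_identical(encode_nc(matrix(0L, 4, 4), matrix(0L, 4, 4)), matrix(0L, 4, 4))
  bad <- sc$types
  bad[which(sc$instances == 0)[1]] <- 2L
  expect_error(encode_nc(sc$instances, bad), "background")
  bad2 <- sc$types
  bad2[which(sc$instances > 0)[1]] <- 0L
  expect_error(encode_nc(sc$instances, bad2), "without a type")
})

test_that("encode_targets bundles consistent NP/HV/NC stacks", {
  sc <- generate_scene(64, 64, 4, 2, 0, 0, seed = 3)
  ts <- encode_targets(sc$instances, sc$types)
  expect_s3_class(ts, "target_stack")
  expect_identical(ts$np, (sc$instances > 0) * 1)
  expect_true(all(ts$hv >= -1 & ts$hv <= 1))
  expect_identical(ts$nc, sc$types)
})
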