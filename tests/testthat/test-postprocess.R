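test_that("the threshold function is strict", {
  expect_equal(threshold_fn(matrix(c(0.2, 0.8), 1), 0.5), matrix(c(0, 1), 1))
  a <- matrix(stats::runif(20), 4, 5)
  expect_true(all(threshold_fn(a, max(a)) == 0))
  expect_true(all(threshold_fn(a, -Inf) == 1))
})

test_that("gradient maximum is zero for constants and flat inside a ramp", {
  z <- matrix(1.7, 12, 12)
  expect_true(all(gradient_max(z, z, 5) == 0))
  ramp <- matrix(rep(seq(0, 1, length.out = 12), each = 12), 12, 12)
  s <- gradient_max(ramp, z, 5)
  interior <- s[4:9, 4:9]
  expect_lt(diff(range(interior)), 1e-12)
  # constant interior response is the per-image maximum after rescaling
  expect_equal(max(interior), max(s))
})

test_that("S_m peaks on the shared boundary of touching nuclei", {
  sc <- generate_scene(96, 96, 2, 2, 0.5, 0, seed = 14)
  st <- ideal_prediction_stack(sc, 0)
  s <- gradient_max(st$hv[, , 1], st$hv[, , 2], 5)
  # brute-force interface: foreground pixels adjacent to the other instance
  i1 <- sc$instances == 1
  i2 <- sc$instances == 2
  expect_true(any(dilate1(i1) & i2))     # the pair indeed touches
  interface <- (dilate1(i1) & i2) | (dilate1(i2) & i1)
  argmax <- which(s == max(s), arr.ind = TRUE)
  near_interface <- dilate1(dilate1(interface))
  expect_true(all(near_interface[argmax]))
})

test_that("energy and markers follow the thresholded algebra", {
  p <- postprocess_params()
  q_low <- matrix(0.2, 10, 10)
  f <- energy_and_markers(matrix(0, 10, 10), q_low, p)
  expect_true(all(f$E == 0))
  expect_equal(max(f$M), 0L)
  q_high <- matrix(0.9, 10, 10)
  f2 <- energy_and_markers(matrix(0.1, 10, 10), q_high, p)
  expect_true(all(f2$E == 1))
  expect_equal(max(f2$M), 1L)
  expect_true(all(f2$M == 1L))
})

test_that("a touching two-nucleus fixture yields exactly two markers (flood-fill oracle)", {
  sc <- generate_scene(96, 96, 2, 2, 0.5, 0, seed = 14)
  st <- ideal_prediction_stack(sc, 0)
  s <- gradient_max(st$hv[, , 1], st$hv[, , 2], 5)
  f <- energy_and_markers(s, st$q, postprocess_params())
  expect_equal(max(f$M), 2L)
  raw <- threshold_fn(st$q, 0.5) - threshold_fn(s, 0.4)
  raw[raw < 0] <- 0
  expect_equal(oracle_component_count_8(raw > 0), 2L)
})

test_that("markers below min_size are discarded and relabeled consecutively", {
  q <- matrix(0, 20, 20)
  q[2:3, 2:3] <- 1          # 4 px: below min_size 10
  q[8:13, 8:13] <- 1        # 36 px: kept
  f <- energy_and_markers(matrix(0, 20, 20), q, postprocess_params(min_size = 10))
  expect_equal(max(f$M), 1L)
  expect_true(all(sort(unique(f$M[f$M > 0]))== 1L))
})

test_that("watershed on a single nucleus returns the thresholded foreground", {
  sc <- generate_scene(64, 64, 1, 2, 0, 0, seed = 4)
  st <- ideal_prediction_stack(sc, 0)
  seg <- postprocess_stack(st)
  expect_equal(max(seg$instances), 1L)
  expect_identical(seg$instances > 0, sc$instances > 0)
})

test_that("watershed partitions touching nuclei with per-instance IoU above 0.5", {
  sc <- generate_scene(96, 96, 2, 2, 0.5, 0, seed = 14)
  st <- ideal_prediction_stack(sc, 0)
  seg <- postprocess_stack(st)
  expect_equal(max(seg$instances), 2L)
  fg <- threshold_fn(st$q, 0.5)
  expect_identical((seg$instances > 0) * 1, fg)   # pixel conservation
  matched <- 0
  for (g in 1:2) {
    ious <- vapply(1:2, function(p) {
      gi <- sc$instances == g; pi <- seg$instances == p
      sum(gi & pi) / sum(gi | pi)
    }, numeric(1))
    if (max(ious) > 0.5) matched <- matched + 1
  }
  expect_equal(matched, 2)
})

test_that("an empty foreground gives an empty instance map", {
  f <- energy_and_markers(matrix(0, 8, 8), matrix(0, 8, 8), postprocess_params())
  expect_true(all(watershed_instances(f) == 0L))
})

test_that("foreground pixel count is monotone nonincreasing in h", {
  sc <- generate_scene(96, 96, 8, 3, 0.3, 0.02, seed = 16)
  st <- ideal_prediction_stack(sc, 1.0)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9),
                   function(h) sum(threshold_fn(st$q, h)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("majority-vote typing counts pixels and breaks ties to the lowest class", {
  inst <- matrix(0L, 6, 6)
  inst[2:5, 2:5] <- 1L
  probs <- array(0, c(6, 6, 3))       # background + 2 classes
  cls <- matrix(1L, 6, 6)
  cls[2:5, 2:3] <- 1L                 # 8 px class 1
  cls[2:5, 4:5] <- 2L                 # 8 px class 2 -> tie, class 1 wins
  probs[, , 2] <- (cls == 1L) * 1
  probs[, , 3] <- (cls == 2L) * 1
  r <- classify_instances(inst, probs)
  expect_equal(r$instance_types$type, 1L)
  # 7 vs 9 pixels: majority wins
  cls[2, 2] <- 2L
  probs[, , 2] <- (cls == 1L) * 1
  probs[, , 3] <- (cls == 2L) * 1
  r2 <- classify_instances(inst, probs)
  expect_equal(r2$instance_types$type, 2L)
  expect_true(all(r2$types[inst == 1L] == 2L))
})

test_that("parameter validation rejects out-of-range thresholds", {
  expect_error(postprocess_params(h = 0))
  expect_error(postprocess_params(k = 1))
  expect_error(postprocess_params(sobel_ksize = 4))
})
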