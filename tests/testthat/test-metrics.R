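test_that("DICE matches direct pixel counting and its conventions", {
  a <- matrix(0, 6, 6); a[2:3, 2:3] <- 1
  expect_equal(dice_score(a, a), 1)
  b <- matrix(0, 6, 6); b[5:6, 5:6] <- 1
  expect_equal(dice_score(a, b), 0)
  x <- matrix(0, 4, 4); x[1, 1:4] <- 1      # |X| = 4
  y <- matrix(0, 4, 4); y[1, 1:2] <- 1      # |Y| = 2, overlap 2
  expect_equal(dice_score(x, y), 2 * 2 / 6)
  expect_equal(dice_score(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
})

test_that("AJI matches single-pair closed forms and conventions", {
  t1 <- matrix(0L, 6, 6); t1[1:2, 1:5] <- 1L          # 10 px
  expect_equal(aji_score(t1, t1), 1)
  p1 <- matrix(0L, 6, 6); p1[2:3, 1:5] <- 1L          # 10 px, overlap 5
  expect_equal(aji_score(t1, p1), 5 / 15)
  expect_equal(aji_score(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
  expect_equal(aji_score(t1, matrix(0L, 6, 6)), 0)
})

test_that("AJI with a merged prediction equals the exhaustive pixel-set oracle", {
  truth <- matrix(0L, 10, 10)
  truth[2:4, 2:4] <- 1L
  truth[2:4, 6:8] <- 2L
  pred <- matrix(0L, 10, 10)
  pred[2:4, 2:8] <- 1L                                 # merges both
  expect_equal(aji_score(truth, pred), oracle_aji(truth, pred))
  # and a split prediction
  pred2 <- truth
  pred2[2, 2:4] <- 3L
  expect_equal(aji_score(truth, pred2), oracle_aji(truth, pred2))
})

test_that("panoptic quality matches the direct evaluation of its definition", {
  t <- matrix(0L, 12, 12)
  t[2:5, 2:5] <- 1L       # 16 px
  t[8:11, 8:11] <- 2L     # missed by pred
  p <- matrix(0L, 12, 12)
  p[2:5, 2:4] <- 1L       # 12 px, inter 12, union 16 -> IoU 0.75
  r <- panoptic_quality(t, p)
  expect_equal(r$dq, 1 / (1 + 0 + 0.5))
  expect_equal(r$sq, 0.75)
  expect_equal(r$pq, r$dq * r$sq)
  expect_equal(r$matches$unmatched_gt, 2L)
  expect_length(r$matches$unmatched_pred, 0L)
  ident <- panoptic_quality(t, t)
  expect_equal(c(ident$dq, ident$sq, ident$pq), c(1, 1, 1))
  empty <- panoptic_quality(matrix(0L, 4, 4), matrix(0L, 4, 4))
  expect_equal(c(empty$dq, empty$sq, empty$pq), c(1, 1, 1))
})

test_that("AJI and PQ agree with brute-force oracles over seeded random maps", {
  set.seed(2024)
  for (i in 1:200) {
    truth <- random_label_map(16, 16, 5L)
    pred <- if (i %% 2 == 0) perturb_label_map(truth) else random_label_map(16, 16, 5L)
    expect_equal(aji_score(truth, pred), oracle_aji(truth, pred),
                 tolerance = 1e-12)
    r <- panoptic_quality(truth, pred)
    o <- oracle_pq(truth, pred)
    expect_equal(r$dq, o$dq, tolerance = 1e-12)
    expect_equal(r$sq, o$sq, tolerance = 1e-12)
    expect_equal(r$pq, o$pq, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under label permutation", {
  set.seed(5)
  truth <- random_label_map(20, 20, 5L)
  pred <- perturb_label_map(truth)
  k <- max(truth)
  perm <- sample(k)
  truth_p <- truth
  truth_p[truth > 0] <- perm[truth[truth > 0]]
  expect_equal(aji_score(truth, pred), aji_score(truth_p, pred))
  expect_equal(panoptic_quality(truth, pred)$pq, panoptic_quality(truth_p, pred)$pq)
  expect_equal(dice_score(truth, pred), dice_score(truth_p, pred))
})

test_that("AJI does not exceed DICE of the binarized maps on seeded fixtures", {
  set.seed(99)
  worst <- 0
  for (i in 1:50) {
    truth <- random_label_map(16, 16, 4L)
    pred <- perturb_label_map(truth)
    worst <- max(worst, aji_score(truth, pred) - dice_score(truth, pred))
  }
  expect_lte(worst, 1e-12)
})

test_that("classification F1 handles perfect, mistyped, and absent classes", {
  inst <- matrix(0L, 10, 10)
  inst[2:4, 2:4] <- 1L
  inst[7:9, 7:9] <- 2L
  types <- matrix(0L, 10, 10)
  types[inst == 1L] <- 1L
  types[inst == 2L] <- 2L
  perfect <- classification_f1(inst, types, inst, types, n_classes = 3L)
  expect_equal(perfect$f_d, 1)
  expect_equal(unname(perfect$f1_per_class[1:2]), c(1, 1))
  expect_true(is.na(perfect$f1_per_class[3]))
  # one matched pair with the wrong predicted type
  one_i <- matrix(0L, 8, 8); one_i[2:5, 2:5] <- 1L
  t1 <- matrix(0L, 8, 8); t1[one_i == 1L] <- 1L
  t2 <- matrix(0L, 8, 8); t2[one_i == 1L] <- 2L
  r <- classification_f1(one_i, t1, one_i, t2, n_classes = 2L)
  expect_equal(r$f_d, 1)
  expect_equal(unname(r$f1_per_class), c(0, 0))
})

test_that("precision equal to recall gives F1 at that same value", {
  # class 1 with TP = 1, FP = 1, FN = 1: precision = recall = 0.5 -> F1 = 0.5
  truth_i <- matrix(0L, 14, 14)
  truth_i[2:4, 2:4] <- 1L        # matched, typed 1
  truth_i[8:10, 8:10] <- 2L      # missed by the prediction, typed 1
  truth_t <- matrix(0L, 14, 14)
  truth_t[truth_i > 0L] <- 1L
  pred_i <- matrix(0L, 14, 14)
  pred_i[2:4, 2:4] <- 1L         # matches gt 1, typed 1
  pred_i[12:14, 12:14] <- 2L     # spurious detection, typed 1
  pred_t <- matrix(0L, 14, 14)
  pred_t[pred_i > 0L] <- 1L
  r <- classification_f1(truth_i, truth_t, pred_i, pred_t, n_classes = 1L)
  expect_equal(unname(r$f1_per_class[1]), 0.5)
})

test_that("the panoptic report bundles all metrics consistently", {
  sc <- generate_scene(96, 96, 8, 3, 0.3, 0, seed = 31)
  rep <- evaluate_panoptic(sc$instances, sc$instances, sc$types, sc$types)
  expect_s3_class(rep, "panoptic_report")
  expect_equal(rep$dice, 1)
  expect_equal(rep$aji, 1)
  expect_equal(rep$pq, 1)
  expect_equal(rep$f_d, 1)
  expect_equal(rep$pq, rep$dq * rep$sq)
})
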