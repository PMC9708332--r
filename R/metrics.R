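# Evaluation suite: DICE, aggregated Jaccard index (AJI), detection /
# segmentation / panoptic quality (DQ, SQ, PQ) with IoU > 0.5 matching, and
# detection + per-class F1 for simultaneous classification.

# sparse cross-tabulation of co-occurring (gt, pred) label pairs
label_overlap <- function(truth, pred) {
  sel <- truth > 0L & pred > 0L
  if (!any(sel)) {
    return(data.frame(gt = integer(0), pr = integer(0), n = integer(0)))
  }
  t <- as.integer(truth[sel]); p <- as.integer(pred[sel])
  key <- (t - 1) * (max(p) + 1) + p
  u <- sort(unique(key))
  cnt <- tabulate(match(key, u))
  data.frame(gt = (u - (u %% (max(p) + 1))) %/% (max(p) + 1) + 1L,
             pr = u %% (max(p) + 1), n = cnt)
}

label_areas <- function(m) {
  if (max(m) == 0L) return(integer(0))
  tabulate(m[m > 0L], nbins = max(m))
}

#' DICE coefficient of two binary masks
#'
#' `2 |X intersect Y| / (|X| + |Y|)`; two empty masks give 1 by convention.
#'
#' @param truth,pred binary maps (any nonzero value counts as foreground).
#' @return scalar in `[0, 1]`.
#' @export
dice_score <- function(truth, pred) {
  stopifnot(all(dim(truth) == dim(pred)))
  x <- truth > 0; y <- pred > 0
  sx <- sum(x); sy <- sum(y)
  if (sx + sy == 0L) return(1)
  2 * sum(x & y) / (sx + sy)
}

#' Aggregated Jaccard index (AJI)
#'
#' For each ground-truth instance the predicted region with the largest
#' intersection is selected — greedily in descending intersection order, and
#' each predicted region may be used by at most one ground-truth instance.
#' AJI is the summed matched intersections divided by the summed matched
#' unions plus the areas of all never-selected predicted regions; unmatched
#' ground-truth instances contribute their full area to the denominator.
#' Both maps empty gives 1 by convention; an empty prediction against a
#' nonempty truth gives 0.
#'
#' @param truth,pred integer instance label maps.
#' @return scalar in `[0, 1]`.
#' @export
aji_score <- function(truth, pred) {
  stopifnot(all(dim(truth) == dim(pred)))
  check_instance_map(truth); check_instance_map(pred)
  gt_area <- label_areas(truth)
  pr_area <- label_areas(pred)
  gt_labs <- which(gt_area > 0L)
  pr_labs <- which(pr_area > 0L)
  if (length(gt_labs) == 0L && length(pr_labs) == 0L) return(1)
  if (length(gt_labs) == 0L || length(pr_labs) == 0L) return(0)
  ov <- label_overlap(truth, pred)
  ord <- order(-ov$n, ov$gt, ov$pr)
  matched_gt <- integer(0)
  used_pr <- integer(0)
  num <- 0; den <- 0
  for (r in ord) {
    g <- ov$gt[r]; p <- ov$pr[r]
    if (g %in% matched_gt || p %in% used_pr) next
    matched_gt <- c(matched_gt, g)
    used_pr <- c(used_pr, p)
    num <- num + ov$n[r]
    den <- den + gt_area[g] + pr_area[p] - ov$n[r]
  }
  den <- den + sum(gt_area[setdiff(gt_labs, matched_gt)])
  den <- den + sum(pr_area[setdiff(pr_labs, used_pr)])
  if (den == 0) return(1)
  num / den
}

#' Panoptic quality (DQ, SQ, PQ) with IoU > 0.5 matching
#'
#' Instances are matched one-to-one at IoU > 0.5 (at most one predicted
#' instance can exceed 0.5 IoU with a given ground-truth instance, so the
#' matching is unique). `DQ = TP / (TP + FP/2 + FN/2)`, `SQ` is the mean IoU
#' over matched pairs (0 when none), and `PQ = DQ * SQ`. Two empty maps
#' give (1, 1, 1) by convention.
#'
#' @param truth,pred integer instance label maps.
#' @return list with `dq`, `sq`, `pq` and `matches` (a `match_set`:
#'   data.frame of pairs with IoU, plus `unmatched_gt`, `unmatched_pred`).
#' @export
panoptic_quality <- function(truth, pred) {
  stopifnot(all(dim(truth) == dim(pred)))
  check_instance_map(truth); check_instance_map(pred)
  gt_area <- label_areas(truth)
  pr_area <- label_areas(pred)
  gt_labs <- which(gt_area > 0L)
  pr_labs <- which(pr_area > 0L)
  ov <- label_overlap(truth, pred)
  iou <- ov$n / (gt_area[ov$gt] + pr_area[ov$pr] - ov$n)
  hit <- iou > 0.5
  pairs <- data.frame(gt = ov$gt[hit], pred = ov$pr[hit], iou = iou[hit])
  matches <- structure(list(pairs = pairs,
                            unmatched_gt = setdiff(gt_labs, pairs$gt),
                            unmatched_pred = setdiff(pr_labs, pairs$pred)),
                       class = "match_set")
  tp <- nrow(pairs)
  fp <- length(matches$unmatched_pred)
  fn <- length(matches$unmatched_gt)
  if (tp + fp + fn == 0L) {
    return(list(dq = 1, sq = 1, pq = 1, matches = matches))
  }
  dq <- tp / (tp + fp / 2 + fn / 2)
  sq <- if (tp > 0L) mean(pairs$iou) else 0
  list(dq = dq, sq = sq, pq = dq * sq, matches = matches)
}

instance_type_table <- function(inst, types) {
  labs <- sort(unique(inst[inst > 0L]))
  vapply(labs, function(l) {
    tt <- types[inst == l]
    tt <- tt[tt > 0L]
    if (length(tt) == 0L) 0L else as.integer(names(which.max(table(tt))))
  }, integer(1)) |> stats::setNames(labs)
}

#' Detection and per-class classification F1
#'
#' Detection pairs instances at IoU > 0.5 (same matching as
#' [panoptic_quality()]). The overall detection score is
#' `F_d = 2 TP / (2 TP + FP + FN)`. For each class `c`, `TP_c` counts
#' matched pairs in which both instances are typed `c`; `FP_c` counts
#' predicted instances typed `c` that are not in such a type-agreeing pair;
#' `FN_c` the same for ground-truth instances. Classes absent from both
#' truth and prediction get `NA`.
#'
#' @param truth_inst,pred_inst integer instance maps.
#' @param truth_types,pred_types integer type maps consistent with the
#'   instance maps.
#' @param n_classes number of classes C (defaults to the largest type seen).
#' @return list with `f_d` and `f1_per_class` (named numeric of length C).
#' @export
classification_f1 <- function(truth_inst, truth_types, pred_inst, pred_types,
                              n_classes = NULL) {
  pq <- panoptic_quality(truth_inst, pred_inst)
  pairs <- pq$matches$pairs
  tp <- nrow(pairs)
  fp <- length(pq$matches$unmatched_pred)
  fn <- length(pq$matches$unmatched_gt)
  f_d <- if (2 * tp + fp + fn == 0L) 1 else 2 * tp / (2 * tp + fp + fn)
  tt <- instance_type_table(truth_inst, truth_types)
  pt <- instance_type_table(pred_inst, pred_types)
  if (is.null(n_classes)) {
    n_classes <- max(0L, tt, pt)
  }
  f1c <- rep(NA_real_, n_classes)
  names(f1c) <- as.character(seq_len(n_classes))
  if (n_classes == 0L) return(list(f_d = f_d, f1_per_class = f1c))
  gt_type <- tt[as.character(pairs$gt)]
  pr_type <- pt[as.character(pairs$pred)]
  for (cl in seq_len(n_classes)) {
    n_gt_c <- sum(tt == cl)
    n_pr_c <- sum(pt == cl)
    if (n_gt_c + n_pr_c == 0L) next
    tp_c <- sum(gt_type == cl & pr_type == cl)
    fp_c <- n_pr_c - tp_c
    fn_c <- n_gt_c - tp_c
    f1c[cl] <- if (2 * tp_c + fp_c + fn_c == 0L) NA_real_ else {
      2 * tp_c / (2 * tp_c + fp_c + fn_c)
    }
  }
  list(f_d = f_d, f1_per_class = f1c)
}

#' Full panoptic evaluation of a predicted segmentation
#'
#' @param truth_inst,pred_inst integer instance maps.
#' @param truth_types,pred_types optional type maps; when given, detection
#'   and per-class F1 are included.
#' @param n_classes optional number of classes for the per-class report.
#' @return a `panoptic_report` with fields `dice`, `aji`, `dq`, `sq`, `pq`,
#'   `matches`, and (with types) `f_d`, `f1_per_class`.
#' @export
evaluate_panoptic <- function(truth_inst, pred_inst, truth_types = NULL,
                              pred_types = NULL, n_classes = NULL) {
  pq <- panoptic_quality(truth_inst, pred_inst)
  rep <- list(dice = dice_score(truth_inst, pred_inst),
              aji = aji_score(truth_inst, pred_inst),
              dq = pq$dq, sq = pq$sq, pq = pq$pq, matches = pq$matches,
              n_truth = length(label_areas(truth_inst)[label_areas(truth_inst) > 0]),
              n_pred = length(label_areas(pred_inst)[label_areas(pred_inst) > 0]))
  if (!is.null(truth_types) && !is.null(pred_types)) {
    cf <- classification_f1(truth_inst, truth_types, pred_inst, pred_types,
                            n_classes = n_classes)
    rep$f_d <- cf$f_d
    rep$f1_per_class <- cf$f1_per_class
  }
  structure(rep, class = "panoptic_report")
}

#' @export
print.panoptic_report <- function(x, ...) {
  cat(sprintf("Panoptic report: DICE %.4f | AJI %.4f | DQ %.4f | SQ %.4f | PQ %.4f\n",
              x$dice, x$aji, x$dq, x$sq, x$pq))
  cat("  instances: truth", x$n_truth, "| predicted", x$n_pred,
      "| matched", nrow(x$matches$pairs), "\n")
  if (!is.null(x$f_d)) {
    cat(sprintf("  detection F1 %.4f | per-class F1: %s\n", x$f_d,
                paste(sprintf("%s=%.3f", names(x$f1_per_class), x$f1_per_class),
                      collapse = " ")))
  }
  invisible(x)
}
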