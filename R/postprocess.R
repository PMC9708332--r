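# Post-processing: Sobel gradients of the predicted HV maps locate the
# boundaries between touching nuclei; thresholding carves the foreground
# into an energy plateau and interior markers; a marker-controlled watershed
# assigns every foreground pixel to a marker basin; a majority vote over the
# class probabilities types each instance.

#' Post-processing parameters
#'
#' @param h nuclear-pixel probability threshold, in (0, 1).
#' @param k normalized-gradient threshold, in (0, 1).
#' @param sobel_ksize odd Sobel kernel size (>= 3).
#' @param min_size markers smaller than this (pixels) are discarded.
#' @return a `postprocess_params` list.
#' @export
postprocess_params <- function(h = 0.5, k = 0.4, sobel_ksize = 5L, min_size = 10L) {
  stopifnot(h > 0, h < 1, k > 0, k < 1,
            sobel_ksize >= 3L, sobel_ksize %% 2L == 1L, min_size >= 0L)
  structure(list(h = h, k = k, sobel_ksize = as.integer(sobel_ksize),
                 min_size = as.integer(min_size)),
            class = "postprocess_params")
}

#' Threshold function
#'
#' Returns 1 where `a > b` (strictly), else 0.
#'
#' @param a numeric array.
#' @param b scalar threshold.
#' @return binary array of the same shape.
#' @export
threshold_fn <- function(a, b) {
  (a > b) * 1
}

#' Extended Sobel derivative kernel
#'
#' The size-`k` Sobel kernel is the outer product of a binomial smoothing
#' vector and a derivative vector (the 3x3 case is the classic
#' `[-1 0 1; -2 0 2; -1 0 1]`). `axis = "x"` differentiates along columns
#' (horizontal), `axis = "y"` along rows (vertical).
#'
#' @param ksize odd kernel size >= 3.
#' @param axis `"x"` or `"y"`.
#' @return ksize x ksize numeric matrix.
#' @export
sobel_kernel <- function(ksize = 5L, axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(ksize >= 3L, ksize %% 2L == 1L)
  smooth <- choose(ksize - 1L, 0:(ksize - 1L))
  deriv <- c(-1, 0, 1)
  base <- c(1, 2, 1)
  for (i in seq_len((ksize - 3L) / 2L)) deriv <- stats::convolve(deriv, rev(base), type = "open")
  # unit gradient gain: response to a unit-slope ramp is exactly 1, so loss
  # terms built on these kernels stay on the scale of the maps themselves
  offs <- seq_len(ksize) - (ksize + 1L) / 2L
  gain <- sum(deriv * offs) * sum(smooth)
  if (axis == "x") outer(smooth, deriv) / gain else outer(deriv, smooth) / gain
}

filter2_replicate <- function(m, kern) {
  as.matrix(EBImage::filter2(m, kern, boundary = "replicate"))
}

minmax01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi > lo) (m - lo) / (hi - lo) else m * 0
}

#' Gradient maximum map from predicted HV maps
#'
#' Computes `S_m` as the elementwise maximum of the Sobel gradient
#' magnitudes of the horizontal and vertical distance maps, each min-max
#' rescaled to `[0, 1]` per image before the maximum. The gradient magnitude
#' (root sum of squares of the horizontal and vertical Sobel responses) is
#' rotation invariant, so `S_m` ridges cover boundaries between touching
#' nuclei at every contact angle — including the diagonal contacts that a
#' single directional derivative per map responds to only weakly. `S_m`
#' peaks where the distance maps jump between adjacent instances, i.e. on
#' shared boundaries of touching nuclei.
#'
#' @param p_x,p_y predicted horizontal and vertical distance maps.
#' @param sobel_ksize odd Sobel kernel size.
#' @return matrix `S_m` in `[0, 1]`.
#' @export
gradient_max <- function(p_x, p_y, sobel_ksize = 5L) {
  stopifnot(all(dim(p_x) == dim(p_y)))
  kx <- sobel_kernel(sobel_ksize, "x")
  ky <- sobel_kernel(sobel_ksize, "y")
  gx <- minmax01(sqrt(filter2_replicate(p_x, kx)^2 +
                        filter2_replicate(p_x, ky)^2))
  gy <- minmax01(sqrt(filter2_replicate(p_y, kx)^2 +
                        filter2_replicate(p_y, ky)^2))
  pmax(gx, gy)
}

# 8-connected labeling: 4-connected labeling (EBImage) followed by merging
# labels that touch diagonally (union-find over the diagonal-adjacency pairs)
label_components_8 <- function(mask) {
  lab4 <- matrix(as.integer(EBImage::bwlabel(mask * 1)), nrow(mask), ncol(mask))
  n <- max(lab4)
  if (n <= 1L) return(lab4)
  H <- nrow(lab4); W <- ncol(lab4)
  pairs <- rbind(
    cbind(as.vector(lab4[-H, -W]), as.vector(lab4[-1, -1])),   # down-right
    cbind(as.vector(lab4[-1, -W]), as.vector(lab4[-H, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab4
  out[lab4 > 0L] <- remap[lab4[lab4 > 0L]]
  out
}

#' Energy landscape and controlling markers
#'
#' The energy landscape is `E = (1 - tau(S_m, k)) * tau(q, h)`: the
#' thresholded foreground with the high-gradient ridges (boundaries between
#' touching nuclei) removed. Markers are the 8-connected components of the
#' positive part of `tau(q, h) - tau(S_m, k)`; components smaller than
#' `min_size` pixels are discarded and the rest relabeled consecutively.
#'
#' @param S_m gradient maximum map from [gradient_max()].
#' @param q nuclear-pixel probability map.
#' @param params a [postprocess_params()].
#' @return an `energy_fields` list: `S_m`, `E`, `M` (marker label map),
#'   `foreground` (the thresholded foreground `tau(q, h)`).
#' @export
energy_and_markers <- function(S_m, q, params = postprocess_params()) {
  stopifnot(all(dim(S_m) == dim(q)), inherits(params, "postprocess_params"))
  fg <- threshold_fn(q, params$h)
  ridge <- threshold_fn(S_m, params$k)
  E <- (1 - ridge) * fg
  raw <- fg - ridge
  raw[raw < 0] <- 0                      # rectifier sigma
  M <- label_components_8(raw > 0)
  if (max(M) > 0L && params$min_size > 0L) {
    sizes <- tabulate(M[M > 0L], nbins = max(M))
    keep <- which(sizes >= params$min_size)
    remap <- integer(max(M))
    remap[keep] <- seq_along(keep)
    M[M > 0L] <- remap[M[M > 0L]]
  }
  structure(list(S_m = S_m, E = E, M = M, foreground = fg),
            class = "energy_fields")
}

#' Marker-controlled watershed on the energy landscape
#'
#' Floods the energy landscape in descending order (the `E = 1` plateau
#' first, then the remaining thresholded foreground) from the labeled
#' markers, restricted to the foreground `tau(q, h)`. Implemented as a
#' two-level multi-source geodesic breadth-first expansion with 4-connected
#' growth; when two basins reach a pixel in the same wave the lower marker
#' label wins (deterministic). Foreground pixels in components containing no
#' marker remain background.
#'
#' @param fields an `energy_fields` object from [energy_and_markers()].
#' @return integer instance map; marker labels relabeled consecutively.
#' @export
watershed_instances <- function(fields) {
  stopifnot(inherits(fields, "energy_fields"))
  M <- fields$M
  H <- nrow(M); W <- ncol(M)
  lab <- matrix(0L, H, W)
  if (max(M) == 0L) return(lab)
  lab[M > 0L] <- M[M > 0L]
  flood <- function(lab, allowed) {
    repeat {
      cand <- matrix(.Machine$integer.max, H, W)
      up <- rbind(lab[-1, , drop = FALSE], rep(0L, W))
      dn <- rbind(rep(0L, W), lab[-H, , drop = FALSE])
      lf <- cbind(lab[, -1, drop = FALSE], rep(0L, H))
      rt <- cbind(rep(0L, H), lab[, -W, drop = FALSE])
      for (nb in list(up, dn, lf, rt)) {
        pos <- nb > 0L
        cand[pos] <- pmin(cand[pos], nb[pos])
      }
      grow <- allowed & lab == 0L & cand < .Machine$integer.max
      if (!any(grow)) break
      lab[grow] <- cand[grow]
    }
    lab
  }
  lab <- flood(lab, fields$E > 0 & fields$foreground > 0)
  lab <- flood(lab, fields$foreground > 0)
  relabel_consecutive(lab)
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) == 0L) return(lab)
  remap <- integer(max(u))
  remap[u] <- seq_along(u)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Majority-vote typing of segmented instances
#'
#' Each instance receives the class holding the most pixels within it, where
#' a pixel's class is the argmax of the non-background class probabilities.
#' Ties (both per pixel and per instance) break to the lowest class index.
#'
#' @param instances integer instance map.
#' @param class_probs H x W x (C+1) probability stack whose first channel is
#'   background.
#' @return list with `types` (integer type map over the instances) and
#'   `instance_types` (data.frame: label, type, n_pixels).
#' @export
classify_instances <- function(instances, class_probs) {
  stopifnot(length(dim(class_probs)) == 3L,
            all(dim(class_probs)[1:2] == dim(instances)),
            dim(class_probs)[3] >= 2L)
  C <- dim(class_probs)[3] - 1L
  H <- nrow(instances); W <- ncol(instances)
  m <- matrix(class_probs[, , -1, drop = FALSE], H * W, C)
  pix_class <- max.col(m, ties.method = "first")
  types <- matrix(0L, H, W)
  labs <- sort(unique(instances[instances > 0L]))
  out <- data.frame(label = labs, type = integer(length(labs)),
                    n_pixels = integer(length(labs)))
  for (i in seq_along(labs)) {
    idx <- which(instances == labs[i])
    counts <- tabulate(pix_class[idx], nbins = C)
    ty <- which.max(counts)              # ties -> lowest class index
    types[idx] <- ty
    out$type[i] <- ty
    out$n_pixels[i] <- length(idx)
  }
  list(types = types, instance_types = out)
}

#' Full post-processing of a prediction stack
#'
#' Runs the gradient / energy / marker / watershed / majority-vote chain on
#' a prediction stack and returns separated, typed nuclear instances.
#'
#' @param stack a `prediction_stack` (fields `q`, `hv`, `classes`), e.g.
#'   from [ideal_prediction_stack()] or [predict_stack()].
#' @param params a [postprocess_params()].
#' @return a `hovseg_segmentation`: list with `instances`, `types`,
#'   `instance_types` (data.frame: label, type, n_pixels, centroid), and the
#'   intermediate `fields`.
#' @export
postprocess_stack <- function(stack, params = postprocess_params()) {
  stopifnot(inherits(stack, "prediction_stack"))
  S_m <- gradient_max(stack$hv[, , 1], stack$hv[, , 2], params$sobel_ksize)
  fields <- energy_and_markers(S_m, stack$q, params)
  instances <- watershed_instances(fields)
  cls <- classify_instances(instances, stack$classes)
  it <- cls$instance_types
  if (nrow(it) > 0L) {
    nr <- nrow(instances)
    cent <- t(vapply(it$label, function(l) {
      idx <- which(instances == l)
      c(mean((idx - 1L) %% nr), mean((idx - 1L) %/% nr))
    }, numeric(2)))
    it$centroid_row <- cent[, 1]
    it$centroid_col <- cent[, 2]
  }
  structure(list(instances = instances, types = cls$types,
                 instance_types = it, fields = fields, params = params),
            class = "hovseg_segmentation")
}

#' @export
print.hovseg_segmentation <- function(x, ...) {
  cat("Segmentation:", max(x$instances), "instances |",
      "foreground px:", sum(x$instances > 0), "\n")
  if (nrow(x$instance_types) > 0L) {
    cat("  types:", paste(sprintf("%d:%d", sort(unique(x$instance_types$type)),
                                  as.integer(table(x$instance_types$type))),
                          collapse = " "), "\n")
  }
  invisible(x)
}
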