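# Independent brute-force oracles, kept deliberately naive: pixel-set loops
# and exhaustive pair enumeration, no shared code with the package internals.

pixset <- function(map, lab) which(map == lab)

# AJI by explicit pixel sets; same greedy no-reuse rule, independently coded
oracle_aji <- function(truth, pred) {
  gts <- setdiff(sort(unique(as.vector(truth))), 0)
  prs <- setdiff(sort(unique(as.vector(pred))), 0)
  if (length(gts) == 0 && length(prs) == 0) return(1)
  if (length(gts) == 0 || length(prs) == 0) return(0)
  inter <- matrix(0, length(gts), length(prs))
  for (i in seq_along(gts)) for (j in seq_along(prs)) {
    inter[i, j] <- length(intersect(pixset(truth, gts[i]), pixset(pred, prs[j])))
  }
  ord <- order(-as.vector(inter),
               as.vector(row(inter)), as.vector(col(inter)))
  used_g <- logical(length(gts)); used_p <- logical(length(prs))
  num <- 0; den <- 0
  for (k in ord) {
    i <- row(inter)[k]; j <- col(inter)[k]
    if (used_g[i] || used_p[j]) next
    used_g[i] <- TRUE; used_p[j] <- TRUE
    gset <- pixset(truth, gts[i]); pset <- pixset(pred, prs[j])
    num <- num + length(intersect(gset, pset))
    den <- den + length(union(gset, pset))
  }
  for (i in which(!used_g)) den <- den + length(pixset(truth, gts[i]))
  for (j in which(!used_p)) den <- den + length(pixset(pred, prs[j]))
  if (den == 0) 1 else num / den
}

# DQ/SQ/PQ by testing every gt x pred pair
oracle_pq <- function(truth, pred) {
  gts <- setdiff(sort(unique(as.vector(truth))), 0)
  prs <- setdiff(sort(unique(as.vector(pred))), 0)
  if (length(gts) == 0 && length(prs) == 0) return(list(dq = 1, sq = 1, pq = 1))
  ious <- c()
  matched_g <- c(); matched_p <- c()
  for (g in gts) for (p in prs) {
    gs <- pixset(truth, g); ps <- pixset(pred, p)
    iou <- length(intersect(gs, ps)) / length(union(gs, ps))
    if (iou > 0.5) {
      ious <- c(ious, iou)
      matched_g <- c(matched_g, g); matched_p <- c(matched_p, p)
    }
  }
  tp <- length(ious)
  fp <- length(setdiff(prs, matched_p))
  fn <- length(setdiff(gts, matched_g))
  dq <- tp / (tp + fp / 2 + fn / 2)
  sq <- if (tp > 0) mean(ious) else 0
  list(dq = dq, sq = sq, pq = dq * sq)
}

# random instance label maps with <= k_max instances (blocky blobs, may abut)
random_label_map <- function(h, w, k_max) {
  m <- matrix(0L, h, w)
  k <- sample.int(k_max + 1L, 1L) - 1L
  for (lab in seq_len(k)) {
    rh <- sample.int(max(2L, h %/% 3L), 1L) + 1L
    rw <- sample.int(max(2L, w %/% 3L), 1L) + 1L
    r0 <- sample.int(h - rh, 1L)
    c0 <- sample.int(w - rw, 1L)
    m[r0 + seq_len(rh), c0 + seq_len(rw)] <- lab
  }
  # labels may be wiped by later rectangles; keep consecutive positive labels
  u <- setdiff(sort(unique(as.vector(m))), 0L)
  if (length(u) > 0L) m[m > 0L] <- match(m[m > 0L], u)
  m
}

# perturbed copy of a label map (shifts + erosions), for pred-vs-truth pairs
perturb_label_map <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  dr <- sample(-2:2, 1L); dc <- sample(-2:2, 1L)
  rows <- pmin(pmax(seq_len(h) + dr, 1L), h)
  cols <- pmin(pmax(seq_len(w) + dc, 1L), w)
  out <- m[rows, cols]
  if (stats::runif(1) < 0.5 && max(out) >= 2L) {
    out[out == max(out)] <- 0L           # drop one instance
  }
  out
}

# 4-connected flood-fill component count (marker-count oracle)
oracle_component_count_8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue) > 0L) {
      px <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- px[1] + dr; cc <- px[2] + dc
        if (r >= 1L && r <= h && cc >= 1L && cc <= w &&
            mask[r, cc] && !seen[r, cc]) {
          seen[r, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  count
}

# brute-force binary dilation by one pixel (8-neighbourhood)
dilate1 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    rs <- pmin(pmax(seq_len(h) + dr, 1L), h)
    cs <- pmin(pmax(seq_len(w) + dc, 1L), w)
    out <- out | mask[rs, cs]
  }
  out
}

# brute-force binary erosion by k pixels (8-neighbourhood)
erode_k <- function(mask, k) {
  for (i in seq_len(k)) {
    h <- nrow(mask); w <- ncol(mask)
    out <- mask
    for (dr in -1:1) for (dc in -1:1) {
      rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
      shifted <- matrix(FALSE, h, w)
      ok_r <- rs >= 1L & rs <= h; ok_c <- cs >= 1L & cs <= w
      shifted[ok_r, ok_c] <- mask[rs[ok_r], cs[ok_c]]
      out <- out & shifted
    }
    mask <- out
  }
  mask
}

# tiny model for fast network tests
tiny_model <- function(input_size = 198L, width = 4L, n_layers = 1L,
                       seed = 5L, ...) {
  build_model(trunk_config(width = width, input_size = input_size),
              transformer_config(n_layers = n_layers, embed_dim = 8L * width,
                                 n_heads = 4L, mlp_dim = 16L * width),
              default_branches(4L), seed = seed, ...)
}

numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
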