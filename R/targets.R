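# Supervision targets for the three branches: NP (binary foreground),
# HV (per-instance horizontal/vertical distance-to-centroid maps in [-1,1]),
# NC (per-pixel nuclear type).

check_instance_map <- function(instances) {
  stopifnot(is.matrix(instances))
  if (any(instances < 0)) stop("instance map contains negative labels")
  if (any(instances != round(instances))) stop("instance map contains non-integer labels")
  invisible(instances)
}

#' Encode the nuclear-pixel (NP) target
#'
#' @param instances integer instance label map (0 = background).
#' @return binary matrix, 1 exactly where the label is positive.
#' @export
encode_np <- function(instances) {
  check_instance_map(instances)
  (instances > 0) * 1
}

#' Encode the horizontal-vertical (HV) distance-map target
#'
#' For every instance, each pixel's horizontal value is its signed column
#' distance to the instance centroid (unweighted pixel mean), rescaled
#' per instance and per side so the extreme left/right pixels map to -1/+1;
#' the vertical map is the row analogue. Background is 0. Single-pixel (or
#' single-column/row) extents give 0. The spatial gradients of these maps
#' peak where touching instances meet, which is what the post-processing
#' exploits.
#'
#' @param instances integer instance label map.
#' @return H x W x 2 array: `[,,1]` horizontal, `[,,2]` vertical.
#' @export
encode_hover <- function(instances) {
  check_instance_map(instances)
  h <- matrix(0, nrow(instances), ncol(instances))
  v <- matrix(0, nrow(instances), ncol(instances))
  fg <- which(instances > 0)
  if (length(fg) == 0L) {
    return(array(c(h, v), dim = c(nrow(instances), ncol(instances), 2L)))
  }
  nr <- nrow(instances)
  rows <- (fg - 1L) %% nr            # 0-based (row, col)
  cols <- (fg - 1L) %/% nr
  for (px in split(seq_along(fg), instances[fg])) {
    r <- rows[px]; cl <- cols[px]
    rbar <- mean(r); cbar <- mean(cl)
    dl <- cbar - min(cl); dr <- max(cl) - cbar
    dc <- cl - cbar
    hv <- numeric(length(px))
    hv[dc < 0] <- dc[dc < 0] / dl
    hv[dc > 0] <- dc[dc > 0] / dr
    h[fg[px]] <- hv
    du <- rbar - min(r); dd <- max(r) - rbar
    drw <- r - rbar
    vv <- numeric(length(px))
    vv[drw < 0] <- drw[drw < 0] / du
    vv[drw > 0] <- drw[drw > 0] / dd
    v[fg[px]] <- vv
  }
  array(c(h, v), dim = c(nrow(instances), ncol(instances), 2L))
}

#' Encode the nuclear-classification (NC) target
#'
#' Validates that the type map agrees with the instance map (a type asserted
#' on a background pixel, or a foreground pixel without a type, is an error)
#' and returns it.
#'
#' @param instances integer instance label map.
#' @param types integer type map (0 = background, `1..C` on nuclei).
#' @return the validated type map.
#' @export
encode_nc <- function(instances, types) {
  check_instance_map(instances)
  stopifnot(is.matrix(types), all(dim(types) == dim(instances)))
  if (any(types != round(types)) || any(types < 0)) {
    stop("type map must contain nonnegative integers")
  }
  if (any(types[instances == 0] != 0)) {
    stop("type asserted on a background pixel")
  }
  if (any(types[instances > 0] == 0)) {
    stop("foreground pixel without a type")
  }
  types
}

#' Encode the full target stack for one tile
#'
#' @param instances integer instance label map.
#' @param types integer type map.
#' @return a `target_stack`: list with `np` (binary), `hv` (H x W x 2),
#'   `nc` (integer map).
#' @export
encode_targets <- function(instances, types) {
  structure(list(np = encode_np(instances),
                 hv = encode_hover(instances),
                 nc = encode_nc(instances, types)),
            class = "target_stack")
}
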