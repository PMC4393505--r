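#' Identify the breast contour of an MLO mammogram
#'
#' Runs a two-phase region-based level-set evolution (piecewise-constant
#' energy with Gaussian-smoothed local region means, so slowly varying
#' intensity inhomogeneity is absorbed into the local fit) initialised from
#' a coarse Otsu threshold, and returns the largest 4-connected foreground
#' component as the breast mask.  Images whose breast centroid falls in the
#' right half are mirrored to the canonical left orientation (chest wall at
#' the left, pectoral muscle at the top-left corner) and flagged.
#'
#' @param image Numeric matrix, 8-bit gray levels, at least 64x64.
#' @param max_iter Iteration cap for the level-set evolution.
#' @param local_sigma Gaussian sigma (pixels) of the local region means.
#' @param tol Convergence threshold as a fraction of pixels changing phase.
#' @return An object of class `breast_contour` with fields `breast_mask`
#'   (logical matrix), `orientation_flipped` (logical) and `image` (the
#'   possibly mirrored input, for downstream stages).
#' @export
extract_breast_contour <- function(image, max_iter = 200L, local_sigma = 8,
                                   tol = 0.001) {
  assert_gray_image(image)
  if (max(image) - min(image) < 1e-9)
    stop("no breast region: image is constant", call. = FALSE)
  mask <- image > otsu_threshold(image)
  n <- length(mask)
  eps <- 1e-3
  for (iter in seq_len(max_iter)) {
    if (!any(mask) || all(mask)) break
    g1 <- mean(image[mask]); g0 <- mean(image[!mask])
    # local phase means, falling back to the global phase mean where a phase
    # has no local support (keeps the fit defined far from the interface)
    c1 <- (gauss_blur(image * mask, local_sigma) + eps * g1) /
      (gauss_blur(mask * 1, local_sigma) + eps)
    c0 <- (gauss_blur(image * !mask, local_sigma) + eps * g0) /
      (gauss_blur((!mask) * 1, local_sigma) + eps)
    new_mask <- (image - c1)^2 <= (image - c0)^2
    # curvature-style regularisation: smooth the indicator and re-threshold
    new_mask <- gauss_blur(new_mask * 1, 1) > 0.5
    changed <- sum(xor(new_mask, mask))
    mask <- new_mask
    if (changed < tol * n) break
  }
  # foreground = the brighter phase
  if (mean(image[mask]) < mean(image[!mask])) mask <- !mask
  mask <- largest_component(mask, connectivity = 4L)
  area <- sum(mask)
  if (area == 0L || area > 0.98 * n)
    stop("no breast region: segmentation produced no usable foreground",
         call. = FALSE)
  flipped <- FALSE
  centroid_col <- mean(col(mask)[mask])
  if (centroid_col > ncol(mask) / 2) {
    mask <- mirror_lr(mask)
    image <- mirror_lr(image)
    flipped <- TRUE
  }
  structure(list(breast_mask = mask, orientation_flipped = flipped,
                 image = image),
            class = "breast_contour")
}

otsu_threshold <- function(image) {
  h <- tabulate(pmin(pmax(floor(image), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1L
}

#' Locate the pectoral-muscle control points
#'
#' On the canonical left-oriented image, the breast contour defines four
#' boundary landmarks: `x1`, the top-left corner pixel of the breast contour;
#' `x2`, the top-right breast pixel on the same boundary row; `y1`, the
#' lowest breast pixel on the left edge; and `y2`, the lowest breast pixel on
#' the right edge.  Two further points mark the pectoral boundary: `x3` is
#' the first pixel walking the straight segment x1 -> x2 whose forward
#' intensity difference exceeds the gradient threshold, and `y3` the first
#' such pixel walking x1 -> y1.  The threshold is
#' `max(10, 2 * median |forward difference|)` along each walk, since an
#' "immediate" intensity variation has no quantified magnitude.
#'
#' @param image Canonical-orientation image (e.g. `contour$image`).
#' @param contour A [extract_breast_contour()] result.
#' @return An object of class `control_points` with `(row, col)` fields
#'   `x1, x2, y1, y2` and, when a pectoral boundary was found, `x3, y3`;
#'   `pectoral_found` is `FALSE` when no intensity drop exists along either
#'   walk (the caller then keeps the whole breast mask as the AOI).
#' @export
locate_control_points <- function(image, contour) {
  mask <- contour$breast_mask
  rows_any <- which(apply(mask, 1, any))
  top_row <- rows_any[1]
  cols_top <- which(mask[top_row, ])
  x1 <- c(top_row, cols_top[1])
  x2 <- c(top_row, cols_top[length(cols_top)])
  left_col <- min(which(apply(mask, 2, any)))
  y1 <- c(max(which(mask[, left_col])), left_col)
  right_col <- max(which(apply(mask, 2, any)))
  y2 <- c(max(which(mask[, right_col])), right_col)

  x3 <- walk_to_drop(image[x1[1], x1[2]:x2[2]])
  y3 <- walk_to_drop(image[x1[1]:y1[1], x1[2]])
  found <- !is.na(x3) && !is.na(y3)
  cp <- list(x1 = x1, x2 = x2, y1 = y1, y2 = y2,
             x3 = if (found) c(x1[1], x1[2] + x3 - 1L) else NULL,
             y3 = if (found) c(x1[1] + y3 - 1L, x1[2]) else NULL,
             pectoral_found = found)
  class(cp) <- "control_points"
  cp
}

# First index along an intensity profile whose forward difference exceeds
# max(10, 2 * median absolute forward difference); NA when none does.
walk_to_drop <- function(profile) {
  if (length(profile) < 3L) return(NA_integer_)
  d <- abs(diff(profile))
  thr <- max(10, 2 * stats::median(d))
  hit <- which(d > thr)
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

#' Remove the pectoral muscle and return the area of interest
#'
#' Segments the pectoral muscle by 4-connected seeded region growing from
#' `x1` under the homogeneity criterion `|I(p) - running region mean| <= tol`
#' (grown within the breast mask), intersects the region with the half-plane
#' on `x1`'s side of the straight line through `x3` and `y3`
#' (`y = m x + c` in (row, col) coordinates), and smooths rough edges with a
#' morphological opening.  The AOI is the breast mask minus the pectoral
#' mask.
#'
#' @param image Canonical-orientation image.
#' @param contour A [extract_breast_contour()] result.
#' @param cp A [locate_control_points()] result.
#' @param srg_tol SRG homogeneity tolerance in gray levels.
#' @param opening_radius Radius (pixels) of the disc structuring element.
#' @return An object of class `aoi_result` with `aoi_mask`, `pectoral_mask`
#'   and `cut_line` (list with slope `m` and intercept `c`, or `NULL`).
#' @export
remove_pectoral_muscle <- function(image, contour, cp, srg_tol = 16,
                                   opening_radius = 3L) {
  breast <- contour$breast_mask
  if (!isTRUE(cp$pectoral_found)) {
    return(structure(list(aoi_mask = breast,
                          pectoral_mask = breast & FALSE,
                          cut_line = NULL),
                     class = "aoi_result"))
  }
  region <- seeded_region_grow(image, seed = cp$x1, tol = srg_tol,
                               within = breast)
  cut <- NULL
  if (all(cp$x3 == cp$y3)) {
    warning("degenerate pectoral cut line (x3 == y3); using SRG region alone")
    pect <- region
  } else {
    # half-plane on x1's side of the line through x3 and y3
    side <- function(r, cc) {
      (cp$y3[1] - cp$x3[1]) * (cc - cp$x3[2]) -
        (cp$y3[2] - cp$x3[2]) * (r - cp$x3[1])
    }
    s1 <- sign(side(cp$x1[1], cp$x1[2]))
    half <- side(row(image), col(image)) * s1 >= 0
    pect <- region & half
    dc <- cp$y3[2] - cp$x3[2]
    if (dc != 0) {
      m <- (cp$y3[1] - cp$x3[1]) / dc
      cut <- list(m = m, c = cp$x3[1] - m * cp$x3[2])
    } else cut <- list(m = Inf, c = cp$x3[2])
  }
  if (opening_radius > 0 && any(pect)) {
    brush <- EBImage::makeBrush(2L * opening_radius + 1L, shape = "disc")
    pect <- matrix(as.logical(EBImage::opening(pect * 1, brush)),
                   nrow(pect), ncol(pect))
  }
  pect <- pect & breast
  structure(list(aoi_mask = breast & !pect, pectoral_mask = pect,
                 cut_line = cut),
            class = "aoi_result")
}

# Greedy breadth-first seeded region growing: a popped neighbour joins the
# region when its intensity is within tol of the running region mean.
seeded_region_grow <- function(image, seed, tol, within = NULL) {
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(within)) within <- matrix(TRUE, nr, nc)
  region <- matrix(FALSE, nr, nc)
  visited <- matrix(FALSE, nr, nc)
  start <- (seed[2] - 1L) * nr + seed[1]
  if (!within[start]) return(region)
  region[start] <- TRUE; visited[start] <- TRUE
  total <- image[start]; count <- 1L
  queue <- integer(256L); queue[1L] <- start; head <- 1L; tail <- 1L
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  while (head <= tail) {
    p <- queue[head]; head <- head + 1L
    r <- ((p - 1L) %% nr) + 1L
    cc <- ((p - 1L) %/% nr) + 1L
    for (k in 1:4) {
      r2 <- r + dr[k]; c2 <- cc + dc[k]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      p2 <- (c2 - 1L) * nr + r2
      if (visited[p2] || !within[p2]) next
      visited[p2] <- TRUE
      if (abs(image[p2] - total / count) <= tol) {
        region[p2] <- TRUE
        total <- total + image[p2]; count <- count + 1L
        tail <- tail + 1L
        if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
        queue[tail] <- p2
      }
    }
  }
  region
}

#' Run the full pre-processing stage
#'
#' Convenience wrapper: breast contour, control points, pectoral removal.
#'
#' @inheritParams extract_breast_contour
#' @inheritParams remove_pectoral_muscle
#' @return List with `contour`, `control_points`, `aoi` and `image` (the
#'   canonical-orientation image).
#' @export
preprocess_mammogram <- function(image, srg_tol = 16, opening_radius = 3L) {
  contour <- extract_breast_contour(image)
  cp <- locate_control_points(contour$image, contour)
  aoi <- remove_pectoral_muscle(contour$image, contour, cp,
                                srg_tol = srg_tol,
                                opening_radius = opening_radius)
  list(contour = contour, control_points = cp, aoi = aoi,
       image = contour$image)
}
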