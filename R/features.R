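# Four-family texture feature extractor with a fixed 1037-slot layout:
#   family A (orthogonal-polynomial texture)          slots   1..113
#   family B (sub-band statistical + spectral)        slots 114..561
#   family C (bivariate discrete orthogonal poly)     slots 562..897
#   family D (gradient gray-level co-occurrence)      slots 898..1037
# The layout is identical between training and test paths; every extractor
# asserts its family length on exit.

STAT12_NAMES <- c("mean", "variance", "skewness", "kurtosis", "energy",
                  "entropy", "min", "max", "range", "median", "mad", "rms")
STAT14_NAMES <- c(STAT12_NAMES, "p10", "p90")

# Twelve first-order statistics of a sample.  Moment-based statistics use
# population moments; skewness/kurtosis are 0 by convention for a constant
# sample; entropy uses 16 equal-width bins over the observed range, log2.
stat12 <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  sk <- if (m2 > 1e-24) mean((x - m)^3) / m2^1.5 else 0
  ku <- if (m2 > 1e-24) mean((x - m)^4) / m2^2 else 0
  c(mean = m, variance = m2, skewness = sk, kurtosis = ku,
    energy = mean(x^2), entropy = binned_entropy(x, 16L),
    min = min(x), max = max(x), range = max(x) - min(x),
    median = stats::median(x), mad = mean(abs(x - m)),
    rms = sqrt(mean(x^2)))
}

stat14 <- function(x) {
  q <- stats::quantile(x, c(0.10, 0.90), names = FALSE, type = 7)
  c(stat12(x), p10 = q[1], p90 = q[2])
}

binned_entropy <- function(x, bins) {
  rng <- range(x)
  if (diff(rng) <= 0) return(0)
  cuts <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(pmin(findInterval(x, cuts, rightmost.closed = TRUE), bins),
                nbins = bins)
  p <- h[h > 0] / length(x)
  -sum(p * log2(p))
}

# Crop image and mask to the mask's bounding box; pixels outside the mask
# are replaced by the in-mask mean so features depend only on masked content.
crop_roi <- function(roi_image, roi_mask) {
  assert_mask(roi_mask, roi_image, "roi_mask")
  if (!any(roi_mask)) stop_field("roi_mask", "must contain pixels")
  rws <- range(which(apply(roi_mask, 1, any)))
  cls <- range(which(apply(roi_mask, 2, any)))
  img <- roi_image[rws[1]:rws[2], cls[1]:cls[2], drop = FALSE]
  msk <- roi_mask[rws[1]:rws[2], cls[1]:cls[2], drop = FALSE]
  fill <- mean(img[msk])
  img[!msk] <- fill
  list(image = img, mask = msk)
}

#' Family A: orthogonal-polynomial texture features (113)
#'
#' Twelve first-order statistics of each of the nine 3x3
#' orthogonal-polynomial coefficient planes restricted to the mask (108),
#' plus five first-order statistics (mean, variance, skewness, kurtosis,
#' entropy) of the masked ROI intensities.
#'
#' @param roi_image,roi_mask Numeric matrix and logical mask of equal size;
#'   the mask's bounding box must be at least 9x9.
#' @return Named numeric vector of length 113.
#' @export
extract_family_a <- function(roi_image, roi_mask) {
  roi <- crop_roi(roi_image, roi_mask)
  if (nrow(roi$image) < 9L || ncol(roi$image) < 9L)
    stop_field("roi_mask", "bounding box must be at least 9x9 for family A")
  planes <- op_planes(roi$image, op_basis3)
  out <- numeric(0)
  for (nm in names(planes)) {
    v <- stat12(planes[[nm]][roi$mask])
    names(v) <- paste("A", nm, STAT12_NAMES, sep = ".")
    out <- c(out, v)
  }
  px <- roi$image[roi$mask]
  fo <- stat12(px)[c("mean", "variance", "skewness", "kurtosis", "entropy")]
  names(fo) <- paste("A.roi", c("mean", "variance", "skewness", "kurtosis",
                                "entropy"), sep = ".")
  out <- c(out, fo)
  stopifnot(length(out) == 113L)
  out
}

# One level of the orthonormal 2x2 sub-band decomposition (basis
# (1,1)/sqrt(2) and (-1,1)/sqrt(2), decimated by 2).  Input dims must be
# even.  Returns bands LL, LH, HL, HH; the transform preserves total energy.
subband_decompose <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  stopifnot(nr %% 2L == 0L, nc %% 2L == 0L)
  a <- x[seq(1, nr, 2), seq(1, nc, 2), drop = FALSE]
  b <- x[seq(1, nr, 2), seq(2, nc, 2), drop = FALSE]
  cc <- x[seq(2, nr, 2), seq(1, nc, 2), drop = FALSE]
  d <- x[seq(2, nr, 2), seq(2, nc, 2), drop = FALSE]
  list(LL = (a + b + cc + d) / 2,
       LH = (-a + b - cc + d) / 2,     # column detail
       HL = (-a - b + cc + d) / 2,     # row detail
       HH = (a - b - cc + d) / 2)
}

# 14 spectral measures of a sub-band's 2-D power spectrum: total energy,
# spectral entropy, 8 radial-band and 4 angular-band energy fractions.
spectral14 <- function(band) {
  P <- Mod(stats::fft(band))^2
  total <- sum(P)
  nr <- nrow(P); nc <- ncol(P)
  fr <- (((seq_len(nr) - 1L) + floor(nr / 2)) %% nr - floor(nr / 2)) / nr
  fc <- (((seq_len(nc) - 1L) + floor(nc / 2)) %% nc - floor(nc / 2)) / nc
  rho <- sqrt(outer(fr^2, fc^2, "+"))
  ang <- atan2(matrix(fr, nr, nc), matrix(fc, nr, nc, byrow = TRUE)) %% pi
  out <- numeric(14)
  names(out) <- c("spec_energy", "spec_entropy",
                  paste0("radial", 1:8), paste0("angular", 1:4))
  out["spec_energy"] <- total
  if (total > 0) {
    p <- P[P > 0] / total
    out["spec_entropy"] <- -sum(p * log2(p))
    rbin <- pmin(1L + floor(rho / (sqrt(0.5) + 1e-12) * 8), 8L)
    for (k in 1:8) out[paste0("radial", k)] <- sum(P[rbin == k]) / total
    abin <- pmin(1L + floor(ang / pi * 4), 4L)
    dc <- rho == 0
    for (k in 1:4)
      out[paste0("angular", k)] <- sum(P[abin == k & !dc]) / total
  }
  out
}

#' Family B: sub-band statistical and spectral features (448)
#'
#' Two-level 2x2 orthonormal sub-band decomposition (each level-1 band is
#' decomposed again) giving 16 level-2 sub-bands; for each, 14 first-order
#' statistics and 14 spectral measures of its 2-D power spectrum.
#'
#' @inheritParams extract_family_a
#' @return Named numeric vector of length 448.
#' @export
extract_family_b <- function(roi_image, roi_mask) {
  roi <- crop_roi(roi_image, roi_mask)
  nr <- nrow(roi$image); nc <- ncol(roi$image)
  if (nr < 16L || nc < 16L)
    stop_field("roi_mask", "bounding box must be at least 16x16 for family B")
  img <- roi$image[seq_len(nr - nr %% 4L), seq_len(nc - nc %% 4L),
                   drop = FALSE]
  lvl1 <- subband_decompose(img)
  out <- numeric(0)
  for (n1 in names(lvl1)) {
    lvl2 <- subband_decompose(lvl1[[n1]])
    for (n2 in names(lvl2)) {
      band <- lvl2[[n2]]
      s <- stat14(as.numeric(band))
      names(s) <- paste("B", n1, n2, STAT14_NAMES, sep = ".")
      sp <- spectral14(band)
      names(sp) <- paste("B", n1, n2, names(sp), sep = ".")
      out <- c(out, s, sp)
    }
  }
  stopifnot(length(out) == 448L)
  out
}

# Discrete orthogonal polynomial basis of degrees 0..4 on 5 points, built
# by Gram-Schmidt on the monomials over x = -2..2.
op_basis5 <- local({
  x <- -2:2
  V <- outer(x, 0:4, "^")
  B <- matrix(0, 5, 5)
  for (j in 1:5) {
    v <- V[, j]
    if (j > 1) for (i in 1:(j - 1))
      v <- v - sum(v * B[, i]) / sum(B[, i]^2) * B[, i]
    B[, j] <- v
  }
  lapply(seq_len(5), function(j) B[, j])
})

#' Family C: bivariate discrete orthogonal polynomial features (336)
#'
#' 5x5 sliding-window transform onto the 25 outer products of the degree
#' 0..4 discrete orthogonal basis; the DC plane is dropped and the 14
#' first-order statistics of each remaining plane (over the mask) are
#' reported: 24 x 14 = 336.
#'
#' @inheritParams extract_family_a
#' @return Named numeric vector of length 336.
#' @export
extract_family_c <- function(roi_image, roi_mask) {
  roi <- crop_roi(roi_image, roi_mask)
  if (nrow(roi$image) < 10L || ncol(roi$image) < 10L)
    stop_field("roi_mask", "bounding box must be at least 10x10 for family C")
  planes <- op_planes(roi$image, op_basis5)
  planes <- planes[names(planes) != "b00"]
  out <- numeric(0)
  for (nm in names(planes)) {
    v <- stat14(planes[[nm]][roi$mask])
    names(v) <- paste("C", nm, STAT14_NAMES, sep = ".")
    out <- c(out, v)
  }
  stopifnot(length(out) == 336L)
  out
}

# Gradient magnitude (central differences), quantised to `levels` equal-width
# bins over the masked range; returns an integer matrix (NA outside mask).
gradient_quantized <- function(image, mask, levels = 8L) {
  gr <- grad2(image)
  g <- sqrt(gr$x^2 + gr$y^2)
  vals <- g[mask]
  rng <- range(vals)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (diff(rng) <= 0) {
    q[mask] <- 1L
  } else {
    q[mask] <- pmin(1L + as.integer(floor((g[mask] - rng[1]) /
                                            diff(rng) * levels)), levels)
  }
  q
}

# Symmetric normalised GLCM of a quantised image for one (direction,
# distance) offset; NULL when fewer than 2 valid pairs exist.
glcm <- function(q, dr, dc, levels = 8L) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r1) == 0L || length(c1) == 0L) return(NULL)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NULL)
  m <- matrix(0, levels, levels)
  tab <- table(factor(a[ok], levels = seq_len(levels)),
               factor(b[ok], levels = seq_len(levels)))
  m[] <- m + tab + t(tab)
  m / sum(m)
}

glcm_measures <- function(m) {
  lv <- nrow(m)
  i <- matrix(seq_len(lv), lv, lv)
  j <- t(i)
  mu_i <- sum(i * m); mu_j <- sum(j * m)
  s_i <- sqrt(sum((i - mu_i)^2 * m)); s_j <- sqrt(sum((j - mu_j)^2 * m))
  corr <- if (s_i > 1e-12 && s_j > 1e-12)
    sum((i - mu_i) * (j - mu_j) * m) / (s_i * s_j) else 0
  p <- m[m > 0]
  c(contrast = sum((i - j)^2 * m),
    correlation = corr,
    energy = sum(m^2),
    homogeneity = sum(m / (1 + (i - j)^2)),
    entropy = -sum(p * log2(p)),
    dissimilarity = sum(abs(i - j) * m),
    maxprob = max(m))
}

GLCM_MEASURES <- c("contrast", "correlation", "energy", "homogeneity",
                   "entropy", "dissimilarity", "maxprob")

#' Family D: gradient gray-level co-occurrence features (140)
#'
#' The gradient magnitude is quantised to 8 equal-width levels over the
#' mask; symmetric normalised co-occurrence matrices are built for the four
#' directions 0/45/90/135 degrees at distances 1..5, and seven Haralick-type
#' measures are reported per matrix: 20 x 7 = 140.  A matrix with fewer
#' than two valid pixel pairs yields zeros with a warning.
#'
#' @inheritParams extract_family_a
#' @return Named numeric vector of length 140.
#' @export
extract_family_d <- function(roi_image, roi_mask) {
  roi <- crop_roi(roi_image, roi_mask)
  if (nrow(roi$image) < 8L || ncol(roi$image) < 8L)
    stop_field("roi_mask", "bounding box must be at least 8x8 for family D")
  q <- gradient_quantized(roi$image, roi$mask)
  dirs <- list(a000 = c(0L, 1L), a045 = c(-1L, 1L),
               a090 = c(-1L, 0L), a135 = c(-1L, -1L))
  out <- numeric(0)
  for (d in 1:5) {
    for (nm in names(dirs)) {
      off <- dirs[[nm]] * d
      m <- glcm(q, off[1], off[2])
      if (is.null(m)) {
        warning(sprintf("GLCM %s distance %d has < 2 pairs; zero-filled",
                        nm, d))
        v <- stats::setNames(numeric(7), GLCM_MEASURES)
      } else v <- glcm_measures(m)
      names(v) <- paste("D", sprintf("d%d", d), nm, GLCM_MEASURES, sep = ".")
      out <- c(out, v)
    }
  }
  stopifnot(length(out) == 140L)
  out
}

#' Extract the full 1037-dimensional feature vector
#'
#' Concatenates families A (113), B (448), C (336) and D (140) in the fixed
#' layout shared by the training and test paths.
#'
#' @inheritParams extract_family_a
#' @return Named numeric vector of length 1037 with attribute `family`, a
#'   factor giving each slot's family.
#' @export
extract_features <- function(roi_image, roi_mask) {
  a <- extract_family_a(roi_image, roi_mask)
  b <- extract_family_b(roi_image, roi_mask)
  cc <- extract_family_c(roi_image, roi_mask)
  d <- extract_family_d(roi_image, roi_mask)
  out <- c(a, b, cc, d)
  stopifnot(length(out) == 1037L, !anyNA(out), all(is.finite(out)))
  attr(out, "family") <- factor(rep(c("A", "B", "C", "D"),
                                    times = c(113L, 448L, 336L, 140L)))
  out
}

#' The fixed feature layout
#'
#' @return A data frame with columns `slot` (1-based index), `name` and
#'   `family` describing all 1037 feature slots.
#' @export
feature_layout <- function() {
  img <- matrix(rep(seq_len(32), 32), 32, 32) %% 7 * 30
  v <- extract_features(img, matrix(TRUE, 32, 32))
  data.frame(slot = seq_along(v), name = names(v),
             family = as.character(attr(v, "family")),
             stringsAsFactors = FALSE)
}
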