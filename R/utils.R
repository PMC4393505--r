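# Internal helpers shared across modules.

# Run code with a private RNG stream: seeds the generator, restores any
# pre-existing .Random.seed on exit, so generation never leaks global state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid %s: %s", field, msg), call. = FALSE)
}

# Validate an 8-bit grayscale image matrix (rows top->bottom, cols
# left->right, 0-based (row, col) convention documented at the API surface;
# R matrices are 1-based internally).
assert_gray_image <- function(image, min_dim = 64L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_field("image", "must be a numeric matrix")
  if (nrow(image) < min_dim || ncol(image) < min_dim)
    stop_field("image", sprintf("must be at least %dx%d", min_dim, min_dim))
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    stop_field("image", "intensities must be finite and within [0, 255]")
  invisible(image)
}

assert_mask <- function(mask, image = NULL, what = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_field(what, "must be a logical matrix")
  if (!is.null(image) && !identical(dim(mask), dim(image)))
    stop_field(what, "dimensions must match the image")
  invisible(mask)
}

# 4- or 8-connected component labelling by flood fill.  Masks in this
# pipeline hold a handful of components, so a queue-based fill is adequate.
label_components <- function(mask, connectivity = 4L) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- rep(c(-1L, 0L, 1L), 3L); dc <- rep(c(-1L, 0L, 1L), each = 3L)
    keep <- !(dr == 0L & dc == 0L); dr <- dr[keep]; dc <- dc[keep]
  }
  lab <- 0L
  idx_all <- which(mask & labels == 0L)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- integer(length(start) + 64L)
    queue[1L] <- start; qlen <- 1L
    labels[start] <- lab
    while (qlen > 0L) {
      p <- queue[qlen]; qlen <- qlen - 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r2 <- r + dr[k]; c2 <- cc + dc[k]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          p2 <- (c2 - 1L) * nr + r2
          if (mask[p2] && labels[p2] == 0L) {
            labels[p2] <- lab
            qlen <- qlen + 1L
            if (qlen > length(queue)) queue <- c(queue, integer(length(queue)))
            queue[qlen] <- p2
          }
        }
      }
    }
  }
  labels
}

largest_component <- function(mask, connectivity = 4L) {
  labels <- label_components(mask, connectivity)
  if (max(labels) == 0L) return(mask & FALSE)
  areas <- tabulate(labels[labels > 0L])
  labels == which.max(areas)
}

dice_coefficient <- function(a, b) {
  inter <- sum(a & b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * inter / denom
}

# Gaussian blur that tolerates plain matrices (EBImage works on Image objects
# but accepts arrays); returns a plain matrix.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  out <- EBImage::gblur(x, sigma = sigma)
  matrix(as.numeric(out), nrow(x), ncol(x))
}

mirror_lr <- function(x) x[, rev(seq_len(ncol(x))), drop = FALSE]

canonical_itemset <- function(items) sort(unique(as.character(items)))

itemset_key <- function(items) paste(canonical_itemset(items), collapse = "\x1f")
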