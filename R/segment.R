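# 1-D orthogonal point-spread basis on 3 points: constant, linear, quadratic.
op_basis3 <- list(u0 = c(1, 1, 1), u1 = c(-1, 0, 1), u2 = c(1, -2, 1))

#' Orthogonal-polynomial transform of an image
#'
#' Computes, for every 3x3 window (borders replicated), the nine transform
#' coefficients `beta_ij = <window, O_ij> / <O_ij, O_ij>`, where `O_ij` is
#' the outer product of the 1-D orthogonal basis `u0 = (1,1,1)`,
#' `u1 = (-1,0,1)`, `u2 = (1,-2,1)`; the first index is the row (vertical)
#' basis and the second the column (horizontal) basis.  `beta_00` is the DC
#' (local mean) plane; the eight AC planes respond to edges and texture.
#'
#' @param image Numeric matrix.
#' @param aoi Optional logical matrix restricting downstream statistics; the
#'   planes themselves are computed everywhere.
#' @return Object of class `coefficient_planes`: a list with `planes` (named
#'   list `b00` ... `b22` of matrices), `window` (3) and `aoi`.
#' @export
op_transform <- function(image, aoi = NULL) {
  stopifnot(is.matrix(image))
  if (is.null(aoi)) aoi <- matrix(TRUE, nrow(image), ncol(image))
  assert_mask(aoi, image, "aoi")
  if (!any(aoi)) stop_field("aoi", "must contain at least one pixel")
  planes <- op_planes(image, op_basis3)
  structure(list(planes = planes, window = 3L, aoi = aoi),
            class = "coefficient_planes")
}

# Sliding-window separable transform via shifted sums on a replicated pad.
op_planes <- function(image, basis) {
  k <- length(basis[[1]])
  half <- (k - 1L) %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  pad <- image[pmin(pmax(seq_len(nr + 2L * half) - half, 1L), nr),
               pmin(pmax(seq_len(nc + 2L * half) - half, 1L), nc)]
  planes <- list()
  for (i in seq_along(basis)) {
    for (j in seq_along(basis)) {
      ui <- basis[[i]]; uj <- basis[[j]]
      acc <- matrix(0, nr, nc)
      for (a in seq_len(k)) {
        for (b in seq_len(k)) {
          wgt <- ui[a] * uj[b]
          if (wgt == 0) next
          acc <- acc + wgt * pad[(a - 1L) + seq_len(nr),
                                 (b - 1L) + seq_len(nc)]
        }
      }
      norm <- sum(ui^2) * sum(uj^2)
      planes[[sprintf("b%d%d", i - 1L, j - 1L)]] <- acc / norm
    }
  }
  planes
}

#' Detect edges from orthogonal-polynomial coefficients
#'
#' Separates edge responses from noise statistically.  The noise level is
#' estimated from the highest-order coefficient `beta_22`, pooled over the
#' AOI (for i.i.d. noise, `Var(beta_01) = Var(beta_10) = 6 E[beta_22^2]`).
#' A window is an edge candidate when the variance-ratio statistic
#' `F = (beta_01^2 + beta_10^2) / (2 sigma2)` exceeds the F critical value
#' at the given significance, and it passes a sign-run consistency check:
#' the dominant gradient coefficient keeps one sign across the three pixels
#' along the edge direction.  The edge magnitude is
#' `E = sqrt(beta_01^2 + beta_10^2)` and the global threshold `t*` maximises
#' the signal-to-noise objective
#' `SNR(t) = mean(E | E >= t) / (sd(E | E < t) + eps)` over the percentile
#' grid 50..99 of `E`.  Edge pixels are exactly the AOI windows passing both
#' tests with `E >= t*`.
#'
#' @param cp A [op_transform()] result.
#' @param significance Test significance level in (0, 1).
#' @return Object of class `edge_map`: `edges` (logical matrix), `E`
#'   (magnitude), `t_star`, `f_pass` / `nair_pass` (the two test masks),
#'   `n_candidates` (count passing the F test) and `significance`.
#' @export
detect_edges <- function(cp, significance = 0.05) {
  stopifnot(inherits(cp, "coefficient_planes"))
  if (significance <= 0 || significance >= 1)
    stop_field("significance", "must lie in (0, 1)")
  aoi <- cp$aoi
  b01 <- cp$planes$b01; b10 <- cp$planes$b10; b22 <- cp$planes$b22
  E <- sqrt(b01^2 + b10^2)
  n_pool <- sum(aoi)
  sigma2 <- 6 * mean(b22[aoi]^2)    # variance of a first-order coefficient
  empty <- aoi & FALSE
  if (sigma2 == 0 && all(E[aoi] == 0)) {
    return(structure(list(edges = empty, E = E, t_star = Inf,
                          f_pass = empty, nair_pass = empty,
                          n_candidates = 0L, significance = significance,
                          aoi = aoi),
                     class = "edge_map"))
  }
  sigma2 <- max(sigma2, .Machine$double.xmin)
  f_stat <- (b01^2 + b10^2) / (2 * sigma2)
  f_crit <- stats::qf(1 - significance, 2, 2 * n_pool)
  f_pass <- aoi & f_stat > f_crit
  nair_pass <- sign_run_check(b01, b10) & aoi
  cand <- E[aoi]
  grid <- unique(stats::quantile(cand, probs = (50:99) / 100, names = FALSE))
  snr <- vapply(grid, function(t) {
    hi <- cand[cand >= t]; lo <- cand[cand < t]
    if (length(hi) == 0L) return(-Inf)
    s <- if (length(lo) > 1L) stats::sd(lo) else 0
    mean(hi) / (s + 1e-8)
  }, numeric(1))
  t_star <- grid[which.max(snr)]
  edges <- f_pass & nair_pass & E >= t_star
  structure(list(edges = edges, E = E, t_star = t_star, f_pass = f_pass,
                 nair_pass = nair_pass, n_candidates = sum(f_pass),
                 significance = significance, aoi = aoi),
            class = "edge_map")
}

# Nair-type sign-run surrogate: along the direction perpendicular to the
# dominant gradient (i.e. along the putative edge), the dominant coefficient
# must keep a constant nonzero sign over a run of three pixels.
sign_run_check <- function(b01, b10) {
  nr <- nrow(b01); nc <- ncol(b01)
  shift <- function(m, dr, dc) {
    m[pmin(pmax(seq_len(nr) + dr, 1L), nr),
      pmin(pmax(seq_len(nc) + dc, 1L), nc)]
  }
  horiz <- abs(b01) >= abs(b10)      # column-basis gradient dominates
  s01 <- sign(b01); s10 <- sign(b10)
  run01 <- s01 != 0 & shift(s01, -1L, 0L) == s01 & shift(s01, 1L, 0L) == s01
  run10 <- s10 != 0 & shift(s10, 0L, -1L) == s10 & shift(s10, 0L, 1L) == s10
  (horiz & run01) | (!horiz & run10)
}

#' Refine edge regions to closed ROI contours
#'
#' Seeds one region per closed edge component (morphological closing + hole
#' filling of the edge map, lightly eroded so the contour starts inside the
#' boundary) and evolves each with a distance-regularised level set: the
#' update is
#' `mu div(d_p(|grad phi|) grad phi) + lambda delta(phi) div(g grad phi / |grad phi|) + alpha g delta(phi)`
#' with the double-well potential and edge indicator
#' `g = 1 / (1 + |grad G_sigma * I|^2)`.  The distance-regularisation term
#' gives the forward-and-backward diffusion that keeps `phi` close to a
#' signed distance function near its zero level, so no reinitialisation is
#' needed and the scheme tolerates relatively large time steps
#' (`dt * mu < 0.25`).
#'
#' @param image Numeric matrix (the intensity image the edges came from).
#' @param edges An [detect_edges()] result.
#' @param params Optional list overriding the defaults `dt = 1`, `mu = 0.2`,
#'   `lambda = 5`, `alpha = -3`, `epsilon = 1.5`, `sigma = 1.5`, `c0 = 2`,
#'   `max_iter = 300`, `min_area = 30`.
#' @return Object of class `roi_set`: list with `rois` (each with `mask`,
#'   `bbox` `c(row1, row2, col1, col2)` and `area`) and the parameters used.
#' @export
refine_contour <- function(image, edges, params = list()) {
  stopifnot(inherits(edges, "edge_map"))
  p <- utils::modifyList(list(dt = 1, mu = 0.2, lambda = 5, alpha = -3,
                              epsilon = 1.5, sigma = 1.5, c0 = 2,
                              max_iter = 300L, min_area = 30L), params)
  if (p$dt * p$mu >= 0.25)
    stop_field("params", "dt * mu must stay below 0.25 for stability")
  edge_mask <- edges$edges
  if (!any(edge_mask))
    return(structure(list(rois = list(), params = p), class = "roi_set"))
  brush3 <- EBImage::makeBrush(3L, shape = "box")
  closed <- matrix(as.logical(EBImage::closing(edge_mask * 1, brush3)),
                   nrow(edge_mask), ncol(edge_mask))
  filled <- matrix(as.logical(EBImage::fillHull(closed * 1)),
                   nrow(edge_mask), ncol(edge_mask))
  seeds <- filled & !closed          # interiors only, already inside the edge
  seeds <- matrix(as.logical(EBImage::erode(seeds * 1, brush3)),
                  nrow(seeds), ncol(seeds))
  seeds <- seeds & edges$aoi
  labels <- label_components(seeds, connectivity = 4L)
  n_seed <- max(labels)
  if (n_seed == 0L)
    return(structure(list(rois = list(), params = p), class = "roi_set"))
  smoothed <- gauss_blur(image, p$sigma)
  gr <- grad2(smoothed)
  g <- 1 / (1 + gr$x^2 + gr$y^2)
  gg <- grad2(g)
  rois <- list()
  for (k in seq_len(n_seed)) {
    seed <- labels == k
    if (sum(seed) < 4L) next
    phi <- matrix(p$c0, nrow(image), ncol(image))
    phi[seed] <- -p$c0
    phi <- drlse_evolve(phi, g, gg, p)
    final <- phi < 0
    comp <- label_components(final, connectivity = 4L)
    olap <- comp[seed]
    olap <- olap[olap > 0L]
    if (length(olap) == 0L) next
    keep <- as.integer(names(which.max(table(olap))))
    mask <- comp == keep & edges$aoi
    if (sum(mask) < p$min_area) next
    rws <- range(which(apply(mask, 1, any)))
    cls <- range(which(apply(mask, 2, any)))
    rois[[length(rois) + 1L]] <- list(mask = mask,
                                      bbox = c(rws[1], rws[2], cls[1], cls[2]),
                                      area = sum(mask), phi = phi)
  }
  structure(list(rois = rois, params = p), class = "roi_set")
}

# Central-difference gradient with one-sided differences at the borders
# (MATLAB gradient convention).
grad2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)   # x = columns, y = rows
  if (nc > 1) {
    gx[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
    gx[, 1] <- m[, 2] - m[, 1]; gx[, nc] <- m[, nc] - m[, nc - 1]
  }
  if (nr > 1) {
    gy[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
    gy[1, ] <- m[2, ] - m[1, ]; gy[nr, ] <- m[nr, ] - m[nr - 1, ]
  }
  list(x = gx, y = gy)
}

laplacian <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1, 1:(nr - 1)), ]; down <- m[c(2:nr, nr), ]
  left <- m[, c(1, 1:(nc - 1))]; right <- m[, c(2:nc, nc)]
  up + down + left + right - 4 * m
}

neumann_bound <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(1, nr), ] <- m[c(3, nr - 2), ]
  m[, c(1, nc)] <- m[, c(3, nc - 2)]
  m
}

drlse_evolve <- function(phi, g, gg, p) {
  eps <- 1e-10
  for (it in seq_len(p$max_iter)) {
    phi <- neumann_bound(phi)
    gphi <- grad2(phi)
    s <- sqrt(gphi$x^2 + gphi$y^2)
    nx <- gphi$x / (s + eps); ny <- gphi$y / (s + eps)
    # double-well distance regularisation (forward-and-backward diffusion)
    a <- s >= 0 & s <= 1
    ps <- a * sin(2 * pi * s) / (2 * pi) + (!a) * (s - 1)
    dps <- ifelse(ps == 0, 1, ps) / ifelse(s == 0, 1, s)
    dist_reg <- divergence((dps - 1) * gphi$x, (dps - 1) * gphi$y) +
      laplacian(phi)
    dirac <- dirac_eps(phi, p$epsilon)
    edge_term <- dirac * (gg$x * nx + gg$y * ny) +
      dirac * g * divergence(nx, ny)
    area_term <- dirac * g
    phi <- phi + p$dt * (p$mu * dist_reg + p$lambda * edge_term +
                           p$alpha * area_term)
  }
  phi
}

divergence <- function(fx, fy) {
  grad2(fx)$x + grad2(fy)$y
}

dirac_eps <- function(x, epsilon) {
  out <- (1 / (2 * epsilon)) * (1 + cos(pi * x / epsilon))
  out * (abs(x) <= epsilon)
}
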