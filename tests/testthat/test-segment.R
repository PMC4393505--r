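# One noisy single-lesion phantom segmented once for the file.
spec_seg <- phantom_spec(bias_amplitude = 0, noise_sigma = 4,
                         lesions = one_lesion(contrast = 50), seed = 21L)
ph_seg <- generate_phantom(spec_seg)
pre_seg <- preprocess_mammogram(ph_seg$image)
cp_seg <- op_transform(pre_seg$image, pre_seg$aoi$aoi_mask)
edges_seg <- detect_edges(cp_seg, significance = 0.05)
rois_seg <- refine_contour(pre_seg$image, edges_seg)

test_that("the orthogonal-polynomial transform has the expected algebra", {
  # constant image: DC plane reproduces the constant, AC planes vanish
  cpl <- op_transform(matrix(77, 64, 64))
  expect_equal(cpl$planes$b00, matrix(77, 64, 64))
  for (nm in setdiff(names(cpl$planes), "b00"))
    expect_equal(max(abs(cpl$planes[[nm]])), 0)

  # vertical unit step: |b01| peaks on the step column, b10 vanishes there
  step <- cbind(matrix(0, 64, 32), matrix(1, 64, 32))
  cps <- op_transform(step)
  expect_equal(max(abs(cps$planes$b01)), abs(cps$planes$b01[32, 32]))
  expect_equal(cps$planes$b10[32, 32], 0)
  expect_equal(cps$planes$b01[32, 32], 1 / 2)   # <-1,0,1> response to a step

  # linearity
  set.seed(8)
  i1 <- matrix(runif(256, 0, 255), 16, 16)
  i2 <- matrix(runif(256, 0, 255), 16, 16)
  mix <- op_transform(2 * i1 - 3 * i2)
  p1 <- op_transform(i1); p2 <- op_transform(i2)
  for (nm in names(mix$planes))
    expect_equal(mix$planes[[nm]], 2 * p1$planes[[nm]] - 3 * p2$planes[[nm]])
})

test_that("the vectorised transform agrees with a naive double loop", {
  set.seed(15)
  img <- matrix(runif(256, 0, 255), 16, 16)
  fast <- op_transform(img)$planes
  slow <- naive_op_transform(img, mammocad:::op_basis3)
  for (nm in names(fast)) expect_equal(fast[[nm]], slow[[nm]])
})

test_that("constant images give an empty edge map", {
  e <- detect_edges(op_transform(matrix(42, 64, 64)))
  expect_false(any(e$edges))
  expect_identical(e$n_candidates, 0L)
})

test_that("edge detection covers the lesion boundary on a noisy phantom", {
  truth <- ph_seg$truth$lesion_masks[[1]]
  interior <- truth[c(1, 1:(nrow(truth) - 1)), ] &
    truth[c(2:nrow(truth), nrow(truth)), ] &
    truth[, c(1, 1:(ncol(truth) - 1))] & truth[, c(2:ncol(truth), ncol(truth))]
  boundary <- truth & !interior
  near_edge <- edges_seg$edges
  for (k in 1:1) {
    e <- near_edge
    near_edge <- e | e[c(1, 1:(nrow(e) - 1)), ] | e[c(2:nrow(e), nrow(e)), ] |
      e[, c(1, 1:(ncol(e) - 1))] | e[, c(2:ncol(e), ncol(e))]
  }
  expect_gte(mean(near_edge[boundary]), 0.9)
})

test_that("the F test is calibrated on pure noise", {
  set.seed(31)
  noise <- matrix(rnorm(100 * 100, 128, 6), 100, 100)
  e <- detect_edges(op_transform(noise), significance = 0.05)
  n <- 100 * 100
  bounds <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(e$n_candidates, bounds[1])
  expect_lte(e$n_candidates, bounds[2])
})

test_that("the edge threshold maximises the stated SNR objective", {
  E <- edges_seg$E[edges_seg$aoi]
  grid <- unique(quantile(E, (50:99) / 100, names = FALSE))
  snr <- vapply(grid, function(t) {
    hi <- E[E >= t]; lo <- E[E < t]
    if (length(hi) == 0) return(-Inf)
    mean(hi) / ((if (length(lo) > 1) sd(lo) else 0) + 1e-8)
  }, numeric(1))
  expect_equal(edges_seg$t_star, grid[which.max(snr)])
  # edge pixels are exactly the both-test survivors above t*
  expect_identical(edges_seg$edges,
                   edges_seg$f_pass & edges_seg$nair_pass &
                     edges_seg$E >= edges_seg$t_star)
})

test_that("contour refinement recovers the lesion as a single ROI", {
  expect_length(rois_seg$rois, 1L)
  roi <- rois_seg$rois[[1]]
  expect_gte(dice(roi$mask, ph_seg$truth$lesion_masks[[1]]), 0.90)
  expect_true(all(roi$mask <= pre_seg$aoi$aoi_mask))
  expect_gte(roi$area, rois_seg$params$min_area)
})

test_that("refinement keeps a signed-distance profile near the zero level", {
  phi <- rois_seg$rois[[1]]$phi
  g <- mammocad:::grad2(phi)
  s <- sqrt(g$x^2 + g$y^2)
  band <- abs(phi) < rois_seg$params$epsilon
  expect_gte(mean(s[band] >= 0.8 & s[band] <= 1.2), 0.9)
})

test_that("an empty edge map yields an empty ROI set, deterministically", {
  e <- detect_edges(op_transform(matrix(42, 64, 64)))
  out <- refine_contour(matrix(42, 64, 64), e)
  expect_length(out$rois, 0L)
  # determinism of the full stage
  again <- refine_contour(pre_seg$image, edges_seg)
  expect_identical(lapply(again$rois, `[[`, "mask"),
                   lapply(rois_seg$rois, `[[`, "mask"))
})
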