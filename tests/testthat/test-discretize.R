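test_that("a separable feature gets one boundary cut and zero inconsistency", {
  mat <- matrix(c(1, 2, 9, 10), ncol = 1, dimnames = list(NULL, "f"))
  sch <- fit_discretization(mat, c("a", "a", "b", "b"))
  expect_equal(sch$features$f$cuts, 5.5)
  expect_equal(sch$features$f$inconsistency, 0)
  expect_true(sch$features$f$selected)
})

test_that("single-class labels yield zero cuts and universal selection", {
  set.seed(2)
  mat <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  sch <- fit_discretization(mat, rep("only", 10))
  expect_equal(sch$avg_inconsistency, 0)
  for (f in sch$features) {
    expect_length(f$cuts, 0)
    expect_true(f$selected)
  }
})

test_that("fitted inconsistency equals brute-force hash-group conflict counts", {
  set.seed(13)
  n <- 40
  mat <- cbind(sig = c(rnorm(n / 2, 0), rnorm(n / 2, 3)),
               noise = rnorm(n))
  labels <- rep(c("neg", "pos"), each = n / 2)
  sch <- fit_discretization(mat, labels, max_cuts = 4)
  for (nm in colnames(mat)) {
    bins <- findInterval(mat[, nm], sch$features[[nm]]$cuts)
    expect_equal(sch$features[[nm]]$inconsistency,
                 brute_inconsistency(as.character(bins), labels))
  }
  # the informative feature is selected, and greedy growth never added a
  # cut that failed to reduce inconsistency
  expect_true(sch$features$sig$selected)
  expect_lte(sch$features$sig$inconsistency, sch$avg_inconsistency)
})

test_that("greedy refinement is monotone and matches exhaustive search on one cut", {
  set.seed(4)
  v <- runif(24, 0, 10)
  labels <- ifelse(v < 4.2, "lo", "hi")
  labels[3] <- "hi"    # one conflict
  mat <- matrix(v, ncol = 1, dimnames = list(NULL, "f"))
  sch <- fit_discretization(mat, labels, max_cuts = 1)
  # exhaustive: best single boundary cut
  cand <- mammocad:::candidate_cuts(v, labels)
  incs <- vapply(cand, function(ct)
    mammocad:::feature_inconsistency(v, labels, ct), numeric(1))
  expect_equal(sch$features$f$inconsistency, min(incs))
  base <- mammocad:::feature_inconsistency(v, labels, numeric(0))
  expect_lte(sch$features$f$inconsistency, base)
})

test_that("itemization respects intervals, selection and the keyword path", {
  # `f` separates the classes with one cut; `jumpy` needs two cuts, so
  # the parsimony criterion (cut count at or below average) drops it
  mat <- matrix(c(1, 2, 9, 10, 3, 9, 4, 8), ncol = 2,
                dimnames = list(NULL, c("f", "jumpy")))
  sch <- fit_discretization(mat, c("a", "a", "b", "b"))
  expect_true(sch$features$f$selected)
  expect_false(sch$features$jumpy$selected)
  # interval lookup with right-open intervals; ties at a cut go right
  expect_identical(apply_discretization(sch, c(f = 2, jumpy = 5)), "f=0")
  expect_identical(apply_discretization(sch, c(f = 7, jumpy = 5)), "f=1")
  expect_identical(apply_discretization(sch, c(f = 5.5, jumpy = 5)), "f=1")
  # unselected features contribute no items; keywords appended verbatim
  its <- apply_discretization(sch, c(f = 2, jumpy = 5),
                              keywords = c("K2", "K1"))
  expect_identical(its, sort(c("f=0", "K1", "K2")))
  # out-of-range values clamp with a warning
  expect_warning(apply_discretization(sch, c(f = 99, jumpy = 5)), "clamped")
})

test_that("re-applying a scheme to its training rows reproduces the pattern table", {
  set.seed(9)
  labels <- sample(c("a", "b"), 20, replace = TRUE)
  mat <- cbind(x = ifelse(labels == "a", 0, 5) + runif(20),
               y = runif(20), z = runif(20))
  sch <- fit_discretization(mat, labels, max_cuts = 3)
  items <- itemize_features(sch, mat)
  sel <- names(sch$features)[vapply(sch$features, `[[`, logical(1),
                                    "selected")]
  expect_gte(length(sel), 1L)
  for (nm in sel) {
    bins <- findInterval(mat[, nm], sch$features[[nm]]$cuts)
    from_items <- vapply(items, function(it) {
      tok <- grep(sprintf("^%s=", nm), it, value = TRUE)
      as.integer(sub(".*=", "", tok))
    }, integer(1))
    expect_identical(from_items, as.integer(bins))
  }
})

test_that("schemes round-trip through JSON", {
  mat <- matrix(c(1, 2, 9, 10), ncol = 1, dimnames = list(NULL, "f"))
  sch <- fit_discretization(mat, c("a", "a", "b", "b"))
  path <- withr::local_tempfile(fileext = ".json")
  write_discretization(sch, path)
  back <- read_discretization(path)
  expect_equal(back$features$f$cuts, sch$features$f$cuts)
  expect_equal(back$avg_inconsistency, sch$avg_inconsistency)
  expect_identical(apply_discretization(back, c(f = 7)),
                   apply_discretization(sch, c(f = 7)))
})
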