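test_that("FP-growth supports equal powerset enumeration on random cohorts", {
  set.seed(17)
  universe <- c(sprintf("i%02d", 1:10), "KA", "KB")
  for (rep in 1:4) {
    trs <- lapply(1:15, function(i)
      sort(sample(universe, sample(2:6, 1))))
    for (minsup in c(0.1, 0.25)) {
      mined <- mine_frequent(trs, minsup)
      oracle <- powerset_frequent(trs, minsup)
      expect_identical(nrow(mined), length(oracle))
      for (i in seq_len(nrow(mined))) {
        key <- paste(mined$items[[i]], collapse = "\x1f")
        expect_equal(mined$support[i], oracle[[key]], info = key)
      }
    }
  }
})

test_that("degenerate mining inputs behave as specified", {
  trs <- list(c("a", "b"), c("a"), c("b", "c"))
  # threshold above any attainable support
  expect_identical(nrow(mine_frequent(trs, 0.99)), 0L)
  expect_error(mine_frequent(list(), 0.5), "nonempty")
  # duplicating every transaction leaves support fractions unchanged
  m1 <- mine_frequent(trs, 0.3)
  m2 <- mine_frequent(c(trs, trs), 0.3)
  expect_equal(m1$support, m2$support)
  expect_identical(m1$items, m2$items)
})

test_that("a single frequent body-keyword itemset yields exactly one rule", {
  trs <- list(c("a", "K"), c("a", "K"), c("a", "K"), c("b"))
  rb <- mine_rulebase(trs, keywords = "K", minsup = 0.5, minconf = 0.8)
  expect_length(rb$rules, 1L)
  expect_identical(rb$rules[[1]]$body, "a")
  expect_identical(rb$rules[[1]]$head, "K")
  expect_equal(rb$rules[[1]]$support, 0.75)
  expect_equal(rb$rules[[1]]$confidence, 1)
})

test_that("the representative set is a cover-complete antichain", {
  set.seed(23)
  keywords <- c("KA", "KB")
  items <- sprintf("i%d", 1:6)
  for (rep in 1:3) {
    trs <- lapply(1:20, function(i)
      unique(c(sample(items, sample(1:4, 1)),
               sample(keywords, sample(1:2, 1)))))
    freq <- mine_frequent(trs, 0.1)
    rb <- derive_representative(freq, 0.6, keywords)
    # rebuild the full confident candidate set independently
    cands <- list()
    for (i in seq_len(nrow(freq))) {
      z <- freq$items[[i]]
      body <- setdiff(z, keywords); head <- intersect(z, keywords)
      if (length(body) == 0 || length(head) == 0) next
      bk <- paste(sort(body), collapse = "\x1f")
      bsup <- NA_real_
      for (j in seq_len(nrow(freq)))
        if (paste(freq$items[[j]], collapse = "\x1f") == bk)
          bsup <- freq$support[j]
      if (is.na(bsup)) next
      conf <- freq$support[i] / bsup
      if (conf >= 0.6 - 1e-12)
        cands[[length(cands) + 1]] <- list(body = sort(body),
                                           head = sort(head),
                                           support = freq$support[i],
                                           confidence = conf)
    }
    in_cover <- function(r, s) mammocad:::rule_in_cover(r, s) ||
      (identical(r$body, s$body) && identical(r$head, s$head))
    # antichain: no retained rule in the cover of another retained rule
    for (a in rb$rules) for (b in rb$rules) {
      if (!identical(a, b)) expect_false(mammocad:::rule_in_cover(a, b))
    }
    # completeness: every confident candidate is covered by a retained rule
    for (cand in cands) {
      expect_true(any(vapply(rb$rules, function(r) in_cover(cand, r),
                             logical(1))))
    }
  }
})

test_that("planted rules are recovered from a noiseless cohort", {
  spec <- planted_cohort_spec(n = 60, noise_rate = 0, seed = 7L)
  coh <- generate_transactions(spec)
  rb <- mine_rulebase(coh, spec$keywords, minsup = 0.3, minconf = 0.8)
  for (rule in spec$planted_rules) {
    found <- any(vapply(rb$rules, function(r)
      identical(r$body, sort(rule$body)) &&
        all(rule$head %in% r$head), logical(1)))
    expect_true(found, info = paste(rule$body, collapse = "+"))
  }
})

test_that("rule ordering is total and deterministic", {
  spec <- planted_cohort_spec(n = 50, noise_rate = 0.05, seed = 19L)
  coh <- generate_transactions(spec)
  rb1 <- mine_rulebase(coh, spec$keywords, minsup = 0.1, minconf = 0.7)
  rb2 <- mine_rulebase(coh, spec$keywords, minsup = 0.1, minconf = 0.7)
  expect_identical(rb1$rules, rb2$rules)
  sups <- vapply(rb1$rules, `[[`, numeric(1), "support")
  expect_true(all(diff(sups) <= 1e-12))
})

test_that("rule bases round-trip through JSON and invalid files are rejected", {
  spec <- planted_cohort_spec(n = 30, noise_rate = 0, seed = 3L)
  rb <- mine_rulebase(generate_transactions(spec), spec$keywords,
                      minsup = 0.3, minconf = 0.8)
  path <- withr::local_tempfile(fileext = ".json")
  save_rulebase(rb, path)
  back <- load_rulebase(path)
  expect_equal(back$rules, rb$rules)
  expect_equal(back$minconf, rb$minconf)

  # empty rule base round-trips
  empty <- derive_representative(mine_frequent(list("a", "b"), 0.9), 0.9, "K")
  save_rulebase(empty, path)
  expect_length(load_rulebase(path)$rules, 0L)

  # hand-edited violation of body/head disjointness
  bad <- list(items = list("a", "K"), minsup = 0.1, minconf = 0.8,
              rules = list(list(body = c("a", "K"), head = "K",
                                support = 0.5, confidence = 0.9)))
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(load_rulebase(path), "intersect")
  writeLines("{not json", path)
  expect_error(load_rulebase(path), "malformed")
})
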