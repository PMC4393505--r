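test_that("match status distinguishes full, partial and non-matches", {
  rule <- list(body = c("a", "b"), head = "K")
  expect_identical(match_status(rule, c("a", "b", "c")), "full")
  expect_identical(match_status(rule, c("a", "c")), "partial")
  expect_identical(match_status(rule, "c"), "none")
  expect_error(match_status(list(body = character(0)), "a"), "nonempty")
})

test_that("condition 1 accepts a head with two full matches out of three rules", {
  rb <- make_rulebase(list(
    list(body = c("a", "b"), head = "Circum Benign"),
    list(body = c("a", "c"), head = "Circum Benign"),
    list(body = c("x", "y"), head = "Circum Benign")))
  sc <- score_head(rb, "Circum Benign", c("a", "b", "c"),
                   alpha = 2 / 3, delta = 0.5)
  expect_true(sc$accepted)
  expect_identical(sc$condition, 1L)
  expect_equal(sc$weight, 2 / 3)
  expect_identical(c(sc$nM, sc$nP, sc$nN), c(2L, 0L, 1L))
})

test_that("condition 2 accepts on partial matches when condition 1 fails", {
  rb <- make_rulebase(list(
    list(body = c("a", "b"), head = "Circum Benign"),
    list(body = c("a", "z"), head = "Circum Benign"),
    list(body = c("x", "y"), head = "Circum Benign")))
  sc <- score_head(rb, "Circum Benign", c("a", "b"),
                   alpha = 0.75, delta = 2 / 3)
  expect_true(sc$accepted)
  expect_identical(sc$condition, 2L)
  expect_equal(sc$weight, 2 / 3)
  expect_identical(c(sc$nM, sc$nP, sc$nN), c(1L, 1L, 1L))
})

test_that("an unknown head or empty rule base rejects with zero counts", {
  rb <- make_rulebase(list(list(body = "a", head = "K")))
  sc <- score_head(rb, "Q", c("a"))
  expect_false(sc$accepted)
  expect_identical(c(sc$nM, sc$nP, sc$nN), c(0L, 0L, 0L))
  empty <- make_rulebase(list())
  sc2 <- score_head(empty, "K", "a")
  expect_false(sc2$accepted)
  expect_equal(sc2$weight, 0)
})

test_that("when every body matches, all heads are accepted with weight 1", {
  rb <- make_rulebase(list(
    list(body = "a", head = "K1"),
    list(body = c("a", "b"), head = "K2"),
    list(body = "b", head = c("K1", "K2"))))
  d <- diagnose(rb, c("a", "b"))
  expect_length(d$accepted, 3L)
  for (e in d$accepted) {
    expect_equal(e$weight, 1)
    expect_identical(e$condition, 1L)
  }
})

test_that("diagnosis agrees head-for-head with an independent brute-force scorer", {
  set.seed(41)
  items <- sprintf("i%d", 1:8)
  heads <- list("KA", "KB", c("KA", "KB"), "KC")
  for (rep in 1:6) {
    rules <- lapply(seq_len(sample(5:20, 1)), function(i)
      list(body = sort(sample(items, sample(1:4, 1))),
           head = heads[[sample(length(heads), 1)]]))
    rb <- make_rulebase(rules)
    test_items <- sort(sample(items, sample(1:5, 1)))
    alpha <- runif(1, 0.2, 0.9); delta <- runif(1, 0.2, 0.9)
    d <- diagnose(rb, test_items, alpha, delta)
    accepted_keys <- vapply(d$accepted, function(e)
      paste(e$head, collapse = "\x1f"), character(1))
    for (h in unique(lapply(rules, function(r) sort(r$head)))) {
      oracle <- brute_score_head(rb$rules, h, test_items, alpha, delta)
      key <- paste(h, collapse = "\x1f")
      expect_identical(key %in% accepted_keys, oracle$accepted, info = key)
      if (oracle$accepted) {
        e <- d$accepted[[match(key, accepted_keys)]]
        expect_equal(e$weight, oracle$weight)
        expect_identical(e$condition, oracle$condition)
      }
    }
  }
})

test_that("weights are bounded and monotone in the stated senses", {
  set.seed(53)
  items <- sprintf("i%d", 1:6)
  for (rep in 1:10) {
    rules <- lapply(1:8, function(i)
      list(body = sort(sample(items, sample(1:3, 1))), head = "K"))
    rb <- make_rulebase(rules)
    test_items <- sort(sample(items, 3))
    sc <- score_head(rb, "K", test_items, alpha = 1, delta = 1)
    w1 <- if (sc$nM + sc$nN > 0) sc$nM / (sc$nM + sc$nN) else 0
    w2 <- if (sc$nM + sc$nP + sc$nN > 0)
      (sc$nM + sc$nP) / (sc$nM + sc$nP + sc$nN) else 0
    expect_gte(w1, 0); expect_lte(w1, 1)
    expect_gte(w2, 0); expect_lte(w2, 1)
    if (sc$nP > 0 && sc$nM + sc$nN > 0) expect_gte(w2, w1)
    # a new fully matching rule never lowers w1
    rb2 <- make_rulebase(c(rules, list(list(body = test_items[1],
                                            head = "K"))))
    sc2 <- score_head(rb2, "K", test_items, alpha = 1, delta = 1)
    w1b <- if (sc2$nM + sc2$nN > 0) sc2$nM / (sc2$nM + sc2$nN) else 0
    expect_gte(w1b, w1)
  }
})

test_that("raising alpha or delta never enlarges the accepted set", {
  set.seed(67)
  items <- sprintf("i%d", 1:6)
  rules <- lapply(1:12, function(i)
    list(body = sort(sample(items, sample(1:3, 1))),
         head = sample(c("KA", "KB"), 1)))
  rb <- make_rulebase(rules)
  test_items <- sort(sample(items, 3))
  grid <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  sizes <- outer(grid, grid, Vectorize(function(a, d)
    length(diagnose(rb, test_items, a, d)$accepted)))
  expect_true(all(diff(sizes[, 1]) <= 0))          # alpha rising
  expect_true(all(diff(sizes[1, ]) <= 0))          # delta rising
})

test_that("accepted heads are sorted by weight with the documented tie-breaks", {
  rb <- make_rulebase(list(
    list(body = "a", head = "K1"),
    list(body = "a", head = "K2"),
    list(body = "b", head = "K2"),
    list(body = c("a", "c"), head = "K3")))
  d <- diagnose(rb, c("a"), alpha = 0.9, delta = 0.4)
  w <- vapply(d$accepted, `[[`, numeric(1), "weight")
  expect_true(all(diff(w) <= 1e-12))
  path <- withr::local_tempfile(fileext = ".json")
  write_diagnosis(d, path, test_id = "t1")
  rep <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_identical(rep$test_id, "t1")
  expect_length(rep$accepted, length(d$accepted))
})
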