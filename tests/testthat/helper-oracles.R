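# Shared fixtures and independent brute-force oracles used across the suite.

dice <- function(a, b) {
  d <- sum(a) + sum(b)
  if (d == 0) return(1)
  2 * sum(a & b) / d
}

# -- phantom fixtures --------------------------------------------------------

clean_phantom_spec <- function(lesions = list(), seed = 1L, ...) {
  phantom_spec(bias_amplitude = 0, noise_sigma = 0, lesions = lesions,
               seed = seed, ...)
}

one_lesion <- function(margin = "circumscribed", center = c(70, 40),
                       radius = 9, contrast = 55) {
  list(list(center = center, radius = radius, contrast = contrast,
            margin = margin))
}

# Analytic pectoral geometry used by generate_phantom: boundary line through
# the chest-wall point at 30% height, tilted pectoral_angle from vertical,
# in 1-based matrix coordinates with 0-based columns measured from col 1.
pectoral_boundary_col <- function(spec, row) {
  1 + tan(spec$pectoral_angle * pi / 180) * (0.30 * spec$height - row)
}
pectoral_boundary_row <- function(spec, col) {
  0.30 * spec$height - (col - 1) / tan(spec$pectoral_angle * pi / 180)
}

# -- brute-force oracles -----------------------------------------------------

# All frequent itemsets by powerset enumeration (universes up to ~12 items).
powerset_frequent <- function(transactions, minsup) {
  transactions <- lapply(transactions, function(tr) {
    if (is.list(tr)) sort(unique(c(tr$items, tr$keywords)))
    else sort(unique(tr))
  })
  universe <- sort(unique(unlist(transactions)))
  stopifnot(length(universe) <= 14L)
  n <- length(transactions)
  out <- list()
  for (bits in seq_len(2^length(universe) - 1L)) {
    subset <- universe[bitwAnd(bits, 2^(seq_along(universe) - 1L)) > 0]
    cnt <- sum(vapply(transactions, function(tr) all(subset %in% tr),
                      logical(1)))
    if (cnt / n >= minsup - 1e-9)
      out[[paste(subset, collapse = "\x1f")]] <- cnt / n
  }
  out
}

# GLCM by explicit enumeration of co-occurring pairs (symmetric, normalised).
brute_glcm <- function(q, dr, dc, levels = 8L) {
  m <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    r2 <- r + dr; c2 <- cc + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- q[r, cc]; b <- q[r2, c2]
    if (is.na(a) || is.na(b)) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  if (sum(m) == 0) return(NULL)
  m / sum(m)
}

# Inconsistency by hash-group conflict counting over pattern keys.
brute_inconsistency <- function(patterns, classes) {
  n <- length(classes)
  conflicts <- 0
  for (key in unique(patterns)) {
    cls <- classes[patterns == key]
    conflicts <- conflicts + length(cls) - max(table(cls))
  }
  conflicts / n
}

# Independent head scorer: recount matches directly from the rule list.
brute_score_head <- function(rules, h, test, alpha, delta) {
  hk <- paste(sort(h), collapse = "\x1f")
  nM <- 0L; nP <- 0L; nN <- 0L
  for (r in rules) {
    if (paste(sort(r$head), collapse = "\x1f") != hk) next
    hit <- sum(r$body %in% test)
    if (hit == length(r$body)) nM <- nM + 1L
    else if (hit > 0L) nP <- nP + 1L
    else nN <- nN + 1L
  }
  w1 <- if (nM + nN > 0) nM / (nM + nN) else 0
  if (w1 >= alpha)
    return(list(accepted = TRUE, weight = w1, condition = 1L))
  w2 <- if (nM + nP + nN > 0) (nM + nP) / (nM + nP + nN) else 0
  if (w2 >= delta)
    return(list(accepted = TRUE, weight = w2, condition = 2L))
  list(accepted = FALSE, weight = max(w1, w2), condition = NA_integer_)
}

# Naive per-window inner-product transform (replicated borders) for a
# separable orthogonal basis; oracle for the vectorised implementation.
naive_op_transform <- function(image, basis) {
  k <- length(basis[[1]]); half <- (k - 1) %/% 2
  nr <- nrow(image); nc <- ncol(image)
  planes <- list()
  for (i in seq_along(basis)) for (j in seq_along(basis)) {
    O <- outer(basis[[i]], basis[[j]])
    plane <- matrix(0, nr, nc)
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      win <- matrix(0, k, k)
      for (a in seq_len(k)) for (b in seq_len(k)) {
        rr <- min(max(r + a - 1 - half, 1), nr)
        cb <- min(max(cc + b - 1 - half, 1), nc)
        win[a, b] <- image[rr, cb]
      }
      plane[r, cc] <- sum(win * O) / sum(O * O)
    }
    planes[[sprintf("b%d%d", i - 1, j - 1)]] <- plane
  }
  planes
}

# Build a small rule base directly (bypassing mining) for engine tests.
make_rulebase <- function(rules, minsup = 0.05, minconf = 0.8) {
  rules <- lapply(rules, function(r) {
    list(body = sort(r$body), head = sort(r$head),
         support = if (is.null(r$support)) 0.2 else r$support,
         confidence = if (is.null(r$confidence)) 0.9 else r$confidence)
  })
  structure(list(rules = rules, minsup = minsup, minconf = minconf,
                 items = sort(unique(unlist(lapply(rules, function(r)
                   c(r$body, r$head)))))),
            class = "rulebase")
}

# Two-rule planted cohort used by the recovery experiments.
planted_cohort_spec <- function(n, noise_rate, seed) {
  transaction_cohort_spec(
    n_transactions = n, item_universe = 12L,
    keyword_universe = c("Benign finding", "Invasive ductal cancer"),
    planted_rules = list(
      list(body = c("item001", "item002"), head = "Benign finding",
           penetrance = 1),
      list(body = c("item005", "item006"), head = "Invasive ductal cancer",
           penetrance = 1)),
    noise_rate = noise_rate, seed = seed)
}
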