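#' Specify a synthetic mammogram phantom
#'
#' Builds the parameter object consumed by [generate_phantom()].  The phantom
#' emulates the structure of a canonical left-oriented MLO mammogram: a dark
#' background, a semi-elliptical breast profile attached to the left edge
#' (chest wall), a brighter pectoral-muscle wedge anchored at the top-left
#' corner, optional lesions, a smooth multiplicative bias field and additive
#' Gaussian noise.
#'
#' The breast profile is a semi-ellipse centred on the chest wall at 45% of
#' the image height; with the default vertical semi-axis it is clipped by the
#' top edge so breast tissue reaches row 0, as in an MLO view.  The pectoral
#' boundary is the straight line through the chest-wall point at 30% of the
#' image height, tilted `pectoral_angle` degrees from vertical.
#'
#' @param width,height Image size in pixels (at least 64).
#' @param breast_axes Semi-ellipse semi-axes `c(rows, cols)` in pixels.
#' @param pectoral_angle Pectoral boundary angle from vertical, degrees.
#' @param pectoral_intensity,breast_intensity,background_intensity Gray
#'   levels in `[0, 255]`.
#' @param lesions List of lesions, each a list with fields `center`
#'   (`c(row, col)`, 1-based), `radius` (pixels), `contrast` (gray-level
#'   delta) and `margin` (one of `"circumscribed"`, `"indistinct"`,
#'   `"spiculated"`).
#' @param bias_amplitude Peak gray-level deviation of the multiplicative
#'   bias field at full-scale intensity.
#' @param noise_sigma Standard deviation of the additive Gaussian noise in
#'   gray levels.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 128L, height = 128L,
                         breast_axes = c(0.50 * height, 0.45 * width),
                         pectoral_angle = 25,
                         pectoral_intensity = 190,
                         breast_intensity = 120,
                         background_intensity = 10,
                         lesions = list(),
                         bias_amplitude = 8,
                         noise_sigma = 3,
                         seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               breast_axes = as.numeric(breast_axes),
               pectoral_angle = as.numeric(pectoral_angle),
               pectoral_intensity = as.numeric(pectoral_intensity),
               breast_intensity = as.numeric(breast_intensity),
               background_intensity = as.numeric(background_intensity),
               lesions = lesions,
               bias_amplitude = as.numeric(bias_amplitude),
               noise_sigma = as.numeric(noise_sigma),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  phantom_geometry(spec)   # also checks lesion placement invariants
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$width < 64L) stop_field("width", "must be >= 64")
  if (spec$height < 64L) stop_field("height", "must be >= 64")
  if (length(spec$breast_axes) != 2L || any(spec$breast_axes <= 0))
    stop_field("breast_axes", "must be two positive semi-axes")
  for (f in c("pectoral_intensity", "breast_intensity",
              "background_intensity")) {
    v <- spec[[f]]
    if (!is.finite(v) || v < 0 || v > 255)
      stop_field(f, "must lie in [0, 255]")
  }
  if (spec$bias_amplitude < 0) stop_field("bias_amplitude", "must be >= 0")
  if (spec$noise_sigma < 0) stop_field("noise_sigma", "must be >= 0")
  margins <- c("circumscribed", "indistinct", "spiculated")
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    if (!all(c("center", "radius", "contrast", "margin") %in% names(les)))
      stop_field("lesions", sprintf("lesion %d is missing fields", i))
    if (les$radius <= 0)
      stop_field("lesions", sprintf("lesion %d radius must be > 0", i))
    if (!les$margin %in% margins)
      stop_field("lesions", sprintf("lesion %d margin must be one of %s",
                                    i, paste(margins, collapse = ", ")))
  }
  invisible(spec)
}

# Analytic geometry shared by image and truth masks.  Row/col grids are
# 1-based matrix indices.
phantom_geometry <- function(spec) {
  h <- spec$height; w <- spec$width
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  r0 <- 0.45 * h                       # breast ellipse centre row
  breast <- ((r - r0) / spec$breast_axes[1])^2 +
    ((cc - 1) / spec$breast_axes[2])^2 <= 1
  rp <- 0.30 * h                       # pectoral line chest-wall anchor
  slope <- tan(spec$pectoral_angle * pi / 180)
  pectoral <- (cc - 1) <= slope * (rp - r)
  pectoral <- pectoral & breast
  lesion_masks <- lapply(spec$lesions, function(les) {
    d2 <- (r - les$center[1])^2 + (cc - les$center[2])^2
    d2 <= les$radius^2
  })
  for (i in seq_along(lesion_masks)) {
    if (any(lesion_masks[[i]] & !breast))
      stop_field("lesions", sprintf("lesion %d extends outside the breast", i))
    if (any(lesion_masks[[i]] & pectoral))
      stop_field("lesions", sprintf("lesion %d overlaps the pectoral muscle", i))
  }
  list(breast = breast, pectoral = pectoral, lesions = lesion_masks,
       r = r, c = cc)
}

# Radial intensity profile for the three margin types.  The ground-truth
# mask is always the core disc of the stated radius; margins change only
# how intensity falls off (and, for spiculated, adds spikes beyond it).
lesion_profile <- function(les, r, cc) {
  d <- sqrt((r - les$center[1])^2 + (cc - les$center[2])^2)
  R <- les$radius
  switch(les$margin,
    circumscribed = les$contrast * (d <= R),
    indistinct = les$contrast * exp(-4 * (d / R)^2) * (d <= 2 * R),
    spiculated = {
      theta <- atan2(r - les$center[1], cc - les$center[2])
      spikes <- (d > R & d <= 1.6 * R) & (cos(8 * theta) > 0.6)
      les$contrast * ((d <= R) + 0.8 * spikes)
    })
}

#' Generate a synthetic mammogram with ground truth
#'
#' Deterministic for a fixed spec (including its seed): the image is
#' background + breast profile + pectoral wedge + lesions, modulated by a
#' smooth multiplicative bias field, plus additive Gaussian noise, clipped
#' to `[0, 255]`.  Truth masks are the analytic shapes before bias/noise.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (numeric matrix) and `truth`, a list holding
#'   `breast_mask`, `pectoral_mask`, `lesion_masks` and `keywords` (diagnosis
#'   keywords consistent with the lesion margins).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  img <- matrix(spec$background_intensity, spec$height, spec$width)
  img[geom$breast] <- spec$breast_intensity
  img[geom$pectoral] <- spec$pectoral_intensity
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    img <- img + lesion_profile(les, geom$r, geom$c)
  }
  if (spec$bias_amplitude > 0) {
    # low-order 2-D polynomial, rescaled to [-1, 1]
    u <- (geom$r / spec$height) - 0.5
    v <- (geom$c / spec$width) - 0.5
    b <- u * v + 0.5 * (u^2 - v^2) + 0.25 * u
    b <- b / max(abs(b))
    img <- img * (1 + spec$bias_amplitude * b / 255)
  }
  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                              nrow(img), ncol(img)))
    img <- img + noise
  }
  img <- pmin(pmax(img, 0), 255)
  keywords <- unique(unlist(lapply(spec$lesions, function(les)
    switch(les$margin,
           circumscribed = c("Mass circumscribed", "Benign finding"),
           indistinct = c("Mass indistinct", "Suspicious abnormality"),
           spiculated = c("Mass spiculated", "Highly suggestive of malignancy")))))
  truth <- list(breast_mask = geom$breast, pectoral_mask = geom$pectoral,
                lesion_masks = geom$lesions,
                keywords = if (is.null(keywords)) character(0) else keywords)
  list(image = img, truth = truth)
}

#' Specify a synthetic labeled transaction cohort
#'
#' Defines a cohort of itemset transactions with planted association rules,
#' emulating the itemized training database consumed by the rule miner.
#'
#' @param n_transactions Number of transactions.
#' @param item_universe Number of feature items (named `item001`, ...), or a
#'   character vector of item names.
#' @param keyword_universe Character vector of diagnosis keyword items.
#' @param planted_rules List of rules, each a list with `body` (character
#'   vector of feature items), `head` (character vector of keywords) and
#'   `penetrance` (probability the body is present in a transaction carrying
#'   that rule's label).
#' @param noise_rate Probability that each feature item's presence is
#'   flipped, independently, after planting.
#' @param seed Integer seed.
#' @return An object of class `transaction_cohort_spec`.
#' @export
transaction_cohort_spec <- function(n_transactions, item_universe,
                                    keyword_universe, planted_rules,
                                    noise_rate = 0, seed = 1L) {
  items <- if (is.character(item_universe)) item_universe
           else sprintf("item%03d", seq_len(item_universe))
  spec <- list(n_transactions = as.integer(n_transactions),
               items = items,
               keywords = as.character(keyword_universe),
               planted_rules = planted_rules,
               noise_rate = as.numeric(noise_rate),
               seed = as.integer(seed))
  class(spec) <- "transaction_cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_transactions < 1L)
    stop_field("n_transactions", "must be >= 1")
  if (length(spec$planted_rules) == 0L)
    stop_field("planted_rules", "must contain at least one rule")
  if (spec$noise_rate < 0 || spec$noise_rate > 1)
    stop_field("noise_rate", "must lie in [0, 1]")
  for (i in seq_along(spec$planted_rules)) {
    rule <- spec$planted_rules[[i]]
    if (!all(c("body", "head") %in% names(rule)))
      stop_field("planted_rules", sprintf("rule %d needs body and head", i))
    pen <- if (is.null(rule$penetrance)) 1 else rule$penetrance
    if (pen < 0 || pen > 1)
      stop_field("planted_rules", sprintf("rule %d penetrance not in [0,1]", i))
    if (!all(rule$body %in% spec$items))
      stop_field("planted_rules",
                 sprintf("rule %d body has items outside the universe", i))
    if (!all(rule$head %in% spec$keywords))
      stop_field("planted_rules",
                 sprintf("rule %d head has keywords outside the universe", i))
  }
  invisible(spec)
}

#' Generate a labeled transaction cohort with planted rules
#'
#' Each transaction picks one planted rule uniformly at random, includes its
#' full body with probability `penetrance`, takes the rule's head as its
#' keyword label, and then flips each feature item's presence independently
#' at `noise_rate`.  Deterministic under the spec's seed.
#'
#' @param spec A [transaction_cohort_spec()].
#' @return List of transactions, each a list with `items` (sorted character
#'   vector), `keywords` (the label) and `rule` (index of the planted rule).
#' @export
generate_transactions <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n_rules <- length(spec$planted_rules)
    lapply(seq_len(spec$n_transactions), function(i) {
      k <- sample.int(n_rules, 1L)
      rule <- spec$planted_rules[[k]]
      pen <- if (is.null(rule$penetrance)) 1 else rule$penetrance
      present <- spec$items %in% rule$body &
        stats::runif(1) <= pen
      if (spec$noise_rate > 0) {
        flips <- stats::runif(length(spec$items)) < spec$noise_rate
        present <- xor(present, flips)
      }
      list(items = sort(spec$items[present]),
           keywords = sort(as.character(rule$head)),
           rule = k)
    })
  })
}

#' Write / read a transaction cohort as JSON lines
#'
#' One transaction per line: `{"items": [...], "keywords": [...]}`.
#'
#' @param cohort List of transactions as returned by
#'   [generate_transactions()].
#' @param path Output path.
#' @return `path` invisibly; `read_cohort_jsonl()` returns the cohort list.
#' @export
write_cohort_jsonl <- function(cohort, path) {
  lines <- vapply(cohort, function(tr) {
    jsonlite::toJSON(list(items = as.character(tr$items),
                          keywords = as.character(tr$keywords)))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cohort_jsonl
#' @export
read_cohort_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    list(items = sort(as.character(x$items)),
         keywords = sort(as.character(x$keywords)))
  })
}
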