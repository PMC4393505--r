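# Joint feature selection and discretization.  For every feature, boundary
# cut points are grown greedily to minimise that feature's inconsistency
# (pattern count minus majority-class count, summed over patterns, over N);
# a feature is then selected iff its inconsistency and its cut count are
# both at or below the global averages.

canonical_label <- function(keywords) paste(sort(keywords), collapse = "|")

# Inconsistency of one feature under a set of cuts: instances falling in the
# same interval but carrying different class labels, counted as
# sum_patterns (count - majority count) / N.
feature_inconsistency <- function(values, classes, cuts) {
  bins <- findInterval(values, cuts)
  n <- length(values)
  conflicts <- 0L
  for (b in unique(bins)) {
    cls <- classes[bins == b]
    conflicts <- conflicts + length(cls) - max(tabulate(factor(cls)))
  }
  conflicts / n
}

# Boundary candidate cuts: midpoints between consecutive distinct sorted
# values whose adjacent value-groups are not label-pure for a single class.
candidate_cuts <- function(values, classes) {
  ord <- order(values)
  v <- values[ord]; y <- classes[ord]
  uv <- unique(v)
  if (length(uv) < 2L) return(numeric(0))
  cuts <- numeric(0)
  for (i in seq_len(length(uv) - 1L)) {
    left <- unique(y[v == uv[i]])
    right <- unique(y[v == uv[i + 1L]])
    if (length(unique(c(left, right))) > 1L)
      cuts <- c(cuts, (uv[i] + uv[i + 1L]) / 2)
  }
  cuts
}

#' Fit a joint feature-selection and discretization scheme
#'
#' For each feature, candidate cuts are the class-boundary midpoints of the
#' sorted values; cuts are added greedily, each step taking the candidate
#' that most decreases the feature's inconsistency (ties broken by the
#' lower cut value), stopping at zero inconsistency, no improvement, or
#' `max_cuts`.  With per-feature inconsistency `I_f` and cut count `C_f`,
#' the global averages `I-bar` and `C-bar` are taken over all features and
#' a feature is selected iff `I_f <= I-bar` and `C_f <= C-bar` — consistent
#' features must be both discriminative and parsimonious.
#'
#' @param features Numeric matrix (rows = instances, named columns =
#'   features) or a list of equally named feature vectors.
#' @param labels List of keyword sets (one per instance) or a character
#'   vector of class labels.
#' @param max_cuts Maximum number of cut points per feature (default 7).
#' @return Object of class `discretization_scheme`: per-feature `cuts`,
#'   `inconsistency`, `n_cuts`, `selected` and training `range`, plus the
#'   global averages `avg_inconsistency` and `avg_cuts`.
#' @export
fit_discretization <- function(features, labels, max_cuts = 7L) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, features)
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%04d", seq_len(ncol(features)))
  if (max_cuts < 1L) stop_field("max_cuts", "must be >= 1")
  classes <- if (is.list(labels)) vapply(labels, canonical_label, character(1))
             else as.character(labels)
  if (length(classes) != nrow(features))
    stop_field("labels", "must supply one label (set) per instance")
  per <- lapply(seq_len(ncol(features)), function(j) {
    v <- features[, j]
    cand <- candidate_cuts(v, classes)
    cuts <- numeric(0)
    inc <- feature_inconsistency(v, classes, cuts)
    while (inc > 0 && length(cuts) < max_cuts && length(cand) > 0L) {
      incs <- vapply(cand, function(ct)
        feature_inconsistency(v, classes, sort(c(cuts, ct))), numeric(1))
      best <- min(incs)
      if (best >= inc - 1e-12) break
      pick <- cand[which(incs <= best + 1e-12)][1]   # tie: lowest cut value
      stopifnot(best <= inc + 1e-12)                 # refinement monotone
      cuts <- sort(c(cuts, pick))
      cand <- setdiff(cand, pick)
      inc <- best
    }
    list(cuts = cuts, inconsistency = inc, n_cuts = length(cuts),
         range = range(v))
  })
  names(per) <- colnames(features)
  avg_inc <- mean(vapply(per, `[[`, numeric(1), "inconsistency"))
  avg_cut <- mean(vapply(per, `[[`, numeric(1), "n_cuts"))
  for (nm in names(per))
    per[[nm]]$selected <- per[[nm]]$inconsistency <= avg_inc &&
      per[[nm]]$n_cuts <= avg_cut
  structure(list(features = per, avg_inconsistency = avg_inc,
                 avg_cuts = avg_cut, max_cuts = as.integer(max_cuts)),
            class = "discretization_scheme")
}

#' Convert a feature vector into an itemset under a fitted scheme
#'
#' Each selected feature emits one item `"<name>=<interval>"`, where the
#' interval index counts right-open intervals under the feature's cuts
#' (values equal to a cut fall to the right).  Values outside the training
#' range are clamped into the first/last interval with a warning.  Keyword
#' items are appended verbatim on the training path and omitted on the test
#' path.
#'
#' @param scheme A [fit_discretization()] result.
#' @param v Named numeric feature vector covering the scheme's features.
#' @param keywords Character vector of diagnosis keywords (may be empty).
#' @return Sorted character itemset.
#' @export
apply_discretization <- function(scheme, v, keywords = character(0)) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  sel <- names(scheme$features)[vapply(scheme$features, `[[`, logical(1),
                                       "selected")]
  missing <- setdiff(sel, names(v))
  if (length(missing) > 0L)
    stop_field("v", sprintf("missing selected features: %s",
                            paste(utils::head(missing, 3), collapse = ", ")))
  items <- vapply(sel, function(nm) {
    f <- scheme$features[[nm]]
    x <- unname(v[[nm]])
    if (x < f$range[1] || x > f$range[2])
      warning(sprintf("feature %s value %.6g outside training range; clamped",
                      nm, x))
    sprintf("%s=%d", nm, findInterval(x, f$cuts))
  }, character(1))
  sort(unique(c(unname(items), as.character(keywords))))
}

#' Itemize a feature matrix
#'
#' @param scheme A [fit_discretization()] result.
#' @param features Numeric matrix with named columns.
#' @param labels Optional list of keyword sets (training path).
#' @return List of sorted character itemsets.
#' @export
itemize_features <- function(scheme, features, labels = NULL) {
  features <- as.matrix(features)
  lapply(seq_len(nrow(features)), function(i) {
    kw <- if (is.null(labels)) character(0) else labels[[i]]
    apply_discretization(scheme, features[i, ], kw)
  })
}

#' Serialize / load a discretization scheme as JSON
#'
#' @param scheme A `discretization_scheme`.
#' @param path File path.
#' @return `path` invisibly; `read_discretization()` returns the scheme.
#' @export
write_discretization <- function(scheme, path) {
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_discretization
#' @export
read_discretization <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$features <- lapply(x$features, function(f) {
    f$cuts <- as.numeric(unlist(f$cuts))
    f$range <- as.numeric(unlist(f$range))
    f
  })
  structure(x, class = "discretization_scheme")
}

#' @export
print.discretization_scheme <- function(x, ...) {
  sel <- sum(vapply(x$features, `[[`, logical(1), "selected"))
  cat(sprintf(paste0("Discretization scheme: %d features, %d selected\n",
                     "  average inconsistency %.4f, average cuts %.2f\n"),
              length(x$features), sel, x$avg_inconsistency, x$avg_cuts))
  invisible(x)
}
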