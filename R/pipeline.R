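# End-to-end orchestration of the training and test pipelines, the stage
# parameter configuration, and the diagnosis keyword vocabulary.

#' The diagnosis keyword vocabulary
#'
#' Standardised assessment categories (BI-RADS 0-5), mass/calcification
#' morphology terms, and histology terms grouped as benign, high-risk and
#' malignant.
#'
#' @return Data frame with columns `term`, `group` and `description`.
#' @export
keyword_vocabulary <- function() {
  birads <- data.frame(
    term = paste("BI-RADS", 0:5),
    group = "assessment",
    description = c(
      "Need additional imaging evaluation.",
      "Negative.",
      "Benign finding.",
      "Probably benign finding; short-interval follow-up suggested.",
      "Suspicious abnormality; biopsy should be considered.",
      "Highly suggestive of malignancy; appropriate action should be taken."))
  morph <- data.frame(
    term = c("Mass circumscribed", "Mass indistinct", "Mass spiculated",
             "Architectural distortion", "Asymmetric density",
             "Calcification amorphous", "Calcification pleomorphic",
             "Calcification linear", "Calcification benign",
             "Benign finding", "Suspicious abnormality",
             "Highly suggestive of malignancy"),
    group = "morphology", description = "")
  hist_b <- c("Breast tissue", "Cyst", "Calcifications", "Ductal hyperplasia",
              "Fibrosis", "Fibroadenoma", "Fatty tissue", "Hematoma",
              "Hamartoma", "Lymphangioma", "Lymphatic node", "Mastitis",
              "Mastopathia", "Papilloma", "Sclerosing adenosis", "Scar")
  hist_h <- c("Atypical ductal hyperplasia", "Lobular carcinoma in situ",
              "Phyllodes tumor", "Radial scar")
  hist_m <- c("Ductal carcinoma in situ", "Invasive ductal cancer",
              "Invasive lobular cancer", "Invasive tubular cancer",
              "Mucinous cancer")
  hist <- data.frame(
    term = c(hist_b, hist_h, hist_m),
    group = rep(c("histology benign", "histology high-risk",
                  "histology malignant"),
                c(length(hist_b), length(hist_h), length(hist_m))),
    description = "")
  out <- rbind(birads, morph, hist)
  out <- out[!duplicated(out$term), ]
  rownames(out) <- NULL
  out
}

PIPELINE_DEFAULTS <- list(
  srg_tol = 16, opening_radius = 3L, significance = 0.05,
  levelset = list(dt = 1, mu = 0.2, lambda = 5, alpha = -3, epsilon = 1.5,
                  sigma = 1.5, c0 = 2, max_iter = 300L, min_area = 30L),
  max_cuts = 7L, minsup = 0.05, minconf = 0.8, alpha = 0.5, delta = 0.5,
  max_features = 12L, max_rule_len = 2L, seed = 1L)

#' Build a validated pipeline configuration
#'
#' Unknown keys are rejected; every parameter is checked against its
#' documented range.
#'
#' @param ... Overrides of the defaults (`srg_tol`, `opening_radius`,
#'   `significance`, `levelset` (list), `max_cuts`, `minsup`, `minconf`,
#'   `alpha`, `delta`, `max_features`, `max_rule_len`, `seed`).
#'   `max_features` caps how many selected features the image-training path
#'   itemizes (the most consistent ones are kept) and `max_rule_len` caps
#'   mined itemset size there; both keep rule mining tractable when the
#'   1037-slot extractor feeds small cohorts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0L)
    stop_field("config", sprintf("unknown keys: %s",
                                 paste(unknown, collapse = ", ")))
  if (!is.null(over$levelset)) {
    bad <- setdiff(names(over$levelset), names(PIPELINE_DEFAULTS$levelset))
    if (length(bad) > 0L)
      stop_field("config", sprintf("unknown levelset keys: %s",
                                   paste(bad, collapse = ", ")))
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
  if (cfg$srg_tol <= 0) stop_field("srg_tol", "must be > 0")
  if (cfg$significance <= 0 || cfg$significance >= 1)
    stop_field("significance", "must lie in (0, 1)")
  if (cfg$minsup <= 0 || cfg$minsup > 1) stop_field("minsup", "not in (0, 1]")
  if (cfg$minconf <= 0 || cfg$minconf > 1)
    stop_field("minconf", "not in (0, 1]")
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop_field("alpha", "not in (0, 1]")
  if (cfg$delta <= 0 || cfg$delta > 1) stop_field("delta", "not in (0, 1]")
  if (cfg$max_cuts < 1L) stop_field("max_cuts", "must be >= 1")
  if (cfg$max_features < 1L) stop_field("max_features", "must be >= 1")
  if (cfg$max_rule_len < 1L) stop_field("max_rule_len", "must be >= 1")
  if (cfg$levelset$dt * cfg$levelset$mu >= 0.25)
    stop_field("levelset", "dt * mu must stay below 0.25")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of configuration overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

run_log <- function(cfg, stage) {
  list(tool = "mammocad",
       version = as.character(utils::packageVersion("mammocad")),
       stage = stage, config = unclass(cfg), config_hash = config_hash(cfg),
       seed = cfg$seed, timestamp = format(Sys.time(), tz = "UTC"))
}

# Run the image stages on one image and return one feature vector per ROI
# (falling back to the AOI itself when no ROI survives refinement, so a
# lesion-free image still yields a transaction).
image_to_features <- function(image, cfg, id = "image") {
  stage <- "preprocess"
  res <- tryCatch({
    pre <- preprocess_mammogram(image, srg_tol = cfg$srg_tol,
                                opening_radius = cfg$opening_radius)
    stage <- "segment"
    cp <- op_transform(pre$image, pre$aoi$aoi_mask)
    edges <- detect_edges(cp, cfg$significance)
    rois <- refine_contour(pre$image, edges, cfg$levelset)
    masks <- lapply(rois$rois, `[[`, "mask")
    if (length(masks) == 0L) masks <- list(pre$aoi$aoi_mask)
    stage <- "features"
    # features are computed over a rectangular patch around each ROI (4 px
    # margin, floor 20x20) so the lesion and its immediate surroundings
    # satisfy every family's window precondition
    lapply(masks, function(m)
      extract_features(pre$image, roi_patch(m, margin = 4L, min_size = 20L)))
  }, error = function(e) {
    stop(sprintf("stage '%s' failed on input '%s': %s", stage, id,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}

#' Train the full pipeline
#'
#' Runs pre-processing, segmentation and feature extraction on each labeled
#' image, fits the joint discretization/selection scheme, itemizes the
#' training rows with their keywords, and mines the representative rule
#' base.  Alternatively, a pre-itemized cohort (as from
#' [generate_transactions()] or [read_cohort_jsonl()]) bypasses the image
#' stages and is mined directly.
#'
#' @param images List of grayscale image matrices (or `NULL` when training
#'   from a cohort).
#' @param labels List of keyword sets, one per image.
#' @param cohort Optional pre-itemized cohort (list of transactions with
#'   `items` and `keywords`).
#' @param config A [pipeline_config()].
#' @return Object of class `cad_model`: list with `rulebase`, `scheme`
#'   (`NULL` for cohort input), `features` (matrix or `NULL`), `keywords`
#'   (vocabulary seen in training) and `log`.
#' @export
cad_train <- function(images = NULL, labels = NULL, cohort = NULL,
                      config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(images) || is.null(labels) ||
        length(images) != length(labels))
      stop_field("images", "image training needs one keyword set per image")
    if (length(unique(vapply(labels, canonical_label, character(1)))) < 2L)
      stop_field("labels", "training needs at least two distinct classes")
    rows <- list(); row_labels <- list()
    for (i in seq_along(images)) {
      fvs <- image_to_features(images[[i]], config, id = as.character(i))
      for (fv in fvs) {
        rows[[length(rows) + 1L]] <- fv
        row_labels[[length(row_labels) + 1L]] <- labels[[i]]
      }
    }
    mat <- do.call(rbind, rows)
    scheme <- fit_discretization(mat, row_labels, max_cuts = config$max_cuts)
    scheme <- cap_selected(scheme, config$max_features)
    transactions <- itemize_features(scheme, mat, row_labels)
    keywords <- sort(unique(unlist(row_labels)))
    max_len <- config$max_rule_len + 2L   # body cap + room for keyword heads
  } else {
    scheme <- NULL; mat <- NULL
    transactions <- lapply(cohort, function(tr)
      canonical_itemset(c(tr$items, tr$keywords)))
    keywords <- sort(unique(unlist(lapply(cohort, `[[`, "keywords"))))
    max_len <- Inf
  }
  rb <- mine_rulebase(transactions, keywords, minsup = config$minsup,
                      minconf = config$minconf, max_len = max_len)
  structure(list(rulebase = rb, scheme = scheme, features = mat,
                 keywords = keywords, log = run_log(config, "train")),
            class = "cad_model")
}

#' Diagnose a new image or itemset with a trained model
#'
#' An image runs through the same pre-processing, segmentation and feature
#' stages as training, is itemized under the training scheme without
#' keywords, and each ROI is scored by the diagnosis engine; a pre-built
#' itemset is scored directly.  Train and test share one feature layout and
#' one vocabulary; unknown items are a hard error.
#'
#' @param model A [cad_train()] result.
#' @param image Grayscale matrix (mutually exclusive with `itemset`).
#' @param itemset Character itemset.
#' @param config A [pipeline_config()].
#' @return List of `diagnosis` objects, one per ROI (a single element for
#'   itemset input).
#' @export
cad_test <- function(model, image = NULL, itemset = NULL,
                     config = pipeline_config()) {
  stopifnot(inherits(model, "cad_model"))
  rb <- model$rulebase
  if (!is.null(itemset)) {
    known <- c(rb$items,
               if (!is.null(model$scheme)) scheme_item_space(model$scheme))
    unknown <- setdiff(itemset, known)
    if (length(known) > 0L && length(unknown) == length(itemset))
      warning("test itemset shares no items with the trained model")
    return(list(diagnose(rb, canonical_itemset(itemset),
                         alpha = config$alpha, delta = config$delta)))
  }
  if (is.null(model$scheme))
    stop_field("model", "image input needs a model trained from images")
  fvs <- image_to_features(image, config, id = "test")
  lapply(fvs, function(fv) {
    its <- apply_discretization(model$scheme, fv)
    diagnose(rb, its, alpha = config$alpha, delta = config$delta)
  })
}

#' Rectangular analysis patch around a ROI
#'
#' Returns the mask of the ROI's bounding box grown by `margin` pixels on
#' every side and expanded to at least `min_size` per dimension (clipped to
#' the image) — the region the pipeline extracts texture features from, so
#' small lesions still satisfy every feature family's window precondition.
#'
#' @param mask Logical ROI mask.
#' @param margin Pixels of context added on each side.
#' @param min_size Minimum patch width/height.
#' @return Logical matrix of the same size as `mask`.
#' @export
roi_patch <- function(mask, margin = 4L, min_size = 20L) {
  rws <- range(which(apply(mask, 1, any)))
  cls <- range(which(apply(mask, 2, any)))
  grow <- function(rng, lim, want) {
    rng <- c(max(1L, rng[1] - margin), min(lim, rng[2] + margin))
    while (diff(rng) + 1L < want) {
      if (rng[1] > 1L) rng[1] <- rng[1] - 1L
      else if (rng[2] < lim) rng[2] <- rng[2] + 1L
      else break
    }
    rng
  }
  rws <- grow(rws, nrow(mask), min_size)
  cls <- grow(cls, ncol(mask), min_size)
  out <- mask & FALSE
  out[rws[1]:rws[2], cls[1]:cls[2]] <- TRUE
  out
}

# Parsimony cap for image training: among the scheme's selected features,
# keep only the `k` most consistent (lowest inconsistency, then fewest cuts,
# then name) so transaction width stays tractable for exhaustive mining.
cap_selected <- function(scheme, k) {
  sel <- names(scheme$features)[vapply(scheme$features, `[[`, logical(1),
                                       "selected")]
  if (length(sel) <= k) return(scheme)
  inc <- vapply(scheme$features[sel], `[[`, numeric(1), "inconsistency")
  ncut <- vapply(scheme$features[sel], `[[`, numeric(1), "n_cuts")
  keep <- sel[order(inc, ncut, sel)][seq_len(k)]
  for (nm in setdiff(sel, keep)) scheme$features[[nm]]$selected <- FALSE
  scheme
}

scheme_item_space <- function(scheme) {
  sel <- names(scheme$features)[vapply(scheme$features, `[[`, logical(1),
                                       "selected")]
  unlist(lapply(sel, function(nm) {
    k <- length(scheme$features[[nm]]$cuts)
    sprintf("%s=%d", nm, 0:k)
  }))
}

#' Write the feature matrix as CSV
#'
#' One row per ROI with the 1037 named slots plus `image_id` and a
#' `keywords` column (terms joined by `;`).
#'
#' @param features Numeric matrix with named columns.
#' @param labels List of keyword sets (optional).
#' @param path Output CSV path.
#' @param ids Row identifiers.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path, labels = NULL,
                              ids = seq_len(nrow(features))) {
  df <- as.data.frame(features)
  df <- cbind(image_id = ids,
              keywords = if (is.null(labels)) ""
                         else vapply(labels, paste, character(1),
                                     collapse = ";"),
              df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
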