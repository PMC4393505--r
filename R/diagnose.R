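# Associative diagnosis engine: scores every distinct rule head against a
# test itemset under two weighted matching conditions and returns the
# accepted heads as the suggested diagnosis.

#' Match status of a rule body against a test itemset
#'
#' A test itemset fully matches a rule when it satisfies the whole body,
#' partially matches when it satisfies only part of the body, and does not
#' match when it satisfies no part of it.
#'
#' @param rule A rule (list with nonempty `body`).
#' @param test Character itemset.
#' @return One of `"full"`, `"partial"`, `"none"`.
#' @export
match_status <- function(rule, test) {
  body <- rule$body
  if (length(body) == 0L) stop_field("rule", "rule body must be nonempty")
  hit <- sum(body %in% test)
  if (hit == length(body)) "full"
  else if (hit > 0L) "partial"
  else "none"
}

#' Score one head itemset against a test itemset
#'
#' Over the rules whose head equals `h` (set equality), counts full matches
#' `nM`, partial matches `nP` and non-matches `nN`.  Condition 1 accepts
#' `h` with weight `w1 = nM / (nM + nN)` when `w1 >= alpha`; otherwise
#' Condition 2 accepts with weight `w2 = (nM + nP) / (nM + nP + nN)` when
#' `w2 >= delta`.  A zero denominator scores 0 (the head has not even one
#' match and is rejected).
#'
#' @param rb A `rulebase`.
#' @param h Character head itemset.
#' @param test Character test itemset.
#' @param alpha,delta Acceptance thresholds in (0, 1].
#' @return List with `accepted`, `weight`, `condition` (1, 2 or `NA`), and
#'   counts `nM`, `nP`, `nN`.
#' @export
score_head <- function(rb, h, test, alpha = 0.5, delta = 0.5) {
  stopifnot(inherits(rb, "rulebase"))
  if (alpha <= 0 || alpha > 1) stop_field("alpha", "must lie in (0, 1]")
  if (delta <= 0 || delta > 1) stop_field("delta", "must lie in (0, 1]")
  hkey <- itemset_key(h)
  status <- vapply(rb$rules, function(r) {
    if (itemset_key(r$head) == hkey) match_status(r, test) else NA_character_
  }, character(1))
  nM <- sum(status == "full", na.rm = TRUE)
  nP <- sum(status == "partial", na.rm = TRUE)
  nN <- sum(status == "none", na.rm = TRUE)
  w1 <- if (nM + nN > 0) nM / (nM + nN) else 0
  if (w1 >= alpha)
    return(list(accepted = TRUE, weight = w1, condition = 1L,
                nM = nM, nP = nP, nN = nN))
  w2 <- if (nM + nP + nN > 0) (nM + nP) / (nM + nP + nN) else 0
  if (w2 >= delta)
    return(list(accepted = TRUE, weight = w2, condition = 2L,
                nM = nM, nP = nP, nN = nN))
  list(accepted = FALSE, weight = max(w1, w2), condition = NA_integer_,
       nM = nM, nP = nP, nN = nN)
}

#' Diagnose a test itemset against a rule base
#'
#' Scores every distinct rule head with [score_head()] and returns the
#' accepted heads sorted by weight (descending), breaking ties by condition
#' (1 before 2), smaller head, then lexicographic order.  The engine can
#' return multiple keyword sets for one test image.
#'
#' @inheritParams score_head
#' @return Object of class `diagnosis`: list with `accepted` (list of
#'   entries `head`, `weight`, `condition`, `nM`, `nP`, `nN`), `alpha`,
#'   `delta`.
#' @export
diagnose <- function(rb, test, alpha = 0.5, delta = 0.5) {
  stopifnot(inherits(rb, "rulebase"))
  heads <- unique(lapply(rb$rules, function(r) canonical_itemset(r$head)))
  entries <- list()
  for (h in heads) {
    sc <- score_head(rb, h, test, alpha, delta)
    if (sc$accepted)
      entries[[length(entries) + 1L]] <-
        list(head = h, weight = sc$weight, condition = sc$condition,
             nM = sc$nM, nP = sc$nP, nN = sc$nN)
  }
  if (length(entries) > 0L) {
    ord <- order(-vapply(entries, `[[`, numeric(1), "weight"),
                 vapply(entries, `[[`, integer(1), "condition"),
                 vapply(entries, function(e) length(e$head), integer(1)),
                 vapply(entries, function(e) itemset_key(e$head),
                        character(1)))
    entries <- entries[ord]
  }
  structure(list(accepted = entries, alpha = alpha, delta = delta),
            class = "diagnosis")
}

#' @export
print.diagnosis <- function(x, ...) {
  cat(sprintf("Diagnosis (alpha = %g, delta = %g): %d accepted head(s)\n",
              x$alpha, x$delta, length(x$accepted)))
  for (e in x$accepted)
    cat(sprintf("  {%s}  weight %.3f  condition %d  (nM=%d nP=%d nN=%d)\n",
                paste(e$head, collapse = ", "), e$weight, e$condition,
                e$nM, e$nP, e$nN))
  invisible(x)
}

#' Write a diagnosis report as JSON
#'
#' @param d A `diagnosis`.
#' @param path File path.
#' @param test_id Identifier recorded in the report.
#' @return `path`, invisibly.
#' @export
write_diagnosis <- function(d, path, test_id = "test") {
  stopifnot(inherits(d, "diagnosis"))
  jsonlite::write_json(
    list(test_id = test_id, alpha = d$alpha, delta = d$delta,
         accepted = lapply(d$accepted, function(e)
           list(head = as.list(e$head), weight = e$weight,
                condition = e$condition, nM = e$nM, nP = e$nP, nN = e$nN))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
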