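# Frequent-itemset mining over an FP-tree (frequency-pattern tree with
# pre-pruning of items below minimum support, items ordered by descending
# support with lexicographic tie-break, recursive conditional-tree growth),
# followed by class-constrained representative-rule derivation.

fp_node <- function(item, parent) {
  e <- new.env(parent = emptyenv())
  e$item <- item; e$count <- 0; e$parent <- parent
  e$children <- new.env(parent = emptyenv())
  e
}

fp_tree_build <- function(transactions, counts, item_order) {
  root <- fp_node(NA_character_, NULL)
  header <- new.env(parent = emptyenv())
  for (i in seq_along(transactions)) {
    items <- transactions[[i]]
    items <- items[items %in% item_order]
    items <- item_order[item_order %in% items]    # frequency order
    node <- root
    for (it in items) {
      child <- if (exists(it, envir = node$children, inherits = FALSE))
        get(it, envir = node$children) else NULL
      if (is.null(child)) {
        child <- fp_node(it, node)
        assign(it, child, envir = node$children)
        lst <- if (exists(it, envir = header, inherits = FALSE))
          get(it, envir = header) else list()
        assign(it, c(lst, child), envir = header)
      }
      child$count <- child$count + counts[i]
      node <- child
    }
  }
  list(root = root, header = header)
}

fp_growth <- function(transactions, counts, min_count, suffix, out,
                      max_len = Inf) {
  if (length(suffix) >= max_len) return(invisible(NULL))
  # support of each item in this (conditional) database
  tab <- new.env(parent = emptyenv())
  for (i in seq_along(transactions)) {
    for (it in transactions[[i]]) {
      cur <- if (exists(it, envir = tab, inherits = FALSE))
        get(it, envir = tab) else 0
      assign(it, cur + counts[i], envir = tab)
    }
  }
  items <- ls(tab)
  sup <- vapply(items, get, numeric(1), envir = tab)
  keep <- sup >= min_count
  items <- items[keep]; sup <- sup[keep]
  if (length(items) == 0L) return(invisible(NULL))
  ord <- order(-sup, items)                # desc support, lexicographic ties
  item_order <- items[ord]
  tree <- fp_tree_build(transactions, counts, item_order)
  # grow from the least frequent item upwards
  for (it in rev(item_order)) {
    itemset <- c(it, suffix)
    nodes <- get(it, envir = tree$header)
    support <- sum(vapply(nodes, function(nd) nd$count, numeric(1)))
    out$n <- out$n + 1L
    if (out$n > length(out$res)) out$res <- c(out$res, vector("list", out$n))
    out$res[[out$n]] <- list(items = sort(itemset), count = support)
    # conditional pattern base: prefix paths of every node for this item
    cond_tr <- list(); cond_ct <- numeric(0)
    for (nd in nodes) {
      path <- character(0)
      up <- nd$parent
      while (!is.null(up) && !is.na(up$item)) {
        path <- c(up$item, path)
        up <- up$parent
      }
      if (length(path) > 0L) {
        cond_tr[[length(cond_tr) + 1L]] <- path
        cond_ct <- c(cond_ct, nd$count)
      }
    }
    if (length(cond_tr) > 0L)
      fp_growth(cond_tr, cond_ct, min_count, itemset, out, max_len)
  }
  invisible(NULL)
}

#' Mine frequent itemsets with FP-growth
#'
#' Builds a frequency-pattern tree over the items whose support clears
#' `minsup` (the bounded portion of the database) and enumerates all
#' frequent itemsets by recursive conditional-tree growth.  Supports are
#' exact fractions of the transaction count.
#'
#' @param transactions List of itemsets (character vectors), or of
#'   transaction lists carrying `items`/`keywords` fields (the two are
#'   unioned).
#' @param minsup Minimum support fraction in (0, 1].
#' @param max_len Optional cap on itemset size (rule bodies stay below this
#'   minus the head size); `Inf` enumerates everything.
#' @return Object of class `frequent_itemsets`: a data frame with list
#'   column `items`, integer `count` and numeric `support`, ordered by
#'   descending support then itemset; `n_transactions` is an attribute.
#' @export
mine_frequent <- function(transactions, minsup, max_len = Inf) {
  if (length(transactions) == 0L)
    stop_field("transactions", "must be a nonempty list")
  if (minsup <= 0 || minsup > 1) stop_field("minsup", "must lie in (0, 1]")
  transactions <- lapply(transactions, function(tr) {
    if (is.list(tr)) canonical_itemset(c(tr$items, tr$keywords))
    else canonical_itemset(tr)
  })
  n <- length(transactions)
  min_count <- minsup * n - 1e-9
  out <- new.env(); out$res <- vector("list", 256L); out$n <- 0L
  fp_growth(transactions, rep(1, n), min_count, character(0), out, max_len)
  res <- out$res[seq_len(out$n)]
  if (length(res) == 0L) {
    df <- data.frame(count = integer(0), support = numeric(0))
    df$items <- list()
  } else {
    df <- data.frame(count = vapply(res, function(r) as.integer(round(r$count)),
                                    integer(1)))
    df$support <- df$count / n
    df$items <- lapply(res, `[[`, "items")
    key <- vapply(df$items, itemset_key, character(1))
    ord <- order(-df$support, key)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("frequent_itemsets", "data.frame"),
            n_transactions = n)
}

#' Derive class-constrained representative association rules
#'
#' Candidate rules are every split of a frequent itemset into a keyword-free
#' body and a nonempty all-keyword head with confidence at or above
#' `minconf`.  The representative filter then removes any rule lying in the
#' cover of another candidate, where the cover of `X -> Y` is every rule
#' `X u Z -> V` with `Z` a subset of `Y` and `V` a nonempty subset of
#' `Y \ Z`: the retained rules form an antichain from which all confident
#' rules are derivable.
#'
#' @param freq A [mine_frequent()] result.
#' @param minconf Minimum confidence in (0, 1].
#' @param keywords Character vector: the diagnosis-keyword item vocabulary.
#' @param minsup Support threshold recorded in the rule base (metadata).
#' @return Object of class `rulebase`: list with `rules` (each with `body`,
#'   `head`, `support`, `confidence`), `minsup`, `minconf` and `items`.
#' @export
derive_representative <- function(freq, minconf, keywords,
                                  minsup = NA_real_) {
  stopifnot(inherits(freq, "frequent_itemsets"))
  if (minconf <= 0 || minconf > 1) stop_field("minconf", "must lie in (0, 1]")
  sup_of <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(freq)))
    assign(itemset_key(freq$items[[i]]), freq$support[i], envir = sup_of)
  cands <- list()
  for (i in seq_len(nrow(freq))) {
    z <- freq$items[[i]]
    head <- z[z %in% keywords]
    body <- z[!z %in% keywords]
    if (length(head) == 0L || length(body) == 0L) next
    bsup <- get0(itemset_key(body), envir = sup_of, ifnotfound = NA_real_)
    if (is.na(bsup)) next     # body itself below minsup: skip
    conf <- freq$support[i] / bsup
    if (conf >= minconf - 1e-12)
      cands[[length(cands) + 1L]] <- list(body = canonical_itemset(body),
                                          head = canonical_itemset(head),
                                          support = freq$support[i],
                                          confidence = conf)
  }
  # With keyword-free bodies and all-keyword heads, rule r can lie in the
  # cover of candidate s only when the bodies coincide (any extra body item
  # of r would have to be a keyword drawn from s's head): the filter
  # reduces to keeping, per body, the rules whose head is not a proper
  # subset of another candidate head for the same body.
  keep <- rep(TRUE, length(cands))
  body_key <- vapply(cands, function(r) itemset_key(r$body), character(1))
  for (grp in split(seq_along(cands), body_key)) {
    if (length(grp) < 2L) next
    for (i in grp) for (j in grp) {
      if (i != j && keep[i] && rule_in_cover(cands[[i]], cands[[j]]))
        keep[i] <- FALSE
    }
  }
  rules <- cands[keep]
  if (length(rules) > 0L) {
    key <- vapply(rules, function(r) itemset_key(c(r$body, r$head)),
                  character(1))
    ord <- order(-vapply(rules, `[[`, numeric(1), "support"),
                 -vapply(rules, `[[`, numeric(1), "confidence"),
                 vapply(rules, function(r) length(r$body), integer(1)),
                 key)
    rules <- rules[ord]
  }
  structure(list(rules = rules, minsup = minsup, minconf = minconf,
                 items = sort(unique(unlist(lapply(rules, function(r)
                   c(r$body, r$head)))))),
            class = "rulebase")
}

# Is rule r in the cover of rule s?  cover(X -> Y) = { X u Z -> V :
# Z subset of Y, V nonempty subset of Y \ Z }.
rule_in_cover <- function(r, s) {
  if (identical(r$body, s$body) && identical(r$head, s$head)) return(FALSE)
  z <- setdiff(r$body, s$body)
  all(s$body %in% r$body) &&
    all(z %in% s$head) &&
    length(r$head) > 0L &&
    all(r$head %in% setdiff(s$head, z))
}

#' Mine a rule base from transactions in one call
#'
#' @param transactions As in [mine_frequent()].
#' @param keywords Keyword item vocabulary (rule heads).
#' @param minsup,minconf Support and confidence thresholds.
#' @param max_len Itemset-size cap passed to [mine_frequent()].
#' @return A `rulebase`.
#' @export
mine_rulebase <- function(transactions, keywords, minsup = 0.05,
                          minconf = 0.8, max_len = Inf) {
  freq <- mine_frequent(transactions, minsup, max_len = max_len)
  derive_representative(freq, minconf, keywords, minsup = minsup)
}

#' Save / load a rule base as JSON
#'
#' The JSON schema is `{items, minsup, minconf, rules: [{body, head,
#' support, confidence}]}`.  Loading validates the rule invariants (disjoint
#' body and head, nonempty all-keyword head, support and confidence in
#' (0, 1]).
#'
#' @param rb A `rulebase`.
#' @param path File path.
#' @return `path` invisibly; `load_rulebase()` returns the `rulebase`.
#' @export
save_rulebase <- function(rb, path) {
  stopifnot(inherits(rb, "rulebase"))
  jsonlite::write_json(list(items = rb$items,
                            minsup = if (is.na(rb$minsup)) NULL
                                     else rb$minsup,
                            minconf = rb$minconf,
                            rules = lapply(rb$rules, function(r)
                              list(body = r$body, head = r$head,
                                   support = r$support,
                                   confidence = r$confidence))),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_rulebase
#' @export
load_rulebase <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  stop(sprintf("malformed rule base file '%s': %s",
                               path, conditionMessage(e)), call. = FALSE))
  rules <- lapply(x$rules, function(r) {
    r <- list(body = canonical_itemset(unlist(r$body)),
              head = canonical_itemset(unlist(r$head)),
              support = as.numeric(r$support),
              confidence = as.numeric(r$confidence))
    if (length(r$head) == 0L)
      stop("invalid rule base: rule with empty head", call. = FALSE)
    if (length(r$body) == 0L)
      stop("invalid rule base: rule with empty body", call. = FALSE)
    if (length(intersect(r$body, r$head)) > 0L)
      stop("invalid rule base: body and head intersect", call. = FALSE)
    if (r$support <= 0 || r$support > 1 || r$confidence <= 0 ||
        r$confidence > 1)
      stop("invalid rule base: support/confidence outside (0, 1]",
           call. = FALSE)
    r
  })
  structure(list(rules = rules,
                 minsup = if (is.null(x$minsup)) NA_real_
                          else as.numeric(x$minsup),
                 minconf = as.numeric(x$minconf),
                 items = sort(as.character(unlist(x$items)))),
            class = "rulebase")
}

#' @export
print.rulebase <- function(x, n = 10L, ...) {
  cat(sprintf("Rule base: %d representative rules (minsup %s, minconf %s)\n",
              length(x$rules), format(x$minsup), format(x$minconf)))
  for (r in utils::head(x$rules, n)) {
    cat(sprintf("  {%s} -> {%s}  sup %.3f conf %.3f\n",
                paste(r$body, collapse = ", "),
                paste(r$head, collapse = ", "), r$support, r$confidence))
  }
  if (length(x$rules) > n) cat(sprintf("  ... %d more\n", length(x$rules) - n))
  invisible(x)
}
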