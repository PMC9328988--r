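#' Mining thresholds
#'
#' @param min_support minimum weighted support of a rule's full itemset
#'   (antecedent together with consequent), in \[0, 1\].
#' @param min_confidence minimum weighted confidence / weighted Bayes
#'   confidence, in \[0, 1\].
#' @param min_lift weighted Bayes lift threshold; a rule must exceed it
#'   strictly to be strong.  1 marks independence.
#' @param max_antecedent_size largest antecedent itemset considered.
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(min_support = 0.36, min_confidence = 0.70,
                             min_lift = 1.0, max_antecedent_size = 3L) {
  if (min_support < 0 || min_support > 1 ||
      min_confidence < 0 || min_confidence > 1)
    stop("min_support and min_confidence must lie in [0, 1]")
  if (min_lift < 0) stop("min_lift must be nonnegative")
  max_antecedent_size <- as.integer(max_antecedent_size)
  if (max_antecedent_size < 1L) stop("max_antecedent_size must be >= 1")
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 min_lift = min_lift,
                 max_antecedent_size = max_antecedent_size),
            class = "threshold_config")
}

itemset_str <- function(ids) paste(sort(as.integer(ids)), collapse = ",")

#' Parse a comma-joined itemset string back to item IDs
#'
#' Rule tables store itemsets as comma-joined sorted item IDs (`"2,4,6"`).
#'
#' @param s itemset string as found in rule tables.
#' @return integer vector of item IDs.
#' @export
parse_itemset <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])

# sort key making itemset order lexicographic on the sorted integer IDs
itemset_key <- function(s) {
  vapply(s, function(x)
    paste(sprintf("%06d", parse_itemset(x)), collapse = "|"), "")
}

# logical record mask: which records contain every item of the itemset
records_with <- function(itemset, ds) {
  owner <- item_owner(ds$schema)
  mask <- rep(TRUE, n_records(ds))
  for (id in itemset) {
    col <- owner[as.character(id)]
    if (is.na(col)) stop(sprintf("item %d is not in the schema", id))
    col <- if (col == "<class>") ".class" else col
    v <- ds$items[, col]
    mask <- mask & !is.na(v) & v == id
  }
  mask
}

#' Weighted support of an itemset
#'
#' The summed record (tuple) weights of the records containing the itemset,
#' over the total record weight of the dataset.  The same quantity serves
#' two-attribute, multi-attribute and class-label rules; only the itemset
#' changes.
#'
#' @param itemset integer vector of item IDs (attribute and/or class items).
#' @param ds a missing-free `item_dataset`.
#' @param wt a `weight_table`.
#' @return weighted support in \[0, 1\].
#' @export
weighted_support <- function(itemset, ds, wt) {
  if (length(itemset) == 0L) stop("itemset must be non-empty")
  rw <- record_weights(ds, wt)
  W <- sum(rw)
  if (W <= 0) stop("total record weight is zero; support undefined")
  sum(rw[records_with(itemset, ds)]) / W
}

#' Weighted confidence of a rule
#'
#' WS(antecedent and consequent) / WS(antecedent); undefined (an error) when
#' the antecedent has zero weighted support.
#'
#' @param antecedent,consequent disjoint non-empty integer itemsets.
#' @inheritParams weighted_support
#' @return weighted confidence in \[0, 1\].
#' @export
weighted_confidence <- function(antecedent, consequent, ds, wt) {
  if (length(intersect(antecedent, consequent)) > 0L)
    stop("antecedent and consequent must be disjoint")
  sa <- weighted_support(antecedent, ds, wt)
  if (sa <= 0) stop("antecedent has zero weighted support; confidence undefined")
  weighted_support(c(antecedent, consequent), ds, wt) / sa
}

# --- internal mining machinery -------------------------------------------

# precompute per-record weights and column lookup for fast repeated supports
mining_env <- function(ds, wt) {
  rw <- record_weights(ds, wt)
  W <- sum(rw)
  if (W <= 0) stop("total record weight is zero; support undefined")
  owner <- item_owner(ds$schema)
  list(ds = ds, rw = rw, W = W, owner = owner,
       supp = function(mask) sum(rw[mask]) / W)
}

mask_for <- function(env, itemset) records_with(itemset, env$ds)

# levelwise Apriori over the given item universe; itemsets never take two
# items of the same attribute (their joint support is structurally zero)
frequent_itemsets <- function(env, universe, min_support, max_size) {
  owner <- env$owner
  masks <- lapply(universe, function(id) mask_for(env, id))
  names(masks) <- as.character(universe)
  s1 <- vapply(masks, env$supp, 1)
  keep <- s1 >= min_support
  out <- list()
  level <- lapply(universe[keep], function(id) id)
  lmask <- masks[keep]
  lsupp <- s1[keep]
  if (length(level))
    out[[1L]] <- list(sets = level, supp = unname(lsupp), mask = lmask)
  k <- 1L
  while (k < max_size && length(level) > 1L) {
    cand <- list(); cmask <- list(); csupp <- numeric(0)
    keys <- vapply(level, itemset_str, "")
    ord <- order(itemset_key(keys))
    level <- level[ord]; lmask <- lmask[ord]
    for (i in seq_along(level)) {
      for (j in seq_along(level)) {
        if (j <= i) next
        a <- level[[i]]; b <- level[[j]]
        if (k > 1L && !identical(a[seq_len(k - 1L)], b[seq_len(k - 1L)])) next
        new_item <- b[k]
        if (owner[as.character(new_item)] %in% owner[as.character(a)]) next
        set <- sort(c(a, new_item))
        m <- lmask[[i]] & mask_for(env, new_item)
        s <- env$supp(m)
        if (s >= min_support) {
          cand[[length(cand) + 1L]] <- set
          cmask[[length(cmask) + 1L]] <- m
          csupp <- c(csupp, s)
        }
      }
    }
    # dedupe joins arriving via different parents
    if (length(cand)) {
      keys <- vapply(cand, itemset_str, "")
      first <- !duplicated(keys)
      cand <- cand[first]; cmask <- cmask[first]; csupp <- csupp[first]
    }
    k <- k + 1L
    level <- cand; lmask <- cmask
    if (length(level))
      out[[k]] <- list(sets = level, supp = csupp, mask = lmask)
  }
  out
}

new_rule_set <- function(antecedent, consequent, ws, wc, mode, cfg) {
  df <- data.frame(antecedent = antecedent, consequent = consequent,
                   ws = ws, wc = wc,
                   mode = rep_len(mode, length(antecedent)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("rule_set", "data.frame"), cfg = cfg)
}

#' Mine weighted association rules
#'
#' Three modes cover the method's rule families:
#' \describe{
#'   \item{`two_attribute`}{single attribute item on each side.}
#'   \item{`multi_attribute`}{antecedent of up to `max_antecedent_size`
#'     attribute items, single attribute-item consequent.}
#'   \item{`class_label`}{attribute-itemset antecedent, one class item as
#'     consequent.}
#' }
#' A rule is emitted when the weighted support of its full itemset reaches
#' `min_support` and its weighted confidence reaches `min_confidence`.
#' Candidate generation is levelwise Apriori; weighted support is
#' anti-monotone because each record's weight is fixed, so pruning is exact.
#'
#' @param ds a missing-free `item_dataset`.
#' @param wt a `weight_table`.
#' @param cfg a [threshold_config()].
#' @param mode one of `"two_attribute"`, `"multi_attribute"`, `"class_label"`.
#' @return a `rule_set` data.frame: `antecedent`, `consequent` (comma-joined
#'   item IDs), `ws`, `wc`, `mode`.
#' @export
mine_rules <- function(ds, wt, cfg = threshold_config(),
                       mode = c("two_attribute", "multi_attribute",
                                "class_label")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "threshold_config"))
  if (any(ds$missing)) stop("dataset still carries missing records")
  env <- mining_env(ds, wt)
  universe <- attribute_item_ids(ds$schema)
  ant <- con <- character(0); ws <- wc <- numeric(0)

  emit <- function(a, c_, s_full, s_ant) {
    if (s_ant <= 0) return()
    conf <- s_full / s_ant
    if (s_full >= cfg$min_support && conf >= cfg$min_confidence) {
      ant <<- c(ant, itemset_str(a)); con <<- c(con, itemset_str(c_))
      ws <<- c(ws, s_full); wc <<- c(wc, conf)
    }
  }

  if (mode == "two_attribute") {
    owner <- env$owner
    masks <- lapply(universe, function(id) mask_for(env, id))
    s1 <- vapply(masks, env$supp, 1)
    for (i in seq_along(universe)) for (j in seq_along(universe)) {
      if (i == j) next
      a <- universe[i]; b <- universe[j]
      if (owner[as.character(a)] == owner[as.character(b)]) next
      s_full <- env$supp(masks[[i]] & masks[[j]])
      emit(a, b, s_full, s1[i])
    }
  } else if (mode == "multi_attribute") {
    freq <- frequent_itemsets(env, universe, cfg$min_support,
                              cfg$max_antecedent_size + 1L)
    for (lvl in freq) {
      for (q in seq_along(lvl$sets)) {
        set <- lvl$sets[[q]]
        if (length(set) < 2L) next
        for (c_ in set) {
          a <- setdiff(set, c_)
          if (length(a) > cfg$max_antecedent_size) next
          emit(a, c_, lvl$supp[q], env$supp(mask_for(env, a)))
        }
      }
    }
  } else { # class_label
    freq <- frequent_itemsets(env, universe, cfg$min_support,
                              cfg$max_antecedent_size)
    for (lvl in freq) {
      for (q in seq_along(lvl$sets)) {
        a <- lvl$sets[[q]]
        for (cls in ds$schema$class_items) {
          m <- lvl$mask[[q]] & mask_for(env, cls)
          emit(a, cls, env$supp(m), lvl$supp[q])
        }
      }
    }
  }
  new_rule_set(ant, con, ws, wc, mode, cfg)
}

#' Score rules with weighted Bayes confidence and lift; flag strong rules
#'
#' WBC of a rule A -> B is P(B|A) computed from weighted supports,
#' WS(A,B)/WS(A) — numerically the weighted confidence.  WBL is
#' WBC / WS(B), the lift of the rule against the consequent's weighted
#' marginal; values above 1 indicate positive association.  A rule is strong
#' when WBC >= `min_confidence` and WBL > `min_lift`.  Rules whose consequent
#' has zero weighted support are dropped with a warning (lift undefined).
#' Output is sorted by descending (WBL, WBC) with a deterministic
#' lexicographic tie-break on the itemsets.
#'
#' @param rules a `rule_set` from [mine_rules()].
#' @inheritParams mine_rules
#' @return the `rule_set` with columns `wbc`, `wbl`, `strong` added.
#' @export
score_strong <- function(rules, ds, wt, cfg = attr(rules, "cfg")) {
  stopifnot(inherits(rules, "rule_set"))
  env <- mining_env(ds, wt)
  n <- nrow(rules)
  wbc <- wbl <- rep(NA_real_, n)
  keep <- rep(TRUE, n)
  cons_supp_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    a <- parse_itemset(rules$antecedent[i])
    b <- parse_itemset(rules$consequent[i])
    sa <- env$supp(mask_for(env, a))
    sab <- env$supp(mask_for(env, c(a, b)))
    key <- rules$consequent[i]
    sb <- if (!is.null(cons_supp_cache[[key]])) cons_supp_cache[[key]]
          else (cons_supp_cache[[key]] <- env$supp(mask_for(env, b)))
    wbc[i] <- sab / sa
    if (sb <= 0) {
      keep[i] <- FALSE
      warning(sprintf("rule %s -> %s dropped: consequent support is zero",
                      rules$antecedent[i], rules$consequent[i]))
    } else {
      wbl[i] <- wbc[i] / sb
    }
  }
  out <- as.data.frame(rules)[keep, , drop = FALSE]
  out$wbc <- wbc[keep]
  out$wbl <- wbl[keep]
  out$strong <- out$wbc >= cfg$min_confidence & out$wbl > cfg$min_lift
  ord <- order(-out$wbl, -out$wbc, itemset_key(out$antecedent),
               itemset_key(out$consequent))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("rule_set", "data.frame"), cfg = cfg)
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("rule_set: %d rules", nrow(x)))
  if ("strong" %in% names(x)) cat(sprintf(" (%d strong)", sum(x$strong)))
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Export rules to CSV or JSON
#'
#' @param rules a `rule_set`.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_rules <- function(rules, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(rules)
  if (format == "csv") utils::write.csv(df, path, row.names = FALSE)
  else jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                            digits = NA)
  invisible(path)
}
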