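# Independent oracles used across the suite.  Deliberately naive: plain
# scans, full enumerations and direct products, sharing no code path with
# the package internals they check.

# items present in one record (row of the item matrix), as a set
row_item_set <- function(ds, i) {
  v <- ds$items[i, ]
  sort(unname(v[!is.na(v)]))
}

# per-record weights by direct fold over each record's attribute items
oracle_record_weights <- function(ds, wt, scheme = "mean") {
  w <- stats::setNames(wt$weight, wt$item)
  vapply(seq_len(n_records(ds)), function(i) {
    ids <- ds$items[i, names(ds$schema$attributes)]
    ids <- ids[!is.na(ids)]
    ws <- w[as.character(ids)]
    ws <- ws[!is.na(ws)]
    if (length(ws) == 0) 0 else if (scheme == "sum") sum(ws) else mean(ws)
  }, 1)
}

# weighted support by linear scan over record item sets
oracle_support <- function(itemset, ds, rw, sets = NULL) {
  sets <- sets %||% lapply(seq_len(n_records(ds)), function(i)
    row_item_set(ds, i))
  has <- vapply(sets, function(s) all(itemset %in% s), TRUE)
  sum(rw[has]) / sum(rw)
}

# all antecedent itemsets of up to max_size attribute items, one per attribute
oracle_antecedents <- function(schema, max_size) {
  universe <- unlist(schema$attributes, use.names = FALSE)
  owner <- rep(names(schema$attributes),
               vapply(schema$attributes, length, 1L))
  names(owner) <- universe
  sets <- list()
  for (k in seq_len(max_size)) {
    for (cmb in utils::combn(universe, k, simplify = FALSE))
      if (!anyDuplicated(owner[as.character(cmb)]))
        sets[[length(sets) + 1L]] <- cmb
  }
  sets
}

# exhaustive enumeration of weighted rules, no Apriori, no shared code
oracle_mine <- function(ds, wt, cfg, mode) {
  schema <- ds$schema
  rw <- oracle_record_weights(ds, wt, attr(wt, "record_scheme") %||% "mean")
  universe <- unlist(schema$attributes, use.names = FALSE)
  owner <- rep(names(schema$attributes),
               vapply(schema$attributes, length, 1L))
  names(owner) <- universe
  sets <- lapply(seq_len(n_records(ds)), function(i) row_item_set(ds, i))
  rows <- list()
  push <- function(a, b) {
    sa <- oracle_support(a, ds, rw, sets)
    if (sa <= 0) return()
    sab <- oracle_support(c(a, b), ds, rw, sets)
    conf <- sab / sa
    if (sab >= cfg$min_support && conf >= cfg$min_confidence)
      rows[[length(rows) + 1L]] <<- data.frame(
        antecedent = paste(sort(a), collapse = ","),
        consequent = paste(sort(b), collapse = ","),
        ws = sab, wc = conf, stringsAsFactors = FALSE)
  }
  if (mode == "two_attribute") {
    for (a in universe) for (b in universe)
      if (a != b && owner[as.character(a)] != owner[as.character(b)])
        push(a, b)
  } else if (mode == "multi_attribute") {
    for (a in oracle_antecedents(schema, cfg$max_antecedent_size))
      for (b in universe)
        if (!(owner[as.character(b)] %in% owner[as.character(a)]))
          push(a, b)
  } else {
    for (a in oracle_antecedents(schema, cfg$max_antecedent_size))
      for (cls in schema$class_items) push(a, cls)
  }
  if (length(rows) == 0L)
    return(data.frame(antecedent = character(0), consequent = character(0),
                      ws = numeric(0), wc = numeric(0)))
  do.call(rbind, rows)
}

# plain (unweighted) Apriori-style reference: classical support/confidence
# by record counting
oracle_classical <- function(ds, cfg, mode) {
  n <- n_records(ds)
  sets <- lapply(seq_len(n), function(i) row_item_set(ds, i))
  supp <- function(itemset)
    sum(vapply(sets, function(s) all(itemset %in% s), TRUE)) / n
  schema <- ds$schema
  universe <- unlist(schema$attributes, use.names = FALSE)
  owner <- rep(names(schema$attributes),
               vapply(schema$attributes, length, 1L))
  names(owner) <- universe
  rows <- list()
  push <- function(a, b) {
    sa <- supp(a)
    if (sa <= 0) return()
    sab <- supp(c(a, b))
    conf <- sab / sa
    if (sab >= cfg$min_support && conf >= cfg$min_confidence)
      rows[[length(rows) + 1L]] <<- data.frame(
        antecedent = paste(sort(a), collapse = ","),
        consequent = paste(sort(b), collapse = ","),
        support = sab, confidence = conf, stringsAsFactors = FALSE)
  }
  if (mode == "two_attribute") {
    for (a in universe) for (b in universe)
      if (a != b && owner[as.character(a)] != owner[as.character(b)])
        push(a, b)
  } else if (mode == "class_label") {
    for (a in oracle_antecedents(schema, cfg$max_antecedent_size))
      for (cls in schema$class_items) push(a, cls)
  } else {
    for (a in oracle_antecedents(schema, cfg$max_antecedent_size))
      for (b in universe)
        if (!(owner[as.character(b)] %in% owner[as.character(a)]))
          push(a, b)
  }
  if (length(rows) == 0L)
    return(data.frame(antecedent = character(0), consequent = character(0),
                      support = numeric(0), confidence = numeric(0)))
  do.call(rbind, rows)
}

# full joint table of a bayes_net by direct CPT products (column lookups by
# name, no call into joint_probability)
oracle_joint_table <- function(bn) {
  grid <- expand.grid(bn$values, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  p <- rep(1, nrow(grid))
  for (nd in bn$nodes) {
    cpt <- bn$cpts[[nd]]
    pa <- bn$parents[[nd]]
    for (r in seq_len(nrow(grid))) {
      idx <- c(grid[r, nd], unlist(grid[r, pa, drop = TRUE]))
      p[r] <- p[r] * do.call(`[`, c(list(cpt), as.list(idx)))
    }
  }
  grid$p <- p
  grid
}

# posterior over the class node by conditioning the full joint table
oracle_posterior <- function(bn, evidence) {
  tab <- oracle_joint_table(bn)
  keep <- rep(TRUE, nrow(tab))
  for (nd in names(evidence))
    if (nd %in% names(tab)) keep <- keep & tab[[nd]] == evidence[[nd]]
  tab <- tab[keep, , drop = FALSE]
  post <- tapply(tab$p, tab$class, sum)
  post <- as.numeric(post[bn$values$class])
  names(post) <- bn$values$class
  post / sum(post)
}

# best-scoring parent set per node by exhaustive search over predecessors
oracle_k2_exhaustive <- function(df, order, max_parents) {
  score <- function(node, pa) wbbn:::ch_family_score(df[[node]],
                                                     if (length(pa)) df[pa])
  dag <- stats::setNames(vector("list", length(order)), order)
  for (i in seq_along(order)) {
    node <- order[i]
    preds <- order[seq_len(i - 1L)]
    best <- character(0); best_s <- score(node, character(0))
    for (k in seq_len(min(length(preds), max_parents))) {
      for (pa in utils::combn(preds, k, simplify = FALSE)) {
        s <- score(node, pa)
        if (s > best_s + 1e-12) { best <- pa; best_s <- s }
      }
    }
    dag[[node]] <- sort(best)
  }
  dag
}

`%||%` <- function(a, b) if (is.null(a)) b else a
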