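#' Convert an item dataset to a factor data frame
#'
#' Network learning works on node values rather than raw item IDs: each
#' attribute column becomes a factor over its bin indices (`"1"`, `"2"`, ...
#' in schema bin order), and the class column a `no`/`yes` factor with `yes`
#' the positive class.
#'
#' @param ds a missing-free `item_dataset`.
#' @return a data.frame of factors, one column per attribute plus `class`.
#' @export
as_value_frame <- function(ds) {
  schema <- ds$schema
  out <- lapply(names(schema$attributes), function(nm)
    factor(as.character(match(ds$items[, nm], schema$attributes[[nm]])),
           levels = as.character(seq_along(schema$attributes[[nm]]))))
  names(out) <- names(schema$attributes)
  neg <- setdiff(schema$class_items, schema$class_positive)
  out$class <- factor(ifelse(ds$items[, ".class"] == schema$class_positive,
                             "yes", "no"), levels = c("no", "yes"))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Node ordering for K2 from strong rules
#'
#' K2 needs a total order over nodes; parents can only precede children.
#' Nodes (the attributes occurring in any strong rule) are ordered by
#' descending total pair weight of their items, so the attributes carrying
#' the most positive-class evidence come first and may become ancestors;
#' ties break alphabetically and the class node always comes last.
#'
#' @param strong_rules a scored `rule_set`; only rows with `strong = TRUE`
#'   are used.
#' @param wt a `weight_table`.
#' @param schema the dataset's `attribute_schema`.
#' @return character vector of node names ending in `"class"`.
#' @export
build_node_order <- function(strong_rules, wt, schema) {
  rules <- strong_rules[strong_rules$strong %||% rep(TRUE, nrow(strong_rules)), ,
                        drop = FALSE]
  if (nrow(rules) == 0L) stop("no strong rules; nothing to order")
  owner <- item_owner(schema)
  ids <- unique(unlist(lapply(c(rules$antecedent, rules$consequent),
                              parse_itemset)))
  attrs <- setdiff(unique(owner[as.character(ids)]), "<class>")
  tot <- vapply(attrs, function(a)
    sum(wt$weight[wt$item %in% schema$attributes[[a]]]), 1)
  # round away last-ulp summation noise so equal totals really tie
  c(attrs[order(-round(tot, 12), attrs)], "class")
}

# pairs of attributes (and attribute-class pairs) co-occurring in a strong
# rule; the allowed K2 edges when candidate restriction is on
rule_candidate_edges <- function(strong_rules, schema) {
  rules <- strong_rules[strong_rules$strong %||% rep(TRUE, nrow(strong_rules)), ,
                        drop = FALSE]
  owner <- item_owner(schema)
  pairs <- list()
  for (i in seq_len(nrow(rules))) {
    ids <- c(parse_itemset(rules$antecedent[i]),
             parse_itemset(rules$consequent[i]))
    nodes <- unique(owner[as.character(ids)])
    nodes[nodes == "<class>"] <- "class"
    if (length(nodes) < 2L) next
    cmb <- utils::combn(sort(nodes), 2L)
    for (j in seq_len(ncol(cmb)))
      pairs[[length(pairs) + 1L]] <- cmb[, j]
  }
  unique(pairs)
}

# Cooper-Herskovits family score (log scale, uniform Dirichlet(1) prior):
# sum over parent configs j of  lgamma(r) - lgamma(N_j + r) +
# sum over child states k of lgamma(N_jk + 1)
ch_family_score <- function(x, parents_df = NULL) {
  r <- nlevels(x)
  if (is.null(parents_df) || ncol(as.data.frame(parents_df)) == 0L) {
    nk <- tabulate(x, nbins = r)
    return(lgamma(r) - lgamma(sum(nk) + r) + sum(lgamma(nk + 1)))
  }
  parents_df <- as.data.frame(parents_df)
  cfg <- interaction(parents_df, drop = TRUE, lex.order = TRUE)
  tab <- table(cfg, x)
  nj <- rowSums(tab)
  sum(lgamma(r) - lgamma(nj + r)) + sum(lgamma(tab + 1))
}

#' K2 structure learning
#'
#' Greedy parent search under a fixed node order: each node starts
#' parentless and repeatedly adopts the earlier-ordered candidate that most
#' improves its Cooper-Herskovits marginal-likelihood score, stopping when
#' no candidate improves the score or `max_parents` is reached.  The result
#' is acyclic by construction.
#'
#' @param df factor data.frame (see [as_value_frame()]); only columns named
#'   in `order` are used.
#' @param order character vector: the node order (ancestors first).
#' @param max_parents cap on parents per node.
#' @param candidate_edges optional list of character pairs (unordered); when
#'   given, a node may only adopt parents it is paired with.  `NULL` leaves
#'   the search unrestricted.
#' @return named list: for each node, the character vector of its parents.
#' @export
k2_learn <- function(df, order, max_parents = 3L, candidate_edges = NULL) {
  if (!all(order %in% names(df)))
    stop("node order names columns absent from the data")
  max_parents <- as.integer(max_parents)
  if (max_parents < 1L) stop("max_parents must be >= 1")
  allowed <- function(node, cand) {
    if (is.null(candidate_edges)) return(TRUE)
    any(vapply(candidate_edges, function(p) setequal(p, c(node, cand)), TRUE))
  }
  dag <- stats::setNames(vector("list", length(order)), order)
  for (i in seq_along(order)) {
    node <- order[i]
    pa <- character(0)
    best <- ch_family_score(df[[node]])
    repeat {
      if (length(pa) >= max_parents) break
      cands <- setdiff(order[seq_len(i - 1L)], pa)
      cands <- cands[vapply(cands, function(cc) allowed(node, cc), TRUE)]
      if (length(cands) == 0L) break
      scores <- vapply(cands, function(cc)
        ch_family_score(df[[node]], df[c(pa, cc)]), 1)
      if (max(scores) > best + 1e-12) {
        j <- which.max(scores)
        pa <- c(pa, cands[j])
        best <- scores[j]
      } else break
    }
    dag[[node]] <- pa
  }
  dag
}

# total CH score of a DAG given data (used in invariants/tests)
ch_dag_score <- function(df, dag) {
  sum(vapply(names(dag), function(nd)
    ch_family_score(df[[nd]], if (length(dag[[nd]])) df[dag[[nd]]]), 1))
}

#' Learn smoothed conditional probability tables
#'
#' For each node and parent configuration, P(v | pa) =
#' (N(v, pa) + alpha) / (N(pa) + alpha * k) where k is the node's arity and
#' alpha the per-cell Dirichlet pseudo-count (default 0.5).  A parent
#' configuration never observed yields the uniform 1/k.
#'
#' @param df factor data.frame of the training records.
#' @param dag named parent list from [k2_learn()].
#' @param alpha smoothing pseudo-count, > 0.
#' @return a `bayes_net`: nodes, values, parents, CPT arrays (child dimension
#'   first), the learning order and `majority_class`.
#' @export
learn_cpts <- function(df, dag, alpha = 0.5) {
  if (alpha <= 0) stop("alpha must be > 0")
  nodes <- names(dag)
  cpts <- vector("list", length(nodes)); names(cpts) <- nodes
  values <- lapply(df[nodes], levels); names(values) <- nodes
  for (nd in nodes) {
    pa <- dag[[nd]]
    k <- nlevels(df[[nd]])
    if (length(pa) == 0L) {
      nk <- tabulate(df[[nd]], nbins = k)
      p <- (nk + alpha) / (sum(nk) + alpha * k)
      cpts[[nd]] <- array(p, dim = k, dimnames = list(values[[nd]]))
    } else {
      counts <- table(df[[nd]], interaction(df[pa], lex.order = TRUE,
                                            drop = FALSE))
      dims <- unname(c(k, vapply(values[pa], length, 1L)))
      arr <- array(as.numeric(counts), dim = dims,
                   dimnames = c(values[nd], values[pa]))
      nj <- apply(arr, seq_along(dims)[-1L], sum)
      p <- sweep(arr + alpha, seq_along(dims)[-1L], nj + alpha * k, "/")
      cpts[[nd]] <- p
    }
  }
  maj <- names(which.max(table(df$class)))
  structure(list(nodes = nodes, values = values, parents = dag, cpts = cpts,
                 node_order = nodes, alpha = alpha,
                 majority_class = if (length(maj)) maj else "no"),
            class = "bayes_net")
}

#' @export
print.bayes_net <- function(x, ...) {
  cat(sprintf("bayes_net: %d nodes, %d edges (alpha = %g)\n",
              length(x$nodes), sum(lengths(x$parents)), x$alpha))
  for (nd in x$nodes)
    if (length(x$parents[[nd]]))
      cat(sprintf("  %s <- {%s}\n", nd, paste(x$parents[[nd]], collapse = ", ")))
  invisible(x)
}

cpt_entry <- function(bn, node, assignment) {
  idx <- c(assignment[[node]], unlist(assignment[bn$parents[[node]]],
                                      use.names = FALSE))
  do.call(`[`, c(list(bn$cpts[[node]]), as.list(idx)))
}

#' Joint probability of a full assignment
#'
#' The factored joint: the product over nodes of P(node value | parent
#' values) read off the CPTs.
#'
#' @param assignment named list or character vector giving one value (level
#'   label) for every node of the network.
#' @param bn a `bayes_net`.
#' @return probability in (0, 1\].
#' @export
joint_probability <- function(assignment, bn) {
  assignment <- as.list(assignment)
  if (!all(bn$nodes %in% names(assignment)))
    stop(sprintf("assignment is missing node(s): %s",
                 paste(setdiff(bn$nodes, names(assignment)), collapse = ", ")))
  prod(vapply(bn$nodes, function(nd) cpt_entry(bn, nd, assignment), 1))
}

# posterior over `target` given evidence (named values), by exact
# enumeration over all unobserved nodes
enumerate_posterior <- function(bn, evidence, target = "class") {
  evidence <- as.list(evidence)
  evidence <- evidence[names(evidence) %in% bn$nodes]
  hidden <- setdiff(bn$nodes, c(names(evidence), target))
  tlev <- bn$values[[target]]
  post <- stats::setNames(numeric(length(tlev)), tlev)
  grids <- bn$values[hidden]
  combos <- if (length(grids)) expand.grid(grids, stringsAsFactors = FALSE)
            else data.frame(row.names = 1L)
  for (tv in tlev) {
    tot <- 0
    for (r in seq_len(max(nrow(combos), 1L))) {
      asg <- c(evidence, stats::setNames(list(tv), target),
               if (length(hidden)) as.list(combos[r, hidden, drop = FALSE]))
      tot <- tot + joint_probability(asg, bn)
    }
    post[tv] <- tot
  }
  post / sum(post)
}

#' Classify records with a learned network
#'
#' Exact-enumeration posterior of the class node given the record's
#' attribute values as evidence; attributes absent from the model are
#' ignored.  Returns the argmax class and its posterior; exact posterior
#' ties go to the training majority class.
#'
#' @param object a `bayes_net`.
#' @param newdata a factor data.frame (e.g. [as_value_frame()] output) or a
#'   single named list of values; the `class` column, if present, is ignored.
#' @param ... unused.
#' @return data.frame with columns `class` and `posterior` (the posterior
#'   probability of the predicted class), one row per record.
#' @export
predict.bayes_net <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(newdata)
  ev_cols <- intersect(setdiff(object$nodes, "class"), names(newdata))
  n <- nrow(newdata)
  cls <- character(n); pp <- numeric(n)
  for (i in seq_len(n)) {
    ev <- lapply(newdata[i, ev_cols, drop = FALSE], as.character)
    post <- enumerate_posterior(object, ev, "class")
    top <- names(post)[post == max(post)]
    cls[i] <- if (length(top) > 1L && object$majority_class %in% top)
      object$majority_class else top[1L]
    pp[i] <- post[cls[i]]
  }
  data.frame(class = cls, posterior = pp, stringsAsFactors = FALSE)
}

#' Serialize a network to JSON and back
#'
#' Nodes, value labels, parent sets and CPT arrays (flattened column-major
#' with their dimensions) survive a round trip exactly.
#'
#' @param bn a `bayes_net`.
#' @param path JSON file path.
#' @export
write_bn_json <- function(bn, path) {
  obj <- list(nodes = bn$nodes, values = bn$values, parents = bn$parents,
              alpha = bn$alpha, majority_class = bn$majority_class,
              cpts = lapply(bn$cpts, function(a)
                list(dim = dim(a), dimnames = dimnames(a),
                     p = as.numeric(a))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_bn_json
#' @export
read_bn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- as.character(unlist(obj$nodes))
  values <- lapply(nodes, function(nd) as.character(unlist(obj$values[[nd]])))
  names(values) <- nodes
  parents <- lapply(nodes, function(nd)
    as.character(unlist(obj$parents[[nd]])))
  names(parents) <- nodes
  cpts <- lapply(nodes, function(nd) {
    cc <- obj$cpts[[nd]]
    dn <- lapply(cc$dimnames, function(v) as.character(unlist(v)))
    array(as.numeric(unlist(cc$p)), dim = as.integer(unlist(cc$dim)),
          dimnames = dn)
  })
  names(cpts) <- nodes
  structure(list(nodes = nodes, values = values, parents = parents,
                 cpts = cpts, node_order = nodes,
                 alpha = as.numeric(obj$alpha),
                 majority_class = as.character(obj$majority_class)),
            class = "bayes_net")
}

#' Export a network in XMLBIF 0.3
#'
#' Interchange format readable by common Bayesian-network viewers.  CPT rows
#' follow XMLBIF convention: one probability block per parent configuration,
#' child states varying fastest.
#'
#' @param bn a `bayes_net`.
#' @param path output path.
#' @param name network name attribute.
#' @export
write_xmlbif <- function(bn, path, name = "wbbn") {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<BIF VERSION="0.3">', "<NETWORK>",
             sprintf("<NAME>%s</NAME>", esc(name)))
  for (nd in bn$nodes) {
    lines <- c(lines, '<VARIABLE TYPE="nature">',
               sprintf("  <NAME>%s</NAME>", esc(nd)),
               sprintf("  <OUTCOME>%s</OUTCOME>", esc(bn$values[[nd]])),
               "</VARIABLE>")
  }
  for (nd in bn$nodes) {
    a <- bn$cpts[[nd]]
    pa <- bn$parents[[nd]]
    # child-first array -> parent-config-major table, child fastest
    tab <- as.numeric(a)
    k <- length(bn$values[[nd]])
    m <- matrix(tab, nrow = k)
    lines <- c(lines, "<DEFINITION>",
               sprintf("  <FOR>%s</FOR>", esc(nd)),
               if (length(pa)) sprintf("  <GIVEN>%s</GIVEN>", esc(pa)),
               sprintf("  <TABLE>%s</TABLE>",
                       paste(format(as.numeric(m), digits = 17),
                             collapse = " ")),
               "</DEFINITION>")
  }
  writeLines(c(lines, "</NETWORK>", "</BIF>"), path)
  invisible(path)
}
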