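#' Specification of a synthetic discretized dataset
#'
#' A generator spec plants a Bayesian network over binary clinical-style
#' attributes plus a binary class node and samples records ancestrally from
#' it, so all ground truth (structure, CPTs, class prior, and the analytic
#' strong-rule set) is known.  The default shape mirrors a discretized
#' breast-cancer table: 9 binary attributes with contiguous item IDs
#' 1..18, class items 19 (no) / 20 (yes), positive-class prior 0.35.
#'
#' @param n_attributes number of binary attributes.
#' @param class_prior P(class = yes) when the class node has no parents.
#' @param dag named list of parent vectors over nodes `A1..An` and `class`;
#'   NULL means no edges.
#' @param cpts named list of CPT arrays (child dimension first, dimnames
#'   from each node's value labels); omitted nodes get uniform bins, and the
#'   class node gets its prior.  Attribute values are labelled `"1"`/`"2"`
#'   (low/high bin), the class `"no"`/`"yes"`.
#' @param n_records records to draw.
#' @param missing_rate per-cell probability of blanking an attribute value
#'   (the record is then flagged missing), in \[0, 1).
#' @param seed RNG seed used by [generate()].
#' @return a `generator_spec`.
#' @export
generator_spec <- function(n_attributes = 9L, class_prior = 0.35,
                           dag = NULL, cpts = NULL, n_records = 683L,
                           missing_rate = 0, seed = 1L) {
  n_attributes <- as.integer(n_attributes)
  stopifnot(n_attributes >= 1L, class_prior > 0, class_prior < 1,
            missing_rate >= 0, missing_rate < 1, n_records >= 0L)
  nodes <- c(paste0("A", seq_len(n_attributes)), "class")
  values <- c(stats::setNames(rep(list(c("1", "2")), n_attributes),
                              nodes[seq_len(n_attributes)]),
              list(class = c("no", "yes")))
  dag <- dag %||% stats::setNames(rep(list(character(0)), length(nodes)),
                                  nodes)
  for (nd in nodes) dag[[nd]] <- as.character(dag[[nd]] %||% character(0))
  if (!setequal(names(dag), nodes)) stop("dag must name exactly the spec's nodes")
  dag <- dag[nodes]
  if (is.null(topological_order(dag))) stop("planted dag is cyclic")
  cpts <- cpts %||% list()
  for (nd in nodes) {
    k <- length(values[[nd]])
    if (is.null(cpts[[nd]])) {
      if (length(dag[[nd]]) > 0L)
        stop(sprintf("node %s has parents but no CPT", nd))
      p <- if (nd == "class") c(1 - class_prior, class_prior)
           else rep(1 / k, k)
      cpts[[nd]] <- array(p, dim = k, dimnames = values[nd])
    } else {
      a <- cpts[[nd]]
      dims <- c(k, vapply(values[dag[[nd]]], length, 1L))
      if (!identical(as.integer(dim(a) %||% length(a)), as.integer(dims)))
        stop(sprintf("CPT for %s has wrong dimensions", nd))
      a <- array(as.numeric(a), dim = dims, dimnames = c(values[nd],
                                                         values[dag[[nd]]]))
      sums <- if (length(dims) > 1L) apply(a, seq_along(dims)[-1L], sum)
              else sum(a)
      if (any(abs(sums - 1) > 1e-9))
        stop(sprintf("CPT for %s is not normalized", nd))
      cpts[[nd]] <- a
    }
  }
  structure(list(n_attributes = n_attributes, class_prior = class_prior,
                 nodes = nodes, values = values, dag = dag,
                 cpts = cpts[nodes], n_records = as.integer(n_records),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "generator_spec")
}

# Kahn topological sort; NULL if cyclic
topological_order <- function(dag) {
  nodes <- names(dag)
  indeg <- vapply(dag, length, 1L)
  out <- character(0)
  ready <- nodes[indeg == 0L]
  while (length(ready)) {
    nd <- sort(ready)[1L]
    ready <- setdiff(ready, nd)
    out <- c(out, nd)
    for (m in nodes) {
      if (nd %in% dag[[m]] && !(m %in% out)) {
        indeg[m] <- indeg[m] - 1L
        if (indeg[m] == 0L) ready <- c(ready, m)
      }
    }
  }
  if (length(out) == length(nodes)) out else NULL
}

# schema matching a spec's item layout (2 items per attribute, class last)
spec_schema <- function(spec) {
  n <- spec$n_attributes
  attrs <- stats::setNames(lapply(seq_len(n), function(i)
    as.integer(c(2L * i - 1L, 2L * i))), paste0("A", seq_len(n)))
  attribute_schema(attrs, class_items = c(2L * n + 1L, 2L * n + 2L),
                   class_positive = 2L * n + 2L)
}

#' Sample a dataset from a generator spec
#'
#' Ancestral sampling: nodes are drawn in topological order, each from its
#' CPT row for the sampled parent values.  Value `"1"`/`"2"` of attribute
#' `Ai` maps to item ID `2i-1`/`2i`; class `no`/`yes` to the last two item
#' IDs.  Missing cells are then blanked independently at `missing_rate`.
#' Reproducible: the spec's `seed` drives all randomness (the caller's RNG
#' state is untouched).
#'
#' @param spec a [generator_spec()].
#' @return an `item_dataset` (records flagged missing where cells were
#'   blanked).
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  schema <- spec_schema(spec)
  ord <- topological_order(spec$dag)
  n <- spec$n_records
  draws <- stats::setNames(vector("list", length(spec$nodes)), spec$nodes)
  with_seed(spec$seed, {
    for (nd in ord) {
      k <- length(spec$values[[nd]])
      pa <- spec$dag[[nd]]
      if (length(pa) == 0L) {
        p <- as.numeric(spec$cpts[[nd]])
        draws[[nd]] <- sample.int(k, n, replace = TRUE, prob = p)
      } else {
        out <- integer(n)
        pav <- do.call(cbind, lapply(draws[pa], identity))
        cfg <- apply(pav, 1L, paste, collapse = "|")
        for (u in unique(cfg)) {
          idx <- which(cfg == u)
          sel <- as.integer(strsplit(u, "|", fixed = TRUE)[[1]])
          slice <- spec$cpts[[nd]]
          args <- c(list(slice), list(seq_len(k)), as.list(sel))
          p <- as.numeric(do.call(`[`, args))
          out[idx] <- sample.int(k, length(idx), replace = TRUE, prob = p)
        }
        draws[[nd]] <- out
      }
    }
    cols <- c(paste0("A", seq_len(spec$n_attributes)), ".class")
    mat <- matrix(NA_integer_, nrow = n, ncol = length(cols),
                  dimnames = list(NULL, cols))
    for (i in seq_len(spec$n_attributes))
      mat[, i] <- schema$attributes[[i]][draws[[paste0("A", i)]]]
    mat[, ".class"] <- schema$class_items[draws[["class"]]]
    if (spec$missing_rate > 0 && n > 0L) {
      blank <- matrix(stats::runif(n * spec$n_attributes) < spec$missing_rate,
                      nrow = n)
      mat[, seq_len(spec$n_attributes)][blank] <- NA_integer_
    }
    item_dataset(mat, schema)
  })
}

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# full joint table of a spec: data.frame of node values + column p
joint_table <- function(spec) {
  if (length(spec$nodes) > 12L)
    stop("joint enumeration supported for at most 12 nodes")
  grid <- expand.grid(spec$values, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  bn <- structure(list(nodes = spec$nodes, values = spec$values,
                       parents = spec$dag, cpts = spec$cpts),
                  class = "bayes_net")
  grid$p <- vapply(seq_len(nrow(grid)), function(r)
    joint_probability(as.list(grid[r, spec$nodes, drop = FALSE]), bn), 1)
  grid
}

# item IDs present in one joint-table row
row_items <- function(grid_row, spec, schema) {
  ids <- integer(0)
  for (i in seq_len(spec$n_attributes)) {
    v <- match(grid_row[[paste0("A", i)]], spec$values[[paste0("A", i)]])
    ids <- c(ids, schema$attributes[[i]][v])
  }
  cls <- match(grid_row[["class"]], c("no", "yes"))
  c(ids, schema$class_items[cls])
}

#' Analytic strong rules of a planted distribution
#'
#' Computes exact supports, confidences and lifts of every candidate rule
#' directly from the spec's joint distribution (enumerated over at most 12
#' nodes) under uniform record weights, then applies the thresholds.  This
#' is the limit the data-driven miner approaches as the sample grows.
#'
#' @param spec a [generator_spec()].
#' @param cfg a [threshold_config()].
#' @param mode rule family, as in [mine_rules()].
#' @return a scored `rule_set` (columns `ws`, `wc`, `wbc`, `wbl`, `strong`).
#' @export
expected_strong_rules <- function(spec, cfg = threshold_config(),
                                  mode = c("two_attribute", "multi_attribute",
                                           "class_label")) {
  mode <- match.arg(mode)
  schema <- spec_schema(spec)
  grid <- joint_table(spec)
  items <- lapply(seq_len(nrow(grid)), function(r)
    row_items(grid[r, , drop = FALSE], spec, schema))
  supp <- function(itemset) {
    sum(grid$p[vapply(items, function(s) all(itemset %in% s), TRUE)])
  }
  universe <- attribute_item_ids(schema)
  owner <- item_owner(schema)
  ant <- con <- character(0); ws <- wc <- numeric(0)
  emit <- function(a, c_) {
    sa <- supp(a)
    if (sa <= 0) return()
    s_full <- supp(c(a, c_))
    conf <- s_full / sa
    if (s_full >= cfg$min_support && conf >= cfg$min_confidence) {
      ant <<- c(ant, itemset_str(a)); con <<- c(con, itemset_str(c_))
      ws <<- c(ws, s_full); wc <<- c(wc, conf)
    }
  }
  antecedent_sets <- function(max_size) {
    sets <- list()
    for (k in seq_len(max_size)) {
      cmb <- utils::combn(universe, k, simplify = FALSE)
      sets <- c(sets, Filter(function(s)
        !anyDuplicated(owner[as.character(s)]), cmb))
    }
    sets
  }
  if (mode == "two_attribute") {
    for (a in universe) for (b in universe) {
      if (a == b || owner[as.character(a)] == owner[as.character(b)]) next
      emit(a, b)
    }
  } else if (mode == "multi_attribute") {
    for (a in antecedent_sets(cfg$max_antecedent_size)) {
      for (b in universe) {
        if (b %in% a || owner[as.character(b)] %in% owner[as.character(a)])
          next
        emit(a, b)
      }
    }
  } else {
    for (a in antecedent_sets(cfg$max_antecedent_size))
      for (cls in schema$class_items) emit(a, cls)
  }
  rules <- new_rule_set(ant, con, ws, wc, mode, cfg)
  n <- nrow(rules)
  if (n == 0L) {
    rules$wbc <- rules$wbl <- numeric(0); rules$strong <- logical(0)
    return(rules)
  }
  rules$wbc <- rules$wc
  rules$wbl <- vapply(seq_len(n), function(i)
    rules$wc[i] / supp(parse_itemset(rules$consequent[i])), 1)
  rules$strong <- rules$wbc >= cfg$min_confidence & rules$wbl > cfg$min_lift
  ord <- order(-rules$wbl, -rules$wbc, itemset_key(rules$antecedent),
               itemset_key(rules$consequent))
  out <- as.data.frame(rules)[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("rule_set", "data.frame"), cfg = cfg)
}

#' Preset generator specs
#'
#' Ready-made study conditions:
#' \describe{
#'   \item{`spec_independent()`}{no edges at all; every attribute an
#'     independent fair coin, class at its prior.  Lifts are 1 in the limit.}
#'   \item{`spec_separable()`}{three informative attributes with
#'     P(high | malignant) = 0.95 and P(high | benign) = 0.05; the rest are
#'     noise.  The Bayes error is below 0.02, so a sound pipeline should
#'     classify held-out records almost perfectly.}
#'   \item{`spec_chain()`}{three nodes A1 -> A2 -> class with strong links
#'     (0.9 / 0.1 conditionals); the ground truth for structure-recovery
#'     experiments.}
#'   \item{`spec_wbc_like()`}{the 9-attribute default shape with a handful of
#'     planted attribute-attribute and attribute-class dependencies,
#'     emulating a discretized clinical table at ~700 records.}
#' }
#'
#' @param n_records records to draw.
#' @param seed RNG seed.
#' @param missing_rate per-cell missingness (default 0).
#' @return a `generator_spec`.
#' @export
spec_independent <- function(n_records = 10000L, seed = 1L,
                             missing_rate = 0) {
  generator_spec(n_attributes = 9L, class_prior = 0.35,
                 n_records = n_records, missing_rate = missing_rate,
                 seed = seed)
}

#' @rdname spec_independent
#' @export
spec_separable <- function(n_records = 683L, seed = 1L, missing_rate = 0) {
  informative <- paste0("A", 1:3)
  dag <- stats::setNames(rep(list(character(0)), 10L),
                         c(paste0("A", 1:9), "class"))
  cpts <- list()
  for (nd in informative) {
    dag[[nd]] <- "class"
    cpts[[nd]] <- array(c(0.95, 0.05,   # class = no : mostly low bin
                          0.05, 0.95),  # class = yes: mostly high bin
                        dim = c(2L, 2L),
                        dimnames = list(c("1", "2"), c("no", "yes")))
  }
  generator_spec(n_attributes = 9L, class_prior = 0.35, dag = dag,
                 cpts = cpts, n_records = n_records,
                 missing_rate = missing_rate, seed = seed)
}

#' @rdname spec_independent
#' @export
spec_chain <- function(n_records = 2000L, seed = 1L) {
  dag <- list(A1 = character(0), A2 = "A1", class = "A2")
  cpts <- list(
    A2 = array(c(0.9, 0.1, 0.1, 0.9), dim = c(2L, 2L),
               dimnames = list(c("1", "2"), c("1", "2"))),
    class = array(c(0.9, 0.1, 0.1, 0.9), dim = c(2L, 2L),
                  dimnames = list(c("no", "yes"), c("1", "2"))))
  generator_spec(n_attributes = 2L, class_prior = 0.35, dag = dag,
                 cpts = cpts, n_records = n_records, seed = seed)
}

#' @rdname spec_independent
#' @export
spec_wbc_like <- function(n_records = 683L, seed = 1L, missing_rate = 0) {
  dag <- stats::setNames(rep(list(character(0)), 10L),
                         c(paste0("A", 1:9), "class"))
  cpts <- list()
  # five class-linked attributes of varying strength, one attribute-attribute
  # dependency (A2 -> A3), mimicking correlated cytology measurements
  strength <- c(A1 = 0.90, A2 = 0.85, A4 = 0.80, A5 = 0.75, A6 = 0.85)
  for (nd in names(strength)) {
    s <- strength[[nd]]
    dag[[nd]] <- "class"
    cpts[[nd]] <- array(c(s, 1 - s, 1 - s, s), dim = c(2L, 2L),
                        dimnames = list(c("1", "2"), c("no", "yes")))
  }
  dag[["A3"]] <- "A2"
  cpts[["A3"]] <- array(c(0.85, 0.15, 0.2, 0.8), dim = c(2L, 2L),
                        dimnames = list(c("1", "2"), c("1", "2")))
  generator_spec(n_attributes = 9L, class_prior = 0.35, dag = dag,
                 cpts = cpts, n_records = n_records,
                 missing_rate = missing_rate, seed = seed)
}
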