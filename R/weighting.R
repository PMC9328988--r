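#' Count attribute-value pairs by class label
#'
#' Tallies, for every attribute item in the schema, how many records carry it
#' together with the positive ("yes", malignant) class and with the negative
#' class.  Records flagged missing must be removed first.
#'
#' @param ds a missing-free `item_dataset`.
#' @return data.frame with columns `item`, `attribute`, `count_yes`,
#'   `count_no`, one row per attribute item, in schema item order.
#' @export
count_class_pairs <- function(ds) {
  if (n_records(ds) == 0L) stop("counts are undefined on an empty dataset")
  if (any(ds$missing)) stop("dataset still carries missing records; drop_missing() first")
  yes <- class_is_positive(ds)
  schema <- ds$schema
  ids <- attribute_item_ids(schema)
  owner <- item_owner(schema)
  cy <- cn <- integer(length(ids))
  for (k in seq_along(ids)) {
    col <- owner[as.character(ids[k])]
    has <- ds$items[, col] == ids[k]
    cy[k] <- sum(has & yes)
    cn[k] <- sum(has & !yes)
  }
  data.frame(item = ids, attribute = unname(owner[as.character(ids)]),
             count_yes = cy, count_no = cn)
}

#' Dense ranks over (item, class-label) pairs
#'
#' Ranks are assigned jointly over both class labels: every (item, yes) and
#' (item, no) count enters one pool, the largest count receives rank 1, equal
#' counts share a rank, and ranks are dense (no gaps).  Only the yes-label
#' rank is usually reported, which is why published rank columns need not
#' start at 1.
#'
#' @param counts output of [count_class_pairs()].
#' @return `counts` with added integer columns `rank_yes` and `rank_no`.
#' @export
assign_ranks <- function(counts) {
  pool <- c(counts$count_yes, counts$count_no)
  lev <- sort(unique(pool), decreasing = TRUE)
  rk <- match(pool, lev)
  n <- nrow(counts)
  counts$rank_yes <- rk[seq_len(n)]
  counts$rank_no <- rk[n + seq_len(n)]
  counts
}

#' Weight attribute-value pairs by their positive-class evidence
#'
#' Weights quantify how strongly an attribute-value pair is tied to the
#' malignant class, assembled from the Bayes-theorem quantities of the
#' pair/class contingency:
#' \describe{
#'   \item{`joint` (default)}{w(item) = P(item AND yes) = count_yes / n; the
#'     scale matches published rank/weight tables for this method.}
#'   \item{`posterior`}{w(item) = P(yes | item) = count_yes / count(item),
#'     0 when the item never occurs.}
#' }
#' Pairs never co-occurring with the positive class get weight 0 under both.
#'
#' @param ds a missing-free `item_dataset`.
#' @param scheme `"joint"` or `"posterior"`.
#' @param record_scheme how [record_weight()] folds pair weights: `"mean"`
#'   (default) or `"sum"`.
#' @return a `weight_table`: the ranked count table with a `weight` column
#'   and attributes `total_records`, `scheme`, `record_scheme`.
#' @export
compute_weights <- function(ds, scheme = c("joint", "posterior"),
                            record_scheme = c("mean", "sum")) {
  scheme <- match.arg(scheme)
  record_scheme <- match.arg(record_scheme)
  tab <- assign_ranks(count_class_pairs(ds))
  n <- n_records(ds)
  occ <- tab$count_yes + tab$count_no
  tab$weight <- switch(scheme,
    joint = tab$count_yes / n,
    posterior = ifelse(occ > 0L, tab$count_yes / occ, 0))
  weight_table(tab, total_records = n, scheme = scheme,
               record_scheme = record_scheme)
}

#' Assemble a weight table directly
#'
#' Mostly used to supply externally chosen or simulated pair weights to the
#' rule miner; [compute_weights()] is the data-driven constructor.
#'
#' @param tab data.frame with at least columns `item` and `weight`
#'   (weights in \[0, 1\]).
#' @param total_records record count behind the weights (0 if synthetic).
#' @param scheme,record_scheme bookkeeping tags; see [compute_weights()].
#' @return an object of class `weight_table`.
#' @export
weight_table <- function(tab, total_records = 0L, scheme = "joint",
                         record_scheme = "mean") {
  stopifnot(is.data.frame(tab), all(c("item", "weight") %in% names(tab)))
  if (any(tab$weight < 0 | tab$weight > 1))
    stop("pair weights must lie in [0, 1]")
  if (anyDuplicated(tab$item)) stop("duplicate item in weight table")
  structure(tab, class = c("weight_table", "data.frame"),
            total_records = total_records, scheme = scheme,
            record_scheme = record_scheme)
}

# fast item -> weight lookup vector indexed by item ID
weight_lookup <- function(wt) {
  w <- rep(NA_real_, max(wt$item))
  w[wt$item] <- wt$weight
  w
}

#' Record ("tuple") weight
#'
#' Folds the weights of a record's attribute items (the class item carries no
#' weight) into one per-record weight: the arithmetic mean by default, or the
#' sum under the `"sum"` scheme.  This is the tuple weight every weighted
#' support sums over.
#'
#' @param record integer vector of item IDs (one record).
#' @param wt a `weight_table`.
#' @param scheme override of the table's `record_scheme`.
#' @return a single numeric weight.
#' @export
record_weight <- function(record, wt, scheme = NULL) {
  scheme <- scheme %||% attr(wt, "record_scheme")
  w <- weight_lookup(wt)
  ids <- record[!is.na(record)]
  ids <- ids[ids <= length(w) & !is.na(w[ids])]
  if (length(ids) == 0L) return(0)
  if (scheme == "sum") sum(w[ids]) else mean(w[ids])
}

# per-record weights for a whole dataset, vectorized over the item matrix
record_weights <- function(ds, wt, scheme = NULL) {
  scheme <- scheme %||% attr(wt, "record_scheme")
  w <- weight_lookup(wt)
  mat <- ds$items[, names(ds$schema$attributes), drop = FALSE]
  vals <- matrix(w[mat], nrow = nrow(mat))
  tot <- rowSums(vals, na.rm = TRUE)
  if (scheme == "sum") return(tot)
  cnt <- rowSums(!is.na(vals))
  ifelse(cnt > 0L, tot / cnt, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a weight table as CSV
#'
#' Columns `attribute`, `item`, `count_yes`, `count_no`, `rank_yes`,
#' `weight` (present columns only), mirroring the published layout of
#' per-pair rank/weight tables.
#'
#' @param wt a `weight_table`.
#' @param path CSV path.
#' @export
write_weight_table <- function(wt, path) {
  keep <- intersect(c("attribute", "item", "count_yes", "count_no",
                      "rank_yes", "weight"), names(wt))
  utils::write.csv(as.data.frame(wt)[, keep], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  weight_table(utils::read.csv(path))
}
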