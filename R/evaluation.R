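#' Stratified train/test split
#'
#' Holdout split preserving the class proportions (within one record per
#' class).  `train_frac = 1` returns the full dataset as both partitions —
#' the resubstitution protocol of a 100/100 evaluation row.  Reproducible
#' for a given seed; the caller's RNG state is untouched.
#'
#' @param ds an `item_dataset`.
#' @param train_frac fraction of records to train on, in (0, 1\].
#' @param seed RNG seed.
#' @param stratified stratify by class (default) or split completely at
#'   random.
#' @return list with elements `train` and `test` (`item_dataset`s).
#' @export
split_dataset <- function(ds, train_frac = 0.7, seed = 1L,
                          stratified = TRUE) {
  if (train_frac <= 0 || train_frac > 1)
    stop("train_frac must lie in (0, 1]")
  if (train_frac == 1)
    return(list(train = ds, test = ds))
  n <- n_records(ds)
  with_seed(seed, {
    if (stratified) {
      yes <- class_is_positive(ds)
      take <- logical(n)
      for (grp in list(which(yes), which(!yes))) {
        k <- round(length(grp) * train_frac)
        take[sample(grp, k)] <- TRUE
      }
    } else {
      take <- logical(n)
      take[sample.int(n, round(n * train_frac))] <- TRUE
    }
    list(train = subset_records(ds, take),
         test = subset_records(ds, !take))
  })
}

#' Classification accuracy
#'
#' @param predictions,truths equal-length vectors of class labels.
#' @return fraction of exact matches.
#' @export
accuracy <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length")
  if (length(truths) == 0L) stop("accuracy undefined on an empty test set")
  mean(as.character(predictions) == as.character(truths))
}

#' Run the full weighted-Bayesian-network pipeline once
#'
#' Splits the data, then — on the training partition only — computes pair
#' weights, mines rules in all three modes, scores them and keeps the strong
#' ones, learns the network (K2 over the strong-rule attributes with the
#' class node last, candidate edges restricted to strong-rule co-occurrence,
#' then smoothed CPTs), and finally classifies the test partition.  With
#' zero strong rules no network is built and the majority training class is
#' predicted throughout (with a warning).
#'
#' @param ds a missing-free `item_dataset`.
#' @param cfg a [threshold_config()].
#' @param train_frac,seed,stratified passed to [split_dataset()].
#' @param alpha CPT smoothing pseudo-count.
#' @param weight_scheme pair-weight scheme, see [compute_weights()].
#' @param max_parents K2 parent cap.
#' @param paper_mode when TRUE, pair weights are computed on the full
#'   dataset before splitting (the protocol some published tables imply)
#'   instead of on the training partition only.
#' @param unrestricted_k2 drop the strong-rule candidate-edge restriction.
#' @return one-row data.frame: thresholds, split, `n_rules`,
#'   `n_strong_rules`, `accuracy`, `seed`; the fitted `bayes_net` (or NULL)
#'   in attribute `"model"`, the strong rules in attribute `"strong_rules"`.
#' @export
run_pipeline <- function(ds, cfg = threshold_config(), train_frac = 0.7,
                         seed = 1L, stratified = TRUE, alpha = 0.5,
                         weight_scheme = "joint", max_parents = 3L,
                         paper_mode = FALSE, unrestricted_k2 = FALSE) {
  parts <- split_dataset(ds, train_frac, seed, stratified)
  train <- parts$train; test <- parts$test
  wt <- compute_weights(if (paper_mode) ds else train, scheme = weight_scheme)
  rules <- do.call(rbind, lapply(
    c("two_attribute", "multi_attribute", "class_label"),
    function(m) as.data.frame(mine_rules(train, wt, cfg, mode = m))))
  rules <- rules[!duplicated(rules[c("antecedent", "consequent")]), ,
                 drop = FALSE]
  rules <- structure(rules, class = c("rule_set", "data.frame"), cfg = cfg)
  scored <- if (nrow(rules)) score_strong(rules, train, wt, cfg) else rules
  strong <- scored[isTRUE_v(scored$strong), , drop = FALSE]
  test_df <- as_value_frame(test)
  if (nrow(strong) == 0L) {
    warning("no strong rules; reporting the majority-class baseline")
    maj <- names(which.max(table(as_value_frame(train)$class)))
    acc <- accuracy(rep(maj, nrow(test_df)), test_df$class)
    model <- NULL
  } else {
    ord <- build_node_order(strong, wt, train$schema)
    cand <- if (unrestricted_k2) NULL
            else rule_candidate_edges(strong, train$schema)
    train_df <- as_value_frame(train)
    dag <- k2_learn(train_df[ord], ord, max_parents = max_parents,
                    candidate_edges = cand)
    model <- learn_cpts(train_df[ord], dag, alpha = alpha)
    pred <- predict(model, test_df)
    acc <- accuracy(pred$class, test_df$class)
  }
  row <- data.frame(min_support = cfg$min_support,
                    min_confidence = cfg$min_confidence,
                    min_lift = cfg$min_lift,
                    train_frac = train_frac, test_frac =
                      if (train_frac == 1) 1 else 1 - train_frac,
                    n_rules = nrow(rules),
                    n_strong_rules = nrow(strong),
                    accuracy = acc, seed = as.integer(seed))
  attr(row, "model") <- model
  attr(row, "strong_rules") <- strong
  row
}

isTRUE_v <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

#' Threshold sweep
#'
#' Runs [run_pipeline()] over a grid of (support, confidence) thresholds
#' crossed with train fractions and seeds, one report row each —
#' the shape of a published threshold-sensitivity table.
#'
#' @param ds a missing-free `item_dataset`.
#' @param grid data.frame with columns `min_support`, `min_confidence`
#'   (default: the four published threshold pairs).
#' @param train_fracs numeric vector of train fractions
#'   (default `c(1, 0.8, 0.7, 0.6)`).
#' @param seeds integer vector of split seeds.
#' @param ... further arguments to [run_pipeline()].
#' @return an `evaluation_report` data.frame, one row per configuration per
#'   seed.
#' @export
threshold_sweep <- function(ds,
                            grid = data.frame(
                              min_support = c(0.36, 0.40, 0.26, 0.10),
                              min_confidence = c(0.70, 0.80, 0.60, 0.50)),
                            train_fracs = c(1, 0.8, 0.7, 0.6),
                            seeds = 1L, ...) {
  if (nrow(grid) == 0L) stop("empty threshold grid")
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- threshold_config(min_support = grid$min_support[g],
                            min_confidence = grid$min_confidence[g])
    for (tf in train_fracs) for (sd in seeds) {
      r <- suppressWarnings(
        run_pipeline(ds, cfg, train_frac = tf, seed = sd, ...))
      attr(r, "model") <- NULL; attr(r, "strong_rules") <- NULL
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("evaluation_report", "data.frame"))
}
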