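# Shared fixtures, all built in code at test time.

# tiny 3-attribute schema with items 1..6 + class 7/8 (8 = positive)
toy_schema <- function() {
  attribute_schema(list(a = c(1L, 2L), b = c(3L, 4L), cc = c(5L, 6L)),
                   class_items = c(7L, 8L), class_positive = 8L)
}

# dataset from explicit records (list of item-ID vectors)
toy_dataset <- function(records, schema = toy_schema()) {
  item_dataset(records, schema)
}

# uniform weight table: every attribute item the same weight
uniform_weights <- function(schema, w = 0.5) {
  weight_table(data.frame(item = unlist(schema$attributes,
                                        use.names = FALSE), weight = w))
}

# random dataset + random pair weights for oracle-equivalence runs
random_case <- function(d, n, seed) {
  set.seed(seed)
  marg <- stats::runif(d, 0.2, 0.8)
  cpts <- stats::setNames(lapply(marg, function(p)
    array(c(p, 1 - p), dim = 2L, dimnames = list(c("1", "2")))),
    paste0("A", seq_len(d)))
  spec <- generator_spec(n_attributes = d,
                         class_prior = stats::runif(1, 0.25, 0.6),
                         cpts = cpts, n_records = n, seed = seed)
  ds <- generate(spec)
  wt <- weight_table(data.frame(
    item = seq_len(2L * d),
    weight = round(stats::runif(2L * d, 0.05, 1), 3)))
  list(ds = ds, wt = wt, spec = spec)
}

# synthetic stand-in .num file in the published breast-cancer table's shape:
# 699 records, exactly 16 of them with one attribute value blanked
make_synthetic_wbc_num <- function(path, seed = 1L) {
  ds <- generate(spec_wbc_like(n_records = 699L, seed = seed))
  mat <- ds$items
  set.seed(seed)
  hit <- sample(nrow(mat), 16L)
  for (i in hit) mat[i, sample(9L, 1L)] <- NA_integer_
  lines <- apply(mat, 1L, function(r) paste(sort(r[!is.na(r)]),
                                            collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

# matched comparison of two rule tables (same rules, same measures);
# nrow guards matter: paste() on zero-length columns still yields " => "
expect_same_rules <- function(got, want, tol = 1e-12,
                              measures = c("ws", "wc")) {
  expect_equal(nrow(got), nrow(want))
  if (nrow(got) == 0L || nrow(want) == 0L) return(invisible(NULL))
  gk <- paste(got$antecedent, "=>", got$consequent)
  wk <- paste(want$antecedent, "=>", want$consequent)
  expect_setequal(gk, wk)
  m <- match(wk, gk)
  for (col in measures) {
    wcol <- if (col == "ws" && !"ws" %in% names(want)) "support"
            else if (col == "wc" && !"wc" %in% names(want)) "confidence"
            else col
    expect_equal(got[[col]][m], want[[wcol]], tolerance = tol,
                 ignore_attr = TRUE)
  }
}
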