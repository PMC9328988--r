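test_that("node order sorts strong-rule attributes by total weight, class last", {
  s <- toy_schema()
  wt <- weight_table(data.frame(item = 1:6,
                                weight = c(.1, .1, .4, .3, .2, .1)))
  rules <- data.frame(antecedent = c("3", "1"), consequent = c("7", "5"),
                      strong = c(TRUE, TRUE))
  ord <- build_node_order(rules, wt, s)
  expect_equal(ord, c("b", "cc", "a", "class"))
  # equal weights fall back to alphabetical order
  wt2 <- uniform_weights(s, 0.2)
  expect_equal(build_node_order(rules, wt2, s), c("a", "b", "cc", "class"))
  expect_error(build_node_order(rules[rules$strong == FALSE, ], wt, s),
               "no strong rules")
})

test_that("K2 leaves independent attributes unconnected", {
  spec <- generator_spec(n_attributes = 4L, n_records = 4000L, seed = 17L)
  df <- as_value_frame(generate(spec))
  dag <- k2_learn(df, c(paste0("A", 1:4), "class"), max_parents = 3L)
  expect_equal(sum(lengths(dag)), 0L)
})

test_that("K2 recovers a planted chain and matches exhaustive search", {
  spec <- spec_chain(n_records = 2000L, seed = 23L)
  df <- as_value_frame(generate(spec))
  ord <- c("A1", "A2", "class")
  dag <- k2_learn(df, ord, max_parents = 2L)
  expect_equal(dag$A2, "A1")
  expect_equal(dag$class, "A2")
  ex <- oracle_k2_exhaustive(df, ord, 2L)
  expect_equal(lapply(dag, sort), ex)
})

test_that("K2 DAG scores at least the empty DAG and respects candidates", {
  spec <- spec_wbc_like(n_records = 400L, seed = 6L)
  df <- as_value_frame(generate(spec))
  ord <- c(paste0("A", 1:9), "class")
  dag <- k2_learn(df, ord, max_parents = 3L)
  empty <- stats::setNames(rep(list(character(0)), length(ord)), ord)
  expect_gte(wbbn:::ch_dag_score(df, dag), wbbn:::ch_dag_score(df, empty))
  # candidate restriction: only the allowed pair may appear
  dag2 <- k2_learn(df, ord, max_parents = 3L,
                   candidate_edges = list(c("A1", "class")))
  for (nd in names(dag2))
    expect_true(all(dag2[[nd]] %in% c("A1", "class")))
  expect_error(k2_learn(df, c("A1", "nonexistent"), 2L), "absent")
})

test_that("smoothed CPTs follow the pseudo-count formula", {
  df <- data.frame(
    p = factor(c("1", "1", "1", "1", "2"), levels = c("1", "2")),
    x = factor(c("1", "1", "1", "2", "1"), levels = c("1", "2")),
    class = factor(c("no", "no", "yes", "yes", "no"),
                   levels = c("no", "yes")))
  bn <- learn_cpts(df, list(p = character(0), x = "p",
                            class = character(0)), alpha = 0.5)
  # under p = 1: counts (3, 1) -> (3 + .5)/(4 + 1) = 0.7
  expect_equal(unname(bn$cpts$x["1", "1"]), 0.7)
  expect_equal(unname(bn$cpts$x["2", "1"]), 0.3)
  # parent config p = 2 observed once; never-seen configs give uniform
  df2 <- df[df$p == "1", ]
  bn2 <- learn_cpts(df2, list(p = character(0), x = "p",
                              class = character(0)), alpha = 0.5)
  expect_equal(unname(bn2$cpts$x[, "2"]), c(0.5, 0.5))
  expect_error(learn_cpts(df, list(p = character(0)), alpha = 0),
               "alpha")
})

test_that("every CPT column normalizes and the joint sums to one", {
  spec <- spec_wbc_like(n_records = 250L, seed = 12L)
  df <- as_value_frame(generate(spec))
  sub <- c("A1", "A2", "A3", "class")
  dag <- k2_learn(df[sub], sub, max_parents = 2L)
  bn <- learn_cpts(df[sub], dag)
  for (nd in bn$nodes) {
    a <- bn$cpts[[nd]]
    sums <- if (length(dim(a)) > 1) apply(a, seq_along(dim(a))[-1], sum)
            else sum(a)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  grid <- expand.grid(bn$values, stringsAsFactors = FALSE)
  tot <- sum(vapply(seq_len(nrow(grid)), function(r)
    joint_probability(as.list(grid[r, ]), bn), 1))
  expect_equal(tot, 1, tolerance = 1e-12)
  expect_error(joint_probability(list(A1 = "1"), bn), "missing node")
})

test_that("edgeless fair binary network gives uniform joint probabilities", {
  df <- data.frame(x = factor(rep(c("1", "2"), 500), levels = c("1", "2")),
                   class = factor(rep(c("no", "yes"), each = 500),
                                  levels = c("no", "yes")))
  bn <- learn_cpts(df, list(x = character(0), class = character(0)))
  expect_equal(joint_probability(list(x = "1", class = "no"), bn), 0.25)
})

test_that("CPT recovery error shrinks as the sample grows", {
  err_at <- function(n) {
    errs <- vapply(1:3, function(s) {
      spec <- spec_wbc_like(n_records = n, seed = 100L + s)
      df <- as_value_frame(generate(spec))
      bn <- learn_cpts(df[c("A1", "class")],
                       list(class = character(0), A1 = "class"))
      max(abs(bn$cpts$A1 - spec$cpts$A1))
    }, 1)
    mean(errs)
  }
  e <- vapply(c(200L, 1000L, 5000L), err_at, 1)
  expect_true(all(diff(e) < 0))
  expect_lt(e[3], 0.05)
})

test_that("posterior inference equals the full-joint oracle", {
  spec <- spec_wbc_like(n_records = 300L, seed = 15L)
  df <- as_value_frame(generate(spec))
  sub <- c("A1", "A2", "A4", "class")
  dag <- k2_learn(df[sub], sub, max_parents = 2L)
  bn <- learn_cpts(df[sub], dag)
  set.seed(3)
  for (i in 1:20) {
    ev <- list(A1 = sample(c("1", "2"), 1), A2 = sample(c("1", "2"), 1))
    got <- wbbn:::enumerate_posterior(bn, ev, "class")
    want <- oracle_posterior(bn, ev)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("predict returns the argmax class; disconnected class gives prior", {
  spec <- spec_separable(n_records = 1500L, seed = 19L)
  df <- as_value_frame(generate(spec))
  nodes <- c("A1", "A2", "A3", "class")
  dag <- list(A1 = character(0), A2 = character(0), A3 = character(0),
              class = c("A1", "A2", "A3"))
  bn <- learn_cpts(df[nodes], dag)
  # near-deterministic evidence pattern
  pred <- predict(bn, data.frame(A1 = "2", A2 = "2", A3 = "2",
                                 stringsAsFactors = FALSE))
  expect_equal(pred$class, "yes")
  expect_gt(pred$posterior, 0.95)
  # attributes absent from the model are ignored
  pred2 <- predict(bn, data.frame(A1 = "2", A2 = "2", A3 = "2", A9 = "1",
                                  stringsAsFactors = FALSE))
  expect_equal(pred2, pred)
  # class disconnected from the evidence: posterior equals smoothed prior
  bn0 <- learn_cpts(df[nodes], list(A1 = character(0), A2 = character(0),
                                    A3 = character(0),
                                    class = character(0)))
  p0 <- predict(bn0, data.frame(A1 = "1", stringsAsFactors = FALSE))
  prior <- unname(bn0$cpts$class["no"])
  expect_equal(p0$posterior, max(prior, 1 - prior), tolerance = 1e-12)
})

test_that("networks round-trip through JSON and export to XMLBIF", {
  spec <- spec_wbc_like(n_records = 200L, seed = 33L)
  df <- as_value_frame(generate(spec))
  sub <- c("A1", "A2", "class")
  dag <- k2_learn(df[sub], sub, max_parents = 2L)
  bn <- learn_cpts(df[sub], dag)
  pj <- withr::local_tempfile(fileext = ".json")
  write_bn_json(bn, pj)
  bn2 <- read_bn_json(pj)
  expect_equal(bn2$nodes, bn$nodes)
  expect_equal(bn2$parents, bn$parents)
  expect_equal(bn2$cpts, bn$cpts)
  ev <- data.frame(A1 = "2", A2 = "1", stringsAsFactors = FALSE)
  expect_equal(predict(bn2, ev), predict(bn, ev))
  px <- withr::local_tempfile(fileext = ".xml")
  write_xmlbif(bn, px)
  txt <- readLines(px)
  expect_true(any(grepl("<BIF VERSION=\"0.3\">", txt)))
  expect_equal(sum(grepl("<FOR>", txt)), length(bn$nodes))
})
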