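test_that("threshold_config validates its ranges", {
  expect_error(threshold_config(min_support = 1.2), "\\[0, 1\\]")
  expect_error(threshold_config(min_confidence = -0.1), "\\[0, 1\\]")
  expect_error(threshold_config(max_antecedent_size = 0), ">= 1")
  expect_equal(threshold_config()$min_support, 0.36)
})

test_that("weighted support handles the degenerate itemsets", {
  ds <- toy_dataset(list(c(1, 3, 5, 8), c(1, 3, 6, 8), c(1, 3, 5, 7)))
  wt <- uniform_weights(toy_schema(), 0.4)
  expect_equal(weighted_support(c(1L, 3L), ds, wt), 1.0)   # in every record
  expect_equal(weighted_support(2L, ds, wt), 0.0)          # in none
  expect_error(weighted_support(integer(0), ds, wt), "non-empty")
  wt0 <- uniform_weights(toy_schema(), 0)
  expect_error(weighted_support(1L, ds, wt0), "total record weight")
})

test_that("weighted support on a hand-weighted toy matches the manual sum", {
  # six records with hand-assigned pair weights
  ds <- toy_dataset(list(c(1, 3, 5, 8), c(1, 4, 5, 8), c(2, 3, 6, 7),
                         c(1, 3, 6, 8), c(2, 4, 5, 7), c(1, 3, 5, 7)))
  wt <- weight_table(data.frame(item = 1:6,
                                weight = c(.6, .2, .5, .1, .4, .3)))
  # record weights (mean of three attribute-item weights):
  rw <- c(mean(c(.6, .5, .4)), mean(c(.6, .1, .4)), mean(c(.2, .5, .3)),
          mean(c(.6, .5, .3)), mean(c(.2, .1, .4)), mean(c(.6, .5, .4)))
  expect_equal(weighted_support(c(1L, 3L), ds, wt),
               sum(rw[c(1, 4, 6)]) / sum(rw))
  expect_equal(weighted_confidence(1L, 3L, ds, wt),
               sum(rw[c(1, 4, 6)]) / sum(rw[c(1, 2, 4, 6)]))
})

test_that("weighted confidence boundary cases", {
  ds <- toy_dataset(list(c(1, 3, 5, 8), c(1, 3, 6, 8), c(2, 4, 5, 7)))
  wt <- uniform_weights(toy_schema())
  expect_equal(weighted_confidence(1L, 3L, ds, wt), 1.0)  # implied always
  expect_equal(weighted_confidence(2L, 3L, ds, wt), 0.0)  # never together
  expect_error(weighted_confidence(1L, 1L, ds, wt), "disjoint")
  # zero-support antecedent: item 2 never occurs in these records
  ds2 <- toy_dataset(list(c(1, 3, 5, 8)))
  expect_error(weighted_confidence(2L, 3L, ds2, wt), "zero weighted support")
})

test_that("nothing passes absurd thresholds on independent data", {
  ds <- generate(generator_spec(n_attributes = 4L, n_records = 120L,
                                seed = 8L))
  wt <- compute_weights(ds)
  cfg <- threshold_config(min_support = 0.9, min_confidence = 0.9,
                          max_antecedent_size = 2L)
  for (m in c("two_attribute", "multi_attribute", "class_label"))
    expect_equal(nrow(mine_rules(ds, wt, cfg, m)), 0L)
})

test_that("miner equals exhaustive enumeration on random weighted cases", {
  cfgs <- list(threshold_config(0.2, 0.5, max_antecedent_size = 2L),
               threshold_config(0.05, 0.3, max_antecedent_size = 3L))
  for (seed in c(11, 12, 13)) {
    case <- random_case(d = 5, n = 80, seed = seed)
    for (cfg in cfgs) for (m in c("two_attribute", "multi_attribute",
                                  "class_label")) {
      got <- mine_rules(case$ds, case$wt, cfg, m)
      want <- oracle_mine(case$ds, case$wt, cfg, m)
      expect_same_rules(got, want)
    }
  }
})

test_that("planted implication surfaces as a rule at the default thresholds", {
  # A1 -> A2 with P(A2 = high | A1 = high) = 0.95 and P(A1 = high) = 0.65
  dag <- list(A1 = character(0), A2 = "A1", A3 = character(0),
              class = character(0))
  cpts <- list(A1 = array(c(0.35, 0.65), 2, list(c("1", "2"))),
               A2 = array(c(0.5, 0.5, 0.05, 0.95), c(2, 2),
                          list(c("1", "2"), c("1", "2"))))
  spec <- generator_spec(n_attributes = 3L, dag = dag, cpts = cpts,
                         n_records = 2000L, seed = 21L)
  ds <- generate(spec)
  wt <- uniform_weights(ds$schema)
  rules <- mine_rules(ds, wt, threshold_config(0.36, 0.70), "two_attribute")
  expect_true(any(rules$antecedent == "2" & rules$consequent == "4"))
})

test_that("uniform record weights reduce to classical support/confidence", {
  for (seed in c(5, 6)) {
    case <- random_case(d = 4, n = 60, seed = seed)
    wt <- uniform_weights(case$ds$schema, 0.37)
    # thresholds chosen off the k/n lattice so knife-edge rounding cannot
    # make the two routes disagree about borderline rules
    cfg <- threshold_config(0.1234, 0.4321, max_antecedent_size = 2L)
    for (m in c("two_attribute", "class_label")) {
      got <- mine_rules(case$ds, wt, cfg, m)
      want <- oracle_classical(case$ds, cfg, m)
      expect_same_rules(got, want, tol = 1e-12)
    }
  }
})

test_that("wbc and wbl match brute-force recomputation; boundary lift", {
  case <- random_case(d = 4, n = 100, seed = 77)
  cfg <- threshold_config(0.1, 0.3, max_antecedent_size = 2L)
  rules <- mine_rules(case$ds, case$wt, cfg, "class_label")
  scored <- score_strong(rules, case$ds, case$wt, cfg)
  rw <- oracle_record_weights(case$ds, case$wt)
  for (i in seq_len(nrow(scored))) {
    a <- parse_itemset(scored$antecedent[i])
    b <- parse_itemset(scored$consequent[i])
    wbc <- oracle_support(c(a, b), case$ds, rw) / oracle_support(a, case$ds, rw)
    expect_equal(scored$wbc[i], wbc, tolerance = 1e-12)
    expect_equal(scored$wbl[i], wbc / oracle_support(b, case$ds, rw),
                 tolerance = 1e-12)
  }
  # strong requires wbl strictly above min_lift, so lift exactly 1 is weak
  expect_true(all(scored$wbl[scored$strong] > cfg$min_lift))
  expect_true(all(scored$wbc[scored$strong] >= cfg$min_confidence))
})

test_that("scored rules come sorted deterministically", {
  case <- random_case(d = 4, n = 100, seed = 78)
  cfg <- threshold_config(0.1, 0.2, max_antecedent_size = 2L)
  rules <- mine_rules(case$ds, case$wt, cfg, "class_label")
  s1 <- score_strong(rules, case$ds, case$wt, cfg)
  s2 <- score_strong(rules[sample(nrow(rules)), ], case$ds, case$wt, cfg)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(diff(s1$wbl) <= 1e-12))
})

test_that("support is anti-monotone and bounds confidence-related measures", {
  case <- random_case(d = 5, n = 60, seed = 91)
  ds <- case$ds; wt <- case$wt
  set.seed(1)
  universe <- unlist(ds$schema$attributes, use.names = FALSE)
  owner <- wbbn:::item_owner(ds$schema)
  for (rep in 1:20) {
    pick <- sample(universe, 3L)
    if (anyDuplicated(owner[as.character(pick)])) next
    s_all <- weighted_support(pick, ds, wt)
    s_sub <- weighted_support(pick[1:2], ds, wt)
    expect_lte(s_all, s_sub + 1e-12)
    expect_gte(s_all, 0); expect_lte(s_all, 1)
  }
})

test_that("rules export to CSV and JSON", {
  case <- random_case(d = 4, n = 50, seed = 14)
  cfg <- threshold_config(0.1, 0.3)
  rules <- score_strong(mine_rules(case$ds, case$wt, cfg, "class_label"),
                        case$ds, case$wt, cfg)
  pc <- withr::local_tempfile(fileext = ".csv")
  pj <- withr::local_tempfile(fileext = ".json")
  write_rules(rules, pc, "csv")
  write_rules(rules, pj, "json")
  back <- utils::read.csv(pc, colClasses = c(antecedent = "character",
                                             consequent = "character"))
  expect_equal(back$antecedent, rules$antecedent)
  expect_equal(jsonlite::read_json(pj, simplifyVector = TRUE)$wbl,
               rules$wbl)
})
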