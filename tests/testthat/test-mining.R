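# Association mining: support, confidence, Apriori with maximal
# filtering, the support-grid sweep and deduplication.

# Four flank-2 windows: L at +2 in all, O at +1 in two.
toy_windows <- c("AANOL", "AANOL", "AANGL", "AANGL")

test_that("support is the fraction of class windows carrying the pattern", {
  expect_equal(pattern_support("<L,2>", toy_windows), 100)
  expect_equal(pattern_support("<O,1>", toy_windows), 50)
  expect_equal(pattern_support("<L,2>", c(toy_windows[1:3], "AANGC")), 75)
  # downward closure on the toy data
  expect_lte(pattern_support("<O,1><L,2>", toy_windows),
             pattern_support("<O,1>", toy_windows))
  expect_error(pattern_support("<L,2>", character(0)), "no class windows")
})

test_that("confidence is the consequent share of matching windows", {
  pos <- c("AANOL", "AANOL", "AANOL", "AANOL", "AANGC")
  neg <- c("AANOL", "AANGC", "AANGC", "AANGC", "AANGC")
  expect_equal(pattern_confidence("<O,1><L,2>", pos, neg), 80)  # 4 / 5
  expect_equal(pattern_confidence("<L,2>", c("AANOL"), c("AANGC")), 100)
  expect_equal(pattern_confidence("<O,1>", pos, pos), 50)
  expect_error(pattern_confidence("<P,-2>", pos, neg), "no window")
})

test_that("maximal frequent itemsets behave as brute force on the toy data", {
  items <- c("<O,1>", "<L,2>")
  at50 <- frequent_maximal_itemsets(items, toy_windows, 50)
  expect_equal(at50$pattern, "<O,1><L,2>")   # singletons are non-maximal
  expect_equal(at50$support_pct, 50)

  at75 <- frequent_maximal_itemsets(items, toy_windows, 75)
  expect_equal(at75$pattern, "<L,2>")
  expect_equal(at75$support_pct, 100)

  at100 <- frequent_maximal_itemsets(items, toy_windows, 100)
  expect_equal(at100$pattern, "<L,2>")

  all50 <- frequent_maximal_itemsets(items, toy_windows, 50,
                                     maximal_only = FALSE)
  expect_setequal(all50$pattern, c("<O,1>", "<L,2>", "<O,1><L,2>"))
})

test_that("support obeys downward closure and emitted sets are maximal", {
  for (seed in 1:40) {
    inst <- random_instance(seed)
    # random subset vs superset
    if (length(inst$items) >= 2) {
      sub <- inst$items[1]
      sup_set <- inst$items[1:2]
      expect_gte(pattern_support(sub, inst$windows),
                 pattern_support(sup_set, inst$windows))
    }
    mined <- frequent_maximal_itemsets(inst$items, inst$windows,
                                       inst$min_support)
    if (nrow(mined) >= 2) {
      for (i in seq_len(nrow(mined))) {
        for (j in seq_len(nrow(mined))) {
          if (i != j) {
            expect_false(all(mined$items[[i]] %in% mined$items[[j]]))
          }
        }
      }
    }
  }
})

test_that("the grid sweep merges thresholds and counts emissions", {
  items <- c("<O,1>", "<L,2>")
  rules <- sweep_support_grid(items, toy_windows,
                              c("AANGC", "AANGC", "AANGC", "AANOL"),
                              grid = c(50, 75))
  expect_equal(nrow(rules), 2L)
  expect_equal(attr(rules, "n_emitted"), 2L)
  expect_equal(attr(rules, "n_unique"), 2L)
  pair <- rules[rules$pattern == "<O,1><L,2>", ]
  expect_equal(pair$thresholds[[1]], 50)
  single <- rules[rules$pattern == "<L,2>", ]
  expect_equal(single$thresholds[[1]], 75)
  # confidence: <L,2> matches 4 positives, 1 negative -> 80
  expect_equal(single$confidence_pct, 80)

  expect_equal(nrow(sweep_support_grid(character(0), toy_windows,
                                       toy_windows)), 0L)
  expect_error(sweep_support_grid(items, toy_windows, toy_windows,
                                  grid = c(50, 20)), "ascending")
})

test_that("deduplication unions thresholds and is idempotent", {
  r <- rules_from_patterns(c("<L,2>", "<L,2>", "<O,1>"),
                           thresholds = list(5, 10, 5))
  d <- dedupe_rules(r)
  expect_equal(nrow(d), 2L)
  expect_equal(d$thresholds[[which(d$pattern == "<L,2>")]], c(5, 10))
  expect_identical(dedupe_rules(d)$pattern, d$pattern)
  expect_identical(dedupe_rules(d)$thresholds, d$thresholds)
})

test_that("rules survive JSON and TSV round trips", {
  rules <- sweep_support_grid(c("<O,1>", "<L,2>"), toy_windows,
                              c("AANGC", "AANGC", "AANGC", "AANOL"),
                              grid = c(25, 50, 75))
  jp <- tempfile(fileext = ".json")
  write_rules_json(rules, jp)
  back <- read_rules_json(jp)
  expect_equal(back$pattern, rules$pattern)
  expect_equal(back$support_pct, rules$support_pct)
  expect_equal(back$confidence_pct, rules$confidence_pct)
  expect_equal(back$thresholds, rules$thresholds)

  tp <- tempfile(fileext = ".tsv")
  write_rules_tsv(rules, tp)
  back2 <- read_rules_tsv(tp)
  expect_equal(back2$pattern, rules$pattern)
  expect_equal(back2$thresholds, rules$thresholds)
})

test_that("published-style pattern tables load as rule sets", {
  path <- system.file("extdata", "published_rules_encoded_pos.tsv",
                      package = "glycoctx")
  rules <- read_rules_tsv(path)
  expect_equal(nrow(rules), 23L)
  expect_true("<O,1><L,2>" %in% rules$pattern)
  lone <- rules[rules$pattern == "<L,2>", ]
  expect_equal(max(lone$thresholds[[1]]), 95)
  expect_equal(lone$confidence_pct, 76.12)
})
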