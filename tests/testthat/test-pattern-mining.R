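test_that("gap-constrained containment matches the definition", {
  expect_true(seq_contains(c("a", "b", "c", "d", "e", "f"),
                           c("a", "c", "e"), max_gap = 5))
  expect_true(seq_contains(c("a", "c", "d", "e", "g", "h"),
                           c("a", "c", "e"), max_gap = 5))
  # index difference 6 exceeds a gap of 5
  expect_false(seq_contains(c("a", "x", "x", "x", "x", "x", "c"),
                            c("a", "c"), max_gap = 5))
  # gap 1 means adjacent
  expect_true(seq_contains(c("a", "c"), c("a", "c"), max_gap = 1))
  expect_false(seq_contains(c("a", "x", "c"), c("a", "c"), max_gap = 1))
  expect_error(seq_contains(c("a", "b"), character(0)), "length >= 1")
})

test_that("containment agrees with the recursive oracle on random cases", {
  set.seed(42)
  for (i in 1:200) {
    s <- sample(letters[1:4], sample(2:8, 1), replace = TRUE)
    p <- sample(letters[1:4], sample(1:3, 1), replace = TRUE)
    g <- sample(1:4, 1)
    expect_equal(seq_contains(s, p, g), oracle_contains(s, p, g),
                 info = sprintf("seq=%s pat=%s gap=%d",
                                paste(s, collapse = ""),
                                paste(p, collapse = ""), g))
  }
})

test_that("support is the fraction of containing sequences", {
  db <- toy_db(list(c("a", "b", "c", "d", "e", "f"),
                    c("a", "c", "d", "e", "g", "h")),
               c("l1", "l2"))
  expect_equal(pattern_support(c("a", "c", "e"), db), 1.0)
  expect_equal(pattern_support("z", db), 0.0)
  single <- toy_db(list(c("x", "y")), "l1")
  expect_equal(pattern_support(c("x", "y"), single), 1.0)
  expect_error(pattern_support("a", toy_db(list(), character(0))), "empty")
})

test_that("confidence partitions over classes of containing sequences", {
  db <- toy_db(list(c("a", "b", "c", "d", "e", "f"),
                    c("a", "c", "d", "e", "g", "h")),
               c("medication", "symptom"))
  expect_equal(pattern_confidence(c("a", "c", "e"), db, "medication"), 0.5)
  expect_equal(pattern_confidence(c("a", "c", "e"), db, "symptom"), 0.5)
  expect_equal(pattern_confidence(c("b"), db, "medication"), 1.0)
  expect_error(pattern_confidence("z", db, "medication"), "zero support")
})

test_that("mining a uniform database returns all subpatterns at support 1", {
  db <- toy_db(rep(list(c("a", "b")), 10), rep("medication", 10))
  fsps <- mine_fsps(db, mining_config(min_support = 0.5))
  expect_setequal(fsps$pattern_id, c("a", "b", "a|b"))
  expect_equal(fsps$support, rep(1, 3))
})

test_that("mining equals exhaustive enumeration on the worked database", {
  db <- toy_db(list(c("a", "b", "c", "d", "e", "f"),
                    c("a", "c", "d", "e", "g", "h")),
               c("l1", "l2"))
  cfg <- mining_config(min_support = 1.0, max_pattern_length = 3)
  fsps <- mine_fsps(db, cfg)
  oracle <- oracle_mine(db$tags, 1.0, cfg$max_gap, 3)
  expect_setequal(fsps$pattern_id, oracle$pattern_id)
  expect_true("a|c|e" %in% fsps$pattern_id)
})

test_that("a threshold above all pair supports leaves only single tags", {
  db <- toy_db(list(c("a", "b"), c("b", "a")), c("l1", "l2"))
  fsps <- mine_fsps(db, mining_config(min_support = 0.6))
  oracle <- oracle_mine(db$tags, 0.6, 5, 6)
  expect_setequal(fsps$pattern_id, oracle$pattern_id)
  expect_setequal(fsps$pattern_id, c("a", "b"))
})

test_that("miner output is deterministic and sorted by support then tags", {
  set.seed(99)
  db <- random_db(6, 5, letters[1:4])
  f1 <- mine_fsps(db, mining_config(min_support = 0.3))
  f2 <- mine_fsps(db, mining_config(min_support = 0.3))
  expect_identical(f1, f2)
  expect_true(all(diff(f1$support) <= 0))
})

test_that("support is anti-monotone under prefix extension", {
  set.seed(7)
  for (rep in 1:20) {
    db <- random_db(8, 6, letters[1:5])
    fsps <- mine_fsps(db, mining_config(min_support = 0.1,
                                        max_pattern_length = 4))
    for (i in sample(nrow(fsps), min(10, nrow(fsps)))) {
      p <- fsps$pattern[[i]]
      ext <- c(p, sample(letters[1:5], 1))
      expect_lte(pattern_support(ext, db), fsps$support[i])
    }
  }
})

test_that("FLSP selection applies the confidence threshold per class", {
  # a pattern exclusive to medication sequences
  db <- toy_db(c(rep(list(c("CD", "DRUG")), 6),
                 rep(list(c("SYMP", "x")), 3),
                 list(c("x", "y"))),
               c(rep("medication", 6), rep("symptom", 3), "background"))
  cfg <- mining_config(min_support = 0.1, min_confidence = 0.85)
  flsps <- select_flsps(mine_fsps(db, cfg), db, cfg)
  drug <- flsps[flsps$pattern_id == "CD|DRUG", ]
  expect_equal(nrow(drug), 1)
  expect_equal(drug$target_class, "medication")
  expect_equal(drug$confidence, 1.0)
  expect_true(all(flsps$confidence >= 0.85))
  expect_true(all(flsps$support >= 0.1))
  # the shared tag "x" has confidence 0.75 at best -> not an FLSP
  expect_false("x" %in% flsps$pattern_id)
})

test_that("a 50/50 pattern is not selected at threshold 0.85", {
  db <- toy_db(list(c("a", "b"), c("a", "b")), c("medication", "symptom"))
  cfg <- mining_config(min_support = 0.5, min_confidence = 0.85)
  flsps <- select_flsps(mine_fsps(db, cfg), db, cfg)
  expect_equal(nrow(flsps), 0)
})

test_that("a planted high-support exclusive pattern is always selected", {
  set.seed(3)
  n_med <- 60; n_other <- 40
  tags <- c(
    lapply(seq_len(n_med), function(i) {
      if (i <= 0.9 * n_med) c("PRP", "CD", "DRUG", "FREQ")
      else c("PRP", "VBD", "DRUG")
    }),
    lapply(seq_len(n_other), function(i) sample(c("NN", "JJ", "SYMP"), 3,
                                                replace = TRUE)))
  db <- toy_db(tags, c(rep("medication", n_med), rep("symptom", n_other)))
  cfg <- mining_config(min_support = 0.05, min_confidence = 0.85)
  flsps <- select_flsps(mine_fsps(db, cfg), db, cfg)
  planted <- flsps[flsps$pattern_id == "CD|DRUG|FREQ", ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$target_class, "medication")
  expect_equal(planted$support, 0.9 * n_med / 100)
})

test_that("pattern tables round-trip through the TSV format", {
  db <- toy_db(c(rep(list(c("CD", "DRUG")), 5), list(c("SYMP", "SYMP"))),
               c(rep("medication", 5), "symptom"))
  cfg <- mining_config(min_support = 0.1)
  flsps <- select_flsps(mine_fsps(db, cfg), db, cfg)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_patterns(flsps, tf)
  back <- read_patterns(tf)
  expect_equal(back$pattern_id, flsps$pattern_id)
  expect_equal(back$support, flsps$support)
  expect_equal(back$pattern, flsps$pattern)
})
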