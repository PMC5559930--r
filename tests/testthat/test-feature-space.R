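toy_flsps <- function(ids) {
  tibble::tibble(pattern = strsplit(ids, "|", fixed = TRUE),
                 pattern_id = ids,
                 support = 0.5, confidence = 1,
                 target_class = "medication")
}

test_that("FLSP indicators are gap-constrained containment bits", {
  flsps <- toy_flsps(c("PRP|CD|CD", "DRUG|FREQ"))
  v <- flsp_features(c("PRP", "CD", "CD", "NN"), flsps, max_gap = 5)
  expect_equal(unname(v), c(1, 0))
  expect_equal(names(v), c("lsp:(PRP, CD, CD)", "lsp:(DRUG, FREQ)"))
  expect_length(flsp_features(c("PRP"), toy_flsps(character(0))), 0)
})

test_that("semantic features flag any phrase mapping to a type", {
  tg <- semantic_tagger(data.frame(
    phrase = c("heartburn", "heartburn", "lantus"),
    code = c("sosy", "patf", "phsu")))
  v <- semantic_features("I have heartburn", tg)
  expect_equal(v[["sem:sosy"]], 1)
  expect_equal(v[["sem:patf"]], 1)  # multi-code phrase sets both
  expect_equal(v[["sem:phsu"]], 0)
  expect_equal(sum(semantic_features("nothing here", tg)), 0)
})

test_that("word features are case-folded indicators with adjacent bigrams", {
  vocab <- list(unigrams = c("prescribed", "nexium"),
                bigrams = c("twice a"))
  v <- word_features("The doctor Prescribed it twice a day", vocab)
  expect_equal(v[["uni:prescribed"]], 1)
  expect_equal(v[["uni:nexium"]], 0)
  expect_equal(v[["bi:twice a"]], 1)
  # non-adjacent tokens do not form the bigram
  v2 <- word_features("twice or a day", vocab)
  expect_equal(v2[["bi:twice a"]], 0)
})

test_that("morphological features detect capitals and abbreviations", {
  expect_equal(unname(morphological_features("I take Lantus")), c(1, 0))
  expect_equal(unname(morphological_features("my IBS flared")), c(1, 1))
  expect_equal(unname(morphological_features("nothing special here")), c(0, 0))
  # sentence-initial capital alone does not count
  expect_equal(unname(morphological_features("Nothing special here"))[1], 0)
})

test_that("heuristic features expose creator flag, position and word count", {
  s <- tibble::tibble(text = "I am taking 90 units Lantus twice a day",
                      label = as_sentence_label("medication"),
                      thread_id = "t1", post_index = 1L,
                      is_thread_creator = TRUE)
  expect_equal(unname(heuristic_features(s)), c(1, 1, 9))
  s2 <- dplyr::mutate(s, post_index = 3L, is_thread_creator = FALSE)
  h <- heuristic_features(s2)
  expect_equal(unname(h[c("thr_creator", "position")]), c(0, 3))
})

small_corpus <- function() {
  tibble::tibble(
    text = c("I am taking 90 units Lantus twice a day",
             "I have heartburn and nausea",
             "Thanks for the advice",
             "I have heartburn again"),
    label = as_sentence_label(c("medication", "symptom", "background",
                                "symptom")),
    thread_id = "t1", post_index = c(1L, 1L, 2L, 3L),
    is_thread_creator = c(TRUE, TRUE, FALSE, TRUE))
}

test_that("featurize assembles named blocks in fixed order", {
  corp <- small_corpus()
  lex <- fixture_lexicons()
  db <- build_database(corp, lex)
  flsps <- toy_flsps("CD|NNS|DRUG")
  tg <- semantic_tagger(data.frame(phrase = c("heartburn", "lantus"),
                                   code = c("sosy", "phsu")))
  spec <- fit_feature_spec(corp, flsps = flsps, sem_tagger = tg)
  X <- featurize(spec, corp, database = db)
  # D = 1 FLSP + 2 semantic + 0 word + 2 morphological + 3 heuristic = 8
  expect_equal(ncol(X) - 1, 8)
  expect_equal(names(X)[-1],
               c("lsp:(CD, NNS, DRUG)", "sem:phsu", "sem:sosy",
                 "morph:capitalized", "morph:abbreviation",
                 "thr_creator", "position", "word_count"))
  expect_equal(X[["lsp:(CD, NNS, DRUG)"]], c(1, 0, 0, 0))
  expect_equal(X[["sem:sosy"]], c(0, 1, 0, 1))
  # binary blocks are 0/1; heuristics integer-valued
  vals <- feature_values(X)
  expect_true(all(vals[, 1:5] %in% 0:1))
  expect_true(all(vals[, 6:8] == round(vals[, 6:8])))
  # transform of training rows reproduces itself
  expect_equal(featurize(spec, corp, database = db), X)
})

test_that("disabling a block removes exactly its columns", {
  corp <- small_corpus()
  spec_all <- fit_feature_spec(corp)
  spec_nomorph <- fit_feature_spec(corp, include_morphological = FALSE)
  X_all <- featurize(spec_all, corp)
  X_nomorph <- featurize(spec_nomorph, corp)
  expect_setequal(setdiff(names(X_all), names(X_nomorph)),
                  c("morph:capitalized", "morph:abbreviation"))
})

test_that("vocabulary is fitted on training sentences only (no leakage)", {
  corp <- small_corpus()
  spec <- fit_feature_spec(corp[1:3, ], include_words = TRUE,
                           min_word_count = 1)
  X_test <- featurize(spec, corp[4, , drop = FALSE])
  # "again" occurs only in the held-out sentence: no such column exists
  expect_false("uni:again" %in% names(X_test))
  expect_equal(nrow(X_test), 1)
})

test_that("word pruning drops terms below the document-count threshold", {
  corp <- small_corpus()
  spec <- fit_feature_spec(corp, include_words = TRUE, min_word_count = 2)
  # "heartburn" occurs in two sentences, "advice" in one
  expect_true("uni:heartburn" %in% names(featurize(spec, corp)))
  expect_false("uni:advice" %in% names(featurize(spec, corp)))
})

test_that("entropy selection keeps perfect splitters and drops constants", {
  set.seed(1)
  n <- 80
  label <- factor(sample(c("medication", "symptom"), n, replace = TRUE))
  X <- tibble::tibble(
    label = label,
    perfect = as.numeric(label == "medication"),
    noise = stats::rbinom(n, 1, 0.5),
    constant = 1)
  sel1 <- entropy_feature_selection(X, 1)
  expect_equal(sel1$feature, "perfect")
  selD <- entropy_feature_selection(X, 3)
  expect_false("constant" %in% selD$feature)
  expect_true("perfect" %in% selD$feature)
  expect_error(entropy_feature_selection(X, 0), "k must be")
})

test_that("restricting a spec keeps only the selected columns", {
  corp <- small_corpus()
  spec <- fit_feature_spec(corp)
  keep <- c("thr_creator", "word_count")
  X <- featurize(restrict_spec(spec, keep), corp)
  expect_equal(setdiff(names(X), "label"), keep)
})
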