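#' Phrase-table semantic-type tagger
#'
#' Maps sentences to UMLS-style semantic-type codes (e.g. `sosy` "sign
#' or symptom", `phsu` "pharmacologic substance", `patf` "pathologic
#' function") via a phrase table. This is a pluggable stand-in for an
#' external concept tagger: any object with the same
#' phrase-to-code-set behaviour can be used wherever an
#' `lspf_semtagger` is accepted.
#'
#' @param phrase_table Data frame with columns `phrase` and `code`; a
#'   phrase may map to several codes (one row per pair).
#' @param codes Optional character vector fixing the code axis order;
#'   defaults to the sorted unique codes of the table.
#' @return An object of class `lspf_semtagger`.
#' @export
#' @examples
#' tg <- semantic_tagger(data.frame(phrase = "heartburn", code = "sosy"))
#' semantic_features("I have heartburn", tg)
semantic_tagger <- function(phrase_table, codes = NULL) {
  stopifnot(all(c("phrase", "code") %in% names(phrase_table)))
  tbl <- tibble::tibble(
    phrase = stringr::str_squish(tolower(phrase_table$phrase)),
    code = as.character(phrase_table$code)
  )
  tbl <- dplyr::distinct(tbl[nzchar(tbl$phrase), ])
  if (is.null(codes)) codes <- sort(unique(tbl$code), method = "radix")
  phrases <- unique(tbl$phrase)
  ptoks <- lapply(phrases, function(ph) tolower(tokenize_sentence(ph)$token))
  structure(list(table = tbl, codes = codes, phrases = phrases,
                 phrase_tokens = ptoks),
            class = "lspf_semtagger")
}

#' @export
print.lspf_semtagger <- function(x, ...) {
  cat(sprintf("<semantic tagger: %d phrases, %d semantic types>\n",
              nrow(x$table), length(x$codes)))
  invisible(x)
}

# Codes present in a sentence: any phrase of the table occurring as a
# contiguous (case-folded) token run.
sentence_codes <- function(text, tagger) {
  toks <- tolower(tokenize_sentence(text)$token)
  n <- length(toks)
  if (n == 0) return(character(0))
  hits <- character(0)
  for (pi in seq_along(tagger$phrases)) {
    ptoks <- tagger$phrase_tokens[[pi]]
    k <- length(ptoks)
    if (k == 0 || k > n) next
    found <- if (k == 1) ptoks %in% toks else {
      any(vapply(seq_len(n - k + 1L),
                 function(s) all(toks[s:(s + k - 1L)] == ptoks), logical(1)))
    }
    if (found) {
      hits <- c(hits, tagger$table$code[tagger$table$phrase == tagger$phrases[pi]])
    }
  }
  unique(hits)
}

#' Per-sentence feature blocks
#'
#' The individual feature extractors composed by [featurize()]:
#' `flsp_features` gives one 0/1 indicator per mined FLSP
#' (gap-constrained containment in the sentence's tag sequence);
#' `semantic_features` one 0/1 indicator per semantic-type code;
#' `word_features` one 0/1 indicator per vocabulary unigram/bigram
#' (case-folded, bigrams require adjacency); `morphological_features`
#' the pair (has capitalized non-initial word, has abbreviation — a
#' token with >= 2 uppercase letters or internal periods);
#' `heuristic_features` the numeric triple (thread-creator flag, post
#' position, word count).
#'
#' @param tags Character tag sequence of the sentence.
#' @param flsps FLSP tibble ([select_flsps()]).
#' @param max_gap Maximum gap for containment.
#' @param text Sentence text.
#' @param tagger An `lspf_semtagger`.
#' @param vocabulary List with character vectors `unigrams`, `bigrams`.
#' @param sentence One-row corpus tibble.
#' @return Named numeric vector (one element per feature in the block).
#' @export
flsp_features <- function(tags, flsps, max_gap = 5L) {
  if (nrow(flsps) == 0) return(setNames(numeric(0), character(0)))
  vals <- vapply(flsps$pattern, function(p) {
    as.numeric(length(tags) > 0 && seq_contains(tags, p, max_gap))
  }, numeric(1))
  setNames(vals, paste0("lsp:(", gsub("\\|", ", ", flsps$pattern_id), ")"))
}

#' @rdname flsp_features
#' @export
semantic_features <- function(text, tagger) {
  present <- sentence_codes(text, tagger)
  setNames(as.numeric(tagger$codes %in% present),
           paste0("sem:", tagger$codes))
}

#' @rdname flsp_features
#' @export
word_features <- function(text, vocabulary) {
  toks <- tolower(tokenize_sentence(text)$token)
  uni <- unique(toks)
  bi <- if (length(toks) >= 2) {
    unique(paste(toks[-length(toks)], toks[-1]))
  } else character(0)
  c(setNames(as.numeric(vocabulary$unigrams %in% uni),
             paste0("uni:", vocabulary$unigrams)),
    setNames(as.numeric(vocabulary$bigrams %in% bi),
             paste0("bi:", vocabulary$bigrams)))
}

#' @rdname flsp_features
#' @export
morphological_features <- function(text) {
  toks <- tokenize_sentence(text)$token
  words <- toks[grepl("[A-Za-z]", toks)]
  # the pronoun "I" is capitalized by orthography, not morphology
  has_cap <- length(words) > 1 &&
    any(grepl("^[A-Z]", words[-1]) & words[-1] != "I")
  has_abbrev <- any(stringr::str_count(toks, "[A-Z]") >= 2) ||
    any(grepl("^[A-Za-z]+(\\.[A-Za-z]+)+\\.?$", toks))
  c(`morph:capitalized` = as.numeric(has_cap),
    `morph:abbreviation` = as.numeric(has_abbrev))
}

#' @rdname flsp_features
#' @export
heuristic_features <- function(sentence) {
  stopifnot(nrow(sentence) == 1)
  c(`thr_creator` = as.numeric(sentence$is_thread_creator),
    `position` = as.numeric(sentence$post_index),
    `word_count` = as.numeric(nrow(tokenize_sentence(sentence$text))))
}

#' Fit a feature specification on training data
#'
#' Freezes everything needed to map sentences into the interpretable
#' feature space: the mined FLSPs, the semantic-type axis, the
#' unigram/bigram vocabulary (built from the training sentences only;
#' terms occurring in fewer than `min_word_count` sentences are
#' dropped), and which optional blocks are enabled. Block order is
#' fixed: FLSP, semantic, word, morphological, heuristic.
#'
#' @param corpus Training corpus tibble.
#' @param flsps FLSP tibble from [select_flsps()] (or `NULL` to disable
#'   the block).
#' @param sem_tagger An `lspf_semtagger` (or `NULL` to disable).
#' @param include_words,include_morphological,include_creator,include_position,include_word_count
#'   Block switches.
#' @param min_word_count Minimum number of training sentences a
#'   unigram/bigram must occur in (default 2).
#' @param max_gap Maximum gap used for FLSP containment.
#' @return An object of class `lspf_feature_spec`.
#' @export
fit_feature_spec <- function(corpus, flsps = NULL, sem_tagger = NULL,
                             include_words = FALSE,
                             include_morphological = TRUE,
                             include_creator = TRUE,
                             include_position = TRUE,
                             include_word_count = TRUE,
                             min_word_count = 2L, max_gap = 5L) {
  vocabulary <- list(unigrams = character(0), bigrams = character(0))
  if (include_words) {
    per_sentence <- purrr::map(corpus$text, function(tx) {
      toks <- tolower(tokenize_sentence(tx)$token)
      list(uni = unique(toks),
           bi = if (length(toks) >= 2)
             unique(paste(toks[-length(toks)], toks[-1])) else character(0))
    })
    uni_tab <- table(unlist(purrr::map(per_sentence, "uni")))
    bi_tab <- table(unlist(purrr::map(per_sentence, "bi")))
    vocabulary$unigrams <- sort(names(uni_tab)[uni_tab >= min_word_count],
                                method = "radix")
    vocabulary$bigrams <- sort(names(bi_tab)[bi_tab >= min_word_count],
                               method = "radix")
  }
  spec <- structure(list(
    flsps = flsps, sem_tagger = sem_tagger, vocabulary = vocabulary,
    include_words = include_words,
    include_morphological = include_morphological,
    include_creator = include_creator,
    include_position = include_position,
    include_word_count = include_word_count,
    max_gap = as.integer(max_gap),
    keep = NULL
  ), class = "lspf_feature_spec")
  nm <- spec_feature_names(spec)
  if (anyDuplicated(nm)) abort("duplicate feature names in specification")
  spec
}

spec_feature_names <- function(spec) {
  nm <- character(0)
  if (!is.null(spec$flsps) && nrow(spec$flsps) > 0) {
    nm <- c(nm, paste0("lsp:(", gsub("\\|", ", ", spec$flsps$pattern_id), ")"))
  }
  if (!is.null(spec$sem_tagger)) {
    nm <- c(nm, paste0("sem:", spec$sem_tagger$codes))
  }
  if (spec$include_words) {
    nm <- c(nm, paste0("uni:", spec$vocabulary$unigrams),
            paste0("bi:", spec$vocabulary$bigrams))
  }
  if (spec$include_morphological) {
    nm <- c(nm, "morph:capitalized", "morph:abbreviation")
  }
  if (spec$include_creator) nm <- c(nm, "thr_creator")
  if (spec$include_position) nm <- c(nm, "position")
  if (spec$include_word_count) nm <- c(nm, "word_count")
  if (!is.null(spec$keep)) nm <- nm[nm %in% spec$keep]
  nm
}

#' @export
print.lspf_feature_spec <- function(x, ...) {
  cat(sprintf(paste0("<feature spec: %d features (%d FLSP, %d semantic, ",
                     "%d word-based)>\n"),
              length(spec_feature_names(x)),
              if (is.null(x$flsps)) 0L else nrow(x$flsps),
              if (is.null(x$sem_tagger)) 0L else length(x$sem_tagger$codes),
              if (x$include_words)
                length(x$vocabulary$unigrams) + length(x$vocabulary$bigrams)
              else 0L))
  invisible(x)
}

#' Transform sentences into the feature space
#'
#' Applies a fitted [fit_feature_spec()] to a corpus (training or
#' unseen), producing the N x D feature matrix. FLSP, semantic, word and
#' morphological columns are 0/1; position and word count are
#' non-negative integers kept numeric so tree models can learn
#' thresholds on them.
#'
#' @param spec An `lspf_feature_spec`.
#' @param corpus Corpus tibble.
#' @param database Optional pre-built `lspf_seqdb` for `corpus` (rebuilt
#'   from `lex`/`tagger` if omitted).
#' @param lex,tagger Used to build the tag sequences when `database` is
#'   not supplied.
#' @return A tibble of class `lspf_features`: column `label` plus one
#'   numeric column per feature, rows aligned with `corpus`.
#' @export
featurize <- function(spec, corpus, database = NULL, lex = NULL,
                      tagger = default_tagger()) {
  need_db <- !is.null(spec$flsps) && nrow(spec$flsps) > 0
  if (need_db && is.null(database)) {
    if (is.null(lex)) abort("supply `database` or `lex` to compute FLSP features")
    database <- build_database(corpus, lex, tagger)
  }
  if (!is.null(database) && nrow(database) != nrow(corpus)) {
    abort("database and corpus are misaligned (different number of rows)")
  }
  n <- nrow(corpus)
  blocks <- list()
  if (need_db) {
    M <- db_contains_many(database, spec$flsps$pattern, spec$max_gap) * 1
    colnames(M) <- paste0("lsp:(", gsub("\\|", ", ", spec$flsps$pattern_id), ")")
    blocks$flsp <- M
  }
  if (!is.null(spec$sem_tagger)) {
    sem <- t(vapply(corpus$text, semantic_features,
                    numeric(length(spec$sem_tagger$codes)),
                    tagger = spec$sem_tagger, USE.NAMES = FALSE))
    colnames(sem) <- paste0("sem:", spec$sem_tagger$codes)
    blocks$semantic <- sem
  }
  if (spec$include_words) {
    nw <- length(spec$vocabulary$unigrams) + length(spec$vocabulary$bigrams)
    wrd <- t(vapply(corpus$text, word_features, numeric(nw),
                    vocabulary = spec$vocabulary, USE.NAMES = FALSE))
    colnames(wrd) <- c(paste0("uni:", spec$vocabulary$unigrams),
                       paste0("bi:", spec$vocabulary$bigrams))
    blocks$word <- wrd
  }
  if (spec$include_morphological) {
    mph <- t(vapply(corpus$text, morphological_features, numeric(2),
                    USE.NAMES = FALSE))
    colnames(mph) <- c("morph:capitalized", "morph:abbreviation")
    blocks$morph <- mph
  }
  heur <- cbind(
    thr_creator = as.numeric(corpus$is_thread_creator),
    position = as.numeric(corpus$post_index),
    word_count = vapply(corpus$text,
                        function(tx) as.numeric(nrow(tokenize_sentence(tx))),
                        numeric(1), USE.NAMES = FALSE))
  keep_h <- c(spec$include_creator, spec$include_position,
              spec$include_word_count)
  blocks$heuristic <- heur[, keep_h, drop = FALSE]
  blocks <- blocks[vapply(blocks, ncol, integer(1)) > 0]
  mat <- if (length(blocks) > 0) do.call(cbind, blocks) else
    matrix(numeric(0), nrow = n, ncol = 0)
  if (!is.null(spec$keep)) {
    mat <- mat[, colnames(mat) %in% spec$keep, drop = FALSE]
  }
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(label = as_sentence_label(corpus$label)),
                          out)
  class(out) <- c("lspf_features", class(out))
  out
}

#' Feature values as a numeric matrix
#'
#' @param X An `lspf_features` tibble.
#' @return Numeric matrix (the feature columns, without `label`).
#' @export
feature_values <- function(X) {
  as.matrix(X[, setdiff(names(X), "label"), drop = FALSE])
}

#' Entropy-based feature selection
#'
#' Fits a single decision tree with the entropy (information) splitting
#' criterion on the feature matrix and retains the `k` features with the
#' largest impurity-decrease importance. Features with zero importance
#' are never retained, so fewer than `k` may be returned. Constant
#' features have zero importance by construction.
#'
#' @param X An `lspf_features` tibble (with `label`).
#' @param k Number of features to retain (1 <= k <= D).
#' @return Tibble with columns `feature` and `importance`, in decreasing
#'   importance order.
#' @export
entropy_feature_selection <- function(X, k) {
  vals <- feature_values(X)
  D <- ncol(vals)
  if (k <= 0) abort("k must be >= 1")
  if (k > D) k <- D
  df <- as.data.frame(vals)
  names(df) <- paste0("f", seq_len(D))
  df$.label <- X$label
  fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                      parms = list(split = "information"),
                      control = rpart::rpart.control(
                        cp = 0, minsplit = 2, minbucket = 1,
                        maxsurrogate = 0, maxcompete = 0, xval = 0))
  imp <- fit$variable.importance
  if (is.null(imp)) imp <- setNames(numeric(0), character(0))
  full <- setNames(rep(0, D), paste0("f", seq_len(D)))
  full[names(imp)] <- imp
  keep <- order(-full, seq_len(D))[seq_len(k)]
  keep <- keep[full[keep] > 0]
  tibble::tibble(feature = colnames(vals)[keep],
                 importance = unname(full[keep]))
}

#' Restrict a feature spec to selected features
#'
#' @param spec An `lspf_feature_spec`.
#' @param features Character vector of feature names to keep (e.g. from
#'   [entropy_feature_selection()]).
#' @return The spec, with transformation restricted to those columns.
#' @export
restrict_spec <- function(spec, features) {
  spec$keep <- features
  spec
}
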