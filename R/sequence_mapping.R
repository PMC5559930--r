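#' Map a sentence to its labeled tag sequence
#'
#' Converts a sentence into an ordered tag sequence over the alphabet of
#' Penn-Treebank POS tags plus the special tags `DRUG`, `SYMP` and
#' `FREQ`. Lexicon phrases are matched first — case-insensitively, left
#' to right, preferring the longest span at each position (ties between
#' lexicons broken `FREQ` > `DRUG` > `SYMP`) — and each matched span
#' collapses to a single special tag. Frequency regular expressions are
#' matched on the raw sentence and mapped back to token ranges. All
#' remaining tokens receive POS tags from `tagger`.
#'
#' @param text Sentence text (a single string), or a one-row corpus
#'   tibble (see [read_corpus()]).
#' @param lex An `lspf_lexicons` object ([lexicons()]).
#' @param tagger A tagger function with the contract of
#'   [dictionary_tagger()]: token vector in, equal-length tag vector out.
#' @param label Optional class label attached to the sequence.
#' @param source_index Optional index of the originating sentence.
#' @return A list of class `lspf_sequence` with elements `tags`
#'   (character), `tokens`, `spans` (token index range per tag), `label`
#'   and `source_index`.
#' @export
#' @examples
#' lex <- lexicons(drug_terms = "Lantus",
#'                 freq_patterns = "(once|twice) a day")
#' map_sentence("I am taking 90 units Lantus twice a day", lex)$tags
map_sentence <- function(text, lex, tagger = default_tagger(),
                         label = NA, source_index = NA_integer_) {
  if (is.data.frame(text)) {
    stopifnot(nrow(text) == 1)
    label <- text$label
    text <- text$text
  }
  toks <- tokenize_sentence(text)
  n <- nrow(toks)
  if (n == 0) {
    return(structure(list(tags = character(0), tokens = character(0),
                          spans = integer(0), label = label,
                          source_index = source_index),
                     class = "lspf_sequence"))
  }
  pos_tags <- tagger(toks$token)
  if (length(pos_tags) != n) {
    abort(sprintf("tagger contract violation: %d tokens in, %d tags out",
                  n, length(pos_tags)))
  }

  # candidate special spans as (first token, last token, tag)
  cand <- special_spans(text, toks, lex)

  # greedy left-to-right longest match; ties FREQ > DRUG > SYMP
  tags <- character(0)
  starts <- integer(0)
  ends <- integer(0)
  i <- 1L
  while (i <= n) {
    here <- cand[cand$first == i, , drop = FALSE]
    if (nrow(here) > 0) {
      here <- here[order(-here$last, here$rank), , drop = FALSE]
      tags <- c(tags, here$tag[1])
      starts <- c(starts, i)
      ends <- c(ends, here$last[1])
      i <- here$last[1] + 1L
    } else {
      tags <- c(tags, pos_tags[i])
      starts <- c(starts, i)
      ends <- c(ends, i)
      i <- i + 1L
    }
  }
  structure(list(tags = tags, tokens = toks$token,
                 spans = cbind(first = starts, last = ends),
                 label = label, source_index = source_index),
            class = "lspf_sequence")
}

# All lexicon-phrase and frequency-regex matches as token spans.
special_spans <- function(text, toks, lex) {
  n <- nrow(toks)
  low <- tolower(toks$token)
  first <- integer(0); last <- integer(0)
  tag <- character(0); rank <- integer(0)

  add <- function(f, l, tg, rk) {
    first <<- c(first, f); last <<- c(last, l)
    tag <<- c(tag, rep(tg, length(f))); rank <<- c(rank, rep(rk, length(f)))
  }
  match_phrases <- function(token_lists, tg, rk) {
    for (ptoks in token_lists) {
      k <- length(ptoks)
      if (k == 0 || k > n) next
      if (k == 1) {
        hits <- which(low == ptoks)
        if (length(hits)) add(hits, hits, tg, rk)
      } else {
        starts <- which(low == ptoks[1])
        starts <- starts[starts <= n - k + 1L]
        for (s in starts) {
          if (all(low[(s + 1L):(s + k - 1L)] == ptoks[-1])) {
            add(s, s + k - 1L, tg, rk)
          }
        }
      }
    }
  }
  match_phrases(lex$drug_tokens, "DRUG", 2L)
  match_phrases(lex$symptom_tokens, "SYMP", 3L)

  # FREQ regexes match the raw sentence; keep matches covering whole tokens
  for (pat in lex$freq_patterns) {
    m <- gregexpr(pat, text, ignore.case = TRUE, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (j in seq_along(m)) {
      mstart <- as.integer(m[j])
      mend <- mstart + attr(m, "match.length")[j] - 1L
      covered <- which(toks$start >= mstart & toks$end <= mend)
      if (length(covered) == 0) next
      add(min(covered), max(covered), "FREQ", 1L)
    }
  }
  unique(data.frame(first = first, last = last, tag = tag, rank = rank))
}

#' @export
print.lspf_sequence <- function(x, ...) {
  cat(sprintf("<labeled sequence: (%s) -> %s>\n",
              paste(x$tags, collapse = ", "),
              if (is.na(x$label[1])) "?" else as.character(x$label)))
  invisible(x)
}

#' Build the labeled-sequence database for a corpus
#'
#' Applies [map_sentence()] to every corpus sentence, yielding the
#' database of labeled sequences that pattern mining operates on.
#'
#' @param corpus Corpus tibble (see [read_corpus()]).
#' @param lex An `lspf_lexicons` object.
#' @param tagger Tagger function (default [default_tagger()]).
#' @return A tibble of class `lspf_seqdb` with list-column `tags`
#'   (character vectors), plus `label` and `source_index`; one row per
#'   sentence, in corpus order.
#' @export
build_database <- function(corpus, lex, tagger = default_tagger()) {
  if (nrow(corpus) == 0) {
    out <- tibble::tibble(tags = list(), label = as_sentence_label(character(0)),
                          source_index = integer(0))
    class(out) <- c("lspf_seqdb", class(out))
    return(out)
  }
  seqs <- purrr::map(seq_len(nrow(corpus)), function(i) {
    map_sentence(corpus$text[i], lex, tagger,
                 label = corpus$label[i], source_index = i)$tags
  })
  out <- tibble::tibble(tags = seqs,
                        label = as_sentence_label(corpus$label),
                        source_index = seq_len(nrow(corpus)))
  class(out) <- c("lspf_seqdb", class(out))
  out
}
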