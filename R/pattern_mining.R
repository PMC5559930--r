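#' Mining configuration
#'
#' Thresholds for frequent labeled sequential pattern mining: minimum
#' support \eqn{\mu} (fraction of database sequences containing a
#' pattern; default 0.05), minimum per-class confidence (default 0.85),
#' maximum gap between consecutive matched positions (index difference;
#' default 5, so `max_gap = 1` means adjacent) and maximum pattern
#' length (default 6 tags).
#'
#' @param min_support Fraction in (0, 1].
#' @param min_confidence Fraction in (0, 1].
#' @param max_gap Integer >= 1.
#' @param max_pattern_length Integer >= 1.
#' @return A list of class `lspf_mining_config`.
#' @export
mining_config <- function(min_support = 0.05, min_confidence = 0.85,
                          max_gap = 5L, max_pattern_length = 6L) {
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1)
    abort("min_support must be in (0, 1]")
  if (!is.numeric(min_confidence) || min_confidence <= 0 || min_confidence > 1)
    abort("min_confidence must be in (0, 1]")
  if (max_gap < 1) abort("max_gap must be >= 1")
  if (max_pattern_length < 1) abort("max_pattern_length must be >= 1")
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 max_gap = as.integer(max_gap),
                 max_pattern_length = as.integer(max_pattern_length)),
            class = "lspf_mining_config")
}

#' Gap-constrained subsequence containment
#'
#' Tests whether `pattern` occurs in `sequence` as a subsequence at
#' strictly increasing positions whose consecutive index differences are
#' at most `max_gap` (so `max_gap = 1` requires adjacency).
#'
#' @param sequence Character vector of tags.
#' @param pattern Character vector of tags, length >= 1.
#' @param max_gap Integer >= 1.
#' @return Logical scalar.
#' @export
#' @examples
#' seq_contains(c("a","b","c","d","e","f"), c("a","c","e"), max_gap = 5)
seq_contains <- function(sequence, pattern, max_gap = 5L) {
  if (length(pattern) == 0) abort("pattern must have length >= 1")
  if (max_gap < 1) abort("max_gap must be >= 1")
  if (length(sequence) == 0) return(FALSE)
  alphabet <- unique(c(sequence, pattern))
  seq_contains_cpp(match(sequence, alphabet), match(pattern, alphabet),
                   as.integer(max_gap))
}

# Encode a sequence database (list of character tag vectors) over its
# alphabet for the C++ layer.
encode_db <- function(tag_lists) {
  alphabet <- sort(unique(unlist(tag_lists, use.names = FALSE)), method = "radix")
  list(alphabet = alphabet,
       seqs = lapply(tag_lists, function(s) match(s, alphabet)))
}

db_tag_lists <- function(database) {
  if (is.data.frame(database)) database$tags else database
}

#' Which database sequences contain a pattern
#'
#' @param database An `lspf_seqdb` tibble ([build_database()]) or a list
#'   of tag vectors.
#' @param pattern Character vector of tags.
#' @param max_gap Integer >= 1.
#' @return Logical vector, one entry per database sequence.
#' @export
db_contains <- function(database, pattern, max_gap = 5L) {
  if (length(pattern) == 0) abort("pattern must have length >= 1")
  tag_lists <- db_tag_lists(database)
  enc <- encode_db(c(tag_lists, list(pattern)))
  db_contains_cpp(enc$seqs[seq_along(tag_lists)],
                  enc$seqs[[length(enc$seqs)]], as.integer(max_gap))
}

# Batch containment: N x K logical matrix over a list of patterns.
db_contains_many <- function(database, patterns, max_gap = 5L) {
  tag_lists <- db_tag_lists(database)
  n <- length(tag_lists)
  if (length(patterns) == 0) {
    return(matrix(logical(0), nrow = n, ncol = 0))
  }
  enc <- encode_db(c(tag_lists, patterns))
  db_contains_multi_cpp(enc$seqs[seq_len(n)],
                        enc$seqs[n + seq_along(patterns)],
                        as.integer(max_gap))
}

#' Support of a sequential pattern
#'
#' Fraction of database sequences containing `pattern` under
#' gap-constrained matching.
#'
#' @inheritParams db_contains
#' @return Fraction in \[0, 1\].
#' @export
pattern_support <- function(pattern, database, max_gap = 5L) {
  n <- length(db_tag_lists(database))
  if (n == 0) abort("database is empty")
  mean(db_contains(database, pattern, max_gap))
}

#' Per-class confidence of a sequential pattern
#'
#' Among database sequences containing `pattern`, the fraction labeled
#' `target_class`. Undefined (an error) for zero-support patterns.
#'
#' @inheritParams db_contains
#' @param target_class One of the [sentence_classes()].
#' @return Fraction in \[0, 1\].
#' @export
pattern_confidence <- function(pattern, database, target_class, max_gap = 5L) {
  stopifnot(is.data.frame(database), "label" %in% names(database))
  target_class <- as.character(as_sentence_label(target_class))
  hits <- db_contains(database, pattern, max_gap)
  if (!any(hits)) abort("pattern has zero support; confidence is undefined")
  mean(as.character(database$label[hits]) == target_class)
}

pattern_id <- function(tags) paste(tags, collapse = "|")

#' Mine frequent sequential patterns
#'
#' Enumerates exactly the tag patterns of length 1 to
#' `max_pattern_length` whose gap-constrained support meets
#' `min_support`, by depth-first prefix growth with support pruning
#' (sound because support is anti-monotone under prefix extension with a
#' maximum gap). Output is sorted by descending support, ties broken
#' lexicographically on the tag symbols, and is a pure function of the
#' database and configuration.
#'
#' @param database An `lspf_seqdb` tibble or list of tag vectors;
#'   must be non-empty.
#' @param config An [mining_config()] object.
#' @return Tibble with columns `pattern` (list of character vectors),
#'   `pattern_id` (tags joined by `|`), `length` and `support`.
#' @export
mine_fsps <- function(database, config = mining_config()) {
  tag_lists <- db_tag_lists(database)
  if (length(tag_lists) == 0) abort("database is empty")
  enc <- encode_db(tag_lists)
  res <- mine_fsps_cpp(enc$seqs, length(enc$alphabet),
                       config$min_support, config$max_gap,
                       config$max_pattern_length)
  pats <- lapply(res$patterns, function(ix) enc$alphabet[ix])
  support <- res$counts / length(tag_lists)
  key <- vapply(pats, function(p) paste(p, collapse = " "), character(1))
  ord <- order(-support, key, method = "radix")
  tibble::tibble(
    pattern = pats[ord],
    pattern_id = vapply(pats[ord], pattern_id, character(1)),
    length = lengths(pats[ord]),
    support = support[ord]
  )
}

#' Select frequent labeled sequential patterns (FLSPs)
#'
#' Filters mined frequent sequential patterns by per-class confidence:
#' for each target class (`medication` and `symptom`; background
#' sentences are not interpreted), an FSP whose confidence for that
#' class meets `min_confidence` becomes one FLSP. A pattern yields at
#' most one FLSP — with a confidence threshold above 0.5 only one class
#' can qualify; if the threshold admits several, the class with the
#' highest confidence (ties broken in class order) is used.
#'
#' @param fsps Output of [mine_fsps()] on the same database.
#' @param database The labeled-sequence database the FSPs were mined on.
#' @param config An [mining_config()] object.
#' @return Tibble with columns `pattern`, `pattern_id`, `support`,
#'   `confidence`, `target_class`, sorted like the input.
#' @export
select_flsps <- function(fsps, database, config = mining_config()) {
  stopifnot(is.data.frame(database), "label" %in% names(database))
  targets <- c("medication", "symptom")
  labels <- as.character(database$label)
  empty <- tibble::tibble(pattern = list(), pattern_id = character(0),
                          support = numeric(0), confidence = numeric(0),
                          target_class = character(0))
  if (nrow(fsps) == 0) return(empty)
  M <- db_contains_many(database, fsps$pattern, config$max_gap)
  total <- colSums(M)
  conf <- vapply(targets, function(cl) {
    colSums(M & (labels == cl)) / pmax(total, 1)
  }, numeric(nrow(fsps)))
  conf <- matrix(conf, ncol = length(targets),
                 dimnames = list(NULL, targets))
  best <- apply(conf, 1, which.max)
  best_conf <- conf[cbind(seq_len(nrow(conf)), best)]
  keep <- total > 0 & best_conf >= config$min_confidence
  if (!any(keep)) return(empty)
  tibble::tibble(pattern = fsps$pattern[keep],
                 pattern_id = fsps$pattern_id[keep],
                 support = fsps$support[keep],
                 confidence = best_conf[keep],
                 target_class = targets[best[keep]])
}

#' Mine FLSPs from a corpus in one call
#'
#' Convenience wrapper: [build_database()], [mine_fsps()] and
#' [select_flsps()].
#'
#' @inheritParams build_database
#' @param config An [mining_config()] object.
#' @return The [select_flsps()] tibble.
#' @export
mine_flsps <- function(corpus, lex, tagger = default_tagger(),
                       config = mining_config()) {
  db <- build_database(corpus, lex, tagger)
  select_flsps(mine_fsps(db, config), db, config)
}

#' Read/write pattern tables
#'
#' Pattern files are TSV with columns `pattern` (tags joined by `|`),
#' `support`, `confidence` and `class`.
#'
#' @param patterns A [select_flsps()] tibble.
#' @param path File path.
#' @return `write_patterns` returns `path` invisibly; `read_patterns`
#'   returns a pattern tibble.
#' @export
write_patterns <- function(patterns, path) {
  out <- tibble::tibble(pattern = patterns$pattern_id,
                        support = patterns$support,
                        confidence = patterns$confidence,
                        class = patterns$target_class)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  raw <- readr::read_tsv(path, col_types = "cddc", progress = FALSE)
  tibble::tibble(
    pattern = strsplit(raw$pattern, "|", fixed = TRUE),
    pattern_id = raw$pattern,
    support = raw$support,
    confidence = raw$confidence,
    target_class = raw$class
  )
}
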