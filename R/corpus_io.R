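#' Read a labeled sentence corpus
#'
#' Reads a corpus of labeled forum sentences from a TSV file (columns
#' `text`, `label`, `thread_id`, `post_index`, `is_creator`) or a JSONL
#' file (one JSON object per line with the same fields). Labels are
#' parsed case-insensitively against the three-class space
#' (`background`/`medication`/`symptom`, with `others` accepted as an
#' alias of `background` and integer codes 0/1/2 allowed).
#'
#' @param path Path to the corpus file.
#' @param format `"tsv"` or `"jsonl"`. Defaults by file extension.
#' @return A tibble with columns `text` (character), `label` (factor),
#'   `thread_id` (character), `post_index` (integer, >= 1) and
#'   `is_thread_creator` (logical), one row per sentence, in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' readr::write_tsv(tibble::tibble(
#'   text = c("I take Lantus.", "I have heartburn."),
#'   label = c("medication", "symptom"),
#'   thread_id = "t1", post_index = 1L, is_creator = c(TRUE, TRUE)), tf)
#' read_corpus(tf)
read_corpus <- function(path, format = c("auto", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  if (!file.exists(path)) abort(sprintf("corpus file not found: %s", path))
  if (format == "tsv") {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  } else {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(trimws(lines))]
    raw <- purrr::map_dfr(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) abort(sprintf(
                        "line %d: invalid JSON record (%s)", i, conditionMessage(e))))
      tibble::as_tibble(lapply(rec, as.character))
    })
  }
  validate_corpus(raw, source = path)
}

# Accepts both is_creator and is_thread_creator column spellings.
validate_corpus <- function(raw, source = "corpus") {
  names(raw)[names(raw) == "is_creator"] <- "is_thread_creator"
  required <- c("text", "label", "thread_id", "post_index", "is_thread_creator")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required field(s): %s",
                  source, paste(missing, collapse = ", ")))
  }
  nas <- which(rowSums(is.na(raw[required]) |
                         vapply(raw[required], function(x) !nzchar(trimws(as.character(x))),
                                logical(nrow(raw)))) > 0)
  if (length(nas) > 0) {
    abort(sprintf("%s: record %d is missing a field value", source, nas[1]))
  }
  label <- tryCatch(as_sentence_label(raw$label), error = function(e) {
    abort(sprintf("%s: %s", source, conditionMessage(e)))
  })
  post_index <- suppressWarnings(as.integer(raw$post_index))
  if (any(is.na(post_index)) || any(post_index < 1L)) {
    abort(sprintf("%s: post_index must be an integer >= 1", source))
  }
  creator_raw <- tolower(trimws(as.character(raw$is_thread_creator)))
  is_creator <- creator_raw %in% c("true", "t", "1", "yes")
  bad_creator <- !creator_raw %in% c("true", "t", "1", "yes", "false", "f", "0", "no")
  if (any(bad_creator)) {
    abort(sprintf("%s: invalid is_thread_creator value '%s'",
                  source, creator_raw[which(bad_creator)[1]]))
  }
  text <- as.character(raw$text)
  if (any(!nzchar(trimws(text)))) {
    abort(sprintf("%s: empty sentence text at record %d",
                  source, which(!nzchar(trimws(text)))[1]))
  }
  tibble::tibble(
    text = text,
    label = label,
    thread_id = as.character(raw$thread_id),
    post_index = post_index,
    is_thread_creator = is_creator
  )
}

#' Write a labeled sentence corpus
#'
#' Inverse of [read_corpus()]: writes the five corpus fields as TSV or
#' JSONL so that reading the file back reproduces the field values.
#'
#' @param corpus Corpus tibble as returned by [read_corpus()].
#' @param path Output path.
#' @param format `"tsv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(path, corpus, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  out <- dplyr::mutate(corpus,
                       label = as.character(.data$label),
                       is_creator = .data$is_thread_creator,
                       is_thread_creator = NULL)
  out <- out[, c("text", "label", "thread_id", "post_index", "is_creator")]
  if (format == "tsv") {
    readr::write_tsv(out, path, progress = FALSE, quote = "needed",
                     escape = "double")
  } else {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE)
    }, character(1))
    readr::write_lines(lines, path)
  }
  invisible(path)
}

# Abbreviations that must not terminate a sentence.
SPLIT_ABBREVIATIONS <- c(
  "dr", "mr", "mrs", "ms", "prof", "st", "jr", "sr", "rev",
  "e.g", "i.e", "etc", "vs", "approx", "fig", "no", "dept", "est",
  "a.m", "p.m", "u.s", "u.k"
)

#' Split a post into sentences
#'
#' Abbreviation-aware sentence splitter for forum post text. Candidate
#' boundaries are terminal punctuation (`.`, `!`, `?`, possibly followed
#' by closing quotes/brackets) followed by whitespace; a boundary is
#' suppressed when the preceding token is a known abbreviation (e.g.
#' "Dr.", "e.g.") or a single initial ("J. Smith"). Concatenating the
#' returned sentences preserves every non-whitespace character of the
#' input; empty strings are never returned.
#'
#' @param post_text A single character string (a forum post).
#' @return Character vector of sentences, in order (empty input gives
#'   `character(0)`).
#' @export
#' @examples
#' split_post("I have heartburn. I take nexium.")
#' split_post("Dr. Smith prescribed 40 mg.")
split_post <- function(post_text) {
  stopifnot(length(post_text) == 1)
  if (is.na(post_text) || !nzchar(trimws(post_text))) return(character(0))
  m <- gregexpr("[.!?]+[\"')\\]]*(\\s+|$)", post_text, perl = TRUE)[[1]]
  if (m[1] == -1) return(trimws(post_text))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  cut_after <- integer(0)
  for (i in seq_along(starts)) {
    punct_end <- starts[i] + lens[i] - 1L
    # token immediately preceding the punctuation
    before <- substr(post_text, 1L, starts[i] - 1L)
    tok <- stringr::str_extract(before, "[A-Za-z][A-Za-z.]*$")
    if (!is.na(tok)) {
      tl <- tolower(sub("\\.$", "", tok))
      if (tl %in% SPLIT_ABBREVIATIONS) next            # known abbreviation
      if (nchar(tl) == 1 && grepl("^[A-Za-z]$", tl) &&
          grepl("^\\.", substr(post_text, starts[i], starts[i]))) next  # initial
    }
    cut_after <- c(cut_after, punct_end)
  }
  bounds <- unique(c(0L, cut_after, nchar(post_text)))
  bounds <- sort(bounds)
  pieces <- vapply(seq_len(length(bounds) - 1L), function(i) {
    substr(post_text, bounds[i] + 1L, bounds[i + 1L])
  }, character(1))
  pieces <- trimws(pieces)
  pieces[nzchar(pieces)]
}

#' Construct a lexicon set
#'
#' Bundles the three lexicons that drive special tagging: drug terms
#' (tagged `DRUG`), symptom terms (tagged `SYMP`) and frequency-phrase
#' regular expressions (tagged `FREQ`). Phrases are normalized to lower
#' case with collapsed whitespace; matching is case-insensitive and
#' prefers the longest phrase at a position.
#'
#' @param drug_terms Character vector of drug phrases.
#' @param symptom_terms Character vector of symptom phrases.
#' @param freq_patterns Character vector of regular expressions for
#'   frequency phrases (e.g. `"twice a day"`).
#' @return An object of class `lspf_lexicons`.
#' @export
#' @examples
#' lexicons(drug_terms = "Lantus", symptom_terms = "heartburn",
#'          freq_patterns = "(once|twice) a day")
lexicons <- function(drug_terms = character(0),
                     symptom_terms = character(0),
                     freq_patterns = character(0)) {
  norm <- function(x) {
    x <- stringr::str_squish(tolower(x))
    x <- x[nzchar(x)]
    unique(x)
  }
  for (i in seq_along(freq_patterns)) {
    ok <- tryCatch({grepl(freq_patterns[i], ""); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(sprintf("invalid frequency regex at entry %d: %s",
                           i, freq_patterns[i]))
  }
  obj <- list(drug_terms = norm(drug_terms),
              symptom_terms = norm(symptom_terms),
              freq_patterns = unique(freq_patterns[nzchar(freq_patterns)]))
  # phrase token lists are precomputed once; matching is token-based
  obj$drug_tokens <- lapply(obj$drug_terms,
                            function(p) tokenize_sentence(p)$token)
  obj$symptom_tokens <- lapply(obj$symptom_terms,
                               function(p) tokenize_sentence(p)$token)
  structure(obj, class = "lspf_lexicons")
}

#' @export
print.lspf_lexicons <- function(x, ...) {
  cat(sprintf("<lexicons: %d drug terms, %d symptom terms, %d frequency patterns>\n",
              length(x$drug_terms), length(x$symptom_terms),
              length(x$freq_patterns)))
  invisible(x)
}

#' Read lexicons from one-entry-per-line files
#'
#' @param drug_path,symptom_path,freq_path Paths to UTF-8 plain-text
#'   files, one phrase (or regular expression, for `freq_path`) per
#'   line. Blank lines and lines starting with `#` are skipped.
#' @return An `lspf_lexicons` object (see [lexicons()]).
#' @export
read_lexicons <- function(drug_path, symptom_path, freq_path) {
  read_list <- function(path) {
    if (is.null(path)) return(character(0))
    x <- readr::read_lines(path)
    x <- trimws(x)
    x[nzchar(x) & !startsWith(x, "#")]
  }
  freq <- read_list(freq_path)
  for (i in seq_along(freq)) {
    ok <- tryCatch({grepl(freq[i], ""); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(sprintf("%s: invalid regular expression on line %d: %s",
                           freq_path, i, freq[i]))
  }
  lexicons(drug_terms = read_list(drug_path),
           symptom_terms = read_list(symptom_path),
           freq_patterns = freq)
}

#' Write lexicons to plain-text files
#'
#' @param lex An `lspf_lexicons` object.
#' @param dir Output directory; files `drugs.txt`, `symptoms.txt`,
#'   `freq.txt` are written inside it.
#' @return `dir`, invisibly.
#' @export
write_lexicons <- function(lex, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_lines(lex$drug_terms, file.path(dir, "drugs.txt"))
  readr::write_lines(lex$symptom_terms, file.path(dir, "symptoms.txt"))
  readr::write_lines(lex$freq_patterns, file.path(dir, "freq.txt"))
  invisible(dir)
}
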