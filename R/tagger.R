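#' Tokenize a sentence with character offsets
#'
#' Splits a sentence into word and punctuation tokens. Word tokens are
#' maximal runs of letters, digits and internal apostrophes/hyphens;
#' every other non-whitespace character is its own punctuation token.
#' Offsets are kept so regex matches on the raw sentence can be mapped
#' back to token ranges.
#'
#' @param text A single character string.
#' @return Tibble with columns `token`, `start`, `end` (1-based,
#'   inclusive character offsets).
#' @export
#' @examples
#' tokenize_sentence("I take 40 mg, twice a day.")
tokenize_sentence <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(token = character(0), start = integer(0),
                          end = integer(0)))
  }
  m <- gregexpr("[A-Za-z0-9]+(?:['\\-][A-Za-z0-9]+)*|[^A-Za-z0-9\\s]",
                text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(0), start = integer(0),
                          end = integer(0)))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tibble::tibble(token = substring(text, starts, starts + lens - 1L),
                 start = starts, end = starts + lens - 1L)
}

# Penn-Treebank-style tags for punctuation tokens. The comma is spelled
# out as "comma" so pattern alphabets serialize cleanly.
punct_tag <- function(tok) {
  if (tok == ",") return("comma")
  if (tok %in% c(".", "!", "?")) return(".")
  if (tok %in% c(":", ";")) return(":")
  if (tok == "(") return("-LRB-")
  if (tok == ")") return("-RRB-")
  if (tok %in% c("\"", "'", "`")) return("''")
  "SYM"
}

#' Build a deterministic dictionary-based POS tagger
#'
#' Returns a tagger function with the contract required by
#' [map_sentence()]: it takes a character vector of tokens and returns an
#' equal-length character vector of Penn-Treebank tags. Tokens are looked
#' up case-insensitively in `dictionary`; numbers are tagged `CD`,
#' punctuation receives its literal tag (`comma`, `.`, ...), and unknown
#' words fall back to `default`.
#'
#' @param dictionary Named character vector mapping lower-cased word to
#'   tag.
#' @param default Tag for out-of-dictionary words (default `"NN"`).
#' @return A function `tokens -> tags`.
#' @export
#' @examples
#' tag <- dictionary_tagger(c(i = "PRP", am = "VBP"))
#' tag(c("I", "am", "90", "happy"))
dictionary_tagger <- function(dictionary = character(0), default = "NN") {
  names(dictionary) <- tolower(names(dictionary))
  function(tokens) {
    if (length(tokens) == 0) return(character(0))
    tags <- unname(dictionary[tolower(tokens)])
    tags[is.na(tags)] <- default
    tags[grepl("^[0-9]+([.,][0-9]+)*$", tokens)] <- "CD"
    punct <- grepl("^[^A-Za-z0-9]$", tokens)
    if (any(punct)) {
      tags[punct] <- vapply(tokens[punct], punct_tag, character(1),
                            USE.NAMES = FALSE)
    }
    tags
  }
}

# Core dictionary: closed-class words plus the vocabulary used by the
# synthetic corpus generator. Open-class words not listed fall back to NN.
base_tag_dictionary <- function() {
  c(
    # pronouns / determiners
    i = "PRP", you = "PRP", he = "PRP", she = "PRP", it = "PRP",
    we = "PRP", they = "PRP", me = "PRP", him = "PRP", her = "PRP$",
    my = "PRP$", your = "PRP$", his = "PRP$", their = "PRP$", our = "PRP$",
    the = "DT", a = "DT", an = "DT", this = "DT", that = "DT",
    these = "DT", those = "DT", some = "DT", any = "DT", no = "DT",
    # verbs
    am = "VBP", is = "VBZ", are = "VBP", was = "VBD", were = "VBD",
    be = "VB", been = "VBN", being = "VBG",
    have = "VBP", has = "VBZ", had = "VBD", having = "VBG",
    do = "VBP", does = "VBZ", did = "VBD",
    take = "VBP", takes = "VBZ", took = "VBD", taking = "VBG",
    taken = "VBN",
    get = "VBP", got = "VBD", getting = "VBG",
    feel = "VBP", feels = "VBZ", felt = "VBD", feeling = "VBG",
    started = "VBD", starting = "VBG", start = "VBP",
    prescribed = "VBD", prescribe = "VBP", prescribes = "VBZ",
    suggested = "VBD", recommended = "VBD", increased = "VBD",
    went = "VBD", going = "VBG", go = "VBP", gone = "VBN",
    suffer = "VBP", suffering = "VBG", suffered = "VBD",
    keeps = "VBZ", keep = "VBP", seems = "VBZ", seem = "VBP",
    helps = "VBZ", helped = "VBD", help = "VB",
    told = "VBD", said = "VBD", says = "VBZ", say = "VBP",
    thanks = "VBZ", thank = "VBP", hope = "VBP", wish = "VBP",
    know = "VBP", think = "VBP", wonder = "VBP", posted = "VBD",
    joined = "VBD", read = "VBP", asked = "VBD", flared = "VBD",
    # modals / auxiliaries
    will = "MD", would = "MD", can = "MD", could = "MD",
    should = "MD", may = "MD", might = "MD", must = "MD",
    # prepositions / conjunctions
    of = "IN", "in" = "IN", on = "IN", at = "IN", "for" = "IN",
    with = "IN", from = "IN", about = "IN", after = "IN",
    before = "IN", since = "IN", during = "IN", per = "IN",
    and = "CC", or = "CC", but = "CC",
    to = "TO",
    # adverbs
    not = "RB", very = "RB", really = "RB", also = "RB", now = "RB",
    then = "RB", here = "RB", there = "EX", again = "RB", often = "RB",
    always = "RB", usually = "RB", still = "RB", just = "RB",
    honestly = "RB", lately = "RB", recently = "RB", yesterday = "NN",
    today = "NN", constantly = "RB", sometimes = "RB",
    # adjectives
    good = "JJ", bad = "JJ", new = "JJ", old = "JJ", severe = "JJ",
    mild = "JJ", chronic = "JJ", nice = "JJ", sunny = "JJ",
    tired = "JJ", worse = "JJR", better = "JJR", constant = "JJ",
    daily = "JJ", sharp = "JJ", dull = "JJ", terrible = "JJ",
    last = "JJ", "next" = "JJ", first = "JJ", same = "JJ", other = "JJ",
    # common nouns (incl. dosage units used by the generator)
    units = "NNS", unit = "NN", mg = "NN", ml = "NN",
    tablets = "NNS", tablet = "NN", pills = "NNS", pill = "NN",
    capsules = "NNS", capsule = "NN", doses = "NNS", dose = "NN",
    doctor = "NN", gp = "NN", nurse = "NN", hospital = "NN",
    week = "NN", weeks = "NNS", day = "NN", days = "NNS",
    month = "NN", months = "NNS", year = "NN", years = "NNS",
    morning = "NN", night = "NN", evening = "NN",
    weather = "NN", forum = "NN", thread = "NN", post = "NN",
    everyone = "NN", anyone = "NN", people = "NNS", advice = "NN",
    luck = "NN", story = "NN", time = "NN", times = "NNS",
    stomach = "NN", head = "NN", chest = "NN", back = "NN",
    thing = "NN", things = "NNS", bit = "NN", lot = "NN",
    wife = "NN", husband = "NN", family = "NN", work = "NN"
  )
}

#' Default bundled tagger
#'
#' A deterministic [dictionary_tagger()] over a built-in dictionary of
#' closed-class English words and the vocabulary used by the synthetic
#' corpus generator. Out-of-dictionary words are tagged `NN`. This is the
#' tagger used throughout the examples and the test fixtures; any
#' function with the same token-list to tag-list contract can replace it.
#'
#' @return A tagger function `tokens -> tags`.
#' @export
#' @examples
#' default_tagger()(c("I", "am", "taking", "90", "units"))
default_tagger <- function() {
  dictionary_tagger(base_tag_dictionary(), default = "NN")
}
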