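#' Synthetic corpus configuration
#'
#' Parameters of the synthetic health-forum corpus generator. The
#' defaults emulate the class balance of a hand-labeled patient-forum
#' corpus of 2099 sentences (about 10% background, 54% medication, 36%
#' symptom), with class-specific planted tag patterns: medication
#' sentences embed a dosage-number + unit + drug-term + frequency-phrase
#' template realizing the tag run (CD, NNS, DRUG, FREQ); symptom
#' sentences embed a three-symptom run with conjunctions realizing
#' (SYMP, SYMP, SYMP); background sentences are filler. Thread metadata
#' is skewed so symptom sentences tend to come from thread creators and
#' early posts.
#'
#' @param n_sentences Number of sentences (default 2099).
#' @param class_mix Named proportions over (background, medication,
#'   symptom); must sum to 1.
#' @param occurrence_prob Probability that a medication/symptom sentence
#'   realizes its full planted template (default 0.9); otherwise a
#'   degraded template without the planted run is used.
#' @param noise_rate Probability of inserting random filler adverbs into
#'   a sentence (default 0.1). Fillers never break a multi-word phrase
#'   and the resulting gaps stay within the default max-gap of 5.
#' @param creator_bias Per-class probability that the sentence's author
#'   is the thread creator.
#' @param first_post_bias Probability that a symptom sentence comes from
#'   the first post of its thread.
#' @return A list of class `lspf_synth_config`.
#' @export
synth_config <- function(n_sentences = 2099L,
                         class_mix = c(background = 0.10,
                                       medication = 0.54,
                                       symptom = 0.36),
                         occurrence_prob = 0.9,
                         noise_rate = 0.1,
                         creator_bias = c(background = 0.3,
                                          medication = 0.3,
                                          symptom = 0.8),
                         first_post_bias = 0.7) {
  if (abs(sum(class_mix) - 1) > 1e-8) abort("class_mix must sum to 1")
  if (any(class_mix < 0)) abort("class_mix proportions must be non-negative")
  stopifnot(occurrence_prob >= 0, occurrence_prob <= 1,
            noise_rate >= 0, noise_rate <= 1)
  structure(list(n_sentences = as.integer(n_sentences),
                 class_mix = class_mix[SENTENCE_CLASSES],
                 occurrence_prob = occurrence_prob,
                 noise_rate = noise_rate,
                 creator_bias = creator_bias[SENTENCE_CLASSES],
                 first_post_bias = first_post_bias),
            class = "lspf_synth_config")
}

synth_vocab <- function() {
  list(
    drugs = c("Lantus", "Nexium", "Metformin", "Omeprazole", "Prednisone",
              "Sertraline"),
    symptoms = c("heartburn", "nausea", "bloating", "dizziness", "fatigue",
                 "cramping", "headache", "insomnia"),
    freq_phrases = c("once a day", "twice a day", "three times a day",
                     "every morning", "every night"),
    freq_patterns = c("(once|twice) a day", "three times a day",
                      "every (morning|night)"),
    units = c("units", "tablets"),
    doses = c("10", "20", "40", "50", "90", "100"),
    fillers = c("really", "honestly", "just", "still")
  )
}

#' Planted-pattern ground truth of the generator
#'
#' Closed-form designed statistics of the planted patterns: designed
#' support = class proportion x occurrence probability (every full
#' template realizes its pattern, and fillers keep gaps within bound);
#' designed confidence = 1 because the special tags each pattern needs
#' are exclusive to its class.
#'
#' @param config An [synth_config()].
#' @return Tibble with `pattern` (list), `pattern_id`, `class`,
#'   `occurrence_prob`, `designed_support`, `designed_confidence`.
#' @export
expected_pattern_stats <- function(config = synth_config()) {
  planted <- list(
    medication = c("CD", "NNS", "DRUG", "FREQ"),
    symptom = c("SYMP", "SYMP", "SYMP")
  )
  tibble::tibble(
    pattern = unname(planted),
    pattern_id = vapply(planted, pattern_id, character(1)),
    class = names(planted),
    occurrence_prob = config$occurrence_prob,
    designed_support = unname(config$class_mix[names(planted)]) *
      config$occurrence_prob,
    designed_confidence = 1
  )
}

# join word parts into sentence text ("," and "." attach leftward)
assemble_text <- function(parts) {
  out <- paste(parts, collapse = " ")
  gsub(" ([,.])", "\\1", out)
}

#' Generate a synthetic labeled corpus
#'
#' Draws a corpus under [synth_config()]: class labels are multinomial
#' with the configured mixture, each sentence is realized from a
#' class-specific word template (full planted template with probability
#' `occurrence_prob`), random filler adverbs are inserted with
#' probability `noise_rate`, and thread metadata is drawn from the
#' thread model. The returned lexicons cover exactly the generated
#' drug/symptom/frequency vocabulary, so [build_database()] with
#' [default_tagger()] reproduces the intended tag sequences. The same
#' seed yields a byte-identical corpus.
#'
#' @param config An [synth_config()].
#' @param seed Integer seed.
#' @return List with `corpus` (corpus tibble; passes [read_corpus()]
#'   validation), `truth` (planted-pattern stats from
#'   [expected_pattern_stats()] plus a per-sentence `template` vector)
#'   and `lexicons` (an `lspf_lexicons`).
#' @export
#' @examples
#' synth <- generate_corpus(synth_config(n_sentences = 50), seed = 1)
#' head(synth$corpus)
generate_corpus <- function(config = synth_config(), seed = 0L) {
  set.seed(seed)
  v <- synth_vocab()
  n <- config$n_sentences
  classes <- sample(SENTENCE_CLASSES, n, replace = TRUE,
                    prob = config$class_mix)
  template <- character(n)
  texts <- character(n)

  med_full <- function() {
    opener <- sample(list(c("I", "am", "taking"),
                          c("I", "started", "taking")), 1)[[1]]
    c(opener, sample(v$doses, 1), sample(v$units, 1), sample(v$drugs, 1),
      sample(v$freq_phrases, 1), ".")
  }
  med_degraded <- function() {
    sample(list(
      c("My", "doctor", "prescribed", sample(v$drugs, 1), "."),
      c("I", "took", sample(v$drugs, 1), "yesterday", "."),
      c("The", "doctor", "suggested", sample(v$drugs, 1), ".")
    ), 1)[[1]]
  }
  sym_full <- function() {
    s <- sample(v$symptoms, 3)
    c(sample(c("I"), 1), sample(c("have", "had"), 1),
      s[1], ",", s[2], "and", s[3], ".")
  }
  sym_degraded <- function() {
    s <- sample(v$symptoms, 1)
    sample(list(
      c("I", "have", s, "again", "."),
      c("My", s, "is", "worse", ".")
    ), 1)[[1]]
  }
  background_parts <- function() {
    sample(list(
      c("Thanks", "for", "the", "advice", "."),
      c("Good", "luck", "to", "everyone", "."),
      c("The", "weather", "was", "nice", "today", "."),
      c("I", "joined", "the", "forum", "last", "week", "."),
      c("Hope", "you", "are", "well", ".")
    ), 1)[[1]]
  }

  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "medication") {
      full <- stats::runif(1) < config$occurrence_prob
      parts <- if (full) med_full() else med_degraded()
      template[i] <- if (full) "med_full" else "med_degraded"
    } else if (cl == "symptom") {
      full <- stats::runif(1) < config$occurrence_prob
      parts <- if (full) sym_full() else sym_degraded()
      template[i] <- if (full) "sym_full" else "sym_degraded"
    } else {
      parts <- background_parts()
      template[i] <- "background"
    }
    if (stats::runif(1) < config$noise_rate) {
      # insert one filler adverb at an internal boundary (never before
      # the terminal period position 1 issue; never splits a phrase
      # because multi-word phrases are single parts)
      pos <- sample(seq_len(max(1L, length(parts) - 1L)), 1)
      parts <- append(parts, sample(v$fillers, 1), after = pos)
    }
    texts[i] <- assemble_text(parts)
  }

  is_creator <- stats::runif(n) < config$creator_bias[classes]
  post_index <- integer(n)
  for (i in seq_len(n)) {
    if (classes[i] == "symptom") {
      post_index[i] <- if (stats::runif(1) < config$first_post_bias) 1L
        else sample(2:4, 1)
    } else {
      post_index[i] <- sample(1:6, 1)
    }
  }
  thread_id <- paste0("t", ceiling(seq_len(n) / 4))

  corpus <- tibble::tibble(
    text = texts,
    label = factor(classes, levels = SENTENCE_CLASSES),
    thread_id = thread_id,
    post_index = post_index,
    is_thread_creator = unname(is_creator)
  )
  lex <- lexicons(drug_terms = v$drugs, symptom_terms = v$symptoms,
                  freq_patterns = v$freq_patterns)
  truth <- expected_pattern_stats(config)
  list(corpus = corpus,
       truth = list(patterns = truth, template = template),
       lexicons = lex)
}

#' Semantic phrase table for the synthetic corpus
#'
#' A small phrase-to-semantic-type table covering the generator
#' vocabulary: drug terms map to `phsu` (pharmacologic substance),
#' symptom terms to `sosy` (sign or symptom; `fatigue` and `insomnia`
#' additionally to `patf`, pathologic function), and care words
#' (`doctor`, `gp`, `prescribed`) to `hlca` (health care activity).
#'
#' @param lex Lexicons of the generated corpus (default: the
#'   generator's own).
#' @return An `lspf_semtagger` (see [semantic_tagger()]).
#' @export
synth_semantic_table <- function(lex = NULL) {
  v <- synth_vocab()
  drugs <- if (is.null(lex)) tolower(v$drugs) else lex$drug_terms
  syms <- if (is.null(lex)) v$symptoms else lex$symptom_terms
  tbl <- dplyr::bind_rows(
    tibble::tibble(phrase = drugs, code = "phsu"),
    tibble::tibble(phrase = syms, code = "sosy"),
    tibble::tibble(phrase = intersect(c("fatigue", "insomnia"), syms),
                   code = "patf"),
    tibble::tibble(phrase = c("doctor", "gp", "prescribed"), code = "hlca")
  )
  semantic_tagger(tbl)
}
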