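#' One-vs-rest binary metrics for a target class
#'
#' Precision, recall, F1 and accuracy of the binary problem "target
#' class vs rest". Empty denominators (no predicted positives, no true
#' positives, or an absent class) yield 0 with a warning.
#'
#' @param truth,pred Label vectors of equal length (anything
#'   [as_sentence_label()] accepts, or plain factors).
#' @param target The target class.
#' @return Tibble with columns `class`, `precision`, `recall`, `f1`,
#'   `accuracy`, `n`.
#' @export
binary_metrics <- function(truth, pred, target) {
  if (length(truth) != length(pred)) abort("truth and pred lengths differ")
  truth <- as.character(truth)
  pred <- as.character(pred)
  target <- as.character(target)
  tp <- sum(truth == target & pred == target)
  fp <- sum(truth != target & pred == target)
  fn <- sum(truth == target & pred != target)
  tn <- sum(truth != target & pred != target)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("empty denominator for %s of class '%s'; reporting 0",
                   what, target))
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble::tibble(class = target, precision = precision, recall = recall,
                 f1 = f1, accuracy = (tp + tn) / length(truth),
                 n = sum(truth == target))
}

#' Weighted multi-class evaluation report
#'
#' Per-class one-vs-rest metrics plus their class-size-weighted
#' averages: weighted metric = sum over classes of (N_l / N) x metric_l.
#' Weighted recall equals the overall multiclass accuracy (one-vs-rest
#' recall is the within-class accuracy).
#'
#' @inheritParams binary_metrics
#' @param classes Classes to report (default: the three sentence
#'   classes).
#' @return Object of class `lspf_eval` with `per_class` (tibble),
#'   `weighted` (named vector: precision, recall, f1) and
#'   `overall_accuracy`.
#' @export
weighted_metrics <- function(truth, pred, classes = sentence_classes()) {
  if (length(truth) != length(pred)) abort("truth and pred lengths differ")
  if (length(truth) == 0) abort("empty label vectors")
  truth <- as.character(truth)
  pred <- as.character(pred)
  per_class <- purrr::map_dfr(classes, ~ binary_metrics(truth, pred, .x))
  w <- per_class$n / length(truth)
  weighted <- c(precision = sum(w * per_class$precision),
                recall = sum(w * per_class$recall),
                f1 = sum(w * per_class$f1))
  structure(list(per_class = per_class, weighted = weighted,
                 overall_accuracy = mean(truth == pred),
                 n = length(truth)),
            class = "lspf_eval")
}

#' @export
print.lspf_eval <- function(x, ...) {
  cat(sprintf("<evaluation on %d sentences: accuracy %.3f; weighted P/R/F1 %.3f/%.3f/%.3f>\n",
              x$n, x$overall_accuracy, x$weighted["precision"],
              x$weighted["recall"], x$weighted["f1"]))
  print(x$per_class)
  invisible(x)
}

#' Pipeline configuration for cross-validation
#'
#' Bundles the choices refit inside every training fold: which feature
#' blocks to use, the classifier, the mining configuration and the
#' forest/selection sizes.
#'
#' @param features Subset of
#'   `c("flsp", "semantic", "word", "morphological", "creator",
#'   "position", "word_count")`.
#' @param model `"forest"`, `"svm"` or `"lasso"`.
#' @param mining An [mining_config()].
#' @param trees,mtry Forest size parameters.
#' @param select_k Optional entropy-based feature-selection size
#'   (`NULL` = keep all features).
#' @param lambda Lasso penalty.
#' @return A list of class `lspf_pipeline`.
#' @export
pipeline_config <- function(features = c("flsp", "semantic"),
                            model = c("forest", "svm", "lasso"),
                            mining = mining_config(),
                            trees = 500L, mtry = NULL,
                            select_k = NULL, lambda = 0.001) {
  model <- match.arg(model)
  known <- c("flsp", "semantic", "word", "morphological", "creator",
             "position", "word_count")
  bad <- setdiff(features, known)
  if (length(bad) > 0) abort(sprintf("unknown feature block(s): %s",
                                     paste(bad, collapse = ", ")))
  structure(list(features = features, model = model, mining = mining,
                 trees = trees, mtry = mtry, select_k = select_k,
                 lambda = lambda),
            class = "lspf_pipeline")
}

# stratified fold assignment, deterministic in seed
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assignment <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    if (length(ix) < folds) {
      warn(sprintf("class '%s' has fewer members (%d) than folds (%d); folds are not fully stratified",
                   cl, length(ix), folds))
    }
    assignment[sample(ix)] <- rep_len(seq_len(folds), length(ix))
  }
  assignment
}

fit_fold_spec <- function(corpus_tr, db_tr, config, lex, sem_tagger) {
  flsps <- NULL
  if ("flsp" %in% config$features) {
    fsps <- mine_fsps(db_tr, config$mining)
    flsps <- select_flsps(fsps, db_tr, config$mining)
  }
  spec <- fit_feature_spec(
    corpus_tr, flsps = flsps,
    sem_tagger = if ("semantic" %in% config$features) sem_tagger else NULL,
    include_words = "word" %in% config$features,
    include_morphological = "morphological" %in% config$features,
    include_creator = "creator" %in% config$features,
    include_position = "position" %in% config$features,
    include_word_count = "word_count" %in% config$features,
    max_gap = config$mining$max_gap)
  spec
}

#' Cross-validated pipeline evaluation
#'
#' Stratified k-fold cross-validation of the full pipeline. Everything
#' that learns from data — FLSP mining, vocabulary, entropy feature
#' selection, model fitting — is refit inside each training fold, and
#' metrics are computed on the held-out fold. The report averages the
#' per-fold metrics and keeps the fold breakdown.
#'
#' @param corpus Corpus tibble.
#' @param lex An `lspf_lexicons` used for tag mapping.
#' @param config An [pipeline_config()].
#' @param sem_tagger Semantic tagger (required if the `semantic` block
#'   is in `config$features`).
#' @param tagger POS tagger.
#' @param folds Number of folds (default 5).
#' @param seed Seed controlling fold assignment and model training.
#' @return An `lspf_eval` object with extra elements `fold_breakdown`
#'   (list of per-fold `lspf_eval`), `predictions` (tibble with `truth`,
#'   `pred`, `fold`) and `majority_baseline`.
#' @export
cross_validate <- function(corpus, lex, config = pipeline_config(),
                           sem_tagger = NULL, tagger = default_tagger(),
                           folds = 5L, seed = 0L) {
  if (nrow(corpus) < folds) abort("fewer sentences than folds")
  labels <- as.character(as_sentence_label(corpus$label))
  db <- build_database(corpus, lex, tagger)
  fold_of <- stratified_folds(labels, folds, seed)
  preds <- character(nrow(corpus))
  fold_reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    corpus_tr <- corpus[tr, ]
    db_tr <- db[tr, ]
    spec <- fit_fold_spec(corpus_tr, db_tr, config, lex, sem_tagger)
    X_tr <- featurize(spec, corpus_tr, database = db_tr)
    if (!is.null(config$select_k)) {
      sel <- entropy_feature_selection(X_tr, config$select_k)
      spec <- restrict_spec(spec, sel$feature)
      X_tr <- featurize(spec, corpus_tr, database = db_tr)
    }
    X_te <- featurize(spec, corpus[te, ], database = db[te, ])
    pred <- switch(config$model,
      forest = {
        m <- train_forest(X_tr, trees = config$trees, mtry = config$mtry,
                          seed = seed + f)
        as.character(predict_forest(m, X_te)$class)
      },
      svm = {
        m <- train_svm_pair(X_tr, seed = seed + f)
        as.character(predict_svm_pair(m, X_te)$class)
      },
      lasso = {
        m <- train_lasso(X_tr, lambda = config$lambda)
        as.character(predict_lasso(m, X_te)$class)
      })
    preds[te] <- pred
    fold_reports[[f]] <- weighted_metrics(labels[te], pred)
  }
  out <- weighted_metrics(labels, preds)
  out$fold_breakdown <- fold_reports
  out$predictions <- tibble::tibble(truth = labels, pred = preds,
                                    fold = fold_of)
  out$majority_baseline <- max(table(labels)) / length(labels)
  out
}
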