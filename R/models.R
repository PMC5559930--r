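#' Train a random forest with interpretable node records
#'
#' Grows a random forest of unpruned CART-style trees (bootstrap samples
#' of size N, best-of-`mtry` Gini splits; tree growing is delegated to
#' \pkg{ranger}) and then reconstructs, for every node of every tree,
#' the class-proportion vector of the in-bag training samples that reach
#' it. These per-node criterion-score vectors are what the prediction
#' and the feature-contribution decomposition ([forest_contributions()])
#' are computed from, so the decomposition conserves exactly.
#'
#' @param X An `lspf_features` tibble ([featurize()]) or any data frame
#'   with a factor column `label` plus numeric feature columns.
#' @param trees Number of trees T (default 500).
#' @param mtry Features tried per split; default `ceiling(sqrt(D))`.
#' @param seed Integer seed; the same seed reproduces the forest
#'   exactly.
#' @param min_node_size Minimum node size (default 1: grown to maximum
#'   size without pruning).
#' @return An object of class `lspf_forest` with elements `trees` (one
#'   node table per tree), `classes`, `feature_names`, `num_trees`,
#'   `mtry` and `oob_accuracy`.
#' @export
train_forest <- function(X, trees = 500L, mtry = NULL, seed = 0L,
                         min_node_size = 1L) {
  y <- X$label
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) abort("training data contains a single class")
  xmat <- feature_values(X)
  if (nrow(xmat) < 2) abort("need at least two training instances")
  D <- ncol(xmat)
  if (is.null(mtry)) mtry <- ceiling(sqrt(D))
  feature_names <- colnames(xmat)
  df <- as.data.frame(xmat)
  names(df) <- paste0("f", seq_len(D))
  df$.label <- y
  rf <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = as.integer(trees), mtry = as.integer(min(mtry, D)),
    replace = TRUE, sample.fraction = 1,
    min.node.size = as.integer(min_node_size),
    splitrule = "gini", keep.inbag = TRUE, seed = as.integer(seed),
    num.threads = 1, verbose = FALSE)
  classes <- levels(y)
  C <- length(classes)
  ycode <- as.integer(y)
  N <- nrow(xmat)

  tree_tables <- purrr::map(seq_len(trees), function(t) {
    ti <- ranger::treeInfo(rf, t)
    nn <- nrow(ti)
    counts <- matrix(0, nn, C)
    inbag <- rf$inbag.counts[[t]]
    active <- which(inbag > 0)
    cur <- rep(1L, N)
    while (length(active) > 0) {
      key <- cur[active] + (ycode[active] - 1L) * nn
      agg <- rowsum(inbag[active], group = key)
      counts[as.integer(rownames(agg))] <-
        counts[as.integer(rownames(agg))] + agg[, 1]
      term <- ti$terminal[cur[active]]
      active <- active[!term]
      if (length(active) == 0) break
      node <- cur[active]
      sv <- ti$splitvarID[node] + 1L
      xv <- xmat[cbind(active, sv)]
      goleft <- xv <= ti$splitval[node]
      cur[active] <- ifelse(goleft, ti$leftChild[node], ti$rightChild[node]) + 1L
    }
    tot <- rowSums(counts)
    prop <- counts / ifelse(tot > 0, tot, 1)
    list(left = ti$leftChild + 1L, right = ti$rightChild + 1L,
         splitvar = ti$splitvarID + 1L, splitval = ti$splitval,
         terminal = ti$terminal, prop = prop, n_node = tot,
         gini = 1 - rowSums(prop^2))
  })
  oob <- rf$predictions
  oob_acc <- mean(as.character(oob) == as.character(y), na.rm = TRUE)
  structure(list(trees = tree_tables, classes = classes,
                 feature_names = feature_names,
                 num_trees = as.integer(trees), mtry = as.integer(mtry),
                 oob_accuracy = oob_acc),
            class = "lspf_forest")
}

#' @export
print.lspf_forest <- function(x, ...) {
  cat(sprintf("<random forest: %d trees, %d features, classes %s; OOB accuracy %.3f>\n",
              x$num_trees, length(x$feature_names),
              paste(x$classes, collapse = "/"), x$oob_accuracy))
  invisible(x)
}

# leaf index of every row of xm in one tree node table (vectorized)
route_all <- function(tree, xm) {
  N <- nrow(xm)
  cur <- rep(1L, N)
  active <- seq_len(N)
  while (length(active) > 0) {
    term <- tree$terminal[cur[active]]
    active <- active[!term]
    if (length(active) == 0) break
    node <- cur[active]
    xv <- xm[cbind(active, tree$splitvar[node])]
    cur[active] <- ifelse(xv <= tree$splitval[node],
                          tree$left[node], tree$right[node])
  }
  cur
}

# leaf index of x (numeric feature vector) in one tree node table
route_to_leaf <- function(tree, x) {
  node <- 1L
  while (!tree$terminal[node]) {
    node <- if (x[tree$splitvar[node]] <= tree$splitval[node])
      tree$left[node] else tree$right[node]
  }
  node
}

check_forest_x <- function(model, x) {
  if (is.data.frame(x)) x <- feature_values(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$feature_names)) {
    abort(sprintf("feature dimension mismatch: model has %d features, input has %d",
                  length(model$feature_names), ncol(x)))
  }
  x
}

#' Predict with a trained forest
#'
#' The forest probability vector is the average of the per-tree leaf
#' class-proportion vectors; the predicted class is the argmax, ties
#' broken by class order (background < medication < symptom).
#'
#' @param model An `lspf_forest`.
#' @param X Feature tibble, numeric matrix, or a single feature vector.
#' @return Tibble with column `class` and one probability column per
#'   class.
#' @export
predict_forest <- function(model, X) {
  xm <- check_forest_x(model, X)
  N <- nrow(xm)
  C <- length(model$classes)
  probs <- matrix(0, N, C)
  for (tree in model$trees) {
    cur <- rep(1L, N)
    active <- seq_len(N)
    while (length(active) > 0) {
      term <- tree$terminal[cur[active]]
      done <- active[term]
      if (length(done) > 0) probs[done, ] <- probs[done, , drop = FALSE] +
          tree$prop[cur[done], , drop = FALSE]
      active <- active[!term]
      if (length(active) == 0) break
      node <- cur[active]
      xv <- xm[cbind(active, tree$splitvar[node])]
      cur[active] <- ifelse(xv <= tree$splitval[node],
                            tree$left[node], tree$right[node])
    }
  }
  probs <- probs / model$num_trees
  colnames(probs) <- model$classes
  cls <- model$classes[apply(probs, 1, which.max)]
  dplyr::bind_cols(tibble::tibble(class = factor(cls, levels = model$classes)),
                   tibble::as_tibble(as.data.frame(probs, check.names = FALSE)))
}

#' Background-fallback decision rule
#'
#' Combines the two one-vs-rest probabilities: if both are below 0.5 the
#' sentence is background; otherwise it takes the class with the larger
#' probability (exact ties go to medication). A probability of exactly
#' 0.5 is not "less than 0.5", so it triggers classification.
#'
#' @param p_med,p_sym Probability vectors in \[0, 1\].
#' @return Factor over the [sentence_classes()].
#' @export
#' @examples
#' predict_with_fallback(c(0.3, 0.6, 0.5), c(0.4, 0.3, 0.4))
predict_with_fallback <- function(p_med, p_sym) {
  stopifnot(length(p_med) == length(p_sym),
            all(p_med >= 0 & p_med <= 1), all(p_sym >= 0 & p_sym <= 1))
  out <- ifelse(p_med < 0.5 & p_sym < 0.5, "background",
                ifelse(p_med >= p_sym, "medication", "symptom"))
  factor(out, levels = SENTENCE_CLASSES)
}

#' Train the one-vs-rest SVM baseline
#'
#' Two binary RBF-kernel support vector machines (medication-vs-rest and
#' symptom-vs-rest) with Platt-scaled probability outputs and
#' `gamma = 1/D` (the reciprocal of the feature count). Prediction uses
#' the background-fallback rule ([predict_with_fallback()]).
#'
#' @param X Feature tibble with `label`.
#' @param gamma RBF width; default `1/D`.
#' @param cost SVM cost parameter (default 1).
#' @param seed Seed for the Platt-scaling cross-validation.
#' @return Object of class `lspf_svm_pair`.
#' @export
train_svm_pair <- function(X, gamma = NULL, cost = 1, seed = 0L) {
  xmat <- feature_values(X)
  D <- ncol(xmat)
  if (is.null(gamma)) gamma <- 1 / D
  y <- as.character(X$label)
  fit_one <- function(target) {
    yb <- factor(ifelse(y == target, "yes", "no"), levels = c("no", "yes"))
    if (nlevels(droplevels(yb)) < 2) {
      abort(sprintf("class '%s' is degenerate (all or none of the labels)", target))
    }
    set.seed(seed)
    e1071::svm(x = xmat, y = yb, kernel = "radial", gamma = gamma,
               cost = cost, probability = TRUE, scale = FALSE)
  }
  structure(list(medication = fit_one("medication"),
                 symptom = fit_one("symptom"),
                 gamma = gamma, feature_names = colnames(xmat)),
            class = "lspf_svm_pair")
}

#' @rdname train_svm_pair
#' @param model An `lspf_svm_pair`.
#' @return `predict_svm_pair`: tibble with `p_medication`, `p_symptom`
#'   and the fallback `class`.
#' @export
predict_svm_pair <- function(model, X) {
  xmat <- if (is.data.frame(X)) feature_values(X) else X
  prob_of <- function(m) {
    pr <- attr(predict(m, xmat, probability = TRUE), "probabilities")
    pr[, "yes"]
  }
  p_med <- prob_of(model$medication)
  p_sym <- prob_of(model$symptom)
  tibble::tibble(p_medication = unname(p_med), p_symptom = unname(p_sym),
                 class = predict_with_fallback(p_med, p_sym))
}

#' Train the lasso baseline
#'
#' One-vs-rest L1-penalized logistic models (one per class) at a fixed
#' penalty, fitted without standardization so the weights of the 0/1
#' indicator features are directly comparable. Per-feature weights are
#' exposed by name via [lasso_weights()].
#'
#' @param X Feature tibble with `label`.
#' @param lambda L1 penalty coefficient (default 0.001).
#' @return Object of class `lspf_lasso`.
#' @export
train_lasso <- function(X, lambda = 0.001) {
  xmat <- feature_values(X)
  y <- as.character(X$label)
  classes <- levels(droplevels(factor(y, levels = SENTENCE_CLASSES)))
  fits <- lapply(classes, function(cl) {
    yb <- factor(ifelse(y == cl, "yes", "no"), levels = c("no", "yes"))
    glmnet::glmnet(xmat, yb, family = "binomial", lambda = lambda,
                   standardize = FALSE)
  })
  names(fits) <- classes
  structure(list(fits = fits, classes = classes, lambda = lambda,
                 feature_names = colnames(xmat)),
            class = "lspf_lasso")
}

#' @rdname train_lasso
#' @param model An `lspf_lasso`.
#' @return `lasso_weights`: tibble `feature` x `class` -> `weight`
#'   (intercepts excluded).
#' @export
lasso_weights <- function(model) {
  purrr::map_dfr(model$classes, function(cl) {
    b <- as.matrix(stats::coef(model$fits[[cl]]))
    tibble::tibble(feature = rownames(b)[-1], class = cl,
                   weight = unname(b[-1, 1]))
  })
}

#' @rdname train_lasso
#' @return `predict_lasso`: tibble with per-class probabilities and the
#'   argmax `class` (ties broken in class order).
#' @export
predict_lasso <- function(model, X) {
  xmat <- if (is.data.frame(X)) feature_values(X) else X
  probs <- vapply(model$classes, function(cl) {
    as.numeric(predict(model$fits[[cl]], xmat, type = "response"))
  }, numeric(nrow(xmat)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(NULL, model$classes))
  cls <- model$classes[apply(probs, 1, which.max)]
  dplyr::bind_cols(
    tibble::tibble(class = factor(cls, levels = model$classes)),
    tibble::as_tibble(as.data.frame(probs, check.names = FALSE)))
}
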