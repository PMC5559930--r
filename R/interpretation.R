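#' Per-tree feature contributions
#'
#' Decomposes one tree's prediction for an instance into per-feature
#' contribution vectors: the bias is the root's class-proportion vector,
#' and each split on feature r along the instance's decision path adds
#' the difference between the child's and the current node's
#' class-proportion vectors to feature r's contribution. By telescoping,
#' bias + sum of contributions equals the leaf vector exactly.
#'
#' @param tree A node table from an `lspf_forest` (`model$trees[[t]]`).
#' @param x Numeric feature vector.
#' @param D Number of features.
#' @return List with `contrib` (D x C matrix), `bias` (length-C vector)
#'   and `leaf` (leaf node index).
#' @export
tree_contributions <- function(tree, x, D = length(x)) {
  C <- ncol(tree$prop)
  contrib <- matrix(0, D, C)
  bias <- tree$prop[1, ]
  node <- 1L
  while (!tree$terminal[node]) {
    sv <- tree$splitvar[node]
    if (sv > D) abort("feature dimension mismatch between tree and input")
    nxt <- if (x[sv] <= tree$splitval[node]) tree$left[node] else tree$right[node]
    contrib[sv, ] <- contrib[sv, ] + (tree$prop[nxt, ] - tree$prop[node, ])
    node <- nxt
  }
  list(contrib = contrib, bias = bias, leaf = node)
}

#' Forest feature contributions for one instance
#'
#' Averages [tree_contributions()] over all trees: the forest bias is
#' the mean of the tree biases, and the contribution of feature k is the
#' mean of its per-tree contributions. The report conserves exactly:
#' bias + sum of per-feature contributions equals the forest probability
#' vector of [predict_forest()].
#'
#' @param model An `lspf_forest`.
#' @param x Feature vector, 1-row feature tibble, or 1-row matrix.
#' @return Object of class `lspf_contribs` with `per_feature` (D x C
#'   matrix, rownames = feature names), `bias`, `prediction` (the forest
#'   probability vector) and `n_instances = 1`.
#' @export
forest_contributions <- function(model, x) {
  xm <- check_forest_x(model, x)
  if (nrow(xm) != 1) abort("forest_contributions expects a single instance")
  xv <- xm[1, ]
  D <- length(model$feature_names)
  C <- length(model$classes)
  acc <- matrix(0, D, C)
  bias <- rep(0, C)
  for (tree in model$trees) {
    tc <- tree_contributions(tree, xv, D)
    acc <- acc + tc$contrib
    bias <- bias + tc$bias
  }
  per_feature <- acc / model$num_trees
  bias <- bias / model$num_trees
  rownames(per_feature) <- model$feature_names
  colnames(per_feature) <- model$classes
  names(bias) <- model$classes
  structure(list(per_feature = per_feature, bias = bias,
                 prediction = bias + colSums(per_feature),
                 classes = model$classes, target_class = NULL,
                 n_instances = 1L),
            class = "lspf_contribs")
}

#' Class-averaged feature contributions
#'
#' Averages the per-instance forest contributions over all instances of
#' one target class (medication or symptom; background sentences are not
#' interpreted), and ranks features by their contribution toward that
#' class. This is the per-class discriminative-feature table.
#'
#' @param model An `lspf_forest`.
#' @param X Feature tibble whose rows all belong to `target_class`
#'   (rows of other classes are dropped if a `label` column is present).
#' @param target_class `"medication"` or `"symptom"`.
#' @return An `lspf_contribs` object whose `per_feature` matrix holds
#'   the class-averaged contributions and whose `ranking` tibble lists
#'   features in decreasing target-class contribution, with a
#'   `condition` column showing the typical feature value among the
#'   averaged instances (Table-style rendering via [tidy()]).
#' @export
class_average_contributions <- function(model, X, target_class) {
  target_class <- as.character(target_class)
  if (target_class == "background") {
    abort("background sentences are not interpreted")
  }
  if (!target_class %in% model$classes) {
    abort(sprintf("class '%s' unknown to the model", target_class))
  }
  if (is.data.frame(X) && "label" %in% names(X)) {
    X <- X[as.character(X$label) == target_class, , drop = FALSE]
  }
  xm <- check_forest_x(model, X)
  if (nrow(xm) == 0) abort("no instances of the target class to average over")
  D <- length(model$feature_names)
  C <- length(model$classes)
  nsub <- nrow(xm)
  acc <- matrix(0, D, C)
  bias <- rep(0, C)
  # contributions depend only on the leaf an instance reaches, so they
  # are computed once per occupied leaf and weighted by occupancy
  for (tree in model$trees) {
    nn <- length(tree$terminal)
    parent <- rep(NA_integer_, nn)
    internal <- which(!tree$terminal)
    parent[tree$left[internal]] <- internal
    parent[tree$right[internal]] <- internal
    leaves <- route_all(tree, xm)
    tab <- table(leaves)
    for (li in seq_along(tab)) {
      lf <- as.integer(names(tab)[li])
      cnt <- tab[[li]]
      node <- lf
      while (node != 1L) {
        p <- parent[node]
        sv <- tree$splitvar[p]
        acc[sv, ] <- acc[sv, ] +
          cnt * (tree$prop[node, ] - tree$prop[p, ])
        node <- p
      }
    }
    bias <- bias + tree$prop[1, ]
  }
  per_feature <- acc / (model$num_trees * nsub)
  bias <- bias / model$num_trees
  pred <- bias + colSums(per_feature)
  rownames(per_feature) <- model$feature_names
  colnames(per_feature) <- model$classes
  # typical observed value of each feature among the averaged instances
  mean_val <- colMeans(xm)
  condition <- ifelse(mean_val <= 1 & apply(xm, 2, function(v) all(v %in% 0:1)),
                      sprintf("= %d", as.integer(round(mean_val))),
                      sprintf("~ %.1f", mean_val))
  ranking <- tibble::tibble(
    feature = model$feature_names,
    condition = condition,
    tibble::as_tibble(as.data.frame(per_feature, check.names = FALSE))
  )
  ranking <- ranking[order(-per_feature[, target_class]), ]
  structure(list(per_feature = per_feature, bias = bias,
                 prediction = pred, classes = model$classes,
                 target_class = target_class, ranking = ranking,
                 n_instances = nrow(xm)),
            class = "lspf_contribs")
}

#' @export
print.lspf_contribs <- function(x, n = 10, ...) {
  if (!is.null(x$target_class)) {
    cat(sprintf("<class-average feature contributions for '%s' (%d instances)>\n",
                x$target_class, x$n_instances))
    print(head(x$ranking, n))
  } else {
    cat("<feature contributions for one instance>\n")
    cat("prediction:", paste(sprintf("%s=%.3f", names(x$prediction),
                                     x$prediction), collapse = ", "), "\n")
    ord <- order(-apply(abs(x$per_feature), 1, max))
    print(head(x$per_feature[ord, , drop = FALSE], n))
  }
  invisible(x)
}

# ---- discriminative patterns -------------------------------------------

canonical_rules <- function(rules) {
  # merge redundant same-feature bounds: tightest <= and tightest >
  merged <- rules |>
    dplyr::group_by(.data$feature, .data$op) |>
    dplyr::summarise(threshold = ifelse(.data$op[1] == "<=",
                                        min(.data$threshold),
                                        max(.data$threshold)),
                     .groups = "drop")
  merged[order(merged$feature, merged$op, merged$threshold), ]
}

rule_id <- function(rules) {
  paste(sprintf("%s%s%.10g", rules$feature, rules$op, rules$threshold),
        collapse = " & ")
}

#' Extract candidate discriminative patterns from a forest
#'
#' A discriminative pattern is a complete root-to-leaf decision path,
#' rendered as a conjunction of threshold rules
#' (feature \eqn{\le} v or feature \eqn{>} v), whose leaf has low Gini
#' impurity. Candidates are canonicalized (rules sorted by feature,
#' redundant same-feature bounds merged) and deduplicated across trees.
#'
#' @param model An `lspf_forest`.
#' @param impurity_threshold Maximum leaf Gini impurity (default 0.2).
#' @param min_leaf_n Minimum in-bag training samples in the leaf
#'   (default 5).
#' @return Tibble with list-column `rules` (tibbles with `feature`,
#'   `op`, `threshold`), `rule_id`, `leaf_class`, `impurity`, `support`.
#' @export
extract_patterns <- function(model, impurity_threshold = 0.2,
                             min_leaf_n = 5) {
  out <- list()
  for (tree in model$trees) {
    walk <- function(node, rules) {
      if (tree$terminal[node]) {
        if (tree$gini[node] <= impurity_threshold &&
            tree$n_node[node] >= min_leaf_n && nrow(rules) > 0) {
          cls <- model$classes[which.max(tree$prop[node, ])]
          out[[length(out) + 1L]] <<- list(rules = rules, leaf_class = cls,
                                           impurity = tree$gini[node],
                                           support = tree$n_node[node])
        }
        return(invisible(NULL))
      }
      fname <- model$feature_names[tree$splitvar[node]]
      walk(tree$left[node],
           dplyr::bind_rows(rules, tibble::tibble(
             feature = fname, op = "<=", threshold = tree$splitval[node])))
      walk(tree$right[node],
           dplyr::bind_rows(rules, tibble::tibble(
             feature = fname, op = ">", threshold = tree$splitval[node])))
    }
    walk(1L, tibble::tibble(feature = character(0), op = character(0),
                            threshold = numeric(0)))
  }
  if (length(out) == 0) {
    return(tibble::tibble(rules = list(), rule_id = character(0),
                          leaf_class = character(0), impurity = numeric(0),
                          support = numeric(0)))
  }
  tbl <- tibble::tibble(
    rules = purrr::map(out, ~ canonical_rules(.x$rules)),
    leaf_class = purrr::map_chr(out, "leaf_class"),
    impurity = purrr::map_dbl(out, "impurity"),
    support = purrr::map_dbl(out, "support")
  )
  tbl$rule_id <- purrr::map_chr(tbl$rules, rule_id)
  tbl <- tbl[order(tbl$impurity, -tbl$support, tbl$rule_id), ]
  tbl[!duplicated(tbl$rule_id), c("rules", "rule_id", "leaf_class",
                                  "impurity", "support")]
}

#' Match an instance against a discriminative pattern
#'
#' @param x Named numeric feature vector or 1-row feature tibble.
#' @param rules Rules tibble of one pattern (columns `feature`, `op`,
#'   `threshold`), as in the `rules` list-column of
#'   [extract_patterns()].
#' @return 1 if every rule holds, else 0.
#' @export
pattern_match <- function(x, rules) {
  if (is.data.frame(x)) x <- feature_values(x)[1, ]
  if (nrow(rules) == 0) abort("empty rule set is not a valid pattern")
  unknown <- setdiff(rules$feature, names(x))
  if (length(unknown) > 0) {
    abort(sprintf("unknown feature(s) in pattern: %s",
                  paste(unknown, collapse = ", ")))
  }
  vals <- x[rules$feature]
  ok <- ifelse(rules$op == "<=", vals <= rules$threshold,
               vals > rules$threshold)
  as.numeric(all(ok))
}

#' Map instances into the discriminative-pattern space
#'
#' @param X Feature tibble or matrix.
#' @param patterns Pattern tibble ([extract_patterns()]) or an
#'   `lspf_dp_selection` (its selected patterns are used).
#' @return N x K binary matrix, one column per pattern (`rule_id`
#'   colnames).
#' @export
dp_transform <- function(X, patterns) {
  if (inherits(patterns, "lspf_dp_selection")) patterns <- patterns$selected
  xm <- if (is.data.frame(X)) feature_values(X) else X
  K <- nrow(patterns)
  out <- matrix(0, nrow(xm), K)
  for (k in seq_len(K)) {
    rules <- patterns$rules[[k]]
    ok <- rep(TRUE, nrow(xm))
    for (r in seq_len(nrow(rules))) {
      v <- xm[, rules$feature[r]]
      ok <- ok & if (rules$op[r] == "<=") v <= rules$threshold[r]
      else v > rules$threshold[r]
    }
    out[, k] <- as.numeric(ok)
  }
  colnames(out) <- patterns$rule_id
  out
}

#' Forward-select the top discriminative patterns
#'
#' Greedy forward selection over candidate patterns: at each iteration
#' every unselected candidate is tentatively added, a linear-kernel SVM
#' is trained on the 0/1 pattern indicators of the enlarged set, and the
#' candidate giving the best validation accuracy is accepted only if it
#' strictly improves on the previous iteration's accuracy. Stops after
#' `K` acceptances or when no candidate improves. The baseline accuracy
#' (before any pattern) is the majority-class rate on the validation
#' split.
#'
#' @param candidates Pattern tibble from [extract_patterns()].
#' @param X Feature tibble with `label` (training + validation pool).
#' @param K Maximum number of patterns to select (default 30).
#' @param val_fraction Stratified validation fraction (default 0.2).
#' @param seed Seed for the validation split.
#' @return Object of class `lspf_dp_selection` with `selected` (pattern
#'   tibble, in acceptance order), `accuracies` (accepted-iteration
#'   accuracy trajectory), `baseline_accuracy` and `K`.
#' @export
forward_select <- function(candidates, X, K = 30L, val_fraction = 0.2,
                           seed = 0L) {
  if (K < 1) abort("K must be >= 1")
  if (nrow(candidates) == 0) abort("no candidate patterns to select from")
  y <- factor(as.character(X$label))
  set.seed(seed)
  val_idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
    n_val <- max(1L, round(length(ix) * val_fraction))
    sample(ix, n_val)
  }), use.names = FALSE)
  train_idx <- setdiff(seq_along(y), val_idx)
  Z <- dp_transform(X, candidates)
  Zt <- Z[train_idx, , drop = FALSE]
  Zv <- Z[val_idx, , drop = FALSE]
  yt <- droplevels(y[train_idx])
  yv <- y[val_idx]
  base_acc <- max(table(yv)) / length(yv)

  selected <- integer(0)
  acc_hist <- numeric(0)
  best_prev <- base_acc
  for (iter in seq_len(K)) {
    remaining <- setdiff(seq_len(ncol(Z)), selected)
    if (length(remaining) == 0) break
    accs <- vapply(remaining, function(j) {
      cols <- c(selected, j)
      fit <- tryCatch(
        e1071::svm(x = Zt[, cols, drop = FALSE], y = yt,
                   kernel = "linear", scale = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) return(-Inf)
      pred <- predict(fit, Zv[, cols, drop = FALSE])
      mean(as.character(pred) == as.character(yv))
    }, numeric(1))
    j_star <- remaining[which.max(accs)]
    if (max(accs) > best_prev) {
      selected <- c(selected, j_star)
      best_prev <- max(accs)
      acc_hist <- c(acc_hist, best_prev)
    } else {
      break
    }
  }
  structure(list(selected = candidates[selected, ],
                 indices = selected, accuracies = acc_hist,
                 baseline_accuracy = base_acc, K = as.integer(K)),
            class = "lspf_dp_selection")
}

#' @export
print.lspf_dp_selection <- function(x, ...) {
  cat(sprintf("<discriminative patterns: %d selected (K = %d), accuracy %.3f -> %.3f>\n",
              nrow(x$selected), x$K, x$baseline_accuracy,
              if (length(x$accuracies)) max(x$accuracies) else x$baseline_accuracy))
  for (i in seq_len(nrow(x$selected))) {
    cat(" ", format_pattern(x$selected$rules[[i]]), "->",
        x$selected$leaf_class[i], "\n")
  }
  invisible(x)
}

#' Render a pattern as a rule conjunction
#'
#' @param rules Rules tibble of one pattern.
#' @return Single string like `"(f1 <= 0.5) & (f2 > 2)"`.
#' @export
format_pattern <- function(rules) {
  paste(sprintf("(%s %s %.3g)", rules$feature, rules$op, rules$threshold),
        collapse = " & ")
}
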