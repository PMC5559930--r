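# Independent oracles and shared fixtures for the test suite.

# Recursive gap-constrained containment, independent of the miner.
oracle_contains <- function(s, p, gap) {
  rec <- function(lo, hi, j) {
    idx <- which(s == p[j])
    idx <- idx[idx >= lo & idx <= hi]
    if (length(idx) == 0) return(FALSE)
    if (j == length(p)) return(TRUE)
    any(vapply(idx, function(i) rec(i + 1L, i + gap, j + 1L), logical(1)))
  }
  rec(1L, length(s), 1L)
}

# All gap-valid subsequence patterns of one sequence (as "a|b|c" ids),
# by direct enumeration of index subsets.
oracle_seq_patterns <- function(s, gap, max_len) {
  n <- length(s)
  out <- character(0)
  for (k in seq_len(min(n, max_len))) {
    cmb <- utils::combn(n, k)
    ok <- apply(cmb, 2, function(ix) all(diff(ix) <= gap))
    if (!any(ok)) next
    pats <- apply(cmb[, ok, drop = FALSE], 2,
                  function(ix) paste(s[ix], collapse = "|"))
    out <- c(out, unique(pats))
  }
  unique(out)
}

# Exhaustive frequent-pattern mining oracle: tally per-sequence pattern
# sets, keep those meeting the same integer support count as the miner.
oracle_mine <- function(tag_lists, min_support, gap, max_len) {
  per_seq <- lapply(tag_lists, oracle_seq_patterns, gap = gap,
                    max_len = max_len)
  tab <- table(unlist(lapply(per_seq, unique)))
  n <- length(tag_lists)
  min_count <- max(1L, as.integer(ceiling(min_support * n - 1e-9)))
  keep <- tab[tab >= min_count]
  tibble::tibble(pattern_id = names(keep),
                 support = as.numeric(keep) / n)
}

# Tiny deterministic lexicon set used across mapping tests.
fixture_lexicons <- function() {
  lexicons(
    drug_terms = c("Lantus", "nexium"),
    symptom_terms = c("heartburn", "stomach", "stomach pain"),
    freq_patterns = c("(once|twice) a day", "every (morning|night)")
  )
}

# A small labeled database over an abstract alphabet, as a tibble
# compatible with the mining functions.
toy_db <- function(tag_lists, labels) {
  structure(tibble::tibble(tags = tag_lists,
                           label = factor(labels),
                           source_index = seq_along(tag_lists)),
            class = c("lspf_seqdb", class(tibble::tibble())))
}

# Random database generator for property tests.
random_db <- function(n_seq, max_len, alphabet, labels = c("l1", "l2")) {
  tags <- lapply(seq_len(n_seq), function(i) {
    sample(alphabet, sample(1:max_len, 1), replace = TRUE)
  })
  toy_db(tags, sample(labels, n_seq, replace = TRUE))
}

# Random feature tibble for model tests.
random_features <- function(n, d, classes = c("a", "b"), binary = TRUE) {
  mat <- if (binary) matrix(rbinom(n * d, 1, 0.5), n, d)
  else matrix(stats::rnorm(n * d), n, d)
  colnames(mat) <- paste0("f", seq_len(d))
  out <- tibble::as_tibble(as.data.frame(mat))
  dplyr::bind_cols(tibble::tibble(label = factor(
    sample(classes, n, replace = TRUE), levels = classes)), out)
}

# Hand-built forest whose node tables are fully specified, for exact
# prediction/contribution arithmetic.
manual_forest <- function(trees, classes, feature_names) {
  structure(list(trees = trees, classes = classes,
                 feature_names = feature_names,
                 num_trees = length(trees),
                 mtry = length(feature_names), oob_accuracy = NA_real_),
            class = "lspf_forest")
}

manual_leaf_tree <- function(prop, n = 10) {
  list(left = NA_integer_, right = NA_integer_, splitvar = NA_integer_,
       splitval = NA_real_, terminal = TRUE,
       prop = matrix(prop, nrow = 1), n_node = n,
       gini = 1 - sum(prop^2))
}

# depth-1 stump: split on feature sv at threshold, children proportions
manual_stump <- function(sv, threshold, root_prop, left_prop, right_prop,
                         n = c(10, 5, 5)) {
  list(left = c(2L, NA, NA), right = c(3L, NA, NA),
       splitvar = c(sv, NA, NA), splitval = c(threshold, NA, NA),
       terminal = c(FALSE, TRUE, TRUE),
       prop = rbind(root_prop, left_prop, right_prop),
       n_node = n,
       gini = c(1 - sum(root_prop^2), 1 - sum(left_prop^2),
                1 - sum(right_prop^2)))
}
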