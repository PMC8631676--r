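#' Misclassification cost matrix
#'
#' Asymmetric costs steer the learner toward sensitivity (penalize false
#' negatives) or specificity (penalize false positives). With equal costs the
#' leaf-labeling rule reduces to the majority (50%) rule.
#'
#' @param cost_fn Cost of a false negative (>= 0).
#' @param cost_fp Cost of a false positive (>= 0).
#' @return A `cost_matrix` list.
#' @export
#' @examples
#' cost_matrix(2, 1)  # the package default: false negatives twice as costly
cost_matrix <- function(cost_fn = 2, cost_fp = 1) {
  if (cost_fn < 0 || cost_fp < 0 || (cost_fn == 0 && cost_fp == 0)) {
    stop("cost_matrix: costs must be non-negative and not both zero",
         call. = FALSE)
  }
  structure(list(cost_fn = cost_fn, cost_fp = cost_fp),
            class = "cost_matrix")
}

#' Tree-learner hyperparameters
#'
#' @param min_cases_per_leaf Minimum cases for a node to be considered for
#'   splitting: nodes with fewer than `2 * min_cases_per_leaf` cases become
#'   leaves (>= 1).
#' @param pruning_confidence Confidence factor in (0, 1) for the pessimistic
#'   upper-bound error estimate used by global pruning; smaller prunes more.
#' @param max_depth Maximum tree depth (`Inf` for unlimited).
#' @param prune Apply the global pruning pass after growing.
#' @param gain_ratio Use gain ratio (gain / split information) instead of
#'   plain information gain to rank splits.
#' @param mdl_correction Penalize continuous-threshold splits by
#'   `log2(#candidate thresholds) / n` before comparing (the classic
#'   minimum-description-length correction that stops spurious splits on
#'   noise features); a node only splits when the penalized gain is
#'   positive.
#' @return A `learner_params` list.
#' @export
learner_params <- function(min_cases_per_leaf = 2, pruning_confidence = 0.25,
                           max_depth = Inf, prune = TRUE, gain_ratio = FALSE,
                           mdl_correction = TRUE) {
  stopifnot(min_cases_per_leaf >= 1,
            pruning_confidence > 0, pruning_confidence < 1,
            max_depth >= 1)
  structure(list(min_cases_per_leaf = as.integer(min_cases_per_leaf),
                 pruning_confidence = pruning_confidence,
                 max_depth = max_depth, prune = prune,
                 gain_ratio = gain_ratio, mdl_correction = mdl_correction),
            class = "learner_params")
}

#' Shannon entropy of class counts
#'
#' `H = -sum(p_i log2 p_i)` in bits, with `0 log 0 = 0`.
#'
#' @param class_counts Non-negative counts, at least one positive.
#' @return Entropy in bits.
#' @export
#' @examples
#' entropy(c(1, 1))  # 1 bit
#' entropy(c(2, 6))  # 0.8113 bits
entropy <- function(class_counts) {
  if (any(class_counts < 0) || sum(class_counts) == 0) {
    stop("entropy: counts must be non-negative with a positive total",
         call. = FALSE)
  }
  p <- class_counts[class_counts > 0] / sum(class_counts)
  -sum(p * log2(p))
}

#' Information gain of a candidate split
#'
#' `H(parent) - sum_j (n_j / n) H(child_j)`; non-negative whenever the
#' children partition the parent.
#'
#' @param parent_counts Class counts at the parent node.
#' @param child_count_list List of class-count vectors, one per child; must
#'   sum component-wise to `parent_counts`.
#' @return Gain in bits.
#' @export
#' @examples
#' information_gain(c(4, 4), list(c(4, 0), c(0, 4)))  # 1 bit
information_gain <- function(parent_counts, child_count_list) {
  total <- Reduce(`+`, child_count_list)
  if (!isTRUE(all.equal(as.numeric(total), as.numeric(parent_counts)))) {
    stop("information_gain: children do not partition the parent counts",
         call. = FALSE)
  }
  n <- sum(parent_counts)
  child_term <- sum(vapply(child_count_list, function(cc) {
    m <- sum(cc)
    if (m == 0) 0 else m / n * entropy(cc)
  }, numeric(1)))
  entropy(parent_counts) - child_term
}

#' Best threshold for a continuous feature
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' values; the split maximizing information gain (or gain ratio) is returned,
#' ties broken by the smallest threshold.
#'
#' @param feature_values Numeric vector.
#' @param labels Logical vector (`TRUE` = positive class), same length.
#' @param gain_ratio Rank candidates by gain ratio instead of gain.
#' @return A list with `threshold` (NA when no split exists), `gain` (plain
#'   information gain of the chosen split; 0 when no split) and `score` (the
#'   ranking value: the gain, or the gain ratio when `gain_ratio = TRUE`).
#' @export
#' @examples
#' best_threshold(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))  # 2.5, gain 1
best_threshold <- function(feature_values, labels, gain_ratio = FALSE) {
  stopifnot(length(feature_values) == length(labels))
  n <- length(feature_values)
  ord <- order(feature_values)
  x <- feature_values[ord]
  y <- as.logical(labels)[ord]
  distinct_end <- which(diff(x) > 0)          # last index of each run but the final
  if (length(distinct_end) == 0) {
    return(list(threshold = NA_real_, gain = 0, score = 0))
  }
  npos <- sum(y)
  parent_h <- entropy(c(npos, n - npos))
  cum_pos <- cumsum(y)
  h2 <- function(pos, tot) {                  # binary entropy from counts, vectorized
    p <- ifelse(tot > 0, pos / tot, 0)
    term <- function(q) ifelse(q > 0, -q * log2(q), 0)
    ifelse(tot > 0, term(p) + term(1 - p), 0)
  }
  nl <- distinct_end
  pl <- cum_pos[distinct_end]
  nr <- n - nl
  pr <- npos - pl
  gains <- parent_h - (nl / n) * h2(pl, nl) - (nr / n) * h2(pr, nr)
  score <- gains
  if (gain_ratio) {
    split_info <- h2(nl, n)                   # entropy of the branch split itself
    score <- ifelse(split_info > 0, gains / split_info, 0)
  }
  best <- which(score >= max(score) - 1e-12)[1]   # ties: smallest threshold
  thr <- (x[distinct_end[best]] + x[distinct_end[best] + 1]) / 2
  list(threshold = thr, gain = gains[best], score = score[best])
}

# leaf from class counts under a cost matrix: the stored probability is the
# cost-weighted posterior, so "positive iff p > 0.5" is exactly the
# minimum-expected-cost rule and reduces to the class frequency at equal costs
make_leaf <- function(npos, nneg, cost) {
  wpos <- npos * cost$cost_fn
  wneg <- nneg * cost$cost_fp
  p <- if (wpos + wneg > 0) wpos / (wpos + wneg) else npos / max(npos + nneg, 1)
  tree_leaf(if (p > 0.5) "positive" else "negative", p = p)
}

#' Grow a cost-sensitive decision tree
#'
#' Greedy recursive partitioning of continuous features by information gain,
#' in the classic entropy-based style: at each node every feature's best
#' midpoint threshold is scored and the highest-gain (feature, threshold)
#' pair splits the node (ties broken by column order, then by smaller
#' threshold). Recursion stops on pure nodes, zero gain, fewer than
#' `2 * min_cases_per_leaf` cases, or `max_depth`. Leaves are labeled by
#' minimum expected misclassification cost under `cost` (the majority rule
#' when costs are equal), and a global pessimistic-error pruning pass
#' ([prune_tree()]) collapses weak subtrees. The build is deterministic:
#' identical data and parameters give an identical serialized tree.
#'
#' @param data A data frame of numeric feature columns plus the outcome.
#' @param outcome Name of the outcome column (logical, or a factor/character
#'   with levels `positive`/`negative`).
#' @param features Feature columns to consider; default all numeric columns
#'   except the outcome.
#' @param cost A [cost_matrix()].
#' @param params A [learner_params()].
#' @return An `lvh_tree`.
#' @export
#' @examples
#' d <- tibble::tibble(x = c(1, 2, 3, 4), y = c(FALSE, FALSE, TRUE, TRUE))
#' train_tree(d, "y")
train_tree <- function(data, outcome, features = NULL,
                       cost = cost_matrix(), params = learner_params()) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 2) stop("train_tree: need at least 2 cases", call. = FALSE)
  if (!outcome %in% names(data)) {
    stop("train_tree: outcome column '", outcome, "' not found", call. = FALSE)
  }
  y <- data[[outcome]]
  if (!is.logical(y)) y <- as.character(y) == "positive"
  if (any(is.na(y))) stop("train_tree: missing outcome values", call. = FALSE)
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(features, outcome)
  }
  if (length(features) == 0) stop("train_tree: no features", call. = FALSE)
  X <- data[features]
  if (!all(vapply(X, is.numeric, logical(1)))) {
    stop("train_tree: features must be numeric", call. = FALSE)
  }
  if (anyNA(X)) stop("train_tree: missing feature values", call. = FALSE)

  grow <- function(idx, depth) {
    yi <- y[idx]
    npos <- sum(yi); nneg <- length(yi) - npos
    if (npos == 0 || nneg == 0 || length(idx) < 2 * params$min_cases_per_leaf ||
        depth >= params$max_depth) {
      return(make_leaf(npos, nneg, cost))
    }
    best <- NULL
    for (f in features) {                     # column order breaks score ties
      xi <- X[[f]][idx]
      cand <- best_threshold(xi, yi, gain_ratio = params$gain_ratio)
      if (is.na(cand$threshold)) next
      score <- cand$score
      if (params$mdl_correction) {
        n_cand <- length(unique(xi)) - 1L
        score <- score - log2(max(n_cand, 1)) / length(idx)
      }
      if (is.null(best) || score > best$score + 1e-12) {
        best <- list(feature = f, threshold = cand$threshold,
                     gain = cand$gain, score = score)
      }
    }
    if (is.null(best) || best$score <= 1e-12) {
      return(make_leaf(npos, nneg, cost))
    }
    go_left <- X[[best$feature]][idx] <= best$threshold
    tree_node(best$feature, "le", best$threshold,
              grow(idx[go_left], depth + 1L),
              grow(idx[!go_left], depth + 1L))
  }
  tree <- as_lvh_tree(grow(seq_len(nrow(data)), 0L))
  if (params$prune) {
    tree <- prune_tree(tree, data, outcome,
                       pruning_confidence = params$pruning_confidence,
                       cost = cost)
  }
  tree
}

# C4.5 pessimistic upper bound on the true error rate of a leaf that made
# e errors in n cases: the p solving P(Binomial(n, p) <= e) = cf
pessimistic_error <- function(e, n, cf) {
  if (n == 0) return(0)
  if (e >= n) return(1)
  stats::qbeta(1 - cf, e + 1, n - e)
}

#' Global pessimistic-error pruning
#'
#' Bottom-up pass over a fitted tree: for each internal node the pessimistic
#' error of the subtree (sum over its leaves of `n_leaf * U(e_leaf, n_leaf)`,
#' where `U` is the one-sided binomial upper confidence bound at
#' `pruning_confidence`) is compared with the pessimistic error of replacing
#' the subtree by a single leaf; the subtree is collapsed whenever it is not
#' strictly better. The returned tree is never larger than the input.
#'
#' Error counts use the majority class at each node, so the pruned topology
#' depends only on the data, not on the cost matrix; `cost` affects only how
#' collapsed leaves are relabeled. Raising the false-negative cost therefore
#' can only relabel leaves from negative to positive, never restructure the
#' tree against sensitivity.
#'
#' @param tree An `lvh_tree` fitted to `data`.
#' @inheritParams train_tree
#' @param pruning_confidence Confidence factor in (0, 1); smaller prunes
#'   harder.
#' @return A pruned `lvh_tree`.
#' @export
prune_tree <- function(tree, data, outcome,
                       pruning_confidence = 0.25, cost = cost_matrix()) {
  tree <- as_lvh_tree(tree)
  y <- data[[outcome]]
  if (!is.logical(y)) y <- as.character(y) == "positive"
  cf <- pruning_confidence

  walk <- function(node, idx) {
    yi <- y[idx]
    npos <- sum(yi); nneg <- length(yi) - npos
    as_leaf <- make_leaf(npos, nneg, cost)
    # majority-class errors: the estimate is cost-free so the pruned
    # topology is identical for every cost matrix
    e_leaf <- min(npos, nneg)
    leaf_est <- length(idx) * pessimistic_error(e_leaf, length(idx), cf)
    if (is_leaf(node)) {
      return(list(node = node, est = leaf_est))
    }
    x <- data[[node$feature]][idx]
    go_left <- if (node$op == "le") x <= node$threshold else x > node$threshold
    left <- walk(node$left, idx[go_left])
    right <- walk(node$right, idx[!go_left])
    sub_est <- left$est + right$est
    if (leaf_est <= sub_est + 1e-9) {
      list(node = as_leaf, est = leaf_est)
    } else {
      node$left <- left$node
      node$right <- right$node
      list(node = node, est = sub_est)
    }
  }
  as_lvh_tree(walk(tree, seq_len(nrow(data)))$node)
}

#' Split a cohort into training and testing sets
#'
#' Simple random split, reproducible under `seed`: the training set has
#' `floor(train_fraction * n)` patients, the test set the remainder; the two
#' are disjoint and exhaustive.
#'
#' @param cohort A data frame.
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
#' @examples
#' s <- split_cohort(tibble::tibble(i = 1:439), 0.70, seed = 1)
#' nrow(s$train); nrow(s$test)  # 307, 132
split_cohort <- function(cohort, train_fraction, seed = 1L) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  if (n < 2) stop("split_cohort: need at least 2 patients", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("split_cohort: train_fraction must be in (0, 1)", call. = FALSE)
  }
  n_train <- floor(train_fraction * n)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = tibble::as_tibble(cohort[idx, , drop = FALSE]),
       test = tibble::as_tibble(cohort[-idx, , drop = FALSE]))
}
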