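#' Build decision-tree nodes
#'
#' A threshold tree is a nested list. Internal nodes test one numeric feature
#' against a threshold with comparator `"le"` (<=) or `"gt"` (>); rows for
#' which the test is true descend into `left`, the rest into `right`. Leaves
#' carry the predicted class, an optional phenotype label for positive
#' leaves, and a class probability `p` (the probability of being positive);
#' the class must satisfy the 50% rule: positive iff `p > 0.5`.
#'
#' @param feature Feature (column) name tested at the node.
#' @param op `"le"` or `"gt"`.
#' @param threshold Numeric threshold, in the feature's units.
#' @param left,right Child nodes (`left` is the true branch).
#' @return A node list (class `lvh_tree` when used as a root via
#'   [as_lvh_tree()]).
#' @export
tree_node <- function(feature, op = c("le", "gt"), threshold, left, right) {
  op <- match.arg(op)
  stopifnot(is.character(feature), length(feature) == 1,
            is.numeric(threshold), length(threshold) == 1)
  list(feature = feature, op = op, threshold = threshold,
       left = left, right = right)
}

#' @rdname tree_node
#' @param class `"positive"` or `"negative"`.
#' @param p Probability of the positive class in `[0, 1]`; must agree with
#'   `class` under the 50% rule.
#' @param phenotype Optional phenotype label (e.g. `"voltage_lvh"`).
#' @export
tree_leaf <- function(class = c("negative", "positive"), p = NULL,
                      phenotype = NULL) {
  class <- match.arg(class)
  if (is.null(p)) p <- if (class == "positive") 1 else 0
  leaf <- list(class = class, p = p)
  if (!is.null(phenotype)) leaf$phenotype <- phenotype
  leaf
}

is_leaf <- function(node) is.null(node$feature)

#' Validate a threshold tree and stamp its class
#'
#' Checks the structural invariants: every internal node has a feature name,
#' a comparator in `{le, gt}`, a finite threshold and exactly two children;
#' every leaf class obeys the 50% rule (`positive` iff `p > 0.5`); and no
#' root-to-leaf path repeats the same (feature, threshold) test.
#'
#' @param x A nested node list (from [tree_node()]/[tree_leaf()] or parsed
#'   from JSON).
#' @return The tree with class `lvh_tree`.
#' @export
as_lvh_tree <- function(x) {
  check <- function(node, path, seen) {
    if (!is.list(node)) stop("malformed tree at ", path, ": node is not a list",
                             call. = FALSE)
    if (is_leaf(node)) {
      if (is.null(node$class) || !node$class %in% c("positive", "negative")) {
        stop("malformed tree at ", path,
             ": leaf class must be \"positive\" or \"negative\"", call. = FALSE)
      }
      if (is.null(node$p) || !is.numeric(node$p) || node$p < 0 || node$p > 1) {
        stop("malformed tree at ", path, ": leaf p must be in [0, 1]",
             call. = FALSE)
      }
      if ((node$p > 0.5) != (node$class == "positive")) {
        stop("malformed tree at ", path,
             ": leaf violates the 50% rule (class positive iff p > 0.5)",
             call. = FALSE)
      }
      return(invisible(NULL))
    }
    if (is.null(node$op) || !node$op %in% c("le", "gt") ||
        !is.numeric(node$threshold) || !is.finite(node$threshold)) {
      stop("malformed tree at ", path,
           ": internal node needs op in {le, gt} and a finite threshold",
           call. = FALSE)
    }
    if (is.null(node$left) || is.null(node$right)) {
      stop("malformed tree at ", path,
           ": internal node must have exactly two children", call. = FALSE)
    }
    key <- paste(node$feature, node$threshold)
    if (key %in% seen) {
      stop("malformed tree at ", path, ": path repeats test on '",
           node$feature, "' at threshold ", node$threshold, call. = FALSE)
    }
    check(node$left, paste0(path, "/left"), c(seen, key))
    check(node$right, paste0(path, "/right"), c(seen, key))
  }
  check(x, "root", character())
  structure(x, class = "lvh_tree")
}

# features referenced anywhere in the tree
tree_features <- function(tree) {
  walk <- function(node) {
    if (is_leaf(node)) character() else
      c(node$feature, walk(node$left), walk(node$right))
  }
  unique(walk(tree))
}

tree_n_nodes <- function(tree) {
  walk <- function(node) {
    if (is_leaf(node)) 1L else 1L + walk(node$left) + walk(node$right)
  }
  walk(tree)
}

tree_depth <- function(tree) {
  walk <- function(node) {
    if (is_leaf(node)) 0L else 1L + max(walk(node$left), walk(node$right))
  }
  walk(tree)
}

# fast vectorized descent: leaf index (preorder) per row, plus a leaf table
tree_apply <- function(tree, data) {
  leaves <- list()
  counter <- local({ i <- 0L; function() { i <<- i + 1L; i } })
  leaf_tbl <- function(node) {
    # enumerate leaves in preorder, collecting class/p/phenotype
    if (is_leaf(node)) {
      id <- counter()
      leaves[[id]] <<- tibble::tibble(
        leaf = id, class = node$class, p = node$p,
        phenotype = node$phenotype %||% NA_character_)
      node$leaf_id <- id
      return(node)
    }
    node$left <- leaf_tbl(node$left)
    node$right <- leaf_tbl(node$right)
    node
  }
  tree2 <- leaf_tbl(tree)
  n <- nrow(data)
  leaf_of <- integer(n)
  descend <- function(node, idx) {
    if (length(idx) == 0) return(invisible(NULL))
    if (is_leaf(node)) {
      leaf_of[idx] <<- node$leaf_id
      return(invisible(NULL))
    }
    x <- data[[node$feature]][idx]
    go_left <- if (node$op == "le") x <= node$threshold else x > node$threshold
    descend(node$left, idx[go_left])
    descend(node$right, idx[!go_left])
  }
  descend(tree2, seq_len(n))
  list(leaf = leaf_of, leaves = dplyr::bind_rows(leaves))
}

#' Evaluate a threshold tree on a cohort
#'
#' Routes each row of `data` through `tree` and returns the leaf decision
#' with, optionally, the full root-to-leaf decision trace.
#'
#' @param tree An `lvh_tree` (see [as_lvh_tree()], [chcm_tree()]).
#' @param data A data frame containing every feature column the tree tests.
#' @param trace If `TRUE`, include a `path` list-column of per-patient trace
#'   tibbles (`feature`, `op`, `threshold`, `observed`, `result`).
#' @return A tibble with columns `positive` (logical), `phenotype`
#'   (`"none"` for negative calls), `p` (leaf probability of the positive
#'   class) and, when `trace = TRUE`, `path`.
#' @export
#' @examples
#' tree <- as_lvh_tree(tree_node("x", "le", 0,
#'   tree_leaf("positive"), tree_leaf("negative")))
#' evaluate_tree(tree, tibble::tibble(x = c(-1, 1)))
evaluate_tree <- function(tree, data, trace = TRUE) {
  tree <- as_lvh_tree(tree)
  feats <- tree_features(tree)
  require_features(data, feats, "evaluate_tree")
  applied <- tree_apply(tree, data)
  res <- applied$leaves[applied$leaf, ]
  out <- tibble::tibble(
    positive = res$class == "positive",
    phenotype = dplyr::if_else(res$class == "positive" & !is.na(res$phenotype),
                               res$phenotype, "none"),
    p = res$p
  )
  if (trace) {
    trace_row <- function(i) {
      node <- tree
      steps <- list()
      while (!is_leaf(node)) {
        x <- data[[node$feature]][i]
        ok <- if (node$op == "le") x <= node$threshold else x > node$threshold
        steps[[length(steps) + 1]] <- tibble::tibble(
          feature = node$feature, op = node$op, threshold = node$threshold,
          observed = x, result = ok)
        node <- if (ok) node$left else node$right
      }
      dplyr::bind_rows(steps)
    }
    out$path <- purrr::map(seq_len(nrow(data)), trace_row)
  }
  out
}

#' The packaged CHCM decision tree
#'
#' The CHCM (cardiac hypertrophy computer-based model) criterion calls
#' echocardiographic LVH from three automated ECG measurements: T-wave
#' voltage in lead I, and peak-to-peak QRS amplitude in aVL and aVF. The
#' packaged tree (shipped as a JSON spec file, not hard code) is:
#' \preformatted{
#' T_amp_I_mV <= 0.055?
#'   yes -> QRS_ppk_aVF_mV > 0.178?  yes -> positive (repolarization_lvh)
#'                                   no  -> negative
#'   no  -> QRS_ppk_aVL_mV > 1.235?  yes -> positive (voltage_lvh)
#'                                   no  -> negative
#' }
#' Low T-wave voltage in lead I flags the repolarization-abnormality LVH
#' phenotype, guarded by a minimum aVF voltage that screens out low-voltage
#' tracings; high aVL peak-to-peak voltage flags the increased-voltage
#' phenotype. No single parameter can produce a positive call.
#'
#' @return An `lvh_tree`.
#' @export
chcm_tree <- function() {
  path <- system.file("extdata", "chcm_tree.json", package = "ecglvh")
  if (!nzchar(path)) stop("packaged CHCM tree spec not found", call. = FALSE)
  load_tree(path)
}

#' Classify a cohort with the CHCM criterion
#'
#' Applies the packaged CHCM tree (see [chcm_tree()]) to the ECG feature
#' columns `T_amp_I_mV`, `QRS_ppk_aVL_mV` and `QRS_ppk_aVF_mV`.
#'
#' @inheritParams evaluate_tree
#' @param ecg A data frame with the three CHCM feature columns.
#' @return As [evaluate_tree()]: `positive`, `phenotype`
#'   (`none` / `repolarization_lvh` / `voltage_lvh`), `p`, and optionally
#'   `path`.
#' @export
#' @examples
#' chcm_classify(tibble::tibble(
#'   T_amp_I_mV = c(0.03, 0.20), QRS_ppk_aVL_mV = c(0.5, 1.3),
#'   QRS_ppk_aVF_mV = c(0.2, 0.1)))
chcm_classify <- function(ecg, trace = TRUE) {
  evaluate_tree(chcm_tree(), ecg, trace = trace)
}

#' Read and write tree spec files
#'
#' Trees serialize to JSON with internal nodes
#' `{"feature": ..., "op": "le"|"gt", "threshold": ..., "left": ...,
#' "right": ...}` and leaves `{"class": ..., "p": ..., "phenotype": ...}`.
#' Loading validates the structural invariants and reports the node path of
#' the first violation; save/load round-trips are exact.
#'
#' @param path File path.
#' @return [load_tree()] returns an `lvh_tree`; [save_tree()] returns `path`
#'   invisibly.
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) stop("tree spec not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  as_lvh_tree(raw)
}

#' @rdname load_tree
#' @param tree An `lvh_tree`.
#' @export
save_tree <- function(tree, path) {
  tree <- as_lvh_tree(tree)
  jsonlite::write_json(unclass(tree), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.lvh_tree <- function(x, ...) {
  cat("<lvh_tree>", tree_n_nodes(x), "nodes, depth", tree_depth(x), "\n")
  show <- function(node, indent, label) {
    pad <- strrep("  ", indent)
    if (is_leaf(node)) {
      cat(sprintf("%s%s %s (p = %.3g%s)\n", pad, label, node$class, node$p,
                  if (!is.null(node$phenotype))
                    paste0(", ", node$phenotype) else ""))
    } else {
      cat(sprintf("%s%s%s %s %.4g?\n", pad, label, node$feature,
                  ifelse(node$op == "le", " <=", " >"), node$threshold))
      show(node$left, indent + 1, "yes: ")
      show(node$right, indent + 1, "no:  ")
    }
  }
  show(x, 0, "")
  invisible(x)
}

#' Tidy a threshold tree into a node table
#'
#' @param x An `lvh_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node: `node`, `parent`, `depth`,
#'   `is_leaf`, `feature`, `op`, `threshold`, `class`, `phenotype`, `p`.
#' @export
tidy.lvh_tree <- function(x, ...) {
  rows <- list()
  counter <- local({ i <- 0L; function() { i <<- i + 1L; i } })
  walk <- function(node, parent, depth) {
    id <- counter()
    leaf <- is_leaf(node)
    row <- tibble::tibble(
      node = id, parent = parent, depth = depth, is_leaf = leaf,
      feature = NA_character_, op = NA_character_, threshold = NA_real_,
      class = NA_character_, phenotype = NA_character_, p = NA_real_)
    if (leaf) {
      row$class <- node$class
      row$phenotype <- node$phenotype %||% NA_character_
      row$p <- node$p
    } else {
      row$feature <- node$feature
      row$op <- node$op
      row$threshold <- node$threshold
    }
    rows[[id]] <<- row
    if (!leaf) {
      walk(node$left, id, depth + 1L)
      walk(node$right, id, depth + 1L)
    }
  }
  walk(x, NA_integer_, 0L)
  dplyr::bind_rows(rows)
}

#' One-row summary of a threshold tree
#'
#' @inheritParams tidy.lvh_tree
#' @return A tibble with `n_nodes`, `n_leaves`, `depth` and the
#'   comma-separated `features` tested.
#' @export
glance.lvh_tree <- function(x, ...) {
  nodes <- tidy(x)
  tibble::tibble(
    n_nodes = nrow(nodes),
    n_leaves = sum(nodes$is_leaf),
    depth = max(nodes$depth),
    features = paste(tree_features(x), collapse = ","))
}

#' Plot a threshold tree
#'
#' Draws the tree as a node-link diagram with split conditions on internal
#' nodes and class/phenotype labels on leaves.
#'
#' @param object An `lvh_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lvh_tree <- function(object, ...) {
  nodes <- tidy(object)
  # inorder x positions for a tidy layout
  xpos <- numeric(nrow(nodes))
  counter <- local({ i <- 0; function() { i <<- i + 1; i } })
  children <- function(id) nodes$node[which(nodes$parent == id)]
  assign_x <- function(id) {
    kids <- children(id)
    if (length(kids) == 0) {
      xpos[id] <<- counter()
    } else {
      assign_x(kids[1])
      assign_x(kids[2])
      xpos[id] <<- mean(xpos[kids])
    }
  }
  assign_x(1)
  nodes$x <- xpos
  nodes$y <- -nodes$depth
  nodes$label <- ifelse(
    nodes$is_leaf,
    paste0(nodes$class,
           ifelse(is.na(nodes$phenotype), "", paste0("\n", nodes$phenotype))),
    sprintf("%s %s %.4g", nodes$feature,
            ifelse(nodes$op == "le", "≤", ">"), nodes$threshold))
  edges <- nodes |>
    dplyr::filter(!is.na(.data$parent)) |>
    dplyr::mutate(xend = nodes$x[.data$parent], yend = nodes$y[.data$parent])
  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          color = "grey50") +
    ggplot2::geom_label(ggplot2::aes(label = .data$label,
                                     fill = .data$is_leaf),
                        size = 3, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#cfe8cf",
                                          `FALSE` = "#dbe9f6")) +
    ggplot2::theme_void()
}
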