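# CART-style recursive partitioning for a binary outcome, with exhaustive
# midpoint split search, Gini impurity, a minimum-node-size rule and
# penalised bottom-up pruning.

gini_impurity <- function(labels) {
  p <- mean(labels)
  2 * p * (1 - p)
}

# Exhaustive best split of one node: all features, all midpoint thresholds.
# Gain is measured in count-weighted impurity units,
#   gain = n * gini(node) - [nL * gini(L) + nR * gini(R)],
# ties broken by lowest feature index, then smallest threshold.
best_split <- function(features, labels, min_gain) {
  n <- length(labels)
  parent <- n * gini_impurity(labels)
  best <- NULL
  for (j in seq_along(features)) {
    x <- features[[j]]
    ux <- sort(unique(x))
    if (length(ux) < 2L) next
    thresholds <- (ux[-length(ux)] + ux[-1L]) / 2
    for (thr in thresholds) {
      left <- x < thr
      nl <- sum(left)
      child <- nl * gini_impurity(labels[left]) +
        (n - nl) * gini_impurity(labels[!left])
      gain <- parent - child
      if (gain > min_gain &&
          (is.null(best) || gain > best$gain + 1e-12)) {
        best <- list(feature = names(features)[j], feature_index = j,
                     threshold = thr, gain = gain)
      }
    }
  }
  best
}

grow_node <- function(features, labels, min_split, min_gain, depth, id) {
  n <- length(labels)
  node <- list(id = id, n = n, n_event = sum(labels),
               event_rate = mean(labels),
               gini = gini_impurity(labels), depth = depth)
  if (n >= min_split && node$gini > 0) {
    sp <- best_split(features, labels, min_gain)
    if (!is.null(sp)) {
      left <- features[[sp$feature_index]] < sp$threshold
      node$split <- list(feature = sp$feature, threshold = sp$threshold,
                         gain = sp$gain)
      node$left <- grow_node(lapply(features, `[`, left), labels[left],
                             min_split, min_gain, depth + 1L, 2L * id)
      node$right <- grow_node(lapply(features, `[`, !left), labels[!left],
                              min_split, min_gain, depth + 1L, 2L * id + 1L)
    }
  }
  node
}

#' Grow a recursive-partitioning tree for a binary outcome
#'
#' Greedy CART-style binary splitting minimising Gini impurity, with an
#' exhaustive search over every feature and every midpoint threshold between
#' adjacent observed values. A node is split only when it holds at least
#' `min_split` observations (default 5) and some split strictly reduces the
#' count-weighted impurity; ties between splits are broken deterministically
#' by lowest feature index, then smallest threshold. Left branches take
#' `feature < threshold`. Missing feature values are rejected.
#'
#' @param features data frame of numeric candidate predictors (no missing
#'   values).
#' @param labels logical (or 0/1) outcome vector, one per row of `features`.
#' @param min_split minimum number of observations a node must hold to be
#'   eligible for further splitting.
#' @return An `rpa_tree` object (nested nodes, each carrying `n`,
#'   `event_rate`, Gini impurity, and for internal nodes the split rule and
#'   children).
#' @examples
#' x <- data.frame(x = 1:6)
#' grow_tree(x, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE), min_split = 2)
#' @export
grow_tree <- function(features, labels, min_split = 5L) {
  features <- as.data.frame(features)
  labels <- as.logical(labels)
  if (nrow(features) == 0L || length(labels) < 2L) {
    stop("need at least 2 observations")
  }
  stopifnot(nrow(features) == length(labels))
  if (anyNA(features) || anyNA(labels)) {
    stop("missing values are not supported; complete the table first")
  }
  if (!all(vapply(features, is.numeric, logical(1)))) {
    stop("all features must be numeric")
  }
  root <- grow_node(as.list(features), labels, min_split,
                    min_gain = 1e-12, depth = 0L, id = 1L)
  structure(list(root = root, min_split = min_split,
                 features = names(features), n = length(labels)),
            class = "rpa_tree")
}

# Dynamic-programming penalised pruning: the optimal pruned subtree under
# cost R(T) + penalty * #leaves(T), with R the count-weighted Gini risk.
prune_node <- function(node, penalty) {
  leaf_cost <- node$n * node$gini + penalty
  if (is.null(node$split)) {
    return(list(node = node, cost = leaf_cost))
  }
  l <- prune_node(node$left, penalty)
  r <- prune_node(node$right, penalty)
  keep_cost <- l$cost + r$cost
  # strict improvement required to keep a split when penalty > 0; at
  # penalty 0 ties keep the split so the tree is unchanged
  collapse <- if (penalty > 0) leaf_cost <= keep_cost else leaf_cost < keep_cost
  if (collapse) {
    leaf <- node
    leaf$split <- NULL
    leaf$left <- NULL
    leaf$right <- NULL
    list(node = leaf, cost = leaf_cost)
  } else {
    node$left <- l$node
    node$right <- r$node
    list(node = node, cost = keep_cost)
  }
}

#' Prune a fitted tree
#'
#' Bottom-up removal of downstream branches whose impurity decrease does not
#' justify their complexity: the returned tree minimises
#' `risk + penalty * (number of leaves)` over all pruned subtrees of the
#' input (count-weighted Gini risk), found by dynamic programming. A penalty
#' of 0 leaves the tree unchanged; a penalty at or above the root's total
#' impurity collapses it to the root. The root node itself is never removed.
#'
#' @param tree an `rpa_tree` from [grow_tree()].
#' @param penalty impurity-decrease threshold (count-weighted Gini units);
#'   the default of 0.5 corresponds to about one reclassified observation.
#' @return The pruned `rpa_tree`.
#' @export
prune_tree <- function(tree, penalty = 0.5) {
  stopifnot(inherits(tree, "rpa_tree"), penalty >= 0)
  tree$root <- prune_node(tree$root, penalty)$node
  tree
}

#' Predict from a recursive-partitioning tree
#'
#' @param object an `rpa_tree`.
#' @param newdata data frame containing the tree's feature columns.
#' @param type `"rate"` for the leaf event rate, `"leaf"` for the leaf node
#'   id (a stable identifier of the partition cell).
#' @param ... unused.
#' @return Numeric event rates or integer leaf ids.
#' @export
predict.rpa_tree <- function(object, newdata, type = c("rate", "leaf"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks feature columns: ", paste(missing_cols, collapse = ", "))
  }
  one <- function(row) {
    node <- object$root
    while (!is.null(node$split)) {
      node <- if (row[[node$split$feature]] < node$split$threshold) {
        node$left
      } else {
        node$right
      }
    }
    if (type == "rate") node$event_rate else node$id
  }
  out <- vapply(seq_len(nrow(newdata)), function(i) {
    one(lapply(newdata[i, object$features, drop = FALSE], identity))
  }, numeric(1))
  if (type == "leaf") as.integer(out) else out
}

# Flat list of leaf nodes.
tree_leaves <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (is.null(node$split)) {
      out[[length(out) + 1L]] <<- node
    } else {
      walk(node$left)
      walk(node$right)
    }
  }
  walk(tree$root)
  out
}

# Features actually used by splits.
tree_split_features <- function(tree) {
  out <- character()
  walk <- function(node) {
    if (!is.null(node$split)) {
      out <<- c(out, node$split$feature)
      walk(node$left)
      walk(node$right)
    }
  }
  walk(tree$root)
  unique(out)
}

#' @export
print.rpa_tree <- function(x, ...) {
  cat(sprintf("Recursive-partitioning tree (%d observations, min_split = %d)\n",
              x$n, x$min_split))
  walk <- function(node, prefix) {
    tag <- sprintf("n = %d, event rate %.2f", node$n, node$event_rate)
    if (is.null(node$split)) {
      cat(prefix, "* leaf: ", tag, "\n", sep = "")
    } else {
      cat(prefix, "+ ", tag, "\n", sep = "")
      cat(prefix, "  [", node$split$feature, " < ",
          format(node$split$threshold), "]\n", sep = "")
      walk(node$left, paste0(prefix, "  "))
      cat(prefix, "  [", node$split$feature, " >= ",
          format(node$split$threshold), "]\n", sep = "")
      walk(node$right, paste0(prefix, "  "))
    }
  }
  walk(x$root, "")
  invisible(x)
}

# Serialisable nested-list view of a tree (for JSON reports).
as_tree_list <- function(tree) {
  walk <- function(node) {
    out <- list(n = node$n, event_rate = node$event_rate)
    if (!is.null(node$split)) {
      out$rule <- list(feature = node$split$feature,
                       threshold = node$split$threshold)
      out$left <- walk(node$left)
      out$right <- walk(node$right)
    }
    out
  }
  walk(tree$root)
}

#' Fixed two-threshold response-group model
#'
#' The published two-split predictive model for pCR after SABR, applied as a
#' fixed rule: patients are partitioned on baseline tumour blood volume and
#' the percent change in SUVmax,
#' * group 1 — `bv_pre >= 9.3` mL/100 g (0% observed pCR rate);
#' * group 2 — `bv_pre < 9.3` and `dsuv_max >= -48.9`% (25%);
#' * group 3 — `bv_pre < 9.3` and `dsuv_max < -48.9`% (92%; predicted pCR).
#'
#' Every finite `(bv, dsuv)` pair maps to exactly one group.
#'
#' @param bv_pre baseline tumour blood volume (mL/100 g).
#' @param dsuv_max percent change in SUVmax after treatment.
#' @param bv_threshold,dsuv_threshold the model thresholds (defaults 9.3
#'   mL/100 g and -48.9%).
#' @return Integer group labels (1, 2 or 3); predicted pCR corresponds to
#'   group 3.
#' @examples
#' response_group(c(9.3, 5, 5), c(-60, -30, -60))  # 1, 2, 3
#' @export
response_group <- function(bv_pre, dsuv_max, bv_threshold = 9.3,
                           dsuv_threshold = -48.9) {
  stopifnot(all(is.finite(bv_pre)), all(is.finite(dsuv_max)))
  ifelse(bv_pre >= bv_threshold, 1L,
         ifelse(dsuv_max >= dsuv_threshold, 2L, 3L))
}
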