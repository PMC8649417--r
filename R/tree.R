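# Shallow regression trees over the expanded summary tables. All predictors
# are categorical design features with two or three levels, so the exact
# best binary split can be found by enumerating level subsets; no greedy
# surrogate or pruning machinery is needed.

# canonical candidate splits for a factor: all binary partitions of its
# levels, represented by the subset containing the first level, ordered by
# subset size then lexicographically (deterministic tie-breaking)
.level_splits <- function(levels) {
  L <- length(levels)
  if (L < 2L) return(list())
  out <- list()
  idx_rest <- seq_len(L)[-1L]
  for (size0 in 0:(L - 2L)) {  # members of the subset beyond the first level
    combos <- if (size0 == 0L) list(integer(0))
              else utils::combn(idx_rest, size0, simplify = FALSE)
    for (cmb in combos) out[[length(out) + 1L]] <- levels[c(1L, cmb)]
  }
  out
}

.sse <- function(y) sum((y - mean(y))^2)

# exhaustive best split of (X, y); returns NULL if no admissible split
# strictly reduces the SSE
.best_split <- function(X, y, minbucket) {
  best <- NULL
  sse0 <- .sse(y)
  for (f in names(X)) {
    x <- X[[f]]
    lev <- levels(x)[levels(x) %in% unique(as.character(x))]
    for (subset in .level_splits(lev)) {
      left <- as.character(x) %in% subset
      nl <- sum(left)
      if (nl < minbucket || length(y) - nl < minbucket) next
      red <- sse0 - .sse(y[left]) - .sse(y[!left])
      if (red > 1e-12 && (is.null(best) || red > best$reduction + 1e-12)) {
        best <- list(feature = f, levels_left = subset, reduction = red)
      }
    }
  }
  best
}

.grow <- function(X, y, depth, id, maxdepth, minsplit, minbucket) {
  node <- list(id = id, n = length(y), mean = mean(y), depth = depth,
               leaf = TRUE)
  if (depth < maxdepth && length(y) >= minsplit) {
    sp <- .best_split(X, y, minbucket)
    if (!is.null(sp)) {
      left <- as.character(X[[sp$feature]]) %in% sp$levels_left
      node$leaf <- FALSE
      node$feature <- sp$feature
      node$levels_left <- sp$levels_left
      node$reduction <- sp$reduction
      node$left <- .grow(X[left, , drop = FALSE], y[left], depth + 1L,
                         2L * id, maxdepth, minsplit, minbucket)
      node$right <- .grow(X[!left, , drop = FALSE], y[!left], depth + 1L,
                          2L * id + 1L, maxdepth, minsplit, minbucket)
    }
  }
  node
}

#' Fit a shallow regression tree to a summary table
#'
#' Binary recursive partitioning minimizing mean squared error, with the
#' study's display settings: maximum depth 4 splits, complexity parameter 0
#' (any split with a positive SSE reduction is eligible), and conventional
#' stopping defaults (at least `minsplit` cases to attempt a split,
#' `minbucket` per child). Predictors are treated as categorical; every
#' binary partition of a predictor's levels is scored exactly, and ties
#' break by predictor declaration order then level-subset order, so the
#' tree is deterministic. Every node carries its outcome mean, so the root
#' mean equals the table-wide average of the outcome.
#'
#' @param table data.frame (e.g. a [summarize_study()] table).
#' @param outcome name of the numeric outcome column (`"rate"` or `"mae"`).
#' @param predictors character vector of predictor column names; defaults
#'   to the design features plus method and prescreening status found in
#'   the table.
#' @param maxdepth maximum number of splits root-to-leaf (default 4).
#' @param minsplit minimum node size to attempt a split (default 20).
#' @param minbucket minimum child size (default 7).
#' @return A `grm_tree` (nested node list; see [render_tree()],
#'   [tree_to_json()], [predict_tree()]).
#' @export
fit_tree <- function(table, outcome,
                     predictors = intersect(
                       c("n_per_group", "n_items", "discrimination",
                         "n_categories", "thresholds_mode", "dif",
                         "missing", "true_focal_mean", "method",
                         "prescreened"), names(table)),
                     maxdepth = 4L, minsplit = 20L, minbucket = 7L) {
  stopifnot(outcome %in% names(table), length(predictors) >= 1L)
  y <- table[[outcome]]
  keep <- !is.na(y)
  y <- y[keep]
  if (length(y) == 0L) stop("no non-missing outcome values")
  X <- table[keep, predictors, drop = FALSE]
  for (f in predictors) {
    v <- X[[f]]
    X[[f]] <- if (is.factor(v)) v else factor(v, levels = unique(v))
  }
  root <- .grow(X, y, 0L, 1L, maxdepth, minsplit, minbucket)
  structure(root, class = "grm_tree", outcome = outcome)
}

#' Render a fitted tree as an indented text diagram
#'
#' @param tree a [fit_tree()] result (or internal node).
#' @param digits digits for node means.
#' @return Character vector of lines (also printed by `print.grm_tree`).
#' @export
render_tree <- function(tree, digits = 3L) {
  fmt <- function(node, label, indent) {
    line <- sprintf("%s%s mean=%s, n=%d", indent, label,
                    formatC(node$mean, digits = digits, format = "f"),
                    node$n)
    if (node$leaf) return(line)
    lab_l <- sprintf("%s in {%s}:", node$feature,
                     paste(node$levels_left, collapse = ","))
    lab_r <- sprintf("%s not in {%s}:", node$feature,
                     paste(node$levels_left, collapse = ","))
    c(line,
      fmt(node$left, lab_l, paste0(indent, "  ")),
      fmt(node$right, lab_r, paste0(indent, "  ")))
  }
  fmt(tree, "root:", "")
}

#' @export
print.grm_tree <- function(x, ...) {
  cat(render_tree(x), sep = "\n")
  invisible(x)
}

#' Export a fitted tree as JSON
#'
#' @param tree a [fit_tree()] result.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(tree, path = NULL) {
  strip <- function(node) {
    out <- list(id = node$id, n = node$n, mean = node$mean,
                depth = node$depth, leaf = node$leaf)
    if (!node$leaf) {
      out$feature <- node$feature
      out$levels_left <- as.list(node$levels_left)
      out$left <- strip(node$left)
      out$right <- strip(node$right)
    }
    out
  }
  js <- jsonlite::toJSON(strip(tree), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Predict leaf means from a fitted tree
#'
#' @param tree a [fit_tree()] result.
#' @param newdata data.frame with the tree's predictor columns.
#' @return Numeric vector of leaf means.
#' @export
predict_tree <- function(tree, newdata) {
  one <- function(node, row) {
    while (!node$leaf) {
      node <- if (as.character(row[[node$feature]]) %in% node$levels_left)
        node$left else node$right
    }
    node$mean
  }
  vapply(seq_len(nrow(newdata)), function(i) one(tree, newdata[i, ]),
         numeric(1))
}
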