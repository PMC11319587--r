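# Simplified CHAID (chi-square automatic interaction detection) for
# continuous predictors and a two-class outcome. Each predictor is
# discretised at candidate cut-points, adjacent categories are merged while
# the chi-square test of label independence is non-significant, and the best
# predictor is chosen by the smallest Bonferroni-adjusted chi-square p-value.
# A designated predictor can be forced into the root split.

#' CHAID parameters
#'
#' @param alpha_merge significance threshold for merging adjacent categories.
#' @param alpha_split Bonferroni-adjusted threshold for accepting a split.
#' @param min_node_size a node is only considered for splitting when it holds
#'   at least `2 * min_node_size` observations.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param forced_first optional predictor name forced into the root split.
#' @param n_bins number of quantile-based candidate cut-points used when a
#'   predictor has more than `n_bins` distinct values (else every distinct
#'   value is a candidate).
#' @param tie_break leaf label used when classes tie (default `"AD"`, the
#'   clinically costlier miss).
#' @return A list with class `"chaid_params"`.
#' @export
chaid_params <- function(alpha_merge = 0.05, alpha_split = 0.05,
                         min_node_size = 10L, max_depth = 3L,
                         forced_first = NULL, n_bins = 20L,
                         tie_break = "AD") {
  stopifnot(alpha_merge > 0, alpha_merge <= 1,
            alpha_split > 0, alpha_split <= 1,
            min_node_size >= 2, max_depth >= 1, n_bins >= 2)
  structure(list(alpha_merge = alpha_merge, alpha_split = alpha_split,
                 min_node_size = as.integer(min_node_size),
                 max_depth = as.integer(max_depth),
                 forced_first = forced_first,
                 n_bins = as.integer(n_bins),
                 tie_break = tie_break),
            class = "chaid_params")
}

chisq_p <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(1)
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  if (!is.finite(p)) 1 else p
}

# Candidate boundaries for a continuous predictor: unique observed values
# (without the maximum, which cannot be a "x <= b" split) when few, else
# quantile-based cuts.
candidate_boundaries <- function(x, n_bins) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(numeric(0))
  if (length(ux) <= n_bins) return(ux[-length(ux)])
  b <- unique(stats::quantile(x, probs = seq_len(n_bins - 1L) / n_bins,
                              names = FALSE, type = 1))
  setdiff(b, max(ux))
}

# Merge adjacent categories of a discretised predictor while the most
# similar adjacent pair's 2x2 chi-square has p > alpha_merge. Returns the
# merged grouping as boundary values plus the Bonferroni-adjusted p of the
# final labels-by-groups table.
merge_categories <- function(x, y, boundaries, alpha_merge) {
  if (length(boundaries) == 0L) return(NULL)
  cat_idx <- vapply(x, function(v) sum(v > boundaries) + 1L, integer(1))
  n_cat <- length(boundaries) + 1L
  occupied <- sort(unique(cat_idx))
  if (length(occupied) < 2L) return(NULL)
  # groups: list of original category index vectors, in order
  groups <- as.list(occupied)
  c0 <- length(groups)
  grp_of <- function(ci) which(vapply(groups, function(g) ci %in% g,
                                      logical(1)))
  assign_groups <- function() {
    vapply(cat_idx, grp_of, integer(1))
  }
  repeat {
    if (length(groups) <= 2L) break
    g <- assign_groups()
    pair_p <- vapply(seq_len(length(groups) - 1L), function(i) {
      sel <- g %in% c(i, i + 1L)
      chisq_p(table(factor(g[sel], levels = c(i, i + 1L)), y[sel]))
    }, numeric(1))
    i_max <- which.max(pair_p)
    if (pair_p[i_max] <= alpha_merge) break
    groups[[i_max]] <- c(groups[[i_max]], groups[[i_max + 1L]])
    groups[[i_max + 1L]] <- NULL
  }
  g <- assign_groups()
  c_final <- length(groups)
  p_raw <- chisq_p(table(g, y))
  multiplier <- choose(c0 - 1L, c_final - 1L)
  # split boundaries: the boundary value at each junction between groups
  cuts <- vapply(seq_len(c_final - 1L), function(i) {
    boundaries[max(groups[[i]])]
  }, numeric(1))
  list(cuts = cuts, p_raw = p_raw, adj_p = min(1, p_raw * multiplier),
       n_groups = c_final, n_initial = c0)
}

best_split <- function(X, y, params, force = NULL) {
  candidates <- list()
  for (nm in names(X)) {
    x <- X[[nm]]
    if (length(unique(x)) < 2L) next           # constant predictor: skipped
    b <- candidate_boundaries(x, params$n_bins)
    m <- merge_categories(x, y, b, params$alpha_merge)
    if (is.null(m)) next
    m$predictor <- nm
    candidates[[nm]] <- m
  }
  if (length(candidates) == 0L) return(NULL)
  if (!is.null(force)) {
    return(candidates[[force]])                # NULL when force is unsplittable
  }
  candidates[[which.min(vapply(candidates, `[[`, numeric(1), "adj_p"))]]
}

leaf_node <- function(y, params, depth) {
  counts <- table(y)
  top <- which(counts == max(counts))
  label <- if (length(top) > 1L && params$tie_break %in% names(counts)[top]) {
    params$tie_break
  } else {
    names(counts)[top[1L]]
  }
  list(is_leaf = TRUE, label = label, counts = counts, n = length(y),
       depth = depth)
}

grow_node <- function(X, y, params, depth) {
  node <- leaf_node(y, params, depth)
  if (depth >= params$max_depth) return(node)
  if (length(y) < 2L * params$min_node_size) return(node)
  if (length(unique(y)) < 2L) return(node)
  force <- if (depth == 0L) params$forced_first else NULL
  if (!is.null(force) && !force %in% names(X)) {
    stop("forced_first predictor '", force, "' not among the features")
  }
  split <- best_split(X, y, params, force = force)
  if (is.null(split)) return(node)
  # a forced root split is accepted regardless of alpha_split
  if (is.null(force) && split$adj_p > params$alpha_split) return(node)
  g <- vapply(X[[split$predictor]], function(v) sum(v > split$cuts) + 1L,
              integer(1))
  children <- lapply(seq_len(split$n_groups), function(i) {
    sel <- g == i
    grow_node(X[sel, , drop = FALSE], y[sel], params, depth + 1L)
  })
  node$is_leaf <- FALSE
  node$predictor <- split$predictor
  node$cuts <- split$cuts
  node$adj_p <- split$adj_p
  node$children <- children
  node
}

#' Fit a CHAID decision tree
#'
#' Recursive partitioning by chi-square tests: each continuous predictor is
#' discretised at candidate cut-points (all distinct values, or quantile
#' cuts when many), adjacent categories are merged while the 2-by-c
#' chi-square test of label independence is non-significant at
#' `alpha_merge`, the winning predictor has the smallest Bonferroni-adjusted
#' p (multiplier = number of ways of reducing the initial categories to the
#' merged ones), and a split is accepted when that adjusted p is at most
#' `alpha_split`. Recursion stops at `max_depth`, at nodes smaller than
#' `2 * min_node_size`, or when no acceptable split exists. A `forced_first`
#' predictor is always split first at the root (its merged categories are
#' used even when its adjusted p exceeds `alpha_split`). Leaves carry the
#' majority class; ties go to `tie_break`. Constant predictors are skipped.
#'
#' @param features data frame of numeric predictors.
#' @param labels two-class vector aligned with `features` rows.
#' @param params a [chaid_params()].
#' @return A list with class `"chaid_tree"`: nested nodes with fields
#'   `predictor`, `cuts` (children are the intervals delimited by the cuts),
#'   `children`, and at leaves `label` and class `counts`.
#' @export
fit_chaid <- function(features, labels, params = chaid_params()) {
  stopifnot(is.data.frame(features), nrow(features) == length(labels))
  y <- factor(as.character(labels))
  if (nlevels(y) < 2L) stop("need >= 2 classes present")
  if (nrow(features) < 2L * params$min_node_size) {
    stop("need n >= 2 * min_node_size observations")
  }
  tree <- grow_node(features, y, params, depth = 0L)
  structure(list(root = tree, params = params,
                 classes = levels(y), n = length(y)),
            class = "chaid_tree")
}

#' Predict with a fitted CHAID tree
#'
#' @param object a `"chaid_tree"`.
#' @param newdata data frame containing the predictors used by the tree.
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.chaid_tree <- function(object, newdata, ...) {
  one <- function(node, row) {
    while (!node$is_leaf) {
      v <- row[[node$predictor]]
      node <- node$children[[sum(v > node$cuts) + 1L]]
    }
    node$label
  }
  vapply(seq_len(nrow(newdata)), function(i) one(object$root, newdata[i, ]),
         character(1))
}

#' Tree depth of a fitted CHAID tree
#'
#' @param tree a `"chaid_tree"`.
#' @return Integer depth; 0 for a root-only tree.
#' @export
chaid_depth <- function(tree) {
  walk <- function(node) {
    if (node$is_leaf) return(node$depth)
    max(vapply(node$children, walk, numeric(1)))
  }
  as.integer(walk(tree$root))
}

render_node <- function(node, indent = "") {
  if (node$is_leaf) {
    return(sprintf("%s-> %s (%s)\n", indent, node$label,
                   paste(sprintf("%s=%d", names(node$counts), node$counts),
                         collapse = ", ")))
  }
  out <- sprintf("%ssplit on %s at {%s} (adj. p = %.3g)\n", indent,
                 node$predictor,
                 paste(signif(node$cuts, 4), collapse = ", "), node$adj_p)
  bounds <- c(-Inf, node$cuts, Inf)
  for (i in seq_along(node$children)) {
    out <- paste0(out, sprintf("%s[%s < x <= %s]\n", paste0(indent, "  "),
                               signif(bounds[i], 4), signif(bounds[i + 1], 4)),
                  render_node(node$children[[i]], paste0(indent, "    ")))
  }
  out
}

#' @export
print.chaid_tree <- function(x, ...) {
  cat("CHAID tree (n =", x$n, ")\n")
  cat(render_node(x$root))
  invisible(x)
}
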