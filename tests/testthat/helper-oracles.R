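# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Levenshtein distance by plain recursion (no memoisation).
lev_recursive <- function(a, b) {
  if (length(a) == 0) return(length(b))
  if (length(b) == 0) return(length(a))
  cost <- if (a[1] == b[1]) 0 else 1
  min(lev_recursive(a[-1], b) + 1,
      lev_recursive(a, b[-1]) + 1,
      lev_recursive(a[-1], b[-1]) + cost)
}

# Between-search errors by scanning all (open, prior-target) pairs.
brute_between <- function(trial) {
  targets <- trial$spec$target_order
  total <- 0
  for (k in seq_along(trial$searches)) {
    for (b in trial$searches[[k]]$opens$box) {
      for (kk in seq_len(k - 1)) {
        if (b == targets[kk]) total <- total + 1
      }
    }
  }
  total
}

# Within-search errors: re-opens of boxes already found empty in the same
# search, excluding past-target boxes (those belong to the between counter).
brute_within <- function(trial) {
  targets <- trial$spec$target_order
  total <- 0
  for (k in seq_along(trial$searches)) {
    prior <- if (k > 1) targets[1:(k - 1)] else integer(0)
    op <- trial$searches[[k]]$opens
    for (j in seq_len(nrow(op))) {
      b <- op$box[j]
      if (b %in% prior) next
      if (j > 1) {
        earlier <- op$box[1:(j - 1)]
        earlier_empty <- op$outcome[1:(j - 1)] == "empty"
        if (any(earlier == b & earlier_empty)) total <- total + 1
      }
    }
  }
  total
}

# AUC by exhaustive pair counting, ties worth 1/2.
auc_paircount <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Benjamini-Hochberg by brute-force scan over all prefixes of the sorted
# p-values.
bh_prefix_scan <- function(pvals, Q) {
  m <- length(pvals)
  ps <- sort(pvals)
  k_star <- 0
  for (k in seq_len(m)) {
    if (ps[k] <= k * Q / m) k_star <- k
  }
  pvals <= if (k_star == 0) -Inf else ps[k_star]
}

# The published decision tree as an explicit truth table over its four paths.
tree_truth_table <- function(ace, ws6, bs4) {
  if (ace > 70 && ws6 >= 1) return("AD")
  if (ace > 70 && ws6 < 1) return("bvFTD")
  if (ace <= 70 && bs4 >= 2) return("AD")
  "bvFTD"
}

# Small simulated patient/control cohort shared by several tests.
tiny_cohort <- function(n = 5L, seed = 99L,
                        groups = c(control = n, bvFTD = n, AD = n)) {
  simulate_cohort(cohort_spec(n_per_group = groups, seed = seed))
}
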