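# Supporting statistics: Benjamini-Hochberg FDR control, standardised-beta
# multiple regression, the group-specific regression-pattern check, and
# permutation-based group contrasts.

#' Benjamini-Hochberg false discovery rate procedure
#'
#' Rejects all hypotheses with sorted p-value rank at most k*, where k* is
#' the largest k such that p_(k) <= k * Q / m (stable sort; rejections form
#' a prefix of the sorted p-values).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param Q target false discovery rate, in (0, 1); default 0.05.
#' @return A list with class `"fdr_result"`: `pvals`, `Q`, `rejected`
#'   (logical, aligned with the input order), `critical_values`
#'   (`k * Q / m` aligned with the input order's ranks) and `n_rejected`.
#' @examples
#' benjamini_hochberg(c(0.01, 0.04, 0.03, 0.20))$rejected
#' @export
benjamini_hochberg <- function(pvals, Q = 0.05) {
  if (length(pvals) == 0L) stop("empty p-value vector")
  stopifnot(all(pvals >= 0 & pvals <= 1), Q > 0, Q < 1)
  m <- length(pvals)
  ord <- order(pvals)                       # stable in R
  crit <- seq_len(m) * Q / m
  below <- which(pvals[ord] <= crit)
  k_star <- if (length(below)) max(below) else 0L
  rejected <- logical(m)
  if (k_star > 0L) rejected[ord[seq_len(k_star)]] <- TRUE
  crit_by_input <- numeric(m)
  crit_by_input[ord] <- crit
  structure(list(pvals = pvals, Q = Q, rejected = rejected,
                 critical_values = crit_by_input,
                 n_rejected = sum(rejected)),
            class = "fdr_result")
}

#' Standardised-beta multiple regression
#'
#' Ordinary least squares on the z-scored response and predictors (all
#' predictors entered simultaneously). The coefficients are the standardised
#' betas; p-values are classical two-sided t-tests with n - k - 1 degrees of
#' freedom.
#'
#' @param design data frame of numeric predictors (k columns).
#' @param response numeric vector (length n > k + 1).
#' @return A list with class `"regression_result"`: `coefficients` (data
#'   frame `term`, `beta`, `se`, `t`, `p`), `r_squared`, `n`, `k`.
#' @export
standardized_regression <- function(design, response) {
  stopifnot(is.data.frame(design), nrow(design) == length(response))
  n <- length(response)
  k <- ncol(design)
  if (n <= k + 1L) stop("need n > k + 1 observations")
  const <- vapply(design, function(x) stats::sd(x) == 0, logical(1))
  if (any(const)) {
    stop("constant predictor(s): ", paste(names(design)[const], collapse = ", "))
  }
  Z <- scale(as.matrix(design))
  qz <- qr(Z)
  if (qz$rank < k) {
    dropped <- qz$pivot[(qz$rank + 1L):k]
    involved <- unique(unlist(lapply(dropped, function(j) {
      cors <- abs(stats::cor(Z[, j], Z[, -j, drop = FALSE]))
      c(colnames(Z)[j], colnames(Z[, -j, drop = FALSE])[cors > 0.9999])
    })))
    stop("rank-deficient design; collinear columns: ",
         paste(involved, collapse = ", "))
  }
  yz <- as.numeric(scale(response))
  fit <- stats::lm(yz ~ Z)
  sm <- summary(fit)
  co <- sm$coefficients[-1L, , drop = FALSE]
  structure(list(
    coefficients = data.frame(term = colnames(Z),
                              beta = unname(co[, 1]),
                              se = unname(co[, 2]),
                              t = unname(co[, 3]),
                              p = unname(co[, 4]),
                              stringsAsFactors = FALSE),
    r_squared = sm$r.squared, n = n, k = k),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("standardised regression: n = %d, k = %d, R^2 = %.3f\n",
              x$n, x$k, x$r_squared))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

FIG3_PREDICTORS <- c("ace_visuospatial", "sspan_forward", "sspan_backward",
                     "rcf_copy", "rcf_recall", "trails_a", "trails_b_minus_a")

#' Per-group regression of 6-box between-search errors on cognitive measures
#'
#' For each patient group, regresses the participant's mean 6-box
#' between-search error score (average of the two trials) on the cognitive
#' battery: ACE-III visuospatial, Spatial Span forward and backward, RCF
#' copy and 3-min recall, Trails A time, and the Trails B minus A difference
#' (the executive index, used instead of Trails B because of collinearity
#' with Trails A). The verdict checks the dissociation the generator
#' encodes: visuospatial episodic memory (RCF 3-min recall) predicts error
#' performance in the AD group (p < 0.05) but not in the bvFTD group.
#'
#' @param per_set_size long score table from [score_cohort()].
#' @param covariates covariate table from [simulate_cohort()].
#' @param groups character vector of patient groups to model.
#' @return A list with class `"pattern_check"`: `results` (named list of
#'   [standardized_regression()] results), `recall_p` (named numeric) and
#'   `verdict` (logical).
#' @export
regression_pattern_check <- function(per_set_size, covariates,
                                     groups = c("AD", "bvFTD")) {
  results <- list()
  recall_p <- numeric(0)
  for (g in groups) {
    cov_g <- covariates[covariates$group == g, ]
    sc_g <- per_set_size[per_set_size$group == g &
                           per_set_size$set_size == 6L, ]
    d <- merge(cov_g, sc_g[, c("participant_id", "between_mean")],
               by = "participant_id")
    res <- standardized_regression(d[, FIG3_PREDICTORS], d$between_mean)
    results[[g]] <- res
    recall_p[[g]] <- res$coefficients$p[res$coefficients$term == "rcf_recall"]
  }
  verdict <- isTRUE(recall_p[["AD"]] < 0.05) &&
    isTRUE(recall_p[["bvFTD"]] > 0.05)
  structure(list(results = results, recall_p = recall_p, verdict = verdict),
            class = "pattern_check")
}

#' @export
print.pattern_check <- function(x, ...) {
  for (g in names(x$results)) {
    cat("==", g, "==\n")
    print(x$results[[g]])
  }
  cat(sprintf("RCF 3-min recall p: %s | dissociation verdict: %s\n",
              paste(sprintf("%s = %.3f", names(x$recall_p), x$recall_p),
                    collapse = ", "),
              x$verdict))
  invisible(x)
}

#' Permutation contrasts of between-search errors by group and set size
#'
#' For every set size and group pair, a two-sided permutation test of the
#' difference in mean between-search errors (group labels shuffled within
#' the pair): p = (1 + #{|T_perm| >= |T_obs|}) / (1 + n_permutations).
#' P-values are Benjamini-Hochberg corrected across the whole family.
#'
#' @param per_set_size long score table from [score_cohort()].
#' @param n_permutations number of label permutations (>= 99; default 9999).
#' @param seed integer seed; results are reproducible under it.
#' @param Q FDR level for the BH correction.
#' @return Data frame with one row per contrast: `set_size`, `group1`,
#'   `group2`, `mean1`, `mean2`, `difference`, `p`, `p_rank_critical`,
#'   `significant`, plus attributes `n_permutations` and `seed`.
#' @export
group_setsize_contrasts <- function(per_set_size, n_permutations = 9999L,
                                    seed = 1L, Q = 0.05) {
  stopifnot(n_permutations >= 99)
  groups <- unique(per_set_size$group)
  if (length(groups) < 2L) stop("need >= 2 groups")
  set.seed(as.integer(seed))
  pairs <- utils::combn(sort(groups), 2L, simplify = FALSE)
  rows <- list()
  for (n in sort(unique(per_set_size$set_size))) {
    for (pr in pairs) {
      d <- per_set_size[per_set_size$set_size == n &
                          per_set_size$group %in% pr, ]
      x <- d$between_mean
      is1 <- d$group == pr[1]
      t_obs <- mean(x[is1]) - mean(x[!is1])
      n1 <- sum(is1)
      exceed <- 0L
      for (b in seq_len(n_permutations)) {
        idx <- sample.int(length(x), n1)
        t_b <- mean(x[idx]) - mean(x[-idx])
        if (abs(t_b) >= abs(t_obs)) exceed <- exceed + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        set_size = n, group1 = pr[1], group2 = pr[2],
        mean1 = mean(x[is1]), mean2 = mean(x[!is1]),
        difference = t_obs,
        p = (1 + exceed) / (1 + n_permutations),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  fdr <- benjamini_hochberg(out$p, Q = Q)
  out$p_rank_critical <- fdr$critical_values
  out$significant <- fdr$rejected
  attr(out, "n_permutations") <- as.integer(n_permutations)
  attr(out, "seed") <- as.integer(seed)
  out
}
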