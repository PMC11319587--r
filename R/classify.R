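# Diagnostic layer: the published fixed decision tree, classifier
# evaluation, and rank-statistic ROC/AUC. (CHAID induction lives in chaid.R.)

#' Classify a patient with the published fixed decision tree
#'
#' The published bvFTD-vs-AD decision tree: the root splits on ACE-III total
#' at 70 (a score of exactly 70 takes the lower branch). Above 70, one or
#' more within-search errors at the 6-box set size (summed over trials 1 and
#' 2) indicates AD, otherwise bvFTD. At 70 and below, two or more
#' between-search errors at the 4-box set size (summed over trials 1 and 2)
#' indicates AD, otherwise bvFTD.
#'
#' @param ace_total ACE-III total score, 0-100.
#' @param ws6_sum 6-box within-search errors, sum of trials 1 and 2.
#' @param bs4_sum 4-box between-search errors, sum of trials 1 and 2.
#' @return Character vector of labels, `"AD"` or `"bvFTD"` (vectorised over
#'   the inputs).
#' @examples
#' classify_published_tree(85, 1, 0)  # "AD"
#' classify_published_tree(65, 0, 1)  # "bvFTD"
#' @export
classify_published_tree <- function(ace_total, ws6_sum, bs4_sum) {
  k <- max(length(ace_total), length(ws6_sum), length(bs4_sum))
  ace_total <- rep_len(ace_total, k)
  ws6_sum <- rep_len(ws6_sum, k)
  bs4_sum <- rep_len(bs4_sum, k)
  if (any(!is.finite(ace_total)) || any(ace_total < 0 | ace_total > 100)) {
    stop("ace_total out of range [0, 100]")
  }
  if (any(ws6_sum < 0) || any(bs4_sum < 0)) stop("error counts must be >= 0")
  ifelse(ace_total > 70,
         ifelse(ws6_sum >= 1, "AD", "bvFTD"),
         ifelse(bs4_sum >= 2, "AD", "bvFTD"))
}

#' Evaluate a two-class classifier
#'
#' @param predictions,labels equal-length vectors of class labels.
#' @return A list with class `"classifier_evaluation"`: `confusion` (truth in
#'   rows, prediction in columns), `per_class_pct_correct`,
#'   `overall_pct_correct`, `risk_estimate` (misclassification proportion,
#'   `1 - overall proportion correct`) and `risk_se`
#'   (`sqrt(r * (1 - r) / n)`).
#' @examples
#' ev <- evaluate_classifier(c("AD", "AD", "bvFTD"), c("AD", "bvFTD", "bvFTD"))
#' ev$risk_estimate
#' @export
evaluate_classifier <- function(predictions, labels) {
  if (length(predictions) == 0L || length(labels) == 0L) {
    stop("empty input")
  }
  stopifnot(length(predictions) == length(labels))
  lev <- sort(unique(c(as.character(predictions), as.character(labels))))
  truth <- factor(as.character(labels), levels = lev)
  pred <- factor(as.character(predictions), levels = lev)
  confusion <- table(truth = truth, prediction = pred)
  n <- length(labels)
  correct <- diag(confusion)
  per_class <- 100 * correct / rowSums(confusion)
  overall <- 100 * sum(correct) / n
  risk <- 1 - sum(correct) / n
  structure(list(confusion = confusion,
                 per_class_pct_correct = per_class,
                 overall_pct_correct = overall,
                 risk_estimate = risk,
                 risk_se = sqrt(risk * (1 - risk) / n),
                 n = n),
            class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("overall %% correct: %.1f | risk %.3f (SE %.3f)\n",
              x$overall_pct_correct, x$risk_estimate, x$risk_se))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC is computed as the Mann-Whitney probability that a randomly chosen
#' positive-class score exceeds a randomly chosen negative-class score, with
#' ties counted 1/2 (rank statistic, exact under ties). The full curve is
#' returned at thresholds midway between consecutive distinct scores plus
#' sentinels.
#'
#' @param scores numeric vector.
#' @param labels vector; `positive` names the positive class.
#' @param positive the positive-class label (default `"AD"`).
#' @param larger_indicates_positive if `FALSE` the scores are reversed first,
#'   so that AUC >= 0.5 always means discrimination in the stated direction
#'   (use for measures where a *lower* score is more positive-like).
#' @return A list with class `"roc_result"`: `auc`, `curve` (data frame
#'   `threshold`, `fpr`, `tpr`, for the rule score > threshold), `positive`,
#'   `n_positive`, `n_negative`.
#' @export
roc_auc <- function(scores, labels, positive = "AD",
                    larger_indicates_positive = TRUE) {
  stopifnot(length(scores) == length(labels))
  is_pos <- as.character(labels) == positive
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  s <- if (larger_indicates_positive) as.numeric(scores) else -as.numeric(scores)
  r <- rank(s)                                    # midranks handle ties
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  us <- sort(unique(s))
  thresholds <- c(-Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2,
                  Inf)
  thresholds <- sort(c(thresholds, us))           # step corners included
  curve <- do.call(rbind, lapply(rev(thresholds), function(th) {
    data.frame(threshold = th,
               fpr = sum(s[!is_pos] > th) / n0,
               tpr = sum(s[is_pos] > th) / n1)
  }))
  rownames(curve) <- NULL
  structure(list(auc = auc, curve = curve, positive = positive,
                 n_positive = n1, n_negative = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (positive class %s; %d vs %d)\n",
              x$auc, x$positive, x$n_positive, x$n_negative))
  invisible(x)
}

#' AUC table over Box Task measures
#'
#' Computes the AUC of every per-set-size Box Task measure for separating
#' two groups (by default AD from bvFTD). Error and time measures are
#' oriented so that higher values indicate the positive class; the strategy
#' score likewise (less efficient search is more impaired).
#'
#' @param per_set_size long score table from [score_cohort()] (columns
#'   `participant_id`, `group`, `set_size` and the aggregated measures).
#' @param groups length-2 character; `groups[1]` is the positive class.
#' @return Data frame with one row per measure and set size: `measure`,
#'   `set_size`, `auc`, `n_positive`, `n_negative`.
#' @export
auc_table <- function(per_set_size, groups = c("AD", "bvFTD")) {
  d <- per_set_size[per_set_size$group %in% groups, ]
  measures <- c("between_mean", "within_mean", "time_mean", "strategy_mean")
  out <- list()
  for (m in measures) {
    for (n in sort(unique(d$set_size))) {
      di <- d[d$set_size == n, ]
      r <- roc_auc(di[[m]], di$group, positive = groups[1],
                   larger_indicates_positive = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        measure = m, set_size = n, auc = r$auc,
        n_positive = r$n_positive, n_negative = r$n_negative)
    }
  }
  do.call(rbind, out)
}
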