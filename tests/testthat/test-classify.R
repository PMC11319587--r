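test_that("the fixed tree agrees with its four-path truth table everywhere", {
  grid <- expand.grid(ace = seq(0, 100, by = 4), ws6 = 0:6, bs4 = 0:10)
  got <- classify_published_tree(grid$ace, grid$ws6, grid$bs4)
  want <- vapply(seq_len(nrow(grid)), function(i) {
    tree_truth_table(grid$ace[i], grid$ws6[i], grid$bs4[i])
  }, character(1))
  expect_equal(got, want)

  # boundary convention: exactly 70 takes the lower branch
  expect_equal(classify_published_tree(70, 5, 0), "bvFTD")
  expect_equal(classify_published_tree(70, 0, 2), "AD")
  expect_equal(classify_published_tree(71, 1, 0), "AD")

  expect_error(classify_published_tree(101, 0, 0), "out of range")
  expect_error(classify_published_tree(-1, 0, 0), "out of range")
})

test_that("classifier evaluation reproduces textbook arithmetic", {
  expect_equal(evaluate_classifier(c("AD", "bvFTD"), c("AD", "bvFTD"))$risk_estimate, 0)

  # 21/28 AD and 23/28 bvFTD correct
  labels <- c(rep("AD", 28), rep("bvFTD", 28))
  preds <- c(rep("AD", 21), rep("bvFTD", 7), rep("bvFTD", 23), rep("AD", 5))
  ev <- evaluate_classifier(preds, labels)
  expect_equal(unname(ev$per_class_pct_correct["AD"]), 75)
  expect_equal(unname(ev$per_class_pct_correct["bvFTD"]), 82.1, tolerance = 1e-3)
  expect_equal(ev$overall_pct_correct, 100 * 44 / 56)
  expect_equal(ev$risk_estimate, 12 / 56)
  expect_equal(ev$risk_se, sqrt((12 / 56) * (44 / 56) / 56))

  expect_error(evaluate_classifier(character(0), character(0)), "empty")
})

test_that("roc_auc equals the pair-counting oracle and behaves at extremes", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c("b", "b", "AD", "AD"))$auc, 1)
  expect_equal(roc_auc(rep(3, 6), rep(c("AD", "b"), 3))$auc, 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 4), c("n", "n", "AD", "AD"))$auc,
               auc_paircount(c(1, 2, 3, 4), c("n", "n", "AD", "AD"), "AD"))

  set.seed(55)
  for (r in 1:100) {
    n <- sample(4:12, 1)
    labels <- c("AD", "bvFTD", sample(c("AD", "bvFTD"), n - 2, replace = TRUE))
    scores <- sample(0:5, n, replace = TRUE)  # integer scores force ties
    res <- roc_auc(scores, labels)
    expect_equal(res$auc, auc_paircount(scores, labels, "AD"))
    # curve is monotone from (0,0) to (1,1)
    expect_equal(res$curve$fpr[1], 0)
    expect_equal(res$curve$tpr[1], 0)
    expect_equal(res$curve$fpr[nrow(res$curve)], 1)
    expect_equal(res$curve$tpr[nrow(res$curve)], 1)
    expect_true(all(diff(res$curve$fpr) >= 0))
    expect_true(all(diff(res$curve$tpr) >= 0))
    # orientation complement for tie-free scores
    sc2 <- seq_len(n) + stats::runif(n, 0, 0.2)
    expect_equal(roc_auc(sc2, labels)$auc +
                   roc_auc(-sc2, labels)$auc, 1)
  }

  # independent reference implementation
  set.seed(56)
  scores <- rnorm(40)
  labels <- sample(c("AD", "bvFTD"), 40, replace = TRUE)
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("bvFTD", "AD"),
                                              direction = "<", quiet = TRUE))))

  expect_error(roc_auc(1:4, rep("AD", 4)), "both classes")
})

test_that("CHAID splits a perfectly separable feature once with full accuracy", {
  set.seed(8)
  x <- c(rnorm(40, 0), rnorm(40, 10))
  labels <- rep(c("bvFTD", "AD"), each = 40)
  feats <- data.frame(score = x, noise = rnorm(80))
  tree <- fit_chaid(feats, labels, chaid_params(min_node_size = 5))
  expect_equal(tree$root$predictor, "score")
  expect_equal(chaid_depth(tree), 1L)
  expect_equal(mean(predict(tree, feats) == labels), 1)
})

test_that("CHAID honours the forced-first predictor at the root", {
  set.seed(12)
  n <- 120
  strong <- rnorm(n)
  weakish <- strong * 0.3 + rnorm(n)
  labels <- ifelse(strong > 0, "AD", "bvFTD")
  feats <- data.frame(strong = strong, weakish = weakish)
  tree <- fit_chaid(feats, labels,
                    chaid_params(forced_first = "weakish", max_depth = 1))
  expect_equal(tree$root$predictor, "weakish")
  expect_error(fit_chaid(feats, labels, chaid_params(forced_first = "absent")),
               "forced_first")
})

test_that("CHAID's split test controls type-I error on permuted labels", {
  set.seed(33)
  n <- 60
  root_only <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    feats <- data.frame(a = rnorm(n), b = rnorm(n), c = sample(0:5, n, TRUE))
    labels <- sample(rep(c("AD", "bvFTD"), n / 2))
    tree <- fit_chaid(feats, labels, chaid_params(min_node_size = 10))
    if (chaid_depth(tree) == 0L) root_only <- root_only + 1L
  }
  expect_gte(root_only, 0.9 * n_rep)
})

test_that("CHAID recovers the published cut-offs from tree-generated data", {
  set.seed(5)
  n <- 400
  low <- runif(n) < 0.5
  ace <- ifelse(low, runif(n, 40, 70), runif(n, 70.5, 100))
  ad_leaf <- ifelse(low, runif(n) < 0.8, runif(n) < 0.3)
  ws6 <- ifelse(!low & ad_leaf, sample(1:4, n, replace = TRUE), 0L)
  bs4 <- ifelse(low & ad_leaf, sample(2:6, n, replace = TRUE),
                sample(0:1, n, replace = TRUE))
  labels <- classify_published_tree(ace, ws6, bs4)
  feats <- data.frame(ace_total = ace, ws6_sum = ws6, bs4_sum = bs4)
  tree <- fit_chaid(feats, labels,
                    chaid_params(forced_first = "ace_total", max_depth = 2))

  expect_equal(tree$root$predictor, "ace_total")
  # the first root cut sits within one candidate bin (~5% of n quantile
  # spacing, about 3 ACE points here) of the published 70
  expect_lt(abs(tree$root$cuts[1] - 70), 3.5)
  # the lowest-ACE child uses 4-box between-search errors at >= 2
  left <- tree$root$children[[1]]
  expect_false(left$is_leaf)
  expect_equal(left$predictor, "bs4_sum")
  expect_equal(left$cuts[1], 1)
  # every higher-ACE child that splits uses 6-box within-search errors at >= 1
  for (ch in tree$root$children[-1]) {
    expect_false(ch$is_leaf)
    expect_equal(ch$predictor, "ws6_sum")
    expect_equal(ch$cuts[1], 0)
  }
  # training accuracy is essentially perfect on separable data
  expect_gte(mean(predict(tree, feats) == labels), 0.97)
})

test_that("fit_chaid rejects degenerate inputs", {
  feats <- data.frame(x = rnorm(30))
  expect_error(fit_chaid(feats, rep("AD", 30)), ">= 2 classes")
  expect_error(fit_chaid(feats[1:6, , drop = FALSE],
                         rep(c("AD", "bvFTD"), 3),
                         chaid_params(min_node_size = 10)),
               "min_node_size")
})
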