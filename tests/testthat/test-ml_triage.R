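planted <- make_fixture("planted-rule", n = 400, n_noise = 9, seed = 3)
truth <- attr(planted, "ground_truth")
feats <- setdiff(names(planted), "label")

test_that("permutation importance recovers a planted threshold rule", {
  imp <- rf_importance(planted, feats, n_trees = 300, seed = 5)
  expect_s3_class(imp, "importance_ranking")
  expect_equal(imp$parameter[1], truth$feature)
  expect_equal(imp$importance[1], 100)
  expect_equal(min(imp$importance), 0)
  expect_true(all(diff(imp$importance) <= 0))
})

test_that("a constant feature scores zero after normalization", {
  tab <- planted
  tab$f_const <- 1
  imp <- rf_importance(tab, c(feats, "f_const"), n_trees = 200, seed = 5)
  expect_equal(imp$importance[imp$parameter == "f_const"], 0)
})

test_that("duplicated informative features both outrank the noise", {
  tab <- planted
  tab$f_signal2 <- tab$f_signal
  imp <- rf_importance(tab, c(feats, "f_signal2"), n_trees = 300, seed = 5)
  sig <- imp$importance[imp$parameter %in% c("f_signal", "f_signal2")]
  noise <- imp$importance[grepl("f_noise", imp$parameter)]
  expect_true(min(sig) > max(noise))
})

test_that("importance requires exactly two classes", {
  one <- planted[planted$label == "control", ]
  expect_error(rf_importance(one, feats),
               class = "vpaxis_degenerate_labels")
})

test_that("tree root threshold falls in the separating gap (oracle-checked)", {
  # 1-D separable data with a gap: any midpoint in (2, 4) is Gini-optimal
  tab <- data.frame(x = c(seq(0, 2, by = 0.25), seq(4, 6, by = 0.25)),
                    label = rep(c("control", "higher"), each = 9))
  # brute-force oracle: best impurity over all midpoints between sorted x
  xs <- sort(tab$x)
  mids <- (xs[-1] + xs[-length(xs)]) / 2
  gini <- vapply(mids, function(m) {
    for_split <- function(sel) {
      if (!sum(sel)) return(0)
      p <- mean(tab$label[sel] == "higher")
      sum(sel) * 2 * p * (1 - p)
    }
    (for_split(tab$x < m) + for_split(tab$x >= m)) / nrow(tab)
  }, numeric(1))
  best <- mids[gini == min(gini)]
  expect_true(all(best > 2 & best < 4))
  fit <- fit_tree(tab, "x", max_depth = 2, min_leaf = 2)
  expect_equal(fit$node$split, "x")
  expect_gt(fit$node$threshold, 2)
  expect_lt(fit$node$threshold, 4)
  expect_equal(fit$node$left$majority_fraction, 1)
  expect_equal(fit$node$right$majority_fraction, 1)
})

test_that("tree structure conserves counts and bounds leaf purity", {
  fit <- fit_tree(planted, feats, max_depth = 3)
  walk <- function(node) {
    expect_gte(node$majority_fraction, 0.5)
    expect_lte(node$majority_fraction, 1)
    if (!is.null(node$split)) {
      expect_equal(node$left$n + node$right$n, node$n)
      expect_equal(node$left$counts + node$right$counts, node$counts)
      walk(node$left); walk(node$right)
    }
  }
  walk(fit$node)
  expect_equal(fit$node$n, nrow(planted))
})

test_that("a pure table yields a single leaf and depth 1 splits the planted feature", {
  tab <- planted[planted$label == "control", ]
  fit <- fit_tree(tab, feats, max_depth = 3)
  expect_null(fit$node$split)
  expect_equal(fit$node$majority_fraction, 1)
  d1 <- fit_tree(planted, feats, max_depth = 1)
  expect_equal(d1$node$split, truth$feature)
  expect_null(d1$node$left$split)
  expect_null(d1$node$right$split)
})

test_that("rule_fraction counts match hand counts and conserve totals", {
  toy <- data.frame(x = c(1, 2, 3, 4, 5, 6),
                    label = c("a", "a", "b", "b", "b", "a"))
  rf <- rule_fraction(toy, ~ x <= 3)
  expect_equal(rf$n, 3)
  expect_equal(rf$counts, c(a = 2, b = 1))
  expect_equal(rf$percent, c(a = 67, b = 33))
  all_rows <- rule_fraction(toy, ~ x == x)
  expect_equal(unname(all_rows$percent), c(50, 50))
  comp <- rule_fraction(toy, ~ x > 3)
  expect_equal(rf$counts + comp$counts, c(a = 3, b = 3))
  none <- rule_fraction(toy, ~ x > 100)
  expect_true(none$empty)
  expect_true(all(is.na(none$percent)))
})

test_that("SVM separates well-separated clusters through the midline", {
  set.seed(8)
  n <- 80
  tab <- data.frame(
    f1 = c(rnorm(n, -2, 0.4), rnorm(n, 2, 0.4)),
    f2 = c(rnorm(n, -2, 0.4), rnorm(n, 2, 0.4)),
    label = rep(c("control", "higher"), each = n))
  sv <- svm_train(tab, c("f1", "f2"), seed = 1)
  expect_equal(mean(predict(sv, tab[, 1:2]) == tab$label), 1.0)
  # decision values change sign across the midline between the centroids
  d <- sv$decision_function(data.frame(f1 = c(-2, 2), f2 = c(-2, 2)))
  expect_lt(d[1] * d[2], 0)
  mid <- abs(sv$decision_function(data.frame(f1 = 0, f2 = 0)))
  expect_lt(mid, min(abs(d)))
})

test_that("SVM boundary inherits a reflection symmetry of the data", {
  set.seed(12)
  x <- runif(120, 0.2, 2)
  y <- runif(120, -2, 2)
  tab <- data.frame(f1 = c(x, -x), f2 = c(y, y),
                    label = rep(c("higher", "control"), each = 120))
  sv <- svm_train(tab, c("f1", "f2"), seed = 2)
  probe <- expand.grid(f1 = seq(0.2, 1.8, by = 0.4),
                       f2 = seq(-1.5, 1.5, by = 0.5))
  d_right <- sv$decision_function(probe)
  d_left <- sv$decision_function(transform(probe, f1 = -f1))
  # reflected probes get (near) opposite decisions
  expect_lt(max(abs(d_right + d_left)), 0.2 * max(abs(d_right)))
})

test_that("contradictory degenerate input is rejected, not silently fit", {
  tab <- data.frame(f1 = rep(1, 10), f2 = rep(2, 10),
                    label = rep(c("a", "b"), 5))
  expect_error(svm_train(tab, c("f1", "f2")), "degenerate")
  one <- data.frame(f1 = rnorm(10), f2 = rnorm(10), label = "a")
  expect_error(svm_train(one, c("f1", "f2")),
               class = "vpaxis_degenerate_labels")
})

test_that("cross-validation partitions rows and scores sensibly", {
  fit_fun <- function(train) fit_tree(train, feats, max_depth = 3)
  cv <- cross_validate(fit_fun, planted, k = 10, seed = 3)
  expect_length(cv$fold_accuracy, 10)
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_equal(length(cv$folds), nrow(planted))
  # planted rule with 5% label noise: accuracy near 95%
  expect_gt(cv$mean_accuracy, 0.85)
  # separable data: perfect accuracy
  set.seed(6)
  sep <- data.frame(x = c(runif(50, 0, 1), runif(50, 3, 4)),
                    label = rep(c("a", "b"), each = 50))
  cv2 <- cross_validate(function(tr) fit_tree(tr, "x", max_depth = 2),
                        sep, k = 5, seed = 1)
  expect_equal(cv2$mean_accuracy, 1.0)
  expect_error(cross_validate(fit_fun, planted[1:15, ], k = 10),
               "smallest class")
})

test_that("shuffled labels give chance-level accuracy", {
  set.seed(21)
  shuf <- planted
  shuf$label <- sample(shuf$label)
  cv <- cross_validate(function(tr) fit_tree(tr, feats, max_depth = 3),
                       shuf, k = 10, seed = 2)
  se <- sqrt(0.25 / nrow(shuf))
  expect_lt(abs(cv$mean_accuracy - 0.5), 3 * se + 0.05)
})

test_that("forest, tree and SVM agree on the informative feature", {
  imp <- rf_importance(planted, feats, n_trees = 300, seed = 5)
  expect_equal(imp$parameter[1], truth$feature)
  tr <- fit_tree(planted, feats, max_depth = 3)
  expect_equal(tr$node$split, truth$feature)
  expect_gt(tr$node$threshold, truth$gap[1])
  expect_lt(tr$node$threshold, truth$gap[2])
  # SVM trained on the top-2 forest features separates along f_signal
  sv <- svm_train(planted, imp$parameter[1:2], seed = 2)
  lo <- data.frame(a = 0.1, b = 0.5); hi <- data.frame(a = 0.9, b = 0.5)
  names(lo) <- names(hi) <- imp$parameter[1:2]
  expect_lt(sv$decision_function(lo) * sv$decision_function(hi), 0)
})

test_that("rankings and trees export to JSON", {
  imp <- rf_importance(planted, feats, n_trees = 100, seed = 5)
  p1 <- tempfile(fileext = ".json")
  write_importance_json(imp, p1)
  back <- jsonlite::read_json(p1, simplifyVector = TRUE)
  expect_equal(back$parameter, imp$parameter)
  expect_equal(back$importance, imp$importance, tolerance = 1e-12)
  tr <- fit_tree(planted, feats, max_depth = 2)
  p2 <- tempfile(fileext = ".json")
  write_tree_json(tr, p2)
  back2 <- jsonlite::read_json(p2)
  expect_equal(back2$root$split, tr$node$split)
  expect_equal(back2$root$n, tr$node$n)
})
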