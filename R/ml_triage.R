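two_class_xy <- function(table, features, classes = NULL) {
  if (is.null(classes)) classes <- unique(as.character(table$label))
  table <- table[table$label %in% classes, , drop = FALSE]
  y <- factor(as.character(table$label))
  if (nlevels(y) != 2L)
    stop(structure(class = c("vpaxis_degenerate_labels", "error",
                             "condition"),
                   list(message = paste0("exactly two classes required, got: ",
                                         paste(levels(y), collapse = ", ")),
                        call = sys.call(-1))))
  missing <- setdiff(features, names(table))
  if (length(missing))
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  x <- table[, features, drop = FALSE]
  if (!all(vapply(x, is.numeric, logical(1))))
    stop("all features must be numeric")
  list(x = x, y = y)
}

#' Random-forest permutation importance
#'
#' Fits a bootstrap ensemble of classification trees on a two-class
#' population table and scores each feature by the mean out-of-bag accuracy
#' drop when that feature's values are permuted, then min-max normalizes the
#' scores so the most important feature scores exactly 100 and the least
#' important exactly 0.
#'
#' @param table a \code{\link{build_population}} table (or any data frame
#'   with a \code{label} column).
#' @param features character vector of feature column names.
#' @param classes the two labels to compare (default: the labels present).
#' @param n_trees number of trees.
#' @param mtry features tried per split (default \code{floor(sqrt(p))}).
#' @param seed RNG seed for the forest.
#' @return a \code{data.frame} of class \code{"importance_ranking"} with
#'   columns \code{parameter}, \code{importance} (0--100, descending) and
#'   \code{raw} (unnormalized mean accuracy decrease); the fitted forest is
#'   kept in attribute \code{"forest"}.
#' @export
rf_importance <- function(table, features, classes = NULL, n_trees = 500,
                          mtry = max(1, floor(sqrt(length(features)))),
                          seed = 1L) {
  d <- two_class_xy(table, features, classes)
  set.seed(seed)
  fit <- randomForest::randomForest(x = d$x, y = d$y, ntree = n_trees,
                                    mtry = mtry, importance = TRUE)
  raw <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  # a negative out-of-bag accuracy drop is permutation noise; floor at zero
  # so that uninformative features share the minimum of the 0-100 scale
  floored <- pmax(raw, 0)
  rng <- range(floored)
  score <- if (diff(rng) == 0) rep(0, length(floored)) else
    100 * (floored - rng[1]) / diff(rng)
  ord <- order(score, decreasing = TRUE)
  out <- data.frame(parameter = features[ord], importance = score[ord],
                    raw = raw[ord], row.names = NULL)
  attr(out, "forest") <- fit
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Fit a depth-limited classification tree
#'
#' Greedy recursive partitioning (Gini impurity) with split thresholds at
#' midpoints between adjacent observed values, limited by depth and minimum
#' leaf size; delegates the partitioning to \code{rpart} and re-expresses the
#' fit as an explicit node structure with per-node class counts.
#'
#' @inheritParams rf_importance
#' @param max_depth maximum tree depth (root split = depth 1).
#' @param min_leaf minimum observations in a leaf.
#' @return an object of class \code{"decision_tree"}: list with
#'   \code{node} (the recursive node structure), \code{classes}, and the
#'   underlying \code{rpart} fit. Each node carries \code{n}, \code{counts},
#'   \code{majority}, \code{majority_fraction}, and for internal nodes
#'   \code{split} (feature), \code{threshold} and \code{left_if} (the
#'   predicate sending a row to the left child).
#' @export
fit_tree <- function(table, features, classes = NULL, max_depth = 3,
                     min_leaf = 7) {
  if (max_depth < 1) stop("max_depth must be >= 1")
  if (nrow(table) == 0L) stop("empty table")
  if (is.null(classes)) classes <- unique(as.character(table$label))
  if (length(classes) == 1L) {
    # pure table: a single leaf, no split
    n <- sum(table$label == classes)
    node <- list(n = n, counts = stats::setNames(n, classes),
                 majority = classes, majority_fraction = 1)
    return(structure(list(node = node, classes = classes, rpart = NULL),
                     class = "decision_tree"))
  }
  d <- two_class_xy(table, features, classes)
  if (nrow(d$x) == 0L) stop("empty table")
  df <- cbind(d$x, .label = d$y)
  fit <- rpart::rpart(
    .label ~ ., data = df, method = "class",
    control = rpart::rpart.control(maxdepth = max_depth,
                                   minbucket = min_leaf,
                                   minsplit = max(2, 2 * min_leaf),
                                   cp = 0, xval = 0, maxcompete = 0,
                                   maxsurrogate = 0))
  node <- rpart_to_nodes(fit, levels(d$y))
  structure(list(node = node, classes = levels(d$y), rpart = fit),
            class = "decision_tree")
}

# convert an rpart frame (maxcompete = maxsurrogate = 0) into nested nodes
rpart_to_nodes <- function(fit, classes) {
  fr <- fit$frame
  nums <- as.integer(rownames(fr))
  counts_mat <- fr$yval2[, 1 + seq_along(classes), drop = FALSE]
  # rows of fit$splits correspond, in frame order, to the non-leaf rows
  split_row <- integer(nrow(fr))
  split_row[fr$var != "<leaf>"] <- seq_len(sum(fr$var != "<leaf>"))
  build <- function(num) {
    i <- match(num, nums)
    counts <- stats::setNames(as.numeric(counts_mat[i, ]), classes)
    maj <- which.max(counts)
    node <- list(n = sum(counts), counts = counts,
                 majority = classes[maj],
                 majority_fraction = counts[[maj]] / max(1, sum(counts)))
    if (fr$var[i] == "<leaf>") return(node)
    s <- fit$splits[split_row[i], , drop = TRUE]
    node$split <- as.character(fr$var[i])
    node$threshold <- unname(s["index"])
    node$left_if <- if (s["ncat"] < 0) "<" else ">="
    node$left <- build(2L * num)
    node$right <- build(2L * num + 1L)
    node
  }
  build(1L)
}

#' @export
print.decision_tree <- function(x, ...) {
  rec <- function(node, indent, head) {
    pct <- round(100 * node$majority_fraction)
    cat(sprintf("%s%s n=%d  %s %d%%\n", strrep("  ", indent), head,
                node$n, node$majority, pct))
    if (!is.null(node$split)) {
      rec(node$left, indent + 1,
          sprintf("[%s %s %.4g] ", node$split, node$left_if,
                  node$threshold))
      op <- if (node$left_if == "<") ">=" else "<"
      rec(node$right, indent + 1,
          sprintf("[%s %s %.4g] ", node$split, op, node$threshold))
    }
  }
  rec(x$node, 0, "")
  invisible(x)
}

#' @export
predict.decision_tree <- function(object, newdata, ...) {
  if (is.null(object$rpart))
    return(rep(object$classes, nrow(as.data.frame(newdata))))
  cls <- predict(object$rpart, newdata = newdata, type = "class")
  as.character(cls)
}

#' Export a decision tree as JSON
#'
#' @param tree a \code{"decision_tree"}.
#' @param path output path.
#' @export
write_tree_json <- function(tree, path) {
  strip <- function(node) {
    out <- node[intersect(names(node),
                          c("n", "counts", "majority", "majority_fraction",
                            "split", "threshold", "left_if"))]
    out$counts <- as.list(node$counts)
    if (!is.null(node$split)) {
      out$left <- strip(node$left)
      out$right <- strip(node$right)
    }
    out
  }
  jsonlite::write_json(list(classes = tree$classes,
                            root = strip(tree$node)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Class composition of the rows satisfying a predicate
#'
#' Counts each label among the rows of a population table that satisfy a
#' predicate, with percentages; used to reproduce printed node purities such
#' as the share of control patients under a threshold rule.
#'
#' @param table a data frame with a \code{label} column.
#' @param predicate either a one-sided formula evaluated in the table (e.g.
#'   \code{~ R_CRH_CRH >= 4.5}) or a function mapping the table to a logical
#'   vector.
#' @param digits rounding for the reported percentages (default 0, i.e.
#'   nearest integer percent).
#' @return list with \code{n} (rows selected), \code{counts},
#'   \code{percent} (composition of the selection, NA when the selection is
#'   empty) and \code{empty}.
#' @export
rule_fraction <- function(table, predicate, digits = 0) {
  sel <- if (inherits(predicate, "formula")) {
    as.logical(eval(predicate[[2]], envir = table, enclos = parent.frame()))
  } else if (is.function(predicate)) {
    as.logical(predicate(table))
  } else stop("predicate must be a one-sided formula or a function")
  if (length(sel) != nrow(table) || anyNA(sel))
    stop("predicate must yield one non-NA logical per row")
  labs <- sort(unique(as.character(table$label)))
  counts <- stats::setNames(
    vapply(labs, function(l) sum(table$label[sel] == l), numeric(1)), labs)
  n <- sum(sel)
  pct <- if (n == 0) stats::setNames(rep(NA_real_, length(labs)), labs) else
    round(100 * counts / n, digits)
  list(n = n, counts = counts, percent = pct, empty = n == 0)
}

#' Train a two-feature SVM boundary
#'
#' Soft-margin support-vector classifier on two features, radial-basis
#' kernel with unit bandwidth after feature standardization; the decision
#' boundary is the zero level set of the continuous decision function over
#' the feature plane.
#'
#' @inheritParams rf_importance
#' @param features exactly two feature names.
#' @param kernel kernel type for \code{e1071::svm}.
#' @param cost soft-margin cost.
#' @param gamma RBF bandwidth parameter (0.5 = unit-variance Gaussian on
#'   standardized features).
#' @return an object of class \code{"svm_boundary"}: list with
#'   \code{features}, \code{classes}, the fitted model, and
#'   \code{decision_function(newdata)} returning signed decision values
#'   (positive predicts \code{classes[1]}).
#' @export
svm_train <- function(table, features, classes = NULL, kernel = "radial",
                      cost = 1, gamma = 0.5, seed = 1L) {
  if (length(features) != 2L) stop("exactly two features required")
  d <- two_class_xy(table, features, classes)
  if (max(vapply(d$x, function(col) diff(range(col)), numeric(1))) == 0 &&
      nlevels(d$y) == 2L)
    stop("degenerate input: identical feature rows with conflicting labels")
  set.seed(seed)
  fit <- e1071::svm(x = d$x, y = d$y, kernel = kernel, cost = cost,
                    gamma = gamma, scale = TRUE)
  obj <- list(features = features, classes = levels(d$y), model = fit)
  obj$decision_function <- function(newdata) {
    newdata <- as.data.frame(newdata)
    names(newdata) <- features
    dv <- attr(predict(fit, newdata, decision.values = TRUE),
               "decision.values")
    sgn <- if (grepl(paste0("^", obj$classes[1], "/"), colnames(dv)[1]))
      1 else -1
    sgn * dv[, 1]
  }
  class(obj) <- "svm_boundary"
  obj
}

#' @export
print.svm_boundary <- function(x, ...) {
  cat("SVM boundary over (", paste(x$features, collapse = ", "),
      "); classes: ", paste(x$classes, collapse = " vs "), "; ",
      x$model$tot.nSV, " support vectors\n", sep = "")
  invisible(x)
}

#' @export
predict.svm_boundary <- function(object, newdata, ...) {
  ifelse(object$decision_function(newdata) > 0, object$classes[1],
         object$classes[2])
}

#' Stratified k-fold cross-validation
#'
#' Splits the table into k folds stratified by label, fits on each training
#' complement with \code{fit_fun} and scores accuracy on the held-out fold;
#' every row is tested exactly once.
#'
#' @param fit_fun function taking a training data frame (with its
#'   \code{label} column) and returning a model for which
#'   \code{predict(model, newdata)} yields class labels.
#' @param table data frame with a \code{label} column.
#' @param k number of folds (>= 2, at most the smallest class count).
#' @param seed RNG seed for fold assignment.
#' @return list with \code{mean_accuracy}, \code{fold_accuracy} and the
#'   fold assignment \code{folds}.
#' @export
cross_validate <- function(fit_fun, table, k = 10, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (nrow(table) < k) stop("table has fewer rows than folds")
  y <- as.character(table$label)
  if (min(table(y)) < k)
    stop("k exceeds the size of the smallest class")
  set.seed(seed)
  folds <- integer(nrow(table))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  acc <- vapply(seq_len(k), function(f) {
    train <- table[folds != f, , drop = FALSE]
    test <- table[folds == f, , drop = FALSE]
    model <- fit_fun(train)
    mean(as.character(predict(model, test)) == y[folds == f])
  }, numeric(1))
  list(mean_accuracy = mean(acc), fold_accuracy = acc, folds = folds)
}

#' Export an importance ranking as JSON
#'
#' @param ranking an \code{"importance_ranking"}.
#' @param path output path.
#' @export
write_importance_json <- function(ranking, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(ranking)), function(i)
      list(parameter = ranking$parameter[i],
           importance = ranking$importance[i])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
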