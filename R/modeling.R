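# Stratified calibration/prediction split, SVM-RBF with cross-validated grid
# search, random forest (50 trees) and KNN classifiers, and evaluation with a
# fixed-order confusion matrix and the moldy-as-healthy safety count.

#' Stratified calibration/prediction split
#'
#' Randomly partitions each class at the 3:1 ratio (60 samples per level give
#' 45 calibration and 15 prediction). When a class size is not divisible the
#' prediction share is floored and the remainder goes to calibration.
#'
#' @param labels class labels (factor or coercible).
#' @param prediction_fraction held-out fraction (default 1/4).
#' @param seed integer seed; the assignment is reproducible from it.
#' @return List of class `split_assignment`: `calibration` and `prediction`
#'   index vectors, per-class `counts`, and the `seed`.
#' @export
stratified_split <- function(labels, prediction_fraction = 0.25, seed = 1L) {
  y <- as.factor(labels)
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  set.seed(seed)
  pred <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_pred <- floor(length(idx) * prediction_fraction)
    if (n_pred >= 1)
      pred <- c(pred, sample(idx, n_pred))
  }
  pred <- sort(pred)
  cal <- setdiff(seq_along(y), pred)
  structure(list(calibration = cal, prediction = pred,
                 counts = table(truth = y, set = ifelse(
                   seq_along(y) %in% pred, "prediction", "calibration")),
                 seed = as.integer(seed)),
            class = "split_assignment")
}

#' Evaluate predictions against true labels
#'
#' Builds the confusion matrix in fixed class order (healthy through severe
#' when grading mold), per-class and overall accuracy, and the
#' moldy-as-healthy count — moldy samples misclassified as healthy, the
#' safety-critical error mode.
#'
#' @param predicted,truth label vectors of equal length.
#' @param class_levels class order for the confusion matrix (defaults to the
#'   levels of `truth`).
#' @return List: `confusion` (rows = truth, cols = predicted), `accuracy`
#'   (percent), `per_class_accuracy` (percent), `moldy_as_healthy`.
#' @export
evaluate_predictions <- function(predicted, truth, class_levels = NULL) {
  if (is.null(class_levels))
    class_levels <- levels(as.factor(truth))
  if (!all(as.character(predicted) %in% class_levels) ||
      !all(as.character(truth) %in% class_levels))
    stop("labels outside the declared classes")
  pr <- factor(as.character(predicted), levels = class_levels)
  tr <- factor(as.character(truth), levels = class_levels)
  cm <- table(truth = tr, predicted = pr)
  acc <- 100 * sum(diag(cm)) / sum(cm)
  per_class <- 100 * diag(cm) / pmax(rowSums(cm), 1)
  list(confusion = cm, accuracy = acc, per_class_accuracy = per_class,
       moldy_as_healthy = sum(cm[-1, 1]))
}

# internal: assemble the standard classifier report
make_report <- function(classifier, hyper, model, pred_cal, pred_pred,
                        y_cal, y_pred, class_levels, seed) {
  ev_cal <- evaluate_predictions(pred_cal, y_cal, class_levels)
  ev_pred <- evaluate_predictions(pred_pred, y_pred, class_levels)
  structure(list(
    classifier = classifier, hyperparameters = hyper, model = model,
    calibration_accuracy = ev_cal$accuracy,
    prediction_accuracy = ev_pred$accuracy,
    overfitting_gap = abs(ev_cal$accuracy - ev_pred$accuracy),
    per_class_accuracy = ev_pred$per_class_accuracy,
    confusion = ev_pred$confusion,
    moldy_as_healthy = ev_pred$moldy_as_healthy,
    seed = seed), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<%s> calibration %.2f%% | prediction %.2f%% (gap %.2f)\n",
              x$classifier, x$calibration_accuracy, x$prediction_accuracy,
              x$overfitting_gap))
  print(x$confusion)
  invisible(x)
}

#' SVM-RBF classifier with cross-validated grid search
#'
#' Searches the cost and kernel-width grids (default `2^-8 .. 2^8` in
#' doubling steps) by stratified k-fold cross-validation on the calibration
#' rows, refits the best pair on the full calibration set, and reports
#' calibration and prediction accuracies. Features should already be scaled
#' (see [fit_scaling()]); the SVM's own rescaling is off.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param split a `split_assignment` from [stratified_split()].
#' @param cost_grid,gamma_grid hyperparameter grids.
#' @param folds CV folds for the grid search (default 5).
#' @param seed integer seed for fold assignment.
#' @return A `classifier_report` with the fitted model attached.
#' @export
train_svm <- function(X, y, split, cost_grid = 2^seq(-8, 8, 1),
                      gamma_grid = 2^seq(-8, 8, 1), folds = 5, seed = 1L) {
  y <- as.factor(y)
  cal <- split$calibration; prd <- split$prediction
  Xc <- unclass(X)[cal, , drop = FALSE]; yc <- droplevels(y[cal])
  fold <- stratified_folds(yc, folds, seed)
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid)
  cv_acc <- vapply(seq_len(nrow(grid)), function(i) {
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- e1071::svm(Xc[tr, , drop = FALSE], yc[tr], kernel = "radial",
                        cost = grid$cost[i], gamma = grid$gamma[i],
                        scale = FALSE)
      hits <- hits + sum(predict(fit, Xc[!tr, , drop = FALSE]) == yc[!tr])
    }
    hits / length(yc)
  }, numeric(1))
  best <- which.max(cv_acc)   # ties: first in grid order (smallest values)
  model <- e1071::svm(Xc, yc, kernel = "radial", cost = grid$cost[best],
                      gamma = grid$gamma[best], scale = FALSE)
  make_report("svm", list(cost = grid$cost[best], gamma = grid$gamma[best],
                          cv_accuracy = cv_acc[best]),
              model,
              predict(model, Xc),
              predict(model, unclass(X)[prd, , drop = FALSE]),
              yc, y[prd], levels(y), seed)
}

#' Random-forest classifier (50 trees)
#'
#' @inheritParams train_svm
#' @param n_trees number of trees (default 50).
#' @return A `classifier_report`.
#' @export
train_rf <- function(X, y, split, n_trees = 50, seed = 1L) {
  y <- as.factor(y)
  cal <- split$calibration; prd <- split$prediction
  Xc <- unclass(X)[cal, , drop = FALSE]; yc <- droplevels(y[cal])
  set.seed(seed)
  model <- randomForest::randomForest(Xc, yc, ntree = n_trees)
  make_report("rf", list(n_trees = n_trees), model,
              predict(model, Xc),
              predict(model, unclass(X)[prd, , drop = FALSE]),
              yc, y[prd], levels(y), seed)
}

# internal: pairwise distances between rows of A and B
pairwise_dist <- function(A, B, metric = c("euclidean", "cityblock")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    sqrt(pmax(d2, 0))
  } else {
    out <- matrix(0, nrow(A), nrow(B))
    for (i in seq_len(nrow(B)))
      out[, i] <- rowSums(abs(sweep(A, 2, B[i, ])))
    out
  }
}

# internal: KNN prediction; vote ties go to the smaller class index
knn_predict <- function(Xtr, ytr, Xte, k, metric) {
  D <- pairwise_dist(Xte, Xtr, metric)
  cls <- levels(ytr)
  out <- character(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    nn <- order(D[i, ], seq_len(ncol(D)))[seq_len(k)]
    votes <- table(factor(ytr[nn], levels = cls))
    out[i] <- cls[which.max(votes)]   # which.max: first max = smaller index
  }
  factor(out, levels = cls)
}

#' KNN classifier with cross-validated choice of k and metric
#'
#' Selects the neighbour count (odd, 1..15 by default) and the distance
#' metric (Euclidean or cityblock) by stratified CV on the calibration rows.
#' Vote ties are broken toward the smaller class index.
#'
#' @inheritParams train_svm
#' @param k_grid candidate neighbour counts.
#' @param metric_grid candidate distance metrics.
#' @return A `classifier_report`.
#' @export
train_knn <- function(X, y, split, k_grid = seq(1, 15, 2),
                      metric_grid = c("euclidean", "cityblock"),
                      folds = 5, seed = 1L) {
  y <- as.factor(y)
  cal <- split$calibration; prd <- split$prediction
  Xc <- unclass(X)[cal, , drop = FALSE]; yc <- droplevels(y[cal])
  if (any(k_grid > length(yc))) stop("k larger than calibration size")
  fold <- stratified_folds(yc, folds, seed)
  grid <- expand.grid(k = k_grid, metric = metric_grid,
                      stringsAsFactors = FALSE)
  cv_acc <- vapply(seq_len(nrow(grid)), function(i) {
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      pr <- knn_predict(Xc[tr, , drop = FALSE], droplevels(yc[tr]),
                        Xc[!tr, , drop = FALSE], grid$k[i], grid$metric[i])
      hits <- hits + sum(as.character(pr) == as.character(yc[!tr]))
    }
    hits / length(yc)
  }, numeric(1))
  best <- which.max(cv_acc)
  pred_cal <- knn_predict(Xc, yc, Xc, grid$k[best], grid$metric[best])
  pred_prd <- knn_predict(Xc, yc, unclass(X)[prd, , drop = FALSE],
                          grid$k[best], grid$metric[best])
  make_report("knn", list(k = grid$k[best], metric = grid$metric[best],
                          cv_accuracy = cv_acc[best]),
              NULL, pred_cal, pred_prd, yc, y[prd], levels(y), seed)
}
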