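#' Confusion-matrix performance metrics
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (FP + TN)`,
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, with the positive class
#' being the patient (neglect-like) group.
#'
#' @param tp,fp,tn,fn non-negative confusion counts; each class must be
#'   represented (`TP + FN > 0`, `TN + FP > 0`).
#' @return Named vector `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stopf("confusion counts must be >= 0")
  if (tp + fn == 0) stopf("no positive-class subjects (TP + FN = 0)")
  if (tn + fp == 0) stopf("no negative-class subjects (TN + FP = 0)")
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (fp + tn),
    accuracy = (tp + tn) / (tp + tn + fp + fn))
}

#' ROC curve and area under it
#'
#' Sweeps a decision threshold over the pooled scores (higher score =
#' more positive), stepping through tied scores simultaneously so ties
#' produce diagonal ROC segments; the area is the trapezoidal integral,
#' identical to the normalized Mann-Whitney U statistic with ties counted
#' one half.
#'
#' @param scores numeric decision scores.
#' @param labels group labels.
#' @param positive label of the positive class.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`,
#'   starting at (0,0) and ending at (1,1)) and `auc`. All-identical
#'   scores give `auc = 0.5` with a warning.
#' @export
roc_auc <- function(scores, labels, positive) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  if (length(unique(scores)) == 1L)
    warning("all decision scores identical; ROC is the chance diagonal")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  cuts <- c(Inf, unique(s))
  tpr <- fpr <- numeric(length(cuts))
  tp_cum <- cumsum(y); fp_cum <- cumsum(!y)
  last <- c(0L, vapply(unique(s), function(v) max(which(s == v)), integer(1)))
  tpr <- c(0, tp_cum[last[-1L]]) / n1
  fpr <- c(0, fp_cum[last[-1L]]) / n0
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(points = data.frame(threshold = cuts, fpr = fpr, tpr = tpr),
       auc = auc)
}

# accuracy of a linear SVM over k inner folds, used by the grid search
inner_cv_accuracy <- function(X, y, cost, kernel, k = 5L) {
  n <- nrow(X)
  folds <- rep_len(seq_len(k), n)
  correct <- 0L
  for (f in unique(folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) return(NA_real_)
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    if (any(sdv == 0)) return(NA_real_)
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    fit <- e1071::svm(Xtr, y[tr], kernel = kernel, cost = cost, scale = FALSE)
    correct <- correct + sum(stats::predict(fit, Xte) == y[!tr])
  }
  correct / n
}

#' Leave-one-out cross-validated SVM classification
#'
#' For each subject in turn, fits a support vector machine on all other
#' subjects and predicts the held-out one. Features are standardized by
#' the training fold's mean and standard deviation only — the held-out
#' subject never influences the standardization (the per-fold parameters
#' are returned so this can be audited). Default hyperparameters are a
#' linear kernel with cost `C = 3`; an optional grid is searched by inner
#' 5-fold cross-validation within each training fold.
#'
#' @param features matrix/data frame subjects x features, no NaN.
#' @param labels group labels, >= 2 subjects per class.
#' @param positive label of the positive (patient) class.
#' @param cost SVM penalty `C`.
#' @param kernel SVM kernel.
#' @param grid optional list with elements `cost` (numeric vector) and
#'   optionally `kernel` (character vector); when supplied, each training
#'   fold picks the combination with the best inner-CV accuracy.
#' @return Object of class `classifier_report`: per-subject predictions
#'   and decision scores, confusion counts, performance metrics, ROC
#'   points and area, hyperparameters, per-fold standardization
#'   parameters.
#' @export
loocv_svm <- function(features, labels, positive = "A", cost = 3,
                      kernel = "linear", grid = NULL) {
  X <- as.matrix(features)
  if (!all(is.finite(X))) stopf("features contain non-finite values")
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L)
    stopf("need exactly two classes, got %d", length(unique(labels)))
  if (!positive %in% labels) stopf("positive class '%s' absent from labels", positive)
  if (min(table(labels)) < 2L) stopf("need >= 2 subjects per class")
  n <- nrow(X)
  lev <- c(positive, setdiff(sort(unique(labels)), positive))
  y <- factor(labels, levels = lev)
  pred <- character(n)
  score <- numeric(n)
  fold_std <- vector("list", n)
  fold_par <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    if (any(sdv == 0))
      stopf("constant feature in training fold %d: %s", i,
            paste(colnames(X)[sdv == 0], collapse = ", "))
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    Xte <- sweep(sweep(X[i, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    par <- list(cost = cost, kernel = kernel)
    if (!is.null(grid)) {
      combos <- expand.grid(cost = grid$cost %||% cost,
                            kernel = grid$kernel %||% kernel,
                            stringsAsFactors = FALSE)
      acc <- mapply(function(cc, kk)
        inner_cv_accuracy(X[tr, , drop = FALSE], y[tr], cc, kk),
        combos$cost, combos$kernel)
      best <- which.max(acc)   # ties and all-NA fall back to the first combo
      if (length(best)) par <- list(cost = combos$cost[best],
                                    kernel = combos$kernel[best])
    }
    fit <- e1071::svm(Xtr, y[tr], kernel = par$kernel, cost = par$cost,
                      scale = FALSE)
    pr <- stats::predict(fit, Xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient the score so that larger = more positive-class
    sgn <- if (grepl(paste0("^", positive, "/"), colnames(dv)[1L])) 1 else -1
    pred[i] <- as.character(pr)
    score[i] <- sgn * dv[1L]
    fold_std[[i]] <- list(mean = mu, sd = sdv)
    fold_par[[i]] <- par
  }
  tp <- sum(pred == positive & labels == positive)
  fn <- sum(pred != positive & labels == positive)
  tn <- sum(pred != positive & labels != positive)
  fp <- sum(pred == positive & labels != positive)
  roc <- roc_auc(score, labels, positive)
  structure(list(predictions = data.frame(label = labels, predicted = pred,
                                          score = score),
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 metrics = confusion_metrics(tp, fp, tn, fn),
                 roc = roc$points, roc_auc = roc$auc,
                 hyperparameters = list(cost = cost, kernel = kernel,
                                        grid = grid),
                 fold_hyperparameters = fold_par,
                 fold_standardization = fold_std,
                 positive = positive),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<classifier_report> LOOCV linear SVM, positive class '%s'\n",
              x$positive))
  cat(sprintf("  counts: TP=%d FP=%d TN=%d FN=%d\n", x$counts["TP"],
              x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  cat(sprintf("  sensitivity %.3f | specificity %.3f | accuracy %.3f | ROC-AUC %.3f\n",
              m["sensitivity"], m["specificity"], m["accuracy"], x$roc_auc))
  invisible(x)
}
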