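# Classifier training/evaluation on masked feature tables and the
# confusion-matrix metric panel.

#' Confusion matrix for binary labels
#'
#' Tallies true/false positives and negatives against a declared positive
#' class (by convention the cancerous class).
#'
#' @param truth,predicted Equal-length binary label vectors (factor,
#'   character, or numeric with exactly two distinct values overall).
#' @param positive The label counted as positive.
#' @return An object of class `confusion_matrix`: a list with integer
#'   `TP`, `TN`, `FP`, `FN`.
#' @examples
#' confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 0), positive = 1)
#' @export
confusion_matrix <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  classes <- unique(c(truth, predicted))
  if (length(classes) > 2L) {
    stop("labels must be binary; found classes: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  positive <- as.character(positive)
  if (!positive %in% classes) {
    stop(sprintf("positive class '%s' not present among labels", positive),
         call. = FALSE)
  }
  tp <- sum(truth == positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (n = %d)\n", x$TP + x$TN + x$FP + x$FN))
  cat(sprintf("  TP = %d  FN = %d\n  FP = %d  TN = %d\n",
              x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Diagnostic metric panel from a confusion matrix
#'
#' Computes the five standard diagnostic indices, each as a percentage:
#' accuracy `(TP + TN) / n * 100`, sensitivity (recall) `TP / (TP + FN) *
#' 100`, specificity `TN / (TN + FP) * 100`, precision `TP / (TP + FP) *
#' 100`, and F1, the harmonic mean of recall and precision. A metric with a
#' zero denominator is undefined and raises an error naming the metric rather
#' than silently returning a sentinel.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `classification_metrics`: a list with
#'   `sensitivity`, `specificity`, `accuracy`, `precision`, `f1`, all in
#'   `[0, 100]`.
#' @examples
#' classification_metrics(confusion_matrix(rep(c(1, 0), c(3, 2)),
#'                                         rep(c(1, 0), c(3, 2)), positive = 1))
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$TP + cm$TN + cm$FP + cm$FN
  if (n == 0L) stop("confusion matrix has no samples", call. = FALSE)
  need <- function(den, metric) {
    if (den == 0L) {
      stop(sprintf("%s is undefined: its denominator is zero", metric),
           call. = FALSE)
    }
    den
  }
  sens <- cm$TP / need(cm$TP + cm$FN, "sensitivity") * 100
  spec <- cm$TN / need(cm$TN + cm$FP, "specificity") * 100
  prec <- cm$TP / need(cm$TP + cm$FP, "precision") * 100
  acc <- (cm$TP + cm$TN) / n * 100
  f1 <- 2 * sens * prec / need_num(sens + prec, "f1")
  structure(
    list(sensitivity = sens, specificity = spec, accuracy = acc,
         precision = prec, f1 = f1),
    class = "classification_metrics"
  )
}

need_num <- function(den, metric) {
  if (den == 0) {
    stop(sprintf("%s is undefined: its denominator is zero", metric),
         call. = FALSE)
  }
  den
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat("Classification metrics (%)\n")
  for (m in names(x)) cat(sprintf("  %-12s %7.3f\n", m, x[[m]]))
  invisible(x)
}

# Stratified fold assignment: within each class, indices are shuffled with
# the seed and dealt round-robin into k folds.
#' Stratified cross-validation folds
#'
#' @param labels Label vector.
#' @param k Number of folds.
#' @param seed Integer seed for the within-class shuffle.
#' @return Integer vector of fold ids in `1:k`, one per sample.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  assert_scalar_num(k, "k", lower = 2)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Fit the requested classifier on (x, y) and predict labels for newx.
# SVM: radial kernel, library defaults. Decision tree: default rpart controls.
fit_predict <- function(x, y, newx, classifier) {
  y <- factor(y)
  if (classifier == "svm") {
    model <- e1071::svm(x = x, y = y, kernel = "radial", scale = TRUE)
    as.character(stats::predict(model, newx))
  } else if (classifier == "decision_tree") {
    df <- data.frame(x, check.names = FALSE)
    names(df) <- paste0("V", seq_len(ncol(x)))
    df$.y <- y
    newdf <- data.frame(newx, check.names = FALSE)
    names(newdf) <- paste0("V", seq_len(ncol(x)))
    model <- rpart::rpart(.y ~ ., data = df, method = "class")
    as.character(stats::predict(model, newdf, type = "class"))
  } else {
    stop("unknown classifier: ", classifier, call. = FALSE)
  }
}

# Pooled cross-validated predictions over precomputed folds.
cv_predict <- function(values, labels, classifier, folds) {
  pred <- character(length(labels))
  for (fk in sort(unique(folds))) {
    test <- folds == fk
    train_y <- labels[!test]
    if (length(unique(train_y)) < 2L) {
      stop("a training fold contains a single class; ",
           "use stratified folds or a larger sample", call. = FALSE)
    }
    pred[test] <- fit_predict(values[!test, , drop = FALSE], train_y,
                              values[test, , drop = FALSE], classifier)
  }
  pred
}

#' Cross-validated training and evaluation on a (masked) feature table
#'
#' Runs seeded stratified k-fold cross-validation of the chosen classifier on
#' the selected columns of a feature table, pools the held-out predictions
#' into a single confusion matrix, and derives the diagnostic metric panel.
#' Pooling keeps the confusion counts integral, so the metric formulas apply
#' exactly.
#'
#' @param table A [feature_table()].
#' @param mask Optional 0/1 integer vector of length `ncol(table$values)`
#'   selecting feature columns; `NULL` uses all features.
#' @param classifier `"svm"` (radial kernel, library defaults) or
#'   `"decision_tree"` (default depth).
#' @param n_folds Number of stratified folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param positive Label treated as positive; defaults to the table's
#'   positive class attribute, else the last factor level (the cancerous
#'   class `"tumor"` for synthetic tables).
#' @return A list with `metrics` ([classification_metrics()]), `confusion`
#'   ([confusion_matrix()]), `classifier`, `n_folds`, and `seed`.
#' @examples
#' tab <- generate_features(synthetic_spec(n_per_class = 30, n_features = 4,
#'                                         n_informative = 2, delta = 4))
#' train_eval(tab, classifier = "decision_tree")$metrics
#' @export
train_eval <- function(table, mask = NULL,
                       classifier = c("svm", "decision_tree"),
                       n_folds = 5L, seed = 1L, positive = NULL) {
  stopifnot(inherits(table, "feature_table"))
  classifier <- match.arg(classifier)
  values <- table$values
  if (!is.null(mask)) {
    if (length(mask) != ncol(values)) {
      stop("`mask` length must equal the number of features", call. = FALSE)
    }
    if (sum(mask) < 1L) stop("`mask` selects zero features", call. = FALSE)
    values <- values[, mask == 1L, drop = FALSE]
  }
  labels <- as.character(table$labels)
  if (length(unique(labels)) < 2L) {
    stop("feature table contains a single class", call. = FALSE)
  }
  if (is.null(positive)) positive <- positive_class(table)
  folds <- make_folds(labels, k = n_folds, seed = seed)
  pred <- cv_predict(values, labels, classifier, folds)
  cm <- confusion_matrix(labels, pred, positive = positive)
  list(metrics = classification_metrics(cm), confusion = cm,
       classifier = classifier, n_folds = as.integer(n_folds),
       seed = as.integer(seed))
}

# Default positive class of a table: its attribute if set, else the last
# level (synthetic tables order levels benign < tumor).
positive_class <- function(table) {
  pos <- table$positive
  if (!is.null(pos)) return(pos)
  lv <- levels(factor(table$labels))
  lv[length(lv)]
}
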