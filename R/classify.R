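# SVM classification and evaluation.
#
# The soft-margin SVM maximises the margin between ictal (label 1,
# positive) and interictal samples by solving the convex quadratic dual
#   max  sum(alpha) - 1/2 alpha' (yy' * K) alpha
#   s.t. 0 <= alpha_i <= C,  sum(alpha_i y_i) = 0,
# here with quadprog::solve.QP (no dedicated SVM backend is available in
# this stack, and the dual is a plain box-constrained QP). Evaluation is
# stratified k-fold cross-validation with per-fold standardisation and
# rank-based AUC of the decision scores.

#' SVM configuration
#'
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param C soft-margin cost (> 0).
#' @param gamma RBF width: `"scale"` (default, `1 / (d * var(X))`) or a
#'   positive number.
#' @param seed recorded for provenance; training itself is deterministic.
#' @return an `svm_config` list.
#' @export
svm_config <- function(kernel = c("rbf", "linear"), C = 1,
                       gamma = "scale", seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0)
  structure(list(kernel = kernel, C = C, gamma = gamma, seed = as.integer(seed)),
            class = "svm_config")
}

kernel_matrix <- function(x, y, kernel, gamma) {
  if (kernel == "linear") return(x %*% t(y))
  # RBF: exp(-gamma * ||xi - yj||^2)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * x %*% t(y)
  exp(-gamma * pmax(d2, 0))
}

#' Train a soft-margin SVM
#'
#' @param x numeric matrix, samples x features (typically a
#'   [mask_columns()] restriction of a feature matrix).
#' @param labels vector in `{0, 1}`; 1 (ictal) is the positive class.
#' @param cfg an [svm_config()].
#' @return an `svm_model` usable with [predict()][predict.svm_model()]
#'   (scores and hard labels).
#' @export
train_svm <- function(x, labels, cfg = svm_config()) {
  x <- as.matrix(x)
  assert_finite(x, "features")
  y <- ifelse(labels == 1, 1, -1)
  if (length(unique(y)) < 2)
    stop("training requires both classes present", call. = FALSE)
  n <- nrow(x)
  gamma <- if (identical(cfg$gamma, "scale")) {
    v <- stats::var(as.vector(x))
    if (v <= 0) 1 else 1 / (ncol(x) * v)
  } else cfg$gamma

  k <- kernel_matrix(x, x, cfg$kernel, gamma)
  d_mat <- (y %o% y) * k
  d_mat <- d_mat + diag(1e-8 * mean(diag(d_mat)) + 1e-12, n)
  a_mat <- cbind(y, diag(n), -diag(n))
  b_vec <- c(0, rep(0, n), rep(-cfg$C, n))
  sol <- quadprog::solve.QP(Dmat = d_mat, dvec = rep(1, n),
                            Amat = a_mat, bvec = b_vec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cfg$C)

  sv <- alpha > 1e-8 * cfg$C
  coefs <- alpha[sv] * y[sv]
  margin <- sv & alpha < cfg$C * (1 - 1e-6)
  f_no_b <- as.vector(k[, sv, drop = FALSE] %*% coefs)
  b <- if (any(margin)) mean(y[margin] - f_no_b[margin])
       else -(max(f_no_b[y == -1 & sv]) + min(f_no_b[y == 1 & sv])) / 2

  structure(list(sv = x[sv, , drop = FALSE], coefs = coefs, b = b,
                 kernel = cfg$kernel, gamma = gamma, C = cfg$C),
            class = "svm_model")
}

#' Decision scores and labels from a trained SVM
#'
#' @param object an `svm_model`.
#' @param newdata numeric matrix, samples x features.
#' @param ... unused.
#' @return data.frame with `score` (signed decision value) and `label`
#'   (1 where `score > 0`).
#' @export
predict.svm_model <- function(object, newdata, ...) {
  k <- kernel_matrix(as.matrix(newdata), object$sv, object$kernel, object$gamma)
  score <- as.vector(k %*% object$coefs) + object$b
  data.frame(score = score, label = as.integer(score > 0))
}

#' Rank-based AUC
#'
#' Probability that a positive sample's score outranks a negative's, with
#' half credit for ties (the Mann-Whitney statistic).
#'
#' @param scores numeric decision scores.
#' @param labels vector in `{0, 1}`.
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)`, accuracy
#' `(TP + TN) / total`; ratios with an empty class are `NA`, never 0.
#' With `scores` and `labels` supplied, rank-based AUC is added.
#'
#' @param counts named list or vector with `TP`, `TN`, `FP`, `FN`.
#' @param scores optional per-sample decision scores.
#' @param labels optional per-sample labels in `{0, 1}`.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `auc`.
#' @export
#' @examples
#' compute_metrics(c(TP = 50, TN = 49, FP = 1, FN = 0))
compute_metrics <- function(counts, scores = NULL, labels = NULL) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  total <- tp + tn + fp + fn
  list(
    accuracy = if (total > 0) (tp + tn) / total else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = if (!is.null(scores)) auc_rank(scores, labels) else NA_real_)
}

confusion_counts <- function(truth, pred) {
  c(TP = sum(truth == 1 & pred == 1), TN = sum(truth == 0 & pred == 0),
    FP = sum(truth == 0 & pred == 1), FN = sum(truth == 1 & pred == 0))
}

#' Stratified k-fold cross-validation of the SVM
#'
#' Folds are stratified by class and fixed by `seed`. Each fold is
#' standardised on its training split only, the SVM is trained and the
#' held-out split scored. Pooled confusion counts give accuracy,
#' sensitivity and specificity; AUC is the mean of the per-fold
#' rank-based AUCs of the decision scores.
#'
#' @param features a `feature_matrix`.
#' @param mask binary channel mask, or `NULL` for all channels.
#' @param cfg an [svm_config()].
#' @param n_folds number of folds (>= 2; each class must have at least
#'   `n_folds` samples).
#' @param seed integer fold seed.
#' @return a `classifier_report`: `per_fold` (counts + AUC per fold),
#'   `pooled` counts, `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   `fold_assignment`, `seed`.
#' @export
cross_validate <- function(features, mask = NULL, cfg = svm_config(),
                           n_folds = 10L, seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"), n_folds >= 2)
  y <- features$labels
  for (cl in c(0L, 1L))
    if (sum(y == cl) < n_folds)
      stop("class ", cl, " has fewer samples than folds", call. = FALSE)
  x <- if (is.null(mask)) features$values else mask_columns(features, mask)

  folds <- stratified_folds(y, n_folds, seed)
  per_fold <- vector("list", n_folds)
  scores <- numeric(length(y)); preds <- integer(length(y))
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    mu <- colMeans(x[tr, , drop = FALSE])
    sig <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sig[sig < .Machine$double.eps] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sig, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sig, "/")
    model <- train_svm(xtr, y[tr], cfg)
    out <- predict(model, xte)
    scores[te] <- out$score; preds[te] <- out$label
    cc <- confusion_counts(y[te], out$label)
    per_fold[[f]] <- list(counts = cc, auc = auc_rank(out$score, y[te]))
  }
  pooled <- Reduce(`+`, lapply(per_fold, `[[`, "counts"))
  metrics <- compute_metrics(pooled)
  structure(list(per_fold = per_fold, pooled = pooled,
                 accuracy = metrics$accuracy,
                 sensitivity = metrics$sensitivity,
                 specificity = metrics$specificity,
                 auc = mean(vapply(per_fold, `[[`, numeric(1), "auc"),
                            na.rm = TRUE),
                 scores = scores, predictions = preds,
                 fold_assignment = folds, seed = as.integer(seed)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<classifier_report> %d folds\n  accuracy %.3f | ",
                     "sensitivity %.3f | specificity %.3f | AUC %.3f\n"),
              length(x$per_fold), x$accuracy, x$sensitivity,
              x$specificity, x$auc))
  cat("  pooled counts: TP", x$pooled[["TP"]], "TN", x$pooled[["TN"]],
      "FP", x$pooled[["FP"]], "FN", x$pooled[["FN"]], "\n")
  invisible(x)
}
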