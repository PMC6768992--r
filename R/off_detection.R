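#' OFF-moment labelling, cross-validated prediction and ROC/AUC
#'
#' Questionnaire instances are labelled OFF from a designated Likert item of
#' the continuous questionnaire (e.g. "I experience tremor", 1-7) with an
#' inclusive cutoff, and a simple logistic-regression classifier is evaluated
#' in stratified 10-fold cross-validation: per fold the features are z-scored
#' on the training folds only and a lightly L2-regularized logistic model
#' emits out-of-fold OFF probabilities, summarized by a ROC curve and its
#' AUC. Labels derive only from the ESM answers (or the simulator's latent
#' truth in oracle checks), never from the sensor features.
#'
#' @name off_detection
NULL

#' Binary OFF label from a designated Likert item
#'
#' @param answers Numeric vector (or matrix column) of Likert answers, 1-7.
#' @param cutoff Inclusive cutoff: label 1 iff `answer >= cutoff`.
#' @return Integer 0/1 vector.
#' @export
label_off <- function(answers, cutoff = 5) {
  if (any(!is.na(answers) & (answers < 1 | answers > 7 | answers != round(answers)))) {
    stop("designated item must be a Likert 1-7 answer")
  }
  as.integer(answers >= cutoff)
}

stratified_folds <- function(y, k, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Out-of-fold OFF probabilities from k-fold logistic regression
#'
#' Stratified, seeded k-fold split; per fold the features are standardized
#' with the training folds' means and standard deviations and a logistic
#' regression with light ridge regularization (near-unregularized but
#' numerically stable with many collinear features) is fit on the training
#' folds; every instance receives exactly one held-out probability. Fold
#' assignment ignores temporal ordering, matching a plain cross-validation
#' design; pass a grouping through `fold` to override.
#'
#' @param x Numeric feature matrix, one row per instance.
#' @param y 0/1 labels, both classes present.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param lambda Ridge penalty passed to [glmnet::glmnet()].
#' @param fold Optional integer vector of pre-assigned folds in `1..k`.
#' @return Numeric vector of out-of-fold probabilities, same order as rows.
#' @export
crossval_off <- function(x, y, k = 10, seed = 1, lambda = 1e-3, fold = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (n < k) stop("need at least k instances")
  if (is.null(fold)) fold <- stratified_folds(y, k, seed)
  probs <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    if (!any(test)) next
    xtr <- x[!test, , drop = FALSE]
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    ztr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    zte <- sweep(sweep(x[test, , drop = FALSE], 2, mu), 2, sdv, "/")
    fit <- glmnet::glmnet(ztr, y[!test], family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    probs[test] <- as.numeric(stats::predict(fit, zte, type = "response"))
  }
  probs
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold (ties cross simultaneously)
#' plus the endpoints (0,0) and (1,1), and integrates by the trapezoid rule —
#' algebraically identical to the Mann-Whitney rank statistic with ties
#' counted one half.
#'
#' @param probs Numeric scores (higher = more OFF-like).
#' @param labels 0/1 labels, both classes present.
#' @return Object of class `roc_result`: list with `thresholds` (descending),
#'   `fpr`, `tpr`, `auc`.
#' @export
roc_auc <- function(probs, labels) {
  labels <- as.integer(labels)
  if (length(probs) != length(labels)) stop("probs and labels differ in length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  o <- order(probs, decreasing = TRUE)
  p <- probs[o]; l <- labels[o]
  ends <- c(which(diff(p) != 0), length(p))  # last index of each tie group
  tpr <- c(0, cumsum(l == 1)[ends] / n_pos)
  fpr <- c(0, cumsum(l == 0)[ends] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, p[ends]), fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d threshold(s), AUC = %.3f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}
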