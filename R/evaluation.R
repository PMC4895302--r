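# Stratified k-fold cross-validation and the four performance measures
# (sensitivity, specificity, accuracy, Matthews correlation coefficient)
# computed from pooled confusion counts.

#' Cross-validation configuration
#'
#' @param k Number of folds (>= 2), default 5.
#' @param seed Integer seed for the fold assignment.
#' @param stratified Preserve the class ratio per fold (default TRUE).
#' @export
cv_config <- function(k = 5L, seed = 1L, stratified = TRUE) {
  stopifnot(k >= 2L)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 stratified = isTRUE(stratified)), class = "cv_config")
}

#' Assign samples to k cross-validation folds
#'
#' Stratified by default: each class is shuffled (reproducibly by seed) and
#' dealt round-robin, so per-class fold sizes differ by at most one.
#'
#' @param labels Label vector (+1/-1).
#' @param cv [cv_config()].
#' @return List of k integer index vectors partitioning `seq_along(labels)`.
#' @export
make_folds <- function(labels, cv = cv_config()) {
  n <- length(labels)
  if (cv$k > n) stop("k = ", cv$k, " exceeds sample count ", n)
  if (cv$stratified) {
    for (cl in unique(labels)) {
      if (sum(labels == cl) < cv$k)
        stop("class ", cl, " has fewer than k = ", cv$k, " members")
    }
  }
  groups <- if (cv$stratified) split(seq_len(n), labels) else list(seq_len(n))
  folds <- replicate(cv$k, integer(), simplify = FALSE)
  with_seed(cv$seed, {
    for (idx in groups) {
      idx <- sample(idx)
      f <- rep_len(seq_len(cv$k), length(idx))
      for (i in seq_len(cv$k)) folds[[i]] <- c(folds[[i]], idx[f == i])
    }
  })
  lapply(folds, sort)
}

#' Confusion counts
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  list(TP = TP, FP = FP, TN = TN, FN = FN)
}

# Tally counts from truth/prediction vectors in {+1,-1}.
tally_counts <- function(truth, pred) {
  confusion_counts(TP = sum(truth == 1L & pred == 1L),
                   FP = sum(truth == -1L & pred == 1L),
                   TN = sum(truth == -1L & pred == -1L),
                   FN = sum(truth == 1L & pred == -1L))
}

#' Performance measures from confusion counts
#'
#' Sn = TP/(TP+FN); Sp = TN/(TN+FP); Acc = (TP+TN)/(TP+FP+TN+FN);
#' MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)), with MCC
#' defined as 0 when any factor of the denominator is 0.
#'
#' @param counts [confusion_counts()].
#' @return Object of class `ptm_metrics`: list(Sn, Sp, Acc, MCC, counts).
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("cannot compute metrics from all-zero counts")
  Sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  Sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  Acc <- (TP + TN) / total
  denom <- as.numeric(TP + FN) * (TN + FP) * (TP + FP) * (TN + FN)
  MCC <- if (denom > 0) (as.numeric(TP) * TN - as.numeric(FN) * FP) / sqrt(denom) else 0
  structure(list(Sn = Sn, Sp = Sp, Acc = Acc, MCC = MCC, counts = counts),
            class = "ptm_metrics")
}

#' @export
format.ptm_metrics <- function(x, ...) {
  sprintf("Sn = %.3f  Sp = %.3f  Acc = %.3f  MCC = %.3f  (TP %d, FP %d, TN %d, FN %d)",
          x$Sn, x$Sp, x$Acc, x$MCC,
          x$counts$TP, x$counts$FP, x$counts$TN, x$counts$FN)
}

#' @export
print.ptm_metrics <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}

#' k-fold cross-validation of an SVM configuration
#'
#' For each fold, the scaler and model are fitted on the other k-1 folds
#' only (no information leaks from the held-out fold) and the fold is
#' predicted. The confusion counts are pooled over folds and a single
#' metrics report computed from the pooled counts; per-fold reports are
#' also returned.
#'
#' @param mat Feature matrix.
#' @param labels +1/-1 labels.
#' @param config [svm_config()].
#' @param cv [cv_config()].
#' @return List: `pooled` (`ptm_metrics` from pooled counts), `folds` (list
#'   of per-fold `ptm_metrics`), `fold_sizes`.
#' @export
cross_validate <- function(mat, labels, config = svm_config(), cv = cv_config()) {
  folds <- make_folds(labels, cv)
  pooled <- confusion_counts(0L, 0L, 0L, 0L)
  per_fold <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    hold <- folds[[i]]
    model <- train_svm(mat[-hold, , drop = FALSE], labels[-hold], config)
    pred <- predict(model, mat[hold, , drop = FALSE])
    cnt <- tally_counts(labels[hold], pred$label)
    per_fold[[i]] <- compute_metrics(cnt)
    pooled <- confusion_counts(pooled$TP + cnt$TP, pooled$FP + cnt$FP,
                               pooled$TN + cnt$TN, pooled$FN + cnt$FN)
  }
  list(pooled = compute_metrics(pooled), folds = per_fold,
       fold_sizes = lengths(folds))
}

#' Evaluate a trained model on an independent test set
#'
#' @param model `ptm_svm` model.
#' @param mat Test feature matrix (must be disjoint from training data;
#'   enforced upstream by [reduce_homology()]).
#' @param labels +1/-1 truth labels.
#' @return `ptm_metrics` report.
#' @export
independent_test <- function(model, mat, labels) {
  if (nrow(mat) == 0L) stop("empty test set")
  if (length(unique(labels)) < 2L)
    stop("independent test set must contain both classes (Sn and Sp undefined otherwise)")
  pred <- predict(model, mat)
  compute_metrics(tally_counts(labels, pred$label))
}
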