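#' Argmax cell labeling from a score matrix
#'
#' Each cell is labeled with the name of its highest-scoring signature.
#' Exact ties go to the first signature in column order; the number of tied
#' cells is reported via a message.
#'
#' @param scores Numeric matrix (cells x signatures) with column names, e.g.
#'   a `score_matrix` from [score_all()].
#' @return Named character vector of per-cell labels.
#' @export
argmax_labels <- function(scores) {
  if (is.null(colnames(scores)) || ncol(scores) < 1L) {
    stop("score matrix must have at least one named signature column")
  }
  if (any(!is.finite(scores))) stop("score matrix contains non-finite values")
  idx <- max.col(scores, ties.method = "first")
  n_ties <- sum(rowSums(scores == scores[cbind(seq_len(nrow(scores)), idx)]) > 1L)
  if (n_ties > 0L) {
    message(n_ties, " cell(s) had tied maximal scores; first signature kept")
  }
  setNames(colnames(scores)[idx], rownames(scores))
}

#' Evaluate predicted labels against ground truth
#'
#' Computes the confusion table (truth in rows), balanced accuracy
#' (unweighted mean of per-class recall over truth classes) and weighted
#' F1 (support-weighted mean of per-class F1). Labels predicted but absent
#' from the truth contribute errors to their truth class and trigger a
#' warning.
#'
#' @param pred,truth Character/factor vectors of equal length.
#' @return List of class `annotation_result`: `balanced_accuracy`,
#'   `weighted_f1`, `confusion` (truth x predicted count table),
#'   `per_class` (data.frame of recall, precision, f1, support).
#' @export
evaluate_labels <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  pred <- as.character(pred)
  truth <- as.character(truth)
  truth_classes <- sort(unique(truth))
  if (length(truth_classes) < 2L) {
    stop("truth must contain at least 2 classes for balanced accuracy")
  }
  extra <- setdiff(unique(pred), truth_classes)
  if (length(extra)) {
    warning("predicted label(s) not present in truth: ",
            paste(extra, collapse = ", "))
  }
  all_labels <- sort(unique(c(truth_classes, pred)))
  confusion <- table(factor(truth, levels = all_labels),
                     factor(pred, levels = all_labels))[truth_classes, ,
                                                        drop = FALSE]
  recall <- precision <- f1 <- numeric(length(truth_classes))
  support <- integer(length(truth_classes))
  for (i in seq_along(truth_classes)) {
    cl <- truth_classes[i]
    tp <- confusion[cl, cl]
    support[i] <- sum(confusion[cl, ])
    pred_pos <- sum(pred == cl)
    recall[i] <- if (support[i] > 0L) tp / support[i] else 0
    precision[i] <- if (pred_pos > 0L) tp / pred_pos else 0
    f1[i] <- if (precision[i] + recall[i] > 0)
      2 * precision[i] * recall[i] / (precision[i] + recall[i]) else 0
  }
  structure(list(
    balanced_accuracy = mean(recall),
    weighted_f1 = sum(f1 * support) / sum(support),
    confusion = confusion,
    per_class = data.frame(class = truth_classes, recall = recall,
                           precision = precision, f1 = f1, support = support,
                           stringsAsFactors = FALSE)
  ), class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("<annotation_result> balanced accuracy ",
      format(x$balanced_accuracy, digits = 4), ", weighted F1 ",
      format(x$weighted_f1, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Area under the ROC or precision-recall curve
#'
#' ROC area is computed through the Mann-Whitney rank identity with averaged
#' ties: `AUC = (R1 - n1(n1+1)/2) / (n1 * n0)` where `R1` is the rank sum of
#' the positive class. The precision-recall area is the average-precision
#' step sum over distinct score thresholds.
#'
#' @param scores Numeric vector.
#' @param truth Binary vector (logical, or coercible: the larger/TRUE level
#'   is the positive class).
#' @param kind `"roc"` or `"pr"`.
#' @return Scalar in `[0, 1]`.
#' @export
binary_auc <- function(scores, truth, kind = c("roc", "pr")) {
  kind <- match.arg(kind)
  if (is.logical(truth)) pos <- truth
  else {
    lv <- sort(unique(as.character(truth)))
    if (length(lv) != 2L) stop("truth must contain exactly 2 classes")
    pos <- as.character(truth) == lv[2L]
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  if (kind == "roc") {
    r <- rank(scores, ties.method = "average")
    return(unname((sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)))
  }
  # average precision over decreasing unique thresholds
  ord <- order(-scores)
  s <- scores[ord]; y <- pos[ord]
  grp_end <- which(s != c(s[-1L], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(!y)[grp_end]
  prec <- tp / (tp + fp)
  d_tp <- diff(c(0, tp))
  sum(prec * d_tp) / n1
}

# Stratified fold assignment: shuffles within class, round-robin to folds.
.stratified_folds <- function(truth, k, seed) {
  folds <- integer(length(truth))
  set.seed(seed)
  for (cl in unique(truth)) {
    idx <- which(truth == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has ", length(idx),
           " members; too few for ", k, "-fold stratification")
    }
    idx <- sample(idx)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Information quantity of a score matrix
#'
#' Mean held-out balanced accuracy of an unpenalized multinomial logistic
#' classifier predicting the truth labels from the score columns, under
#' stratified k-fold cross-validation. This quantifies how much label
#' information the scores carry jointly, regardless of whether their ranges
#' are comparable across signatures; the gap to argmax accuracy is the scale
#' imbalance.
#'
#' @param scores Numeric matrix, cells x signatures.
#' @param truth Per-cell class labels; every class needs at least `k_folds`
#'   members.
#' @param k_folds Number of stratified folds (default 10).
#' @param seed Seed controlling fold assignment (default 42); results are
#'   deterministic given the seed.
#' @return Scalar in `[0, 1]`.
#' @export
information_quantity <- function(scores, truth, k_folds = 10L, seed = 42L) {
  truth <- as.character(truth)
  stopifnot(nrow(scores) == length(truth))
  folds <- .stratified_folds(truth, k_folds, seed)
  df <- as.data.frame(unclass(scores[, , drop = FALSE]))
  colnames(df) <- paste0("s", seq_len(ncol(scores)))  # syntactic safety
  df$.label <- factor(truth)
  accs <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    train <- df[folds != f, , drop = FALSE]
    test <- df[folds == f, , drop = FALSE]
    fit <- nnet::multinom(.label ~ ., data = train, trace = FALSE,
                          maxit = 500L, MaxNWts = 10000L)
    pred <- as.character(predict(fit, newdata = test))
    recalls <- vapply(levels(df$.label), function(cl) {
      in_cl <- test$.label == cl
      if (!any(in_cl)) return(NA_real_)
      mean(pred[in_cl] == cl)
    }, numeric(1))
    accs[f] <- mean(recalls, na.rm = TRUE)
  }
  mean(accs)
}

#' Scale imbalance of a score matrix
#'
#' Absolute difference between the information quantity (supervised,
#' cross-validated) and the balanced accuracy of unsupervised argmax
#' labeling. Near-zero values indicate score ranges comparable enough that
#' argmax labeling realizes the information the scores carry.
#'
#' @inheritParams information_quantity
#' @return Non-negative scalar.
#' @export
scale_imbalance <- function(scores, truth, k_folds = 10L, seed = 42L) {
  iq <- information_quantity(scores, truth, k_folds = k_folds, seed = seed)
  ba <- evaluate_labels(argmax_labels(scores), truth)$balanced_accuracy
  abs(iq - ba)
}
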