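# Downstream evaluation: validation MSE, random-forest phenotype AUC under
# the cross-validated and held-out protocols, and cross-split method
# comparison.

#' Validation mean squared error
#'
#' Elementwise MSE between generated and measured target rows for the
#' validation samples; rows are matched by sample id.
#'
#' @param generated matrix of generated rows (rownames = sample ids).
#' @param truth matrix of measured rows with identical ids and order.
#' @return Scalar MSE.
#' @export
validationMSE <- function(generated, truth) {
  generated <- as.matrix(generated)
  truth <- as.matrix(truth)
  if (!identical(dim(generated), dim(truth)))
    stopf("generated and truth matrices differ in shape")
  if (!is.null(rownames(generated)) && !is.null(rownames(truth)) &&
      !identical(rownames(generated), rownames(truth)))
    stopf("sample id mismatch between generated and truth rows")
  mean((generated - truth)^2)
}

# Stratified fold assignment: within each class, seeded shuffle then
# round-robin, so every fold sees every class.
stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

rf_auc <- function(prob, y, positive) {
  pROC::auc(pROC::roc(response = y, predictor = prob,
                      levels = c(setdiff(levels(y), positive), positive),
                      direction = "<", quiet = TRUE))[[1L]]
}

#' Cross-validated phenotype AUC on the completed matrix
#'
#' Stratified k-fold cross-validation of a random-forest classifier over
#' all labelled samples of the completed matrix (observed and imputed
#' alike); the per-fold AUC is computed from out-of-fold class
#' probabilities and the fold mean returned.
#'
#' @param cm a [CompletedMatrix-class].
#' @param labels data.frame with columns `sample_id` and `label` (binary).
#' @param folds number of folds, default 5.
#' @param seed seed for fold assignment and forest fitting.
#' @param ntree random-forest size, default 100.
#' @return Mean out-of-fold AUC.
#' @export
overallAUC <- function(cm, labels, folds = 5L, seed = 1L, ntree = 100L) {
  stopifnot(is(cm, "CompletedMatrix"))
  lab <- prep_labels(cm, labels)
  y <- lab$y
  Xm <- lab$X
  if (min(table(y)) < folds)
    stopf("need at least %d samples per class for %d-fold stratification",
          folds, folds)
  fold <- stratified_folds(y, folds, sub_seed(seed, "folds"))
  positive <- levels(y)[2L]
  aucs <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- with_local_seed(sub_seed(seed, paste0("rf", f)),
      randomForest::randomForest(Xm[tr, , drop = FALSE], y[tr], ntree = ntree))
    prob <- stats::predict(fit, Xm[!tr, , drop = FALSE], type = "prob")[, positive]
    aucs[f] <- rf_auc(prob, y[!tr], positive)
  }
  mean(aucs)
}

#' Held-out phenotype AUC on the imputed samples
#'
#' Fits the random forest on the observed (training + validation) labelled
#' samples and scores only the imputed missing samples, measuring how
#' useful the imputations are for a classifier that never saw them.
#'
#' @inheritParams overallAUC
#' @param plan the [SplitPlan-class] used for training (identifies the
#'   missing samples).
#' @return AUC on the imputed samples.
#' @export
testSetAUC <- function(cm, labels, plan, seed = 1L, ntree = 100L) {
  stopifnot(is(cm, "CompletedMatrix"), is(plan, "SplitPlan"))
  lab <- prep_labels(cm, labels)
  test_ids <- intersect(missingIds(plan), rownames(lab$X))
  train_ids <- setdiff(rownames(lab$X), missingIds(plan))
  if (length(test_ids) < 2L)
    stopf("need at least 2 labelled imputed samples, got %d", length(test_ids))
  y_test <- lab$y[match(test_ids, rownames(lab$X))]
  if (length(unique(y_test)) < 2L)
    stopf("imputed samples are all one class; AUC is undefined")
  y_train <- lab$y[match(train_ids, rownames(lab$X))]
  positive <- levels(lab$y)[2L]
  fit <- with_local_seed(sub_seed(seed, "rf_test"),
    randomForest::randomForest(lab$X[train_ids, , drop = FALSE], y_train,
                               ntree = ntree))
  prob <- stats::predict(fit, lab$X[test_ids, , drop = FALSE],
                         type = "prob")[, positive]
  rf_auc(prob, y_test, positive)
}

prep_labels <- function(cm, labels) {
  if (!all(c("sample_id", "label") %in% colnames(labels)))
    stopf("labels need columns 'sample_id' and 'label'")
  ids <- as.character(labels$sample_id)
  unknown <- setdiff(ids, sampleIds(cm))
  if (length(unknown))
    stopf("labelled sample(s) missing from the completed matrix: %s",
          paste(utils::head(unknown, 5L), collapse = ", "))
  y <- factor(labels$label)
  if (nlevels(y) != 2L) stopf("labels must be binary, got %d classes", nlevels(y))
  if (min(table(y)) < 2L) stopf("need at least 2 samples per class")
  list(X = exprValues(cm)[ids, , drop = FALSE], y = y)
}

#' Pairwise cross-split method comparison
#'
#' Two-sided paired Wilcoxon signed-rank tests between every pair of
#' methods across shared splits, with Holm correction over the pairs.
#'
#' @param per_split_metrics numeric matrix, rows = methods (rownames
#'   required), columns = splits; at least 10 splits.
#' @return data.frame with columns `method_a`, `method_b`, `p`, `p_adj`.
#' @export
compareMethods <- function(per_split_metrics) {
  M <- as.matrix(per_split_metrics)
  if (is.null(rownames(M))) stopf("method names required as rownames")
  if (ncol(M) < 10L) stopf("need at least 10 shared splits, got %d", ncol(M))
  if (any(!is.finite(M))) stopf("all methods must be measured on all splits")
  methods <- rownames(M)
  pairs <- utils::combn(methods, 2L)
  p <- apply(pairs, 2L, function(pr) {
    d <- M[pr[1L], ] - M[pr[2L], ]
    if (all(d == 0)) return(1)
    suppressWarnings(stats::wilcox.test(M[pr[1L], ], M[pr[2L], ],
                                        paired = TRUE, exact = FALSE)$p.value)
  })
  data.frame(method_a = pairs[1L, ], method_b = pairs[2L, ],
             p = p, p_adj = stats::p.adjust(p, method = "holm"),
             row.names = NULL)
}
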