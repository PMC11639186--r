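# Reading, writing, transforming and aligning expression matrices.

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV expression table into an [OmicsMatrix-class]. Public
#' repositories commonly distribute expression as feature-by-sample tables;
#' `orientation` declares the layout of the file and the result is always
#' stored samples x features internally. The first field of the header row
#' is treated as a corner label and ignored.
#'
#' @param path path to a delimited text file.
#' @param orientation `"samples_by_features"` (rows are samples) or
#'   `"features_by_samples"` (rows are features, the common repository
#'   layout).
#' @param delimiter field separator, default tab.
#' @return An [OmicsMatrix-class] in samples x features orientation,
#'   preserving the file's identifier order.
#' @export
readExpressionMatrix <- function(path,
                                 orientation = c("samples_by_features",
                                                 "features_by_samples"),
                                 delimiter = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA, comment.char = "")
  if (ncol(tab) < 2L) stopf("expected at least one identifier and one value column")
  row_ids <- as.character(tab[[1L]])
  col_ids <- colnames(tab)[-1L]
  if (anyDuplicated(row_ids))
    stopf("duplicate row identifier: %s", row_ids[duplicated(row_ids)][1L])
  if (anyDuplicated(col_ids))
    stopf("duplicate column identifier: %s", col_ids[duplicated(col_ids)][1L])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- !is.finite(vals) | vals < 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stopf("negative or non-finite value at row '%s', column '%s'",
          row_ids[idx[1L]], col_ids[idx[2L]])
  }
  dimnames(vals) <- list(row_ids, col_ids)
  if (orientation == "features_by_samples") vals <- t(vals)
  omicsMatrix(vals)
}

#' Write an expression matrix to a delimited file
#'
#' Inverse of [readExpressionMatrix()]: values are written at full precision
#' so a write/read round trip reproduces the matrix exactly.
#'
#' @param m an [OmicsMatrix-class].
#' @param path output path.
#' @param orientation layout of the written file.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(m, path,
                                  orientation = c("samples_by_features",
                                                  "features_by_samples"),
                                  delimiter = "\t") {
  orientation <- match.arg(orientation)
  stopifnot(is(m, "OmicsMatrix"))
  vals <- exprValues(m)
  if (orientation == "features_by_samples") vals <- t(vals)
  df <- data.frame(id = rownames(vals),
                   format(vals, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' log2(x + 1) transform
#'
#' The standard variance-stabilizing transform applied to RSEM/RPM
#' expression before imputation. Shape and identifiers are unchanged and
#' the output stays non-negative.
#'
#' @param m an [OmicsMatrix-class] of non-negative values.
#' @return The transformed [OmicsMatrix-class].
#' @examples
#' m <- omicsMatrix(matrix(c(0, 1, 7, 15), 2, 2,
#'   dimnames = list(c("a", "b"), c("f1", "f2"))))
#' exprValues(log2p1Transform(m))
#' @export
log2p1Transform <- function(m) {
  stopifnot(is(m, "OmicsMatrix"))
  v <- exprValues(m)
  if (any(v < 0)) stopf("log2(x+1) requires non-negative values")
  omicsMatrix(log2(v + 1))
}

#' Align a source and a target modality into a paired dataset
#'
#' Samples are matched by exact identifier equality. Every target sample
#' must be present in the source; source-only samples become the missing
#' set of size k = n - m. Source rows are reordered so the observed block
#' (in the target's order) comes first, followed by the missing block in
#' the source's original order.
#'
#' @param source [OmicsMatrix-class] observed for all samples (n x p).
#' @param target [OmicsMatrix-class] observed for a subset (m x q).
#' @return A [PairedOmicsDataset-class].
#' @export
alignSamples <- function(source, target) {
  stopifnot(is(source, "OmicsMatrix"), is(target, "OmicsMatrix"))
  src_ids <- sampleIds(source)
  tgt_ids <- sampleIds(target)
  orphan <- setdiff(tgt_ids, src_ids)
  if (length(orphan))
    stopf("target sample(s) absent from source: %s",
          paste(utils::head(orphan, 5L), collapse = ", "))
  observed <- tgt_ids
  missing <- src_ids[!(src_ids %in% tgt_ids)]
  src_sorted <- omicsMatrix(exprValues(source)[c(observed, missing), , drop = FALSE])
  new("PairedOmicsDataset", source = src_sorted, target = target,
      observedIds = observed, missingIds = missing)
}

#' Partition the observed samples into training and validation sets
#'
#' A seeded permutation of the observed ids; the first
#' `round(trainFraction * m)` (half-up) become the training set. Missing
#' ids are carried through untouched.
#'
#' @param ds a [PairedOmicsDataset-class].
#' @param trainFraction fraction of observed samples used for training,
#'   default 0.8.
#' @param seed integer seed; the same seed always yields the same plan.
#' @return A [SplitPlan-class].
#' @export
makeSplit <- function(ds, trainFraction = 0.8, seed = 1L) {
  stopifnot(is(ds, "PairedOmicsDataset"))
  if (trainFraction <= 0 || trainFraction >= 1)
    stopf("trainFraction must lie strictly between 0 and 1")
  obs <- observedIds(ds)
  m <- length(obs)
  if (m < 2L) stopf("need at least 2 observed samples to split, got %d", m)
  n_train <- round_half_up(trainFraction * m)
  n_train <- max(1L, min(m - 1L, as.integer(n_train)))
  perm <- with_local_seed(seed, sample.int(m))
  new("SplitPlan",
      trainIds = obs[perm[seq_len(n_train)]],
      validationIds = obs[perm[(n_train + 1L):m]],
      missingIds = missingIds(ds),
      splitSeed = as.integer(seed),
      trainFraction = trainFraction)
}

#' Move a seeded fraction of observed samples into the missing set
#'
#' Emulates the assumed-missing evaluation protocol: `round(fraction * m)`
#' observed samples have their target rows withheld and are re-labelled
#' missing. The withheld rows are returned separately as ground truth so
#' that training code can never see them through the dataset object.
#'
#' @param ds a [PairedOmicsDataset-class].
#' @param fraction fraction of observed samples to withhold, in (0, 1).
#' @param seed integer seed.
#' @return A list with elements `dataset` (the reduced
#'   [PairedOmicsDataset-class]) and `heldTarget` (matrix of withheld
#'   target rows, rownames = the held-out sample ids).
#' @export
holdOutMissing <- function(ds, fraction, seed = 1L) {
  stopifnot(is(ds, "PairedOmicsDataset"))
  if (fraction <= 0 || fraction >= 1)
    stopf("fraction must lie strictly between 0 and 1")
  obs <- observedIds(ds)
  m <- length(obs)
  n_hold <- as.integer(round_half_up(fraction * m))
  if (n_hold < 1L) stopf("hold-out fraction %.3g selects 0 of %d samples", fraction, m)
  if (n_hold >= m) stopf("hold-out would leave no observed samples")
  held <- with_local_seed(seed, sample(obs, n_hold))
  held <- obs[obs %in% held]                       # stable order
  keep <- setdiff(obs, held)
  tgt <- exprValues(targetOmics(ds))
  new_target <- omicsMatrix(tgt[keep, , drop = FALSE])
  src <- exprValues(sourceOmics(ds))
  new_missing <- c(missingIds(ds), held)
  src_sorted <- omicsMatrix(src[c(keep, new_missing), , drop = FALSE])
  list(dataset = new("PairedOmicsDataset", source = src_sorted,
                     target = new_target, observedIds = keep,
                     missingIds = new_missing),
       heldTarget = tgt[held, , drop = FALSE])
}

#' Serialize / restore a SplitPlan as JSON
#'
#' @param plan a [SplitPlan-class].
#' @param path JSON file path.
#' @return `writeSplitPlan` returns `path` invisibly; `readSplitPlan`
#'   returns the restored [SplitPlan-class].
#' @export
writeSplitPlan <- function(plan, path) {
  stopifnot(is(plan, "SplitPlan"))
  jsonlite::write_json(list(
    train_ids = plan@trainIds, validation_ids = plan@validationIds,
    missing_ids = plan@missingIds, split_seed = plan@splitSeed,
    train_fraction = plan@trainFraction), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSplitPlan
#' @export
readSplitPlan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SplitPlan",
      trainIds = as.character(x$train_ids),
      validationIds = as.character(x$validation_ids),
      missingIds = as.character(x$missing_ids %||% character()),
      splitSeed = as.integer(x$split_seed),
      trainFraction = as.numeric(x$train_fraction))
}
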