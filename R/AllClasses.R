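#' @import methods
NULL

#' OmicsMatrix: one omics modality
#'
#' A samples-by-features matrix of non-negative, finite expression values
#' (e.g. log2(x+1) RSEM or RPM) with unique sample and feature identifiers.
#' Non-negativity is required downstream by the non-negative matrix
#' factorization machinery, so it is enforced at construction.
#'
#' @slot values numeric matrix, rows = samples, columns = features;
#'   dimnames carry the sample and feature identifiers.
#' @export
setClass("OmicsMatrix", representation(values = "matrix"))

setValidity("OmicsMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must have sample rownames and feature colnames")
  else {
    if (anyDuplicated(rownames(v)))
      msgs <- c(msgs, sprintf("duplicate sample id: %s",
                              rownames(v)[duplicated(rownames(v))][1L]))
    if (anyDuplicated(colnames(v)))
      msgs <- c(msgs, sprintf("duplicate feature id: %s",
                              colnames(v)[duplicated(colnames(v))][1L]))
  }
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  else {
    bad <- !is.finite(v) | v < 0
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      msgs <- c(msgs, sprintf(
        "value at sample '%s', feature '%s' is negative or non-finite",
        rownames(v)[idx[1L]] %||% idx[1L], colnames(v)[idx[2L]] %||% idx[2L]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix (samples x features by default).
#' @param sampleIds,featureIds optional identifier vectors; taken from
#'   `dimnames(values)` when omitted.
#' @return An [OmicsMatrix-class] object.
#' @examples
#' m <- omicsMatrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("s1", "s2", "s3"), c("f1", "f2"))))
#' dim(m)
#' @export
omicsMatrix <- function(values, sampleIds = rownames(values),
                        featureIds = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sampleIds)) stopf("sample identifiers are required")
  if (is.null(featureIds)) stopf("feature identifiers are required")
  if (length(sampleIds) != nrow(values))
    stopf("%d sample ids for %d rows", length(sampleIds), nrow(values))
  if (length(featureIds) != ncol(values))
    stopf("%d feature ids for %d columns", length(featureIds), ncol(values))
  dimnames(values) <- list(as.character(sampleIds), as.character(featureIds))
  new("OmicsMatrix", values = values)
}

#' PairedOmicsDataset: aligned source and target modalities
#'
#' Holds a source modality observed for all n samples and a target modality
#' observed for a subset of m of them; the remaining k = n - m samples are
#' the completely missing target rows to be imputed. Source rows are stored
#' with the observed samples first (in the target's row order) followed by
#' the missing samples.
#'
#' @slot source,target [OmicsMatrix-class] objects.
#' @slot observedIds character, sample ids present in both modalities.
#' @slot missingIds character, sample ids present only in the source.
#' @export
setClass("PairedOmicsDataset", representation(
  source = "OmicsMatrix", target = "OmicsMatrix",
  observedIds = "character", missingIds = "character"))

setValidity("PairedOmicsDataset", function(object) {
  src <- rownames(object@source@values)
  tgt <- rownames(object@target@values)
  msgs <- character()
  if (!setequal(tgt, object@observedIds) || !identical(tgt, object@observedIds))
    msgs <- c(msgs, "observedIds must equal the target sample ids in order")
  if (!all(tgt %in% src)) msgs <- c(msgs, "target samples must be a subset of source samples")
  if (length(intersect(object@observedIds, object@missingIds)))
    msgs <- c(msgs, "observed and missing ids overlap")
  if (!setequal(src, c(object@observedIds, object@missingIds)))
    msgs <- c(msgs, "source ids must be the union of observed and missing ids")
  if (!identical(src[seq_along(tgt)], tgt))
    msgs <- c(msgs, "source rows restricted to observed ids must match target row order")
  if (length(msgs)) msgs else TRUE
})

#' SplitPlan: train/validation partition of the observed samples
#'
#' @slot trainIds,validationIds disjoint partitions of the observed ids.
#' @slot missingIds the missing-sample ids, carried through unchanged.
#' @slot splitSeed integer seed that generated the partition.
#' @slot trainFraction fraction of observed samples assigned to training.
#' @export
setClass("SplitPlan", representation(
  trainIds = "character", validationIds = "character",
  missingIds = "character", splitSeed = "integer",
  trainFraction = "numeric"))

setValidity("SplitPlan", function(object) {
  msgs <- character()
  if (length(intersect(object@trainIds, object@validationIds)))
    msgs <- c(msgs, "train and validation ids overlap")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msgs <- c(msgs, "trainFraction must lie in (0,1)")
  if (length(msgs)) msgs else TRUE
})

#' NMFFactors: a non-negative matrix factorization Y ~ V U
#'
#' V (samples x c) holds cluster memberships, U (c x features) the cluster
#' centroids. After fitting, each column of V is rescaled to unit maximum
#' with the scale absorbed into the matching row of U, removing the
#' scale ambiguity of NMF.
#'
#' @slot V,U non-negative factor matrices.
#' @slot c integer cluster count.
#' @slot reconError Frobenius norm of the reconstruction residual.
#' @slot objectiveTrace squared-error objective per iteration (diagnostic).
#' @export
setClass("NMFFactors", representation(
  V = "matrix", U = "matrix", c = "integer",
  reconError = "numeric", objectiveTrace = "numeric"))

setValidity("NMFFactors", function(object) {
  msgs <- character()
  if (any(object@V < 0) || any(object@U < 0))
    msgs <- c(msgs, "factors must be non-negative")
  if (ncol(object@V) != object@c || nrow(object@U) != object@c)
    msgs <- c(msgs, "factor inner dimension must equal the cluster count")
  if (object@reconError < 0) msgs <- c(msgs, "reconError must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' TrainedImputer: fitted generator/critic pair with training history
#'
#' @slot generator,critic internal network parameter lists.
#' @slot config the validated training configuration (see [trainingConfig()]).
#' @slot history data.frame with one row per epoch: critic loss, the three
#'   generator loss terms, and validation MSE.
#' @slot referenceU the fixed reference centroid matrix used by the NMF
#'   loss (0 x 0 when the NMF term was off).
#' @slot bestEpoch epoch whose validation MSE selected the kept parameters.
#' @export
setClass("TrainedImputer", representation(
  generator = "ANY", critic = "ANY", config = "list",
  history = "data.frame", referenceU = "matrix", bestEpoch = "integer"))

#' CompletedMatrix: target modality with imputed rows filled in
#'
#' @slot values n x q non-negative matrix over all source samples.
#' @slot provenance factor with levels observed/imputed, one per sample.
#' @export
setClass("CompletedMatrix", representation(
  values = "matrix", provenance = "factor"))

setValidity("CompletedMatrix", function(object) {
  msgs <- character()
  if (length(object@provenance) != nrow(object@values))
    msgs <- c(msgs, "one provenance flag per sample required")
  if (!all(levels(object@provenance) %in% c("observed", "imputed")))
    msgs <- c(msgs, "provenance levels must be observed/imputed")
  if (is.null(rownames(object@values)))
    msgs <- c(msgs, "values must carry sample ids as rownames")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix: %d samples x %d features\n",
              nrow(object@values), ncol(object@values)))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "PairedOmicsDataset", function(object) {
  cat(sprintf("PairedOmicsDataset: source %d x %d, target %d x %d\n",
              nrow(object@source@values), ncol(object@source@values),
              nrow(object@target@values), ncol(object@target@values)))
  cat(sprintf("  observed m = %d, missing k = %d\n",
              length(object@observedIds), length(object@missingIds)))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d train / %d validation / %d missing (seed %d)\n",
              length(object@trainIds), length(object@validationIds),
              length(object@missingIds), object@splitSeed))
})

setMethod("show", "NMFFactors", function(object) {
  cat(sprintf("NMFFactors: %d x %d ~ V(%d x %d) U(%d x %d), recon error %.4g\n",
              nrow(object@V), ncol(object@U), nrow(object@V), object@c,
              object@c, ncol(object@U), object@reconError))
})

setMethod("show", "TrainedImputer", function(object) {
  cat(sprintf("TrainedImputer: mode '%s', %d epochs run, best epoch %s\n",
              object@config$mode, nrow(object@history),
              if (length(object@bestEpoch)) object@bestEpoch else "none"))
  if (nrow(object@history))
    cat(sprintf("  final validation MSE %.4g\n",
                utils::tail(object@history$val_mse, 1L)))
})

setMethod("show", "CompletedMatrix", function(object) {
  tb <- table(object@provenance)
  cat(sprintf("CompletedMatrix: %d x %d (%d observed, %d imputed)\n",
              nrow(object@values), ncol(object@values),
              tb[["observed"]], tb[["imputed"]]))
})

setMethod("dim", "OmicsMatrix", function(x) dim(x@values))
setMethod("dim", "CompletedMatrix", function(x) dim(x@values))
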