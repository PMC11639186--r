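#' Accessors for CrossImpute classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("sourceOmics", function(x) standardGeneric("sourceOmics"))
#' @rdname accessors
#' @export
setGeneric("targetOmics", function(x) standardGeneric("targetOmics"))
#' @rdname accessors
#' @export
setGeneric("observedIds", function(x) standardGeneric("observedIds"))
#' @rdname accessors
#' @export
setGeneric("missingIds", function(x) standardGeneric("missingIds"))
#' @rdname accessors
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))
#' @rdname accessors
#' @export
setGeneric("validationIds", function(x) standardGeneric("validationIds"))
#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))
#' @rdname accessors
#' @export
setGeneric("centroidMatrix", function(x) standardGeneric("centroidMatrix"))
#' @rdname accessors
#' @export
setGeneric("reconError", function(x) standardGeneric("reconError"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname accessors
setMethod("sampleIds", "OmicsMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("featureIds", "OmicsMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("exprValues", "OmicsMatrix", function(x) x@values)
#' @rdname accessors
setMethod("sampleIds", "CompletedMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("featureIds", "CompletedMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("exprValues", "CompletedMatrix", function(x) x@values)
#' @rdname accessors
setMethod("provenance", "CompletedMatrix", function(x) x@provenance)
#' @rdname accessors
setMethod("sourceOmics", "PairedOmicsDataset", function(x) x@source)
#' @rdname accessors
setMethod("targetOmics", "PairedOmicsDataset", function(x) x@target)
#' @rdname accessors
setMethod("observedIds", "PairedOmicsDataset", function(x) x@observedIds)
#' @rdname accessors
setMethod("missingIds", "PairedOmicsDataset", function(x) x@missingIds)
#' @rdname accessors
setMethod("trainIds", "SplitPlan", function(x) x@trainIds)
#' @rdname accessors
setMethod("validationIds", "SplitPlan", function(x) x@validationIds)
#' @rdname accessors
setMethod("missingIds", "SplitPlan", function(x) x@missingIds)
#' @rdname accessors
setMethod("basisMatrix", "NMFFactors", function(x) x@V)
#' @rdname accessors
setMethod("centroidMatrix", "NMFFactors", function(x) x@U)
#' @rdname accessors
setMethod("reconError", "NMFFactors", function(x) x@reconError)
#' @rdname accessors
setMethod("trainingHistory", "TrainedImputer", function(x) x@history)
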