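#' @include AllClasses.R
NULL

#' Accessors for volume and table classes
#'
#' `waterVolume`/`fatVolume` return the contrast grids, `voxelSpacing` the
#' spacing in mm, `labelArray`/`labelMap` the label grid and its legend,
#' `featureValues` the subjects-by-features value matrix, `featureKeys` the
#' parsed feature key table and `subjectMeta` the subject metadata.
#'
#' @param x object
#' @return the corresponding component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("waterVolume", function(x) standardGeneric("waterVolume"))
#' @rdname accessors
#' @export
setGeneric("fatVolume", function(x) standardGeneric("fatVolume"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureKeys", function(x) standardGeneric("featureKeys"))
#' @rdname accessors
#' @export
setGeneric("subjectMeta", function(x) standardGeneric("subjectMeta"))
#' @rdname accessors
#' @export
setGeneric("foldAssignment", function(x) standardGeneric("foldAssignment"))

#' @rdname accessors
setMethod("waterVolume", "DixonVolumes", function(x) x@water)
#' @rdname accessors
setMethod("fatVolume", "DixonVolumes", function(x) x@fat)
#' @rdname accessors
setMethod("voxelSpacing", "DixonVolumes", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("labelArray", "LabelVolume", function(x) x@labels)
#' @rdname accessors
setMethod("labelMap", "LabelVolume", function(x) x@labelMap)

#' @rdname accessors
setMethod("featureValues", "MuscleFeatureTable", function(x)
  t(SummarizedExperiment::assay(x, "features")))
#' @rdname accessors
setMethod("featureKeys", "MuscleFeatureTable", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))
#' @rdname accessors
setMethod("subjectMeta", "MuscleFeatureTable", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))
#' @rdname accessors
setMethod("foldAssignment", "FoldSplit", function(x) x@assignment)

#' @rdname accessors
#' @export
setGeneric("rankAggregate", function(x) standardGeneric("rankAggregate"))
#' @rdname accessors
setMethod("rankAggregate", "RankTable", function(x) x@aggregate)

#' @rdname accessors
#' @export
setGeneric("evalResults", function(x) standardGeneric("evalResults"))
#' @rdname accessors
setMethod("evalResults", "EvalReport", function(x) x@results)

#' @rdname accessors
#' @export
setGeneric("traceCounts", function(x) standardGeneric("traceCounts"))
#' @rdname accessors
setMethod("traceCounts", "SelectionTrace", function(x) x@counts)
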