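#' Accessors for SPECT data objects
#'
#' `voxelCounts()` returns the raw 3D count array, `voxelSpacing()` the voxel
#' spacing in mm, `voxelVolume()` the volume of one voxel in cubic mm,
#' `maskFlags()` the logical membership array of a mask, `maskVolume()` the
#' physical mask volume in mL, and `stageLabel()` / `subjectId()` the label
#' metadata of a \linkS4class{LabeledVolume}.
#'
#' @param x a \linkS4class{SpectVolume}, \linkS4class{VoxelMask} or
#'   \linkS4class{LabeledVolume}.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelCounts", function(x) standardGeneric("voxelCounts"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname accessors
#' @export
setGeneric("maskFlags", function(x) standardGeneric("maskFlags"))
#' @rdname accessors
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))
#' @rdname accessors
#' @export
setGeneric("stageLabel", function(x) standardGeneric("stageLabel"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
setMethod("voxelCounts", "SpectVolume", function(x) x@counts)
#' @rdname accessors
setMethod("voxelCounts", "LabeledVolume", function(x) x@volume@counts)
#' @rdname accessors
setMethod("voxelSpacing", "SpectVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "VoxelMask", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "LabeledVolume", function(x) x@volume@spacing)
#' @rdname accessors
setMethod("voxelVolume", "SpectVolume", function(x) prod(x@spacing))
#' @rdname accessors
setMethod("voxelVolume", "VoxelMask", function(x) prod(x@spacing))
#' @rdname accessors
setMethod("maskFlags", "VoxelMask", function(x) x@flags)
#' @rdname accessors
setMethod("maskVolume", "VoxelMask",
          function(x) sum(x@flags) * prod(x@spacing) / 1000)
#' @rdname accessors
setMethod("stageLabel", "LabeledVolume", function(x) x@stage)
#' @rdname accessors
setMethod("subjectId", "LabeledVolume", function(x) x@subjectId)

#' @rdname extractFeatures
#' @export
setGeneric("extractFeatures",
           function(x, config = pipelineConfig(), ...)
               standardGeneric("extractFeatures"))
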