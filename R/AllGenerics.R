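#' @include AllClasses.R
NULL

#' @export
setGeneric("mapData", function(x) standardGeneric("mapData"))
#' @export
setGeneric("mapAffine", function(x) standardGeneric("mapAffine"))
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @export
setGeneric("paramId", function(x) standardGeneric("paramId"))
#' @export
setGeneric("paramUnits", function(x) standardGeneric("paramUnits"))
#' @export
setGeneric("subjectMaps", function(x) standardGeneric("subjectMaps"))
#' @export
setGeneric("subjectGroup", function(x) standardGeneric("subjectGroup"))
#' @export
setGeneric("lesionMask", function(x) standardGeneric("lesionMask"))
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @export
setGeneric("recordedTransform", function(x) standardGeneric("recordedTransform"))
#' @export
setGeneric("atlasMean", function(x) standardGeneric("atlasMean"))
#' @export
setGeneric("atlasSD", function(x) standardGeneric("atlasSD"))
#' @export
setGeneric("atlasN", function(x) standardGeneric("atlasN"))
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))
#' @export
setGeneric("roiInfo", function(x) standardGeneric("roiInfo"))
#' @export
setGeneric("probMap", function(x, roi) standardGeneric("probMap"))
#' @export
setGeneric("zData", function(x) standardGeneric("zData"))
#' @export
setGeneric("diffData", function(x) standardGeneric("diffData"))
#' @export
setGeneric("flaggedVoxels", function(x) standardGeneric("flaggedVoxels"))

#' Apply a spatial transform by resampling
#'
#' @param x volume to resample (a `QMapVolume`).
#' @param transform a `SpatialTransform` (target-to-source pull-back).
#' @param ... passed to methods.
#' @export
setGeneric("applyTransform",
    function(x, transform, ...) standardGeneric("applyTransform"))

#' @export
setGeneric("invertTransform", function(x, ...) standardGeneric("invertTransform"))
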