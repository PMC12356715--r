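#' @include AllGenerics.R
NULL

#' Construct a QMapVolume
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm); default built from
#'   `voxelSize` with the volume centre at the world origin.
#' @param param parameter identity string.
#' @param units unit string; defaults per parameter ("%" for MVF/PD, "1/s"
#'   for R1/R2, "a.u." otherwise).
#' @param voxelSize length-3 voxel spacing in mm (used only when `affine` is
#'   missing).
#' @return a `QMapVolume`.
#' @export
qMapVolume <- function(data, affine = NULL, param = "other", units = NULL,
                       voxelSize = c(1, 1, 1)) {
    if (is.null(affine)) {
        affine <- diag(c(voxelSize, 1))
        affine[1:3, 4] <- -voxelSize * (dim(data) - 1) / 2
    }
    if (is.null(units))
        units <- switch(param, MVF = "%", PD = "%", R1 = "1/s", R2 = "1/s",
                        T1w = "a.u.", label = "index", mask = "binary",
                        "a.u.")
    new("QMapVolume", data = data, affine = affine, param = param,
        units = units)
}

#' @describeIn qMapVolume voxel data array
#' @param x a `QMapVolume`
#' @export
setMethod("mapData", "QMapVolume", function(x) x@data)

#' @export
setMethod("mapAffine", "QMapVolume", function(x) x@affine)

#' @export
setMethod("voxelSize", "QMapVolume",
    function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @export
setMethod("paramId", "QMapVolume", function(x) x@param)

#' @export
setMethod("paramUnits", "QMapVolume", function(x) x@units)

setMethod("show", "QMapVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("QMapVolume '%s' [%s]: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
                object@param, object@units, d[1], d[2], d[3],
                voxelSize(object)[1], voxelSize(object)[2],
                voxelSize(object)[3]))
    cat(sprintf("  range: [%.4g, %.4g]\n", min(object@data),
                max(object@data)))
})

#' @export
setMethod("subjectMaps", "SubjectRecord", function(x) x@maps)
#' @export
setMethod("subjectGroup", "SubjectRecord", function(x) x@group)
#' @export
setMethod("lesionMask", "SubjectRecord", function(x) x@lesionMask)
#' @export
setMethod("groundTruth", "SubjectRecord", function(x) x@truth)
#' @export
setMethod("recordedTransform", "SubjectRecord", function(x) x@transform)

setMethod("show", "SubjectRecord", function(object) {
    cat(sprintf("SubjectRecord %s: %s, age %.0f, sex %s\n", object@id,
                object@group, object@age, object@sex))
    cat(sprintf("  maps: %s; lesion voxels: %d\n",
                paste(names(object@maps), collapse = ", "),
                sum(object@lesionMask > 0)))
})

#' @export
setMethod("atlasMean", "AtlasPair", function(x) x@mean)
#' @export
setMethod("atlasSD", "AtlasPair", function(x) x@sd)
#' @export
setMethod("atlasN", "AtlasPair", function(x) x@n)
#' @export
setMethod("brainMask", "AtlasPair", function(x) x@mask)

setMethod("show", "AtlasPair", function(object) {
    cat(sprintf("AtlasPair '%s': n = %d subjects, %s voxels in brain mask\n",
                object@param, object@n, sum(object@mask > 0)))
    m <- object@mean@data[object@mask > 0]
    s <- object@sd@data[object@mask > 0]
    cat(sprintf("  in-mask mean of means %.4g, median SD %.4g (provenance %s)\n",
                mean(m), stats::median(s), object@provenance))
})

#' @export
setMethod("roiInfo", "ROISet", function(x) x@rois)
#' @export
setMethod("probMap", "ROISet", function(x, roi) {
    if (!roi %in% names(x@probMaps)) stop("unknown ROI: ", roi)
    x@probMaps[[roi]]
})
#' @export
setMethod("brainMask", "ROISet", function(x) {
    lab <- x@labels@data
    array(as.numeric(lab > 0), dim(lab))
})

setMethod("show", "ROISet", function(object) {
    cat(sprintf("ROISet: %d ROIs (%d WM, %d GM, %d deep GM) on %s grid\n",
                nrow(object@rois), sum(object@rois$class == "WM"),
                sum(object@rois$class == "GM"),
                sum(object@rois$class == "deepGM"),
                paste(dim(object@labels@data), collapse = "x")))
})

#' @export
setMethod("zData", "DeviationResult", function(x) x@z@data)
#' @export
setMethod("diffData", "DeviationResult", function(x) x@diff@data)
#' @export
setMethod("flaggedVoxels", "DeviationResult", function(x) x@flaggedVoxels)

setMethod("show", "DeviationResult", function(object) {
    cat(sprintf("DeviationResult '%s': %d voxels |z| > 3 (SD floor %.4g, %d floored)\n",
                object@param, object@flaggedVoxels, object@sdFloor,
                object@flooredVoxels))
})

setMethod("show", "SpatialTransform", function(object) {
    disp <- if (prod(dim(object@displacement)[1:3]) > 0)
        sprintf("with displacement field (max |d| %.3g mm)",
                max(abs(object@displacement)))
    else "affine only"
    cat(sprintf("SpatialTransform (order-%d B-spline), %s\n", object@order,
                disp))
    print(round(object@affine, 4))
})

setMethod("show", "SequenceParams", function(object) {
    cat(sprintf("SequenceParams: TR %g ms, TE %g/%g ms, TI %g ms, delays {%s} ms, B1 %.3g\n",
                object@tr, object@te1, object@te2, object@ti,
                paste(object@delays, collapse = ", "), object@b1))
})

setMethod("show", "CompartmentSet", function(object) {
    cat("CompartmentSet (fast-exchange linear mixing):\n")
    print(round(object@constants, 3))
})
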