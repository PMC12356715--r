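#' @include AllClasses.R atlas.R
NULL

#' Voxel-wise difference map
#'
#' `diff = atlas mean - subject` (so demyelination shows as positive MVF
#' differences); for PD the absolute value is reported.
#'
#' @param atlas an [AtlasPair-class] (or its mean `QMapVolume`).
#' @param subjectMap subject `QMapVolume` on the atlas grid.
#' @param param parameter id; decides the PD absolute-value rule. Defaults
#'   to the subject map's parameter.
#' @return a `QMapVolume`.
#' @export
diffMap <- function(atlas, subjectMap, param = NULL) {
    mu <- if (is(atlas, "AtlasPair")) atlas@mean else atlas
    if (is.null(param)) param <- subjectMap@param
    if (!identical(dim(mu@data), dim(subjectMap@data)))
        stop("grid mismatch between atlas and subject")
    d <- mu@data - subjectMap@data
    if (param == "PD") d <- abs(d)
    qMapVolume(d, affine = mu@affine, param = param,
               units = subjectMap@units)
}

#' Voxel-wise z-score map
#'
#' `z = (atlas mean - subject) / max(SD, floor)`, masked to the brain.
#' The sign convention makes tissue loss (lower MVF/R1/R2 than the
#' reference) a positive z. The SD floor (default: the 1st percentile of
#' the in-mask SD) guards the division at zero-variance voxels; floored
#' voxels are counted.
#'
#' @param atlas an [AtlasPair-class].
#' @param subjectMap subject `QMapVolume` on the atlas grid.
#' @param sdFloor positive SD floor, or NULL for the 1st-percentile default.
#' @param mask 0/1 mask (default: the atlas brain mask).
#' @param flip flip to the conventional (subject - mean) sign.
#' @return a [DeviationResult-class] (diff map included).
#' @export
zMap <- function(atlas, subjectMap, sdFloor = NULL, mask = NULL,
                 flip = FALSE) {
    if (!identical(dim(atlas@mean@data), dim(subjectMap@data)))
        stop("grid mismatch between atlas and subject")
    if (is.null(mask)) mask <- atlas@mask
    sd <- atlas@sd@data
    if (is.null(sdFloor))
        sdFloor <- as.numeric(stats::quantile(sd[mask > 0], 0.01))
    if (!is.finite(sdFloor) || sdFloor <= 0)
        sdFloor <- max(1e-6, min(sd[sd > 0 & mask > 0], na.rm = TRUE))
    floored <- sum(sd[mask > 0] < sdFloor)
    z <- (atlas@mean@data - subjectMap@data) / pmax(sd, sdFloor)
    if (flip) z <- -z
    z[mask <= 0] <- 0
    dm <- diffMap(atlas, subjectMap)
    dm@data[mask <= 0] <- 0
    new("DeviationResult", param = atlas@param,
        diff = dm,
        z = qMapVolume(z, affine = atlas@mean@affine, param = atlas@param,
                       units = "z"),
        mask = mask, sdFloor = sdFloor, flooredVoxels = as.integer(floored),
        flaggedVoxels = as.integer(sum(abs(z[mask > 0]) > 3)))
}

#' Summarise deviation maps
#'
#' Per parameter: the number and fraction of in-mask voxels beyond the
#' |z| threshold, their attribution to ROIs, and (when a lesion mask is
#' supplied) the voxel-flagging sensitivity and specificity against it.
#'
#' @param results list of [DeviationResult-class] (one per parameter).
#' @param phantom optional [ROISet-class] for ROI attribution.
#' @param lesionMask optional ground-truth lesion mask.
#' @param threshold |z| threshold, default 3.
#' @return list with `summary` (data.frame per parameter) and `roiCounts`
#'   (data.frame roi x parameter flagged-voxel counts, or NULL).
#' @export
deviationReport <- function(results, phantom = NULL, lesionMask = NULL,
                            threshold = 3) {
    rows <- lapply(results, function(r) {
        inMask <- r@mask > 0
        flag <- abs(r@z@data) > threshold & inMask
        row <- data.frame(param = r@param, nFlagged = sum(flag),
                          fracFlaggedPct = 100 * sum(flag) / sum(inMask),
                          sdFloor = r@sdFloor)
        if (!is.null(lesionMask)) {
            les <- lesionMask > 0 & inMask
            row$sensitivityPct <- if (any(les))
                100 * sum(flag & les) / sum(les) else NA_real_
            row$specificityPct <- 100 * sum(!flag & !les & inMask) /
                sum(!les & inMask)
        } else {
            row$sensitivityPct <- NA_real_
            row$specificityPct <- NA_real_
        }
        row
    })
    roiCounts <- NULL
    if (!is.null(phantom)) {
        roiCounts <- do.call(rbind, lapply(results, function(r) {
            flag <- abs(r@z@data) > threshold & r@mask > 0
            cnt <- vapply(phantom@rois$roi, function(roi)
                sum(flag & makeMask(probMap(phantom, roi),
                                    phantom@threshold)), numeric(1))
            data.frame(param = r@param, roi = phantom@rois$roi,
                       nFlagged = as.numeric(cnt), row.names = NULL)
        }))
    }
    list(summary = do.call(rbind, rows), roiCounts = roiCounts)
}
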