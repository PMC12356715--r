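#' @include AllClasses.R phantom.R
NULL

#' Threshold a probabilistic ROI map
#'
#' Strict 50 % rule: a voxel is included iff its probability exceeds the
#' threshold (boundary voxels at exactly 0.5 are excluded), minimising
#' misclassification from partial-volume boundary voxels.
#'
#' @param prob probability array in `[0, 1]` (or an [ROISet-class] plus
#'   `roi` name).
#' @param threshold inclusion threshold, default 0.5.
#' @param roi ROI name when `prob` is an `ROISet`.
#' @return logical mask array; warns when the mask is empty.
#' @export
makeMask <- function(prob, threshold = 0.5, roi = NULL) {
    if (is(prob, "ROISet")) prob <- probMap(prob, roi)
    if (min(prob) < 0 || max(prob) > 1)
        stop("probability map must lie in [0, 1]")
    m <- prob > threshold
    if (!any(m))
        warning("empty mask after thresholding at ", threshold)
    m
}

#' Masked ROI mean (with bilateral averaging)
#'
#' Arithmetic mean of the map over a mask. For bilateral cortical ROIs pass
#' both hemisphere masks: the result is the mean of the two per-hemisphere
#' means (order-invariant; equal to the pooled-mask mean when the
#' hemispheres have equal voxel counts).
#'
#' @param map `QMapVolume` or array.
#' @param mask logical/0-1 mask.
#' @param mask2 optional second-hemisphere mask.
#' @return scalar mean; `NA` (with a warning) for an empty mask.
#' @export
roiMean <- function(map, mask, mask2 = NULL) {
    vals <- if (is(map, "QMapVolume")) map@data else map
    one <- function(m) {
        if (!any(m > 0)) {
            warning("empty ROI mask: missing value recorded")
            return(NA_real_)
        }
        mean(vals[m > 0])
    }
    if (is.null(mask2)) one(mask) else mean(c(one(mask), one(mask2)))
}

#' Per-subject ROI means for all parameters
#'
#' Extracts the mean of each parameter map within every thresholded ROI.
#' Cortical ROI pairs (shared `pairId`) are averaged over both hemispheres
#' and reported once under the pair name; all other ROIs are reported per
#' side.
#'
#' @param subject [SubjectRecord-class] (or named list of `QMapVolume`s).
#' @param phantom [ROISet-class] defining the ROIs.
#' @param params parameters to extract.
#' @return data.frame with columns `roi`, `class`, `param`, `value`.
#' @export
subjectROIMeans <- function(subject, phantom,
                            params = c("MVF", "PD", "R1", "R2")) {
    maps <- if (is(subject, "SubjectRecord")) subject@maps else subject
    info <- phantom@rois
    masks <- lapply(info$roi, function(r)
        makeMask(probMap(phantom, r), phantom@threshold))
    names(masks) <- info$roi
    paired <- !is.na(info$pairId)
    pairIds <- unique(info$pairId[paired])
    rows <- list()
    for (p in params) {
        m <- maps[[p]]
        for (i in which(!paired))
            rows[[length(rows) + 1L]] <- data.frame(
                roi = info$roi[i], class = info$class[i], param = p,
                value = roiMean(m, masks[[info$roi[i]]]))
        for (pid in pairIds) {
            sides <- info$roi[paired & info$pairId == pid]
            rows[[length(rows) + 1L]] <- data.frame(
                roi = pid, class = info$class[match(sides[1], info$roi)],
                param = p,
                value = roiMean(m, masks[[sides[1]]], masks[[sides[2]]]))
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Cohort reference table with +/- 3 SD normal ranges
#'
#' For every ROI and parameter, the mean, sample SD (n - 1) and coefficient
#' of variation across subjects' ROI means, plus the normal-range limits
#' `mean -/+ 3 SD` (covering about 99.7 % of a normal distribution).
#' Reference statistics are computed across per-subject ROI means, not
#' pooled voxels.
#'
#' @param cohortMeans either a data.frame of stacked [subjectROIMeans()]
#'   outputs with an `id` column, or a list of such data.frames.
#' @param nsd range half-width in SDs (default 3).
#' @return data.frame: `roi`, `class`, `param`, `mean`, `sd`, `cv`, `lower`,
#'   `upper`, `n`.
#' @export
referenceTable <- function(cohortMeans, nsd = 3) {
    if (is.list(cohortMeans) && !is.data.frame(cohortMeans))
        cohortMeans <- do.call(rbind, cohortMeans)
    key <- interaction(cohortMeans$roi, cohortMeans$param, drop = TRUE)
    parts <- split(cohortMeans, key)
    out <- do.call(rbind, lapply(parts, function(g) {
        if (nrow(g) < 2L) stop("reference table needs n >= 2 per ROI")
        m <- mean(g$value); s <- stats::sd(g$value)
        data.frame(roi = g$roi[1], class = g$class[1], param = g$param[1],
                   mean = m, sd = s, cv = 100 * s / m, lower = m - nsd * s,
                   upper = m + nsd * s, n = nrow(g))
    }))
    rownames(out) <- NULL
    out
}

#' Classify a subject against the reference ranges
#'
#' Region-by-region verdicts: `below` / `within` / `above` the
#' `mean +/- 3 SD` reference range (closed interval: a value exactly on a
#' limit is `within`).
#'
#' @param subjectMeans data.frame from [subjectROIMeans()].
#' @param reference data.frame from [referenceTable()].
#' @return list with `verdicts` (data.frame: roi, param, value, lower,
#'   upper, verdict) and `summary` (counts below/within/above).
#' @export
classifySubject <- function(subjectMeans, reference) {
    key <- paste(subjectMeans$roi, subjectMeans$param)
    refKey <- paste(reference$roi, reference$param)
    idx <- match(key, refKey)
    if (anyNA(idx))
        stop("unmatched ROI x parameter: ",
             paste(key[is.na(idx)], collapse = ", "))
    lo <- reference$lower[idx]; hi <- reference$upper[idx]
    verdict <- ifelse(subjectMeans$value < lo, "below",
               ifelse(subjectMeans$value > hi, "above", "within"))
    verdicts <- data.frame(roi = subjectMeans$roi,
                           class = subjectMeans$class,
                           param = subjectMeans$param,
                           value = subjectMeans$value, lower = lo,
                           upper = hi, verdict = verdict)
    list(verdicts = verdicts,
         summary = c(below = sum(verdict == "below"),
                     within = sum(verdict == "within"),
                     above = sum(verdict == "above")))
}
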