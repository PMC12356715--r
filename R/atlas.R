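#' @include AllClasses.R utils.R
NULL

asSubjectList <- function(cohort) {
    if (is(cohort, "SubjectRecord")) return(list(cohort))
    if (is.list(cohort) && !is.null(cohort$subjects)) return(cohort$subjects)
    cohort
}

#' Build the voxel-wise normative atlas for one parameter
#'
#' Computes the voxel-wise mean and sample standard deviation (n - 1
#' denominator) of one parameter across a normalized cohort. All subjects
#' must already live on the template grid. Zero-SD voxels are retained;
#' z-scoring applies a floor later (see [zMap()]).
#'
#' @param cohort list of [SubjectRecord-class] (or the list returned by
#'   [simulateCohort()], whose atlasHC subjects are used), or a list of
#'   `QMapVolume`s of the parameter.
#' @param param parameter id ("MVF", "PD", "R1" or "R2").
#' @param mask 0/1 template brain mask; defaults to the union of the
#'   subjects' intracranial masks (or all voxels for bare volume lists).
#' @param provenance provenance string; defaults to a hash of the subject
#'   ids.
#' @return an [AtlasPair-class].
#' @export
buildAtlas <- function(cohort, param, mask = NULL, provenance = NULL) {
    subjects <- asSubjectList(cohort)
    if (is(subjects[[1]], "SubjectRecord")) {
        keep <- vapply(subjects, function(s) s@group == "atlasHC", logical(1))
        if (any(keep)) subjects <- subjects[keep]
        vols <- lapply(subjects, function(s) s@maps[[param]])
        if (is.null(mask)) {
            mask <- Reduce(`+`, lapply(subjects, function(s) s@icvMask))
            mask <- array(as.numeric(mask > 0), dim(mask))
        }
        if (is.null(provenance))
            provenance <- provenanceTag(vapply(subjects, function(s) s@id,
                                               character(1)))
    } else {
        vols <- subjects
        if (is.null(mask)) mask <- array(1, dim(vols[[1]]@data))
        if (is.null(provenance)) provenance <- provenanceTag(param)
    }
    n <- length(vols)
    if (n < 2L) stop("atlas needs at least 2 subjects")
    d <- dim(vols[[1]]@data)
    aff <- vols[[1]]@affine
    for (v in vols)
        if (!identical(dim(v@data), d) || max(abs(v@affine - aff)) > 1e-9)
            stop("grid mismatch across the cohort")
    s1 <- array(0, d); s2 <- array(0, d)
    for (v in vols) {
        s1 <- s1 + v@data
        s2 <- s2 + v@data^2
    }
    mu <- s1 / n
    var <- pmax(s2 - n * mu^2, 0) / (n - 1)
    units <- vols[[1]]@units
    new("AtlasPair", param = param,
        mean = qMapVolume(mu, affine = aff, param = param, units = units),
        sd = qMapVolume(sqrt(var), affine = aff, param = param,
                        units = units),
        n = as.integer(n), mask = mask, provenance = provenance)
}

#' Build the synthetic T1-weighted template
#'
#' Voxel-wise mean of the cohort's synthetic T1w images (computed on demand
#' when subjects lack a T1w map).
#'
#' @param cohort as in [buildAtlas()].
#' @return a `QMapVolume` with `param = "T1w"`.
#' @export
buildT1wTemplate <- function(cohort) {
    subjects <- asSubjectList(cohort)
    if (is(subjects[[1]], "SubjectRecord")) {
        keep <- vapply(subjects, function(s) s@group == "atlasHC", logical(1))
        if (any(keep)) subjects <- subjects[keep]
        vols <- lapply(subjects, function(s)
            if (!is.null(s@maps$T1w)) s@maps$T1w else synthT1w(s))
    } else vols <- subjects
    d <- dim(vols[[1]]@data)
    s1 <- array(0, d)
    for (v in vols) s1 <- s1 + v@data
    qMapVolume(s1 / length(vols), affine = vols[[1]]@affine, param = "T1w",
               units = "a.u.")
}

#' Global brain metrics for one subject
#'
#' Brain parenchymal fraction `BPF = 100 * parenchyma volume / ICV`, the
#' intracranial-volume-normalised global myelin volume
#' `100 * sum(MVF/100 * voxel volume) / ICV`, and whole-brain means of the
#' four parameters over the parenchyma mask.
#'
#' @param subject a [SubjectRecord-class].
#' @param parenchymaMask,icvMask override masks (default: the subject's).
#' @return data.frame with one row: `BPF`, `normMyelin`, `MVF`, `R1`, `R2`,
#'   `PD`.
#' @export
globalMetrics <- function(subject, parenchymaMask = NULL, icvMask = NULL) {
    if (is.null(parenchymaMask)) parenchymaMask <- subject@parenchymaMask
    if (is.null(icvMask)) icvMask <- subject@icvMask
    if (!sum(icvMask > 0)) stop("empty intracranial mask")
    if (any(parenchymaMask > 0 & !(icvMask > 0)))
        stop("ICV mask must contain the parenchyma mask")
    vv <- prod(voxelSize(subject@maps[[1]]))
    icvVol <- sum(icvMask > 0) * vv
    p <- parenchymaMask > 0
    bpf <- 100 * sum(p) * vv / icvVol
    myelinVol <- sum(subject@maps$MVF@data[p] / 100) * vv
    data.frame(
        BPF = bpf,
        normMyelin = 100 * myelinVol / icvVol,
        MVF = mean(subject@maps$MVF@data[p]),
        R1 = mean(subject@maps$R1@data[p]),
        R2 = mean(subject@maps$R2@data[p]),
        PD = mean(subject@maps$PD@data[p]))
}
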