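#' @import methods
NULL

#' Quantitative parameter map volume
#'
#' A single 3-D scalar grid together with its voxel-to-world affine, the
#' identity of the mapped parameter and its physical units. This is the
#' elementary container moved through the whole pipeline: tissue parameter
#' maps (MVF in %, PD in %, R1 and R2 in 1/s), synthetic T1-weighted
#' contrasts, label volumes and masks are all `QMapVolume` objects.
#'
#' @slot data 3-D numeric array of voxel values.
#' @slot affine 4x4 voxel-to-world matrix (mm); column-major, 1-based voxel
#'   indices map through `affine %*% c(i - 1, j - 1, k - 1, 1)`.
#' @slot param parameter identity, e.g. `"MVF"`, `"PD"`, `"R1"`, `"R2"`,
#'   `"T1w"`, `"label"`, `"mask"`.
#' @slot units unit string, e.g. `"%"`, `"1/s"`, `"a.u."`.
#' @exportClass QMapVolume
setClass("QMapVolume",
    representation(data = "array", affine = "matrix",
                   param = "character", units = "character"))

setValidity("QMapVolume", function(object) {
    if (length(dim(object@data)) != 3L)
        return("data must be a 3-D array")
    if (!all(dim(object@affine) == c(4L, 4L)))
        return("affine must be a 4x4 matrix")
    if (abs(det(object@affine[1:3, 1:3])) < 1e-12)
        return("affine must be invertible")
    if (length(object@param) != 1L || length(object@units) != 1L)
        return("param and units must be single strings")
    TRUE
})

#' Spatial transform between two volume spaces
#'
#' Pull-back convention: for a point `x` (mm, world coordinates of the target
#' grid), the sampled source location is `affine %*% x` plus, when present,
#' the displacement vector stored at the target voxel. `displacement` is a
#' 4-D array (nx, ny, nz, 3) of mm offsets on the target grid.
#'
#' @slot affine 4x4 matrix mapping target world coordinates to source world
#'   coordinates (mm).
#' @slot displacement 4-D displacement array (mm) on the target grid, or a
#'   0-length array when the transform is purely affine.
#' @slot order B-spline interpolation order used when the transform is
#'   applied (0-5).
#' @exportClass SpatialTransform
setClass("SpatialTransform",
    representation(affine = "matrix", displacement = "array",
                   order = "integer"),
    prototype(affine = diag(4), displacement = array(0, c(0, 0, 0, 3)),
              order = 4L))

setValidity("SpatialTransform", function(object) {
    if (!all(dim(object@affine) == c(4L, 4L)) ||
        abs(det(object@affine[1:3, 1:3])) < 1e-12)
        return("affine must be an invertible 4x4 matrix")
    d <- dim(object@displacement)
    if (length(d) != 4L || d[4] != 3L)
        return("displacement must be (nx, ny, nz, 3)")
    if (object@order < 0L || object@order > 5L)
        return("interpolation order must be in 0..5")
    TRUE
})

#' MDME sequence parameters
#'
#' Timing of the multi-dynamic multi-echo acquisition used by the simplified
#' forward signal model: a set of saturation-recovery delays crossed with two
#' spin-echo readouts. All times in milliseconds.
#'
#' @slot tr repetition time (ms).
#' @slot te1,te2 first and second echo times (ms), `0 < te1 < te2 < tr`.
#' @slot ti inversion time (ms); carried for provenance, the simplified
#'   saturation-recovery model does not use it.
#' @slot delays strictly increasing saturation-recovery delays (ms), length
#'   at least 2.
#' @slot b1 global B1 transmit scale (dimensionless).
#' @exportClass SequenceParams
setClass("SequenceParams",
    representation(tr = "numeric", te1 = "numeric", te2 = "numeric",
                   ti = "numeric", delays = "numeric", b1 = "numeric"))

setValidity("SequenceParams", function(object) {
    if (!(object@te1 > 0 && object@te1 < object@te2 && object@te2 < object@tr))
        return("need 0 < te1 < te2 < tr")
    if (length(object@delays) < 2L || any(diff(object@delays) <= 0))
        return("delays must be >= 2 strictly increasing values")
    if (object@b1 <= 0) return("b1 must be positive")
    TRUE
})

#' Four-compartment relaxometry model constants
#'
#' Fixed (R1, R2, PD) of the myelin (MY), cellular (CL), free-water (FW) and
#' excess-parenchymal-water (EPW) partial volumes, under a fast-exchange
#' linear mixing rule: an observed voxel is modelled as the volume-fraction
#' weighted average of the compartment constants. `scales` holds the
#' per-observable scale used to weight the least-squares mismatch so that
#' R1 (about 1/s), R2 (about 10/s) and PD (about 100 %) contribute
#' comparably.
#'
#' @slot constants 4x3 numeric matrix, rows MY/CL/FW/EPW, columns R1/R2/PD.
#' @slot scales length-3 positive numeric, mismatch scales for R1/R2/PD.
#' @exportClass CompartmentSet
setClass("CompartmentSet",
    representation(constants = "matrix", scales = "numeric"))

setValidity("CompartmentSet", function(object) {
    if (!all(dim(object@constants) == c(4L, 3L)))
        return("constants must be 4x3 (MY,CL,FW,EPW x R1,R2,PD)")
    if (!identical(rownames(object@constants), c("MY", "CL", "FW", "EPW")))
        return("constants rows must be named MY, CL, FW, EPW")
    if (!identical(colnames(object@constants), c("R1", "R2", "PD")))
        return("constants columns must be named R1, R2, PD")
    if (any(object@constants[, c("R1", "R2")] <= 0))
        return("compartment R1/R2 must be positive")
    if (length(object@scales) != 3L || any(object@scales <= 0))
        return("scales must be 3 positive numbers")
    TRUE
})

#' Parcellated phantom region set
#'
#' The label volume of the digital brain phantom together with the region
#' bookkeeping table and per-region probabilistic maps (emulating a
#' probabilistic anatomical atlas, to be thresholded at 50 %).
#'
#' @slot labels integer-valued `QMapVolume` of tissue labels.
#' @slot rois data.frame with columns `roi`, `tissue` (label name),
#'   `class` (WM/GM/deepGM/CSF/background), `laterality`
#'   (left/right/midline), `pairId` (shared id for bilateral cortical pairs,
#'   NA otherwise).
#' @slot probMaps named list of 3-D probability arrays in `[0, 1]`, one per
#'   ROI.
#' @slot threshold probability inclusion threshold (strict `>`), 0.5.
#' @exportClass ROISet
setClass("ROISet",
    representation(labels = "QMapVolume", rois = "data.frame",
                   probMaps = "list", threshold = "numeric"),
    prototype(threshold = 0.5))

setValidity("ROISet", function(object) {
    need <- c("roi", "tissue", "class", "laterality", "pairId")
    if (!all(need %in% names(object@rois)))
        return("rois table must have roi, tissue, class, laterality, pairId")
    if (!all(object@rois$roi %in% names(object@probMaps)))
        return("every ROI needs a probability map")
    rng <- range(vapply(object@probMaps, function(p) range(p),
                        numeric(2)))
    if (rng[1] < 0 || rng[2] > 1)
        return("probability maps must lie in [0, 1]")
    TRUE
})

#' One simulated (or measured) subject
#'
#' Holds a subject's four co-registered quantitative maps plus metadata and,
#' for synthetic subjects, the generating ground truth: the realised tissue
#' table, the applied spatial transform and the lesion mask.
#'
#' @slot id subject identifier.
#' @slot age age in years.
#' @slot sex "F" or "M".
#' @slot group one of "atlasHC", "testHC", "testMS".
#' @slot maps named list of `QMapVolume` (MVF, PD, R1, R2; optionally T1w),
#'   all sharing grid and affine.
#' @slot truth data.frame: the per-tissue parameter values realised for this
#'   subject (ground truth before voxel noise).
#' @slot transform the recorded generating `SpatialTransform` (template to
#'   subject pull-back), or NULL.
#' @slot lesionMask logical/0-1 3-D array; empty (all FALSE) unless group is
#'   "testMS".
#' @slot parenchymaMask,icvMask 0/1 arrays used for global metrics.
#' @slot qc list of QC counters (e.g. clipped-voxel counts).
#' @exportClass SubjectRecord
setClass("SubjectRecord",
    representation(id = "character", age = "numeric", sex = "character",
                   group = "character", maps = "list", truth = "data.frame",
                   transform = "ANY", lesionMask = "array",
                   parenchymaMask = "array", icvMask = "array", qc = "list"))

setValidity("SubjectRecord", function(object) {
    if (!object@group %in% c("atlasHC", "testHC", "testMS"))
        return("group must be atlasHC, testHC or testMS")
    if (!all(c("MVF", "PD", "R1", "R2") %in% names(object@maps)))
        return("maps must include MVF, PD, R1, R2")
    dims <- lapply(object@maps, function(m) dim(m@data))
    if (length(unique(dims)) != 1L)
        return("all maps must share one grid")
    affs <- lapply(object@maps, function(m) m@affine)
    if (any(vapply(affs, function(a) max(abs(a - affs[[1]])) > 1e-9,
                   logical(1))))
        return("all maps must share one affine")
    if (object@group != "testMS" && any(object@lesionMask > 0))
        return("lesion mask must be empty unless group is testMS")
    TRUE
})

#' Voxel-wise normative atlas for one parameter
#'
#' Per-parameter cohort mean and sample standard deviation (n - 1) volumes on
#' the template grid, with the cohort size and a provenance tag.
#'
#' @slot param parameter identity.
#' @slot mean,sd `QMapVolume` mean and SD volumes (shared grid).
#' @slot n number of subjects averaged.
#' @slot mask 0/1 brain mask array on the template grid.
#' @slot provenance cohort manifest hash.
#' @exportClass AtlasPair
setClass("AtlasPair",
    representation(param = "character", mean = "QMapVolume",
                   sd = "QMapVolume", n = "integer", mask = "array",
                   provenance = "character"))

setValidity("AtlasPair", function(object) {
    if (!identical(dim(object@mean@data), dim(object@sd@data)))
        return("mean and SD must share one grid")
    if (min(object@sd@data) < 0)
        return("SD must be non-negative everywhere")
    if (object@n < 2L) return("atlas needs n >= 2 subjects")
    TRUE
})

#' Single-subject voxel-wise deviation result
#'
#' @slot param parameter identity.
#' @slot diff difference map (atlas mean minus subject; absolute value for
#'   PD) as a `QMapVolume`.
#' @slot z z-score map as a `QMapVolume`.
#' @slot mask 0/1 brain mask within which maps are defined.
#' @slot sdFloor the SD floor applied before division.
#' @slot flooredVoxels number of in-mask voxels whose SD was raised to the
#'   floor.
#' @slot flaggedVoxels number of in-mask voxels with |z| > 3.
#' @exportClass DeviationResult
setClass("DeviationResult",
    representation(param = "character", diff = "QMapVolume",
                   z = "QMapVolume", mask = "array", sdFloor = "numeric",
                   flooredVoxels = "integer", flaggedVoxels = "integer"))

setValidity("DeviationResult", function(object) {
    if (!identical(dim(object@diff@data), dim(object@z@data)))
        return("diff and z must share one grid")
    z <- object@z@data[object@mask > 0]
    if (any(!is.finite(z)))
        return("z must be finite inside the mask")
    TRUE
})
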