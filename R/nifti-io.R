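#' @include AllClasses.R accessors.R
NULL

#' Write a parameter map as NIfTI-1
#'
#' Stores the voxel data (float64), the affine (sform, code 2) and a
#' `"param|units"` tag in the header description field so the parameter
#' identity survives a round trip.
#'
#' @param map a `QMapVolume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
writeQMap <- function(map, path) {
    img <- RNifti::asNifti(map@data, datatype = "double")
    RNifti::sform(img) <- structure(map@affine, code = 2L)
    img$descrip <- paste(map@param, map@units, sep = "|")
    RNifti::writeNifti(img, path, datatype = "double")
    invisible(path)
}

#' Read a parameter map from NIfTI-1
#'
#' Accepts 3-D scalar volumes only; the parameter identity and units are
#' recovered from the description tag when present.
#'
#' @param path NIfTI file path.
#' @return a `QMapVolume`.
#' @export
readQMap <- function(path) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop("expected a 3-D volume, got ", length(d), "-D: ", path)
    aff <- unclass(RNifti::xform(img))
    attributes(aff) <- list(dim = c(4L, 4L))
    desc <- RNifti::niftiHeader(img)$descrip
    parts <- strsplit(desc, "|", fixed = TRUE)[[1]]
    param <- if (length(parts) >= 1 && nzchar(parts[1])) parts[1] else "other"
    units <- if (length(parts) >= 2) parts[2] else "a.u."
    qMapVolume(array(as.numeric(img), d), affine = aff, param = param,
               units = units)
}

#' Per-subject global metrics of the bundled testing groups
#'
#' A small bundled example: per-subject global brain metrics (age, brain
#' parenchymal fraction, ICV-normalised myelin volume fraction, R1, R2, PD)
#' for a four-subject healthy-control testing group and a four-patient MS
#' testing group, as used in the worked examples and the validation
#' statistics.
#'
#' @return data.frame with columns `id`, `group`, `sex`, `age`, `BPF`,
#'   `MVF`, `R1`, `R2`, `PD`.
#' @export
testingGroupMetrics <- function() {
    data.frame(
        id = c(paste0("HC", 1:4), paste0("MS", 1:4)),
        group = rep(c("testHC", "testMS"), each = 4),
        sex = c("F", "M", "M", "F", "F", "M", "F", "M"),
        age = c(28, 24, 34, 41, 26, 20, 40, 39),
        BPF = c(87.7, 88.5, 86.6, 81.3, 91.4, 77.1, 74.0, 71.1),
        MVF = c(11.6, 10.6, 10.9, 11.2, 9.1, 8.3, 7.8, 7.6),
        R1 = c(1.08, 1.05, 1.063, 1.09, 1.02, 1.00, 1.01, 0.98),
        R2 = c(11.76, 11.77, 11.65, 11.96, 11.51, 11.41, 11.12, 10.99),
        PD = c(77.9, 79.0, 78.1, 76.9, 80.0, 79.5, 78.9, 78.4))
}
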