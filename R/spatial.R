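#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Build a spatial transform
#'
#' @param affine 4x4 matrix mapping target world coordinates (mm) to source
#'   world coordinates (mm) -- the pull-back convention used by resampling.
#' @param displacement optional (nx, ny, nz, 3) array of mm offsets added
#'   after the affine, defined on the grid described by `dispAffine`.
#' @param dispAffine voxel-to-world affine of the displacement grid.
#' @param order interpolation order used when applying the transform.
#' @return a [SpatialTransform-class].
#' @export
spatialTransform <- function(affine = diag(4), displacement = NULL,
                             dispAffine = diag(4), order = 4L) {
    if (is.null(displacement)) displacement <- array(0, c(0, 0, 0, 3))
    t <- new("SpatialTransform", affine = affine,
             displacement = displacement, order = as.integer(order))
    attr(t@displacement, "dispAffine") <- dispAffine
    t
}

hasDisplacement <- function(t) prod(dim(t@displacement)[1:3]) > 0

dispAffineOf <- function(t) {
    a <- attr(t@displacement, "dispAffine")
    if (is.null(a)) diag(4) else a
}

# evaluate a transform at world points (n x 3 mm): affine part plus
# trilinearly interpolated displacement
evalTransform <- function(t, xyz) {
    out <- xyz %*% t(t@affine[1:3, 1:3])
    out <- sweep(out, 2, t@affine[1:3, 4], "+")
    if (hasDisplacement(t)) {
        dd <- dim(t@displacement)[1:3]
        vox <- worldToVoxel(xyz, dispAffineOf(t))
        for (c in 1:3)
            out[, c] <- out[, c] +
                .bsplineSample(as.numeric(t@displacement[, , , c]), dd, vox,
                               1L, FALSE)
    }
    out
}

#' @describeIn spatialTransform invert a transform; a pure affine inverts
#'   exactly, a displacement field is inverted by fixed-point iteration on
#'   the grid given by `gridDim`/`gridAffine`.
#' @param x a `SpatialTransform`.
#' @param gridDim,gridAffine grid on which to tabulate the inverse
#'   displacement (defaults to the displacement's own grid).
#' @param iterations fixed-point iterations.
#' @export
setMethod("invertTransform", "SpatialTransform",
    function(x, gridDim = NULL, gridAffine = NULL, iterations = 10L) {
        Ainv <- solve(x@affine)
        if (!hasDisplacement(x))
            return(spatialTransform(Ainv, order = x@order))
        if (is.null(gridDim)) gridDim <- dim(x@displacement)[1:3]
        if (is.null(gridAffine)) gridAffine <- dispAffineOf(x)
        xw <- voxelWorldCoords(gridDim, gridAffine)
        A <- x@affine[1:3, 1:3]; b <- x@affine[1:3, 4]
        affPart <- sweep(xw, 2, b, "-") %*% t(solve(A))
        y <- affPart
        dd <- dim(x@displacement)[1:3]
        sampleD <- function(pts) {
            vox <- worldToVoxel(pts, dispAffineOf(x))
            vapply(1:3, function(c)
                .bsplineSample(as.numeric(x@displacement[, , , c]), dd, vox,
                               1L, FALSE), numeric(nrow(pts)))
        }
        for (it in seq_len(iterations))
            y <- sweep(xw - sampleD(y), 2, b, "-") %*% t(solve(A))
        e <- y - affPart
        disp <- array(0, c(gridDim, 3))
        for (c in 1:3) disp[, , , c] <- array(e[, c], gridDim)
        spatialTransform(Ainv, disp, gridAffine, x@order)
    })

#' Resample a volume through a spatial transform
#'
#' Interpolates `map` at the transformed coordinates of a target grid using
#' a B-spline of the requested order (degree-4 by default, with the
#' recursive prefilter and mirror boundaries); voxels mapping outside the
#' source field of view are set to 0.
#'
#' @param map a `QMapVolume`.
#' @param transform a [SpatialTransform-class] (target-to-source pull-back);
#'   identity by default.
#' @param targetDim,targetAffine target grid (defaults: the source grid).
#' @param order spline order 0-5 (0 = nearest neighbour, for labels/masks).
#' @return a `QMapVolume` on the target grid.
#' @export
resampleVolume <- function(map, transform = spatialTransform(),
                           targetDim = NULL, targetAffine = NULL,
                           order = 4L) {
    if (!order %in% 0:5) stop("spline order must be in 0..5")
    if (is.null(targetDim)) targetDim <- dim(map@data)
    if (is.null(targetAffine)) targetAffine <- map@affine
    targetDim <- as.integer(targetDim)
    if (any(targetDim < 1L)) stop("degenerate target grid")
    xw <- voxelWorldCoords(targetDim, targetAffine)
    src <- evalTransform(transform, xw)
    vox <- worldToVoxel(src, map@affine)
    coef <- .bsplinePrefilter(as.numeric(map@data), dim(map@data),
                              as.integer(order))
    vals <- .bsplineSample(coef, dim(map@data), vox, as.integer(order), TRUE)
    qMapVolume(array(vals, targetDim), affine = targetAffine,
               param = map@param, units = map@units)
}

#' @export
setMethod("applyTransform", "QMapVolume",
    function(x, transform, targetDim = NULL, targetAffine = NULL,
             order = transform@order)
        resampleVolume(x, transform, targetDim, targetAffine, order))

#' Reslice a map to an isotropic grid
#'
#' Covers the same world extent at the requested isotropic spacing (default
#' 1.5 mm) with a degree-4 B-spline.
#'
#' @param map a `QMapVolume`.
#' @param spacing target spacing in mm.
#' @param order spline order.
#' @return a `QMapVolume`.
#' @export
resliceIsotropic <- function(map, spacing = 1.5, order = 4L) {
    vs <- voxelSize(map)
    d <- dim(map@data)
    extent <- vs * (d - 1)
    newDim <- pmax(2L, as.integer(floor(extent / spacing)) + 1L)
    aff <- map@affine
    R <- aff[1:3, 1:3] %*% diag(1 / vs)       # direction cosines
    newAff <- diag(4)
    newAff[1:3, 1:3] <- R %*% diag(rep(spacing, 3))
    newAff[1:3, 4] <- aff[1:3, 4]
    resampleVolume(map, spatialTransform(), newDim, newAff, order)
}

#' Bias-field correction
#'
#' Estimates a smooth multiplicative intensity field by large-kernel
#' Gaussian smoothing of the log-intensities inside the brain mask
#' (normalised convolution, so the mask boundary does not leak), divides it
#' out and rescales so the in-mask mean is preserved.
#'
#' @param map a `QMapVolume`, positive inside the mask.
#' @param mask 0/1 brain-mask array (required non-empty).
#' @param fwhmFrac kernel FWHM as a fraction of the brain extent (largest
#'   bounding-box side), default 1/3.
#' @return list with `corrected` (`QMapVolume`) and `field` (array, mean 1
#'   inside the mask).
#' @export
correctBias <- function(map, mask, fwhmFrac = 1 / 3) {
    m <- mask > 0
    if (!any(m)) stop("empty brain mask")
    vals <- map@data
    inm <- vals[m]
    if (all(inm <= 0)) stop("map must be positive inside the mask")
    floorVal <- min(inm[inm > 0])
    v <- pmax(vals, floorVal)                  # guard for log
    bb <- apply(which(m, arr.ind = TRUE), 2, range)
    extent <- max(bb[2, ] - bb[1, ] + 1)
    sigma <- fwhmFrac * extent / (2 * sqrt(2 * log(2)))
    w <- array(as.numeric(m), dim(vals))
    num <- gaussianSmooth3D(log(v) * w, sigma)
    den <- gaussianSmooth3D(w, sigma)
    logf <- num / pmax(den, 1e-12)
    logf <- logf - mean(logf[m])               # mean-1 field in log domain
    field <- exp(logf)
    corrected <- vals / field
    corrected <- corrected * mean(vals[m]) / mean(corrected[m])
    list(corrected = qMapVolume(corrected, affine = map@affine,
                                param = map@param, units = map@units),
         field = field)
}

#' Co-register a moving to a fixed volume
#'
#' In `"known"` mode the recorded generator transform is inverted and
#' returned (synthetic ground truth round-trips exactly). In
#' `"affine-estimate"` mode the translation is estimated by FFT
#' cross-correlation (integer voxel) followed by Nelder-Mead refinement of
#' translation and a global scale, maximising the normalised
#' cross-correlation of the overlapping intensities.
#'
#' @param moving,fixed `QMapVolume`s on commensurate grids.
#' @param mode "known" or "affine-estimate".
#' @param known the recorded generating [SpatialTransform-class] (template
#'   to subject pull-back) required in "known" mode; NULL means the subject
#'   was generated in template space (identity).
#' @param refine logical: run the continuous refinement after the FFT stage.
#' @return a [SpatialTransform-class] mapping fixed-space points to
#'   moving-space points (ready for [resampleVolume()]).
#' @export
coregister <- function(moving, fixed, mode = c("known", "affine-estimate"),
                       known = NULL, refine = TRUE) {
    mode <- match.arg(mode)
    if (mode == "known") {
        if (is.null(known)) return(spatialTransform())
        return(invertTransform(known))
    }
    if (!identical(dim(moving@data), dim(fixed@data)))
        stop("affine-estimate mode expects equal grids")
    d <- dim(fixed@data)
    F <- fixed@data - mean(fixed@data)
    M <- moving@data - mean(moving@data)
    cc <- Re(fft(fft(M) * Conj(fft(F)), inverse = TRUE)) / length(F)
    peak <- arrayInd(which.max(cc), d)
    shift <- peak - 1L
    shift <- ifelse(shift > d / 2, shift - d, shift)   # voxel shift of moving
    ncc <- function(par) {
        tmm <- par[1:3]
        sc <- exp(par[4])
        aff <- diag(c(rep(sc, 3), 1)); aff[1:3, 4] <- tmm
        xw <- voxelWorldCoords(d, fixed@affine)
        vox <- worldToVoxel(sweep(xw %*% diag(c(sc, sc, sc)), 2, tmm, "+"),
                            moving@affine)
        v <- .bsplineSample(as.numeric(moving@data), d, vox, 1L, FALSE)
        f <- as.numeric(fixed@data)
        suppressWarnings(stats::cor(v, f))
    }
    vs <- voxelSize(fixed)
    t0 <- shift * vs
    best <- c(t0, 0)
    if (refine) {
        opt <- stats::optim(best, function(p) -ncc(p),
                            method = "Nelder-Mead",
                            control = list(maxit = 120, reltol = 1e-7))
        best <- opt$par
    }
    quality <- ncc(best)
    if (!is.finite(quality) || quality < 0.1)
        stop("volumes do not overlap: registration quality ",
             round(quality, 3))
    sc <- exp(best[4])
    aff <- diag(c(rep(sc, 3), 1)); aff[1:3, 4] <- best[1:3]
    spatialTransform(aff, order = 4L)
}

#' Normalize a subject to the template
#'
#' Estimates (or replays) the template-space transform from the subject's
#' T1-weighted contrast only; the identical transform object is then to be
#' applied to all four parameter maps (see [applySubjectTransform()]),
#' mirroring deformation-field reuse in standard-space normalisation.
#'
#' @param t1wSubject subject T1w `QMapVolume`.
#' @param template template T1w `QMapVolume`.
#' @param mode "known" or "affine-estimate".
#' @param known recorded generating transform (see [coregister()]).
#' @return a [SpatialTransform-class].
#' @export
normalizeToTemplate <- function(t1wSubject, template,
                                mode = c("known", "affine-estimate"),
                                known = NULL) {
    mode <- match.arg(mode)
    coregister(t1wSubject, template, mode = mode, known = known)
}

#' Apply one transform to all maps of a subject
#'
#' Enforces the contract that every parameter map of a subject is moved by
#' the same transform: parameter maps are resampled with a degree-4
#' B-spline, the lesion and brain masks with nearest neighbour.
#'
#' @param subject a [SubjectRecord-class].
#' @param transform a [SpatialTransform-class].
#' @param targetDim,targetAffine target (template) grid.
#' @return the subject with all maps and masks resampled.
#' @export
applySubjectTransform <- function(subject, transform, targetDim = NULL,
                                  targetAffine = NULL) {
    srcAffine <- subject@maps[[1]]@affine
    for (p in names(subject@maps))
        subject@maps[[p]] <- resampleVolume(subject@maps[[p]], transform,
                                            targetDim, targetAffine,
                                            order = 4L)
    rs0 <- function(arr) {
        v <- qMapVolume(array(as.numeric(arr), dim(arr)), affine = srcAffine,
                        param = "mask")
        out <- resampleVolume(v, transform, targetDim, targetAffine,
                              order = 0L)@data
        array(as.numeric(out > 0.5), dim(out))
    }
    lm <- rs0(subject@lesionMask)
    subject@lesionMask <- array(lm > 0, dim(lm))
    subject@parenchymaMask <- rs0(subject@parenchymaMask)
    subject@icvMask <- rs0(subject@icvMask)
    subject
}

#' Dice overlap coefficient
#'
#' @param a,b binary masks (arrays or logical).
#' @return 2|A & B| / (|A| + |B|).
#' @export
diceCoefficient <- function(a, b) {
    a <- a > 0; b <- b > 0
    2 * sum(a & b) / (sum(a) + sum(b))
}
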