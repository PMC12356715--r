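#' @include AllClasses.R mdme.R utils.R
NULL

#' Cohort simulation settings
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults encode the
#' study conditions the package is validated under: a 58-subject healthy
#' atlas cohort aged 20-62 with the age-decade composition 18/21/10/9,
#' inter-subject multiplicative variability per tissue class and parameter
#' set to the observed cohort coefficients of variation (white matter: 9.1 %
#' MVF, 3.9 % PD, 6.6 % R1, 4.4 % R2; grey matter: 23.1 % MVF, 3.2 % PD,
#' 7.2 % R1, 6.2 % R2), and additive voxel noise of roughly 2 % of typical
#' white-matter values. Subjects are generated in template space; spatial
#' deformations (for exercising registration) are applied outward only when
#' `deformationMm > 0`.
#'
#' @slot n number of subjects (>= 1).
#' @slot gridShape,voxelSize voxel grid (>= 32 each) and spacing (mm).
#' @slot cv named list of per-class CV vectors (fraction, not %), entries
#'   WM/GM/deepGM/CSF each with MVF/PD/R1/R2.
#' @slot noiseSD additive Gaussian voxel-noise SD per parameter.
#' @slot deformationMm RMS random-deformation magnitude (mm); 0 = none.
#' @slot lesions list: `count`, `radiusVox`, `effects` (multipliers per
#'   parameter; MVF/R1/R2 < 1, PD > 1).
#' @slot msEffects diffuse normal-appearing-white-matter multipliers applied
#'   to all WM tissue of MS subjects.
#' @slot atrophyFraction fraction of parenchyma converted to CSF (outermost
#'   first) for MS subjects, emulating atrophy (lowers BPF).
#' @slot ageBins,ageWeights age-decade bins (2-column matrix) and sampling
#'   weights.
#' @slot ageSlopes named list `"tissue.param" -> relative slope per year`
#'   (centred at age 40) for injecting age effects.
#' @slot seed root RNG seed; a fixed seed makes the cohort bit-identical.
#' @exportClass CohortSpec
setClass("CohortSpec",
    representation(n = "integer", gridShape = "integer",
                   voxelSize = "numeric", cv = "list", noiseSD = "numeric",
                   deformationMm = "numeric", lesions = "list",
                   msEffects = "numeric", atrophyFraction = "numeric",
                   ageBins = "matrix", ageWeights = "numeric",
                   ageSlopes = "list", seed = "numeric"))

setValidity("CohortSpec", function(object) {
    if (object@n < 1L) return("n must be >= 1")
    if (any(object@gridShape < 32L))
        return("grid must be at least 32 voxels per axis")
    for (cl in c("WM", "GM", "deepGM", "CSF"))
        if (is.null(object@cv[[cl]]) || any(object@cv[[cl]] < 0))
            return("cv must have non-negative WM/GM/deepGM/CSF entries")
    if (any(object@noiseSD < 0)) return("noiseSD must be >= 0")
    if (object@deformationMm < 0) return("deformationMm must be >= 0")
    TRUE
})

#' @rdname CohortSpec-class
#' @param n,gridShape,voxelSize,cv,noiseSD,deformationMm,lesions,msEffects,atrophyFraction,ageBins,ageWeights,ageSlopes,seed see slot documentation.
#' @return a `CohortSpec`.
#' @export
cohortSpec <- function(n = 58,
                       gridShape = c(48L, 48L, 48L),
                       voxelSize = c(3, 3, 3),
                       cv = list(
                           WM     = c(MVF = 0.091, PD = 0.039, R1 = 0.066, R2 = 0.044),
                           GM     = c(MVF = 0.231, PD = 0.032, R1 = 0.072, R2 = 0.062),
                           deepGM = c(MVF = 0.231, PD = 0.032, R1 = 0.072, R2 = 0.062),
                           CSF    = c(MVF = 0, PD = 0.03, R1 = 0.03, R2 = 0.03)),
                       noiseSD = c(MVF = 0.4, PD = 1.0, R1 = 0.03, R2 = 0.25),
                       deformationMm = 0,
                       lesions = list(count = 3L, radiusVox = 2.5,
                                      effects = c(MVF = 0.5, PD = 1.1,
                                                  R1 = 0.8, R2 = 0.8)),
                       msEffects = c(MVF = 0.60, PD = 1.05, R1 = 0.90,
                                     R2 = 0.93),
                       atrophyFraction = 0.10,
                       ageBins = rbind(c(20, 29), c(30, 39), c(40, 49),
                                       c(50, 62)),
                       ageWeights = c(18, 21, 10, 9),
                       ageSlopes = list(),
                       seed = 1) {
    new("CohortSpec", n = as.integer(n), gridShape = as.integer(gridShape),
        voxelSize = voxelSize, cv = cv, noiseSD = noiseSD,
        deformationMm = deformationMm, lesions = lesions,
        msEffects = msEffects, atrophyFraction = atrophyFraction,
        ageBins = ageBins, ageWeights = ageWeights, ageSlopes = ageSlopes,
        seed = seed)
}

# fast-exchange mixture of the compartment constants, plus an additive
# (dR1, dR2) offset for iron-rich deep grey matter
mixTissue <- function(vMY, vCL, vFW, vEPW, dR1 = 0, dR2 = 0,
                      compartments = defaultCompartments()) {
    v <- c(vMY, vCL, vFW, vEPW)
    stopifnot(abs(sum(v) - 1) < 1e-9, all(v >= 0))
    cc <- compartments@constants
    c(MVF = 100 * vMY,
      PD = sum(v * cc[, "PD"]),
      R1 = sum(v * cc[, "R1"]) + dR1,
      R2 = sum(v * cc[, "R2"]) + dR2)
}

#' Default tissue parameter table
#'
#' Ground-truth (MVF %, PD %, R1 1/s, R2 1/s) per phantom tissue. White and
#' grey matter tissues are fast-exchange mixtures of the four-compartment
#' constants (so the compartment solver is consistent with the phantom by
#' construction); iron-rich deep grey nuclei carry an additive R1/R2 offset
#' emulating paramagnetic shortening, which deliberately places them off the
#' compartment manifold. Values land in the physiological bands: white
#' matter MVF 14.5-28.5 %, the pallidum with MVF > 15 %, R1 > 1.3,
#' R2 > 14 1/s and PD < 74 %, the insular cortex with the lowest MVF/R1/R2
#' and highest PD.
#'
#' @param compartments a [CompartmentSet-class] used for the mixing.
#' @return data.frame with columns `tissue`, `class`, `laterality`, `MVF`,
#'   `PD`, `R1`, `R2`.
#' @export
defaultTissueTable <- function(compartments = defaultCompartments()) {
    mk <- function(tissue, class, lat, v, dR1 = 0, dR2 = 0) {
        vals <- mixTissue(v[1], v[2], v[3], v[4], dR1, dR2, compartments)
        data.frame(tissue = tissue, class = class, laterality = lat,
                   MVF = vals["MVF"], PD = vals["PD"], R1 = vals["R1"],
                   R2 = vals["R2"], row.names = NULL)
    }
    lr <- function(base, class, v, dR1 = 0, dR2 = 0)
        rbind(mk(paste0(base, "L"), class, "left", v, dR1, dR2),
              mk(paste0(base, "R"), class, "right", v, dR1, dR2))
    tab <- rbind(
        mk("ccGenu", "WM", "midline", c(0.240, 0.700, 0.020, 0.040)),
        mk("ccBody", "WM", "midline", c(0.155, 0.745, 0.040, 0.060)),
        lr("cingulum", "WM", c(0.145, 0.775, 0.020, 0.060)),
        lr("internalCapsule", "WM", c(0.285, 0.685, 0.010, 0.020)),
        lr("coronaRadiata", "WM", c(0.260, 0.700, 0.010, 0.030)),
        lr("sagittalStratum", "WM", c(0.255, 0.705, 0.010, 0.030)),
        lr("frontalWM", "WM", c(0.210, 0.730, 0.020, 0.040)),
        mk("otherWM", "WM", "midline", c(0.200, 0.740, 0.020, 0.040)),
        lr("frontalCortex", "GM", c(0.040, 0.770, 0.070, 0.120)),
        lr("parietalCortex", "GM", c(0.035, 0.775, 0.070, 0.120)),
        lr("occipitalCortex", "GM", c(0.030, 0.780, 0.070, 0.120)),
        lr("insularCortex", "GM", c(0.020, 0.740, 0.100, 0.140)),
        lr("thalamus", "deepGM", c(0.120, 0.800, 0.020, 0.060), 0.05, 0.8),
        lr("putamen", "deepGM", c(0.100, 0.820, 0.020, 0.060), 0.12, 1.8),
        lr("pallidum", "deepGM", c(0.200, 0.780, 0.010, 0.010), 0.25, 3.0),
        mk("csf", "CSF", "midline", c(0, 0, 1, 0)),
        data.frame(tissue = "background", class = "background",
                   laterality = "midline", MVF = 0, PD = 0, R1 = 0, R2 = 0))
    rownames(tab) <- NULL
    validateTissueTable(tab)
    tab
}

validateTissueTable <- function(tab) {
    stopifnot(all(c("tissue", "class", "laterality", "MVF", "PD", "R1",
                    "R2") %in% names(tab)))
    if (any(tab$MVF < 0 | tab$MVF > 100 | tab$PD < 0 | tab$PD > 100))
        stop("MVF and PD must lie in [0, 100]")
    nb <- tab$class != "background"
    if (any(tab$R1[nb] <= 0) || any(tab$R2[nb] <= 0))
        stop("R1 and R2 must be positive for non-background tissue")
    if (any(tab$MVF[tab$class == "CSF"] != 0))
        stop("CSF must have MVF = 0")
    invisible(tab)
}

#' Build the parcellated digital brain phantom
#'
#' Deterministically constructs a brain-like labelled volume: an ellipsoidal
#' intracranial space with a CSF rim, a cortical grey-matter ribbon split
#' into four bilateral regions, a ventricular CSF core, six deep
#' grey-matter nuclei (thalamus, putamen, pallidum, left/right), and a
#' parcellated white-matter interior (twelve named WM regions plus a
#' catch-all). Each named region also gets a probabilistic map (its
#' indicator smoothed with a small Gaussian, emulating a probabilistic
#' anatomical atlas) to be thresholded at the 50 % level.
#'
#' @param gridShape integer length-3, all >= 32.
#' @param voxelSize voxel spacing (mm).
#' @param seed kept for interface symmetry; the construction is
#'   deterministic.
#' @param probSigma smoothing (voxels) used to build the probabilistic maps.
#' @return an [ROISet-class]; the labels volume carries the tissue names as
#'   `attr(, "tissueNames")` (label i = i-th name; 0 = background).
#' @export
makeLabelPhantom <- function(gridShape = c(48L, 48L, 48L),
                             voxelSize = c(3, 3, 3), seed = 1,
                             probSigma = 0.8) {
    gridShape <- as.integer(gridShape)
    if (any(gridShape < 32L))
        stop("grid too small: need at least 32 voxels per axis to host all tissues")
    d <- gridShape
    ctr <- (d + 1) / 2
    s <- d / 48                              # scale of the reference layout
    idx <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                       z = seq_len(d[3]))
    dx <- (idx$x - ctr[1]) / s[1]
    dy <- (idx$y - ctr[2]) / s[2]
    dz <- (idx$z - ctr[3]) / s[3]
    rad <- c(20.2, 21.5, 19.0)               # brain ellipsoid, ref voxels
    rho <- sqrt((dx / rad[1])^2 + (dy / rad[2])^2 + (dz / rad[3])^2)

    tissues <- defaultTissueTable()$tissue
    tissues <- tissues[tissues != "background"]
    code <- function(name) match(name, tissues)
    lab <- integer(length(rho))

    icv <- rho <= 1
    lab[icv] <- code("otherWM")              # provisional interior fill
    lab[icv & rho > 0.95] <- code("csf")     # subarachnoid rim
    cortex <- icv & rho > 0.80 & rho <= 0.95
    side <- ifelse(dx < 0, "L", "R")
    sector <- ifelse(dy >= abs(dz), "frontalCortex",
              ifelse(dy <= -abs(dz), "occipitalCortex",
              ifelse(dz > 0, "parietalCortex", "insularCortex")))
    lab[cortex] <- code(paste0(sector, side))[cortex]

    interior <- icv & rho <= 0.80
    sphere <- function(cx, cy, cz, r)
        (dx - cx)^2 + (dy - cy)^2 + (dz - cz)^2 <= r^2
    vent <- ((dx + 2.4)^2 / 1.8^2 + dy^2 / 5^2 + (dz - 1)^2 / 2.5^2 <= 1) |
            ((dx - 2.4)^2 / 1.8^2 + dy^2 / 5^2 + (dz - 1)^2 / 2.5^2 <= 1)
    deep <- list(
        thalamusL = sphere(-4.5, -1, 0, 3.2), thalamusR = sphere(4.5, -1, 0, 3.2),
        putamenL = sphere(-8.5, 1, 0, 2.8), putamenR = sphere(8.5, 1, 0, 2.8),
        pallidumL = sphere(-6.5, 0, -1.2, 2.0), pallidumR = sphere(6.5, 0, -1.2, 2.0))
    # assignment priority: pallidum > putamen > thalamus > ventricle
    lab[interior & vent] <- code("csf")
    lab[interior & deep$thalamusL] <- code("thalamusL")
    lab[interior & deep$thalamusR] <- code("thalamusR")
    lab[interior & deep$putamenL] <- code("putamenL")
    lab[interior & deep$putamenR] <- code("putamenR")
    lab[interior & deep$pallidumL] <- code("pallidumL")
    lab[interior & deep$pallidumR] <- code("pallidumR")

    wm <- interior & lab == code("otherWM")
    assign_wm <- function(cond, name) {
        sel <- wm & cond & lab == code("otherWM")
        lab[sel] <<- code(name)[1]
        invisible(NULL)
    }
    assign_wm(abs(dx) < 2.2 & dy > 3, "ccGenu")
    assign_wm(abs(dx) < 2.2 & dy >= -3 & dz > 2, "ccBody")
    assign_wm(abs(dx) >= 2.2 & abs(dx) < 4.5 & dz > 4 & dx < 0, "cingulumL")
    assign_wm(abs(dx) >= 2.2 & abs(dx) < 4.5 & dz > 4 & dx >= 0, "cingulumR")
    assign_wm(dx <= -4.5 & dx > -8 & abs(dy) <= 4 & abs(dz) <= 3, "internalCapsuleL")
    assign_wm(dx >= 4.5 & dx < 8 & abs(dy) <= 4 & abs(dz) <= 3, "internalCapsuleR")
    assign_wm(dz > 3 & dx < -4.5, "coronaRadiataL")
    assign_wm(dz > 3 & dx >= 4.5, "coronaRadiataR")
    assign_wm(dy < -4 & dx < -3, "sagittalStratumL")
    assign_wm(dy < -4 & dx >= 3, "sagittalStratumR")
    assign_wm(dy > 4 & dx < 0, "frontalWML")
    assign_wm(dy > 4 & dx >= 0, "frontalWMR")

    labArr <- array(lab, d)
    labVol <- qMapVolume(labArr, param = "label",
                         voxelSize = voxelSize)
    attr(labVol@data, "tissueNames") <- tissues

    ttab <- defaultTissueTable()
    roiTissues <- setdiff(tissues, c("csf", "otherWM"))
    rois <- data.frame(
        roi = roiTissues,
        tissue = roiTissues,
        class = ttab$class[match(roiTissues, ttab$tissue)],
        laterality = ttab$laterality[match(roiTissues, ttab$tissue)],
        pairId = NA_character_, stringsAsFactors = FALSE)
    # bilateral averaging applies to cortical ROI pairs
    cort <- rois$class == "GM"
    rois$pairId[cort] <- sub("[LR]$", "", rois$roi[cort])

    probMaps <- lapply(seq_len(nrow(rois)), function(i) {
        ind <- array(as.numeric(labArr == code(rois$tissue[i])), d)
        p <- gaussianSmooth3D(ind, probSigma)
        p[p < 0] <- 0; p[p > 1] <- 1
        # cap at 0.5 outside the generating region so the strict 50 %
        # threshold can never pick up neighbouring tissue
        p[ind == 0] <- pmin(p[ind == 0], 0.5)
        p
    })
    names(probMaps) <- rois$roi
    new("ROISet", labels = labVol, rois = rois, probMaps = probMaps,
        threshold = 0.5)
}

tissueNames <- function(phantom) attr(phantom@labels@data, "tissueNames")

# class lookup per label code (0 = background)
labelClasses <- function(phantom, tissueTable) {
    tn <- tissueNames(phantom)
    tissueTable$class[match(tn, tissueTable$tissue)]
}

# smooth random displacement field (mm) with RMS magnitude `amp` inside mask
randomDisplacement <- function(dim, amp, sigmaVox = 4) {
    disp <- array(0, c(dim, 3L))
    for (c in 1:3)
        disp[, , , c] <- gaussianSmooth3D(array(stats::rnorm(prod(dim)), dim),
                                          sigmaVox)
    rms <- sqrt(mean(disp^2) * 3)
    disp * (amp / max(rms, 1e-12))
}

#' Generate one synthetic subject
#'
#' Realises a subject from the phantom: each tissue's true parameter values
#' are the table values times a per-tissue, per-parameter lognormal subject
#' factor (unit mean; CV per tissue class from the cohort spec), optionally
#' modulated by injected age slopes; voxel values add Gaussian noise inside
#' the intracranial space. For MS subjects (`group = "testMS"`) diffuse
#' normal-appearing-white-matter multipliers and outer-rim atrophy are
#' applied (focal lesions are added separately by [insertLesions()]). When
#' `spec@deformationMm > 0` a smooth random deformation (plus a small random
#' translation) moves the subject out of template space; the exact transform
#' is recorded so registration can be tested against its inverse.
#'
#' Negative R1/R2 arising from noise are clipped to a small positive floor
#' and counted in the subject's QC log.
#'
#' @param phantom an [ROISet-class] from [makeLabelPhantom()].
#' @param tissueTable tissue truth table (see [defaultTissueTable()]).
#' @param spec a [CohortSpec-class].
#' @param subjectSeed integer seed that fully determines this subject.
#' @param id subject id string.
#' @param group "atlasHC", "testHC" or "testMS".
#' @param age,sex fixed values, or NULL to sample from the cohort specification.
#' @return a [SubjectRecord-class].
#' @export
generateSubject <- function(phantom, tissueTable = defaultTissueTable(),
                            spec = cohortSpec(), subjectSeed = 1,
                            id = "S001", group = "atlasHC", age = NULL,
                            sex = NULL) {
    tn <- tissueNames(phantom)
    if (!all(tn %in% tissueTable$tissue))
        stop("tissue table does not cover every phantom label")
    labArr <- phantom@labels@data
    d <- dim(labArr)
    params <- c("MVF", "PD", "R1", "R2")
    withSeed(subjectSeed, {
        if (is.null(age)) {
            bin <- sample.int(nrow(spec@ageBins), 1, prob = spec@ageWeights)
            age <- sample(seq(spec@ageBins[bin, 1], spec@ageBins[bin, 2]), 1)
        }
        if (is.null(sex)) sex <- sample(c("F", "M"), 1)

        # per-tissue, per-parameter lognormal subject factors with mean 1
        truth <- tissueTable[match(tn, tissueTable$tissue), ]
        rownames(truth) <- NULL
        for (p in params) {
            cvv <- vapply(truth$class, function(cl)
                if (cl == "background") 0 else spec@cv[[cl]][[p]], numeric(1))
            sdlog <- sqrt(log(1 + cvv^2))
            fac <- exp(stats::rnorm(nrow(truth)) * sdlog - sdlog^2 / 2)
            fac[cvv == 0] <- 1
            truth[[p]] <- truth[[p]] * fac
        }
        # injected age effects (relative slope per year, centred at 40)
        for (nm in names(spec@ageSlopes)) {
            parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
            i <- which(truth$tissue == parts[1])
            truth[i, parts[2]] <- truth[i, parts[2]] *
                (1 + spec@ageSlopes[[nm]] * (age - 40))
        }
        qc <- list(clippedTruth = 0L, clippedVoxels = 0L,
                   atrophiedVoxels = 0L)
        for (p in c("R1", "R2")) {
            bad <- truth$class != "background" & truth[[p]] <= 0
            qc$clippedTruth <- qc$clippedTruth + sum(bad)
            truth[[p]][bad] <- 1e-3
        }
        truth$MVF <- pmin(pmax(truth$MVF, 0), 100)
        truth$PD <- pmin(pmax(truth$PD, 0), 100)

        classOf <- labelClasses(phantom, tissueTable)  # per label code
        if (group == "testMS") {
            for (p in params)
                truth[[p]][truth$class == "WM"] <-
                    truth[[p]][truth$class == "WM"] * spec@msEffects[[p]]
        }

        icvMask <- array(as.numeric(labArr > 0), d)
        parenMask <- array(0, d)
        paren <- labArr > 0 &
            classOf[pmax(labArr, 1)] %in% c("WM", "GM", "deepGM")
        parenMask[paren] <- 1

        # paint template-space maps from the realised truth
        maps <- list()
        lookup <- function(vals) {
            v <- c(0, vals)[labArr + 1L]
            array(v, d)
        }
        for (p in params) maps[[p]] <- lookup(truth[[p]])

        if (group == "testMS" && spec@atrophyFraction > 0) {
            # atrophy is modelled as white-matter loss, nearest to CSF
            # first (periventricular-dominant), so cortical and deep grey
            # ROIs keep their tissue composition
            depth <- peelDepth(parenMask)
            wmVox <- which(paren & array(classOf[pmax(labArr, 1L)] == "WM",
                                         d))
            target <- min(round(spec@atrophyFraction * sum(parenMask)),
                          length(wmVox))
            sel <- wmVox[order(depth[wmVox])][seq_len(target)]
            csfRow <- truth[truth$tissue == "csf", ]
            for (p in params) maps[[p]][sel] <- csfRow[[p]]
            parenMask[sel] <- 0
            qc$atrophiedVoxels <- length(sel)
        }

        transform <- NULL
        if (spec@deformationMm > 0) {
            disp <- randomDisplacement(d, spec@deformationMm)
            shift <- stats::runif(3, -0.5, 0.5) * spec@deformationMm
            aff <- diag(4); aff[1:3, 4] <- shift
            transform <- new("SpatialTransform", affine = aff,
                             displacement = disp, order = 4L)
            for (p in params) {
                v <- qMapVolume(maps[[p]], param = p,
                                voxelSize = spec@voxelSize)
                maps[[p]] <- resampleVolume(v, transform, order = 4L)@data
            }
            labNew <- resampleVolume(
                qMapVolume(array(as.numeric(labArr), d), param = "label",
                           voxelSize = spec@voxelSize),
                transform, order = 0L)@data
            labDef <- array(as.integer(round(labNew)), d)
            icvMask <- array(as.numeric(labDef > 0), d)
            parenMask <- array(0, d)
            parenMask[labDef > 0 &
                      classOf[pmax(labDef, 1)] %in% c("WM", "GM", "deepGM")] <- 1
        }

        # additive voxel noise inside the intracranial space
        for (p in params) {
            noise <- array(stats::rnorm(prod(d), sd = spec@noiseSD[[p]]), d)
            maps[[p]] <- maps[[p]] + noise * icvMask
        }
        for (p in c("R1", "R2")) {
            bad <- icvMask > 0 & maps[[p]] <= 0
            qc$clippedVoxels <- qc$clippedVoxels + sum(bad)
            maps[[p]][bad] <- 1e-3
        }
        qmaps <- lapply(params, function(p)
            qMapVolume(maps[[p]], param = p, voxelSize = spec@voxelSize))
        names(qmaps) <- params
        new("SubjectRecord", id = id, age = as.numeric(age), sex = sex,
            group = group, maps = qmaps, truth = truth,
            transform = transform, lesionMask = array(FALSE, d),
            parenchymaMask = parenMask, icvMask = icvMask, qc = qc)
    })
}

#' Insert focal demyelinating lesions
#'
#' Samples spherical lesion centres inside white-matter labels (only where a
#' sphere of the requested radius fits entirely in white matter) and, within
#' each sphere, multiplies MVF/R1/R2 by factors below 1 and PD by a factor
#' above 1 (defaults 0.5 / 0.8 / 0.8 / 1.1), mirroring the focal pattern of
#' demyelinating disease. The lesion mask is updated; overlapping spheres
#' compound.
#'
#' @param subject a [SubjectRecord-class] with `group == "testMS"`.
#' @param phantom the [ROISet-class] the subject was generated from.
#' @param lesions list with `count`, `radiusVox`, `effects`; defaults from
#'   the subject-generating [cohortSpec()].
#' @param seed RNG seed for centre sampling.
#' @param tissueTable tissue table used to identify WM labels.
#' @return the modified [SubjectRecord-class].
#' @export
insertLesions <- function(subject, phantom,
                          lesions = cohortSpec()@lesions, seed = 1,
                          tissueTable = defaultTissueTable()) {
    if (subject@group != "testMS")
        stop("lesions can only be inserted into testMS subjects")
    if (lesions$count == 0L) return(subject)
    labArr <- phantom@labels@data
    d <- dim(labArr)
    classOf <- labelClasses(phantom, tissueTable)
    wm <- array(FALSE, d)
    wm[labArr > 0] <- classOf[labArr[labArr > 0]] == "WM"
    r <- lesions$radiusVox
    # a centre is admissible iff the full Euclidean sphere fits inside WM
    rr <- ceiling(r)
    off <- expand.grid(x = -rr:rr, y = -rr:rr, z = -rr:rr)
    off <- off[off$x^2 + off$y^2 + off$z^2 <= r^2, ]
    pad <- array(FALSE, d + 2L * rr)
    pad[rr + seq_len(d[1]), rr + seq_len(d[2]), rr + seq_len(d[3])] <- wm
    host <- array(TRUE, d)
    ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
    for (o in seq_len(nrow(off)))
        host <- host & pad[ix + rr + off$x[o], iy + rr + off$y[o],
                           iz + rr + off$z[o]]
    if (!any(host))
        stop("lesion radius exceeds the white-matter extent")
    withSeed(seed, {
        centers <- which(host)
        centers <- centers[sample.int(length(centers),
                                      min(lesions$count, length(centers)))]
        coords <- arrayInd(centers, d)
        mask <- subject@lesionMask
        for (li in seq_len(nrow(coords))) {
            cc <- coords[li, ]
            rng <- lapply(1:3, function(ax)
                max(1, floor(cc[ax] - r)):min(d[ax], ceiling(cc[ax] + r)))
            g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
            inside <- (g$x - cc[1])^2 + (g$y - cc[2])^2 + (g$z - cc[3])^2 <= r^2
            vox <- cbind(g$x, g$y, g$z)[inside, , drop = FALSE]
            for (p in names(lesions$effects))
                subject@maps[[p]]@data[vox] <-
                    subject@maps[[p]]@data[vox] * lesions$effects[[p]]
            mask[vox] <- TRUE
        }
        subject@lesionMask <- mask
    })
    validObject(subject)
    subject
}

#' Synthetic T1-weighted contrast
#'
#' Computes a T1-weighted-like image from the subject's (R1, R2, PD) maps
#' with a saturation-recovery spoiled-gradient-echo signal equation,
#' `S = PD (1 - exp(-TR R1)) exp(-TE R2)` (TR 500 ms, TE 10 ms by default).
#' The signal is linear in PD and monotone increasing in R1, so on the
#' default tissue table white matter is brighter than grey matter, which is
#' brighter than CSF.
#'
#' @param subject a [SubjectRecord-class] (or a named list of `QMapVolume`s
#'   with PD, R1, R2).
#' @param trMs,teMs repetition and echo time of the synthetic readout (ms).
#' @return a `QMapVolume` with `param = "T1w"`.
#' @export
synthT1w <- function(subject, trMs = 500, teMs = 10) {
    maps <- if (is(subject, "SubjectRecord")) subject@maps else subject
    pd <- maps$PD@data; r1 <- maps$R1@data; r2 <- maps$R2@data
    sig <- pd * (1 - exp(-trMs / 1000 * r1)) * exp(-teMs / 1000 * r2)
    qMapVolume(sig, affine = maps$PD@affine, param = "T1w", units = "a.u.")
}

#' Simulate a full cohort
#'
#' Builds the phantom once, then generates `spec@n` atlas subjects plus the
#' requested testing subjects, each from a seed derived from the root seed
#' (fixed root seed implies a bit-identical cohort). MS testing subjects
#' receive diffuse effects, atrophy and focal lesions.
#'
#' @param spec a [CohortSpec-class].
#' @param nTestHC,nTestMS number of held-out healthy / MS testing subjects.
#' @param tissueTable tissue truth table.
#' @param withT1w also attach a synthetic T1w map per subject.
#' @return list with `phantom` ([ROISet-class]), `tissueTable`, `subjects`
#'   (list of [SubjectRecord-class]) and `manifest` (data.frame: id, age,
#'   sex, group, seed).
#' @export
simulateCohort <- function(spec = cohortSpec(), nTestHC = 0L, nTestMS = 0L,
                           tissueTable = defaultTissueTable(),
                           withT1w = FALSE) {
    phantom <- makeLabelPhantom(spec@gridShape, spec@voxelSize,
                                seed = spec@seed)
    groups <- c(rep("atlasHC", spec@n), rep("testHC", nTestHC),
                rep("testMS", nTestMS))
    # stable ids per group in order of appearance
    cnt <- c(atlasHC = 0L, testHC = 0L, testMS = 0L)
    ids <- vapply(groups, function(g) {
        cnt[g] <<- cnt[g] + 1L
        sprintf("%s%03d", c(atlasHC = "HCA", testHC = "HCT",
                            testMS = "MS")[g], cnt[g])
    }, character(1))
    subjects <- vector("list", length(groups))
    for (i in seq_along(groups)) {
        sseed <- deriveSeed(spec@seed, paste0("subject:", ids[i]))
        s <- generateSubject(phantom, tissueTable, spec, sseed,
                             id = ids[i], group = groups[i])
        if (groups[i] == "testMS")
            s <- insertLesions(s, phantom, spec@lesions,
                               seed = deriveSeed(spec@seed,
                                                 paste0("lesion:", ids[i])),
                               tissueTable = tissueTable)
        if (withT1w) s@maps$T1w <- synthT1w(s)
        subjects[[i]] <- s
    }
    manifest <- data.frame(
        id = vapply(subjects, function(s) s@id, character(1)),
        age = vapply(subjects, function(s) s@age, numeric(1)),
        sex = vapply(subjects, function(s) s@sex, character(1)),
        group = vapply(subjects, function(s) s@group, character(1)),
        seed = vapply(ids, function(id) deriveSeed(spec@seed,
                                                   paste0("subject:", id)),
                      numeric(1)), row.names = NULL)
    list(phantom = phantom, tissueTable = tissueTable, subjects = subjects,
         manifest = manifest)
}
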