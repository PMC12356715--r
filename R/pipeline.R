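#' @include AllClasses.R phantom.R spatial.R atlas.R roi.R deviation.R stats.R nifti-io.R
NULL

pipelineStages <- c("simulate", "mdme", "preprocess", "build-atlas",
                    "roi-report", "deviation", "validate")

#' Pipeline configuration
#'
#' Single structured configuration for [runPipeline()]; unknown keys are
#' rejected, and all randomness derives from the one root seed. The stage
#' list must respect the canonical order simulate -> mdme -> preprocess ->
#' build-atlas -> roi-report -> deviation -> validate (stages may be
#' dropped, never reordered).
#'
#' @param seed root RNG seed.
#' @param stages character vector of stages to run (in canonical order).
#' @param cohort named list of [cohortSpec()] arguments.
#' @param nTestHC,nTestMS testing-subject counts.
#' @param normalizationMode "known" or "affine-estimate".
#' @param biasCorrect run the bias-field correction stage step.
#' @param zThreshold |z| flagging threshold.
#' @param sdFloor SD floor for z maps, NULL = 1st-percentile default.
#' @param correction multiplicity correction for age correlations.
#' @param writeVolumes write per-subject NIfTI volumes (atlases are always
#'   written).
#' @return validated config (list, class `qmriPipelineConfig`).
#' @export
pipelineConfig <- function(seed = 1,
                           stages = setdiff(pipelineStages, "mdme"),
                           cohort = list(n = 12),
                           nTestHC = 2, nTestMS = 2,
                           normalizationMode = "known",
                           biasCorrect = TRUE,
                           zThreshold = 3,
                           sdFloor = NULL,
                           correction = "bonferroni",
                           writeVolumes = FALSE) {
    cfg <- list(seed = seed, stages = stages, cohort = cohort,
                nTestHC = nTestHC, nTestMS = nTestMS,
                normalizationMode = normalizationMode,
                biasCorrect = biasCorrect, zThreshold = zThreshold,
                sdFloor = sdFloor, correction = correction,
                writeVolumes = writeVolumes)
    validatePipelineConfig(cfg)
}

validatePipelineConfig <- function(cfg) {
    known <- c("seed", "stages", "cohort", "nTestHC", "nTestMS",
               "normalizationMode", "biasCorrect", "zThreshold", "sdFloor",
               "correction", "writeVolumes")
    extra <- setdiff(names(cfg), known)
    if (length(extra))
        stop("unknown config keys: ", paste(extra, collapse = ", "))
    for (k in setdiff(known, names(cfg)))
        cfg[[k]] <- eval(formals(pipelineConfig)[[k]],
                         envir = environment(pipelineConfig))
    bad <- setdiff(cfg$stages, pipelineStages)
    if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
    # fixed order: the requested stages must appear in canonical order
    if (is.unsorted(match(cfg$stages, pipelineStages)))
        stop("pipeline stages out of order; canonical order is: ",
             paste(pipelineStages, collapse = " -> "))
    badCohort <- setdiff(names(cfg$cohort), names(formals(cohortSpec)))
    if (length(badCohort))
        stop("unknown cohort keys: ", paste(badCohort, collapse = ", "))
    class(cfg) <- "qmriPipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with [pipelineConfig()] keys.
#' @return validated config.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (!is.null(cfg$cohort)) {
        cfg$cohort <- as.list(cfg$cohort)
        # YAML 1.1 reads the bare key `n` as a boolean; restore it
        names(cfg$cohort)[names(cfg$cohort) %in% c("FALSE", "no")] <- "n"
    }
    validatePipelineConfig(cfg)
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in their fixed order -- simulate, optional
#' MDME signal refitting, preprocessing (bias correction, normalization to
#' template space), atlas building, ROI reference report, single-subject
#' deviation maps and validation statistics -- writing all artefacts plus a
#' provenance manifest (`manifest.json`) into `outDir`. The run is
#' idempotent: the same config and seed reproduce identical results and an
#' identical manifest.
#'
#' @param config from [pipelineConfig()] / [readPipelineConfig()].
#' @param outDir output directory (created).
#' @return invisibly, a list with the in-memory results (`cohort`,
#'   `atlases`, `reference`, `verdicts`, `deviations`, `validation`,
#'   `manifest`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("qmri")) {
    config <- validatePipelineConfig(unclass(config))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(package = as.character(utils::packageVersion("qmriAtlas")),
                     seed = config$seed, stages = config$stages,
                     config = config[setdiff(names(config), "stages")],
                     stageHashes = list(), files = character())
    res <- list()
    addFile <- function(path) {
        manifest$files <<- c(manifest$files, basename(path))
        path
    }
    stageHash <- function(stage, obj) {
        manifest$stageHashes[[stage]] <<-
            provenanceTag(paste(utils::capture.output(utils::str(obj)),
                                collapse = ""))
    }
    if (!"simulate" %in% config$stages)
        stop("stage 'simulate' is required: nothing to consume otherwise")

    cohortArgs <- config$cohort
    cohortArgs$seed <- deriveSeed(config$seed, "simulate")
    spec <- do.call(cohortSpec, cohortArgs)
    cohort <- simulateCohort(spec, nTestHC = config$nTestHC,
                             nTestMS = config$nTestMS, withT1w = TRUE)
    utils::write.csv(cohort$manifest,
                     addFile(file.path(outDir, "cohort_manifest.csv")),
                     row.names = FALSE)
    stageHash("simulate", cohort$manifest)
    res$cohort <- cohort
    params <- c("MVF", "PD", "R1", "R2")
    templateAffine <- cohort$phantom@labels@affine
    templateDim <- dim(cohort$phantom@labels@data)

    if ("mdme" %in% config$stages) {
        seqp <- mdmeSequence()
        comp <- defaultCompartments()
        cohort$subjects <- lapply(cohort$subjects, function(s) {
            d <- dim(s@maps$R1@data)
            inb <- which(s@icvMask > 0)
            sig <- synthesizeSignal(s@maps$R1@data[inb],
                                    s@maps$R2@data[inb],
                                    s@maps$PD@data[inb], seqp, noiseSD = 0)
            # amplitudes are already on the PD scale of the forward model;
            # the CSF anchor is for externally acquired signals
            fit <- fitQMaps(sig, seqp, comp, reference = NULL)
            for (p in c("R1", "R2", "PD", "MVF")) {
                arr <- array(0, d)
                arr[inb] <- fit[[tolower(p)]]
                s@maps[[p]]@data <- arr
            }
            s
        })
        stageHash("mdme", length(cohort$subjects))
    }

    if ("preprocess" %in% config$stages) {
        template <- buildT1wTemplate(cohort)
        cohort$subjects <- lapply(cohort$subjects, function(s) {
            if (config$biasCorrect) {
                for (p in params)
                    s@maps[[p]] <- correctBias(s@maps[[p]], s@icvMask)$corrected
            }
            tfm <- normalizeToTemplate(s@maps$T1w, template,
                                       mode = config$normalizationMode,
                                       known = s@transform)
            if (!is.null(s@transform) ||
                config$normalizationMode != "known")
                s <- applySubjectTransform(s, tfm, templateDim,
                                           templateAffine)
            s
        })
        stageHash("preprocess", config$normalizationMode)
    }

    atlases <- NULL
    if ("build-atlas" %in% config$stages) {
        brain <- brainMask(cohort$phantom)
        atlases <- lapply(params, function(p)
            buildAtlas(cohort, p, mask = brain))
        names(atlases) <- params
        template <- buildT1wTemplate(cohort)
        for (p in params) {
            writeQMap(atlasMean(atlases[[p]]),
                      addFile(file.path(outDir, paste0("atlas_", p, "_mean.nii.gz"))))
            writeQMap(atlasSD(atlases[[p]]),
                      addFile(file.path(outDir, paste0("atlas_", p, "_sd.nii.gz"))))
        }
        writeQMap(template, addFile(file.path(outDir, "template_T1w.nii.gz")))
        jsonlite::write_json(
            list(n = atlasN(atlases[[1]]),
                 provenance = atlases[[1]]@provenance),
            addFile(file.path(outDir, "atlas_sidecar.json")),
            auto_unbox = TRUE)
        stageHash("build-atlas", lapply(atlases, function(a)
            c(sum(atlasMean(a)@data), sum(atlasSD(a)@data))))
        res$atlases <- atlases
        res$template <- template
    }

    reference <- NULL
    if ("roi-report" %in% config$stages) {
        if (is.null(atlases)) stop("roi-report requires build-atlas")
        hc <- Filter(function(s) s@group == "atlasHC", cohort$subjects)
        cm <- do.call(rbind, lapply(hc, function(s) {
            df <- subjectROIMeans(s, cohort$phantom)
            df$id <- s@id
            df
        }))
        reference <- referenceTable(cm)
        utils::write.csv(reference,
                         addFile(file.path(outDir, "reference_ranges.csv")),
                         row.names = FALSE)
        test <- Filter(function(s) s@group != "atlasHC", cohort$subjects)
        verdicts <- do.call(rbind, lapply(test, function(s) {
            v <- classifySubject(subjectROIMeans(s, cohort$phantom),
                                 reference)$verdicts
            v$id <- s@id
            v
        }))
        if (!is.null(verdicts))
            utils::write.csv(verdicts,
                             addFile(file.path(outDir, "range_verdicts.csv")),
                             row.names = FALSE)
        stageHash("roi-report", reference)
        res$reference <- reference
        res$verdicts <- verdicts
        res$cohortMeans <- cm
    }

    if ("deviation" %in% config$stages) {
        if (is.null(atlases)) stop("deviation requires build-atlas")
        test <- Filter(function(s) s@group != "atlasHC", cohort$subjects)
        devs <- lapply(test, function(s) {
            rs <- lapply(params, function(p)
                zMap(atlases[[p]], s@maps[[p]], sdFloor = config$sdFloor))
            names(rs) <- params
            deviationReport(rs, cohort$phantom,
                            lesionMask = if (any(s@lesionMask)) s@lesionMask,
                            threshold = config$zThreshold)$summary
        })
        names(devs) <- vapply(test, function(s) s@id, character(1))
        devTab <- do.call(rbind, Map(function(d, id)
            cbind(id = id, d), devs, names(devs)))
        utils::write.csv(devTab,
                         addFile(file.path(outDir, "deviation_summary.csv")),
                         row.names = FALSE)
        if (length(test)) {
            s1 <- test[[length(test)]]
            for (p in params) {
                dz <- zMap(atlases[[p]], s1@maps[[p]],
                           sdFloor = config$sdFloor)
                writeQMap(dz@z, addFile(file.path(
                    outDir, paste0("zmap_", s1@id, "_", p, ".nii.gz"))))
                writeQMap(dz@diff, addFile(file.path(
                    outDir, paste0("diffmap_", s1@id, "_", p, ".nii.gz"))))
            }
        }
        stageHash("deviation", devTab)
        res$deviations <- devTab
    }

    if ("validate" %in% config$stages) {
        val <- list()
        man <- cohort$manifest
        hcman <- man[man$group == "atlasHC", ]
        ag <- splitAgeGroups(hcman)
        val$ageGroups <- ag$counts
        if (!is.null(res$cohortMeans)) {
            cmI <- res$cohortMeans[res$cohortMeans$id %in% ag$groupI$id, ]
            cmII <- res$cohortMeans[res$cohortMeans$id %in% ag$groupII$id, ]
            val$ageGroupTests <- lapply(params, function(p) {
                mw <- mannWhitney(cmI$value[cmI$param == p],
                                  cmII$value[cmII$param == p])
                data.frame(param = p, U = mw$U, p = mw$p,
                           significant = mw$significant)
            })
            val$ageGroupTests <- do.call(rbind, val$ageGroupTests)
            val$ageCorrelation <- ageCorrelation(
                res$cohortMeans, man, correction = config$correction)
        }
        if (!is.null(res$template)) {
            truthT1w <- buildT1wTemplate(
                list(synthT1w(truthMaps(cohort$phantom, cohort$tissueTable)),
                     synthT1w(truthMaps(cohort$phantom, cohort$tissueTable))))
            brain <- brainMask(cohort$phantom)
            val$cccWhole <- ccc(res$template, truthT1w, brain)$ccc
            seg <- segmentTissues(res$template, brain)
            tt <- cohort$tissueTable
            cls <- labelClasses(cohort$phantom, tt)
            lab <- cohort$phantom@labels@data
            wmTruth <- lab > 0 & cls[pmax(lab, 1)] == "WM"
            gmTruth <- lab > 0 & cls[pmax(lab, 1)] %in% c("GM", "deepGM")
            val$diceWM <- diceCoefficient(seg$labels@data == 3, wmTruth)
            val$diceGM <- diceCoefficient(seg$labels@data == 2, gmTruth)
            val$cccWM <- ccc(res$template, truthT1w, wmTruth)$ccc
            val$cccGM <- ccc(res$template, truthT1w, gmTruth)$ccc
        }
        jsonlite::write_json(val,
                             addFile(file.path(outDir, "validation.json")),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
        stageHash("validate", val)
        res$validation <- val
    }

    manifest$configHash <- provenanceTag(paste(
        utils::capture.output(utils::str(config)), collapse = ""))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
    res$manifest <- manifest
    res$outDir <- outDir
    invisible(res)
}

# noise-free template-space truth maps painted straight from the table
truthMaps <- function(phantom, tissueTable) {
    lab <- phantom@labels@data
    tn <- tissueNames(phantom)
    truth <- tissueTable[match(tn, tissueTable$tissue), ]
    d <- dim(lab)
    vs <- voxelSize(phantom@labels)
    maps <- lapply(c("MVF", "PD", "R1", "R2"), function(p)
        qMapVolume(array(c(0, truth[[p]])[lab + 1L], d),
                   affine = phantom@labels@affine, param = p))
    names(maps) <- c("MVF", "PD", "R1", "R2")
    maps
}
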