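mkVol <- function(vals, d = c(8, 8, 8), param = "MVF")
    qMapVolume(array(vals, d), voxelSize = c(2, 2, 2), param = param)

test_that("atlas mean/SD follow the n-1 sample definition", {
    v1 <- mkVol(10); v2 <- mkVol(14)
    atl <- buildAtlas(list(v1, v2), "MVF")
    expect_equal(unique(as.numeric(mapData(atlasMean(atl)))), 12)
    expect_equal(unique(as.numeric(mapData(atlasSD(atl)))), sqrt(8),
                 tolerance = 1e-9)          # 2.828, not the n-divisor 2
    expect_equal(atlasN(atl), 2L)

    idv <- replicate(5, mkVol(7), simplify = FALSE)
    atl0 <- buildAtlas(idv, "MVF")
    expect_true(all(mapData(atlasSD(atl0)) == 0))
    expect_equal(mapData(atlasMean(atl0)), mapData(idv[[1]]))

    expect_error(buildAtlas(list(v1), "MVF"), "at least 2")
    v3 <- qMapVolume(array(1, c(4, 4, 4)), param = "MVF")
    expect_error(buildAtlas(list(v1, v3), "MVF"), "mismatch")
})

test_that("a simulated cohort yields all four atlas pairs on one grid", {
    co <- simulateCohort(cohortSpec(n = 4, seed = 3))
    atlases <- lapply(c("MVF", "PD", "R1", "R2"), function(p)
        buildAtlas(co, p, mask = brainMask(co$phantom)))
    expect_length(atlases, 4)
    for (a in atlases) {
        expect_s4_class(a, "AtlasPair")
        expect_equal(atlasN(a), 4L)
        expect_true(min(mapData(atlasSD(a))) >= 0)
        expect_identical(dim(mapData(atlasMean(a))),
                         dim(mapData(atlasSD(a))))
    }
    expect_identical(atlases[[1]]@provenance, atlases[[2]]@provenance)
})

test_that("SD maps match the generator's composite noise model", {
    # voxel SD in a homogeneous tissue should be
    # sqrt((truth * cv)^2 + noiseSD^2); averaged over parameters to tame
    # the sampling error of the shared per-tissue factors
    co <- simulateCohort(cohortSpec(n = 58, seed = 6))
    ph <- co$phantom; tt <- co$tissueTable
    lab <- mapData(ph@labels); tn <- attr(lab, "tissueNames")
    ratios <- c()
    for (p in c("MVF", "PD", "R1", "R2")) {
        atl <- buildAtlas(co, p, mask = brainMask(ph))
        for (tis in c("otherWM", "frontalWML")) {
            vox <- lab == match(tis, tn)
            truth <- tt[tt$tissue == tis, p]
            pred <- sqrt((truth * cohortSpec()@cv$WM[[p]])^2 +
                         cohortSpec()@noiseSD[[p]]^2)
            ratios <- c(ratios, median(mapData(atlasSD(atl))[vox]) / pred)
        }
    }
    expect_lt(abs(mean(ratios) - 1), 0.10)
})

test_that("the T1w template is the voxel-wise mean (two-pass oracle)", {
    co <- simulateCohort(cohortSpec(n = 3, seed = 5), withT1w = TRUE)
    tpl <- buildT1wTemplate(co)
    d <- dim(mapData(tpl))
    acc <- array(0, d)
    for (s in co$subjects) acc <- acc + mapData(subjectMaps(s)$T1w)
    expect_equal(mapData(tpl), acc / 3, tolerance = 1e-12)

    one <- subjectMaps(co$subjects[[1]])$T1w
    same <- buildT1wTemplate(list(one, one))
    expect_equal(mapData(same), mapData(one), tolerance = 1e-12)

    # template preserves the WM > GM ordering of its member images
    ph <- co$phantom
    lab <- mapData(ph@labels); tn <- attr(lab, "tissueNames")
    cls <- co$tissueTable$class[match(tn, co$tissueTable$tissue)]
    wm <- mean(mapData(tpl)[lab > 0 & cls[pmax(lab, 1)] == "WM"])
    gm <- mean(mapData(tpl)[lab > 0 & cls[pmax(lab, 1)] == "GM"])
    expect_gt(wm, gm)
})

test_that("global metrics implement the ICV-normalised definitions", {
    d <- c(8, 8, 8)
    maps <- lapply(c("MVF", "PD", "R1", "R2"), function(p)
        qMapVolume(array(50, d), voxelSize = c(1, 1, 1), param = p))
    names(maps) <- c("MVF", "PD", "R1", "R2")
    icv <- array(0, d); icv[1:10] <- 1
    paren <- array(0, d); paren[1:8] <- 1
    s <- new("SubjectRecord", id = "t", age = 30, sex = "F",
             group = "atlasHC", maps = maps,
             truth = data.frame(), transform = NULL,
             lesionMask = array(FALSE, d), parenchymaMask = paren,
             icvMask = icv, qc = list())
    gm <- globalMetrics(s)
    expect_equal(gm$BPF, 80)                       # 8 of 10 ICV voxels
    expect_equal(gm$normMyelin, 100 * (8 * 0.5) / 10)
    gmFull <- globalMetrics(s, parenchymaMask = icv)
    expect_equal(gmFull$BPF, 100)
    s@maps$MVF@data[] <- 0
    expect_equal(globalMetrics(s)$normMyelin, 0)
    expect_error(globalMetrics(s, icvMask = array(0, d)), "empty")
    expect_error(globalMetrics(s, parenchymaMask = icv,
                               icvMask = paren), "contain")
})
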