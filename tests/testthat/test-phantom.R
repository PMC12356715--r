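test_that("label phantom is deterministic, partitions the grid and hosts all ROIs", {
    ph1 <- makeLabelPhantom(c(48, 48, 48), seed = 1)
    ph2 <- makeLabelPhantom(c(48, 48, 48), seed = 1)
    expect_identical(mapData(ph1@labels), mapData(ph2@labels))

    lab <- mapData(ph1@labels)
    tn <- attr(lab, "tissueNames")
    counts <- table(factor(lab, levels = 0:length(tn)))
    expect_equal(sum(counts), prod(dim(lab)))

    info <- roiInfo(ph1)
    expect_gte(sum(info$class == "WM"), 6)
    expect_gte(sum(info$class == "GM"), 4)
    expect_true(all(c("left", "right") %in%
                    info$laterality[info$class == "GM"]))
    expect_gte(sum(info$class == "deepGM"), 2)
    expect_true("csf" %in% tn)

    for (r in info$roi) {
        p <- probMap(ph1, r)
        expect_gte(max(p), 0.5)
        expect_true(min(p) >= 0 && max(p) <= 1)
        # strict 50 % mask never picks up neighbouring tissue
        m <- makeMask(p, 0.5)
        expect_true(all(lab[m] == match(r, tn)))
    }

    expect_error(makeLabelPhantom(c(16, 16, 16)), "too small")
})

test_that("a zero-variability subject reproduces the tissue table exactly", {
    ph <- defaultPhantom(); tt <- tissueTab()
    s <- quietSubject()
    lab <- mapData(ph@labels); tn <- attr(lab, "tissueNames")
    for (p in c("MVF", "PD", "R1", "R2")) {
        m <- mapData(subjectMaps(s)[[p]])
        for (tis in c("ccGenu", "insularCortexL", "pallidumR", "csf")) {
            vox <- lab == match(tis, tn)
            expect_equal(unique(m[vox]), tt[tt$tissue == tis, p],
                         tolerance = 1e-12)
        }
        expect_true(all(m[lab == 0] == 0))
    }
})

test_that("a known subject factor scales the realised ROI truth arithmetically", {
    ph <- defaultPhantom(); tt <- tissueTab()
    tt2 <- tt
    tt2$MVF[tt2$tissue == "coronaRadiataL"] <-
        1.05 * tt$MVF[tt$tissue == "coronaRadiataL"]
    s <- generateSubject(ph, tt2, quietSpec(), 3)
    m <- subjectROIMeans(s, ph)
    got <- m$value[m$roi == "coronaRadiataL" & m$param == "MVF"]
    expect_equal(got, 1.05 * tt$MVF[tt$tissue == "coronaRadiataL"],
                 tolerance = 1e-12)
})

test_that("deep grey nuclei carry the expected iron-rich signature", {
    ph <- defaultPhantom()
    s <- quietSubject()
    lab <- mapData(ph@labels); tn <- attr(lab, "tissueNames")
    pal <- lab %in% match(c("pallidumL", "pallidumR"), tn)
    m <- subjectMaps(s)
    expect_true(all(mapData(m$MVF)[pal] > 15))
    expect_true(all(mapData(m$R1)[pal] > 1.3))
    expect_true(all(mapData(m$R2)[pal] > 14))
    expect_true(all(mapData(m$PD)[pal] < 74))
})

test_that("subject generation is seed-deterministic and cohort ROI means stay unbiased", {
    ph <- defaultPhantom(); tt <- tissueTab()
    s1 <- generateSubject(ph, tt, cohortSpec(), 42)
    s2 <- generateSubject(ph, tt, cohortSpec(), 42)
    expect_identical(mapData(subjectMaps(s1)$MVF),
                     mapData(subjectMaps(s2)$MVF))
    expect_identical(s1@age, s2@age)

    # law of large numbers at n = 58: ROI means within 3 SE of table truth
    cm <- cohortMeansFixture(58, 1)$means
    ref <- referenceTable(cm)
    ref$truth <- mapply(truthValue, ref$roi, ref$param)
    z <- abs(ref$mean - ref$truth) / (ref$sd / sqrt(58))
    expect_lte(sum(z > 3), 2)   # 88 trials; >2 exceedances is implausible
})

test_that("lesion insertion matches the voxelised-sphere oracle and effect directions", {
    ph <- defaultPhantom(); tt <- tissueTab()
    s <- generateSubject(ph, tt,
                         quietSpec(atrophyFraction = 0,
                                   msEffects = c(MVF = 1, PD = 1, R1 = 1,
                                                 R2 = 1)),
                         7, group = "testMS")
    les <- list(count = 1L, radiusVox = 3,
                effects = c(MVF = 0.5, PD = 1.1, R1 = 0.8, R2 = 0.8))
    sl <- insertLesions(s, ph, les, seed = 3)
    # brute-force voxelised sphere count for r = 3
    off <- expand.grid(x = -3:3, y = -3:3, z = -3:3)
    oracle <- sum(off$x^2 + off$y^2 + off$z^2 <= 9)
    expect_equal(sum(lesionMask(sl)), oracle)
    # all four parameters move in the demyelination direction
    i <- which(lesionMask(sl))
    for (p in c("MVF", "R1", "R2"))
        expect_true(all(mapData(subjectMaps(sl)[[p]])[i] <
                        mapData(subjectMaps(s)[[p]])[i]))
    expect_true(all(mapData(subjectMaps(sl)$PD)[i] >
                    mapData(subjectMaps(s)$PD)[i]))
    # modified voxels are exactly the mask
    chg <- which(mapData(subjectMaps(sl)$MVF) !=
                 mapData(subjectMaps(s)$MVF))
    expect_identical(sort(chg), sort(i))

    s0 <- insertLesions(s, ph, list(count = 0L, radiusVox = 3,
                                    effects = les$effects), seed = 3)
    expect_identical(mapData(subjectMaps(s0)$MVF),
                     mapData(subjectMaps(s)$MVF))

    expect_error(insertLesions(s, ph, list(count = 1L, radiusVox = 40,
                                           effects = les$effects), 1),
                 "exceeds")
    expect_error(insertLesions(quietSubject(), ph, les, 1), "testMS")
})

test_that("synthetic T1w has WM > GM > CSF contrast, is deterministic and linear in PD", {
    ph <- defaultPhantom(); tt <- tissueTab()
    s <- quietSubject()
    t1 <- synthT1w(s)
    lab <- mapData(ph@labels); tn <- attr(lab, "tissueNames")
    cls <- tt$class[match(tn, tt$tissue)]
    byClass <- function(cl) mean(mapData(t1)[lab > 0 &
                                             cls[pmax(lab, 1)] == cl])
    expect_gt(byClass("WM"), byClass("GM"))
    expect_gt(byClass("GM"), byClass("CSF"))
    expect_identical(mapData(synthT1w(s)), mapData(t1))
    # doubling PD doubles the signal (linear-PD formula)
    s2 <- s
    s2@maps$PD@data <- 2 * s2@maps$PD@data
    expect_equal(mapData(synthT1w(s2)), 2 * mapData(t1), tolerance = 1e-12)
})

test_that("simulated cohorts are reproducible and atrophy spares grey-matter ROIs", {
    sp <- cohortSpec(n = 3, seed = 9)
    c1 <- simulateCohort(sp, nTestMS = 1)
    c2 <- simulateCohort(sp, nTestMS = 1)
    expect_identical(c1$manifest, c2$manifest)
    expect_identical(mapData(subjectMaps(c1$subjects[[4]])$MVF),
                     mapData(subjectMaps(c2$subjects[[4]])$MVF))
    ms <- c1$subjects[[4]]
    expect_identical(subjectGroup(ms), "testMS")
    expect_gt(sum(lesionMask(ms)), 0)
    expect_gt(ms@qc$atrophiedVoxels, 0)
    # atrophied voxels live in white matter only: GM masks keep pure tissue
    ph <- c1$phantom
    lab <- mapData(ph@labels); tn <- attr(lab, "tissueNames")
    gmMask <- makeMask(probMap(ph, "insularCortexL"), 0.5)
    pd <- mapData(subjectMaps(ms)$PD)[gmMask]
    expect_true(all(pd < 95))   # no CSF-valued (PD ~ 100) voxels leaked in
})
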