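test_that("identity resampling reproduces the volume to 1e-10", {
    set.seed(5)
    a <- array(rnorm(18 * 16 * 14), c(18, 16, 14))
    v <- qMapVolume(a, voxelSize = c(2, 2, 2))
    for (ord in c(0L, 1L, 3L, 4L, 5L)) {
        out <- resampleVolume(v, order = ord)
        expect_lt(max(abs(mapData(out) - a)), 1e-10)
    }
    expect_error(resampleVolume(v, targetDim = c(0, 4, 4)), "degenerate")
})

test_that("degree-4 B-spline reproduces a linear ramp at half-spacing (interior)", {
    d <- c(64, 8, 8)
    ramp <- array(rep(seq_len(d[1]), times = prod(d[2:3])), d)
    v <- qMapVolume(ramp, voxelSize = c(2, 1, 1))
    half <- resliceIsotropic(v, spacing = 1, order = 4L)  # halves x spacing
    hd <- dim(mapData(half))
    # deep interior: beyond the reach of the mirror-boundary transient
    xs <- 41:(hd[1] - 41)
    vals <- mapData(half)[xs, 4, 4]
    expect_lt(max(abs(vals - (1 + (xs - 1) * 0.5))), 1e-6)
})

test_that("reslicing defaults to 1.5 mm isotropic", {
    v <- qMapVolume(array(0, c(32, 32, 32)), voxelSize = c(3, 3, 3))
    out <- resliceIsotropic(v)
    expect_equal(unname(voxelSize(out)), c(1.5, 1.5, 1.5))
})

test_that("bias correction is the identity on flat maps and inverts a known field", {
    d <- c(32, 32, 32)
    ctr <- (d + 1) / 2
    idx <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                       z = seq_len(d[3]))
    rho2 <- ((idx$x - ctr[1])^2 + (idx$y - ctr[2])^2 +
             (idx$z - ctr[3])^2) / 14^2
    mask <- array(as.numeric(rho2 <= 1), d)
    flat <- qMapVolume(array(10, d), voxelSize = c(3, 3, 3))
    cb <- correctBias(flat, mask)
    expect_lt(max(abs(cb$field[mask > 0] - 1)), 1e-3)
    expect_lt(max(abs(mapData(cb$corrected)[mask > 0] - 10)), 1e-2)

    # flat map times a smooth (low-frequency) multiplicative field; the
    # kernel must be narrower than the field's spatial scale
    field <- array(exp(0.10 * sin(pi * idx$x / d[1]) *
                       cos(pi * idx$y / d[2])), d)
    biased <- qMapVolume(array(10, d) * field, voxelSize = c(3, 3, 3))
    cb2 <- correctBias(biased, mask, fwhmFrac = 0.2)
    got <- mapData(cb2$corrected)[mask > 0]
    expect_lt(max(abs(got - 10) / 10), 0.02)
    # in-mask mean preserved to 0.1 %
    expect_lt(abs(mean(got) - mean(mapData(biased)[mask > 0])) /
              mean(mapData(biased)[mask > 0]), 0.001)

    expect_error(correctBias(flat, array(0, d)), "empty")
})

test_that("co-registration recovers identity, translations and known transforms", {
    s <- quietSubject()
    t1 <- synthT1w(s)
    # moving = fixed: identity
    tf <- coregister(t1, t1, mode = "affine-estimate", refine = FALSE)
    expect_lt(max(abs(tf@affine - diag(4))), 1e-6)
    # integer shift by (3, -2, 1) voxels recovered within 0.5 voxel
    arr <- mapData(t1)
    d <- dim(arr)
    sh <- array(0, d)
    sh[4:d[1], 1:(d[2] - 2), 2:d[3]] <-
        arr[1:(d[1] - 3), 3:d[2], 1:(d[3] - 1)]
    fx <- qMapVolume(sh, voxelSize = c(3, 3, 3))
    tf <- coregister(t1, fx, mode = "affine-estimate", refine = FALSE)
    expect_lt(max(abs(tf@affine[1:3, 4] - c(-9, 6, -3))), 1.5) # 0.5 voxel
    aligned <- resampleVolume(t1, tf, order = 1L)
    expect_gt(ccc(aligned, fx)$ccc, 0.98)
    # known mode replays the generator's inverse exactly (affine part)
    sp <- quietSpec(deformationMm = 1.5)
    sd1 <- generateSubject(defaultPhantom(), tissueTab(), sp, 13)
    kt <- coregister(subjectMaps(sd1)$MVF, subjectMaps(sd1)$MVF,
                     mode = "known", known = recordedTransform(sd1))
    expect_equal(kt@affine, solve(recordedTransform(sd1)@affine),
                 tolerance = 1e-12)
    # non-overlapping (uncorrelated) volumes are rejected
    set.seed(1)
    n1 <- qMapVolume(array(rnorm(16^3), c(16, 16, 16)))
    n2 <- qMapVolume(array(rnorm(16^3), c(16, 16, 16)))
    expect_error(coregister(n1, n2, mode = "affine-estimate",
                            refine = FALSE), "overlap")
})

test_that("known-transform replay re-enters template space accurately", {
    # a finer grid so that homogeneous cores deeper than the combined
    # interpolation support (2 x 2.5 voxels) exist
    ph <- makeLabelPhantom(c(64, 64, 64), voxelSize = c(2.25, 2.25, 2.25))
    tt <- tissueTab()
    sp <- cohortSpec(gridShape = c(64, 64, 64),
                     voxelSize = c(2.25, 2.25, 2.25), cv = zeroCV(),
                     noiseSD = zeroNoise(), deformationMm = 1.5)
    s <- generateSubject(ph, tt, sp, 11)
    inv <- invertTransform(recordedTransform(s))
    back <- resampleVolume(subjectMaps(s)$MVF, inv, order = 4L)
    truth <- mapData(qmriAtlas:::truthMaps(ph, tt)$MVF)
    lab <- mapData(ph@labels)
    contrast <- diff(range(truth[lab > 0]))
    # away from boundaries: beyond the combined support of the two
    # degree-4 interpolation passes (2 x 2.5 voxels) from any value jump
    d <- dim(lab)
    jump <- array(FALSE, d)
    for (ax in 1:3) for (by in c(-1, 1)) {
        idx <- lapply(seq_along(d), function(a) seq_len(d[a]))
        idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1), d[ax])
        jump <- jump | (abs(truth - truth[idx[[1]], idx[[2]], idx[[3]]]) >
                        0.01 * contrast)
    }
    calm <- array(lab > 0 & !jump, d)
    core <- calm & qmriAtlas:::peelDepth(calm) > 5
    expect_gt(sum(core), 20)
    err <- abs(mapData(back) - truth)[core]
    expect_lt(max(err) / contrast, 0.01)

    # label overlap after replay: Dice > 0.95 against template labels
    labv <- qMapVolume(array(as.numeric(lab), d),
                       affine = mapAffine(ph@labels), param = "label")
    labDef <- resampleVolume(labv, recordedTransform(s), order = 0L)
    labBack <- resampleVolume(labDef, inv, order = 0L)
    expect_gt(diceCoefficient(mapData(labBack) > 0, lab > 0), 0.95)
})

test_that("one transform object moves all four maps of a subject", {
    ph <- defaultPhantom(); tt <- tissueTab()
    s <- generateSubject(ph, tt, quietSpec(deformationMm = 1.5), 23)
    tfm <- normalizeToTemplate(synthT1w(s), synthT1w(quietSubject()),
                               mode = "known",
                               known = recordedTransform(s))
    sN <- applySubjectTransform(s, tfm)
    # every map went through the identical transform: each re-enters
    # template space (compare against per-map manual application)
    for (p in c("MVF", "PD", "R1", "R2")) {
        manual <- resampleVolume(subjectMaps(s)[[p]], tfm, order = 4L)
        expect_identical(mapData(subjectMaps(sN)[[p]]), mapData(manual))
    }
    # template-space subject: identity transform
    s0 <- quietSubject()
    tf0 <- normalizeToTemplate(synthT1w(s0), synthT1w(s0), mode = "known",
                               known = recordedTransform(s0))
    expect_equal(tf0@affine, diag(4))
})
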