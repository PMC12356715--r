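test_that("sequence parameter validity is enforced", {
    expect_s4_class(mdmeSequence(), "SequenceParams")
    expect_error(mdmeSequence(te1 = 200, te2 = 100), "te1 < te2")
    expect_error(mdmeSequence(delays = c(500, 200)), "increasing")
})

test_that("forward signal model obeys its limits", {
    sq <- mdmeSequence()
    # R2 -> 0: both echoes identical
    s <- synthesizeSignal(1, 0, 80, sq)
    expect_equal(s[, 1, 1], s[, 2, 1], tolerance = 1e-12)
    # t -> infinity: saturation recovery complete, S -> PD exp(-R2 TE)
    sqLong <- mdmeSequence(tr = 1e6, delays = c(200, 6e5))
    s <- synthesizeSignal(1.2, 10, 80, sqLong)
    expect_equal(s[2, 1, 1], 80 * exp(-10 * 0.023), tolerance = 1e-8)
    expect_true(all(s >= 0))
    expect_error(synthesizeSignal(-1, 10, 80, sq), "non-physical")
})

test_that("synthesize -> fit round-trips R1, R2, PD to 1e-6 relative", {
    sq <- mdmeSequence()
    set.seed(11)
    r1 <- runif(200, 0.3, 2); r2 <- runif(200, 1, 20)
    pd <- runif(200, 40, 100)
    fit <- fitQMaps(synthesizeSignal(r1, r2, pd, sq), sq,
                    compartments = NULL)
    expect_lt(max(abs(fit$r1 - r1) / r1), 1e-6)
    expect_lt(max(abs(fit$r2 - r2) / r2), 1e-6)
    expect_lt(max(abs(fit$pd - pd) / pd), 1e-6)
})

test_that("fitR2 matches the closed form, flags non-decay and ignores scale", {
    sq <- mdmeSequence()
    f <- fitR2(100, 100, sq)
    expect_equal(f$r2, 0)
    expect_true(f$flagged)
    # TE2 - TE1 = 79 ms; a signal ratio of exp(-0.079 * 11.78) inverts to
    # the global white-matter-scale R2 scenario value 11.78 1/s
    f <- fitR2(100, 100 * exp(-0.079 * 11.78), sq)
    expect_equal(f$r2, 11.78, tolerance = 1e-10)
    f2 <- fitR2(200, 200 * exp(-0.079 * 11.78), sq)
    expect_equal(f2$r2, f$r2, tolerance = 1e-12)
})

test_that("fitR1PD matches the two-delay closed form and anchors PD at CSF", {
    # delays t and 2t admit a closed form: q = S2/S1 - 1, R1 = -log(q)/t
    sq <- mdmeSequence(delays = c(400, 800))
    r1true <- 1.07                     # scenario value, global R1 scale
    pdtrue <- 78
    sig <- synthesizeSignal(r1true, 0, pdtrue, sq)
    s1 <- sig[1, 1, 1]; s2 <- sig[2, 1, 1]
    closed <- -log(s2 / s1 - 1) / 0.4
    fit <- fitR1PD(matrix(sig[, 1, 1], ncol = 1), sq)
    expect_equal(fit$r1, closed, tolerance = 1e-6)
    expect_equal(fit$r1, r1true, tolerance = 1e-6)

    # CSF reference voxel is normalised to PD = 100 %
    sq4 <- mdmeSequence()
    sig <- synthesizeSignal(c(1.07, 0.25), c(12, 1), c(70, 100), sq4)
    f <- fitQMaps(sig, sq4, compartments = NULL, reference = 2)
    expect_equal(f$pd[2], 100, tolerance = 1e-8)
    expect_equal(f$pd[1], 70, tolerance = 1e-5)
    expect_equal(f$r1[1], 1.07, tolerance = 1e-6)

    # invariance to a consistent reordering of delays and signal rows
    sig1 <- matrix(synthesizeSignal(0.9, 0, 80, sq4)[, 1, 1], ncol = 1)
    a <- fitR1PD(sig1, sq4)
    b <- fitR1PD(sig1[4:1, , drop = FALSE], sq4,
                 delaysMs = rev(mdmeSequence()@delays))
    expect_equal(a$r1, b$r1, tolerance = 1e-10)
})

test_that("relaxation time/rate inversion is reciprocal and involutive", {
    expect_equal(invertRelaxation(1, 1)$r1, 1)
    r <- invertRelaxation(0.6, 0.0849)
    expect_equal(r$r2, 11.78, tolerance = 1e-3)
    twice <- invertRelaxation(r$r1, r$r2)
    expect_equal(twice$r1, 0.6)
    expect_equal(twice$r2, 0.0849)
    expect_error(invertRelaxation(0, 1), "positive")
})

test_that("the compartment solver recovers fractions exactly on-model", {
    cs <- defaultCompartments()
    cc <- cs@constants
    # pure compartments
    expect_equal(fitMVF(cc["FW", 1], cc["FW", 2], cc["FW", 3], cs)$mvf, 0)
    expect_equal(fitMVF(cc["MY", 1], cc["MY", 2], cc["MY", 3], cs)$mvf, 100)
    # forward-mix V_MY = 0.20 then invert
    v <- c(0.20, 0.70, 0.04, 0.06)
    o <- colSums(cc * v)
    f <- fitMVF(o["R1"], o["R2"], o["PD"], cs)
    expect_equal(f$mvf, 20, tolerance = 1e-6)
    expect_equal(as.numeric(f$fractions), v, tolerance = 1e-9)
    expect_false(f$flagged)
    # idempotent on compartment-consistent voxels
    o2 <- colSums(cc * as.numeric(f$fractions))
    expect_equal(fitMVF(o2["R1"], o2["R2"], o2["PD"], cs)$mvf, f$mvf,
                 tolerance = 1e-9)
})

test_that("off-model voxels get a flagged nearest-feasible simplex solution", {
    cs <- defaultCompartments()
    set.seed(21)
    r1 <- runif(50, 0.1, 4); r2 <- runif(50, 0.5, 40)
    pd <- runif(50, 20, 110)
    f <- fitMVF(r1, r2, pd, cs)
    expect_true(all(f$fractions >= 0))
    expect_true(all(f$fractions <= 1 + 1e-9))
    expect_equal(unname(rowSums(f$fractions)), rep(1, 50), tolerance = 1e-9)
    # the iron-offset pallidum sits off the mixing manifold and is flagged
    tt <- tissueTab()
    pal <- tt[tt$tissue == "pallidumL", ]
    fp <- fitMVF(pal$R1, pal$R2, pal$PD, cs)
    expect_true(fp$flagged)
})

test_that("white-matter tissue values invert to the physiological MVF band", {
    cs <- defaultCompartments()
    tt <- tissueTab()
    wm <- tt[tt$class == "WM", ]
    f <- fitMVF(wm$R1, wm$R2, wm$PD, cs)
    expect_true(all(f$mvf >= 13.89 & f$mvf <= 29.84))
})
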