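test_that("group summaries reproduce the bundled testing-group averages", {
    tg <- testingGroupMetrics()
    hc <- tg[tg$group == "testHC", ]
    gs <- groupSummary(hc$age, digits = 1)
    expect_equal(gs$mean, 31.8)
    expect_equal(gs$sd, 7.4)
    gs <- groupSummary(hc$R2)
    # the exact mean 11.785 is a rounding tie; agree with the printed
    # 11.78 to half a printed unit
    expect_equal(gs$mean, 11.785, tolerance = 1e-12)
    expect_lte(abs(gs$mean - 11.78), 0.005 + 1e-9)
    expect_equal(round(gs$sd, 2), 0.13)
    expect_equal(groupSummary(c(5, 5, 5))$sd, 0)
    one <- groupSummary(3)
    expect_true(one$flagged)
    expect_true(is.na(one$sd))
})

test_that("Mann-Whitney matches exhaustive permutation enumeration", {
    mw <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
    expect_equal(mw$U, 0)
    expect_equal(mw$p, 0.1)          # 2 of 20 assignments as extreme
    expect_false(mw$significant)

    exhaustiveP <- function(a, b) {
        n1 <- length(a)
        r <- rank(c(a, b))
        Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
        EU <- n1 * length(b) / 2
        Us <- apply(utils::combn(length(a) + length(b), n1), 2,
                    function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
        mean(abs(Us - EU) >= abs(Uobs - EU) - 1e-9)
    }
    set.seed(14)
    for (n1 in 2:6) for (n2 in n1:6) {
        a <- rnorm(n1); b <- rnorm(n2) + runif(1, -1, 1)
        expect_equal(mannWhitney(a, b)$p, exhaustiveP(a, b),
                     tolerance = 1e-12,
                     info = sprintf("n1=%d n2=%d", n1, n2))
    }

    same <- mannWhitney(c(2, 2, 2), c(2, 2))
    expect_equal(same$p, 1)
    expect_true(same$flagged)
    expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("type-I error of the rank test stays at nominal level on null cohorts", {
    set.seed(15)
    hits <- 0
    for (i in 1:500) {
        a <- exp(rnorm(10, sd = 0.09))
        b <- exp(rnorm(10, sd = 0.09))
        if (mannWhitney(a, b)$p < 0.01) hits <- hits + 1
    }
    # 500 replicates at alpha = 0.01: binomial 99 % upper bound
    expect_lte(hits, qbinom(0.995, 500, 0.01))
})

test_that("age-group splitting uses the 20-40 / 41-62 bounds", {
    man <- data.frame(id = c("a", "b", "c", "d"),
                      age = c(40, 41, 20, 62))
    g <- splitAgeGroups(man)
    expect_identical(g$groupI$id, c("a", "c"))
    expect_identical(g$groupII$id, c("b", "d"))
    expect_warning(g2 <- splitAgeGroups(
        data.frame(id = "x", age = 70)), "excluded")
    expect_equal(unname(g2$counts), c(0L, 0L))
    g3 <- splitAgeGroups(data.frame(id = character(), age = numeric()))
    expect_equal(unname(g3$counts), c(0L, 0L))

    # the default age sampler reproduces a 41/17-like split in expectation
    splits <- vapply(1:6, function(k) {
        man <- simulateCohort(cohortSpec(n = 58, gridShape = c(32, 32, 32),
                                         seed = k))$manifest
        unname(splitAgeGroups(man)$counts["groupI"])
    }, numeric(1))
    expect_gt(mean(splits), 34)
    expect_lt(mean(splits), 46)
})

test_that("age correlations recover an injected slope and only that slope", {
    ph <- defaultPhantom(); tt <- tissueTab()
    sp <- cohortSpec(ageSlopes = list(coronaRadiataL.MVF = -0.012))
    cm <- vector("list", 40)
    ages <- numeric(40)
    for (i in 1:40) {
        s <- generateSubject(ph, tt, sp,
                             qmriAtlas:::deriveSeed(4, paste0("s", i)),
                             id = sprintf("S%03d", i))
        df <- subjectROIMeans(s, ph); df$id <- s@id
        cm[[i]] <- df; ages[i] <- s@age
    }
    man <- data.frame(id = sprintf("S%03d", 1:40), age = ages)
    ac <- ageCorrelation(do.call(rbind, cm), man,
                         correction = "bonferroni", alpha = 0.01)
    sig <- ac[ac$significant, ]
    expect_equal(nrow(sig), 1)
    expect_equal(sig$roi, "coronaRadiataL")
    expect_equal(sig$param, "MVF")
    expect_lt(sig$r, 0)
})

test_that("Pearson r matches the covariance formula and degenerate input flags", {
    x <- c(1, 2, 3, 4, 5)
    y <- c(2.2, 2.8, 3.9, 5.1, 5.4)
    cm <- data.frame(roi = "r", param = "MVF", value = y,
                     id = letters[1:5])
    man <- data.frame(id = letters[1:5], age = x)
    ac <- ageCorrelation(cm, man, correction = "none")
    brute <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(ac$r, brute, tolerance = 1e-12)

    cm$value <- 3                     # exactly linear -> r = 1 case next
    expect_true(ageCorrelation(cm, man, correction = "none")$flagged)
    cm$value <- 2 * x + 1
    expect_equal(ageCorrelation(cm, man, correction = "none")$r, 1)
})

test_that("image cross-correlation bands and invariances hold", {
    set.seed(16)
    d <- c(10, 10, 10)
    a <- array(rnorm(prod(d)), d)
    expect_equal(ccc(a, a)$ccc, 1)
    expect_equal(ccc(a, a)$band, "strong")
    expect_equal(ccc(a, -a)$ccc, -1)
    # affine intensity rescaling leaves the coefficient unchanged
    b <- array(rnorm(prod(d)), d)
    expect_equal(ccc(a, b)$ccc, ccc(a, 5 * b + 3)$ccc, tolerance = 1e-12)
    # construct an exact empirical correlation of 0.55 via Gram-Schmidt
    x <- as.numeric(scale(rnorm(prod(d))))
    e <- rnorm(prod(d)); e <- resid(lm(e ~ x)); e <- as.numeric(scale(e))
    y <- 0.55 * x + sqrt(1 - 0.55^2) * e
    r <- ccc(array(x, d), array(y, d))
    expect_equal(r$ccc, 0.55, tolerance = 1e-9)
    expect_equal(r$band, "moderate")
    expect_true(ccc(array(1, d), a)$flagged)
    expect_error(ccc(a, b, mask = array(0, d)), "empty")
})

test_that("tissue segmentation recovers a well-separated 3-level phantom", {
    d <- c(16, 16, 16)
    lab <- array(sample(1:3, prod(d), replace = TRUE), d)
    set.seed(17)
    t1 <- array(c(10, 50, 90)[lab] + rnorm(prod(d), sd = 2), d)
    seg <- segmentTissues(qMapVolume(t1, param = "T1w"), array(1, d))
    expect_equal(mapData(seg$labels), lab)
    expect_true(all(diff(seg$means) > 0))      # CSF < GM < WM ordering
    expect_error(segmentTissues(qMapVolume(array(5, d), param = "T1w"),
                                array(1, d)), "modes")
})

test_that("segmenting the cohort T1w template recovers the phantom tissues", {
    co <- simulateCohort(cohortSpec(n = 6, seed = 19), withT1w = TRUE)
    tpl <- buildT1wTemplate(co)
    ph <- co$phantom
    seg <- segmentTissues(tpl, brainMask(ph))
    lab <- mapData(ph@labels); tn <- attr(lab, "tissueNames")
    cls <- co$tissueTable$class[match(tn, co$tissueTable$tissue)]
    wmTruth <- lab > 0 & cls[pmax(lab, 1)] == "WM"
    expect_gt(diceCoefficient(mapData(seg$labels) == 3, wmTruth), 0.9)
})
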