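#' @include AllClasses.R
NULL

#' Group summary (mean and sample SD)
#'
#' @param values numeric vector, `n >= 2` for a defined SD.
#' @param digits optional rounding for reporting (NULL = none).
#' @return list with `mean`, `sd` (n - 1), `n` and `flagged` (TRUE when
#'   n < 2 leaves the SD undefined).
#' @export
groupSummary <- function(values, digits = NULL) {
    n <- length(values)
    m <- mean(values)
    s <- if (n >= 2) stats::sd(values) else NA_real_
    if (!is.null(digits)) {
        m <- round(m, digits); s <- round(s, digits)
    }
    list(mean = m, sd = s, n = n, flagged = n < 2)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples: exact
#' enumeration when `min(n1, n2) <= 8` and the data are tie-free, otherwise
#' the tie-corrected normal approximation (with continuity correction).
#' Completely tied data (every value equal) short-circuit to p = 1 and are
#' flagged.
#'
#' @param a,b numeric samples.
#' @param alpha significance level (default 0.01).
#' @param exactMax largest min(n1, n2) for which the exact distribution is
#'   used.
#' @return list: `U`, `p`, `n1`, `n2`, `alpha`, `significant`, `flagged`.
#' @export
mannWhitney <- function(a, b, alpha = 0.01, exactMax = 8) {
    if (!length(a) || !length(b)) stop("both samples must be non-empty")
    U <- sum(rank(c(a, b))[seq_along(a)]) - length(a) * (length(a) + 1) / 2
    if (length(unique(c(a, b))) == 1L)
        return(list(U = U, p = 1, n1 = length(a), n2 = length(b),
                    alpha = alpha, significant = FALSE, flagged = TRUE))
    ties <- anyDuplicated(c(a, b)) > 0
    useExact <- min(length(a), length(b)) <= exactMax && !ties
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = useExact,
                                              correct = TRUE))
    list(U = unname(wt$statistic), p = wt$p.value, n1 = length(a),
         n2 = length(b), alpha = alpha, significant = wt$p.value < alpha,
         flagged = FALSE)
}

#' Split a cohort into the two age groups
#'
#' Group I: 20-40 years (inclusive); group II: 41-62 years. Ages outside
#' 20-62 are excluded with a warning.
#'
#' @param manifest data.frame with `id` and `age` columns.
#' @return list with `groupI`, `groupII` (data.frames) and `counts`.
#' @export
splitAgeGroups <- function(manifest) {
    ok <- manifest$age >= 20 & manifest$age <= 62
    if (any(!ok))
        warning(sum(!ok), " subject(s) outside the 20-62 age range excluded")
    m <- manifest[ok, , drop = FALSE]
    gI <- m[m$age <= 40, , drop = FALSE]
    gII <- m[m$age >= 41, , drop = FALSE]
    list(groupI = gI, groupII = gII,
         counts = c(groupI = nrow(gI), groupII = nrow(gII)))
}

#' Age correlations per ROI and parameter
#'
#' Pearson correlation of per-subject ROI means with age, with
#' multiple-comparison correction applied within each parameter's ROI
#' family (Bonferroni by default; Benjamini-Hochberg optional).
#'
#' @param cohortMeans stacked [subjectROIMeans()] rows with an `id` column.
#' @param manifest data.frame with `id` and `age`.
#' @param correction "bonferroni", "BH" or "none".
#' @param alpha significance level after correction (default 0.01).
#' @param family "per-parameter" (default) or "global" correction family.
#' @return data.frame: roi, param, n, r, p, pAdj, significant, flagged
#'   (zero-variance input).
#' @export
ageCorrelation <- function(cohortMeans, manifest,
                           correction = c("bonferroni", "BH", "none"),
                           alpha = 0.01,
                           family = c("per-parameter", "global")) {
    correction <- match.arg(correction)
    family <- match.arg(family)
    ages <- manifest$age[match(cohortMeans$id, manifest$id)]
    cohortMeans$age <- ages
    key <- interaction(cohortMeans$roi, cohortMeans$param, drop = TRUE)
    out <- do.call(rbind, lapply(split(cohortMeans, key), function(g) {
        if (nrow(g) < 3L) stop("age correlation needs n >= 3")
        flagged <- stats::sd(g$value) == 0 || stats::sd(g$age) == 0
        if (flagged) {
            r <- NA_real_; p <- NA_real_
        } else {
            ct <- stats::cor.test(g$age, g$value, method = "pearson")
            r <- unname(ct$estimate); p <- ct$p.value
        }
        data.frame(roi = g$roi[1], param = g$param[1], n = nrow(g), r = r,
                   p = p, flagged = flagged)
    }))
    rownames(out) <- NULL
    meth <- if (correction == "none") "none" else correction
    if (family == "per-parameter") {
        out$pAdj <- NA_real_
        for (p in unique(out$param)) {
            i <- out$param == p
            out$pAdj[i] <- stats::p.adjust(out$p[i], method = meth)
        }
    } else out$pAdj <- stats::p.adjust(out$p, method = meth)
    out$significant <- !is.na(out$pAdj) & out$pAdj < alpha
    out
}

#' Masked image cross-correlation
#'
#' Pearson correlation of the in-mask voxel intensities of two images
#' (`fslcc`-style), with the strength bands: < 0.40 weak, 0.40-0.69
#' moderate, >= 0.70 strong. Invariant to affine intensity rescaling of
#' either image.
#'
#' @param a,b `QMapVolume`s or arrays on one grid.
#' @param mask 0/1 mask (default: everywhere).
#' @return list: `ccc`, `band`, `n`, `flagged` (zero variance).
#' @export
ccc <- function(a, b, mask = NULL) {
    av <- if (is(a, "QMapVolume")) a@data else a
    bv <- if (is(b, "QMapVolume")) b@data else b
    if (!identical(dim(av), dim(bv))) stop("grid mismatch")
    if (is.null(mask)) mask <- array(1, dim(av))
    m <- mask > 0
    if (!any(m)) stop("empty mask")
    x <- av[m]; y <- bv[m]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(ccc = NA_real_, band = NA_character_, n = sum(m),
                    flagged = TRUE))
    r <- stats::cor(x, y)
    band <- if (abs(r) < 0.40) "weak" else if (abs(r) < 0.70) "moderate"
            else "strong"
    list(ccc = r, band = band, n = sum(m), flagged = FALSE)
}

#' Three-class tissue segmentation of a T1-weighted template
#'
#' Intensity-only segmentation into CSF / GM / WM: k-means seeded at the
#' 10th/50th/90th in-mask intensity percentiles, refined by a univariate
#' Gaussian-mixture EM (unequal variances), with classes labelled by
#' ascending mean intensity (CSF < GM < WM on T1w).
#'
#' @param t1w `QMapVolume`.
#' @param mask 0/1 brain mask (required: segmentation is only meaningful
#'   within the brain).
#' @param maxFit max number of voxels used to fit the mixture (all voxels
#'   are classified).
#' @return list: `labels` (`QMapVolume`, 0 outside mask, 1 CSF, 2 GM,
#'   3 WM), `means` (ordered class means), `prob` (n x 3 in-mask posterior
#'   matrix).
#' @export
segmentTissues <- function(t1w, mask, maxFit = 20000L) {
    m <- mask > 0
    x <- t1w@data[m]
    qs <- stats::quantile(x, c(0.1, 0.5, 0.9))
    if (length(unique(round(qs, 10))) < 3L)
        stop("fewer intensity modes than classes")
    km <- stats::kmeans(x, centers = matrix(sort(unique(as.numeric(qs))),
                                            ncol = 1))
    fitIdx <- if (length(x) > maxFit)
        withSeed(1, sample.int(length(x), maxFit)) else seq_along(x)
    mc <- tryCatch(
        mclust::Mclust(x[fitIdx], G = 3, modelNames = "V", verbose = FALSE),
        error = function(e) NULL)
    if (!is.null(mc) && !is.null(mc$parameters)) {
        pr <- mclust::predict.Mclust(mc, newdata = x)
        cls <- pr$classification
        post <- pr$z
        mu <- mc$parameters$mean
    } else {
        cls <- km$cluster
        post <- matrix(0, length(x), 3)
        post[cbind(seq_along(x), cls)] <- 1
        mu <- as.numeric(km$centers)
    }
    ord <- order(mu)                       # CSF < GM < WM
    relabel <- match(seq_len(3), ord)
    cls <- relabel[cls]
    post <- post[, ord, drop = FALSE]
    lab <- array(0, dim(t1w@data))
    lab[m] <- cls
    list(labels = qMapVolume(lab, affine = t1w@affine, param = "label",
                             units = "index"),
         means = sort(mu), prob = post)
}
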