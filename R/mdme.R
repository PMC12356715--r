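#' @include AllClasses.R
NULL

#' MDME sequence parameters
#'
#' Constructor with the acquisition timing used throughout: TR 6930 ms,
#' TE 23/102 ms, TI 29 ms. The saturation-recovery delay set is a synthetic
#' stand-in for the interleaved 2-D acquisition timing (which a scanner does
#' not expose voxel-wise) and spans short to near-complete recovery.
#'
#' @param tr repetition time (ms).
#' @param te1,te2 echo times (ms).
#' @param ti inversion time (ms), provenance only.
#' @param delays saturation-recovery delays (ms), strictly increasing.
#' @param b1 global B1 transmit scale.
#' @return a [SequenceParams-class] object.
#' @export
mdmeSequence <- function(tr = 6930, te1 = 23, te2 = 102, ti = 29,
                         delays = c(200, 600, 2000, 6900), b1 = 1) {
    new("SequenceParams", tr = tr, te1 = te1, te2 = te2, ti = ti,
        delays = delays, b1 = b1)
}

#' Default four-compartment constants
#'
#' Fixed (R1, R2, PD) for the myelin (MY), cellular (CL), free-water (FW)
#' and excess-parenchymal-water (EPW) partial volumes under the fast-exchange
#' linear mixing rule (observed rate = sum of fraction-weighted compartment
#' rates; same for PD). The constants are calibrated so that white-matter
#' mixtures with myelin fractions of 0.14-0.30 land inside the physiological
#' white-matter band of the four parameters (MVF about 14-30 %, PD 66-77 %,
#' R1 1.1-1.7 1/s, R2 10.8-13.7 1/s). They are configurable: proprietary
#' multi-compartment implementations do not publish their constants.
#'
#' @param scales per-observable least-squares scales for (R1, R2, PD);
#'   defaults weight rates and PD to comparable magnitude.
#' @return a [CompartmentSet-class] object.
#' @export
defaultCompartments <- function(scales = c(1, 10, 100)) {
    constants <- matrix(c(
        2.50, 24.0, 40,    # MY: short T1/T2, low water content
        0.90,  9.5, 82,    # CL: cellular parenchyma
        0.25,  1.0, 100,   # FW: free water (CSF-like)
        0.55,  5.0, 100),  # EPW: excess parenchymal water
        nrow = 4, byrow = TRUE,
        dimnames = list(c("MY", "CL", "FW", "EPW"), c("R1", "R2", "PD")))
    new("CompartmentSet", constants = constants, scales = scales)
}

#' Forward-simulate MDME signals
#'
#' Saturation-recovery spin-echo signal under monoexponential relaxation:
#' `S(t, TE) = B1 * PD * (1 - exp(-R1 t)) * exp(-R2 TE)` for each
#' saturation-recovery delay `t` and the two echo times. The model is
#' deliberately simple and exactly invertible by [fitR2()]/[fitR1PD()].
#'
#' @param r1,r2,pd numeric vectors (R1 > 0 in 1/s, R2 >= 0 in 1/s, PD >= 0
#'   in %), recycled to a common length.
#' @param seq a [SequenceParams-class] object.
#' @param noiseSD additive Gaussian noise SD (same units as the signal);
#'   0 for noise-free.
#' @param seed RNG seed used when `noiseSD > 0`.
#' @return numeric array of dim (delays, echoes = 2, voxels) with attributes
#'   `delays` (ms), `te` (ms) and `noiseSD`.
#' @export
synthesizeSignal <- function(r1, r2, pd, seq = mdmeSequence(), noiseSD = 0,
                             seed = 1) {
    n <- max(length(r1), length(r2), length(pd))
    r1 <- rep_len(r1, n); r2 <- rep_len(r2, n); pd <- rep_len(pd, n)
    if (any(r1 <= 0) || any(r2 < 0) || any(pd < 0))
        stop("non-physical inputs: need R1 > 0, R2 >= 0, PD >= 0")
    tsec <- seq@delays / 1000
    te <- c(seq@te1, seq@te2) / 1000
    rec <- 1 - exp(-outer(tsec, r1))                 # delays x voxels
    dec <- exp(-outer(te, r2))                       # echoes x voxels
    sig <- array(0, c(length(tsec), 2L, n))
    for (e in 1:2)
        sig[, e, ] <- seq@b1 * rec * matrix(pd * dec[e, ], length(tsec), n,
                                            byrow = TRUE)
    if (noiseSD > 0)
        sig <- withSeed(seed, sig + stats::rnorm(length(sig), sd = noiseSD))
    attr(sig, "delays") <- seq@delays
    attr(sig, "te") <- c(seq@te1, seq@te2)
    attr(sig, "noiseSD") <- noiseSD
    sig
}

#' Estimate R2 from the two spin echoes
#'
#' `R2 = log(S(TE1) / S(TE2)) / (TE2 - TE1)` with echo times in seconds.
#' Voxels whose second echo is not smaller than the first give R2 <= 0 and
#' are flagged (to be excluded from maps); R2 is invariant to a global
#' rescaling of both signals.
#'
#' @param s1,s2 signals at TE1 and TE2 (positive numeric vectors).
#' @param seq a [SequenceParams-class] object.
#' @return list with `r2` (1/s) and logical `flagged`.
#' @export
fitR2 <- function(s1, s2, seq = mdmeSequence()) {
    if (any(s1 <= 0) || any(s2 <= 0)) stop("signals must be positive")
    dte <- (seq@te2 - seq@te1) / 1000
    r2 <- log(s1 / s2) / dte
    list(r2 = r2, flagged = r2 <= 0)
}

#' Estimate R1 and proton density from saturation-recovery signals
#'
#' Least-squares fit of `S(t) = A (1 - exp(-R1 t))` across the delay set
#' (first-echo signals), via a vectorised golden-section search on R1 with
#' the amplitude profiled out in closed form. The amplitude is then
#' de-decayed by `exp(R2 TE1)`, divided by B1 and, when a 100 %-water
#' reference is given, normalised so that the reference amplitude reads
#' PD = 100 %.
#'
#' @param signals matrix (delays x voxels) of first-echo signals, or a
#'   vector for a single voxel.
#' @param seq a [SequenceParams-class] object.
#' @param r2 R2 estimate per voxel (1/s) used to undo the TE1 decay
#'   (default 0: amplitude returned as-is).
#' @param reference index of a 100 % water (CSF) reference voxel, or NULL to
#'   skip normalisation.
#' @param bounds search interval for R1 (1/s).
#' @param delaysMs optional delay vector (ms) overriding the sequence's
#'   (rows of `signals` in matching order); the fit is invariant to a
#'   consistent reordering of delays and rows.
#' @return list with `r1` (1/s), `pd` (%), amplitude `a`, and logical
#'   `flagged` for non-convergent (non-positive amplitude) voxels.
#' @export
fitR1PD <- function(signals, seq = mdmeSequence(), r2 = 0, reference = NULL,
                    bounds = c(1e-4, 25), delaysMs = NULL) {
    if (is.null(dim(signals))) signals <- matrix(signals, ncol = 1)
    tsec <- (if (is.null(delaysMs)) seq@delays else delaysMs) / 1000
    if (nrow(signals) != length(tsec))
        stop("signals must have one row per delay")
    nv <- ncol(signals)
    # profile likelihood of R1: A(R1) = sum(S g)/sum(g^2); maximise
    # (sum(S g))^2 / sum(g^2) by golden-section (invariant to delay order)
    score <- function(r1) {
        g <- 1 - exp(-outer(tsec, r1))              # delays x voxels
        num <- colSums(signals * g)
        den <- colSums(g * g)
        num^2 / pmax(den, 1e-300)
    }
    gr <- (sqrt(5) - 1) / 2
    lo <- rep(bounds[1], nv); hi <- rep(bounds[2], nv)
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- score(x1); f2 <- score(x2)
    for (it in 1:70) {
        takeRight <- f2 >= f1
        lo <- ifelse(takeRight, x1, lo)
        hi <- ifelse(takeRight, hi, x2)
        x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
        f1 <- score(x1); f2 <- score(x2)
    }
    r1 <- (lo + hi) / 2
    g <- 1 - exp(-outer(tsec, r1))
    a <- colSums(signals * g) / colSums(g * g)
    flagged <- !(a > 0) | !is.finite(a)
    r2 <- rep_len(r2, nv)
    pd <- a * exp(r2 * seq@te1 / 1000) / seq@b1
    if (!is.null(reference)) {
        if (pd[reference] <= 0) stop("reference voxel has non-positive PD")
        pd <- 100 * pd / pd[reference]
    }
    list(r1 = r1, pd = pd, a = a, flagged = flagged)
}

#' Convert relaxation times to rates (and back)
#'
#' `R1 = 1/T1`, `R2 = 1/T2` for times in seconds; applying the function
#' twice is the identity.
#'
#' @param t1,t2 relaxation times (s), strictly positive.
#' @return list with `r1` and `r2` (1/s).
#' @export
invertRelaxation <- function(t1, t2) {
    if (any(t1 <= 0) || any(t2 <= 0))
        stop("relaxation times must be positive")
    list(r1 = 1 / t1, r2 = 1 / t2)
}

#' Solve the four-compartment myelin volume fraction
#'
#' Finds non-negative, sum-to-one volume fractions (V_MY, V_CL, V_FW, V_EPW)
#' minimising the scaled squared mismatch between the observed (R1, R2, PD)
#' and the fraction-weighted compartment predictions (fast-exchange linear
#' mixing). Solved exactly by enumerating the 15 possible active supports
#' and solving each equality-constrained least-squares problem in closed
#' form; observations outside the compartment simplex get the
#' nearest-feasible solution and are flagged.
#'
#' @param r1,r2,pd observed values (vectors, recycled).
#' @param compartments a [CompartmentSet-class] object.
#' @param tol scaled squared-residual threshold above which a voxel is
#'   flagged as off-model.
#' @return list with `mvf` (%, = 100 V_MY), `fractions` (n x 4 matrix),
#'   `residual` (scaled L2 mismatch) and logical `flagged`.
#' @export
fitMVF <- function(r1, r2, pd, compartments = defaultCompartments(),
                   tol = 1e-6) {
    n <- max(length(r1), length(r2), length(pd))
    obs <- cbind(rep_len(r1, n), rep_len(r2, n), rep_len(pd, n))
    sc <- compartments@scales
    O <- sweep(obs, 2, sc, "/")
    M <- sweep(compartments@constants, 2, sc, "/")   # 4 x 3, scaled
    supports <- lapply(seq_len(15), function(code) which(bitwAnd(code, 2^(0:3)) > 0))
    bestRes <- rep(Inf, n)
    bestV <- matrix(0, n, 4, dimnames = list(NULL, rownames(M)))
    for (S in supports) {
        k <- length(S)
        Ms <- M[S, , drop = FALSE]
        K <- rbind(cbind(2 * Ms %*% t(Ms), 1), c(rep(1, k), 0))
        Kinv <- tryCatch(solve(K), error = function(e) NULL)
        if (is.null(Kinv)) next
        P <- 2 * Kinv[seq_len(k), seq_len(k), drop = FALSE] %*% Ms  # k x 3
        q <- Kinv[seq_len(k), k + 1]
        V <- O %*% t(P) + matrix(q, n, k, byrow = TRUE)              # n x k
        feasible <- rowSums(V < -1e-9) == 0
        if (!any(feasible)) next
        R <- O - V %*% Ms
        res <- rowSums(R * R)
        better <- feasible & (res < bestRes - 1e-15)
        if (any(better)) {
            bestRes[better] <- res[better]
            bestV[better, ] <- 0
            bestV[better, S] <- pmax(V[better, , drop = FALSE], 0)
        }
    }
    list(mvf = 100 * unname(bestV[, "MY"]), fractions = bestV,
         residual = sqrt(bestRes),
         flagged = bestRes > tol)
}

#' Full MDME map fitting
#'
#' Inverts a synthesised signal array back to (R1, R2, PD) maps and solves
#' the compartment model for MVF: R2 from the two echoes at the longest
#' delay, R1 and amplitude from the first-echo saturation-recovery curve, PD
#' normalised to an optional 100 % water reference voxel.
#'
#' @param sig signal array from [synthesizeSignal()].
#' @param seq a [SequenceParams-class] object.
#' @param compartments a [CompartmentSet-class] object, or NULL to skip MVF.
#' @param reference index of a CSF (100 % water) reference voxel, or NULL.
#' @return list with vectors `r1`, `r2`, `pd`, `mvf` (or NULL) and logical
#'   `flagged` (union of the per-step flags).
#' @export
fitQMaps <- function(sig, seq = mdmeSequence(),
                     compartments = defaultCompartments(),
                     reference = NULL) {
    nd <- dim(sig)[1]
    s1 <- sig[nd, 1, ]; s2 <- sig[nd, 2, ]
    bad <- !(s1 > 0 & s2 > 0)
    s1[bad] <- 1e-12; s2[bad] <- 1e-12
    f2 <- fitR2(s1, s2, seq)
    f1 <- fitR1PD(sig[, 1, ], seq, r2 = pmax(f2$r2, 0),
                  reference = reference)
    mvf <- if (is.null(compartments)) NULL else
        fitMVF(f1$r1, f2$r2, f1$pd, compartments)$mvf
    list(r1 = f1$r1, r2 = f2$r2, pd = f1$pd, mvf = mvf,
         flagged = bad | f2$flagged | f1$flagged)
}
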