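#' @useDynLib qmriAtlas, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# run code with a local, restored RNG state
withSeed <- function(seed, code) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    force(code)
}

# derive a child seed from a root seed and a stream label; keeps results
# reproducible per stage while funnelling all randomness through one root
deriveSeed <- function(seed, label) {
    (fnvHash(paste0(label, ":", seed)) %% 21474831) + 1
}

# FNV-1a 32-bit string hash (provenance tags, derived seeds)
fnvHash <- function(x) {
    bytes <- utf8ToInt(paste(x, collapse = "|"))
    h <- 2166136261
    for (b in bytes) {
        # xor on the low byte only (doubles keep exactness below 2^53)
        low <- h %% 256
        h <- h - low + bitwXor(as.integer(low), as.integer(b))
        # h * 16777619 mod 2^32 without exceeding double precision:
        # 16777619 = 2^24 + 403
        h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
    }
    h
}

provenanceTag <- function(x) {
    h <- fnvHash(x)
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# world coordinates (mm) of every voxel of a grid, as an n x 3 matrix
voxelWorldCoords <- function(dim, affine) {
    ijk <- as.matrix(expand.grid(i = seq_len(dim[1]) - 1,
                                 j = seq_len(dim[2]) - 1,
                                 k = seq_len(dim[3]) - 1))
    xyz <- ijk %*% t(affine[1:3, 1:3])
    sweep(xyz, 2, affine[1:3, 4], "+")
}

worldToVoxel <- function(xyz, affine) {
    inv <- solve(affine)
    out <- xyz %*% t(inv[1:3, 1:3])
    sweep(out, 2, inv[1:3, 4], "+")   # 0-based voxel coordinates
}

# separable Gaussian smoothing with mirror boundaries; sigma in voxels,
# scalar or length 3
gaussianSmooth3D <- function(arr, sigma) {
    sigma <- rep(sigma, length.out = 3)
    d <- dim(arr)
    for (ax in 1:3) {
        if (sigma[ax] <= 0) next
        n <- d[ax]
        r <- max(1L, ceiling(3 * sigma[ax]))
        k <- stats::dnorm(seq(-r, r), sd = sigma[ax])
        k <- k / sum(k)
        # banded smoothing matrix with mirror boundary handling
        S <- matrix(0, n, n)
        for (off in seq(-r, r)) {
            idx <- seq_len(n) + off
            idx <- mirrorIdx(idx, n)
            S[cbind(seq_len(n), idx)] <- S[cbind(seq_len(n), idx)] +
                k[off + r + 1]
        }
        arr <- applyAxisMatrix(arr, S, ax)
    }
    arr
}

mirrorIdx <- function(i, n) {
    if (n == 1L) return(rep(1L, length(i)))
    period <- 2L * n - 2L
    i <- (i - 1L) %% period
    i[i < 0] <- i[i < 0] + period
    ifelse(i >= n, period - i, i) + 1L
}

# multiply an n x n matrix along one axis of a 3-D array
applyAxisMatrix <- function(arr, S, axis) {
    d <- dim(arr)
    perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(arr, perm)
    dp <- dim(a)
    m <- S %*% matrix(a, nrow = dp[1])
    a <- array(m, dp)
    aperm(a, order(perm))
}

# 6-neighbourhood binary erosion
erodeMask <- function(mask, iterations = 1L) {
    m <- mask > 0
    d <- dim(m)
    shift <- function(x, ax, by) {
        idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
        src <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
        pad <- idx
        pad[[ax]] <- src
        out <- x[pad[[1]], pad[[2]], pad[[3]], drop = FALSE]
        # treat out-of-volume as background
        if (by > 0) {
            edge <- idx; edge[[ax]] <- (d[ax] - by + 1L):d[ax]
            out[edge[[1]], edge[[2]], edge[[3]]] <- FALSE
        } else if (by < 0) {
            edge <- idx; edge[[ax]] <- 1L:(-by)
            out[edge[[1]], edge[[2]], edge[[3]]] <- FALSE
        }
        out
    }
    for (it in seq_len(iterations)) {
        keep <- m
        for (ax in 1:3) for (by in c(-1L, 1L))
            keep <- keep & shift(m, ax, by)
        m <- keep
    }
    m
}

# distance (in erosion steps) from the outside of a mask; cheap layered peel
peelDepth <- function(mask, maxDepth = 64L) {
    depth <- array(0L, dim(mask))
    m <- mask > 0
    d <- 0L
    while (any(m) && d < maxDepth) {
        d <- d + 1L
        depth[m] <- d
        m <- erodeMask(m, 1L)
    }
    depth
}
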