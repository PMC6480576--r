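# Independent oracles, written directly from the defining formulas and kept
# deliberately naive; the production code must agree with them.

naiveSkewness <- function(x) {
    n <- length(x)
    m <- sum(x) / n
    (sum((x - m)^3) / (n - 1)) / ((sum((x - m)^2) / (n - 1))^(3 / 2))
}

naiveKurtosis <- function(x, excess = FALSE) {
    n <- length(x)
    m <- sum(x) / n
    k <- (sum((x - m)^4) / (n - 1)) / ((sum((x - m)^2) / (n - 1))^2)
    if (excess) k - 3 else k
}

naiveCyhelsky <- function(x) {
    m <- sum(x) / length(x)
    nb <- 0; na <- 0
    for (v in x) {
        if (v < m) nb <- nb + 1
        if (v > m) na <- na + 1
    }
    (nb - na) / length(x)
}

naiveMES <- function(x) {
    n <- length(x)
    m <- sum(x) / n
    s <- sqrt(sum((x - m)^2) / (n - 1))
    xs <- sort(x)
    md <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
    3 * (m - md) / s
}

# Breadth-first flood fill over a 3D grid: queue of voxels, one pop at a
# time. Independent of the package's frontier-batch implementation.
floodFillOracle <- function(counts, seed, connectivity = 26,
                            includeFraction = 0.5) {
    dims <- dim(counts)
    thr <- includeFraction * counts[seed[1], seed[2], seed[3]]
    offs <- if (connectivity == 6) {
        list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
             c(0, 0, -1), c(0, 0, 1))
    } else {
        o <- list()
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
            if (dx != 0 || dy != 0 || dz != 0)
                o[[length(o) + 1]] <- c(dx, dy, dz)
        o
    }
    offMat <- do.call(rbind, offs)
    inRegion <- array(FALSE, dims)
    inRegion[seed[1], seed[2], seed[3]] <- TRUE
    queue <- list(seed)
    while (length(queue)) {
        v <- queue[[1]]
        queue <- queue[-1]
        nb <- sweep(offMat, 2, v, "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
              nb[, 2] >= 1 & nb[, 2] <= dims[2] &
              nb[, 3] >= 1 & nb[, 3] <= dims[3]
        for (r in which(ok)) {
            w <- nb[r, ]
            if (!inRegion[w[1], w[2], w[3]] &&
                counts[w[1], w[2], w[3]] >= thr) {
                inRegion[w[1], w[2], w[3]] <- TRUE
                queue[[length(queue) + 1]] <- w
            }
        }
    }
    inRegion
}

# Mann-Whitney U by full pairwise enumeration (pairs with a > b plus half
# the tied pairs).
bruteU <- function(a, b) {
    u <- 0
    for (x in a) for (y in b)
        u <- u + (x > y) + 0.5 * (x == y)
    u
}

# AUC as the concordant-pair fraction (ties count one half).
bruteAUC <- function(scores, positive) {
    pos <- scores[positive]
    neg <- scores[!positive]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}
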