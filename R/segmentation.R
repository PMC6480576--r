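#' Whole-brain single-threshold mask
#'
#' Includes every voxel whose count value is strictly greater than the
#' threshold. The default threshold of 15 counts removes the background
#' outside the head, leaving the whole brain as the region of interest.
#'
#' @param volume a \linkS4class{SpectVolume}.
#' @param threshold count threshold (>= 0); inclusion is strict (`count >
#'   threshold`).
#' @return A \linkS4class{VoxelMask}.
#' @export
thresholdMask <- function(volume, threshold = 15) {
    stopifnot(is(volume, "SpectVolume"))
    if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
    VoxelMask(voxelCounts(volume) > threshold, voxelSpacing(volume))
}

#' Locate the hottest voxel (region-growing seed)
#'
#' Returns the index of the global maximum count, optionally restricted to a
#' mask or to a range of axial slices. In DAT imaging the striatum is the
#' hottest structure, so the global maximum inside the brain mask is a
#' reliable automatic seed; the restriction arguments support operator
#' overrides for pathological cases. Ties are broken by the lexicographically
#' smallest (i, j, k) index.
#'
#' @param volume a \linkS4class{SpectVolume}.
#' @param within optional \linkS4class{VoxelMask} restricting the search.
#' @param sliceRange optional integer(2), inclusive range of axial (third
#'   axis) slices to search.
#' @return integer(3) voxel index.
#' @export
findSeed <- function(volume, within = NULL, sliceRange = NULL) {
    stopifnot(is(volume, "SpectVolume"))
    a <- voxelCounts(volume)
    keep <- array(TRUE, dim(a))
    if (!is.null(within)) {
        stopifnot(is(within, "VoxelMask"))
        if (!identical(dim(maskFlags(within)), dim(a)))
            stop("mask shape does not match the volume", call. = FALSE)
        keep <- keep & maskFlags(within)
    }
    if (!is.null(sliceRange)) {
        sl <- logical(dim(a)[3])
        sl[sliceRange[1]:sliceRange[2]] <- TRUE
        keep <- keep & rep(sl, each = dim(a)[1] * dim(a)[2])
    }
    if (!any(keep)) stop("empty search region for seed", call. = FALSE)
    vals <- a[keep]
    mx <- max(vals)
    cand <- which(keep & a == mx)
    ijk <- arrayInd(cand, dim(a))
    ijk <- ijk[order(ijk[, 1], ijk[, 2], ijk[, 3]), , drop = FALSE]
    as.integer(ijk[1, ])
}

.neighborOffsets <- function(connectivity) {
    if (connectivity == 6L) {
        rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
              c(0, 0, -1), c(0, 0, 1))
    } else if (connectivity == 26L) {
        g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
        dimnames(g) <- NULL
        g[rowSums(abs(g)) > 0, , drop = FALSE]
    } else stop("connectivity must be 6 or 26", call. = FALSE)
}

#' 3D seed region growing
#'
#' Grows the connected component containing the seed under the relative
#' inclusion rule `count >= includeFraction * seed count` (and
#' `>= absoluteFloor` when given). The result is independent of traversal
#' order: it is exactly the set of voxels connected to the seed through
#' voxels satisfying the rule. The default 50%-of-maximum isocontour is the
#' standard nuclear-medicine volumetric convention.
#'
#' @param volume a \linkS4class{SpectVolume}.
#' @param seed integer(3) voxel index with a positive count.
#' @param connectivity 26 (full 3D neighbourhood, default) or 6 (faces only).
#' @param includeFraction fraction of the seed count in (0, 1] that a voxel
#'   must reach to join the region.
#' @param absoluteFloor optional absolute count floor added to the rule.
#' @return A \linkS4class{VoxelMask}.
#' @examples
#' v <- SpectVolume(array(c(10, 15, 16, 20), c(2, 2, 1)))
#' sum(maskFlags(regionGrow(v, findSeed(v), includeFraction = 0.8)))
#' @export
regionGrow <- function(volume, seed, connectivity = 26,
                       includeFraction = 0.5, absoluteFloor = NULL) {
    stopifnot(is(volume, "SpectVolume"))
    a <- voxelCounts(volume)
    dims <- dim(a)
    seed <- as.integer(seed)
    if (length(seed) != 3L || any(seed < 1L) || any(seed > dims))
        stop("seed index out of bounds", call. = FALSE)
    if (includeFraction <= 0 || includeFraction > 1)
        stop("includeFraction must be in (0, 1]", call. = FALSE)
    seedCount <- a[seed[1], seed[2], seed[3]]
    if (seedCount <= 0)
        stop("seed count must be positive (relative rule undefined)",
             call. = FALSE)
    thr <- includeFraction * seedCount
    if (!is.null(absoluteFloor)) thr <- max(thr, absoluteFloor)
    eligible <- a >= thr
    offs <- .neighborOffsets(as.integer(connectivity))
    visited <- array(FALSE, dims)
    visited[seed[1], seed[2], seed[3]] <- TRUE
    strides <- c(1L, dims[1], dims[1] * dims[2])
    frontier <- matrix(seed, nrow = 1)
    while (nrow(frontier) > 0) {
        nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
            cbind(frontier[, 1] + offs[o, 1], frontier[, 2] + offs[o, 2],
                  frontier[, 3] + offs[o, 3])))
        ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
              nb[, 2] >= 1L & nb[, 2] <= dims[2] &
              nb[, 3] >= 1L & nb[, 3] <= dims[3]
        nb <- nb[ok, , drop = FALSE]
        lin <- 1L + (nb[, 1] - 1L) * strides[1] + (nb[, 2] - 1L) * strides[2] +
            (nb[, 3] - 1L) * strides[3]
        first <- !duplicated(lin)
        nb <- nb[first, , drop = FALSE]
        lin <- lin[first]
        grow <- eligible[lin] & !visited[lin]
        visited[lin[grow]] <- TRUE
        frontier <- nb[grow, , drop = FALSE]
    }
    VoxelMask(visited, voxelSpacing(volume))
}

#' Segment the striatal activity region
#'
#' Full striatal segmentation as used by the feature pipeline: a whole-brain
#' threshold mask localizes the seed (the hottest voxel in the brain), seed
#' region growing extracts the primary striatal activity region, and - since
#' striatal uptake is bilateral - a second pass grows from the hottest voxel
#' outside the first region, keeping it only when its seed count is
#' comparable to the primary seed (`secondaryRatio`). This captures both
#' striata whether or not they merge at the half-maximum level.
#'
#' @param volume a \linkS4class{SpectVolume}.
#' @param threshold whole-brain count threshold (default 15).
#' @param connectivity 26 or 6.
#' @param includeFraction relative growth rule fraction, default 0.5.
#' @param bilateral grow a second, contralateral region (default TRUE).
#' @param secondaryRatio minimum secondary/primary seed-count ratio for the
#'   second region to be accepted.
#' @param seed optional explicit integer(3) seed overriding localization.
#' @param sliceRange optional axial slice range for seed localization.
#' @return A \linkS4class{VoxelMask} of the striatal activity region.
#' @export
growStriatum <- function(volume, threshold = 15, connectivity = 26,
                         includeFraction = 0.5, bilateral = TRUE,
                         secondaryRatio = 0.7, seed = NULL,
                         sliceRange = NULL) {
    brain <- thresholdMask(volume, threshold)
    if (!any(maskFlags(brain)))
        stop("empty brain mask: no voxel exceeds threshold ", threshold,
             call. = FALSE)
    a <- voxelCounts(volume)
    if (is.null(seed))
        seed <- findSeed(volume, within = brain, sliceRange = sliceRange)
    primary <- regionGrow(volume, seed, connectivity, includeFraction)
    region <- maskFlags(primary)
    if (bilateral) {
        rest <- maskFlags(brain) & !region
        if (any(rest)) {
            seed2 <- findSeed(volume, within = VoxelMask(rest,
                                                         voxelSpacing(volume)))
            c1 <- a[seed[1], seed[2], seed[3]]
            c2 <- a[seed2[1], seed2[2], seed2[3]]
            if (c2 >= secondaryRatio * c1) {
                second <- regionGrow(volume, seed2, connectivity,
                                     includeFraction)
                region <- region | maskFlags(second)
            }
        }
    }
    VoxelMask(region, voxelSpacing(volume))
}
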