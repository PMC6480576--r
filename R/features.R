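#' Histogram shape statistics of a count sample
#'
#' The four whole-brain activity-distribution features. All use the sample
#' (n-1) denominator convention for the variance-type terms:
#' \describe{
#'   \item{`sampleSkewness`}{third-moment skewness,
#'     \eqn{(\sum d_i^3/(n-1)) / (\sum d_i^2/(n-1))^{3/2}} with
#'     \eqn{d_i = x_i - \bar x}.}
#'   \item{`sampleKurtosis`}{fourth-moment kurtosis,
#'     \eqn{(\sum d_i^4/(n-1)) / (\sum d_i^2/(n-1))^2}; with `excess = TRUE`
#'     3 is subtracted so a normal sample scores ~0. The default is the
#'     non-excess convention, on which a normal sample scores ~3.}
#'   \item{`cyhelskySkew`}{Cyhelsky's skewness coefficient
#'     \eqn{(n_{below} - n_{above})/n_{total}}, counting voxels strictly
#'     below/above the mean; values equal to the mean count in neither.
#'     Always in [-1, 1].}
#'   \item{`pearsonMedianSkew`}{Pearson's median skewness
#'     \eqn{3(\bar x - Md)/SD}; always in [-3, 3].}
#' }
#'
#' @param x numeric vector of counts (the masked-voxel sample).
#' @param excess logical; subtract 3 from the kurtosis (default FALSE).
#' @return A single numeric value.
#' @examples
#' sampleSkewness(c(1, 2, 3, 4, 10))
#' sampleKurtosis(c(1, 2, 3, 4, 5), excess = TRUE)
#' cyhelskySkew(c(1, 2, 3, 4, 10))
#' pearsonMedianSkew(c(1, 2, 3, 4, 10))
#' @name shapeStatistics
NULL

.momentPrep <- function(x, minN, what) {
    x <- as.numeric(x)
    n <- length(x)
    if (n < minN)
        stop(what, " requires at least ", minN, " values", call. = FALSE)
    d <- x - mean(x)
    s2 <- sum(d^2) / (n - 1)
    if (s2 <= 0)
        stop(what, " is undefined for a constant sample (zero variance)",
             call. = FALSE)
    list(n = n, d = d, s2 = s2)
}

#' @rdname shapeStatistics
#' @export
sampleSkewness <- function(x) {
    m <- .momentPrep(x, 3L, "skewness")
    (sum(m$d^3) / (m$n - 1)) / m$s2^1.5
}

#' @rdname shapeStatistics
#' @export
sampleKurtosis <- function(x, excess = FALSE) {
    m <- .momentPrep(x, 4L, "kurtosis")
    (sum(m$d^4) / (m$n - 1)) / m$s2^2 - if (excess) 3 else 0
}

#' @rdname shapeStatistics
#' @export
cyhelskySkew <- function(x) {
    x <- as.numeric(x)
    if (!length(x)) stop("empty sample", call. = FALSE)
    m <- mean(x)
    (sum(x < m) - sum(x > m)) / length(x)
}

#' @rdname shapeStatistics
#' @export
pearsonMedianSkew <- function(x) {
    x <- as.numeric(x)
    s <- sd(x)
    if (is.na(s) || s <= 0)
        stop("Pearson's median skewness is undefined for a constant sample",
             call. = FALSE)
    3 * (mean(x) - median(x)) / s
}

#' DAT activity volume (DTAV)
#'
#' Physical volume of the striatal activity region: the per-axial-slice
#' member area times the slice thickness, summed over slices. This equals
#' the member-voxel count times the voxel volume.
#'
#' @param region a non-empty \linkS4class{VoxelMask}.
#' @return Volume in mL.
#' @export
dtav <- function(region) {
    stopifnot(is(region, "VoxelMask"))
    f <- maskFlags(region)
    if (!any(f)) stop("empty region: DTAV undefined", call. = FALSE)
    sp <- voxelSpacing(region)
    sliceArea <- apply(f, 3, sum) * sp[1] * sp[2]
    sum(sliceArea * sp[3]) / 1000
}

#' DAT activity maximum (DTAM)
#'
#' Peak measure of the striatal activity region. `mode = "max_count"` (the
#' default) returns the maximum voxel count inside the region, on the count
#' scale of the reported group statistics. `mode = "max_slice_volume"`
#' returns the largest single-slice member area times the slice thickness
#' (in mL), the literal area-based formula; the two conventions are both
#' offered because their units are used inconsistently in the staging
#' literature.
#'
#' @param volume a \linkS4class{SpectVolume}.
#' @param region a non-empty \linkS4class{VoxelMask}.
#' @param mode "max_count" or "max_slice_volume".
#' @return Counts, or mL for `"max_slice_volume"`.
#' @export
dtam <- function(volume, region, mode = c("max_count", "max_slice_volume")) {
    mode <- match.arg(mode)
    stopifnot(is(volume, "SpectVolume"), is(region, "VoxelMask"))
    f <- maskFlags(region)
    if (!any(f)) stop("empty region: DTAM undefined", call. = FALSE)
    if (mode == "max_count") {
        max(voxelCounts(volume)[f])
    } else {
        sp <- voxelSpacing(region)
        max(apply(f, 3, sum)) * sp[1] * sp[2] * sp[3] / 1000
    }
}

#' Compute the six-feature vector of one volume
#'
#' Runs the two segmentation procedures and derives the six per-subject
#' features: SK, KUR, CSK and MES from the whole-brain threshold sample, and
#' DTAV and DTAM from the grown striatal activity region.
#'
#' @param volume a \linkS4class{SpectVolume} or \linkS4class{LabeledVolume}.
#' @param config a [pipelineConfig()] list.
#' @return Named numeric(6): SK, KUR, CSK, MES, DTAV (mL), DTAM.
#' @export
computeFeatures <- function(volume, config = pipelineConfig()) {
    if (is(volume, "LabeledVolume")) volume <- volume@volume
    stopifnot(is(volume, "SpectVolume"))
    brain <- thresholdMask(volume, config$threshold)
    sample <- voxelCounts(volume)[maskFlags(brain)]
    if (!length(sample))
        stop("empty brain mask: no voxel exceeds threshold ",
             config$threshold, call. = FALSE)
    region <- growStriatum(volume, threshold = config$threshold,
                           connectivity = config$connectivity,
                           includeFraction = config$includeFraction,
                           bilateral = config$bilateral,
                           secondaryRatio = config$secondaryRatio)
    c(SK = sampleSkewness(sample),
      KUR = sampleKurtosis(sample, excess = config$kurtosisExcess),
      CSK = cyhelskySkew(sample),
      MES = pearsonMedianSkew(sample),
      DTAV = dtav(region),
      DTAM = dtam(volume, region, mode = config$dtamMode))
}

.FEATURES <- c("SK", "KUR", "CSK", "MES", "DTAV", "DTAM")

.featureSE <- function(mat, ids, stages) {
    SummarizedExperiment::SummarizedExperiment(
        assays = list(features = mat),
        colData = S4Vectors::DataFrame(subject_id = ids,
                                       stage = factor(stages,
                                                      levels = .STAGES)))
}

#' Extract the feature table of a cohort
#'
#' Computes the six-feature vector of every subject and assembles a
#' `SummarizedExperiment` with one column per subject (features as rows,
#' stage labels in `colData`). Methods exist for an in-memory cohort (a list
#' of \linkS4class{LabeledVolume}) and for a manifest `data.frame` with
#' columns subject_id, stage, path, whose volumes are read one at a time.
#'
#' @param x cohort list or manifest data.frame.
#' @param config a [pipelineConfig()] list.
#' @param ... unused.
#' @return A `SummarizedExperiment`; see [featureFrame()] for a flat view.
#' @name extractFeatures
NULL

#' @rdname extractFeatures
setMethod("extractFeatures", "list", function(x, config = pipelineConfig(),
                                              ...) {
    stopifnot(all(vapply(x, is, TRUE, "LabeledVolume")))
    mat <- vapply(x, computeFeatures, numeric(6), config = config)
    rownames(mat) <- .FEATURES
    .featureSE(mat, vapply(x, subjectId, ""), vapply(x, stageLabel, ""))
})

#' @rdname extractFeatures
setMethod("extractFeatures", "data.frame",
          function(x, config = pipelineConfig(), ...) {
    .validStage(x$stage)
    mat <- vapply(seq_len(nrow(x)), function(i) {
        if (!file.exists(x$path[i]))
            stop("volume file missing for subject '", x$subject_id[i],
                 "': ", x$path[i], call. = FALSE)
        computeFeatures(readVolume(x$path[i]), config = config)
    }, numeric(6))
    rownames(mat) <- .FEATURES
    .featureSE(mat, as.character(x$subject_id), x$stage)
})

#' Flat per-subject feature table
#'
#' Converts the `SummarizedExperiment` produced by [extractFeatures()] into
#' a data.frame with one row per subject: subject_id, stage, SK, KUR, CSK,
#' MES, DTAV, DTAM. This is the layout consumed by the statistics and
#' classification stages.
#'
#' @param se a `SummarizedExperiment` from [extractFeatures()].
#' @return A data.frame.
#' @export
featureFrame <- function(se) {
    mat <- SummarizedExperiment::assay(se, "features")
    cd <- SummarizedExperiment::colData(se)
    df <- data.frame(subject_id = cd$subject_id,
                     stage = factor(cd$stage, levels = .STAGES),
                     t(mat), row.names = NULL, stringsAsFactors = FALSE)
    names(df) <- c("subject_id", "stage", rownames(mat))
    df
}
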