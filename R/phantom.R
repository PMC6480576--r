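#' Default phantom configuration
#'
#' Builds a \linkS4class{PhantomParams} describing the digital striatal
#' phantom: an ellipsoidal brain with a graded cortical background and a
#' dimmer deep interior, plus two bilateral striatal ellipsoids whose size
#' (and, mildly, peak count) depend on disease stage. Defaults are chosen so
#' that a simulated cohort reproduces the qualitative group structure seen in
#' DAT SPECT staging studies: striatal activity volume decreasing
#' healthy > mild > severe, whole-brain skewness moving from right-skewed
#' (healthy) through near-symmetric (mild) to left-skewed (severe), and
#' kurtosis decreasing with stage.
#'
#' Geometry is specified in millimetres; the default sampling grid is
#' 128 x 128 in-plane with 64 axial slices at 3.9 mm isotropic spacing.
#'
#' @param gridShape integer(3) voxel grid.
#' @param voxelSpacing numeric(3) mm per voxel.
#' @param brainSemiAxes brain ellipsoid semi-axes, mm.
#' @param backgroundMean cortical plateau count level.
#' @param backgroundGradient fractional radial fall-off of the cortical
#'   level from centre to rim.
#' @param interiorValue count level of the deep interior compartment.
#' @param coreFraction deep-interior ellipsoid size as a fraction of the
#'   brain semi-axes.
#' @param striatalSemiAxes 3x3 matrix (rows healthy, mild, severe) of
#'   striatal semi-axes in mm. Defaults give analytic bilateral volumes of
#'   about 34, 16 and 10 mL.
#' @param striatalPeak named numeric(3) striatal peak counts per stage.
#' @param striatalGap midline gap between the two striata, mm.
#' @param striatalCenterY anterior offset of the striatal centres, mm.
#' @param subjectCV per-subject lognormal jitter CV on striatal size and peak.
#' @param intensityCV per-subject lognormal jitter CV on global intensity.
#' @param blurSigma Gaussian sigma in mm emulating reconstruction blur.
#' @param noise logical, Poisson counting noise.
#' @param separation in [0, 1]; scales the stage differences of the striatal
#'   geometry and peaks towards their across-stage mean. `separation = 0`
#'   removes all stage information from the images.
#' @return A \linkS4class{PhantomParams}.
#' @examples
#' p <- phantomParams()
#' striatalVolume(p, "healthy")
#' @export
phantomParams <- function(gridShape = c(128L, 128L, 64L),
                          voxelSpacing = c(3.9, 3.9, 3.9),
                          brainSemiAxes = c(70, 85, 60),
                          backgroundMean = 200,
                          backgroundGradient = 0.3,
                          interiorValue = 60,
                          coreFraction = 0.55,
                          striatalSemiAxes = rbind(
                              healthy = c(13.0, 24.0, 12.85),
                              mild    = c(10.0, 19.0, 9.95),
                              severe  = c(8.6, 16.5, 8.5)),
                          striatalPeak = c(healthy = 450, mild = 465,
                                           severe = 450),
                          striatalGap = 4,
                          striatalCenterY = 10,
                          subjectCV = 0.04,
                          intensityCV = 0.05,
                          blurSigma = 4,
                          noise = TRUE,
                          separation = 1) {
    new("PhantomParams",
        gridShape = as.integer(gridShape),
        voxelSpacing = as.numeric(voxelSpacing),
        brainSemiAxes = as.numeric(brainSemiAxes),
        backgroundMean = as.numeric(backgroundMean),
        backgroundGradient = as.numeric(backgroundGradient),
        interiorValue = as.numeric(interiorValue),
        coreFraction = as.numeric(coreFraction),
        striatalSemiAxes = striatalSemiAxes,
        striatalPeak = striatalPeak,
        striatalGap = as.numeric(striatalGap),
        striatalCenterY = as.numeric(striatalCenterY),
        subjectCV = as.numeric(subjectCV),
        intensityCV = as.numeric(intensityCV),
        blurSigma = as.numeric(blurSigma),
        noise = noise,
        separation = as.numeric(separation))
}

## Stage-effective striatal semi-axes and peak after applying `separation`.
.stageGeometry <- function(params, stage) {
    ax <- params@striatalSemiAxes
    pk <- params@striatalPeak
    s <- params@separation
    axBar <- colMeans(ax)
    pkBar <- mean(pk)
    list(semiAxes = axBar + s * (ax[stage, ] - axBar),
         peak = pkBar + s * (pk[[stage]] - pkBar))
}

#' Analytic striatal volume of a phantom stage
#'
#' Volume of the bilateral striatal ellipsoid pair, in mL, before per-subject
#' jitter and independent of the sampling grid.
#'
#' @param params a \linkS4class{PhantomParams}.
#' @param stage "healthy", "mild" or "severe".
#' @return Volume in mL.
#' @export
striatalVolume <- function(params, stage) {
    stage <- match.arg(stage, .STAGES)
    g <- .stageGeometry(params, stage)
    2 * (4 / 3) * pi * prod(g$semiAxes) / 1000
}

#' Generate one phantom SPECT volume
#'
#' Renders the piecewise-constant intensity model (brain background with a
#' graded cortical level and deep interior, plus two bilateral striatal
#' ellipsoids at the stage's peak count), applies optional Gaussian
#' reconstruction blur, and draws Poisson counting noise around the blurred
#' intensity. Per-subject biological variability is emulated by a lognormal
#' jitter on striatal size and peak and on the global intensity scale.
#' Output is deterministic for a fixed seed.
#'
#' @param stage "healthy", "mild" or "severe".
#' @param params a \linkS4class{PhantomParams}.
#' @param seed integer seed for the subject's jitter and noise.
#' @param subjectId optional subject identifier.
#' @return A \linkS4class{LabeledVolume}. Its `info` slot records the
#'   realized (jittered) striatal semi-axes, peak, centres and the analytic
#'   bilateral striatal volume in mL.
#' @examples
#' p <- phantomParams(gridShape = c(48L, 48L, 24L),
#'                    voxelSpacing = c(6, 6, 6), noise = FALSE)
#' lv <- generatePhantom("healthy", p, seed = 1)
#' stageLabel(lv)
#' @export
generatePhantom <- function(stage, params = phantomParams(), seed = 1L,
                            subjectId = paste0(stage, "_", seed)) {
    stage <- match.arg(stage, .STAGES)
    validObject(params)
    withSeed(seed, {
        geom <- .stageGeometry(params, stage)
        sizeJit <- exp(rnorm(1, 0, params@subjectCV))
        peakJit <- exp(rnorm(1, 0, params@subjectCV))
        globJit <- exp(rnorm(1, 0, params@intensityCV))
        semi <- geom$semiAxes * sizeJit
        peak <- geom$peak * peakJit
        xoff <- semi[1] + params@striatalGap / 2
        centers <- list(c(-xoff, params@striatalCenterY, 0),
                        c(+xoff, params@striatalCenterY, 0))
        B <- params@brainSemiAxes
        for (ctr in centers) {
            ## support bound: ellipsoid inside brain if ||c/B|| + max(s/B) <= 1
            reach <- sqrt(sum((ctr / B)^2)) + max(semi / B)
            if (reach > 1)
                stop("striatal region exceeds brain bounds for stage '",
                     stage, "' (reach ", round(reach, 3),
                     "); shrink striatalSemiAxes or striatalGap",
                     call. = FALSE)
        }
        co <- .axisCoords(params@gridShape, params@voxelSpacing)
        qBrain <- .ellipsoidQ(co, c(0, 0, 0), B)
        field <- array(0, params@gridShape)
        inBrain <- qBrain <= 1
        field[inBrain] <- params@backgroundMean *
            (1 - params@backgroundGradient * qBrain[inBrain])
        field[.ellipsoidQ(co, c(0, 0, 0), params@coreFraction * B) <= 1] <-
            params@interiorValue
        for (ctr in centers)
            field[.ellipsoidQ(co, ctr, semi) <= 1] <- peak
        field <- field * globJit
        field <- .gaussianBlur3D(field, params@blurSigma, params@voxelSpacing)
        counts <- if (params@noise)
            array(rpois(length(field), field), dim(field))
        else field
        new("LabeledVolume",
            volume = SpectVolume(counts, params@voxelSpacing),
            stage = stage, subjectId = as.character(subjectId),
            info = list(semiAxes = semi, peak = peak * globJit,
                        centers = centers,
                        striatalVolumeML = 2 * (4 / 3) * pi * prod(semi) / 1000))
    })
}

#' Generate a phantom cohort
#'
#' Draws independent subjects for each stage with per-subject seeds derived
#' reproducibly from the master seed.
#'
#' @param nPerStage integer(3) subjects per stage, in the order healthy,
#'   mild, severe (names are honoured if given).
#' @param params a \linkS4class{PhantomParams}.
#' @param seed master seed.
#' @return A list of \linkS4class{LabeledVolume} objects.
#' @examples
#' p <- phantomParams(gridShape = c(48L, 48L, 24L), voxelSpacing = c(6, 6, 6))
#' cohort <- generateCohort(c(2, 2, 2), p, seed = 7)
#' length(cohort)
#' @export
generateCohort <- function(nPerStage, params = phantomParams(), seed = 1L) {
    if (length(nPerStage) != 3L || any(nPerStage < 0))
        stop("nPerStage must be three non-negative counts", call. = FALSE)
    n <- as.integer(nPerStage)
    if (!is.null(names(nPerStage))) {
        if (!setequal(names(nPerStage), .STAGES))
            stop("nPerStage names must be ", paste(.STAGES, collapse = ", "),
                 call. = FALSE)
        n <- as.integer(nPerStage[.STAGES])
    }
    total <- sum(n)
    if (total == 0L) return(list())
    subSeeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, total))
    stages <- rep(.STAGES, times = n)
    ids <- unlist(lapply(1:3, function(i)
        sprintf("%s_%02d", .STAGES[i], seq_len(n[i]))), use.names = FALSE)
    lapply(seq_len(total), function(i)
        generatePhantom(stages[i], params, seed = subSeeds[i],
                        subjectId = ids[i]))
}

#' Simulate a cohort to disk
#'
#' Writes one NIfTI volume per subject plus a CSV manifest
#' (subject_id, stage, path).
#'
#' @param nPerStage integer(3) subjects per stage (healthy, mild, severe).
#' @param params a \linkS4class{PhantomParams}.
#' @param seed master seed.
#' @param outDir output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
simulateToDisk <- function(nPerStage, params = phantomParams(), seed = 1L,
                           outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    cohort <- generateCohort(nPerStage, params, seed)
    rows <- lapply(cohort, function(lv) {
        file <- paste0(subjectId(lv), ".nii.gz")
        writeVolume(lv@volume, file.path(outDir, file))
        data.frame(subject_id = subjectId(lv), stage = stageLabel(lv),
                   path = file, stringsAsFactors = FALSE)
    })
    manifest <- do.call(rbind, rows)
    path <- file.path(outDir, "manifest.csv")
    writeManifest(manifest, path)
    invisible(path)
}
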