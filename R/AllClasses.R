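#' SpectVolume: a 3D SPECT count volume
#'
#' Container for a reconstructed emission volume: a 3D grid of non-negative
#' count values plus the physical voxel spacing in millimetres (in-plane
#' dx, dy and the axial slice thickness dz). Axis 3 is the axial slice index.
#'
#' @slot counts 3D numeric array of voxel counts (finite, non-negative).
#' @slot spacing numeric(3), voxel spacing in mm (all positive).
#' @export
setClass("SpectVolume",
    representation(counts = "array", spacing = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(dim(object@counts)) != 3L)
            msg <- c(msg, "counts must be a 3D array")
        else {
            if (!all(is.finite(object@counts)))
                msg <- c(msg, "counts must be finite")
            else if (any(object@counts < 0))
                msg <- c(msg, "counts must be non-negative")
        }
        if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
            any(object@spacing <= 0))
            msg <- c(msg, "spacing must be three positive values (mm)")
        if (length(msg)) msg else TRUE
    })

#' Construct a SpectVolume
#'
#' @param counts 3D numeric array of voxel counts.
#' @param spacing numeric(3) voxel spacing in mm; defaults to 1 mm isotropic.
#' @return A \linkS4class{SpectVolume}.
#' @examples
#' v <- SpectVolume(array(rpois(8 * 8 * 4, 10), c(8, 8, 4)), c(3.9, 3.9, 3.9))
#' voxelSpacing(v)
#' @export
SpectVolume <- function(counts, spacing = c(1, 1, 1)) {
    storage.mode(counts) <- if (is.integer(counts)) "integer" else "double"
    new("SpectVolume", counts = counts, spacing = as.numeric(spacing))
}

#' VoxelMask: a boolean region congruent with a SpectVolume
#'
#' Result of thresholding or seed region growing; carries the spacing of the
#' volume it was derived from so that physical volumes can be computed.
#'
#' @slot flags 3D logical array of voxel membership.
#' @slot spacing numeric(3), voxel spacing in mm.
#' @export
setClass("VoxelMask",
    representation(flags = "array", spacing = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(dim(object@flags)) != 3L || !is.logical(object@flags))
            msg <- c(msg, "flags must be a 3D logical array")
        if (any(is.na(object@flags)))
            msg <- c(msg, "flags must not contain NA")
        if (length(object@spacing) != 3L || any(object@spacing <= 0))
            msg <- c(msg, "spacing must be three positive values (mm)")
        if (length(msg)) msg else TRUE
    })

#' Construct a VoxelMask
#' @param flags 3D logical array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return A \linkS4class{VoxelMask}.
#' @export
VoxelMask <- function(flags, spacing = c(1, 1, 1)) {
    new("VoxelMask", flags = flags, spacing = as.numeric(spacing))
}

#' PhantomParams: configuration of the digital striatal phantom
#'
#' Describes an ellipsoidal brain with a graded cortical background, a dimmer
#' deep interior, and two bilateral striatal ellipsoids whose size and peak
#' count depend on disease stage (healthy, mild, severe). All geometry is in
#' millimetres so the same phantom can be sampled on any grid.
#'
#' @slot gridShape integer(3) voxel counts per axis.
#' @slot voxelSpacing numeric(3) mm per voxel.
#' @slot brainSemiAxes numeric(3) brain ellipsoid semi-axes, mm.
#' @slot backgroundMean cortical plateau count level (the brightest
#'   background tissue).
#' @slot backgroundGradient fractional radial fall-off of the cortical level
#'   between brain centre and rim (0 = flat shell).
#' @slot interiorValue count level of the deep interior compartment in which
#'   the striata sit.
#' @slot coreFraction fraction of the brain semi-axes occupied by the deep
#'   interior ellipsoid.
#' @slot striatalSemiAxes 3x3 numeric matrix (rows healthy/mild/severe) of
#'   per-stage striatal semi-axes, mm.
#' @slot striatalPeak named numeric(3) per-stage striatal peak counts.
#' @slot striatalGap midline gap between the two striatal ellipsoids, mm.
#' @slot striatalCenterY anterior offset of the striatal centres, mm.
#' @slot subjectCV lognormal coefficient of variation of per-subject striatal
#'   size and peak jitter.
#' @slot intensityCV lognormal CV of the per-subject global intensity scale.
#' @slot blurSigma Gaussian sigma (mm) emulating reconstruction blur.
#' @slot noise logical; draw Poisson counting noise around the intensity.
#' @slot separation scalar in [0, 1]; 1 keeps the stage-dependent striatal
#'   geometry, 0 collapses all stages onto their across-stage mean.
#' @export
setClass("PhantomParams",
    representation(gridShape = "integer", voxelSpacing = "numeric",
        brainSemiAxes = "numeric", backgroundMean = "numeric",
        backgroundGradient = "numeric", interiorValue = "numeric",
        coreFraction = "numeric", striatalSemiAxes = "matrix",
        striatalPeak = "numeric", striatalGap = "numeric",
        striatalCenterY = "numeric", subjectCV = "numeric",
        intensityCV = "numeric", blurSigma = "numeric", noise = "logical",
        separation = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
            msg <- c(msg, "gridShape must be three voxel counts >= 8")
        if (any(object@voxelSpacing <= 0))
            msg <- c(msg, "voxelSpacing must be positive")
        if (any(object@brainSemiAxes <= 0))
            msg <- c(msg, "brainSemiAxes must be positive")
        for (nm in c("backgroundMean", "interiorValue", "striatalPeak"))
            if (any(slot(object, nm) < 0))
                msg <- c(msg, paste(nm, "must be non-negative"))
        if (object@backgroundGradient < 0 || object@backgroundGradient >= 1)
            msg <- c(msg, "backgroundGradient must be in [0, 1)")
        if (object@coreFraction <= 0 || object@coreFraction > 1)
            msg <- c(msg, "coreFraction must be in (0, 1]")
        if (!identical(rownames(object@striatalSemiAxes), .STAGES) ||
            ncol(object@striatalSemiAxes) != 3L)
            msg <- c(msg, "striatalSemiAxes must be a 3x3 matrix with rows healthy, mild, severe")
        else if (any(object@striatalSemiAxes <= 0))
            msg <- c(msg, "striatalSemiAxes must be positive")
        if (!identical(names(object@striatalPeak), .STAGES))
            msg <- c(msg, "striatalPeak must be named healthy, mild, severe")
        if (object@striatalGap < 0)
            msg <- c(msg, "striatalGap must be non-negative")
        if (object@subjectCV < 0 || object@intensityCV < 0)
            msg <- c(msg, "jitter CVs must be non-negative")
        if (object@blurSigma < 0)
            msg <- c(msg, "blurSigma must be non-negative")
        if (object@separation < 0 || object@separation > 1)
            msg <- c(msg, "separation must be in [0, 1]")
        if (length(msg)) msg else TRUE
    })

#' LabeledVolume: a phantom or patient volume with its stage label
#'
#' @slot volume the \linkS4class{SpectVolume}.
#' @slot stage one of "healthy", "mild", "severe".
#' @slot subjectId subject identifier.
#' @slot info list of generator metadata (realized striatal geometry, peak,
#'   analytic striatal volume in mL) for phantoms; empty for read volumes.
#' @export
setClass("LabeledVolume",
    representation(volume = "SpectVolume", stage = "character",
        subjectId = "character", info = "list"),
    validity = function(object) {
        if (!object@stage %in% .STAGES)
            return(paste("stage must be one of", paste(.STAGES, collapse = ", ")))
        TRUE
    })

#' ValidityReport: the validity panel of one fitted stage classifier
#'
#' Holds the test-set confusion matrix of a three-group classifier together
#' with the per-class one-vs-rest breakdown and the prevalence-weighted
#' summary metrics: sensitivity, specificity, PPV, NPV, accuracy, macro AUC
#' and Cohen's kappa.
#'
#' @slot method "LR" or "SVM".
#' @slot varGroup name of the predictor set (SK, KUR, FAV, FAD, FADV).
#' @slot confusion k x k table, rows = truth, columns = prediction.
#' @slot perClass data.frame of one-vs-rest metrics per class.
#' @slot sensitivity,specificity,ppv,npv prevalence-weighted averages.
#' @slot accuracy trace of the confusion matrix over its total.
#' @slot auc macro-averaged one-vs-rest AUC.
#' @slot kappa Cohen's kappa of the confusion matrix.
#' @export
setClass("ValidityReport",
    representation(method = "character", varGroup = "character",
        confusion = "matrix", perClass = "data.frame",
        sensitivity = "numeric", specificity = "numeric", ppv = "numeric",
        npv = "numeric", accuracy = "numeric", auc = "numeric",
        kappa = "numeric"),
    validity = function(object) {
        msg <- character()
        if (any(object@confusion < 0))
            msg <- c(msg, "confusion matrix entries must be non-negative")
        for (nm in c("sensitivity", "specificity", "ppv", "npv", "accuracy",
                     "auc")) {
            v <- slot(object, nm)
            if (length(v) && !is.na(v) && (v < 0 || v > 1))
                msg <- c(msg, paste(nm, "must be in [0, 1]"))
        }
        if (length(object@kappa) && !is.na(object@kappa) &&
            (object@kappa < -1 || object@kappa > 1))
            msg <- c(msg, "kappa must be in [-1, 1]")
        if (length(msg)) msg else TRUE
    })

setMethod("show", "SpectVolume", function(object) {
    d <- dim(object@counts)
    cat(sprintf("SpectVolume: %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
                d[1], d[2], d[3], object@spacing[1], object@spacing[2],
                object@spacing[3]))
    cat(sprintf("  counts: min %.1f, max %.1f, mean %.1f\n",
                min(object@counts), max(object@counts), mean(object@counts)))
})

setMethod("show", "VoxelMask", function(object) {
    d <- dim(object@flags)
    cat(sprintf("VoxelMask: %d x %d x %d voxels, %d in mask (%.2f mL)\n",
                d[1], d[2], d[3], sum(object@flags),
                sum(object@flags) * prod(object@spacing) / 1000))
})

setMethod("show", "PhantomParams", function(object) {
    cat(sprintf("PhantomParams: grid %s, spacing %s mm, blur %.1f mm, noise %s\n",
                paste(object@gridShape, collapse = "x"),
                paste(format(object@voxelSpacing), collapse = "x"),
                object@blurSigma, object@noise))
    v <- vapply(.STAGES, function(s) striatalVolume(object, s), 0)
    cat(sprintf("  striatal volume (mL): healthy %.1f, mild %.1f, severe %.1f (separation %.2f)\n",
                v[1], v[2], v[3], object@separation))
})

setMethod("show", "LabeledVolume", function(object) {
    cat(sprintf("LabeledVolume '%s' (stage: %s)\n", object@subjectId,
                object@stage))
    show(object@volume)
})

setMethod("show", "ValidityReport", function(object) {
    cat(sprintf("ValidityReport: %s / %s\n", object@method, object@varGroup))
    cat(sprintf("  sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f\n",
                object@sensitivity, object@specificity, object@ppv,
                object@npv))
    cat(sprintf("  accuracy %.3f  AUC %.3f  kappa %.3f\n", object@accuracy,
                object@auc, object@kappa))
    cat("  confusion (rows = truth):\n")
    print(object@confusion)
})
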