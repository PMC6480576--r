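#' @import methods
#' @importFrom stats rnorm rpois dnorm median sd qt pnorm pchisq kruskal.test
#'   wilcox.test coef predict
#' @importFrom utils read.csv write.csv
NULL

.STAGES <- c("healthy", "mild", "severe")

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

## Centered physical coordinates (mm) along each axis of a voxel grid.
.axisCoords <- function(dims, spacing) {
    lapply(1:3, function(ax)
        (seq_len(dims[ax]) - (dims[ax] + 1) / 2) * spacing[ax])
}

## Squared normalized ellipsoid radius at every voxel: values <= 1 are inside.
.ellipsoidQ <- function(coords, center, semiAxes) {
    outer(outer(((coords[[1]] - center[1]) / semiAxes[1])^2,
                ((coords[[2]] - center[2]) / semiAxes[2])^2, "+"),
          ((coords[[3]] - center[3]) / semiAxes[3])^2, "+")
}

## Separable Gaussian smoothing with a physical sigma in mm. The kernel matrix
## is row-normalized, so flat fields (and edge slices) keep their level.
.gaussianBlur3D <- function(a, sigmaMM, spacing) {
    if (sigmaMM <= 0) return(a)
    for (ax in 1:3) {
        s <- sigmaMM / spacing[ax]
        n <- dim(a)[ax]
        K <- outer(seq_len(n), seq_len(n), function(i, j) dnorm(j - i, sd = s))
        K <- K / rowSums(K)
        ord <- c(ax, setdiff(1:3, ax))
        m <- matrix(aperm(a, ord), nrow = n)
        a <- aperm(array(K %*% m, dim = c(n, dim(a)[ord[2]], dim(a)[ord[3]])),
                   order(ord))
    }
    a
}

.assertCount3D <- function(x, what = "counts") {
    if (!is.array(x) || length(dim(x)) != 3L)
        stop(what, " must be a 3-dimensional array", call. = FALSE)
    if (!all(is.finite(x)))
        stop(what, " must be finite", call. = FALSE)
    if (any(x < 0))
        stop(what, " must be non-negative", call. = FALSE)
    invisible(TRUE)
}

.validStage <- function(stage) {
    stage <- as.character(stage)
    bad <- setdiff(unique(stage), .STAGES)
    if (length(bad))
        stop("unknown stage label(s): ", paste(bad, collapse = ", "),
             " (expected one of ", paste(.STAGES, collapse = ", "), ")",
             call. = FALSE)
    stage
}
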