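#' Pipeline configuration
#'
#' One auditable container for the pipeline's small constants: the
#' whole-brain count threshold, the region-growing rule, the kurtosis and
#' DTAM conventions, and the split/classifier settings. Every [runPipeline()]
#' run serializes its resolved configuration next to its outputs.
#'
#' @param threshold whole-brain count threshold (default 15).
#' @param includeFraction region-growing inclusion fraction (default 0.5).
#' @param connectivity 26 or 6.
#' @param kurtosisExcess subtract 3 from kurtosis (default FALSE).
#' @param dtamMode "max_count" or "max_slice_volume".
#' @param bilateral grow both striatal regions (default TRUE).
#' @param secondaryRatio secondary seed acceptance ratio (default 0.7).
#' @param splitSeed seed of the 50/50 percentage split.
#' @param stratified stratify the split (default TRUE).
#' @param svmC,svmGamma SVM hyperparameters (see [fitSvmRbf()]).
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(threshold = 15, includeFraction = 0.5,
                           connectivity = 26, kurtosisExcess = FALSE,
                           dtamMode = c("max_count", "max_slice_volume"),
                           bilateral = TRUE, secondaryRatio = 0.7,
                           splitSeed = 1L, stratified = TRUE, svmC = 1,
                           svmGamma = NULL) {
    structure(list(threshold = threshold,
                   includeFraction = includeFraction,
                   connectivity = connectivity,
                   kurtosisExcess = kurtosisExcess,
                   dtamMode = match.arg(dtamMode),
                   bilateral = bilateral,
                   secondaryRatio = secondaryRatio,
                   splitSeed = as.integer(splitSeed),
                   stratified = stratified,
                   svmC = svmC, svmGamma = svmGamma),
              class = "PipelineConfig")
}

.logLine <- function(logPath, ...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    cat(line, "\n", file = logPath, append = TRUE, sep = "")
    message(line)
}

#' Run the full analysis pipeline
#'
#' Orchestrates feature extraction, group statistics and the classifier
#' grid, writing four artifacts to `outDir`: `features.csv` (per-subject
#' feature table), `group_stats.json` (descriptives, Kruskal-Wallis and
#' Dunn-Bonferroni per feature), `validity.json` (the ten-model validity
#' panel), and `config.json` plus `pipeline.log`. Input is either a manifest
#' (path or data.frame) of existing volumes or a simulation request. Outputs
#' are deterministic for fixed seeds. On failure, partial outputs are kept
#' and a `FAILED` marker records the error.
#'
#' @param outDir output directory (created if needed).
#' @param config a [pipelineConfig()].
#' @param manifest manifest CSV path or data.frame (subject_id, stage, path).
#' @param simulate alternatively, a list
#'   `list(nPerStage =, params = phantomParams(), seed =)`.
#' @return `outDir`, invisibly.
#' @export
runPipeline <- function(outDir, config = pipelineConfig(), manifest = NULL,
                        simulate = NULL) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logPath <- file.path(outDir, "pipeline.log")
    ok <- FALSE
    on.exit(if (!ok) writeLines("pipeline failed; see pipeline.log",
                                file.path(outDir, "FAILED")))
    tryCatch({
        .logLine(logPath, "pipeline start")
        if (is.null(manifest) == is.null(simulate))
            stop("provide exactly one of 'manifest' or 'simulate'",
                 call. = FALSE)
        se <- if (!is.null(manifest)) {
            if (is.character(manifest)) manifest <- readManifest(manifest)
            .logLine(logPath, "extracting features for ", nrow(manifest),
                     " subjects from manifest")
            extractFeatures(manifest, config = config)
        } else {
            params <- if (is.null(simulate$params)) phantomParams()
                      else simulate$params
            seed <- if (is.null(simulate$seed)) 1L else simulate$seed
            .logLine(logPath, "simulating cohort (",
                     paste(simulate$nPerStage, collapse = "/"),
                     ") with seed ", seed)
            cohort <- generateCohort(simulate$nPerStage, params, seed)
            extractFeatures(cohort, config = config)
        }
        ff <- featureFrame(se)
        write.csv(ff, file.path(outDir, "features.csv"), row.names = FALSE)
        .logLine(logPath, "wrote features.csv (", nrow(ff), " subjects)")
        stats <- groupStatsReport(ff)
        jsonlite::write_json(stats, file.path(outDir, "group_stats.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             dataframe = "rows")
        .logLine(logPath, "wrote group_stats.json")
        grid <- runModelGrid(ff, seed = config$splitSeed, C = config$svmC,
                             gamma = config$svmGamma,
                             stratified = config$stratified)
        jsonlite::write_json(
            list(summary = validitySummary(grid),
                 confusion = lapply(grid, function(r)
                     as.data.frame.matrix(r@confusion))),
            file.path(outDir, "validity.json"), auto_unbox = TRUE,
            digits = NA, pretty = TRUE, dataframe = "rows")
        .logLine(logPath, "wrote validity.json")
        resolved <- unclass(config)
        resolved$svmGamma <- if (is.null(config$svmGamma)) "auto"
                             else config$svmGamma
        if (!is.null(simulate))
            resolved$simulate <- list(
                nPerStage = as.integer(simulate$nPerStage),
                seed = if (is.null(simulate$seed)) 1L
                       else as.integer(simulate$seed))
        jsonlite::write_json(resolved, file.path(outDir, "config.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        .logLine(logPath, "pipeline done")
        ok <- TRUE
    }, error = function(e) {
        .logLine(logPath, "ERROR: ", conditionMessage(e))
        stop(e)
    })
    invisible(outDir)
}
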