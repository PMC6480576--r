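# Shared fixtures, built once per test run.

# Coarser sampling of the same physical phantom geometry, for fast unit
# tests (the default 128 x 128 x 64 grid is used by the cohort-level tests).
smallParams <- function(...) {
    phantomParams(gridShape = c(64L, 64L, 32L),
                  voxelSpacing = c(4.4, 4.4, 4.4), ...)
}

.fixtureCache <- new.env(parent = emptyenv())

# Feature table of a 30/30/30 phantom cohort at the default study
# conditions (separation = 1) or with stage separation disabled.
cohortFeatures <- function(separation = 1, seed = 42) {
    key <- paste0("sep_", separation)
    if (is.null(.fixtureCache[[key]])) {
        cohort <- generateCohort(c(30, 30, 30),
                                 phantomParams(separation = separation),
                                 seed = seed)
        .fixtureCache[[key]] <- featureFrame(extractFeatures(cohort))
    }
    .fixtureCache[[key]]
}
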