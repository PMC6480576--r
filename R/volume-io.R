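#' Read a 3D SPECT count volume from a NIfTI file
#'
#' Reads a NIfTI-1 volume into a \linkS4class{SpectVolume}, taking the voxel
#' spacing from the header. Negative intensities (which can arise from
#' filtered reconstruction) are clamped to zero with a warning, since counts
#' are non-negative by definition.
#'
#' @param path path to a 3D NIfTI file (.nii or .nii.gz).
#' @return A \linkS4class{SpectVolume}.
#' @seealso [writeVolume()], [readManifest()]
#' @export
readVolume <- function(path) {
    if (!file.exists(path))
        stop("cannot read volume: file not found: ", path, call. = FALSE)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    arr <- structure(as.vector(arr), dim = dim(arr))  # strip niftiImage class
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
        arr <- arr[, , , 1L, drop = TRUE]
    if (length(dim(arr)) != 3L)
        stop("expected a 3D volume, got ", length(dim(arr)),
             " dimensions: ", path, call. = FALSE)
    if (any(arr < 0)) {
        warning(sum(arr < 0), " negative voxel(s) clamped to 0 in ", path)
        arr[arr < 0] <- 0
    }
    sp <- RNifti::pixdim(img)[1:3]
    SpectVolume(arr, sp)
}

#' Write a SpectVolume to a NIfTI file
#'
#' Integer count volumes round-trip exactly through [readVolume()].
#'
#' @param volume a \linkS4class{SpectVolume}.
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, path) {
    stopifnot(is(volume, "SpectVolume"))
    arr <- voxelCounts(volume)
    if (all(arr == round(arr)) && max(arr) < .Machine$integer.max)
        storage.mode(arr) <- "integer"
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- voxelSpacing(volume)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read a subject manifest
#'
#' A manifest is a CSV with header `subject_id,stage,path` mapping each
#' subject to a stage label (healthy, mild or severe) and a volume file.
#' Relative volume paths are resolved against the manifest's directory.
#'
#' @param path path to the manifest CSV.
#' @return A data.frame with columns subject_id, stage, path.
#' @export
readManifest <- function(path) {
    if (!file.exists(path))
        stop("manifest not found: ", path, call. = FALSE)
    df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) data.frame())
    if (nrow(df) == 0L) {
        warning("manifest is empty: ", path)
        return(data.frame(subject_id = character(), stage = character(),
                          path = character(), stringsAsFactors = FALSE))
    }
    need <- c("subject_id", "stage", "path")
    if (!all(need %in% names(df)))
        stop("manifest must have columns ", paste(need, collapse = ", "),
             call. = FALSE)
    df$stage <- .validStage(df$stage)
    rel <- !grepl("^(/|[A-Za-z]:)", df$path)
    df$path[rel] <- file.path(dirname(path), df$path[rel])
    df[need]
}

#' Write a subject manifest
#'
#' @param manifest data.frame with columns subject_id, stage, path.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeManifest <- function(manifest, path) {
    .validStage(manifest$stage)
    write.csv(manifest[c("subject_id", "stage", "path")], path,
              row.names = FALSE)
    invisible(path)
}

#' Export a mask as a 0/1 NIfTI volume for visual QC
#'
#' @param mask a \linkS4class{VoxelMask}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeMask <- function(mask, path) {
    stopifnot(is(mask, "VoxelMask"))
    arr <- array(as.integer(maskFlags(mask)), dim(maskFlags(mask)))
    writeVolume(SpectVolume(arr, voxelSpacing(mask)), path)
}
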