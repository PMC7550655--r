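#' Read and write volumes in NIfTI-1 format
#'
#' Thin wrappers around RNifti preserving the data array and spatial
#' metadata. Gzipped (.nii.gz) and plain (.nii) files are both handled. The
#' 4th dimension of a 4D volume is the measurement axis and must match the
#' protocol sidecar it travels with; [fitIvimMap()] and [fitR2starMap()]
#' check that at fit time. Parameter maps use NaN as the on-disk
#' missing-value sentinel for voxels outside the mask.
#'
#' @param path file path (.nii or .nii.gz).
#' @param volume numeric array (3D or 4D), optionally an RNifti image.
#' @param protocol optional protocol; when given, the volume's 4th dimension
#'   is validated against it before writing/after reading.
#' @return \code{readVolume}: the image as a plain numeric array with the
#'   NIfTI header retained in attributes (RNifti "niftiImage").
#' @export
readVolume <- function(path, protocol = NULL) {
  img <- RNifti::readNifti(path)
  .checkVolumeProtocol(img, protocol)
  img
}

#' @rdname readVolume
#' @export
writeVolume <- function(volume, path, protocol = NULL) {
  .checkVolumeProtocol(volume, protocol)
  RNifti::writeNifti(volume, path)
  invisible(path)
}

.checkVolumeProtocol <- function(volume, protocol) {
  if (is.null(protocol)) return(invisible())
  nmeas <- if (is(protocol, "DiffusionProtocol")) length(protocol@bvalues)
           else length(protocol@echo_times)
  d <- dim(volume)
  if (length(d) != 4L || d[4L] != nmeas)
    stop("volume 4th dimension (", if (length(d) == 4L) d[4L] else "absent",
         ") does not match the protocol length (", nmeas, ")")
  invisible()
}

#' Read and write long-format study tables as CSV
#'
#' Columns: animal_id, group, timepoint, quantity, value.
#'
#' @param records study table data.frame.
#' @param path CSV path.
#' @export
writeStudyTable <- function(records, path) {
  need <- c("animal_id", "group", "timepoint", "quantity", "value")
  stopifnot(all(need %in% names(records)))
  utils::write.csv(records[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStudyTable
#' @export
readStudyTable <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "timepoint", "quantity", "value")
  if (!all(need %in% names(rec)))
    stop("study table must have columns ", paste(need, collapse = ", "))
  rec
}

#' Write a run manifest
#'
#' Records what produced the contents of an output directory: the
#' configuration (hashed and verbatim), the seed, and package/R versions.
#' Every pipeline run is deterministic given (config, seed); the manifest
#' makes that pair auditable.
#'
#' @param out_dir output directory (created if needed).
#' @param config a named list describing the run.
#' @param seed the integer seed used.
#' @return path of the written manifest (JSON), invisibly.
#' @export
writeRunManifest <- function(out_dir, config, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(config, digits = NA, auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    seed = seed,
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    package = as.character(utils::packageVersion("tumorQMRI")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))
  unlink(tmp)
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
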