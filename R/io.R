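# Standard-format I/O: 16-bit grayscale TIFF per channel with a JSON
# metadata/ground-truth sidecar, and CSV tables with header rows.

#' Write a micrograph as per-channel TIFF files plus a JSON sidecar
#'
#' Writes one 16-bit grayscale TIFF per channel, named
#' `<prefix>_<role>.tif`, and a `<prefix>_meta.json` sidecar holding the
#' pixel size, well and treatment metadata and, when supplied, the
#' generator's ground truth (object tables and background model).
#'
#' @param m A [micrograph()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the well id.
#' @param truth Optional `scene_truth` to embed in the sidecar.
#' @return Invisibly, the character vector of files written.
#' @export
write_micrograph <- function(m, dir, prefix = m$well_id, truth = NULL) {
  if (!inherits(m, "micrograph")) stop_bad_input("`m` must be a micrograph.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (ch in names(m$channels)) {
    path <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    tiff::writeTIFF(m$channels[[ch]] / 65535, path, bits.per.sample = 16,
                    compression = "none")
    files <- c(files, path)
  }
  meta <- list(
    pixel_size = m$pixel_size,
    well_id = m$well_id,
    treatment = m$treatment,
    channels = names(m$channels)
  )
  if (!is.null(truth)) {
    meta$truth <- list(
      nuclei = as.data.frame(truth$nuclei),
      foci = as.data.frame(truth$foci),
      puncta = as.data.frame(truth$puncta),
      vesicles = as.data.frame(truth$vesicles),
      cytosol_background = truth$cytosol_background,
      camera_offset = truth$camera_offset,
      noise_sd = truth$noise_sd
    )
  }
  meta_path <- file.path(dir, sprintf("%s_meta.json", prefix))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(files, meta_path))
}

#' Read a micrograph written by [write_micrograph()]
#'
#' @param dir Directory holding the TIFFs and sidecar.
#' @param prefix File-name prefix (the well id used when writing).
#' @return A list with elements `micrograph` and (when the sidecar carries
#'   ground truth) `truth`, else `truth = NULL`.
#' @export
read_micrograph <- function(dir, prefix) {
  meta_path <- file.path(dir, sprintf("%s_meta.json", prefix))
  if (!file.exists(meta_path)) {
    stop_bad_input(sprintf("Micrograph sidecar not found: %s", meta_path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  channels <- list()
  for (ch in meta$channels) {
    path <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    if (!file.exists(path)) {
      stop_bad_input(sprintf("Channel TIFF not found: %s", path))
    }
    channels[[ch]] <- round(tiff::readTIFF(path) * 65535)
  }
  treatment <- meta$treatment
  treatment$concentration_uM <- treatment$concentration_uM %||% NA_real_
  treatment$compound <- treatment$compound %||% NA_character_
  truth <- NULL
  if (!is.null(meta$truth)) {
    as_obj <- function(x) {
      if (is.null(x) || length(x) == 0) {
        tibble::tibble(row = numeric(0), col = numeric(0), radius = numeric(0),
                       peak = numeric(0))
      } else tibble::as_tibble(x)
    }
    truth <- structure(
      list(nuclei = as_obj(meta$truth$nuclei), foci = as_obj(meta$truth$foci),
           puncta = as_obj(meta$truth$puncta),
           vesicles = as_obj(meta$truth$vesicles),
           cytosol_background = meta$truth$cytosol_background,
           camera_offset = meta$truth$camera_offset,
           noise_sd = meta$truth$noise_sd),
      class = "scene_truth"
    )
  }
  list(
    micrograph = micrograph(channels, pixel_size = meta$pixel_size,
                            well_id = meta$well_id, treatment = treatment),
    truth = truth
  )
}

#' Read or write tidy pipeline tables
#'
#' Thin wrappers around [readr::read_csv()] / [readr::write_csv()] using the
#' pipeline's conventions (UTF-8, header row, `.` decimal separator).
#'
#' @param data A data frame.
#' @param path CSV file path.
#' @return `write_pipeline_csv()` returns `data` invisibly;
#'   `read_pipeline_csv()` returns a tibble.
#' @export
write_pipeline_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}

#' @rdname write_pipeline_csv
#' @export
read_pipeline_csv <- function(path) {
  if (!file.exists(path)) stop_bad_input(sprintf("File not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
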