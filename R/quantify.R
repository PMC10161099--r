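#' Quantify one micrograph
#'
#' Runs the full per-image pipeline on every channel present: top-hat
#' background removal, thresholding and segmentation with optional watershed
#' splitting, and object counting. Per-cell ratios are the ratios of image
#' totals -- e.g. `foci_per_cell = foci / nuclei` -- since each stitched
#' image carries on the order of a hundred cells and no per-cell assignment
#' step is performed. When the image contains no nuclei the ratios are
#' undefined (`NA`) but the raw counts are still reported.
#'
#' @param m A [micrograph()].
#' @param config A [quant_config()].
#' @return A one-row tibble (the image-level count record) with the well and
#'   treatment metadata, the per-channel counts (`nuclei`, `foci`, `puncta`,
#'   `vesicles`; `NA` for absent channels) and the per-cell ratios
#'   (`foci_per_cell`, `puncta_per_cell`, `vesicles_per_cell`).
#' @examples
#' sc <- simulate_micrograph(n_nuclei = 12, n_foci = 5, n_puncta = 30,
#'                           image_shape = c(256, 256), seed = 1)
#' quantify_image(sc$micrograph)
#' @export
quantify_image <- function(m, config = quant_config()) {
  if (!inherits(m, "micrograph")) stop_bad_input("`m` must be a micrograph.")
  if (!inherits(config, "quant_config")) {
    stop_bad_input("`config` must be a quant_config.")
  }
  counts <- c(nuclei = NA_integer_, foci = NA_integer_,
              puncta = NA_integer_, vesicles = NA_integer_)
  obj_of <- channel_object()
  for (ch in names(m$channels)) {
    cfg <- config[[ch]]
    labels <- segment_objects(filter_channel(m$channels[[ch]], cfg), cfg, ch)
    counts[[obj_of[[ch]]]] <- count_objects(labels)
  }
  n_cells <- counts[["nuclei"]]
  ratio <- function(x) {
    if (is.na(n_cells) || n_cells == 0 || is.na(x)) NA_real_ else x / n_cells
  }
  tr <- m$treatment
  tibble::tibble(
    well_id = m$well_id,
    compound = tr$compound %||% NA_character_,
    concentration_uM = tr$concentration_uM %||% NA_real_,
    blocker = isTRUE(tr$blocker),
    nuclei = counts[["nuclei"]],
    foci = counts[["foci"]],
    puncta = counts[["puncta"]],
    vesicles = counts[["vesicles"]],
    foci_per_cell = ratio(counts[["foci"]]),
    puncta_per_cell = ratio(counts[["puncta"]]),
    vesicles_per_cell = ratio(counts[["vesicles"]])
  )
}

#' Average image-level counts into biological replicates
#'
#' Averages the per-cell ratios of the images belonging to each biological
#' replicate (nominally three images, each from a separate well of the same
#' treatment). The aggregate is the unweighted arithmetic mean of the member
#' images' ratios.
#'
#' @param counts Image-level tibble from [quantify_image()] rows, with a
#'   grouping column identifying the replicate.
#' @param group Name of the grouping column (default `"replicate_id"`, falling
#'   back to `"well_id"` when absent).
#' @return A tibble with one row per replicate: the grouping column, the
#'   treatment metadata (taken from the first image), `n_images`, and the
#'   mean ratios `foci_per_cell`, `puncta_per_cell`, `vesicles_per_cell`.
#' @export
aggregate_replicates <- function(counts, group = NULL) {
  if (!is.data.frame(counts) || nrow(counts) == 0) {
    stop_bad_input("`counts` must be a data frame with at least one image record.")
  }
  group <- group %||% if ("replicate_id" %in% names(counts)) "replicate_id" else "well_id"
  check_data_frame(counts, c(group, "foci_per_cell", "puncta_per_cell",
                             "vesicles_per_cell"), "counts")
  meta_cols <- intersect(c("compound", "concentration_uM", "blocker"), names(counts))
  counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(meta_cols), dplyr::first),
      n_images = dplyr::n(),
      foci_per_cell = mean(.data$foci_per_cell),
      puncta_per_cell = mean(.data$puncta_per_cell),
      vesicles_per_cell = mean(.data$vesicles_per_cell),
      .groups = "drop"
    )
}

# Per-channel preprocessing: subtract the channel minimum (makes the whole
# chain exactly invariant to a uniform intensity offset, since the shifted
# integer raster minus its minimum is bit-identical), optionally smooth at
# the spot scale, then remove background with the white top-hat.
filter_channel <- function(raster, cfg) {
  r0 <- raster - min(raster)
  if (cfg$smooth_sigma > 0) {
    r0 <- as.matrix(EBImage::gblur(r0 / 65535, sigma = cfg$smooth_sigma)) * 65535
  }
  tophat_filter(r0, cfg$tophat_radius)
}

#' Count focus/punctum colocalizations
#'
#' Reports the number of mutual overlaps between the segmented objects of
#' two channels: pairs where the first object's centroid pixel lies inside
#' the second object's mask and vice versa. Colocalization is reported for
#' inspection only and feeds nothing downstream.
#'
#' @param m A [micrograph()] containing both channels.
#' @param config A [quant_config()].
#' @param channels Length-2 character vector of channel roles
#'   (default Gal8 foci vs DiD puncta).
#' @return Integer overlap count.
#' @export
count_overlaps <- function(m, config = quant_config(),
                           channels = c("gal8", "did")) {
  if (!inherits(m, "micrograph")) stop_bad_input("`m` must be a micrograph.")
  if (length(channels) != 2 || !all(channels %in% names(m$channels))) {
    stop_bad_input("`channels` must name two channels present in the micrograph.")
  }
  labs <- lapply(channels, function(ch) {
    cfg <- config[[ch]]
    segment_objects(filter_channel(m$channels[[ch]], cfg), cfg, ch)
  })
  cents <- lapply(labs, label_centroids)
  a_in_b <- centroid_hits(cents[[1]], labs[[2]])
  b_in_a <- centroid_hits(cents[[2]], labs[[1]])
  # mutual pairs: label of the object under each centroid must point back
  n <- 0L
  for (i in seq_len(nrow(cents[[1]]))) {
    hit <- a_in_b[i]
    if (hit > 0 && b_in_a[hit] == i) n <- n + 1L
  }
  n
}

label_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    return(matrix(numeric(0), 0, 2))
  }
  nr <- nrow(labels)
  t(vapply(ids, function(l) {
    pix <- which(labels == l)
    c(mean(((pix - 1) %% nr) + 1), mean(((pix - 1) %/% nr) + 1))
  }, numeric(2)))
}

centroid_hits <- function(centroids, labels) {
  if (nrow(centroids) == 0) return(integer(0))
  r <- pmin(pmax(round(centroids[, 1]), 1), nrow(labels))
  cc <- pmin(pmax(round(centroids[, 2]), 1), ncol(labels))
  labels[cbind(r, cc)]
}
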