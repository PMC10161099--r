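#' Multi-channel fluorescence micrograph
#'
#' A micrograph bundles one 2-D grayscale raster per imaging channel with the
#' pixel size and per-well treatment metadata. Channel rasters are numeric
#' matrices in arbitrary fluorescence units on a 16-bit camera scale
#' (0--65535), indexed row-major with the origin at the top-left.
#'
#' The recognised channel roles and the objects they carry are:
#' \describe{
#'   \item{`nuclei`}{Hoechst-stained cell nuclei.}
#'   \item{`gal8`}{mCherry-Gal8: diffuse cytosolic signal plus punctate foci
#'     marking disrupted endo-lysosomes.}
#'   \item{`did`}{DiD lipid dye: puncta marking colloid-containing vesicles.}
#'   \item{`nbdpe`}{NBD-PE lipid: phospholipidosis vesicles.}
#' }
#'
#' @param channels Named list of numeric matrices, one per channel role.
#'   All matrices must share one shape.
#' @param pixel_size Pixel edge length in micrometres; must be positive.
#' @param well_id Well identifier string.
#' @param treatment List with elements `compound` (identifier),
#'   `concentration_uM` (dose in micromolar) and `blocker` (logical; was
#'   dynamin-mediated endocytosis blocked, e.g. with hydroxydynasore).
#'
#' @return An object of class `micrograph`.
#' @seealso [simulate_micrograph()], [quantify_image()]
#' @export
micrograph <- function(channels,
                       pixel_size = 0.227,
                       well_id = "W01",
                       treatment = list(compound = NA_character_,
                                        concentration_uM = NA_real_,
                                        blocker = FALSE)) {
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stop_bad_input("`channels` must be a non-empty named list of matrices.")
  }
  unknown <- setdiff(names(channels), channel_roles())
  if (length(unknown) > 0) {
    stop_bad_input(sprintf(
      "Unknown channel role(s): %s. Recognised roles: %s.",
      paste(unknown, collapse = ", "), paste(channel_roles(), collapse = ", ")
    ))
  }
  if (!all(vapply(channels, is.matrix, logical(1)))) {
    stop_bad_input("Every channel must be a numeric matrix.")
  }
  dims <- vapply(channels, dim, integer(2))
  if (ncol(dims) > 1 && any(dims != dims[, 1])) {
    stop_bad_input("All channel rasters must share one shape.")
  }
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  structure(
    list(channels = channels, pixel_size = pixel_size,
         well_id = well_id, treatment = treatment),
    class = "micrograph"
  )
}

channel_roles <- function() c("nuclei", "gal8", "did", "nbdpe")

# Which object type each channel's segmented features are counted as.
channel_object <- function() {
  c(nuclei = "nuclei", gal8 = "foci", did = "puncta", nbdpe = "vesicles")
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<micrograph> %d x %d px (%.3g um/px), well %s\n",
              d[1], d[2], x$pixel_size, x$well_id))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  tr <- x$treatment
  cat(sprintf("  treatment: %s at %s uM%s\n",
              tr$compound %||% NA, format(tr$concentration_uM %||% NA),
              if (isTRUE(tr$blocker)) " (endocytosis blocked)" else ""))
  invisible(x)
}

#' Per-channel segmentation settings
#'
#' Settings for one channel of the quantification pipeline: the top-hat
#' structuring-element radius, the thresholding rule, feature-size limits, and
#' watershed splitting of touching objects.
#'
#' Three threshold methods are available. `"otsu"` computes Otsu's threshold
#' on the top-hat-filtered image, floored at the robust noise level
#' `median + noise_floor_k * sigma`, where `sigma` is estimated from the
#' upper quantiles of the image (`(q90 - median) / z_0.90`; the top-hat
#' residual is right-skewed, so symmetric scale estimators understate its
#' upper tail); the floor keeps object-free channels empty, since on a
#' pure-noise raster Otsu's split falls inside the noise distribution.
#' `"noise"` uses the robust noise level alone, the standard choice for
#' sparse diffraction-limited spots where Otsu's two-class assumption breaks
#' down (with very few bright pixels Otsu lands far up the spot intensity
#' range and clips dim foci). `"fixed"` applies `threshold_value` directly.
#'
#' @param tophat_radius Disk radius (pixels, >= 1) of the top-hat structuring
#'   element; features wider than about twice this radius are treated as
#'   background.
#' @param threshold_method `"otsu"`, `"noise"` or `"fixed"`.
#' @param threshold_value Threshold in AU, required when
#'   `threshold_method = "fixed"`.
#' @param noise_floor_k Multiplier on the robust noise scale (estimated from
#'   the upper quantiles of the top-hat image) used by the `"noise"` method
#'   and as the floor under the Otsu threshold; set to 0 to disable the
#'   floor. The default 6 sits above the maximum of the noise field over a
#'   megapixel image, while pre-smoothed diffraction-limited spots at the
#'   nominal peak-SNR of 10 stand at roughly 20 noise standard deviations.
#' @param min_area,max_area Feature-area limits in px^2; features outside
#'   `[min_area, max_area]` are discarded. `min_area >= 1` and
#'   `min_area < max_area`.
#' @param watershed Logical; split touching features with marker-based
#'   watershed?
#' @param min_seed_separation Minimum distance (pixels) between watershed
#'   seeds (local maxima of the distance transform).
#' @param smooth_sigma Standard deviation (pixels) of the Gaussian
#'   pre-smoothing applied by [quantify_image()] before the top-hat; 0
#'   disables it. Matched-filter-style smoothing at about the spot scale
#'   attenuates pixel noise several-fold while barely reducing
#'   diffraction-limited peaks, which is what makes a noise-relative
#'   threshold reliable: without it, the opening's locally correlated
#'   baseline produces occasional above-threshold noise clusters on
#'   object-free channels.
#'
#' @return A list of class `channel_config`.
#' @seealso [quant_config()]
#' @export
channel_config <- function(tophat_radius = 5,
                           threshold_method = c("noise", "otsu", "fixed"),
                           threshold_value = NULL,
                           noise_floor_k = 6,
                           min_area = 3,
                           max_area = Inf,
                           watershed = TRUE,
                           min_seed_separation = 5,
                           smooth_sigma = 1) {
  threshold_method <- match.arg(threshold_method)
  check_number(tophat_radius, "tophat_radius", min = 1)
  check_number(min_area, "min_area", min = 1)
  if (!is.numeric(max_area) || length(max_area) != 1 || max_area <= min_area) {
    stop_bad_input("`max_area` must be a single number greater than `min_area`.")
  }
  check_number(noise_floor_k, "noise_floor_k", min = 0)
  check_number(min_seed_separation, "min_seed_separation", min = 1)
  check_number(smooth_sigma, "smooth_sigma", min = 0)
  if (threshold_method == "fixed") {
    if (is.null(threshold_value)) {
      stop_bad_input("`threshold_value` is required when threshold_method = \"fixed\".")
    }
    check_number(threshold_value, "threshold_value")
  }
  structure(
    list(tophat_radius = tophat_radius,
         threshold_method = threshold_method,
         threshold_value = threshold_value,
         noise_floor_k = noise_floor_k,
         min_area = min_area,
         max_area = max_area,
         watershed = isTRUE(watershed),
         min_seed_separation = min_seed_separation,
         smooth_sigma = smooth_sigma),
    class = "channel_config"
  )
}

#' Quantification configuration for all channels
#'
#' Bundles one [channel_config()] per channel role. Defaults use a larger
#' structuring element and size filter for nuclei (extended objects,
#' ~12 px radius at the default simulated scale) than for the
#' diffraction-limited foci/puncta/vesicle channels (~3 px radius).
#'
#' Nuclei default to Otsu thresholding (extended objects give a genuinely
#' bimodal top-hat histogram); the sparse spot channels default to the
#' robust-noise threshold.
#'
#' @param nuclei,gal8,did,nbdpe Per-channel [channel_config()] objects.
#'
#' @return A named list of class `quant_config`.
#' @export
quant_config <- function(nuclei = channel_config(tophat_radius = 15, min_area = 40,
                                                 threshold_method = "otsu",
                                                 min_seed_separation = 9),
                         gal8 = channel_config(),
                         did = channel_config(),
                         nbdpe = channel_config()) {
  cfgs <- list(nuclei = nuclei, gal8 = gal8, did = did, nbdpe = nbdpe)
  ok <- vapply(cfgs, inherits, logical(1), what = "channel_config")
  if (!all(ok)) {
    stop_bad_input("All elements of a quant_config must be channel_config objects.")
  }
  structure(cfgs, class = "quant_config")
}
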