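#' Simulate a multi-channel fluorescence micrograph with known ground truth
#'
#' Generates a synthetic stitched wide-field image of reporter cells treated
#' with dye-labelled colloids: a nucleus channel, an mCherry-Gal8 channel
#' (diffuse cytosolic signal plus disruption foci), a DiD channel (colloid
#' puncta), and an NBD-PE channel (phospholipidosis vesicles). Every channel
#' is composed additively from a constant camera offset, Gaussian-profile
#' objects at randomly placed centres, a wide per-cell diffuse Gal8 halo
#' (Gal8 channel only), and pixelwise Gaussian read noise, then rounded and
#' clipped to the 16-bit range. Object profiles are isotropic 2-D Gaussians
#' with the stated radius equal to 2 standard deviations, matching
#' diffraction-limited spots while keeping the ground truth analytic.
#'
#' Object centres are placed by rejection sampling with a minimum
#' centre-to-centre distance of `min_separation` object radii within each
#' channel; if a channel's requested density cannot be placed, the error
#' names that channel. The returned `truth` is the generator-side record of
#' every placed object and is the oracle for counting tests: its list lengths
#' are, by construction, the true object counts before noise.
#'
#' @param n_nuclei,n_foci,n_puncta,n_vesicles Object counts per channel.
#' @param image_shape Integer vector `c(rows, cols)` in pixels.
#' @param nucleus_radius,spot_radius Object radii in pixels (radius = 2 sigma
#'   of the Gaussian profile); spots are the foci/puncta/vesicles.
#' @param nucleus_amplitude,spot_amplitude Mean peak intensity above local
#'   background, AU.
#' @param intensity_cv Lognormal coefficient of variation of per-object peak
#'   intensities.
#' @param cytosol_amplitude Peak amplitude of the diffuse cytosolic Gal8 halo
#'   rendered around each nucleus (Gal8 channel only), AU. This is exactly the
#'   signal the top-hat stage must remove.
#' @param halo_sigma Standard deviation (pixels) of the diffuse Gal8 halo.
#' @param camera_offset Constant detector offset, AU.
#' @param noise_sd Pixelwise Gaussian noise standard deviation, AU. The peak
#'   signal-to-noise ratio of a spot channel is `spot_amplitude / noise_sd`.
#' @param min_separation Minimum centre separation within a channel, in units
#'   of the object radius.
#' @param pixel_size,well_id,treatment Metadata stored on the [micrograph()].
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A list with elements `micrograph` (a [micrograph()]) and `truth`
#'   (class `scene_truth`: per-channel tibbles of object centres, radii and
#'   peak intensities, plus the background model).
#' @examples
#' sc <- simulate_micrograph(n_nuclei = 20, n_puncta = 50, n_foci = 10,
#'                           image_shape = c(256, 256), seed = 7)
#' nrow(sc$truth$puncta)
#' @export
simulate_micrograph <- function(n_nuclei = 100,
                                n_foci = 40,
                                n_puncta = 250,
                                n_vesicles = 0,
                                image_shape = c(768, 768),
                                nucleus_radius = 12,
                                spot_radius = 3,
                                nucleus_amplitude = 20000,
                                spot_amplitude = 10000,
                                intensity_cv = 0.1,
                                cytosol_amplitude = 3000,
                                halo_sigma = 25,
                                camera_offset = 400,
                                noise_sd = 1000,
                                min_separation = 3,
                                pixel_size = 0.227,
                                well_id = "W01",
                                treatment = list(compound = NA_character_,
                                                 concentration_uM = NA_real_,
                                                 blocker = FALSE),
                                seed) {
  if (missing(seed)) stop_bad_input("`seed` is required for reproducible generation.")
  for (nm in c("n_nuclei", "n_foci", "n_puncta", "n_vesicles")) {
    check_number(get(nm), nm, min = 0)
  }
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2 || any(image_shape < 16)) {
    stop_bad_input("`image_shape` must be two integers >= 16.")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(camera_offset, "camera_offset", min = 0)

  with_seed_maybe(seed, {
    nuclei <- place_objects(n_nuclei, image_shape, nucleus_radius,
                            min_separation, "nuclei")
    foci <- place_objects(n_foci, image_shape, spot_radius,
                          min_separation, "gal8")
    puncta <- place_objects(n_puncta, image_shape, spot_radius,
                            min_separation, "did")
    vesicles <- place_objects(n_vesicles, image_shape, spot_radius,
                              min_separation, "nbdpe")

    draw_peaks <- function(tab, mean_amp) {
      n <- nrow(tab)
      peaks <- if (n == 0) numeric(0) else if (intensity_cv > 0) {
        sdlog <- sqrt(log(1 + intensity_cv^2))
        mean_amp * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(mean_amp, n)
      tab$peak <- peaks
      tab
    }
    nuclei <- draw_peaks(nuclei, nucleus_amplitude)
    foci <- draw_peaks(foci, spot_amplitude)
    puncta <- draw_peaks(puncta, spot_amplitude)
    vesicles <- draw_peaks(vesicles, spot_amplitude)

    compose <- function(objects, halo_centers = NULL) {
      img <- matrix(camera_offset, image_shape[1], image_shape[2])
      if (!is.null(halo_centers) && nrow(halo_centers) > 0) {
        img <- add_gaussians(img, halo_centers$row, halo_centers$col,
                             rep(cytosol_amplitude, nrow(halo_centers)),
                             halo_sigma)
      }
      if (nrow(objects) > 0) {
        img <- add_gaussians(img, objects$row, objects$col, objects$peak,
                             objects$radius / 2)
      }
      if (noise_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                            nrow(img), ncol(img))
      }
      matrix(pmin(pmax(round(img), 0), 65535), nrow(img), ncol(img))
    }

    channels <- list(
      nuclei = compose(nuclei),
      gal8 = compose(foci, halo_centers = nuclei),
      did = compose(puncta),
      nbdpe = compose(vesicles)
    )

    truth <- structure(
      list(nuclei = nuclei, foci = foci, puncta = puncta, vesicles = vesicles,
           cytosol_background = cytosol_amplitude,
           camera_offset = camera_offset, noise_sd = noise_sd),
      class = "scene_truth"
    )
    list(
      micrograph = micrograph(channels, pixel_size = pixel_size,
                              well_id = well_id, treatment = treatment),
      truth = truth
    )
  })
}

# Rejection-sample `n` centres inside the image with a minimum pairwise
# centre distance of `min_separation * radius`; errors naming the channel
# when the density is unplaceable.
place_objects <- function(n, image_shape, radius, min_separation, channel) {
  check_number(radius, paste0("radius (", channel, ")"), min = 0, strict_min = TRUE)
  empty <- tibble::tibble(row = numeric(0), col = numeric(0), radius = numeric(0))
  if (n == 0) return(empty)
  margin <- ceiling(radius)
  if (image_shape[1] - 2 * margin < 1 || image_shape[2] - 2 * margin < 1) {
    stop_bad_input(sprintf(
      "Objects of radius %g do not fit in a %d x %d image (channel %s).",
      radius, image_shape[1], image_shape[2], channel
    ))
  }
  min_dist <- min_separation * radius
  rows <- numeric(n)
  cols <- numeric(n)
  placed <- 0
  tries <- 0
  max_tries <- 400 * n
  while (placed < n && tries < max_tries) {
    tries <- tries + 1
    r <- stats::runif(1, margin + 1, image_shape[1] - margin)
    c <- stats::runif(1, margin + 1, image_shape[2] - margin)
    if (placed == 0 ||
        min((rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2) >= min_dist^2) {
      placed <- placed + 1
      rows[placed] <- r
      cols[placed] <- c
    }
  }
  if (placed < n) {
    stop_bad_input(sprintf(
      "Requested object density is physically unplaceable in channel %s (%d of %d placed).",
      channel, placed, n
    ))
  }
  tibble::tibble(row = rows, col = cols, radius = radius)
}

# Add isotropic 2-D Gaussians (peak `amp`, sd `sigma`, possibly per-object)
# to `img`, rendered on local +/- 4 sigma windows.
add_gaussians <- function(img, rows, cols, amps, sigma) {
  sigma <- rep_len(sigma, length(rows))
  nr <- nrow(img)
  nc <- ncol(img)
  for (i in seq_along(rows)) {
    half <- ceiling(4 * sigma[i])
    r0 <- max(1L, floor(rows[i] - half))
    r1 <- min(nr, ceiling(rows[i] + half))
    c0 <- max(1L, floor(cols[i] - half))
    c1 <- min(nc, ceiling(cols[i] + half))
    rr <- r0:r1
    cc <- c0:c1
    g <- amps[i] * exp(-outer((rr - rows[i])^2, (cc - cols[i])^2, `+`) /
                         (2 * sigma[i]^2))
    img[rr, cc] <- img[rr, cc] + g
  }
  img
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth> %d nuclei, %d foci, %d puncta, %d vesicles (offset %g AU, noise sd %g AU)\n",
    nrow(x$nuclei), nrow(x$foci), nrow(x$puncta), nrow(x$vesicles),
    x$camera_offset, x$noise_sd
  ))
  invisible(x)
}

#' Ground-truth object counts of a simulated scene
#'
#' @param truth A `scene_truth` from [simulate_micrograph()].
#' @return A one-row tibble with columns `nuclei`, `foci`, `puncta`,
#'   `vesicles`.
#' @export
truth_counts <- function(truth) {
  if (!inherits(truth, "scene_truth")) stop_bad_input("`truth` must be a scene_truth.")
  tibble::tibble(
    nuclei = nrow(truth$nuclei), foci = nrow(truth$foci),
    puncta = nrow(truth$puncta), vesicles = nrow(truth$vesicles)
  )
}
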