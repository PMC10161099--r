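#' Specification of a two-mechanism well panel
#'
#' Describes a simulated panel of treatment wells for a set of compounds
#' under the two-mechanism model of endo-lysosomal disruption: Gal8 foci
#' arise in proportion to colloid uptake (colloid-mediated disruption, slope
#' `colloid_efficiency`) plus an uptake-independent free-drug term
#' (`free_drug_rate`); the two mechanisms are not mutually exclusive. A
#' fraction of wells are endocytosis-blocker wells (hydroxydynasore-style)
#' whose colloid uptake is forced to zero, anchoring the regression at x = 0.
#'
#' @param compounds Data frame with one row per compound and columns
#'   `compound` (identifier), `pka` (apparent pKa), `colloid_efficiency`
#'   (foci per punctum, >= 0), `free_drug_rate` (foci per cell, >= 0) and
#'   `phospholipidosis_rate` (vesicles per cell, >= 0).
#' @param wells_per_compound Number of wells per compound (>= 2).
#' @param blocker_fraction Fraction of wells with endocytosis blocked, in
#'   `[0, 1]`.
#' @param uptake_mean,uptake_sd Mean and standard deviation of colloid
#'   uptake (puncta per cell) in unblocked wells; uptake is drawn from a
#'   lognormal with these moments (non-negative and right-skewed, matching
#'   the fairly uniform uptake seen across cells at low spread).
#' @param noise_sd Standard deviation of the additive well-to-well noise on
#'   foci per cell (and on vesicles per cell).
#' @param seed Integer seed.
#'
#' @return A list of class `panel_spec`.
#' @seealso [simulate_mechanism_panel()], [simulate_compound_library()]
#' @export
panel_spec <- function(compounds,
                       wells_per_compound = 15,
                       blocker_fraction = 0.2,
                       uptake_mean = 15,
                       uptake_sd = 5,
                       noise_sd = 0.1,
                       seed = 1) {
  check_data_frame(compounds,
                   c("compound", "pka", "colloid_efficiency",
                     "free_drug_rate", "phospholipidosis_rate"),
                   "compounds")
  if (anyDuplicated(compounds$compound)) {
    stop_bad_input("`compounds$compound` must be unique.")
  }
  for (col in c("colloid_efficiency", "free_drug_rate", "phospholipidosis_rate")) {
    if (any(compounds[[col]] < 0)) {
      stop_bad_input(sprintf("`compounds$%s` must be >= 0.", col))
    }
  }
  check_number(wells_per_compound, "wells_per_compound", min = 2)
  check_number(blocker_fraction, "blocker_fraction", min = 0, max = 1)
  check_number(uptake_mean, "uptake_mean", min = 0)
  check_number(uptake_sd, "uptake_sd", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  structure(
    list(compounds = tibble::as_tibble(compounds),
         wells_per_compound = as.integer(wells_per_compound),
         blocker_fraction = blocker_fraction,
         uptake_mean = uptake_mean, uptake_sd = uptake_sd,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "panel_spec"
  )
}

#' Simulate a two-mechanism well panel
#'
#' Draws per-well replicate-level measurements under a [panel_spec()]. In
#' unblocked wells colloid uptake (puncta per cell) is lognormal with the
#' spec's mean and sd; in blocker wells it is exactly zero. Gal8 foci per
#' cell are `colloid_efficiency * puncta + free_drug_rate + noise`, truncated
#' at zero; phospholipidosis vesicles per cell are drawn around
#' `phospholipidosis_rate` with the same noise scale, truncated at zero.
#' By construction the population regression of foci on puncta has slope
#' `colloid_efficiency` and intercept `free_drug_rate`.
#'
#' @param spec A [panel_spec()].
#' @return A tibble with columns `compound`, `well_id`, `blocker`,
#'   `puncta_per_cell`, `foci_per_cell`, `vesicles_per_cell`. Identical spec
#'   (including seed) gives an identical table.
#' @examples
#' lib <- simulate_compound_library(n_compounds = 3, seed = 2)
#' panel <- simulate_mechanism_panel(panel_spec(lib, seed = 2))
#' head(panel)
#' @export
simulate_mechanism_panel <- function(spec) {
  if (!inherits(spec, "panel_spec")) {
    stop_bad_input("`spec` must be a panel_spec object.")
  }
  n_wells <- spec$wells_per_compound
  n_block <- round(spec$blocker_fraction * n_wells)
  with_seed_maybe(spec$seed, {
    purrr::map_dfr(seq_len(nrow(spec$compounds)), function(i) {
      cmp <- spec$compounds[i, ]
      blocker <- c(rep(TRUE, n_block), rep(FALSE, n_wells - n_block))
      uptake <- numeric(n_wells)
      free <- !blocker
      if (any(free)) {
        uptake[free] <- if (spec$uptake_sd > 0 && spec$uptake_mean > 0) {
          sdlog <- sqrt(log(1 + (spec$uptake_sd / spec$uptake_mean)^2))
          stats::rlnorm(sum(free), meanlog = log(spec$uptake_mean) - sdlog^2 / 2,
                        sdlog = sdlog)
        } else {
          rep(spec$uptake_mean, sum(free))
        }
      }
      foci <- cmp$colloid_efficiency * uptake + cmp$free_drug_rate +
        stats::rnorm(n_wells, 0, spec$noise_sd)
      vesicles <- stats::rnorm(n_wells, cmp$phospholipidosis_rate, spec$noise_sd)
      tibble::tibble(
        compound = cmp$compound,
        well_id = sprintf("%s_w%02d", cmp$compound, seq_len(n_wells)),
        blocker = blocker,
        puncta_per_cell = uptake,
        foci_per_cell = pmax(foci, 0),
        vesicles_per_cell = pmax(vesicles, 0)
      )
    })
  })
}

#' Simulate a compound library with a shared free-drug/phospholipidosis driver
#'
#' Builds the per-compound parameter table for a synthetic screening panel
#' that reproduces the qualitative mechanism pattern seen across ionizable
#' analog libraries: the uptake-independent (free-drug) disruption rate and
#' the phospholipidosis rate share a latent per-compound driver (both are
#' consequences of free cationic drug accumulating in lysosomes), while the
#' colloid-mediated disruption efficiency varies independently. Apparent pKa
#' increases with the latent driver, mirroring the tendency of high-pKa
#' analogs to act through the free-drug mechanism.
#'
#' @param n_compounds Number of compounds.
#' @param seed Integer seed.
#' @param efficiency_range Range of the (independent) colloid disruption
#'   efficiency, foci per punctum.
#' @param driver_range Range of the latent free-drug driver, foci per cell.
#' @param phospholipidosis_coupling Vesicles per cell produced per unit of
#'   the latent driver.
#' @param pka_range Apparent-pKa range mapped linearly onto the driver.
#'
#' @return A tibble suitable as the `compounds` argument of [panel_spec()].
#' @export
simulate_compound_library <- function(n_compounds = 15, seed = 1,
                                      efficiency_range = c(0, 0.4),
                                      driver_range = c(0.5, 3),
                                      phospholipidosis_coupling = 0.8,
                                      pka_range = c(4.5, 8.5)) {
  check_number(n_compounds, "n_compounds", min = 1)
  with_seed_maybe(seed, {
    driver <- stats::runif(n_compounds, driver_range[1], driver_range[2])
    eff <- stats::runif(n_compounds, efficiency_range[1], efficiency_range[2])
    scale01 <- (driver - driver_range[1]) / diff(driver_range)
    tibble::tibble(
      compound = sprintf("C%02d", seq_len(n_compounds)),
      pka = pka_range[1] + scale01 * diff(pka_range),
      colloid_efficiency = eff,
      free_drug_rate = driver,
      phospholipidosis_rate = phospholipidosis_coupling * driver
    )
  })
}
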