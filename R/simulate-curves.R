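# Generators for titration and dose-response inputs, plus the shared model
# evaluators they and the fitters use.

# Sigmoidal TNS titration model: fluorescence as a function of pH for an
# ionizable compound with the given apparent pKa. Decreases from `maximum`
# (fully protonated, low pH) to `background` (deprotonated, high pH), with
# the midpoint at pH = pKa.
pka_model <- function(ph, background, maximum, pka) {
  background + (maximum - background) / (1 + 10^(ph - pka))
}

# Monophasic inhibition model: activity (%) vs dose, decreasing from `top`
# to `bottom` with midpoint `ic50` and slope `hill` (> 0). Zero doses map to
# `top`.
dose_response_mono <- function(conc, top, bottom, ic50, hill) {
  ifelse(conc == 0, top,
         bottom + (top - bottom) / (1 + (conc / ic50)^hill))
}

# Biphasic model: a growth-suppression (static) transition from `top` to
# `plateau` around `ic50_stat`, then a cytotoxic transition from `plateau`
# to `bottom` around `ic50_tox`. Collapses to the monophasic model when
# `plateau == top`.
dose_response_bi <- function(conc, top, plateau, bottom,
                             ic50_stat, hill_stat, ic50_tox, hill_tox) {
  ifelse(conc == 0, top,
         bottom + (plateau - bottom) / (1 + (conc / ic50_tox)^hill_tox) +
           (top - plateau) / (1 + (conc / ic50_stat)^hill_stat))
}

#' Simulate a TNS titration curve
#'
#' Generates fluorescence-versus-pH data for the TNS assay of apparent pKa:
#' the environment-sensitive dye fluoresces in the presence of the protonated
#' (cationic) compound, so fluorescence falls sigmoidally from `maximum` at
#' low pH to `background` at high pH with the midpoint at `pka`.
#'
#' @param pka Apparent pKa (dimensionless).
#' @param background,maximum Fluorescence asymptotes, AU; `maximum` must
#'   exceed `background` (otherwise the titration direction is
#'   unidentifiable).
#' @param ph_grid pH values, each within the assayed range 3--10.
#' @param noise_sd Additive Gaussian noise, AU.
#' @param seed Integer seed; required when `noise_sd > 0`.
#'
#' @return A tibble with columns `ph` and `fluorescence`.
#' @examples
#' simulate_titration(pka = 6.4, background = 10, maximum = 1000)
#' @export
simulate_titration <- function(pka, background = 10, maximum = 1000,
                               ph_grid = seq(3, 10, by = 0.5),
                               noise_sd = 0, seed = NULL) {
  check_number(pka, "pka")
  check_number(noise_sd, "noise_sd", min = 0)
  if (!is.numeric(ph_grid) || length(ph_grid) < 1 ||
      any(ph_grid < 3 - 1e-9) || any(ph_grid > 10 + 1e-9)) {
    stop_bad_input("`ph_grid` values must lie within the assayed pH range [3, 10].")
  }
  if (maximum <= background) {
    stop_bad_input("`maximum` must exceed `background` (unidentifiable direction).")
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop_bad_input("`seed` is required when `noise_sd` > 0.")
  }
  with_seed_maybe(seed, {
    f <- pka_model(ph_grid, background, maximum, pka)
    if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
    tibble::tibble(ph = ph_grid, fluorescence = f)
  })
}

#' Simulate dose-response data
#'
#' Generates percent-activity versus dose data under the monophasic
#' inhibition model (supply `ic50` and `hill`) or the biphasic model (supply
#' `plateau`, `ic50_stat`, `hill_stat`, `ic50_tox`, `hill_tox`), the latter
#' combining a sub-micromolar growth-suppression transition with a micromolar
#' cytotoxic transition.
#'
#' @param concentration Doses in micromolar; non-negative (zero doses are
#'   top-anchor controls).
#' @param top,bottom Activity asymptotes, percent.
#' @param ic50,hill Monophasic midpoint (uM) and slope.
#' @param plateau Intermediate activity plateau (percent) between the two
#'   biphasic transitions.
#' @param ic50_stat,hill_stat,ic50_tox,hill_tox Biphasic transition
#'   midpoints (uM) and slopes; `ic50_stat` must be below `ic50_tox`.
#' @param noise_sd Additive Gaussian noise, percent activity.
#' @param seed Integer seed; required when `noise_sd > 0`.
#'
#' @return A tibble with columns `concentration_uM` and `activity_percent`.
#' @examples
#' simulate_dose_response(10^seq(-4, 1, 0.5), ic50 = 0.005)
#' @export
simulate_dose_response <- function(concentration,
                                   top = 100, bottom = 0,
                                   ic50 = NULL, hill = 1,
                                   plateau = NULL,
                                   ic50_stat = NULL, hill_stat = 1,
                                   ic50_tox = NULL, hill_tox = 1,
                                   noise_sd = 0, seed = NULL) {
  if (!is.numeric(concentration) || any(concentration < 0)) {
    stop_bad_input("`concentration` must be non-negative doses in uM.")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  if (noise_sd > 0 && is.null(seed)) {
    stop_bad_input("`seed` is required when `noise_sd` > 0.")
  }
  biphasic <- !is.null(plateau)
  if (biphasic) {
    if (is.null(ic50_stat) || is.null(ic50_tox)) {
      stop_bad_input("Biphasic simulation needs `ic50_stat` and `ic50_tox`.")
    }
    check_number(ic50_stat, "ic50_stat", min = 0, strict_min = TRUE)
    check_number(ic50_tox, "ic50_tox", min = 0, strict_min = TRUE)
    if (ic50_stat >= ic50_tox) {
      stop_bad_input("`ic50_stat` must be below `ic50_tox`.")
    }
    y <- dose_response_bi(concentration, top, plateau, bottom,
                          ic50_stat, hill_stat, ic50_tox, hill_tox)
  } else {
    if (is.null(ic50)) stop_bad_input("Monophasic simulation needs `ic50`.")
    check_number(ic50, "ic50", min = 0, strict_min = TRUE)
    y <- dose_response_mono(concentration, top, bottom, ic50, hill)
  }
  with_seed_maybe(seed, {
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    tibble::tibble(concentration_uM = concentration, activity_percent = y)
  })
}
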