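#' Decompose endo-lysosomal disruption into colloid- and free-drug-mediated
#' components
#'
#' Fits, for one compound, the ordinary least-squares regression of Gal8
#' foci per cell on colloid (DiD) puncta per cell across replicate-level
#' wells. The slope is the efficiency of colloid-mediated endo-lysosomal
#' disruption (disruption events per unit colloid uptake) and the intercept
#' is the endocytosis-independent, free-drug-mediated disruption (foci per
#' cell at zero uptake). Endocytosis-blocker wells enter the same pooled
#' regression as ordinary wells -- their near-zero uptake anchors the
#' intercept. Negative intercepts are reported as-is (no truncation), which
#' preserves estimator properties for the downstream cross-compound
#' correlation.
#'
#' @param wells Data frame of replicate-aggregated wells with numeric
#'   columns `puncta_per_cell` and `foci_per_cell` (each point nominally the
#'   average of three images); at least 3 points with at least 2 distinct
#'   uptake values. An optional `compound` column (single value) labels the
#'   fit.
#' @return An object of class `mechanism_fit` with `slope`, `slope_se`,
#'   `intercept`, `intercept_se`, `r_squared`, `n_points`, the underlying
#'   [stats::lm] fit, and the data. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' wells <- tibble::tibble(puncta_per_cell = 0:5,
#'                         foci_per_cell = 2 * (0:5) + 1)
#' glance(fit_mechanism(wells))
#' @export
fit_mechanism <- function(wells) {
  check_data_frame(wells, c("puncta_per_cell", "foci_per_cell"), "wells")
  wells <- tibble::as_tibble(wells)
  compound <- if ("compound" %in% names(wells)) {
    u <- unique(wells$compound)
    if (length(u) > 1) {
      stop_bad_input("`wells` contains multiple compounds; use fit_mechanism_panel().")
    }
    u
  } else NA_character_
  ok <- is.finite(wells$puncta_per_cell) & is.finite(wells$foci_per_cell)
  wells <- wells[ok, ]
  if (nrow(wells) < 3) {
    stop_bad_input("At least 3 replicate-level points are required.")
  }
  if (length(unique(wells$puncta_per_cell)) < 2) {
    stop_degenerate("degenerate design: uptake has no variation")
  }
  fit <- stats::lm(foci_per_cell ~ puncta_per_cell, data = wells)
  # summary.lm warns on exact (zero-residual) fits; those are legitimate here
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(
    list(compound = compound,
         slope = co["puncta_per_cell", "Estimate"],
         slope_se = co["puncta_per_cell", "Std. Error"],
         intercept = co["(Intercept)", "Estimate"],
         intercept_se = co["(Intercept)", "Std. Error"],
         r_squared = sm$r.squared,
         n_points = nrow(wells),
         lm = fit, data = wells),
    class = "mechanism_fit"
  )
}

#' @export
print.mechanism_fit <- function(x, ...) {
  cat(sprintf(
    "<mechanism_fit>%s slope = %.4g +/- %.3g foci/punctum, intercept = %.4g +/- %.3g foci/cell\n",
    if (is.na(x$compound)) "" else paste0(" ", x$compound, ":"),
    x$slope, x$slope_se, x$intercept, x$intercept_se))
  cat(sprintf("  R^2 = %.4f over %d points\n", x$r_squared, x$n_points))
  invisible(x)
}

#' @export
tidy.mechanism_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se)
  )
}

#' @export
glance.mechanism_fit <- function(x, ...) {
  tibble::tibble(
    compound = x$compound, slope = x$slope, slope_se = x$slope_se,
    intercept = x$intercept, intercept_se = x$intercept_se,
    r_squared = x$r_squared, n_points = x$n_points
  )
}

#' Fit the mechanism regression for every compound in a panel
#'
#' @param panel Replicate-level data frame with columns `compound`,
#'   `puncta_per_cell`, `foci_per_cell`.
#' @return A tibble with one [glance()] row per compound (slope, intercept,
#'   standard errors, R^2, n).
#' @export
fit_mechanism_panel <- function(panel) {
  check_data_frame(panel, c("compound", "puncta_per_cell", "foci_per_cell"),
                   "panel")
  panel |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_modify(~ glance(fit_mechanism(.x)) |> dplyr::select(-"compound")) |>
    dplyr::ungroup()
}

#' Correlate mechanism estimates with phospholipidosis across compounds
#'
#' Computes the Pearson correlation, across compounds, between the mean
#' phospholipidosis vesicle count and either the colloid disruption
#' efficiency (regression slope) or the endocytosis-independent disruption
#' (regression intercept). The correlation is invariant to affine rescaling
#' of either variable.
#'
#' @param summaries Data frame with one row per compound containing
#'   `vesicles_per_cell` and the column named by `pairing` (`slope` for
#'   efficiency, `intercept`); see [build_compound_summary()].
#' @param pairing `"intercept"` (free-drug-mediated disruption vs
#'   phospholipidosis) or `"efficiency"` (colloid-mediated efficiency vs
#'   phospholipidosis).
#' @return A one-row tibble with columns `pairing`, `r`, `n`.
#' @export
correlate_mechanism <- function(summaries, pairing = c("intercept", "efficiency")) {
  pairing <- match.arg(pairing)
  col <- if (pairing == "intercept") "intercept" else "slope"
  check_data_frame(summaries, c("vesicles_per_cell", col), "summaries")
  x <- summaries[[col]]
  y <- summaries$vesicles_per_cell
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    stop_bad_input("At least 3 compounds with finite values are required.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_degenerate("Zero variance in one of the correlated variables.")
  }
  tibble::tibble(
    pairing = paste0(pairing, "-vs-phospholipidosis"),
    r = stats::cor(x, y),
    n = length(x)
  )
}

#' Join per-compound mechanism, pKa and phospholipidosis estimates
#'
#' Builds the per-compound summary table joining the mechanism regression
#' estimates, the fitted apparent pKa, and the mean phospholipidosis
#' vesicle count. Compounds missing from any input are reported (message +
#' `missing` attribute), never silently dropped into the joined rows.
#'
#' @param mechanism Tibble from [fit_mechanism_panel()] (columns `compound`,
#'   `slope`, `intercept`, ...).
#' @param pka Tibble with columns `compound`, `pka` (e.g. from
#'   [fit_pka_panel()]).
#' @param phospholipidosis Tibble with columns `compound`,
#'   `vesicles_per_cell` (mean per compound).
#' @return A tibble with one row per compound present in all three inputs
#'   (`compound`, `pka`, `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `vesicles_per_cell`), with attribute `missing`: a tibble naming every
#'   compound absent from at least one input and where it is missing from.
#' @export
build_compound_summary <- function(mechanism, pka, phospholipidosis) {
  check_data_frame(mechanism, c("compound", "slope", "intercept"), "mechanism")
  check_data_frame(pka, c("compound", "pka"), "pka")
  check_data_frame(phospholipidosis, c("compound", "vesicles_per_cell"),
                   "phospholipidosis")
  inputs <- list(mechanism = mechanism, pka = pka,
                 phospholipidosis = phospholipidosis)
  for (nm in names(inputs)) {
    if (anyDuplicated(inputs[[nm]]$compound)) {
      stop_bad_input(sprintf("Duplicate compound id in `%s`.", nm))
    }
  }
  all_ids <- unique(unlist(lapply(inputs, function(x) x$compound)))
  missing <- purrr::map_dfr(names(inputs), function(nm) {
    absent <- setdiff(all_ids, inputs[[nm]]$compound)
    if (length(absent) == 0) return(NULL)
    tibble::tibble(compound = absent, missing_from = nm)
  })
  shared <- Reduce(intersect, lapply(inputs, function(x) x$compound))
  out <- tibble::tibble(compound = shared) |>
    dplyr::left_join(dplyr::select(pka, "compound", "pka"), by = "compound") |>
    dplyr::left_join(
      dplyr::select(mechanism, "compound", "slope", "slope_se",
                    dplyr::any_of(c("intercept_se")), "intercept"),
      by = "compound") |>
    dplyr::left_join(dplyr::select(phospholipidosis, "compound",
                                   "vesicles_per_cell"), by = "compound")
  if (nrow(missing) > 0) {
    message(sprintf(
      "%d compound(s) missing from at least one input: %s",
      length(unique(missing$compound)),
      paste(unique(missing$compound), collapse = ", ")))
  }
  attr(out, "missing") <- missing
  out
}
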