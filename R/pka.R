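#' Fit an apparent-pKa titration curve
#'
#' Fits the sigmoidal TNS titration model
#' `Fluorescence = Background + (Maximum - Background) / (1 + 10^(pH - pKa))`
#' to fluorescence-versus-pH data by Levenberg-Marquardt nonlinear least
#' squares. The model value at the fitted pKa is exactly
#' `(Background + Maximum) / 2`.
#'
#' A compound is flagged non-ionizable when the fit fails to converge, when
#' the fitted dynamic range `Maximum - Background` is below three residual
#' standard deviations (the curve is flat relative to noise, as for a
#' compound that is never protonated over the assayed range), or when the
#' fitted pKa falls outside the sampled pH range. A converged fit with
#' `Maximum <= Background` (fluorescence rising with pH, the wrong direction
#' for a protonation titration) is reported as non-converged since the
#' titration direction is unidentifiable.
#'
#' @param data Data frame with numeric columns `ph` and `fluorescence`;
#'   at least 4 points.
#' @return An object of class `pka_fit` with fields `pka`, `background`,
#'   `maximum`, their standard errors, `rss`, `sigma`, `converged`,
#'   `ionizable`, `n`, and the data. Supports [predict()],
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' curve <- simulate_titration(pka = 6.4)
#' fit <- fit_pka(curve)
#' glance(fit)
#' @export
fit_pka <- function(data) {
  check_data_frame(data, c("ph", "fluorescence"), "data")
  data <- tibble::as_tibble(data[c("ph", "fluorescence")])
  if (nrow(data) < 4) {
    stop_bad_input("At least 4 (pH, fluorescence) points are required.")
  }
  if (!all(is.finite(data$ph)) || !all(is.finite(data$fluorescence))) {
    stop_bad_input("`ph` and `fluorescence` must be finite.")
  }

  f <- data$fluorescence
  ph <- data$ph
  # deterministic starts: asymptotes from the data range, pKa from the pH
  # closest to half-maximal fluorescence
  b0 <- min(f)
  m0 <- max(f)
  mid <- (b0 + m0) / 2
  pka0 <- ph[which.min(abs(f - mid))]

  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      fluorescence ~ background + (maximum - background) / (1 + 10^(ph - pka)),
      data = data,
      start = list(background = b0, maximum = m0, pka = pka0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)
    )),
    error = function(e) NULL
  )

  est <- c(background = NA_real_, maximum = NA_real_, pka = NA_real_)
  se <- est
  rss <- NA_real_
  sigma <- NA_real_
  converged <- FALSE
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    est[names(cf)] <- cf
    sm <- tryCatch(summary(fit), error = function(e) NULL)
    if (!is.null(sm)) se[rownames(sm$coefficients)] <- sm$coefficients[, "Std. Error"]
    rss <- sum(stats::resid(fit)^2)
    sigma <- sqrt(rss / max(nrow(data) - 3, 1))
    converged <- isTRUE(fit$convInfo$isConv) && est[["maximum"]] > est[["background"]]
  }
  dynamic_range <- est[["maximum"]] - est[["background"]]
  ionizable <- isTRUE(converged) &&
    isTRUE(dynamic_range >= 3 * sigma) &&
    isTRUE(est[["pka"]] >= min(ph)) && isTRUE(est[["pka"]] <= max(ph))

  structure(
    list(pka = unname(est[["pka"]]),
         background = unname(est[["background"]]),
         maximum = unname(est[["maximum"]]),
         se = se, rss = rss, sigma = sigma,
         converged = converged, ionizable = ionizable,
         n = nrow(data), data = data),
    class = "pka_fit"
  )
}

#' @export
print.pka_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<pka_fit> pKa = %.3f (SE %.3g), background = %.4g, maximum = %.4g AU\n",
      x$pka, x$se[["pka"]], x$background, x$maximum))
    cat(sprintf("  n = %d, RSS = %.4g, %s\n", x$n, x$rss,
                if (x$ionizable) "ionizable" else "not ionizable over the assayed range"))
  } else {
    cat("<pka_fit> did not converge; compound classified non-ionizable\n")
  }
  invisible(x)
}

#' Predict fluorescence from a fitted titration model
#'
#' @param object A `pka_fit`.
#' @param ph pH values at which to evaluate the fitted model (defaults to
#'   the fitted data's pH grid).
#' @param ... Unused.
#' @return Numeric vector of fitted fluorescence, AU.
#' @export
predict.pka_fit <- function(object, ph = object$data$ph, ...) {
  if (!object$converged) {
    stop_numerical("Cannot predict from a non-converged pKa fit.")
  }
  pka_model(ph, object$background, object$maximum, object$pka)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pka_fit <- function(x, ...) {
  tibble::tibble(
    term = c("background", "maximum", "pka"),
    estimate = c(x$background, x$maximum, x$pka),
    std.error = unname(x$se[c("background", "maximum", "pka")])
  )
}

#' @export
glance.pka_fit <- function(x, ...) {
  tibble::tibble(
    pka = x$pka, background = x$background, maximum = x$maximum,
    rss = x$rss, sigma = x$sigma, converged = x$converged,
    ionizable = x$ionizable, n = x$n
  )
}

#' Fit titration curves for a panel of compounds
#'
#' @param data Data frame with columns `compound`, `ph`, `fluorescence`.
#' @return A tibble with one [glance()] row per compound.
#' @export
fit_pka_panel <- function(data) {
  check_data_frame(data, c("compound", "ph", "fluorescence"), "data")
  data |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_modify(~ glance(fit_pka(.x))) |>
    dplyr::ungroup()
}
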