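#' Fit a mono- or biphasic dose-response curve
#'
#' Fits percent-activity versus dose data by Levenberg-Marquardt least
#' squares in log10-dose space (for conditioning over wide concentration
#' spans). The monophasic model is
#' `Y = Bottom + (Top - Bottom) / (1 + ([Drug]/IC50)^Hill)`,
#' activity decreasing with dose for `Hill > 0`. The biphasic model adds a
#' second transition,
#' `Y = Bottom + (Plateau - Bottom) / (1 + ([Drug]/IC50_tox)^Hill_tox) +
#' (Top - Plateau) / (1 + ([Drug]/IC50_stat)^Hill_stat)`,
#' separating a sub-micromolar growth-suppression (static) effect from
#' micromolar cytotoxicity; the constraint `IC50_stat <= IC50_tox` is imposed
#' during fitting to keep the two terms identifiable. With `Plateau = Top`
#' the biphasic model collapses exactly to the monophasic one.
#'
#' Zero-dose rows are permitted and anchor the fitted `Top`. Starting values
#' are derived deterministically from the data (asymptotes from the activity
#' range, midpoints from the doses bracketing half-range crossings).
#' Non-convergence is reported via `converged = FALSE`, not an error.
#'
#' @param data Data frame with numeric columns `concentration_uM` (>= 0) and
#'   `activity_percent`.
#' @param model `"monophasic"` or `"biphasic"`.
#' @return An object of class `dose_response_fit` with the fitted parameters
#'   (IC50s in micromolar, on the dose scale), standard errors, `rss`,
#'   `sigma`, `converged`, `n`, and the data. Supports [predict()],
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' dat <- simulate_dose_response(10^seq(-4, 1, 0.25), ic50 = 0.005)
#' glance(fit_dose_response(dat))
#' @export
fit_dose_response <- function(data, model = c("monophasic", "biphasic")) {
  model <- match.arg(model)
  check_data_frame(data, c("concentration_uM", "activity_percent"), "data")
  conc <- data$concentration_uM
  act <- data$activity_percent
  if (any(!is.finite(conc)) || any(!is.finite(act)) || any(conc < 0)) {
    stop_bad_input("Concentrations must be finite and >= 0; activities finite.")
  }
  n_par <- if (model == "monophasic") 4L else 7L
  if (length(unique(conc)) < n_par + 1) {
    stop_bad_input(sprintf(
      "The %s model needs at least %d distinct concentrations.", model, n_par + 1))
  }
  if (sum(conc > 0) < n_par) {
    stop_bad_input("Too few nonzero doses to identify the model.")
  }

  top0 <- max(act)
  bottom0 <- min(act)
  # dose whose activity is nearest to `level`, on the log10 scale
  crossing <- function(level) {
    pos <- conc > 0
    log10(conc[pos][which.min(abs(act[pos] - level))])
  }

  if (model == "monophasic") {
    par0 <- c(top = top0, bottom = bottom0,
              logic50 = crossing((top0 + bottom0) / 2), hill = 1)
    lower <- c(-Inf, -Inf, -Inf, 1e-3)
    predict_par <- function(p, x) {
      dose_response_mono(x, p[["top"]], p[["bottom"]], 10^p[["logic50"]],
                         p[["hill"]])
    }
  } else {
    plateau0 <- stats::median(act)
    l_stat0 <- crossing((top0 + plateau0) / 2)
    l_tox0 <- crossing((plateau0 + bottom0) / 2)
    par0 <- c(top = top0, plateau = plateau0, bottom = bottom0,
              logic50_stat = min(l_stat0, l_tox0),
              dlog = max(l_tox0 - l_stat0, 0.5),
              hill_stat = 1, hill_tox = 1)
    lower <- c(-Inf, -Inf, -Inf, -Inf, 0, 1e-3, 1e-3)
    predict_par <- function(p, x) {
      dose_response_bi(x, p[["top"]], p[["plateau"]], p[["bottom"]],
                       10^p[["logic50_stat"]], p[["hill_stat"]],
                       10^(p[["logic50_stat"]] + p[["dlog"]]), p[["hill_tox"]])
    }
  }

  res_fn <- function(p) {
    p <- stats::setNames(p, names(par0))
    act - predict_par(p, conc)
  }
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = par0, lower = lower, fn = res_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)
    )),
    error = function(e) NULL
  )

  converged <- !is.null(fit) && fit$info %in% 1:4
  est <- if (is.null(fit)) stats::setNames(rep(NA_real_, n_par), names(par0)) else
    stats::setNames(fit$par, names(par0))
  se <- stats::setNames(rep(NA_real_, n_par), names(par0))
  rss <- sigma <- NA_real_
  if (!is.null(fit)) {
    rss <- sum(fit$fvec^2)
    dof <- max(length(conc) - n_par, 1)
    sigma <- sqrt(rss / dof)
    cov <- tryCatch(sigma^2 * solve(fit$hessian / 2), error = function(e) NULL)
    if (!is.null(cov)) se[] <- sqrt(pmax(diag(cov), 0))
  }

  # report IC50s on the dose scale (delta method for the SEs)
  ln10 <- log(10)
  params <- if (model == "monophasic") {
    tibble::tibble(
      term = c("top", "bottom", "ic50", "hill"),
      estimate = c(est[["top"]], est[["bottom"]], 10^est[["logic50"]],
                   est[["hill"]]),
      std.error = c(se[["top"]], se[["bottom"]],
                    ln10 * 10^est[["logic50"]] * se[["logic50"]], se[["hill"]])
    )
  } else {
    l_stat <- est[["logic50_stat"]]
    l_tox <- est[["logic50_stat"]] + est[["dlog"]]
    se_tox <- if (all(is.finite(se[c("logic50_stat", "dlog")]))) {
      # conservative: treat the two components as independent
      sqrt(se[["logic50_stat"]]^2 + se[["dlog"]]^2)
    } else NA_real_
    tibble::tibble(
      term = c("top", "plateau", "bottom", "ic50_stat", "hill_stat",
               "ic50_tox", "hill_tox"),
      estimate = c(est[["top"]], est[["plateau"]], est[["bottom"]],
                   10^l_stat, est[["hill_stat"]], 10^l_tox, est[["hill_tox"]]),
      std.error = c(se[["top"]], se[["plateau"]], se[["bottom"]],
                    ln10 * 10^l_stat * se[["logic50_stat"]], se[["hill_stat"]],
                    ln10 * 10^l_tox * se_tox, se[["hill_tox"]])
    )
  }

  structure(
    list(model = model, params = params, raw = est, rss = rss, sigma = sigma,
         converged = converged, n = length(conc),
         data = tibble::as_tibble(data[c("concentration_uM", "activity_percent")]),
         predict_par = predict_par),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> %s, n = %d, %s\n", x$model, x$n,
              if (x$converged) sprintf("RSS = %.4g", x$rss) else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' Predict activity from a fitted dose-response model
#'
#' @param object A `dose_response_fit`.
#' @param concentration Doses (uM) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Numeric vector of percent activity.
#' @export
predict.dose_response_fit <- function(object,
                                      concentration = object$data$concentration_uM,
                                      ...) {
  if (!object$converged) {
    stop_numerical("Cannot predict from a non-converged dose-response fit.")
  }
  object$predict_par(object$raw, concentration)
}

#' @export
tidy.dose_response_fit <- function(x, ...) x$params

#' @export
glance.dose_response_fit <- function(x, ...) {
  wide <- stats::setNames(as.list(x$params$estimate), x$params$term)
  tibble::as_tibble(wide) |>
    dplyr::mutate(model = x$model, rss = x$rss, sigma = x$sigma,
                  converged = x$converged, n = x$n, .before = 1)
}
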