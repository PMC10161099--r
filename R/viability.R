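#' Metabolic activity relative to the blank-treated control
#'
#' Computes, per well,
#' `100 * (I_sample_6d - I_background_6d) / (I_control_6d - I_background_6d)`,
#' the background-corrected metabolic-activity readout of a treated well as
#' a percentage of the blank-treated control at the same endpoint.
#'
#' @param data Data frame with numeric intensity columns `i_sample_6d`,
#'   `i_background_6d` and `i_control_6d` (AU).
#' @return The input as a tibble with an added `relative_activity_pct`
#'   column.
#' @examples
#' relative_activity(tibble::tibble(
#'   i_sample_6d = 55, i_background_6d = 10, i_control_6d = 100))
#' @export
relative_activity <- function(data) {
  check_data_frame(data, c("i_sample_6d", "i_background_6d", "i_control_6d"),
                   "data")
  denom <- data$i_control_6d - data$i_background_6d
  if (any(denom == 0)) {
    stop_bad_input("Zero denominator: i_control_6d equals i_background_6d in some rows.")
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    relative_activity_pct =
      100 * (.data$i_sample_6d - .data$i_background_6d) / denom
  )
}

#' Metabolic activity relative to the pretreatment value
#'
#' Computes, per well,
#' `100 * (I_sample_6d - I_background_6d) / (I_sample_0d - I_background_0d)`,
#' the endpoint metabolic activity as a percentage of the same well's
#' pre-treatment (day 0) activity -- the proliferation readout. Values above
#' 100% indicate net growth over the treatment window.
#'
#' @param data Data frame with numeric intensity columns `i_sample_6d`,
#'   `i_background_6d`, `i_sample_0d` and `i_background_0d` (AU).
#' @return The input as a tibble with an added `original_activity_pct`
#'   column.
#' @export
original_activity <- function(data) {
  check_data_frame(data, c("i_sample_6d", "i_background_6d",
                           "i_sample_0d", "i_background_0d"), "data")
  denom <- data$i_sample_0d - data$i_background_0d
  if (any(denom == 0)) {
    stop_bad_input("Zero denominator: i_sample_0d equals i_background_0d in some rows.")
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    original_activity_pct =
      100 * (.data$i_sample_6d - .data$i_background_6d) / denom
  )
}
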