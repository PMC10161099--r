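# Internal helpers: condition classes and input checks.

stop_bad_input <- function(msg, ...) {
  rlang::abort(msg, class = "colloidquant_bad_input", ...)
}

stop_numerical <- function(msg, ...) {
  rlang::abort(msg, class = "colloidquant_numerical", ...)
}

stop_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = c("colloidquant_degenerate_design", "colloidquant_bad_input"), ...)
}

check_data_frame <- function(data, cols, what = "data") {
  if (!is.data.frame(data)) {
    stop_bad_input(sprintf("`%s` must be a data frame.", what))
  }
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop_bad_input(sprintf(
      "`%s` is missing required column%s: %s.",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

check_number <- function(x, what, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_bad_input(sprintf("`%s` must be a single finite number.", what))
  }
  if (strict_min && x <= min) {
    stop_bad_input(sprintf("`%s` must be > %g.", what, min))
  }
  if (!strict_min && x < min) {
    stop_bad_input(sprintf("`%s` must be >= %g.", what, min))
  }
  if (x > max) {
    stop_bad_input(sprintf("`%s` must be <= %g.", what, max))
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed without touching the caller's RNG state.
# When `seed` is NULL the expression runs against the current RNG stream.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

`%||%` <- rlang::`%||%`
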