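#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported tables in this field
#' round half up. Used only at presentation time — all computation keeps
#' full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up at `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by a few ulp so values stored just under .5 (e.g. 16.5105) behave
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Complement-product aggregation of independent probabilities
#'
#' Probability that at least one of a set of independent events occurs:
#' `1 - prod(1 - p)`. This is the aggregation rule used to lift route-level
#' invasion probabilities to port pairs and port-pair probabilities to
#' region pairs.
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @return Single probability in \[0, 1\]; 0 for empty input.
#' @export
complement_aggregate <- function(p) {
  if (length(p) == 0) return(0)
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  1 - prod(1 - p)
}

# shared input check: data frame with required columns
check_columns <- function(df, required, what = "input") {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
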