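#' Expected number of NIS for a donor-recipient pair
#'
#' The null model of species exchange irrespective of species traits:
#' donor-region average species richness multiplied by the region-pair
#' invasion probability. Full precision is returned;
#' [display_expected()] reproduces the reporting convention.
#'
#' @param richness Donor average richness (species per grid cell, > 0);
#'   vectorized.
#' @param p_inv Region-pair invasion probability in \[0, 1\]; vectorized.
#' @return Expected NIS count(s), full precision.
#' @export
expected_nis <- function(richness, p_inv) {
  stopifnot(all(richness >= 0), all(p_inv >= 0 & p_inv <= 1))
  richness * p_inv
}

#' Display rounding for expected NIS counts
#'
#' Reporting convention inferred from the reference comparison table:
#' values of at least 1 round half-up to integers; values below 1 round
#' half-up to one significant digit (92.18 -> 92, 0.036 -> 0.04,
#' 0.0045 -> 0.005).
#'
#' @param e Expected count(s), full precision.
#' @return Rounded value(s) on the reported scale.
#' @export
display_expected <- function(e) {
  purrr::map_dbl(e, function(x) {
    if (x == 0) return(0)
    if (x >= 1) return(round_half_up(x))
    digits <- -floor(log10(x))
    round_half_up(x, digits)
  })
}

#' Display rounding for chi-square statistics
#'
#' Two decimals below 1000, integers above (25.043 -> 25.04,
#' 7511.2 -> 7511), matching the reference table's precision.
#'
#' @param x Chi-square value(s).
#' @return Rounded value(s).
#' @export
display_chi_square <- function(x) {
  ifelse(x >= 1000, round_half_up(x), round_half_up(x, 2))
}

#' Display formatting for p-values
#'
#' `"<.001"` below 0.001, otherwise three decimals without the leading
#' zero (`.279`, `.021`, `1`).
#'
#' @param p P-value(s).
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  purrr::map_chr(p, function(x) {
    if (x < 0.001) return("<.001")
    r <- round_half_up(x, 3)
    if (r >= 0.9995) "1" else sub("^0", "", sprintf("%.3f", r))
  })
}

#' One-cell chi-square comparison of observed and expected counts
#'
#' `chi_square = (O - E)^2 / E` with the upper-tail p-value of the
#' chi-square distribution at 1 degree of freedom. Zero exactly when
#' `O = E`. Expected values below 0.005 are permitted but flagged with a
#' warning: the chi-square approximation is unreliable there (no
#' continuity correction is applied).
#'
#' @param observed Integer observed count(s).
#' @param expected Positive expected count(s) on whatever precision the
#'   caller intends (the reference table uses the reported, rounded
#'   expected counts).
#' @return Tibble with columns `chi_square`, `p_value`, `df` (= 1).
#' @export
#' @examples
#' pair_chi_square(44, 92) # chi-square 25.04
pair_chi_square <- function(observed, expected) {
  if (any(expected <= 0)) {
    stop(paste(
      "expected count must be positive;",
      "pairs with no shipping connection should be skipped upstream"
    ), call. = FALSE)
  }
  if (any(expected < 0.005)) {
    warning(paste(
      "expected count below 0.005: the chi-square approximation",
      "is unreliable for such sparse expectations"
    ), call. = FALSE)
  }
  chi <- (observed - expected)^2 / expected
  tibble::tibble(
    chi_square = chi,
    p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
    df = 1L
  )
}

#' Overall chi-square across the donors of a recipient region
#'
#' Sums the per-donor `(O - E)^2 / E` contributions over all donors of
#' each recipient with `df = n_donors - 1`, testing whether the observed
#' donor profile is consistent with the null expectations as a whole.
#' With `pooled = TRUE` a single statistic over every row is returned
#' instead (both readings of an "overall" test are offered; neither is
#' canonical).
#'
#' @param results Comparison rows: tibble with columns `recipient`,
#'   `observed`, `expected` (or a [comparison_table()] result, whose
#'   reported `expected_display` values are then used, consistent with
#'   its per-pair statistics).
#' @param recipient Optional recipient code to restrict to.
#' @param pooled Pool all rows into one statistic.
#' @return Tibble with columns `recipient`, `chi_square`, `df`,
#'   `p_value`.
#' @export
overall_chi_square <- function(results, recipient = NULL, pooled = FALSE) {
  check_columns(results, c("recipient", "observed"), "results")
  expected <- if (inherits(results, "nis_comparison")) {
    results$expected_display
  } else {
    check_columns(results, "expected", "results")
    results$expected
  }
  if (any(expected <= 0)) {
    stop("all expected counts must be positive", call. = FALSE)
  }
  df <- tibble::tibble(
    recipient = if (pooled) "(pooled)" else results$recipient,
    observed = results$observed, expected = expected
  )
  if (!is.null(recipient)) df <- df[df$recipient == recipient, ]
  out <- df |>
    dplyr::group_by(.data$recipient) |>
    dplyr::summarise(
      chi_square = sum((.data$observed - .data$expected)^2 / .data$expected),
      df = dplyr::n() - 1L,
      .groups = "drop"
    )
  if (any(out$df < 1)) {
    stop("overall chi-square needs at least two donor rows per recipient",
         call. = FALSE)
  }
  dplyr::mutate(out, p_value = stats::pchisq(.data$chi_square, df = .data$df,
                                             lower.tail = FALSE))
}

#' Assemble the expected-versus-observed comparison table
#'
#' Joins donor richness, region-pair invasion probabilities, and observed
#' checklist counts into one row per (donor, recipient) pair with
#' expected counts and chi-square statistics, sorted by recipient then
#' descending expected count.
#'
#' Reporting conventions follow the reference table: the expected count
#' is display-rounded first ([display_expected()]), the chi-square
#' statistic is computed from that rounded expected count (the test
#' operates on the reported counts), and the reported p-value corresponds
#' to the display-rounded statistic. Full-precision `expected` is also
#' kept.
#'
#' @param richness Tibble with columns `region`, `average_richness`
#'   (e.g. from [average_grid_richness()] /
#'   [corrected_average_richness()]).
#' @param probs Tibble with columns `donor`, `recipient`, `p_invasion`
#'   (e.g. from [region_invasion_probability()]).
#' @param observed Tibble with columns `donor`, `recipient`, `observed`
#'   (e.g. from [observed_counts()]).
#' @return Tibble of class `nis_comparison`: `donor`, `recipient`,
#'   `average_richness`, `p_invasion`, `expected`, `expected_display`,
#'   `observed`, `chi_square`, `chi_square_display`, `p_value`,
#'   `p_display`, `df`.
#' @export
comparison_table <- function(richness, probs, observed) {
  check_columns(richness, c("region", "average_richness"), "richness")
  check_columns(probs, c("donor", "recipient", "p_invasion"), "probs")
  check_columns(observed, c("donor", "recipient", "observed"), "observed")
  if (nrow(probs) == 0) {
    out <- tibble::tibble(
      donor = character(), recipient = character(),
      average_richness = numeric(), p_invasion = numeric(),
      expected = numeric(), expected_display = numeric(),
      observed = integer(), chi_square = numeric(),
      chi_square_display = numeric(), p_value = numeric(),
      p_display = character(), df = integer()
    )
    class(out) <- c("nis_comparison", class(out))
    return(out)
  }

  tab <- probs |>
    dplyr::left_join(
      dplyr::select(richness, donor = "region", "average_richness"),
      by = "donor"
    ) |>
    dplyr::left_join(
      dplyr::select(observed, "donor", "recipient", "observed"),
      by = c("donor", "recipient")
    )
  bad <- is.na(tab$average_richness) | is.na(tab$observed)
  if (any(bad)) {
    stop(sprintf(
      "missing richness or observed count for pair(s): %s",
      paste(sprintf("%s->%s", tab$donor[bad], tab$recipient[bad]),
            collapse = ", ")
    ), call. = FALSE)
  }

  out <- tab |>
    dplyr::mutate(
      expected = expected_nis(.data$average_richness, .data$p_invasion),
      expected_display = display_expected(.data$expected)
    )
  if (any(out$expected_display < 0.005)) {
    warning(paste(
      "expected count(s) below 0.005: the chi-square approximation is",
      "unreliable for such sparse expectations"
    ), call. = FALSE)
  }
  out <- out |>
    dplyr::mutate(
      chi_square = (.data$observed - .data$expected_display)^2 /
        .data$expected_display,
      chi_square_display = display_chi_square(.data$chi_square),
      p_value = stats::pchisq(.data$chi_square_display, df = 1,
                              lower.tail = FALSE),
      p_display = format_p_value(.data$p_value),
      df = 1L
    ) |>
    dplyr::select(
      "donor", "recipient", "average_richness",
      p_invasion = "p_invasion", "expected", "expected_display",
      "observed", "chi_square", "chi_square_display", "p_value",
      "p_display", "df"
    ) |>
    dplyr::arrange(.data$recipient, dplyr::desc(.data$expected))
  class(out) <- c("nis_comparison", class(out))
  out
}

#' Expected/observed scatter data
#'
#' The (expected, observed) pairs with donor/recipient labels exactly as
#' tabulated — the data behind the expected-versus-observed scatter.
#'
#' @param comparison A [comparison_table()] result.
#' @return Tibble with columns `donor`, `recipient`, `expected`,
#'   `observed`.
#' @export
scatter_data <- function(comparison) {
  dplyr::select(tibble::as_tibble(comparison),
                "donor", "recipient", expected = "expected_display",
                "observed")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a comparison table
#'
#' One row per donor-recipient pair with the statistic columns, in the
#' broom column vocabulary (`estimate` = expected count, `statistic` =
#' chi-square, `p.value`).
#'
#' @param x A `nis_comparison` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy nis_comparison
#' @export
tidy.nis_comparison <- function(x, ...) {
  tibble::tibble(
    donor = x$donor, recipient = x$recipient,
    estimate = x$expected_display, observed = x$observed,
    statistic = x$chi_square_display, p.value = x$p_value,
    parameter = x$df
  )
}

#' Recipient-level summary of a comparison table
#'
#' Overall chi-square per recipient region, broom-style.
#'
#' @param x A `nis_comparison` object.
#' @param ... Unused.
#' @return A tibble with one row per recipient.
#' @method glance nis_comparison
#' @export
glance.nis_comparison <- function(x, ...) {
  overall_chi_square(x) |>
    dplyr::rename(statistic = "chi_square", parameter = "df",
                  p.value = "p_value")
}

#' @export
print.nis_comparison <- function(x, ...) {
  cat(sprintf("Expected vs observed NIS: %d donor-recipient pair(s)\n",
              nrow(x)))
  disp <- tibble::tibble(
    donor = x$donor, recipient = x$recipient,
    richness = x$average_richness, `P(Inv)` = x$p_invasion,
    expected = x$expected_display, observed = x$observed,
    `chi-square` = x$chi_square_display, p = x$p_display
  )
  print(disp, n = nrow(disp))
  invisible(x)
}

#' Expected-versus-observed scatter plot
#'
#' Log-log scatter of observed against expected NIS counts per
#' donor-recipient pair, colored by recipient, with the line of unity.
#' Points above the line mark donors over-represented relative to the
#' shipping/environment null model.
#'
#' @param object A `nis_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nis_comparison
#' @export
autoplot.nis_comparison <- function(object, ...) {
  dat <- scatter_data(object) |>
    dplyr::mutate(observed = pmax(.data$observed, 0.001))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$expected, y = .data$observed,
                                    color = .data$recipient)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Expected NIS", y = "Observed NIS",
                  color = "Recipient") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
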