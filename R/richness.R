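#' Read an equal-area richness grid
#'
#' Delimited text with columns `cell_id, region, coastal (0/1), richness`.
#' Cell ids must be unique and richness non-negative.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; `NULL` to infer (`,` vs tab).
#' @return Tibble with columns `cell_id`, `region`, `coastal` (logical),
#'   `richness`.
#' @export
read_richness_grid <- function(path, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("grid file not found: %s", path), call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  grid <- readr::read_delim(path, delim = delim, progress = FALSE,
                            col_types = readr::cols())
  validate_richness_grid(grid)
}

validate_richness_grid <- function(grid) {
  check_columns(grid, c("cell_id", "region", "coastal", "richness"), "richness grid")
  grid <- dplyr::mutate(tibble::as_tibble(grid),
                        coastal = as.logical(as.integer(.data$coastal)))
  if (anyDuplicated(grid$cell_id)) {
    stop("richness grid has duplicated cell_id values", call. = FALSE)
  }
  if (any(grid$richness < 0)) {
    stop("richness grid has negative richness values", call. = FALSE)
  }
  grid
}

#' Average per-cell species richness of a region's coastal grid cells
#'
#' Sums derived richness over the coastal cells of each region and divides
#' by their number. Averaging over coastal cells (rather than summing)
#' avoids over-counting species shared between neighbouring cells.
#' Non-coastal cells are ignored.
#'
#' @param grid A richness grid tibble (see [read_richness_grid()]).
#' @param region Region code(s) to average; `NULL` for every region with
#'   at least one coastal cell.
#' @return Tibble with columns `region`, `average_richness`, `n_cells`,
#'   `source = "derived"`.
#' @export
average_grid_richness <- function(grid, region = NULL) {
  grid <- validate_richness_grid(grid)
  if (!is.null(region)) {
    missing <- setdiff(region, grid$region[grid$coastal])
    if (length(missing) > 0) {
      stop(sprintf("region(s) with no coastal grid cell: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    grid <- dplyr::filter(grid, .data$region %in% .env$region)
  }
  grid |>
    dplyr::filter(.data$coastal) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      average_richness = mean(.data$richness),
      n_cells = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(source = "derived")
}

#' Cross-source richness correction factor
#'
#' Ratio of a reference region's per-grid-cell average richness to its
#' total richness reported by an independent source. Regions absent from
#' the gridded source can then be put on the per-grid-cell scale by
#' multiplying their total richness by this factor. For realistic inputs
#' the factor is about 0.1 (regional totals run roughly ten times higher
#' than per-cell averages).
#'
#' @param reference_average Per-cell average richness of the reference
#'   region (a number, or a one-row tibble from [average_grid_richness()]).
#' @param reference_total Total richness of the same region from the
#'   independent source; must be positive.
#' @return The scalar correction factor.
#' @export
correction_factor <- function(reference_average, reference_total) {
  if (is.data.frame(reference_average)) {
    reference_average <- reference_average$average_richness[1]
  }
  if (!is.numeric(reference_total) || reference_total <= 0) {
    stop("reference_total must be a positive number", call. = FALSE)
  }
  if (!is.numeric(reference_average) || reference_average <= 0) {
    stop("reference_average must be a positive number", call. = FALSE)
  }
  reference_average / reference_total
}

#' Corrected average richness from a regional total
#'
#' Applies the [correction_factor()] to a region's total richness to
#' estimate its per-grid-cell average, for regions the gridded source
#' does not cover.
#'
#' @param total Total species richness of the region (> 0).
#' @param factor Correction factor (> 0).
#' @param region Region code the estimate belongs to.
#' @return Tibble with columns `region`, `average_richness`,
#'   `source = "corrected"`.
#' @export
corrected_average_richness <- function(total, factor, region) {
  if (!is.numeric(total) || any(total <= 0)) {
    stop("total richness must be positive", call. = FALSE)
  }
  if (!is.numeric(factor) || factor <= 0) {
    stop("correction factor must be positive", call. = FALSE)
  }
  tibble::tibble(
    region = region,
    average_richness = total * factor,
    n_cells = NA_integer_,
    source = "corrected"
  )
}
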