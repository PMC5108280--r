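#' Normalize a scientific species name
#'
#' Lower-cases, collapses internal whitespace, and strips inline
#' parenthesized synonym fragments of the form `"(=Synonym)"`, so that
#' e.g. `"Chelicorophium (=Corophium) curvispinum"` compares equal to
#' `"chelicorophium curvispinum"`. All name comparison in this package
#' (deduplication, shared-species intersection) happens on the
#' normalized form; display keeps the original spelling.
#'
#' @param x Character vector of species names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_species_name("Chelicorophium (=Corophium)  curvispinum")
normalize_species_name <- function(x) {
  x <- stringr::str_remove_all(x, "\\(\\s*=[^)]*\\)")
  x <- stringr::str_squish(x)
  tolower(x)
}

#' Construct a validated NIS checklist
#'
#' A checklist is a tibble of species records for one recipient region:
#' columns `name`, `kingdom`, `phylum`, `class`, a list-column
#' `native_regions` (character vectors of region codes), and one logical
#' presence column per subregion. Validation enforces the record
#' invariants: non-empty unique names, non-empty native-range sets drawn
#' from the region vocabulary, and at least one presence flag per species.
#' Duplicate rows (same normalized name) are collapsed to one record with
#' the union of presence flags and native ranges, with a warning.
#'
#' @param records Data frame with the columns above; `native_regions` may
#'   be a list-column or a character vector of `;`-separated codes.
#' @param recipient_region Label of the recipient region the checklist
#'   describes (free label; typically a [region_codes()] entry).
#' @param subregion_ids Character vector naming the presence columns, in
#'   display order. Defaults to every column not in the core schema.
#' @param regions Closed vocabulary for `native_regions` validation.
#' @return A tibble of class `nis_checklist` with attributes
#'   `recipient_region` and `subregion_ids`.
#' @export
as_nis_checklist <- function(records, recipient_region,
                             subregion_ids = NULL,
                             regions = region_codes()) {
  records <- tibble::as_tibble(records)
  core <- c("name", "kingdom", "phylum", "class", "native_regions")
  check_columns(records, core, "checklist")
  if (is.null(subregion_ids)) {
    subregion_ids <- setdiff(names(records), core)
  }
  if (length(subregion_ids) == 0) {
    stop("checklist needs at least one subregion presence column", call. = FALSE)
  }
  check_columns(records, subregion_ids, "checklist")

  if (!is.list(records$native_regions)) {
    records$native_regions <- stringr::str_split(records$native_regions, ";")
  }
  records$native_regions <- purrr::map(
    records$native_regions,
    ~ unique(stringr::str_squish(.x[nzchar(stringr::str_squish(.x))]))
  )
  records <- dplyr::mutate(
    records,
    dplyr::across(dplyr::all_of(subregion_ids), ~ as.logical(as.integer(.x)))
  )

  if (nrow(records) > 0) {
    if (any(!nzchar(stringr::str_squish(records$name)))) {
      stop("checklist contains an empty species name", call. = FALSE)
    }
    n_ranges <- lengths(records$native_regions)
    if (any(n_ranges == 0)) {
      stop(sprintf(
        "species '%s' has an empty native-range set (use the code 'unknown')",
        records$name[which(n_ranges == 0)[1]]
      ), call. = FALSE)
    }
    assert_region_codes(
      unlist(records$native_regions), regions,
      rows = rep(seq_len(nrow(records)), n_ranges)
    )
    present <- rowSums(as.matrix(records[subregion_ids])) > 0
    if (any(!present)) {
      stop(sprintf(
        "species '%s' has no presence flag set in any subregion",
        records$name[which(!present)[1]]
      ), call. = FALSE)
    }

    norm <- normalize_species_name(records$name)
    if (anyDuplicated(norm)) {
      dups <- unique(norm[duplicated(norm)])
      warning(sprintf(
        "collapsing %d duplicated species name(s): %s",
        length(dups), paste(utils::head(dups, 5), collapse = ", ")
      ), call. = FALSE)
      records <- records |>
        dplyr::mutate(.norm = norm) |>
        dplyr::group_by(.data$.norm) |>
        dplyr::summarise(
          name = dplyr::first(.data$name),
          kingdom = dplyr::first(.data$kingdom),
          phylum = dplyr::first(.data$phylum),
          class = dplyr::first(.data$class),
          native_regions = list(unique(unlist(.data$native_regions))),
          dplyr::across(dplyr::all_of(subregion_ids), any),
          .groups = "drop"
        ) |>
        dplyr::select(-".norm")
    }
  }

  out <- records[, c(core, subregion_ids)]
  attr(out, "recipient_region") <- recipient_region
  attr(out, "subregion_ids") <- subregion_ids
  class(out) <- c("nis_checklist", class(tibble::tibble()))
  out
}

#' Read a NIS checklist from delimited text
#'
#' Expects UTF-8 comma- or tab-separated text with one row per species and
#' columns `name, kingdom, phylum, class, native_regions` (semicolon-
#' separated region codes) plus one 0/1 column per subregion. The
#' delimiter is inferred from the header line unless given.
#'
#' @inheritParams as_nis_checklist
#' @param path Path to the file.
#' @param delim Field delimiter; `NULL` to infer (`,` vs tab).
#' @return A validated [as_nis_checklist()] tibble.
#' @export
read_checklist <- function(path, recipient_region,
                           subregion_ids = NULL,
                           regions = region_codes(),
                           delim = NULL) {
  if (!file.exists(path)) stop(sprintf("checklist file not found: %s", path), call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  core <- c("name", "kingdom", "phylum", "class", "native_regions")
  check_columns(raw, core, sprintf("checklist file '%s'", basename(path)))
  sub_cols <- subregion_ids %||% setdiff(names(raw), core)
  raw <- dplyr::mutate(
    raw,
    dplyr::across(dplyr::all_of(sub_cols), ~ dplyr::coalesce(as.integer(.x), 0L)),
    dplyr::across(dplyr::all_of(setdiff(core, "native_regions")),
                  ~ dplyr::coalesce(.x, ""))
  )
  as_nis_checklist(raw, recipient_region,
                   subregion_ids = sub_cols, regions = regions)
}

subregion_ids <- function(checklist) attr(checklist, "subregion_ids")
recipient_region <- function(checklist) attr(checklist, "recipient_region")

# records after phylum exclusion; the denominator for all composition stats
retained_records <- function(checklist, exclude_phyla = character()) {
  dplyr::filter(tibble::as_tibble(checklist), !(.data$phylum %in% exclude_phyla))
}

#' Fractional native-range attribution per donor region
#'
#' Each species contributes `1 / k` to each of its `k` native regions, so
#' the tallies over all regions sum exactly to the number of retained
#' species. Species of unknown origin are tallied under `"unknown"`,
#' never dropped.
#'
#' @param checklist An [as_nis_checklist()] tibble.
#' @param exclude_phyla Character vector of phylum labels to drop before
#'   tallying (e.g. `"Tracheophyta"` for the vascular-plant-free view).
#' @return Tibble with columns `region`, `tally` (non-negative, summing to
#'   the retained species count), sorted by descending tally.
#' @export
tally_origins <- function(checklist, exclude_phyla = character()) {
  recs <- retained_records(checklist, exclude_phyla)
  if (nrow(recs) == 0) {
    return(tibble::tibble(region = character(), tally = numeric()))
  }
  recs |>
    dplyr::mutate(.w = 1 / lengths(.data$native_regions)) |>
    tidyr::unnest_longer("native_regions", values_to = "region") |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(tally = sum(.data$.w), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$tally), .data$region)
}

#' Donor-region percentages of a checklist
#'
#' Percent contribution of each donor region:
#' `100 * fractional tally / retained species count`. Full precision is
#' returned; round only for display (the conventional reports print
#' integer percents).
#'
#' @inheritParams tally_origins
#' @return Tibble with columns `region`, `tally`, `n_species`, `percent`.
#' @export
origin_percentages <- function(checklist, exclude_phyla = character()) {
  n <- nrow(retained_records(checklist, exclude_phyla))
  if (n == 0) {
    stop("no species retained after exclusion; percentages undefined", call. = FALSE)
  }
  tally_origins(checklist, exclude_phyla) |>
    dplyr::mutate(n_species = n, percent = 100 * .data$tally / n)
}

#' Taxonomic composition at a rank
#'
#' Integer species counts and percentages per taxonomic label at the
#' chosen rank, ordered by descending count with alphabetical tie-break.
#'
#' @inheritParams tally_origins
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`.
#' @return Tibble with columns `label`, `count`, `percent`.
#' @export
taxonomic_composition <- function(checklist,
                                  rank = c("phylum", "kingdom", "class"),
                                  exclude_phyla = character()) {
  rank <- match.arg(rank)
  recs <- retained_records(checklist, exclude_phyla)
  if (nrow(recs) == 0) {
    return(tibble::tibble(label = character(), count = integer(),
                          percent = numeric()))
  }
  recs |>
    dplyr::count(label = .data[[rank]], name = "count") |>
    dplyr::mutate(percent = 100 * .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$label)
}

#' Two-subregion establishment partition
#'
#' Splits the species present in subregion `a` or `b` into those
#' established only in `a`, only in `b`, and in both. Species absent from
#' both subregions are excluded from the total, so
#' `only_a + only_b + both == total` always holds.
#'
#' @inheritParams tally_origins
#' @param a,b Distinct subregion ids of the checklist.
#' @return One-row tibble with columns `only_a`, `only_b`, `both`, `total`.
#' @export
subregion_partition <- function(checklist, a, b) {
  ids <- subregion_ids(checklist)
  if (!all(c(a, b) %in% ids)) {
    stop(sprintf(
      "unknown subregion id(s): %s; checklist has: %s",
      paste(setdiff(c(a, b), ids), collapse = ", "),
      paste(ids, collapse = ", ")
    ), call. = FALSE)
  }
  if (a == b) stop("subregions 'a' and 'b' must differ", call. = FALSE)
  in_a <- checklist[[a]]
  in_b <- checklist[[b]]
  tibble::tibble(
    only_a = sum(in_a & !in_b),
    only_b = sum(!in_a & in_b),
    both   = sum(in_a & in_b),
    total  = sum(in_a | in_b)
  )
}

#' Species present in any of a set of subregions
#'
#' @inheritParams tally_origins
#' @param subregions Character vector of subregion ids.
#' @return Character vector of normalized species names present in at
#'   least one of the given subregions.
#' @export
species_present <- function(checklist, subregions) {
  ids <- subregion_ids(checklist)
  if (!all(subregions %in% ids)) {
    stop(sprintf("unknown subregion id(s): %s",
                 paste(setdiff(subregions, ids), collapse = ", ")), call. = FALSE)
  }
  present <- rowSums(as.matrix(checklist[, subregions, drop = FALSE])) > 0
  sort(normalize_species_name(checklist$name[present]))
}

#' Species shared between two checklists
#'
#' Exact name intersection after [normalize_species_name()], so inline
#' synonym spellings do not split a species across lists.
#'
#' @param x,y Checklists.
#' @return Sorted character vector of shared normalized names.
#' @export
shared_species <- function(x, y) {
  sort(intersect(normalize_species_name(x$name), normalize_species_name(y$name)))
}

#' Donor-by-recipient species flow table
#'
#' Tabulates species flows from donor regions into each checklist's
#' recipient region. `mode = "fractional"` applies the `1/k` attribution
#' rule, so flows into each recipient sum to its retained species count
#' (conservation). `mode = "flows"` counts one unit flow per
#' (species, native region) pair — the convention of chord-diagram style
#' displays, which double-counts multi-origin species.
#'
#' @param checklists A list of checklists (or a single checklist).
#' @param exclude_phyla Phylum labels to drop.
#' @param mode `"fractional"` or `"flows"`.
#' @return Tibble with columns `donor`, `recipient`, `flow`.
#' @export
flow_matrix <- function(checklists, exclude_phyla = character(),
                        mode = c("fractional", "flows")) {
  mode <- match.arg(mode)
  if (inherits(checklists, "nis_checklist")) checklists <- list(checklists)
  purrr::map_dfr(checklists, function(cl) {
    recs <- retained_records(cl, exclude_phyla)
    if (nrow(recs) == 0) {
      return(tibble::tibble(donor = character(), recipient = character(),
                            flow = numeric()))
    }
    recs |>
      dplyr::mutate(
        .w = if (mode == "fractional") 1 / lengths(.data$native_regions) else 1
      ) |>
      tidyr::unnest_longer("native_regions", values_to = "donor") |>
      dplyr::group_by(donor = .data$donor) |>
      dplyr::summarise(flow = sum(.data$.w), .groups = "drop") |>
      dplyr::mutate(recipient = recipient_region(cl), .after = "donor")
  })
}

#' Observed NIS counts per donor region
#'
#' Integer species counts per donor: the number of species whose
#' native-range set includes the donor region. This is the observed-count
#' convention of the model-vs-data comparison (a species native to two
#' regions counts fully toward both), distinct from the fractional
#' attribution of [tally_origins()].
#'
#' @inheritParams tally_origins
#' @param donors Donor region codes to count; `NULL` for all present.
#' @return Tibble with columns `donor`, `recipient`, `observed`.
#' @export
observed_counts <- function(checklist, donors = NULL,
                            exclude_phyla = character()) {
  recs <- retained_records(checklist, exclude_phyla)
  counts <- recs |>
    tidyr::unnest_longer("native_regions", values_to = "donor") |>
    dplyr::distinct(.data$name, .data$donor) |>
    dplyr::count(.data$donor, name = "observed")
  if (!is.null(donors)) {
    counts <- tibble::tibble(donor = donors) |>
      dplyr::left_join(counts, by = "donor") |>
      dplyr::mutate(observed = dplyr::coalesce(.data$observed, 0L))
  }
  dplyr::mutate(counts, recipient = recipient_region(checklist),
                .after = "donor")
}
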