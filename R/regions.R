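#' Canonical donor/recipient region vocabulary
#'
#' The closed set of biogeographic donor and recipient groups used for
#' native-range attribution of aquatic nonindigenous species: the four
#' quadrants of the Atlantic and Pacific, the marginal seas and inland
#' systems that act as major donors or recipients, and the literal code
#' `"unknown"` for species whose origin could not be established (treated
#' as a donor category in its own right, never dropped).
#'
#' Inland-water codes are scoped as in the source checklists: `eurasia`
#' excludes the Yangtze; `north_america` excludes the Laurentian Great
#' Lakes, St. Lawrence and Mississippi; `australia`, `new_zealand` and
#' `africa` refer to inland freshwaters.
#'
#' @return Character vector of valid region codes.
#' @export
#' @examples
#' region_codes()
region_codes <- function() {
  c(
    "northeast_atlantic", "northwest_atlantic",
    "southeast_atlantic", "southwest_atlantic",
    "northeast_pacific", "northwest_pacific",
    "southeast_pacific", "southwest_pacific",
    "north_sea", "baltic_sea",
    "great_lakes_st_lawrence",
    "mediterranean",
    "eurasia",
    "mississippi",
    "yangtze",
    "arctic",
    "australia",
    "new_zealand",
    "indo_pacific",
    "africa",
    "north_america",
    "south_america",
    "ponto_caspian",
    "unknown"
  )
}

# validate a character vector of region codes against a vocabulary,
# reporting the offending rows for load-time diagnostics
assert_region_codes <- function(codes, regions = region_codes(),
                                rows = NULL, what = "native_regions") {
  bad <- !(codes %in% regions)
  if (any(bad)) {
    where <- if (!is.null(rows)) sprintf(" (row %s)", rows[bad][1]) else ""
    stop(sprintf(
      "unrecognized region code in %s: '%s'%s; valid codes: %s",
      what, codes[bad][1], where, paste(regions, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(codes)
}
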