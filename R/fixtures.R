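#' Packaged checklist of Ponto-Caspian NIS in both recipient systems
#'
#' The transcribed reference list of Ponto-Caspian species established in
#' the North Sea, Baltic Sea, Great Lakes and/or St. Lawrence River (54
#' species with kingdom/phylum/class assignments and per-subregion
#' presence flags). All species are native to the Ponto-Caspian region.
#' The checklist spans both recipient systems, so its recipient label is
#' the combined `"north_baltic_great_lakes"`.
#'
#' @return An [as_nis_checklist()] tibble with subregions `north_sea`,
#'   `baltic_sea`, `great_lakes`, `st_lawrence_river`.
#' @export
#' @examples
#' cl <- nis_table1()
#' subregion_partition(cl, "great_lakes", "st_lawrence_river")
nis_table1 <- function() {
  read_checklist(
    system.file("extdata", "table1_ponto_caspian.csv", package = "invexpect",
                mustWork = TRUE),
    recipient_region = "north_baltic_great_lakes"
  )
}

#' Packaged donor-recipient comparison inputs
#'
#' The reference table of model-versus-data comparison inputs: for each
#' of ten (donor, recipient) region pairs, the donor's estimated average
#' species richness (per 880-km equal-area grid cell), the region-pair
#' invasion probability, and the observed NIS count from the curated
#' checklists. Feeding this to [comparison_table()] reproduces the
#' published expected counts and chi-square statistics.
#'
#' @return Tibble with columns `donor`, `recipient`, `richness`,
#'   `p_inv`, `observed`.
#' @export
#' @examples
#' t2 <- nis_table2()
#' comparison_table(
#'   richness = dplyr::distinct(
#'     dplyr::tibble(region = t2$donor, average_richness = t2$richness)
#'   ),
#'   probs = dplyr::tibble(donor = t2$donor, recipient = t2$recipient,
#'                         p_invasion = t2$p_inv),
#'   observed = t2[c("donor", "recipient", "observed")]
#' )
nis_table2 <- function() {
  readr::read_csv(
    system.file("extdata", "table2.csv", package = "invexpect",
                mustWork = TRUE),
    col_types = readr::cols(
      donor = readr::col_character(),
      recipient = readr::col_character(),
      richness = readr::col_double(),
      p_inv = readr::col_double(),
      observed = readr::col_integer()
    )
  )
}

#' Reference comparison table
#'
#' Convenience wrapper running [comparison_table()] on the packaged
#' [nis_table2()] inputs.
#'
#' @return A `nis_comparison` tibble with ten rows.
#' @export
reference_comparison <- function() {
  t2 <- nis_table2()
  comparison_table(
    richness = dplyr::distinct(
      tibble::tibble(region = t2$donor, average_richness = t2$richness)
    ),
    probs = tibble::tibble(donor = t2$donor, recipient = t2$recipient,
                           p_invasion = t2$p_inv),
    observed = t2[c("donor", "recipient", "observed")]
  )
}
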