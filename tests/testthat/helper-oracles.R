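# Test helpers: random fixture builders and independent oracles.

# A random synthetic checklist with multi-region native ranges.
random_checklist <- function(n_species, regions = region_codes(),
                             subregions = c("sub_a", "sub_b"),
                             max_origins = 4) {
  k <- sample.int(max_origins, n_species, replace = TRUE)
  recs <- tibble::tibble(
    name = sprintf("Testspecies %04d", seq_len(n_species)),
    kingdom = "Animalia",
    phylum = sample(c("Arthropoda", "Mollusca", "Chordata", "Tracheophyta"),
                    n_species, replace = TRUE),
    class = "",
    native_regions = lapply(k, function(ki) sample(regions, ki))
  )
  pres <- matrix(stats::runif(n_species * length(subregions)) < 0.6,
                 nrow = n_species)
  none <- rowSums(pres) == 0
  pres[cbind(which(none), sample.int(ncol(pres), sum(none), replace = TRUE))] <- TRUE
  for (j in seq_along(subregions)) recs[[subregions[j]]] <- pres[, j]
  as_nis_checklist(recs, recipient_region = "unknown",
                   subregion_ids = subregions, regions = regions)
}

# A checklist realizing a prescribed two-subregion partition.
partition_checklist <- function(only_a, only_b, both,
                                subregions = c("sub_a", "sub_b")) {
  n <- only_a + only_b + both
  recs <- tibble::tibble(
    name = sprintf("Partitionspecies %04d", seq_len(n)),
    kingdom = "Animalia", phylum = "Arthropoda", class = "",
    native_regions = "unknown"
  )
  recs[[subregions[1]]] <- rep(c(TRUE, FALSE, TRUE), c(only_a, only_b, both))
  recs[[subregions[2]]] <- rep(c(FALSE, TRUE, TRUE), c(only_a, only_b, both))
  as_nis_checklist(recs, recipient_region = "unknown",
                   subregion_ids = subregions)
}

# Inclusion-exclusion oracle for P(at least one of n independent events):
# exhaustive sum over non-empty subsets, independent of the 1 - prod(1 - p)
# code path it checks.
union_probability_ie <- function(p) {
  n <- length(p)
  total <- 0
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    total <- total + (-1)^(length(members) + 1) * prod(p[members])
  }
  total
}

# Spherical law of cosines: independent second formula for great-circle
# distances on the 6371-km sphere.
slc_distance <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  cosang <- sin(lat1 * to_rad) * sin(lat2 * to_rad) +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * cos((lon2 - lon1) * to_rad)
  6371 * acos(pmin(pmax(cosang, -1), 1))
}
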