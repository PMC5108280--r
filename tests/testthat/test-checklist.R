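test_that("packaged Ponto-Caspian checklist loads with one record per row", {
  cl <- nis_table1()
  expect_s3_class(cl, "nis_checklist")
  expect_identical(nrow(cl), 54L)
  expect_setequal(attr(cl, "subregion_ids"),
                  c("north_sea", "baltic_sea", "great_lakes",
                    "st_lawrence_river"))
  expect_true(all(vapply(cl$native_regions, identical, logical(1),
                         "ponto_caspian")))
})

test_that("checklist loading validates schema, regions, and empty files", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,kingdom,phylum,class,native_regions,sub_a", tmp)
  empty <- read_checklist(tmp, recipient_region = "unknown")
  expect_identical(nrow(empty), 0L)

  writeLines(c("name,kingdom,phylum,native_regions,sub_a",
               "Dreissena polymorpha,Animalia,Mollusca,ponto_caspian,1"), tmp)
  expect_error(read_checklist(tmp, "unknown"), "class")

  writeLines(c("name,kingdom,phylum,class,native_regions,sub_a",
               "Dreissena polymorpha,Animalia,Mollusca,Bivalvia,atlantis,1"),
             tmp)
  expect_error(read_checklist(tmp, "unknown"), "atlantis")
})

test_that("duplicated names collapse to one record with unioned presence", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "name,kingdom,phylum,class,native_regions,sub_a,sub_b",
    "Dreissena polymorpha,Animalia,Mollusca,Bivalvia,ponto_caspian,1,0",
    "Dreissena polymorpha,Animalia,Mollusca,Bivalvia,ponto_caspian;unknown,0,1"
  ), tmp)
  expect_warning(cl <- read_checklist(tmp, "unknown"), "duplicated")
  expect_identical(nrow(cl), 1L)
  expect_true(cl$sub_a && cl$sub_b)
  expect_setequal(cl$native_regions[[1]], c("ponto_caspian", "unknown"))
})

test_that("fractional origin attribution follows the 1/k rule", {
  recs <- tibble::tibble(
    name = c("Sp a", "Sp b", "Sp c"),
    kingdom = "Animalia", phylum = "Arthropoda", class = "",
    native_regions = list("x", c("x", "y"), c("x", "y", "z", "w")),
    sub_a = TRUE
  )
  cl <- as_nis_checklist(recs, "unknown", regions = c("x", "y", "z", "w"))
  tal <- tally_origins(cl)
  expect_equal(tal$tally[match(c("x", "y", "z", "w"), tal$region)],
               c(1.75, 0.75, 0.25, 0.25))
  expect_equal(sum(tal$tally), 3)

  # two native regions -> 0.5 each; one -> 1.0
  one <- as_nis_checklist(recs[2, ], "unknown", regions = c("x", "y"))
  expect_equal(tally_origins(one)$tally, c(0.5, 0.5))
})

test_that("origin percentages use the retained-species denominator", {
  # single species, single region -> 100%
  recs <- tibble::tibble(name = "Solo species", kingdom = "Animalia",
                         phylum = "Mollusca", class = "",
                         native_regions = "arctic", sub_a = TRUE)
  cl <- as_nis_checklist(recs, "unknown")
  expect_equal(origin_percentages(cl)$percent, 100)

  # 42 single-origin species of one donor among 281 total -> 14.95%
  n <- 281
  recs <- tibble::tibble(
    name = sprintf("Bulk species %03d", seq_len(n)),
    kingdom = "Animalia", phylum = "Arthropoda", class = "",
    native_regions = rep(c("ponto_caspian", "eurasia"), c(42, n - 42)),
    sub_a = TRUE
  )
  cl <- as_nis_checklist(recs, "unknown")
  pc <- origin_percentages(cl)
  expect_equal(pc$percent[pc$region == "ponto_caspian"], 100 * 42 / 281)
  expect_equal(round_half_up(pc$percent[pc$region == "ponto_caspian"]), 15)
  expect_equal(sum(pc$percent), 100, tolerance = 1e-9)

  expect_error(origin_percentages(cl, exclude_phyla = "Arthropoda"),
               "no species retained")
})

test_that("taxonomic composition counts, sorts, and excludes phyla", {
  recs <- tibble::tibble(
    name = sprintf("Mix species %d", 1:4),
    kingdom = "Animalia",
    phylum = c("Arthropoda", "Arthropoda", "Arthropoda", "Mollusca"),
    class = "", native_regions = "unknown", sub_a = TRUE
  )
  cl <- as_nis_checklist(recs, "unknown")
  comp <- taxonomic_composition(cl, rank = "phylum")
  expect_equal(comp$label, c("Arthropoda", "Mollusca"))
  expect_equal(comp$count, c(3L, 1L))
  expect_equal(comp$percent, c(75, 25))
  expect_error(taxonomic_composition(cl, rank = "order"))
  expect_identical(
    nrow(taxonomic_composition(cl, exclude_phyla = c("Arthropoda", "Mollusca"))),
    0L
  )
})

test_that("subregion partition sums to the union and rejects bad ids", {
  cl <- partition_checklist(156, 53, 72)
  part <- subregion_partition(cl, "sub_a", "sub_b")
  expect_equal(unlist(part), c(only_a = 156, only_b = 53, both = 72,
                               total = 281))
  expect_error(subregion_partition(cl, "sub_a", "nowhere"), "nowhere")
  expect_error(subregion_partition(cl, "sub_a", "sub_a"), "differ")

  all_both <- partition_checklist(0, 0, 7)
  expect_equal(unlist(subregion_partition(all_both, "sub_a", "sub_b")),
               c(only_a = 0, only_b = 0, both = 7, total = 7))
})

test_that("shared species intersect on normalized names", {
  mk <- function(names) {
    as_nis_checklist(
      tibble::tibble(name = names, kingdom = "Animalia",
                     phylum = "Mollusca", class = "",
                     native_regions = "ponto_caspian", sub_a = TRUE),
      "unknown"
    )
  }
  x <- mk(c("Dreissena polymorpha", "Hemimysis anomala", "Jaera istri"))
  y <- mk(c("Dreissena  POLYMORPHA", "Cyprinus carpio", "Huso huso"))
  expect_identical(shared_species(x, y), "dreissena polymorpha")
  expect_identical(shared_species(x, y), shared_species(y, x))
  expect_identical(shared_species(x, x),
                   sort(normalize_species_name(x$name)))
  z <- mk(c("Chelicorophium (=Corophium) curvispinum"))
  w <- mk(c("Chelicorophium curvispinum"))
  expect_identical(shared_species(z, w), "chelicorophium curvispinum")
  expect_length(shared_species(mk("Sp one"), mk("Sp two")), 0)
})

test_that("flow matrix conserves fractional counts and doubles unit flows", {
  set.seed(101)
  cl <- random_checklist(40)
  fl <- flow_matrix(cl)
  expect_equal(sum(fl$flow), 40)
  expect_identical(unique(fl$recipient), "unknown")

  two_origin <- as_nis_checklist(
    tibble::tibble(name = "Duo species", kingdom = "Animalia",
                   phylum = "Chordata", class = "",
                   native_regions = list(c("arctic", "eurasia")),
                   sub_a = TRUE),
    "unknown"
  )
  unit <- flow_matrix(two_origin, mode = "flows")
  expect_equal(unit$flow, c(1, 1))
  frac <- flow_matrix(two_origin, mode = "fractional")
  expect_equal(frac$flow, c(0.5, 0.5))
})

test_that("observed counts are integer per-donor species counts", {
  recs <- tibble::tibble(
    name = c("Sp a", "Sp b", "Sp c"),
    kingdom = "Animalia", phylum = "Arthropoda", class = "",
    native_regions = list("arctic", c("arctic", "eurasia"), "eurasia"),
    sub_a = TRUE
  )
  cl <- as_nis_checklist(recs, "baltic_sea")
  obs <- observed_counts(cl, donors = c("arctic", "eurasia", "yangtze"))
  expect_equal(obs$observed, c(2L, 2L, 0L))
  expect_identical(unique(obs$recipient), "baltic_sea")
})
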