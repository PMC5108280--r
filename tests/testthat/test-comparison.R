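test_that("expected counts and display rounding match the reporting rule", {
  expect_equal(expected_nis(570, 0.16172), 92.1804)
  expect_equal(display_expected(92.1804), 92)
  expect_equal(expected_nis(123, 0), 0)
  expect_equal(expected_nis(500, 0.00014), 0.07)
  expect_equal(display_expected(c(14.928, 16.5105, 2.57, 0.0342, 0.036,
                                  0.0045)),
               c(15, 17, 3, 0.03, 0.04, 0.005))
})

test_that("pair chi-square is the one-cell statistic with df 1", {
  r <- pair_chi_square(44, 92)
  expect_equal(round(r$chi_square, 2), 25.04)
  expect_lt(r$p_value, 0.001)

  same <- pair_chi_square(17, 17)
  expect_equal(same$chi_square, 0)
  expect_equal(same$p_value, 1)

  r2 <- pair_chi_square(4, 12)
  expect_equal(round(r2$chi_square, 2), 5.33)
  expect_identical(format_p_value(r2$p_value), ".021")

  expect_error(pair_chi_square(5, 0), "positive")
  expect_warning(pair_chi_square(1, 0.001), "unreliable")
})

test_that("chi-square grows with |O - E| and p decreases with chi-square", {
  e <- 20
  chis <- pair_chi_square(c(21, 25, 30, 40), e)$chi_square
  expect_true(all(diff(chis) > 0))
  expect_true(all(diff(pair_chi_square(c(21, 25, 30, 40), e)$p_value) < 0))
})

test_that("overall chi-square sums pair contributions per recipient", {
  rows <- tibble::tibble(
    recipient = "north_baltic",
    observed = c(44, 2, 17, 49, 42),
    expected = c(92, 15, 17, 42, 3)
  )
  ov <- overall_chi_square(rows)
  expect_equal(round(ov$chi_square, 2), 544.48)
  expect_equal(ov$df, 4L)
  expect_equal(ov$chi_square,
               sum(pair_chi_square(rows$observed, rows$expected)$chi_square))

  null <- overall_chi_square(tibble::tibble(
    recipient = "r", observed = c(5, 9), expected = c(5, 9)
  ))
  expect_equal(null$chi_square, 0)
  expect_equal(null$p_value, 1)

  expect_error(
    overall_chi_square(tibble::tibble(recipient = "r", observed = 3,
                                      expected = 4)),
    "at least two"
  )
})

test_that("the reference comparison reproduces every printed value", {
  cmp <- reference_comparison()
  expect_s3_class(cmp, "nis_comparison")
  key <- paste(cmp$donor, cmp$recipient, sep = "->")
  expected_disp <- c(
    "northwest_atlantic->north_baltic" = 92,
    "great_lakes_st_lawrence->north_baltic" = 15,
    "northeast_pacific->north_baltic" = 17,
    "northwest_pacific->north_baltic" = 42,
    "ponto_caspian->north_baltic" = 3,
    "north_baltic->great_lakes_st_lawrence" = 12,
    "ponto_caspian->great_lakes_st_lawrence" = 0.07,
    "northwest_atlantic->great_lakes_st_lawrence" = 0.03,
    "northwest_pacific->great_lakes_st_lawrence" = 0.04,
    "northeast_pacific->great_lakes_st_lawrence" = 0.005
  )
  chi_disp <- c(
    "northwest_atlantic->north_baltic" = 25.04,
    "great_lakes_st_lawrence->north_baltic" = 11.27,
    "northeast_pacific->north_baltic" = 0,
    "northwest_pacific->north_baltic" = 1.17,
    "ponto_caspian->north_baltic" = 507,
    "north_baltic->great_lakes_st_lawrence" = 5.33,
    "ponto_caspian->great_lakes_st_lawrence" = 7511,
    "northwest_atlantic->great_lakes_st_lawrence" = 3313,
    "northwest_pacific->great_lakes_st_lawrence" = 96.04,
    "northeast_pacific->great_lakes_st_lawrence" = 3192
  )
  expect_equal(cmp$expected_display, unname(expected_disp[key]))
  expect_equal(cmp$chi_square_display, unname(chi_disp[key]))
  p <- setNames(cmp$p_display, key)
  expect_identical(unname(p["northeast_pacific->north_baltic"]), "1")
  expect_identical(unname(p["northwest_pacific->north_baltic"]), ".279")
  expect_identical(unname(p["north_baltic->great_lakes_st_lawrence"]), ".021")
  expect_true(all(p[setdiff(key, c(
    "northeast_pacific->north_baltic", "northwest_pacific->north_baltic",
    "north_baltic->great_lakes_st_lawrence"
  ))] == "<.001"))
})

test_that("comparison table is deterministic under input permutation", {
  t2 <- nis_table2()
  richness <- dplyr::distinct(
    tibble::tibble(region = t2$donor, average_richness = t2$richness)
  )
  probs <- tibble::tibble(donor = t2$donor, recipient = t2$recipient,
                          p_invasion = t2$p_inv)
  obs <- t2[c("donor", "recipient", "observed")]
  a <- comparison_table(richness, probs, obs)
  perm <- sample.int(nrow(probs))
  b <- comparison_table(richness[sample.int(nrow(richness)), ],
                        probs[perm, ], obs[rev(perm), ])
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("comparison table rejects incomplete inputs and empty maps", {
  empty <- comparison_table(
    tibble::tibble(region = character(), average_richness = numeric()),
    tibble::tibble(donor = character(), recipient = character(),
                   p_invasion = numeric()),
    tibble::tibble(donor = character(), recipient = character(),
                   observed = integer())
  )
  expect_identical(nrow(empty), 0L)
  expect_s3_class(empty, "nis_comparison")

  expect_error(
    comparison_table(
      tibble::tibble(region = "a", average_richness = 100),
      tibble::tibble(donor = c("a", "b"), recipient = "r",
                     p_invasion = c(0.1, 0.2)),
      tibble::tibble(donor = c("a", "b"), recipient = "r",
                     observed = c(1L, 2L))
    ),
    "b->r"
  )
})

test_that("tidy, glance, scatter and autoplot expose the comparison", {
  cmp <- reference_comparison()
  td <- tidy(cmp)
  expect_named(td, c("donor", "recipient", "estimate", "observed",
                     "statistic", "p.value", "parameter"))
  expect_identical(nrow(td), 10L)
  gl <- glance(cmp)
  expect_identical(nrow(gl), 2L)
  expect_true(all(gl$p.value < 0.05))
  sc <- scatter_data(cmp)
  expect_named(sc, c("donor", "recipient", "expected", "observed"))
  expect_s3_class(autoplot(cmp), "ggplot")
})
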