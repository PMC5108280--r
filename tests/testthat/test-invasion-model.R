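params0 <- model_params(alpha = 1, beta = 1, gamma = 1, lambda = 0.001,
                        mu = 0.01, sigma_t = 2, sigma_s = 10)

test_that("great-circle distance matches an independent formula", {
  expect_equal(great_circle_distance(0, 0, 0, 0), 0)
  expect_equal(great_circle_distance(0, 0, 180, 0), 6371 * pi,
               tolerance = 1e-9)
  # Rotterdam-ish vs Black-Sea-ish coordinates against the spherical law
  # of cosines
  d <- great_circle_distance(4, 52, 28, 43)
  expect_equal(d, slc_distance(4, 52, 28, 43), tolerance = 0.1 / d)
  expect_error(great_circle_distance(0, 95, 0, 0), "coordinates")
})

test_that("nonindigenous probability is the distance sigmoid", {
  expect_equal(p_nonindigenous(1, params0), 0.5)
  expect_gt(p_nonindigenous(1e12, params0), 1 - 1e-9)
  p2 <- model_params(alpha = 1, beta = 2, gamma = 10, lambda = 1, mu = 0,
                     sigma_t = 1, sigma_s = 1)
  expect_equal(p_nonindigenous(5, p2), 1 / (1 + 10 / 25))
  expect_equal(p_nonindigenous(0, params0), 0)
  expect_error(p_nonindigenous(-1, params0), "non-negative")
})

test_that("introduction probability saturates in volume, decays in time", {
  expect_equal(p_intro(0, 5, params0), 0)
  mu0 <- model_params(alpha = 1, beta = 1, gamma = 1, lambda = 1, mu = 0,
                      sigma_t = 1, sigma_s = 1)
  expect_gte(p_intro(50, 100, mu0), 1 - 1e-9)
  expect_equal(p_intro(1000, 10, params0),
               (1 - exp(-1)) * exp(-0.1), tolerance = 1e-12)
  expect_equal(round(p_intro(1000, 10, params0), 6), 0.571966)
  expect_error(p_intro(-1, 0, params0))
  expect_error(p_intro(1, -1, params0))
})

test_that("establishment probability is a symmetric Gaussian match", {
  p <- model_params(alpha = 1, beta = 1, gamma = 1, lambda = 1, mu = 0,
                    sigma_t = 2, sigma_s = 10)
  expect_equal(p_establish(15, 20, 15, 20, p), 1)       # alpha at zero delta
  expect_equal(p_establish(17, 20, 15, 20, p), exp(-0.5))
  expect_equal(p_establish(17, 25, 15, 20, p),
               p_establish(15, 20, 17, 25, p))
  a <- model_params(alpha = 0.3, beta = 1, gamma = 1, lambda = 1, mu = 0,
                    sigma_t = 2, sigma_s = 10)
  expect_equal(p_establish(15, 20, 15, 20, a), 0.3)
  expect_error(p_establish(NA, 20, 15, 20, p), "finite")
})

mini_ports <- tibble::tibble(
  port_id = c("i", "j", "k"),
  name = c("i", "j", "k"),
  region = c("A", "B", "B"),
  lon = c(0, 30, 32), lat = c(0, 10, 12),
  temperature = c(15, 17, 16), salinity = c(30, 25, 26)
)

test_that("route invasion probability is the three-factor product", {
  parcels <- tibble::tibble(origin_port = "i", discharge_port = "j",
                            volume = 1000, travel_time = 10)
  routes <- route_invasion_probability(parcels, mini_ports, params0)
  expect_equal(routes$p_invasion,
               routes$p_nonindigenous * routes$p_intro * routes$p_establish)
  zero <- route_invasion_probability(
    dplyr::mutate(parcels, volume = 0), mini_ports, params0)
  expect_equal(zero$p_invasion, 0)
  expect_error(
    route_invasion_probability(
      dplyr::mutate(parcels, origin_port = "ghost"), mini_ports, params0),
    "ghost"
  )
})

test_that("port-pair aggregation is the complement product over routes", {
  parcels <- tibble::tibble(
    origin_port = "i", discharge_port = "j",
    volume = c(1000, 1000), travel_time = c(10, 10)
  )
  one <- port_pair_invasion_probability(parcels[1, ], mini_ports, params0)
  two <- port_pair_invasion_probability(parcels, mini_ports, params0)
  r1 <- route_invasion_probability(parcels[1, ], mini_ports, params0)$p_invasion
  expect_equal(one$p_invasion, r1)
  expect_equal(two$p_invasion, 1 - (1 - r1)^2)
  expect_gte(two$p_invasion, one$p_invasion)

  set.seed(11)
  many <- tibble::tibble(
    origin_port = "i", discharge_port = "j",
    volume = stats::runif(10, 100, 5000),
    travel_time = stats::runif(10, 1, 40)
  )
  agg <- port_pair_invasion_probability(many, mini_ports, params0)
  p_r <- route_invasion_probability(many, mini_ports, params0)$p_invasion
  expect_equal(agg$p_invasion, 1 - prod(1 - p_r), tolerance = 1e-12)
  expect_equal(agg$n_routes, 10L)
})

test_that("region aggregation mirrors the complement product over pairs", {
  pair_probs <- tibble::tibble(
    origin_port = c("i", "i"), discharge_port = c("j", "k"),
    p_invasion = c(0.1, 0.2)
  )
  reg <- region_invasion_probability(pair_probs, mini_ports, "A", "B")
  expect_equal(reg$p_invasion, 1 - 0.9 * 0.8)

  # a single pair carries through unchanged
  single <- region_invasion_probability(pair_probs[1, ], mini_ports)
  expect_equal(single$p_invasion, 0.1)
  solo <- tibble::tibble(origin_port = "i", discharge_port = "j",
                         p_invasion = 0.04849)
  expect_equal(region_invasion_probability(solo, mini_ports)$p_invasion,
               0.04849)

  expect_warning(
    none <- region_invasion_probability(pair_probs, mini_ports, "B", "A"),
    "no shipping connection"
  )
  expect_equal(none$p_invasion, 0)
})

test_that("ballast provenance tracks a well-mixed tank", {
  ships <- tibble::tibble(ship_id = "s1", tank_volume = 1000,
                          mean_discharge = 500)
  two <- tibble::tibble(ship_id = "s1", port_id = c("i", "j"),
                        arrival = c(0, 5), departure = c(1, 6))
  p <- ballast_provenance(two, ships, discharge_fraction = 0.5)
  expect_identical(nrow(p), 1L)
  expect_equal(p$volume, 500)
  expect_equal(p$travel_time, 4)  # departure at i (day 1) to arrival at j

  three <- tibble::tibble(ship_id = "s1", port_id = c("i", "j", "k"),
                          arrival = c(0, 5, 12), departure = c(1, 6, 13))
  p3 <- ballast_provenance(three, ships, discharge_fraction = 0.5)
  at_k <- p3[p3$discharge_port == "k", ]
  expect_equal(sort(at_k$origin_port), c("i", "j"))
  expect_equal(at_k$volume, c(250, 250))
  expect_equal(at_k$travel_time[at_k$origin_port == "i"], 11)
  expect_equal(at_k$travel_time[at_k$origin_port == "j"], 6)

  # conservation at every call
  per_call <- dplyr::summarise(dplyr::group_by(p3, route_id),
                               v = sum(volume))
  expect_true(all(abs(per_call$v - 500) < 1e-9))

  expect_error(ballast_provenance(two, ships, discharge_fraction = 1.5),
               "0, 1")
  bad <- dplyr::mutate(two, departure = c(1, 4))
  expect_error(ballast_provenance(bad, ships, 0.5), "departure")
})

test_that("provenance handles port revisits as separate uptakes", {
  ships <- tibble::tibble(ship_id = "s1", tank_volume = 100,
                          mean_discharge = 50)
  calls <- tibble::tibble(ship_id = "s1", port_id = c("i", "j", "i", "j"),
                          arrival = c(0, 10, 20, 30),
                          departure = c(1, 11, 21, 31))
  p <- ballast_provenance(calls, ships, discharge_fraction = 0.5)
  last <- p[p$route_id == "s1_4", ]
  expect_equal(sum(last$volume), 50)
  # two distinct uptakes at port i with different travel times
  i_parcels <- last[last$origin_port == "i", ]
  expect_identical(nrow(i_parcels), 2L)
  expect_setequal(i_parcels$travel_time, c(29, 9))
  # full-voyage conservation: f * V per call after the first
  expect_equal(sum(p$volume), 0.5 * 100 * 3)
})
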