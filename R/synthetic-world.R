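#' Configuration for a synthetic shipping world
#'
#' Defines a seed-reproducible miniature of the data structure behind the
#' expected-NIS analysis: regionally clustered ports with per-region
#' environmental means, ships performing biased random walks over them,
#' equal-area richness grids, per-region species pools, and the "true"
#' model constants used both to generate and to analyse the world.
#'
#' Defaults describe a 4-region world whose region-pair invasion
#' probabilities span roughly 0.01-0.5, so that every expected count
#' lands in the range where the chi-square approximation is sound
#' (E of order 1 or more). Temperatures and salinities are annual means
#' (degrees C / ppt) with regional structure mimicking gridded
#' climatologies; richness cells are gamma-distributed around per-region
#' means as in stacked range-map richness products.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical worlds.
#' @param n_regions,ports_per_region,n_ships,calls_per_ship World size.
#' @param cells_per_region,noncoastal_cells_per_region Richness grid
#'   cells per region (non-coastal cells exercise the coastal filter and
#'   never enter averages).
#' @param intra_region_affinity Probability that a ship's next call stays
#'   within its current region.
#' @param ship_speed Cruising speed in km/day.
#' @param port_stay Range (days) of the uniform in-port stay.
#' @param tank_volume_meanlog,tank_volume_sdlog Lognormal ballast-tank
#'   volume distribution (m^3).
#' @param discharge_fraction Fraction of the tank discharged per call.
#' @param temperature_mean_range,temperature_sd Per-region mean
#'   temperature range and within-region port-level sd (degrees C).
#' @param salinity_mean_range,salinity_sd Same for salinity (ppt).
#' @param richness_mean_range,richness_shape Per-region per-cell mean
#'   richness range and gamma shape (dispersion) of cell values.
#' @param params True [model_params()] of the world.
#' @return A validated list of class `synthetic_world_config`.
#' @export
synthetic_world_config <- function(seed,
                                   n_regions = 4,
                                   ports_per_region = 5,
                                   n_ships = 50,
                                   calls_per_ship = 20,
                                   cells_per_region = 6,
                                   noncoastal_cells_per_region = 2,
                                   intra_region_affinity = 0.7,
                                   ship_speed = 500,
                                   port_stay = c(0.5, 3),
                                   tank_volume_meanlog = log(5000),
                                   tank_volume_sdlog = 0.5,
                                   discharge_fraction = 0.2,
                                   temperature_mean_range = c(10, 20),
                                   temperature_sd = 1.5,
                                   salinity_mean_range = c(10, 30),
                                   salinity_sd = 2,
                                   richness_mean_range = c(80, 300),
                                   richness_shape = 25,
                                   params = model_params(
                                     alpha = 0.4, beta = 4, gamma = 1000^4,
                                     lambda = 1e-4, mu = 0.06,
                                     sigma_t = 5, sigma_s = 10
                                   )) {
  cfg <- list(
    seed = as.integer(seed), n_regions = n_regions,
    ports_per_region = ports_per_region, n_ships = n_ships,
    calls_per_ship = calls_per_ship, cells_per_region = cells_per_region,
    noncoastal_cells_per_region = noncoastal_cells_per_region,
    intra_region_affinity = intra_region_affinity, ship_speed = ship_speed,
    port_stay = port_stay, tank_volume_meanlog = tank_volume_meanlog,
    tank_volume_sdlog = tank_volume_sdlog,
    discharge_fraction = discharge_fraction,
    temperature_mean_range = temperature_mean_range,
    temperature_sd = temperature_sd,
    salinity_mean_range = salinity_mean_range, salinity_sd = salinity_sd,
    richness_mean_range = richness_mean_range,
    richness_shape = richness_shape,
    params = as_model_params(params)
  )
  counts <- c("n_regions", "ports_per_region", "n_ships", "calls_per_ship",
              "cells_per_region")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1) {
      stop(sprintf("config field '%s' must be a count >= 1", f), call. = FALSE)
    }
  }
  if (cfg$noncoastal_cells_per_region < 0) {
    stop("config field 'noncoastal_cells_per_region' must be >= 0", call. = FALSE)
  }
  for (f in c("temperature_sd", "salinity_sd")) {
    if (cfg[[f]] < 0) stop(sprintf("config field '%s' must be >= 0", f), call. = FALSE)
  }
  if (cfg$intra_region_affinity < 0 || cfg$intra_region_affinity > 1) {
    stop("config field 'intra_region_affinity' must be in [0, 1]", call. = FALSE)
  }
  if (cfg$discharge_fraction <= 0 || cfg$discharge_fraction > 1) {
    stop("config field 'discharge_fraction' must be in (0, 1]", call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("config field 'seed' must be an integer", call. = FALSE)
  structure(cfg, class = "synthetic_world_config")
}

synthetic_taxonomy <- function(n) {
  phyla <- c("Arthropoda", "Chordata", "Mollusca", "Annelida", "Ochrophyta",
             "Tracheophyta", "Cnidaria", "Rhodophyta")
  classes <- c("Malacostraca", "Actinopterygii", "Gastropoda", "Polychaeta",
               "Phaeophyceae", "Magnoliopsida", "Hydrozoa", "Florideophyceae")
  kingdoms <- c("Animalia", "Animalia", "Animalia", "Animalia", "Chromista",
                "Plantae", "Animalia", "Plantae")
  idx <- sample.int(length(phyla), n, replace = TRUE,
                    prob = c(25, 20, 12, 10, 9, 8, 8, 8))
  tibble::tibble(kingdom = kingdoms[idx], phylum = phyla[idx],
                 class = classes[idx])
}

#' Generate a synthetic world
#'
#' Draws all components of a [synthetic_world_config()] in a documented,
#' fixed order from one RNG stream seeded once (regions, ports, ships,
#' port calls, richness grid, species pool, then the realized
#' checklists), so identical seeds give byte-identical worlds and adding
#' later draws never reshuffles earlier ones. Ground-truth region-pair
#' invasion probabilities are computed from the generated traffic with
#' the package's own model functions and stored in the world.
#'
#' @param config A [synthetic_world_config()].
#' @return A list of class `synthetic_world` with elements `config`,
#'   `regions`, `ports`, `ships`, `calls`, `grid`, `species_pool`,
#'   `region_probs`, `checklists`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "synthetic_world_config"))
  set.seed(config$seed)
  region_ids <- sprintf("region_%d", seq_len(config$n_regions))

  # 1. regions: geographic centers and environmental/richness means
  regions <- tibble::tibble(
    region = region_ids,
    center_lon = stats::runif(config$n_regions, -160, 160),
    center_lat = stats::runif(config$n_regions, -50, 50),
    temperature_mean = stats::runif(config$n_regions,
                                    config$temperature_mean_range[1],
                                    config$temperature_mean_range[2]),
    salinity_mean = stats::runif(config$n_regions,
                                 config$salinity_mean_range[1],
                                 config$salinity_mean_range[2]),
    richness_mean = stats::runif(config$n_regions,
                                 config$richness_mean_range[1],
                                 config$richness_mean_range[2])
  )

  # 2. ports, clustered around their region center
  n_ports <- config$n_regions * config$ports_per_region
  ports <- regions[rep(seq_len(config$n_regions),
                       each = config$ports_per_region), ] |>
    dplyr::mutate(
      port_id = sprintf("p%03d", seq_len(n_ports)),
      name = sprintf("port_%03d", seq_len(n_ports)),
      lon = pmin(pmax(.data$center_lon + stats::rnorm(n_ports, 0, 3), -180), 180),
      lat = pmin(pmax(.data$center_lat + stats::rnorm(n_ports, 0, 3), -89), 89),
      temperature = .data$temperature_mean +
        stats::rnorm(n_ports, 0, config$temperature_sd),
      salinity = pmax(.data$salinity_mean +
                        stats::rnorm(n_ports, 0, config$salinity_sd), 0)
    ) |>
    dplyr::select("port_id", "name", "region", "lon", "lat",
                  "temperature", "salinity")

  # 3. ship specs
  tank <- stats::rlnorm(config$n_ships, config$tank_volume_meanlog,
                        config$tank_volume_sdlog)
  ships <- tibble::tibble(
    ship_id = sprintf("s%03d", seq_len(config$n_ships)),
    ship_type = sample(c("bulk_carrier", "container", "tanker", "general_cargo"),
                       config$n_ships, replace = TRUE),
    size_class = cut(tank, stats::quantile(tank, c(0, 1/3, 2/3, 1)),
                     labels = c("small", "medium", "large"),
                     include.lowest = TRUE) |> as.character(),
    tank_volume = tank,
    mean_discharge = config$discharge_fraction * tank
  )

  # 4. port-call log: biased random walk with intra-region affinity
  calls <- purrr::map_dfr(seq_len(config$n_ships), function(s) {
    cur <- sample.int(n_ports, 1)
    t <- stats::runif(1, 0, 30)
    out <- vector("list", config$calls_per_ship)
    for (k in seq_len(config$calls_per_ship)) {
      stay <- stats::runif(1, config$port_stay[1], config$port_stay[2])
      out[[k]] <- list(port = cur, arrival = t, departure = t + stay)
      if (k == config$calls_per_ship) break
      same_region <- which(ports$region == ports$region[cur])
      same_region <- setdiff(same_region, cur)
      other_region <- which(ports$region != ports$region[cur])
      candidates <- if (length(same_region) > 0 &&
                        (length(other_region) == 0 ||
                           stats::runif(1) < config$intra_region_affinity)) {
        same_region
      } else {
        other_region
      }
      if (length(candidates) == 0) candidates <- cur  # lone port: stay
      nxt <- candidates[sample.int(length(candidates), 1)]
      d <- great_circle_distance(ports$lon[cur], ports$lat[cur],
                                 ports$lon[nxt], ports$lat[nxt])
      t <- t + stay + d / config$ship_speed
      cur <- nxt
    }
    tibble::tibble(
      ship_id = ships$ship_id[s],
      port_id = ports$port_id[purrr::map_int(out, "port")],
      arrival = purrr::map_dbl(out, "arrival"),
      departure = purrr::map_dbl(out, "departure")
    )
  })

  # 5. richness grid: gamma cells around the per-region mean
  grid <- purrr::map_dfr(seq_len(config$n_regions), function(r) {
    nc <- config$cells_per_region
    nn <- config$noncoastal_cells_per_region
    mean_r <- regions$richness_mean[r]
    tibble::tibble(
      region = region_ids[r],
      coastal = rep(c(TRUE, FALSE), c(nc, nn)),
      richness = stats::rgamma(nc + nn, shape = config$richness_shape,
                               rate = config$richness_shape / mean_r)
    )
  }) |>
    dplyr::mutate(cell_id = sprintf("c%03d", dplyr::row_number()),
                  .before = "region")

  # 6. species pool: size = rounded per-cell average richness per region
  avg <- average_grid_richness(grid)
  pool <- purrr::map_dfr(seq_len(config$n_regions), function(r) {
    n_sp <- max(1L, as.integer(round(
      avg$average_richness[avg$region == region_ids[r]]
    )))
    dplyr::bind_cols(
      tibble::tibble(
        name = sprintf("Species %s_%04d", region_ids[r], seq_len(n_sp)),
        native_region = region_ids[r]
      ),
      synthetic_taxonomy(n_sp)
    )
  })

  world <- structure(
    list(config = config, regions = regions, ports = ports, ships = ships,
         calls = calls, grid = grid, species_pool = pool),
    class = "synthetic_world"
  )

  # ground truth: the model's own probabilities on the generated traffic
  parcels <- ballast_provenance(calls, ships,
                                discharge_fraction = config$discharge_fraction)
  pair <- port_pair_invasion_probability(parcels, ports, config$params)
  world$region_probs <- region_invasion_probability(pair, ports)

  # 7. realized checklists (continues the same RNG stream)
  world$checklists <- if (nrow(world$region_probs) > 0) {
    realize_invasions(world)
  } else {
    stats::setNames(list(), character())  # fully intra-regional traffic
  }
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "Synthetic world (seed %d): %d regions, %d ports, %d ships, %d calls, %d species\n",
    x$config$seed, nrow(x$regions), nrow(x$ports), nrow(x$ships),
    nrow(x$calls), nrow(x$species_pool)
  ))
  invisible(x)
}

apply_odds <- function(p, multiplier) {
  odds <- multiplier * p / (1 - p)
  out <- odds / (1 + odds)
  # p = 1 or an infinite multiplier on p > 0 saturate at certainty
  out[p == 1 | (is.infinite(multiplier) & p > 0)] <- 1
  out[p == 0 | multiplier == 0] <- 0
  out
}

#' Realize invasions on a synthetic world
#'
#' Monte-Carlo draw of the observed checklists: each species of donor
#' region A establishes in recipient region B independently with the
#' world's ground-truth probability `P(A,B)` (recomputed if `params`
#' differ from the generating constants). Checklists conform to the
#' checklist schema, with two subregions per recipient (`<region>_a/_b`)
#' whose presence flags are drawn conditioned on establishment.
#'
#' @param world A [generate_world()] result.
#' @param params Optional [model_params()] to recompute probabilities
#'   with; default uses the world's stored ground truth.
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @param odds_multiplier Optional named numeric vector inflating the
#'   establishment odds of given donor regions (e.g.
#'   `c(region_2 = 10)`) — for misspecification experiments.
#' @param format `"checklists"` (default) or `"counts"` (fast path: a
#'   tibble of established-species counts per region pair, skipping
#'   checklist assembly).
#' @return Named list of [as_nis_checklist()] objects (one per recipient
#'   region), or a counts tibble.
#' @export
realize_invasions <- function(world, params = NULL, seed = NULL,
                              odds_multiplier = NULL,
                              format = c("checklists", "counts")) {
  format <- match.arg(format)
  stopifnot(inherits(world, "synthetic_world"))
  if (!is.null(seed)) set.seed(seed)
  probs <- if (is.null(params)) {
    world$region_probs
  } else {
    parcels <- ballast_provenance(world$calls, world$ships,
                                  world$config$discharge_fraction)
    pair <- port_pair_invasion_probability(parcels, world$ports,
                                           as_model_params(params))
    region_invasion_probability(pair, world$ports)
  }
  if (nrow(probs) == 0) stop("world has no cross-region routes", call. = FALSE)
  if (!is.null(odds_multiplier)) {
    idx <- match(probs$donor, names(odds_multiplier))
    m <- ifelse(is.na(idx), 1, odds_multiplier[idx])
    probs <- dplyr::mutate(probs, p_invasion = apply_odds(.data$p_invasion, m))
  }

  pool_sizes <- dplyr::count(world$species_pool, .data$native_region)
  probs <- dplyr::left_join(
    probs, dplyr::rename(pool_sizes, donor = "native_region"), by = "donor"
  )

  if (format == "counts") {
    return(dplyr::transmute(
      probs, donor = .data$donor, recipient = .data$recipient,
      p_invasion = .data$p_invasion, n_species = .data$n,
      observed = stats::rbinom(dplyr::n(), .data$n, .data$p_invasion)
    ))
  }

  recipients <- sort(unique(probs$recipient))
  region_ids <- world$regions$region
  checklists <- purrr::map(recipients, function(b) {
    rows <- probs[probs$recipient == b, ]
    est <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      sp <- world$species_pool[
        world$species_pool$native_region == rows$donor[i], ]
      hit <- stats::runif(nrow(sp)) < rows$p_invasion[i]
      sp[hit, ]
    })
    subs <- paste0(b, c("_a", "_b"))
    n_est <- nrow(est)
    if (n_est > 0) {
      in_a <- stats::runif(n_est) < 0.6
      in_b <- stats::runif(n_est) < 0.6
      neither <- !in_a & !in_b
      pick_a <- stats::runif(sum(neither)) < 0.5
      in_a[neither] <- pick_a
      in_b[neither] <- !pick_a
    } else {
      in_a <- logical(0)
      in_b <- logical(0)
      est <- tibble::tibble(name = character(), kingdom = character(),
                            phylum = character(), class = character(),
                            native_region = character())
    }
    recs <- tibble::tibble(
      name = est$name, kingdom = est$kingdom, phylum = est$phylum,
      class = est$class, native_regions = as.list(est$native_region)
    )
    recs[[subs[1]]] <- in_a
    recs[[subs[2]]] <- in_b
    as_nis_checklist(recs, recipient_region = b, subregion_ids = subs,
                     regions = region_ids)
  })
  stats::setNames(checklists, recipients)
}
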