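#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6371 km (via
#' \pkg{geosphere}). Symmetric, zero only for identical coordinates.
#' Sea-route distances from an external router can be substituted
#' downstream via the `distances` argument of
#' [port_pair_invasion_probability()].
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectorized).
#' @return Distance(s) in km.
#' @export
#' @examples
#' great_circle_distance(0, 0, 180, 0) # half the equator, 6371 * pi
great_circle_distance <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180) ||
      any(!is.finite(c(lon1, lat1, lon2, lat2)))) {
    stop("coordinates must satisfy |lat| <= 90, |lon| <= 180", call. = FALSE)
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Probability that transported water carries nonindigenous species
#'
#' Sigmoid of inter-port distance: `1 / (1 + gamma * d^(-beta))`. Water
#' from nearby ports mostly contains species already native to the
#' recipient; with growing distance the transported assemblage becomes
#' increasingly nonindigenous, approaching 1. By convention the
#' probability at `d = 0` is 0 (same-port water is never nonindigenous;
#' the formula itself is singular there).
#'
#' @param d Distance(s) in km, non-negative.
#' @param params A [model_params()] object.
#' @return Probability vector in \[0, 1\].
#' @export
p_nonindigenous <- function(d, params) {
  params <- as_model_params(params)
  if (any(d < 0)) stop("distance must be non-negative", call. = FALSE)
  out <- 1 / (1 + params$gamma * d^(-params$beta))
  out[d == 0] <- 0
  out
}

#' Probability of introduction for a ballast parcel
#'
#' `(1 - exp(-lambda * volume)) * exp(-mu * travel_time)`: saturating in
#' the discharged volume originating at the donor port (propagule
#' pressure), decaying with en-route mortality over the travel time.
#'
#' @param volume Discharged ballast volume(s) in m^3, non-negative.
#' @param travel_time Time(s) between uptake and discharge in days,
#'   non-negative.
#' @param params A [model_params()] object.
#' @return Probability vector in \[0, 1).
#' @export
p_intro <- function(volume, travel_time, params) {
  params <- as_model_params(params)
  if (any(volume < 0)) stop("volume must be non-negative", call. = FALSE)
  if (any(travel_time < 0)) stop("travel_time must be non-negative", call. = FALSE)
  (1 - exp(-params$lambda * volume)) * exp(-params$mu * travel_time)
}

#' Probability of establishment between two port environments
#'
#' Gaussian environmental match:
#' `alpha * exp(-0.5 * ((dT/sigma_t)^2 + (dS/sigma_s)^2))` with signed
#' differences of annual mean temperature (degrees C) and salinity (ppt).
#' Maximal (`alpha`) for identical environments; symmetric in the two
#' ports.
#'
#' @param t1,s1 Donor port mean temperature and salinity.
#' @param t2,s2 Recipient port mean temperature and salinity.
#' @param params A [model_params()] object.
#' @return Probability vector in (0, alpha\].
#' @export
p_establish <- function(t1, s1, t2, s2, params) {
  params <- as_model_params(params)
  if (any(!is.finite(c(t1, s1, t2, s2)))) {
    stop("ports must carry finite temperature and salinity", call. = FALSE)
  }
  dt <- (t1 - t2) / params$sigma_t
  ds <- (s1 - s2) / params$sigma_s
  params$alpha * exp(-0.5 * (dt^2 + ds^2))
}

resolve_ports <- function(ids, ports, what) {
  idx <- match(ids, ports$port_id)
  if (anyNA(idx)) {
    stop(sprintf("unknown %s port id(s): %s", what,
                 paste(unique(ids[is.na(idx)]), collapse = ", ")), call. = FALSE)
  }
  ports[idx, , drop = FALSE]
}

#' Per-route invasion probabilities for ballast parcels
#'
#' Resolves each parcel's origin and discharge ports, computes the three
#' component probabilities and their product, the route-level invasion
#' probability. Input and output are tibbles, one row per parcel.
#'
#' @param parcels Tibble with columns `origin_port`, `discharge_port`,
#'   `volume` (m^3), `travel_time` (days); typically from
#'   [ballast_provenance()].
#' @param ports Port table with columns `port_id`, `region`, `lon`,
#'   `lat`, `temperature`, `salinity`.
#' @param params A [model_params()] object.
#' @param distances Optional precomputed distance matrix (km) with port
#'   ids as dimnames, overriding the haversine default (e.g. sea-route
#'   distances).
#' @return The parcels tibble with added columns `distance`,
#'   `p_nonindigenous`, `p_intro`, `p_establish`, `p_invasion`.
#' @export
route_invasion_probability <- function(parcels, ports, params,
                                       distances = NULL) {
  params <- as_model_params(params)
  check_columns(parcels, c("origin_port", "discharge_port", "volume",
                           "travel_time"), "parcels")
  check_columns(ports, c("port_id", "region", "lon", "lat", "temperature",
                         "salinity"), "ports")
  if (nrow(parcels) == 0) {
    return(dplyr::mutate(tibble::as_tibble(parcels), distance = numeric(0),
                         p_nonindigenous = numeric(0), p_intro = numeric(0),
                         p_establish = numeric(0), p_invasion = numeric(0)))
  }
  from <- resolve_ports(parcels$origin_port, ports, "origin")
  to <- resolve_ports(parcels$discharge_port, ports, "discharge")
  d <- if (!is.null(distances)) {
    distances[cbind(as.character(parcels$origin_port),
                    as.character(parcels$discharge_port))]
  } else {
    great_circle_distance(from$lon, from$lat, to$lon, to$lat)
  }
  tibble::as_tibble(parcels) |>
    dplyr::mutate(
      distance = d,
      p_nonindigenous = p_nonindigenous(d, params),
      p_intro = p_intro(.data$volume, .data$travel_time, params),
      p_establish = p_establish(from$temperature, from$salinity,
                                to$temperature, to$salinity, params),
      p_invasion = .data$p_nonindigenous * .data$p_intro * .data$p_establish
    )
}

#' Port-pair invasion probabilities
#'
#' Aggregates route-level probabilities over all ballast parcels moving
#' between each ordered (origin, discharge) port pair with the
#' complement product `1 - prod(1 - p_r)`: the probability that at least
#' one route seeds an invasion, treating routes as independent. The same
#' aggregation rule is applied one level up by
#' [region_invasion_probability()].
#'
#' @inheritParams route_invasion_probability
#' @return Tibble with one row per ordered port pair: `origin_port`,
#'   `discharge_port`, `distance`, `n_routes`, `p_invasion`.
#' @export
port_pair_invasion_probability <- function(parcels, ports, params,
                                           distances = NULL) {
  routes <- route_invasion_probability(parcels, ports, params, distances)
  routes |>
    dplyr::group_by(.data$origin_port, .data$discharge_port) |>
    dplyr::summarise(
      distance = .data$distance[1],
      n_routes = dplyr::n(),
      p_invasion = complement_aggregate(.data$p_invasion),
      .groups = "drop"
    )
}

#' Region-pair invasion probabilities
#'
#' Lifts port-pair probabilities to ordered (donor, recipient) region
#' pairs with the complement product over all port pairs connecting the
#' regions. Monotone non-decreasing as pairs are added. A requested pair
#' with no shipping connection yields probability 0 with a warning.
#'
#' @param pair_probs Tibble from [port_pair_invasion_probability()].
#' @param ports Port table mapping `port_id` to `region`.
#' @param donor,recipient Optional region codes restricting the output to
#'   one ordered pair (reported even if unconnected).
#' @return Tibble with columns `donor`, `recipient`, `n_pairs`,
#'   `p_invasion`, excluding within-region pairs.
#' @export
region_invasion_probability <- function(pair_probs, ports,
                                        donor = NULL, recipient = NULL) {
  check_columns(pair_probs, c("origin_port", "discharge_port", "p_invasion"),
                "pair_probs")
  from <- resolve_ports(pair_probs$origin_port, ports, "origin")
  to <- resolve_ports(pair_probs$discharge_port, ports, "discharge")
  agg <- pair_probs |>
    dplyr::mutate(donor = from$region, recipient = to$region) |>
    dplyr::filter(.data$donor != .data$recipient) |>
    dplyr::group_by(.data$donor, .data$recipient) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      p_invasion = complement_aggregate(.data$p_invasion),
      .groups = "drop"
    )
  if (!is.null(donor) && !is.null(recipient)) {
    hit <- agg$donor == donor & agg$recipient == recipient
    if (!any(hit)) {
      warning(sprintf(
        "no shipping connection from '%s' to '%s'; invasion probability 0",
        donor, recipient
      ), call. = FALSE)
      return(tibble::tibble(donor = donor, recipient = recipient,
                            n_pairs = 0L, p_invasion = 0))
    }
    agg <- agg[hit, ]
  }
  agg
}
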