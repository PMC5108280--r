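#' Origin-tagged ballast parcels from port-call logs
#'
#' Reconstructs where each ship's discharged ballast water was taken up,
#' modelling the ballast tank as a well-mixed reservoir of fixed volume.
#' The tank starts full of water from the ship's first observed call (any
#' earlier history is censored by the observation window). At every
#' subsequent call a constant fraction of the tank volume is discharged
#' — split over the uptake origins currently in the tank in proportion to
#' their share, emitting one parcel per origin — and replaced by local
#' water. A parcel's travel time is the elapsed time between departure
#' from its uptake port and arrival at the discharge port; revisits to
#' the same port are tracked as separate uptake events so travel times
#' stay exact.
#'
#' The total discharged volume at each call equals
#' `discharge_fraction * tank_volume`; over a voyage of `n` calls the
#' discharge therefore totals `fraction * tank_volume * (n - 1)`.
#'
#' @param calls Port-call log: tibble with columns `ship_id`, `port_id`,
#'   `arrival`, `departure` (days); each ship's calls must be
#'   time-ordered with `departure >= arrival`.
#' @param ships Ship specs: tibble with columns `ship_id`, `tank_volume`
#'   (m^3) and, if `discharge_fraction` is `NULL`,
#'   `mean_discharge` (m^3 per call, at most the tank volume).
#' @param discharge_fraction Fraction of the tank discharged per call,
#'   in (0, 1\]; `NULL` to derive per ship as
#'   `mean_discharge / tank_volume`.
#' @return Tibble of ballast parcels: `ship_id`, `route_id`,
#'   `origin_port`, `discharge_port`, `volume` (m^3), `travel_time`
#'   (days).
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   ship_id = "s1", port_id = c("a", "b", "c"),
#'   arrival = c(0, 4, 9), departure = c(1, 5, 10)
#' )
#' ships <- tibble::tibble(ship_id = "s1", tank_volume = 1000,
#'                         mean_discharge = 500)
#' ballast_provenance(calls, ships)
ballast_provenance <- function(calls, ships, discharge_fraction = NULL) {
  check_columns(calls, c("ship_id", "port_id", "arrival", "departure"), "calls")
  check_columns(ships, c("ship_id", "tank_volume"), "ships")
  if (!is.null(discharge_fraction) &&
      (discharge_fraction <= 0 || discharge_fraction > 1)) {
    stop("discharge_fraction must be in (0, 1]", call. = FALSE)
  }
  if (any(calls$departure < calls$arrival)) {
    stop("port calls must have departure >= arrival", call. = FALSE)
  }

  purrr::map_dfr(split(calls, calls$ship_id), function(sc) {
    sc <- dplyr::arrange(sc, .data$arrival)
    n <- nrow(sc)
    if (n < 2) return(NULL)
    spec <- ships[match(sc$ship_id[1], ships$ship_id), ]
    if (is.na(spec$tank_volume)) {
      stop(sprintf("no ship spec for '%s'", sc$ship_id[1]), call. = FALSE)
    }
    v <- spec$tank_volume
    f <- discharge_fraction %||% (spec$mean_discharge / v)
    if (is.na(f) || f <= 0 || f > 1) {
      stop(sprintf("ship '%s': derived discharge fraction %s outside (0, 1]",
                   sc$ship_id[1], format(f)), call. = FALSE)
    }

    # tank state: one entry per uptake event
    tank_port <- sc$port_id[1]
    tank_time <- sc$departure[1]
    tank_vol <- v
    acc_origin <- acc_dest <- acc_route <- vector("list", n - 1)
    acc_vol <- acc_tt <- vector("list", n - 1)
    for (k in 2:n) {
      d_total <- f * v
      parcel_vol <- (tank_vol / v) * d_total
      m <- length(tank_port)
      acc_origin[[k - 1]] <- tank_port
      acc_dest[[k - 1]] <- rep(sc$port_id[k], m)
      acc_route[[k - 1]] <- rep(paste0(sc$ship_id[1], "_", k), m)
      acc_vol[[k - 1]] <- parcel_vol
      acc_tt[[k - 1]] <- sc$arrival[k] - tank_time
      tank_vol <- tank_vol - parcel_vol
      keep <- tank_vol > 0
      tank_port <- c(tank_port[keep], sc$port_id[k])
      tank_time <- c(tank_time[keep], sc$departure[k])
      tank_vol <- c(tank_vol[keep], d_total)
    }
    tibble::tibble(
      ship_id = sc$ship_id[1],
      route_id = unlist(acc_route),
      origin_port = unlist(acc_origin),
      discharge_port = unlist(acc_dest),
      volume = unlist(acc_vol),
      travel_time = unlist(acc_tt)
    )
  })
}
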