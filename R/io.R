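#' Read a port table
#'
#' Delimited text with columns `port_id, name, region, lon, lat,
#' temperature, salinity` (annual means, degrees C and ppt).
#'
#' @param path Path to the file.
#' @return Validated tibble.
#' @export
read_port_table <- function(path) {
  ports <- readr::read_csv(path, col_types = readr::cols(
    port_id = readr::col_character(), name = readr::col_character(),
    region = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  check_columns(ports, c("port_id", "name", "region", "lon", "lat",
                         "temperature", "salinity"),
                sprintf("port table '%s'", basename(path)))
  if (any(abs(ports$lat) > 90) || any(abs(ports$lon) > 180)) {
    stop("port table has out-of-range coordinates", call. = FALSE)
  }
  if (any(ports$salinity < 0)) {
    stop("port table has negative salinity", call. = FALSE)
  }
  ports
}

#' Read a port-call log
#'
#' Delimited text with columns `ship_id, port_id, arrival, departure`
#' (days), sorted in time per ship.
#'
#' @param path Path to the file.
#' @return Validated tibble.
#' @export
read_port_calls <- function(path) {
  calls <- readr::read_csv(path, col_types = readr::cols(
    ship_id = readr::col_character(), port_id = readr::col_character(),
    arrival = readr::col_double(), departure = readr::col_double()
  ), progress = FALSE)
  check_columns(calls, c("ship_id", "port_id", "arrival", "departure"),
                sprintf("port-call log '%s'", basename(path)))
  if (any(calls$departure < calls$arrival)) {
    stop("port-call log has departure before arrival", call. = FALSE)
  }
  calls
}

#' Read ship specifications
#'
#' Delimited text with columns `ship_id, ship_type, size_class,
#' tank_volume, mean_discharge` (m^3).
#'
#' @param path Path to the file.
#' @return Validated tibble.
#' @export
read_ship_specs <- function(path) {
  ships <- readr::read_csv(path, col_types = readr::cols(
    ship_id = readr::col_character(), ship_type = readr::col_character(),
    size_class = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  check_columns(ships, c("ship_id", "ship_type", "size_class",
                         "tank_volume", "mean_discharge"),
                sprintf("ship specs '%s'", basename(path)))
  if (any(ships$mean_discharge <= 0 |
            ships$mean_discharge > ships$tank_volume)) {
    stop("ship specs must satisfy 0 < mean_discharge <= tank_volume",
         call. = FALSE)
  }
  ships
}

checklist_to_df <- function(checklist) {
  subs <- subregion_ids(checklist)
  df <- tibble::as_tibble(checklist)
  df$native_regions <- purrr::map_chr(df$native_regions, paste, collapse = ";")
  dplyr::mutate(df, dplyr::across(dplyr::all_of(subs), as.integer))
}

#' Write a checklist to delimited text
#'
#' Inverse of [read_checklist()]: semicolon-joined native regions and
#' 0/1 presence columns.
#'
#' @param checklist An [as_nis_checklist()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(checklist, path) {
  readr::write_csv(checklist_to_df(checklist), path)
  invisible(path)
}

#' Serialize a synthetic world to a directory of text files
#'
#' Writes every component in the exact formats the analysis stages
#' consume (`ports.csv`, `ships.csv`, `calls.csv`, `grid.csv`,
#' `species_pool.csv`, `regions.csv`, `region_probs.csv`,
#' `checklist_<region>.csv`, `config.yaml`), so generated files feed the
#' pipeline without manual edits. [read_world()] round-trips the result.
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
world_to_files <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory: %s", dir), call. = FALSE)
  paths <- c(
    regions = file.path(dir, "regions.csv"),
    ports = file.path(dir, "ports.csv"),
    ships = file.path(dir, "ships.csv"),
    calls = file.path(dir, "calls.csv"),
    grid = file.path(dir, "grid.csv"),
    species_pool = file.path(dir, "species_pool.csv"),
    region_probs = file.path(dir, "region_probs.csv")
  )
  for (nm in names(paths)) readr::write_csv(world[[nm]], paths[nm])
  cfg <- unclass(world$config)
  cfg$params <- unclass(cfg$params)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path, precision = 15)
  cl_paths <- purrr::imap_chr(world$checklists, function(cl, nm) {
    p <- file.path(dir, sprintf("checklist_%s.csv", nm))
    write_checklist(cl, p)
    p
  })
  invisible(c(paths, cfg_path, cl_paths))
}

#' Load a serialized synthetic world
#'
#' @param dir Directory written by [world_to_files()].
#' @return A `synthetic_world` object equal (to numeric round-trip
#'   precision) to the one serialized.
#' @export
read_world <- function(dir) {
  need <- file.path(dir, "config.yaml")
  if (!file.exists(need)) stop(sprintf("not a world directory: %s", dir), call. = FALSE)
  cfg <- yaml::read_yaml(need)
  params <- do.call(model_params, cfg$params)
  cfg$params <- NULL
  config <- do.call(synthetic_world_config, c(cfg, list(params = params)))

  read_tbl <- function(name, types) {
    readr::read_csv(file.path(dir, name), col_types = types, progress = FALSE)
  }
  world <- structure(list(
    config = config,
    regions = read_tbl("regions.csv", readr::cols(
      region = readr::col_character(), .default = readr::col_double()
    )),
    ports = read_port_table(file.path(dir, "ports.csv")),
    ships = read_ship_specs(file.path(dir, "ships.csv")),
    calls = read_port_calls(file.path(dir, "calls.csv")),
    grid = read_tbl("grid.csv", readr::cols(
      cell_id = readr::col_character(), region = readr::col_character(),
      coastal = readr::col_logical(), richness = readr::col_double()
    )),
    species_pool = read_tbl("species_pool.csv", readr::cols(
      .default = readr::col_character()
    )),
    region_probs = read_tbl("region_probs.csv", readr::cols(
      donor = readr::col_character(), recipient = readr::col_character(),
      n_pairs = readr::col_integer(), p_invasion = readr::col_double()
    ))
  ), class = "synthetic_world")

  cl_files <- list.files(dir, pattern = "^checklist_.*\\.csv$",
                         full.names = TRUE)
  recipients <- sub("^checklist_(.*)\\.csv$", "\\1", basename(cl_files))
  world$checklists <- stats::setNames(
    purrr::map2(cl_files, recipients, function(p, r) {
      read_checklist(p, recipient_region = r, regions = world$regions$region)
    }),
    recipients
  )
  world
}
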