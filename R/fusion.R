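#' KNN-IDW fusion configuration
#'
#' Settings for the fused ground-measurement feature: for a target location
#' and day, the k nearest reporting monitoring stations (great-circle
#' distance) are found and their PM2.5 values combined by inverse-distance
#' weighting. In `leave_target_out` mode the target station's own same-day
#' record is excluded, preventing leakage from the prediction target into its
#' own feature; `full` mode uses all available records and is meant for
#' production surfaces after evaluation.
#'
#' @param k Neighbour count (default 9).
#' @param idw_power Exponent on inverse distance (default 1: weights
#'   proportional to 1/d).
#' @param mode `"leave_target_out"` or `"full"`.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(k = 9, idw_power = 1,
                          mode = c("leave_target_out", "full")) {
  stopifnot(k >= 1, idw_power > 0)
  structure(list(k = as.integer(k), idw_power = idw_power,
                 mode = match.arg(mode)),
            class = "fusion_config")
}

# Great-circle distance in km on the WGS84 mean sphere (radius 6371.0088 km).
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088)
}

#' Find the nearest reporting stations for one target
#'
#' Returns the `min(k, available)` nearest stations among the day's reporting
#' records, by haversine distance, with deterministic tie-breaking by station
#' id. With `exclude_station_id`, that station's record is removed first
#' (leave-target-out); exclusion is by station identity, so a co-located but
#' distinct station remains eligible.
#'
#' @param target_lon,target_lat Target coordinates, degrees WGS84.
#' @param day_observations Tibble of the day's records with columns
#'   `station_id`, `lon`, `lat`, `pm25`.
#' @param config A [fusion_config()].
#' @param exclude_station_id Station id to exclude, or `NULL`.
#' @return A `neighbor_set`: list with `station_id`, `distance_km` (ascending),
#'   `value`, normalized `weight`, and `underfilled` (fewer than k found).
#'   Zero available stations yields an empty set (`n = 0`), not an error; the
#'   downstream feature is marked missing.
#' @export
find_neighbors <- function(target_lon, target_lat, day_observations, config,
                           exclude_station_id = NULL) {
  obs <- day_observations
  if (!is.null(exclude_station_id)) {
    obs <- obs[obs$station_id != exclude_station_id, , drop = FALSE]
  }
  if (nrow(obs) == 0) {
    return(structure(list(station_id = character(0), distance_km = numeric(0),
                          value = numeric(0), weight = numeric(0),
                          n = 0L, underfilled = TRUE),
                     class = "neighbor_set"))
  }
  d <- haversine_km(target_lon, target_lat, obs$lon, obs$lat)
  ord <- order(d, obs$station_id)
  keep <- ord[seq_len(min(config$k, length(ord)))]
  dk <- d[keep]
  vals <- obs$pm25[keep]
  w <- idw_weights(dk, config$idw_power)
  structure(list(station_id = obs$station_id[keep], distance_km = dk,
                 value = vals, weight = w, n = length(keep),
                 underfilled = length(keep) < config$k),
            class = "neighbor_set")
}

# Normalized inverse-distance weights; an exact zero distance short-circuits
# to full weight on the first zero-distance neighbour.
idw_weights <- function(d, power) {
  if (any(d == 0)) {
    w <- numeric(length(d))
    w[which(d == 0)[1]] <- 1
    return(w)
  }
  raw <- d^(-power)
  raw / sum(raw)
}

#' Inverse-distance-weighted estimate from a neighbour set
#'
#' `sum(w_i * v_i)` with weights proportional to `d_i^(-power)`, already
#' normalized in the set. A zero-distance neighbour short-circuits to that
#' neighbour's value. An empty set yields `NA` (missing-feature marker).
#'
#' @param neighbors A `neighbor_set` from [find_neighbors()].
#' @return Estimated PM2.5 in ug/m3, or `NA_real_` if the set is empty.
#' @export
idw_estimate <- function(neighbors) {
  if (neighbors$n == 0L) return(NA_real_)
  sum(neighbors$weight * neighbors$value)
}

#' Build the fused IDW PM2.5 feature for a table of targets
#'
#' Applies [find_neighbors()] and [idw_estimate()] to every `(lon, lat, date)`
#' target. In `leave_target_out` mode a target that carries a `station_id`
#' excludes its own same-day record; in `full` mode all records are used.
#'
#' @param observations Station records: `station_id`, `lon`, `lat`, `date`,
#'   `pm25`.
#' @param targets Tibble with `lon`, `lat`, `date` and optionally
#'   `station_id` (used for exclusion in leave-target-out mode).
#' @param config A [fusion_config()].
#' @return `targets` with added columns `idw_pm25` (NA when no station
#'   reported), `n_neighbors` and `underfilled`.
#' @export
build_idw_feature <- function(observations, targets,
                              config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  has_id <- "station_id" %in% names(targets)
  obs_by_day <- split(observations, as.character(observations$date))
  res <- purrr::pmap(
    list(targets$lon, targets$lat, as.character(targets$date),
         if (has_id) targets$station_id else
           rep(NA_character_, nrow(targets))),
    function(lon, lat, day, sid) {
      day_obs <- obs_by_day[[day]]
      if (is.null(day_obs)) {
        return(list(idw_pm25 = NA_real_, n_neighbors = 0L,
                    underfilled = TRUE))
      }
      excl <- if (config$mode == "leave_target_out" && !is.na(sid)) sid
      ns <- find_neighbors(lon, lat, day_obs, config, exclude_station_id = excl)
      list(idw_pm25 = idw_estimate(ns), n_neighbors = ns$n,
           underfilled = ns$underfilled)
    })
  targets$idw_pm25 <- purrr::map_dbl(res, "idw_pm25")
  targets$n_neighbors <- purrr::map_int(res, "n_neighbors")
  targets$underfilled <- purrr::map_lgl(res, "underfilled")
  targets
}
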