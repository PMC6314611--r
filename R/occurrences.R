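#' Read occurrence records from delimited text
#'
#' Expects named columns for longitude, latitude and (optionally) coordinate
#' uncertainty in meters; common aliases (`lon`, `long`, `x`, `lat`, `y`,
#' `uncertainty`, `error_m`) are recognized. Rows with unparseable or
#' out-of-range coordinates are dropped with a message giving the count, as
#' are exact duplicate coordinate pairs. Missing uncertainty is retained as
#' `NA` ("absent").
#'
#' @param path path to a CSV/TSV file.
#' @return occurrence tibble with columns `species`, `longitude`, `latitude`,
#'   `uncertainty_m`, `source_id`.
#' @export
read_occurrences <- function(path) {
  raw <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0L) stop("empty occurrence file: ", path, call. = FALSE)
  nm <- tolower(names(raw))
  lon_i <- match(TRUE, nm %in% c("longitude", "lon", "long", "x"))
  lat_i <- match(TRUE, nm %in% c("latitude", "lat", "y"))
  unc_i <- match(TRUE, nm %in% c("uncertainty_m", "uncertainty", "error_m",
                                 "uncertainty_meters", "coord_uncertainty_m"))
  if (is.na(lon_i) || is.na(lat_i)) {
    stop("occurrence file must have longitude and latitude columns", call. = FALSE)
  }
  sp_i <- match(TRUE, nm %in% c("species", "taxon", "name"))
  id_i <- match(TRUE, nm %in% c("source_id", "id", "record_id"))
  occ <- tibble::tibble(
    species = if (!is.na(sp_i)) as.character(raw[[sp_i]]) else "unknown",
    longitude = suppressWarnings(as.numeric(raw[[lon_i]])),
    latitude = suppressWarnings(as.numeric(raw[[lat_i]])),
    uncertainty_m = if (!is.na(unc_i))
      suppressWarnings(as.numeric(raw[[unc_i]])) else NA_real_,
    source_id = if (!is.na(id_i)) as.character(raw[[id_i]])
      else sprintf("row-%06d", seq_len(nrow(raw)))
  )
  ok <- !is.na(occ$longitude) & !is.na(occ$latitude) &
    occ$longitude >= -180 & occ$longitude <= 180 &
    occ$latitude >= -90 & occ$latitude <= 90 &
    (is.na(occ$uncertainty_m) | occ$uncertainty_m >= 0)
  if (any(!ok)) message(sum(!ok), " record(s) with invalid coordinates dropped")
  occ <- occ[ok, ]
  dup <- duplicated(occ[, c("longitude", "latitude")])
  if (any(dup)) message(sum(dup), " duplicate coordinate pair(s) dropped")
  occ[!dup, ]
}

guess_delim <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (grepl("\t", l1)) "\t" else ","
}

#' Remove records from an exclusion list
#'
#' Expert-judgment removals (e.g. records outside the species' plausible
#' range) are supplied as a list of `source_id`s rather than hard-coded.
#'
#' @param occ occurrence tibble.
#' @param exclude_ids character vector of `source_id`s to remove.
#' @return filtered occurrence tibble.
#' @export
exclude_records <- function(occ, exclude_ids) {
  dplyr::filter(occ, !.data$source_id %in% exclude_ids)
}

#' Filter records by coordinate uncertainty
#'
#' Removes records whose uncertainty is absent or strictly greater than
#' `max_m` meters; a record at exactly `max_m` is kept. Relative order is
#' preserved.
#'
#' @param occ occurrence tibble.
#' @param max_m maximum tolerated uncertainty radius in meters (default
#'   10,000).
#' @return filtered occurrence tibble.
#' @export
filter_uncertainty <- function(occ, max_m = 10000) {
  stopifnot(max_m > 0)
  dplyr::filter(occ, !is.na(.data$uncertainty_m), .data$uncertainty_m <= max_m)
}

#' Great-circle distance in kilometers (haversine)
#'
#' @param p,q two-column matrices (or length-2 vectors) of lon/lat in decimal
#'   degrees.
#' @return distances in km (vectorized elementwise like
#'   [geosphere::distHaversine()]).
#' @export
gc_distance_km <- function(p, q) {
  geosphere::distHaversine(p, q, r = .earth_radius_m) / 1000
}

#' Pairwise great-circle distance matrix in kilometers
#' @keywords internal
gc_dist_matrix_km <- function(lon, lat) {
  n <- length(lon)
  m <- matrix(0, n, n)
  pts <- cbind(lon, lat)
  for (i in seq_len(n)) {
    m[i, ] <- geosphere::distHaversine(pts[i, ], pts, r = .earth_radius_m) / 1000
  }
  m
}

#' Spatially rarefy occurrences to a minimum separation
#'
#' Greedy thinning: repeatedly delete the record with the most neighbors
#' closer than `min_km`; ties are broken by higher summed inverse-distance
#' crowding, then by later input position. A final repair pass re-adds any
#' deleted record that no longer conflicts, so the result is maximal: every
#' retained pair is at least `min_km` apart (great-circle) and no removed
#' record could be re-added without violating that.
#'
#' @param occ occurrence tibble.
#' @param min_km minimum pairwise separation in km (default 50).
#' @param seed unused unless a residual random tie remains (kept for
#'   reproducibility of that edge case).
#' @return thinned occurrence tibble (input order preserved).
#' @export
thin_occurrences <- function(occ, min_km = 50, seed = NULL) {
  stopifnot(min_km > 0)
  n <- nrow(occ)
  if (n <= 1L) return(occ)
  if (!is.null(seed)) set.seed(seed)
  d <- gc_dist_matrix_km(occ$longitude, occ$latitude)
  conflict <- d < min_km
  diag(conflict) <- FALSE
  inv <- 1 / pmax(d, 1e-9)
  inv[!conflict] <- 0
  alive <- rep(TRUE, n)
  repeat {
    deg <- rowSums(conflict[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    worst <- which(deg == max(deg))
    if (length(worst) > 1L) {
      crowd <- rowSums(inv[worst, alive, drop = FALSE])
      worst <- worst[crowd == max(crowd)]
      worst <- worst[length(worst)]  # later input position removed first
    }
    alive[worst] <- FALSE
  }
  # repair pass: maximality (earlier records get priority to return)
  for (i in which(!alive)) {
    if (!any(conflict[i, alive])) alive[i] <- TRUE
  }
  occ[alive, ]
}

#' Split occurrences into calibration and evaluation halves
#'
#' Random equal halves; with an odd count the calibration half receives the
#' extra record. Deterministic given `seed`.
#'
#' @param occ occurrence tibble with at least 2 records.
#' @param seed integer seed.
#' @return list with tibbles `calibration` and `evaluation`.
#' @export
split_half <- function(occ, seed = 1L) {
  n <- nrow(occ)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n)
  n_cal <- ceiling(n / 2)
  list(
    calibration = occ[sort(idx[seq_len(n_cal)]), ],
    evaluation = occ[sort(idx[(n_cal + 1L):n]), ]
  )
}

#' Clean occurrences through the standard filter sequence
#'
#' Applies, in order: exclusion list, uncertainty filter, spatial thinning.
#' Returns the cleaned set with a stage-by-stage audit of record counts in
#' the `"audit"` attribute (also printed as a message).
#'
#' @param occ occurrence tibble.
#' @param max_uncertainty_m uncertainty cutoff in meters.
#' @param thin_km minimum separation in km.
#' @param exclude_ids optional `source_id`s to drop first.
#' @param seed passed to [thin_occurrences()].
#' @return cleaned occurrence tibble with attribute `"audit"` (tibble of
#'   stage, n_in, n_out).
#' @export
clean_occurrences <- function(occ, max_uncertainty_m = 10000, thin_km = 50,
                              exclude_ids = character(), seed = 1L) {
  stages <- list()
  n0 <- nrow(occ)
  occ1 <- exclude_records(occ, exclude_ids)
  stages[[1]] <- c("exclusion_list", n0, nrow(occ1))
  occ2 <- filter_uncertainty(occ1, max_uncertainty_m)
  stages[[2]] <- c("uncertainty_filter", nrow(occ1), nrow(occ2))
  occ3 <- thin_occurrences(occ2, thin_km, seed = seed)
  stages[[3]] <- c("spatial_thinning", nrow(occ2), nrow(occ3))
  audit <- tibble::tibble(
    stage = vapply(stages, `[[`, "", 1L),
    n_in = as.integer(vapply(stages, `[[`, "", 2L)),
    n_out = as.integer(vapply(stages, `[[`, "", 3L))
  )
  message(paste(sprintf("%s: %d -> %d", audit$stage, audit$n_in, audit$n_out),
                collapse = "; "))
  attr(occ3, "audit") <- audit
  occ3
}
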