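# Station geometry: geodesic distance matrix, ROM statistics, minimum
# transit time across the array.

#' Build the receiver-distance matrix
#'
#' Pairwise center-to-center geodesic distances (WGS84 ellipsoid) between
#' stations, in meters. Direct ("as the fish swims in a straight line")
#' distances — no routing around obstacles.
#'
#' @param stations data.frame with \code{station_id}, \code{lon}, \code{lat}.
#'   Duplicate deployment rows per station are collapsed; duplicate station
#'   ids with conflicting coordinates are an error.
#' @return symmetric numeric matrix with station ids as dimnames, zero
#'   diagonal, class \code{dist_matrix}.
#' @export
build_distance_matrix <- function(stations) {
  st <- unique(stations[, c("station_id", "lon", "lat")])
  if (anyDuplicated(st$station_id))
    stop("duplicate station_id with conflicting coordinates")
  if (nrow(st) < 1) stop("no stations")
  p <- as.matrix(st[, c("lon", "lat")])
  n <- nrow(st)
  m <- matrix(0, n, n, dimnames = list(st$station_id, st$station_id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      d <- geosphere::distGeo(p[i, , drop = FALSE], p[j, , drop = FALSE])
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  class(m) <- c("dist_matrix", class(m))
  m
}

#' Minimum transit time across the array
#'
#' Time to cross the array at its longest point at a given sustained rate of
#' movement: max(distance matrix) / max_rom, in hours. With the maximum
#' observed ROM this bounds how quickly an individual could traverse the
#' site, which underpins the independence assumption for daily counts.
#'
#' @param dm distance matrix from \code{\link{build_distance_matrix}}, or any
#'   numeric matrix of meters.
#' @param max_rom sustained rate of movement, m/s (> 0).
#' @return hours (numeric scalar, unrounded).
#' @examples
#' m <- matrix(c(0, 40600, 40600, 0), 2)
#' min_transit_time(m, 0.86)  # ~13.1 h
#' @export
min_transit_time <- function(dm, max_rom) {
  if (!length(dm)) stop("empty distance matrix")
  if (!is.numeric(max_rom) || max_rom <= 0) stop("max_rom must be > 0")
  max(dm) / max_rom / 3600
}

#' Summarize rates of movement
#'
#' @param movements movement-event data.frame with a \code{rom} column
#'   (m/s), or a numeric vector of ROM values.
#' @return list with \code{n}, \code{max}, \code{mean}, \code{sd} (sd uses
#'   the n-1 denominator; NA when n < 2).
#' @export
rom_summary <- function(movements) {
  rom <- if (is.data.frame(movements)) movements$rom else movements
  rom <- rom[!is.na(rom)]
  if (!length(rom)) stop("no movement events")
  list(n = length(rom), max = max(rom), mean = mean(rom),
       sd = if (length(rom) > 1) sd(rom) else NA_real_)
}

# median nearest-neighbour spacing of a distance matrix (m)
nn_spacing <- function(dm) {
  if (nrow(dm) < 2) return(NA_real_)
  d <- dm
  diag(d) <- Inf
  median(apply(d, 1, min))
}
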