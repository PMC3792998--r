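#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0 km. Inputs are recycled,
#' so vectors of points can be compared pairwise.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 Coordinates of the second point(s), decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' great_circle_distance(0, 0, 1, 0)  # one degree of longitude at the equator
#' @export
great_circle_distance <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  r <- 6371.0
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * r * asin(sqrt(a))
}

#' Forward azimuth between points
#'
#' Initial bearing of the great circle from point 1 to point 2.
#'
#' @inheritParams great_circle_distance
#' @return Bearing in degrees true, in [0, 360).
#' @export
forward_azimuth <- function(lon1, lat1, lon2, lat2) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  (atan2(y, x) * 180 / pi) %% 360
}

#' Interval kinematics of a classified state series
#'
#' Computes per-interval great-circle distance, elapsed time, speed and
#' heading between consecutive state locations. Each interval inherits the
#' behaviour class of its starting state, so speeds can be pooled by
#' behavioural mode downstream.
#'
#' @param states A `state_series` data frame (see [classify_behaviour()])
#'   with columns `animal_id`, `time`, `lon`, `lat`, `class`.
#' @return A `kinematic_series` data frame with one row per consecutive
#'   state pair: `animal_id`, `t_start`, `t_end`, `distance_km`,
#'   `elapsed_h`, `speed_kmh`, `heading_deg`, `class`.
#' @export
speed_series <- function(states) {
  states <- as.data.frame(states)
  stopifnot(all(c("animal_id", "time", "lon", "lat") %in% names(states)))
  out <- lapply(split(states, states$animal_id), function(s) {
    s <- s[order(s$time), ]
    if (nrow(s) < 2) return(NULL)
    dt_h <- as.numeric(difftime(s$time[-1], s$time[-nrow(s)], units = "hours"))
    if (any(dt_h <= 0)) stop("duplicate or non-increasing grid times", call. = FALSE)
    i <- seq_len(nrow(s) - 1)
    d <- great_circle_distance(s$lon[i], s$lat[i], s$lon[i + 1], s$lat[i + 1])
    data.frame(
      animal_id = s$animal_id[i],
      t_start = s$time[i],
      t_end = s$time[i + 1],
      distance_km = d,
      elapsed_h = dt_h,
      speed_kmh = d / dt_h,
      heading_deg = forward_azimuth(s$lon[i], s$lat[i], s$lon[i + 1], s$lat[i + 1]),
      class = if ("class" %in% names(s)) s$class[i] else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("kinematic_series", "data.frame")
  out
}

#' Turn angles along a state series
#'
#' Signed angle between successive displacement bearings, wrapped to
#' (-pi, pi]. The boundary case of a full reversal maps to +pi. Angles are
#' undefined (NA) where either displacement has zero length.
#'
#' @param states A `state_series` data frame for a single animal (columns
#'   `time`, `lon`, `lat`; a `class` column, if present, is carried through
#'   as the class of the vertex state).
#' @return Data frame with `time` (vertex state), `turn_rad` and `class`.
#' @export
turn_angle_series <- function(states) {
  states <- as.data.frame(states)
  s <- states[order(states$time), ]
  if (nrow(s) < 3) stop("need at least 3 states for turn angles", call. = FALSE)
  n <- nrow(s)
  i <- seq_len(n - 1)
  az <- forward_azimuth(s$lon[i], s$lat[i], s$lon[i + 1], s$lat[i + 1])
  d <- great_circle_distance(s$lon[i], s$lat[i], s$lon[i + 1], s$lat[i + 1])
  v <- 2:(n - 1)                      # vertex states
  # counterclockwise positive (a left turn is positive), hence the sign flip
  # relative to compass azimuths, which grow clockwise
  turn <- wrap_angle((az[v - 1] - az[v]) * pi / 180)
  turn[d[v - 1] == 0 | d[v] == 0] <- NA_real_
  data.frame(
    time = s$time[v],
    turn_rad = turn,
    class = if ("class" %in% names(s)) s$class[v] else NA_character_,
    stringsAsFactors = FALSE
  )
}

# wrap radians to (-pi, pi]; the reversal boundary maps to +pi
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
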