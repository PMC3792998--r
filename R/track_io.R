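#' Read Argos-style observation tables
#'
#' Parses a CSV of satellite uplinks (one row per fix) into a list of
#' per-animal tracks. Rows are deduplicated exactly, sorted by time, and
#' animals with fewer than two usable fixes are skipped with a warning.
#' Where two fixes share a timestamp the first is kept and the rest logged.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named list mapping the canonical column roles
#'   `id`, `date`, `lc`, `lon`, `lat` to column names in the file.
#'   Defaults to those names themselves.
#' @param species Species label attached to every track (`"fin"` or
#'   `"blue"`); tracks for mixed-species files can be relabelled afterwards.
#' @param quiet Suppress the per-track summary messages.
#' @return A list of `whale_track` objects.
#' @export
read_argos_observations <- function(path,
                                    schema = list(id = "id", date = "date",
                                                  lc = "lc", lon = "lon", lat = "lat"),
                                    species = "fin", quiet = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("id", "date", "lc", "lon", "lat")
  for (role in required) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("schema error: required column '", if (is.null(col)) role else col,
           "' (role '", role, "') not present in ", path, call. = FALSE)
    }
  }
  df <- data.frame(
    animal_id = raw[[schema$id]],
    time_str = raw[[schema$date]],
    loc_class = raw[[schema$lc]],
    lon_str = raw[[schema$lon]],
    lat_str = raw[[schema$lat]],
    line = seq_len(nrow(raw)) + 1L,   # header is line 1
    stringsAsFactors = FALSE
  )

  time <- as.POSIXct(df$time_str, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                    "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  lon <- suppressWarnings(as.numeric(df$lon_str))
  lat <- suppressWarnings(as.numeric(df$lat_str))
  bad_time <- is.na(time)
  bad_coord <- is.na(lon) | is.na(lat) | lat < -90 | lat > 90 | lon < -180 | lon >= 180
  bad_class <- !df$loc_class %in% argos_classes()
  bad <- bad_time | bad_coord | bad_class
  if (any(bad)) {
    stop("unparseable row(s) at line(s) ",
         paste(utils::head(df$line[bad], 5), collapse = ", "),
         ": check timestamp/coordinates/location class", call. = FALSE)
  }
  df$time <- time
  df$lon <- lon
  df$lat <- lat

  rows_in <- nrow(df)
  key <- paste(df$animal_id, format(df$time, "%Y-%m-%d %H:%M:%OS3"),
               df$loc_class, df$lon_str, df$lat_str)
  df <- df[!duplicated(key), ]
  # duplicate-time fixes of different class: keep the first, log the rest
  df <- df[order(df$animal_id, df$time, df$line), ]
  dup_t <- duplicated(paste(df$animal_id, format(df$time, "%Y-%m-%d %H:%M:%OS3")))
  if (any(dup_t) && !quiet) {
    message("dropped ", sum(dup_t), " fix(es) sharing a timestamp with an earlier fix")
  }
  df <- df[!dup_t, ]
  rows_kept <- nrow(df)
  if (!quiet) {
    message("read ", path, ": rows_in=", rows_in, " rows_kept=", rows_kept,
            " rows_dropped=", rows_in - rows_kept)
  }

  tracks <- lapply(split(df, df$animal_id), function(a) {
    if (nrow(a) < 2) {
      warning("animal ", a$animal_id[1], " has <2 usable fixes; skipped",
              call. = FALSE)
      return(NULL)
    }
    if (any(a$lon > 170) && any(a$lon < -170)) {
      stop("track ", a$animal_id[1], " appears to cross the antimeridian; ",
           "this longitude convention does not support it", call. = FALSE)
    }
    whale_track(
      animal_id = a$animal_id[1], species = species,
      tag_date = as.Date(a$time[1]),
      observations = data.frame(
        time = a$time, lon = a$lon, lat = a$lat, loc_class = a$loc_class,
        stringsAsFactors = FALSE
      )
    )
  })
  tracks[!vapply(tracks, is.null, logical(1))]
}

#' Construct a whale track object
#'
#' @param animal_id Animal identifier.
#' @param species `"fin"` or `"blue"`.
#' @param tag_date Date of tag deployment.
#' @param observations Data frame with columns `time` (POSIXct UTC), `lon`,
#'   `lat`, `loc_class`.
#' @return A `whale_track`.
#' @export
whale_track <- function(animal_id, species, tag_date, observations) {
  stopifnot(nrow(observations) >= 2,
            all(c("time", "lon", "lat", "loc_class") %in% names(observations)))
  observations <- observations[order(observations$time), ]
  structure(
    list(animal_id = as.character(animal_id), species = species,
         tag_date = as.Date(tag_date), observations = observations),
    class = "whale_track"
  )
}

#' @export
print.whale_track <- function(x, ...) {
  o <- x$observations
  cat("Whale track", x$animal_id, "(", x$species, ") tagged", format(x$tag_date), "\n")
  cat(" ", nrow(o), "fixes,", format(min(o$time)), "to", format(max(o$time)), "\n")
  cat("  classes:", paste(names(table(o$loc_class)), table(o$loc_class),
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}

argos_classes <- function() c("3", "2", "1", "0", "A", "B")

#' Build the regular state-time grid for a track
#'
#' The switching state-space model estimates locations on a regular grid
#' (2 h for fin whales, 4 h for blue whales). Each irregular observation is
#' located within a grid interval `t` with a fractional weight `j` in
#' [0, 1), so that `time = t0 + (t + j) * dt`; the observation model
#' interpolates the bracketing states with weights `(1-j, j)`.
#'
#' @param track A `whale_track`.
#' @param dt_hours Grid spacing in hours (> 0).
#' @return A `regular_grid` list: `t0`, `dt_hours`, `n_states`, and
#'   `obs_index` data frame with integer interval `t` (1-based state index
#'   of the left bracket) and weight `j`.
#' @export
build_time_grid <- function(track, dt_hours) {
  if (!is.numeric(dt_hours) || length(dt_hours) != 1 || dt_hours <= 0) {
    stop("dt_hours must be a positive number", call. = FALSE)
  }
  tm <- track$observations$time
  t0 <- tm[1]
  span_h <- as.numeric(difftime(tm[length(tm)], t0, units = "hours"))
  n_states <- as.integer(ceiling(span_h / dt_hours)) + 1L
  frac <- as.numeric(difftime(tm, t0, units = "hours")) / dt_hours
  t_idx <- pmin(floor(frac), n_states - 2L)  # last obs maps into final interval
  j <- frac - t_idx
  structure(
    list(t0 = t0, dt_hours = dt_hours, n_states = n_states,
         obs_index = data.frame(t = as.integer(t_idx) + 1L, j = j)),
    class = "regular_grid"
  )
}

#' Grid times of a regular grid
#' @param grid A `regular_grid`.
#' @return POSIXct vector of length `n_states`.
#' @export
grid_times <- function(grid) {
  grid$t0 + (seq_len(grid$n_states) - 1) * grid$dt_hours * 3600
}

#' Write a classified state series to disk
#'
#' @param states A `state_series` data frame.
#' @param path Output path.
#' @param format `"csv"` or `"geojson"` (RFC 7946, coordinates in
#'   (lon, lat) order, one Point feature per state).
#' @return `path`, invisibly.
#' @export
write_states <- function(states, path, format = c("csv", "geojson")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown format: use 'csv' or 'geojson'",
                                              call. = FALSE))
  states <- as.data.frame(states)
  if (nrow(states) == 0) stop("empty state series", call. = FALSE)
  if (format == "csv") {
    out <- states
    out$time <- format(out$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    features <- lapply(seq_len(nrow(states)), function(i) {
      s <- states[i, ]
      props <- as.list(s[setdiff(names(s), c("lon", "lat"))])
      props$time <- format(s$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = c(s$lon, s$lat)),
           properties = props)
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a state series written by [write_states()]
#' @param path CSV path.
#' @return A `state_series` data frame.
#' @export
read_states <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$time <- as.POSIXct(df$time, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  df$animal_id <- as.character(df$animal_id)
  class(df) <- c("state_series", "data.frame")
  df
}
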