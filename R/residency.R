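#' Pooled median ARS speed
#'
#' Median speed over all intervals classified as area-restricted search,
#' pooled across the animals of one species. This is the speed threshold
#' the departure rule compares against.
#'
#' @param kinematics A `kinematic_series` (possibly covering many animals)
#'   or a list of them.
#' @return Median ARS speed in km/h.
#' @export
median_ars_speed <- function(kinematics) {
  if (is.data.frame(kinematics)) kinematics <- list(kinematics)
  sp <- unlist(lapply(kinematics, function(k) k$speed_kmh[k$class == "ARS"]))
  sp <- sp[!is.na(sp)]
  if (length(sp) == 0) {
    stop("no ARS-classified intervals: classify states before calling, ",
         "or check the behavioural cut-offs", call. = FALSE)
  }
  stats::median(sp)
}

#' Detect departure from the study area
#'
#' Departure is the start of the earliest run of consecutive intervals
#' whose total elapsed duration reaches `window_h`, with every interval
#' speed strictly above `threshold`. If no such run occurs the animal is
#' censored at the end of its track.
#'
#' @param kinematics A `kinematic_series` for one animal.
#' @param threshold Speed threshold (km/h), typically [median_ars_speed()].
#' @param window_h Minimum sustained duration (h); default 48.
#' @return List with `departed` (logical), `time` (departure time, or track
#'   end if censored).
#' @export
detect_departure <- function(kinematics, threshold, window_h = 48) {
  if (is.null(kinematics) || nrow(kinematics) == 0) {
    stop("empty kinematic series", call. = FALSE)
  }
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  fast <- kinematics$speed_kmh > threshold
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- starts[i]:ends[i]
    if (sum(kinematics$elapsed_h[idx]) >= window_h) {
      return(list(departed = TRUE, time = kinematics$t_start[starts[i]]))
    }
  }
  list(departed = FALSE, time = kinematics$t_end[nrow(kinematics)])
}

#' Build per-animal residency records
#'
#' Applies [detect_departure()] to each animal and assembles residence
#' durations with censoring flags (tags that stopped before departure).
#'
#' @param kinematics A pooled `kinematic_series` with an `animal_id` column.
#' @param threshold Speed threshold (km/h); default the pooled
#'   [median_ars_speed()].
#' @param window_h Sustained-speed window (h).
#' @return A `residency_records` data frame: `animal_id`, `tagging_date`,
#'   `residence_days`, `censored`, `track_days`.
#' @export
residency_records <- function(kinematics, threshold = median_ars_speed(kinematics),
                              window_h = 48) {
  recs <- lapply(split(kinematics, kinematics$animal_id), function(k) {
    k <- k[order(k$t_start), ]
    dep <- detect_departure(k, threshold, window_h)
    t0 <- k$t_start[1]
    data.frame(
      animal_id = k$animal_id[1],
      tagging_date = as.Date(t0),
      residence_days = as.numeric(difftime(dep$time, t0, units = "days")),
      censored = !dep$departed,
      track_days = as.numeric(difftime(k$t_end[nrow(k)], t0, units = "days")),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("residency_records", "data.frame")
  out
}

#' Kaplan-Meier estimate of time to departure
#'
#' Product-limit estimator of the probability of not having departed by a
#' given number of days since tagging, with right censoring for tags that
#' stopped transmitting first. Quartiles are read off as the smallest time
#' at which the survival curve drops to or below 0.75 / 0.5 / 0.25.
#'
#' @param records A `residency_records` data frame (columns
#'   `residence_days`, `censored`).
#' @return A `km_estimate` list: `time`, `surv`, `n_events`, `n_censored`,
#'   `median`, `q25`, `q75` (departure-time quartiles; `NA` if the curve
#'   never reaches the level).
#' @export
kaplan_meier <- function(records) {
  if (nrow(records) < 1) stop("no residency records", call. = FALSE)
  if (any(records$residence_days < 0)) stop("negative durations", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(records$residence_days, !records$censored) ~ 1
  )
  level_time <- function(level) {
    i <- which(fit$surv <= level)
    if (length(i) == 0) NA_real_ else fit$time[min(i)]
  }
  structure(
    list(time = fit$time, surv = fit$surv,
         n_events = sum(!records$censored),
         n_censored = sum(records$censored),
         median = level_time(0.5), q25 = level_time(0.75), q75 = level_time(0.25)),
    class = "km_estimate"
  )
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier departure estimate:", x$n_events, "departures,",
      x$n_censored, "censored\n")
  cat("  quartile departure times (days): 25% =", x$q25, " median =", x$median,
      " 75% =", x$q75, "\n")
  invisible(x)
}

#' Logistic regression of departure probability on days since tagging
#'
#' From the residency records, builds per-day counts of whales still
#' present versus departed among those whose tags were still working on
#' that relative day, and fits a binomial-logit regression of the
#' departure proportion on days since tagging (DST), weighted by the
#' number of whales at risk. Fitting uses iteratively reweighted least
#' squares via [stats::glm()].
#'
#' @param records A `residency_records` data frame.
#' @return List with `slope`, `intercept` (on the departure log-odds
#'   scale), `dst_at_half` (DST at 50% departure probability), and the
#'   per-day table used for the fit.
#' @export
logistic_departure_curve <- function(records) {
  max_day <- ceiling(max(records$track_days))
  tab <- do.call(rbind, lapply(seq_len(max_day), function(d) {
    at_risk <- sum(records$track_days >= d | records$residence_days >= d)
    if (at_risk == 0) return(NULL)
    present <- sum((records$track_days >= d | records$residence_days >= d) &
                     records$residence_days >= d)
    data.frame(dst = d, present = present, departed = at_risk - present,
               at_risk = at_risk)
  }))
  informative <- tab$at_risk > 0
  tab <- tab[informative, ]
  has_both <- any(tab$departed > 0) && any(tab$present > 0)
  if (length(unique(tab$dst)) < 2 || !has_both) {
    stop("need >= 2 distinct DST values with both outcomes represented",
         call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(cbind(departed, present) ~ dst, family = stats::binomial(),
               data = tab)
  )
  co <- stats::coef(fit)
  fitted_p <- stats::fitted(fit)
  degenerate <- all(pmin(fitted_p, 1 - fitted_p) < 1e-6)
  if (any(!is.finite(co)) || any(abs(co) > 30) || degenerate) {
    stop("perfect separation: departure is a step function of DST; ",
         "the logistic curve is not identifiable", call. = FALSE)
  }
  list(slope = unname(co["dst"]), intercept = unname(co["(Intercept)"]),
       dst_at_half = unname(-co["(Intercept)"] / co["dst"]),
       table = tab)
}

#' Extract discrete ARS areas from a classified state series
#'
#' A discrete area-restricted search area is a maximal run of three or
#' more consecutive ARS-classified positions within one animal's track;
#' uncertain or transiting states break a run. Each area is summarised by
#' its minimum convex polygon size, duration and centroid.
#'
#' @param states A `state_series` data frame.
#' @return List of `ars_area` lists: `animal_id`, `idx` (row indices into
#'   the animal's series), `polygon` (hull vertices, lon/lat), `area_km2`,
#'   `duration_h`, `centroid` (lon, lat), `n_positions`.
#' @export
extract_ars_areas <- function(states) {
  states <- as.data.frame(states)
  areas <- list()
  for (s in split(states, states$animal_id)) {
    s <- s[order(s$time), ]
    r <- rle(s$class == "ARS")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in seq_along(r$values)) {
      if (!r$values[i] || r$lengths[i] < 3) next
      idx <- starts[i]:ends[i]
      pts <- cbind(s$lon[idx], s$lat[idx])
      mcp <- mcp_area(pts)
      areas[[length(areas) + 1]] <- structure(
        list(animal_id = s$animal_id[1], idx = idx,
             polygon = attr(mcp, "hull"),
             area_km2 = as.numeric(mcp),
             degenerate = isTRUE(attr(mcp, "degenerate")),
             duration_h = as.numeric(difftime(s$time[max(idx)], s$time[min(idx)],
                                              units = "hours")),
             centroid = c(lon = mean(pts[, 1]), lat = mean(pts[, 2])),
             n_positions = length(idx)),
        class = "ars_area")
    }
  }
  areas
}

#' Minimum convex polygon area of a point set
#'
#' Points are projected with a Lambert azimuthal equal-area projection
#' centred on their centroid, the convex hull is taken in the projected
#' plane, and the polygon area computed by the shoelace formula. Collinear
#' or duplicate-point sets return area 0 with a degeneracy flag.
#'
#' @param points Two-column matrix or data frame of (lon, lat) in degrees.
#' @return Area in km^2, with attributes `hull` (vertex lon/lat matrix)
#'   and `degenerate`.
#' @export
mcp_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need >= 3 points for a polygon", call. = FALSE)
  xy <- laea_project(points[, 1], points[, 2],
                     lon0 = mean(points[, 1]), lat0 = mean(points[, 2]))
  h <- grDevices::chull(xy)
  hull_ll <- points[h, , drop = FALSE]
  if (length(h) < 3) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    attr(out, "hull") <- hull_ll
    return(out)
  }
  x <- xy[h, 1]; y <- xy[h, 2]
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  out <- a
  attr(out, "degenerate") <- a == 0
  attr(out, "hull") <- hull_ll
  out
}

# Lambert azimuthal equal-area projection, km, centred at (lon0, lat0)
laea_project <- function(lon, lat, lon0, lat0) {
  r <- 6371.0
  lam <- (lon - lon0) * pi / 180
  phi <- lat * pi / 180
  phi0 <- lat0 * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  k <- sqrt(2 / denom)
  cbind(x = r * k * cos(phi) * sin(lam),
        y = r * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam)))
}

#' Behaviour time budget
#'
#' Fraction of grid positions in each behavioural class, overall or
#' grouped by calendar day or month (months pooled across years, as
#' multi-year tracking data must be). Each grid position stands for one
#' grid interval of the state time step, so fractions are time fractions.
#'
#' @param states A `state_series` data frame.
#' @param grouping `"overall"`, `"day"` or `"month"`.
#' @return Data frame with `group`, `n`, and columns `transiting`, `ARS`,
#'   `uncertain` summing to 1 within each group.
#' @export
behaviour_time_budget <- function(states, grouping = c("overall", "day", "month")) {
  grouping <- match.arg(grouping)
  states <- as.data.frame(states)
  g <- switch(grouping,
              overall = rep("overall", nrow(states)),
              day = format(states$time, "%Y-%m-%d"),
              month = format(states$time, "%m"))
  parts <- split(states, g)
  out <- do.call(rbind, lapply(names(parts), function(nm) {
    s <- parts[[nm]]
    n <- nrow(s)
    data.frame(group = nm,
               n = n,
               transiting = sum(s$class == "transiting") / n,
               ARS = sum(s$class == "ARS") / n,
               uncertain = sum(s$class == "uncertain") / n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Summary means of a residency table
#'
#' Arithmetic means of residence time and ARS proportion over the animals
#' retained after exclusions (short-duration tracks are conventionally
#' excluded from the means), rounded to one decimal for reporting.
#'
#' @param table Data frame with columns `whale_id`, `residence_days`,
#'   `ars_percent` (ARS proportion on the 0-100 scale; NA allowed).
#' @param exclusions Character vector of `whale_id`s to exclude.
#' @return List `mean_residence_days`, `mean_ars_percent`, `n_included`.
#' @export
summarize_residency <- function(table, exclusions = character()) {
  keep <- !(as.character(table$whale_id) %in% as.character(exclusions))
  t2 <- table[keep, ]
  if (nrow(t2) == 0) stop("all animals excluded", call. = FALSE)
  list(
    mean_residence_days = round(mean(t2$residence_days, na.rm = TRUE), 1),
    mean_ars_percent = round(mean(t2$ars_percent, na.rm = TRUE), 1),
    n_included = nrow(t2)
  )
}

#' Published Azores residency table
#'
#' Per-whale residence times and ARS time proportions for the
#' satellite-tagged Azores fin and blue whales, as published; shipped as a
#' plain-text fixture for the reporting stage. The `short_track` flag
#' marks the two fin whales with 2-3 day tracks that are excluded from
#' reported means.
#'
#' @return Data frame with `species`, `whale_id`, `tagging_date`,
#'   `residence_days`, `ars_percent`, `track_days`, `censored` (tag stopped
#'   before departure), `short_track`.
#' @export
azores_residency_table <- function() {
  path <- system.file("extdata", "azores_residency.csv", package = "whaletrack")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(whale_id = "character"))
  df$tagging_date <- as.Date(df$tagging_date, format = "%d/%m/%Y")
  df$short_track <- as.logical(df$short_track)
  df$censored <- as.logical(df$censored)
  df
}
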