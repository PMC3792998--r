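#' Solar events for a date and position
#'
#' Sunrise, sunset and solar noon from the NOAA solar position algorithm
#' (fractional year, equation of time, solar declination, hour angle at
#' zenith 90.833 degrees). Polar situations are reported through
#' `polar_flag`: `midnight_sun` (sun never sets), `polar_night` (never
#' rises), or `no_full_darkness` when the sun sets but never drops more
#' than 12 degrees below the horizon (no nautical darkness).
#'
#' @param lat,lon Position in decimal degrees (lon positive east).
#' @param date A `Date` (or string coercible to one), the civil UTC date.
#' @return A `solar_events` list: `date`, `lat`, `lon`, `sunrise`,
#'   `sunset`, `solar_noon` (POSIXct UTC; `NA` under polar flags),
#'   `day_length_h`, `min_elevation_deg`, `polar_flag`.
#' @export
solar_events <- function(lat, lon, date) {
  if (abs(lat) > 90 || lon < -180 || lon >= 360) {
    stop("invalid coordinates", call. = FALSE)
  }
  date <- as.Date(date)
  doy <- as.integer(format(date, "%j"))
  # fractional year (radians), evaluated at 12:00
  g <- 2 * pi / 365 * (doy - 1 + (12 - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g)
                      - 0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g)
           - 0.006758 * cos(2 * g) + 0.000907 * sin(2 * g)
           - 0.002697 * cos(3 * g) + 0.00148 * sin(3 * g))
  phi <- lat * pi / 180
  cos_ha <- (cos(90.833 * pi / 180) / (cos(phi) * cos(decl))
             - tan(phi) * tan(decl))
  # solar elevation at local solar midnight (hour angle 180 deg)
  sin_el_min <- sin(phi) * sin(decl) - cos(phi) * cos(decl)
  min_elev <- asin(pmin(pmax(sin_el_min, -1), 1)) * 180 / pi

  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  noon_min <- 720 - 4 * lon - eqtime
  out <- list(date = date, lat = lat, lon = lon,
              sunrise = NA, sunset = NA,
              solar_noon = midnight + noon_min * 60,
              day_length_h = NA_real_,
              min_elevation_deg = min_elev,
              polar_flag = "none")
  if (cos_ha < -1) {
    out$polar_flag <- "midnight_sun"
    out$day_length_h <- 24
  } else if (cos_ha > 1) {
    out$polar_flag <- "polar_night"
    out$day_length_h <- 0
  } else {
    ha_deg <- acos(cos_ha) * 180 / pi
    out$sunrise <- midnight + (720 - 4 * (lon + ha_deg) - eqtime) * 60
    out$sunset <- midnight + (720 - 4 * (lon - ha_deg) - eqtime) * 60
    out$day_length_h <- 8 * ha_deg / 60
    if (min_elev > -12) out$polar_flag <- "no_full_darkness"
  }
  class(out) <- "solar_events"
  out
}

#' @export
print.solar_events <- function(x, ...) {
  cat("Solar events", format(x$date), "at", x$lat, "N", x$lon, "E:\n")
  cat("  sunrise", format(x$sunrise, "%H:%M UTC"),
      " noon", format(x$solar_noon, "%H:%M UTC"),
      " sunset", format(x$sunset, "%H:%M UTC"),
      " day length", round(x$day_length_h, 2), "h\n")
  if (x$polar_flag != "none") cat("  flag:", x$polar_flag, "\n")
  invisible(x)
}

#' Solar-local hour of day
#'
#' Hour used for diel binning: UTC hour shifted by longitude (15 degrees
#' per hour), so that 12 is approximately local solar noon wherever the
#' animal is.
#'
#' @param time POSIXct (UTC).
#' @param lon Longitude in degrees east.
#' @return Numeric hour in [0, 24).
#' @export
solar_hour <- function(time, lon) {
  h <- as.numeric(format(time, "%H")) + as.numeric(format(time, "%M")) / 60 +
    as.numeric(format(time, "%S")) / 3600
  (h + lon / 15) %% 24
}

harmonic_design <- function(hours, n_harmonics) {
  X <- matrix(1, length(hours), 1)
  colnames(X) <- "intercept"
  for (k in seq_len(n_harmonics)) {
    X <- cbind(X, sin(2 * pi * k * hours / 24), cos(2 * pi * k * hours / 24))
    colnames(X)[ncol(X) - 1:0] <- paste0(c("sin", "cos"), k)
  }
  X
}

#' Cyclic-harmonic diel profile of a response
#'
#' Least-squares regression of a response on sine/cosine harmonics of the
#' 24 h cycle (default two harmonics), a transparent stand-in for a cyclic
#' smoother. The fitted profile is 24 h-periodic by construction.
#'
#' @param hours Numeric hours of day in [0, 24).
#' @param responses Numeric response (e.g. speed in km/h).
#' @param n_harmonics Number of harmonics (0 gives the sample mean).
#' @return A `diel_profile` list: `hour` (0..24), `fit`, `se`,
#'   `coefficients`, `n`, `scale = "identity"`.
#' @export
diel_profile <- function(hours, responses, n_harmonics = 2) {
  stopifnot(length(hours) == length(responses))
  ok <- is.finite(hours) & is.finite(responses)
  hours <- hours[ok] %% 24
  responses <- responses[ok]
  if (length(hours) < 4 * max(n_harmonics, 1)) {
    stop("too few observations for ", n_harmonics, " harmonic(s)", call. = FALSE)
  }
  X <- harmonic_design(hours, n_harmonics)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: hours do not span the daily cycle", call. = FALSE)
  }
  fit <- stats::lm.fit(X, responses)
  sigma2 <- sum(fit$residuals^2) / max(1, length(responses) - ncol(X))
  XtXi <- chol2inv(chol(crossprod(X)))
  hgrid <- 0:24
  Xg <- harmonic_design(hgrid, n_harmonics)
  pred <- drop(Xg %*% fit$coefficients)
  se <- sqrt(pmax(0, rowSums((Xg %*% XtXi) * Xg) * sigma2))
  structure(list(hour = hgrid, fit = pred, se = se,
                 coefficients = fit$coefficients, n = length(responses),
                 scale = "identity"),
            class = "diel_profile")
}

#' Diel profile of ARS occurrence probability
#'
#' Binomial-logit regression (IRLS via [stats::glm()]) of the ARS
#' indicator on cyclic harmonics of the solar-local hour; uncertain states
#' are excluded. Predictions are mapped through the inverse logit, so the
#' profile lives on the probability scale.
#'
#' @param states A classified `state_series`.
#' @param n_harmonics Number of harmonics (default 2).
#' @return A `diel_profile` with `scale = "probability"`.
#' @export
hourly_ars_probability <- function(states, n_harmonics = 2) {
  states <- as.data.frame(states)
  s <- states[states$class != "uncertain", ]
  yy <- as.integer(s$class == "ARS")
  if (length(unique(yy)) < 2) {
    stop("need both ARS and non-ARS states to fit an occurrence profile",
         call. = FALSE)
  }
  hours <- solar_hour(s$time, s$lon)
  X <- harmonic_design(hours, n_harmonics)
  df <- as.data.frame(X[, -1, drop = FALSE])
  df$y <- yy
  fit <- stats::glm(y ~ ., family = stats::binomial(), data = df)
  hgrid <- 0:24
  Xg <- harmonic_design(hgrid, n_harmonics)
  dg <- as.data.frame(Xg[, -1, drop = FALSE])
  pr <- stats::predict(fit, newdata = dg, type = "link", se.fit = TRUE)
  inv <- stats::plogis
  structure(list(hour = hgrid, fit = inv(pr$fit), se = pr$se.fit,
                 fit_lo = inv(pr$fit - 2 * pr$se.fit),
                 fit_hi = inv(pr$fit + 2 * pr$se.fit),
                 coefficients = stats::coef(fit), n = nrow(s),
                 scale = "probability"),
            class = "diel_profile")
}

#' @export
print.diel_profile <- function(x, ...) {
  cat("Diel profile (", x$scale, " scale, n = ", x$n, ")\n", sep = "")
  pk <- x$hour[which.max(x$fit)]
  cat("  range", round(min(x$fit), 3), "-", round(max(x$fit), 3),
      "; maximum near hour", pk, "\n")
  invisible(x)
}

#' Permutation test of homogeneity of circular means across groups
#'
#' Tests whether groups of angles (e.g. turn angles by geographic area or
#' by hour block) share a common mean direction. The statistic is the
#' excess of summed per-group resultant lengths over the pooled resultant
#' length, which grows when group mean directions diverge; its null
#' distribution is built by randomly relabelling angles.
#'
#' @param angles_by_group Named list of numeric angle vectors (radians).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the relabelling.
#' @return List with `statistic`, `p_value`, `n_perm`.
#' @export
circular_homogeneity_test <- function(angles_by_group, n_perm = 999, seed = 1L) {
  if (length(angles_by_group) < 2) stop("need >= 2 groups", call. = FALSE)
  sizes <- lengths(angles_by_group)
  if (any(sizes < 5)) stop("each group needs >= 5 angles", call. = FALSE)
  pooled <- unlist(angles_by_group, use.names = FALSE)
  labels <- rep(seq_along(sizes), sizes)
  stat <- function(a, lab) {
    per_group <- vapply(split(a, lab), function(g) {
      sqrt(sum(cos(g))^2 + sum(sin(g))^2)
    }, numeric(1))
    total <- sqrt(sum(cos(a))^2 + sum(sin(a))^2)
    sum(per_group) - total
  }
  obs <- stat(pooled, labels)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    stat(pooled, sample(labels))
  }, numeric(1))
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1),
       n_perm = n_perm)
}
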