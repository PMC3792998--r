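#' Simulation configuration for synthetic whale tracks
#'
#' Builds the configuration for the two-regime track simulator. The
#' defaults (and the two presets) emulate the tagging-study regimes the
#' package is designed around: fin-whale-like tracks on a 2 h grid with
#' around a dozen Argos fixes per day, and blue-whale-like tracks on a
#' 4 h grid with sparser uplinks, both started at the Azores tagging
#' grounds (38 N, 28 W).
#'
#' @param preset `"fin_2009_2012"` or `"blue_2009_2011"`, or `NULL` to use
#'   the explicit arguments as given.
#' @param n_animals Number of simulated animals.
#' @param duration_days Track length in days.
#' @param dt_hours Process time step (h).
#' @param params True `movement_params` driving the simulation.
#' @param error_model `argos_error_model` used to corrupt the fixes.
#' @param fixes_per_day Mean Argos uplink rate (Poisson process).
#' @param class_freq Named probabilities over the six location classes.
#' @param start_lon,start_lat Release position (decimal degrees).
#' @param start_date First timestamp (UTC).
#' @param speed0_deg Magnitude of the initial displacement (degrees per
#'   step); sets the scale the persistent regime cruises at.
#' @param start_state Behavioural state at the first step: 1 (transiting,
#'   the default), 2 (ARS), or `"random"`.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(preset = NULL,
                       n_animals = 8, duration_days = 30, dt_hours = 2,
                       params = movement_params(
                         theta = c(0, pi), gamma = c(0.9, 0.3),
                         Sigma = diag(0.025^2, 2), alpha = c(0.95, 0.1)),
                       error_model = argos_error_model(),
                       fixes_per_day = 12,
                       class_freq = c("3" = 0.05, "2" = 0.10, "1" = 0.15,
                                      "0" = 0.15, "A" = 0.25, "B" = 0.30),
                       start_lon = -28, start_lat = 38,
                       start_date = as.POSIXct("2012-04-15 00:00:00", tz = "UTC"),
                       speed0_deg = 0.1,
                       start_state = 1,
                       seed) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("fin_2009_2012", "blue_2009_2011"))
    if (preset == "blue_2009_2011") {
      dt_hours <- 4; fixes_per_day <- 7; duration_days <- 45; n_animals <- 3
    }
  }
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_animals >= 1, duration_days > 0, dt_hours > 0, fixes_per_day > 0)
  class_freq <- class_freq[argos_classes()]
  if (abs(sum(class_freq) - 1) > 1e-8) {
    stop("class frequencies must sum to 1", call. = FALSE)
  }
  structure(
    list(preset = preset, n_animals = n_animals, duration_days = duration_days,
         dt_hours = dt_hours, params = params, error_model = error_model,
         fixes_per_day = fixes_per_day, class_freq = class_freq,
         start_lon = start_lon, start_lat = start_lat, start_date = start_date,
         speed0_deg = speed0_deg, start_state = start_state,
         seed = as.integer(seed),
         species = if (identical(preset, "blue_2009_2011")) "blue" else "fin"),
    class = "sim_config"
  )
}

#' Simulate true two-regime tracks
#'
#' Generates, per animal, a behaviour sequence from the first-order Markov
#' chain with switching probabilities `alpha`, then displacement vectors
#' from the first-difference correlated random walk
#' `d_t = gamma[b] * T(theta[b]) %*% d_{t-1} + N2(0, Sigma)`, and positions
#' by cumulative summation from the start point. Fully reproducible given
#' the configured seed.
#'
#' @param config A `sim_config`.
#' @return List of per-animal data frames (`time`, `lon`, `lat`, `b`) with
#'   attributes `config`.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  S <- p$Sigma
  ev <- eigen(S, symmetric = TRUE)
  if (any(ev$values < 0)) stop("degenerate process covariance", call. = FALSE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) # Sigma^(1/2)
  n_steps <- as.integer(ceiling(config$duration_days * 24 / config$dt_hours))
  set.seed(config$seed)
  out <- lapply(seq_len(config$n_animals), function(k) {
    b <- integer(n_steps)
    b[1] <- if (identical(config$start_state, "random")) sample(1:2, 1) else
      as.integer(config$start_state)
    for (t in 2:n_steps) {
      p1 <- p$alpha[b[t - 1]]
      b[t] <- if (stats::runif(1) < p1) 1L else 2L
    }
    d <- matrix(0, n_steps, 2)
    ang0 <- stats::runif(1, 0, 2 * pi)
    d[1, ] <- config$speed0_deg * c(cos(ang0), sin(ang0))
    noise <- matrix(stats::rnorm(2 * n_steps), ncol = 2) %*% t(A)
    for (t in 2:n_steps) {
      d[t, ] <- p$gamma[b[t]] * (rotation_matrix(p$theta[b[t]]) %*% d[t - 1, ]) +
        noise[t, ]
    }
    pos <- apply(d, 2, cumsum)
    pos <- rbind(c(0, 0), pos)
    data.frame(
      animal_id = sprintf("sim%02d", k),
      time = config$start_date + (0:n_steps) * config$dt_hours * 3600,
      lon = config$start_lon + pos[, 1],
      lat = config$start_lat + pos[, 2],
      b = c(b[1], b),   # state i carries the behaviour of the step ending at i
      stringsAsFactors = FALSE
    )
  })
  attr(out, "config") <- config
  out
}

#' Observe true tracks through an Argos-like sensor
#'
#' Draws uplink times from a homogeneous Poisson process (exponential
#' inter-fix gaps at the configured rate), samples a location class per fix
#' from the class-frequency table, interpolates the true path linearly to
#' the fix times and adds independent scaled-t noise in longitude and
#' latitude with that class's `(nu, tau)`.
#'
#' @param true_tracks Output of [simulate_tracks()].
#' @param config The same `sim_config`.
#' @return List of `whale_track` objects.
#' @export
observe_tracks <- function(true_tracks, config) {
  stopifnot(inherits(config, "sim_config"))
  em <- config$error_model
  rate_h <- config$fixes_per_day / 24
  set.seed(config$seed + 1L)
  tracks <- lapply(true_tracks, function(tt) {
    span_h <- as.numeric(difftime(max(tt$time), min(tt$time), units = "hours"))
    for (attempt in 1:20) {
      gaps <- stats::rexp(ceiling(span_h * rate_h * 2) + 20, rate_h)
      t_h <- cumsum(gaps)
      t_h <- t_h[t_h < span_h]
      if (length(t_h) >= 2) break
    }
    if (length(t_h) < 2) {
      warning("animal ", tt$animal_id[1], " drew <2 observations; skipped",
              call. = FALSE)
      return(NULL)
    }
    t_h <- c(0, t_h)  # a fix at release anchors the grid origin
    obs_time <- min(tt$time) + t_h * 3600
    base_h <- as.numeric(difftime(tt$time, min(tt$time), units = "hours"))
    lon_true <- stats::approx(base_h, tt$lon, xout = t_h)$y
    lat_true <- stats::approx(base_h, tt$lat, xout = t_h)$y
    cls <- sample(names(config$class_freq), length(t_h), replace = TRUE,
                  prob = config$class_freq)
    pe <- em[cls, ]
    whale_track(
      animal_id = tt$animal_id[1], species = config$species,
      tag_date = as.Date(min(tt$time)),
      observations = data.frame(
        time = obs_time,
        lon = lon_true + stats::rt(length(t_h), pe$nu) * pe$tau_lon,
        lat = lat_true + stats::rt(length(t_h), pe$nu) * pe$tau_lat,
        loc_class = cls,
        stringsAsFactors = FALSE
      )
    )
  })
  tracks[!vapply(tracks, is.null, logical(1))]
}

#' Write tracks in the Argos CSV schema
#'
#' Writes one row per fix with columns `id,date,lc,lon,lat`, the schema
#' [read_argos_observations()] reads back.
#'
#' @param tracks List of `whale_track` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_argos_observations <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(id = tr$animal_id,
               date = format(tr$observations$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               lc = tr$observations$loc_class,
               lon = sprintf("%.8f", tr$observations$lon),
               lat = sprintf("%.8f", tr$observations$lat),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' True state series of a simulated track
#'
#' Reshapes simulator output into the `state_series` layout (with perfect
#' knowledge: `b_mean` is the true behaviour), for decoding-accuracy
#' comparisons against fitted classifications.
#'
#' @param true_tracks Output of [simulate_tracks()].
#' @return A `state_series` data frame with a `b_true` column.
#' @export
truth_states <- function(true_tracks) {
  out <- do.call(rbind, lapply(true_tracks, function(tt) {
    data.frame(animal_id = tt$animal_id, time = tt$time,
               lon = tt$lon, lat = tt$lat,
               b_mean = as.numeric(tt$b), b_true = tt$b,
               class = classify_b(as.numeric(tt$b)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("state_series", "data.frame")
  out
}
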