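# shared fixtures, built in code

# a minimal classified state series on a regular 2 h grid
make_states <- function(classes, lon = NULL, lat = NULL, animal_id = "w1",
                        t0 = as.POSIXct("2012-04-15 00:00:00", tz = "UTC"),
                        dt_hours = 2) {
  n <- length(classes)
  df <- data.frame(
    animal_id = animal_id,
    time = t0 + (seq_len(n) - 1) * dt_hours * 3600,
    lon = if (is.null(lon)) seq(0, by = 0.1, length.out = n) else lon,
    lat = if (is.null(lat)) rep(0, n) else lat,
    b_mean = ifelse(classes == "transiting", 1, ifelse(classes == "ARS", 2, 1.5)),
    class = classes,
    stringsAsFactors = FALSE
  )
  class(df) <- c("state_series", "data.frame")
  df
}

# kinematics with prescribed speeds on a regular grid (km/h, 2 h steps)
make_kinematics <- function(speeds, classes = rep("transiting", length(speeds)),
                            dt_hours = 2, animal_id = "w1",
                            t0 = as.POSIXct("2012-04-15 00:00:00", tz = "UTC")) {
  n <- length(speeds)
  df <- data.frame(
    animal_id = animal_id,
    t_start = t0 + (seq_len(n) - 1) * dt_hours * 3600,
    t_end = t0 + seq_len(n) * dt_hours * 3600,
    distance_km = speeds * dt_hours,
    elapsed_h = dt_hours,
    speed_kmh = speeds,
    heading_deg = 90,
    class = classes,
    stringsAsFactors = FALSE
  )
  class(df) <- c("kinematic_series", "data.frame")
  df
}

# residency records from explicit durations
make_records <- function(durations, censored) {
  data.frame(
    animal_id = sprintf("w%02d", seq_along(durations)),
    tagging_date = as.Date("2012-04-15"),
    residence_days = durations,
    censored = censored,
    track_days = ifelse(censored, durations, durations + 5),
    stringsAsFactors = FALSE
  )
}

# fake two-chain fit carrying given parameter samples (for R-hat tests)
make_fake_fit <- function(chain_samples) {
  structure(
    list(chains = lapply(chain_samples, function(m) list(params = m)),
         param_names = colnames(chain_samples[[1]])),
    class = "hssm_fit"
  )
}

# smallest-time quantile of a credible interval on the circle: rotate
# samples so the target is at 0, then check central coverage
circular_covered <- function(samples, truth, level = 0.95) {
  d <- atan2(sin(samples - truth), cos(samples - truth))
  q <- stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2))
  q[1] <= 0 && q[2] >= 0
}
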