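test_that("solar events reproduce equinox, midnight sun and rotation shifts", {
  eq <- solar_events(0, 0, "2012-03-20")          # March equinox at (0, 0)
  expect_equal(eq$day_length_h, 12, tolerance = 10 / 60)
  noon_h <- as.numeric(difftime(eq$solar_noon,
                                as.POSIXct("2012-03-20 00:00:00", tz = "UTC"),
                                units = "hours"))
  expect_equal(noon_h, 12, tolerance = 20 / 60)

  expect_equal(solar_events(70, 0, "2012-06-21")$polar_flag, "midnight_sun")
  expect_equal(solar_events(70, 0, "2012-12-21")$polar_flag, "polar_night")

  # 15 degrees west shifts solar noon one hour later
  a <- solar_events(40, 0, "2012-05-01")
  b <- solar_events(40, -15, "2012-05-01")
  expect_equal(as.numeric(difftime(b$solar_noon, a$solar_noon, units = "hours")),
               1, tolerance = 1e-6)

  # on a June date, day length grows with latitude up to the midnight sun
  lens <- vapply(c(0, 20, 40, 55, 64), function(la) {
    solar_events(la, -25, "2012-06-10")$day_length_h
  }, numeric(1))
  expect_true(all(diff(lens) > 0))

  # high-latitude June night never gets fully dark (sun above -12 degrees)
  rockall <- solar_events(57.5, -14, "2012-06-21")
  expect_equal(rockall$polar_flag, "no_full_darkness")
  expect_gt(rockall$min_elevation_deg, -12)
})

test_that("harmonic regression is exact on planted cycles and periodic", {
  h <- rep(seq(0, 23.5, by = 0.5), 3)
  const <- diel_profile(h, rep(4.2, length(h)), n_harmonics = 2)
  expect_equal(const$fit, rep(4.2, 25), tolerance = 1e-10)
  expect_equal(max(abs(const$coefficients[-1])), 0, tolerance = 1e-10)

  y <- 3 + sin(2 * pi * h / 24)
  fit <- diel_profile(h, y, n_harmonics = 2)
  expect_equal(unname(fit$coefficients["intercept"]), 3, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["sin1"]), 1, tolerance = 1e-8)
  expect_equal(max(abs(fit$fit - (3 + sin(2 * pi * (0:24) / 24)))), 0,
               tolerance = 1e-8)
  expect_equal(fit$fit[1], fit$fit[25])            # 24 h periodicity

  # zero harmonics: the sample mean everywhere
  m0 <- diel_profile(h, y, n_harmonics = 0)
  expect_equal(m0$fit, rep(mean(y), 25))

  expect_error(diel_profile(rep(6, 50), rnorm(50), 2), "rank")
})

test_that("ARS occurrence profile behaves on flat and windowed regimes", {
  t0 <- as.POSIXct("2012-04-15 00:00:00", tz = "UTC")
  n <- 960
  hours <- (seq_len(n) - 1) %% 24
  st <- make_states(rep("transiting", n), lon = rep(0, n), lat = rep(40, n))
  st$time <- t0 + (seq_len(n) - 1) * 3600

  # 50/50 uniformly over hours: flat profile at 0.5
  st$class <- rep(c("ARS", "transiting"), n / 2)
  flat <- hourly_ars_probability(st)
  expect_equal(max(abs(flat$fit - 0.5)), 0, tolerance = 0.05)
  expect_equal(max(abs(flat$coefficients[-1])), 0, tolerance = 0.15)

  # ARS concentrated between 20:00 and 04:00: the peak falls in the window
  set.seed(12)
  in_window <- hours >= 20 | hours < 4
  st$class <- ifelse(runif(n) < ifelse(in_window, 0.85, 0.15),
                     "ARS", "transiting")
  night <- hourly_ars_probability(st)
  peak <- night$hour[which.max(night$fit)]
  expect_true(peak >= 20 || peak <= 4)
  expect_true(all(night$fit > 0 & night$fit < 1))

  st$class <- rep("ARS", n)
  expect_error(hourly_ars_probability(st), "both")
})

test_that("logit IRLS for the occurrence profile matches a grid-search oracle", {
  set.seed(4)
  n <- 300
  hours <- runif(n, 0, 24)
  p_true <- plogis(-0.4 + 1.2 * sin(2 * pi * hours / 24))
  y <- rbinom(n, 1, p_true)
  st <- make_states(rep("transiting", n), lon = rep(0, n), lat = rep(40, n))
  st$time <- as.POSIXct("2012-04-15 00:00:00", tz = "UTC") + hours * 3600
  st$class <- ifelse(y == 1, "ARS", "transiting")
  fit <- hourly_ars_probability(st, n_harmonics = 1)

  hh <- solar_hour(st$time, st$lon)
  nll <- function(b) {
    eta <- b[1] + b[2] * sin(2 * pi * hh / 24) + b[3] * cos(2 * pi * hh / 24)
    -sum(y * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0, 0); width <- c(4, 4, 4)
  for (pass in 1:30) {
    grids <- lapply(1:3, function(i) seq(centre[i] - width[i], centre[i] + width[i],
                                         length.out = 13))
    best <- NULL; best_v <- Inf
    for (a in grids[[1]]) for (b in grids[[2]]) for (cc in grids[[3]]) {
      v <- nll(c(a, b, cc))
      if (v < best_v) { best_v <- v; best <- c(a, b, cc) }
    }
    centre <- best; width <- width / 3
  }
  expect_equal(unname(fit$coefficients), centre, tolerance = 1e-4)
})

test_that("circular homogeneity permutation test behaves at the extremes", {
  set.seed(6)
  # identical data in both groups: every permutation ties, p = 1
  a <- rep(c(0.1, 0.2, 0.3, 0.4, 0.5), 2)
  same <- circular_homogeneity_test(list(g1 = a, g2 = a), n_perm = 99, seed = 2)
  expect_equal(same$p_value, 1)

  # opposite concentrations: maximal separation
  g1 <- rnorm(30, 0, 0.05); g2 <- rnorm(30, pi, 0.05)
  opp <- circular_homogeneity_test(list(g1 = g1, g2 = g2), n_perm = 999, seed = 3)
  expect_lte(opp$p_value, 2 / 1000)

  expect_error(circular_homogeneity_test(list(g1 = 1:10)), "2 groups")
  expect_error(circular_homogeneity_test(list(g1 = 1:10, g2 = 1:3)), ">= 5")
})
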