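test_that("process log likelihood matches an independent Gaussian oracle", {
  # brute-force bivariate normal density via solve()/determinant()
  oracle <- function(d_prev, d_curr, b, p) {
    R <- matrix(c(cos(p$theta[b]), sin(p$theta[b]),
                  -sin(p$theta[b]), cos(p$theta[b])), 2, 2)
    r <- d_curr - p$gamma[b] * as.numeric(R %*% d_prev)
    -log(2 * pi) - 0.5 * as.numeric(determinant(p$Sigma)$modulus) -
      0.5 * as.numeric(t(r) %*% solve(p$Sigma) %*% r)
  }
  set.seed(42)
  for (i in 1:100) {
    sd1 <- runif(1, 0.01, 0.2); sd2 <- runif(1, 0.01, 0.2)
    rho <- runif(1, -0.9, 0.9)
    p <- movement_params(
      theta = c(runif(1, -pi / 4, pi / 4), runif(1, -pi, pi)),
      gamma = sort(runif(2), decreasing = TRUE) * c(1, 0.99),
      Sigma = matrix(c(sd1^2, rho * sd1 * sd2, rho * sd1 * sd2, sd2^2), 2, 2))
    d1 <- rnorm(2, 0, 0.1); d2 <- rnorm(2, 0, 0.1)
    b <- sample(1:2, 1)
    expect_equal(process_loglik(d1, d2, b, p), oracle(d1, d2, b, p),
                 tolerance = 1e-10)
  }
})

test_that("process model mode and rotation identities hold", {
  p <- movement_params(theta = c(0, pi), gamma = c(1, 0.3),
                       Sigma = diag(0.01, 2))
  d <- c(0.1, -0.05)
  # gamma = 1, theta = 0, d_prev = d_curr: zero residual, density at the mode
  at_mode <- -log(2 * pi) - 0.5 * log(det(diag(0.01, 2)))
  expect_equal(process_loglik(d, d, 1, p), at_mode)
  # theta = pi flips the sign of the conditional mean
  expect_equal(process_loglik(d, -0.3 * d, 2, p), at_mode)
  p_bad <- p
  p_bad$Sigma <- matrix(0, 2, 2)
  expect_error(process_loglik(d, d, 1, p_bad), "singular")
})

test_that("observation likelihood interpolates, ranks classes, honours j = 0", {
  em <- argos_error_model()
  y <- list(lon = 0.05, lat = 38.02, loc_class = "3")
  x_t <- c(0, 38); x_next <- c(0.1, 38.04)
  # fix exactly at the interpolated position: both t terms at their mode
  mode_ll <- dt(0, em["3", "nu"], log = TRUE) - log(em["3", "tau_lon"]) +
    dt(0, em["3", "nu"], log = TRUE) - log(em["3", "tau_lat"])
  expect_equal(observation_loglik(x_t, x_next, 0.5, y, em), mode_ll)

  # class B is flatter than class 3 at the same small nonzero residual
  # (within both scales), because tau_B > tau_3 spreads its density
  y_off3 <- list(lon = 0.001, lat = 38, loc_class = "3")
  y_offB <- list(lon = 0.001, lat = 38, loc_class = "B")
  expect_lt(observation_loglik(x_t, x_next, 0, y_offB, em),
            observation_loglik(x_t, x_next, 0, y_off3, em))

  # with j = 0 the right bracket has no influence
  expect_equal(observation_loglik(x_t, x_next, 0, y, em),
               observation_loglik(x_t, c(50, -10), 0, y, em))
  expect_error(observation_loglik(x_t, x_next, 0, list(lon = 0, lat = 0, loc_class = "G"), em),
               "missing")
})

test_that("behavioural index cut-offs classify as transiting/uncertain/ARS", {
  expect_equal(classify_b(c(1, 1.10, 1.2499)), rep("transiting", 3))
  expect_equal(classify_b(c(1.25, 1.5, 1.75)), rep("uncertain", 3))
  expect_equal(classify_b(c(1.7501, 1.90, 2)), rep("ARS", 3))
})

test_that("classification averages behaviour samples per grid time", {
  t0 <- as.POSIXct("2012-04-15 00:00:00", tz = "UTC")
  grid <- structure(list(t0 = t0, dt_hours = 2, n_states = 3L), class = "regular_grid")
  mk_chain <- function(bvals) {
    list(params = matrix(0, 2, 9),
         x = list(matrix(0, nrow(bvals), 6)),
         b = list(bvals))
  }
  fit <- structure(list(
    chains = list(mk_chain(matrix(1L, 2, 3)), mk_chain(matrix(2L, 2, 3))),
    animal_ids = "w1", grids = list(grid), dt_hours = 2,
    param_names = paste0("p", 1:9)), class = "hssm_fit")
  st <- classify_behaviour(fit)
  expect_equal(st$b_mean, rep(1.5, 3))          # half 1, half 2
  expect_equal(st$class, rep("uncertain", 3))
  fit$chains <- list(mk_chain(matrix(1L, 4, 3)))
  expect_equal(classify_behaviour(fit)$class, rep("transiting", 3))
  fit$chains <- list(mk_chain(matrix(2L, 4, 3)))
  expect_equal(classify_behaviour(fit)$class, rep("ARS", 3))
})

test_that("Gelman-Rubin diagnostic separates mixed from divergent chains", {
  m <- function(v) matrix(v, ncol = 1, dimnames = list(NULL, "gamma1"))
  identical_chains <- make_fake_fit(list(m(rep(0.7, 100)), m(rep(0.7, 100))))
  expect_equal(unname(gelman_rubin(identical_chains)), 1.0)

  set.seed(1)
  iid <- make_fake_fit(list(m(rnorm(5000)), m(rnorm(5000))))
  expect_lt(gelman_rubin(iid)["gamma1"], 1.05)

  apart <- make_fake_fit(list(m(rnorm(5000)), m(rnorm(5000, 10))))
  expect_gt(gelman_rubin(apart)["gamma1"], 2)

  one <- make_fake_fit(list(m(rnorm(10))))
  expect_error(gelman_rubin(one), "2 chains")
})

test_that("behaviour samples stay in {1,2} and fits are seed-reproducible", {
  cfg <- sim_config(n_animals = 1, duration_days = 6, seed = 9)
  tracks <- observe_tracks(simulate_tracks(cfg), cfg)
  mc <- list(n_chains = 2, n_iter = 600, burn_in = 400, thin = 2)
  fit1 <- fit_hssm(tracks, 2, mcmc = mc, seed = 21)
  fit2 <- fit_hssm(tracks, 2, mcmc = mc, seed = 21)
  for (ch in fit1$chains) expect_true(all(ch$b[[1]] %in% 1:2))
  st1 <- classify_behaviour(fit1)
  st2 <- classify_behaviour(fit2)
  expect_identical(st1, st2)
  expect_true(all(st1$b_mean >= 1 & st1$b_mean <= 2))
})
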