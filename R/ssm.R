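#' Movement parameters of the two-state switching model
#'
#' The process model is a first-difference correlated random walk on
#' displacement vectors: `d_t = gamma[b] * T(theta[b]) %*% d_{t-1} + e_t`,
#' `e_t ~ N2(0, Sigma)`, with turn angle `theta` and move persistence
#' `gamma` indexed by the behavioural state `b` (1 = transiting, 2 = ARS).
#' Behaviour evolves as a first-order Markov chain with switching
#' probabilities `alpha = (P(b_t=1 | b_{t-1}=1), P(b_t=1 | b_{t-1}=2))`.
#'
#' @param theta Length-2 mean turn angles (radians), transiting first.
#' @param gamma Length-2 move persistence in [0, 1]; `gamma[1] > gamma[2]`
#'   (transiting is the more persistent state).
#' @param Sigma 2x2 positive-definite process covariance (degrees^2).
#' @param alpha Length-2 switching probabilities in (0, 1).
#' @return A validated `movement_params` list.
#' @export
movement_params <- function(theta, gamma, Sigma, alpha = c(0.9, 0.1)) {
  stopifnot(length(theta) == 2, length(gamma) == 2, length(alpha) == 2)
  if (!all(gamma >= 0 & gamma <= 1)) stop("gamma must lie in [0, 1]", call. = FALSE)
  if (gamma[1] <= gamma[2]) {
    stop("gamma[1] (transiting) must exceed gamma[2] (ARS)", call. = FALSE)
  }
  if (!all(alpha > 0 & alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  Sigma <- as.matrix(Sigma)
  if (!isTRUE(all.equal(Sigma, t(Sigma))) || any(eigen(Sigma, only.values = TRUE)$values <= 0)) {
    stop("Sigma must be symmetric positive-definite", call. = FALSE)
  }
  structure(list(theta = theta, gamma = gamma, Sigma = Sigma, alpha = alpha),
            class = "movement_params")
}

rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Process-model log likelihood of one displacement
#'
#' Bivariate normal log density of the current displacement given the
#' previous one under the state-`b` correlated random walk:
#' mean `gamma[b] * T(theta[b]) %*% d_prev`, covariance `Sigma`.
#'
#' @param d_prev,d_curr Length-2 displacement vectors (degrees lon, lat).
#' @param b Behavioural state, 1 or 2.
#' @param params A `movement_params`.
#' @return Log density (scalar).
#' @export
process_loglik <- function(d_prev, d_curr, b, params) {
  stopifnot(b %in% c(1, 2))
  mu <- params$gamma[b] * (rotation_matrix(params$theta[b]) %*% d_prev)
  S <- params$Sigma
  det_s <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  if (det_s <= 0) stop("singular process covariance", call. = FALSE)
  r <- as.numeric(d_curr) - as.numeric(mu)
  q <- (r[1]^2 * S[2, 2] - 2 * r[1] * r[2] * S[1, 2] + r[2]^2 * S[1, 1]) / det_s
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}

#' Observation-model log likelihood of one Argos fix
#'
#' The fix at fractional position `j` within a grid interval is compared
#' with the linear interpolation of the bracketing states; longitude and
#' latitude residuals get independent scaled-t densities with the
#' parameters of the fix's location class.
#'
#' @param x_t,x_next Length-2 state locations (lon, lat) bracketing the fix.
#' @param j Interpolation weight in [0, 1).
#' @param y One-row data frame or list with `lon`, `lat`, `loc_class`.
#' @param em An `argos_error_model`.
#' @return Log density (scalar).
#' @export
observation_loglik <- function(x_t, x_next, j, y, em) {
  stopifnot(j >= 0, j < 1)
  cls <- as.character(y$loc_class)
  if (!cls %in% rownames(em)) {
    stop("location class '", cls, "' missing from the error model", call. = FALSE)
  }
  p <- em[cls, ]
  pred <- (1 - j) * as.numeric(x_t) + j * as.numeric(x_next)
  dt_scaled_log(y$lon - pred[1], p$nu, p$tau_lon) +
    dt_scaled_log(y$lat - pred[2], p$nu, p$tau_lat)
}

#' Fit the hierarchical switching state-space model
#'
#' Fits the two-state first-difference correlated random walk with
#' class-specific t observation errors jointly to all tracks of one
#' species by Markov chain Monte Carlo (Metropolis-within-Gibbs: exact
#' discrete Gibbs updates of behaviour states, single-site random-walk
#' Metropolis for locations and movement parameters, conjugate Beta
#' updates for the switching probabilities). Movement parameters are
#' shared across animals; locations and behaviours are per-animal.
#'
#' Priors: `theta[1] ~ U(-pi/4, pi/4)`, `theta[2] ~ U(-pi, pi)`,
#' `gamma[1] ~ Beta(2,1)`, `gamma[2] ~ Beta(1,2)` with the ordering
#' `gamma[1] > gamma[2]` enforced, `alpha ~ Beta(1,1)`, process standard
#' deviations half-normal(0.1 deg), correlation `U(-1, 1)`.
#'
#' @param tracks List of `whale_track` objects (same species).
#' @param dt_hours State-grid spacing in hours (2 for fin, 4 for blue).
#' @param em An `argos_error_model`; default [argos_error_model()].
#' @param mcmc List with `n_chains`, `n_iter`, `burn_in`, `thin`. Defaults
#'   follow the study protocol: 2 chains of 50000 iterations, 45000
#'   burn-in, thin 5.
#' @param seed Integer seed; the fit is reproducible given seed and input.
#' @return An `hssm_fit` with retained samples of movement parameters,
#'   per-animal states and behaviours, plus chain metadata.
#' @export
fit_hssm <- function(tracks, dt_hours, em = argos_error_model(),
                     mcmc = list(n_chains = 2, n_iter = 50000,
                                 burn_in = 45000, thin = 5),
                     seed = 1L) {
  if (length(tracks) < 1) stop("need at least one track", call. = FALSE)
  stopifnot(mcmc$n_iter > 0, mcmc$burn_in >= 0, mcmc$burn_in < mcmc$n_iter,
            mcmc$thin >= 1, mcmc$n_chains >= 1)
  species <- unique(vapply(tracks, function(t) t$species, character(1)))
  if (length(species) != 1) stop("all tracks must share one species", call. = FALSE)

  grids <- lapply(tracks, build_time_grid, dt_hours = dt_hours)
  animals <- lapply(seq_along(tracks), function(k) {
    tr <- tracks[[k]]; g <- grids[[k]]
    o <- tr$observations
    gt <- as.numeric(grid_times(g))
    ot <- as.numeric(o$time)
    # initialise states on a lightly smoothed interpolation of the fixes,
    # so the chain does not start in a noise-chasing zigzag configuration
    x0 <- cbind(smooth5(stats::approx(ot, o$lon, xout = gt, rule = 2)$y),
                smooth5(stats::approx(ot, o$lat, xout = gt, rule = 2)$y))
    p <- em[as.character(o$loc_class), ]
    list(x0 = x0,
         y = cbind(o$lon, o$lat),
         obs_t = g$obs_index$t, obs_j = g$obs_index$j,
         nu = p$nu, tau_lon = p$tau_lon, tau_lat = p$tau_lat)
  })

  n_keep <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed((seed + 104729L * (ch - 1L)) %% .Machine$integer.max)
    init <- draw_initial_params()
    chains[[ch]] <- hssm_mcmc(animals, init, mcmc$n_iter, mcmc$burn_in, mcmc$thin)
  }

  structure(
    list(chains = chains,
         animal_ids = vapply(tracks, function(t) t$animal_id, character(1)),
         species = species, grids = grids, dt_hours = dt_hours,
         mcmc = c(mcmc, list(seed = seed, n_keep = n_keep)),
         param_names = c("theta1", "theta2", "gamma1", "gamma2",
                         "alpha1", "alpha2", "sigma_lon", "sigma_lat", "rho")),
    class = "hssm_fit"
  )
}

# centred 5-point running mean, ends untouched
smooth5 <- function(x) {
  if (length(x) < 5) return(x)
  s <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  out <- as.numeric(s)
  out[is.na(out)] <- x[is.na(out)]
  out
}

# overdispersed starting values drawn from the priors (ordering respected)
draw_initial_params <- function() {
  g <- sort(c(stats::rbeta(1, 2, 1), stats::rbeta(1, 1, 2)), decreasing = TRUE)
  while (g[1] - g[2] < 0.05) {
    g <- sort(c(stats::rbeta(1, 2, 1), stats::rbeta(1, 1, 2)), decreasing = TRUE)
  }
  list(theta = c(stats::runif(1, -pi / 4, pi / 4), stats::runif(1, -pi, pi)),
       gamma = g,
       alpha = stats::runif(2, 0.2, 0.8),
       sigma = abs(stats::rnorm(2, 0, 0.05)) + 0.01,
       rho = stats::runif(1, -0.3, 0.3))
}

#' @export
print.hssm_fit <- function(x, ...) {
  cat("Hierarchical switching state-space model fit (", x$species, " preset)\n", sep = "")
  cat(" ", length(x$animal_ids), "animal(s), dt =", x$dt_hours, "h\n")
  m <- x$mcmc
  cat("  MCMC:", m$n_chains, "chain(s) x", m$n_iter, "iterations, burn-in",
      m$burn_in, ", thin", m$thin, "->", m$n_keep, "samples/chain\n")
  p <- posterior_params(x)
  med <- apply(p, 2, stats::median)
  cat("  posterior medians:\n")
  print(round(med, 3))
  invisible(x)
}

#' Pooled posterior parameter samples
#' @param fit An `hssm_fit`.
#' @return Matrix (samples x 9 parameters) pooled over chains.
#' @export
posterior_params <- function(fit) {
  out <- do.call(rbind, lapply(fit$chains, function(ch) ch$params))
  colnames(out) <- fit$param_names
  out
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per movement parameter, from between-
#' and within-chain variances of the retained samples. Values near 1
#' indicate the chains agree; 1.1 is a common warning threshold.
#'
#' @param fit An `hssm_fit` with at least two chains.
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(fit) {
  if (length(fit$chains) < 2) {
    stop("Gelman-Rubin needs >= 2 chains; re-run the fit with n_chains >= 2",
         call. = FALSE)
  }
  mats <- lapply(fit$chains, function(ch) ch$params)
  vapply(seq_along(fit$param_names), function(p) {
    psrf(lapply(mats, function(m) m[, p]))
  }, numeric(1), USE.NAMES = FALSE) -> r
  names(r) <- fit$param_names
  r
}

# potential scale reduction factor for one scalar parameter
psrf <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  w <- mean(vars)
  b_over_n <- stats::var(means)          # = B/n
  if (w == 0) {
    if (max(means) - min(means) == 0) return(1.0)
    return(Inf)
  }
  sqrt((n - 1) / n + b_over_n / w * (m + 1) / m)
}

#' Classify behaviour from the posterior
#'
#' The behavioural index `b` at each grid time is the mean of the retained
#' MCMC behaviour samples (which take values 1 = transiting, 2 = ARS).
#' States with `b < 1.25` are classified transiting, `b > 1.75` ARS, and
#' anything between uncertain. Locations are summarised by posterior
#' medians with central 95% credible bounds.
#'
#' @param fit An `hssm_fit`.
#' @return A `state_series` data frame: `animal_id`, `time`, `lon`, `lat`,
#'   `lon_lo`, `lon_hi`, `lat_lo`, `lat_hi`, `b_mean`, `class`.
#' @export
classify_behaviour <- function(fit) {
  out <- lapply(seq_along(fit$animal_ids), function(k) {
    xs <- do.call(rbind, lapply(fit$chains, function(ch) ch$x[[k]]))   # samples x (2n)
    bs <- do.call(rbind, lapply(fit$chains, function(ch) ch$b[[k]]))   # samples x n
    n <- ncol(bs)
    lon <- xs[, 1:n, drop = FALSE]
    lat <- xs[, n + (1:n), drop = FALSE]
    b_mean <- colMeans(bs)
    data.frame(
      animal_id = fit$animal_ids[k],
      time = grid_times(fit$grids[[k]]),
      lon = apply(lon, 2, stats::median),
      lat = apply(lat, 2, stats::median),
      lon_lo = apply(lon, 2, stats::quantile, 0.025),
      lon_hi = apply(lon, 2, stats::quantile, 0.975),
      lat_lo = apply(lat, 2, stats::quantile, 0.025),
      lat_hi = apply(lat, 2, stats::quantile, 0.975),
      b_mean = b_mean,
      class = classify_b(b_mean),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("state_series", "data.frame")
  out
}

#' Behavioural class from the mean behavioural index
#' @param b_mean Numeric vector in [1, 2].
#' @return Character vector: `"transiting"` (< 1.25), `"ARS"` (> 1.75),
#'   else `"uncertain"`.
#' @export
classify_b <- function(b_mean) {
  ifelse(b_mean < 1.25, "transiting", ifelse(b_mean > 1.75, "ARS", "uncertain"))
}
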