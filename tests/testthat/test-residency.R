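test_that("pooled median ARS speed follows the median conventions", {
  k1 <- make_kinematics(c(1, 2, 3), rep("ARS", 3))
  expect_equal(median_ars_speed(k1), 2)
  k2 <- make_kinematics(c(1, 2, 3, 4), rep("ARS", 4))
  expect_equal(median_ars_speed(k2), 2.5)          # mean-of-middle
  k3 <- make_kinematics(c(10, 20), rep("ARS", 2), animal_id = "w2")
  pooled <- rbind(k1, k3)
  expect_equal(median_ars_speed(pooled), median(c(1, 2, 3, 10, 20)))
  expect_equal(median_ars_speed(list(k1, k3)), median(c(1, 2, 3, 10, 20)))
  expect_error(median_ars_speed(make_kinematics(1, "transiting")), "ARS")
})

test_that("departure rule is strict, windowed, and censors otherwise", {
  # constant speed exactly at the threshold: never departs
  flat <- make_kinematics(rep(2, 100))
  expect_false(detect_departure(flat, threshold = 2)$departed)

  # 5 slow days then 3 fast days: departure at the transition
  speeds <- c(rep(1, 60), rep(6, 36))
  kin <- make_kinematics(speeds)
  dep <- detect_departure(kin, threshold = 2)
  expect_true(dep$departed)
  expect_equal(dep$time, kin$t_start[61])

  # a 47 h burst does not satisfy the 48 h window
  burst <- make_kinematics(c(rep(1, 10), rep(6, 23), rep(1, 20)))
  expect_false(detect_departure(burst, threshold = 2, window_h = 48)$departed)
  # ... but 48 h does
  burst48 <- make_kinematics(c(rep(1, 10), rep(6, 24), rep(1, 20)))
  expect_true(detect_departure(burst48, threshold = 2, window_h = 48)$departed)

  expect_error(detect_departure(flat[0, ], 2), "empty")
})

test_that("raising the departure threshold never advances the departure time", {
  set.seed(5)
  for (rep in 1:20) {
    kin <- make_kinematics(rexp(80, 1 / 3))
    times <- vapply(c(0.5, 1, 2, 4), function(th) {
      d <- detect_departure(kin, th)
      if (d$departed) as.numeric(d$time) else 8e18   # censored: after any time
    }, numeric(1))
    expect_false(is.unsorted(times))
  }
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  # events {1,2,3}, no censoring
  km <- kaplan_meier(make_records(c(1, 2, 3), rep(FALSE, 3)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)
  expect_equal(km$n_censored, 0)

  # all censored: survival never drops
  km2 <- kaplan_meier(make_records(c(5, 8, 11), rep(TRUE, 3)))
  expect_true(all(km2$surv == 1))
  expect_true(is.na(km2$median))

  # mixed toy set, hand product-limit: S(6)=0.60, S(13)=0.45, median 13
  rec <- make_records(c(3, 4, 6, 6, 13, 17, 11, 12, 18, 22),
                      c(rep(FALSE, 6), rep(TRUE, 4)))
  km3 <- kaplan_meier(rec)
  expect_equal(km3$surv[km3$time == 6], 0.60, tolerance = 1e-12)
  expect_equal(km3$surv[km3$time == 13], 0.45, tolerance = 1e-12)
  expect_equal(km3$median, 13)

  # with zero censoring the curve is the empirical survival function
  set.seed(2)
  d <- sample(1:30, 12, replace = TRUE)
  km4 <- kaplan_meier(make_records(d, rep(FALSE, 12)))
  emp <- vapply(km4$time, function(t) mean(d > t), numeric(1))
  expect_equal(km4$surv, emp)

  expect_error(kaplan_meier(make_records(c(-1, 2), c(FALSE, FALSE))), "negative")
})

test_that("logistic departure curve recovers symmetry and flags separation", {
  # departures symmetric around DST 10
  rec <- make_records(c(6, 8, 9, 11, 12, 14), rep(FALSE, 6))
  rec$track_days <- rep(20, 6)
  fit <- logistic_departure_curve(rec)
  # the per-day table is symmetric around DST 10.5 by construction
  expect_equal(fit$dst_at_half, 10.5, tolerance = 1e-6)
  expect_gt(fit$slope, 0)

  rec1 <- make_records(rep(1, 5), rep(FALSE, 5))
  rec1$track_days <- rep(10, 5)
  expect_error(logistic_departure_curve(rec1), "separation|outcomes")
})

test_that("IRLS logistic fit matches a likelihood grid-search oracle", {
  rec <- make_records(c(4, 7, 9, 12, 15), rep(FALSE, 5))
  rec$track_days <- rep(18, 5)
  fit <- logistic_departure_curve(rec)
  tab <- fit$table
  nll <- function(b0, b1) {
    p <- plogis(b0 + b1 * tab$dst)
    lp <- ifelse(tab$departed > 0, tab$departed * log(p), 0)
    lq <- ifelse(tab$present > 0, tab$present * log(1 - p), 0)
    -sum(lp + lq)
  }
  # coarse-to-fine grid search, independent of glm
  b0 <- 0; b1 <- 0; width0 <- 20; width1 <- 4
  for (pass in 1:40) {
    g0 <- seq(b0 - width0, b0 + width0, length.out = 41)
    g1 <- seq(b1 - width1, b1 + width1, length.out = 41)
    vals <- outer(g0, g1, Vectorize(nll))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    b0 <- g0[ix[1]]; b1 <- g1[ix[2]]
    width0 <- width0 / 4; width1 <- width1 / 4
  }
  expect_equal(fit$intercept, b0, tolerance = 1e-4)
  expect_equal(fit$slope, b1, tolerance = 1e-4)
})

test_that("ARS area extraction follows the >=3 consecutive rule", {
  st <- make_states(c("transiting", "ARS", "ARS", "ARS", "transiting"))
  areas <- extract_ars_areas(st)
  expect_length(areas, 1)
  expect_equal(areas[[1]]$n_positions, 3)

  st2 <- make_states(c("ARS", "ARS", "uncertain", "ARS", "ARS"))
  expect_length(extract_ars_areas(st2), 0)       # uncertain breaks the runs

  st3 <- make_states(rep("ARS", 10))
  a3 <- extract_ars_areas(st3)
  expect_length(a3, 1)
  expect_equal(a3[[1]]$duration_h, 9 * 2)

  # members are disjoint and maximal across multiple runs
  st4 <- make_states(c(rep("ARS", 4), "transiting", rep("ARS", 5)))
  a4 <- extract_ars_areas(st4)
  expect_length(a4, 2)
  expect_length(intersect(a4[[1]]$idx, a4[[2]]$idx), 0)
  expect_equal(lengths(lapply(a4, `[[`, "idx")), c(4, 5))
})

test_that("minimum convex polygon area matches planar shoelace oracles", {
  deg_km <- 1 / (pi / 180 * 6371)     # degrees per km at the equator
  tri <- cbind(c(0, 4, 0) * deg_km, c(0, 0, 3) * deg_km)
  expect_equal(as.numeric(mcp_area(tri)), 6, tolerance = 0.01)

  # adding interior points must not change the hull area
  with_centroid <- rbind(tri, colMeans(tri))
  expect_equal(as.numeric(mcp_area(with_centroid)), as.numeric(mcp_area(tri)),
               tolerance = 1e-9)

  # permutation invariance
  set.seed(8)
  pts <- cbind(runif(12, -0.05, 0.05), runif(12, -0.05, 0.05)) + 30
  expect_equal(as.numeric(mcp_area(pts)), as.numeric(mcp_area(pts[sample(12), ])),
               tolerance = 1e-9)

  # 0.1 x 0.1 degree equatorial square: (111.195 * 0.1)^2 km^2 within 0.5%
  sq <- cbind(c(0, 0.1, 0.1, 0), c(0, 0, 0.1, 0.1))
  expect_equal(as.numeric(mcp_area(sq)), (0.1 * pi / 180 * 6371)^2,
               tolerance = 0.005)

  col <- cbind(c(0, 0.1, 0.2), c(0, 0, 0))
  expect_equal(as.numeric(mcp_area(col)), 0)
  expect_true(attr(mcp_area(col), "degenerate"))
  expect_error(mcp_area(cbind(0:1, 0:1)), "3 points")
})

test_that("behaviour time budgets partition and sum to one", {
  st <- make_states(rep("ARS", 12))
  b <- behaviour_time_budget(st)
  expect_equal(b$ARS, 1)

  st2 <- make_states(rep(c("transiting", "ARS"), 10))
  b2 <- behaviour_time_budget(st2)
  expect_equal(b2$transiting, 0.5)
  expect_equal(b2$ARS, 0.5)
  expect_equal(b2$uncertain, 0)

  # monthly grouping partitions the states
  st3 <- make_states(rep(c("transiting", "ARS", "uncertain"), 40))
  st3$time <- st3$time + rep(c(0, 31), each = 60) * 86400
  b3 <- behaviour_time_budget(st3, "month")
  expect_equal(sum(b3$n), nrow(st3))
  expect_equal(b3$transiting + b3$ARS + b3$uncertain, rep(1, nrow(b3)))
})

test_that("residency summary means reproduce the published reporting values", {
  tab <- azores_residency_table()
  fin <- tab[tab$species == "fin", ]
  excl <- fin$whale_id[fin$short_track]
  s <- summarize_residency(fin, exclusions = excl)
  expect_equal(s$mean_residence_days, 11.2)
  expect_equal(s$mean_ars_percent, 55.3)
  expect_equal(s$n_included, 10)

  blue <- tab[tab$species == "blue" & !is.na(tab$ars_percent), ]
  expect_equal(summarize_residency(blue)$mean_ars_percent, 78.0)
  expect_error(summarize_residency(fin, exclusions = fin$whale_id), "excluded")
})
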