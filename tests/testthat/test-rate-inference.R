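test_that("noiseless segment fits recover the generating slopes exactly", {
  v <- velocity_profile(replichore_velocity(1000 / (c(0.408, 0.646) * 40), 1.0))
  p <- expected_async_profile(v, growth_law(40), wt_map, right_arm_probes(2))
  for (mode in c("independent", "continuous")) {
    suppressWarnings(fits <- fit_segments(p, wt_map, boundaries = 1.0,
                                          continuity = mode))
    expect_equal(fits$slope, c(0.408, 0.646), tolerance = 1e-6)
    expect_equal(fits$replichore, c("right", "right"))
  }
})

test_that("flat profiles fit slope 0 and intercept-only errors are caught", {
  p <- dosage_profile(right_arm_probes(1), rep(0.2, 1000))
  suppressWarnings(fit <- fit_segments(p, wt_map))
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_error(fit_segments(dosage_profile(1:5 * 1000, rnorm(5)), wt_map),
               "data-sufficiency")
})

test_that("independent-mode OLS equals the brute-force covariance ratio", {
  set.seed(31)
  pos <- sort(sample(seq(1e4, 9e5, 1e3), 40))
  y <- -0.5 * pos / 1e6 + rnorm(40, sd = 0.05)
  p <- dosage_profile(pos, y)
  fit <- fit_segments(p, wt_map)
  d <- replichore_coordinate(pos, wt_map)$distance_Mbp
  # closed-form slope: cov(d, y) / var(d), computed by brute force
  slope_bf <- sum((d - mean(d)) * (y - mean(y))) / sum((d - mean(d))^2)
  expect_equal(fit$slope, -slope_bf, tolerance = 1e-12)
  resid <- y - mean(y) - slope_bf * (d - mean(d))
  se_bf <- sqrt(sum(resid^2) / (40 - 2) / sum((d - mean(d))^2))
  expect_equal(fit$slope_se, se_bf, tolerance = 1e-12)
})

test_that("fitted slopes are unbiased and within 3 SE at realistic noise", {
  v <- velocity_profile(replichore_velocity(1000 / (c(0.408, 0.646) * 40), 1.0))
  g <- growth_law(40)
  pos <- right_arm_probes(2)
  res <- vapply(1:100, function(s) {
    p <- sample_async_profile(v, g, wt_map, pos, noise_sd = 0.05, seed = s)
    f <- fit_segments(p, wt_map, boundaries = 1.0)
    c(f$slope, f$slope_se)
  }, numeric(4))
  within3 <- abs(res[1:2, ] - c(0.408, 0.646)) <= 3 * res[3:4, ]
  expect_gte(mean(within3), 0.99)
  # unbiasedness: mean over seeds within 2 SE-of-mean of truth
  for (k in 1:2) {
    mu <- mean(res[k, ]); sem <- stats::sd(res[k, ]) / 10
    expect_lt(abs(mu - c(0.408, 0.646)[k]), 2 * sem)
  }
})

test_that("continuous mode recovers connected piecewise-linear tracks", {
  pos <- right_arm_probes(2)
  v <- velocity_profile(replichore_velocity(1000 / (c(0.4, 0.7) * 40), 1.0))
  p <- sample_async_profile(v, growth_law(40), wt_map, pos, noise_sd = 0.05, seed = 77)
  fc <- fit_segments(p, wt_map, boundaries = 1.0, continuity = "continuous")
  fi <- fit_segments(p, wt_map, boundaries = 1.0, continuity = "independent")
  expect_equal(fc$slope, c(0.4, 0.7), tolerance = 0.02)
  # when the truth is continuous the two conventions agree closely
  expect_equal(fc$slope, fi$slope, tolerance = 0.02)
  # but on a track with a level break at the boundary they differ:
  # the constrained fit cannot absorb the offset into the intercepts
  pb <- p
  rcb <- replichore_coordinate(pb$probes$position_bp, wt_map)
  pb$probes$log2_ratio[rcb$distance_Mbp > 1.0] <-
    pb$probes$log2_ratio[rcb$distance_Mbp > 1.0] - 0.3
  fib <- fit_segments(pb, wt_map, boundaries = 1.0, continuity = "independent")
  fcb <- fit_segments(pb, wt_map, boundaries = 1.0, continuity = "continuous")
  expect_equal(fib$slope, c(0.4, 0.7), tolerance = 0.02)  # per-segment OLS unaffected
  expect_gt(max(abs(fcb$slope - fib$slope)), 0.1)         # constraint binds
})

test_that("slope-to-velocity conversion matches the steady-state relation", {
  expect_equal(velocity_from_slope(0.5, 40)$velocity_kb_min, 50)
  expect_equal(velocity_from_slope(0.5, growth_law(40))$velocity_kb_min, 50)
  # published head-on Min slope at T = 44 min
  expect_equal(velocity_from_slope(0.408, 44)$velocity_kb_min, 55.7,
               tolerance = 1e-3)
  # delta-method SE
  v <- velocity_from_slope(0.5, 40, slope_se = 0.05)
  expect_equal(v$velocity_se_kb_min, 50 * 0.1)
  # stall limit and error contract
  expect_lt(velocity_from_slope(1e6, 40)$velocity_kb_min, 1e-4)
  expect_error(velocity_from_slope(-0.1, 40), "non-declining")
})

test_that("percent speed change reproduces the published comparison", {
  # head-on vs co-directional right-replichore slopes, minimal medium
  expect_equal(percent_speed_change(0.646, 0.462), 28.48297, tolerance = 1e-5)
  # against the left replichore instead
  expect_equal(percent_speed_change(0.646, 0.408), 36.8, tolerance = 0.05)
  expect_equal(percent_speed_change(0.5, 0.5), 0)
  # invariant to intercept and doubling time: pure slope ratio
  f1 <- data.frame(slope = 0.6, intercept = 2)
  f2 <- data.frame(slope = 0.4, intercept = -1)
  expect_equal(percent_speed_change(f1, f2), 100 * (1 - 0.4 / 0.6))
  expect_error(percent_speed_change(-1, 0.5), "non-positive")
})

test_that("stall flagging picks out anomalously steep segments", {
  fits <- data.frame(replichore = "right",
                     start_Mbp = 0:3, end_Mbp = 1:4,
                     slope = c(0.64, 0.62, 0.65, 1.51))
  out <- stall_segments(fits, fold_threshold = 2)
  expect_equal(out$stall, c(FALSE, FALSE, FALSE, TRUE))
  flat <- data.frame(replichore = "right", slope = rep(0.5, 4))
  expect_false(any(stall_segments(flat, 2)$stall))
  # fold 1: anything above the median of the others
  out1 <- stall_segments(data.frame(replichore = "left", slope = c(0.4, 0.5, 0.6)), 1)
  expect_equal(out1$stall, c(FALSE, FALSE, TRUE))
  # single segment: nothing to compare
  expect_false(stall_segments(data.frame(replichore = "left", slope = 1), 2)$stall)
})

test_that("changepoint search is exact without noise and clean on single slopes", {
  v <- velocity_profile(replichore_velocity(1000 / (c(0.408, 0.646) * 40), 1.0))
  pe <- expected_async_profile(v, growth_law(40), wt_map, right_arm_probes(2))
  cp <- detect_changepoints(pe, wt_map, "right", penalty = 1e-8)
  expect_equal(cp, 1.0, tolerance = 1e-3)
  # no breakpoints on single-slope noisy profiles
  v1 <- velocity_profile(replichore_velocity(1000 / (0.5 * 40)))
  for (s in 1:5) {
    p <- sample_async_profile(v1, growth_law(40), wt_map, right_arm_probes(2),
                              noise_sd = 0.05, seed = s)
    expect_length(detect_changepoints(p, wt_map, "right"), 0)
  }
  expect_error(detect_changepoints(pe, wt_map, "right", penalty = -1),
               "parameter error")
})

test_that("changepoints localize slope breaks at the information-limited scale", {
  v <- velocity_profile(replichore_velocity(1000 / (c(0.408, 0.646) * 40), 1.0))
  g <- growth_law(40)
  errs <- vapply(1:20, function(s) {
    p <- sample_async_profile(v, g, wt_map, right_arm_probes(2), noise_sd = 0.05,
                              seed = s)
    cp <- detect_changepoints(p, wt_map, "right")
    if (length(cp)) min(abs(cp - 1.0)) else Inf
  }, numeric(1))
  expect_gte(mean(is.finite(errs)), 0.9)           # the break is found
  expect_gte(mean(errs <= 0.12), 0.9)              # and localized
})

test_that("a short steep stall segment is delimited on both sides", {
  # steep 1.51-per-Mbp segment over ~160 kb flanked by 0.65, as at the
  # inverted rrnGHI-aprE interval in rich medium
  v <- velocity_profile(replichore_velocity(1000 / (c(0.65, 1.51, 0.65) * 40),
                                            c(0.94, 1.10)))
  g <- growth_law(40)
  hits <- vapply(1:20, function(s) {
    p <- sample_async_profile(v, g, wt_map, right_arm_probes(2), noise_sd = 0.05,
                              seed = 100 + s)
    cp <- detect_changepoints(p, wt_map, "right")
    length(cp) >= 2 && min(abs(cp - 0.94)) <= 0.1 && min(abs(cp - 1.10)) <= 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("velocity round trip: generate, fit, invert within 5% under noise", {
  true_v <- c(55, 35)
  v <- velocity_profile(replichore_velocity(true_v, 1.0))
  g <- growth_law(40)
  est <- vapply(1:10, function(s) {
    p <- sample_async_profile(v, g, wt_map, right_arm_probes(2), noise_sd = 0.05,
                              seed = s)
    fits <- fit_segments(p, wt_map, boundaries = 1.0)
    velocity_table(fits, g)$velocity_kb_min
  }, numeric(2))
  expect_true(all(abs(est / true_v - 1) < 0.05))
})
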