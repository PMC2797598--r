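test_that("expected asynchronous profile follows g(x) = -t(x)/T", {
  g40 <- growth_law(40)
  v50 <- velocity_profile(replichore_velocity(50))
  p <- expected_async_profile(v50, g40, wt_map, c(0, 1e6))
  expect_equal(p$probes$log2_ratio, c(0, -0.5))  # (1000/50)/40 log2 units
  # doubling v halves the slope everywhere
  v100 <- velocity_profile(replichore_velocity(100))
  p2 <- expected_async_profile(v100, g40, wt_map, c(0, 1e6))
  expect_equal(p2$probes$log2_ratio, p$probes$log2_ratio / 2)
  # two-segment field: t(1 Mbp) = 10 + 20 min
  v2 <- velocity_profile(replichore_velocity(c(50, 25), 0.5))
  expect_equal(expected_async_profile(v2, g40, wt_map, 1e6)$probes$log2_ratio, -0.75)
})

test_that("expected profile declines monotonically with replichore distance", {
  v <- velocity_profile(replichore_velocity(c(40, 20, 55), c(0.4, 1.1)),
                        replichore_velocity(c(60, 30), 0.8))
  p <- expected_async_profile(v, growth_law(35), wt_map,
                              seq(0, L_BS - 1, length.out = 401))
  rc <- replichore_coordinate(p$probes$position_bp, wt_map)
  for (arm in c("left", "right")) {
    ord <- order(rc$distance_Mbp[rc$replichore == arm])
    expect_true(all(diff(p$probes$log2_ratio[rc$replichore == arm][ord]) <= 1e-12))
  }
})

test_that("origin:terminus dosage ratio equals 2^(C/T) (numeric-integration oracle)", {
  rv <- replichore_velocity(c(40, 20, 55), c(0.4, 1.1))
  T <- 35
  arm_len <- replichore_lengths(wt_map)[["right"]] / 1e6
  # brute-force trapezoid integral of 1/v over the replichore
  xs <- seq(0, arm_len, length.out = 20001)
  vx <- 1000 * c(40, 20, 55)[findInterval(xs, c(0, 0.4, 1.1))] / 1000
  C_num <- sum(diff(xs) * (1 / vx[-1] + 1 / vx[-length(vx)]) / 2) * 1000
  v <- velocity_profile(replichore_velocity(1), rv)  # left arm irrelevant here
  p <- expected_async_profile(v, growth_law(T), wt_map,
                              c(0, wt_map$terC_bp - 1))
  ratio <- 2^(p$probes$log2_ratio[1] - p$probes$log2_ratio[2])
  expect_equal(ratio, 2^(C_num / T), tolerance = 1e-4)
})

test_that("samplers are deterministic given a seed and exact at zero noise", {
  v <- velocity_profile(replichore_velocity(50))
  g <- growth_law(40)
  pos <- right_arm_probes(1.5)
  a1 <- sample_async_profile(v, g, wt_map, pos, noise_sd = 0.1, seed = 11)
  a2 <- sample_async_profile(v, g, wt_map, pos, noise_sd = 0.1, seed = 11)
  expect_identical(a1$probes, a2$probes)
  a0 <- sample_async_profile(v, g, wt_map, pos, noise_sd = 0, seed = 5)
  expect_equal(a0$probes$log2_ratio,
               expected_async_profile(v, g, wt_map, pos)$probes$log2_ratio)
  expect_error(sample_async_profile(v, g, wt_map, pos, noise_sd = 0.1),
               "seed")
})

test_that("cell-sampling mode converges to the closed form", {
  v <- velocity_profile(replichore_velocity(50))
  g <- growth_law(40)
  pos <- seq(1e4, 1.9e6, length.out = 40)
  n_cells <- 40000
  p <- sample_async_profile(v, g, wt_map, pos, mode = "cell_sampling",
                            n_cells = n_cells, seed = 3)
  expected <- expected_async_profile(v, g, wt_map, pos)$probes$log2_ratio
  # per-probe MC standard error of the mean copy number, mapped to log2
  u <- -expected  # = t(x)/T
  # var of 2^-m: E[2^-2m] - (2^-u)^2 with m in {floor(u), ceil(u)} mixture
  fl <- floor(u); fr <- u - fl
  e2 <- (1 - (1 - 2^(-fr)) * 2) * 4^(-fl) + (2 - 2^(1 - fr)) * 4^(-fl - 1)
  mc_se_log2 <- sqrt(pmax(e2 - 4^(-u), 0) / n_cells) / (2^(-u) * log(2))
  dev <- abs(p$probes$log2_ratio - expected)
  expect_true(all(dev <= pmax(3 * mc_se_log2, 1e-3)))
  expect_error(sample_async_profile(v, g, wt_map, pos, mode = "cell_sampling",
                                    n_cells = 50, seed = 1), "sampling-size")
})

test_that("expected synchronized profiles are two-plateau steps", {
  pos <- right_arm_probes(2)
  sch <- uniform_schedule(0.82)
  flat <- expected_sync_profile(sch, 0, 30, wt_map, pos)
  expect_true(all(flat$probes$log2_ratio == 0))
  p <- expected_sync_profile(sch, 0.5, 30, wt_map, pos)
  rc <- replichore_coordinate(pos, wt_map)
  expect_equal(unique(p$probes$log2_ratio[rc$distance_Mbp <= 0.81]), log2(1.5))
  expect_equal(unique(p$probes$log2_ratio[rc$distance_Mbp > 0.83]), 0)
  # two-phase schedule: 10 kb/min x 4 min + 30 kb/min x 26 min = 0.82 Mbp front
  sch2 <- velocity_schedule(c(0, 4), c(4, 30), list(
    velocity_profile(replichore_velocity(10)),
    velocity_profile(replichore_velocity(30))))
  p2 <- expected_sync_profile(sch2, 0.5, 30, wt_map, pos)
  expect_equal(p2$probes$log2_ratio, p$probes$log2_ratio)
  expect_error(expected_sync_profile(sch, 1.2, 30, wt_map, pos), "f_init")
  expect_error(expected_sync_profile(sch, 0.5, 45, wt_map, pos), "schedule error")
})

test_that("sync sampler reproduces the plateau after smoothing", {
  pos <- right_arm_probes(2)
  sch <- uniform_schedule(0.82)
  p0 <- sample_sync_profile(sch, 0.5, 30, wt_map, pos, noise_sd = 0, seed = 2)
  expect_equal(p0$probes$log2_ratio,
               expected_sync_profile(sch, 0.5, 30, wt_map, pos)$probes$log2_ratio)
  est <- vapply(1:5, function(s) {
    p <- sample_sync_profile(sch, 0.5, 30, wt_map, pos, noise_sd = 0.1, seed = s)
    sm <- rolling_average(p, 200)
    rc <- replichore_coordinate(sm$probes$position_bp, wt_map)
    stats::median(sm$probes$log2_ratio[rc$distance_Mbp < 0.6])
  }, numeric(1))
  expect_true(all(abs(est - log2(1.5)) < 0.02))
})

test_that("fluctuation sampler matches the analytic zero-culture probability", {
  mu <- 5e-9; Nt <- 2e8
  a <- simulate_fluctuation_assay(mu, 1, Nt, n_cultures = 10000, seed = 9)
  p0_true <- exp(-mu * (Nt - 1))
  se <- sqrt(p0_true * (1 - p0_true) / 10000)
  expect_lt(abs(a$n_zero / a$n_cultures - p0_true), 3 * se)
  # the count distribution is right-skewed (jackpots)
  expect_gt(mean(a$mutant_counts), stats::median(a$mutant_counts))
  # determinism and degenerate rates
  b <- simulate_fluctuation_assay(mu, 1, Nt, n_cultures = 100, seed = 9)
  b2 <- simulate_fluctuation_assay(mu, 1, Nt, n_cultures = 100, seed = 9)
  expect_identical(b$mutant_counts, b2$mutant_counts)
  z <- simulate_fluctuation_assay(0, 1, Nt, n_cultures = 20, seed = 1)
  expect_true(all(z$mutant_counts == 0))
  expect_warning(simulate_fluctuation_assay(1e-7, 1, 2e8, 10, seed = 1),
                 "P0")
})

test_that("competition simulator realizes the requested fitness", {
  cmp <- simulate_competition(0.92, generations_ref = 10, N0_each = 1e5,
                              count_noise_cv = 0, seed = 1)
  expect_equal(cmp$n_final[cmp$strain == "reference"] / 1e5, 2^10)
  expect_equal(cmp$n_final[cmp$strain == "test"] / 1e5, 2^9.2)
  neutral <- simulate_competition(1, 10, 1e5, 0, seed = 2)
  expect_equal(neutral$n_final[1], neutral$n_final[2])
  r1 <- simulate_competition(0.9, 10, 1e5, 0.05, seed = 3)
  r2 <- simulate_competition(0.9, 10, 1e5, 0.05, seed = 3)
  expect_identical(r1, r2)
})

test_that("published-slope velocity configurations invert back to the slopes", {
  v <- ht_velocity_profile("Min", doubling_time_min = 44)
  # slope of the head-on segment = 1/(vT)
  expect_equal(1000 / (v$right$velocities_kb_min[1] * 44), 0.646)
  expect_equal(1000 / (v$right$velocities_kb_min[2] * 44), 0.462)
  expect_equal(1000 / (v$left$velocities_kb_min[1] * 44), 0.408)
  vc <- ht_velocity_profile("CAA", doubling_time_min = 55)
  expect_equal(1000 / (vc$right$velocities_kb_min * 55),
               c(0.640, 0.615, 0.654, 1.51, 0.456))
  # the steep stall segment spans the inverted rrnGHI-aprE interval (80-94 deg)
  expect_equal(vc$right$breakpoints_Mbp[3:4],
               c(80, 94) / 360 * L_BS / 1e6, tolerance = 1e-9)
})
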