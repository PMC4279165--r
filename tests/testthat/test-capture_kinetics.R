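test_that("nothing leaves the native state when unfolding is switched off", {
  p <- capture_params(k_u = 0, k_f = 0.3, k_c = 0.35, k_agg = 0.02)
  traj <- simulate_capture(p, experiment_condition(3), fast_times)
  expect_equal(traj$soluble_frac, rep(1, length(fast_times)),
               tolerance = 1e-8)
})

test_that("mass is conserved and captured/aggregated pools are monotone", {
  set.seed(42)
  for (i in 1:8) {
    p <- random_capture_params()
    el <- stats::runif(1, 0, 6)
    cond <- experiment_condition(el, protein0 = 2)
    traj <- simulate_capture(p, cond, seq(0, 60, by = 2))
    total <- traj$n_uM + traj$i_uM + traj$c_uM + traj$a_uM
    expect_true(all(abs(total - cond$protein0) < 1e-6))
    expect_true(all(traj[c("n_uM", "i_uM", "c_uM", "a_uM")] >= -1e-10))
    expect_true(all(diff(traj$c_uM) >= -1e-10))
    expect_true(all(diff(traj$a_uM) >= -1e-10))
    expect_true(all(diff(traj$soluble_frac) <= 1e-10))
  }
})

test_that("simulated decay matches the closed-form apparent rate", {
  # I154F defaults at 3 uM chaperonin: soluble fraction at 60 min is close
  # to exp(-k_app * 60) ~ 0.25 of the start
  p <- i154f_params()
  traj <- simulate_capture(p, experiment_condition(3), fast_times)
  k_app <- apparent_rate(p, 3)
  expect_equal(k_app, 0.03 * 1.05 / 1.35, tolerance = 1e-12)
  s60 <- traj$soluble_frac[traj$time_min == 60]
  expect_equal(s60, exp(-k_app * 60), tolerance = 0.05)
  expect_equal(s60, 0.25, tolerance = 0.02)
})

test_that("apparent rate is zero without chaperonin, saturates at k_u", {
  p <- i154f_params()
  expect_identical(apparent_rate(p, 0), 0)
  expect_lt(apparent_rate(p, 1e6), p$k_u)
  expect_equal(apparent_rate(p, 1e6), p$k_u, tolerance = 1e-5)
  el <- seq(0, 20, by = 0.5)
  expect_true(all(diff(apparent_rate(p, el)) >= 0))
})

test_that("chaperonin suppresses the aggregation channel", {
  p <- i154f_params()
  a60 <- vapply(c(0, 0.5, 1, 2, 3, 6, 12), function(el) {
    traj <- simulate_capture(p, experiment_condition(el), c(0, 30, 60))
    traj$a_uM[traj$time_min == 60]
  }, numeric(1))
  expect_gt(a60[1], 0)  # aggregation happens without the trap
  expect_true(all(diff(a60) <= 1e-10))
})

test_that("invalid inputs are rejected", {
  expect_error(capture_params(-0.1, 0.3, 0.35), "non-negative")
  expect_error(capture_params(Inf, 0.3, 0.35), "finite")
  expect_error(experiment_condition(-1), "non-negative")
  expect_error(experiment_condition(3, protein0 = 0), "positive")
  p <- i154f_params()
  expect_error(simulate_capture(p, experiment_condition(3), c(1, 2, 3)),
               "start at 0")
  expect_error(simulate_capture(p, experiment_condition(3), c(0, 2, 2)),
               "strictly increasing")
  expect_error(apparent_rate(capture_params(0.03, 0, 0.35), 0), "positive")
})

test_that("trajectory CSV export round-trips", {
  traj <- simulate_capture(i154f_params(), experiment_condition(3),
                           c(0, 10, 30, 60))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- utils::read.csv(path)
  expect_named(back, c("time_min", "n_uM", "i_uM", "c_uM", "a_uM",
                       "soluble_frac"))
  expect_equal(back$soluble_frac, traj$soluble_frac, tolerance = 1e-6)
})
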