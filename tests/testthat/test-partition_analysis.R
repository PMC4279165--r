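test_that("noiseless decay data return the generating parameters", {
  t <- c(0, 1, 5, 10, 20, 30, 45, 60)
  tc <- time_course(t, 0.10 + 0.90 * exp(-0.02 * t))
  fit <- fit_first_order(tc)
  expect_true(fit$converged)
  expect_equal(fit$k_app, 0.02, tolerance = 1e-4 / 0.02)
  expect_equal(fit$s0, 1.00, tolerance = 1e-4)
  expect_equal(fit$s_inf, 0.10, tolerance = 1e-4)
  # weighted and unweighted fits agree on noiseless data
  tcw <- time_course(t, 0.10 + 0.90 * exp(-0.02 * t),
                     sd = rep(0.02, length(t)))
  expect_equal(fit_first_order(tcw)$k_app, fit$k_app, tolerance = 1e-6)
  # the plateau-fixed mode reduces to a pure exponential
  tc0 <- time_course(t, exp(-0.02 * t))
  expect_equal(fit_first_order(tc0, fix_plateau_zero = TRUE)$k_app, 0.02,
               tolerance = 1e-6)
})

test_that("flat series and short series are handled as specified", {
  t <- c(0, 10, 20, 30)
  flat <- fit_first_order(time_course(t, rep(1, 4)))
  expect_identical(flat$k_app, 0)
  expect_true(flat$converged)
  expect_true(flat$degenerate_flat)
  expect_error(fit_first_order(time_course(c(0, 1, 2), c(1, 0.9, 0.8))),
               "4 time points")
  expect_error(time_course(c(0, 1), c(1, -0.1)), "\\[0, 1.1\\]")
})

test_that("seeded noisy time course recovers the generating rate", {
  tc <- gen_timecourse(preset("I154F"), experiment_condition(3),
                       noise_sd = 0.02, seed = 11)
  fit <- fit_first_order(tc)
  expect_equal(fit$k_app, apparent_rate(preset("I154F")$capture, 3),
               tolerance = 0.15)
})

test_that("exact hyperbola points recover k_max and k_half", {
  el <- c(0.5, 1, 2, 3)
  prof <- rate_profile(el, 0.03 * el / (0.857 + el))
  fit <- fit_rate_saturation(prof)
  expect_true(fit$converged)
  expect_equal(fit$k_max, 0.030, tolerance = 0.01)
  expect_equal(fit$k_half, 0.857, tolerance = 0.01)
  expect_false(fit$saturation_not_reached)
})

test_that("degenerate and undersized rate profiles raise errors", {
  expect_error(fit_rate_saturation(rate_profile(c(1, 2, 3), c(0, 0, 0))),
               "degenerate")
  expect_error(fit_rate_saturation(rate_profile(c(1, 2), c(0.01, 0.02))),
               "3 distinct")
})

test_that("a far-from-saturation profile is flagged", {
  el <- c(0.5, 1, 2, 3)
  prof <- rate_profile(el, 0.5 * el / (100 + el))
  fit <- fit_rate_saturation(prof)
  expect_true(fit$saturation_not_reached)
})

test_that("end-to-end simulated profiles recover the unfolding rate", {
  el <- c(0.5, 1, 2, 3, 6, 12)
  k_max <- vapply(c("I154F", "D122Y"), function(v) {
    tcs <- lapply(el, function(e) {
      gen_timecourse(preset(v), experiment_condition(e), noise_sd = 0,
                     seed = 1)
    })
    fit_rate_saturation(profile_from_timecourses(tcs))$k_max
  }, numeric(1))
  expect_equal(k_max[["I154F"]], preset("I154F")$capture$k_u,
               tolerance = 0.10)
  expect_equal(k_max[["D122Y"]], preset("D122Y")$capture$k_u,
               tolerance = 0.10)
  # the more liable variant partitions at the higher limiting rate
  expect_gt(k_max[["I154F"]], k_max[["D122Y"]])
})

test_that("fraction_remaining evaluates the fitted decay", {
  fit <- structure(list(k_app = 0.0231, s0 = 1, s_inf = 0),
                   class = "decay_fit")
  expect_equal(fraction_remaining(fit, 0), 1)
  expect_equal(fraction_remaining(fit, 60), 0.250, tolerance = 1e-3)
  expect_equal(fraction_remaining(fit, 1e9), 0, tolerance = 1e-9)
  expect_error(fraction_remaining(fit, -1), "non-negative")
})
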