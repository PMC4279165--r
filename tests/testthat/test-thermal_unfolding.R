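test_that("half the molecules are unfolded at the melting temperature", {
  set.seed(5)
  for (i in 1:10) {
    tm <- stats::runif(1, 30, 80)
    dh <- stats::runif(1, 20, 150)
    expect_equal(fraction_unfolded(tm, tm, dh), 0.5, tolerance = 1e-12)
  }
})

test_that("fraction unfolded follows the van 't Hoff expression", {
  # direct evaluation with R = 1.987e-3 kcal/(mol K)
  expect_equal(fraction_unfolded(60.1, 55.1, 45), 0.738, tolerance = 1e-3)
  expect_lt(fraction_unfolded(55.1 - 30, 55.1, 45), 0.01)
  # strictly increasing in temperature
  t <- seq(25, 85, by = 0.5)
  expect_true(all(diff(fraction_unfolded(t, 55.1, 45)) > 0))
  expect_error(fraction_unfolded(50, 55, -10), "positive")
})

test_that("a larger enthalpy sharpens the transition", {
  slope_at_tm <- function(dh) {
    eps <- 1e-4
    (fraction_unfolded(55 + eps, 55, dh) -
        fraction_unfolded(55 - eps, 55, dh)) / (2 * eps)
  }
  dhs <- c(20, 45, 90, 150)
  expect_true(all(diff(vapply(dhs, slope_at_tm, numeric(1))) > 0))
})

test_that("melt signal reduces to the baselines in the two limits", {
  fit <- two_state_fit(55, 45, a_n = 1000, b_n = 1, a_u = 9000, b_u = -4)
  expect_equal(melt_signal(25, fit), 1000 + 1 * 25, tolerance = 0.5)
  expect_equal(melt_signal(85, fit), 9000 - 4 * 85, tolerance = 0.5)
  mid <- ((1000 + 55) + (9000 - 4 * 55)) / 2
  expect_equal(melt_signal(55, fit), mid, tolerance = 1e-9)
})

test_that("noiseless melt curves return all six generating parameters", {
  cur <- gen_meltcurve(preset("D122Y"), noise_frac = 0)
  fit <- fit_melt(cur)
  expect_true(fit$converged)
  expect_equal(fit$tm, 48.80, tolerance = 0.05 / 48.8)
  expect_equal(fit$dh_vh, 45, tolerance = 1e-3)
  expect_equal(fit$a_n, 1000, tolerance = 1e-2)
  expect_equal(fit$b_n, 1, tolerance = 1e-3)
  expect_equal(fit$a_u, 9000, tolerance = 1e-2)
  expect_equal(fit$b_u, -4, tolerance = 1e-3)
})

test_that("noisy WT curves recover the melting temperature", {
  cur <- gen_meltcurve(preset("WT"), noise_frac = 0.01, seed = 7)
  fit <- fit_melt(cur)
  expect_true(fit$converged)
  expect_equal(fit$tm, 55.1, tolerance = 0.3 / 55.1)
})

test_that("normalized equilibrium curves fit with fixed baselines", {
  cur <- gen_meltcurve(preset("WT"), t_range = c(40, 85),
                       noise_frac = 0.01, seed = 7, equilibrium = TRUE)
  fit <- fit_melt(cur, fix_baselines = c(0, 1))
  expect_equal(fit$tm, 66.3, tolerance = 0.3 / 66.3)
  expect_identical(fit$a_n, 0)
  expect_identical(fit$a_u, 1)
})

test_that("featureless curves raise a no-transition error", {
  t <- seq(25, 80, by = 0.5)
  expect_error(fit_melt(melt_curve(t, rep(1000, length(t)))), "flat")
  expect_error(fit_melt(melt_curve(c(25, 30, 50), c(1, 2, 3))),
               ">= 20 points")
})

test_that("melting-temperature shifts match the published table rows", {
  tab <- dsf_tm_table()
  wt <- tab[tab$variant == "WT" & tab$osmolyte == "trehalose", ]
  control <- two_state_fit(tab$tm_c[tab$variant == "WT" &
                                      tab$osmolyte == "none"], 45)
  d75 <- delta_tm(two_state_fit(wt$tm_c[wt$conc_M == 0.750], 45), control)
  d25 <- delta_tm(two_state_fit(wt$tm_c[wt$conc_M == 0.250], 45), control)
  expect_equal(d75, 5.1, tolerance = 1e-9)
  expect_equal(d25, 1.4, tolerance = 1e-9)
  d025 <- delta_tm(two_state_fit(wt$tm_c[wt$conc_M == 0.025], 45), control)
  expect_equal(d025, -0.5, tolerance = 1e-9)
  expect_identical(delta_tm(control, control), 0)
  bad <- two_state_fit(50, 45, converged = FALSE)
  expect_error(delta_tm(bad, control), "converged")
  # the published WT trehalose shifts are self-consistent; several other
  # rows are not, and the loader flags them instead of fixing them
  expect_false(any(wt$inconsistent))
  expect_true(any(tab$inconsistent[tab$variant == "D122Y"]))
})

test_that("osmolyte series arithmetic and trend slope are exact", {
  s <- osmolyte_series("TMAO", c(0.1, 0.3, 0.5), 50 + 6 * c(0.1, 0.3, 0.5),
                       control_tm = 50)
  expect_equal(s$dtms, s$tms - 50)
  tr <- stabilization_trend(s)
  expect_equal(tr$slope, 6.00, tolerance = 1e-9)
  expect_identical(tr$sign, "stabilizing")
  flat <- osmolyte_series("glycerol", c(0.1, 0.3, 0.5), rep(50, 3), 50)
  tr0 <- stabilization_trend(flat)
  expect_equal(tr0$slope, 0)
  expect_identical(tr0$sign, "neutral")
  # published WT trehalose series trends upward
  tab <- dsf_tm_table()
  wt <- tab[tab$variant == "WT" & tab$osmolyte == "trehalose", ]
  wt <- wt[order(wt$conc_M), ]
  trw <- stabilization_trend(osmolyte_series("trehalose", wt$conc_M,
                                             wt$tm_c, 55.1))
  expect_gt(trw$slope, 0)
  expect_error(stabilization_trend(
    osmolyte_series("x", c(0.1, 0.2), c(50, 51), 50)), "3 concentrations")
})
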