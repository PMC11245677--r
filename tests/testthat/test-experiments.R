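# Grid sweeps, sensitivity analysis, stability scenarios, and the nuclear
# degradation arithmetic. Grids here are deliberately coarse and short; the
# study-resolution sweeps live in the acceptance suite.

test_that("grid results are structured, monotone in delay, and contiguous", {
  g <- small_grid(axolotl_bm_params(), target = 60)
  expect_equal(nrow(g$cells), 5 * 4)
  expect_false(any(g$cells$failed))
  # period non-decreasing in total delay along each protein half-life row
  for (h in unique(g$cells$h_p)) {
    row <- g$cells[g$cells$h_p == h, ]
    row <- row[order(row$total_delay), ]
    fin <- row$period[is.finite(row$period)]
    if (length(fin) > 1) expect_true(all(diff(fin) > -0.1))
    # the oscillatory region is a single contiguous band in delay
    expect_true(all(diff(which(is.finite(row$period))) == 1))
  }
  expect_true(all(abs(g$capture$period - 60) <= g$spec$capture_tol))
  # a grid centred on the frog's delays captures its 56-min clock
  gf <- small_grid(frog_bm_params(), target = 56)
  expect_gt(nrow(gf$capture), 0)
  expect_true(all(abs(gf$capture$period - 56) <= 2))
})

test_that("doubling grid resolution barely moves the maximum finite period", {
  pars <- axolotl_bm_params()
  # window around the long-period corner of the axolotl sweep
  coarse <- run_grid(grid_spec(pars, delay_center = 37.82, delay_halfwidth = 1,
                               delay_step = 1, h_p = seq(12, 20, 2),
                               t_span = 3100))
  fine <- run_grid(grid_spec(pars, delay_center = 37.82, delay_halfwidth = 1,
                             delay_step = 0.5, h_p = seq(12, 20, 1),
                             t_span = 3100))
  expect_lt(abs(fine$max_finite_period - coarse$max_finite_period) /
              coarse$max_finite_period, 0.01)
})

test_that("grid spec validates its axes", {
  pars <- axolotl_bm_params()
  expect_error(grid_spec(pars, delay_center = 2, delay_halfwidth = 1),
               "protein delay")
  expect_error(grid_spec(pars, h_p = numeric()), "non-empty")
})

test_that("sensitivity report covers 12 perturbations around a robust baseline", {
  rep <- sensitivity(t_span = 1600) # short span; pattern only
  expect_equal(nrow(rep), 12L)
  expect_equal(sort(unique(rep$parameter)),
               sort(c("a", "k", "p_crit", "h_m", "h_p", "total_delay")))
  expect_true(all(rep$damped == !is.finite(rep$period)))
  expect_gt(attr(rep, "baseline_period"), 0)
  # synthesis-rate perturbations barely move the period
  small <- rep[rep$parameter %in% c("a", "k", "p_crit"), "pct_change"]
  expect_true(all(small < 3))
})

test_that("a damped baseline is rejected", {
  damped <- update_parameters(sensitivity_baseline(), total_delay = 16.91)
  expect_error(sensitivity(damped, t_span = 1600), "damped")
})

test_that("stability scenarios scale h_m with the export delay", {
  sc <- stability_scenarios("fractional", h_m_factors = c(1, 0.25),
                            delay_step = 2.5, t_span = 1600,
                            h_p = c(4, 10, 16, 22))
  expect_named(sc, c("h_m=1xT_exp", "h_m=0.25xT_exp"))
  expect_equal(attr(sc, "t_exp"), 26.27)
  expect_equal(sc[["h_m=1xT_exp"]]$spec$base_params$h_m, 26.27)
  expect_equal(sc[["h_m=0.25xT_exp"]]$spec$base_params$h_m, 26.27 / 4)
})

test_that("nuclear degradation fractions follow first-order decay", {
  expect_equal(nuclear_degradation_fraction(26.27, 26.27), 0.5)
  expect_equal(nuclear_degradation_fraction(26.27, 26.27 / 2), 0.75)
  expect_equal(nuclear_degradation_fraction(26.27, 26.27 / 4), 1 - 2^-4)
  expect_equal(nuclear_degradation_fraction(0, 3), 0)
  expect_error(nuclear_degradation_fraction(-1, 3), "non-negative")
  expect_error(nuclear_degradation_fraction(3, 0), "positive")
})

test_that("distribution-based degradation never exceeds the mean-based figure", {
  set.seed(77)
  for (i in 1:5) {
    exits <- stats::rexp(500, rate = 1 / 10) # right-skewed exit times, mean 10
    mean_based <- nuclear_degradation_fraction(mean(exits), 3)
    dist_based <- expected_nuclear_degradation(exits, 3)
    expect_lte(dist_based, mean_based) # Jensen: survival is convex in T
  }
})
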