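# First-exit-time simulation of nuclear mRNA export.

test_that("fGn generator matches the theoretical increment autocovariance", {
  set.seed(101)
  h <- 0.25
  g <- fgn_davies_harte(512, h, 400)
  lag1 <- mean(vapply(seq_len(ncol(g)),
                      function(j) stats::cor(g[-1, j], g[-512, j]), numeric(1)))
  theory <- 2^(2 * h - 1) - 1 # -0.293 for H = 0.25
  expect_lt(abs(lag1 - theory), 0.01)
  expect_lt(abs(mean(apply(g, 2, stats::var)) - 1), 0.02)
})

test_that("circulant-embedding and Cholesky fGn generators agree", {
  set.seed(102)
  h <- 0.25
  a <- fgn_davies_harte(512, h, 300)
  b <- fgn_cholesky(512, h, 300)
  stat <- function(x) c(var = mean(apply(x, 2, stats::var)),
                        lag1 = mean(vapply(seq_len(ncol(x)), function(j)
                          stats::cor(x[-1, j], x[-512, j]), numeric(1))))
  expect_lt(max(abs(stat(a) - stat(b))), 0.025)
})

test_that("fGn with H = 0.5 is indistinguishable from i.i.d. increments", {
  set.seed(103)
  g <- fgn_davies_harte(512, 0.5, 300)
  lag1 <- mean(vapply(seq_len(ncol(g)),
                      function(j) stats::cor(g[-1, j], g[-512, j]), numeric(1)))
  expect_lt(abs(lag1), 0.01)
  expect_lt(abs(mean(g^2) - 1), 0.02)
})

test_that("path increments respect mode, seed, and domain checks", {
  s <- diffusion_settings("normal", seed = 5)
  inc <- generate_path_increments(s, 100)
  expect_equal(dim(inc), c(100L, 3L))
  expect_identical(inc, generate_path_increments(s, 100)) # seeded reproducibility
  expect_error(diffusion_settings("fractional", hurst = 1.2), "\\(0, 1\\)")
  expect_error(generate_path_increments(s, 0), ">= 1")
})

test_that("analytic MFET evaluates and scales as r^2 / (6D)", {
  expect_equal(mfet_analytic(3, 0.45), 10 / 3)
  expect_equal(mfet_analytic(6, 0.45), 40 / 3)
  expect_equal(mfet_analytic(4, 0.45), 4 * mfet_analytic(2, 0.45))
  expect_equal(mfet_analytic(3, 0.9), mfet_analytic(3, 0.45) / 2)
  expect_error(mfet_analytic(-3, 0.45), "positive")
})

test_that("Brownian mean exit steps follow the r^2 law at fixed scale", {
  # The last step lands beyond the boundary, so the walk is absorbed at an
  # effective radius about 0.6 step-lengths past r; that common boundary
  # layer is absorbed into the fitted proportionality constant and only its
  # mild radius-dependence (~1% across 3-6 um at sigma = 0.125) remains.
  sigma <- 0.125
  radii <- c(3, 4.5, 6)
  means <- ses <- numeric(3)
  for (i in seq_along(radii)) {
    s <- diffusion_settings("normal", n_trajectories = 3000, seed = 200 + i)
    st <- first_exit_steps(radii[i], s, sigma)
    means[i] <- mean(st)
    ses[i] <- stats::sd(st) / sqrt(length(st))
  }
  w <- 1 / ses^2
  a_hat <- sum(w * means * radii^2) / sum(w * radii^4)
  # fitted constant close to the continuum 1/(3 sigma^2)
  expect_lt(abs(a_hat * 3 * sigma^2 - 1), 0.06)
  for (i in seq_along(radii))
    expect_lt(abs(means[i] - a_hat * radii[i]^2), 3 * ses[i] + 0.015 * means[i])
})

test_that("a vanishing radius exits on the first step", {
  s <- diffusion_settings("normal", n_trajectories = 200, seed = 7)
  st <- first_exit_steps(1e-6, s, 0.1)
  expect_true(all(st == 1L))
})

test_that("calibration hits the reference exit time and rescales linearly", {
  s <- diffusion_settings("normal", n_trajectories = 4000, seed = 11)
  sc <- calibrate_scale(s)
  res <- export_delay(3, s, sc) # fresh seed relative to the pilot
  se <- res$sd_time / sqrt(length(res$exit_steps))
  expect_lt(abs(res$mean_time - 3.36), 0.02 * 3.36 + 3 * se)
  # doubling the reference time must double the mean exit time
  sc2 <- calibrate_scale(s, reference_time = 6.72)
  res2 <- export_delay(3, s, sc2)
  expect_lt(abs(res2$mean_time / res$mean_time - 2), 0.12)
})

test_that("fractional mode with H = 0.5 reproduces Brownian exit times", {
  sigma <- 0.125
  bm <- diffusion_settings("normal", n_trajectories = 800, seed = 31)
  fb <- diffusion_settings("fractional", hurst = 0.5, n_trajectories = 800, seed = 32)
  st_b <- first_exit_steps(3, bm, sigma)
  st_f <- first_exit_steps(3, fb, sigma)
  se <- sqrt(stats::var(st_b) / length(st_b) + stats::var(st_f) / length(st_f))
  expect_lt(abs(mean(st_b) - mean(st_f)), 3 * se)
})

test_that("calibrated subdiffusive walks also hit the reference time", {
  s <- diffusion_settings("fractional", n_trajectories = 1200, seed = 41)
  sc <- calibrate_scale(s, n_pilot = 1200)
  res <- export_delay(3, s, sc)
  se <- res$sd_time / sqrt(length(res$exit_steps))
  expect_lt(abs(res$mean_time - 3.36), 0.02 * 3.36 + 3 * se)
})

test_that("exit-step ensembles are right-skewed and seed-reproducible", {
  s <- diffusion_settings("normal", n_trajectories = 2000, seed = 13)
  sc <- 0.125
  st <- first_exit_steps(4, s, sc)
  expect_lt(stats::median(st), mean(st))
  expect_identical(first_exit_steps(4, s, sc), st)
  expect_true(all(st >= 1L))
})

test_that("uniform interior starts exit faster than centre starts", {
  sc <- 0.125
  ctr <- diffusion_settings("normal", n_trajectories = 1500, seed = 17)
  uni <- diffusion_settings("normal", n_trajectories = 1500, seed = 17,
                            start_rule = "uniform_three_quarter")
  expect_lt(export_delay(4, uni, sc)$mean_time,
            export_delay(4, ctr, sc)$mean_time)
})

test_that("radius sweep is monotone, consistent, and validates its domain", {
  s <- diffusion_settings("normal", n_trajectories = 1500, seed = 19)
  sc <- 0.125
  sw <- radius_sweep(c(3, 4, 5, 6), s, sc)
  expect_true(all(diff(sw$mean_min) > 0))
  one <- radius_sweep(4, s, sc)
  expect_equal(one$mean_min, export_delay(4, s, sc)$mean_time)
  expect_error(radius_sweep(numeric(), s, sc), "non-empty")
  expect_error(radius_sweep(c(3, 14), s, sc), "13")
})
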