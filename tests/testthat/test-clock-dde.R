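# Delayed-autorepression oscillator: Hill kinetics, integration, steady
# state, and linear stability.

test_that("Hill repression has the defining limits", {
  expect_equal(hill_repression(0, 33, 420), 33)
  expect_equal(hill_repression(420, 33, 420), 16.5)
  expect_lt(hill_repression(1e9, 33, 420), 1e-6)
  expect_error(hill_repression(-1, 33, 420), "non-negative")
})

test_that("steady state satisfies the equilibrium balance", {
  pars <- sensitivity_baseline()
  ss <- steady_state(pars)
  expect_lt(abs(pars$b * ss[["p"]] - pars$a * ss[["m"]]), 1e-9)
  expect_lt(abs(hill_repression(ss[["p"]], pars$k, pars$p_crit, pars$n) -
                  pars$c * ss[["m"]]), 1e-9)
  # repression vanishes as p_crit grows: p* -> a k / (b c)
  free <- update_parameters(pars, p_crit = 1e12)
  expect_equal(steady_state(free)[["p"]],
               free$a * free$k / (free$b * free$c), tolerance = 1e-6)
  # weak synthesis: steady state collapses toward zero
  weak <- update_parameters(pars, k = 1e-9)
  expect_lt(steady_state(weak)[["p"]], 1e-6)
})

test_that("zero synthesis with zero history stays at the absorbing state", {
  pars <- update_parameters(sensitivity_baseline(), k = 1e-300)
  sol <- dde_integrate(pars, t_end = 200)
  expect_lt(max(abs(sol$mrna)), 1e-250)
  expect_lt(max(abs(sol$protein)), 1e-250)
})

test_that("the undelayed system converges to the fixed point (ODE oracle)", {
  pars <- clock_parameters(a = 4.5, k = 33, h_p = 3, h_m = 3, p_crit = 420,
                           delays = delay_breakdown(0, 0, 0, 0))
  sol <- dde_integrate(pars, t_end = 400, step = 0.02)
  ss <- steady_state(pars)
  expect_equal(utils::tail(sol$mrna, 1), ss[["m"]], tolerance = 1e-8)
  expect_equal(utils::tail(sol$protein, 1), ss[["p"]], tolerance = 1e-8)
  # independent stiff ODE oracle on the same undelayed system
  ode_sol <- deSolve::ode(
    c(m = 0, p = 0), c(0, 400),
    function(t, y, parms) list(c(
      hill_repression(y[2], pars$k, pars$p_crit, pars$n) - pars$c * y[1],
      pars$a * y[1] - pars$b * y[2])), NULL)
  expect_equal(unname(ode_sol[2, "m"]), ss[["m"]], tolerance = 1e-5)
  expect_equal(unname(ode_sol[2, "p"]), ss[["p"]], tolerance = 1e-5)
})

test_that("the integrator agrees with an independent adaptive DDE solver", {
  pars <- sensitivity_baseline()
  ours <- estimate_period(dde_integrate(pars))$period
  lagged <- function(t, y, parms) {
    pd <- if (t > pars$delays$t_m) deSolve::lagvalue(t - pars$delays$t_m, 2) else 0
    md <- if (t > pars$delays$t_p) deSolve::lagvalue(t - pars$delays$t_p, 1) else 0
    list(c(hill_repression(pd, pars$k, pars$p_crit, pars$n) - pars$c * y[1],
           pars$a * md - pars$b * y[2]))
  }
  ref <- deSolve::dede(c(m = 0, p = 0), seq(0, 3100, 0.05), lagged, NULL)
  ref_period <- estimate_period(ref[, 2], time = ref[, 1])$period
  expect_lt(abs(ours - ref_period), 0.1)
})

test_that("solutions depend on the delays only through their sum", {
  pars <- sensitivity_baseline()
  base <- estimate_period(dde_integrate(pars))$period
  for (shift in c(-1.5, 0.7, 2)) {
    moved <- clock_parameters(
      a = pars$a, k = pars$k, h_p = pars$h_p, h_m = pars$h_m,
      p_crit = pars$p_crit, n = pars$n,
      delays = delay_breakdown(pars$delays$t_tx, pars$delays$t_in,
                               pars$delays$t_exp - shift,
                               pars$delays$t_p + shift))
    expect_lt(abs(estimate_period(dde_integrate(moved))$period - base), 0.1)
  }
})

test_that("step halving changes the extracted period by far less than 0.1%", {
  pars <- sensitivity_baseline()
  p1 <- estimate_period(dde_integrate(pars, step = 0.02))$period
  p2 <- estimate_period(dde_integrate(pars, step = 0.01))$period
  expect_lt(abs(p1 - p2) / p1, 0.001)
})

test_that("trajectories from non-negative history stay non-negative", {
  for (h_p in c(3, 10, 22)) {
    sol <- dde_integrate(axolotl_bm_params(h_p), t_end = 800)
    expect_gte(min(sol$mrna), -1e-9)
    expect_gte(min(sol$protein), -1e-9)
  }
})

test_that("periods are insensitive to the pre-interval history", {
  pars <- sensitivity_baseline()
  p0 <- estimate_period(dde_integrate(pars))$period
  p1 <- estimate_period(dde_integrate(pars, history = c(m = 10, p = 300)))$period
  expect_lt(abs(p1 - p0), 0.1)
})

test_that("too-large steps and invalid inputs are configuration errors", {
  pars <- sensitivity_baseline()
  expect_error(dde_integrate(pars, step = 1), "step")
  expect_error(dde_integrate(pars, t_end = -5), "positive")
})

test_that("critical delay rises with protein half-life and bounds oscillation", {
  pars <- sensitivity_baseline()
  tc <- vapply(c(3, 8, 15, 22),
               function(h) critical_delay(update_parameters(pars, h_p = h))$t_crit,
               numeric(1))
  expect_true(all(diff(tc) > 0))
  # gain below the geometric-mean bound: no Hopf crossing exists
  weak <- update_parameters(pars, k = 0.05)
  st <- critical_delay(weak)
  expect_false(st$oscillation_possible)
  expect_identical(st$t_crit, Inf)
})

test_that("simulation brackets the computed Hopf point", {
  pars <- sensitivity_baseline()
  st <- critical_delay(pars)
  above <- dde_integrate(update_parameters(pars, total_delay = st$t_crit + 2))
  below <- dde_integrate(update_parameters(pars, total_delay = st$t_crit - 2))
  expect_gt(envelope_ratio(above), 0.5)  # settling onto a limit cycle
  expect_lt(envelope_ratio(below), 0.2)  # decaying to the steady state
  # just above threshold the period matches the crossing frequency
  near <- estimate_period(
    dde_integrate(update_parameters(pars, total_delay = st$t_crit + 0.5)),
    min_amplitude = 0)
  expect_lt(abs(near$period - st$period_at_hopf) / st$period_at_hopf, 0.05)
})
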