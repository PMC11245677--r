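# The delayed-autorepression oscillator: integration, steady state, and
# linear stability (Hopf / critical delay).

#' Hill repression function
#'
#' Transcription rate under delayed autorepression:
#' \eqn{f(p) = k / (1 + (p/p_{crit})^n)}. Half-maximal at `p = p_crit` by
#' construction.
#'
#' @param p_delayed Repressor molecule count at the delayed time (>= 0).
#' @param k Maximal mRNA synthesis rate, mRNA/min/cell.
#' @param p_crit Critical repressor molecule count.
#' @param n Hill coefficient (default 2).
#' @return mRNA synthesis rate, mRNA/min/cell.
#' @export
#' @examples
#' hill_repression(0, 33, 420)   # 33
#' hill_repression(420, 33, 420) # 16.5
hill_repression <- function(p_delayed, k, p_crit, n = 2) {
  if (any(p_delayed < 0)) stop_domain("`p_delayed` must be non-negative")
  check_positive(k, "k")
  check_positive(p_crit, "p_crit")
  if (n < 1) stop_domain("Hill coefficient `n` must be >= 1")
  k / (1 + (p_delayed / p_crit)^n)
}

#' Integrate the delayed-autorepression oscillator
#'
#' Fixed-step classical RK4 with the method of steps: delayed state values
#' are read from the stored dense solution by cubic Hermite interpolation.
#' Pre-history is constant (`m = p = 0` by default, i.e. expression switches
#' on at t = 0). Fixed-step integration is bit-reproducible; convergence is
#' checked in the test suite by step halving (period changes < 0.1%).
#'
#' @param params A [clock_parameters()] object.
#' @param t_end End of the integration window, minutes (default 3100,
#'   spanning at least 20 cycles of the slowest clock studied).
#' @param step Step size, minutes (default 0.02). Must satisfy
#'   `step <= delay/10` for every positive delay; a delay of exactly zero is
#'   allowed (the term becomes undelayed).
#' @param history Named numeric vector `c(m = , p = )` with the constant
#'   pre-history on `[-max(T_m, T_p), 0]`.
#' @return An object of class `dde_solution`: `time`, `mrna`, `protein`
#'   (molecule counts per time point), `params`, `step`.
#' @export
#' @examples
#' pars <- clock_parameters(h_p = 15, p_crit = 420,
#'                          delays = delay_breakdown(6.89, 12.78, 11.97, 2.18))
#' sol <- dde_integrate(pars, t_end = 600)
#' range(sol$mrna)
dde_integrate <- function(params, t_end = 3100, step = 0.02,
                          history = c(m = 0, p = 0)) {
  if (!inherits(params, "clock_parameters"))
    stop_domain("`params` must be a clock_parameters object")
  check_positive(t_end, "t_end")
  check_positive(step, "step")
  t_m <- params$delays$t_m
  t_p <- params$delays$t_p
  for (d in c(T_m = t_m, T_p = t_p)) {
    if (d > 0 && step > d / 10)
      stop_domain(sprintf(
        "step %.4g min is too large for delay %.4g min (need step <= delay/10)",
        step, d))
  }
  if (length(history) < 2L) stop_domain("`history` must supply m and p")
  m0 <- if ("m" %in% names(history)) unname(history[["m"]]) else history[[1L]]
  p0 <- if ("p" %in% names(history)) unname(history[["p"]]) else history[[2L]]
  if (is.na(m0) || is.na(p0)) stop_domain("`history` must supply m and p")
  out <- dde_lewis_rk4(params$a, params$b, params$c, params$k, params$p_crit,
                       params$n, t_m, t_p, t_end, step, m0, p0)
  n_nodes <- length(out$mrna)
  structure(
    list(time = seq(0, by = step, length.out = n_nodes),
         mrna = out$mrna, protein = out$protein,
         params = params, step = step),
    class = "dde_solution"
  )
}

#' @export
print.dde_solution <- function(x, ...) {
  cat(sprintf("<dde_solution> t in [0, %g] min, step %g min (%d points)\n",
              max(x$time), x$step, length(x$time)))
  cat(sprintf("  mRNA in [%.3g, %.3g], protein in [%.3g, %.3g]\n",
              min(x$mrna), max(x$mrna), min(x$protein), max(x$protein)))
  invisible(x)
}

#' @export
as.data.frame.dde_solution <- function(x, ...) {
  data.frame(time = x$time, mrna = x$mrna, protein = x$protein)
}

#' Positive steady state of the oscillator
#'
#' Solves the equilibrium conditions `a m* = b p*` and `f(p*) = c m*` as a
#' one-dimensional monotone root-find in `p*` (unique positive root for
#' positive parameters).
#'
#' @param params A [clock_parameters()] object.
#' @param tol Root-finder tolerance (default 1e-12).
#' @return Named numeric `c(m = m*, p = p*)`.
#' @export
steady_state <- function(params, tol = 1e-12) {
  with(params, {
    upper <- a * k / (b * c) # repression-free balance bounds p*
    fn <- function(p) p - a * hill_repression(p, k, p_crit, n) / (b * c)
    root <- stats::uniroot(fn, c(0, upper), tol = tol)$root
    c(m = hill_repression(root, params$k, params$p_crit, params$n) / c, p = root)
  })
}

#' Linear stability and critical delay of the steady state
#'
#' Linearizes the oscillator about its positive steady state. The
#' characteristic equation is
#' \eqn{(\lambda + b)(\lambda + c) = a f'(p^*) e^{-\lambda T}} with
#' \eqn{T = T_m + T_p} (dynamics depend on the delays only through their
#' sum). A purely imaginary root \eqn{\lambda = i\omega} exists iff the
#' feedback gain exceeds the geometric-mean degradation bound,
#' \eqn{|a f'(p^*)| > bc}; then \eqn{\omega} solves the modulus equation
#' \eqn{(\omega^2+b^2)(\omega^2+c^2) = (a f'(p^*))^2} and the smallest
#' delay with a crossing is
#' \eqn{T_{crit} = (\pi - \arctan(\omega/b) - \arctan(\omega/c)) / \omega}.
#' Sustained oscillations require total delay >= `t_crit`; otherwise the
#' steady state is stable for every delay and `t_crit` is `Inf`.
#'
#' @param params A [clock_parameters()] object (its delays are not used
#'   except for reporting the margin).
#' @return An object of class `stability_result`: `steady_state`, `sqrt_k`
#'   (geometric mean of degradation rates, min^-1), `gain` (`a f'(p*)`),
#'   `oscillation_possible`, `omega` (rad/min), `t_crit` (minutes or `Inf`),
#'   `period_at_hopf` (`2 pi / omega`), `total_delay`.
#' @export
#' @examples
#' pars <- clock_parameters(h_p = 15, p_crit = 420,
#'                          delays = delay_breakdown(6.89, 12.78, 11.97, 2.18))
#' critical_delay(pars)
critical_delay <- function(params) {
  ss <- steady_state(params)
  b <- params$b; c <- params$c
  x <- ss[["p"]] / params$p_crit
  fprime <- -params$k * params$n * x^(params$n - 1) /
    (params$p_crit * (1 + x^params$n)^2)
  gain <- params$a * fprime
  possible <- abs(gain) > b * c
  if (possible) {
    s2 <- b^2 + c^2
    omega <- sqrt((-s2 + sqrt(s2^2 - 4 * (b^2 * c^2 - gain^2))) / 2)
    t_crit <- (pi - atan(omega / b) - atan(omega / c)) / omega
    period <- 2 * pi / omega
  } else {
    omega <- NA_real_; t_crit <- Inf; period <- NA_real_
  }
  structure(
    list(steady_state = ss, sqrt_k = sqrt(b * c), gain = gain,
         oscillation_possible = possible, omega = omega, t_crit = t_crit,
         period_at_hopf = period, total_delay = total_delay(params)),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result>\n")
  cat(sprintf("  steady state: m* = %.4g, p* = %.4g molecules\n",
              x$steady_state[["m"]], x$steady_state[["p"]]))
  cat(sprintf("  sqrt(bc) = %.4g /min, gain a f'(p*) = %.4g /min\n", x$sqrt_k, x$gain))
  if (x$oscillation_possible) {
    cat(sprintf("  Hopf crossing: omega = %.4g rad/min, T_crit = %.4g min (period %.4g min)\n",
                x$omega, x$t_crit, x$period_at_hopf))
    cat(sprintf("  total delay %.4g min: %s\n", x$total_delay,
                if (x$total_delay >= x$t_crit) "oscillatory" else "damped"))
  } else {
    cat("  no Hopf crossing exists (steady state stable for all delays); T_crit = Inf\n")
  }
  invisible(x)
}
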