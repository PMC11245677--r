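# The three computational experiments: species/diffusion period grids,
# the +/-50% sensitivity analysis, and the mRNA-stability scaling scenarios,
# plus the nuclear-degradation arithmetic.

#' Specification of a (total delay x protein half-life) period grid
#'
#' @param base_params A [clock_parameters()] object giving the kinetic
#'   constants and the species delay split; across the grid `T_p` stays at
#'   its species value and `T_m` is adjusted to realize each total delay
#'   (the dynamics depend on the delays only through their sum).
#' @param delay_center Centre of the total-delay axis, minutes (default: the
#'   base parameters' total delay).
#' @param delay_halfwidth Half-width of the total-delay axis (default 5 min).
#' @param delay_step Total-delay resolution (default 0.5 min; 21 columns).
#' @param h_p Protein half-life axis, minutes (default `seq(3, 22, 1)`).
#' @param t_span Integration span per cell, minutes (default 3100).
#' @param dde_step Integrator step (default 0.02 min).
#' @param target_period Species' observed clock period, minutes (optional).
#' @param capture_tol Cells with `|period - target| <= capture_tol` form the
#'   capture set (default 2 min).
#' @param drop_cycles,min_amplitude Passed to [estimate_period()].
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(base_params, delay_center = total_delay(base_params),
                      delay_halfwidth = 5, delay_step = 0.5,
                      h_p = seq(3, 22, by = 1), t_span = 3100, dde_step = 0.02,
                      target_period = NULL, capture_tol = 2,
                      drop_cycles = 5, min_amplitude = 10) {
  delays <- seq(delay_center - delay_halfwidth, delay_center + delay_halfwidth,
                by = delay_step)
  if (length(delays) == 0L || length(h_p) == 0L)
    stop_domain("grid axes must be non-empty")
  if (any(delays <= base_params$delays$t_p))
    stop_domain("all total delays must exceed the protein delay")
  structure(
    list(base_params = base_params, total_delays = delays, h_p = h_p,
         t_span = t_span, dde_step = dde_step, target_period = target_period,
         capture_tol = capture_tol, drop_cycles = drop_cycles,
         min_amplitude = min_amplitude),
    class = "grid_spec"
  )
}

#' Period and amplitude across a parameter grid
#'
#' Integrates the oscillator and extracts the oscillation summary for every
#' (total delay, protein half-life) cell. A cell whose integration fails is
#' recorded as damped (`period = Inf`) with `failed = TRUE` rather than
#' aborting the sweep.
#'
#' @param spec A [grid_spec()].
#' @return An object of class `clock_grid`: `cells` (tidy data frame with
#'   `total_delay`, `h_p`, `period`, `amplitude`, `robust`, `failed`),
#'   `spec`, `max_finite_period`, and (when a target is set) `capture`
#'   (subset of cells within tolerance of the target).
#' @export
#' @examples
#' \donttest{
#' cfg <- species_defaults("xenopus_laevis", "normal")
#' sp <- grid_spec(assemble_parameters(cfg), target_period = 56)
#' g <- run_grid(sp)
#' g$max_finite_period
#' }
run_grid <- function(spec) {
  if (!inherits(spec, "grid_spec")) stop_domain("`spec` must be a grid_spec")
  cells <- expand.grid(total_delay = spec$total_delays, h_p = spec$h_p,
                       KEEP.OUT.ATTRS = FALSE)
  n <- nrow(cells)
  period <- numeric(n); amplitude <- numeric(n)
  robust <- logical(n); failed <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      pars <- update_parameters(spec$base_params, h_p = cells$h_p[i],
                                total_delay = cells$total_delay[i])
      sol <- dde_integrate(pars, t_end = spec$t_span, step = spec$dde_step)
      estimate_period(sol, drop_cycles = spec$drop_cycles,
                      min_amplitude = spec$min_amplitude)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      period[i] <- Inf; amplitude[i] <- 0; robust[i] <- FALSE; failed[i] <- TRUE
    } else {
      period[i] <- res$period; amplitude[i] <- res$mean_amplitude
      robust[i] <- res$robust
    }
  }
  cells$period <- period; cells$amplitude <- amplitude
  cells$robust <- robust; cells$failed <- failed
  finite <- is.finite(period)
  capture <- NULL
  if (!is.null(spec$target_period))
    capture <- cells[finite &
                       abs(period - spec$target_period) <= spec$capture_tol, ,
                     drop = FALSE]
  structure(
    list(cells = cells, spec = spec,
         max_finite_period = if (any(finite)) max(period[finite]) else NA_real_,
         capture = capture),
    class = "clock_grid"
  )
}

#' @export
print.clock_grid <- function(x, ...) {
  cells <- x$cells
  cat(sprintf("<clock_grid> %d x %d cells (total delay %.4g-%.4g min, h_p %g-%g min)\n",
              length(x$spec$total_delays), length(x$spec$h_p),
              min(x$spec$total_delays), max(x$spec$total_delays),
              min(x$spec$h_p), max(x$spec$h_p)))
  cat(sprintf("  oscillatory cells: %d/%d; max finite period %.2f min\n",
              sum(cells$robust), nrow(cells), x$max_finite_period))
  if (!is.null(x$spec$target_period))
    cat(sprintf("  capture set at %g +/- %g min: %d cells\n",
                x$spec$target_period, x$spec$capture_tol,
                if (is.null(x$capture)) 0L else nrow(x$capture)))
  invisible(x)
}

#' Heatmap of a period grid
#'
#' Periods as an image over (total delay, protein half-life); damped cells
#' are blank and the capture set, if any, is outlined with points.
#'
#' @param x A [run_grid()] result.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.clock_grid <- function(x, ...) {
  td <- x$spec$total_delays; hp <- x$spec$h_p
  z <- matrix(x$cells$period, nrow = length(td))
  z[!is.finite(z)] <- NA
  graphics::image(td, hp, z, xlab = "total delay T_m + T_p (min)",
                  ylab = "protein half-life h_p (min)",
                  main = if (!is.null(x$spec$target_period))
                    sprintf("oscillation period (target %g min)", x$spec$target_period)
                  else "oscillation period (min)", ...)
  if (!is.null(x$capture) && nrow(x$capture) > 0L)
    graphics::points(x$capture$total_delay, x$capture$h_p, pch = 1, cex = 0.8)
  invisible(x)
}

#' Baseline parameters for the sensitivity analysis
#'
#' The A. mexicanum Brownian-diffusion parameter set with protein half-life
#' fixed at 15 min: `a = 4.5`, `k = 33`, `p_crit = 420`, `h_m = 3`,
#' `h_p = 15`, total delay 33.82 min (T_m 31.64 + T_p 2.18).
#'
#' @return A [clock_parameters()] object.
#' @export
sensitivity_baseline <- function() {
  clock_parameters(a = 4.5, k = 33, h_p = 15, h_m = 3, p_crit = 420, n = 2,
                   delays = delay_breakdown(6.89, 12.78, 11.97, 2.18))
}

#' One-at-a-time sensitivity of the oscillation period
#'
#' Increases and decreases each of `a`, `k`, `p_crit`, `h_m`, `h_p`, and the
#' total delay (varied as a single parameter, with `T_p` held at its species
#' value) by `fraction`, holding all other parameters at baseline, and
#' tracks the resulting change in period.
#'
#' @param baseline A [clock_parameters()] object (default
#'   [sensitivity_baseline()]); must itself oscillate robustly.
#' @param fraction Relative perturbation (default 0.5, i.e. +/-50%).
#' @param t_span,step Integration settings (defaults 3100 min, 0.02 min).
#' @param drop_cycles,min_amplitude Passed to [estimate_period()].
#' @return An object of class `sensitivity_report`: a data frame with one row
#'   per (parameter, direction): `parameter`, `direction`, `value`, `period`,
#'   `pct_change` (magnitude of the percent change, `NA` when damped),
#'   `damped`. The baseline period is attached as attribute
#'   `baseline_period`.
#' @export
#' @examples
#' \donttest{
#' sensitivity()
#' }
sensitivity <- function(baseline = sensitivity_baseline(), fraction = 0.5,
                        t_span = 3100, step = 0.02,
                        drop_cycles = 5, min_amplitude = 10) {
  summarize <- function(pars) {
    sol <- dde_integrate(pars, t_end = t_span, step = step)
    estimate_period(sol, drop_cycles = drop_cycles, min_amplitude = min_amplitude)
  }
  base_sum <- summarize(baseline)
  if (!base_sum$robust)
    stop_domain("the baseline parameter set is itself damped; sensitivity is undefined")
  p0 <- base_sum$period

  settings <- list(
    a = baseline$a, k = baseline$k, p_crit = baseline$p_crit,
    h_m = baseline$h_m, h_p = baseline$h_p, total_delay = total_delay(baseline)
  )
  rows <- list()
  for (nm in names(settings)) {
    for (dirn in c(1, -1)) {
      value <- settings[[nm]] * (1 + dirn * fraction)
      pars <- if (nm == "total_delay")
        update_parameters(baseline, total_delay = value)
      else
        do.call(update_parameters, stats::setNames(list(baseline, value), c("params", nm)))
      s <- summarize(pars)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm,
        direction = if (dirn > 0) sprintf("+%d%%", round(100 * fraction))
        else sprintf("-%d%%", round(100 * fraction)),
        value = value,
        period = s$period,
        pct_change = if (s$robust) 100 * abs(s$period - p0) / p0 else NA_real_,
        damped = !s$robust
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline_period") <- p0
  attr(out, "baseline") <- baseline
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> baseline period %.2f min\n",
              attr(x, "baseline_period")))
  df <- as.data.frame(x)
  df$pct_change <- ifelse(df$damped, "damped", sprintf("%.2f%%", df$pct_change))
  print(df, row.names = FALSE)
  invisible(x)
}

#' mRNA-stability scaling scenarios for A. mexicanum
#'
#' Re-runs the A. mexicanum period grid with the mRNA half-life scaled to the
#' diffusion-specific export delay: `h_m = T_exp`, `T_exp/2`, and `T_exp/4`,
#' all other parameters at their species/diffusion values. Asks whether the
#' observed ~154-min clock is still captured once transcripts are made stable
#' enough to survive the long nuclear transit.
#'
#' @param diffusion `"normal"` or `"fractional"`.
#' @param h_m_factors Multipliers applied to `T_exp` (default `c(1, .5, .25)`).
#' @param target_period Clock period to capture (default 154 min).
#' @param ... Passed to [grid_spec()] (e.g. `delay_step`, `t_span`).
#' @return Named list of [run_grid()] results (`"h_m=1xT_exp"`, ...), with
#'   attribute `t_exp`.
#' @export
stability_scenarios <- function(diffusion = c("normal", "fractional"),
                                h_m_factors = c(1, 0.5, 0.25),
                                target_period = 154, ...) {
  diffusion <- match.arg(diffusion)
  cfg <- species_defaults("ambystoma_mexicanum", diffusion)
  t_exp <- cfg$t_exp
  out <- lapply(h_m_factors, function(f) {
    cfg$h_m <- f * t_exp
    pars <- assemble_parameters(cfg)
    run_grid(grid_spec(pars, target_period = target_period, ...))
  })
  names(out) <- sprintf("h_m=%gxT_exp", h_m_factors)
  attr(out, "t_exp") <- t_exp
  attr(out, "diffusion") <- diffusion
  out
}

#' Fraction of transcripts degrading before nuclear exit
#'
#' Under first-order decay with half-life `h_m`, the fraction of transcripts
#' degraded over the mean export time `T_exp` is `1 - 2^(-T_exp/h_m)`:
#' 50% when `h_m = T_exp`, 75% when `h_m = T_exp/2`.
#'
#' @param t_exp Mean export delay, minutes (>= 0).
#' @param h_m mRNA half-life, minutes (> 0).
#' @return Degraded fraction in `[0, 1)`.
#' @export
#' @examples
#' nuclear_degradation_fraction(26.27, 26.27) # 0.5
nuclear_degradation_fraction <- function(t_exp, h_m) {
  if (any(t_exp < 0)) stop_domain("`t_exp` must be non-negative")
  if (any(h_m <= 0)) stop_domain("`h_m` must be positive")
  1 - 2^(-t_exp / h_m)
}

#' Expected nuclear degradation over an exit-time distribution
#'
#' Averages first-order survival over simulated per-transcript exit times
#' instead of plugging in their mean: `1 - mean(2^(-T_i/h_m))`. By Jensen's
#' inequality this is at most the mean-based figure; the two are exposed side
#' by side because right-skewed exit-time ensembles can make them differ
#' noticeably.
#'
#' @param exit_minutes Vector of per-transcript exit times, minutes (e.g.
#'   `exit_steps * step_duration / 60` from an [export_delay()] result).
#' @param h_m mRNA half-life, minutes.
#' @return Expected degraded fraction in `[0, 1)`.
#' @export
expected_nuclear_degradation <- function(exit_minutes, h_m) {
  if (any(exit_minutes < 0)) stop_domain("exit times must be non-negative")
  if (any(h_m <= 0)) stop_domain("`h_m` must be positive")
  1 - mean(2^(-exit_minutes / h_m))
}
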