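# Synthetic fixtures with known ground truth, used to test every pipeline
# stage without external data: gene models built to hit printed totals
# (make_gene_model, in gene-model.R), oscillatory traces with known
# period/amplitude/damping, and diffusion cases with analytically known mean
# first-exit times.

#' Synthetic oscillatory trace with known ground truth
#'
#' Offset sinusoid with optional exponential damping and additive Gaussian
#' noise:
#' `value = offset + amplitude * exp(-damping_rate * t) * sin(2 pi t / period) + N(0, noise_sigma)`.
#' The generating parameters are attached as attribute `ground_truth`. The
#' deterministic clock model produces noise-free traces; noisy fixtures test
#' estimator robustness, not biology.
#'
#' @param period Oscillation period, minutes (> 0).
#' @param amplitude Half peak-to-trough height, molecules (so the min-to-max
#'   cycle amplitude of the noiseless trace is `2 * amplitude`).
#' @param damping_rate Exponential decay rate of the envelope, min^-1
#'   (default 0).
#' @param noise_sigma Additive Gaussian noise SD, molecules (default 0).
#' @param t_span Trace length, minutes (must be at least `10 * period`).
#' @param dt Sample spacing, minutes (default 0.02).
#' @param offset Vertical offset, molecules (default `2 * amplitude`, keeping
#'   the noiseless trace positive).
#' @param seed Seed for the noise draw (`NULL` = current stream).
#' @return `data.frame(time, value)` with attribute `ground_truth`
#'   (list with `period`, `amplitude`, `cycle_amplitude`, `damping_rate`,
#'   `noise_sigma`, `offset`).
#' @export
#' @examples
#' tr <- make_trace(56, 25, t_span = 3100, dt = 0.1)
#' estimate_period(tr)$period # 56
make_trace <- function(period, amplitude, damping_rate = 0, noise_sigma = 0,
                       t_span, dt = 0.02, offset = 2 * amplitude, seed = NULL) {
  check_positive(period, "period")
  check_positive(amplitude, "amplitude")
  check_positive(dt, "dt")
  check_nonnegative(damping_rate, "damping_rate")
  check_nonnegative(noise_sigma, "noise_sigma")
  if (t_span < 10 * period)
    stop_domain("`t_span` must be at least 10 periods (transient removal discards 5 cycles)")
  time <- seq(0, t_span, by = dt)
  value <- offset + amplitude * exp(-damping_rate * time) * sin(2 * pi * time / period)
  if (noise_sigma > 0)
    value <- value + with_seed(seed, stats::rnorm(length(time), sd = noise_sigma))
  structure(
    data.frame(time = time, value = value),
    ground_truth = list(period = period, amplitude = amplitude,
                        cycle_amplitude = 2 * amplitude,
                        damping_rate = damping_rate,
                        noise_sigma = noise_sigma, offset = offset)
  )
}

#' Diffusion test case with analytically known mean first-exit time
#'
#' Packages a sphere radius and an effective diffusion coefficient with the
#' analytic centre-start MFET \eqn{r^2/(6D)}, as an oracle for the Brownian
#' first-exit simulations.
#'
#' @param radius Sphere radius, um.
#' @param D_effective Diffusion coefficient, um^2/min (default 0.45, the
#'   value calibrated to the zebrafish export time).
#' @return List with `radius`, `D`, `expected_minutes`, and `scale_factor`,
#'   the per-step spatial scale (um per unit increment at 1-s steps) whose
#'   Brownian walk has that diffusion coefficient (`sigma = sqrt(2 D / 60)`
#'   per axis).
#' @export
#' @examples
#' make_diffusion_case(3)$expected_minutes # 3.33
make_diffusion_case <- function(radius, D_effective = 0.45) {
  check_positive(radius, "radius")
  check_positive(D_effective, "D_effective")
  list(radius = radius, D = D_effective,
       expected_minutes = mfet_analytic(radius, D_effective),
       scale_factor = sqrt(2 * D_effective / 60))
}
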