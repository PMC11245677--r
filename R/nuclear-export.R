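# Nuclear mRNA export as a first-exit-time problem.
#
# A newly transcribed mRNA starts at its chromatin address (nuclear centre by
# default, reflecting the gene-rich central territories of hes7-bearing
# chromosomes) and diffuses until it first crosses the nuclear periphery.
# Normal diffusion is a 3D random walk with i.i.d. Gaussian increments;
# obstructed diffusion is fractional Brownian motion with Hurst exponent
# H = 0.25 (anomalous exponent alpha = 2H = 0.5), whose anti-correlated
# increments make walkers backtrack as if blocked by chromatin. Each step
# lasts one second; the spatial step scale is calibrated so that the mean
# first-exit time from a 3-um sphere (zebrafish PSM nucleus) matches the
# empirical 3.36-min her1 export time (about 202 steps).

#' Diffusion simulation settings
#'
#' @param mode `"normal"` (Brownian) or `"fractional"` (fractional Brownian).
#' @param hurst Hurst exponent in (0,1); default 0.25 for fractional mode,
#'   0.5 for normal mode (where it is only informational: fBM with H = 0.5
#'   is ordinary Brownian motion).
#' @param step_duration Seconds per simulation step (default 1).
#' @param n_trajectories Walkers per ensemble (default 10000).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param start_rule `"center"` or `"uniform_three_quarter"` (uniform within
#'   the ball of radius 3r/4, excluding the heterochromatin-rich periphery).
#' @param max_steps Hard cap on steps per trajectory; non-exited walkers are
#'   excluded with a recorded count (default 1e7).
#' @param path_mult Fractional mode only: paths are pre-generated with length
#'   the next power of two above `path_mult` times the scaling-law estimate
#'   of the mean exit step count (default 8; the estimate is itself an upper
#'   bound because the running maximum of a path exceeds its endpoint
#'   displacement), capped at `max_steps`. The exit-time tail is exponential,
#'   so the observed maximum is about 6-7x the mean at these ensemble sizes.
#' @return An object of class `diffusion_settings`.
#' @export
diffusion_settings <- function(mode = c("normal", "fractional"),
                               hurst = NULL, step_duration = 1,
                               n_trajectories = 10000, seed = NULL,
                               start_rule = c("center", "uniform_three_quarter"),
                               max_steps = 1e7, path_mult = 8) {
  mode <- match.arg(mode)
  start_rule <- match.arg(start_rule)
  hurst <- hurst %||% if (mode == "fractional") 0.25 else 0.5
  if (!is.numeric(hurst) || hurst <= 0 || hurst >= 1)
    stop_domain("`hurst` must lie strictly in (0, 1)")
  check_positive(step_duration, "step_duration")
  check_positive(n_trajectories, "n_trajectories")
  structure(
    list(mode = mode, hurst = hurst, alpha = 2 * hurst,
         step_duration = step_duration,
         n_trajectories = as.integer(n_trajectories), seed = seed,
         start_rule = start_rule, max_steps = max_steps,
         path_mult = path_mult),
    class = "diffusion_settings"
  )
}

#' @export
print.diffusion_settings <- function(x, ...) {
  cat(sprintf("<diffusion_settings> %s (H = %g, alpha = %g), %d trajectories, %gs steps, start: %s\n",
              x$mode, x$hurst, x$alpha, x$n_trajectories, x$step_duration, x$start_rule))
  invisible(x)
}

# Autocovariance of unit-variance fractional Gaussian noise at integer lags.
fgn_autocovariance <- function(lag, hurst) {
  h2 <- 2 * hurst
  0.5 * (abs(lag + 1)^h2 - 2 * abs(lag)^h2 + abs(lag - 1)^h2)
}

# Eigenvalues of the circulant embedding are deterministic per (n, H);
# cache them across the thousands of path batches a sweep generates.
.fgn_cache <- new.env(parent = emptyenv())

fgn_eigenvalues <- function(n, hurst) {
  key <- sprintf("%d_%.17g", n, hurst)
  ev <- .fgn_cache[[key]]
  if (is.null(ev)) {
    g <- fgn_autocovariance(0:n, hurst)
    circ <- c(g, g[n:2])                    # length 2n
    ev <- Re(stats::fft(circ))
    ev[ev < 0 & ev > -1e-8 * max(ev)] <- 0  # clip tiny negative rounding error
    if (any(ev < 0))
      stop_domain("circulant embedding is not non-negative definite for this H/n")
    .fgn_cache[[key]] <- ev
  }
  ev
}

#' Fractional Gaussian noise by circulant embedding
#'
#' Generates exact unit-variance fGn (the increment process of fractional
#' Brownian motion) by the circulant-embedding (Davies-Harte) construction in
#' the paired Dietrich-Newsam form: one complex FFT of the eigenvalue-scaled
#' Gaussian vector yields two independent real fGn paths (its real and
#' imaginary parts). Exact whenever the embedding is non-negative definite,
#' which holds for all H <= 0.5 (the regime used here) and in practice for
#' the full (0,1) range at these path lengths.
#'
#' @param n_steps Increments per path.
#' @param hurst Hurst exponent in (0,1).
#' @param n_paths Number of independent paths (columns).
#' @return `n_steps x n_paths` numeric matrix of increments.
#' @export
fgn_davies_harte <- function(n_steps, hurst, n_paths = 1) {
  if (n_steps < 1) stop_domain("`n_steps` must be >= 1")
  if (hurst <= 0 || hurst >= 1) stop_domain("`hurst` must lie strictly in (0, 1)")
  n <- as.integer(n_steps)
  if (n == 1L) return(matrix(stats::rnorm(n_paths), 1L, n_paths))
  ev <- fgn_eigenvalues(n, hurst)
  m <- 2L * n
  half <- as.integer(ceiling(n_paths / 2))
  z <- matrix(complex(real = stats::rnorm(m * half),
                      imaginary = stats::rnorm(m * half)), m, half)
  e <- stats::mvfft(sqrt(ev) * z) / sqrt(m)
  out <- cbind(Re(e[seq_len(n), , drop = FALSE]),
               Im(e[seq_len(n), , drop = FALSE]))
  out[, seq_len(n_paths), drop = FALSE]
}

#' Fractional Gaussian noise by Cholesky factorization
#'
#' Direct O(n^3) reference generator used as the independent oracle for
#' [fgn_davies_harte()] in tests; exact for any valid covariance. Intended
#' for short paths only.
#'
#' @inheritParams fgn_davies_harte
#' @return `n_steps x n_paths` numeric matrix.
#' @export
fgn_cholesky <- function(n_steps, hurst, n_paths = 1) {
  if (n_steps > 4096) stop_domain("Cholesky generator is for short paths (n <= 4096)")
  g <- stats::toeplitz(fgn_autocovariance(0:(n_steps - 1L), hurst))
  r <- chol(g)
  z <- matrix(stats::rnorm(n_steps * n_paths), n_steps, n_paths)
  crossprod(r, z)
}

#' Per-axis increment streams for one trajectory
#'
#' @param settings A [diffusion_settings()].
#' @param n_steps Number of increments.
#' @return `n_steps x 3` matrix of unit-scale increments (columns x, y, z);
#'   i.i.d. Gaussian in normal mode, fGn in fractional mode (negatively
#'   correlated for H < 0.5).
#' @export
generate_path_increments <- function(settings, n_steps) {
  if (n_steps < 1) stop_domain("`n_steps` must be >= 1")
  with_seed(settings$seed, {
    if (settings$mode == "normal") {
      matrix(stats::rnorm(3L * n_steps), n_steps, 3L,
             dimnames = list(NULL, c("x", "y", "z")))
    } else {
      out <- fgn_davies_harte(n_steps, settings$hurst, 3L)
      dimnames(out) <- list(NULL, c("x", "y", "z"))
      out
    }
  })
}

# Start positions as a 3 x n matrix according to the start rule. Uniform
# starts are rejection-sampled inside the ball of radius 3r/4 (per-axis
# uniforms alone would put cube corners outside the sphere).
start_positions <- function(radius, n, rule) {
  if (rule == "center") return(matrix(0, 3L, n))
  rmax <- 0.75 * radius
  out <- matrix(NA_real_, 3L, n)
  need <- n
  filled <- 0L
  while (need > 0L) {
    cand <- matrix(stats::runif(3L * ceiling(need * 2.2), -rmax, rmax), nrow = 3L)
    keep <- colSums(cand^2) <= rmax^2
    take <- min(sum(keep), need)
    if (take > 0L) {
      out[, filled + seq_len(take)] <- cand[, which(keep)[seq_len(take)], drop = FALSE]
      filled <- filled + take
      need <- need - take
    }
  }
  out
}

# Vectorized Brownian first-exit: walkers advance together, exited columns
# are dropped. Returns list(steps, excluded_index).
sim_exit_normal <- function(radius, n, sigma, start, max_steps) {
  r2 <- radius^2
  steps <- rep(NA_integer_, n)
  pos <- start
  idx <- seq_len(n)
  # columns already outside (possible only for off-centre starts) exit at step 1
  s <- 0L
  while (length(idx) > 0L && s < max_steps) {
    s <- s + 1L
    m <- length(idx)
    pos <- pos + sigma * matrix(stats::rnorm(3L * m), 3L, m)
    out <- .colSums(pos^2, 3L, m) > r2
    if (any(out)) {
      steps[idx[out]] <- s
      keep <- !out
      pos <- pos[, keep, drop = FALSE]
      idx <- idx[keep]
    }
  }
  list(steps = steps[!is.na(steps)], excluded = idx)
}

# Fractional first-exit: full fGn paths generated in batches, exit located as
# the first index whose cumulative position leaves the sphere.
sim_exit_fractional <- function(radius, n, sigma, hurst, start, path_len,
                                max_cells = 3e6) {
  r2 <- radius^2
  steps <- rep(NA_integer_, n)
  batch <- max(1L, floor(max_cells / path_len))
  done <- 0L
  while (done < n) {
    m <- min(batch, n - done)
    cols <- done + seq_len(m)
    px <- sweep(sigma * apply(fgn_davies_harte(path_len, hurst, m), 2, cumsum),
                2, start[1L, cols], `+`)
    py <- sweep(sigma * apply(fgn_davies_harte(path_len, hurst, m), 2, cumsum),
                2, start[2L, cols], `+`)
    pz <- sweep(sigma * apply(fgn_davies_harte(path_len, hurst, m), 2, cumsum),
                2, start[3L, cols], `+`)
    hit <- px^2 + py^2 + pz^2 > r2
    steps[cols] <- apply(hit, 2, function(v) match(TRUE, v))
    done <- done + m
  }
  list(steps = steps[!is.na(steps)], excluded = which(is.na(steps)))
}

# Expected mean exit steps from the centre at unit-variance increments scaled
# by sigma: E[T] ~ (r / (sqrt(3) sigma))^(1/H) (exact r^2/(3 sigma^2) for BM).
expected_exit_steps <- function(radius, sigma, hurst) {
  (radius / (sqrt(3) * sigma))^(1 / hurst)
}

#' First-exit step counts for an ensemble of walkers
#'
#' Simulates `settings$n_trajectories` walkers from the configured start rule
#' and returns the first step index at which each scaled 3D position's
#' Euclidean norm exceeds `radius` (strict crossing, no within-step
#' interpolation). Walkers that have not exited by the step cap are excluded;
#' their count is attached as attribute `n_excluded` and warned about.
#'
#' @param radius Sphere radius, um.
#' @param settings A [diffusion_settings()].
#' @param scale_factor Spatial scale, um per unit increment (from
#'   [calibrate_scale()]).
#' @return Integer vector of exit step counts (attribute `n_excluded`).
#' @export
first_exit_steps <- function(radius, settings, scale_factor) {
  check_positive(radius, "radius")
  check_positive(scale_factor, "scale_factor")
  with_seed(settings$seed, {
    n <- settings$n_trajectories
    start <- start_positions(radius, n, settings$start_rule)
    res <- if (settings$mode == "normal") {
      sim_exit_normal(radius, n, scale_factor, start, settings$max_steps)
    } else {
      expected <- expected_exit_steps(radius, scale_factor, settings$hurst)
      path_len <- min(settings$max_steps,
                      2^ceiling(log2(max(1024, settings$path_mult * expected))))
      sim_exit_fractional(radius, n, scale_factor, settings$hurst, start, path_len)
    }
    if (length(res$excluded) > 0L)
      warning(sprintf("%d of %d walkers did not exit within the step cap and were excluded",
                      length(res$excluded), n))
    structure(as.integer(res$steps), n_excluded = length(res$excluded))
  })
}

#' Calibrate the spatial step scale to a reference exit time
#'
#' Finds the spatial scale (um per unit increment at fixed one-second steps)
#' such that the mean first-exit time from the centre of a sphere of
#' `reference_radius` equals `reference_time`. Defaults anchor both diffusion
#' modes to the empirical zebrafish export time: 3.36 min (about 202
#' one-second steps) from a 3-um nucleus. The search runs a fixed-seed pilot
#' ensemble and updates the scale by the exact scaling law
#' `E[T] proportional to scale^(-1/H)`, which converges in a few iterations
#' under common random numbers.
#'
#' @param settings A [diffusion_settings()]; calibration always starts
#'   walkers at the centre (the reference is a centre-start exit time).
#' @param reference_radius Reference sphere radius, um (default 3).
#' @param reference_time Target mean exit time, minutes (default 3.36).
#' @param tol Relative tolerance on the pilot mean (default 0.02).
#' @param n_pilot Pilot ensemble size (default 2000).
#' @param max_iter Iteration cap (default 12).
#' @return Scale factor (um per unit increment) with attributes `mode`,
#'   `hurst`, `reference_radius`, `reference_time`, `pilot_mean_minutes`.
#' @export
calibrate_scale <- function(settings, reference_radius = 3, reference_time = 3.36,
                            tol = 0.02, n_pilot = 2000, max_iter = 12) {
  check_positive(reference_radius, "reference_radius")
  check_positive(reference_time, "reference_time")
  target_steps <- reference_time * 60 / settings$step_duration
  h_eff <- if (settings$mode == "normal") 0.5 else settings$hurst
  pilot <- settings
  pilot$n_trajectories <- as.integer(n_pilot)
  pilot$start_rule <- "center"
  pilot$seed <- (settings$seed %||% 0L) + 104729L
  sigma <- reference_radius / (sqrt(3) * target_steps^h_eff)
  for (it in seq_len(max_iter)) {
    st <- first_exit_steps(reference_radius, pilot, sigma)
    mean_steps <- mean(st)
    if (abs(mean_steps - target_steps) / target_steps <= tol) {
      return(structure(sigma,
                       mode = settings$mode, hurst = settings$hurst,
                       reference_radius = reference_radius,
                       reference_time = reference_time,
                       pilot_mean_minutes = mean_steps * settings$step_duration / 60))
    }
    sigma <- sigma * (mean_steps / target_steps)^h_eff
  }
  stop_domain(sprintf(
    "calibration did not reach %.3g min +/- %.0f%% at r = %g um within %d iterations (last pilot mean %.3g min)",
    reference_time, 100 * tol, reference_radius, max_iter,
    mean_steps * settings$step_duration / 60))
}

#' Mean export delay for one nuclear radius
#'
#' @inheritParams first_exit_steps
#' @return An object of class `exit_time_result`: `radius`, `settings`,
#'   `exit_steps`, `n_excluded`, `mean_time` and `sd_time` (minutes),
#'   `scale_factor`.
#' @export
#' @examples
#' \donttest{
#' s <- diffusion_settings("normal", n_trajectories = 2000, seed = 1)
#' sc <- calibrate_scale(s)
#' export_delay(4, s, sc)$mean_time # ~5.9 min (r^2/(6D) with D = 0.45)
#' }
export_delay <- function(radius, settings, scale_factor) {
  steps <- first_exit_steps(radius, settings, scale_factor)
  to_min <- settings$step_duration / 60
  structure(
    list(radius = radius, settings = settings,
         exit_steps = as.integer(steps),
         n_excluded = attr(steps, "n_excluded"),
         mean_time = mean(steps) * to_min,
         sd_time = stats::sd(steps) * to_min,
         scale_factor = as.numeric(scale_factor)),
    class = "exit_time_result"
  )
}

#' @export
print.exit_time_result <- function(x, ...) {
  cat(sprintf("<exit_time_result> r = %g um, %s: mean %.3f min (sd %.3f, n = %d, excluded %d)\n",
              x$radius, x$settings$mode, x$mean_time, x$sd_time,
              length(x$exit_steps), x$n_excluded))
  invisible(x)
}

#' Analytic mean first-exit time from the centre of a sphere
#'
#' Closed form for normal diffusion: \eqn{r^2 / (6D)}. With the study's
#' calibrated diffusion coefficient D = 0.45 um^2/min this reproduces the
#' 3.36-min zebrafish export time at r = 3 um. No analytic counterpart exists
#' for the subdiffusive case.
#'
#' @param radius Sphere radius, um.
#' @param D Diffusion coefficient, um^2/min (default 0.45).
#' @return MFET in minutes.
#' @export
#' @examples
#' mfet_analytic(3)   # 3.33 min
#' mfet_analytic(5.5) # 11.2 min
mfet_analytic <- function(radius, D = 0.45) {
  if (!is.numeric(radius) || any(!is.finite(radius) | radius <= 0))
    stop_domain("`radius` must be positive and finite")
  if (!is.numeric(D) || any(!is.finite(D) | D <= 0))
    stop_domain("`D` must be positive and finite")
  radius^2 / (6 * D)
}

#' Export delay across a range of nuclear radii
#'
#' @param radii Numeric vector of radii in (0, 13] um (the observed range of
#'   nuclear radii across the tree of life).
#' @param settings A [diffusion_settings()]. Each radius uses seed
#'   `settings$seed + position - 1`, so a single-radius sweep reproduces
#'   [export_delay()] with the same seed.
#' @param scale_factor Calibrated spatial scale for this mode.
#' @return Data frame: `radius`, `mode`, `hurst`, `start_rule`, `mean_min`,
#'   `sd_min`, `median_min`, `n`, `n_excluded`, `seed`.
#' @export
radius_sweep <- function(radii, settings, scale_factor) {
  if (length(radii) == 0L) stop_domain("`radii` must be non-empty")
  if (any(radii <= 0 | radii > 13)) stop_domain("radii must lie in (0, 13] um")
  rows <- lapply(seq_along(radii), function(i) {
    si <- settings
    if (!is.null(settings$seed)) si$seed <- settings$seed + i - 1L
    res <- export_delay(radii[i], si, scale_factor)
    data.frame(radius = radii[i], mode = settings$mode, hurst = settings$hurst,
               start_rule = settings$start_rule,
               mean_min = res$mean_time, sd_min = res$sd_time,
               median_min = stats::median(res$exit_steps) * settings$step_duration / 60,
               n = length(res$exit_steps), n_excluded = res$n_excluded,
               seed = si$seed %||% NA_integer_)
  })
  do.call(rbind, rows)
}
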