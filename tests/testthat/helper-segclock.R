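# Shared fixtures for the test suite. Everything is generated in code; the
# printed two-species values live in species_defaults().

axolotl_bm_params <- function(h_p = 15) {
  assemble_parameters(modifyList(
    species_defaults("ambystoma_mexicanum", "normal"), list(h_p = h_p)))
}

frog_bm_params <- function(h_p = 15) {
  assemble_parameters(modifyList(
    species_defaults("xenopus_laevis", "normal"), list(h_p = h_p)))
}

# A coarse, short grid for structural tests (not the study resolution).
small_grid <- function(params, target = NULL, t_span = 1600) {
  run_grid(grid_spec(params, delay_halfwidth = 4, delay_step = 2,
                     h_p = c(4, 8, 12, 16), t_span = t_span,
                     target_period = target))
}

# Envelope decay diagnostic: ratio of the last to the first retained cycle
# amplitude (max minus following min), on extrema after the 5-cycle burn-in.
envelope_ratio <- function(sol) {
  ext <- find_extrema(sol)
  mx <- ext[ext$type == "max", ]
  mn <- ext[ext$type == "min", ]
  n <- min(nrow(mx), nrow(mn))
  stopifnot(n >= 8)
  (mx$value[n - 1] - mn$value[n - 1]) / (mx$value[6] - mn$value[6])
}
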