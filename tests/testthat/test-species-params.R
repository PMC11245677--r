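# Species-specific parameter derivation from gene structure, nuclear
# geometry, and clock-period fractions.

test_that("critical threshold reproduces the two-species molecule counts", {
  expect_equal(round(critical_threshold(4)), 161)
  expect_equal(round(critical_threshold(5.5)), 420)
})

test_that("critical threshold scales linearly in concentration, cubically in radius", {
  set.seed(42)
  for (r in runif(5, 0.5, 12)) {
    base <- critical_threshold(r)
    expect_equal(critical_threshold(r, 3e-9), 3 * base)
    expect_equal(critical_threshold(2 * r), 8 * base)
  }
  expect_error(critical_threshold(-1), "positive")
  expect_error(critical_threshold(4, 0), "positive")
})

test_that("delay arithmetic matches the printed species table at printed precision", {
  frog <- gene_model("hes5.7L", 1604, 465, c(166, 113))
  axolotl <- gene_model("hes7", 8272, 783, c(3017, 1260, 2030))
  expect_equal(round_half_up(translation_delay(frog), 2), 1.29)
  expect_equal(round_half_up(translation_delay(axolotl), 2), 2.18)
  expect_equal(round_half_up(transcription_delay(frog), 2), 1.34)
  expect_equal(round_half_up(transcription_delay(axolotl), 2), 6.89)
  expect_equal(round_half_up(splicing_delay(56), 2), 4.65)
  expect_equal(round_half_up(splicing_delay(154), 2), 12.78)
})

test_that("delay operations handle trivial and invalid inputs", {
  expect_equal(translation_delay(0), 0)
  expect_equal(transcription_delay(1200), 1.0)
  expect_equal(splicing_delay(0), 0)
  expect_error(translation_delay(465, rate = 0), "positive")
  expect_error(transcription_delay(1604, rate = -5), "positive")
  expect_error(splicing_delay(56, 1.2), "\\[0, 1\\]")
})

test_that("delay breakdown sums exactly and parameter derivations hold", {
  d <- delay_breakdown(6.89, 12.78, 11.97, 2.18)
  expect_identical(d$t_m, 6.89 + 12.78 + 11.97)
  pars <- clock_parameters(h_p = 15, h_m = 3, p_crit = 420, delays = d)
  expect_equal(pars$b * pars$h_p, log(2))
  expect_equal(pars$c * pars$h_m, log(2))
  expect_equal(total_delay(pars), 33.82)
})

test_that("assemble_parameters composes the study totals and is deterministic", {
  xl <- assemble_parameters(species_defaults("xenopus_laevis", "normal"))
  expect_equal(xl$delays$t_m, 12.38)
  am <- assemble_parameters(species_defaults("ambystoma_mexicanum", "fractional"))
  expect_equal(am$delays$t_m, 45.94)
  cfg <- species_defaults("xenopus_laevis", "fractional")
  expect_identical(assemble_parameters(cfg), assemble_parameters(cfg))
})

test_that("assemble_parameters names the missing field", {
  cfg <- species_defaults("xenopus_laevis", "normal")
  cfg$t_exp <- NULL
  expect_error(assemble_parameters(cfg), "t_exp")
  cfg <- species_defaults("xenopus_laevis", "normal")
  cfg$h_p <- NULL
  expect_error(assemble_parameters(cfg), "h_p")
})

test_that("rederived species table matches printed values within 0.01 min", {
  tab <- derive_species_params()
  get <- function(p, sp) tab[tab$parameter == p, sp]
  printed <- rbind(
    c("p_crit", 161, 420), c("t_p", 1.29, 2.18), c("t_tx", 1.34, 6.89),
    c("t_in", 4.65, 12.78), c("t_m_bm", 12.38, 31.64), c("t_m_fbm", 14.35, 45.94))
  for (i in seq_len(nrow(printed))) {
    expect_lt(abs(get(printed[i, 1], "xenopus_laevis") - as.numeric(printed[i, 2])), 0.011)
    expect_lt(abs(get(printed[i, 1], "ambystoma_mexicanum") - as.numeric(printed[i, 3])), 0.011)
  }
})

test_that("update_parameters redistributes total delay without moving T_p", {
  pars <- sensitivity_baseline()
  up <- update_parameters(pars, total_delay = 50.73)
  expect_equal(total_delay(up), 50.73)
  expect_equal(up$delays$t_p, pars$delays$t_p)
  expect_error(update_parameters(pars, total_delay = 1), "protein delay")
})

test_that("gene_model enforces its structural invariants", {
  expect_error(gene_model("g", 100, 90, c(20, 10)), "primary_length")
  expect_error(gene_model("g", 100, 50, c(-5)), "positive")
  g <- make_gene_model("g", 300, c(100, 50), utr_padding = 25)
  expect_equal(g$primary_length, 475)
})
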