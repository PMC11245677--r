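---
title: "Methods: delayed-autorepression clock models across genome and nuclear sizes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delayed-autorepression clock models across genome and nuclear sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segclock)
```

## The model

The somitogenesis segmentation clock is modelled as a single gene whose
protein represses its own transcription after production delays (the Lewis
oscillator):

$$\frac{dp}{dt} = a\, m(t - T_p) - b\, p(t), \qquad
  \frac{dm}{dt} = f\big(p(t - T_m)\big) - c\, m(t), \qquad
  f(p) = \frac{k}{1 + (p/p_{crit})^n}.$$

Here $m$ and $p$ are mRNA and protein molecule counts per cell, $a$ is the
protein synthesis rate (protein/mRNA/min), $k$ the maximal transcription rate
(mRNA/min/cell), and $b = \ln 2 / h_p$, $c = \ln 2 / h_m$ are first-order
degradation rate constants set by the protein and mRNA half-lives (minutes).
Repressors act as dimers, so the Hill coefficient is $n = 2$, and $p_{crit}$
is the molecule count at which nuclear repressor concentration reaches the
half-repression value of $10^{-9}$ M. The state is continuous (no demographic
noise) and there is no cell--cell coupling or wavefront term: the package
models the cell-autonomous clock whose period sets the somite segmentation
rate.

The delays carry the biology that genome and nuclear size can touch:

* $T_p$ — translation: coding length / 6 nt s$^{-1}$.
* $T_{tx}$ — transcription: primary transcript length / 20 nt s$^{-1}$.
  Introns inflate the primary length, so genome expansion acts here.
* $T_{in}$ — intron splicing: a conserved ~8.3% of the observed clock period.
* $T_{exp}$ — nuclear export: the mean first-exit time of a transcript
  diffusing from its chromatin address to the nuclear periphery, simulated
  below. Nuclear volume acts here and in $p_{crit}$.
* $T_m = T_{tx} + T_{in} + T_{exp}$.

For the two focal amphibians — *Xenopus laevis* (clock candidate *hes5.7L*:
primary 1,604 nt, CDS 465 nt, introns 166+113 nt; nuclear radius 4 µm; clock
~56 min) and *Ambystoma mexicanum* (*hes7*: primary 8,272 nt, CDS 783 nt,
introns 3,017+1,260+2,030 nt; radius 5.5 µm; clock ~154 min) — the derived
values are:

```{r}
derive_species_params()
```

Unit conventions: all delays and half-lives in minutes (seconds converted at
the boundary), volumes via $1\,\mu m^3 = 10^{-15}$ L and Avogadro's number
$6.02214076 \times 10^{23}$. `p_crit` is carried as a real number and rounded
only for display, since the Hill function uses it as a continuous scale.
Values compared against printed two-decimal tables are rounded half away from
zero; the printed table composes $T_m$ from already-rounded components, so
re-derived totals can differ by 0.01 min and comparisons use that tolerance.

## Nuclear export as a first-exit problem

A transcript starts at the nuclear centre (the focal gene's chromosome
occupies central, gene-rich territory) and takes 1-second steps until its 3D
position first leaves the sphere of radius $r$; "exit" is the first step index
strictly beyond $r$, with no within-step interpolation. Normal diffusion uses
i.i.d. Gaussian per-axis increments. Obstructed diffusion — transcripts
backtracking through chromatin — uses fractional Brownian motion with Hurst
exponent $H = 0.25$ (anomalous exponent $\alpha = 2H = 0.5$, mid-range of
reported nucleoplasmic values), generated exactly by circulant embedding
(Davies–Harte) in the paired Dietrich–Newsam form; a direct Cholesky
factorization of the fGn covariance serves as the test oracle. Because fGn
cannot be cheaply extended conditionally, paths are pre-generated whole, with
length a power of two at least `path_mult` (default 8) times the scaling-law
estimate $\mathbb{E}[T] \approx (r/\sqrt{3}\sigma)^{1/H}$ — itself an upper
bound, since a path's running maximum exceeds its endpoint displacement. The
exit-time tail is exponential (small-ball scaling), and the observed maximum
is ~6–7× the mean, so non-exits are rare; any walker that fails to exit is
excluded and counted.

The spatial step scale $\sigma$ is calibrated per diffusion mode so that the
mean exit time from a 3-µm sphere (zebrafish PSM nucleus) is 3.36 min — about
202 steps — matching the measured *her1* export time. Calibration runs a
fixed-seed pilot ensemble and updates $\sigma$ by the exact self-similarity
law $\mathbb{E}[T] \propto \sigma^{-1/H}$ under common random numbers, to a
2% tolerance. Scaling space at fixed 1-s steps is equivalent, for mean exit
times, to scaling time, and keeps the "202 steps ≈ 202 s" identity.

Two numerical facts matter when comparing simulations with the analytic
centre-start mean first-exit time $r^2/6D$ (with $D = 0.45\ \mu m^2/min$
implied by the anchor):

* **Boundary overshoot.** The absorbing step lands ~0.6 per-axis step-lengths
  beyond $r$, so the walk effectively exits a slightly larger sphere; at the
  calibrated scale this inflates means by ~5% at $r = 3$ µm, fading to ~2.6%
  at 6 µm. Tests therefore check proportionality to $r^2$ (one fitted
  constant, which is exactly what the analytic law asserts) with a 1.5%
  allowance for the overshoot's residual radius-dependence, and check the
  fitted constant against $D = 0.45$ separately.
* **Fixed export inputs.** The canonical export delays used by the downstream
  grids (BM 6.39/11.97 min; fBM 8.36/26.27 min for frog/axolotl) are carried
  as fixed study inputs. Freshly calibrated simulations reproduce their
  qualitative structure — export roughly doubles (BM) to triples (fBM) from
  4 to 5.5 µm — but not those exact numbers (e.g. pure $r^2$ scaling gives
  $3.36 \times (5.5/3)^2 = 11.3$ min, not 11.97); the upstream scaling
  procedure behind the printed values is not recoverable from their
  description. The package therefore reports simulated values alongside the
  fixed inputs rather than forcing agreement, and no test asserts them.

Off-centre transcripts are supported through a `uniform_three_quarter` start
rule: positions drawn uniformly inside the ball of radius $3r/4$ (rejection
sampling — per-axis uniforms alone would put cube corners outside the
sphere), excluding the heterochromatin-rich periphery. Interior starts shorten
and right-skew exit times, which is the expected direction.

## Integrating the delay equations

The integrator is fixed-step classical RK4 with the method of steps: delayed
values are read from the stored solution by cubic Hermite interpolation on
the uniform grid. The default step is 0.02 min, and each positive delay must
be at least ten steps long (a delay of exactly 0 degenerates to an undelayed
term). Pre-history is $m = p = 0$ — expression switches on at $t = 0$; tests
confirm the extracted period is history-independent after transient removal.
A fixed-step solver was chosen over an adaptive one because it is
bit-reproducible and trivially verifiable: halving the step moves the
extracted period by ~4 × 10⁻⁴ %, and an independent adaptive DDE solver
(`deSolve::dede`) agrees on the baseline period to better than 0.1 min.
Because the dynamics depend on the delays only through $T_m + T_p$ (shift
$\tilde m(t) = m(t - T_p)$), grids vary total delay by holding $T_p$ at its
species value and adjusting $T_m$; the invariance is asserted in tests.

Steady state solves $b p^* = a f(p^*)/c$ by monotone bisection. Linearizing
about $(m^*, p^*)$ gives the characteristic equation
$(\lambda + b)(\lambda + c) = a f'(p^*) e^{-\lambda T}$. A purely imaginary
root exists iff the feedback gain exceeds the geometric-mean degradation
bound, $|a f'(p^*)| > bc$; then $\omega$ solves
$(\omega^2 + b^2)(\omega^2 + c^2) = (a f'(p^*))^2$ in closed form and the
critical delay is $T_{crit} = (\pi - \arctan(\omega/b) -
\arctan(\omega/c))/\omega$. Oscillations require $T_m + T_p \ge T_{crit}$,
and $T_{crit}$ rises with protein half-life: stable proteins demand long
delays. The derivation is verified by simulation bracketing the threshold and
by the near-threshold period matching $2\pi/\omega$ within 5%, not against
any external algebra.

## Extracting period, amplitude, robustness

Periods come from local extrema on the sampled grid: a cycle is the interval
between successive minima, the first 5 cycles are discarded (expression
spikes before settling; using minima or maxima as anchors gives the same
result, which is tested), and the period is the mean gap between retained
minima over a 3100-min span — at least 20 cycles of the slowest clock
studied. A trajectory is robust only if *every* retained cycle spans at least
10 molecules min-to-max; otherwise it is damped: period $\infty$, amplitude
0. Plateaus resolve to their midpoint sample; extrema are not interpolated
between samples, so the induced period error is below the 0.02-min step. For
noisy synthetic traces (the deterministic model produces none), an optional
hysteresis mode confirms an extremum only after the trace retreats from it by
a set prominence. mRNA periodicity is the reported summary; the protein-based
period always agrees within 0.2 min.

## The three experiments

**Period grids.** For each species × diffusion regime, total delay spans the
species value ± 5 min in 0.5-min steps and protein half-life spans 3–22 min
in 1-min steps (21 × 20 cells; the resolution is this package's choice — it
resolves the capture bands at desk-scale cost, and doubling it does not move
the maxima appreciably). Cells whose period lies within ±2 min of the
species' observed clock form the capture set. Outcomes: the frog's 56-min
clock is captured under both diffusion regimes; the axolotl's 154-min clock
tops out near 125 min under normal diffusion and is captured only under
subdiffusion.

**Sensitivity.** From the axolotl normal-diffusion baseline ($a = 4.5$,
$k = 33$, $p_{crit} = 420$, $h_m = 3$, $h_p = 15$, total delay 33.82 min),
each of the six parameters (total delay varied as one quantity) moves ±50%.
Period responds strongly to total delay (+50% → ~40% longer) and to the
half-lives, and barely (<2%) to $a$, $k$, $p_{crit}$; lowering total delay or
$h_m$ by half, or raising $h_p$ by half, kills robust oscillation.

**mRNA-stability scenarios.** With axolotl export delays of ~12 (BM) and
~26 min (fBM) against a 3-min mRNA half-life, most transcripts would decay in
the nucleus: the degraded fraction over the mean export time is
$1 - 2^{-T_{exp}/h_m}$ (50% at $h_m = T_{exp}$, 75% at $T_{exp}/2$; the
package also exposes the distribution-based expectation
$1 - \mathbb{E}[2^{-T/h_m}]$, which Jensen's inequality makes no larger).
Rerunning the axolotl grids with $h_m$ set to $T_{exp}$, $T_{exp}/2$, and
$T_{exp}/4$ shows the 154-min clock captured in all three subdiffusive
scenarios and in none of the normal-diffusion ones: stability alone cannot
substitute for the spatial delay. Note two arithmetic quirks in the source
tables that the package does not reproduce: $\tfrac14 \times 26.27$ is
6.5675 min (printed elsewhere as 6.54), and first-order decay at
$h_m = T_{exp}/4$ gives 93.75% nuclear degradation (87.5% corresponds to
three half-lives). The formula is implemented as stated above; no result
depends on either printed figure.

## What the synthetic fixtures do and do not show

`make_trace` builds offset sinusoids with optional exponential damping and
Gaussian noise, `make_gene_model` pads coding and intronic lengths to printed
primary-transcript totals (UTR padding is explicit filler — only lengths
matter), and `make_diffusion_case` packages radii with the analytic
$r^2/6D$ oracle. These fixtures validate the estimators — exact period
recovery across 20–300 min, correct damped classification at the 10-molecule
cutoff, first-exit means on the analytic curve — under known ground truth.
They are deliberately idealized: real trajectories from the model are
anharmonic relaxation-style oscillations, and real nuclei are neither
perfectly spherical nor homogeneous, so passing fixtures demonstrates
correctness of the machinery, not fidelity of the biology.

## Problem sizes and limitations

Default study conditions: 10,000 walkers per export ensemble, 21 × 20 grid
cells per species × regime, 3100-min integrations at 0.02-min steps. The
full grid sweep runs in a couple of minutes per grid on one CPU; unit tests
use coarser grids and smaller ensembles.

Known limitations: no pore-search or docking kinetics (sub-second,
deliberately neglected); chromatin obstruction enters only through the Hurst
exponent, not explicit geometry; synthesis and degradation rates are held
constant across species although they may scale with cell volume; the clock
gene assignments are phylogenetic inferences, not experimental
demonstrations; and the model is single-cell — noise damping by
cell--cell coupling and the posterior slowing of the clock are out of scope.
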