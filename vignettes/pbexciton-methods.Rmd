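---
title: "Methods: compartmental exciton transfer and single-molecule photon-stream analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmental exciton transfer and single-molecule photon-stream analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbexciton)
```

# The scientific problem

Cyanobacteria protect their photosynthetic machinery through
non-photochemical quenching: under strong blue-green light the Orange
Carotenoid Protein (OCP) photoactivates, binds the phycobilisome (PB)
antenna core, and thermally dissipates excitation energy. Single-molecule
multiparameter spectroscopy of trapped PB particles resolves distinct
photophysical states — unquenched (U), singly quenched (Q1), doubly
quenched (Q2), and detached C-phycocyanin hexamers (B) — each characterized
by brightness (Br, cts s^-1 uW^-1), fluorescence lifetime (tau, ns),
spectral center of mass (lambda_CM, nm), and polarization (FPol).

`pbexciton` implements the computational core of that research program:

1. a compartmental exciton-transfer model of the truncated CB-PB
   phycobilisome with attachable OCP quencher sinks (`model_core`),
2. photon-by-photon stochastic simulation of exciton migration
   (`exciton_sim`),
3. a synthetic-data generator emulating the trap instrument's photon and
   spectral-camera streams (`synthetic_data`),
4. the per-photon-group analysis pipeline (`photon_analysis`), and
5. state classification and population kinetics (`state_populations`).

# The compartmental model

## Structure

Each compartment is a C-PC or APC hexamer (or the red-shifted APC680
subunit group of a terminal disc), connected to its closest geometric
neighbors by directed transfer rates k[i -> j] (ns^-1). The CB-PB core is
three cylinders: two antiparallel bottom cylinders whose terminal discs
carry the APC660 portions `a`, `d` and the APC680 subunits `a'`, `d'`
(ApcD/ApcE/ApcF), with `b`, `c` the remaining bottom-cylinder hexamers and
`e`, `f` the top cylinder. Six single-hexamer C-PC rods each feed one core
hexamer. The eight admissible OCP attachment sites are `a`-`f`, `a'`, `d'`.
An attached OCP is a non-emissive sink, reachable only from its site at the
quenching rate `k_Q`; back transfer out of a sink is not permitted, so an
excitation entering it terminates immediately as "quenched".

The exact adjacency of the core is only depicted graphically in the source
structure, so the default configuration documents its assumed edge set
(within-cylinder `a-b`, `c-d`, `e-f`; bottom-bottom contacts `a-c`, `b-d`;
top-bottom contacts `f-a`, `f-c`, `e-b`, `e-d`) and any user configuration
can override it: the JSON configuration file is the single source of truth
for the topology and every rate value.

## Analytic observables (the oracle)

The exciton's position is a continuous-time Markov chain: transient states
are the pigment compartments; absorbing states are radiative decay,
nonradiative decay, and quenching. With transient generator block `T`,
initial distribution `p0` (absorption probabilities at 590 nm, extinction
weights normalized over the complex), and radiative absorption rates
`r_rad,i = Gamma_i * Phi_i`:

* yields: `p0' (-T)^-1 r` for each absorption class,
* emission distribution: per-compartment share of the radiative yield,
* mean radiative delay: `p0' (-T)^-2 r_rad / P(radiative)` — the
  amplitude-weighted lifetime a fluorescence fit measures, conditioned on
  radiative termination.

`analytic_observables()` solves these linear systems with no sampling; it
is the deterministic oracle against which both stochastic samplers are
validated (yields and conditional mean delays within three standard errors
at n = 1e5 events, enforced in the test suite).

## The synthetic default configuration

The published rate table for this model is in supplementary material that
is not available to this package, so the shipped default
(`inst/extdata/cbpb_synthetic_default.json`) is an explicitly **synthetic**
stand-in, constructed as follows and then frozen:

* Intrinsic decay: a uniform rate `Gamma = 1/1.66 ns^-1` with radiative
  fraction `Phi = 0.5` (50% quantum yield) for every pigment compartment.
  With uniform `Gamma` the unquenched amplitude-weighted lifetime is
  exactly 1.66 ns, the measured unquenched value, making this the stated
  one-parameter calibration rather than a fit.
* Absorption weights at 590 nm: 0.15 per C-PC rod hexamer (C-PC dominates
  absorption at 590 nm), 0.02 per non-terminal core hexamer, 0.007 per
  APC660 terminal portion, 0.003 per APC680 subunit group. These imply a
  detached single C-PC hexamer at 15% of the complex extinction, i.e.
  Br ~ 1560 cts s^-1 uW^-1 under the unquenched normalization — inside the
  measured detached-hexamer range (1630 +/- 320) and the rod-dissociation
  estimate (1500 +/- 400).
* Transfer-rate scales (rod <-> core 13.46 / 4.04 ns^-1, core-core
  27.16 ns^-1, APC660 <-> APC680 265.1 / 66.3 ns^-1) were calibrated
  **once**, against the analytic oracle and before any test was written, to
  the published operating point: one OCP at `k_Q = 540 ns^-1` gives
  ~0.21 ns and ~11% relative brightness; two C2-symmetric OCPs give
  ~0.09 ns and ~6%; and the `a'd'` pair (like `ad` and `bc`) reaches the
  doubly-quenched state. The back/forward ratios (0.3 for rods, 0.25 for
  the terminal emitters) set the equilibrium occupancy so the composite
  unquenched emission spectrum has its center of mass near 669 nm.

What a green test on this configuration establishes is therefore
*kinetic self-consistency* — that a network with the stated topology and
this calibration reproduces the published state structure (single sites
saturate near Q1 regardless of site; `ad`, `a'd'`, `bc` reach Q2 while
`ef`, the top-cylinder pair, never does; brightness and mean delay are
non-increasing in `k_Q` everywhere) — not an independent confirmation of
the published rate values.

# Stochastic samplers

`simulate_fixed_step()` reproduces the reference procedure: a random walk
with 100 fs steps in which transfer to each neighbor, radiative decay, and
nonradiative decay compete within a single categorical draw per step
(probabilities `k * dt`, `Gamma Phi dt`, `Gamma (1-Phi) dt`), delays
recorded on the step grid. Whether decay and transfer compete within one
step or are evaluated sequentially is not specified by the source; the
single-draw convention is used and verified against the exact sampler —
the difference is O(dt * rate), about 3e-3 at the fastest default rate.

`simulate_exact()` draws exponential waiting times and categorical jumps
from the embedded chain: statistically exact, used to bound the fixed-step
discretization bias and for large production runs. Both samplers are
implemented in C++ on R's RNG, so results are reproducible from `set.seed`
/ the `seed` argument.

# The synthetic instrument

`generate_photon_stream()` emulates the trap data streams: Poisson photon
arrivals at `Br * power + background`, quantized to the 12.5 ns detection
clock; TCSPC delays drawn from the state's exponential-lifetime mixture
plus Gaussian IRF jitter (default FWHM 50 ps); two polarization channels
split so the expected FPol matches the state. Numerical conventions:

* Negative IRF-jittered delays are **redrawn** rather than truncated,
  preserving the mixture normalization; the fit model's window
  renormalization matches this convention exactly.
* Delays are recorded by the TCSPC bin they fall in (floor to the 4 ps
  grid). Rounding instead of flooring would shift the histogram half a
  quantum against the fit model and bias a 0.1 ns component by ~2%.
* Delays wrap modulo the 12.5 ns pulse window (as in an 80 MHz train);
  for a 1.66 ns lifetime the wrapped fraction is 5e-4.
* Background photons carry uniform delays and a flat spectrum; there is no
  afterpulsing, dead time, or dark-count delay structure. Default
  background is 25 cts s^-1, low enough that the dimmest quenched state
  (~300 cts s^-1 at the powers used for quenched samples) remains
  detectable.

`generate_spectral_frames()` bins photons into 20 ms camera frames; each
photon deposits one count in a wavelength bin drawn from its source
spectrum. Per-state spectra are two-Gaussian band mixtures (C-PC-like
650 nm, APC-like 680 nm) mixed so each state's analytic center of mass
equals its measured value; they are stand-ins for real emission lineshapes
and are stated in configuration, not code.

`generate_trace()` concatenates per-segment streams with background-only
gaps and retains the truth labels, closing the loop for classification
tests. It does not emulate trap-feedback failures, particle swaps, or
photodamage at high intensity.

# Lifetime fitting

`fit_lifetime_mle()` maximizes the Poisson likelihood of the binned decay
under an IRF-convolved multi-exponential (optional flat background).
Choices that matter:

* **Binning**: the 4 ps native grid rebinned to 16 ps over the 12.5 ns
  window. Expected bin contents are CDF differences of the
  exponential-Gaussian convolution (closed form, evaluated in log space for
  stability), so binning introduces no model error; fits are insensitive
  to the bin width for lifetimes above ~3 bins (checked down to 0.09 ns).
* **Initialization**: method-of-moments (mean delay) for one component;
  two-component fits start at (2x, 0.2x) the one-component estimate with
  equal amplitudes; three multiplicative perturbations of the start are run
  and the best likelihood kept. This makes fits deterministic given the
  data.
* **Errors**: square roots of the diagonal of the inverse observed Fisher
  information (numerical Hessian at the optimum), delta-method transformed
  to the tau scale; a non-invertible Hessian flags the fit rather than
  silently reporting errors.
* **Background**: off by default for simulated (background-free) delays,
  on for synthetic instrument streams that carry background; both are
  runnable for bulk decays since the original choice is unstated.
* A measured-IRF path (`irf_histogram()`) uses discrete convolution on the
  fit grid; it agrees with the analytic Gaussian path to well under the
  statistical error on matched inputs.

# Spectral calibration and Eq.-2 center of mass

Pixels map to wavelength by a cubic polynomial (fit by ordinary least
squares from calibration line positions when needed); per-pixel counts are
divided by the local bin width (the polynomial's derivative) to form a
density whose integral equals the total counts, and the center of mass is
the weighted normalized sum over bins. Applying the weighted sum to the
bin-width-corrected density on a nonuniform grid weights the continuous
spectrum by 1/(dlambda/dpixel); for the mild calibrations used here this
shifts lambda_CM by ~0.1 nm, far below the state separations (~2-4 nm),
and the operation order is kept as stated in the analysis description.

# Classification and populations

Per-dimension Gaussians are fit to histograms of the grouped parameters
(`fit_state_gaussians()`, >= 30 groups per state recommended; least-squares
on histogram counts with a sample-moments fallback for degenerate fits).
Classification tests membership in the **axis-aligned** Br-tau 95%
confidence ellipse (squared radius 5.991, chi-square with 2 d.o.f.) — the
per-dimension Gaussian description carries no covariance, and Br-tau is
the discriminating projection; lambda_CM and FPol are recorded but not
used for assignment. Groups brighter than 5000 cts s^-1 uW^-1 are counted
as U regardless; ambiguous membership resolves to the smallest Mahalanobis
distance; a group inside no ellipse stays unassigned.

A **level** is a maximal run of consecutive same-state groups; unassigned
groups break runs. Rare mid-event transitions can either be counted as two
levels (default) or censored (`censor_transitions = TRUE`), since the
original counting rule is unstated. Population fractions per 5-min window
are `f_Q2 = N_Q2/(N_Q1+N_Q2)` and `f_U = N_U/(N_Q1+N_Q2+N_U)` with
binomial errors `sqrt(f(1-f)/n)` — level counts are the only stochastic
input, so binomial propagation is the natural reading of "error
propagation".

OCP unbinding is modeled as two independent exponential clocks per complex
(`generate_unbinding_timeseries()`): the surviving-OCP count at time t is
Binomial(2, exp(-k_off t)), mapping 2/1/0 to Q2/Q1/U. The unbinding rate
constant is not published; `k_off` is a free generator parameter and the
multi-hour population shift is reproduced qualitatively only.

# Worked example

```{r example, eval = FALSE}
net <- default_network()
scale <- calibrate_brightness_scale(net, br_reference = 10420)

q1 <- attach_quenchers(net, data.frame(site = "a", k_q = 540))
sim <- simulate_exact(q1, 1e5, seed = 7)
derive_observables(sim, scale)

quencher_sweep(net, list("a", c("a", "d")), c(54, 540))
```

# Known limitations

* The default rate table is synthetic (see above); analyses that depend on
  the true microscopic rates must supply their own configuration.
* No polarization physics in the exciton simulator (measured FPol ~ 0 for
  all states; the generator reproduces it statistically).
* No exciton-exciton annihilation, no OCP photoactivation kinetics, no
  structure-based (Forster/Redfield) rate computation, no hidden-Markov
  segmentation of within-event transitions.
* The spectral generator's band mixtures reproduce centers of mass, not
  true phycobiliprotein lineshapes; recovered lambda_CM values are
  meaningful relative to the generator, not as absolute spectroscopy.
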