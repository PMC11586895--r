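---
title: "Models and methods behind peptherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peptherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptherm)
```

# The scientific problem

Small osmolytes such as trimethylamine N-oxide (TMAO) can shift the
self-assembly equilibrium of peptides without ever binding them
tightly, by restructuring the hydration shell. peptherm packages the
quantitative machinery needed to study one such system — the
undecapeptide substance P (RPKPQQFFGLM, amidated C-terminus) whose
dimerization is promoted by TMAO — from three complementary angles:

1. **Equilibrium thermodynamics from native MS.** Variable-temperature
   electrospray holds the solution in the emitter at a controlled
   temperature (278–358 K) before ionization, so ion intensities report
   on the solution equilibrium at that temperature.
2. **Free-energy landscapes from trajectories.** The interchain
   centre-of-mass (COM) distance from molecular-dynamics-style
   simulations is Boltzmann-inverted into a free-energy profile.
3. **Oligomer census from spectra.** Theoretical oligomer charge-state
   m/z values are matched against centroided peak lists to quantify how
   much signal resides in dimers and trimers for sequence mutants.

Because neither raw spectra nor trajectories ship with the package,
every input has a seeded synthetic generator whose statistical
properties are known exactly; the analysis code is validated by round
trips through those generators.

# Van't Hoff thermodynamics from ion intensities

## Apparent association constants

For self-assembly, the apparent constant is
$K_a = I_\mathrm{dimer} / I_\mathrm{monomer}^2$ — the monomer intensity
is squared because the free ligand of the reaction is the monomer
itself. For osmolyte binding,
$K_a = I_\mathrm{complex} / (I_\mathrm{monomer}\,[\mathrm{TMAO}])$,
with the osmolyte in large excess so that its free concentration equals
the nominal one. Intensities are not converted to concentrations: the
constants carry inverse-intensity units. This shifts the van't Hoff
*intercept* by a constant but leaves the *slope* — and therefore every
enthalpy — untouched; the entropic term inherits the convention and is
comparable only within a fixed instrument response, which is exactly
how such data are interpreted in practice.

## The linear model and the two-regime fit

Under the standard van't Hoff model
$$\ln K_a = -\frac{\Delta H}{R}\cdot\frac 1 T + \frac{\Delta S}{R},$$
so an ordinary-least-squares line through $(1/T, \ln K_a)$ yields
$\Delta H = -R\,\mathrm{slope}$ and $\Delta S = R\,\mathrm{intercept}$
with $R = 8.314\times10^{-3}$ kJ mol$^{-1}$ K$^{-1}$. A change of
mechanism appears as a slope discontinuity. `fit_two_regime()` searches
every interior measured temperature that leaves at least three points
on each side, fits the two segments by OLS and keeps the breakpoint
with the smallest total residual sum of squares. The search is
data-driven rather than hard-coded because the two reactions analyzed
here break at different temperatures (~293 K for dimerization, ~298 K
for osmolyte binding); a fixed breakpoint can be supplied instead.
Ties in RSS — which occur systematically on noiseless piecewise-linear
data, where the shared breakpoint point lies on both lines — are broken
toward the candidate closest to the median temperature, which selects
the true generating breakpoint in that situation. The fit is flagged
*degenerate* when the two slopes differ by no more than their pooled
standard error (plus a $10^{-8}$ relative floor so that exact fits with
equal slopes, whose OLS errors collapse to zero, are still flagged).

Replicates are averaged on the log scale, matching the multiplicative
noise model below; Ka-scale averaging is available as a switch.
Replicate spread, not OLS standard errors, is the primary uncertainty
channel (`replicate_uncertainty()`), mirroring the triplicate
error-bar convention of the experiments.

## The synthetic intensity generator as a stated world

`two_regime_thermo()` is parameterized by the published dimerization
regimes: $\Delta H = -26.4$ kJ/mol below 293 K, $\Delta H = -71.1$
kJ/mol and $-T\Delta S(293\,\mathrm K) = +53.6$ kJ/mol above it.
Enthalpy–entropy compensation keeps $\Delta G$ essentially constant
across the break, so the generator **pins $\ln K_a$ to be continuous at
the breakpoint**: the high-temperature regime is anchored by its
$(\Delta H, -T\Delta S)$ pair and the low-temperature regime inherits
its intercept from continuity, differing in slope only. The implied
low-regime $-T\Delta S$ at 293 K is then $+8.9$ kJ/mol versus the
printed $+8.8$ — agreement to within the rounding of the printed
inputs (the printed low-regime pair itself sums to $-17.6$ kJ/mol
against a printed $\Delta G$ of $-17.5$). We treat 0.1 kJ/mol as the
rounding granularity of all of these values.

Noise is multiplicative log-normal with unit mean: ion counts are
positive and their error scale-proportional. The coefficient of
variation is interpreted on the linear scale
($\sigma_{\log}^2 = \log(1+\mathrm{cv}^2)$). No noise magnitude is
published for the triplicates; the default cv = 0.05 is a typical
relative intensity spread for electrospray replicates and was fixed
once, before any tests were run. Temperatures are accepted in kelvin
only — input below 200 K is rejected as probable Celsius.

What a green round-trip test establishes: the estimator chain
(intensities → Ka → series → segmented fit → thermodynamics) is exact
on noiseless data and unbiased enough at cv = 0.05 (median
$|\Delta H|$ error well under 5 kJ/mol over 100 seeds). What it does
not establish: correctness of ionization-efficiency assumptions,
charge-state aggregation, or any instrument systematics — the
generator's monomer intensity is flat in temperature by construction.

# Trajectory analysis

## States and occupancies

The COM distance separates the three coarse states: dimer below 2 nm,
fully separated monomers above 3.5 nm, transition in between. The
defining inequalities are strict, so a frame exactly at a threshold is
a transition frame. Occupancy is the frame-count fraction, and coarse
free energies follow from $-RT\ln P$.

## Boltzmann inversion and its discretization

`free_energy_profile()` histograms the coordinate (raw nm or min-max
normalized; a fixed normalization range is available for
cross-trajectory comparability) and sets
$F_i = -R T \ln P_i$, shifted so the minimum over populated bins is
zero — the profiles are relative, as in any potential of mean force.
Bins holding fewer than `min_count` (default 10) samples are masked
(NA) rather than extrapolated or assigned infinite energy, and masked
bins never enter the min-shift. Energies are reported in kJ/mol at the
trajectory temperature (not in units of kT), which keeps profiles at
different temperatures on one scale.

Two discretization effects matter when validating against a known
potential. First, a histogram estimates the *bin-integrated* Boltzmann
probability, so where the potential varies steeply across one bin the
estimate sits systematically below the bin-centre value; at the bin
widths used in the tests this bias stays inside the stated tolerances.
Second, the Euler–Maruyama integrator of the synthetic trajectory
generator has a stationary-variance bias of relative order
$\theta\,\Delta t$ where $\theta = U'' D / RT$ is the local relaxation
rate; the acceptance tests therefore use $\Delta t$ small enough that
$\theta\,\Delta t \lesssim 0.1$ even on the steep quartic walls. These
are properties of the *fixtures*, chosen once from the physics, not
tuned to outcomes.

## Bootstrap variance

Diffusive trajectories are strongly autocorrelated, so the default
uncertainty is a circular block bootstrap (block = 100 frames):
contiguous blocks are resampled with wraparound, each resample is
re-binned with the point estimate's breaks, and the per-bin variance of
the min-shifted free energy across resamples forms the band. The naive
iid bootstrap is available by setting block length 1, but it
underestimates the band on correlated data and is off by default.

## Hydrogen bonds and RDFs

No geometric hydrogen-bond criterion is stated for the simulations
analyzed here, so the package adopts the standard convention —
donor–acceptor distance ≤ 0.35 nm and donor–hydrogen–acceptor
deviation from linearity ≤ 30° — with both cutoffs configurable.
The radial distribution function normalizes the minimum-image
pair-distance histogram by the ideal-gas shell expectation at the
target density (exact shell volumes, self-pairs excluded when the
selections coincide), so uncorrelated particles give $g(r) = 1$; it is
defined only up to half the box edge.

## The Langevin generator

The overdamped Langevin update
$x' = x - \frac{D\,\Delta t}{RT}U'(x) + \sqrt{2D\Delta t}\,\xi$
with *reflecting* boundaries (a COM distance is non-negative and
bounded by the box, so reflection, not wrapping, is physical) has the
Boltzmann stationary law the FEP estimator inverts. Potentials: flat,
harmonic, quartic double-well and tabulated; forces are pre-tabulated
on a 4096-point grid. A per-step drift exceeding 10% of the domain
triggers a warning that `dt` is too large. The published occupancies
(≈39% dimer at 280–300 K, ≈20% at 360 K) come from microsecond-scale
force-field simulations and are **not** reproducible from this
stand-in; the trajectory tests therefore validate estimator properties
(stationary laws, profile recovery, band shrinkage) rather than those
numbers.

# Oligomer census

Theoretical m/z uses monoisotopic residue masses, one water per
monomer, a −0.98402 Da amidation correction and 1.00728 Da per proton;
an average-mass mode exists because printed labels on low-resolution
spectra are average-mass quantities (the computed monoisotopic 2+
peptide–TMAO complex lands at 711.91 against a printed 711.8). Peaks
are assigned to the nearest species within tolerance; when several
species fall inside the tolerance the intensity is split by
inverse-distance weights and flagged, and intensity is conserved
exactly (assigned + unassigned = total).

"Degree of oligomerization" is not defined in the source literature.
The package's default is the monomer-equivalent mass fraction in
oligomers,
$$\mathrm{DO} = \frac{\sum_{n\ge 2} n I_n}{\sum_{n\ge 1} n I_n},$$
which weighs each oligomer by the number of monomers it sequesters; the
plain signal fraction $\sum_{n\ge2} I_n / \sum_n I_n$ is selectable.
Orders are capped at 3 by default, mirroring the quantification limit
of the commercial software the experiments used; the cap is
configurable. The charge-state inventory per order is user-supplied
because only the 2+ dimer was observed in the source spectra.

# Pipeline and reproducibility

`run_pipeline()` executes a scenario (`vtesi_thermo`, `trajectory`,
`census` or `full`) from one YAML configuration: simulate, analyze,
write every intermediate as CSV, and aggregate headline quantities into
`summary.json`. A resolved copy of the configuration is written beside
the outputs; its MD5 (computed over the scientific content, excluding
the output path) and the seed are recorded in the summary, and a rerun
with the same configuration and seed is bit-identical. Stage failures
halt with the failing stage named; configuration validation collects
*all* schema problems, not just the first.

# Numerical choices and known limitations

* $R = 8.314\times10^{-3}$ kJ mol$^{-1}$ K$^{-1}$ everywhere; molar
  free energies throughout.
* A 2-point OLS fit is exact; its standard errors are reported as 0
  rather than NaN.
* The nominal box concentration of two chains in an 8 nm cube is
  6.49 mM with the exact Avogadro constant; the printed 6.51 mM is
  recovered with the two-significant-figure constant
  $6.0\times10^{23}$, and `box_concentration()` exposes the constant
  so both conventions are checkable.
* The published osmolyte-binding pair "+3.7 and −19.0 kJ/mol with
  ΔG ≈ +15.3 to +15.5" is internally inconsistent under
  $\Delta G = \Delta H + (-T\Delta S)$ (the pair sums to −15.3);
  peptherm does not guess a sign correction and asserts nothing about
  those numbers.
* Chains are assumed whole (not wrapped) when computing per-chain COMs;
  the minimum image is applied to the COM–COM displacement only.
* No reweighting estimators (WHAM/MBAR), no 2-D surfaces, no isotope
  pattern fitting, no charge deconvolution, no CCS analysis.

# A worked example

```{r example, eval = FALSE}
th <- two_regime_thermo(breakpoint_temperature = 293,
                        dH_low = -26.4, dH_high = -71.1,
                        mTdS_ref_high = 53.6)
tab <- generate_vant_hoff_intensities(th, seq(278, 358, 5),
                                      noise = noise_spec(3, 0.05, 1))
series <- build_vant_hoff_series(tab, "dimerization")
fit <- fit_two_regime(series)
thermo_from_fit(fit$high_regime, 293)
```
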