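# peptherm

Quantitative analysis of osmolyte-modulated peptide self-assembly, for
researchers who study weak biomolecular association with native mass
spectrometry and molecular simulation. The motivating system is the
undecapeptide substance P (RPKPQQFFGLM, amidated C-terminus), whose
dimerization is promoted indirectly by the osmolyte trimethylamine
N-oxide (TMAO); the machinery is generic.

The package covers three linked analyses plus the synthetic data to
test them offline:

* **Van't Hoff thermodynamics from ion intensities.** Apparent
  association constants `Ka = I_dimer / I_monomer^2` (self-assembly)
  and `Ka = I_complex / (I_monomer [TMAO])` (osmolyte binding) are
  built into `ln Ka = -ΔH/(R T) + ΔS/R` series; single- and two-regime
  (segmented, RSS-minimizing breakpoint) OLS fits yield ΔH, ΔS, −TΔS
  and ΔG with replicate uncertainties.
* **Trajectory thermodynamics.** Centre-of-mass distance series are
  classified into dimer (< 2 nm) / transition / monomer (> 3.5 nm)
  states; Boltzmann inversion `F_i = -R T ln P_i` gives free-energy
  profiles with circular-block-bootstrap variance bands; geometric
  hydrogen-bond counting and radial distribution functions complete
  the structural picture.
* **Oligomer census.** Theoretical oligomer charge-state m/z values
  (monoisotopic or average, amidation- and adduct-aware), tolerance-
  based peak assignment with ambiguity splitting, and a
  degree-of-oligomerization statistic
  `DO = Σ_{n≥2} n I_n / Σ_{n≥1} n I_n` for mutant/condition
  comparisons.
* **Synthetic generators** (all pure functions of parameters + seed):
  two-regime intensity tables with log-normal replicate noise,
  overdamped Langevin trajectories on flat/harmonic/double-well/
  tabulated potentials with reflecting boundaries, hydrogen-bond
  micro-geometries, ideal-gas frames, Gaussian peak lists.

## Worked example

```r
library(peptherm)

# the two published dimerization regimes, continuous at 293 K
th <- two_regime_thermo(breakpoint_temperature = 293,
                        dH_low = -26.4, dH_high = -71.1,
                        mTdS_ref_high = 53.6)
tab <- generate_vant_hoff_intensities(th, seq(278, 358, 5),
                                      noise = noise_spec(3, 0.05, 1))
series <- build_vant_hoff_series(tab, "dimerization")
fit <- fit_two_regime(series)
fit
#> Two-regime van't Hoff fit: breakpoint 293.0 K (RSS 0.0296)
#> low regime:  van't Hoff regime fit over 278-293 K (4 points)
#>   slope = 3309 K (dH = -27.51 kJ/mol), intercept = -4.145
#> high regime: van't Hoff regime fit over 298-358 K (13 points)
#>   slope = 8527 K (dH = -70.89 kJ/mol), intercept = -21.92
thermo_from_fit(fit$high_regime, 293)
#> dH = -70.9 kJ/mol, -TdS(293 K) = 53.4 kJ/mol, dG = -17.5 kJ/mol
```

At 5% replicate noise the fit recovers the generating high-temperature
regime (ΔH = −71.1, −TΔS = +53.6 kJ/mol) to within a fraction of a
kJ/mol and finds the 293 K breakpoint exactly; with `cv = 0` the
recovery is exact to machine precision.

```r
traj <- generate_langevin_com_trajectory(
  potential_spec("double_well", domain = c(0, 4), wells = c(1, 3),
                 barrier_height = 5),
  temperature = 300, dt = 0.002, n_steps = 2e5, seed = 1)
round(state_occupancy(classify_states(traj)), 3)
#>      dimer transition    monomer
#>      0.516      0.482      0.002

theoretical_mz("RPKPQQFFGLM", oligomer_order = 1, charge = 2,
               c_terminal_amide = TRUE, adduct_mass = 75.068)
#> [1] 711.9053   # the 2+ peptide-TMAO complex
```

The occupancies are the frame fractions below 2 nm, between the
thresholds, and above 3.5 nm; the m/z is the monoisotopic prediction
for the singly-adducted doubly-protonated monomer.

End-to-end scenarios run from one YAML config:

```r
run_pipeline("config.yaml", seed = 1, out_dir = "out")
# writes intensity_table.csv, thermo_report.csv, com_trajectory.csv,
# state_occupancy.csv, fep.csv, peaks.csv, oligomer_abundances.csv,
# resolved_config.yaml and summary.json
```

or from the thin CLI in `inst/cli/peptherm`
(`peptherm pipeline run --config config.yaml --seed 1`).

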