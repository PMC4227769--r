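# flipkin

Transient-kinetic modelling of enzyme-catalyzed nucleotide flipping.

DNA glycosylases find rare damaged bases hidden in duplex DNA, rotate the
damaged nucleotide out of the helix into their active site, and cut the
N-glycosidic bond. For human alkyladenine DNA glycosylase (AAG) acting on
1,N<sup>6</sup>-ethenoadenine (εA), every step of this multistep
recognition is observable: εA fluorescence reports on base stacking in
stopped-flow experiments, and gel-based pulse-chase assays measure how the
bound complex partitions between excision and dissociation. Comparing the
wild-type enzyme with mutants of the intercalating tyrosine (Y162F,
Y162A) dissects what DNA intercalation contributes to each microscopic
step.

`flipkin` is for kineticists who want to simulate, fit and reason about
this class of mechanism:

* a mass-action model of the minimal scheme

  `E + D ⇌ ENS ⇌ IRC ⇌ SRC → E + P`

  (nonspecific binding with rate constant *k*<sub>on</sub>, searching with
  macroscopic constant *k*<sub>find</sub>, flipping *k*<sub>flip</sub> /
  unflipping *k*<sub>unflip</sub>, cleavage *k*<sub>chem</sub>), with an
  additive multi-protein searching model for excess-protein conditions and
  an absorbing chase mode for pulse-chase/double-mixing experiments —
  integrated deterministically (`simulate_timecourse()`) or per molecule
  by the Gillespie algorithm (`simulate_stochastic()`);
* synthetic-data generators for every experiment class: association
  traces in the two εA sequence contexts, double-mixing chase recovery,
  tight-binding titrations, single-turnover excision, pulse-chase gel
  series, and competition by undamaged DNA, all with instrument dead time
  and Gaussian noise;
* phase-level analysis: multistart variable-projection multi-exponential
  fits (`fit_exponential_phases()`), bimolecular slope and
  concentration-dependence tests, quadratic tight-binding and IC50 fits;
* global fitting of the mechanism across concentration regimes
  (`global_fit()`, a classed model object with `coef`, `summary`,
  `predict`, `residuals`, `plot` methods) and phase-vs-global concordance
  checks (`compare_fits()`);
* bookkeeping from observables to constants: commitment to catalysis
  *C* = *k*<sub>chem</sub>/(*k*<sub>chem</sub> + *k*<sub>unflip</sub>),
  *k*<sub>flip</sub> = *k*<sub>2,obs</sub> − *k*<sub>unflip</sub>,
  *K*<sub>flip</sub> = *k*<sub>flip</sub>/*k*<sub>unflip</sub>, fold
  changes and nucleotide-excess arithmetic, compiled into a
  provenance-tagged parameter table (`compile_parameter_table()`).

## Worked example

Simulate a wild-type association experiment (300 nM enzyme mixed with
50 nM εA-DNA in the TEC context), then fit three exponential phases:

```r
library(flipkin)

wt <- aag_rates("WT")
print(wt)
#> Microscopic rate constants [WT]
#>   k_on      1.1e+09 M^-1 s^-1
#>   k_find    116 s^-1  (k_search 115.4, k_escape 0.58)
#>   k_off_ns  0.232 s^-1
#>   k_flip    3.6 s^-1   k_unflip 0.0016 s^-1
#>   K_flip    2.25e+03
#>   k_chem    0.0008 s^-1

trace <- synthesize_association_trace(
  mechanism(wt, "additive"),
  fluorescence_model("TEC", "WT"),
  mixing_experiment("association", E_tot = 3e-7, D_tot = 5e-8,
                    times = stopped_flow_times(5e-4, 2, 300),
                    noise_sd = 0.005, seed = 7))

fit <- fit_exponential_phases(trace, n_phases = 3)
print(fit)
#> Multi-exponential fit: 3 phase(s)
#>   phase 1: k = 755.166 +/- 1.8e+02 s^-1, A = +0.3137
#>   phase 2: k = 284.713 +/- 9.4 s^-1, A = -0.9501
#>   phase 3: k = 3.58746 +/- 0.011 s^-1, A = +1.069
#>   offset y_inf = 0.549277, residual RMS = 0.0048
```

The three phases are the mechanism's three relaxations: parallel
searching (fast, mostly within the dead time), bimolecular binding
(≈ *k*<sub>on</sub>·[E]; its rate grows linearly across a concentration
series with slope ≈ 1.1 × 10⁹ M⁻¹s⁻¹), and nucleotide flipping. The
slowest phase reads *k*<sub>2,obs</sub> = 3.59 s⁻¹ — the observed
flipping relaxation, equal to *k*<sub>flip</sub> + *k*<sub>unflip</sub>.
Combining it with the unflipping rate from a double-mixing chase
experiment gives the microscopic constants:

```r
k_flip <- derive_k_flip(3.6016, 1.6e-3)        # 3.6 s^-1
signif_half_up(equilibrium_flip_constant(k_flip, 1.6e-3), 2)
#> [1] 2300
round(100 * commitment_to_catalysis(8.0e-4, 1.6e-3))
#> [1] 33
```

meaning the wild-type enzyme holds the flipped-out base with an
equilibrium constant of ~2300 and, once flipped, excises it on one of
every three encounters before the substrate escapes.

A YAML-driven pipeline (`cmd_simulate()` → `cmd_fit()` → `cmd_report()`,
or the thin wrapper script in `inst/cli/flipkin.R`) runs whole synthetic
studies and writes trace CSVs, fit reports (JSON) and the final parameter
table (CSV/JSON/markdown).

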