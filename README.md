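# azperm

Membrane permeation of the azide ion / hydrazoic acid pair (N₃⁻/HN₃,
"AHA") predicted from pH-dependent octanol/water partitioning.

Azide inhibits cytochrome c oxidase, but it must cross the plasma
membrane first — almost certainly as the neutral acid HN₃ (pKa 4.65),
since the anion's hydration is far too favourable. `azperm` is for
physical chemists and ADME/tox modellers who want the complete,
testable chain from two partition measurements to a predicted membrane
permeability:

1. **Ionization/partition model.** With β = 10^(pKa−pH), the
   distribution coefficient of the pooled protonation states is

   Q(pH) = (P⁰·β + P⁻) / (1 + β),

   fitted from measured (pH, K_ow) pairs; free energies follow from
   ΔG = −k_BT·ln Q (k_BT = 0.593 kcal/mol by default), and
   concentration ratios between compartments at different pH from
   Q(pH₁)/Q(pH₂).
2. **PAMPA assay arithmetic.** Effective permeability from a
   single-timepoint parallel-artificial-membrane readout,
   P_e = −ln(1 − C_A/C_eq) / (S·(1/V_D + 1/V_A)·t), plus equilibrium
   concentration and signed mass-retention fractions.
3. **Free-energy profile.** Donor water (reference 0) → membrane
   plateau (−k_BT ln Q at donor pH) → acceptor water (difference of
   the two transfer free energies), discretized on a uniform 1-D grid
   with optional interface ramps and explicit reservoir cells.
4. **Smoluchowski solver.** Finite-difference drift-diffusion
   ∂u/∂t = ∇·[D(∇u + u∇G/k_BT)] with thermodynamically weighted
   face fluxes (exact Boltzmann stationarity), explicit or implicit
   stepping, steady-state flux → permeability P and rate constant
   k = P/d, cross-checked against the solubility–diffusion closed form
   1/P = ∫ e^{G(x)/k_BT}/D dx.

Synthetic-data generators (lognormal partition noise, exact
two-compartment PAMPA kinetics with Gaussian noise) provide ground
truth for every stage.

## Worked example

```r
library(azperm)

fit <- fit_partition(data.frame(pH = c(2, 8), Kow = c(2.01, 0.00034)),
                     pKa = 4.65)
fit
#> Two-species octanol/water partition model
#>   P0 (neutral) = 2.01   P- (anion) = 0.00034   pKa = 4.65
#>   kBT = 0.593 kcal/mol   fit mode: direct

q_table(fit, pH = c(2, 4.65, 6.8, 7.2, 7.4, 8))
#>    pH       Q   logQ dG (kcal/mol)
#>  2.00 2.00551  0.302        -0.413
#>  4.65 1.00517  0.002        -0.003
#>  6.80 0.01447 -1.840         2.512
#>  7.20 0.00599 -2.223         3.035
#>  7.40 0.00391 -2.408         3.288
#>  8.00 0.00124 -2.908         3.970
```

At physiological pH only ~0.4% of an aqueous-phase-equivalent
concentration sits in the organic phase (Q = 0.00391), i.e. a
3.288 kcal/mol transfer barrier. The bundled PAMPA plate:

```r
plate <- read_pampa_plate(system.file("extdata", "pampa_table2.csv",
                                      package = "azperm"))
analyze_plate(plate)
#> PAMPA effective permeability
#>   pH Ceq (uM) retention Pe (cm/s) logPe   ok
#>  7.4   1704.4     -0.15  1.12e-05 -4.95 TRUE
#>  8.0   1516.7     -0.03  5.45e-06 -5.26 TRUE
```

— measured effective permeabilities of 11.2×10⁻⁶ and 5.5×10⁻⁶ cm/s at
pH 7.4 and 8.0. Predicting permeability of a 50 Å bilayer between
extracellular fluid (pH 7.4) and cytoplasm (pH 7.2):

```r
plat <- build_compartment_profile(fit, compartment("ECF", 7.4),
                                  compartment("CYT", 7.2))
round(plat, 3)
#>    donor membrane acceptor
#>    0.000    3.288    0.253

pr <- discretize_profile(plat, d = 50e-8, dx = 1e-8)
steady_state_flux(pr, solver_config(scheme = "implicit", dt = 1e-10))
#> Smoluchowski steady-state permeation
#>   membrane 5e-07 cm, D = 8.2e-06 cm^2/s, implicit scheme, dt = 1e-10 s
#>   converged: TRUE after 2e+03 steps (2e-07 s simulated)
#>   flux          = 0.0651504 conc.cm/s
#>   P (membrane)  = 0.0652958 cm/s   (logP = -1.185)
#>   P (apparent)  = 0.0651504 cm/s   incl. reservoir layers
#>   k = P/d       = 130592 1/s

analytic_permeability(pr)
#> [1] 0.06408125
```

The numerical permeability agrees with the solubility–diffusion oracle
(the ~2% gap is the abrupt-interface discretization; it vanishes with
ramped interfaces). A rate constant of ~1.3×10⁵ s⁻¹ means bilayer
crossing is orders of magnitude faster than the ~200 s⁻¹ association
at the enzyme target — diffusion through the membrane is not the
rate-limiting step.

A command-line wrapper lives at `inst/cli/azperm`
(`fit`, `qtable`, `pampa`, `profile`, `permeate`, `simulate`), e.g.

```sh
Rscript inst/cli/azperm qtable --out qtable.csv
Rscript inst/cli/azperm permeate --thickness 125e-4 --dx 1e-4 --out result.json
```

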