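---
title: "From pH-dependent partitioning to membrane permeability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pH-dependent partitioning to membrane permeability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azperm)
```

## The problem

Azide poisons cells by inhibiting cytochrome c oxidase, but to reach its
target it must first cross the plasma membrane. The azide anion
N~3~^−^ and its conjugate acid, hydrazoic acid HN~3~ (pKa 4.65), form a
single ionizable solute ("AHA") whose lipophilicity is strongly
pH-dependent: the neutral acid partitions into octanol, the anion stays
in water. `azperm` models the full chain from two octanol/water
partition measurements to a predicted membrane permeability and
permeation rate constant:

1. a two-species distribution model Q(pH) fitted from measured
   (pH, K~ow~) pairs;
2. effective permeability, equilibrium concentration and mass retention
   from PAMPA (parallel artificial membrane permeability assay) well
   concentrations;
3. a one-dimensional free-energy profile for transfer from a donor
   compartment (extracellular fluid, pH 7.4) through the membrane to an
   acceptor compartment (cytoplasm, pH 7.2);
4. a finite-difference solution of the Smoluchowski drift-diffusion
   equation on that profile, cross-checked against the
   solubility–diffusion closed form.

## The two-species distribution model

With β = 10^(pKa − pH) the fraction-weighted distribution coefficient is

$$Q(\mathrm{pH}) = \frac{P^0\beta + P^-}{1+\beta},$$

where $P^0$ and $P^-$ are the single-species partition coefficients of
HN~3~ and N~3~^−^. Free energies follow from
$\Delta G = -k_BT\ln Q$; compartment concentration ratios from
$Q(\mathrm{pH_1})/Q(\mathrm{pH_2})$.

```{r fit}
fit <- fit_partition(data.frame(pH = c(2, 8), Kow = c(2.01, 0.00034)),
                     pKa = 4.65)
fit
q_table(fit)
```

**Fitting modes.** The default `direct` mode assigns the acidic-side
measurement to $P^0$ and the basic-side measurement to $P^-$ unchanged.
This is deliberate: the `exact` mode (solving the 2×2 linear system at
the two measured pH values) applied to the azide data yields
$P^- \approx -5.6\times10^{-4}$ — the measurements are slightly
inconsistent with the two-species model at pKa 4.65, most plausibly
through measurement error in the tiny basic-side ratio. `exact` mode is
kept for well-posed data and refuses, rather than clamps, a
non-positive solution. Note that the quality of the direct assignment
depends on the $P^0/P^-$ contrast: at two pH units from the pKa the
minority-species contamination is $\sim 10^{-2}\,P^0/P^-$ relative, so
for strongly contrasted solutes like azide the basic-side measurement
must sit several units above the pKa.

**Thermal energy.** All conversions use $k_BT$ = 0.593 kcal/mol
(≈ 298 K) by default. The physiological temperature 310 K
($k_BT$ ≈ 0.616) might seem the natural choice, but 0.593 is the value
consistently used in the experimental free-energy table this package
reproduces; it is exposed as a configurable `thermo_context()` field.

**pH handling.** Inputs are clamped to [0, 14] with a warning; values
outside [1, 13] warn without clamping. Both limits of Q are approached
smoothly ($Q \to P^0$ in acid, $Q \to P^-$ in base).

**Sign conventions.** `transfer_free_energy()` is negative when the
organic phase is favoured. `neutral_formation_free_energy()` returns
$\ln 10 \cdot k_BT\,(\mathrm{p}K_a - \mathrm{pH})$, the convention that
reproduces both published protonation numbers (−3.75 kcal/mol at
pH 7.4; +3.62 kcal/mol at pH 2.0); note that one of the two is quoted
as a protonation and the other as a deprotonation energy, so the
published sign usage is itself asymmetric and this function simply
standardizes on the formula above.

**Compartment ratios.** The exact ratio of Q values is canonical. The
pKa-free closed form $10^{\mathrm{pH_2}-\mathrm{pH_1}}$ is exposed only
as `mode = "approx"` with a warning: it is the limit in which the
anionic term is negligible, and for the ECF→CYT pair it gives 0.631
against the exact 0.653.

## PAMPA effective permeability

A donor well (0.2 mL) and an acceptor well (0.3 mL) exchange solute
through a filter-supported membrane of area 0.3 cm² for 18,000 s. The
single-timepoint estimator inverts the two-compartment kinetics:

$$P_e = \frac{-\ln\left(1 - C_A(t)/C_{eq}\right)}
        {S\,(1/V_D + 1/V_A)\,t},\qquad
  C_{eq} = \frac{C_D(t)V_D + C_A(t)V_A}{V_D + V_A}.$$

Volumes in mL are used as cm³ directly, so $P_e$ carries cm/s.

```{r pampa}
plate <- read_pampa_plate(system.file("extdata", "pampa_table2.csv",
                                      package = "azperm"))
analyze_plate(plate)
```

Design points worth recording:

* **Mass retention reference volume.** Retention is
  $1 - (C_DV_D + C_AV_A)/(C_0V_0)$ and the reference $V_0$ is taken to
  be the donor volume $V_D$ — the sample is loaded into the donor well,
  and this choice reproduces both published retention entries. The
  column is reported as a *fraction* (the published "%" column holds
  fractions: −0.151 and −0.026 recompute exactly; read as percentages
  they do not).
* **The pH 7.4 log-permeability.** The well's concentrations give
  $P_e = 1.122\times10^{-5}$ cm/s, i.e. $\log P_e = -4.95$; the
  published −4.97 next to the same row is not consistent with its own
  concentrations (plausibly a mean over unreported replicates). The
  package reports the recomputed value.
* **Negative retention** means more mass was recovered than nominally
  loaded; it is reported signed, not truncated.
* Wells whose acceptor concentration has reached $C_{eq}$ make the
  estimator undefined; `analyze_plate()` flags such rows and continues.

## The free-energy profile

The membrane interior is treated as octanol-like: the plateau above the
donor water is the transfer free energy at the donor pH, and the
acceptor water sits at the difference of the two transfer free
energies. For ECF (7.4) → CYT (7.2):

```{r profile}
plat <- build_compartment_profile(fit, compartment("ECF", 7.4),
                                  compartment("CYT", 7.2))
round(plat, 4)
```

a 3.29 kcal/mol barrier and a +0.25 kcal/mol offset — AHA is more
concentrated in the (slightly more acidic) cytoplasm at equilibrium.
The profile is discretized on a uniform cell-centered grid with x = 0
at the donor-side membrane face. The shape *inside* the membrane is not
experimentally resolved; a flat plateau is assumed, with an optional
linear `ramp_width` at each interface because interface handling is
what the discretized solver is most sensitive to. Explicit water
reservoirs (default 5 cells per side) close the system for boundary
conditions and stand in for unstirred water layers of unknown
thickness; their depth is configurable for sensitivity runs.

## The Smoluchowski solver

The concentration field obeys

$$\frac{\partial u}{\partial t} = \nabla\!\cdot\!\left[D\left(\nabla u +
  \frac{u\,\nabla G}{k_BT}\right)\right]$$

with a coordinate- and time-independent $D$ = 820 µm²/s
(8.2×10⁻⁶ cm²/s). The spatial discretization uses symmetric exponential
(thermodynamic) face weights,

$$j_{i+1/2} = -\frac{D}{\Delta x}\left[u_{i+1}e^{(G_{i+1}-G_i)/2k_BT} -
  u_ie^{(G_i-G_{i+1})/2k_BT}\right],$$

chosen over plain central differences because it (a) reduces to Fick
flux where G is constant and (b) admits the Boltzmann distribution as
an *exact* stationary state, so detailed balance holds at machine
precision on any grid. Time stepping is either forward Euler
(`explicit`) or backward Euler with a pre-factorized tridiagonal solve
(`implicit`, the default).

Numerical choices:

* **Stability.** `check_stability()` returns the Fickian bound
  0.9 dx²/(2D). Free-energy steps tighten the true explicit bound by
  the face weight $e^{\Delta G_{face}/2k_BT}$, so abrupt interfaces
  need either a reduced dt, a ramped interface, or the implicit scheme.
  On the fine bilayer grid (1 Å) the bound is ~5.5 ps, which is why the
  50 Å case defaults to the implicit scheme even at its nominal
  0.1 ns step; the 125 µm / 1 µs pairing satisfies the bound and is run
  explicitly.
* **Steady state** is declared when the outlet-face flux changes by
  less than 10⁻⁹ (relative) between checks *and* inlet/outlet fluxes
  agree to 10⁻⁶; both are required because a slowly filling membrane
  can plateau its outlet flux early.
* **Initial condition**: donor reservoir at the Dirichlet value,
  everything else empty; Dirichlet values are pinned at the outermost
  reservoir cells.
* **Permeability definition.** The flux is measured at the
  acceptor-side membrane face. Because the explicit reservoirs add
  series resistance of their own (that is what unstirred layers do),
  dividing the flux by the *pinned* concentration difference would
  mix membrane and reservoir resistance. The reported `P` therefore
  divides by the Boltzmann-weighted concentration difference
  $\tilde u = u\,e^{G/k_BT}$ extrapolated to the two membrane faces
  (half-face resistance split); this makes `P` a property of the
  membrane alone — exactly $D/d$ for a flat profile, and matching the
  solubility–diffusion integral on resolved profiles. The raw quotient
  is kept as `P_apparent`, and the gap between the two is the
  reservoir-layer contribution.
* **Oracle.** `analytic_permeability()` evaluates
  $1/P = \int_0^d e^{G(x)/k_BT}/D\,\mathrm{d}x$ by the midpoint rule on
  the same grid — an independent closed form the time-stepped solution
  must reproduce (to 1% at dx ≤ d/50 on ramped profiles; an abrupt step
  adds an O(dx/d) interface discrepancy between the trapezoid-like
  face resistances and the midpoint integral, ~0.8% at 125 cells).

```{r solver}
pr <- discretize_profile(plat, d = 1e-4, dx = 1e-6, ramp_width = 2e-5)
res <- steady_state_flux(pr, solver_config(scheme = "implicit"))
res
analytic_permeability(pr)
```

The two study geometries are a 50 Å bilayer (1 Å grid) and the 125 µm
PAMPA filter membrane (1 µm grid). With the step-profile barrier of
3.288 kcal/mol, both reduce analytically to
$P \approx (D/d)\,Q(7.4)$: about 6.4×10⁻² cm/s and 2.6×10⁻⁶ cm/s. The
published solver values (4.23×10⁻² and 22.3×10⁻⁶ cm/s) are mutually
inconsistent with that closed form for any single barrier height — the
interface discretization used to produce them is not described — so the
package asserts order-of-magnitude agreement with both (its own runs
land within factors of ~1.5 and ~9 respectively) and exact agreement
with its own oracle instead. The rate constant is defined as
$k = P/d$, the definition consistent with the published 50 Å pair
(4.23×10⁻² / 50 Å = 8.46×10⁴ s⁻¹). For context, permeation with
$k \sim 10^5$ s⁻¹ across a real bilayer is far faster than the
~200 s⁻¹ association step at the enzyme target, so membrane crossing is
not the rate-limiting step at cellular scale; the CLI `permeate`
subcommand prints this comparison as a log line (the 200 s⁻¹ constant
is carried for reporting only, never computed).

## Synthetic data and what the tests do (and do not) show

Both generators draw from the forward models with known ground truth:

* partition measurements: $K_{ow} = Q(\mathrm{pH})\,e^\varepsilon$ with
  $\varepsilon \sim N(0, \mathrm{cv}^2)$ — multiplicative lognormal
  noise, since chromatographic concentration ratios are positive and
  their error is proportional;
* PAMPA wells: the exact two-compartment kinetics
  $C_A(t) = C_{eq}(1 - e^{-P S (1/V_D+1/V_A) t})$ with mass-balanced
  $C_D(t)$, plus additive Gaussian concentration noise truncated at
  zero.

Neither error model is experimentally calibrated (no replicate data
exist to calibrate against); the defaults emulate the published study
conditions (C₀ ≈ 3700 µM, single 18,000 s readout, standard geometry).
The generators deliberately omit membrane retention, evaporation and
well-to-well contamination — the assay protocol sealed wells precisely
to suppress evaporation, and the estimator assumes no retention — so a
passing round-trip test certifies the *estimator is the exact inverse
of the ideal kinetics* (to 10⁻¹⁰) and that 1% concentration noise
propagates to ~5% median permeability error; it does not certify
robustness to the systematic effects a real plate can show (the
published plate itself shows negative retention, i.e. recovered mass
above nominal load, which no noise-free forward model with these
assumptions can produce).

All randomness flows through a caller-supplied seed and the caller's
RNG state is restored afterwards.

## Problem sizes and runtimes

The test suite exercises the solver at the full published geometries:
the 50 Å / 1 Å implicit run converges in a few thousand steps
(milliseconds), and the 125 µm / 1 µs explicit run needs ~3×10⁷ steps
(a few seconds of compiled stepping) to pass the 10⁻⁹ flux
tolerance — the membrane diffusion time is $d^2/D \approx 19$ s, and
steady state requires simulating ~30 s. Property tests use smaller
grids (1–2 µm membranes, 30–100 cells) where the same invariants are
checked in milliseconds.

## Known limitations

* Single ionization only: no multiprotic species, no activity
  corrections, no temperature-dependent pKa, and the pKa is an input,
  never estimated.
* One spatial dimension, constant D, no membrane potential, no
  coordinate-dependent diffusivity.
* The membrane interior profile is an assumption (flat plateau with
  optional interface ramps), not a measured potential of mean force.
* The PAMPA estimator is single-timepoint by design; multi-timepoint
  kinetic fitting is out of scope.
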