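---
title: "Equilibrium transfer-matrix models of amyloid fibril formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium transfer-matrix models of amyloid fibril formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyloidtm)
```

## The models

Amyloid formation is treated here as an equilibrium self-assembly problem on
1D and quasi-1D lattices.  A protein in an aggregate occupies a lattice site
and adopts one of `q` conformational states — coil (the reference, weight 1),
sheet, and optionally helix.  All interactions are short-ranged and
dimensionless (units of RT):

* `P1`, `P2` — propagation free energies: the gain when a helix or sheet
  protein interacts with its neighbour along the growth (x) axis
  (`s_i = exp(P_i)`);
* `R1`, `R2`, `R3` — interfacial free energies between unlike neighbours
  (helix–coil, sheet–coil, helix–sheet).  Each single interface carries
  `exp(-R_i)`, so a completed ordered segment with two ends pays the
  classic initiation factor `sigma_i = exp(-2 R_i)`;
* `K` — conformation-independent polymerization free energy, one factor
  `k = exp(K)` per nearest-neighbour protein pair anywhere on the lattice;
* `B` — lateral (inter-filament) binding between two sheet proteins in the
  canonical strip and cube models; `F` plays the same role in the
  grand-canonical models;
* `A` — nucleation/surface free energy of the grand-canonical models; each
  solvent–protein boundary pays `exp(-A)` (`alpha = exp(-2A)` for an
  isolated aggregate with two ends).

A **filament** is a 1D chain of proteins; a **strip** of `Ly` filaments
bound laterally is a protofibril; the **cube** (two `Ly = 2` strips stacked
in register) is a mature fibril cross-section.  Because all interactions
couple adjacent columns only, the partition function of an aggregate of
`Lx` columns factors through a transfer matrix over composite column states
(`q^(Ly*Lz)` of them), contracted with boundary vectors:

```{r tm}
p <- energy_params(P2 = 0.9, R2 = 0.4, B = 0.7, K = 0.2)
tm <- build_transfer_matrix(lattice_spec("strip", Ly = 2), p)
tm
partition_open(tm, Lx = 4)
```

Every partition function in the package is certified against
`enumerate_partition()`, an independent exhaustive sum over all lattice
configurations that assembles each Boltzmann weight term by term from the
effective Hamiltonian.

### Two printed conventions for the propagation weight

The source models write the propagation term in two inequivalent ways: the
Ising-form Hamiltonian attaches `P` to *every* ordered protein, while the
Potts-form Hamiltonian attaches it to every ordered protein *that has a
right neighbour* — i.e. once per bond, so that an isolated protein carries
no interaction weight at all.  Both are implemented (`prop = "site"` vs
`prop = "bond"` in `partition_open()` and `fibril_species()`), and they
share a spectrum, differing only in the boundary contraction.

The dilute ensembles default to the bond placement, for a physical reason:
with site placement a lone monomer at the published sheet weight
(`s2 = e^{2.7} ≈ 15`) would be 94% sheet, and the ensemble sheet fraction
would *start* near 0.9 at vanishing concentration instead of rising
sigmoidally from zero the way CD titrations do.  Under bond placement the
monomer is conformationally unweighted, the sheet fraction rises from ~0,
and it tracks the fibril mass share closely over the experimentally probed
window — which is exactly how the model is used as a CD fit function.

### Interfaces: `exp(-R)` per crossing

Printed transfer matrices in this literature sometimes put the whole
`sigma` in a single matrix element and sometimes split it.  The package
always charges `exp(-R)` per unlike interface, which (i) reproduces the
classic characteristic polynomial
`lambda^2 - (1+s) lambda + s(1-sigma) = 0` for the two-state filament,
(ii) makes the helix-coil and aggregation matrices spectrally identical,
and (iii) is what the effective Hamiltonian literally says.  The
enumeration oracle uses the same convention, so the certification is
end-to-end.

## Dilute multi-species equilibrium

In dilute solution every aggregate species and size is an ideal-gas
component with number density `rho(L) = Z(L) z^L`, where `z = exp(mu)` is
the protein fugacity.  Species sums over all lengths are geometric in the
spectral basis and are evaluated in closed form; an adaptive direct sum
(tail-bounded at 1e-12) provides a second, independent evaluation route
(`ensemble_sums(..., method = "both")`).

The total protein concentration fixes `z` through the mass balance
`phi = sum_species sum_Lx L rho(L)`, which is strictly increasing in `z`
and diverges at the convergence radius `z_max = (k^g lambda_1)^(-1/m)` —
the finite-concentration echo of equilibrium polymerization.  The solver is
a safeguarded Newton iteration on `log z` with the analytic slope; the
round trip is exact to 1e-10 over at least four decades of concentration
(tested).

```{r ensemble}
ens <- asyn_ensemble()     # strips Ly = 1..4; the Ly = 4 strip is the fibril
pars <- params_asyn()      # P2 = K = 2.7 RT, B = 1.95 RT, R2 = -1.64 RT
solve_fugacity(30, ens, pars)
```

Observables compared to experiment:

* `sheet_fraction()` — the mass-weighted sheet content
  `theta_2 = (s2/phi) d rho_T / d s2`, the CD fit function.  The exported
  function uses the centred log-derivative with Richardson extrapolation;
  the curve/fitting path uses an exact resolvent-form derivative
  (`rho = pre * f1 * i' (I - f1 T)^{-1} f` differentiated analytically);
  a test certifies the two against each other and against enumeration.
* `mean_length()` — mean aggregate size per species; the fibril species'
  mean column count is the AFM-comparable length.
* `ensemble_curve()` / `take_off_concentration()` — concentration sweeps
  and the half-rise concentration of the fibril mass share, the
  "concentration at which fibril content takes off".

### The standard state

The published dimensionless parameter sets leave the concentration unit of
the fugacity unstated, yet it sets the absolute concentration scale of
every prediction.  The package reads the activity as a **lattice volume
fraction**: `z = c * v_site` with one protein-sized lattice cell per
protein.  For a 3.5–5 nm cell, `1/v_site` is 16–62 mM; the default
standard state is the round value **30 mM** (`standard_state_uM = 3e4`).
Under it the polymerization window of both published parameter sets falls
in the micromolar range actually probed by the CD and AFM experiments they
were fitted to, and the predicted fibril lengths at 10–100 µM are hundreds
of columns (tens to hundreds of nm), the magnitude AFM reports.  The
choice is a single global unit, exposed as an argument everywhere; it was
fixed by this physical argument, not adjusted per system.

### Numerical choices

* Species sums use the spectral closed form; eigenvalues numerically at
  zero are handled through their (nilpotent) one-column contribution.
  Ill-conditioned eigenbases (condition > 1e8) are flagged and the direct
  product route is used instead.
* The cube's polymerization exponent counts `K` once per nearest-neighbour
  bond (`8 Lx - 4` for the 2x2 cube), the count the enumeration oracle
  validates; a printed closed form with a smaller exponent exists in the
  source literature and is not used.
* `log_derivative()` uses a centred difference in `log x` (step 1e-4) with
  one Richardson step; analytic routes exist where they matter (mass
  balance slope, sheet fraction) and are cross-checked against it.
* Degenerate inputs: `sigma -> 0` (all-or-none), `s = 1` (transition
  midpoint) and `B = 0` (independent filaments; the strip matrix becomes a
  Kronecker product) are all covered by tests.

## Grand-canonical lattice gas

`gc_model()` adds explicit solvent: each site is empty or holds a coil or
sheet protein, the protein count is controlled by `z = exp(beta mu_PC)`,
and solvent–protein boundaries pay the nucleation penalty `A`.  Variant A
places the `nc`-column nucleus along the growth axis (composite states
remember `nc` columns, dimension `(q+1)^(nc*Ly)`, capped at 8 sites);
variant B makes the whole column the nucleus (dimension `(q+1)^Ly`).
Periodic boundaries are used throughout, and `gc_log_partition_per_site()`
is the per-site grand potential `log(lambda_1)/Ly`.

Observables are logarithmic derivatives of the grand potential: occupancy
(`z d lnQ/dz`), sheet bonds (`d lnQ/dP1`), filament count (half the mean
number of solvent–protein boundaries — note the printed derivative
`(1/2) d lnQ/dA` has the opposite sign for a penalty, so the package
differentiates with respect to `-A`), and filament protein count.  All are
certified against `enumerate_gc_partition()` on small periodic lattices.

`mu_pc_from_concentration()` supplies the bridge from solution
concentration: `mu_PC = mu_ST + mu_SR + RT log c - mu_PV`, with the
translational-plus-rotational solution term defaulting to -29 kcal/mol and
the vibrational term to three quarters of it (the hemoglobin-derived
rule); temperature defaults to 298 K, concentration is molar.

## Fitting and synthetic data

`generate_synthetic_curve()` evaluates the exact model observable on a
concentration grid and adds independent Gaussian noise (sheet fractions
clipped to [0, 1], lengths to >= 1), recording the generating truth.
`fit_observable_curve()` performs bounded Levenberg–Marquardt least
squares with seeded multi-start.  Because the take-off concentration
depends exponentially on the free energies, the least-squares landscape
has narrow curved valleys; each start is therefore preceded by a short
one-dimensional fit of the leading free parameter, which reliably lands
the full fit in the correct valley.  Standard errors come from the
quadratic approximation at the optimum; parameters flat across their whole
bound interval or resting on a bound are flagged instead.

What the synthetic generator does and does not emulate: it reproduces the
model's own concentration response with homoscedastic additive noise —
appropriate for normalized CD fractions — but real titrations have
baseline and normalization errors, concentration-dependent noise, and
possible kinetic trapping far from equilibrium.  Passing the recovery
tests therefore demonstrates that the estimator and its reported
uncertainties are internally calibrated, not that the model is identified
by any particular real data set.  The recovery study uses the
sheet-fraction observable: an additive noise SD of 0.02 is a realistic
fractional error there, whereas on mean lengths measured in columns it
would amount to ~1e-4 relative error, a regime in which any quadratic
standard error of this strongly nonlinear model is miscalibrated.

Problem sizes used by the test-suite studies: oracle certification runs
~220 seeded parameter draws on lattices of up to 16 canonical (10
grand-canonical composite) sites; the recovery study runs 100 replicates
of 30-point curves.

## Known limitations

* Only quasi-1D geometries with finite transfer matrices; no 2D/3D bulk
  solutions and no kinetics (the models are strictly equilibrium).
* The grand-canonical implementation is two-state (sheet-coil) only.
* Off-pathway species (micellar oligomers, amylospheroids) are outside the
  species algebra.
* The absolute concentration scale rests on the standard-state argument
  above; all dimensionless results are independent of it, but reported
  take-off concentrations scale linearly with the chosen `1/v_site`.
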