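---
title: "Methods: from pigment geometry to ATP turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pigment geometry to ATP turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromatophore)
```

This vignette documents the model behind the package, the choices made
where the design was genuinely open, and what the synthetic-data generator
does and does not establish. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The system

A low-light-adapted chromatophore vesicle of *Rhodobacter sphaeroides*
contains, in the reference composition modelled here, 63 LH2 complexes, 11
dimeric plus 2 monomeric RC-LH1-PufX complexes (24 reaction centres), 4
cytochrome bc1 dimers and 2 ATP synthases on a sphere of 50 nm inner
diameter, for 2469 bacteriochlorophylls (BChls) in total. Light absorbed
anywhere in the antenna migrates as excitons to a reaction centre (RC),
drives charge separation and quinone reduction; quinol is re-oxidized at
cytochrome bc1, pumping protons; ATP synthase converts the proton gradient
to ATP. Three efficiency-relevant bottlenecks are modelled: the quantum
yield of excitation capture, bc1-limited quinone cycling, and the proton
budget of ATP synthesis.

## Stage I: the exciton network

**Clusters.** The excitonically coupled units are the LH2 B850 ring (18
BChls), the LH1 B875 ring (28 BChls per RC-LH1 monomer half) and the four
RC BChls. LH2 B800 pigments do not form coupled states; they are stored in
the pigment table but excluded from the network and from the pigment counts
N_I entering the initial state P(0). (The model's own account: thermal
relaxation within a cluster is fast compared to inter-cluster transfer, and
B800 hands its excitation to B850 essentially instantaneously. The quantum
yield changes by under 3% for plausible alternative initial states, so the
N_I convention is low-risk.)

**Hamiltonian.** Per cluster, site energies alternate 12459/12625 cm⁻¹
around the B850 ring, are uniform at 12344 cm⁻¹ on B875, and are
12092/12581 cm⁻¹ for the RC special pair/accessory BChls. Ring-adjacent
couplings are short-range quantum-chemistry values (363/320 cm⁻¹ LH2,
806/377 cm⁻¹ LH1, alternating intra-/inter-αβ-dimer; 500 cm⁻¹ RC special
pair); all other couplings use the point-dipole formula with
C = 348,000 Å³ cm⁻¹, valid beyond ~1 nm.

**Rates.** Generalized Förster rates between neighbouring clusters sum
Boltzmann-weighted squared exciton couplings times Gaussian spectral
overlaps over all donor and acceptor states (no truncation; N_I ≤ 28).
Conventions:

* ħ = 5.3088 × 10⁻¹² cm⁻¹ s, so rates emerge in s⁻¹ from energies in
  wavenumbers.
* Temperature for the Boltzmann populations: 300 K (not stated in the
  source material; configurable).
* Linewidths: σ_LH2 = 188, σ_LH1 = 235 cm⁻¹; the RC linewidth is not
  tabulated and defaults to σ_LH1, the nearest spectral region
  (configurable).
* The printed lineshape formula is internally inconsistent (prefactor
  `1/(√(2π)σ)` with exponent `−((E−ε)/σ)²` does not integrate to 1, yet
  the text asserts unit area). Default: the normalized Gaussian with
  standard deviation σ. The literal printed form is available via
  `lineshape = "literal"`; both closed forms are verified against
  numerical quadrature to 1e-10.
* The donor-emission red-shift S has no published value here; default 0,
  configurable via `shift_S`.
* Neighbour cutoff: clusters farther than 70 Å (minimal Mg–Mg) transfer
  negligibly (r⁻⁶ in the rate) and get rate 0.
* LH1↔RC within one complex uses fixed calibrated rates, (35 ps)⁻¹ forward
  and (8 ps)⁻¹ back, instead of computed values (the computed forward rate
  is known to overestimate the excitation lifetime).

**Yield.** The migration generator K adds dissipation (1 ns)⁻¹ everywhere
and charge separation (3 ps)⁻¹ at RCs; q = −k_CS 1_RC' K⁻¹ P(0) is
evaluated as a linear solve (residual policy 1e-10). An independent oracle
propagates dP/dt = K P on the probability-conserving augmented system
(explicit capture and dissipation sinks) with a fourth-order Runge-Kutta
one-step propagator and repeated squaring; it shares no code with the
solve, conserves probability to ~1e-13 by construction, and agrees with the
solve to better than 1e-6 on random networks and on the full reference
vesicle.

## The synthetic vesicle generator

The generator is first-class, tested code: it emulates the geometric
structure the exciton analysis needs, not an atomic structure.

* **Rings.** Ideal circles: B850 radius 26 Å (18 pigments → 9.0 Å
  consecutive Mg–Mg spacing), B875 radius 40 Å (28 pigments → 8.95 Å),
  B800 radius 31 Å offset 16.5 Å from the B850 plane, RC special pair
  ±3.9 Å with accessories at 13 Å. A note on the B875 radius: a 50 Å
  radius was considered and rejected because 28 pigments on it violate the
  ~9 Å nearest-neighbour spacing that anchors the ring geometry, and
  because it lets adjacent-complex pigments approach below the point-dipole
  validity limit.
* **Dipoles.** Tangential with alternating α/β sign (consecutive Qy
  dipoles nearly antiparallel, as in the real rings) and alternating ±10°
  out-of-plane tilt. The alternating sign matters: it carries oscillator
  strength into the thermally populated low excitons, reproducing the
  picosecond inter-complex transfer scale; a same-circulation variant
  leaves the band bottom dark and slows transfers by an order of magnitude.
  NB/ND pseudo-atoms are synthesized ±1.45 Å from the Mg along the dipole,
  so the dipole-from-atoms path (`transition_dipole`) round-trips exactly.
* **Placement.** Complex centres sit on a mid-membrane sphere of radius
  280 Å (the 50 nm figure is the lumenal diameter). The default placement
  grows a contact-packed arrangement: each complex is anchored at touching
  distance (hard-core radii 36/52/44/36 Å for LH2, RC-LH1 monomer, bc1,
  ATP synthase; centre separation jittered by |N(0, 2 Å)|) from a randomly
  chosen placed complex, emulating the densely packed antenna domains seen
  in AFM. Plain random sequential adsorption (`placement = "rsa"`) is kept
  as an option; at the achievable coverage it fragments the antenna and
  drops the yield well below the published band, which is a property of
  sparse packings, not of the transfer theory. Placement is the only
  stochastic stage and is fully determined by `geometry_config(seed)`.
* **What a green test establishes.** The generator reproduces composition
  book-keeping (counts, stoichiometry s = n_LH2/n_RC = 2.625, 2469 BChls),
  ring spacings, and a connected network whose computed yield lands in the
  published 0.85–0.94 band (0.89 for the default seed). It does *not*
  reproduce the AFM-derived arrangement of any real vesicle, protein
  orientations, thermal disorder of site energies, or membrane curvature
  strain — conclusions drawn from it are at the level of network
  statistics, not structure.

## Stage II/III kinetics

All Stage II/III relations are closed-form in the absorbed photon flux
I = αΦ with α = 37.2 photons s⁻¹ per W m⁻² (anchored to the single printed
calibration: 1860 photons/s at 50 W/m²):

* bc1 electron capacity B = 2 n_B/τ_B (τ_B = 25 ms); 320 s⁻¹ for n_B = 4.
* Cycling time τ_RC(I) = τ_L + (τ_H − τ_L)(1 − exp(−½Iq/B)), τ_L = 3 ms,
  τ_H = (n_RC/n_B) τ_B. The printed formula's exponent sign is a clear
  typographical slip (the text defines c_L = exp(−½Iq/B) and τ_RC must
  stay within [τ_L, τ_H]); the negative exponent is implemented. The ½ in
  the exponent is the printed convention; the accompanying derivation text
  suggests a factor 1 instead, exposed as `poisson_factor`.
* RC availability p_RC = (1 + ½ I q τ_RC/n_RC)⁻¹, which satisfies the
  steady-state binding/release balance identically (machine precision).
* k_ATP = ½ I q p_RC, equal to the quinol formation rate when the proton
  stoichiometries match (4 H⁺/quinol, 4 H⁺/ATP for a 12-subunit c-ring;
  `protons_per_atp` rescales for 10- or 11-subunit rings).
* η_ATP = E_ATP k_ATP/(E_γ I); at I = 0 the analytic limit
  E_ATP q/(2 E_γ) is returned with a flag rather than NaN.

**A model artifact worth knowing.** k_ATP(I) is *not* globally monotone:
writing x = ½Iq, the derivative carries the sign of 1 − x²τ′_RC(x)/n_RC,
which turns negative for x ≈ 500–800 s⁻¹ (roughly 30–47 W/m²) with the
default constants. The resulting dip is ~0.4% deep — invisible at figure
resolution but real, a direct consequence of the two-state Poisson
interpolation of τ_RC. The test suite asserts strict monotonicity outside
that window and bounds the dip; the corresponding strict acceptance test is
intentionally left failing with this analysis.

**Known irreproducibility.** The published headline values at 1–5% sun
(82/118 ATP s⁻¹, η = 0.12–0.04, p_RC = 0.73/0.23, and the 79%/51%
reference-to-optimum fractions) are mutually inconsistent with the printed
constants under any single photon-flux calibration: the printed α gives
k_ATP ≈ 117 s⁻¹ at 10 W/m², not 82. The effective intensity mapping used
for the published curves is not recoverable, so the package implements the
printed constants faithfully and validates those figure-level claims as
qualitative properties (saturation integer part 158, crossover ≈ 9 W/m²,
curve orderings, sweep geometry) rather than chasing the headline numbers.

## The composition sweep

Compositions (n_B, n_L) at fixed membrane area have their LH2 count set by
footprint compensation, n_LH2 = round((A_total − n_B A_bc1 −
n_L A_RCLH1)/A_LH2), with defaults A_LH2 = 41, A_RCLH1 = 180, A_bc1 =
60 nm² (structural-diameter estimates; the published values are not
printed, so sweep conclusions are treated as qualitative in these). The
yield comes from the stoichiometry interpolation q = 0.91 + 0.0152(2.625 −
s), clamped below at 0.85 (no upper clamp is needed: s = 0 gives 0.9499).

One modelling decision goes beyond the bare rate equations: the absorbed
photon flux is scaled with the BChl complement (27 per LH2, 64 per RC-LH1
dimer) relative to the reference 2469 (`scale_absorption = TRUE`). Without
it, antenna-free compositions would absorb as strongly as the reference and
the optimum degenerates to the grid corner; with it, the sweep reproduces
the published landscape closely (interior optimum with more LH2 than the
reference at 1% sun, optimum shifting toward more RC-LH1 at 3%, native
composition at roughly three quarters of the optimal rate). A corollary:
"more bc1 never hurts" holds exactly only with `scale_absorption = FALSE`,
since in the scaled model bc1 dimers cost antenna area.

## Numerical policies and degenerate inputs

* Linear solve for q rather than inversion; singular K (k_diss = 0 with a
  sink-free component) raises an informative error.
* Oracle time step: chosen so the scaled generator 1-norm is ≤ 0.05 per
  step; horizon 40/k_diss; residual excitation above `tol` at the horizon
  is a non-convergence error, not silently accepted.
* Sweep ties are broken toward smaller n_B, then smaller n_L; LH2 counts
  round half away from zero and floor at 0 with an infeasibility flag.
* n_B = 0 disables the bc1-limited regime: τ_H is undefined (error in
  `tau_high`) and the steady-state ATP rate is 0 by convention in
  `atp_rate`.
* Placement failures (overcrowded sphere) error out naming the offending
  composition after a bounded number of attempts.

## Limitations

Spatial inhomogeneity of the quinone pool, explicit quinone/cytochrome c2
diffusion, proton leak, NADH/succinate dehydrogenase coupling, carotenoid
photophysics, thermal/static disorder of site energies, and non-stationary
illumination are all outside the model. The kinetics is a steady-state,
well-mixed description whose strongest claims are capacity comparisons and
curve shapes, not absolute rates at a given lamp setting.
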