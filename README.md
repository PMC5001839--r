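# chromatophore

Steady-state energy conversion modelling of the purple-bacterial
chromatophore — the ~50–70 nm spherical vesicle in which *Rhodobacter
sphaeroides* converts absorbed sunlight into ATP. The package is aimed at
computational biophysicists studying organelle-scale photosynthesis: it
connects pigment-level exciton transfer to vesicle-level photophosphorylation
in one reproducible pipeline.

## The model

Energy conversion is treated in three stages.

**Stage I — light harvesting.** Each LH2 B850 ring (18 BChls), LH1 B875 ring
(28 BChls per RC-LH1-PufX monomer half) and reaction-centre (RC) BChl
quartet forms an excitonically coupled cluster with effective Hamiltonian

    H_I = Σ_i E_i |i><i| + Σ_{i>j} V_ij (|i><j| + |j><i|),

site energies and short-range couplings from a constants registry, and
longer-range couplings from the point-dipole formula
`V_ij = C (d_i·d_j / r³ − 3 (d_i·r)(d_j·r) / r⁵)` with
C = 348,000 Å³ cm⁻¹. Inter-cluster generalized Förster rates

    k_IJ = (2π/ħ) Σ_{μν} p_μ |(μ|H_IJ|ν)|² J_μν

use Boltzmann donor populations p_μ and Gaussian spectral overlaps J_μν.
Excitation migration with dissipation k_diss = (1 ns)⁻¹ and charge
separation k_CS = (3 ps)⁻¹ at open RCs gives the quantum yield

    q = −k_CS · 1_RC' K⁻¹ P(0),

cross-checked by an independent time-propagation oracle.

**Stage II — quinone cycling.** Quinol turnover at the cytochrome bc1
complexes (capacity B = 2 n_B/τ_B, τ_B = 25 ms) limits the quinone cycling
time at the RC, which interpolates between a diffusion-limited τ_L = 3 ms
and the bc1-limited τ_H = (n_RC/n_B) τ_B with a zero-event-Poisson weight
c_L = exp(−½Iq/B). RC availability follows the steady-state balance
p_RC = (1 + ½ I q τ_RC / n_RC)⁻¹.

**Stage III — ATP synthesis.** With 4 H⁺ per quinol and 4 H⁺ per ATP
(12-subunit c-ring), k_ATP = ½ I q p_RC(I), and the efficiency is
η_ATP = E_ATP k_ATP / (E_γ I) with E_ATP = 4197 cm⁻¹, E_γ = 11765 cm⁻¹.

A composition sweep evaluates k_ATP over (n_B, n_L) grids at fixed membrane
area, with LH2 counts compensating footprint changes, q interpolated from
the LH2:RC stoichiometry and absorption scaled with the BChl complement.

## Worked example

```r
library(chromatophore)

v <- build_reference_vesicle()   # 63 LH2, 11 dimeric + 2 monomeric RC-LH1,
v                                # 4 cytbc1 dimers, 2 ATP synthases
#> Chromatophore vesicle model
#>   LH2: 63   RC-LH1 dimer-equivalents: 12 (monomers: 2)
#>   RCs: 24   cytbc1 dimers: 4   ATP synthases: 2
#>   BChls: 2469 (network clusters: 111)   LH2:RC s = 2.625
#>   inner diameter: 50 nm

q <- vesicle_quantum_yield(v)    # solve the 111-cluster migration network
sprintf("q = %.4f", as.numeric(q))
#> [1] "q = 0.8919"
```

The quantum yield of the synthetic vesicle falls in the 0.85–0.94 range
reported for such networks; 89% of absorbed photons drive charge
separation. Steady-state kinetics over light intensities (W/m²):

```r
kinetics_profile(c(10, 30, 50, 1000), kinetic_params(), q = 0.91)[,
  c("intensity", "I", "tau_RC", "p_RC", "k_ATP", "eta_ATP")]
#>   intensity     I tau_RC   p_RC    k_ATP eta_ATP
#> 1        10   372 0.0634 0.6911 116.9723  0.1122
#> 2        30  1116 0.1199 0.2827 143.5477  0.0459
#> 3        50  1860 0.1396 0.1689 142.9272  0.0274
#> 4      1000 37200 0.1500 0.0094 158.5017  0.0015
```

At 1% of full sunlight the vesicle turns over ~117 ATP/s at ~11%
efficiency; at full sunlight the rate saturates toward the bc1-limited
bound n_RC/τ_H = 160 s⁻¹ (integer part 158 at I = 37,200 photons/s) while
efficiency collapses — the hallmark of a low-light-adapted machine. The
capacity comparison that identifies cytbc1 as rate limiting:

```r
capacity_report()
#>                       quantity       value      units
#> 1           rc_quinol_capacity  846.300000   quinol/s
#> 2          bc1_quinol_capacity  160.000000   quinol/s
#> 3        bc1_electron_capacity  320.000000 electron/s
#> 4          bc1_proton_capacity  640.000000       H+/s
#> 5 atp_synthase_proton_capacity 2160.000000       H+/s
#> 6          crossover_intensity    9.452913      W/m^2
```

Composition optimality at 1% of full sunlight:

```r
sweep_composition(10)
#> Composition sweep at 10 W/m^2 (528 grid points, 392 feasible)
#>   optimum: n_B = 10, n_L = 3, n_lh2 = 94, k_ATP = 151.2 /s
#>   reference: k_ATP = 117 /s (77.4% of optimum)
```

The native composition is suboptimal for steady-state ATP production
(77% of the achievable rate; the optimum carries more antenna and more bc1
per RC-LH1), consistent with a design protecting against over-illumination
rather than maximizing steady-state output.

## Command line

```sh
Rscript -e 'chromatophore::chromatophore_cli()' all --out=out --seed=1
```

Subcommands: `build`, `rates`, `qy`, `kinetics`, `sweep`, `all`,
`fixtures`; flat key-value config files (e.g. `kinetics.tau_B = 0.025`)
via `--config=FILE`.
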