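# idpbd — coarse-grained Brownian dynamics for intrinsically disordered proteins

Intrinsically disordered proteins (IDPs) have no stable fold; their
behaviour is governed by sequence-level charge patterning and sampled over
large ensembles of conformations, which makes overdamped (Brownian)
dynamics of bead-per-residue models the natural simulation tool. `idpbd`
is an R package for scientists studying IDP dimensions and association: it
combines CIDER-style sequence statistics, a spline-tabulated coarse-grained
force field with screened electrostatics, a constrained Brownian-dynamics
engine (compiled core), and the structural/association observables used to
analyse such simulations.

## What it computes

**Sequence statistics** (per sequence, as a tibble): net charge per residue
NCPR = (n⁺ − n⁻)/N, fraction of charged residues FCR = (n⁺ + n⁻)/N, the
charge-segregation measure

κ = mean over blob sizes g ∈ {5, 6} of δ_g / δ_g^max,  δ_g = ⟨(σ_blob − σ_seq)²⟩,  σ = (f⁺ − f⁻)²/(f⁺ + f⁻),

rescaled Kyte–Doolittle hydropathy (0–9), the disorder-promoting residue
fraction, and the Das–Pappu phase classification.

**Energetics**: natural-cubic-spline evaluation of tabulated bond / angle /
dihedral / non-bonded potentials with a global non-bonded scaling factor
`s` (default 0.786), plus Debye–Hückel electrostatics
U = 332.0637 q₁q₂ exp(−r/λ_D)/(ε r) with λ_D from
λ_D = √(ε₀ε_τ k_B T / 2e²N_A C).

**Dynamics**: the Ermak–McCammon propagator
Δr = (Δt/k_BT) D F + ξ, ⟨ξξᵀ⟩ = 2DΔt, with free-draining or
Rotne–Prager–Yamakawa hydrodynamics (refreshed every 400 steps by
default), SHAKE-style bond constraints permitting 0.2 ps steps (0.05 ps
unconstrained), reduced-frequency non-bonded updates, and half-harmonic
inter-chain restraints.

**Observables**: radius of gyration, Kirkwood hydrodynamic radius
1/R_h = ⟨1/r_ij⟩ with the ×1.186 + 1.03 Å bead-shell calibration,
inter-residue distance profiles R_ij(|j−i|), the entanglement index (mean
Cα–Cα distance between two chains), distance autocorrelation convergence
checks, and a non-bonded scaling-factor scan against reference R_h values.

## Worked example

Two oppositely charged synthetic 50-mers (poly-Glu vs poly-Lys) in the
crosswise association geometry — middle Cαs 15 Å apart, restrained below
20 Å — with WCA excluded volume plus screened electrostatics at the
reference salt condition:

```r
library(idpbd)

seq_profile(c(sv10 = unname(ek_variant("alternating")),
              sv30 = unname(ek_variant("diblock")),
              abeta40()))
#> # A tibble: 3 × 8
#>   name    length   ncpr   fcr    kappa hydropathy disorder category
#>   <chr>    <int>  <dbl> <dbl>    <dbl>      <dbl>    <dbl> <chr>
#> 1 sv10        50  0     1     0.000871       0.8       1   Strong polyampholytes
#> 2 sv30        50  0     1     1              0.8       1   Strong polyampholytes
#> 3 abeta40     40 -0.075 0.225 0.351          4.56      0.6 Weak polyampholytes

ff <- synthetic_forcefield(
  nonbonded = list(form = "wca", epsilon = 0.3, sigma = 4),
  scaling_factor = 0.786)
sys <- two_chain_fixture(50, "opposite", separation = 15, cap = 20,
                         debye_length = debye_length(150))  # 7.85 Å
params <- bd_params(max_steps = 2e5, snapshot_stride = 2000, seed = 1,
                    constraints_on = TRUE, force_update_interval = 10)
traj <- run_bd(sys, ff, params)

glance(traj)
#> # A tibble: 1 × 5
#>   n_beads n_snapshots total_time_ps mean_rg mean_rh_calibrated
#> 1     100         101         40000    22.5               20.8

trajectory_mean(entanglement_series(traj), burn_in = 0.3)
#> # A tibble: 1 × 3
#>    mean    se n_used
#> 1  23.2 0.257     71
```

The profile table reads as a CIDER-style summary: both (Glu-Lys)₂₅
variants are length-50 strong polyampholytes with NCPR 0 and FCR 1 and
differ only in κ — 0.0009 for the strictly alternating arrangement versus
exactly 1 for the fully segregated diblock — while Aβ(1–40) is a weakly
charged (FCR 0.225), moderately hydrophobic (4.56/9) weak polyampholyte.
The trajectory summary shows a 40 ns run of the restrained pair; the mean
entanglement index of ≈ 23 Å (middle-Cα cap 20 Å) is the association
proxy: it drops as the chains interpenetrate and rises toward and beyond
the cap when screening weakens their attraction. Rerunning with
`debye_length = debye_length(1250)` (2.72 Å, excess salt) raises it —
long-range attraction between the oppositely charged chains is screened
away.

`tidy()`, `glance()`, `autoplot()` methods cover trajectories and scans;
`plot_rij_profile()` plots distance profiles. A thin command-line wrapper
for shell pipelines is installed at `inst/cli/idpbd`
(`seqstats`, `build`, `run`, `analyze`, `make-fixtures` subcommands).

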