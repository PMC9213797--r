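---
title: "Coarse-grained Brownian dynamics for disordered proteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained Brownian dynamics for disordered proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpbd)
```

## The model

`idpbd` simulates intrinsically disordered proteins (IDPs) at one bead per
residue. A chain is an ordered set of beads (residue type, charge in
elementary units, hydrodynamic radius in Å, position in Å) connected by
consecutive bonds. The potential energy of a one- or two-chain system is

$$U = \sum_{\text{bonds}} U_b(r) + \sum_{\text{angles}} U_a(\theta)
    + \sum_{\text{dihedrals}} U_d(\phi)
    + s \sum_{\text{pairs}} U_{nb}(r_{ij})
    + \sum_{\text{pairs}} \frac{332.0637\, q_i q_j}{\epsilon_\tau r_{ij}}
      e^{-r_{ij}/\lambda_D}
    + U_{\text{restraint}},$$

where every bonded and non-bonded term is a *tabulated* potential evaluated
as a natural cubic spline (the format used by coarse-grained force fields of
the COFFDROP family), $s$ is a global scaling factor applied to the
tabulated non-bonded energies only, and the electrostatics are
Debye–Hückel-screened Coulomb interactions. Pairs separated by fewer than
three bonds within a chain (1-2 and 1-3 neighbours) are excluded from both
non-bonded sums; all cross-chain pairs are included. At the system sizes
this package targets (≤ ~400 beads) interactions are summed over all pairs;
there are no neighbour lists or tree approximations.

The screening length comes from the ionic strength $C$ (mol·m⁻³) via

$$\lambda_D = \sqrt{\frac{\epsilon_0\,\epsilon_\tau\,k_B T}{2 e^2 N_A C}},$$

so `debye_length(150)` ≈ 7.85 Å and `debye_length(1250)` ≈ 2.72 Å at 298 K
in water ($\epsilon_\tau$ = 78.4). Note the unit subtlety: those two
screening lengths correspond to 150 and 1250 mol·m⁻³. Literature values of
"15 mM" and "125 mM" NaCl paired with 7.85/2.72 Å imply a √10 discrepancy
with the formula's SI units; this package treats $\lambda_D$ as the
authoritative simulation parameter and lets the user supply either
$\lambda_D$ directly or an ionic strength in mol·m⁻³ (exactly one of the
two in a config file).

## Sequence statistics

`seq_profile()` computes the standard charge-pattern descriptors used to
place IDP sequences on the Das–Pappu diagram, with the neutral-pH charge
convention (Asp/Glu −1, Lys/Arg +1, His and termini neutral):

* **NCPR** $(n_+ - n_-)/N$ and **FCR** $(n_+ + n_-)/N$;
* **κ**, the blob-averaged charge-segregation measure: for blob sizes
  $g \in \{5, 6\}$, windows of $g$ residues slide one residue at a time;
  each window's charge asymmetry $\sigma = (f_+ - f_-)^2/(f_+ + f_-)$ is
  compared with the whole-sequence asymmetry, and the mean squared
  deviation $\delta_g$ is normalized by $\delta_g^{max}$ of the maximally
  segregated rearrangement of the same composition. κ is the mean of
  $\delta_g/\delta_g^{max}$ over the blob sizes, clamped to [0, 1];
* rescaled **Kyte–Doolittle hydropathy** (mean of KD + 4.5, range 0–9) and
  the **disorder-promoting fraction** over {A, R, G, Q, S, P, E, K, D, H};
* the **Das–Pappu region**: FCR < 0.25 weak polyampholytes;
  0.25 ≤ FCR ≤ 0.35 Janus; FCR > 0.35 with |NCPR| ≤ 0.35 strong
  polyampholytes, otherwise strong polyelectrolytes.

Two design choices deserve a note. The maximally segregated arrangement is
taken as the contiguous diblock of the sorted charge vector (negative
block, neutral block, positive block) rather than a search over all
placements of the neutral residues. This is exact for sequences without
neutral residues — in particular the (Glu-Lys)₂₅ family, where the diblock
variant scores κ = 1 identically — but for mixed sequences it can differ
from implementations that optimize neutral-residue placement (for
Aβ(1–40) this estimator gives ≈ 0.35 where such implementations report
≈ 0.21). κ values of sequences with neutral residues should therefore be
compared only within this package. Second, protonation is deliberately not
recomputed: bead charges for structure-derived chains come from the PQR
input, which encodes the upstream pKa assignment.

```{r}
seq_profile(c(sv30 = unname(ek_variant("diblock")),
              sv10 = unname(ek_variant("alternating")),
              abeta40()))
```

## Chains, systems and the association geometry

Chains come from three sources: `chain_from_pqr()` (one bead per residue at
the Cα position, bead charge = sum of the residue's atomic charges, bead
radius from a per-type table, default 4 Å), `chain_from_pdb()`, or
`build_chain()` for synthetic starting structures (extended, ideal helix,
or fixed-bond random coil at 3.8 Å Cα spacing). Bond constraint targets are
the consecutive bead distances at construction.

`two_chain_system()` reproduces the standard pairwise starting arrangement
for association runs: each chain's middle Cα (0-based index ⌊N/2⌋) is
placed at the origin, chain A's principal axis is rotated onto x and chain
B's onto y ("crosswise" — the geometry is stated only qualitatively in the
source literature, so perpendicular principal axes is this package's
concrete realization), then B is translated 15 Å along z. A half-harmonic
restraint (zero inside the cap, $k(d - \text{cap})^2/2$ beyond, default
cap 20 Å, k = 10 kcal·mol⁻¹·Å⁻² — the cap is the physically meaningful
number; the spring constant merely has to be stiff on the kBT scale) keeps
the pair associated.

## The propagator

`run_bd()` advances positions with the first-order overdamped
(Ermak–McCammon) rule

$$\Delta r = \frac{\Delta t}{k_B T}\, D\, F + \xi, \qquad
  \langle \xi \xi^T \rangle = 2 D \Delta t,$$

with no inertial term and no mobility-divergence term (both supported
diffusion operators are divergence-free). $D$ is either the free-draining
Stokes–Einstein diagonal $k_B T/(6\pi\eta a_i)$ or the
Rotne–Prager–Yamakawa tensor with the standard overlapping-sphere
correction (equal-radius form, evaluated at the mean radius for unequal
pairs). Correlated noise uses a Cholesky factor of $D$, recomputed only
when $D$ is refreshed — every `hi_update_interval` steps (default 400).
Defaults: water viscosity 0.89 cP at 298 K (configurable; the solvent
enters only through $\eta$ and $T$), $k_B$ = 0.0019872041 kcal/mol/K, and
Å/ps/kcal·mol⁻¹/e units throughout.

Three performance features matter for long chains:

* **Reduced-frequency interaction evaluation**: non-bonded forces (tables +
  electrostatics) are recomputed every `force_update_interval` steps while
  bonded and restraint forces are recomputed every step. Stale non-bonded
  forces introduce an error that grows with the distance a bead diffuses
  between updates (≈ 0.7 Å over 10 steps of 0.2 ps for a 4 Å bead), so
  intervals ≳ 10 at 0.2 ps trade visible accuracy for speed; equilibrium
  *trend* comparisons are robust to this, quantitative single-run averages
  should use small intervals.
* **Bond constraints**: SHAKE-style iterative projection (symmetric move of
  the two beads along the current bond direction, over-relaxation factor
  1.4, sweeps until every bond is within `shake_tol` = 10⁻⁴ relative of its
  target, hard failure after 500 sweeps naming the worst bond). With
  constraints on, bond tables are dropped from the energy — the constraint
  replaces the potential — and the recommended step rises from 0.05 ps to
  0.2 ps. The projection differs from classic SHAKE only in using the
  current rather than the pre-step bond directions; for bead-spring chains
  the two fixed points coincide (all bonds at target length).
* **Snapshots**: the initial state plus every `snapshot_stride`-th step.

One documented artifact of constrained stepping: at 0.2 ps the projection
interacts with the finite step to bias chain statistics slightly — a
bonds-only 10-mer samples ⟨Rg²⟩ about 2% above the freely jointed value
$b^2(N^2-1)/(6N)$, and the bias vanishes at 0.05 ps. The ideal-chain
acceptance check therefore runs constrained at 0.05 ps; production runs at
0.2 ps inherit a same-order discretization error, which is the usual cost
of the larger constrained step.

Reproducibility: the engine draws all noise from R's RNG, so
`bd_params(seed = ...)` makes trajectories bit-identical; the seed and
scaling factor are echoed into `traj$provenance`.

## Observables

* `radius_of_gyration()`: RMS distance to the unweighted centroid.
* `kirkwood_rh()`: $1/R_h = \langle 1/r_{ij}\rangle_{i\neq j}$ over all
  distinct Cα pairs; `calibrate_rh()` maps it to the bead-shell
  (HYDROPRO-convention) scale as $1.186\,R_h + 1.03$ Å.
* `rij_profile()`: mean Cα–Cα distance versus sequence separation
  $|j - i|$, averaged over all snapshots ($N - k$ pairs per snapshot).
* `entanglement_index()`: mean Cα–Cα distance over **all** inter-chain
  pairs. The defining phrase "average Cα distances to the other chain"
  admits a per-residue-minimum reading too; the all-pairs mean is chosen
  because published magnitudes (~25–27 Å for restrained 50-mer pairs)
  match the all-pairs statistic and not nearest-contact means. The choice
  is isolated in this one function.
* `autocorrelation()`: $C(\tau)$ with full-series mean and population
  variance and divisor $n-\tau$ covariance, so $C(0) = 1$ exactly and a
  strictly alternating series gives $C(1) = -1$; used on the slow
  terminus/middle distances (`distance_series()`) as the convergence check
  for run length. A constant series returns `NA` with a warning rather
  than failing.
* `trajectory_mean()` (burn-in default 0 — whole-run averages are the
  convention) and `replica_summary()` (mean ± 1.96 SE over independent
  runs; per-run naive SEs understate errors because snapshots are
  correlated).

## Scaling-factor scan

`run_scaling_scan()` reruns a system at each scaling factor (default
0.5–1.0 in steps of 0.1), averages calibrated Rh per run and across
replicas, and `ideal_scaling_factor()` linearly interpolates the factor at
which the mean-Rh curve crosses a reference value — never extrapolating; an
out-of-range reference yields `NA` with a warning. `average_ideal_factor()`
averages per-system ideal factors after excluding named outliers (strong
polyelectrolytes are the known outlier class). The package ships
`scaling_factor = 0.786` as the default: that is the published averaged
ideal factor for disordered proteins under this calibration, adopted as a
constant because recomputing it requires the genuine tabulated force field,
experimental reference radii and multi-microsecond sampling.

## The synthetic force field, and what tests do and do not show

External tabulated force-field data cannot be assumed present, so
`synthetic_forcefield()` generates spline tables from closed forms —
harmonic bonds ($k/2\,(r-r_0)^2$), harmonic angles, cosine dihedrals, a
purely repulsive WCA sphere (cutoff $2^{1/6}\sigma$), and a shifted
Gaussian well — and attaches the exact analytic energy/derivative functions
as oracles. Tables are sampled on 41–81 point grids; natural-spline
interpolation then reproduces the analytic energies to better than
10⁻³ kcal/mol away from the steep WCA core. Spline boundary behaviour is
part of the contract: exact at knots, zero energy *and* force at/beyond the
non-bonded cutoff knot, linear slope continuation below the first knot
(a finite repulsive wall with continuous force, never NaN), angle/dihedral
arguments normalized into [0°, 360°).

The default study conditions used by the test battery mirror the published
protocol at desk scale: T = 298 K, ε = 78.4, λ_D ∈ {7.85, 2.72} Å,
s = 0.786, bond 3.8 Å with constraints at 0.2 ps, crosswise two-chain
starts 15 Å apart with a 20 Å middle-Cα restraint, WCA excluded volume
(ε = 0.3 kcal/mol, σ = 4 Å — a generic residue-size repulsion) plus
screened Coulomb. Trend checks (entanglement indices rising at excess salt
for an oppositely charged 50-mer pair; diblock EK Rg below alternating EK
Rg at reference salt) use ≥ 5 replicas of 10⁶ constrained steps (0.2 µs
per replica) with non-bonded updates every 10 steps and 30% burn-in.
These settings demonstrate the *direction* of salt and charge-patterning
effects under a generic excluded-volume-plus-electrostatics model; they do
not reproduce quantitative ensemble averages of the genuine tabulated
force field, which require the external tables and ~25 µs sampling.
Equally, passing the ideal-chain, Boltzmann-sampling and free-diffusion
checks validates the propagator and constraint machinery, not the realism
of any particular force field for real IDPs — COFFDROP-class potentials
are themselves known to struggle with highly charged sequences, which is
precisely what the scaling factor compensates for.

## Numerical and degenerate-input conventions

* Kirkwood Rh on coincident beads, r = 0 electrostatics, empty sequences,
  κ of charge-free sequences, sequences shorter than a blob: structured
  errors or `NA` signals, never silent propagation.
* The RPY Cholesky retries once with a 10⁻¹⁰ jitter (roundoff-scale
  indefiniteness only) before raising a numerical error.
* Non-finite positions abort a run with the step number.
* Middle bead of an even-length chain: 0-based index N/2, deterministic
  for both parities.
* PQR parsing accepts the whitespace (APBS) dialect with or without a
  chain-id column; malformed records report their line number; a residue
  without a Cα atom is an error naming the residue.

## Known limitations

* Single- and two-chain systems only; no periodic boundaries, no solvent
  beyond implicit viscosity/dielectric, no reaction criteria or rate
  constants.
* The all-pairs electrostatics are exact but O(N²); chains beyond a few
  hundred beads need the update-interval features.
* Rigid-constraint sampling at 0.2 ps carries the few-percent
  discretization bias quantified above.
* κ for sequences with neutral residues uses the sorted-diblock
  normalization (see above).
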