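---
title: "Methods: cleft geometry, contact occupancy, electrostatic forces and MM/PBSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cleft geometry, contact occupancy, electrostatic forces and MM/PBSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleftforce)
```

## Scope and model

`cleftforce` analyses trajectories of two-domain protein systems — the
motivating case is a Janus-kinase catalytic domain (JH1), whose N-lobe/C-lobe
cleft houses the nucleotide-binding pocket and whose interface with the
pseudokinase domain (JH2) holds the autoinhibited state. A trajectory is an
ordered set of structure frames sharing one atom table; every statistic below
is a per-frame quantity aggregated over frames.

Four analyses are provided:

1. **Cleft topology.** The cleft size is the distance between the mass
   centers of two residue-range selections (e.g. N-lobe T815–P906 vs C-lobe
   S907–S1100). `window_stats()` reports mean and sample SD over a time
   window; `kabsch_rmsd()` is the stability check; `separate()` rigidly
   displaces one domain along the mass-center axis.
2. **Contacts.** Salt bridges (basic N to acidic O within 4 Å, one record
   per residue pair at the minimum atom distance) and hydrogen bonds
   (donor–acceptor ≤ 3.5 Å and D–H deviating ≤ 20° from the D→A direction),
   aggregated into per-pair occupancy: the percentage of all frames in which
   the criterion holds.
3. **Electrostatic forces.** The force on a target selection from a source
   selection is a pairwise screened Coulomb (Yukawa) sum in the solvent
   dielectric,
   $F(r) = k_e\,q_i q_j\,e^{-\kappa r}(1+\kappa r)/(\varepsilon_s r^2)$,
   reported in kT/Å. It is decomposed along the mass-center connection:
   $F_\mathrm{binding} = |F_T|\cos\alpha$ (positive = attraction) and
   $F_\mathrm{sliding} = |F_T|\sin\alpha$. A finite-difference linearized
   Poisson–Boltzmann (FD-PB) solver supplies potentials and polar solvation
   in the two-dielectric cavity model.
4. **MM/PBSA.** Per entity, $E = E_c + E_v + E_p + E_{np}$ (Coulomb,
   Lennard-Jones, PB polar solvation, SASA-linear nonpolar solvation), and
   the single-trajectory binding energy
   $\Delta E_\mathrm{bind} = E_\mathrm{complex} - E_A - E_B$ with parts cut
   unchanged from each complex frame.

## Parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| salt-bridge cutoff | 4.0 | Å | N⋯O distance, inclusive |
| H-bond distance cutoff | 3.5 | Å | donor–acceptor, inclusive |
| H-bond angle cutoff | 20 | ° | D–H deviation from D→A |
| solvent / solute dielectric | 80 / 2 | — | water / protein interior |
| ionic strength | 150 | mM | 1:1 salt; κ⁻¹ ≈ 8.1 Å |
| temperature | 310 | K | kT = 0.6160 kcal/mol |
| probe radius | 1.4 | Å | SASA and exposure tests |
| grid resolution | 2 | points/Å | FD-PB spacing 0.5 Å |
| filling ratio | 0.70 | — | solute span / box edge |
| nonpolar slope α / intercept β | 0.0054 / 0.92 | kcal/(mol Å²), kcal/mol | $E_{np}=\alpha\,\mathrm{SASA}+\beta$ |
| analysis window | (70, 100] | ns | 300 frames at 0.1 ns spacing |
| occupancy thresholds | 10 / 30 | % | strict `>` filtering |

The angle convention matters: the 20° cutoff bounds the deviation of the
covalent D–H bond from the D→A direction. An interior D–H⋯A angle
convention classifies differently and is deliberately not offered to avoid
silent mismatches.

## Synthetic generators and what they show

The generators build the smallest structures for which each downstream
statistic has an exact oracle:

- `make_two_domain_trajectory()`: two *rigid* tetrahedral pseudo-domains
  whose mass-center distance is drawn per frame from a truncated
  Normal(mean, sd). Rigidity makes the cleft series equal the generator's
  draws exactly, so window statistics are checked against direct
  recomputation rather than against another estimator. Negative draws are
  rejected and resampled; at sd ≪ mean (the regime used, 0.5 Å on 10 Å) the
  truncation bias is far below the test tolerances.
- `make_hbond_triple()` / `make_salt_bridge_pair()`: exact distances and
  angles straddling the cutoffs.
- `make_point_charge_pair()` / `make_born_sphere()`: analytic Coulomb,
  Yukawa and Born solutions.
- `make_occupancy_trajectory()`: a per-frame boolean contact pattern encoded
  geometrically (2.9 Å when bonded, 6.0 Å when not).

These fixtures contain no conformational coupling, no force-field realism
and no solvent structure. Passing tests therefore demonstrate that the
*analyses* are correct — counting, geometry, electrostatics, energy
composition — not that any biological conclusion about a real kinase
follows; real trajectories remain the user's input.

## Numerical choices

- **Windows are half-open** `(t_start, t_end]`: frames at 0.1 ns spacing
  over 100 ns put exactly 300 frames in a 70–100 ns window. SD uses the
  sample (n−1) denominator, treating frames as a sample of the run.
- **Cutoffs are inclusive** (≤): a stated 4 Å cutoff admits a pair at
  exactly 4.0 Å. Occupancy thresholds are exclusive (>): a ">10%" filter
  drops a pair at exactly 10%.
- **FD-PB.** 7-point stencil for ∇·(ε∇φ) − ε_s κ²φ = −4π k_e ρ; dielectric
  sampled at edge midpoints (ε_in inside any atom sphere); screening active
  only at solvent nodes; charges spread trilinearly; Dirichlet boundary
  from the analytic Debye–Hückel superposition; red–black SOR with
  ω = 2/(1+sin(π/n)) iterated to a relative update below 1e−6. Polar
  solvation is ½Σqφ differenced between the two-dielectric solve and a
  homogeneous solute-dielectric reference on the *identical* grid and
  charge discretization, so the grid self-energy cancels. On the Born ion
  (q = 1 e, a = 2 Å) the solver reproduces the closed form within 10% at
  2 grid/Å and within 5% at 4 grid/Å, with the error shrinking under
  refinement (the acceptance script prints the measured error). The box is sized so the solute spans
  the filling ratio of the edge; an explicit `box_length` override exists
  because Å-scale fixtures would otherwise get boxes too small to probe
  the far field.
- **Forces** use the solvent dielectric and Debye screening throughout
  (effective-medium screening); the FD-PB solver cross-validates the
  homogeneous limits. The full two-dielectric force density is not
  extracted from the grid — the analytic path is the production route
  because it is oracle-exact and fast.
- **Kabsch RMSD** uses SVD with the determinant correction to exclude
  reflections; the test oracle is an independent quaternion
  eigen-decomposition.
- **SASA** uses a deterministic golden-spiral point set (reproducible at
  fixed `n_points`), 1% accurate on a sphere at 1000 points.
- **Degenerate inputs** error early and specifically: empty selections,
  coincident mass centers (undefined separation axis), single-frame CIs,
  r = 0 atom pairs, unparameterised atoms (all listed by label), models
  with inconsistent atom counts (named by model number).

## Design decisions on genuinely open points

- **Separation axis.** The displacement protocol (10/15/20 Å) needs an
  axis; the mass-center connection line is used — the same axis the
  binding/sliding decomposition projects onto, making the two analyses
  commensurable. Displacements compose additively along it.
- **RMSD atom set.** Whether stability checks should use Cα only or all
  atoms is left to the caller via the `sel` argument (default: all atoms);
  on Cα-free synthetic structures a backbone-only default would be
  meaningless.
- **Phosphate protonation.** Whether a phosphotyrosine phosphate carries
  −1 e or −2 e changes every electrostatic result, so
  `default_parameter_table()` has no PTR entries unless `phosphate_charge`
  is passed explicitly — it is a required chemical decision, not a default.
- **Nonpolar intercept in differences.** $E_{np}$ is evaluated once per
  entity (complex, A, B), so ΔE_np = α·ΔSASA − β. Some MM/PBSA conventions
  drop β in differences; composing the entity energies literally keeps
  every reported breakdown additive to machine precision, and the −β
  offset is documented and tested (−0.92 kcal/mol for far-apart neutral
  parts).
- **Per-residue occupancy.** `residue_occupancy()` sums a residue's
  per-pair occupancies (possibly exceeding 100%); this is an aggregate
  interpretation of "contributing over 100%-occupancy bonds", flagged in
  its documentation because no frame-wise definition reproduces it.

## Problem sizes

The test suite and the acceptance script run on: 1000-frame / 8-atom
two-domain trajectories for window statistics; 1000-frame / 3-atom
trajectories for occupancy; 26 Å boxes at 2 grid/Å (~140k nodes) for the
homogeneous PB checks and small two-dielectric boxes at 2–4 grid/Å for the
Born oracle; 300-frame charged-pair trajectories for CI coverage; and 2–4
atom complexes for MM/PBSA. These sizes make every oracle exact or
statistically sharp while keeping the full suite in the low minutes;
protein-scale systems use the same code paths with larger grids and
selections.

## Known limitations

- Linearized PB only; no nonlinear term, Stern layer, or multigrid.
- Effective-medium screening in the pairwise force path (see above).
- No mmCIF, binary trajectory formats (DCD/XTC), altloc or insertion-code
  handling; trajectories travel as multi-model PDB.
- No entropy term in MM/PBSA, no per-residue energy decomposition.
- Contact chemistry is table-driven (Lys/Arg/His nitrogens, Asp/Glu and
  phosphate oxygens by default) and config-exposed, not inferred from
  connectivity; π-stacking, cation-π and water-mediated bridges are out of
  scope.

## A worked example

```{r example}
tr <- make_two_domain_trajectory(1000, 0.1, mean_distance = 10, sd = 0.5,
                                 seed = 7)
lobeA <- selection("lobeA", chain = "A")
lobeB <- selection("lobeB", chain = "B")
series <- cleft_series(tr, lobeA, lobeB)
window_stats(series, 70, 100)

occ <- occupancy(make_occupancy_trajectory(runif(1000) < 0.166), "hbond")
occ[, c("pair", "occupancy", "n_present", "n_frames")]

pc <- make_point_charge_pair(1, -1, 10)
f <- pairwise_force(pc, lobeA, lobeB, ionic_medium())
decompose_force(f, mass_center(pc, lobeA), mass_center(pc, lobeB))
```
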