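---
title: "Modeling KCNQ1-KCNE channel complexes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling KCNQ1-KCNE channel complexes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kda)
```

## The scientific problem

KCNQ1 is a tetrameric voltage-gated potassium channel whose gating is
reprogrammed by single-transmembrane KCNE accessory (beta) subunits:
KCNE1 slows activation and shifts it to depolarized potentials
(producing the cardiac I~Ks~ current), while KCNE3 locks the channel
open. The KCNE transmembrane helix binds in a cleft between the
voltage-sensing domain (VSD) of one subunit and the pore domain (PD) of
another, and a three-residue "activation motif" in the middle of the
helix (FTL in KCNE1, TVG in KCNE3) largely determines which phenotype
results.

No experimental structure of the KCNQ1-KCNE1 complex exists. The
package implements the computational workflow used to build and
validate such complexes from sparse experimental contact data:

1. **Restraint-guided rigid-body docking.** Disulfide-crosslink,
   Cd(II)-cysteine-bridge and mutagenesis contacts are encoded as
   Calpha-Calpha upper-bound distance restraints (12 A for disulfide
   and mutagenesis contacts -- a 7 A extended crosslink plus 5 A of
   flexibility padding -- and 15 A for metal bridges), compiled
   separately for the closed and open channel states. A harmonic
   penalty (zero below the bound, quadratic beyond) scores candidate
   poses, and an iterative dock-filter protocol converges on
   restraint-consistent, low-energy placements.
2. **Interface analytics.** Per-residue contact numbers (4 A
   heavy-atom criterion), solvent-accessibility changes on complex
   formation (a residue is interfacial when binding buries more than
   20% of its free-state SASA), hydrogen-bond detection, and a
   chi-squared association between interface membership and
   mutational impact, with a helical-rotation null model.
3. **Trajectory analytics.** Contact persistence, residue displacement
   correlations, a dynamical residue-interaction network with
   Girvan-Newman communities and weighted shortest ("allosteric")
   paths, and a pore-radius profile along the permeation axis.
4. **Electrophysiology.** Boltzmann fits of normalized tail-current
   activation curves, exponential gating kinetics, conversion of the
   fit into an activation energy, and double-mutant-cycle coupling
   energies.

Everything is exercised against synthetic inputs with exact ground
truth, so each stage is testable without any external structure or
download.

## The docking protocol

The docking engine is deliberately minimal: the receptor is fixed, the
ligand moves as a rigid body, and a pose is scored by

* `clash_score` -- a soft-sphere repulsion summing
  `(0.8 (r_i + r_j) - d)^2` over heavy-atom pairs closer than the
  soft-core limit `0.8 (r_i + r_j)` (Bondi-style vdW radii);
* `contact_energy` -- `-0.1` per heavy-atom pair in the shell between
  the soft-core limit and 5 A;
* `restraint_score` -- the harmonic restraint penalty with unit spring
  constant (there is no single established convention for the prefactor, so it
  is exposed as a parameter).

The binding proxy `dG = clash_score + contact_energy` replaces an
all-atom energy function on purpose: what this module reproduces is the
protocol's *control flow*, which it follows quantitatively -- score gates (interface score < 0, binding proxy < 0,
restraint score below a cutoff ramped linearly from 350 to 100 across
the scheduled iterations), retention of the best-scoring models as
seeds for the next round, perturbation magnitudes ramped from
3 A / 8 degrees to 1 A / 3 degrees, and convergence when the mean proxy
over the ten lowest-energy models changes by less than 5% between
iterations. The ramps are meant to reach their endpoints by the last round, so the
implementation declares convergence only after the cutoff ramp has
completed; the 5% criterion is evaluated from that
iteration onward. Default desk-scale budgets are 2000 generated / 100
retained models per round (the production-scale analogue being
40000 / 1000); both are parameters.

Two deviations from a literal transcription were required by the
surrogate energy and are worth recording:

* **Lineage-stratified retention.** With a C4-symmetric receptor every
  binding groove is geometrically equivalent, so the binding proxy
  alone cannot rank lineages early on, and purely global
  best-N retention lets sampling drift extinguish the
  restraint-consistent lineage before the cutoff ramp becomes
  discriminating. Retention therefore guarantees every surviving
  start-pose lineage an even share of the retained slots; which
  lineages survive is still decided solely by the score gates, and the
  final ranking is purely by the binding proxy. A physics-based energy breaks
  groove degeneracy by itself; a protocol driven by one needs no such
  safeguard.
* **Upper-bound slack.** Upper-bound restraints never penalize a pose
  for being too close, so the synthetic restraint generator spreads its
  samples across the ligand helix and round-robins across receptor
  20-residue segments -- exactly the character of the experimental
  restraint lists, which span the KCNE helix end to end and touch
  several KCNQ1 helices from different subunits. Clustered restraint
  sets discriminate poorly between symmetry-related grooves.

Model comparison uses the two standard docking-accuracy metrics.
`interface_rmsd()` superposes the model on the receptor chains and
evaluates the heavy-atom RMSD over the ligand-side interface residues
(those within 10 A of the partner in the reference); restricting to the
ligand side keeps the metric faithful to rigid displacements -- a 2 A
rigid shift of the ligand reads out as exactly 2 A instead of being
diluted by unmoved receptor atoms. `fraction_native_contacts()` counts
reference residue pairs (5 A heavy-atom criterion) recovered by the
model.

## The synthetic study system

`make_toy_complex()` builds the C4 channel analogue: per subunit, two
pore-lining helices (axis distance `pore + 5` A) and two outer helices
interleaved at 22.5 degrees (axis distance 4 A further out), all ideal
poly-Ala helices (1.5 A rise, 100 degrees twist per residue, backbone
N/CA/C/O plus CB). The two rings overlap radially, so the channel wall
is dense and the only pockets are the surface grooves between adjacent
outer helices, repeating every 45 degrees -- the toy analogue of the
VSD-PD cleft. The ligand helix is planted by scanning insertion depth
along the groove direction and then locally relaxing all six rigid-body
degrees of freedom, so the planted pose is a genuine optimum of the toy
energy; this is the generator's contract (the planted pose must
out-score random poses, otherwise "recovery" would be meaningless).
Poses are recovered from a ring of coarse seeded placements encircling
the channel (the analogue of placing the accessory helix "near the
transmembrane region" without revealing the correct groove), jittered
by about the protocol's initial perturbation step.

The trajectory generator realizes two kinds of ground truth. Scheduled
contacts toggle a residue pair between separations of 3.5 and 8 A in an
exact, seeded fraction of frames (scheduled residues carry no thermal
noise, so measured persistence equals the schedule to machine
precision). Correlation blocks use a factor model: members share a
common 3-vector factor with loading `sqrt(rho)` plus independent noise
with loading `sqrt(1 - rho)`, which gives within-block displacement
correlation exactly `rho` and zero across blocks, and is positive
semidefinite by construction. One caveat matters in practice: any
rigid-body component of a concerted block motion is absorbed by the
frame superposition that precedes the correlation estimate, biasing
recovered correlations downward when the moving blocks are a large
fraction of the fitted atoms. `correlation_matrix()` therefore accepts
a separate `fit_selection`, and the recommended usage (followed in the
tests) aligns on a stable core region -- ordinary practice in MD
analysis.

The G(V) generator draws per-cell activation curves from the
three-parameter Boltzmann form
`I/I_max = (1 - I_bottom)/(1 + exp((V1/2 - V)/k)) + I_bottom` plus iid
Gaussian noise. Default study conditions mirror typical CHO-K1
recordings of KCNQ1-KCNE1: voltages -80..60 mV in 10 mV steps, 14 cells
per genotype, noise sigma 0.03 on the normalized current, WT
`V1/2app` = +25 mV and slope 15 mV. Because the normalized tail currents
do not saturate over this range, the fitted half-activation voltage is
an *apparent* V1/2 -- the package keeps that language.

## Interface and network conventions

* "Contact number" counts partner heavy atoms within a 4 A closed ball
  of any heavy atom of the residue. The term "heteroatom" in this
  context is ambiguous between *partner* atoms and *non-carbon* atoms;
  the package defaults to all heavy atoms and exposes
  `atoms = "hetero"` for the stricter chemical reading.
* SASA is Shrake-Rupley quadrature on a deterministic Fibonacci sphere
  (default 960 points, 1.4 A probe) with radii C 1.70 / N 1.55 /
  O 1.52 / S 1.80 A; hydrogens are excluded. This is not bit-compatible
  with NACCESS; all checks use tolerance bands (1% against the analytic
  sphere, 2% per atom against an independent implementation).
* Relative dSASA is clamped at zero (a residue that gains surface on
  binding through a conformational quirk is not "negatively
  interfacial"), and the interface flag is `dSASA > 20%`.
* Hydrogen bonds use 3.5 A donor-acceptor distance and a 120 degree
  D-H...A angle where hydrogens exist; structures without hydrogens
  fall back to the heavy-atom distance criterion. These are common
  trajectory-analysis defaults; no single standard exists.
* Mutational impact thresholds are dataset-specific: |dV1/2| > 20 mV
  for oocyte literature data, > 10 mV for CHO-K1 recordings.
* The association test is Pearson's chi-squared without continuity
  correction; the Yates-corrected variant is always reported alongside.
* The rotation null model spins the ligand about the principal axis of
  its Calpha cloud in 30 degree steps (the step size is a
  parameter), recomputing the dSASA profile and association at each
  angle; angle 0 reproduces the direct analysis identically and the
  scan is 360-degree periodic.
* Network edges require a minimal heavy-atom distance of at most 4.5 A
  in at least 75% of frames. Edge weights are `-log |C_ij|` (clamped at
  |C| = 1e-6), the convention of the standard dynamical-network
  toolchain. Sequence-adjacent same-chain pairs are excluded
  by default (exposed as a flag) to avoid trivial backbone paths; in
  the perfectly rigid limit a zero-variance pair is treated as fully
  correlated (weight 0). Communities come from Girvan-Newman edge
  betweenness with the partition chosen at maximal modularity; paths
  from Dijkstra plus Yen's loopless next-shortest scheme.
* The pore profile maximizes, per 0.5 A slice, the clearance
  `min_i(|p - x_i| - r_i)` over the slice plane with a Nelder-Mead
  local search started on the axis, capped at a 15 A search radius;
  an occluded slice records 0 rather than erroring.

## Electrophysiology conventions

Per-cell nonlinear least-squares Boltzmann fits (starting values from
the data: V at half range, slope from the 20-80% span) are aggregated
as mean +/- SEM across cells, matching how such recordings are
reported; a pooled global fit is deliberately not the default. A fit
with non-positive slope is flagged rather than silently kept, and flat
traces are rejected. Gating kinetics use single-exponential fits per
phase (a double-exponential is out of scope). The activation energy
uses the convention `dG0 = z F V1/2` with the equivalent gating charge
`z = RT/(F k)` taken from the Boltzmann slope, i.e.
`dG0 = RT V1/2 / k`, reported in kcal/mol at 295 K; since more than one convention is
in use, the choice is configurable and labelled in the output. Double-mutant-cycle coupling is
`ddG = dG_double - dG_mut1 - dG_mut2` with the conventional
1.0 kcal/mol interaction cutoff; the worked example of 0.66, -0.36 and
0.90 kcal/mol gives |ddG| = 0.60, below the cutoff, and is reproduced
exactly by `mutant_cycle()`.

## Problem sizes and what the tests do (and do not) show

The test suite and the acceptance script run everything at desk scale:
docking with 800 generated / 200 retained models per round on a
~1400-atom receptor, trajectories of 200-500 frames, 200 simulated
G(V) datasets, brute-force enumeration oracles up to 10-node partitions
and 12-node path sets. These sizes were chosen so the full pipeline
reruns in minutes while every comparison stays against an exact oracle
(closed forms, exhaustive enumeration, an independent SASA
implementation, generator ground truth).

Passing these checks shows that the machinery is correct, not that the
toy system reproduces biology: the generators emulate the *statistical
and geometric structure* the analyses assume (C4 symmetry, scheduled
persistence, block correlations, Boltzmann-shaped noise), not force
fields, membranes, solvent, sidechain packing or experimental artefacts
(rundown, leak, capacitance). Full-scale results that depend on
external engines or deposited datasets -- all-atom docking energies,
MD contact and dSASA profiles of real trajectories, hydrogen-bond
occupancies, binding free energies -- are out of scope by design, and
an offline environment additionally rules out checks against deposited
models or journal source-data files; the property-based suites above
stand in for them.

## Known limitations

* The toy energy has no attraction beyond 5 A, so docking relies on
  restraint-guided placement rather than long-range funnels; with
  upper-bound-only restraints, basins deeper than the planted groove
  would win if the receptor wall were sparse enough to interdigitate
  into -- which is precisely why the generator builds a dense wall.
* Girvan-Newman selects its partition along its own dendrogram; on
  adversarial graphs the global modularity optimum can lie off the
  dendrogram. The enumeration comparisons use structured (community-
  bearing) graphs, where the two coincide.
* mmCIF input is read-only; PDB is the only write format.
* The correlation estimator inherits the superposition ambiguity
  discussed above; `fit_selection` mitigates but cannot remove it.
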