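# kda — restraint-guided docking and interface analysis for KCNQ1–KCNE channel complexes

KCNQ1 is the tetrameric voltage-gated K⁺ channel behind the cardiac
I<sub>Ks</sub> current. Its gating is reprogrammed by single-transmembrane
KCNE accessory subunits — KCNE1 slows activation and shifts it to
depolarized potentials, KCNE3 locks the channel open — and the KCNE
transmembrane helix binds in a cleft between the voltage-sensing domain of
one subunit and the pore domain of another. Because no experimental
structure of the KCNQ1–KCNE1 complex exists, such complexes are modeled by
integrating sparse experimental contacts (disulfide crosslinks,
Cd²⁺–cysteine bridges, mutagenesis couplings) into restraint-guided
docking, then validated against solvent-accessibility, mutational-impact
and electrophysiological data.

`kda` implements that workflow as a tested, reusable R package, for
structural and channel biophysicists who want each stage scriptable and
verifiable:

* **Restraints** — Cα–Cα upper-bound distance restraints (12 Å for
  disulfide/mutagenesis contacts, 15 Å for metal bridges), state-tagged
  (closed/open/both), scored with a harmonic penalty
  `spring · max(0, d − bound)²` and summarized in violation reports
  (satisfied / medium / large by excess over the bound).
* **Docking** — a self-contained rigid-body engine (soft-sphere clash +
  contact count + restraint penalty) driving the iterative
  dock–filter–converge protocol: score gates (interface score < 0, binding
  proxy < 0, restraint score under a cutoff ramped 350 → 100), perturbation
  ramps 3 Å/8° → 1 Å/3°, convergence when the 10-best mean binding proxy
  changes < 5%; plus greedy RMSD clustering and C2 symmetrization of a 4:1
  complex to the physiological 4:2 stoichiometry.
* **Model comparison** — Kabsch superposition, interface RMSD (10 Å
  interface definition) and fraction of native contacts (5 Å).
* **Interface analytics** — per-residue contact numbers (4 Å),
  Shrake–Rupley SASA and ΔSASA interface calls (> 20 % burial), hydrogen
  bonds, χ² association of interface membership with mutational impact
  (|ΔV₁/₂| > 20 mV oocyte / > 10 mV CHO), and a helical-rotation null model
  for the binding orientation.
* **Trajectory analytics** — contact persistence (4.5 Å for ≥ 75 % of
  frames), residue displacement correlations, dynamical networks with
  `-log|C|` edge weights, Girvan–Newman communities, Yen k-shortest
  allosteric paths, and HOLE-style pore-radius profiles.
* **Electrophysiology** — per-cell Boltzmann fits
  `I/I_max = (1 − I_bottom)/(1 + exp((V₁/₂ − V)/k)) + I_bottom` with
  apparent-V₁/₂ semantics, exponential activation/deactivation kinetics,
  activation energies (ΔG⁰ = RT·V₁/₂/k), and double-mutant-cycle coupling
  (|ΔΔG| ≥ 1 kcal/mol ⇒ interacting).
* **Synthetic data** — a C4-symmetric toy channel with a planted ligand
  pose, restraint sets consistent or inconsistent with it, trajectories
  with exactly scheduled contact persistence and block correlations, and
  Boltzmann-shaped G(V) datasets — every generator seeded and carrying its
  ground truth.

## Worked example

Dock the toy accessory helix back into its channel from a ring of coarse
starting placements, using 12 restraints sampled at the (known) planted
pose:

```r
library(kda)

tc <- make_toy_complex()                      # receptor, ligand, planted pose
rs <- make_restraints(tc$receptor, tc$ligand, tc$pose, n = 12, seed = 42)
starts <- ring_start_poses(tc$pose, n = 8, seed = 42)

fit <- run_protocol(tc$receptor, list(tc$ligand), rs, starts,
                    n_generate = 800, n_keep = 200, seed = 42)
fit
#> ProtocolState: 7 iteration(s), converged, 200 model(s), best dG = -105.279
fit$ensemble[[1]]
#> ScoredModel: dG = -105.279 (clash 45.721, contacts -151.000), restraint 0.000
```

The best model satisfies every restraint (restraint score 0) and sits on
top of the planted pose:

```r
cx  <- merge_structures(tc$receptor, apply_pose(tc$ligand, fit$ensemble[[1]]$pose))
ref <- merge_structures(tc$receptor, apply_pose(tc$ligand, tc$pose))
interface_rmsd(cx, ref, c("A", "B", "C", "D"), "E")
#> [1] 0.3808276
fraction_native_contacts(cx, ref, c("A", "B", "C", "D"), "E")
#> [1] 0.9882353
```

An interface RMSD of 0.38 Å with 99 % of native contacts recovered is a
sub-Ångström reconstruction — the restraint gates eliminated the seven
symmetry-equivalent decoy grooves and the binding proxy picked the correct
pose within the remaining one.

Electrophysiology on simulated CHO-scale recordings (14 cells/genotype,
noise σ = 0.03) and a mutant cycle at literature scale:

```r
gv <- make_gv_dataset(data.frame(genotype = c("WT", "Y46A"),
                                 v12 = c(25, -11.3), k = c(15, 15),
                                 bottom = c(0.05, 0.05)), seed = 42)
fit_boltzmann(gv, "WT")
#> BoltzmannFit [WT]: V1/2app = 25.05 +/- 0.26 mV, k = 15.16 mV, bottom = 0.049 (n = 14)
delta_v12(fit_boltzmann(gv, "Y46A"), fit_boltzmann(gv, "WT"))$delta_v12
#> [1] -36.66  # planted shift was -36.3 mV

mutant_cycle(0.66, -0.36, 0.90)
#> Mutant cycle: ddG = 0.60 kcal/mol (|ddG| = 0.60) -> not interacting (cutoff 1.0)
```

A coupling energy of 0.60 kcal/mol is below the conventional 1 kcal/mol
cutoff, so these two positions are not called as directly interacting.

See `vignettes/kcnq1-kcne-modeling.Rmd` for the model conventions, the
design decisions behind the toy system, and known limitations.

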