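---
title: "Clash-tolerant ligand pose sampling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clash-tolerant ligand pose sampling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In cross-docking, a ligand is docked into a receptor structure that was not
determined with that ligand bound — an apo structure, a structure holding a
different ligand, or a predicted model. Pocket side chains then frequently
occupy part of the volume the correct pose needs. Rigid docking scores the
correct pose poorly (its van der Waals repulsion explodes on the clashes), so
the pose never survives into the reported list, no matter how good the
scoring function otherwise is. This package implements two sampling
protocols that attack exactly this failure mode:

* **GLOW** pools poses from two rigid docking runs: one under the normal
  steric potential and one under a *softened* potential whose short-range
  repulsion is capped, so clashing-but-otherwise-good poses survive
  sampling. The soft run's poses are rescored under the normal potential so
  a single scale ranks the merged list.
* **IVES** goes one step further: the top *N* soft-potential poses become
  *seed poses*, each guiding a constrained minimization of the receptor
  (residues with any heavy atom within 8 Å of the seed pose may move; the
  ligand and everything else stays fixed). The ligand is redocked onto each
  of the *N* relaxed conformations with both potentials, and all pose sets
  — including the initial ones — are merged. The loop can iterate, re-seeding
  from the merged set; one iteration is the default because later rounds add
  little.

Two baselines frame the comparison: `run_default()` (one normal-potential
run, capped at 20 poses — the typical docking configuration) and the same
run without the cap. Success for a case means *any* sampled pose lies within
2.0 Å (inclusive) heavy-atom symmetry-corrected RMSD of the reference pose.

## The steric model

The score of a pose is a sum over receptor–ligand heavy-atom pairs within
an 8 Å cutoff, in the surface distance \(d = r - (R_i + R_j)\) with \(R\)
the element vdW radii (fixed internal table: C 1.70, N 1.55, O 1.52, …):

\[
E \;=\; w_\mathrm{att}\sum_\text{pairs} e^{-(d/0.5)^2}
\;+\; w_\mathrm{rep}\sum_\text{pairs} \rho(d) \;+\; E_\mathrm{internal},
\qquad
\rho(d) = \begin{cases} \min(d^2,\; e_\mathrm{cap}) & d<0,\ \text{soft}\\
d^2 & d<0,\ \text{normal}\\ 0 & d \ge 0,\end{cases}
\]

with defaults \(w_\mathrm{att}=-0.8\), \(w_\mathrm{rep}=1.6\),
\(e_\mathrm{cap}=0.25\) (clashes deeper than 0.5 Å cost no extra in soft
mode). \(E_\mathrm{internal}\) penalizes ligand self-overlap over atom pairs
at least four bonds apart and is *never* capped, so softening cannot reward
self-clashing conformers. The function is continuous in \(r\) everywhere,
including at \(d=0\), at the cap crossover and (to numerical precision) at
the cutoff.

Two width choices deserve a note. The attractive well is a Gaussian of
unit depth in \(d\); its width is a free parameter of the design. We use
\(\sigma = 0.5\) Å (the scale of the classic docking `gauss1` term). A
wider well (\(\sigma = 1\) Å) produces a long-range collective pull that
rewards burying the ligand into the densest wall of a pocket rather than
settling at all-around contact — a qualitatively wrong landscape for our
test systems — so the narrow width is load-bearing, not cosmetic. Second,
soft-mode totals are pointwise \(\le\) normal-mode totals for every pose,
because the cap is the only difference; this ordering is asserted in the
test suite.

This is deliberately **not** a reimplementation of any production scoring
function: no electrostatics, hydrogen bonding, hydrophobic or torsional
entropy terms. The protocols only need the one mechanism the problem
statement turns on — clashes make correct poses score terribly, and a
capped repulsion bounds that penalty — and extra terms would be invented
chemistry with no way to validate them here. Hydrogens are excluded
throughout (scoring, RMSD, torsion detection), matching heavy-atom docking
conventions.

## The sampler

`sample_poses()` is a compact iterated-local-search engine in the Vina
family's spirit: `n_chains` independent Metropolis chains (default 8), each
`n_steps` long (default 2000) at temperature 0.3, starting from a uniform
random placement (position in the box, orientation from a random
quaternion, torsions uniform). One move per step: translation ≤ 0.5 Å,
rotation ≤ 15°, or a single-torsion twist ≤ 30°, chosen uniformly; the
ligand centroid is confined to the box. Each chain's best state is polished
by a derivative-free coordinate descent with shrinking steps. Accepted
states are archived (strided to ~250 per chain), pooled across chains,
deduplicated by leader clustering at 1.0 Å symmetry-corrected RMSD, and
truncated to `max_poses`.

Determinism: chain *k* seeds R's RNG with `seed + k − 1`; every sub-run of
a protocol derives its seed from the master seed and a stage label hash. So
a fixed master seed reproduces byte-identical outputs, and IVES's
per-conformation runs are independent of processing order (a property the
tests assert by permuting the order). Rotatable bonds are detected from the
bond graph: single, acyclic (bridge) bonds whose two ends each have at
least two heavy neighbours; the moving set is the smaller component (ties:
the higher-indexed axis atom's side). Note that this, correctly, yields
zero torsions for a three-heavy-atom chain like ethanol without hydrogens —
three atoms have no dihedral.

## Pocket minimization

`minimize_pocket()` relaxes the movable shell with a greedy per-atom
line search (initial step 0.2 Å, halved on stalls, tolerance 1e-4, at most
200 sweeps) on the objective

\[
E_\mathrm{rec\text{-}lig}^{(\mathrm{normal})}
+ \sum_{\text{overlaps}} \max(0,\; 0.6\,(R_a+R_b) - r_{ab})^2
+ k_\mathrm{tether}\sum_{a\,\in\,\text{movable}} \lVert x_a - x_a^0\rVert^2 .
\]

The first term pulls clashing pocket atoms off the seed pose (uncapped
repulsion, so relief is strongly rewarded); the soft-sphere term (contact
distance scaled by 0.6 so packed neighbours are tolerated) prevents the
shell from collapsing onto itself; the tethers (default \(k=1\)) keep the
relaxation local — the tests verify displacement shrinks as \(k\) grows and
that a very stiff tether (\(10^6\)) pins atoms to within \(10^{-3}\) Å.
Frozen residues and the ligand are never touched (exact equality, not
approximate). A production pipeline would substitute a force-field
minimizer here; the contract it must honour is exactly the one the tests
state: frozen coordinates bit-identical, objective non-increasing, clash
repulsion at the seed pose strictly reduced.

The 8 Å shell is measured atom-to-atom (any heavy atom of the residue
within 8 Å of any seed-pose atom): the residue-level alternative
(centroid distance) was rejected because single-atom and large residues
would be treated inconsistently.

## The synthetic test systems

`make_toy_complex()` builds a pseudo-receptor around a known ligand pose:
one of three all-carbon templates (`rigid4`, a star with no torsions;
`flex6`, two three-rings joined by the single rotatable bond; `ring6`, a
benzene-like ring with 12 graph automorphisms) centred at the origin, and
~48 single-atom residues placed on a jittered shell covering every
direction except a 70° entrance cone. Each pocket atom is adjusted
radially to a 0.05–0.3 Å surface gap from its nearest ligand atom. The
construction makes three properties true at once: the reference pose is
clash-free; it is in tight all-around contact, hence the global optimum of
the scoring function (the sampler re-finds it to ≤ 0.5 Å on the holo
pocket); and the pocket has an opening through which decoy placements
exist. A sparser or purely hemispherical shell fails the second property —
the ligand finds better-scoring nestling positions against the shell — so
pocket density and near-contact placement are part of the study conditions,
not tuning.

`make_cross_dock_case()` converts a holo complex to an apo-like one by
displacing the *n* pocket atoms nearest the ligand straight toward their
nearest ligand atom — the cross-docking scenario in which pocket atoms
occupy the ligand's volume. Reference-pose repulsion grows monotonically
with the displacement (asserted over a 0–2.5 Å scan). A case is labelled
*challenging* when that repulsion exceeds the soft-mode cap.
`make_benchmark()` draws a mixed suite: challenging cases displace 6–9
atoms by 1.0–2.0 Å, typical cases 2–3 atoms by 0–0.3 Å.

The frozen regression fixture (`challenge_fixture()`: rigid4 pocket, eight
atoms displaced 2.0 Å) was constructed by the escalation procedure the
design prescribes — increase the clash until the Default baseline fails —
and then frozen. On it, a 20-pose normal-potential run reports only poses
> 2 Å from the reference, while GLOW and IVES recover it; this separation
holds across independent sampler seeds, not just one.

What these toys do *not* emulate: real protein topology (residues are
single atoms), chemistry beyond carbon spheres, backbone motion, rotameric
side-chain states, solvent, or the error modes of predicted structures.
Passing here shows the protocols' *mechanism* works — softening and
seed-guided pocket relaxation recover clash-blocked poses that rigid
normal-potential docking provably loses on the same engine — not that any
particular real-world success percentage would be reproduced.

## Evaluation choices

RMSD is computed in the shared receptor frame without re-superposition (the
docking convention), minimized over the ligand's bond-graph automorphism
group (element- and bond-order-preserving, enumerated by colored VF2 with a
10,000-mapping cap; beyond the cap the identity mapping is used with a
warning). Both the corrected and the naive value are reported, since
symmetry correction only tightens fairness for symmetric ligands. The
2.0 Å success threshold is inclusive. Benchmark runs derive per-case seeds
from the master seed and the case id, record per-case failures without
aborting the suite, and write JSON/TSV reports.

## Problem sizes and scaled-down configurations

The shipped defaults are the protocol's study configuration: 20 seed
conformations, ≤ 300 poses per conformation per run, one iteration, 8 Å
shell, 20-pose Default cap, 8 chains × 2000 steps. The test suite and the
acceptance script exercise the full pipeline at reduced search effort
chosen as reasonable for the toy systems' size (4–8 chains × 400–1000
steps, 3–5 seed conformations, minimizer capped at 40–80 sweeps): the toy
pockets have a few dozen atoms and ligands of 4–6 atoms, for which these
settings already reach the landscape's optima (the oracle-equivalence tests
document that). All monotonicity and rescue properties are stated so that
they hold at any effort level, because they compare runs under shared
derived seeds.

## Known limitations

* The softened potential's exact form (a per-pair cap) is one reasonable
  realization of "allow some clashes"; alternatives (linear switching via
  `d_soft`) are parameterized but not the default.
* The sampler is not tuned for speed or for large flexible ligands; it is
  written to be verifiable against exhaustive search on small systems.
* `run_benchmark()` measures sampling success only — no top-1 ranking
  metrics, by design: pose *sampling*, not scoring, is the quantity under
  study.
* MOL2 input requires the optional ChemmineOB package; SDF V2000 and PDB
  are the native paths.
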