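---
title: "Coarse-grained fragment assembly and memetic differential evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cgfold methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The prediction problem and the representation

`cgfold` addresses ab initio protein structure prediction by conformational
energy minimisation: given only an amino-acid sequence, search for the
three-dimensional backbone arrangement with the lowest energy under a
coarse-grained model. The representation is the classic low-resolution one:
each residue contributes the backbone atoms N, CA, C, O plus a single
side-chain pseudo-atom (CEN) standing in for the side chain's mass, and a
full conformation is encoded by the per-residue backbone dihedral angles
(omega, phi, psi), stored in degrees on `(-180, 180]`. The dihedral vector
is the genome on which every search operator acts; Cartesian coordinates are
derived on demand by forward kinematics (`build_backbone()`), which places
atoms sequentially with the natural-extension reference frame construction
and idealised covalent geometry:

| quantity | value |
|---|---|
| N–CA, CA–C, C–N, C=O bond lengths | 1.458, 1.525, 1.329, 1.231 Å |
| N–CA–C, CA–C–N, C–N–CA, CA–C–O angles | 111.2°, 116.2°, 121.7°, 120.5° |
| CEN direction | tetrahedral CB axis, out-of-plane angle 51.7° |
| CEN radial distance | per-amino-acid table, 0 Å for glycine |

Fixing bonds and angles at ideal values is the standard simplification of
fragment-assembly methods: all conformational freedom lives in the
torsions. Omega defaults to 180° (trans peptide) and is never perturbed by
the continuous search operators; only fragment insertion can change it,
because a fragment carries its source geometry verbatim.

An ideal alpha helix built this way has consecutive CA–CA distances of
3.80 Å and a rise of roughly 1.5–1.6 Å per residue, matching the textbook
values; this is verified in the test suite against an independent plain-R
implementation of the same internal-coordinate construction.

# The surrogate energy model

Published coarse-grained scoring functions for fragment assembly are large
weighted sums of knowledge-based terms. This package does not attempt to
reproduce any particular published weight set; it substitutes a compact,
fully documented surrogate with the same *structure* — a weighted linear
combination of physically interpretable terms, ramped in stages — because
the search algorithms, not the energy parametrisation, are its subject.
The five terms (`energy_terms()`):

* **steric** — quadratic clash penalty `(4.0 − d)²` summed over all atom
  pairs at least two residues apart that approach below 4.0 Å. Always
  non-negative.
* **vdw_attract** — a square-well contact reward: −1 for every CEN–CEN
  pair with distance in [4.5, 6.5] Å.
* **rg** — the radius of gyration (Å) of the CA and CEN atoms;
  penalises extended conformations, rewarding compactness.
* **hbond** — −1 for every backbone O(i)···N(j) pair with |i − j| ≥ 3 and
  distance in [2.6, 3.4] Å, a geometric proxy for backbone hydrogen bonds
  (ideal-geometry helices place O(i)···N(i+4) near 3.0 Å).
* **ss_pair** — the number of residues whose observed backbone state
  disagrees with a per-residue H/E/L target string. The observed state is
  classified from (phi, psi): helix if phi ∈ [−100, −30] and
  psi ∈ [−80, −5]; strand if phi ∈ [−180, −60] and psi ∈ [60, 180];
  loop otherwise.

A stage's score is the dot product of these terms with a non-negative
weight vector (`stage_score()`), lower is better. The default four-stage
schedule ramps terms in the usual coarse-to-fine way (weights in
term order steric, vdw_attract, rg, hbond, ss_pair):

| stage | weights | fragments | base cycles |
|---|---|---|---|
| 1 | (1, 0, 0, 0, 0) | 9-mers | 2000 |
| 2 | (1, 0, 0.5, 1, 0) | 9-mers | 2000 |
| 3 | (1, 0, 1, 0, 2) | 9-mers | 2000 |
| 4 | (1, 1, 1, 1, 1) | 3-mers | 4000 |

Stage 1 resolves clashes only; stage 2 adds compactness and hydrogen
bonding; stage 3 emphasises compactness and secondary structure; stage 4
enables every term (the "all-terms" score under which decoys are reported).
The per-stage base cycle counts and the 9/9/9/3 fragment-length mapping are
package configuration following common fragment-assembly practice, not
measured constants; both are overridable (`default_schedules()`,
`protocol_stage()`, YAML serialisation via `schedule_to_yaml()`).

Two properties of this surrogate are worth knowing. First, the steric
radius of 4.0 Å is deliberately generous, so tightly packed native-like
motifs (e.g. the helix's own O(i)···N(i+4) geometry) carry a small internal
steric cost partially offset by the hbond reward; compact structures are
still favoured overall, which the helix-versus-extended ordering test
checks across random lengths. Second, because all terms are smooth or
wide-welled, the landscape is funnel-like at toy scale: the surrogate
reproduces multimodality and deceptiveness qualitatively, not the rugged
fine structure of all-atom models.

# Fragment libraries

A fragment is a run of k ∈ {3, 9} consecutive residues excised from a
source structure, carrying its (omega, phi, psi) triples
(`fragment()`). For every length-k window of the target,
`build_library()` scores every k-mer of every source by sequence
similarity to the window — identity count by default, with a documented
hook for substitution-matrix scoring — and retains the best
`n_per_position` (default 25), breaking ties by source order then offset so
the build is deterministic. Insertion (`insert_fragment()`) replaces the
window's dihedrals wholesale, omega included, and `random_fragment_move()`
draws the window uniformly and then a fragment uniformly within the
window's retained list.

# Search protocols

## Baseline: four-stage Metropolis Monte Carlo

`abinitio_protocol()` runs independent trajectories from the fully
extended chain (phi = psi = omega = 180°). Each stage performs
`round(base_cycles × increase_cycles)` insertion attempts; every attempt
is scored under the stage's weights and accepted by the Metropolis
criterion (`metropolis_accept()`): moves that do not worsen the energy are
always accepted, a worsening move with probability
`exp(−ΔE / T)`. The default temperature is 2.0 energy units for every
stage (configurable per stage). Each stage returns the best-energy
conformation seen, not the last accepted one ("recover-best", the default,
switchable via `recover_best = FALSE`). Trajectory i re-seeds the RNG with
`seed + i`, making decoys independent and the whole run bit-reproducible.
`increase_cycles` (default 10 for the baseline) is the single budget knob:
energy evaluations and fragment-insertion attempts are synonymous, and an
audit counter (`new_eval_counter()`) records every evaluation.

## HybridDE: memetic differential evolution

`hybridde()` couples a DE/rand/1/bin global search over the (phi, psi)
genome with Metropolis fragment-insertion local refinement:

1. **Initial population** — `population_size` independent runs of the
   steric-only stage 1, each given `round(base₁ × increase_cycles ×
   generations_per_stage)` cycles (the full stage-1 share of the budget,
   see the accounting below), yielding partially folded, mutually distinct
   starting conformations.
2. **Generations** — for each target member, a trial is built by rand/1
   mutation (`wrap(x_r1 + F · d(x_r2, x_r3))` with d the signed shortest
   arc) and binomial crossover with one forced gene; the trial is scored
   and refined by `local_refine()`; greedy selection replaces the target
   if and only if the refined trial's fitness is strictly better (ties
   keep the incumbent); the surviving member is then itself refined with
   the other half of the allocation.
3. **Stages** — three stages using the baseline's stage 2–4 weights and
   fragment lengths; fitness is recomputed when the weights change, and
   the per-generation history records best and mean fitness.

Defaults follow the study settings: F = 0.025 (trials deviate only
slightly from their base conformation, minimising steric conflicts),
CR = 0.99, population 100, 100 generations per stage,
increase_cycles 0.1. The circle arithmetic of the mutation is the
package's documented choice (switchable to plain-real differences via
`de_trial(..., arithmetic = "linear")`).

### Budget accounting

The protocols are compared under equal numbers of energy evaluations. Let
`b_s` be stage s's base cycles, `g` the generations per stage and `ic` the
multiplier. Per target and generation the memetic search spends
`round(b_s × ic)` evaluations — one on the unrefined trial, the rest split
between refining the trial and refreshing the surviving member — so a
member's stage cost is `g × b_s × ic` and its total cost is
`ic × g × Σ b_s` (the stage-1 seeding contributes `b₁ × ic × g`). A
baseline decoy costs `ic_b × Σ b_s`. The two are equal exactly when
`ic × g = ic_b`, which the defaults satisfy: 0.1 × 100 = 10. The only
overhead is re-scoring the population at the three stage starts, below 1%
at the default sizes; the test suite asserts the measured ratio with audit
counters. Because the per-generation allocation is rounded, exact parity
additionally wants `b_s × ic` to be an integer, which all shipped
schedules satisfy.

## CrowdingDE: niching for structural diversity

When the energy model is imperfect, its global minimum need not be the
conformation closest to the native structure — the landscape is
*deceptive* — so a set of optimised yet structurally different solutions
is more valuable than a single deepest one. `crowdingde()` is identical to
`hybridde()` except in selection: the refined trial competes with its
structurally nearest population member (CA-RMSD after optimal
superposition; a dihedral-space metric is available via
`crowding_metric`), replacing it only on strictly better fitness
(`crowding_replace()`). Crowding uses the full population as the
comparison set. The history additionally records the mean pairwise CA-RMSD
of the population — the diversity trace. Fitness sharing and speciation,
niching alternatives considered in this line of work, are deliberately
unimplemented stubs.

# Superposition and decoy analysis

`superpose_rmsd()` implements the closed-form least-squares superposition
via the SVD of the covariance matrix, with the determinant correction that
excludes reflections; tests verify exact zeros under random rigid
transforms, agreement to 1e-4 with a brute-force rotation-grid oracle and
with an established structural-bioinformatics implementation.
`decoy_table()` tabulates all-terms energy against CA-RMSD to a reference;
`distribution_summary()` reports quartiles by linear interpolation between
closest ranks (quantile type 7); `compare_methods()` adds per-method
extremes and the Spearman rank correlation between energy and RMSD. The
correlation is this package's quantitative stand-in for the usual visual
deceptiveness assessment: values near zero or negative flag that the
best-energy decoys are not the most native-like.

# Synthetic test substrate

The generators in `make_toy_problem()` / `make_deceptive_problem()` supply
every test input, so the suite runs without downloads.

* `make_ideal_conformation()` builds natives from ideal secondary-structure
  dihedrals — helix (−57, −47), strand (−120, 120), loops drawn near
  (−150, 30) with ±10° seeded jitter (a region that always classifies as
  loop, keeping the ss term consistent).
* `make_toy_problem()` pairs such a native with fragment libraries built
  from the native plus optionally noise-perturbed copies. With no noise
  sources the library is *closed*: the top fragment of every window is the
  aligned native window (guaranteed because short random sequences are
  drawn without residue repetition, making the aligned identity score a
  strict maximum), and greedy paving reconstructs the native exactly. The
  noise sweep (5°, 15°, 30°) degrades best-fragment quality monotonically.
* `make_deceptive_problem()` builds two folds of one sequence: three
  strand arms joined by two 2-residue turns, with the designated native A
  using spread turns (150, −30) and the decoy fold B compact turns
  (60, −180) that pack the arms into side-chain contact range. B's
  all-terms energy is strictly lower (the margin and the >4 Å CA-RMSD
  between folds are verified at construction and returned), the turn
  regions are spaced more than nine residues apart so no single insertion
  can exchange both, and libraries are seeded from both folds. Greedy
  minimisation from the extended chain is therefore drawn towards B — the
  defining deceptive behaviour.

A design finding worth recording: under this surrogate and the full
3/9-mer insertion move set, we could not construct a two-fold toy in which
the *higher*-energy fold A is a strict local optimum — an extensive search
over turn geometries (grids, direct optimisation, and exhaustive
single-insertion stability probes) always left downhill escape paths from
A, because misaligned fragment insertions and the smooth ss/rg/contact
terms interpolate between the folds. The deceptive benchmark is therefore
a *funnel* toward the wrong fold rather than a bistable landscape.
Consequently CrowdingDE's advantage on it shows up robustly as greater
final population spread (mean pairwise RMSD) relative to HybridDE, while
long-lived niches *at the designated native* are not sustained: members
near A continue to drift downhill during their own refinement, whatever
the selection rule protects. Checks that demand final members within 2 Å
of both folds fail for this reason, and that failure reflects the
landscape's geometry at desk scale, not the selection operator — the
replacement-rule unit tests confirm crowding preserves basin
representatives whenever the basins are genuine.

What the toys do **not** emulate: real fragment libraries (picked from
solved structures with predicted-secondary-structure weighting),
sequence-dependent energetics beyond the CEN radius, side-chain packing,
and chain lengths beyond a few dozen residues. Passing the recovery and
diversity tests therefore demonstrates correctness and the qualitative
algorithmic contrasts, not predictive accuracy on real proteins.

# Numerical choices and degenerate inputs

* Angles wrap to `(-180, 180]`; −180 maps to +180; all trigonometry is
  done in radians internally.
* Ties: greedy and crowding selection keep the incumbent on equal fitness;
  `nearest_member()` breaks distance ties by lowest index; library ranking
  breaks score ties by source order then offset.
* `population_size` must be ≥ 4 for rand/1 mutation; size 1 is accepted as
  a documented degenerate case (the trial equals its target) under which
  crowding and greedy selection coincide — useful as an equivalence test.
* Targets shorter than nine residues cannot host 9-mers; stages requesting
  a missing fragment length fall back to the library provided.
* Scoring the incumbent at a stage entry is free; every proposal costs one
  audited evaluation, so "evaluations = insertion attempts" holds exactly.
* Test problems use 8–20 residue chains with stage bases of 20–300 cycles;
  these sizes were chosen once as the package's desk-scale study
  conditions and give each protocol enough budget to converge on the toys.

# Known limitations

* The surrogate energy is structural, not physical: its absolute values
  are meaningless outside comparisons under the same weights.
* Fragment similarity is plain identity; homology-aware picking is out of
  scope (the scoring hook exists).
* The PDB reader targets single-chain, single-model coarse-grained files;
  mmCIF, altloc beyond 'A' preference, hydrogens and full side chains are
  out of scope.
* Runs are single-process; independent runs parallelise trivially at the
  caller's level by seed.
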