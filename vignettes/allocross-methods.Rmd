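---
title: "Methods: interdomain crosstalk statistics and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interdomain crosstalk statistics and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`allocross` quantifies how ligands bound to the two domains of an
Hsp70-like chaperone modulate the interdomain arrangement and the local
rigidity of the connecting linker. This vignette documents the models and
procedures behind each statistic, the tunable parameters and their
defaults, what the synthetic generator does and does not emulate, and the
numerical and design choices a maintainer should know about.

## The analysis model

The input is an ensemble: one or more trajectories over a shared topology,
each labelled with its ligand state (for DnaK, `NBD ∈ {ADP, ATP}` crossed
with `SBD ∈ {free, NR, Api88}`) and replica index. All analyses operate on
the *equilibrated tail* of each run — a configured window (`tail_ns`,
default 90 ns, following common MD practice for runs of a few hundred ns) —
rather than attempting automatic equilibration detection, which is fragile
on short replicas. Internally lengths are nm and times ps; distances in
user-facing distributions are reported in Å because that is the scale on
which interdomain displacements are conventionally discussed.

### Interdomain arrangement: centre-of-mass clouds

Every retained frame is superposed onto the reference structure by a Kabsch
least-squares fit over the anchor-domain Cα atoms (DnaK preset: residues
1–380), and the mass-weighted centre of mass of the mobile domain (preset:
all atoms of residues 393–603) is recorded. The resulting point cloud is
summarised two ways:

- *distance from start*: `‖x_f − x_ref‖`, histogrammed; its mean measures
  the dynamic flexibility of the arrangement;
- *pair distance distribution*: all unordered point-pair distances; its
  modal bin distinguishes unimodal clouds (peak near 0) from multimodal
  ones (secondary mode at the inter-blob separation).

COM weighting is mass-weighted over all atoms of the mobile-domain residue
interval; the atom scope of the original convention is ambiguous, so
`weighting = "geometric"` is provided as a switch. Replicas of one system
are merged before histogramming, since per-replica clouds of flexible
states can occupy disjoint regions.

### Conformational clustering and ligand-state decomposition

Clustering uses the gromos (Daura) greedy neighbour-counting algorithm on a
pairwise RMSD matrix over a Cα residue subset, with least-squares fitting
on the same subset before each pairwise RMSD (the behaviour of the
reference implementation; the fit can be disabled). DnaK subset presets:
373–393 and 393–433 at 0.35 nm, 393–503 at 0.15 nm (the tighter cutoff
suits a compact β-sandwich), whole protein at 0.35 nm.

Rather than clustering each system separately, the package clusters a
*meta-trajectory* — the concatenated tails of all runs regardless of ligand
state — and then decomposes each cluster's population by source label. This
guarantees that "cluster 1" means the same conformation for every system,
so the decomposition table directly shows which ligand combinations
populate which conformer.

Determinism rules: ties on the neighbour count (centre choice) break toward
the lowest frame index; clusters are renumbered by decreasing size with
formation order breaking size ties. Two centre notions coexist: the
algorithm's *seed* (neighbour-richest frame) and the *medoid* (member
minimising summed RMSD to the cluster). `representative()` exports the
medoid, which is the better single-structure summary; both are kept in the
result because they are genuinely different frames on asymmetric clusters.

### Distance-fluctuation maps

For residues *i*, *j* the map entry is the temporal variance of the Cα pair
distance, `A_ij = ⟨d_ij²⟩ − ⟨d_ij⟩²` (nm²). Low entries mark pairs whose
separation barely fluctuates — internally coordinated, locally rigid
blocks; blocks of low values identify sub-domains that move as one.
`df_difference()` exposes ligand-induced rigidification as negative
entries; `coordination_score()` averages the inter-block rectangle of two
residue ranges (e.g. the two lobes of the anchor domain). The exponent is
switchable to the standard deviation (`exponent = "sd"`) for workflows that
prefer nm-scaled maps; variance is the default as the direct second moment.

### Interactions, interfaces, strand content, dihedrals

- *Contacts*: minimum heavy-atom distance ≤ 0.45 nm — a standard
  residue-contact convention, configurable, since in-house contact scripts
  in this literature rarely state their cutoff.
- *Hydrogen bonds*: donor–acceptor (N···O) distance ≤ 0.35 nm and
  H–D–A angle ≤ 30°, the defaults of the common MD analysis tool. When the
  topology carries no hydrogens the angle criterion is dropped and the
  result flagged (`hydrogen_free`); this keeps the detector usable on
  Cα/backbone-only models.
- *Persistence*: an interaction is reported when present in ≥ 30% of
  analysed frames (configurable); occupancies are reported exactly, per
  replica and pooled, because pooling can mask replica-specific contacts.
- *Interface maps*: per-pair minimum distances averaged over time; a
  residue is an interface member when its average distance to some partner
  is below 6 Å. Average semantics (not any-frame) follow the averaged
  distance matrix convention; a per-frame-fraction mode exists for
  sensitivity checks.
- *Strand content*: a reduced ladder criterion — residues *p*, *q* with
  sequence separation ≥ 5 are bridged when a backbone N(p)–O(q) distance is
  ≤ 0.35 nm, and a residue is strand when it sits on two consecutive rungs
  (parallel or antiparallel register). The separation floor excludes
  helical i,i+4 hydrogen bonds. This is deliberately not full DSSP: only
  strand fractions are needed, and the criterion is documented and
  swappable.
- *Dihedrals*: IUPAC-signed angles from the standard atan2 formulation;
  summaries use circular statistics (mean resultant vector), so e.g. the
  mean of {+170°, −170°} is 180°, never 0°. Hinge ψ/φ-like angles at the
  linker entry and exit are the intended use. The package reports raw
  circular means and does not attach cis/trans labels to them.

## The synthetic generator

`make_toy_structure()` builds a chain of four consecutive segments — two
lobes, a linker, an appended domain — with every consecutive Cα pair
exactly 0.38 nm apart (ideal chain spacing). Domains are compact globules
laid out by a deterministic boustrophedon grid walk; the linker is
extended. Optional backbone N, C, O atoms support the hydrogen-bond and
strand machinery.

`simulate_hinge_trajectory()` draws a placement state per frame (i.i.d. by
default; a two-state Markov chain with a configurable switch probability is
available to probe time-correlation robustness — the analyses are
time-average statistics, so ordering should not matter, and tests confirm
it), applies the state's rigid placement to the appended domain, and adds
isotropic Gaussian noise per atom: `sigma_domain` (default 0.02 nm) inside
domains, `sigma_linker` (default 0.05 nm) on the linker. Small domain noise
against larger linker noise emulates the differential internal rigidity the
fluctuation maps are designed to detect. `plant_interaction()` and
`plant_strand_segment()` overwrite the geometry of specific residues in a
seeded random subset of ⌈f·n⌉ frames so that occupancy and strand content
have exact planted values; non-planted frames violate the criteria by wide
margins (≥ 0.1 nm beyond the cutoff for interactions), and the planted
strand block is displaced far from the rest of the chain so no accidental
contact can blur the ground truth.

What the generator does **not** emulate: physical force fields, solvent,
realistic side chains, sterics between domains, or thermodynamically
consistent state populations. Passing tests therefore demonstrate that the
*estimators* are correct — that clustering recovers mixture weights, that
fluctuation maps converge to planted variances, that occupancies are
counted exactly — not that any biological conclusion about a real chaperone
follows. On real MD data the statistics inherit all the usual sampling
caveats (replica convergence, equilibration choice).

## Numerical choices

- *Histograms*: bins of width 1 Å centred on integer multiples of the
  width, so a point mass at an integer distance reports that integer as its
  peak; modal-bin ties resolve toward the smaller distance. Pair-distance
  evaluation subsamples (seeded) above 5·10⁴ points, as exhaustive pairs
  are O(N²).
- *Kabsch fits* enforce a proper rotation (determinant +1) and reject
  degenerate (collinear/coincident) point sets, where the rotation is
  undetermined.
- *Fluctuation maps* accumulate `d_ij` relative to the first frame's
  distances. The variance is shift-invariant, and this removes the
  catastrophic cancellation that otherwise leaves O(1e-12 nm²) artefacts on
  rigid-body ensembles whose distances are orders of magnitude larger than
  their fluctuations. Accumulation is streaming: memory is O(selection²),
  independent of frame count.
- *Degenerate inputs*: collinear dihedral quadruples yield per-frame `NA`
  with a warning; empty selections are flagged; tail windows longer than a
  run, reversed residue ranges, atom-count mismatches and truncated
  trajectory files are hard errors naming the offender.
- *Tail windows*: a frame is in the tail when its time exceeds
  `t_max − tail`; the run duration is `t_max − t_min + dt`, so a tail equal
  to the full duration reproduces the run exactly.
- *Determinism*: every stochastic step (state draws, noise, planted-frame
  subsets, subsampling) is a pure function of an explicit integer seed, and
  seeded helpers restore the caller's RNG state. Identical configuration
  and seed give byte-identical serialized reports.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle: a
brute-force reimplementation of the gromos algorithm (exact agreement on
100 seeded random matrices), a rotation-grid-plus-refinement search for
minimum RMSD (≤ 1e-3 nm agreement), a second dihedral formulation
(≤ 1e-9°), exhaustive pair enumeration for distribution peaks, binomial
error bounds for mixture recovery, and the generators' exact ground truth
for occupancies and strand fractions. Property tests assert rigid-motion
invariance (fluctuation maps to 1e-12 nm², fitted clouds to 1e-6 nm),
partition and monotonicity properties of clustering, and label-shuffle
nulls for the decomposition.

Simulation sizes in the tests and acceptance script — ensembles of
100–1000 frames on toy chains of 40–214 residues, two systems with two
replicas each in the end-to-end study — were chosen as the smallest sizes
at which the statistical checks have clean 3σ margins; all generator
parameters are stated at their call sites.

## Known limitations

- Trajectory formats are DCD and (multi-model) PDB; GROMACS XTC is not
  read. Periodic-boundary re-imaging is out of scope: frames must be
  PBC-whole, and analyses apply no minimum-image correction.
- The strand criterion is a minimal ladder, not DSSP; absolute strand
  fractions can differ from DSSP's on real proteins even though planted and
  ideal geometries are classified exactly.
- Hydrogen-bond detection considers backbone-style N donors and O
  acceptors; side-chain-specific chemistry (salt bridges, π interactions)
  is not modelled.
- The pairwise RMSD matrix is O(n²) in frames; meta-trajectories beyond a
  few thousand frames should be strided before clustering.
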