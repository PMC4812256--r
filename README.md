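# allocross

Trajectory analysis of interdomain allosteric crosstalk in two-domain
proteins.

Hsp70-family chaperones such as bacterial DnaK consist of a nucleotide
binding domain (NBD) and a substrate binding domain (SBD) joined by a
flexible linker. The ligand occupying each domain — ADP or ATP at the NBD,
a free, substrate-loaded, or inhibitor-bound SBD — reshapes how the two
domains arrange relative to each other and how rigid the linker and its
flanking loops are. `allocross` implements the molecular-dynamics analysis
toolbox used to dissect that bidirectional communication, for anyone who has
ensembles of two-domain conformations (MD replicas, multi-model PDB bundles)
and wants quantitative, per-ligand-state statistics:

- **gromos conformational clustering** (Daura neighbour counting) of residue
  subsets on a *meta-trajectory* — the concatenated tails of all runs,
  clustered jointly — with decomposition of cluster populations by source
  ligand state, so common conformers can be traced back to the ligand
  combinations that populate them;
- **distance-fluctuation (coordination) maps**
  `A_ij = ⟨d_ij²⟩ − ⟨d_ij⟩²`, where `d_ij` is the Cα–Cα distance of residues
  *i*, *j* and `⟨·⟩` is the time average: low values mark internally rigid,
  coordinated blocks; map differences expose ligand-induced rigidification;
- **centre-of-mass clouds**: each frame is Kabsch-superposed on the anchor
  domain, the mobile domain's centre of mass recorded, and the cloud
  summarised by its distance-from-start and pair-distance distributions —
  the interdomain-arrangement statistics;
- **persistent contacts and hydrogen bonds** (minimum heavy-atom distance
  ≤ 0.45 nm; donor–acceptor ≤ 0.35 nm with a 30° H–D–A angle when hydrogens
  exist), filtered at an occupancy threshold (conventionally 30% of the
  analysed frames), plus **interface maps** from time-averaged minimum
  distances (6 Å);
- **β-strand content** by a minimal backbone hydrogen-bond ladder criterion,
  and **hinge dihedral statistics** with proper circular means.

Because no public trajectories accompany this kind of study, the package
ships a first-class **synthetic generator**: toy two-domain proteins with
ideal chain geometry, programmable mixtures of interdomain placements,
per-domain noise levels, planted hydrogen bonds with exact occupancies and
planted strand fractions. Every generator is a pure function of
(parameters, seed) and emits its ground truth, so each analysis stage can be
validated against known answers.

## Worked example

Simulate a 500-frame two-domain hinge whose appended domain sits at its
reference placement 70% of the time and 20 Å away 30% of the time, then
recover that structure from the analyses alone:

```r
library(allocross)

arch <- toy_architecture(lobe_a = 50, lobe_b = 50, linker = 14, appended = 100)
ref  <- make_toy_structure(arch)
mix  <- state_mixture(list(list(),                          # docked placement
                           list(translation = c(2, 0, 0))), # displaced by 20 A
                      weights = c(0.7, 0.3))
sim  <- simulate_hinge_trajectory(ref, mix, noise_model(0.01, 0.02, seed = 42),
                                  n_frames = 500)

top     <- ref$topology
fit_sel <- select_atoms(top, c(1, 100),   "CA")   # anchor lobes
com_sel <- select_atoms(top, c(115, 214), "all")  # appended domain
cloud   <- com_cloud(sim$trajectory, fit_sel, com_sel, ref)
cloud
#> COM cloud: 500 points, mean distance from start 6.0 A
distance_from_start(cloud)
#> distance distribution: n = 500, mean 6.00 A, peak 0.0 A
pair_distance_distribution(cloud)
#> distance distribution: n = 124750, mean 8.45 A, peak 0.0 A

cl <- gromos_cluster(rmsd_matrix(subset_frames(sim$trajectory, 1:200),
                                 select_atoms(top, c(1, 214), "CA")),
                     cutoff = 0.35)
cl
#> gromos clustering: 2 clusters over 200 frames (cutoff 0.35 nm)
#>   cluster population center
#> 1       1      0.645    174
#> 2       2      0.355     63
```

The numbers tell a consistent story. The mean distance from the starting
position, 6.0 Å, equals the mixture expectation 0.3 × 20 Å; the
pair-distance peak sits at 0 Å because same-state pairs
(0.7² + 0.3² = 0.58) outnumber cross-state pairs (2·0.7·0.3 = 0.42); and the
clustering finds exactly two conformers whose populations, 0.645/0.355,
match the planted state fractions of those 200 frames (0.645/0.355)
frame-for-frame. On real data the same calls, driven by a YAML run manifest
(`read_manifest()`, `analysis_config()`, `run_system()`, `run_meta()`),
produce per-ligand-state reports with decomposition tables, persistent
interaction tables, fluctuation maps and dihedral summaries
(`write_report()`).

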