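# filmlattice

Tools for connecting the crystal contacts of biofilm surface-layer
(hydrophobin-like) proteins — BslA and its paralogues from *Bacillus
subtilis* — to the ordered two-dimensional lattice they form in interfacial
films.

These proteins adsorb to air–water interfaces through a hydrophobic cap and
assemble into a monolayer whose electron micrographs show a rectangular
lattice (unit cell ≈ 4.3 nm × 3.9 nm, P2 plane symmetry). Their crystal
structures contain two distinct two-fold symmetric dimer interfaces. The
package implements the quantitative pipeline that tests whether those two
interfaces generate the observed lattice, for structural biologists who
want each step reusable and testable:

- **Superposition** (`kabsch()`, `iterative_superpose()`,
  `chain_rmsd_matrix()`, `pairwise_identity()`): SVD rigid-body fits with
  proper-rotation guarantees, sequence-matched residue pairing (BLOSUM62),
  and iterative outlier trimming for "core RMSD over N of M residues"
  comparisons.
- **Interface analysis** (`compute_sasa()`, `interface_report()`,
  `find_salt_bridges()`, `find_hbonds()`, `find_stacking()`):
  Shrake–Rupley solvent-accessible surface area with per-residue burial,
  and geometric contact typing (4 Å carboxylate-carbon-to-ammonium-nitrogen
  salt bridges, heavy-atom hydrogen bonds, ring stacking).
- **Lattice construction** (`extract_dimer_transform()`, `build_zigzag()`,
  `build_lattice()`, `detect_clashes()`, `measure_unit_cell()`): each dimer
  is reduced to a two-fold (C2) transform; composing two C2 operations
  about parallel axes through points p1, p2 is a pure translation by
  2(p1 − p2), so alternating the interfaces propagates a monomer into a
  zigzag chain, and a perpendicular 3.9 nm row shift extends it to a 2D
  lattice, checked for clashes and re-measured from its own placements.
- **Image validation** (`project_density()`, `find_reciprocal_peaks()`,
  `average_unit_cell()`, `score_model()`): Gaussian projection of heavy
  atoms (σ = 4 Å), Fourier unit-cell averaging of a periodic image
  (keeping only reciprocal-lattice peaks), and a Pearson score maximized
  over registration, mirror and 180° settings.
- **Trajectory quantities** (`orientation_series()`, `separation_series()`,
  `detect_dissociation()`, `contact_occupancy()`, `delta_g_bind()`):
  orientation to the interface normal, minimum-image separations,
  change-point detection, 4 Å contact occupancy, and standard binding free
  energy ΔG = kT·ln[∫ e^(−W(r)/kT) dr / δ°] from a PMF with explicit
  standard-state length δ° = 1.186 nm.
- **Synthetic data** (`make_toy_protein()`, `make_c2_dimer()`,
  `make_crystal_standin()`, `make_chain_family()`, `make_homolog_pair()`,
  `make_lattice_image()`, `make_trajectory()`, `make_pmf()`): deterministic
  generators with exact ground truth for every input the pipeline consumes,
  so the whole analysis is testable offline.

Structures are plain atom tibbles (one row per atom) that flow through
dplyr verbs; results are light S3 objects with `tidy()`/`glance()` and
`autoplot()` methods.

## Worked example

The bundled pipeline runs end to end on synthetic inputs:

```r
library(filmlattice)
report <- run_full_analysis(run_config(seed = 1, pixel_size = 0.1))
report
#> <analysis report>
#>   interface: dimer1 28 A^2 (2/2 buried), dimer2 18 A^2 (1/1)
#>   lattice: repeat 4.30 nm, cell 4.30 x 3.90 nm (90.0 deg), 0 clashes
#>   correlation vs lattice image: r = 0.975
#>   trajectory: occupancy 0.851, dG 9.17 +/- 0.01 kcal/mol
```

Reading the output: the two synthetic dimers bury 28 and 18 Å² per
monomer (their interfaces touch over a few residues); composing their
two-fold transforms propagates the monomer into a zigzag with a 4.30 nm
repeat; with the 3.9 nm perpendicular row shift the re-measured unit cell
is 4.30 × 3.90 nm at 90° and the three-copy patch has no steric clashes;
the model projection correlates with the lattice-averaged synthetic
micrograph (20 × 20 cells at signal-to-noise 1) at r = 0.975; a 10⁴-frame
synthetic trajectory reproduces its 86% salt-bridge occupancy
(85.1% measured), and the square-well PMF of depth 11 kcal/mol gives
ΔG_bind = 9.17 kcal/mol after the standard-state correction
kT·ln(0.295/1.186) ≈ −0.83.

The same functions run on deposited coordinates directly:

```r
bsla <- read_structure("4bhu.pdb")
ywea <- read_structure("5mkd.pdb")
fit  <- iterative_superpose(bsla, "C", ywea, "B")  # cross-paralogue core fit
rep  <- interface_report(bsla, "C", "H")           # dimer interface burial
```

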