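---
title: "From dimer interfaces to a 2D lattice model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dimer interfaces to a 2D lattice model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filmlattice)
```

## The problem this package addresses

Bacterial biofilms of *Bacillus subtilis* carry a hydrophobic surface layer
built from BslA, a small Ig-fold protein with a hydrophobic "cap" that
orients it at air-water and oil-water interfaces, where it assembles into an
ordered two-dimensional film. Electron microscopy of such films shows a
rectangular lattice with a unit cell of about 4.3 nm by 3.9 nm and P2 plane
symmetry. Crystal structures of BslA and of its paralogue YweA each contain,
in their packing, a distinct two-fold symmetric dimer interface (called
dimer1 and dimer2 here) whose cap regions co-orient — exactly the property a
monolayer lattice requires.

`filmlattice` implements the quantitative chain of reasoning that connects
those crystal contacts to the film lattice:

1. **Structural comparison.** Kabsch superposition with iterative outlier
   trimming quantifies how similar the protomers are (chain-to-chain RMSD
   within one crystal; core RMSD and sequence identity across paralogues).
2. **Interface characterization.** Shrake-Rupley solvent accessible surface
   area (SASA) gives per-residue burial on each side of a dimer contact,
   plus a geometric inventory of salt bridges, hydrogen bonds and ring
   stacking.
3. **Lattice construction.** Each dimer is reduced to a rigid two-fold
   (C2) transform. Composing two C2 operations about parallel axes yields a
   pure translation — the crystallographic fact that powers the whole
   construction — so alternating the two interface operations propagates a
   monomer into an infinite zigzag chain with repeat $2\,|p_1 - p_2|$,
   where $p_1$, $p_2$ are the two axis positions. A perpendicular row
   translation taken from the micrograph cell extends the chain into a 2D
   lattice, which is checked for steric clashes and re-measured.
4. **Validation against an image.** Heavy atoms are projected onto the
   interface plane as a sum of unit-mass 2D Gaussians; a periodic lattice
   image is reduced to its average unit cell by keeping only
   reciprocal-lattice Fourier peaks; and the model projection is scored
   against the averaged cell by a Pearson correlation maximized over
   registration (cyclic translations, mirror, and 180° rotation — the
   mirror matters because a film imaged from the far side is the mirror
   image of the model).
5. **Trajectory-derived quantities.** Orientation of a body axis to the
   interface normal, inter-monomer separation with minimum-image
   correction, dissociation detection, contact occupancy under a 4 Å
   cutoff, and a standard binding free energy from a potential of mean
   force (PMF).

## Worked example

Everything below runs on the package's synthetic generators, so the
vignette is self-contained:

```{r pipeline}
report <- run_full_analysis(run_config(seed = 1, pixel_size = 0.1))
report
glance(report)
```

## Model and conventions

### Superposition and residue matching

`kabsch()` is the standard SVD solution with the determinant sign
correction, so the returned rotation is always proper even for
mirror-image inputs. Cross-paralogue comparisons first pair residues by
global sequence alignment with free end gaps (BLOSUM62, gap open 10,
extend 0.5, via Biostrings); at the ~50% identity of the BslA/YweA pair
any standard parameterization recovers the same core pairing.
`iterative_superpose()` then alternates fitting with rejection of pairs
beyond 3.5 Å until a fixed point, reproducing the "core RMSD over N of M
residues" style of structure-comparison servers. The trim cutoff is the
conventional 3.5 Å; because published residue counts depend on the
particular server's (unpublished) trimming rule, counts within a few
pairs of a reported value should be considered equivalent.

### SASA and burial

SASA uses Shrake-Rupley sampling with a deterministic golden-spiral point
set (960 points/atom by default) on spheres of radius $r_{vdW} + 1.4$ Å,
with radii C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 and a 1.70 Å fallback.
Burial of a residue is the SASA it loses between the isolated chain and
the complex; a residue counts as "buried" above 1 Å², a threshold that
suppresses point-sampling noise while keeping genuinely grazing contacts.
Published interface areas from black-box servers carry algorithmic spread
of order 10%, which is the tolerance used throughout. Hydrogens are
excluded everywhere (crystal structures rarely resolve them); waters and
het groups never enter interface calculations.

### Contact geometry

Salt bridges follow the criterion of a 4 Å cutoff between the carboxylate
carbon (Asp CG / Glu CD) and the ammonium nitrogen (Lys NZ). Arginine is
additionally screened via its guanidinium carbon CZ and flagged
`arg_extension`, since the literal criterion names only the ammonium
nitrogen. Hydrogen bonds use heavy-atom geometry: donor-acceptor distance
≤ 3.5 Å with an antecedent-donor-acceptor angle ≥ 90°. Ring stacking
reduces aromatic rings and the Arg guanidinium plane to centroid plus
fitted normal, reporting pairs with centroid separation ≤ 6 Å and their
interplanar angle.

### Two-fold transforms and the lattice

`extract_dimer_transform()` fits protomer 1 onto protomer 2 and
decomposes the transform into screw form; a dimer is accepted as C2 when
the rotation is within 10° of 180° (crystal dimers are approximately,
not exactly, symmetric). `build_zigzag()` alternates the two interface
operations; the composed operation must be a pure translation up to a
15° residual before the repeat is trusted. The row shift is an
experimental input (3.9 nm from the micrograph cell), applied
perpendicular to the repeat by default. An offset along the repeat is
configurable, but the default is zero: the imaging evidence is a
rectangular, 90° cell, and a pure perpendicular shift is the construction
that reproduces it; `measure_unit_cell()` recomputes the cell from
placement centroids as an independent self-check, and a perpendicular
shift is what makes that check return 90°.

### Density projection and image averaging

Heavy atoms are projected along the mean C2 axis direction with
unit-integral Gaussian kernels of σ = 4 Å, truncated at 4σ (mass loss
< 1e-4) on a grid with a 3σ margin, so the grid sum equals the heavy-atom
count to < 1%. The default pixel is 0.2 nm (σ/2, Nyquist-adequate); the
pipeline uses 0.1 nm so that the 4.3 × 3.9 nm cell is an exact integer
number of pixels, which keeps the fold-and-tile comparison free of
resampling drift. All heavy atoms are weighted equally by default
(element weighting is available but off), matching a projection of
"heavy atoms" rather than of scattering density.

Lattice averaging keeps the DC term plus the Fourier coefficients at the
reciprocal-lattice bins for $|h|,|k| \le$ `n_orders` (default 3, read as
the fundamental reflections of the two cell periodicities plus
harmonics) and inverse-transforms; this equals real-space averaging over
all cells, suppressing i.i.d. noise by the square root of the cell
count. Peak detection without a known cell requires a candidate local
maximum to exceed its radial annulus mean + 5 SD and a relative floor of
1e-6 of the strongest peak (guarding against numerically-zero bins on
noise-free images).

The registration search in `score_model()` is exhaustive over cyclic
pixel translations (computed exactly via FFT cross-correlation) plus the
two discrete settings (mirror, 180° rotation). This is deterministic and
oracle-checkable; on ideal P2 data the 180° setting is a lattice symmetry
and leaves r unchanged. The reported p-value uses n_pixels − 2 degrees of
freedom and is informational only: smoothing correlates neighbouring
pixels, so those degrees of freedom are inflated and the p-value should
never gate a decision.

### Trajectory quantities and ΔG from a PMF

The orientation of a protomer is the angle between a body axis — the
vector from a "core" atom-group centroid to a "cap" group centroid, a
definition chosen here because orientation plots in the literature rarely
define their axis — and the fixed interface normal (+z by convention).
Separation uses mass-weighted centres with minimum-image correction when
a periodic box is present. Dissociation is flagged at the first frame
that exceeds the baseline mean + k·SD (default k = 5 over the first
window) and never returns below that level.

The standard binding free energy integrates the 1D configuration
integral over the bound region of the PMF:
$\Delta G = k_B T \ln\!\big[\int_0^{r_b} e^{-W(r)/k_BT}\,dr \,/\, \delta^0\big]$,
with W anchored to 0 in the unbound region (an unanchored profile — tail
beyond 3× its uncertainty — is rejected). The sign convention reports a
binding strength: positive ΔG is favourable. The standard state enters
through $\delta^0 = (1\,\mathrm{M})^{-1/3} = 1.186$ nm applied along the
single pulled coordinate; 1D, 2D and 3D binding free energies are not
directly comparable, so δ° is explicit, configurable, and carried in
every result row. Uncertainty is first-order propagation of per-point PMF
errors through the Boltzmann weights. Temperature defaults to 300 K with
$k_B = 0.0019872$ kcal/(mol·K).

## The synthetic generators: what they emulate, and what they do not

The deposited crystal structures and the published micrograph are
external inputs. So that every stage is testable offline, the
`make_*` generators produce each input with exact ground truth, and the
generator defaults encode the study conditions the analysis is meant to
operate in:

- `make_toy_protein()`: a self-avoiding Cα walk (3.8 Å steps) with named
  backbone and simplified sidechain atoms for 16 residue types, always
  containing Lys/Asp/Glu/Arg/Phe so contact finders have substrates.
- `make_c2_dimer()` / `make_crystal_standin()`: exact two-fold dimers
  about parallel z axes placed just outside the monomer surface on
  opposite sides, 21.5 Å apart, so the composed C2 operations translate
  by exactly 4.3 nm, both interfaces are in SASA contact range
  (closest approach ~3-5 Å), and the propagated trimer is clash-free.
- `make_chain_family()`: copies with calibrated coordinate noise giving
  pairwise Cα RMSD ≈ 0.45 Å and all-atom ≈ 1.15 Å — the mid-points of
  the 0.4-0.5 Å and 1.0-1.3 Å bands typical of independent copies in a
  crystal asymmetric unit.
- `make_homolog_pair()`: a 124-residue chain and a diverged copy — core
  perturbed to 1.2 Å Cα RMSD, nine terminal residues displaced beyond
  the trim cutoff (so the iterative fit retains ~115 pairs), and exactly
  the number of core mutations that leaves 50.4% identity over the
  retained core.
- `make_lattice_image()`: a motif folded to one cell, tiled, plus i.i.d.
  Gaussian noise; the noise-free image and true motif ride along as
  attributes for oracle checks.
- `make_trajectory()`: rigid bodies realizing a wrapped-normal
  orientation distribution (mean 30°, SD 8°), a stable or change-point
  separation process, and a contact-atom pair whose bound/unbound state
  is i.i.d. Bernoulli per frame with stationary occupancy 0.86. The
  memoryless choice makes the empirical occupancy's sampling error
  exactly binomial, which is what the recovery check assumes; real
  salt-bridge trajectories are time-correlated, which widens the error
  of an occupancy estimate without biasing it.
- `make_pmf()`: square-well (closed-form ΔG) and harmonic profiles with
  constant synthetic uncertainty.

All generators consume a private RNG stream (the caller's `.Random.seed`
is restored), so identical arguments give bit-identical output and no
global state leaks.

What passing on synthetic data does **not** show: that the code
reproduces numbers measured on the real deposited structures or the real
micrograph. The stand-ins have simplified sidechain geometry, no
crystallographic disorder, exact (not approximate) two-fold symmetry,
and purely Gaussian image noise (no shot noise or contrast transfer
function). Structure-derived checks are therefore *recovery* checks —
the pipeline must re-measure the generator's ground truth within the
stated tolerance — and the same functions apply unchanged to any real
PDB/mmCIF file and TIFF-derived density map.

## Numerical choices and degenerate inputs

- Alt-locs collapse to the highest-occupancy conformer, ties broken by
  the alphabetically first alt-loc id: downstream geometry assumes one
  position per atom.
- Kabsch requires ≥ 3 non-collinear pairs; collinearity is detected via
  the second singular value of the centred cloud.
- Axis extraction near 0° and 180° uses the numerically stable branches
  (off-diagonal vector, and dominant column of R + I, respectively).
- Clash detection uses a cell-list spatial hash whose results are
  identical to the exhaustive all-pairs scan (tested against it).
- The PDB writer refuses models with more than 62 chains (the dialect's
  chain-id alphabet) and non-finite coordinates.
- Problem sizes in the test-suite and acceptance script are desk-scale
  by design: 28-125 residue toy proteins, 8-copy lattice patches,
  20 × 20-cell images, 1e4-frame trajectories. They were chosen as the
  smallest sizes at which the statistical checks (binomial occupancy
  error, noise suppression by cell averaging) have comfortable margins.

## Known limitations

- SASA reproduces the *kind* of numbers interface servers report, not
  any specific server's output; their algorithms differ in sampling and
  radii at the few-percent level.
- The lattice model is a rigid-body guide to possible interactions; no
  coordinate regularization or energy minimization is performed, exactly
  because the construction is meant to stay faithful to the
  crystallographic dimers.
- MD-derived quantities (occupancies, orientation distributions, PMF
  depths) require trajectories or profiles supplied from outside; the
  package analyses them but does not simulate.
- Micrographs enter as grayscale TIFF (`read_tem_image()`, pixel size
  supplied by the caller since TIFF carries no physical scale) or
  directly as density maps; the binary MRC format is not parsed.
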