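Package: filmlattice
Title: Dimer Interfaces and 2D Lattice Models of Biofilm Surface-Layer Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes crystallographic dimer interfaces of bacterial
    biofilm surface-layer (hydrophobin-like) proteins and propagates them into
    two-dimensional interfacial lattice models. Provides rigid-body (Kabsch)
    superposition with iterative outlier trimming, residue matching and
    pairwise sequence identity across paralogues, Shrake-Rupley solvent
    accessible surface area and per-residue interface burial, geometric
    contact typing (salt bridges, hydrogen bonds, ring stacking), extraction
    of two-fold dimer transforms and their composition into zigzag chains and
    rectangular P2 lattices, Gaussian projection of heavy atoms to 2D density
    maps, Fourier unit-cell averaging of periodic lattice images with
    registration-maximized Pearson scoring against model projections, and
    trajectory-derived quantities: orientation series, inter-monomer
    separation, dissociation detection, contact occupancy, and standard
    binding free energies from potentials of mean force. A deterministic
    synthetic-data generator supplies toy proteins, exact two-fold dimers,
    noisy periodic images, trajectories and PMF profiles with known ground
    truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
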