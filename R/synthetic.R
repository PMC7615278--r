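# Deterministic generators: every input the pipeline needs, with known
# ground truth, so all stages are testable offline. Each generator consumes
# its own seed through a private RNG stream (no global state).

toy_sidechain_templates <- function() {
  list(GLY = character(0),
       ALA = "CB",
       SER = c("CB", "OG"),
       THR = c("CB", "OG1", "CG2"),
       VAL = c("CB", "CG1", "CG2"),
       LEU = c("CB", "CG", "CD1", "CD2"),
       ILE = c("CB", "CG1", "CG2", "CD1"),
       ASN = c("CB", "CG", "OD1", "ND2"),
       GLN = c("CB", "CG", "CD", "OE1", "NE2"),
       LYS = c("CB", "CG", "CD", "CE", "NZ"),
       ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
       ASP = c("CB", "CG", "OD1", "OD2"),
       GLU = c("CB", "CG", "CD", "OE1", "OE2"),
       PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
       TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
       HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"))
}

#' Generate a toy protein
#'
#' A self-avoiding pseudo-peptide: Calpha trace with 3.8 Angstrom steps
#' (adjacent distances within [3.6, 4.0]), full backbone atom names
#' (N, CA, C, O), and simplified but correctly named sidechains for 16
#' residue types, placed outward from the chain. The sequence always
#' contains at least one each of Lys, Asp, Glu, Arg and Phe so that contact
#' finders have substrates. The last fifth of the chain is designated the
#' "cap" region (attribute `cap_residues`). Identical arguments give
#' bit-identical output.
#'
#' @param n_residues chain length (>= 3).
#' @param seed integer seed.
#' @param extent half-widths `c(x, y, z)` (Angstrom) of the box confining
#'   the Calpha walk; default scales with chain length.
#' @param chain chain id (default `"A"`).
#' @return An atom tibble with attributes `cap_residues` and `sequence`.
#' @export
make_toy_protein <- function(n_residues, seed = 1, extent = NULL, chain = "A") {
  if (n_residues < 3) stop("n_residues must be >= 3", call. = FALSE)
  if (is.null(extent)) {
    r <- 2.6 * n_residues^(1 / 3) + 4
    extent <- c(r, r, 0.75 * r)
  }
  with_private_seed(seed, {
    aas <- names(toy_sidechain_templates())
    seq3 <- sample(aas, n_residues, replace = TRUE)
    must <- c("LYS", "ASP", "GLU", "ARG", "PHE")
    slots <- sample(n_residues, length(must))
    seq3[slots] <- must
    ca <- toy_ca_walk(n_residues, extent)
    atoms <- build_toy_atoms(ca, seq3, chain)
  })
  cap <- seq(max(1, ceiling(0.8 * n_residues) + 1), n_residues)
  st <- as_structure(atoms, id = sprintf("toy%d_seed%d", n_residues, seed))
  attr(st, "cap_residues") <- cap
  attr(st, "sequence") <- paste(aa_three_to_one(seq3), collapse = "")
  st
}

# Self-avoiding Calpha walk (step 3.8 A, non-adjacent clearance 3.6 A)
# confined to a centred box, with a weak bias back towards the origin.
# Restarts from scratch when it jams, consuming further RNG draws, so the
# result is still a pure function of the seed.
toy_ca_walk <- function(n, extent, step = 3.8, clearance = 3.6) {
  for (restart in seq_len(200)) {
    pos <- matrix(0, n, 3)
    dir <- unit(stats::rnorm(3))
    k <- 2
    tries <- 0
    budget <- 400 * n
    while (k <= n && budget > 0) {
      budget <- budget - 1
      prop_dir <- unit(dir + 0.8 * unit(stats::rnorm(3)) -
                         0.05 * pos[k - 1, ] / max(extent))
      cand <- pos[k - 1, ] + step * prop_dir
      ok <- all(abs(cand) <= extent)
      if (ok && k > 2) {
        d2 <- rowSums(sweep(pos[seq_len(k - 2), , drop = FALSE], 2, cand)^2)
        ok <- min(d2) >= clearance^2
      }
      tries <- tries + 1
      if (ok) {
        pos[k, ] <- cand
        dir <- prop_dir
        k <- k + 1
        tries <- 0
      } else if (tries > 100) {
        # back up a few residues and re-try from there
        k <- max(2, k - 3)
        dir <- unit(stats::rnorm(3))
        tries <- 0
      }
    }
    if (k > n) return(sweep(pos, 2, colMeans(pos)))
  }
  stop("self-avoiding walk failed: box too small for ", n, " residues",
       call. = FALSE)
}

build_toy_atoms <- function(ca, seq3, chain) {
  n <- nrow(ca)
  templates <- toy_sidechain_templates()
  ctr <- colMeans(ca)
  rows <- list()
  for (i in seq_len(n)) {
    t_vec <- if (i == 1) ca[2, ] - ca[1, ]
    else if (i == n) ca[n, ] - ca[n - 1, ]
    else ca[i + 1, ] - ca[i - 1, ]
    t_vec <- unit(t_vec)
    out_vec <- ca[i, ] - ctr
    s_vec <- out_vec - sum(out_vec * t_vec) * t_vec
    if (vnorm(s_vec) < 1e-6) s_vec <- vector_cross(t_vec, c(0, 0, 1))
    if (vnorm(s_vec) < 1e-6) s_vec <- vector_cross(t_vec, c(0, 1, 0))
    s_vec <- unit(s_vec)
    u_vec <- vector_cross(t_vec, s_vec)
    res <- seq3[i]
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(ca[i, ] - 1.2 * t_vec + 0.35 * u_vec,
                 ca[i, ],
                 ca[i, ] + 1.25 * t_vec + 0.3 * u_vec,
                 ca[i, ] + 1.3 * t_vec + 1.5 * u_vec)
    side <- templates[[res]]
    # radial distances from CA, compressed so no sidechain reaches past
    # ~5.7 A (keeps the toy fold compact and its width controllable)
    sc_dist <- c(1.53, 2.5, 3.3, 4.0, 4.6, 4.9, 5.1)
    if (res %in% c("PHE", "TYR", "HIS")) {
      xyz <- rbind(xyz, ca[i, ] + 1.53 * s_vec)  # CB
      nm <- c(nm, "CB")
      ring_names <- setdiff(side, c("CB", "OH"))
      nr <- length(ring_names)
      rad <- if (nr == 6) 1.39 else 1.16
      m <- ca[i, ] + 2.9 * s_vec
      angs <- pi + 2 * pi * (seq_len(nr) - 1) / nr   # first vertex faces CB
      ring <- t(vapply(angs, function(a)
        m + rad * (cos(a) * s_vec + sin(a) * u_vec), numeric(3)))
      xyz <- rbind(xyz, ring)
      nm <- c(nm, ring_names)
      if ("OH" %in% side) {
        xyz <- rbind(xyz, m + (rad + 1.36) * s_vec)
        nm <- c(nm, "OH")
      }
    } else if (length(side)) {
      for (k in seq_along(side)) {
        xyz <- rbind(xyz, ca[i, ] + sc_dist[k] * s_vec +
                       0.45 * ((k %% 2) * 2 - 1) * u_vec)
      }
      nm <- c(nm, side)
    }
    el <- substr(nm, 1, 1)
    rows[[i]] <- tibble::tibble(chain = chain, res_seq = i, res_name = res,
                                atom_name = nm, element = el,
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  dplyr::bind_rows(rows)
}

#' Build an exact two-fold dimer from a monomer
#'
#' The second protomer is the monomer rotated exactly 180 degrees about the
#' given axis, so [extract_dimer_transform()] on the output recovers the
#' axis to numerical precision. If `separation` is given, the axis point is
#' moved along the (perpendicular) direction from the monomer centroid
#' towards it so that the two protomer centroids end up `separation`
#' Angstrom apart.
#'
#' @param monomer single-chain atom tibble.
#' @param axis_point point on the two-fold axis (Angstrom).
#' @param axis_direction axis direction (normalized internally).
#' @param separation optional centroid-centroid distance, Angstrom.
#' @param min_gap reject outputs with any heavy-atom pair closer than this
#'   (default 2 Angstrom).
#' @return A two-chain atom tibble (chains `"A"`, `"B"`).
#' @export
make_c2_dimer <- function(monomer, axis_point, axis_direction,
                          separation = NULL, min_gap = 2) {
  u <- unit(axis_direction)
  p <- as.numeric(axis_point)
  ctr <- centroid(coords(monomer[monomer$is_heavy, ]))
  if (!is.null(separation)) {
    w <- (p - ctr) - sum((p - ctr) * u) * u
    if (vnorm(w) < 1e-9) {
      w <- vector_cross(u, c(1, 0, 0))
      if (vnorm(w) < 1e-9) w <- vector_cross(u, c(0, 1, 0))
    }
    p <- ctr + unit(w) * separation / 2
  }
  c2 <- rotation_about_axis(p, u, 180)
  a <- monomer; a$chain <- "A"
  b <- transform_apply(c2, monomer); b$chain <- "B"
  gap <- min_chain_distance(a, b)
  if (gap < min_gap)
    stop("copies overlap (closest heavy-atom pair ", round(gap, 2),
         " A); increase the axis separation", call. = FALSE)
  out <- as_structure(dplyr::bind_rows(a, b), id = "c2_dimer")
  attr(out, "axis_point") <- p
  attr(out, "axis_direction") <- u
  out
}

min_chain_distance <- function(a, b) {
  xa <- coords(a[a$is_heavy, ]); xb <- coords(b[b$is_heavy, ])
  sqrt(min(outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)))
}

#' Synthetic crystal stand-in for the two-interface dimer system
#'
#' Builds, from one toy monomer, the geometry the lattice analysis needs:
#' two exact two-fold dimers about parallel z axes placed just outside the
#' monomer surface on opposite sides, 21.5 Angstrom apart, so that the
#' composed two-fold operations translate by 43 Angstrom (the 4.3 nm
#' lattice repeat) and the propagated chain is clash-free while both
#' interfaces stay in contact range. A synthetic stand-in for a deposited
#' crystal structure, with exact ground truth attached.
#'
#' @param seed integer seed.
#' @param n_residues monomer size (default 28).
#' @param repeat_nm target zigzag repeat length in nm (default 4.3).
#' @return List with `monomer`, `dimer1`, `dimer2` (atom tibbles),
#'   `axis1`, `axis2` (points), `repeat_nm` (ground truth).
#' @export
make_crystal_standin <- function(seed = 1, n_residues = 28, repeat_nm = 4.3) {
  half_repeat <- nm_to_ang(repeat_nm) / 2      # axis separation, A
  # the monomer must be nearly as wide as the protomer spacing so both
  # interfaces are in contact range but clash-free: accept a generated fold
  # whose heavy-atom width leaves 1.45-2.5 A of clearance per axis
  # Each axis is a z-line placed just beyond the molecule on opposite x
  # sides, at the y of the extreme atom so that interface contact happens
  # there; for every atom the axis distance is >= its x clearance, so the
  # closest image pair sits at twice the clearance (no clash). The axis
  # separation |p1 - p2| is held at exactly half the repeat.
  mono <- NULL
  for (attempt in seq_len(200)) {
    cand <- make_toy_protein(n_residues, seed = 1000 * seed + attempt,
                             extent = c(4.2, 9, 7))
    heavy <- cand[cand$is_heavy, ]
    i_hi <- which.max(heavy$x); i_lo <- which.min(heavy$x)
    w <- heavy$x[i_hi] - heavy$x[i_lo]
    dy <- heavy$y[i_hi] - heavy$y[i_lo]
    if (abs(dy) >= half_repeat) next
    slack <- sqrt(half_repeat^2 - dy^2) - w
    if (slack >= 2.9 && slack <= 5.0) {
      mono <- cand
      gap <- slack / 2
      p1 <- c(heavy$x[i_hi] + gap, heavy$y[i_hi], 0)
      p2 <- c(heavy$x[i_lo] - gap, heavy$y[i_lo], 0)
      break
    }
  }
  if (is.null(mono))
    stop("could not generate a monomer of suitable width; try another seed",
         call. = FALSE)
  dimer1 <- make_c2_dimer(mono, p1, c(0, 0, 1))
  dimer2 <- make_c2_dimer(mono, p2, c(0, 0, 1))
  list(monomer = mono, dimer1 = dimer1, dimer2 = dimer2,
       axis1 = p1, axis2 = p2, repeat_nm = repeat_nm)
}

#' Synthetic family of near-identical chains
#'
#' Emulates the several copies of one protein in a crystal asymmetric
#' unit: `n_chains` copies of a toy monomer with independent Gaussian
#' coordinate noise calibrated so that the expected pairwise Calpha RMSD
#' between copies is `ca_rmsd` and the pairwise all-atom RMSD is
#' `all_atom_rmsd` (sidechains get extra noise, as real sidechains are the
#' more variable part). Chains are labelled A, B, C, ... Ground truth
#' (targets and realized noise) is attached as attributes.
#'
#' @param seed integer seed.
#' @param n_residues residues per chain (default 125).
#' @param n_chains number of copies (default 4).
#' @param ca_rmsd target pairwise Calpha RMSD, Angstrom (default 0.45).
#' @param all_atom_rmsd target pairwise all-atom RMSD, Angstrom
#'   (default 1.15).
#' @return Atom tibble with `n_chains` chains; attribute `targets`.
#' @export
make_chain_family <- function(seed = 1, n_residues = 125, n_chains = 4,
                              ca_rmsd = 0.45, all_atom_rmsd = 1.15) {
  mono <- make_toy_protein(n_residues, seed = seed)
  bb <- mono$atom_name %in% c("N", "CA", "C", "O")
  f_bb <- mean(bb)
  # independent noise on both copies: pairwise msd = 2 * per-copy msd
  sd_bb <- ca_rmsd / sqrt(6)
  sd_sc <- sqrt(max(all_atom_rmsd^2 - f_bb * ca_rmsd^2, 0.01) /
                  (6 * (1 - f_bb)))
  chains <- with_private_seed(seed + 1, {
    lapply(seq_len(n_chains), function(k) {
      m <- mono
      noise_sd <- ifelse(bb, sd_bb, sd_sc)
      m$x <- m$x + stats::rnorm(nrow(m), 0, noise_sd)
      m$y <- m$y + stats::rnorm(nrow(m), 0, noise_sd)
      m$z <- m$z + stats::rnorm(nrow(m), 0, noise_sd)
      # a random rigid motion per copy: RMSD must be invariant to it
      rot <- rotation_about_axis(c(0, 0, 0), stats::rnorm(3),
                                 stats::runif(1, 0, 360))
      m <- transform_apply(rot, m)
      m$x <- m$x + stats::runif(1, -20, 20)
      m$chain <- LETTERS[k]
      m
    })
  })
  out <- as_structure(dplyr::bind_rows(chains), id = "chain_family")
  attr(out, "targets") <- list(ca_rmsd = ca_rmsd, all_atom_rmsd = all_atom_rmsd)
  out
}

#' Synthetic diverged structural homolog pair
#'
#' Emulates a paralogue pair for the superposition/identity pipeline: chain
#' A is a toy monomer; chain B is a copy whose core is perturbed to a
#' prescribed Calpha RMSD, whose terminal residues (`n_outlier`) are
#' displaced far enough to be trimmed by the iterative fit, and whose
#' sequence is mutated at exactly the number of core positions giving the
#' prescribed identity over the surviving core. Used for backbone-level
#' comparisons (sidechains keep their template geometry). Ground truth is
#' attached as attribute `targets`.
#'
#' @param seed integer seed.
#' @param n_residues chain length (default 124).
#' @param core_rmsd target Calpha RMSD over the retained core, Angstrom
#'   (default 1.2).
#' @param n_outlier terminal residues displaced beyond the trim cutoff
#'   (default 9: 4 N-terminal + 5 C-terminal).
#' @param outlier_shift displacement of outlier residues, Angstrom
#'   (default 7).
#' @param core_identity fraction of identical residues over the retained
#'   core (default 0.504).
#' @return Atom tibble with chains `"A"` and `"B"`; attribute `targets`.
#' @export
make_homolog_pair <- function(seed = 1, n_residues = 124, core_rmsd = 1.2,
                              n_outlier = 9, outlier_shift = 7,
                              core_identity = 0.504) {
  mono <- make_toy_protein(n_residues, seed = seed)
  n_nt <- floor(n_outlier / 2); n_ct <- n_outlier - n_nt
  outliers <- c(seq_len(n_nt), seq(n_residues - n_ct + 1, n_residues))
  core <- setdiff(seq_len(n_residues), outliers)
  aas <- names(toy_sidechain_templates())
  b <- with_private_seed(seed + 2, {
    m <- mono
    m$chain <- "B"
    sd_core <- core_rmsd / sqrt(3)   # B noisy vs clean A
    m$x <- m$x + stats::rnorm(nrow(m), 0, sd_core)
    m$y <- m$y + stats::rnorm(nrow(m), 0, sd_core)
    m$z <- m$z + stats::rnorm(nrow(m), 0, sd_core)
    for (r in outliers) {
      shift <- outlier_shift * unit(stats::rnorm(3))
      sel <- m$res_seq == r
      m$x[sel] <- m$x[sel] + shift[1]
      m$y[sel] <- m$y[sel] + shift[2]
      m$z[sel] <- m$z[sel] + shift[3]
    }
    n_mut_core <- round((1 - core_identity) * length(core))
    mut <- c(sample(core, n_mut_core), sample(outliers, ceiling(n_outlier / 2)))
    for (r in mut) {
      sel <- m$res_seq == r
      old <- m$res_name[sel][1]
      m$res_name[sel] <- sample(setdiff(aas, old), 1)
    }
    # a rigid motion so the pair is not pre-superposed
    rot <- rotation_about_axis(c(5, 0, 0), c(1, 2, 0), 73)
    transform_apply(rot, m)
  })
  out <- as_structure(dplyr::bind_rows(mono, b), id = "homolog_pair")
  attr(out, "targets") <- list(core_rmsd = core_rmsd,
                               n_core = length(core),
                               core_identity = core_identity,
                               outliers = outliers)
  out
}

#' Tile a motif into a noisy periodic lattice image
#'
#' The motif is folded onto one unit cell (wrapped modulo the cell and
#' averaged), tiled `n_cells` times per axis, and i.i.d. Gaussian noise of
#' standard deviation `noise_sd` x max(motif) is added; values are clipped
#' at zero. The noise-free image, the folded motif cell and the cell
#' dimensions are attached as attributes (`clean`, `motif_cell`, `cell`)
#' for oracle checks.
#'
#' @param motif an `fl_density` (must fit within one cell).
#' @param cell `c(a, b)` cell edges, nm.
#' @param n_cells `c(nx, ny)` cells per axis.
#' @param noise_sd noise SD as a fraction of the motif maximum (default 0;
#'   1 gives SNR ~ 1).
#' @param seed integer seed for the noise.
#' @return An `fl_density` with provenance `"synthetic"`.
#' @export
make_lattice_image <- function(motif, cell, n_cells = c(10, 10),
                               noise_sd = 0, seed = 1) {
  cellmap <- fold_to_cell(motif, cell, n_tiles = 1)
  g <- cellmap$grid
  img <- g[rep(seq_len(nrow(g)), n_cells[1]), rep(seq_len(ncol(g)), n_cells[2])]
  clean <- img
  if (noise_sd > 0) {
    img <- with_private_seed(seed, {
      img + stats::rnorm(length(img), 0, noise_sd * max(g))
    })
    img[img < 0] <- 0
  }
  out <- density_map(img, cellmap$pixel_size, c(0, 0), provenance = "synthetic")
  attr(out, "clean") <- clean
  attr(out, "motif_cell") <- g
  attr(out, "cell") <- c(nrow(g), ncol(g)) * cellmap$pixel_size
  out
}

#' Synthetic rigid-body trajectory with known ground truth
#'
#' Two small rigid bodies (chains A and B) plus one dedicated contact-atom
#' pair. Per frame: the body axes make an angle to the +z interface normal
#' drawn from a wrapped normal; the bodies' centres sit a prescribed
#' distance apart (stable noise around `separation_nm`, with an optional
#' change point after which the distance drifts apart: a dissociation);
#' and the contact-atom distance follows a two-state bound/unbound process
#' with stationary occupancy `occupancy`. The generator law is returned
#' alongside the frames.
#'
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param time_step ns per frame (default 0.01).
#' @param orientation_mean,orientation_sd wrapped-normal parameters for the
#'   body-axis angle, degrees (defaults 30 and 8).
#' @param separation_nm mean separation (default 2 nm).
#' @param separation_sd separation noise SD, nm (default 0.05).
#' @param change_point frame index after which the separation drifts, or
#'   `NULL` for a stable dimer.
#' @param drift_nm_per_frame drift rate after the change point.
#' @param occupancy stationary bound fraction of the contact pair
#'   (default 0.86).
#' @param bound_range,unbound_range contact distance ranges (Angstrom) in
#'   the bound and unbound state.
#' @return List with `frames` (an `fl_frames`) and `truth` (tibble of
#'   per-frame ground truth plus the selections used: `sel_a`, `sel_b`,
#'   `contact_i`, `contact_j` as attributes).
#' @export
make_trajectory <- function(n_frames = 5000, seed = 1, time_step = 0.01,
                            orientation_mean = 30, orientation_sd = 8,
                            separation_nm = 2, separation_sd = 0.05,
                            change_point = NULL, drift_nm_per_frame = 0.01,
                            occupancy = 0.86, bound_range = c(3.0, 3.8),
                            unbound_range = c(5, 8)) {
  body <- rbind(c(0, 0, -2), c(0, 0, 2), c(1.5, 0, 0), c(-1.5, 0, 0))
  topo <- tibble::tibble(
    chain = rep(c("A", "B"), each = 5),
    res_seq = 1L,
    res_name = "UNK",
    atom_name = rep(c("TAIL", "HEAD", "LAT1", "LAT2", "CTC"), 2),
    element = "C",
    x = 0, y = 0, z = 0)
  truth <- with_private_seed(seed, {
    ang <- stats::rnorm(n_frames, orientation_mean, orientation_sd)
    ang <- abs(ang) %% 360
    ang[ang > 180] <- 360 - ang[ang > 180]
    sep <- separation_nm + stats::rnorm(n_frames, 0, separation_sd)
    if (!is.null(change_point)) {
      post <- seq_len(n_frames) > change_point
      sep[post] <- sep[post] + drift_nm_per_frame *
        (seq_len(n_frames)[post] - change_point)
    }
    state <- stats::rbinom(n_frames, 1, occupancy)
    dc <- ifelse(state == 1,
                 stats::runif(n_frames, bound_range[1], bound_range[2]),
                 stats::runif(n_frames, unbound_range[1], unbound_range[2]))
    tibble::tibble(frame = seq_len(n_frames), angle = ang, separation = sep,
                   bound = state == 1, contact_distance = dc)
  })
  xyz <- array(0, c(10, 3, n_frames))
  for (f in seq_len(n_frames)) {
    th <- truth$angle[f] * pi / 180
    axis_v <- c(sin(th), 0, cos(th))
    w <- c(cos(th), 0, -sin(th))
    bf <- rbind(-2 * axis_v, 2 * axis_v, 1.5 * w, -1.5 * w)
    ctr_b <- c(nm_to_ang(truth$separation[f]), 0, 0)
    xyz[1:4, , f] <- bf
    xyz[5, , f] <- c(0, 6, 0)
    xyz[6:9, , f] <- sweep(bf, 2, ctr_b, `+`)
    xyz[10, , f] <- c(truth$contact_distance[f], 6, 0)
  }
  frames <- frame_set(topo, xyz, time_step = time_step)
  attr(truth, "sel_a") <- 1:4
  attr(truth, "sel_b") <- 6:9
  attr(truth, "contact_i") <- 5L
  attr(truth, "contact_j") <- 10L
  attr(truth, "occupancy_param") <- occupancy
  attr(truth, "change_point") <- change_point
  list(frames = frames, truth = truth)
}

#' Synthetic PMF profile with known well depth
#'
#' Square well: W = -depth for r < width, 0 beyond (closed-form binding
#' free energy `depth + kT log(width / delta0)`). Harmonic: a parabolic
#' well of the given depth centred at `r0`, clipped at 0 where it would
#' become positive.
#'
#' @param depth well depth, kcal/mol (>= 0).
#' @param width nm: the square-well bound region, or the harmonic
#'   half-width at W = 0.
#' @param form `"square_well"` or `"harmonic"`.
#' @param grid_step r spacing, nm (default 0.005).
#' @param r_max profile extent = unbound reference, nm (default 4).
#' @param r0 harmonic well centre, nm (default 0.5).
#' @param w_err constant synthetic per-point uncertainty (default 0.1).
#' @return An `fl_pmf`.
#' @export
make_pmf <- function(depth, width, form = c("square_well", "harmonic"),
                     grid_step = 0.005, r_max = 4, r0 = 0.5, w_err = 0.1) {
  form <- match.arg(form)
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  r <- seq(0, r_max, by = grid_step)
  w <- if (form == "square_well") ifelse(r < width, -depth, 0)
  else pmin(0, -depth + depth * ((r - r0) / width)^2)
  pmf_profile(r, w, w_err = w_err, r_unbound = r_max)
}
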