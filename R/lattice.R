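#' Extract the dimer transform of two matched chains
#'
#' Fits chain 1 onto chain 2 (Kabsch over sequence-matched Calpha pairs) and
#' decomposes the resulting rigid transform into axis/angle form. A dimer is
#' flagged two-fold (`is_c2`) when the rotation angle is within
#' `c2_tolerance` of 180 degrees; crystallographic dimers are approximately,
#' not exactly, symmetric.
#'
#' @param atoms atom tibble containing both chains.
#' @param chain_1,chain_2 chain ids of the two protomers (same protein).
#' @param c2_tolerance degrees of allowed deviation from 180 (default 10).
#' @return An object of class `fl_dimer_transform`: list with `transform`
#'   (maps chain 1 onto chain 2), `axis_point`, `axis_direction`,
#'   `rotation_angle` (degrees), `is_c2`, `screw` (axis-parallel residual,
#'   Angstrom), `rmsd`, `n_pairs`.
#' @export
extract_dimer_transform <- function(atoms, chain_1, chain_2, c2_tolerance = 10) {
  pairs <- match_residues(atoms, chain_1, atoms, chain_2)
  n_res1 <- nrow(residue_table(select_atoms(atoms, chain = chain_1, drop_het = TRUE)))
  if (nrow(pairs) < 0.8 * n_res1)
    stop("chains share fewer than 80% of residues; not the same protein?",
         call. = FALSE)
  pc <- pair_ca_coords(atoms, chain_1, atoms, chain_2, pairs)
  fit <- kabsch(pc$a, pc$b)
  if (fit$rmsd > 2)
    stop("monomer self-superposition rmsd ", round(fit$rmsd, 2),
         " A > 2 A: chains are not conformationally equivalent", call. = FALSE)
  aa <- transform_axis_angle(fit$transform)
  structure(list(transform = fit$transform,
                 axis_point = aa$point,
                 axis_direction = aa$axis,
                 rotation_angle = aa$angle_deg,
                 is_c2 = abs(aa$angle_deg - 180) <= c2_tolerance,
                 screw = vnorm(aa$screw),
                 rmsd = fit$rmsd, n_pairs = fit$n_pairs),
            class = "fl_dimer_transform")
}

#' @export
print.fl_dimer_transform <- function(x, ...) {
  cat(sprintf("<dimer_transform> angle %.1f deg%s, fit rmsd %.3f A over %d CA\n",
              x$rotation_angle, if (x$is_c2) " (C2)" else "", x$rmsd, x$n_pairs))
  invisible(x)
}

#' Express a dimer transform in another frame
#'
#' Conjugates a dimer transform by a rigid motion `u`: if `t` maps protomer
#' 1 onto protomer 2 in its own frame, the result maps `u`(protomer 1) onto
#' `u`(protomer 2). Used to bring two dimers onto a shared reference
#' monomer before composing their two-fold operations.
#'
#' @param t an `fl_dimer_transform`.
#' @param u a `rigid_transform`.
#' @return An `fl_dimer_transform` in the new frame.
#' @export
conjugate_dimer_transform <- function(t, u) {
  tc <- transform_compose(u, transform_compose(t$transform, transform_invert(u)))
  aa <- transform_axis_angle(tc)
  out <- t
  out$transform <- tc
  out$axis_point <- aa$point
  out$axis_direction <- aa$axis
  out$rotation_angle <- aa$angle_deg
  out$screw <- vnorm(aa$screw)
  out
}

#' Model a dimer of protein Y on the template of a protein X dimer
#'
#' Superposes the target monomer onto each chain of the template dimer
#' (iterative trimmed fit) and emits a two-chain model of the target placed
#' by the two resulting transforms. No coordinate regularization is done:
#' the output is a guide to possible interactions, not a refined structure.
#'
#' @param template_atoms atom tibble with the template dimer.
#' @param template_chains length-2 chain ids of the template dimer.
#' @param target_atoms atom tibble with the target monomer.
#' @param target_chain chain id of the target monomer.
#' @param max_rmsd reject templates whose chains the target does not
#'   superpose onto within this trimmed rmsd (Angstrom, default 3).
#' @return A two-chain atom tibble (chains `"A"` and `"B"`).
#' @export
model_dimer_by_template <- function(template_atoms, template_chains,
                                    target_atoms, target_chain, max_rmsd = 3) {
  mono <- select_atoms(target_atoms, chain = target_chain, drop_het = TRUE)
  out <- list()
  for (k in 1:2) {
    fit <- iterative_superpose(target_atoms, target_chain,
                               template_atoms, template_chains[k])
    if (fit$rmsd > max_rmsd)
      stop("target does not superpose on template chain ", template_chains[k],
           " (rmsd ", round(fit$rmsd, 2), " A)", call. = FALSE)
    placed <- transform_apply(fit$transform, mono)
    placed$chain <- c("A", "B")[k]
    out[[k]] <- placed
  }
  as_structure(dplyr::bind_rows(out), id = "modelled_dimer")
}

#' Propagate two C2 dimer transforms into a zigzag chain
#'
#' Starting from a reference monomer (placement `M0 = I`), copies alternate
#' through the two interfaces: the partner of copy k placed by `M` is
#' `M o T` where T is the next interface transform in alternation. The
#' composition of the two two-fold operations is (for parallel axes) a pure
#' translation: the lattice repeat. Its length is reported in nm.
#'
#' @param reference atom tibble of the reference monomer.
#' @param t1,t2 `fl_dimer_transform` objects, both C2.
#' @param n_copies total number of placements to generate (>= 2).
#' @return An object of class `fl_zigzag`: list with `reference`,
#'   `placements` (tibble: copy, interface, transform list-column),
#'   `repeat_vector` (nm, 3-vector), `repeat_length` (nm),
#'   `axis_direction` (mean C2 axis), `residual_rotation` (degrees of the
#'   composed operation; a warning is recorded in `warnings` if > 15).
#' @export
build_zigzag <- function(reference, t1, t2, n_copies = 6) {
  for (tt in list(t1, t2))
    if (!inherits(tt, "fl_dimer_transform") || !tt$is_c2)
      stop("build_zigzag requires two C2 dimer transforms", call. = FALSE)
  warnings <- character()
  M <- transform_identity()
  placements <- list(tibble::tibble(copy = 0L, interface = NA_integer_,
                                    transform = list(M)))
  for (k in seq_len(n_copies - 1)) {
    Tk <- if (k %% 2 == 1) t1$transform else t2$transform
    M <- transform_compose(M, Tk)
    placements[[k + 1]] <- tibble::tibble(copy = k,
                                          interface = ifelse(k %% 2 == 1, 1L, 2L),
                                          transform = list(M))
  }
  placements <- dplyr::bind_rows(placements)
  comp <- transform_compose(t1$transform, t2$transform)
  aa <- transform_axis_angle(comp)
  if (aa$angle_deg > 15)
    warnings <- c(warnings, sprintf(
      "composition of the two C2 operations deviates from a pure translation by %.1f deg",
      aa$angle_deg))
  # displacement between copy k and copy k+2 measured on the reference centroid
  ctr <- centroid(coords(reference[reference$is_heavy, ]))
  rep_vec_ang <- as.numeric(transform_apply(comp, matrix(ctr, 1, 3))) - ctr
  axis_dir <- unit(t1$axis_direction * sign(sum(t1$axis_direction * t2$axis_direction)) +
                     t2$axis_direction)
  structure(list(reference = reference, placements = placements,
                 repeat_vector = ang_to_nm(rep_vec_ang),
                 repeat_length = ang_to_nm(vnorm(rep_vec_ang)),
                 axis_direction = axis_dir,
                 residual_rotation = aa$angle_deg,
                 warnings = warnings),
            class = "fl_zigzag")
}

#' @export
print.fl_zigzag <- function(x, ...) {
  cat(sprintf("<zigzag> %d copies, repeat %.2f nm%s\n", nrow(x$placements),
              x$repeat_length,
              if (length(x$warnings)) paste0(" [", x$warnings, "]") else ""))
  invisible(x)
}

#' Default perpendicular row shift for lattice assembly
#'
#' The row translation is an experimental input (taken from the TEM unit
#' cell), not derived from the dimers: direction perpendicular to the
#' zigzag repeat within the interface plane, length `b_nm`, plus an optional
#' registry offset along the repeat of `offset_frac` cells (default 0, a
#' pure perpendicular shift, which reproduces the rectangular cell).
#'
#' @param zigzag an `fl_zigzag`.
#' @param b_nm row spacing in nm (default 3.9).
#' @param offset_frac offset along the repeat vector, in cells.
#' @return 3-vector, nm.
#' @export
default_row_shift <- function(zigzag, b_nm = 3.9, offset_frac = 0) {
  a_dir <- unit(zigzag$repeat_vector)
  n_dir <- zigzag$axis_direction
  perp <- unit(n_dir - sum(n_dir * a_dir) * a_dir)
  perp <- vector_cross(a_dir, perp)  # in-plane, perpendicular to repeat
  b_nm * unit(perp) + offset_frac * zigzag$repeat_vector
}

vector_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Replicate a zigzag into a 2D lattice
#'
#' @param zigzag an `fl_zigzag`.
#' @param b_translation row shift, 3-vector in nm (see [default_row_shift()]).
#' @param n_rows number of rows.
#' @return An object of class `fl_lattice`: list with `reference`,
#'   `placements` (tibble: i (copy along the zigzag), j (row), transform),
#'   `cell_a`, `cell_b` (nm), `cell_angle` (degrees), `plane_normal`.
#' @export
build_lattice <- function(zigzag, b_translation, n_rows = 2) {
  b_translation <- as.numeric(b_translation)
  a_vec <- zigzag$repeat_vector
  cosang <- abs(sum(unit(a_vec) * unit(b_translation)))
  if (cosang > 1 - 1e-9)
    stop("row translation is parallel to the zigzag repeat", call. = FALSE)
  rows <- list()
  for (j in seq_len(n_rows) - 1L) {
    shift <- rigid_transform(diag(3), nm_to_ang(j * b_translation))
    pl <- zigzag$placements
    pl$transform <- lapply(pl$transform, function(m) transform_compose(shift, m))
    pl$i <- pl$copy
    pl$j <- j
    rows[[j + 1]] <- pl[, c("i", "j", "transform")]
  }
  ang <- acos(max(-1, min(1, sum(unit(a_vec) * unit(b_translation))))) * 180 / pi
  structure(list(reference = zigzag$reference,
                 placements = dplyr::bind_rows(rows),
                 cell_a = vnorm(a_vec), cell_b = vnorm(b_translation),
                 cell_angle = ang,
                 b_translation = b_translation,
                 plane_normal = zigzag$axis_direction),
            class = "fl_lattice")
}

#' @export
print.fl_lattice <- function(x, ...) {
  cat(sprintf("<lattice> %d copies, cell %.2f x %.2f nm, %g deg\n",
              nrow(x$placements), x$cell_a, x$cell_b, x$cell_angle))
  invisible(x)
}

#' Expand lattice placements to an explicit multi-chain model
#'
#' @param lattice an `fl_lattice` or `fl_zigzag`.
#' @return An atom tibble with one chain per copy (ids A, B, C, ...).
#' @export
expand_lattice <- function(lattice) {
  ref <- lattice$reference
  pl <- lattice$placements
  ids <- chain_id_pool(nrow(pl))
  out <- vector("list", nrow(pl))
  for (k in seq_len(nrow(pl))) {
    copy <- transform_apply(pl$transform[[k]], ref)
    copy$chain <- ids[k]
    out[[k]] <- copy
  }
  as_structure(dplyr::bind_rows(out), id = "lattice")
}

#' Detect steric clashes between copies
#'
#' All inter-copy heavy-atom pairs closer than `cutoff`, found with a
#' cell-list spatial hash whose results are identical to an exhaustive
#' all-pairs scan. Intra-copy (same chain) pairs are ignored.
#'
#' @param model an atom tibble (chains = copies), or an `fl_lattice` /
#'   `fl_zigzag` (expanded automatically).
#' @param cutoff clash distance in Angstrom (default 2.5).
#' @return An object of class `fl_clashes`: tibble of pairs (`chain_i`,
#'   `atom_i`, `chain_j`, `atom_j`, `distance`) with attribute `cutoff`.
#' @export
detect_clashes <- function(model, cutoff = 2.5) {
  if (inherits(model, c("fl_lattice", "fl_zigzag"))) model <- expand_lattice(model)
  heavy <- model[model$is_heavy, ]
  xyz <- coords(heavy)
  pr <- neighbor_pairs(xyz, cutoff)
  keep <- pr[heavy$chain[pr[, 1]] != heavy$chain[pr[, 2]], , drop = FALSE]
  d <- sqrt(rowSums((xyz[keep[, 1], , drop = FALSE] -
                       xyz[keep[, 2], , drop = FALSE])^2))
  out <- tibble::tibble(chain_i = heavy$chain[keep[, 1]],
                        atom_i = atom_label(heavy, keep[, 1]),
                        chain_j = heavy$chain[keep[, 2]],
                        atom_j = atom_label(heavy, keep[, 2]),
                        distance = d)
  out <- dplyr::arrange(out, .data$atom_i, .data$atom_j)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("fl_clashes", class(out))
  out
}

#' Re-measure the unit cell from lattice placements
#'
#' Recomputes the cell from placement centroids as a self-check, ignoring
#' the stored `cell_a`/`cell_b`: a = mean displacement between copies
#' (i, j) and (i+2, j); b = mean displacement between rows. Invariant under
#' global rigid motion.
#'
#' @param lattice an `fl_lattice` with at least a 2x2 set of copies.
#' @return List with `a` (nm), `b` (nm), `angle` (degrees).
#' @export
measure_unit_cell <- function(lattice) {
  pl <- lattice$placements
  if (length(unique(pl$j)) < 2 || length(unique(pl$i)) < 3)
    stop("need at least 2 rows and 3 copies per row to measure the cell",
         call. = FALSE)
  ctr <- centroid(coords(lattice$reference[lattice$reference$is_heavy, ]))
  pos <- t(vapply(pl$transform,
                  function(m) as.numeric(transform_apply(m, matrix(ctr, 1, 3))),
                  numeric(3)))
  key <- paste(pl$i, pl$j)
  a_vecs <- list(); b_vecs <- list()
  for (k in seq_len(nrow(pl))) {
    ka <- match(paste(pl$i[k] + 2, pl$j[k]), key)
    if (!is.na(ka)) a_vecs[[length(a_vecs) + 1]] <- pos[ka, ] - pos[k, ]
    kb <- match(paste(pl$i[k], pl$j[k] + 1), key)
    if (!is.na(kb)) b_vecs[[length(b_vecs) + 1]] <- pos[kb, ] - pos[k, ]
  }
  if (!length(a_vecs) || !length(b_vecs))
    stop("degenerate placements: cannot form cell vectors", call. = FALSE)
  a_vec <- colMeans(do.call(rbind, a_vecs))
  b_vec <- colMeans(do.call(rbind, b_vecs))
  if (vnorm(a_vec) < 1e-6 || vnorm(b_vec) < 1e-6)
    stop("degenerate placements: zero-length cell vector", call. = FALSE)
  ang <- acos(max(-1, min(1, sum(unit(a_vec) * unit(b_vec))))) * 180 / pi
  list(a = ang_to_nm(vnorm(a_vec)), b = ang_to_nm(vnorm(b_vec)), angle = ang)
}
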