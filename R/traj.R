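#' Frame sets
#'
#' A frame set is an ordered collection of coordinate snapshots over a
#' fixed atom topology: `topology` (atom tibble), `xyz` (array
#' n_atoms x 3 x n_frames, Angstrom), `time_step` (ns between frames),
#' `interface_normal` (fixed lab-frame unit vector, +z by convention) and
#' optional periodic `box` (length-3, Angstrom). Frames can come from a
#' multi-model PDB ([read_frames()]) or the synthetic generator.
#'
#' @param topology atom tibble.
#' @param xyz numeric array `n_atoms x 3 x n_frames`.
#' @param time_step ns per frame (> 0).
#' @param interface_normal lab-frame normal of the interface plane.
#' @param box optional periodic box dimensions, Angstrom.
#' @return An object of class `fl_frames`.
#' @export
frame_set <- function(topology, xyz, time_step = 1,
                      interface_normal = c(0, 0, 1), box = NULL) {
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3)
  if (dim(xyz)[1] != nrow(topology))
    stop("xyz first dimension must match the topology atom count", call. = FALSE)
  if (time_step <= 0) stop("time_step must be > 0", call. = FALSE)
  structure(list(topology = topology, xyz = xyz, time_step = time_step,
                 interface_normal = unit(interface_normal), box = box),
            class = "fl_frames")
}

#' @export
print.fl_frames <- function(x, ...) {
  cat(sprintf("<frames> %d frames x %d atoms, dt %.3g ns\n",
              dim(x$xyz)[3], dim(x$xyz)[1], x$time_step))
  invisible(x)
}

#' Read a multi-model PDB as a frame set
#'
#' @param path multi-model PDB file.
#' @param time_step ns per frame.
#' @param interface_normal lab-frame interface normal.
#' @return An `fl_frames`.
#' @export
read_frames <- function(path, time_step = 1, interface_normal = c(0, 0, 1)) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  topo <- read_structure(path)
  nf <- nrow(pdb$xyz)
  xyz <- array(0, c(nrow(topo), 3, nf))
  for (f in seq_len(nf)) xyz[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  frame_set(topo, xyz, time_step, interface_normal)
}

sel_index <- function(frames, sel) {
  topo <- frames$topology
  if (is.logical(sel)) which(sel)
  else if (is.numeric(sel)) as.integer(sel)
  else which(topo$chain %in% sel)
}

#' Orientation of a body axis relative to the interface normal
#'
#' The body axis is defined by two atom groups (tail -> head, e.g. the
#' structural core -> the hydrophobic cap): per frame, the angle between
#' the vector joining the group centroids and the fixed interface normal.
#'
#' @param frames an `fl_frames`.
#' @param tail_sel,head_sel atom selections (chain ids, atom indices or a
#'   logical mask over the topology).
#' @return A tibble with `frame`, `time` (ns), `angle` (degrees in
#'   `[0, 180]`).
#' @export
orientation_series <- function(frames, tail_sel, head_sel) {
  it <- sel_index(frames, tail_sel); ih <- sel_index(frames, head_sel)
  if (!length(it) || !length(ih)) stop("empty atom group", call. = FALSE)
  nf <- dim(frames$xyz)[3]
  nrm <- frames$interface_normal
  grp <- function(idx, f) colMeans(matrix(frames$xyz[idx, , f], ncol = 3))
  ang <- vapply(seq_len(nf), function(f) {
    v <- grp(ih, f) - grp(it, f)
    acos(max(-1, min(1, sum(unit(v) * nrm)))) * 180 / pi
  }, numeric(1))
  tibble::tibble(frame = seq_len(nf), time = (seq_len(nf) - 1) * frames$time_step,
                 angle = ang)
}

# centre of mass with standard atomic masses
atomic_mass <- function(element) {
  tab <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
           P = 30.974, S = 32.06, SE = 78.97)
  m <- unname(tab[toupper(element)])
  m[is.na(m)] <- 12.011
  m
}

#' Inter-group separation per frame
#'
#' Centre-of-mass distance between two disjoint atom groups, per frame, in
#' nm; the minimum-image convention is applied when the frame set carries a
#' periodic box.
#'
#' @param frames an `fl_frames`.
#' @param sel_a,sel_b disjoint atom selections.
#' @return A tibble with `frame`, `time` (ns), `distance` (nm).
#' @export
separation_series <- function(frames, sel_a, sel_b) {
  ia <- sel_index(frames, sel_a); ib <- sel_index(frames, sel_b)
  if (length(intersect(ia, ib))) stop("overlapping selections", call. = FALSE)
  if (!length(ia) || !length(ib)) stop("empty atom group", call. = FALSE)
  ma <- atomic_mass(frames$topology$element[ia])
  mb <- atomic_mass(frames$topology$element[ib])
  nf <- dim(frames$xyz)[3]
  d <- vapply(seq_len(nf), function(f) {
    ca <- colSums(matrix(frames$xyz[ia, , f], ncol = 3) * ma) / sum(ma)
    cb <- colSums(matrix(frames$xyz[ib, , f], ncol = 3) * mb) / sum(mb)
    dv <- cb - ca
    if (!is.null(frames$box)) dv <- dv - frames$box * round(dv / frames$box)
    vnorm(dv)
  }, numeric(1))
  tibble::tibble(frame = seq_len(nf), time = (seq_len(nf) - 1) * frames$time_step,
                 distance = ang_to_nm(d))
}

#' Detect a dissociation event in a separation series
#'
#' The baseline is the first `baseline_window` frames. The event is the
#' first frame whose distance exceeds baseline mean +
#' `threshold_multiplier` x baseline SD and never returns below that level
#' afterwards; `NA` when no such frame exists (stable dimer).
#'
#' @param distances numeric vector of distances (any unit), or a tibble
#'   with a `distance` column.
#' @param baseline_window number of initial frames defining the baseline.
#' @param threshold_multiplier SD multiplier (default 5).
#' @return The event frame index, or `NA_integer_`.
#' @export
detect_dissociation <- function(distances, baseline_window = 100,
                                threshold_multiplier = 5) {
  if (is.data.frame(distances)) distances <- distances$distance
  n <- length(distances)
  if (n <= baseline_window)
    stop("series not longer than the baseline window", call. = FALSE)
  base <- distances[seq_len(baseline_window)]
  thr <- mean(base) + threshold_multiplier * stats::sd(base)
  above <- distances > thr
  # last frame at/below threshold; the event must start after it
  last_below <- max(which(!above), 0L)
  if (last_below >= n) return(NA_integer_)
  cand <- which(above & seq_len(n) > last_below)
  if (!length(cand)) NA_integer_ else as.integer(min(cand))
}

#' Contact occupancy of an atom pair across frames
#'
#' Fraction of frames with the inter-atom distance at or below `cutoff`
#' (4 Angstrom by default: the salt-bridge criterion between a carboxylate
#' carbon and an ammonium nitrogen).
#'
#' @param frames an `fl_frames`.
#' @param atom_i,atom_j single atom indices into the topology, or a
#'   `list(chain=, res_seq=, atom_name=)` locator.
#' @param cutoff Angstrom (default 4.0).
#' @return Occupancy fraction in `[0, 1]`.
#' @export
contact_occupancy <- function(frames, atom_i, atom_j, cutoff = 4.0) {
  locate <- function(a) {
    if (is.numeric(a)) return(as.integer(a))
    topo <- frames$topology
    idx <- which(topo$chain == a$chain & topo$res_seq == a$res_seq &
                   topo$atom_name == a$atom_name)
    if (length(idx) != 1) stop("atom not found (or ambiguous) in topology",
                               call. = FALSE)
    idx
  }
  i <- locate(atom_i); j <- locate(atom_j)
  if (i > dim(frames$xyz)[1] || j > dim(frames$xyz)[1])
    stop("atom index outside topology", call. = FALSE)
  dv <- frames$xyz[i, , ] - frames$xyz[j, , ]
  if (!is.null(frames$box)) dv <- dv - frames$box * round(dv / frames$box)
  d <- sqrt(colSums(dv^2))
  mean(d <= cutoff)
}

#' PMF profiles
#'
#' Tabulated free energy vs. separation: `r` (nm, strictly increasing),
#' `w` (kcal/mol, anchored to 0 at and beyond `r_unbound`), `w_err`
#' (per-point uncertainty).
#'
#' @param r,w,w_err numeric vectors of equal length.
#' @param r_unbound reference (unbound) distance, nm; defaults to `max(r)`.
#' @return A tibble of class `fl_pmf` with attribute `r_unbound`.
#' @export
pmf_profile <- function(r, w, w_err = 0, r_unbound = max(r)) {
  if (any(diff(r) <= 0)) stop("r must be strictly increasing", call. = FALSE)
  out <- tibble::tibble(r = r, w = w,
                        w_err = rep_len(w_err, length(r)))
  attr(out, "r_unbound") <- r_unbound
  class(out) <- c("fl_pmf", class(out))
  out
}

#' Standard binding free energy from a PMF
#'
#' Integrates the bound-state configuration integral along the 1D
#' separation coordinate and normalizes by a standard-state length:
#' `dG = kT * ln( integral_0^r_bound_max exp(-W(r)/kT) dr / delta0 )`,
#' with W anchored to 0 in the unbound region. The sign convention reports
#' a binding strength: positive dG = favourable binding. `delta0` is the
#' cube root of the volume per molecule at 1 M (11.86 Angstrom = 1.186 nm)
#' applied along the single pulled coordinate; 1D, 2D and 3D binding free
#' energies are not directly comparable, so the convention is explicit and
#' configurable. Uncertainty is first-order propagation of the per-point
#' PMF errors through the Boltzmann weights.
#'
#' @param pmf an `fl_pmf` (see [pmf_profile()], [make_pmf()]).
#' @param r_bound_max nm; upper limit of the bound region (must be below
#'   the unbound reference distance).
#' @param temperature K (default 300).
#' @param delta0 standard-state length in nm (default 1.186).
#' @return A tibble with `dg` and `dg_err` (kcal/mol), plus the convention
#'   fields `delta0`, `temperature`, `r_bound_max`.
#' @export
delta_g_bind <- function(pmf, r_bound_max, temperature = 300, delta0 = 1.186) {
  kT <- 0.0019872 * temperature
  r_unbound <- attr(pmf, "r_unbound") %||% max(pmf$r)
  if (r_bound_max >= r_unbound)
    stop("r_bound_max must be below the unbound reference distance", call. = FALSE)
  tail_w <- pmf$w[pmf$r >= r_unbound - 1e-9]
  tail_err <- pmf$w_err[pmf$r >= r_unbound - 1e-9]
  if (length(tail_w) && any(abs(tail_w) > pmax(3 * tail_err, 1e-6)))
    stop("PMF is not anchored: |W(r_unbound)| exceeds 3 x its uncertainty",
         call. = FALSE)
  sel <- pmf$r <= r_bound_max + 1e-12
  if (sum(sel) < 2) stop("PMF does not resolve the bound region", call. = FALSE)
  r <- pmf$r[sel]; w <- pmf$w[sel]; werr <- pmf$w_err[sel]
  f <- exp(-w / kT)
  # trapezoid weights
  dr <- diff(r)
  tw <- c(dr / 2, 0) + c(0, dr / 2)
  Z <- sum(tw * f)
  dg <- kT * log(Z / delta0)
  # d(dg)/d(w_i) = -tw_i f_i / Z ; independent point errors
  dg_err <- sqrt(sum((tw * f / Z)^2 * werr^2))
  tibble::tibble(dg = dg, dg_err = dg_err, delta0 = delta0,
                 temperature = temperature, r_bound_max = r_bound_max)
}
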