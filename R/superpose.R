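#' Kabsch rigid-body superposition
#'
#' Finds the proper rotation + translation minimizing the least-squares
#' deviation of `moving` onto `fixed` (SVD of the cross-covariance with the
#' determinant sign correction, so a reflection is never returned even for
#' mirror-image inputs). RMSD is reported over all input pairs.
#'
#' @param moving,fixed n x 3 coordinate matrices, or atom tibbles with the
#'   same number of atoms in matched order.
#' @return An object of class `fl_superposition`: list with `transform`
#'   (a [rigid_transform()] mapping moving onto fixed), `rmsd` (Angstrom),
#'   `n_pairs`, `pair_list` (`NULL` for raw coordinate input), `trimmed`.
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' kabsch(p, p)$rmsd
#' @export
kabsch <- function(moving, fixed) {
  if (is.data.frame(moving)) moving <- coords(moving)
  if (is.data.frame(fixed)) fixed <- coords(fixed)
  if (nrow(moving) != nrow(fixed))
    stop("mismatched coordinate lengths: ", nrow(moving), " vs ", nrow(fixed),
         call. = FALSE)
  n <- nrow(moving)
  if (n < 3) stop("need at least 3 atom pairs for superposition", call. = FALSE)
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  # collinearity check: second singular value of the centered cloud
  if (svd(A, nu = 0, nv = 0)$d[2] < 1e-8)
    stop("degenerate (collinear) coordinates: rotation is underdetermined",
         call. = FALSE)
  H <- crossprod(A, B)            # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cf - as.numeric(R %*% cm)
  tr <- rigid_transform(R, t)
  dev <- transform_apply(tr, moving) - fixed
  res <- list(transform = tr,
              rmsd = sqrt(mean(rowSums(dev^2))),
              n_pairs = n, pair_list = NULL, trimmed = FALSE)
  class(res) <- "fl_superposition"
  res
}

#' @export
print.fl_superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.3f A over %d pairs%s\n", x$rmsd,
              x$n_pairs, if (isTRUE(x$trimmed)) " (trimmed)" else ""))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
glance.fl_superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_pairs = x$n_pairs,
                 trimmed = isTRUE(x$trimmed),
                 rotation_angle_deg = transform_axis_angle(x$transform)$angle_deg)
}

#' @export
tidy.fl_superposition <- function(x, ...) {
  if (is.null(x$pair_list)) return(tibble::tibble())
  x$pair_list
}

#' Match residues of two chains by global sequence alignment
#'
#' Aligns the one-letter sequences of two chains (Needleman-Wunsch with free
#' end gaps, BLOSUM62, gap open 10 / extend 0.5) and returns the aligned
#' residue pairs restricted to Calpha-bearing residues. At the 48-50%
#' identity typical of the paralogue pairs this package targets, any
#' standard parameterization recovers the same core pairing.
#'
#' @param atoms_a,atoms_b atom tibbles.
#' @param chain_a,chain_b chain ids.
#' @return A tibble with columns `res_a`, `ins_a`, `aa_a`, `res_b`, `ins_b`,
#'   `aa_b`, one row per aligned residue pair.
#' @export
match_residues <- function(atoms_a, chain_a, atoms_b, chain_b) {
  ca_a <- select_atoms(atoms_a, chain = chain_a, atom_names = "CA", drop_het = TRUE)
  ca_b <- select_atoms(atoms_b, chain = chain_b, atom_names = "CA", drop_het = TRUE)
  if (nrow(ca_a) == 0 || nrow(ca_b) == 0)
    stop("empty chain in match_residues", call. = FALSE)
  seq_a <- paste(aa_three_to_one(ca_a$res_name), collapse = "")
  seq_b <- paste(aa_three_to_one(ca_b$res_name), collapse = "")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "overlap", substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- Biostrings::start(Biostrings::pattern(al)) - 1L
  ib <- Biostrings::start(Biostrings::subject(al)) - 1L
  rows <- list()
  for (k in seq_along(pa)) {
    ga <- pa[k] == "-"; gb <- pb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) rows[[length(rows) + 1L]] <- c(ia, ib)
  }
  idx <- do.call(rbind, rows)
  tibble::tibble(
    res_a = ca_a$res_seq[idx[, 1]], ins_a = ca_a$ins[idx[, 1]],
    aa_a = aa_three_to_one(ca_a$res_name[idx[, 1]]),
    res_b = ca_b$res_seq[idx[, 2]], ins_b = ca_b$ins[idx[, 2]],
    aa_b = aa_three_to_one(ca_b$res_name[idx[, 2]])
  )
}

# Calpha coordinate matrices for a pair list (rows aligned).
pair_ca_coords <- function(atoms_a, chain_a, atoms_b, chain_b, pairs) {
  ca_a <- select_atoms(atoms_a, chain = chain_a, atom_names = "CA", drop_het = TRUE)
  ca_b <- select_atoms(atoms_b, chain = chain_b, atom_names = "CA", drop_het = TRUE)
  key_a <- paste(ca_a$res_seq, ca_a$ins); key_b <- paste(ca_b$res_seq, ca_b$ins)
  ia <- match(paste(pairs$res_a, pairs$ins_a), key_a)
  ib <- match(paste(pairs$res_b, pairs$ins_b), key_b)
  ok <- !is.na(ia) & !is.na(ib)
  list(a = coords(ca_a)[ia[ok], , drop = FALSE],
       b = coords(ca_b)[ib[ok], , drop = FALSE],
       pairs = pairs[ok, ])
}

#' Iterative superposition with outlier rejection
#'
#' Superposes chain `a` onto chain `b` over sequence-matched Calpha pairs,
#' then repeatedly drops pairs whose post-fit distance exceeds
#' `reject_cutoff` and refits, until the retained set stops changing. This
#' reproduces the usual "core" RMSD of structure-comparison servers:
#' flexible loops and termini are trimmed, the conserved fold remains.
#'
#' @param atoms_a,atoms_b atom tibbles (moving and fixed).
#' @param chain_a,chain_b chain ids.
#' @param reject_cutoff post-fit distance cutoff in Angstrom (default 3.5;
#'   `Inf` reproduces a plain Kabsch fit over all matched pairs).
#' @param max_cycles safety bound on refit cycles.
#' @return An `fl_superposition`; `pair_list` holds the surviving pairs with
#'   their final distances, `rmsd`/`n_pairs` refer to the surviving set.
#' @export
iterative_superpose <- function(atoms_a, chain_a, atoms_b, chain_b,
                                reject_cutoff = 3.5, max_cycles = 50) {
  pairs <- match_residues(atoms_a, chain_a, atoms_b, chain_b)
  if (nrow(pairs) < 10)
    stop("fewer than 10 matched residue pairs; chains are not alignable",
         call. = FALSE)
  pc <- pair_ca_coords(atoms_a, chain_a, atoms_b, chain_b, pairs)
  keep <- rep(TRUE, nrow(pc$a))
  fit <- NULL
  for (cycle in seq_len(max_cycles)) {
    fit <- kabsch(pc$a[keep, , drop = FALSE], pc$b[keep, , drop = FALSE])
    d <- sqrt(rowSums((transform_apply(fit$transform, pc$a) - pc$b)^2))
    new_keep <- d <= reject_cutoff
    if (sum(new_keep) < 3)
      stop("iterative superposition diverged: fewer than 3 pairs within cutoff",
           call. = FALSE)
    if (identical(new_keep, keep)) {
      out <- fit
      out$pair_list <- dplyr::mutate(pc$pairs[keep, ], distance = d[keep])
      out$n_pairs <- sum(keep)
      out$trimmed <- any(!keep)
      return(out)
    }
    keep <- new_keep
    if (cycle == max_cycles)
      stop("iterative superposition failed to converge after ", max_cycles,
           " cycles (", sum(keep), " pairs retained)", call. = FALSE)
  }
}

#' Pairwise sequence identity over a residue pairing
#'
#' @param pairs a pair tibble from [match_residues()] or the `pair_list` of
#'   an [iterative_superpose()] result.
#' @return Percent identity (identical pairs / total pairs * 100).
#' @export
pairwise_identity <- function(pairs) {
  if (nrow(pairs) == 0) stop("empty pair list", call. = FALSE)
  100 * mean(pairs$aa_a == pairs$aa_b)
}

#' All-against-all chain RMSD matrix
#'
#' Plain Kabsch RMSD between every pair of chains of one model, over
#' sequence-matched Calpha pairs (`atom_set = "calpha"`) or over all heavy
#' atoms shared by matched residues with identical atom names
#' (`atom_set = "all"`).
#'
#' @param atoms atom tibble.
#' @param chains chain ids to compare (default: all chains present).
#' @param atom_set `"calpha"` or `"all"`.
#' @return Symmetric matrix of RMSDs (Angstrom) with zero diagonal.
#' @export
chain_rmsd_matrix <- function(atoms, chains = NULL, atom_set = c("calpha", "all")) {
  atom_set <- match.arg(atom_set)
  chains <- chains %||% unique(atoms$chain[!atoms$is_het])
  n <- length(chains)
  m <- matrix(0, n, n, dimnames = list(chains, chains))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pairs <- match_residues(atoms, chains[i], atoms, chains[j])
    if (atom_set == "calpha") {
      pc <- pair_ca_coords(atoms, chains[i], atoms, chains[j], pairs)
      r <- kabsch(pc$a, pc$b)$rmsd
    } else {
      ab <- shared_atom_coords(atoms, chains[i], atoms, chains[j], pairs)
      r <- kabsch(ab$a, ab$b)$rmsd
    }
    m[i, j] <- m[j, i] <- r
  }
  m
}

# Heavy atoms shared (same atom name) by paired residues, matched order.
shared_atom_coords <- function(atoms_a, chain_a, atoms_b, chain_b, pairs) {
  sa <- select_atoms(atoms_a, chain = chain_a, heavy_only = TRUE, drop_het = TRUE)
  sb <- select_atoms(atoms_b, chain = chain_b, heavy_only = TRUE, drop_het = TRUE)
  la <- list(); lb <- list()
  for (k in seq_len(nrow(pairs))) {
    ra <- sa[sa$res_seq == pairs$res_a[k] & sa$ins == pairs$ins_a[k], ]
    rb <- sb[sb$res_seq == pairs$res_b[k] & sb$ins == pairs$ins_b[k], ]
    common <- intersect(ra$atom_name, rb$atom_name)
    if (length(common) == 0) next
    la[[length(la) + 1]] <- coords(ra[match(common, ra$atom_name), ])
    lb[[length(lb) + 1]] <- coords(rb[match(common, rb$atom_name), ])
  }
  list(a = do.call(rbind, la), b = do.call(rbind, lb))
}
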