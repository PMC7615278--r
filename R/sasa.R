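#' Van der Waals radii used for SASA (Angstrom)
#'
#' C 1.70, N 1.55, O 1.52, S 1.80, P 1.80; anything else falls back to 1.70
#' unless `strict = TRUE`.
#' @noRd
vdw_radius <- function(element, strict = FALSE) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           H = 1.20, D = 1.20, SE = 1.90)
  r <- unname(tab[toupper(element)])
  if (any(is.na(r))) {
    if (strict)
      stop("no van der Waals radius for element(s): ",
           paste(unique(element[is.na(r)]), collapse = ", "), call. = FALSE)
    r[is.na(r)] <- 1.70
  }
  r
}

# Deterministic, near-uniform unit sphere points (golden-spiral / Fibonacci
# lattice). Same n always gives the same points, so SASA is reproducible.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals surface by uniform
#' sphere-point sampling: for each atom, points on a sphere of radius
#' r_vdw + probe are tested against all neighbouring spheres; the accessible
#' fraction times the sphere area is that atom's SASA. Deterministic for a
#' fixed `n_points` (golden-spiral point set).
#'
#' @param atoms atom tibble; hydrogens are excluded automatically (the
#'   calculation is a heavy-atom one, matching crystal structures).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 960).
#' @return An object of class `fl_sasa`: list with `per_atom` (Angstrom^2,
#'   aligned to the heavy atoms of the input in order), `atoms` (the heavy
#'   atom tibble used), `total`, `probe`, `n_points`.
#' @export
compute_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  heavy <- atoms[atoms$is_heavy, ]
  n <- nrow(heavy)
  if (n == 0) stop("no heavy atoms", call. = FALSE)
  xyz <- coords(heavy)
  radii <- vdw_radius(heavy$element) + probe
  pts <- sphere_points(n_points)
  # neighbour lists via cell hashing on the maximum interaction distance
  rmax <- max(radii)
  nb <- neighbor_pairs(xyz, 2 * rmax)
  nb_list <- split(c(nb[, 2], nb[, 1]), factor(c(nb[, 1], nb[, 2]), levels = seq_len(n)))
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    js <- nb_list[[i]]
    surf <- pts * radii[i]
    surf <- sweep(surf, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    if (length(js)) {
      # drop neighbours that cannot intersect this sphere
      dj <- sqrt(rowSums(sweep(xyz[js, , drop = FALSE], 2, xyz[i, ])^2))
      js <- js[dj < radii[i] + radii[js]]
      for (j in js) {
        if (!any(acc)) break
        d2 <- (surf[acc, 1] - xyz[j, 1])^2 + (surf[acc, 2] - xyz[j, 2])^2 +
          (surf[acc, 3] - xyz[j, 3])^2
        acc[acc] <- d2 >= radii[j]^2
      }
    }
    per_atom[i] <- 4 * pi * radii[i]^2 * mean(acc)
  }
  structure(list(per_atom = per_atom, atoms = heavy, total = sum(per_atom),
                 probe = probe, n_points = n_points),
            class = "fl_sasa")
}

#' @export
print.fl_sasa <- function(x, ...) {
  cat(sprintf("<sasa> %.1f A^2 over %d heavy atoms (probe %.2f, %d points)\n",
              x$total, length(x$per_atom), x$probe, x$n_points))
  invisible(x)
}

#' @export
tidy.fl_sasa <- function(x, ...) {
  dplyr::mutate(x$atoms[, c("chain", "res_seq", "ins", "res_name", "atom_name")],
                sasa = x$per_atom)
}

# All index pairs (i < j) closer than cutoff, via grid (cell-list) hashing;
# identical in content to an exhaustive O(n^2) scan.
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), 0, 2))
  cell <- max(cutoff, 1e-6)
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  kstr <- paste(key[, 1], key[, 2], key[, 3])
  buckets <- split(seq_len(n), kstr)
  first <- vapply(buckets, `[`, integer(1), 1L)
  bk <- key[first, , drop = FALSE]
  lookup <- stats::setNames(seq_along(buckets),
                            paste(bk[, 1], bk[, 2], bk[, 3]))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  # keep a half-space of offsets so each cell pair is visited once
  offs <- offs[offs[, 1] > 0 |
                 (offs[, 1] == 0 & (offs[, 2] > 0 |
                                      (offs[, 2] == 0 & offs[, 3] > 0))), ,
               drop = FALSE]
  out <- list()
  c2 <- cutoff^2
  for (b in seq_along(buckets)) {
    ii <- buckets[[b]]
    if (length(ii) > 1) {
      pr <- t(utils::combn(ii, 2))
      d2 <- rowSums((xyz[pr[, 1], , drop = FALSE] - xyz[pr[, 2], , drop = FALSE])^2)
      out[[length(out) + 1]] <- pr[d2 < c2, , drop = FALSE]
    }
    for (o in seq_len(nrow(offs))) {
      nb <- lookup[paste(bk[b, 1] + offs[o, 1], bk[b, 2] + offs[o, 2],
                         bk[b, 3] + offs[o, 3])]
      if (is.na(nb)) next
      jj <- buckets[[nb]]
      pr <- cbind(rep(ii, times = length(jj)), rep(jj, each = length(ii)))
      d2 <- rowSums((xyz[pr[, 1], , drop = FALSE] - xyz[pr[, 2], , drop = FALSE])^2)
      out[[length(out) + 1]] <- pr[d2 < c2, , drop = FALSE]
    }
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs) || nrow(pairs) == 0) return(matrix(integer(0), 0, 2))
  cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
}
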