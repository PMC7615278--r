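# Shared fixtures and independent oracles. Everything is generated in code;
# oracles use different algorithms than the implementation they check.

# quick atom tibble: one row per atom
mk_atoms <- function(chain, res_seq, res_name, atom_name, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  as_structure(tibble::tibble(
    chain = chain, res_seq = res_seq, res_name = res_name,
    atom_name = atom_name, element = substr(gsub("[0-9]", "", atom_name), 1, 1),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# cached toy structures (generation is the slow part of several tests)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}
toy12 <- function() cached("toy12", make_toy_protein(12, seed = 42))
standin1 <- function() cached("standin1", make_crystal_standin(seed = 1))

# Brute-force Shrake-Rupley with a *random* point set (independent of the
# implementation's deterministic golden spiral).
sasa_oracle <- function(atoms, probe = 1.4, n_pts = 1e5, seed = 123) {
  heavy <- atoms[atoms$is_heavy, ]
  xyz <- cbind(heavy$x, heavy$y, heavy$z)
  rad <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)[heavy$element]
  rad[is.na(rad)] <- 1.70
  rad <- rad + probe
  set.seed(seed)
  pts <- matrix(stats::rnorm(3 * n_pts), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2))
  out <- numeric(nrow(heavy))
  for (i in seq_len(nrow(heavy))) {
    surf <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_pts)
    di <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    for (j in which(di < rad[i] + rad)) {
      if (j == i) next
      d2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
        (surf[, 3] - xyz[j, 3])^2
      acc <- acc & d2 >= rad[j]^2
    }
    out[i] <- 4 * pi * rad[i]^2 * mean(acc)
  }
  out
}

# Exhaustive all-pairs clash scan.
clash_oracle <- function(atoms, cutoff = 2.5) {
  heavy <- atoms[atoms$is_heavy, ]
  xyz <- cbind(heavy$x, heavy$y, heavy$z)
  n <- nrow(xyz)
  hits <- 0L
  for (i in seq_len(n - 1)) {
    d2 <- rowSums(sweep(xyz[(i + 1):n, , drop = FALSE], 2, xyz[i, ])^2)
    near <- which(d2 < cutoff^2)
    if (length(near))
      hits <- hits + sum(heavy$chain[i] != heavy$chain[i + near])
  }
  hits
}

# Direct real-space averaging of an exactly tiled image (na x nb px cells).
cell_average_oracle <- function(grid, na, nb) {
  nx <- nrow(grid) %/% na
  ny <- ncol(grid) %/% nb
  acc <- matrix(0, na, nb)
  for (cx in seq_len(nx) - 1) for (cy in seq_len(ny) - 1)
    acc <- acc + grid[cx * na + seq_len(na), cy * nb + seq_len(nb)]
  acc / (nx * ny)
}

# A smooth two-blob motif on an exact pixel grid, used as the "protein"
# for image tests (near band-limited: negligible power beyond order ~6).
blob_motif <- function(px = 0.1, cell = c(2.0, 1.6)) {
  na <- round(cell[1] / px); nb <- round(cell[2] / px)
  xs <- (seq_len(na) - 1) * px
  ys <- (seq_len(nb) - 1) * px
  g <- outer(xs, ys, function(x, y)
    exp(-((x - 0.7)^2 + (y - 0.5)^2) / 0.08) +
      0.6 * exp(-((x - 1.4)^2 + (y - 1.1)^2) / 0.1))
  density_map(g, px)
}

unit_vec <- function(v) v / sqrt(sum(v^2))
vec_len <- function(v) sqrt(sum(v^2))

expect_rigid_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a$R - b$R)), tol)
  expect_lt(max(abs(a$t - b$t)), tol)
}
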