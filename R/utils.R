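# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream, restoring the caller's
# .Random.seed afterwards. All generators route randomness through this so
# identical specs give bit-identical output and no global state leaks.
with_private_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Extract an n x 3 coordinate matrix from an atom tibble.
coords <- function(atoms) {
  stopifnot(all(c("x", "y", "z") %in% names(atoms)))
  cbind(atoms$x, atoms$y, atoms$z)
}

set_coords <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}

centroid <- function(xyz) colMeans(xyz)

# Angstrom <-> nanometre conversion at the lattice/image boundary.
ang_to_nm <- function(x) x / 10
nm_to_ang <- function(x) x * 10
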