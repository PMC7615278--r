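#' 2D density maps
#'
#' A density map is a non-negative matrix with a physical pixel size in nm.
#' Rows index the first in-plane axis (x), columns the second (y), so
#' `grid[i, j]` sits at `origin + ((i-1) * px, (j-1) * px)` nm (pixel
#' centres). Shared representation of model projections, lattice images and
#' synthetic micrographs.
#'
#' @param grid numeric matrix, all values >= 0.
#' @param pixel_size nm per pixel (> 0).
#' @param origin 2-vector, nm position of pixel (1, 1).
#' @param provenance one of `"model_projection"`, `"tem_image"`,
#'   `"synthetic"`.
#' @return An object of class `fl_density`.
#' @export
density_map <- function(grid, pixel_size, origin = c(0, 0),
                        provenance = "synthetic") {
  grid <- as.matrix(grid)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (any(grid < 0)) stop("density values must be >= 0", call. = FALSE)
  structure(list(grid = grid, pixel_size = pixel_size,
                 origin = as.numeric(origin), provenance = provenance),
            class = "fl_density")
}

#' @export
print.fl_density <- function(x, ...) {
  cat(sprintf("<density_map %s> %d x %d px @ %.3f nm/px (%.1f x %.1f nm)\n",
              x$provenance, nrow(x$grid), ncol(x$grid), x$pixel_size,
              nrow(x$grid) * x$pixel_size, ncol(x$grid) * x$pixel_size))
  invisible(x)
}

#' @export
tidy.fl_density <- function(x, ...) {
  g <- x$grid
  tibble::tibble(
    x = x$origin[1] + (rep(seq_len(nrow(g)), times = ncol(g)) - 1) * x$pixel_size,
    y = x$origin[2] + (rep(seq_len(ncol(g)), each = nrow(g)) - 1) * x$pixel_size,
    density = as.numeric(g))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.fl_density <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

# Orthonormal in-plane basis (u, v) for a plane normal.
plane_basis <- function(normal) {
  n <- unit(normal)
  seed <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(seed - sum(seed * n) * n)
  v <- vector_cross(n, u)
  list(u = u, v = v, n = n)
}

#' Project heavy atoms to a 2D Gaussian density
#'
#' Each heavy atom contributes a unit-integral 2D Gaussian of standard
#' deviation `sigma` (Angstrom) centred at its in-plane coordinates; the
#' grid extends 3 sigma beyond the atoms so boundary loss is < 1%, and the
#' kernel is truncated at 4 sigma (mass loss < 1e-4). The grid sum
#' therefore approximates the heavy-atom count. All heavy atoms are
#' weighted equally unless `weight_by_z` is set, in which case atomic
#' numbers are used.
#'
#' @param model atom tibble, or an `fl_lattice`/`fl_zigzag` (expanded).
#' @param plane_normal projection direction (default +z).
#' @param pixel_size nm per pixel (default 0.2 = sigma/2 for the default
#'   kernel; must be <= sigma/2 for adequate sampling).
#' @param sigma Gaussian kernel standard deviation in Angstrom (default 4).
#' @param origin optional 2-vector (nm) forcing the grid origin.
#' @param size optional `c(nx, ny)` forcing the grid dimensions.
#' @param weight_by_z weight atoms by atomic number (default `FALSE`).
#' @return An `fl_density` with provenance `"model_projection"`.
#' @export
project_density <- function(model, plane_normal = c(0, 0, 1),
                            pixel_size = 0.2, sigma = 4.0,
                            origin = NULL, size = NULL, weight_by_z = FALSE) {
  if (inherits(model, c("fl_lattice", "fl_zigzag"))) model <- expand_lattice(model)
  heavy <- model[model$is_heavy, ]
  if (nrow(heavy) == 0) stop("no heavy atoms to project", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  sigma_nm <- ang_to_nm(sigma)
  if (pixel_size > sigma_nm / 2 + 1e-9)
    stop("pixel_size must be <= sigma/2 for adequate sampling", call. = FALSE)
  basis <- plane_basis(plane_normal)
  xyz <- coords(heavy)
  px <- ang_to_nm(xyz %*% basis$u)
  py <- ang_to_nm(xyz %*% basis$v)
  w <- if (weight_by_z) atomic_number(heavy$element) else rep(1, nrow(heavy))
  margin <- 3 * sigma_nm
  if (is.null(origin)) origin <- c(min(px) - margin, min(py) - margin)
  if (is.null(size)) {
    size <- c(ceiling((max(px) + margin - origin[1]) / pixel_size) + 1,
              ceiling((max(py) + margin - origin[2]) / pixel_size) + 1)
  }
  grid <- matrix(0, size[1], size[2])
  half <- ceiling(4 * sigma_nm / pixel_size)
  norm_const <- pixel_size^2 / (2 * pi * sigma_nm^2)
  for (k in seq_len(nrow(heavy))) {
    ic <- (px[k] - origin[1]) / pixel_size + 1
    jc <- (py[k] - origin[2]) / pixel_size + 1
    ii <- max(1, floor(ic) - half):min(size[1], ceiling(ic) + half)
    jj <- max(1, floor(jc) - half):min(size[2], ceiling(jc) + half)
    if (!length(ii) || !length(jj)) next
    dx2 <- ((ii - ic) * pixel_size)^2
    dy2 <- ((jj - jc) * pixel_size)^2
    grid[ii, jj] <- grid[ii, jj] +
      w[k] * norm_const * exp(-outer(dx2, dy2, `+`) / (2 * sigma_nm^2))
  }
  density_map(grid, pixel_size, origin, provenance = "model_projection")
}

atomic_number <- function(element) {
  tab <- c(H = 1, D = 1, C = 6, N = 7, O = 8, P = 15, S = 16, SE = 34)
  z <- unname(tab[toupper(element)])
  z[is.na(z)] <- 6
  z
}

#' Read a TIFF micrograph as a density map
#'
#' Grayscale TIFF images carry no physical scale, so the pixel size must be
#' supplied. Multi-channel images are averaged to one channel; values are
#' shifted to be non-negative.
#'
#' @param path TIFF file.
#' @param pixel_size nm per pixel.
#' @return An `fl_density` with provenance `"tem_image"`.
#' @export
read_tem_image <- function(path, pixel_size) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF images requires the 'tiff' package", call. = FALSE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  # readTIFF returns row = image y (top down); transpose to x-major grid
  g <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
  g <- g - min(g)
  density_map(g, pixel_size, provenance = "tem_image")
}

#' Write a density map as a grayscale TIFF
#'
#' Intensities are rescaled to the unit interval (TIFF carries no physical
#' units); the pixel size is not stored in the file.
#'
#' @param map an `fl_density`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_density_tiff <- function(map, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF images requires the 'tiff' package", call. = FALSE)
  g <- map$grid
  rng <- range(g)
  g <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  tiff::writeTIFF(t(g[, rev(seq_len(ncol(g))), drop = FALSE]), path)
  invisible(path)
}

#' Mirror a density map
#'
#' Flips the grid along the second in-plane axis (an involution:
#' `mirror_map(mirror_map(m))` is `m`). Needed because a film imaged from
#' the far side is the mirror image of the model projection.
#'
#' @param map an `fl_density`.
#' @return The mirrored `fl_density`.
#' @export
mirror_map <- function(map) {
  map$grid <- map$grid[, rev(seq_len(ncol(map$grid))), drop = FALSE]
  map
}

# round-trip note: read_tem_image(write_density_tiff(m)) recovers m up to
# the affine intensity rescaling, which correlation scoring is invariant to

#' Fold a projection onto one unit cell and tile it
#'
#' Wraps pixel coordinates modulo the cell and averages, producing the
#' lattice-averaged model motif; optionally tiles the folded cell
#' `n_tiles x n_tiles` for comparison with an averaged micrograph patch.
#' The cell is assumed aligned with the map axes (the frame produced by the
#' lattice module).
#'
#' @param map an `fl_density`.
#' @param cell `c(a, b)` cell edges in nm.
#' @param n_tiles tile count per axis (default 2).
#' @return An `fl_density` covering `n_tiles` cells per axis.
#' @export
fold_to_cell <- function(map, cell, n_tiles = 2) {
  px <- map$pixel_size
  na <- max(2, round(cell[1] / px)); nb <- max(2, round(cell[2] / px))
  g <- map$grid
  acc <- matrix(0, na, nb); cnt <- matrix(0, na, nb)
  ii <- ((seq_len(nrow(g)) - 1) %% na) + 1
  jj <- ((seq_len(ncol(g)) - 1) %% nb) + 1
  for (j in seq_len(ncol(g))) {
    col_acc <- tapply(g[, j], ii, sum)
    idx <- as.integer(names(col_acc))
    acc[idx, jj[j]] <- acc[idx, jj[j]] + col_acc
    cnt[idx, jj[j]] <- cnt[idx, jj[j]] + tabulate(ii, nbins = na)[idx]
  }
  cellg <- acc / pmax(cnt, 1)
  tiled <- cellg[rep(seq_len(na), n_tiles), rep(seq_len(nb), n_tiles)]
  density_map(tiled, px, c(0, 0), provenance = map$provenance)
}
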