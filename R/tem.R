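#' Locate reciprocal-lattice peaks of a periodic image
#'
#' Computes the discrete Fourier transform of the image. If the unit cell is
#' known (or expected), peaks are read at the frequency bins nearest the
#' predicted reciprocal-lattice points h a* + k b* for |h|,|k| <= n_orders.
#' Otherwise candidate peaks are detected as local maxima whose amplitude
#' exceeds the noise floor of their radial annulus (mean + 5 SD), and the
#' two shortest independent candidate vectors define the cell estimate.
#' Cell axes are assumed aligned with the image axes (rectangular cell),
#' which is the frame every map in this package is produced in.
#'
#' @param image an `fl_density`, at least ~4 cells across per direction.
#' @param expected_cell optional `c(a, b)` in nm (angle 90 assumed).
#' @param n_orders maximum |h|, |k| retained (default 3).
#' @return An object of class `fl_peaks`: list with `peaks` (tibble: h, k,
#'   fx, fy (nm^-1), amplitude, phase, bin_i, bin_j), `cell_estimate`
#'   (`c(a, b)` nm), `dims`, `pixel_size`.
#' @export
find_reciprocal_peaks <- function(image, expected_cell = NULL, n_orders = 3) {
  g <- image$grid
  n1 <- nrow(g); n2 <- ncol(g)
  px <- image$pixel_size
  FT <- stats::fft(g)
  amp <- Mod(FT)
  if (is.null(expected_cell)) {
    expected_cell <- estimate_cell_from_fft(amp, n1, n2, px)
  }
  a <- expected_cell[1]; b <- expected_cell[2]
  if (n1 * px < 4 * a || n2 * px < 4 * b)
    warning("image covers fewer than 4 cells per direction; peak bins are coarse")
  hk <- expand.grid(h = -n_orders:n_orders, k = -n_orders:n_orders)
  hk <- hk[!(hk$h == 0 & hk$k == 0), ]
  rows <- list()
  for (r in seq_len(nrow(hk))) {
    h <- hk$h[r]; k <- hk$k[r]
    m1 <- round(h / a * n1 * px) %% n1
    m2 <- round(k / b * n2 * px) %% n2
    rows[[r]] <- tibble::tibble(
      h = h, k = k,
      fx = ifelse(m1 <= n1 / 2, m1, m1 - n1) / (n1 * px),
      fy = ifelse(m2 <= n2 / 2, m2, m2 - n2) / (n2 * px),
      amplitude = amp[m1 + 1, m2 + 1], phase = Arg(FT[m1 + 1, m2 + 1]),
      bin_i = m1 + 1L, bin_j = m2 + 1L)
  }
  peaks <- dplyr::bind_rows(rows)
  structure(list(peaks = peaks, cell_estimate = c(a = a, b = b),
                 dims = c(n1, n2), pixel_size = px),
            class = "fl_peaks")
}

# Blind cell estimate: strongest non-DC local maxima above their annulus
# noise floor; shortest independent vectors give the reciprocal basis.
estimate_cell_from_fft <- function(amp, n1, n2, px) {
  fx <- ifelse(seq_len(n1) - 1 <= n1 / 2, seq_len(n1) - 1,
               seq_len(n1) - 1 - n1) / (n1 * px)
  fy <- ifelse(seq_len(n2) - 1 <= n2 / 2, seq_len(n2) - 1,
               seq_len(n2) - 1 - n2) / (n2 * px)
  fr <- sqrt(outer(fx^2, fy^2, `+`))
  a <- amp
  a[1, 1] <- 0                      # drop DC
  # local maxima in a 3x3 neighbourhood (cyclic)
  sh <- function(m, di, dj) {
    m[(seq_len(n1) - 1 + di) %% n1 + 1, (seq_len(n2) - 1 + dj) %% n2 + 1]
  }
  ismax <- a > 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (a >= sh(a, di, dj))
  }
  # annulus noise floor per candidate; a relative amplitude floor first
  # discards numerically-zero bins that would otherwise look locally maximal
  cand <- which(ismax & a > 1e-6 * max(a), arr.ind = TRUE)
  if (nrow(cand) == 0)
    stop("no detectable lattice: no reciprocal peaks above the noise floor",
         call. = FALSE)
  cand <- cand[order(a[cand], decreasing = TRUE)[seq_len(min(40, nrow(cand)))], ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    f0 <- fr[cand[r, 1], cand[r, 2]]
    ann <- abs(fr - f0) < 1.5 / (min(n1, n2) * px)
    vals <- a[ann]
    vals <- vals[vals < a[cand[r, 1], cand[r, 2]]]
    if (length(vals) < 8) next
    keep[r] <- a[cand[r, 1], cand[r, 2]] > mean(vals) + 5 * stats::sd(vals)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    stop("no detectable lattice: no reciprocal peaks above the noise floor",
         call. = FALSE)
  vecs <- cbind(fx[cand[, 1]], fy[cand[, 2]])
  len <- sqrt(rowSums(vecs^2))
  ord <- order(len)
  v1 <- vecs[ord[1], ]
  v2 <- NULL
  for (r in ord[-1]) {
    v <- vecs[r, ]
    cross <- abs(v1[1] * v[2] - v1[2] * v[1])
    if (cross > 1e-6 * vnorm(v1) * vnorm(v)) { v2 <- v; break }
  }
  # axis-aligned rectangular cell: report periods along each image axis
  a_est <- 1 / vnorm(v1)
  b_est <- if (is.null(v2)) NA_real_ else 1 / vnorm(v2)
  if (is.na(b_est))
    stop("no detectable lattice: only one independent reciprocal vector found",
         call. = FALSE)
  # order as (x period, y period) when vectors are axis-aligned
  if (abs(v1[1]) >= abs(v1[2])) c(a_est, b_est) else c(b_est, a_est)
}

#' Lattice-average an image over its unit cells
#'
#' Keeps only the Fourier coefficients at the selected reciprocal-lattice
#' bins (plus DC), zeroes everything else, and inverse-transforms. This is
#' equivalent to averaging the motif over all unit cells (noise is
#' suppressed by roughly the square root of the cell count). The filtered
#' image is resampled (bilinear, periodic) onto a `n_tiles x n_tiles`-cell
#' patch. The operation is linear in the input image; tiny negative
#' excursions from the truncated Fourier series are clipped to zero.
#'
#' @param image an `fl_density`.
#' @param peaks an `fl_peaks` from [find_reciprocal_peaks()].
#' @param n_tiles cells per axis of the output patch (default 2).
#' @return An object of class `fl_cell_average`: list with `map`
#'   (`fl_density`), `cell` (nm), `n_orders`.
#' @export
average_unit_cell <- function(image, peaks, n_tiles = 2) {
  if (nrow(peaks$peaks) == 0) stop("empty peak set", call. = FALSE)
  g <- image$grid
  FT <- stats::fft(g)
  mask <- matrix(FALSE, nrow(g), ncol(g))
  mask[1, 1] <- TRUE
  mask[cbind(peaks$peaks$bin_i, peaks$peaks$bin_j)] <- TRUE
  FT[!mask] <- 0
  filt <- Re(stats::fft(FT, inverse = TRUE)) / length(g)
  filt[filt < 0] <- 0
  px <- image$pixel_size
  cell <- peaks$cell_estimate
  na <- max(2, round(cell[1] / px)); nb <- max(2, round(cell[2] / px))
  patch <- resample_periodic(filt, px,
                             nx = n_tiles * na, ny = n_tiles * nb,
                             new_px = px)
  structure(list(map = density_map(patch, px, c(0, 0), provenance = image$provenance),
                 cell = cell,
                 n_orders = max(abs(c(peaks$peaks$h, peaks$peaks$k)))),
            class = "fl_cell_average")
}

# Bilinear sampling of a matrix treated as cyclic, at a new pixel grid.
resample_periodic <- function(g, px, nx, ny, new_px) {
  n1 <- nrow(g); n2 <- ncol(g)
  xs <- (seq_len(nx) - 1) * new_px / px
  ys <- (seq_len(ny) - 1) * new_px / px
  i0 <- floor(xs); fx <- xs - i0
  j0 <- floor(ys); fy <- ys - j0
  i1 <- (i0 %% n1) + 1; i2 <- ((i0 + 1) %% n1) + 1
  j1 <- (j0 %% n2) + 1; j2 <- ((j0 + 1) %% n2) + 1
  g11 <- g[i1, j1, drop = FALSE]; g21 <- g[i2, j1, drop = FALSE]
  g12 <- g[i1, j2, drop = FALSE]; g22 <- g[i2, j2, drop = FALSE]
  wx <- matrix(1 - fx, nx, ny); wy <- matrix(1 - fy, nx, ny, byrow = TRUE)
  g11 * wx * wy + g21 * (1 - wx) * wy + g12 * wx * (1 - wy) +
    g22 * (1 - wx) * (1 - wy)
}

#' Score a model projection against an averaged unit cell
#'
#' Pearson correlation over all pixels, maximized over every cyclic
#' in-plane translation (pixel step, exhaustive via FFT cross-correlation)
#' and, when enabled, over the mirror and 180-degree-rotation settings.
#' The p-value comes from the t statistic with n_pixels - 2 degrees of
#' freedom; note that smoothing inflates these degrees of freedom, so the
#' p-value is reported for completeness, never used as a gate.
#'
#' @param cell_avg an `fl_cell_average` (or `fl_density`).
#' @param model_map an `fl_density` (model projection patch).
#' @param try_mirror also try the mirrored model (default `TRUE`).
#' @param try_180 also try the 180-degree-rotated model (default `TRUE`).
#' @return An object of class `fl_correlation`: list with `r`, `p_value`,
#'   `best_shift` (nm), `mirrored`, `rotated_180`, `n_pixels`, `settings`
#'   (tibble of every tried setting and its best r).
#' @export
score_model <- function(cell_avg, model_map, try_mirror = TRUE, try_180 = TRUE) {
  ref <- if (inherits(cell_avg, "fl_cell_average")) cell_avg$map else cell_avg
  px <- max(ref$pixel_size, model_map$pixel_size)
  nx <- min(floor(nrow(ref$grid) * ref$pixel_size / px),
            floor(nrow(model_map$grid) * model_map$pixel_size / px))
  ny <- min(floor(ncol(ref$grid) * ref$pixel_size / px),
            floor(ncol(model_map$grid) * model_map$pixel_size / px))
  if (nx < 4 || ny < 4) stop("maps too small after resampling to a common grid",
                             call. = FALSE)
  A <- resample_periodic(ref$grid, ref$pixel_size, nx, ny, px)
  B0 <- resample_periodic(model_map$grid, model_map$pixel_size, nx, ny, px)
  settings <- expand.grid(mirrored = if (try_mirror) c(FALSE, TRUE) else FALSE,
                          rotated_180 = if (try_180) c(FALSE, TRUE) else FALSE)
  best <- NULL
  logs <- list()
  for (s in seq_len(nrow(settings))) {
    B <- B0
    if (settings$mirrored[s]) B <- B[, rev(seq_len(ncol(B))), drop = FALSE]
    if (settings$rotated_180[s])
      B <- B[rev(seq_len(nrow(B))), rev(seq_len(ncol(B))), drop = FALSE]
    cc <- cyclic_pearson(A, B)
    logs[[s]] <- tibble::tibble(mirrored = settings$mirrored[s],
                                rotated_180 = settings$rotated_180[s],
                                r = cc$r)
    if (is.null(best) || cc$r > best$r) {
      best <- c(cc, settings[s, ])
    }
  }
  n <- nx * ny
  r <- best$r
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(r = r, p_value = p,
                 best_shift = c(best$shift[1], best$shift[2]) * px,
                 mirrored = best$mirrored, rotated_180 = best$rotated_180,
                 n_pixels = n, settings = dplyr::bind_rows(logs)),
            class = "fl_correlation")
}

# Max Pearson r over all cyclic shifts of B relative to A, via FFT.
cyclic_pearson <- function(A, B) {
  n <- length(A)
  muA <- mean(A); muB <- mean(B)
  sdA <- stats::sd(as.numeric(A)) * sqrt((n - 1) / n)
  sdB <- stats::sd(as.numeric(B)) * sqrt((n - 1) / n)
  if (sdA == 0 || sdB == 0) return(list(r = 0, shift = c(0, 0)))
  cross <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE)) / n
  rmat <- (cross / n - muA * muB) / (sdA * sdB)
  ij <- which(rmat == max(rmat), arr.ind = TRUE)[1, ]
  list(r = max(rmat), shift = c(ij[1] - 1, ij[2] - 1))
}

#' @export
print.fl_correlation <- function(x, ...) {
  cat(sprintf("<correlation> r = %.3f (p = %.3g) shift (%.2f, %.2f) nm%s%s\n",
              x$r, x$p_value, x$best_shift[1], x$best_shift[2],
              if (x$mirrored) " mirrored" else "",
              if (x$rotated_180) " rot180" else ""))
  invisible(x)
}

#' @export
glance.fl_correlation <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value,
                 shift_x = x$best_shift[1], shift_y = x$best_shift[2],
                 mirrored = x$mirrored, rotated_180 = x$rotated_180,
                 n_pixels = x$n_pixels)
}
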