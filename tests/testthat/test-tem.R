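test_that("a pure cosine grating yields its period as the cell estimate", {
  px <- 0.1
  n <- 320
  xs <- (seq_len(n) - 1) * px
  g <- outer(xs, xs, function(x, y) 2 + cos(2 * pi * x / 4.0) +
               cos(2 * pi * y / 3.2))
  img <- density_map(g, px)
  pk <- find_reciprocal_peaks(img, n_orders = 1)
  expect_equal(unname(pk$cell_estimate[1]), 4.0, tolerance = 0.15)
  expect_equal(unname(pk$cell_estimate[2]), 3.2, tolerance = 0.15)
})

test_that("a synthetic lattice image built on a known cell is re-measured
          blind", {
  motif <- blob_motif()
  img <- make_lattice_image(motif, cell = c(2.0, 1.6), n_cells = c(10, 10))
  pk <- find_reciprocal_peaks(img, n_orders = 2)
  expect_equal(unname(pk$cell_estimate), c(2.0, 1.6), tolerance = 0.05)
})

test_that("pure noise raises a 'no detectable lattice' error", {
  set.seed(8)
  img <- density_map(matrix(abs(rnorm(128 * 128)), 128, 128), 0.1)
  expect_error(find_reciprocal_peaks(img), "no detectable lattice")
})

test_that("peak sets are closed under Friedel symmetry", {
  motif <- blob_motif()
  img <- make_lattice_image(motif, cell = c(2.0, 1.6), n_cells = c(8, 8))
  pk <- find_reciprocal_peaks(img, expected_cell = c(2.0, 1.6), n_orders = 2)
  key <- paste(pk$peaks$h, pk$peaks$k)
  expect_true(all(paste(-pk$peaks$h, -pk$peaks$k) %in% key))
  amp <- setNames(pk$peaks$amplitude, key)
  expect_equal(unname(amp[paste(1, 1)]), unname(amp[paste(-1, -1)]),
               tolerance = 1e-9)
})

test_that("retaining every Fourier coefficient reproduces the image exactly", {
  set.seed(9)
  g <- matrix(abs(rnorm(24 * 18)), 24, 18)
  FT <- stats::fft(g)
  back <- Re(stats::fft(FT, inverse = TRUE)) / length(g)
  expect_lt(max(abs(back - g)), 1e-10)
})

test_that("lattice averaging is the identity on a noiseless periodic image
          and matches real-space cell averaging under noise", {
  motif <- blob_motif()
  clean <- make_lattice_image(motif, cell = c(2.0, 1.6), n_cells = c(8, 8))
  pk <- find_reciprocal_peaks(clean, expected_cell = c(2.0, 1.6), n_orders = 6)
  avg <- average_unit_cell(clean, pk, n_tiles = 1)
  truth <- attr(clean, "motif_cell")
  expect_gt(stats::cor(as.numeric(avg$map$grid), as.numeric(truth)), 0.999)

  noisy <- make_lattice_image(motif, cell = c(2.0, 1.6), n_cells = c(20, 20),
                              noise_sd = 1, seed = 21)
  pkn <- find_reciprocal_peaks(noisy, expected_cell = c(2.0, 1.6), n_orders = 6)
  avgn <- average_unit_cell(noisy, pkn, n_tiles = 1)
  # oracle: direct box averaging over the 400 cells
  oracle <- cell_average_oracle(noisy$grid, nrow(truth), ncol(truth))
  rms <- function(m) sqrt(mean(m^2))
  expect_lt(rms(avgn$map$grid - oracle) / rms(oracle), 0.10)
  expect_gt(stats::cor(as.numeric(avgn$map$grid), as.numeric(truth)), 0.95)
})

test_that("one perturbed cell averages towards the mean over cells", {
  motif <- blob_motif()
  img <- make_lattice_image(motif, cell = c(2.0, 1.6), n_cells = c(6, 6))
  g <- img$grid
  na <- nrow(attr(img, "motif_cell")); nb <- ncol(attr(img, "motif_cell"))
  g[seq_len(na), seq_len(nb)] <- 2 * g[seq_len(na), seq_len(nb)]  # one odd cell
  pert <- density_map(g, img$pixel_size)
  pk <- find_reciprocal_peaks(pert, expected_cell = c(2.0, 1.6), n_orders = 6)
  avg <- average_unit_cell(pert, pk, n_tiles = 1)
  oracle <- cell_average_oracle(g, na, nb)
  expect_lt(sqrt(mean((avg$map$grid - oracle)^2)) / sqrt(mean(oracle^2)), 0.10)
})

test_that("self-correlation is exactly 1 and translations are recovered", {
  motif <- blob_motif()
  img <- make_lattice_image(motif, cell = c(2.0, 1.6), n_cells = c(4, 4))
  sc <- score_model(img, img, try_mirror = FALSE, try_180 = FALSE)
  expect_equal(sc$r, 1, tolerance = 1e-9)
  expect_equal(unname(sc$best_shift), c(0, 0))
  # cyclic translation by a known pixel offset is recovered (mod the cell)
  g <- img$grid
  sh <- c(11, 7)
  g2 <- g[c((sh[1] + 1):nrow(g), 1:sh[1]), c((sh[2] + 1):ncol(g), 1:sh[2])]
  sc2 <- score_model(img, density_map(g2, img$pixel_size),
                     try_mirror = FALSE, try_180 = FALSE)
  expect_equal(sc2$r, 1, tolerance = 1e-9)
  # the recovered shift equals the applied one up to direction convention
  # and lattice periodicity (the image is 20 x 16 px per cell)
  shift_px <- round(sc2$best_shift / img$pixel_size) %% c(20, 16)
  expect_true(shift_px[1] %in% c(sh[1] %% 20, (20 - sh[1]) %% 20))
  expect_true(shift_px[2] %in% c(sh[2] %% 16, (16 - sh[2]) %% 16))
})

test_that("correlation is invariant under affine intensity rescaling", {
  motif <- blob_motif()
  img <- make_lattice_image(motif, cell = c(2.0, 1.6), n_cells = c(4, 4),
                            noise_sd = 0.3, seed = 5)
  ref <- make_lattice_image(motif, cell = c(2.0, 1.6), n_cells = c(4, 4))
  r1 <- score_model(ref, img)$r
  img2 <- density_map(3.5 * img$grid + 2, img$pixel_size)
  r2 <- score_model(ref, img2)$r
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_lte(abs(r1), 1)
})

test_that("mirroring the model is compensated by the mirror search setting", {
  motif <- blob_motif()
  img <- make_lattice_image(motif, cell = c(2.0, 1.6), n_cells = c(4, 4))
  mir <- mirror_map(img)
  sc <- score_model(img, mir, try_mirror = TRUE, try_180 = FALSE)
  expect_equal(sc$r, 1, tolerance = 1e-9)
  expect_true(sc$mirrored)
})
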