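test_that("orientation is 0 along the normal, 90 in the plane, and recovers
          a wrapped-normal distribution", {
  topo <- tibble::tibble(chain = "A", res_seq = 1L, res_name = "UNK",
                         atom_name = c("TAIL", "HEAD"), element = "C",
                         x = 0, y = 0, z = 0)
  xyz <- array(0, c(2, 3, 2))
  xyz[, , 1] <- rbind(c(0, 0, -1), c(0, 0, 1))   # axis along +z
  xyz[, , 2] <- rbind(c(-1, 0, 0), c(1, 0, 0))   # axis in the plane
  fr <- frame_set(topo, xyz)
  ori <- orientation_series(fr, 1L, 2L)
  expect_equal(ori$angle, c(0, 90), tolerance = 1e-9)

  tr <- make_trajectory(n_frames = 5000, seed = 31,
                        orientation_mean = 30, orientation_sd = 8)
  ang <- orientation_series(tr$frames, 1L, 2L)$angle
  h <- hist(ang, breaks = seq(0, 180, by = 1), plot = FALSE)
  mode_angle <- h$mids[which.max(h$counts)]
  expect_lt(abs(mode_angle - 30), 2)
  expect_true(all(ang >= 0 & ang <= 180))
})

test_that("orientation is invariant under global rotation about the normal", {
  tr <- make_trajectory(n_frames = 50, seed = 32)
  a0 <- orientation_series(tr$frames, 1L, 2L)$angle
  rot <- rotation_about_axis(c(0, 0, 0), c(0, 0, 1), 137)
  fr2 <- tr$frames
  for (f in seq_len(dim(fr2$xyz)[3]))
    fr2$xyz[, , f] <- transform_apply(rot, fr2$xyz[, , f])
  expect_equal(orientation_series(fr2, 1L, 2L)$angle, a0, tolerance = 1e-9)
})

test_that("separation is the centre-of-mass distance with minimum image", {
  topo <- tibble::tibble(chain = rep(c("A", "B"), each = 2), res_seq = 1L,
                         res_name = "UNK", atom_name = rep(c("C1", "C2"), 2),
                         element = "C", x = 0, y = 0, z = 0)
  xyz <- array(0, c(4, 3, 1))
  xyz[1:2, 1, 1] <- c(-1, 1)          # group A centred at 0
  xyz[3:4, 1, 1] <- c(29, 31)         # group B centred at 30 A = 3 nm
  fr <- frame_set(topo, xyz)
  expect_equal(separation_series(fr, 1:2, 3:4)$distance, 3, tolerance = 1e-12)
  # 9 A apart in a 10 A periodic box is 1 A by minimum image
  xyz2 <- array(0, c(4, 3, 1))
  xyz2[3:4, 1, 1] <- 9
  fr2 <- frame_set(topo, xyz2, box = c(10, 10, 10))
  expect_equal(separation_series(fr2, 1:2, 3:4)$distance, 0.1,
               tolerance = 1e-12)
  expect_error(separation_series(fr, 1:2, 2:3), "overlap")
})

test_that("synthetic separation series matches the generator exactly and a
          stable dimer has no dissociation event", {
  tr <- make_trajectory(n_frames = 2000, seed = 33)
  sep <- separation_series(tr$frames, attr(tr$truth, "sel_a"),
                           attr(tr$truth, "sel_b"))
  expect_equal(sep$distance, tr$truth$separation, tolerance = 1e-9)
  expect_true(is.na(detect_dissociation(sep, baseline_window = 200)))
})

test_that("dissociation detection localizes step and drift change points", {
  d <- c(rep(2, 499), rep(5, 500))
  expect_equal(detect_dissociation(d, baseline_window = 100,
                                   threshold_multiplier = 5), 500L)
  set.seed(34)
  flat <- 2 + rnorm(1000, sd = 0.05)
  expect_true(is.na(detect_dissociation(flat, baseline_window = 100)))
  tr <- make_trajectory(n_frames = 3000, seed = 35, change_point = 1500,
                        drift_nm_per_frame = 0.005)
  sep <- separation_series(tr$frames, attr(tr$truth, "sel_a"),
                           attr(tr$truth, "sel_b"))
  ev <- detect_dissociation(sep, baseline_window = 200)
  expect_false(is.na(ev))
  expect_lt(abs(ev - 1500), 200)
  expect_error(detect_dissociation(d[1:50], baseline_window = 100), "window")
})

test_that("contact occupancy is a per-frame reduction, invariant to frame
          order", {
  topo <- tibble::tibble(chain = c("A", "B"), res_seq = 1L, res_name = "UNK",
                         atom_name = "CTC", element = "C", x = 0, y = 0, z = 0)
  xyz <- array(0, c(2, 3, 3))
  xyz[2, 1, ] <- c(3.5, 4.5, 3.9)
  fr <- frame_set(topo, xyz)
  expect_equal(contact_occupancy(fr, 1L, 2L, cutoff = 4), 2 / 3)
  xyz_all <- array(0, c(2, 3, 4)); xyz_all[2, 1, ] <- 3
  expect_equal(contact_occupancy(frame_set(topo, xyz_all), 1L, 2L), 1)
  perm <- sample(3)
  fr_perm <- frame_set(topo, xyz[, , perm, drop = FALSE])
  expect_equal(contact_occupancy(fr_perm, 1L, 2L), 2 / 3)
  expect_error(contact_occupancy(fr, list(chain = "A", res_seq = 9,
                                          atom_name = "XX"), 2L), "not found")
})

test_that("two-state occupancy recovers the generator parameter at n = 1e4", {
  tr <- make_trajectory(n_frames = 1e4, seed = 36, occupancy = 0.86)
  occ <- contact_occupancy(tr$frames, attr(tr$truth, "contact_i"),
                           attr(tr$truth, "contact_j"), cutoff = 4)
  expect_equal(occ, mean(tr$truth$bound))       # exact against own truth
  expect_lt(abs(occ - 0.86), 0.01)              # binomial error bound (~3 sd)
})

test_that("square-well binding free energy matches the closed form", {
  kT <- 0.0019872 * 300
  for (D in c(2, 8, 11)) {
    pmf <- make_pmf(depth = D, width = 0.3, grid_step = 0.005)
    r_b <- 0.3 - 0.005   # last grid point inside the well
    dg <- delta_g_bind(pmf, r_bound_max = r_b)
    expect_equal(dg$dg, D + kT * log(r_b / 1.186), tolerance = 1e-6)
  }
  flat <- make_pmf(depth = 0, width = 0.3, grid_step = 0.002)
  expect_equal(delta_g_bind(flat, r_bound_max = 1.186)$dg, 0,
               tolerance = 1e-9)
})

test_that("harmonic-well binding free energy matches a quadrature oracle", {
  kT <- 0.0019872 * 300
  pmf <- make_pmf(depth = 10, width = 0.1, form = "harmonic",
                  grid_step = 0.001, r0 = 0.5)
  dg <- delta_g_bind(pmf, r_bound_max = 1.0)
  wfun <- function(r) pmin(0, -10 + 10 * ((r - 0.5) / 0.1)^2)
  Z <- stats::integrate(function(r) exp(-wfun(r) / kT), 0, 1,
                        rel.tol = 1e-10)$value
  expect_equal(dg$dg, kT * log(Z / 1.186), tolerance = 0.05)
})

test_that("binding free energy deepens monotonically with the well and is
          invariant to pre-anchoring shifts", {
  dgs <- vapply(c(4, 6, 8, 10), function(D)
    delta_g_bind(make_pmf(D, 0.3), r_bound_max = 0.25)$dg, numeric(1))
  expect_true(all(diff(dgs) > 0))
  # shifting W by a constant and re-anchoring gives the same answer
  pmf <- make_pmf(8, 0.3)
  shifted <- pmf_profile(pmf$r, pmf$w + 5 - 5, pmf$w_err,
                         r_unbound = attr(pmf, "r_unbound"))
  expect_equal(delta_g_bind(shifted, 0.25)$dg, delta_g_bind(pmf, 0.25)$dg)
  # an unanchored PMF is rejected
  bad <- pmf_profile(pmf$r, pmf$w + 5, w_err = 0.1,
                     r_unbound = attr(pmf, "r_unbound"))
  expect_error(delta_g_bind(bad, 0.25), "anchored")
})

test_that("frame sets survive a multi-model PDB round trip", {
  p <- toy12()
  f <- tempfile(fileext = ".pdb")
  lines <- character(0)
  for (m in 1:3) {
    q <- p
    q$x <- q$x + m
    tmp <- tempfile(fileext = ".pdb")
    write_structure(q, tmp)
    body <- readLines(tmp)
    body <- body[grepl("^ATOM|^HETATM", body)]
    lines <- c(lines, sprintf("MODEL     %4d", m), body, "ENDMDL")
  }
  writeLines(c(lines, "END"), f)
  fr <- read_frames(f, time_step = 0.5)
  expect_equal(dim(fr$xyz), c(nrow(p), 3, 3))
  expect_equal(fr$xyz[1, 1, 3] - fr$xyz[1, 1, 1], 2, tolerance = 1e-9)
  ori <- orientation_series(fr, 1:4, (nrow(p) - 3):nrow(p))
  expect_equal(nrow(ori), 3)
  expect_equal(ori$time, c(0, 0.5, 1.0))
})
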