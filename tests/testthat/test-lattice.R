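test_that("an exact C2 dimer yields a two-fold transform with the right axis", {
  p <- toy12()
  d <- make_c2_dimer(p, c(15, 2, 0), c(0, 0, 1))
  tr <- extract_dimer_transform(d, "A", "B")
  expect_true(tr$is_c2)
  expect_equal(tr$rotation_angle, 180, tolerance = 1e-6)
  expect_equal(abs(tr$axis_direction[3]), 1, tolerance = 1e-6)
  expect_equal(tr$axis_point[1:2], c(15, 2), tolerance = 1e-6)
})

test_that("a pure-translation 'dimer' is not two-fold", {
  p <- toy12()
  q <- p
  q$chain <- "B"
  q$x <- q$x + 12
  both <- as_structure(dplyr::bind_rows(p, q))
  tr <- extract_dimer_transform(both, "A", "B")
  expect_false(tr$is_c2)
  expect_equal(tr$rotation_angle, 0, tolerance = 1e-6)
})

test_that("template-based dimer modelling reproduces the template for the
          same protein and is rigid-motion invariant", {
  p <- make_toy_protein(20, seed = 15)
  template <- make_c2_dimer(p, c(16, 0, 0), c(0, 0, 1))
  modelled <- model_dimer_by_template(template, c("A", "B"), p, "A")
  expect_equal(nrow(modelled), 2 * nrow(p))
  for (ch in c("A", "B")) {
    ta <- select_atoms(template, chain = ch)
    ma <- select_atoms(modelled, chain = ch)
    expect_lt(max(abs(cbind(ta$x, ta$y, ta$z) - cbind(ma$x, ma$y, ma$z))), 1e-6)
  }
  # a rigidly displaced target gives a congruent dimer
  mot <- rotation_about_axis(c(1, 1, 0), c(1, 1, 1), 65)
  pd <- transform_apply(mot, p)
  pd$x <- pd$x + 7
  modelled2 <- model_dimer_by_template(template, c("A", "B"),
                                       as_structure(pd), "A")
  fit <- kabsch(cbind(modelled2$x, modelled2$y, modelled2$z),
                cbind(modelled$x, modelled$y, modelled$z))
  expect_equal(fit$rmsd, 0, tolerance = 1e-6)
})

test_that("zigzag repeat equals the analytic composition of parallel-axis C2s", {
  p <- toy12()
  p1 <- c(14, 3, 0); p2 <- c(-13, -4, 0)
  t1 <- extract_dimer_transform(make_c2_dimer(p, p1, c(0, 0, 1)), "A", "B")
  t2 <- extract_dimer_transform(make_c2_dimer(p, p2, c(0, 0, 1)), "A", "B")
  zz <- build_zigzag(p, t1, t2, n_copies = 6)
  expect_equal(vec_len(zz$repeat_vector) * 10, vec_len(2 * (p1 - p2)),
               tolerance = 1e-6)
  expect_equal(abs(sum(unit_vec(zz$repeat_vector) * unit_vec(p1 - p2))), 1,
               tolerance = 1e-6)
  expect_equal(zz$residual_rotation, 0, tolerance = 1e-6)
  # t1 = t2: the chain oscillates between two positions, zero repeat
  zz0 <- build_zigzag(p, t1, t1, n_copies = 4)
  expect_equal(vec_len(zz0$repeat_vector), 0, tolerance = 1e-9)
  # every placement carries a proper rotation
  dets <- vapply(zz$placements$transform, function(m) det(m$R), numeric(1))
  expect_equal(dets, rep(1, 6), tolerance = 1e-9)
})

test_that("non-C2 inputs are rejected by build_zigzag", {
  p <- toy12()
  q <- p; q$chain <- "B"; q$x <- q$x + 12
  tr <- extract_dimer_transform(as_structure(dplyr::bind_rows(p, q)), "A", "B")
  t1 <- extract_dimer_transform(make_c2_dimer(p, c(14, 0, 0), c(0, 0, 1)),
                                "A", "B")
  expect_error(build_zigzag(p, t1, tr), "C2")
})

test_that("clash detection matches the exhaustive all-pairs oracle", {
  p <- toy12()
  apart <- dplyr::bind_rows(p, within(p, { chain <- "B"; x <- x + 50 }))
  expect_equal(nrow(detect_clashes(as_structure(apart))), 0)
  onTop <- dplyr::bind_rows(p, within(p, chain <- "B"))
  cl <- detect_clashes(as_structure(onTop))
  expect_gte(nrow(cl), sum(p$is_heavy))   # every atom at 0 A from its twin
  expect_true(all(cl$distance < 2.5))
  set.seed(77)
  for (k in 1:3) {
    q <- p
    q$chain <- "B"
    q$x <- q$x + runif(1, 2, 12)
    q$y <- q$y + runif(1, -3, 3)
    model <- as_structure(dplyr::bind_rows(p, q))
    expect_equal(nrow(detect_clashes(model)), clash_oracle(model))
  }
})

test_that("unit-cell measurement recovers the built cell and is invariant
          under global rigid motion", {
  p <- make_toy_protein(8, seed = 16, extent = c(5, 7, 7))
  t1 <- extract_dimer_transform(make_c2_dimer(p, c(12, 0, 0), c(0, 0, 1)),
                                "A", "B")
  t2 <- extract_dimer_transform(make_c2_dimer(p, c(-12, 0, 0), c(0, 0, 1)),
                                "A", "B")
  zz <- build_zigzag(p, t1, t2, n_copies = 6)   # repeat 4.8 nm
  lat <- build_lattice(zz, c(0, 3, 0), n_rows = 3)
  cell <- measure_unit_cell(lat)
  expect_equal(cell$a, 4.8, tolerance = 1e-6)
  expect_equal(cell$b, 3.0, tolerance = 1e-6)
  expect_equal(cell$angle, 90, tolerance = 1e-6)
  # rigid motion of the whole lattice leaves the cell unchanged
  mot <- rotation_about_axis(c(5, 5, 5), c(1, 2, 3), 40)
  lat2 <- lat
  lat2$reference <- transform_apply(mot, lat$reference)
  lat2$placements$transform <- lapply(
    lat$placements$transform,
    function(m) transform_compose(mot, transform_compose(m, transform_invert(mot))))
  cell2 <- measure_unit_cell(lat2)
  expect_equal(cell2$a, cell$a, tolerance = 1e-6)
  expect_equal(cell2$b, cell$b, tolerance = 1e-6)
  expect_equal(cell2$angle, cell$angle, tolerance = 1e-6)
  expect_error(build_lattice(zz, c(4, 0, 0), n_rows = 2), "parallel")
})
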