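test_that("kabsch recovers rigid motions and is symmetric in rmsd", {
  set.seed(1)
  a <- matrix(rnorm(30, sd = 5), 10, 3)
  expect_equal(kabsch(a, a)$rmsd, 0, tolerance = 1e-12)
  expect_rigid_equal(kabsch(a, a)$transform, transform_identity(), 1e-8)

  mot <- rotation_about_axis(c(0, 0, 0), c(0, 0, 1), 90)
  b <- sweep(transform_apply(mot, a), 2, c(5, 0, 0), `+`)
  fit <- kabsch(a, b)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_lt(max(abs(transform_apply(fit$transform, a) - b)), 1e-9)

  set.seed(2)
  bn <- b + matrix(rnorm(30, sd = 0.5), 10, 3)
  expect_equal(kabsch(a, bn)$rmsd, kabsch(bn, a)$rmsd, tolerance = 1e-9)
})

test_that("rmsd is invariant under rigid pre-motion of either input", {
  set.seed(3)
  a <- matrix(rnorm(60, sd = 5), 20, 3)
  b <- a + matrix(rnorm(60, sd = 1), 20, 3)
  r0 <- kabsch(a, b)$rmsd
  for (k in 1:5) {
    mot <- rotation_about_axis(rnorm(3), rnorm(3), runif(1, 0, 360))
    a2 <- sweep(transform_apply(mot, a), 2, rnorm(3, sd = 10), `+`)
    expect_equal(kabsch(a2, b)$rmsd, r0, tolerance = 1e-6)
  }
})

test_that("mirrored input still yields a proper rotation, matching a brute-force
          oracle over SVD sign corrections", {
  set.seed(4)
  a <- matrix(rnorm(12, sd = 3), 4, 3)
  b <- a %*% diag(c(-1, 1, 1))   # reflection
  fit <- kabsch(a, b)
  expect_gt(fit$rmsd, 0)
  expect_equal(det(fit$transform$R), 1, tolerance = 1e-9)
  # oracle: try all 8 sign flips of the SVD axes, keep proper rotations,
  # minimize rmsd by enumeration
  cm <- colMeans(a); cf <- colMeans(b)
  H <- crossprod(sweep(a, 2, cm), sweep(b, 2, cf))
  s <- svd(H)
  best <- Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    R <- s$v %*% diag(c(s1, s2, s3)) %*% t(s$u)
    if (det(R) < 0) next
    dev <- sweep(sweep(a, 2, cm) %*% t(R), 2, cf, `+`) - b
    best <- min(best, sqrt(mean(rowSums(dev^2))))
  }
  expect_equal(fit$rmsd, best, tolerance = 1e-9)
})

test_that("degenerate and mismatched inputs are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line + 1), "collinear")
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  expect_error(kabsch(matrix(rnorm(9), 3, 3), matrix(rnorm(12), 4, 3)),
               "mismatched")
})

test_that("match_residues pairs identical chains completely and survives
          deletions", {
  p <- toy12()
  pairs <- match_residues(p, "A", p, "A")
  expect_equal(nrow(pairs), 12)
  expect_equal(pairs$res_a, pairs$res_b)
  expect_true(all(pairs$aa_a == pairs$aa_b))
  # delete 5 central residues from the copy
  p2 <- make_toy_protein(30, seed = 9)
  del <- p2[!p2$res_seq %in% 13:17, ]
  del$chain <- "B"
  both <- as_structure(dplyr::bind_rows(p2, del))
  pr <- match_residues(both, "A", both, "B")
  expect_equal(nrow(pr), 25)
  expect_true(all(pr$res_a == pr$res_b))   # uniqueness forces the pairing
})

test_that("iterative superposition trims displaced residues and reduces to
          plain kabsch at infinite cutoff", {
  p <- make_toy_protein(30, seed = 10)
  q <- p
  q$chain <- "B"
  sel <- q$res_seq == 15
  q$x[sel] <- q$x[sel] + 20          # one residue thrown 20 A away
  both <- as_structure(dplyr::bind_rows(p, q))
  fit <- iterative_superpose(both, "A", both, "B", reject_cutoff = 3.5)
  expect_true(fit$trimmed)
  expect_equal(fit$n_pairs, 29)
  expect_false(15 %in% fit$pair_list$res_a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  # cutoff = Inf equals plain kabsch over all matched pairs
  fit_inf <- iterative_superpose(both, "A", both, "B", reject_cutoff = Inf)
  pairs <- match_residues(both, "A", both, "B")
  ca_a <- select_atoms(both, chain = "A", atom_names = "CA")
  ca_b <- select_atoms(both, chain = "B", atom_names = "CA")
  plain <- kabsch(cbind(ca_a$x, ca_a$y, ca_a$z), cbind(ca_b$x, ca_b$y, ca_b$z))
  expect_equal(fit_inf$rmsd, plain$rmsd, tolerance = 1e-9)
  expect_false(fit_inf$trimmed)
})

test_that("pairwise identity is the fraction of identical aligned residues", {
  p <- toy12()
  pairs <- match_residues(p, "A", p, "A")
  expect_equal(pairwise_identity(pairs), 100)
  half <- pairs
  half$aa_b[seq(1, 12, by = 2)] <- "X"
  expect_equal(pairwise_identity(half), 50)
  expect_error(pairwise_identity(pairs[0, ]), "empty")
})

test_that("the all-chain rmsd matrix is symmetric with zero diagonal", {
  fam <- make_chain_family(seed = 11, n_residues = 40, n_chains = 3)
  m <- chain_rmsd_matrix(fam)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 3), c("A", "B", "C")))
  expect_true(all(m[upper.tri(m)] > 0))
})
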