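test_that("combining rules are symmetric and follow the configured means", {
  ff <- force_field(data.frame(ff_type = c("X", "Y"),
                               A = c(100, 400), B = c(3, 4), C = c(9, 16)))
  same <- combine_params("X", "X", ff)
  expect_equal(same$A, 100)
  xy <- combine_params("X", "Y", ff)
  expect_equal(xy$A, 200)      # geometric mean
  expect_equal(xy$B, 3.5)      # arithmetic mean
  expect_equal(xy$C, 12)       # geometric mean
  yx <- combine_params("Y", "X", ff)
  expect_identical(xy, yx)
  expect_error(combine_params("X", "Z", ff), "Z")
})

test_that("toy force field pair tables are symmetric and positive", {
  ff <- fx_ff()
  mol <- make_toy_molecule("chiral_tetrahedron")
  pt <- cspland:::pair_tables(mol, ff)
  expect_equal(pt$A, t(pt$A))
  expect_equal(pt$B, t(pt$B))
  expect_true(all(pt$rwall > 0 & pt$rwall < 1.5))
  ## the inner cap joins the exp-6 curve at its inner maximum
  p <- combine_params("C", "O", ff)
  rw <- pt$rwall["C", "O"]
  expect_equal(exp6_pair(p, rw), pt$uwall["C", "O"], tolerance = 1e-8)
})

test_that("molecular_rmsd removes rigid motion and matches a search oracle", {
  mol <- make_toy_molecule("chiral_tetrahedron")
  expect_equal(molecular_rmsd(mol, mol), 0)
  rot <- cspland:::quat_to_matrix(cspland:::quat_normalize(c(.4, .3, -.2, .6)))
  moved <- mol
  moved$coords <- mol$coords %*% t(rot) + rep(c(3, -1, 2), each = n_atoms(mol))
  expect_lt(molecular_rmsd(mol, moved), 1e-10)

  ## two-atom molecule, one atom displaced 0.2 A along the bond -> 0.1:
  ## independent oracle = exhaustive search over rigid transforms
  a <- rigid_molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  b <- rigid_molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.7, 0, 0)))
  oracle <- Inf
  for (ang in seq(0, pi, length.out = 181)) {
    R <- cspland:::quat_to_matrix(c(cos(ang / 2), 0, 0, sin(ang / 2)))
    bc <- b$coords %*% t(R)
    ## optimal translation = centroid alignment for fixed rotation
    bc <- sweep(bc, 2, colMeans(bc) - colMeans(a$coords))
    oracle <- min(oracle, sqrt(mean(rowSums((a$coords - bc)^2))))
  }
  expect_equal(oracle, 0.1, tolerance = 1e-6)
  expect_equal(molecular_rmsd(a, b), 0.1, tolerance = 1e-8)
  expect_error(molecular_rmsd(a, mol), "mismatch")
})

test_that("mirror_image is an involution, preserves distances, and detects chirality", {
  chir <- make_toy_molecule("chiral_tetrahedron")
  mir <- mirror_image(chir)
  expect_equal(mirror_image(mir)$coords, chir$coords)
  d <- function(m) as.numeric(dist(m$coords))
  expect_equal(d(mir), d(chir), tolerance = 1e-12)
  ## chiral: not superimposable under any proper rotation
  expect_gt(molecular_rmsd(chir, mir), 0.1)
  ## a planar molecule is superimposable on its mirror image
  ring <- make_toy_molecule("planar_ring")
  expect_lt(molecular_rmsd(ring, mirror_image(ring)), 1e-10)
  ## dipole components flip sign, charges do not
  mp <- multipole_set(chir$charges,
                      dipoles = matrix(0.1, n_atoms(chir), 3))
  chir2 <- rigid_molecule(chir$elements, chir$coords,
                          charges = chir$charges, multipoles = mp,
                          is_chiral = TRUE)
  m2 <- mirror_image(chir2)
  expect_equal(cspland:::dipole_cartesian(m2$multipoles),
               -cspland:::dipole_cartesian(chir2$multipoles))
  expect_equal(m2$charges, chir2$charges)
})

test_that("spherical multipole components match point-charge definitions", {
  set.seed(4)
  pos <- matrix(rnorm(12, 0, 0.5), 4, 3)
  q <- rnorm(4); q <- q - mean(q)
  ref <- cspland:::point_charge_multipoles(q, pos)
  ## dipole: Cartesian (x,y,z) = (Q11c, Q11s, Q10)
  mu <- colSums(q * pos)
  expect_equal(c(ref$Q11c, ref$Q11s, ref$Q10), unname(mu), tolerance = 1e-12)
  ## quadrupole conversion reproduces the Buckingham Cartesian tensor
  ms <- multipole_set(0, dipoles = NULL,
                      quadrupoles = matrix(c(ref$Q20, ref$Q21c, ref$Q21s,
                                             ref$Q22c, ref$Q22s), 1))
  Th <- matrix(cspland:::quadrupole_cartesian(ms)[1, ], 3, 3)
  Th_ref <- matrix(0, 3, 3)
  for (i in 1:4) {
    r <- pos[i, ]
    Th_ref <- Th_ref + q[i] * (3 * outer(r, r) - sum(r^2) * diag(3)) / 2
  }
  expect_equal(Th, Th_ref, tolerance = 1e-10)
})

test_that("molecule and force-field files round-trip", {
  mol <- make_toy_molecule("bent_triatomic")
  mol$multipoles <- multipole_set(mol$charges,
                                  dipoles = matrix(c(0.1, -0.2, 0.3), 3, 3,
                                                   byrow = TRUE),
                                  quadrupoles = matrix(0.05, 3, 5))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_molecule(mol, path)
  back <- read_molecule(path)
  expect_equal(back$coords, mol$coords, tolerance = 1e-7)
  expect_equal(back$charges, mol$charges)
  expect_equal(back$multipoles$Q, mol$multipoles$Q, tolerance = 1e-9)
  expect_identical(back$ff_types, mol$ff_types)

  ffpath <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# toy table", "C 1000 3.6 1400", "H 5000 4.6 130"), ffpath)
  ff <- read_forcefield(ffpath)
  expect_equal(combine_params("C", "C", ff)$B, 3.6)
})

test_that("molecule invariants are enforced", {
  expect_error(rigid_molecule("C", matrix(0, 1, 3)), "2 atoms")
  expect_error(rigid_molecule(c("C", "O"), rbind(c(0, 0, 0), c(1, 0, 0)),
                              charges = c(0.5, 0)), "neutral")
  expect_error(rigid_molecule(c("C", "Xe"), rbind(c(0, 0, 0), c(1, 0, 0))),
               "Xe")
})
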