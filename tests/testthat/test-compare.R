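test_that("Bragg peak positions follow the reciprocal lattice", {
  mol <- make_toy_molecule("diatomic")
  cr <- crystal(mol, "P1", cell(10, 10, 10),
                placement(c(0, 0, 0), c(1, 0, 0, 0)))
  pat <- simulate_pxrd(cr)
  expect_true(all(pat$intensity >= 0))
  expect_true(all(diff(pat$two_theta) > 0))
  peaks <- pat$two_theta[which(diff(sign(diff(pat$intensity))) == -2) + 1]
  ## lowest-angle reflection: d = 10 A, lambda = 1.5406 A -> 8.84 deg
  expect_equal(min(peaks), 2 * asin(1.5406 / 20) * 180 / pi,
               tolerance = 0.05)
  expect_equal(min(peaks), 8.84, tolerance = 0.05)
})

test_that("patterns are invariant to supercell description and translation", {
  mol <- make_toy_molecule("bent_triatomic")
  cr <- crystal(mol, "P1", cell(6, 7, 8, 80, 95, 100),
                placement(c(0.2, 0.3, 0.4), c(0.9, 0.1, 0.2, -0.3)))
  p1 <- simulate_pxrd(cr)
  cr2 <- cr
  cr2$placement <- placement(cr$placement$centroid + c(2, -1, 5),
                             cr$placement$quat)
  p2 <- simulate_pxrd(cr2)
  expect_gt(pxrd_similarity(p1, p2), 0.9999)
})

test_that("pxrd similarity is symmetric, scale-invariant and separates peaks", {
  mol <- make_toy_molecule("diatomic")
  cr <- crystal(mol, "P1", cell(5, 6, 7),
                placement(c(0.1, 0.1, 0.1), c(1, 0, 0, 0)))
  p <- simulate_pxrd(cr)
  expect_equal(pxrd_similarity(p, p), 1)
  p2 <- p; p2$intensity <- 2.5 * p2$intensity
  expect_equal(pxrd_similarity(p, p2), 1, tolerance = 1e-12)
  ## two single peaks far beyond the correlation width -> ~0
  cfg <- compare_config()
  g <- p$two_theta
  mk <- function(center) {
    q <- p
    q$intensity <- exp(-(g - center)^2 / (2 * 0.2^2))
    q
  }
  expect_lt(pxrd_similarity(mk(10), mk(40), cfg), 0.01)
  expect_equal(pxrd_similarity(mk(10), mk(40), cfg),
               pxrd_similarity(mk(40), mk(10), cfg), tolerance = 1e-12)
})

test_that("cluster_match confirms identity and rejects distinct packings", {
  batch <- fx_multimin_batch(seed = 7L, n = 12L)
  E <- vapply(batch, function(m) m$energy$E_latt, numeric(1))
  a <- batch[[which.min(E)]]
  cfg <- compare_config()
  self <- cluster_match(a, a, cfg, n = 15)
  expect_true(self$matched)
  expect_equal(self$n_matched, 15L)
  expect_lt(self$rmsd_n, 1e-8)
  ## isotropic 1% expansion: still a match, small nonzero rmsd
  b <- a
  b$cell <- cell(a$cell$a * 1.01, a$cell$b * 1.01, a$cell$c * 1.01,
                 a$cell$alpha, a$cell$beta, a$cell$gamma)
  cm <- cluster_match(a, b, cfg, n = 15)
  expect_true(cm$matched)
  expect_gt(cm$rmsd_n, 1e-4)
  expect_lt(cm$rmsd_n, 0.2)
  ## structurally distinct packing (energy gap > 1 kJ/mol): no match
  far <- batch[[which(E - min(E) > 1)[1]]]
  cm2 <- cluster_match(a, far, cfg, n = 15)
  expect_false(cm2$matched)
  ## symmetry of the decision
  expect_equal(cluster_match(far, a, cfg, n = 15)$matched, cm2$matched)
  expect_error(cluster_match(a, crystal(make_toy_molecule("bent_triatomic"),
                                        "P1", cell(8, 8, 8),
                                        placement(c(0, 0, 0), c(1, 0, 0, 0))),
                             cfg), "same molecule")
})

test_that("rmsd_n is invariant to which symmetry image is central", {
  mol <- make_toy_molecule("bent_triatomic")
  tr <- generate_batch("P21", mol, sampler_config(seed = 41), 3)
  m <- minimize_batch(tr, fx_ff(), quick_schedule())
  a <- m[[1]]
  cfg <- compare_config()
  base <- cluster_match(a, a, cfg, n = 12)
  expect_true(base$matched)
  ## re-describe with the other image as the asymmetric unit: shift the
  ## placement through the screw operation
  op <- a$group$ops[[2]]
  contents <- cspland:::cell_contents(a)
  im <- expand_to_cell(a$group, a$cell, a$molecule, a$placement)[[2]]
  M <- cell_matrix(a$cell)
  quat2 <- cspland:::matrix_to_quat(im$rotation)
  b <- crystal(a$molecule, a$group, a$cell,
               placement(im$centroid_frac, quat2), id = "redesc")
  cm <- cluster_match(a, b, cfg, n = 12)
  expect_true(cm$matched)
  expect_lt(cm$rmsd_n, 1e-6)
})

test_that("deduplicate collapses re-descriptions and is idempotent", {
  batch <- fx_multimin_batch(seed = 7L, n = 12L)
  dd0 <- deduplicate(batch, compare_config())
  k <- dd0$n_unique
  ## inject 3 re-descriptions of each of the two best uniques
  uniq <- dd0$unique
  redescribe <- function(cr, shift) {
    out <- cr
    out$placement <- placement(cr$placement$centroid + shift,
                               cr$placement$quat)
    out$id <- paste0(cr$id, "-t", paste(shift, collapse = ""))
    out
  }
  inflated <- c(uniq,
                lapply(1:3, function(i) redescribe(uniq[[1]], c(i, -i, 2))),
                lapply(1:3, function(i) redescribe(uniq[[2]], c(0, i, i))))
  dd <- deduplicate(inflated, compare_config())
  expect_equal(dd$n_unique, k)
  ## sorted by energy and idempotent
  E <- vapply(dd$unique, function(s) s$energy$E_latt, numeric(1))
  expect_true(all(diff(E) >= 0))
  dd2 <- deduplicate(dd$unique, compare_config())
  expect_equal(dd2$n_unique, dd$n_unique)
  expect_equal(deduplicate(list(), compare_config())$n_unique, 0L)
})
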