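mk_ls <- function(Es, groups, densities = NULL, mol = NULL) {
  if (is.null(mol)) mol <- make_toy_molecule("chiral_tetrahedron")
  if (is.null(densities)) densities <- rep(1.2, length(Es))
  landscape(lapply(seq_along(Es), function(i)
    fake_structure(mol, groups[i], Es[i], densities[i],
                   sprintf("s%02d", i))), molecule = mol)
}

test_that("landscapes sort ascending with the global minimum first", {
  ls <- mk_ls(c(-48, -50, -49), c("P21", "P-1", "P21/c"))
  expect_equal(ls$summary$E_latt, c(-50, -49, -48))
  expect_equal(ls$summary$group[1], "P-1")
})

test_that("delta_e follows its definition with and without the Sohncke restriction", {
  ls <- mk_ls(c(-50, -48, -49), c("P-1", "P21", "P21/c"))
  expect_equal(delta_e(ls, 1), 0)
  expect_equal(vapply(1:3, function(i) delta_e(ls, i), numeric(1)),
               c(0, 1, 2))
  ## Sohncke-restricted reference: best Sohncke is -48 (P21)
  expect_equal(delta_e(ls, which(ls$summary$group == "P21"),
                       chiral_restriction = TRUE), 0)
  ## restriction is a no-op when every structure is Sohncke
  ls2 <- mk_ls(c(-50, -48), c("P21", "P212121"))
  for (i in 1:2)
    expect_equal(delta_e(ls2, i, chiral_restriction = TRUE),
                 delta_e(ls2, i))
  ## shift invariance
  ls3 <- mk_ls(c(-50, -48, -49) + 17.3, c("P-1", "P21", "P21/c"))
  expect_equal(vapply(1:3, function(i) delta_e(ls3, i), numeric(1)),
               vapply(1:3, function(i) delta_e(ls, i), numeric(1)))
  ls_empty <- mk_ls(c(-50), c("P-1"))
  expect_error(delta_e(ls_empty, 1, chiral_restriction = TRUE), "empty")
})

test_that("match_summary builds the histogram and cumulative curve", {
  m <- data.frame(matched = c(TRUE, TRUE, TRUE),
                  delta_e = c(0, 1.4, 3.0))
  s <- match_summary(m)
  expect_equal(s$n_matched, 3L)
  expect_equal(s$n_at_zero, 1L)
  expect_equal(s$n_within_thermal, 2L)
  expect_equal(s$n_within_8, 3L)
  expect_equal(s$cumulative$fraction[s$cumulative$delta_e == 2.0], 2 / 3)
  ## all matches at zero: curve is 1 everywhere
  s2 <- match_summary(data.frame(matched = TRUE, delta_e = 0))
  expect_true(all(s2$cumulative$fraction == 1))
  ## unmatched references cap the asymptote below 1
  s3 <- match_summary(data.frame(matched = c(TRUE, FALSE),
                                 delta_e = c(0, NA)))
  expect_equal(max(s3$cumulative$fraction), 0.5)
})

test_that("space-group frequencies normalise under every selector", {
  mol <- make_toy_molecule("chiral_tetrahedron")
  ls1 <- mk_ls(c(-50, -49, -45), c("P-1", "P21", "P21/c"),
               c(1.3, 1.25, 1.2), mol)
  ls2 <- mk_ls(c(-40, -39.5), c("P21", "P212121"), c(1.1, 1.35), mol)
  for (sel in c("global_min", "densest", "window")) {
    tab <- spacegroup_frequencies(list(ls1, ls2), selector = sel)
    expect_equal(sum(tab$frequency), 1, tolerance = 1e-12)
  }
  g1 <- spacegroup_frequencies(list(ls1), selector = "global_min")
  expect_equal(g1$group, "P-1")
  expect_equal(g1$frequency, 1)
  d1 <- spacegroup_frequencies(list(ls2), selector = "densest")
  expect_equal(d1$group, "P212121")
  ## window -> infinity counts every structure exactly once
  w <- spacegroup_frequencies(list(ls1, ls2), selector = "window",
                              window = Inf)
  expect_equal(sum(w$count), 5)
  ## landscapes where densest = global min give identical tables
  ls3 <- mk_ls(c(-50, -45), c("P21", "P-1"), c(1.4, 1.2), mol)
  expect_equal(spacegroup_frequencies(list(ls3), selector = "global_min"),
               spacegroup_frequencies(list(ls3), selector = "densest"))
})

test_that("chirality analysis applies the declared sign conventions", {
  mol <- make_toy_molecule("chiral_tetrahedron")
  ## Sohncke min -48 vs racemic min -50: racemate favoured by +2
  ls <- mk_ls(c(-48, -50, -47), c("P21", "P-1", "P212121"),
              c(1.20, 1.25, 1.18), mol)
  rec <- chirality_analysis(ls)
  expect_equal(rec$dE_latt, 2)
  expect_false(rec$resolution_predicted)
  expect_equal(rec$d_rho, 100 * (1.20 - 1.25) / 1.25)
  ## exact tie: strict inequality means no predicted resolution
  ls_tie <- mk_ls(c(-50, -50), c("P21", "P-1"), c(1.2, 1.2), mol)
  expect_false(chirality_analysis(ls_tie)$resolution_predicted)
  expect_equal(chirality_analysis(ls_tie)$dE_latt, 0)
  ## swapping the partitions flips the sign exactly: relabel groups
  ls_swap <- mk_ls(c(-48, -50, -47), c("P-1", "P21", "P21/c"),
                   c(1.20, 1.25, 1.18), mol)
  ## (P21 now holds the -50 minimum; the non-Sohncke minimum is -48)
  expect_equal(chirality_analysis(ls_swap)$dE_latt, -rec$dE_latt)
  ## error paths
  achiral <- make_toy_molecule("diatomic")
  ls_a <- mk_ls(c(-50, -49), c("P21", "P-1"), c(1.2, 1.2), achiral)
  expect_error(chirality_analysis(ls_a), "chiral")
  ls_one <- mk_ls(c(-50), c("P21"), 1.2, mol)
  expect_error(chirality_analysis(ls_one), "required")
})

test_that("match_reference finds a planted structure in its own landscape", {
  ref <- fx_planted("diatomic", "P1", seed = 101L)
  batch <- fx_minimised_batch(seed = 7L, n = 12L)
  ls <- landscape(deduplicate(batch, compare_config())$unique,
                  make_toy_molecule("diatomic"))
  mr <- match_reference(ls, ref, compare_config(), n = 15)
  expect_true(mr$matched)
  expect_lt(mr$rmsd_n, 0.3)
  expect_equal(mr$delta_e, 0, tolerance = 0.2)
})
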