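## shared small landscape collection for the correction tests: cheap
## fake compounds with real geometry (needed by featurize) built from
## perturbed conformers of one template
ml_landscapes <- function(n_compounds = 4L, n_structs = 6L) {
  key <- paste("mlls", n_compounds, n_structs, sep = "|")
  if (is.null(.fx[[key]])) {
    base <- make_toy_molecule("diatomic")
    batch <- fx_minimised_batch(seed = 7L, n = 12L)
    lss <- lapply(seq_len(n_compounds), function(ci) {
      mol <- if (ci == 1) base else
        perturb_conformer(base, 0.05 * ci, seed = ci)
      mol$name <- sprintf("compound%02d", ci)
      structs <- lapply(seq_len(n_structs), function(si) {
        src <- batch[[(si - 1) %% length(batch) + 1]]
        cr <- crystal(mol, src$group, src$cell, src$placement,
                      id = sprintf("%s-%02d", mol$name, si))
        cr$energy <- src$energy
        cr$density <- src$density
        cr$converged <- TRUE
        cr
      })
      landscape(structs, molecule = mol)
    })
    .fx[[key]] <- lss
  }
  .fx[[key]]
}

test_that("descriptors are locality-aware and permutation-invariant", {
  cfg <- descriptor_config()
  mol <- make_toy_molecule("planar_ring")
  cr <- crystal(mol, "P1", cell(12, 13, 14),
                placement(c(0.5, 0.5, 0.5), c(1, 0, 0, 0)))
  d <- featurize(cr, cfg)
  expect_equal(dim(d), c(8L, cspland:::descriptor_length(cfg)))
  ## swapping two same-element atoms permutes rows, multiset unchanged
  perm <- c(2, 1, 3:8)
  mol2 <- rigid_molecule(mol$elements[perm], mol$coords[perm, ],
                         charges = mol$charges[perm], name = "perm")
  cr2 <- crystal(mol2, "P1", cr$cell, cr$placement)
  d2 <- featurize(cr2, cfg)
  expect_equal(d2[perm, ], d, tolerance = 1e-10)
  ## lattice translation leaves descriptors unchanged
  cr3 <- cr
  cr3$placement <- placement(cr$placement$centroid + c(1, 2, -1),
                             cr$placement$quat)
  expect_equal(featurize(cr3, cfg), d, tolerance = 1e-10)
  ## a 90-degree rotation in a cell that maps onto itself is a rigid
  ## motion of the whole crystal: descriptors are unchanged
  cr4 <- crystal(mol, "P1", cell(12, 12, 14),
                 placement(c(0.5, 0.5, 0.5), c(1, 0, 0, 0)))
  rot90 <- cspland:::rotvec_to_quat(c(0, 0, pi / 2))
  cr5 <- crystal(mol, "P1", cell(12, 12, 14),
                 placement(c(0.5, 0.5, 0.5),
                           cspland:::quat_multiply(rot90, c(1, 0, 0, 0))))
  expect_equal(featurize(cr5, cfg), featurize(cr4, cfg), tolerance = 1e-8)
})

test_that("dataset building filters, splits and withholds as specified", {
  lss <- ml_landscapes(4L, 6L)
  orc <- synthetic_oracle(amplitude = 3, noise_sd = 0.2, seed = 11L)
  ds <- build_dataset(lss, orc, per_compound_n = 4L, window = 8.0,
                      seed = 2L)
  s <- ds$summary
  expect_lte(max(table(s$compound)), 4L)
  ## every selected structure is within the window on its landscape
  for (ls in lss) {
    ids <- vapply(ls$structures, `[[`, character(1), "id")
    sel <- s$compound == ls$molecule$name
    expect_true(all(s$e_ff[sel] - min(ls$summary$E_latt) <= 8.0 + 1e-9))
  }
  ## 4 compounds -> 3 train (floor 0.85*4), 1 extrapolation
  comp_split <- unique(s[, c("compound", "split")])
  extrap <- unique(s$compound[s$split == "extrapolation"])
  expect_length(extrap, 1L)
  train_comps <- setdiff(unique(s$compound), extrap)
  ## one in-domain test structure withheld per training compound
  for (comp in train_comps)
    expect_equal(sum(s$compound == comp & s$split == "test"), 1L)
  ## empty request gives an empty dataset
  ds0 <- build_dataset(lss, orc, per_compound_n = 0L, seed = 2L)
  expect_length(ds0$records, 0L)
})

test_that("committee training is deterministic and handles degenerate targets", {
  lss <- ml_landscapes(4L, 6L)
  zero_oracle <- function(cr) cr$energy$E_latt # targets identically zero
  ds <- build_dataset(lss, zero_oracle, per_compound_n = 5L, seed = 3L)
  expect_true(all(abs(ds$summary$target) < 1e-12))
  m1 <- train_committee(ds, M = 4L, seed = 7L)
  expect_lt(m1$mae[["test"]], 0.05)
  pr <- predict_correction(m1, lss[[1]]$structures[[1]])
  expect_lt(abs(pr$dE_pred), 0.05)
  m2 <- train_committee(ds, M = 4L, seed = 7L)
  expect_identical(m1$members, m2$members)
  ## a committee of identical members has zero predictive spread
  m3 <- train_committee(ds, M = 4L, seed = 7L, bootstrap = FALSE)
  pr3 <- predict_correction(m3, lss[[1]]$structures[[1]])
  expect_equal(pr3$sigma, 0)
  expect_error(train_committee(build_dataset(lss[1], zero_oracle,
                                             per_compound_n = 2L, seed = 1L),
                               M = 2L), "at least 10")
})

test_that("query-by-committee selection respects budget and determinism", {
  lss <- ml_landscapes(4L, 6L)
  orc <- synthetic_oracle(amplitude = 3, noise_sd = 0.2, seed = 11L)
  ds <- build_dataset(lss, orc, per_compound_n = 5L, seed = 3L)
  model <- train_committee(ds, M = 4L, seed = 7L)
  pool <- lss[[1]]$structures
  expect_identical(active_learning_round(model, pool, 0L), integer(0))
  all_sel <- active_learning_round(model, pool, length(pool) + 5L)
  expect_setequal(all_sel, seq_along(pool))
  s2 <- active_learning_round(model, pool, 2L)
  expect_length(s2, 2L)
  expect_identical(s2, active_learning_round(model, pool, 2L))
})

test_that("corrected landscapes preserve ranking under trivial corrections", {
  lss <- ml_landscapes(4L, 6L)
  zero_oracle <- function(cr) cr$energy$E_latt
  ds <- build_dataset(lss, zero_oracle, per_compound_n = 5L, seed = 3L)
  model <- train_committee(ds, M = 4L, seed = 7L)
  ls <- lss[[1]]
  corr <- corrected_landscape(ls, model, sigma_cap = 25)
  expect_identical(corr$summary$id, ls$summary$id)
  expect_equal(corr$summary$E_latt, ls$summary$E_latt, tolerance = 0.05)
  ## constant correction: delta_e values unchanged
  const_oracle <- function(cr) cr$energy$E_latt + 4.2
  dsc <- build_dataset(lss, const_oracle, per_compound_n = 5L, seed = 3L)
  mc <- train_committee(dsc, M = 4L, seed = 7L)
  corr2 <- corrected_landscape(ls, mc, sigma_cap = 25)
  de_old <- ls$summary$E_latt - min(ls$summary$E_latt)
  de_new <- corr2$summary$E_latt - min(corr2$summary$E_latt)
  expect_equal(de_new, de_old, tolerance = 0.05)
  ## raising the cap never removes structures
  orc <- synthetic_oracle(amplitude = 3, noise_sd = 0.2, seed = 11L)
  dso <- build_dataset(lss, orc, per_compound_n = 5L, seed = 3L)
  mo <- train_committee(dso, M = 4L, seed = 7L)
  sig <- vapply(ls$structures, function(cr)
    predict_correction(mo, cr)$sigma, numeric(1))
  caps <- sort(unique(c(stats::quantile(sig, c(0.5, 0.9)), 25)))
  sizes <- vapply(caps, function(cp)
    tryCatch(length(corrected_landscape(ls, mo, cp)$structures),
             error = function(e) 0L), integer(1))
  expect_true(all(diff(sizes) >= 0))
})
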