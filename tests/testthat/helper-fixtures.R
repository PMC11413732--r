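## Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_ff <- function() toy_forcefield()

## cached planted reference structures
fx_planted <- function(template = "diatomic", group = "P1", seed = 101L,
                       n_trials = 30L) {
  key <- paste(template, group, seed, sep = "|")
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- plant_reference(make_toy_molecule(template), group,
                                  seed = seed, n_trials = n_trials,
                                  ff = fx_ff(), schedule = quick_schedule())
  }
  .fx[[key]]
}

## cached small minimised batch (diatomic, P1)
fx_minimised_batch <- function(seed = 7L, n = 12L) {
  key <- paste("batch", seed, n, sep = "|")
  if (is.null(.fx[[key]])) {
    mol <- make_toy_molecule("diatomic")
    trials <- generate_batch("P1", mol, sampler_config(seed = seed), n)
    .fx[[key]] <- minimize_batch(trials, fx_ff(), quick_schedule())
  }
  .fx[[key]]
}

## cached multi-minimum batch (linear triatomic, P21): several distinct
## packings with a spread of energies
fx_multimin_batch <- function(seed = 7L, n = 12L) {
  key <- paste("multimin", seed, n, sep = "|")
  if (is.null(.fx[[key]])) {
    mol <- make_toy_molecule("linear_triatomic")
    trials <- generate_batch("P21", mol, sampler_config(seed = seed), n)
    .fx[[key]] <- minimize_batch(trials, fx_ff(), quick_schedule())
  }
  .fx[[key]]
}

## a lightweight hand-made "minimised" structure for analysis tests that
## only need energies/groups/densities, not real geometry
fake_structure <- function(mol, group, E, density, id) {
  cr <- crystal(mol, group, cell(6, 7, 8, 90,
                                 if (get_spacegroup(group)$system ==
                                     "monoclinic") 100 else 90, 90),
                placement(c(0.1, 0.2, 0.3), c(1, 0, 0, 0)), id = id)
  cr$energy <- structure(list(E_repdisp = E, E_elec = 0, E_latt = E,
                              converged = TRUE),
                         class = "energy_breakdown")
  cr$density <- density
  cr$converged <- TRUE
  cr
}

## small perturbation of a minimised crystal: ~0.1 A centroid shift,
## ~5 degree rotation, ~2 percent cell strain
perturb_crystal <- function(cr, seed, shift_ang = 0.1, rot_deg = 5,
                            cell_frac = 0.02) {
  r <- cspland:::local_rnorm(seed, 7)
  cl <- cr$cell
  f <- 1 + cell_frac * tanh(r[1])
  cl2 <- constrain_cell(cr$group,
                        cell(cl$a * f, cl$b * (2 - f), cl$c * f,
                             cl$alpha, cl$beta, cl$gamma))
  M <- cell_matrix(cl2)
  dir <- r[2:4] / sqrt(sum(r[2:4]^2))
  dcen <- as.numeric(solve(M) %*% (dir * shift_ang))
  axis <- r[5:7] / sqrt(sum(r[5:7]^2))
  dq <- cspland:::rotvec_to_quat(axis * rot_deg * pi / 180)
  out <- cr
  out$cell <- cl2
  out$placement <- placement(cr$placement$centroid + dcen,
                             cspland:::quat_multiply(dq, cr$placement$quat))
  out$energy <- NULL
  out$converged <- NA
  out
}
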