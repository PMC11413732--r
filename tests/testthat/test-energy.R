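test_that("exp6_pair evaluates the closed form and its limits", {
  p <- list(A = 1000, B = 3, C = 10)
  expect_equal(exp6_pair(p, 2), 1000 * exp(-6) - 10 / 64, tolerance = 1e-12)
  expect_equal(exp6_pair(p, 2), 2.3225, tolerance = 1e-4)
  expect_error(exp6_pair(p, 0), "positive")
  expect_error(exp6_pair(p, -1), "positive")
  p0 <- list(A = 1000, B = 3, C = 0)
  expect_true(all(exp6_pair(p0, c(0.1, 1, 5)) > 0))
  r <- 10 # >= 5/B, dispersion-dominated
  expect_lt(abs(exp6_pair(p, r)), p$C / r^6 * 1.01)
})

test_that("an isolated molecule has ~zero repdisp energy", {
  mol <- make_toy_molecule("diatomic")
  cr <- crystal(mol, "P1", cell(40, 41, 42),
                placement(c(0.5, 0.5, 0.5), c(1, 0, 0, 0)))
  st <- energy_settings(rd_cutoff = 10, elec_cutoff = 10,
                        tail_correction = FALSE)
  expect_lt(abs(repdisp_energy(cr, fx_ff(), st)), 1e-10)
})

test_that("an isolated dimer equals the explicit pair sum", {
  ## P-1 in a huge cell: the two symmetry images form a dimer with no
  ## other neighbours inside the cutoff
  mol <- make_toy_molecule("diatomic")
  cr <- crystal(mol, "P-1", cell(50, 50, 50),
                placement(c(0.535, 0.5, 0.5), c(1, 0, 0, 0)))
  st <- energy_settings(rd_cutoff = 10, elec_cutoff = 10,
                        tail_correction = FALSE, clash_action = "wall")
  contents <- cspland:::cell_contents(cr)
  ff <- fx_ff()
  a <- contents$coords[1:2, ]; b <- contents$coords[3:4, ]
  direct_rd <- 0; direct_q <- 0
  for (i in 1:2) for (j in 1:2) {
    pr <- combine_params(mol$ff_types[i], mol$ff_types[j], ff)
    r <- sqrt(sum((a[i, ] - b[j, ])^2))
    direct_rd <- direct_rd + exp6_pair(pr, r)
    direct_q <- direct_q +
      cspland:::COULOMB_KJ * mol$charges[i] * mol$charges[j] / r
  }
  eb <- lattice_energy(cr, ff, st)
  ## exp-6 part: exact (no periodic neighbours inside the cutoff)
  expect_equal(eb$E_repdisp, direct_rd / 2, tolerance = 1e-10)
  ## charge part: Ewald keeps a tiny periodic residue even at 50 A,
  ## so the dimer Coulomb sum is matched at 1e-3 kJ/mol (absolute)
  expect_equal(eb$E_elec, direct_q / 2, tolerance = 1e-3)
})

test_that("Ewald matches the neutral-shell direct sum on a rocksalt lattice", {
  a <- 5.64
  fr <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5),
              c(.5, 0, 0), c(0, .5, 0), c(0, 0, .5), c(.5, .5, .5))
  q <- c(1, 1, 1, 1, -1, -1, -1, -1)
  M <- diag(a, 3)
  coords <- fr %*% t(M)
  zero1 <- matrix(0, 1, 1)
  stc <- cspland:::settings_for_cpp(
    energy_settings(rd_cutoff = 1e-6, elec_cutoff = 14,
                    tail_correction = FALSE))
  ewald <- cspland:::cpp_cell_energy(coords, 1:8, rep(1L, 8), zero1,
                                     matrix(1, 1, 1), zero1, zero1, zero1,
                                     q, matrix(0, 8, 3), matrix(0, 8, 9),
                                     M, stc)$e_qq
  ## independent oracle: direct Coulomb over expanding cubes of whole
  ## (neutral) cells
  direct_shell <- function(radius) {
    acc <- 0
    for (shell in 0:radius) {
      offs <- cspland:::shell_offsets(shell)
      for (o in seq_len(nrow(offs))) {
        tv <- as.numeric(M %*% offs[o, ])
        home <- all(offs[o, ] == 0)
        for (i in 1:8) {
          d <- sweep(coords, 2, coords[i, ] - tv, FUN = "-")
          r <- sqrt(rowSums(d^2))
          keep <- r > 1e-9
          acc <- acc + sum(q[i] * q[keep] / r[keep])
        }
      }
    }
    0.5 * acc * cspland:::COULOMB_KJ / 8
  }
  d8 <- direct_shell(8)
  expect_lt(abs(ewald - d8) / abs(d8), 1e-4)
  ## and the literature Madelung constant as a second, independent anchor
  madelung <- -ewald * (a / 2) * 2 / cspland:::COULOMB_KJ
  expect_equal(madelung, 1.747565, tolerance = 1e-5)
  ## splitting-parameter independence
  st2 <- stc; st2$ewald_alpha <- 2 * 4.5 / 14
  ewald2 <- cspland:::cpp_cell_energy(coords, 1:8, rep(1L, 8), zero1,
                                      matrix(1, 1, 1), zero1, zero1, zero1,
                                      q, matrix(0, 8, 3), matrix(0, 8, 9),
                                      M, st2)$e_qq
  expect_lt(abs(ewald2 - ewald), 1e-6)
})

test_that("electrostatics handles degenerate and zero-charge inputs", {
  mol0 <- rigid_molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.13, 0, 0)))
  cr <- crystal(mol0, "P1", cell(6, 7, 8),
                placement(c(0.2, 0.2, 0.2), c(1, 0, 0, 0)))
  expect_equal(electrostatic_energy(cr, settings = energy_settings(elec_rank = 0L)), 0)
  mol_bad <- make_toy_molecule("diatomic")
  mol_bad$charges <- c(0.2, -0.1) # bypass constructor for the error path
  crb <- cr; crb$molecule <- mol_bad
  expect_error(electrostatic_energy(crb), "neutral")
})

test_that("dipole lattice terms match the closed form for a dipole chain", {
  ## one molecule per cell, dipoles on both atoms along z, chain along x
  mol <- rigid_molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                        multipoles = multipole_set(
                          c(0, 0), dipoles = rbind(c(0, 0, 0.3),
                                                   c(0, 0, 0.3))))
  a <- 6
  cr <- crystal(mol, "P1", cell(a, 80, 80),
                placement(c(0.5, 0.5, 0.5), c(1, 0, 0, 0)))
  st <- energy_settings(rd_cutoff = 1e-6, elec_cutoff = 10,
                        tail_correction = FALSE, clash_action = "wall")
  got <- electrostatic_energy(cr, settings = st, ff = fx_ff())
  ## closed form: parallel side-by-side dipoles at separations n*a (and
  ## the two intramolecular offsets). Rank >= 1 terms are summed over
  ## whole image cells in a block covering the cutoff: along the chain
  ## the block spans ceiling((cutoff + molecular extent)/a) = 2 cells.
  k <- cspland:::COULOMB_KJ
  u_pair <- function(d) {
    r <- sqrt(sum(d^2))
    (sum(c(0, 0, 0.3) * c(0, 0, 0.3)) * r^2 -
       3 * (sum(c(0, 0, 0.3) * d))^2) * k / r^5
  }
  expected <- 0
  for (nx in -2:2) for (ny in -1:1) for (nz in -1:1) {
    if (nx == 0 && ny == 0 && nz == 0) next # home cell: intramolecular
    for (i in c(0, 1.5)) for (j in c(0, 1.5)) {
      expected <- expected +
        0.5 * u_pair(c(j - i + nx * a, ny * 80, nz * 80))
    }
  }
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("truncated multipole energies converge to exact point-charge sums", {
  ## two rigid 3-charge linear quadrupoles; as separation grows the
  ## rank-2 truncated interaction approaches the exact Coulomb sum
  d <- 0.3
  pos <- rbind(c(0, 0, d), c(0, 0, -d), c(0, 0, 0))
  qv <- c(1, 1, -2) * 0.2
  Th <- matrix(0, 3, 3)
  for (i in 1:3) {
    r <- pos[i, ]
    Th <- Th + qv[i] * (3 * outer(r, r) - sum(r^2) * diag(3)) / 2
  }
  k <- cspland:::COULOMB_KJ
  exact <- function(R) {
    acc <- 0
    for (i in 1:3) for (j in 1:3)
      acc <- acc + k * qv[i] * qv[j] /
        sqrt(sum((pos[j, ] + c(0, 0, R) - pos[i, ])^2))
    acc
  }
  multi <- function(R) {
    zero1 <- matrix(0, 1, 1)
    stc <- cspland:::settings_for_cpp(
      energy_settings(rd_cutoff = 1e-6, elec_cutoff = R + 1,
                      tail_correction = FALSE))
    o <- cspland:::cpp_cell_energy(
      rbind(c(100, 100, 50), c(100, 100, 50 + R)), 1:2, c(1L, 1L),
      zero1, matrix(1, 1, 1), zero1, zero1, zero1, c(0, 0),
      matrix(0, 2, 3), rbind(as.numeric(Th), as.numeric(Th)),
      diag(200, 3), stc)
    (o$e_qq + o$e_multi) * 2
  }
  ## collinear axial quadrupoles: closed form 6 k Theta_zz^2 / R^5
  ## (1e-5 relative: the block sum includes far periodic images of the
  ## huge host cell, a ~1e-9 absolute contribution)
  expect_equal(multi(12), 6 * k * Th[3, 3]^2 / 12^5, tolerance = 1e-5)
  err6 <- abs(multi(6) - exact(6))
  err12 <- abs(multi(12) - exact(12))
  err24 <- abs(multi(24) - exact(24))
  expect_lt(err12, err6 / 16)   # hexadecapole-order decay or faster
  expect_lt(err24, err12 / 16)
  expect_lt(abs(multi(12) - exact(12)) / abs(exact(12)), 0.005)
})

test_that("lattice energy is additive, translation-invariant and converged in cutoff", {
  mol <- make_toy_molecule("bent_triatomic")
  cr <- crystal(mol, "P21/c", cell(5.5, 6.5, 7.0, 90, 98, 90),
                placement(c(0.13, 0.41, 0.72), c(0.9, 0.2, -0.3, 0.2)))
  ff <- fx_ff()
  st <- energy_settings(clash_action = "wall")
  eb <- lattice_energy(cr, ff, st)
  expect_equal(eb$E_latt, eb$E_repdisp + eb$E_elec, tolerance = 1e-12)
  ## shifting the centroid by a lattice vector changes nothing
  cr2 <- cr
  cr2$placement <- placement(cr$placement$centroid + c(1, -2, 3),
                             cr$placement$quat)
  eb2 <- lattice_energy(cr2, ff, st)
  expect_equal(eb2$E_latt, eb$E_latt, tolerance = 1e-10)
  ## raising the repdisp cutoff by 5 A moves E_latt by < 0.05 kJ/mol
  st_hi <- energy_settings(rd_cutoff = 20, clash_action = "wall")
  eb3 <- lattice_energy(cr, ff, st_hi)
  expect_lt(abs(eb3$E_repdisp - eb$E_repdisp), 0.05)
})

test_that("symmetry-reduced, P1-expanded and supercell energies agree", {
  mol <- make_toy_molecule("bent_triatomic")
  ff <- fx_ff()
  st <- energy_settings(rd_cutoff = 10, elec_cutoff = 10,
                        clash_action = "wall")
  for (sym in c("P21/c", "P212121")) {
    cl <- if (sym == "P21/c") cell(5.5, 6.5, 7.0, 90, 98, 90)
          else cell(5.5, 6.5, 7.0)
    cr <- crystal(mol, sym, cl,
                  placement(c(0.13, 0.41, 0.72), c(0.9, 0.2, -0.3, 0.2)))
    e_sym <- lattice_energy(cr, ff, st)$E_latt
    e_p1 <- lattice_energy_p1(cr, ff, st)
    expect_lt(abs(e_p1 - e_sym) / abs(e_sym), 1e-6)
    e_super <- lattice_energy_p1(cr, ff, st, supercell = c(2, 1, 1))
    expect_lt(abs(e_super - e_sym) / abs(e_sym), 1e-6)
  }
})

test_that("brute-force oracle converges and matches the production path", {
  mol <- make_toy_molecule("diatomic")
  ff <- fx_ff()
  ## radius 0 on a roomy single-molecule cell: no intermolecular pairs
  iso <- crystal(mol, "P1", cell(30, 30, 30),
                 placement(c(0.5, 0.5, 0.5), c(1, 0, 0, 0)))
  expect_equal(brute_force_energy(iso, ff, radius = 0L), 0)
  ## shell convergence is Cauchy by radius 6
  cr <- crystal(mol, "P21/c", cell(5, 6, 7, 90, 95, 90),
                placement(c(0.1, 0.2, 0.3), c(1, 0.3, 0.2, 0.1)))
  tr <- brute_force_energy(cr, ff, radius = 6L, trace = TRUE)
  expect_lt(abs(tr$shell_trace[7] - tr$shell_trace[6]), 5e-3)
  e_prod <- lattice_energy(cr, ff, energy_settings(clash_action = "wall"))
  expect_lt(abs(e_prod$E_latt - tr$energy), 0.01)
})

test_that("clash handling follows the configured action", {
  mol <- make_toy_molecule("diatomic")
  bad <- crystal(mol, "P1", cell(0.9, 25, 25), # 0.9 A image contact < floor
                 placement(c(0.5, 0.5, 0.5), c(1, 0, 0, 0)))
  expect_error(lattice_energy(bad, fx_ff(), energy_settings()), "clash")
  wall <- lattice_energy(bad, fx_ff(),
                         energy_settings(clash_action = "wall"))
  expect_true(is.finite(wall$E_latt))
  expect_gt(wall$E_latt, 1e3)
})
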