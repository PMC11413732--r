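## energy: lattice energy of a periodic rigid-molecule crystal.

#' Energy model settings
#'
#' @param rd_cutoff exp-6 repulsion-dispersion cutoff, Angstrom; an
#'   analytic -C/r^6 tail correction assuming uniform density is applied
#'   beyond it.
#' @param elec_cutoff real-space cutoff for electrostatics (Ewald real
#'   part and the rank >= 1 direct sums), Angstrom.
#' @param elec_rank electrostatic rank to use: 0 charges only, 1 adds
#'   dipoles, 2 adds quadrupoles (default).
#' @param ewald_alpha Ewald splitting parameter, 1/Angstrom; `0` selects
#'   `4.5 / elec_cutoff` automatically.
#' @param ewald_eps reciprocal-space truncation threshold.
#' @param tail_correction logical.
#' @param clash_floor hard floor on intermolecular pair distances; below
#'   it the geometry is considered unphysical.
#' @param clash_action `"error"` (raise a clash error, the default for
#'   user-level evaluation) or `"wall"` (continue on the inner repulsive
#'   cap, used during minimisation).
#' @return a list of class `energy_settings`.
#' @export
energy_settings <- function(rd_cutoff = 15, elec_cutoff = 15, elec_rank = 2L,
                            ewald_alpha = 0, ewald_eps = 1e-12,
                            tail_correction = TRUE, clash_floor = 0.3,
                            clash_action = c("error", "wall")) {
  stopifnot(rd_cutoff > 0, elec_cutoff > 0, elec_rank %in% 0:2)
  structure(list(rd_cutoff = rd_cutoff, elec_cutoff = elec_cutoff,
                 elec_rank = as.integer(elec_rank),
                 ewald_alpha = ewald_alpha, ewald_eps = ewald_eps,
                 tail_correction = isTRUE(tail_correction),
                 clash_floor = clash_floor,
                 clash_action = match.arg(clash_action),
                 kcoul = COULOMB_KJ),
            class = "energy_settings")
}

settings_for_cpp <- function(settings) {
  settings[c("rd_cutoff", "elec_cutoff", "elec_rank", "ewald_alpha",
             "ewald_eps", "tail_correction", "clash_floor", "kcoul")]
}

#' Trial / minimised crystal structure
#'
#' One rigid molecule in the asymmetric unit (Z' = 1) of a space group,
#' with a unit cell and a placement (fractional centroid + orientation
#' quaternion). Minimisation attaches an `energy` breakdown, `density`,
#' and convergence information to the same object.
#'
#' @param molecule a `rigid_molecule`.
#' @param group a `space_group` (or symbol/number resolvable by
#'   [get_spacegroup()]).
#' @param cl a `cell`; must satisfy the group's crystal-system constraints.
#' @param plc a [placement()].
#' @param id optional structure identifier.
#' @param provenance optional list (e.g. sampling seed and sequence index).
#' @return object of class `crystal`.
#' @export
crystal <- function(molecule, group, cl, plc, id = NULL, provenance = NULL) {
  group <- get_spacegroup(group)
  if (!cell_is_valid_for(group, cl))
    stop("cell violates ", group$system, " constraints for ", group$symbol)
  structure(list(molecule = molecule, group = group, cell = cl,
                 placement = plc, id = id, provenance = provenance,
                 energy = NULL, density = NULL, converged = NA,
                 n_steps = NULL, stage_history = NULL),
            class = "crystal")
}

#' @export
print.crystal <- function(x, ...) {
  cat(sprintf("<crystal %s | %s in %s | V = %.1f A^3%s%s>\n",
              if (is.null(x$id)) "" else x$id,
              x$molecule$name, x$group$symbol, cell_volume(x$cell),
              if (!is.null(x$energy))
                sprintf(" | E_latt = %.4f kJ/mol", x$energy$E_latt) else "",
              if (!is.null(x$density))
                sprintf(" | rho = %.3f g/cm^3", x$density) else ""))
  invisible(x)
}

#' Crystal density in g/cm^3
#' @param cr a `crystal`.
#' @export
crystal_density <- function(cr) {
  Z <- cr$group$multiplicity
  V <- cell_volume(cr$cell) # A^3
  Z * molecular_mass(cr$molecule) / (6.02214076e23 * V * 1e-24)
}

## Full unit-cell contents of a crystal as flat arrays for the kernels:
## coords (N x 3 Cartesian), molid, charges, Cartesian dipoles (N x 3),
## Cartesian quadrupole tensors (N x 9), plus per-image metadata.
cell_contents <- function(cr) {
  mol <- cr$molecule
  images <- expand_to_cell(cr$group, cr$cell, mol, cr$placement)
  n <- n_atoms(mol)
  Z <- length(images)
  dip_l <- dipole_cartesian(mol$multipoles)
  quad_l <- quadrupole_cartesian(mol$multipoles)
  coords <- do.call(rbind, lapply(images, `[[`, "coords"))
  frac <- do.call(rbind, lapply(images, `[[`, "frac"))
  dip <- do.call(rbind, lapply(images, function(im) dip_l %*% t(im$rotation)))
  quad <- do.call(rbind, lapply(images, function(im) {
    R <- im$rotation
    t(apply(quad_l, 1, function(qv) as.numeric(R %*% matrix(qv, 3, 3) %*% t(R))))
  }))
  list(coords = coords, frac = frac,
       molid = rep(seq_len(Z), each = n),
       elements = rep(mol$elements, Z),
       charges = rep(mol$charges, Z),
       dip = dip, quad = quad,
       parity = rep(vapply(images, `[[`, numeric(1), "parity"), each = n),
       centroids = do.call(rbind, lapply(images, `[[`, "centroid_frac")),
       Z = Z, n = n)
}

## Evaluate the kernels on explicit cell contents (used by lattice_energy,
## the P1 / supercell representation checks, and tests).
cell_energy <- function(contents, cellM, mol, ff, settings) {
  pt <- pair_tables(mol, ff)
  type_idx <- rep(pt$type_idx, contents$Z)
  out <- cpp_cell_energy(contents$coords, as.integer(contents$molid),
                         as.integer(type_idx), pt$A, pt$B, pt$C,
                         pt$rwall, pt$uwall, contents$charges,
                         contents$dip, contents$quad, cellM,
                         settings_for_cpp(settings))
  if (isTRUE(out$clash) && settings$clash_action == "error")
    stop(sprintf("clash: intermolecular contact %.3f A below floor %.2f A",
                 out$min_r, settings$clash_floor))
  out
}

#' Exp-6 pair energy
#'
#' `U(r) = A exp(-B r) - C r^-6`, kJ/mol.
#' @param params list with `A`, `B`, `C` (e.g. from [combine_params()]).
#' @param r separation, Angstrom (> 0).
#' @export
exp6_pair <- function(params, r) {
  if (any(r <= 0)) stop("exp-6 pair distance must be positive")
  params$A * exp(-params$B * r) - params$C / r^6
}

#' Repulsion-dispersion lattice energy
#'
#' Half-sum of [exp6_pair()] over all intermolecular atom pairs within the
#' cutoff (asymmetric-unit atoms against all symmetry/periodic images,
#' intramolecular pairs excluded), per molecule, plus the analytic uniform
#' density tail correction beyond the cutoff.
#'
#' @param cr a `crystal`.
#' @param ff a `force_field`.
#' @param settings an [energy_settings()].
#' @return energy in kJ/mol per molecule.
#' @export
repdisp_energy <- function(cr, ff, settings = energy_settings()) {
  contents <- cell_contents(cr)
  out <- cell_energy(contents, cell_matrix(cr$cell), cr$molecule, ff, settings)
  out$repdisp
}

#' Electrostatic lattice energy
#'
#' Charge-charge term by Ewald summation (independent of the splitting
#' parameter within tolerance); dipole and quadrupole terms by direct
#' summation with the electrostatic cutoff. Intramolecular interactions
#' are excluded; the result is per molecule. Requires a neutral cell.
#'
#' @inheritParams repdisp_energy
#' @param multipoles optional `multipole_set` overriding the molecule's.
#' @export
electrostatic_energy <- function(cr, multipoles = NULL,
                                 settings = energy_settings(), ff = NULL) {
  mol <- cr$molecule
  if (!is.null(multipoles)) {
    mol$multipoles <- multipoles
    mol$charges <- multipoles$Q[, "Q00"]
    cr$molecule <- mol
  }
  if (abs(sum(mol$charges)) > 1e-8)
    stop("electrostatics requires a charge-neutral cell")
  if (is.null(ff)) ff <- toy_forcefield()
  contents <- cell_contents(cr)
  ## suppress the repdisp part cheaply
  s2 <- settings; s2$rd_cutoff <- 1e-6; s2$tail_correction <- FALSE
  s2$clash_action <- "wall"
  out <- cell_energy(contents, cell_matrix(cr$cell), cr$molecule, ff, s2)
  out$elec
}

#' Total lattice energy with breakdown
#'
#' @inheritParams repdisp_energy
#' @return list of class `energy_breakdown` with `E_repdisp`, `E_elec`,
#'   `E_latt`, `converged` and a `settings` snapshot.
#' @export
lattice_energy <- function(cr, ff, settings = energy_settings()) {
  contents <- cell_contents(cr)
  out <- cell_energy(contents, cell_matrix(cr$cell), cr$molecule, ff, settings)
  ## net cell dipole (e A): dipole-dipole lattice sums are conditionally
  ## convergent, so energies of strongly polar cells depend on the
  ## summation convention (tin-foil Ewald here); report the magnitude
  P <- colSums(contents$charges * contents$coords) + colSums(contents$dip)
  structure(list(E_repdisp = out$repdisp, E_elec = out$elec,
                 E_qq = out$e_qq, E_multi = out$e_multi,
                 E_latt = out$repdisp + out$elec,
                 min_contact = out$min_r,
                 cell_dipole = sqrt(sum(P^2)),
                 converged = TRUE,
                 settings = settings),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<E_latt = %.4f kJ/mol (repdisp %.4f, elec %.4f)>\n",
              x$E_latt, x$E_repdisp, x$E_elec))
  invisible(x)
}

#' Evaluate the lattice energy from an explicit P1 / supercell expansion
#'
#' Re-describes the crystal as an explicit list of molecules in P1
#' (optionally replicated into a supercell) and evaluates the same
#' kernels on that representation. Used for the representation-invariance
#' checks: the result must agree with [lattice_energy()] on the
#' symmetry-reduced description.
#'
#' @inheritParams repdisp_energy
#' @param supercell integer vector of cell replications along a, b, c.
#' @return energy per molecule, kJ/mol.
#' @export
lattice_energy_p1 <- function(cr, ff, settings = energy_settings(),
                              supercell = c(1, 1, 1)) {
  contents <- cell_contents(cr)
  M <- cell_matrix(cr$cell)
  reps <- as.matrix(expand.grid(seq_len(supercell[1]) - 1,
                                seq_len(supercell[2]) - 1,
                                seq_len(supercell[3]) - 1))
  ncopy <- nrow(reps)
  N <- nrow(contents$coords)
  coords <- do.call(rbind, lapply(seq_len(ncopy), function(k)
    contents$coords + rep(as.numeric(M %*% reps[k, ]), each = N)))
  molid <- as.integer(rep(contents$molid, ncopy) +
                        rep((seq_len(ncopy) - 1) * contents$Z, each = N))
  big <- list(coords = coords, molid = molid,
              elements = rep(contents$elements, ncopy),
              charges = rep(contents$charges, ncopy),
              dip = do.call(rbind, replicate(ncopy, contents$dip,
                                             simplify = FALSE)),
              quad = do.call(rbind, replicate(ncopy, contents$quad,
                                              simplify = FALSE)),
              Z = contents$Z * ncopy, n = contents$n)
  Mbig <- M %*% diag(supercell)
  out <- cell_energy(big, Mbig, cr$molecule, ff, settings)
  out$repdisp + out$elec
}

#' Brute-force lattice energy oracle
#'
#' Direct double sum over an expanding block of image cells: no neighbour
#' lists, no Ewald. The charge part is summed over whole (neutral) cells,
#' shell by shell, so the conditionally convergent Coulomb sum converges
#' as the block grows. Intended as an independent test oracle on small
#' systems only.
#'
#' @param cr a `crystal`.
#' @param ff a `force_field`.
#' @param radius integer: image cells from -radius..radius are included
#'   along each axis.
#' @param elec_rank electrostatic rank (0-2).
#' @param trace if TRUE, also return the per-shell energy estimates.
#' @param accelerate apply Aitken delta-squared extrapolation to the last
#'   three shell partial sums (the Coulomb tail decays slowly and
#'   smoothly, so the acceleration gains roughly one shell's accuracy).
#' @return energy per molecule (kJ/mol), or a list with `energy` and
#'   `shell_trace` when `trace = TRUE`.
#' @export
brute_force_energy <- function(cr, ff, radius = 6L, elec_rank = 2L,
                               trace = FALSE, accelerate = FALSE) {
  contents <- cell_contents(cr)
  M <- cell_matrix(cr$cell)
  pt <- pair_tables(cr$molecule, ff)
  type_idx <- rep(pt$type_idx, contents$Z)
  N <- nrow(contents$coords)
  Z <- contents$Z
  coords <- contents$coords
  q <- contents$charges
  dip <- contents$dip
  quad <- contents$quad
  use_mp <- elec_rank >= 1 && (any(dip != 0) || any(quad != 0))

  shell_totals <- numeric(radius + 1)
  acc <- 0
  for (shell in 0:radius) {
    offsets <- shell_offsets(shell)
    for (o in seq_len(nrow(offsets))) {
      tvec <- as.numeric(M %*% offsets[o, ])
      home <- all(offsets[o, ] == 0)
      for (i in seq_len(N)) {
        dx <- sweep(coords, 2, coords[i, ] - tvec, FUN = "-")
        ## dx rows: r_j + t - r_i
        r2 <- rowSums(dx^2)
        keep <- rep(TRUE, N)
        if (home) keep <- contents$molid != contents$molid[i]
        keep <- keep & r2 > 1e-12
        if (!any(keep)) next
        r <- sqrt(r2[keep])
        ti <- type_idx[i]; tj <- type_idx[keep]
        u <- pt$A[ti, tj] * exp(-pt$B[ti, tj] * r) - pt$C[ti, tj] / r^6
        u <- u + q[i] * q[keep] * COULOMB_KJ / r
        if (use_mp) {
          u <- u + COULOMB_KJ * multipole_pair_terms(
            q[i], dip[i, ], matrix(quad[i, ], 3, 3),
            q[keep], dip[keep, , drop = FALSE], quad[keep, , drop = FALSE],
            dx[keep, , drop = FALSE])
        }
        acc <- acc + sum(u)
      }
    }
    shell_totals[shell + 1] <- 0.5 * acc / Z
  }
  est <- shell_totals[radius + 1]
  if (accelerate && radius >= 2) {
    s <- shell_totals[(radius - 1):(radius + 1)]
    denom <- (s[3] - s[2]) - (s[2] - s[1])
    if (abs(denom) > 1e-14) est <- s[3] - (s[3] - s[2])^2 / denom
  }
  if (trace) list(energy = est, shell_trace = shell_totals)
  else est
}

## integer offsets on the surface of the cube of the given radius
shell_offsets <- function(shell) {
  if (shell == 0) return(matrix(0L, 1, 3))
  g <- as.matrix(expand.grid(n1 = -shell:shell, n2 = -shell:shell,
                             n3 = -shell:shell))
  g[apply(abs(g), 1, max) == shell, , drop = FALSE]
}

## Vectorised rank>=1 multipole interaction terms (everything except the
## pure charge-charge Coulomb), energies WITHOUT the Coulomb prefactor.
## Independent R implementation used by the brute-force oracle.
multipole_pair_terms <- function(qi, mui, Thi, qj, muj, quadj, Rv) {
  r2 <- rowSums(Rv^2)
  r <- sqrt(r2)
  ir3 <- 1 / (r * r2); ir5 <- ir3 / r2; ir7 <- ir5 / r2; ir9 <- ir7 / r2
  mdR <- Rv %*% mui                      # (n)
  TiR <- Rv %*% Thi                      # n x 3, rows (Th R)_a
  TRR <- rowSums(TiR * Rv)
  phi <- mdR * ir3 + TRR * ir5
  u <- qj * phi
  ## gradient terms contracted with mu_j
  mjR <- rowSums(muj * Rv)
  mjmi <- as.numeric(muj %*% mui)
  mjTiR <- rowSums(muj * TiR)
  u <- u - qi * mjR * ir3 +
    (mjmi * ir3 - 3 * mdR * mjR * ir5) +
    (2 * mjTiR * ir5 - 5 * TRR * mjR * ir7)
  ## Hessian terms contracted with Theta_j / 3
  n <- nrow(Rv)
  qh <- numeric(n)
  if (all(quadj == 0)) return(as.numeric(u))
  for (k in seq_len(n)) {
    Tj <- matrix(quadj[k, ], 3, 3)
    R1 <- Rv[k, ]
    trTj <- sum(diag(Tj)) # ~0 (traceless)
    RTjR <- as.numeric(R1 %*% Tj %*% R1)
    h <- qi * (3 * RTjR * ir5[k] - trTj * ir3[k])
    h <- h + (-3 * (2 * as.numeric(mui %*% Tj %*% R1) + mdR[k] * trTj) * ir5[k] +
              15 * mdR[k] * RTjR * ir7[k])
    TiTj <- sum(Thi * Tj)
    TiRk <- TiR[k, ]
    h <- h + (2 * TiTj * ir5[k] -
              20 * as.numeric(TiRk %*% Tj %*% R1) * ir7[k] -
              5 * TRR[k] * trTj * ir7[k] +
              35 * TRR[k] * RTjR * ir9[k])
    qh[k] <- h / 3
  }
  as.numeric(u) + qh
}
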