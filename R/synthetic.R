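## synthetic_data: reproducible toy fixtures — molecules, planted
## reference crystals, and the stand-in high-level energy oracle.

TOY_TEMPLATES <- c("diatomic", "linear_triatomic", "bent_triatomic",
                   "planar_ring", "chiral_tetrahedron", "chiral_dipolar")

#' Construct a toy rigid molecule from a named template
#'
#' Small, neutral C/H/N/O/F molecules with frozen geometries and charge
#' patterns, mapped onto the bundled toy force-field types:
#' \describe{
#'   \item{diatomic}{polar CO-like rod (2 atoms).}
#'   \item{linear_triatomic}{CO2-like quadrupolar rod (3 atoms).}
#'   \item{bent_triatomic}{water-like bent dipole (3 atoms).}
#'   \item{planar_ring}{C4H4 square ring, apolar (8 atoms).}
#'   \item{chiral_tetrahedron}{C centre with H, N, O, F substituents at
#'     unequal bond lengths; chiral, moderately polar (5 atoms).}
#'   \item{chiral_dipolar}{the chiral tetrahedron with an amplified
#'     charge separation, engineered so heterochiral (racemic) packings
#'     are electrostatically favoured; used by the spontaneous-resolution
#'     fixtures (5 atoms).}
#' }
#' Deterministic: the same template always yields the same molecule.
#'
#' @param template template id.
#' @param name molecule name (defaults to the template id).
#' @return a `rigid_molecule`.
#' @export
make_toy_molecule <- function(template = TOY_TEMPLATES, name = NULL) {
  template <- match.arg(template)
  if (is.null(name)) name <- template
  tet <- function(d) {
    ## tetrahedral unit vectors scaled per-substituent
    u <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    u * d
  }
  out <- switch(template,
    diatomic = rigid_molecule(
      c("C", "O"), rbind(c(0, 0, 0), c(1.13, 0, 0)),
      charges = c(0.2, -0.2), name = name),
    linear_triatomic = rigid_molecule(
      c("O", "C", "O"),
      rbind(c(-1.16, 0, 0), c(0, 0, 0), c(1.16, 0, 0)),
      charges = c(-0.3, 0.6, -0.3), name = name),
    bent_triatomic = rigid_molecule(
      c("O", "H", "H"),
      rbind(c(0, 0, 0),
            c(0.9572, 0, 0),
            c(-0.2400, 0.9266, 0)),
      charges = c(-0.66, 0.33, 0.33), name = name),
    planar_ring = {
      s <- 1.45 / sqrt(2)
      cpos <- rbind(c(s, 0, 0), c(0, s, 0), c(-s, 0, 0), c(0, -s, 0))
      hpos <- cpos + cpos / sqrt(rowSums(cpos^2)) * 1.08
      rigid_molecule(c(rep("C", 4), rep("H", 4)), rbind(cpos, hpos),
                     charges = c(rep(-0.1, 4), rep(0.1, 4)), name = name)
    },
    chiral_tetrahedron = rigid_molecule(
      c("C", "H", "N", "O", "F"),
      rbind(c(0, 0, 0), tet(c(1.09, 1.47, 1.43, 1.35))),
      charges = c(0.50, 0.05, -0.10, -0.20, -0.25),
      name = name, is_chiral = TRUE, stereo_label = "R"),
    chiral_dipolar = rigid_molecule(
      c("C", "H", "N", "O", "F"),
      rbind(c(0, 0, 0), tet(c(1.09, 1.47, 1.43, 1.35))),
      charges = c(0.75, 0.15, -0.10, -0.35, -0.45),
      name = name, is_chiral = TRUE, stereo_label = "R"))
  out
}

#' Perturb a conformer by a target RMSD
#'
#' Seeded Gaussian displacements rescaled so that
#' `molecular_rmsd(original, perturbed)` equals `magnitude` (up to the
#' rigid-body component removed by the superposition, compensated
#' iteratively to within 10%).
#'
#' @param mol a `rigid_molecule`.
#' @param magnitude target RMSD, Angstrom (>= 0).
#' @param seed integer seed.
#' @return the perturbed `rigid_molecule`.
#' @export
perturb_conformer <- function(mol, magnitude, seed = 1L) {
  stopifnot(magnitude >= 0)
  if (magnitude == 0) return(mol)
  n <- n_atoms(mol)
  disp <- matrix(local_rnorm(seed, n * 3), n, 3)
  out <- mol
  scale <- magnitude / sqrt(mean(rowSums(disp^2)))
  for (it in 1:8) {
    out$coords <- mol$coords + disp * scale
    got <- molecular_rmsd(mol, out)
    if (abs(got - magnitude) <= 0.1 * magnitude) break
    scale <- scale * magnitude / max(got, 1e-12)
  }
  out$name <- paste0(mol$name, "-pert")
  out
}

local_rnorm <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  rnorm(n)
}

#' Plant a reference crystal structure
#'
#' Runs a short CSP (generate, minimise, deduplicate) in one space group
#' and returns the global minimum, re-minimised and certified as a local
#' minimum of the energy model. Plays the role of an experimentally
#' observed structure in matching tests: a fresh search should rediscover
#' it.
#'
#' @param mol a `rigid_molecule`.
#' @param group space group (symbol or `space_group`).
#' @param seed sampling seed.
#' @param n_trials accepted trial structures for the planting search.
#' @param ff force field.
#' @param schedule minimisation schedule.
#' @return a converged minimised `crystal` with provenance.
#' @export
plant_reference <- function(mol, group, seed = 1L, n_trials = 40L,
                            ff = toy_forcefield(),
                            schedule = quick_schedule()) {
  cfg <- sampler_config(seed = seed)
  trials <- generate_batch(group, mol, cfg, n_trials)
  mins <- minimize_batch(trials, ff, schedule)
  if (!length(mins)) stop("planting failed: no converged structure")
  E <- vapply(mins, function(m) m$energy$E_latt, numeric(1))
  best <- mins[[which.min(E)]]
  best <- run_schedule(best, ff, schedule) # certify fixed point
  if (!isTRUE(best$converged)) stop("planting failed: minimum not certified")
  best$id <- sprintf("ref-%s-%s-s%d", mol$name,
                     gsub("/", "_", get_spacegroup(group)$symbol), seed)
  best$provenance <- c(best$provenance,
                       list(planted = TRUE, n_trials = n_trials))
  best
}

#' Synthetic high-level energy oracle
#'
#' A deterministic stand-in for periodic electronic-structure lattice
#' energies: `E_high = E_latt(FF) + f(structure) + noise`, where `f` is a
#' fixed seeded linear functional of the per-molecule summed
#' atom-centred-descriptor vector (so the correction is learnable from
#' those descriptors by construction, making recovery experiments
#' well-posed) and the noise is Gaussian, seeded per structure id.
#'
#' @param amplitude target standard deviation of `f` across typical
#'   structures, kJ/mol.
#' @param noise_sd sd of the per-structure noise, kJ/mol.
#' @param seed seed fixing the functional's weights.
#' @param density_coef coefficient (kJ/mol per (g/cm^3)^2) of a mild
#'   quadratic density term. This part of `f` lies outside the linear
#'   descriptor span, so sparsely sampled regions of structure space
#'   carry a small systematic residual — the signal query-by-committee
#'   active learning exists to find. Set to 0 for a perfectly linear
#'   oracle.
#' @param descriptor a [descriptor_config()].
#' @return an object of class `synthetic_oracle`; call it via
#'   [oracle_energy()].
#' @export
synthetic_oracle <- function(amplitude = 5, noise_sd = 0.5, seed = 99L,
                             density_coef = 2, descriptor = descriptor_config()) {
  D <- descriptor_length(descriptor)
  w <- local_rnorm(seed, D)
  structure(list(w = w, amplitude = amplitude, noise_sd = noise_sd,
                 density_coef = density_coef,
                 seed = as.integer(seed), descriptor = descriptor,
                 scale = NA_real_),
            class = "synthetic_oracle")
}

## fold a structure id into a reproducible integer sub-seed
id_seed <- function(oracle_seed, id) {
  h <- sum(utf8ToInt(id) * (seq_len(nchar(id)) %% 97 + 1))
  as.integer((oracle_seed * 7919 + h) %% .Machine$integer.max)
}

#' Evaluate the synthetic oracle on a crystal
#'
#' @param oracle a [synthetic_oracle()].
#' @param cr a minimised `crystal` (with energy attached) or a `crystal`
#'   plus `ff` to evaluate the baseline.
#' @param ff force field for the baseline energy when not attached.
#' @return `E_high` in kJ/mol per molecule.
#' @export
oracle_energy <- function(oracle, cr, ff = toy_forcefield()) {
  e_ff <- if (!is.null(cr$energy)) cr$energy$E_latt
          else lattice_energy(cr, ff)$E_latt
  e_ff + oracle_f(oracle, cr) + oracle_noise(oracle, cr)
}

## the smooth functional part (no noise); per molecule
oracle_f <- function(oracle, cr) {
  phi <- structure_features(cr, oracle$descriptor)
  raw <- sum(oracle$w * phi) / n_atoms(cr$molecule)
  rho <- if (is.null(cr$density)) crystal_density(cr) else cr$density
  dc <- if (is.null(oracle$density_coef)) 0 else oracle$density_coef
  raw * oracle$amplitude / 25 + dc * (rho - 1.2)^2
}

oracle_noise <- function(oracle, cr) {
  if (oracle$noise_sd <= 0) return(0)
  id <- if (is.null(cr$id)) "anonymous" else cr$id
  local_rnorm(id_seed(oracle$seed, id), 1) * oracle$noise_sd
}

## per-molecule summed descriptor vector (sum over asymmetric-unit atoms)
structure_features <- function(cr, descriptor) {
  d <- featurize(cr, descriptor)
  colSums(d)
}
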