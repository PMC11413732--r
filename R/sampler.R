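## sampler: quasi-random trial crystal generation.

#' Halton low-discrepancy sequence with seeded Cranley-Patterson rotation
#'
#' Deterministic given (seed, index): the raw radical-inverse Halton point
#' in the first `dim` prime bases is shifted modulo 1 by a fixed random
#' offset derived from the seed. A leap of 409 decorrelates the higher
#' bases at small sample counts.
#'
#' @param index 0-based sequence index (scalar or vector).
#' @param dim dimensionality (<= 12 used by the sampler).
#' @param seed integer seed for the rotation offsets.
#' @return matrix `length(index)` x `dim` of points in `[0, 1)`.
#' @export
halton_point <- function(index, dim, seed = 1L) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41)
  if (dim > length(primes)) stop("halton_point supports up to 13 dimensions")
  shift <- withr_seed_uniform(seed, dim)
  out <- matrix(0, length(index), dim)
  for (d in seq_len(dim)) {
    b <- primes[d]
    k <- (index + 1) * 409 # leaped index, 1-based
    v <- numeric(length(k))
    f <- 1
    while (any(k > 0)) {
      f <- f / b
      v <- v + f * (k %% b)
      k <- k %/% b
    }
    out[, d] <- (v + shift[d]) %% 1
  }
  out
}

## uniforms from a seed without touching the global RNG state
withr_seed_uniform <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  runif(n)
}

#' Sampler configuration
#'
#' @param seed integer; all sampling is a pure function of (seed, index).
#' @param volume_range multiplicative window on the estimated molecular
#'   volume x multiplicity for the target cell volume.
#' @param length_ratio_range window of raw axial ratios before volume
#'   scaling.
#' @param angle_range sampled window for the free cell angles, degrees.
#' @param overlap_s intermolecular contacts closer than
#'   `s * (vdW_i + vdW_j)` fail the geometry check; contacts exactly at
#'   the threshold pass.
#' @param max_attempts attempts allowed per accepted structure before
#'   [generate_batch()] gives up.
#' @export
sampler_config <- function(seed = 1L, volume_range = c(0.5, 2.5),
                           length_ratio_range = c(0.5, 2.0),
                           angle_range = c(60, 120), overlap_s = 0.6,
                           max_attempts = 200L) {
  stopifnot(volume_range[1] > 0, diff(volume_range) > 0,
            diff(length_ratio_range) > 0, diff(angle_range) > 0,
            overlap_s > 0, overlap_s < 1, max_attempts >= 1)
  structure(list(seed = as.integer(seed), volume_range = volume_range,
                 length_ratio_range = length_ratio_range,
                 angle_range = angle_range, overlap_s = overlap_s,
                 max_attempts = as.integer(max_attempts)),
            class = "sampler_config")
}

#' Generate the index-th trial crystal for a space group
#'
#' Packing variables are drawn from the Halton sequence: free cell
#' parameters for the crystal system (axial ratios and free angles, then
#' an isotropic rescale to the target volume), centroid fractional
#' coordinates, and a uniform random orientation via the Shoemake
#' quaternion construction from three sequence dimensions. Deterministic
#' given `(cfg$seed, index)`.
#'
#' @param group a `space_group` (or key).
#' @param mol a `rigid_molecule`.
#' @param cfg a [sampler_config()].
#' @param index 0-based sequence index.
#' @return a `crystal` (not yet geometry-checked).
#' @export
next_trial <- function(group, mol, cfg, index) {
  group <- get_spacegroup(group)
  stopifnot(index >= 0)
  u <- halton_point(index, 13L, cfg$seed)[1, ]
  lr <- cfg$length_ratio_range
  ar <- cfg$angle_range
  ratios <- lr[1] + (lr[2] - lr[1]) * u[1:3]
  nfree_ang <- switch(group$system, triclinic = 3L, monoclinic = 1L,
                      orthorhombic = 0L)
  angles <- c(90, 90, 90)
  if (nfree_ang == 3L) {
    angles <- ar[1] + (ar[2] - ar[1]) * u[4:6]
  } else if (nfree_ang == 1L) {
    angles[2] <- ar[1] + (ar[2] - ar[1]) * u[4]
  }
  vr <- cfg$volume_range
  v_target <- (vr[1] + (vr[2] - vr[1]) * u[7]) *
    group$multiplicity * molecular_volume(mol)
  raw <- tryCatch(cell(ratios[1], ratios[2], ratios[3],
                       angles[1], angles[2], angles[3]),
                  error = function(e) NULL)
  if (is.null(raw)) {
    ## degenerate angle draw: fall back to right angles at same ratios
    raw <- cell(ratios[1], ratios[2], ratios[3])
  }
  scale <- (v_target / cell_volume(raw))^(1 / 3)
  cl <- constrain_cell(group, cell(ratios[1] * scale, ratios[2] * scale,
                                   ratios[3] * scale,
                                   raw$alpha, raw$beta, raw$gamma))
  plc <- placement(u[8:10], shoemake_quat(u[11:13]))
  crystal(mol, group, cl, plc,
          id = sprintf("%s-%s-i%06d-s%d", mol$name,
                       gsub("/", "_", group$symbol), index, cfg$seed),
          provenance = list(index = index, seed = cfg$seed))
}

#' Geometric sanity check for a trial crystal
#'
#' TRUE iff no intermolecular atom pair (over symmetry images and
#' neighbouring cells) is closer than `s * (vdW_i + vdW_j)` — pairs
#' exactly at the threshold pass — and the cell volume lies within the
#' configured window.
#'
#' @param trial a `crystal`.
#' @param cfg a [sampler_config()].
#' @export
geometry_check <- function(trial, cfg) {
  vr <- cfg$volume_range
  v <- cell_volume(trial$cell)
  v_est <- trial$group$multiplicity * molecular_volume(trial$molecule)
  if (!is.finite(v) || v < vr[1] * v_est || v > vr[2] * v_est) return(FALSE)
  contents <- cell_contents(trial)
  radii <- VDW_RADII[contents$elements]
  out <- cpp_min_contact(contents$coords, as.integer(contents$molid),
                         as.numeric(radii), cell_matrix(trial$cell),
                         cfg$overlap_s)
  out$min_margin >= -1e-9 # contacts exactly at the threshold pass
}

#' Generate a batch of geometry-checked trial crystals
#'
#' Consumes Halton indices in order until `n_valid` trials pass
#' [geometry_check()]. Reproducible: the batch is a pure function of
#' (molecule, group, config). Disjoint index ranges give disjoint work,
#' so per-group generation parallelises trivially.
#'
#' @inheritParams next_trial
#' @param n_valid number of accepted structures required.
#' @param start_index first sequence index to consume (0-based).
#' @return list of `crystal` objects of length `n_valid`.
#' @export
generate_batch <- function(group, mol, cfg, n_valid, start_index = 0L) {
  stopifnot(n_valid >= 0)
  out <- vector("list", n_valid)
  found <- 0L
  idx <- as.integer(start_index)
  attempts <- 0L
  max_att <- cfg$max_attempts * max(n_valid, 1L)
  while (found < n_valid) {
    if (attempts >= max_att)
      stop(sprintf(
        "sampler exhausted: %d/%d accepted after %d attempts (rate %.1f%%)",
        found, n_valid, attempts, 100 * found / attempts))
    trial <- next_trial(group, mol, cfg, idx)
    idx <- idx + 1L
    attempts <- attempts + 1L
    if (geometry_check(trial, cfg)) {
      found <- found + 1L
      out[[found]] <- trial
    }
  }
  out
}

#' Star-discrepancy estimate of a point set
#'
#' Sup over boxes `[0, x)` anchored at the origin of the difference
#' between the empirical fraction of points inside and the box volume,
#' with corners taken at the sample points (the standard lower-bound
#' estimator, adequate for comparing two samplers).
#' @param pts n x d matrix in the unit cube.
#' @export
star_discrepancy <- function(pts) {
  n <- nrow(pts)
  d <- ncol(pts)
  worst <- 0
  for (i in seq_len(n)) {
    x <- pts[i, ]
    vol <- prod(x)
    lt <- rep(TRUE, n); le <- rep(TRUE, n)
    for (k in seq_len(d)) {
      lt <- lt & pts[, k] < x[k]
      le <- le & pts[, k] <= x[k]
    }
    worst <- max(worst, abs(vol - sum(lt) / n), abs(vol - sum(le) / n))
  }
  worst
}
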