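## compare_dedup: PXRD screening, COMPACK-style cluster matching, dedup.

#' Comparison configuration
#'
#' @param n_molecules cluster size for reported match quality (RMSD_30
#'   convention uses 30; desk-scale fixtures use 15 through the same code
#'   path).
#' @param n_dedup cluster size used during deduplication.
#' @param dist_tol fractional tolerance on centroid distances from the
#'   central molecule (COMPACK-style, default 20%).
#' @param angle_tol orientation tolerance between paired molecules,
#'   degrees (default 20).
#' @param pxrd_threshold similarity above which a pair is nominated for
#'   cluster confirmation during dedup. The screen is a nomination
#'   filter, not a decision: the default is set low enough that no
#'   confirmed-duplicate pair on the bundled fixtures falls below it
#'   (imperfectly converged copies of one minimum can differ noticeably
#'   in peak positions).
#' @param two_theta_range,two_theta_step simulated pattern grid, degrees.
#' @param wavelength X-ray wavelength, Angstrom (Cu K-alpha default).
#' @param fwhm peak full width at half maximum, degrees 2-theta.
#' @param corr_width triangle weighting width for the de Gelder-style
#'   cross-correlation, degrees.
#' @export
compare_config <- function(n_molecules = 30L, n_dedup = 15L,
                           dist_tol = 0.20, angle_tol = 20,
                           pxrd_threshold = 0.85,
                           two_theta_range = c(5, 50), two_theta_step = 0.02,
                           wavelength = 1.5406, fwhm = 0.8,
                           corr_width = 4.0) {
  stopifnot(dist_tol > 0, angle_tol > 0, pxrd_threshold > 0,
            pxrd_threshold <= 1, fwhm > 0, corr_width > 0)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_dedup = as.integer(n_dedup), dist_tol = dist_tol,
                 angle_tol = angle_tol, pxrd_threshold = pxrd_threshold,
                 two_theta_range = two_theta_range,
                 two_theta_step = two_theta_step, wavelength = wavelength,
                 fwhm = fwhm, corr_width = corr_width),
            class = "compare_config")
}

#' Simulate a powder X-ray diffraction pattern
#'
#' Bragg peak positions from the reciprocal lattice
#' (`2theta = 2 asin(lambda / 2 d_hkl)`); intensities from structure
#' factors with atomic form factors approximated by the atomic number
#' (declared sufficient for similarity screening, not for Rietveld-grade
#' work); pseudo-Voigt broadening with fixed width; max-normalised.
#'
#' @param cr a `crystal`.
#' @param config a [compare_config()].
#' @param lorentz_polarization apply the standard LP factor?
#' @return list of class `powder_pattern` with `two_theta`, `intensity`,
#'   `wavelength`.
#' @export
simulate_pxrd <- function(cr, config = compare_config(),
                          lorentz_polarization = FALSE) {
  lam <- config$wavelength
  grid <- seq(config$two_theta_range[1], config$two_theta_range[2],
              by = config$two_theta_step)
  contents <- cell_contents(cr)
  M <- cell_matrix(cr$cell)
  B <- 2 * pi * t(solve(M))                 # reciprocal lattice (columns)
  zN <- ATOMIC_NUMBERS[contents$elements]
  frac <- contents$frac
  smax <- 2 * sin(max(grid) / 2 * pi / 180) / lam  # |G|/2pi upper bound
  hmax <- vapply(1:3, function(i) ceiling(smax * sqrt(sum(M[, i]^2))), numeric(1))
  hkl <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                               l = -hmax[3]:hmax[3]))
  hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE]
  G <- hkl %*% t(B)
  gnorm <- sqrt(rowSums(G^2))
  s <- gnorm / (2 * pi)                      # 1/d
  keep <- s <= smax & s >= 1e-8
  hkl <- hkl[keep, , drop = FALSE]
  s <- s[keep]
  two_theta <- 2 * asin(pmin(lam * s / 2, 1)) * 180 / pi
  keep2 <- two_theta >= grid[1] & two_theta <= grid[length(grid)]
  hkl <- hkl[keep2, , drop = FALSE]; two_theta <- two_theta[keep2]
  phase <- 2 * pi * (frac %*% t(hkl))        # natoms x npeaks
  Fre <- colSums(zN * cos(phase))
  Fim <- colSums(zN * sin(phase))
  I <- Fre^2 + Fim^2
  if (lorentz_polarization) {
    th <- two_theta / 2 * pi / 180
    I <- I * (1 + cos(2 * th)^2) / (sin(th)^2 * cos(th))
  }
  inten <- numeric(length(grid))
  if (length(I) && any(I > 0)) {
    fwhm <- config$fwhm
    sig <- fwhm / 2.354820045
    gam <- fwhm / 2
    for (p in seq_along(I)) {
      if (I[p] <= 0) next
      d <- grid - two_theta[p]
      w <- abs(d) < 5 * fwhm
      if (!any(w)) next
      pv <- 0.5 * exp(-d[w]^2 / (2 * sig^2)) +
        0.5 * gam^2 / (d[w]^2 + gam^2)       # eta = 0.5 pseudo-Voigt
      inten[w] <- inten[w] + I[p] * pv
    }
    if (max(inten) > 0) inten <- inten / max(inten)
  }
  structure(list(two_theta = grid, intensity = inten, wavelength = lam),
            class = "powder_pattern")
}

#' De Gelder-style weighted cross-correlation similarity of two patterns
#'
#' Normalised cross-correlation with triangle weighting of width
#' `config$corr_width` degrees; symmetric, scale-invariant in the
#' intensities, 1 for identical patterns.
#'
#' @param p,q `powder_pattern` objects on the same grid.
#' @param config a [compare_config()].
#' @export
pxrd_similarity <- function(p, q, config = compare_config()) {
  if (length(p$two_theta) != length(q$two_theta) ||
      max(abs(p$two_theta - q$two_theta)) > 1e-9)
    stop("powder patterns are on different 2-theta grids")
  step <- p$two_theta[2] - p$two_theta[1]
  ## weighted cross-correlation via one triangle smoothing:
  ## sum_k w_k sum_x f(x) g(x+k)  =  f . (w * g)
  sq <- triangle_smooth(q$intensity, config$corr_width, step)
  sp <- triangle_smooth(p$intensity, config$corr_width, step)
  cpq <- sum(p$intensity * sq)
  cpp_ <- sum(p$intensity * sp)
  cqq <- sum(q$intensity * sq)
  if (cpp_ <= 0 || cqq <= 0) return(0)
  max(min(cpq / sqrt(cpp_ * cqq), 1), 0)
}

triangle_smooth <- function(x, width, step) {
  nw <- max(1L, round(width / step))
  w <- 1 - abs(-nw:nw) / (nw + 1)
  y <- stats::filter(x, w, sides = 2)
  y[is.na(y)] <- 0
  as.numeric(y)
}

## molecular cluster around a central image: the n molecules whose
## centroids are nearest the central molecule's centroid
build_cluster <- function(cr, n, center_op = 1L) {
  contents <- cell_contents(cr)
  M <- cell_matrix(cr$cell)
  Z <- contents$Z
  natom <- contents$n
  cen_frac <- contents$centroids
  ## enough cells to surround the cluster
  vol_per_mol <- cell_volume(cr$cell) / Z
  rad <- (3 * n * vol_per_mol / (4 * pi))^(1 / 3) + 6
  hmax <- vapply(1:3, function(i) {
    others <- setdiff(1:3, i)
    nvec <- pracma_cross(M[, others[1]], M[, others[2]])
    h <- abs(cell_volume(cr$cell)) / sqrt(sum(nvec^2))
    ceiling(rad / h)
  }, numeric(1))
  offs <- as.matrix(expand.grid(-hmax[1]:hmax[1], -hmax[2]:hmax[2],
                                -hmax[3]:hmax[3]))
  cen0 <- as.numeric(M %*% cen_frac[center_op, ])
  mols <- list()
  for (o in seq_len(nrow(offs))) {
    tcart <- as.numeric(M %*% offs[o, ])
    for (z in seq_len(Z)) {
      idx <- which(contents$molid == z)
      cen <- as.numeric(M %*% cen_frac[z, ]) + tcart
      d <- sqrt(sum((cen - cen0)^2))
      mols[[length(mols) + 1]] <-
        list(coords = contents$coords[idx, , drop = FALSE] +
               rep(tcart, each = natom),
             centroid = cen, d = d, op = z,
             parity = contents$parity[idx[1]])
    }
  }
  ord <- order(vapply(mols, `[[`, numeric(1), "d"))
  mols[ord[seq_len(min(n, length(mols)))]]
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## rotation angle (degrees) between two placed copies of the same
## molecule. For linear molecules the Kabsch rotation has an arbitrary
## axial spin, so the angle between the (atom-order-signed) molecular
## axes is used instead.
orientation_angle <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  sv <- svd(a0)
  if (nrow(a0) < 3 || sv$d[2] < 1e-6 * sv$d[1]) {
    axa <- a0[nrow(a0), ] - a0[1, ]
    axb <- b0[nrow(b0), ] - b0[1, ]
    cs <- sum(axa * axb) / sqrt(sum(axa^2) * sum(axb^2))
    return(acos(pmin(pmax(cs, -1), 1)) * 180 / pi)
  }
  k <- kabsch_rmsd(a, b)
  ang <- acos(pmin(pmax((sum(diag(k$rotation)) - 1) / 2, -1), 1))
  ang * 180 / pi
}

#' COMPACK-style cluster match between two crystal structures
#'
#' Builds an `n`-molecule cluster around a central molecule in each
#' structure, superposes the central molecules, and seeks a one-to-one
#' correspondence in which every paired molecule agrees with the
#' reference within the distance-fraction and orientation-angle
#' tolerances. If all `n` molecules pair, the match is confirmed and
#' `rmsd_n` is the all-atom RMSD after least-squares superposition of the
#' complete clusters. The central molecule in the second structure is
#' searched over its symmetry images (and the pairing refined by two
#' assignment passes); ties break to the lowest RMSD.
#'
#' @param a,b `crystal` objects of the same molecule (same atom count and
#'   ordering).
#' @param config a [compare_config()].
#' @param n cluster size override (default `config$n_molecules`).
#' @return list of class `cluster_match` with `matched`, `n_matched`,
#'   `rmsd_n`.
#' @export
cluster_match <- function(a, b, config = compare_config(), n = NULL) {
  if (n_atoms(a$molecule) != n_atoms(b$molecule) ||
      !all(a$molecule$elements == b$molecule$elements))
    stop("structures are not of the same molecule")
  if (is.null(n)) n <- config$n_molecules
  natom <- n_atoms(a$molecule)
  cl_a <- build_cluster(a, n, center_op = 1L)
  if (length(cl_a) < n)
    return(structure(list(matched = FALSE, n_matched = 0L, rmsd_n = NA_real_),
                     class = "cluster_match"))
  best <- NULL
  ## the b-cluster carries a buffer beyond n so that ties at the cluster
  ## boundary (symmetry-equidistant shells) cannot spoil the pairing
  n_buf <- n + max(8L, ceiling(n / 2))
  for (cop in seq_len(b$group$multiplicity)) {
    cl_b <- build_cluster(b, n_buf, center_op = cop)
    if (length(cl_b) < n) next
    res <- try_cluster_pair(cl_a, cl_b, natom, config)
    if (!is.null(res) && (is.null(best) || res$rmsd_n < best$rmsd_n))
      best <- res
  }
  if (is.null(best))
    best <- list(matched = FALSE, n_matched = 0L, rmsd_n = NA_real_)
  structure(best, class = "cluster_match")
}

## The central-molecule superposition alone is degenerate for linear or
## near-symmetric molecules, so every alignment is seeded by the central
## molecule PLUS one neighbour, the pairing is made on atom-level
## distances, and the whole cluster is refined by joint superpositions.
try_cluster_pair <- function(cl_a, cl_b, natom, config) {
  n <- length(cl_a)
  transform_all <- function(cl, R, tvec) lapply(cl, function(m)
    list(coords = m$coords %*% t(R) + rep(tvec, each = natom),
         centroid = as.numeric(m$centroid %*% t(R) + tvec), d = m$d))
  best <- NULL
  seed_a <- rbind(cl_a[[1]]$coords, cl_a[[2]]$coords)
  for (j in 2:min(n + 2, length(cl_b))) {
    ka <- kabsch_rmsd(seed_a, rbind(cl_b[[1]]$coords, cl_b[[j]]$coords))
    if (ka$rmsd > 2) next # hopeless seed
    bco <- transform_all(cl_b, ka$rotation, as.numeric(ka$translation))
    pairing <- greedy_pair_atoms(cl_a, bco)
    if (is.null(pairing)) next
    for (iter in 1:2) {
      A <- do.call(rbind, lapply(cl_a, `[[`, "coords"))
      B <- do.call(rbind, lapply(bco[pairing], `[[`, "coords"))
      kj <- kabsch_rmsd(A, B)
      bco <- transform_all(bco, kj$rotation, as.numeric(kj$translation))
      p2 <- greedy_pair_atoms(cl_a, bco)
      if (is.null(p2) || identical(p2, pairing)) break
      pairing <- p2
    }
    ok <- TRUE
    for (i in seq_len(n)) {
      ma <- cl_a[[i]]; mb <- bco[[pairing[i]]]
      dref <- max(ma$d, 1e-6)
      if (i > 1 && abs(ma$d - mb$d) / dref > config$dist_tol) {
        ok <- FALSE; break
      }
      if (orientation_angle(ma$coords, mb$coords) > config$angle_tol) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    A <- do.call(rbind, lapply(cl_a, `[[`, "coords"))
    B <- do.call(rbind, lapply(bco[pairing], `[[`, "coords"))
    rmsd <- kabsch_rmsd(A, B)$rmsd
    if (is.null(best) || rmsd < best$rmsd_n)
      best <- list(matched = TRUE, n_matched = n, rmsd_n = rmsd)
  }
  best
}

## pair molecules by mean squared atomwise distance in the common frame,
## taking the globally smallest entries first (deterministic)
greedy_pair_atoms <- function(cl_a, bco) {
  n <- length(cl_a)
  msd <- matrix(Inf, n, length(bco))
  for (i in seq_len(n)) for (j in seq_along(bco)) {
    cd <- sum((cl_a[[i]]$centroid - bco[[j]]$centroid)^2)
    if (cd > 25) next # beyond any plausible pairing
    msd[i, j] <- mean(rowSums((cl_a[[i]]$coords - bco[[j]]$coords)^2))
  }
  pairing <- integer(n)
  for (k in seq_len(n)) {
    idx <- arrayInd(which.min(msd), dim(msd))
    if (!is.finite(msd[idx[1], idx[2]])) return(NULL)
    pairing[idx[1]] <- idx[2]
    msd[idx[1], ] <- Inf
    msd[, idx[2]] <- Inf
  }
  pairing
}

#' Deduplicate a set of minimised structures
#'
#' Two-stage duplicate removal: simulated-PXRD similarity at or above the
#' threshold nominates candidate pairs; [cluster_match()] at the dedup
#' cluster size confirms them. Connected components are collapsed to one
#' representative: lowest lattice energy, ties broken by higher density,
#' then input order. Output is sorted by energy.
#'
#' @param structures list of minimised `crystal` objects (same molecule).
#' @param config a [compare_config()].
#' @return list with `unique` (representatives, sorted by energy),
#'   `cluster` (integer label per input structure), and `n_unique`.
#' @export
deduplicate <- function(structures, config = compare_config()) {
  k <- length(structures)
  if (k == 0) return(list(unique = list(), cluster = integer(0), n_unique = 0L))
  pats <- lapply(structures, simulate_pxrd, config = config)
  ## all pairwise similarities at once via the smoothing identity
  step <- pats[[1]]$two_theta[2] - pats[[1]]$two_theta[1]
  P <- vapply(pats, `[[`, numeric(length(pats[[1]]$intensity)), "intensity")
  S <- vapply(pats, function(p)
    triangle_smooth(p$intensity, config$corr_width, step),
    numeric(nrow(P)))
  C <- crossprod(P, S)
  nrm <- sqrt(pmax(diag(C), 1e-300))
  simmat <- C / outer(nrm, nrm)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ord <- order(vapply(structures, function(s)
    if (is.null(s$energy)) NA_real_ else s$energy$E_latt, numeric(1)))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    i <- ord[a]; j <- ord[b]
    if (find(i) == find(j)) next
    if (simmat[i, j] < config$pxrd_threshold) next
    cm <- cluster_match(structures[[i]], structures[[j]], config,
                        n = config$n_dedup)
    if (cm$matched) parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(k), find, integer(1))
  labels <- match(roots, unique(roots))
  E <- vapply(structures, function(s)
    if (is.null(s$energy)) NA_real_ else s$energy$E_latt, numeric(1))
  rho <- vapply(structures, function(s)
    if (is.null(s$density)) crystal_density(s) else s$density, numeric(1))
  reps <- vapply(unique(roots), function(r) {
    members <- which(roots == r)
    members[order(E[members], -rho[members], members)][1]
  }, integer(1))
  reps <- reps[order(E[reps])]
  list(unique = structures[reps], cluster = labels,
       n_unique = length(reps))
}
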