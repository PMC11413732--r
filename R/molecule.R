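## chem_model: rigid molecules, atomic multipoles, exp-6 force field.

STANDARD_ELEMENTS <- c("C", "H", "N", "O", "F")

## Bondi-style van der Waals radii (Angstrom); used only for overlap checks
## and molecular volume estimates, never in the energy model.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47)

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998)
ATOMIC_NUMBERS <- c(H = 1, C = 6, N = 7, O = 8, F = 9)

#' Construct a rigid molecule
#'
#' A rigid molecule is an ordered set of atoms with Cartesian coordinates
#' (Angstrom), force-field atom types, point charges (elementary charge
#' units) and, optionally, atom-centred dipoles and quadrupoles. The
#' internal geometry is never altered by any pipeline stage; crystal
#' packings only translate and rotate the molecule as a whole.
#'
#' @param elements character vector of chemical symbols (C, H, N, O, F).
#' @param coords numeric n x 3 matrix of Cartesian coordinates, Angstrom.
#' @param ff_types force-field atom-type labels; defaults to the element.
#' @param charges point charges, elementary charge units; must sum to ~0.
#' @param name molecule identifier.
#' @param multipoles optional [multipole_set()]; its rank-0 components must
#'   equal `charges`.
#' @param is_chiral logical flag; see [make_toy_molecule()] templates.
#' @param stereo_label optional enantiomer tag (e.g. "R", "S", "mirror").
#' @return an object of class `rigid_molecule`.
#' @export
rigid_molecule <- function(elements, coords, ff_types = elements,
                           charges = numeric(length(elements)),
                           name = "mol", multipoles = NULL,
                           is_chiral = FALSE, stereo_label = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  if (n < 2L) stop("a rigid molecule needs at least 2 atoms")
  if (nrow(coords) != n || ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix matching 'elements'")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!all(elements %in% STANDARD_ELEMENTS))
    stop("elements outside the standard C,H,N,O,F set: ",
         paste(setdiff(elements, STANDARD_ELEMENTS), collapse = ", "))
  if (abs(sum(charges)) > 1e-8)
    stop(sprintf("molecule must be neutral; net charge %.3g", sum(charges)))
  if (is.null(multipoles)) {
    multipoles <- multipole_set(charges)
  } else {
    stopifnot(inherits(multipoles, "multipole_set"))
    if (nrow(multipoles$Q) != n)
      stop("multipole set size does not match atom count")
    if (max(abs(multipoles$Q[, "Q00"] - charges)) > 1e-8)
      stop("rank-0 multipole components must equal the atom charges")
  }
  structure(list(
    name = name,
    elements = as.character(elements),
    coords = unname(coords),
    ff_types = as.character(ff_types),
    charges = as.numeric(charges),
    multipoles = multipoles,
    is_chiral = isTRUE(is_chiral),
    stereo_label = stereo_label
  ), class = "rigid_molecule")
}

#' @export
print.rigid_molecule <- function(x, ...) {
  cat(sprintf("<rigid_molecule '%s': %d atoms (%s), net charge %.3f%s>\n",
              x$name, n_atoms(x), paste(unique(x$elements), collapse = ","),
              sum(x$charges), if (x$is_chiral) ", chiral" else ""))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `rigid_molecule`.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Molecular mass in g/mol
#' @param mol a `rigid_molecule`.
#' @export
molecular_mass <- function(mol) sum(ATOMIC_MASSES[mol$elements])

#' Estimated molecular volume (Angstrom^3)
#'
#' Sum of atomic van der Waals sphere volumes divided by a packing
#' efficiency prior of 0.7, i.e. an estimate of the crystal volume a
#' molecule occupies. Used only to set sampling bounds on cell volumes.
#' @param mol a `rigid_molecule`.
#' @param packing_efficiency assumed fraction of space filled by the
#'   vdW spheres in a crystal.
#' @export
molecular_volume <- function(mol, packing_efficiency = 0.7) {
  r <- VDW_RADII[mol$elements]
  sum(4 / 3 * pi * r^3) / packing_efficiency
}

#' Atom-centred multipole set (charges, dipoles, quadrupoles)
#'
#' Moments are stored as real spherical-tensor components per atom:
#' rank 0 `Q00` (charge, e), rank 1 `Q10,Q11c,Q11s` (dipole, e A) and
#' rank 2 `Q20,Q21c,Q21s,Q22c,Q22s` (quadrupole, e A^2), in the molecular
#' frame. Components are in e-Angstrom^l units throughout the package
#' (1 atomic unit of dipole = 0.529177 e A).
#'
#' @param charges rank-0 components (one per atom).
#' @param dipoles optional n x 3 matrix of Cartesian dipoles (e A) or an
#'   n x 3 matrix of spherical components `(Q10, Q11c, Q11s)`; Cartesian
#'   `(x, y, z)` equals spherical `(Q11c, Q11s, Q10)` reordered.
#' @param quadrupoles optional n x 5 matrix of spherical components
#'   `(Q20, Q21c, Q21s, Q22c, Q22s)` (e A^2).
#' @param rank highest rank present (0-2); inferred if missing.
#' @return object of class `multipole_set` with elements `rank` and `Q`
#'   (n x 9 matrix of spherical components, zero-padded).
#' @export
multipole_set <- function(charges, dipoles = NULL, quadrupoles = NULL,
                          rank = NULL) {
  n <- length(charges)
  Q <- matrix(0, n, 9,
              dimnames = list(NULL, c("Q00", "Q10", "Q11c", "Q11s",
                                      "Q20", "Q21c", "Q21s", "Q22c", "Q22s")))
  Q[, "Q00"] <- charges
  if (!is.null(dipoles)) {
    dipoles <- as.matrix(dipoles)
    stopifnot(nrow(dipoles) == n, ncol(dipoles) == 3)
    ## accept Cartesian (x,y,z); spherical is (Q10,Q11c,Q11s) = (z,x,y)
    Q[, c("Q11c", "Q11s", "Q10")] <- dipoles
  }
  if (!is.null(quadrupoles)) {
    quadrupoles <- as.matrix(quadrupoles)
    stopifnot(nrow(quadrupoles) == n, ncol(quadrupoles) == 5)
    Q[, c("Q20", "Q21c", "Q21s", "Q22c", "Q22s")] <- quadrupoles
  }
  if (is.null(rank)) {
    rank <- 0L
    if (any(Q[, 2:4] != 0)) rank <- 1L
    if (any(Q[, 5:9] != 0)) rank <- 2L
  }
  if (rank > 2L) stop("multipole ranks above 2 (quadrupole) are not implemented")
  structure(list(rank = as.integer(rank), Q = Q), class = "multipole_set")
}

## Cartesian dipole vectors (n x 3) from the spherical components.
dipole_cartesian <- function(mp) {
  cbind(mp$Q[, "Q11c"], mp$Q[, "Q11s"], mp$Q[, "Q10"])
}

## Cartesian traceless quadrupole tensors, Buckingham convention
## Theta_ab = sum_q q (3 x_a x_b - r^2 delta_ab) / 2, as an n x 9 matrix
## (rows are the 3x3 tensor in column-major order).
quadrupole_cartesian <- function(mp) {
  Q20 <- mp$Q[, "Q20"]; Q21c <- mp$Q[, "Q21c"]; Q21s <- mp$Q[, "Q21s"]
  Q22c <- mp$Q[, "Q22c"]; Q22s <- mp$Q[, "Q22s"]
  s3 <- sqrt(3) / 2
  xx <- -Q20 / 2 + s3 * Q22c
  yy <- -Q20 / 2 - s3 * Q22c
  zz <- Q20
  xy <- s3 * Q22s
  xz <- s3 * Q21c
  yz <- s3 * Q21s
  cbind(xx, xy, xz, xy, yy, yz, xz, yz, zz)
}

## Spherical multipoles (rank <= 2) of a set of point charges about an
## origin; the independent reference used to validate the conversions.
point_charge_multipoles <- function(charges, coords, origin = c(0, 0, 0)) {
  r <- sweep(as.matrix(coords), 2, origin)
  x <- r[, 1]; y <- r[, 2]; z <- r[, 3]
  rr <- x^2 + y^2 + z^2
  list(Q00 = sum(charges),
       Q10 = sum(charges * z),
       Q11c = sum(charges * x),
       Q11s = sum(charges * y),
       Q20 = sum(charges * (3 * z^2 - rr)) / 2,
       Q21c = sqrt(3) * sum(charges * x * z),
       Q21s = sqrt(3) * sum(charges * y * z),
       Q22c = sqrt(3) / 2 * sum(charges * (x^2 - y^2)),
       Q22s = sqrt(3) * sum(charges * x * y))
}

#' Exp-6 force field
#'
#' Homonuclear exp-6 parameters per force-field atom type, with combining
#' rules for the cross terms. The pair energy is
#' `U(r) = A exp(-B r) - C / r^6` with A, C in kJ/mol (C in kJ/mol A^6)
#' and B in 1/Angstrom.
#'
#' @param params data frame with columns `ff_type`, `A`, `B`, `C`.
#' @param combine named list of combining rules for A, B and C; each is
#'   `"geometric"` or `"arithmetic"`. Defaults: geometric mean for A and C,
#'   arithmetic mean for B.
#' @return object of class `force_field`.
#' @seealso [toy_forcefield()], [read_forcefield()], [combine_params()]
#' @export
force_field <- function(params,
                        combine = list(A = "geometric", B = "arithmetic",
                                       C = "geometric")) {
  params <- as.data.frame(params)
  stopifnot(all(c("ff_type", "A", "B", "C") %in% names(params)))
  if (anyDuplicated(params$ff_type)) stop("duplicate ff_type in parameter table")
  if (any(params$A < 0) || any(params$B <= 0) || any(params$C < 0))
    stop("exp-6 parameters must satisfy A >= 0, B > 0, C >= 0")
  stopifnot(all(unlist(combine) %in% c("geometric", "arithmetic")))
  structure(list(params = params, combine = combine), class = "force_field")
}

#' Bundled toy exp-6 parameter table
#'
#' A small self-consistent parameter set for C, H, N, O, F, derived once
#' from per-element well positions/depths (r0 = 2.6-3.6 A, eps =
#' 0.08-0.55 kJ/mol, steepness alpha = 13) via the standard exp-6
#' reparameterisation and frozen. These are *not* the published FIT
#' values; real parameter sets load via [read_forcefield()].
#' @return a `force_field`.
#' @export
toy_forcefield <- function() {
  force_field(data.frame(
    ff_type = c("H", "C", "N", "O", "F"),
    A = c(30336.92, 132724.02, 170645.17, 208566.31, 151684.59),
    B = c(5.000, 3.611, 3.824, 4.062, 4.333),
    C = c(45.896, 1414.909, 1291.015, 1096.751, 541.543)))
}

#' Combine exp-6 parameters for a type pair
#'
#' Cross-term parameters from the homonuclear values using the force
#' field's combining rules (default: geometric mean for A and C,
#' arithmetic mean for B). Symmetric in its type arguments.
#'
#' @param type_i,type_j force-field atom-type labels.
#' @param ff a [force_field()].
#' @return list with elements `A`, `B`, `C`.
#' @export
combine_params <- function(type_i, type_j, ff) {
  p <- ff$params
  i <- match(type_i, p$ff_type)
  j <- match(type_j, p$ff_type)
  if (is.na(i)) stop("no force-field parameters for type '", type_i, "'")
  if (is.na(j)) stop("no force-field parameters for type '", type_j, "'")
  comb <- function(x, y, rule)
    if (rule == "geometric") sqrt(x * y) else (x + y) / 2
  list(A = comb(p$A[i], p$A[j], ff$combine$A),
       B = comb(p$B[i], p$B[j], ff$combine$B),
       C = comb(p$C[i], p$C[j], ff$combine$C))
}

## Pair-parameter matrices (and the inner repulsive cap) for the set of
## types present in a molecule. The cap replaces the unphysical short-range
## attractive hole of the exp-6 form below its inner maximum r_wall by
## U(r_wall) + K (r_wall - r)^2, which joins with a continuous derivative.
pair_tables <- function(mol, ff) {
  types <- unique(mol$ff_types)
  nt <- length(types)
  A <- B <- C <- RW <- UW <- matrix(0, nt, nt, dimnames = list(types, types))
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    p <- combine_params(types[i], types[j], ff)
    A[i, j] <- p$A; B[i, j] <- p$B; C[i, j] <- p$C
    if (p$C > 0 && p$A > 0) {
      ## inner maximum of exp-6: A B e^{-B r} = 6 C / r^7, smallest root
      f <- function(r) p$A * p$B * exp(-p$B * r) - 6 * p$C / r^7
      lo <- 0.05; hi <- 0.05
      while (f(hi) < 0 && hi < 10) hi <- hi + 0.05
      rw <- if (hi >= 10) 0.1 else stats::uniroot(f, c(lo, hi))$root
      RW[i, j] <- rw
      UW[i, j] <- p$A * exp(-p$B * rw) - p$C / rw^6
    } else {
      RW[i, j] <- 0
      UW[i, j] <- p$A
    }
  }
  list(types = types, A = A, B = B, C = C, rwall = RW, uwall = UW,
       type_idx = match(mol$ff_types, types))
}

#' All-atom RMSD between two conformers after optimal superposition
#'
#' Least-squares superposition (translation plus proper rotation, Kabsch
#' algorithm) of two conformers of the same molecule, using atom order as
#' the correspondence.
#'
#' @param conf_a,conf_b `rigid_molecule` objects with identical atom counts
#'   and ordering.
#' @return RMSD in Angstrom.
#' @export
molecular_rmsd <- function(conf_a, conf_b) {
  if (n_atoms(conf_a) != n_atoms(conf_b))
    stop("atom count mismatch: ", n_atoms(conf_a), " vs ", n_atoms(conf_b))
  kabsch_rmsd(conf_a$coords, conf_b$coords)$rmsd
}

## Kabsch superposition of point sets (rows are points); returns the
## proper rotation R and translation mapping b onto a, plus the RMSD.
kabsch_rmsd <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(crossprod(b0, a0))            # 3x3
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)              # maps b0 rows: b0 %*% t(R)
  brot <- b0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((a0 - brot)^2)))
  list(rmsd = rmsd, rotation = R, translation = ca - cb %*% t(R))
}

#' Mirror image of a molecule
#'
#' Inverts all coordinates through the origin. Dipole components (polar
#' vectors) change sign; quadrupole components (even parity) are
#' unchanged; charges are unchanged.
#'
#' @param mol a `rigid_molecule`.
#' @return the inverted `rigid_molecule` (stereo_label gains/loses a
#'   `"mirror:"` prefix).
#' @export
mirror_image <- function(mol) {
  mp <- mol$multipoles
  Q <- mp$Q
  Q[, c("Q10", "Q11c", "Q11s")] <- -Q[, c("Q10", "Q11c", "Q11s")]
  label <- if (is.null(mol$stereo_label)) "mirror"
           else if (startsWith(mol$stereo_label, "mirror:"))
             sub("^mirror:", "", mol$stereo_label)
           else paste0("mirror:", mol$stereo_label)
  out <- mol
  out$coords <- -mol$coords
  out$multipoles <- multipole_set(Q[, "Q00"],
                                  dipoles = cbind(Q[, "Q11c"], Q[, "Q11s"], Q[, "Q10"]),
                                  quadrupoles = Q[, 5:9, drop = FALSE],
                                  rank = mp$rank)
  out$stereo_label <- label
  out
}

#' Write / read molecules in extended XYZ format
#'
#' Plain-text XYZ with two extension columns: `element x y z ff_type
#' charge`. An optional multipole block after the atom records carries
#' one line per atom with rank >= 1 components:
#' `MULTIPOLES <rank>` then `<atom index> Q10 Q11c Q11s [Q20 Q21c Q21s Q22c Q22s]`.
#'
#' @param mol a `rigid_molecule`.
#' @param path file path.
#' @return `read_molecule` returns a `rigid_molecule`.
#' @export
write_molecule <- function(mol, path) {
  n <- n_atoms(mol)
  lines <- c(as.character(n), mol$name,
             sprintf("%-2s %14.8f %14.8f %14.8f %s %10.6f",
                     mol$elements, mol$coords[, 1], mol$coords[, 2],
                     mol$coords[, 3], mol$ff_types, mol$charges))
  if (mol$multipoles$rank >= 1L) {
    Q <- mol$multipoles$Q
    lines <- c(lines, paste("MULTIPOLES", mol$multipoles$rank),
               sprintf("%d %s", seq_len(n),
                       apply(Q[, 2:9, drop = FALSE], 1,
                             function(v) paste(sprintf("%.10g", v), collapse = " "))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_molecule
#' @export
read_molecule <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  if (is.na(n) || length(lines) < n + 2L) stop("malformed molecule file: ", path)
  name <- lines[2]
  rec <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  if (any(lengths(rec) != 6L))
    stop("molecule records must have 6 fields: element x y z ff_type charge")
  rec <- do.call(rbind, rec)
  coords <- matrix(as.numeric(rec[, 2:4]), ncol = 3)
  mp <- NULL
  rest <- lines[-seq_len(n + 2L)]
  mi <- grep("^MULTIPOLES", rest)
  if (length(mi) == 1L) {
    rank <- as.integer(strsplit(trimws(rest[mi]), "\\s+")[[1]][2])
    mrec <- strsplit(trimws(rest[(mi + 1):(mi + n)]), "\\s+")
    mrec <- do.call(rbind, lapply(mrec, as.numeric))
    ord <- order(mrec[, 1])
    comps <- mrec[ord, -1, drop = FALSE]
    mp <- multipole_set(as.numeric(rec[, 6]),
                        dipoles = cbind(comps[, 2], comps[, 3], comps[, 1]),
                        quadrupoles = if (ncol(comps) >= 8) comps[, 4:8] else NULL,
                        rank = rank)
  }
  rigid_molecule(rec[, 1], coords, ff_types = rec[, 5],
                 charges = as.numeric(rec[, 6]), name = name, multipoles = mp)
}

#' Read an exp-6 parameter file
#'
#' Plain text, one record per type: `label A B C`. Lines starting with `#`
#' are comments.
#' @param path file path.
#' @param combine combining rules, as in [force_field()].
#' @return a `force_field`.
#' @export
read_forcefield <- function(path, combine = list(A = "geometric",
                                                 B = "arithmetic",
                                                 C = "geometric")) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rec <- strsplit(lines, "\\s+")
  if (any(lengths(rec) != 4L)) stop("force-field records must be: label A B C")
  rec <- do.call(rbind, rec)
  force_field(data.frame(ff_type = rec[, 1],
                         A = as.numeric(rec[, 2]),
                         B = as.numeric(rec[, 3]),
                         C = as.numeric(rec[, 4])), combine = combine)
}
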