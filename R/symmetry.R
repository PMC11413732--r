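## symmetry: space-group registry, asymmetric-unit expansion, cell handling.

## General positions (standard ITA settings: b-unique monoclinic, standard
## origin choices) for the bundled space groups. Triclinic, monoclinic and
## orthorhombic systems only; other groups load via read_spacegroup_table().
SG_TABLE <- list(
  list(1, "P1", "triclinic", "x,y,z"),
  list(2, "P-1", "triclinic", "x,y,z;-x,-y,-z"),
  list(4, "P21", "monoclinic", "x,y,z;-x,y+1/2,-z"),
  list(5, "C2", "monoclinic", "x,y,z;-x,y,-z;x+1/2,y+1/2,z;-x+1/2,y+1/2,-z"),
  list(7, "Pc", "monoclinic", "x,y,z;x,-y,z+1/2"),
  list(9, "Cc", "monoclinic", "x,y,z;x,-y,z+1/2;x+1/2,y+1/2,z;x+1/2,-y+1/2,z+1/2"),
  list(11, "P21/m", "monoclinic", "x,y,z;-x,y+1/2,-z;-x,-y,-z;x,-y+1/2,z"),
  list(12, "C2/m", "monoclinic",
       "x,y,z;-x,y,-z;-x,-y,-z;x,-y,z;x+1/2,y+1/2,z;-x+1/2,y+1/2,-z;-x+1/2,-y+1/2,-z;x+1/2,-y+1/2,z"),
  list(13, "P2/c", "monoclinic", "x,y,z;-x,y,-z+1/2;-x,-y,-z;x,-y,z+1/2"),
  list(14, "P21/c", "monoclinic", "x,y,z;-x,y+1/2,-z+1/2;-x,-y,-z;x,-y+1/2,z+1/2"),
  list(15, "C2/c", "monoclinic",
       "x,y,z;-x,y,-z+1/2;-x,-y,-z;x,-y,z+1/2;x+1/2,y+1/2,z;-x+1/2,y+1/2,-z+1/2;-x+1/2,-y+1/2,-z;x+1/2,-y+1/2,z+1/2"),
  list(18, "P21212", "orthorhombic",
       "x,y,z;-x,-y,z;x+1/2,-y+1/2,-z;-x+1/2,y+1/2,-z"),
  list(19, "P212121", "orthorhombic",
       "x,y,z;-x+1/2,-y,z+1/2;x+1/2,-y+1/2,-z;-x,y+1/2,-z+1/2"),
  list(29, "Pca21", "orthorhombic",
       "x,y,z;-x,-y,z+1/2;-x+1/2,y,z+1/2;x+1/2,-y,z"),
  list(33, "Pna21", "orthorhombic",
       "x,y,z;-x,-y,z+1/2;-x+1/2,y+1/2,z+1/2;x+1/2,-y+1/2,z"),
  list(36, "Cmc21", "orthorhombic",
       "x,y,z;-x,-y,z+1/2;-x,y,z;x,-y,z+1/2;x+1/2,y+1/2,z;-x+1/2,-y+1/2,z+1/2;-x+1/2,y+1/2,z;x+1/2,-y+1/2,z+1/2"),
  list(56, "Pccn", "orthorhombic",
       "x,y,z;-x+1/2,-y+1/2,z;x+1/2,-y,-z+1/2;-x,y+1/2,-z+1/2;-x,-y,-z;x+1/2,y+1/2,-z;-x+1/2,y,z+1/2;x,-y+1/2,z+1/2"),
  list(57, "Pbcm", "orthorhombic",
       "x,y,z;-x,-y,z+1/2;x,-y+1/2,-z;-x,y+1/2,-z+1/2;-x,-y,-z;x,y,-z+1/2;-x,y+1/2,z;x,-y+1/2,z+1/2"),
  list(60, "Pbcn", "orthorhombic",
       "x,y,z;-x+1/2,-y+1/2,z+1/2;x+1/2,-y+1/2,-z;-x,y,-z+1/2;-x,-y,-z;x+1/2,y+1/2,-z+1/2;-x+1/2,y+1/2,z;x,-y,z+1/2"),
  list(61, "Pbca", "orthorhombic",
       "x,y,z;-x+1/2,-y,z+1/2;x+1/2,-y+1/2,-z;-x,y+1/2,-z+1/2;-x,-y,-z;x+1/2,y,-z+1/2;-x+1/2,y+1/2,z;x,-y+1/2,z+1/2"),
  list(62, "Pnma", "orthorhombic",
       "x,y,z;-x+1/2,-y,z+1/2;x+1/2,-y+1/2,-z+1/2;-x,y+1/2,-z;-x,-y,-z;x+1/2,y,-z+1/2;-x+1/2,y+1/2,z+1/2;x,-y+1/2,z")
)

#' Parse a symmetry operation triplet
#'
#' Converts coordinate-triplet notation such as `"-x,y+1/2,-z+1/2"` into a
#' fractional 3x3 rotation part `W` and translation `w`.
#' @param triplet character scalar.
#' @return list with `W` (3x3) and `w` (length 3).
#' @export
parse_symop <- function(triplet) {
  parts <- strsplit(gsub(" ", "", tolower(triplet)), ",")[[1]]
  if (length(parts) != 3L) stop("bad symmetry triplet: ", triplet)
  W <- matrix(0, 3, 3)
  w <- numeric(3)
  for (k in 1:3) {
    expr <- parts[k]
    ## tokenize into signed terms
    expr <- gsub("-", "+-", expr, fixed = TRUE)
    terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
    terms <- terms[nzchar(terms)]
    for (t in terms) {
      sgn <- 1
      if (startsWith(t, "-")) { sgn <- -1; t <- substring(t, 2) }
      if (t %in% c("x", "y", "z")) {
        W[k, match(t, c("x", "y", "z"))] <- sgn
      } else if (grepl("^[0-9]+/[0-9]+$", t)) {
        f <- as.numeric(strsplit(t, "/", fixed = TRUE)[[1]])
        w[k] <- w[k] + sgn * f[1] / f[2]
      } else if (grepl("^[0-9.]+$", t)) {
        w[k] <- w[k] + sgn * as.numeric(t)
      } else stop("bad symmetry term '", t, "' in ", triplet)
    }
  }
  list(W = W, w = w %% 1)
}

symop_triplet <- function(op) {
  axes <- c("x", "y", "z")
  frac_str <- function(v) {
    if (abs(v) < 1e-9) return("")
    for (d in c(2, 3, 4, 6)) {
      n <- v * d
      if (abs(n - round(n)) < 1e-9)
        return(sprintf("%+d/%d", as.integer(round(n)), d))
    }
    sprintf("%+g", v)
  }
  paste(vapply(1:3, function(k) {
    s <- ""
    for (j in 1:3) {
      c <- op$W[k, j]
      if (c == 1) s <- paste0(s, if (nzchar(s)) "+" else "", axes[j])
      else if (c == -1) s <- paste0(s, "-", axes[j])
      else if (c != 0) stop("non-unit rotation element")
    }
    paste0(s, frac_str(op$w[k]))
  }, character(1)), collapse = ",")
}

make_spacegroup <- function(number, symbol, system, ops_str) {
  ops <- lapply(strsplit(ops_str, ";", fixed = TRUE)[[1]], parse_symop)
  dets <- vapply(ops, function(o) det(o$W), numeric(1))
  structure(list(number = as.integer(number), symbol = symbol,
                 system = system, ops = ops,
                 multiplicity = length(ops),
                 sohncke = all(dets > 0)),
            class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("<space_group %s (No. %d), %s, Z = %d, %s>\n", x$symbol,
              x$number, x$system, x$multiplicity,
              if (x$sohncke) "Sohncke" else "non-Sohncke"))
  invisible(x)
}

registry_env <- new.env(parent = emptyenv())

#' Space-group registry
#'
#' Bundled registry of the space groups most commonly adopted by Z' = 1
#' organic molecular crystals in the triclinic, monoclinic and
#' orthorhombic crystal systems (21 groups including P1), stored in their
#' standard ITA settings (b-unique monoclinic). Additional groups can be
#' loaded from a plain-text operation table via
#' [read_spacegroup_table()].
#'
#' @param default unused placeholder for future filtered registries.
#' @return named list of `space_group` objects (names are the
#'   Hermann-Mauguin symbols).
#' @export
spacegroup_registry <- function(default = TRUE) {
  if (is.null(registry_env$groups)) {
    registry_env$groups <- setNames(
      lapply(SG_TABLE, function(r) make_spacegroup(r[[1]], r[[2]], r[[3]], r[[4]])),
      vapply(SG_TABLE, function(r) r[[2]], character(1)))
  }
  registry_env$groups
}

#' Look up a space group by symbol or number
#' @param key Hermann-Mauguin symbol (e.g. `"P21/c"`) or international
#'   number; `space_group` objects pass through.
#' @param registry registry to search, default the bundled one.
#' @return a `space_group`.
#' @export
get_spacegroup <- function(key, registry = spacegroup_registry()) {
  if (inherits(key, "space_group")) return(key)
  if (is.numeric(key)) {
    hit <- Filter(function(g) g$number == key, registry)
    if (!length(hit)) stop("space group number ", key, " not in registry")
    return(hit[[1]])
  }
  g <- registry[[key]]
  if (is.null(g)) stop("space group symbol '", key, "' not in registry")
  g
}

#' Load space groups from a plain-text operation table
#'
#' Format: a header line `<number> <symbol> <crystal system>` followed by
#' one operation triplet per line; groups separated by blank lines.
#' @param path file path.
#' @return named list of `space_group` objects.
#' @export
read_spacegroup_table <- function(path) {
  lines <- trimws(readLines(path))
  groups <- list()
  block <- character()
  flush <- function(block, groups) {
    if (!length(block)) return(groups)
    hdr <- strsplit(block[1], "\\s+")[[1]]
    if (length(hdr) != 3L) stop("bad space-group header: ", block[1])
    g <- make_spacegroup(as.integer(hdr[1]), hdr[2], hdr[3],
                         paste(block[-1], collapse = ";"))
    groups[[g$symbol]] <- g
    groups
  }
  for (ln in lines) {
    if (!nzchar(ln)) { groups <- flush(block, groups); block <- character() }
    else block <- c(block, ln)
  }
  flush(block, groups)
}

#' Sohncke test
#'
#' TRUE iff every operation's rotation part is proper (determinant +1),
#' i.e. the group contains only translations, rotations and screw
#' rotations — the groups available to an enantiopure crystal.
#' @param group a `space_group`.
#' @export
is_sohncke <- function(group) {
  all(vapply(group$ops, function(o) det(o$W), numeric(1)) > 0)
}

## --- unit cell ---------------------------------------------------------

#' Unit cell
#' @param a,b,c lengths, Angstrom.
#' @param alpha,beta,gamma angles, degrees.
#' @return object of class `cell`.
#' @export
cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180,
            gamma > 0, gamma < 180)
  x <- structure(list(a = a, b = b, c = c,
                      alpha = alpha, beta = beta, gamma = gamma),
                 class = "cell")
  if (!is.finite(cell_volume(x)) || cell_volume(x) <= 0)
    stop("cell angles incompatible (non-positive metric volume)")
  x
}

#' @export
print.cell <- function(x, ...) {
  cat(sprintf("<cell %.3f %.3f %.3f A, %.2f %.2f %.2f deg, V = %.2f A^3>\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Cartesian lattice-vector matrix of a cell
#'
#' Columns are the lattice vectors a, b, c, with a along x and b in the
#' xy plane; `cart = M %*% frac`.
#' @param cl a `cell`.
#' @export
cell_matrix <- function(cl) {
  ca <- cos(cl$alpha * pi / 180); cb <- cos(cl$beta * pi / 180)
  cg <- cos(cl$gamma * pi / 180); sg <- sin(cl$gamma * pi / 180)
  czx <- cb
  czy <- (ca - cb * cg) / sg
  arg <- 1 - czx^2 - czy^2
  czz <- if (arg > 0) sqrt(arg) else NaN
  matrix(c(cl$a, 0, 0,
           cl$b * cg, cl$b * sg, 0,
           cl$c * czx, cl$c * czy, cl$c * czz), 3, 3)
}

#' Cell volume in Angstrom^3
#' @param cl a `cell`.
#' @export
cell_volume <- function(cl) {
  ca <- cos(cl$alpha * pi / 180); cb <- cos(cl$beta * pi / 180)
  cg <- cos(cl$gamma * pi / 180)
  arg <- 1 + 2 * ca * cb * cg - ca^2 - cb^2 - cg^2
  if (arg <= 0) return(NaN)
  cl$a * cl$b * cl$c * sqrt(arg)
}

#' Apply crystal-system constraints to a cell
#'
#' Fixes the constrained angles per crystal system (monoclinic: alpha =
#' gamma = 90 with b-unique setting; orthorhombic: all angles 90;
#' triclinic: unchanged). Idempotent.
#' @param group a `space_group` (or crystal-system string).
#' @param raw a `cell`.
#' @return the constrained `cell`.
#' @export
constrain_cell <- function(group, raw) {
  system <- if (inherits(group, "space_group")) group$system else group
  switch(system,
         triclinic = raw,
         monoclinic = cell(raw$a, raw$b, raw$c, 90, raw$beta, 90),
         orthorhombic = cell(raw$a, raw$b, raw$c, 90, 90, 90),
         stop("unsupported crystal system: ", system))
}

## number of free cell parameters per crystal system
n_free_cell_params <- function(system) {
  switch(system, triclinic = 6L, monoclinic = 4L, orthorhombic = 3L,
         stop("unsupported crystal system: ", system))
}

cell_is_valid_for <- function(group, cl) {
  tol <- 1e-6
  switch(group$system,
         triclinic = TRUE,
         monoclinic = abs(cl$alpha - 90) < tol && abs(cl$gamma - 90) < tol,
         orthorhombic = abs(cl$alpha - 90) < tol && abs(cl$beta - 90) < tol &&
           abs(cl$gamma - 90) < tol,
         FALSE)
}

## --- quaternions -------------------------------------------------------

## q = (w, x, y, z), unit norm
quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

## rotation vector (axis * angle, radians) -> quaternion
rotvec_to_quat <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(c(1, v / 2))
  c(cos(theta / 2), sin(theta / 2) * v / theta)
}

## Shoemake's mapping of three uniforms in [0,1) to a uniform rotation
shoemake_quat <- function(u) {
  s1 <- sqrt(1 - u[1]); s2 <- sqrt(u[1])
  quat_normalize(c(s1 * sin(2 * pi * u[2]), s1 * cos(2 * pi * u[2]),
                   s2 * sin(2 * pi * u[3]), s2 * cos(2 * pi * u[3])))
}

#' Molecular placement in the asymmetric unit
#' @param centroid fractional coordinates of the molecular centroid,
#'   each wrapped into `[0, 1)`.
#' @param quat unit quaternion `(w, x, y, z)` giving the molecular
#'   orientation.
#' @export
placement <- function(centroid, quat) {
  stopifnot(length(centroid) == 3, length(quat) == 4)
  structure(list(centroid = centroid %% 1, quat = quat_normalize(quat)),
            class = "placement")
}

## --- symmetry expansion ------------------------------------------------

#' Expand the asymmetric unit to the full cell contents
#'
#' Places the rigid molecule (rotated by the placement quaternion about
#' its centroid, centroid at the fractional position) and applies every
#' symmetry operation, producing one molecule image per operation. Images
#' are wrapped so their centroids lie in `[0,1)^3`. Improper operations
#' produce the mirror enantiomer; each image carries a `parity` flag
#' (determinant of its operation's rotation part).
#'
#' @param group a `space_group`.
#' @param cl a `cell` satisfying the group's crystal-system constraints.
#' @param mol a `rigid_molecule`.
#' @param plc a [placement()].
#' @return list of images, each a list with `coords` (n x 3 Cartesian, A),
#'   `frac` (n x 3 fractional), `rotation` (total 3x3 Cartesian transform
#'   applied to the molecular frame, improper for parity -1), `parity`,
#'   and `centroid_frac`.
#' @export
expand_to_cell <- function(group, cl, mol, plc) {
  if (!cell_is_valid_for(group, cl))
    stop("cell violates ", group$system, " constraints for ", group$symbol)
  M <- cell_matrix(cl)
  Minv <- solve(M)
  R0 <- quat_to_matrix(plc$quat)
  local <- sweep(mol$coords, 2, colMeans(mol$coords))
  cart0 <- t(R0 %*% t(local)) # rotated molecule about origin
  cen_cart <- as.numeric(M %*% plc$centroid)
  frac0 <- t(Minv %*% (t(cart0) + cen_cart))
  lapply(group$ops, function(op) {
    frac <- t(op$W %*% t(frac0)) + rep(op$w, each = nrow(frac0))
    cen <- colMeans(frac)
    shift <- floor(cen)
    frac <- sweep(frac, 2, shift)
    Ccart <- M %*% op$W %*% Minv
    list(coords = t(M %*% t(frac)),
         frac = frac,
         rotation = Ccart %*% R0,
         parity = det(op$W),
         centroid_frac = cen - shift)
  })
}
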