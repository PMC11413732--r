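## io_cli: CIF subset, landscape JSON-lines, and run configuration.

RUN_CONFIG_SECTIONS <- c("seed", "sampler", "energy", "schedule",
                         "compare", "analysis", "ml", "log_level")

#' Assemble a run configuration
#'
#' A serialisable container of every module's configuration plus the
#' global seed. Unknown sections are rejected.
#'
#' @param ... named sections from `r toString(RUN_CONFIG_SECTIONS)`.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  bad <- setdiff(names(cfg), RUN_CONFIG_SECTIONS)
  if (length(bad))
    stop("unknown run_config section(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Stable hash of a configuration
#'
#' Canonicalises the configuration (recursively sorting names) before
#' hashing, so semantically identical configurations (key reordering)
#' hash identically; any change to an energy-affecting value changes the
#' hash.
#' @param cfg any serialisable list.
#' @return hex string (32-bit FNV-1a over the canonical JSON).
#' @export
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canon)
      if (!is.null(names(x)) && any(nzchar(names(x))))
        x <- x[order(names(x))]
    }
    x
  }
  txt <- as.character(jsonlite::toJSON(canon(unclass(cfg)),
                                       auto_unbox = TRUE, digits = NA))
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a crystal structure to CIF
#'
#' Minimal crystallographic information file: cell parameters, space
#' group (symbol, number, and the full operation list as
#' `_symmetry_equiv_pos_as_xyz`), and fractional coordinates of the
#' asymmetric unit.
#'
#' @param cr a `crystal`.
#' @param path file path.
#' @export
write_cif <- function(cr, path) {
  mol <- cr$molecule
  contents <- cell_contents(cr)
  frac_asym <- contents$frac[contents$molid == 1, , drop = FALSE]
  cl <- cr$cell
  lines <- c(
    sprintf("data_%s", gsub("[^A-Za-z0-9_-]", "_",
                            if (is.null(cr$id)) mol$name else cr$id)),
    sprintf("_cell_length_a %.6f", cl$a),
    sprintf("_cell_length_b %.6f", cl$b),
    sprintf("_cell_length_c %.6f", cl$c),
    sprintf("_cell_angle_alpha %.6f", cl$alpha),
    sprintf("_cell_angle_beta %.6f", cl$beta),
    sprintf("_cell_angle_gamma %.6f", cl$gamma),
    sprintf("_symmetry_space_group_name_H-M '%s'", cr$group$symbol),
    sprintf("_space_group_IT_number %d", cr$group$number),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    vapply(cr$group$ops, function(op)
      sprintf("'%s'", symop_triplet(op)), character(1)),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    sprintf("%s%d %s %.7f %.7f %.7f",
            mol$elements, seq_len(n_atoms(mol)), mol$elements,
            frac_asym[, 1], frac_asym[, 2], frac_asym[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a crystal structure from CIF
#'
#' Parses the subset written by [write_cif()] (and simple external
#' files): cell, symmetry (H-M symbol, IT number, or explicit operation
#' list — groups are reconstructed by operation-set matching against the
#' registry when only operations are present), and fractional atom
#' sites. Falls back to P1 when no symmetry is given. The molecule is
#' rebuilt from the atom sites with the given template's ff_types and
#' charges when a `molecule` argument supplies them; otherwise types
#' default to elements and charges to zero.
#'
#' @param path file path.
#' @param molecule optional `rigid_molecule` supplying ff_types, charges
#'   and multipoles for the atom sites (atom order must match).
#' @param registry space-group registry for lookup.
#' @return a `crystal`.
#' @export
read_cif <- function(path, molecule = NULL,
                     registry = spacegroup_registry()) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  grab <- function(tag) {
    hit <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    val <- sub(paste0("^", tag, "\\s+"), "", hit[1])
    gsub("^'|'$", "", val)
  }
  cellvals <- suppressWarnings(vapply(
    c("_cell_length_a", "_cell_length_b", "_cell_length_c",
      "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma"),
    function(t) as.numeric(grab(t)), numeric(1)))
  cellvals <- unname(cellvals)
  if (anyNA(cellvals))
    stop("CIF missing cell parameters in ", path)
  cl <- cell(cellvals[1], cellvals[2], cellvals[3],
             cellvals[4], cellvals[5], cellvals[6])
  ## symmetry: prefer symbol, then number, then operation matching
  group <- NULL
  sym <- grab("_symmetry_space_group_name_H-M")
  if (!is.na(sym)) {
    sym2 <- gsub(" ", "", sym)
    group <- tryCatch(get_spacegroup(sym2, registry), error = function(e) NULL)
  }
  if (is.null(group)) {
    num <- suppressWarnings(as.integer(grab("_space_group_IT_number")))
    if (!is.na(num))
      group <- tryCatch(get_spacegroup(num, registry), error = function(e) NULL)
  }
  ops_idx <- grep("_symmetry_equiv_pos_as_xyz", lines)
  ops <- NULL
  if (length(ops_idx)) {
    k <- ops_idx[1] + 1
    trips <- character(0)
    while (k <= length(lines) && grepl("^'", lines[k])) {
      trips <- c(trips, gsub("^'|'$", "", lines[k]))
      k <- k + 1
    }
    if (length(trips)) ops <- lapply(trips, parse_symop)
  }
  if (is.null(group) && !is.null(ops)) {
    group <- match_group_by_ops(ops, registry)
    if (is.null(group))
      group <- structure(list(number = NA_integer_, symbol = "(from ops)",
                              system = "triclinic", ops = ops,
                              multiplicity = length(ops),
                              sohncke = all(vapply(ops, function(o)
                                det(o$W), numeric(1)) > 0)),
                         class = "space_group")
  }
  if (is.null(group)) group <- get_spacegroup("P1", registry)
  ## atom sites
  site_idx <- grep("^_atom_site_fract_x", lines)
  if (!length(site_idx)) stop("CIF missing atom sites in ", path)
  hdr_start <- grep("^_atom_site_", lines)
  cols <- lines[hdr_start[hdr_start <= max(hdr_start)]]
  first_data <- max(hdr_start) + 1
  recs <- list()
  k <- first_data
  while (k <= length(lines) && !startsWith(lines[k], "_") &&
         !startsWith(lines[k], "loop_") && !startsWith(lines[k], "data_")) {
    recs[[length(recs) + 1]] <- strsplit(lines[k], "\\s+")[[1]]
    k <- k + 1
  }
  if (!length(recs)) stop("CIF atom site loop is empty in ", path)
  nf <- lengths(recs)
  if (length(unique(nf)) != 1)
    stop("ragged atom site records in ", path)
  tab <- do.call(rbind, recs)
  col_names <- cols
  ix <- function(tag) {
    i <- match(tag, col_names)
    if (is.na(i)) stop("CIF missing column ", tag, " in ", path)
    i
  }
  fx <- as.numeric(tab[, ix("_atom_site_fract_x")])
  fy <- as.numeric(tab[, ix("_atom_site_fract_y")])
  fz <- as.numeric(tab[, ix("_atom_site_fract_z")])
  elems <- tab[, ix("_atom_site_type_symbol")]
  frac <- cbind(fx, fy, fz)
  M <- cell_matrix(cl)
  cart <- frac %*% t(M)
  if (!is.null(molecule)) {
    if (n_atoms(molecule) != nrow(cart) ||
        !all(molecule$elements == elems))
      stop("CIF atom sites do not match the supplied molecule")
    mol <- molecule
    mol$coords <- cart
  } else {
    mol <- rigid_molecule(elems, cart, name = "from_cif")
  }
  ## recover the placement: centroid + orientation of the asymmetric unit
  cen_frac <- colMeans(frac)
  local_ref <- sweep(if (!is.null(molecule)) molecule$coords else cart, 2,
                     colMeans(if (!is.null(molecule)) molecule$coords else cart))
  here <- sweep(cart, 2, colMeans(cart))
  kb <- kabsch_rmsd(here, local_ref)
  quat <- matrix_to_quat(kb$rotation)
  base_mol <- if (!is.null(molecule)) molecule else mol
  crystal(base_mol, group, cl, placement(cen_frac %% 1, quat),
          id = paste0("cif:", basename(path)))
}

## match a set of operations against the registry (mod lattice
## translations, order-insensitive)
match_group_by_ops <- function(ops, registry) {
  key <- function(oplist) {
    paste(sort(vapply(oplist, function(o)
      paste(c(round(o$W), round(o$w * 12) %% 12), collapse = ","),
      character(1))), collapse = ";")
  }
  target <- key(ops)
  for (g in registry) if (key(g$ops) == target) return(g)
  NULL
}

## quaternion from a proper rotation matrix (Shepperd's method)
matrix_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  quat_normalize(q)
}

#' Write / read a landscape as JSON-lines
#'
#' One JSON record per structure: id, space group symbol and number,
#' cell parameters, placement (centroid + quaternion), energies (total
#' and components, 1e-4 kJ/mol precision in the format contract but
#' stored at full precision), density, convergence and Sohncke flags,
#' and provenance. A header record carries the molecule (elements,
#' coordinates, types, charges, multipole components). Round-trips are
#' lossless to the stated precisions.
#'
#' @param ls a `landscape`.
#' @param path file path.
#' @export
write_landscape <- function(ls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  mol <- ls$molecule
  header <- list(record = "header", name = mol$name,
                 elements = mol$elements,
                 coords = unname(mol$coords),
                 ff_types = mol$ff_types, charges = mol$charges,
                 multipole_rank = mol$multipoles$rank,
                 multipoles = unname(mol$multipoles$Q),
                 is_chiral = mol$is_chiral,
                 n_structures = length(ls$structures))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (s in ls$structures) {
    rec <- list(record = "structure",
                id = if (is.null(s$id)) NA else s$id,
                group = s$group$symbol, number = s$group$number,
                sohncke = s$group$sohncke,
                cell = s$cell[c("a", "b", "c", "alpha", "beta", "gamma")],
                centroid = s$placement$centroid,
                quat = s$placement$quat,
                E_latt = s$energy$E_latt,
                E_repdisp = s$energy$E_repdisp,
                E_elec = s$energy$E_elec,
                density = s$density,
                converged = isTRUE(s$converged),
                provenance = s$provenance)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_landscape
#' @param registry space-group registry for symbol lookup.
#' @return `read_landscape` returns a [landscape()] (sorted by energy on
#'   read).
#' @export
read_landscape <- function(path, registry = spacegroup_registry()) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty landscape file: ", path)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$record, "header"))
    stop("landscape file must start with a header record: ", path)
  Q <- matrix(unlist(header$multipoles), ncol = 9)
  mp <- multipole_set(Q[, 1], dipoles = Q[, c(3, 4, 2)],
                      quadrupoles = Q[, 5:9, drop = FALSE],
                      rank = header$multipole_rank)
  mol <- rigid_molecule(header$elements,
                        matrix(unlist(header$coords), ncol = 3),
                        ff_types = header$ff_types,
                        charges = header$charges, name = header$name,
                        multipoles = mp,
                        is_chiral = isTRUE(header$is_chiral))
  structures <- lapply(lines[-1], function(ln) {
    rec <- jsonlite::fromJSON(ln)
    if (!identical(rec$record, "structure"))
      stop("unexpected record type '", rec$record, "' in ", path)
    cl <- cell(rec$cell[["a"]], rec$cell[["b"]], rec$cell[["c"]],
               rec$cell[["alpha"]], rec$cell[["beta"]], rec$cell[["gamma"]])
    group <- get_spacegroup(rec$group, registry)
    cr <- crystal(mol, group, cl, placement(rec$centroid, rec$quat),
                  id = if (is.null(rec$id) || is.na(rec$id)) NULL else rec$id,
                  provenance = rec$provenance)
    cr$energy <- structure(list(E_repdisp = rec$E_repdisp,
                                E_elec = rec$E_elec,
                                E_latt = rec$E_latt,
                                converged = isTRUE(rec$converged),
                                settings = NULL),
                           class = "energy_breakdown")
    cr$density <- rec$density
    cr$converged <- isTRUE(rec$converged)
    cr
  })
  landscape(structures, molecule = mol)
}
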