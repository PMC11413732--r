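## landscape_analysis: statistics over one or many crystal energy landscapes.

#' Crystal energy landscape
#'
#' An energy-sorted collection of unique (post-deduplication) minimised
#' structures of one molecule. Entry 1 is the global minimum.
#'
#' @param structures list of minimised `crystal` objects.
#' @param molecule optional `rigid_molecule` (defaults to the first
#'   structure's).
#' @return object of class `landscape` with `molecule`, `structures`
#'   (sorted by energy) and a `summary` data frame (id, group, number,
#'   sohncke, E_latt, density, converged).
#' @export
landscape <- function(structures, molecule = NULL) {
  if (length(structures)) {
    E <- vapply(structures, function(s) s$energy$E_latt, numeric(1))
    structures <- structures[order(E)]
  }
  if (is.null(molecule) && length(structures))
    molecule <- structures[[1]]$molecule
  summary <- if (length(structures)) data.frame(
    id = vapply(structures, function(s)
      if (is.null(s$id)) NA_character_ else s$id, character(1)),
    group = vapply(structures, function(s) s$group$symbol, character(1)),
    number = vapply(structures, function(s) s$group$number, integer(1)),
    sohncke = vapply(structures, function(s) s$group$sohncke, logical(1)),
    E_latt = vapply(structures, function(s) s$energy$E_latt, numeric(1)),
    density = vapply(structures, function(s)
      if (is.null(s$density)) crystal_density(s) else s$density, numeric(1)),
    converged = vapply(structures, function(s) isTRUE(s$converged), logical(1)),
    stringsAsFactors = FALSE)
  else data.frame(id = character(0), group = character(0),
                  number = integer(0), sohncke = logical(0),
                  E_latt = numeric(0), density = numeric(0),
                  converged = logical(0))
  structure(list(molecule = molecule, structures = structures,
                 summary = summary),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape '%s': %d unique structures%s>\n",
              if (is.null(x$molecule)) "?" else x$molecule$name,
              nrow(x$summary),
              if (nrow(x$summary))
                sprintf(", E_min = %.4f kJ/mol (%s)", x$summary$E_latt[1],
                        x$summary$group[1]) else ""))
  invisible(x)
}

#' Run a small CSP search and return the deduplicated landscape
#'
#' Convenience driver: [generate_batch()] + [minimize_batch()] +
#' [deduplicate()] over one or more space groups.
#'
#' @param mol a `rigid_molecule`.
#' @param groups character vector of space-group symbols (or list of
#'   `space_group`s).
#' @param n_per_group accepted trial structures per group.
#' @param cfg a [sampler_config()].
#' @param ff a `force_field`.
#' @param schedule a [stage_schedule()].
#' @param compare a [compare_config()].
#' @return a [landscape()].
#' @export
csp_search <- function(mol, groups, n_per_group = 100,
                       cfg = sampler_config(), ff = toy_forcefield(),
                       schedule = default_schedule(),
                       compare = compare_config()) {
  minimised <- list()
  for (g in groups) {
    trials <- generate_batch(g, mol, cfg, n_per_group)
    minimised <- c(minimised, minimize_batch(trials, ff, schedule))
  }
  dd <- deduplicate(minimised, compare)
  landscape(dd$unique, molecule = mol)
}

#' Analysis configuration
#'
#' @param polymorph_window energy window used for "low-energy structure"
#'   counting, kJ/mol (the usual limit of polymorphism).
#' @param thermal_window estimated error from neglecting thermal/
#'   vibrational contributions, kJ/mol.
#' @export
analysis_config <- function(polymorph_window = 7.2, thermal_window = 2.0) {
  stopifnot(polymorph_window > 0, thermal_window > 0)
  list(polymorph_window = polymorph_window, thermal_window = thermal_window)
}

#' Energy of a structure above the landscape minimum
#'
#' `E_latt(structure) - min(E_latt)` over the admissible reference set:
#' all structures, or only those in Sohncke groups when
#' `chiral_restriction = TRUE` (the convention for single-enantiomer
#' chiral molecules, whose racemic packings are not accessible
#' experimentally).
#'
#' @param ls a `landscape`.
#' @param structure a `crystal` in the landscape, or an index into it.
#' @param chiral_restriction restrict the reference set to Sohncke
#'   groups?
#' @return energy difference, kJ/mol.
#' @export
delta_e <- function(ls, structure, chiral_restriction = FALSE) {
  E <- if (is.numeric(structure)) ls$summary$E_latt[structure]
       else structure$energy$E_latt
  ref <- ls$summary$E_latt
  if (chiral_restriction) ref <- ref[ls$summary$sohncke]
  if (!length(ref)) stop("empty reference set for delta_e")
  E - min(ref)
}

#' Summarise reference matches across landscapes
#'
#' @param matches data frame with columns `matched` (logical) and
#'   `delta_e` (kJ/mol, NA when unmatched), one row per reference
#'   structure.
#' @param config an [analysis_config()].
#' @param bin histogram bin width, kJ/mol.
#' @return list with the histogram (`breaks`, `counts`), a cumulative
#'   curve evaluated on the bin edges (fraction of all references matched
#'   at or below each energy), and headline counts (at 0, within the
#'   thermal window, within 8 kJ/mol).
#' @export
match_summary <- function(matches, config = analysis_config(), bin = 0.5) {
  de <- matches$delta_e[matches$matched]
  n_total <- nrow(matches)
  top <- max(c(de, 8), na.rm = TRUE)
  breaks <- seq(0, ceiling(top / bin) * bin + bin, by = bin)
  counts <- if (length(de)) hist(de, breaks = breaks, plot = FALSE)$counts
            else integer(length(breaks) - 1)
  cumfrac <- if (n_total) cumsum(counts) / n_total else numeric(0)
  list(breaks = breaks, counts = counts,
       cumulative = data.frame(delta_e = breaks[-1], fraction = cumfrac),
       n_total = n_total, n_matched = sum(matches$matched),
       n_at_zero = sum(de <= 1e-6),
       n_within_thermal = sum(de <= config$thermal_window),
       n_within_8 = sum(de <= 8.0))
}

#' Space-group frequencies over a set of landscapes
#'
#' Three selectors: `"global_min"` counts each landscape once at its
#' minimum-energy structure's group; `"densest"` once at its
#' maximum-density structure's group; `"window"` pools every unique
#' structure within `window` kJ/mol of its landscape's minimum (set
#' `per_landscape = TRUE` to weight each landscape equally instead).
#' Frequencies are normalised to sum to 1.
#'
#' @param landscapes list of `landscape` objects.
#' @param selector one of `"global_min"`, `"densest"`, `"window"`.
#' @param window energy window for the window selector, kJ/mol.
#' @param per_landscape normalise window counts within each landscape
#'   before pooling?
#' @return data frame with `group`, `count`, `frequency`.
#' @export
spacegroup_frequencies <- function(landscapes,
                                   selector = c("global_min", "densest",
                                                "window"),
                                   window = 7.2, per_landscape = FALSE) {
  selector <- match.arg(selector)
  stopifnot(length(landscapes) >= 1)
  tally <- list()
  add <- function(tally, groups, w) {
    for (i in seq_along(groups)) {
      g <- groups[i]
      tally[[g]] <- (if (is.null(tally[[g]])) 0 else tally[[g]]) + w[i]
    }
    tally
  }
  for (ls in landscapes) {
    s <- ls$summary
    if (!nrow(s)) next
    if (selector == "global_min") {
      tally <- add(tally, s$group[which.min(s$E_latt)], 1)
    } else if (selector == "densest") {
      tally <- add(tally, s$group[which.max(s$density)], 1)
    } else {
      sel <- s$E_latt - min(s$E_latt) <= window
      w <- rep(if (per_landscape) 1 / sum(sel) else 1, sum(sel))
      tally <- add(tally, s$group[sel], w)
    }
  }
  counts <- unlist(tally)
  data.frame(group = names(counts), count = as.numeric(counts),
             frequency = as.numeric(counts) / sum(counts),
             row.names = NULL)[order(-unlist(tally)), ]
}

#' Chiral resolution analysis of one landscape
#'
#' Compares the best enantiopure (Sohncke) and best racemic
#' (non-Sohncke) packings of a chiral molecule:
#' `dE_latt = E_min(Sohncke) - E_min(non-Sohncke)` (positive means the
#' racemate is favoured) and
#' `d_rho = 100 * (rho_Sohncke - rho_racemic) / rho_racemic` (negative
#' means the enantiopure crystal is less dense, the Wallach direction).
#' Spontaneous resolution is predicted when `dE_latt < 0` strictly.
#'
#' @param ls a `landscape` of a chiral molecule with both group classes
#'   populated.
#' @return list of class `chirality_record` with `dE_latt`, `d_rho`,
#'   `resolution_predicted`, and the contributing structure ids.
#' @export
chirality_analysis <- function(ls) {
  if (!isTRUE(ls$molecule$is_chiral))
    stop("chirality analysis requires a chiral molecule")
  s <- ls$summary
  iS <- which(s$sohncke)
  iR <- which(!s$sohncke)
  if (!length(iS) || !length(iR))
    stop("both Sohncke and non-Sohncke structures are required")
  bS <- iS[which.min(s$E_latt[iS])]
  bR <- iR[which.min(s$E_latt[iR])]
  ## density at each class's energy minimum
  d_rho <- 100 * (s$density[bS] - s$density[bR]) / s$density[bR]
  structure(list(dE_latt = s$E_latt[bS] - s$E_latt[bR],
                 d_rho = d_rho,
                 resolution_predicted = s$E_latt[bS] < s$E_latt[bR],
                 sohncke_id = s$id[bS], racemic_id = s$id[bR]),
            class = "chirality_record")
}

#' @export
print.chirality_record <- function(x, ...) {
  cat(sprintf(
    "<chirality: dE_latt = %+.3f kJ/mol (%s favoured), d_rho = %+.2f%%>\n",
    x$dE_latt, if (x$resolution_predicted) "enantiopure" else "racemate",
    x$d_rho))
  invisible(x)
}

#' Match a landscape against a reference structure
#'
#' COMPACK-style search of every landscape entry against the reference;
#' returns the best confirmed match with its energy rank and distance
#' above the (optionally Sohncke-restricted) minimum.
#'
#' @param ls a `landscape`.
#' @param reference a `crystal`.
#' @param config a [compare_config()].
#' @param n cluster size (default `config$n_molecules`).
#' @param chiral_restriction compute `delta_e` among Sohncke groups only.
#' @return list of class `match_record`: `matched`, `rank`, `delta_e`,
#'   `rmsd_n`, `id`.
#' @export
match_reference <- function(ls, reference, config = compare_config(),
                            n = NULL, chiral_restriction = FALSE) {
  best <- list(matched = FALSE, rank = NA_integer_, delta_e = NA_real_,
               rmsd_n = NA_real_, id = NA_character_)
  for (i in seq_along(ls$structures)) {
    cm <- tryCatch(cluster_match(ls$structures[[i]], reference, config, n = n),
                   error = function(e) NULL)
    if (!is.null(cm) && cm$matched) {
      best <- list(matched = TRUE, rank = i,
                   delta_e = delta_e(ls, i, chiral_restriction),
                   rmsd_n = cm$rmsd_n, id = ls$summary$id[i])
      break # structures are energy-sorted; first confirmed match is best
    }
  }
  structure(best, class = "match_record")
}
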