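## minimizer: symmetry-constrained rigid-body lattice-energy minimisation.

#' Stage schedule for staged minimisation
#'
#' Each stage is a list with `elec_rank`, `rd_cutoff`, `elec_cutoff`
#' (Angstrom), `tol` (energy convergence tolerance, kJ/mol), and `maxit`.
#' Tolerances must tighten strictly down the schedule. The bundled
#' default reconstructs the usual staged protocol: (1) charges only at a
#' coarse cutoff and loose tolerance, (2) charges at production cutoffs,
#' (3) the configured multipole rank at the tightest tolerance; the final
#' energy is evaluated at stage-3 settings.
#'
#' @param stages list of stage lists.
#' @export
stage_schedule <- function(stages) {
  stopifnot(length(stages) >= 1)
  tols <- vapply(stages, `[[`, numeric(1), "tol")
  if (length(tols) > 1 && any(diff(tols) >= 0))
    stop("stage tolerances must tighten strictly down the schedule")
  structure(stages, class = "stage_schedule")
}

#' @rdname stage_schedule
#' @param elec_rank final-stage electrostatic rank.
#' @param rd_cutoff,elec_cutoff final-stage cutoffs, Angstrom.
#' @export
default_schedule <- function(elec_rank = 2L, rd_cutoff = 15,
                             elec_cutoff = 15) {
  stage_schedule(list(
    list(elec_rank = 0L, rd_cutoff = 8, elec_cutoff = 8,
         tol = 1e-2, maxit = 80L),
    list(elec_rank = 0L, rd_cutoff = rd_cutoff, elec_cutoff = elec_cutoff,
         tol = 1e-4, maxit = 120L),
    list(elec_rank = as.integer(elec_rank), rd_cutoff = rd_cutoff,
         elec_cutoff = elec_cutoff, tol = 1e-6, maxit = 200L)))
}

#' @rdname stage_schedule
#' @details `search_schedule()` is the economy protocol used when many
#'   hundreds of trial structures are swept in a search: same cutoffs as
#'   `quick_schedule()` but a looser final tolerance (1e-4 kJ/mol),
#'   enough to identify and rank packings for matching.
#' @export
search_schedule <- function(elec_rank = 0L) {
  stage_schedule(list(
    list(elec_rank = 0L, rd_cutoff = 8, elec_cutoff = 8,
         tol = 1e-2, maxit = 60L, ewald_alpha = 3.5 / 8, ewald_eps = 1e-8),
    list(elec_rank = as.integer(elec_rank), rd_cutoff = 8, elec_cutoff = 8,
         tol = 1e-4, maxit = 120L, ewald_alpha = 3.5 / 8,
         ewald_eps = 1e-8)))
}

#' @rdname stage_schedule
#' @details `quick_schedule()` is a two-stage economy protocol (8 A
#'   cutoffs throughout) used by the bundled desk-scale fixtures.
#' @export
quick_schedule <- function(elec_rank = 0L) {
  ## economy Ewald accuracy: real-space truncation ~1e-5 kJ/mol, well
  ## below the stage tolerances that matter during a search
  stage_schedule(list(
    list(elec_rank = 0L, rd_cutoff = 8, elec_cutoff = 8,
         tol = 1e-2, maxit = 80L, ewald_alpha = 3.5 / 8, ewald_eps = 1e-8),
    list(elec_rank = as.integer(elec_rank), rd_cutoff = 8, elec_cutoff = 8,
         tol = 1e-6, maxit = 250L, ewald_alpha = 3.5 / 8,
         ewald_eps = 1e-8)))
}

## pack free packing variables: free cell params + centroid + rotation
## increment (zero at the current orientation)
pack_params <- function(cr) {
  cl <- cr$cell
  cellp <- switch(cr$group$system,
                  triclinic = c(cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma),
                  monoclinic = c(cl$a, cl$b, cl$c, cl$beta),
                  orthorhombic = c(cl$a, cl$b, cl$c))
  c(cellp, cr$placement$centroid, c(0, 0, 0))
}

unpack_params <- function(p, cr) {
  sys <- cr$group$system
  nc <- n_free_cell_params(sys)
  cellp <- switch(sys,
                  triclinic = p[1:6],
                  monoclinic = c(p[1:3], 90, p[4], 90),
                  orthorhombic = c(p[1:3], 90, 90, 90))
  centroid <- p[(nc + 1):(nc + 3)]
  rotvec <- p[(nc + 4):(nc + 6)]
  quat <- quat_normalize(quat_multiply(rotvec_to_quat(rotvec),
                                       cr$placement$quat))
  list(cellpar = cellp, centroid = centroid, quat = quat)
}

param_bounds <- function(cr, mol) {
  sys <- cr$group$system
  nc <- n_free_cell_params(sys)
  ## generous box: lengths can shrink/grow substantially within a stage
  len_lo <- rep(1.5, 3); len_hi <- rep(80, 3)
  ang_lo <- rep(50, nc - 3); ang_hi <- rep(130, nc - 3)
  list(lower = c(len_lo, ang_lo, rep(-2, 3), rep(-pi, 3)),
       upper = c(len_hi, ang_hi, rep(3, 3), rep(pi, 3)))
}

## objective closure used by both minimize_stage and gradient certificates
make_objective <- function(cr, ff, stage) {
  mol <- cr$molecule
  pt <- pair_tables(mol, ff)
  local <- sweep(mol$coords, 2, colMeans(mol$coords))
  opsW <- do.call(rbind, lapply(cr$group$ops, function(o) as.numeric(t(o$W))))
  opsw <- do.call(rbind, lapply(cr$group$ops, function(o) o$w))
  dl <- dipole_cartesian(mol$multipoles)
  ql <- quadrupole_cartesian(mol$multipoles)
  st <- energy_settings(rd_cutoff = stage$rd_cutoff,
                        elec_cutoff = stage$elec_cutoff,
                        elec_rank = stage$elec_rank,
                        ewald_alpha = if (is.null(stage$ewald_alpha)) 0
                                      else stage$ewald_alpha,
                        ewald_eps = if (is.null(stage$ewald_eps)) 1e-12
                                    else stage$ewald_eps,
                        clash_action = "wall")
  stc <- settings_for_cpp(st)
  type_idx <- as.integer(pt$type_idx)
  q <- mol$charges
  sys <- cr$group$system
  nc <- n_free_cell_params(sys)
  quat0 <- cr$placement$quat
  eval_full <- function(p) {
    cellp <- switch(sys,
                    triclinic = p[1:6],
                    monoclinic = c(p[1:3], 90, p[4], 90),
                    orthorhombic = c(p[1:3], 90, 90, 90))
    quat <- quat_normalize(quat_multiply(rotvec_to_quat(p[(nc + 4):(nc + 6)]),
                                         quat0))
    cpp_param_energy(cellp, p[(nc + 1):(nc + 3)], quat, local, type_idx, q,
                     dl, ql, opsW, opsw, pt$A, pt$B, pt$C, pt$rwall,
                     pt$uwall, stc)
  }
  cache <- new.env(parent = emptyenv())
  fn <- function(p) {
    v <- eval_full(p)$e_latt
    cache$p <- p
    cache$f <- v
    v
  }
  ## forward-difference gradient reusing the objective value at p (the
  ## optimiser always evaluates fn(p) before requesting the gradient)
  gr <- function(p) {
    f0 <- if (!is.null(cache$p) && identical(cache$p, p)) cache$f
          else eval_full(p)$e_latt
    h <- 1e-4
    vapply(seq_along(p), function(i) {
      ph <- p
      ph[i] <- ph[i] + h
      (eval_full(ph)$e_latt - f0) / h
    }, numeric(1))
  }
  list(fn = fn, gr = gr, eval_full = eval_full)
}

#' Minimise the lattice energy for one stage
#'
#' Bounded quasi-Newton (L-BFGS-B) descent over the free packing
#' variables only: the crystal-system-free cell parameters (6/4/3 for
#' triclinic/monoclinic/orthorhombic), the centroid fractional
#' coordinates, and a 3-parameter rotation increment composed onto the
#' orientation quaternion. Space-group symmetry is preserved exactly by
#' construction. Gradients are central finite differences (step 1e-3).
#'
#' @param start a `crystal` (trial or previously minimised).
#' @param ff a `force_field`.
#' @param stage one stage of a [stage_schedule()].
#' @return the updated `crystal` with `energy`, `density`, `converged`,
#'   `n_steps` and an appended `stage_history` record. The energy trace of
#'   accepted (best-so-far) evaluations is non-increasing.
#' @export
minimize_stage <- function(start, ff, stage) {
  obj <- make_objective(start, ff, stage)
  p0 <- pack_params(start)
  bounds <- param_bounds(start, start$molecule)
  trace_env <- new.env(parent = emptyenv())
  trace_env$best <- Inf
  trace_env$accepted <- numeric(0)
  trace_env$n <- 0L
  fn <- function(p) {
    v <- obj$fn(p)
    trace_env$n <- trace_env$n + 1L
    if (v < trace_env$best) {
      trace_env$best <- v
      trace_env$accepted <- c(trace_env$accepted, v)
    }
    v
  }
  ## factr is relative to |f| ~ O(10) kJ/mol for these systems; divide by
  ## a characteristic scale so stage$tol acts as an absolute tolerance
  ctl <- list(maxit = stage$maxit,
              factr = max(stage$tol / .Machine$double.eps / 100, 10),
              ndeps = rep(1e-3, length(p0)))
  run_once <- function(p) tryCatch(
    optim(p, fn, gr = obj$gr, method = "L-BFGS-B", lower = bounds$lower,
          upper = bounds$upper, control = ctl),
    error = function(e) NULL)
  res <- run_once(p0)
  ## L-BFGS-B line searches occasionally abort on the small derivative
  ## discontinuities at the pair cutoffs; polish with derivative-free
  ## Nelder-Mead and restart with fresh curvature memory, then fall back
  ## on a numerical gradient certificate.
  restarts <- 0L
  while (!is.null(res) && res$convergence != 0 && restarts < 3L) {
    nm <- tryCatch(optim(res$par, fn, method = "Nelder-Mead",
                         control = list(maxit = 400)),
                   error = function(e) NULL)
    p_next <- if (!is.null(nm) && nm$value <= res$value) nm$par else res$par
    p_next <- pmin(pmax(p_next, bounds$lower), bounds$upper)
    res2 <- run_once(p_next)
    if (is.null(res2)) break
    if (!is.null(nm) && res2$value > nm$value) {
      res2$par <- nm$par; res2$value <- nm$value
    }
    res <- res2
    restarts <- restarts + 1L
  }
  grad_certified <- FALSE
  if (!is.null(res) && res$convergence != 0) {
    g <- vapply(seq_along(res$par), function(i) {
      ph <- res$par; pl <- res$par
      ph[i] <- ph[i] + 1e-4; pl[i] <- pl[i] - 1e-4
      (obj$fn(ph) - obj$fn(pl)) / 2e-4
    }, numeric(1))
    grad_certified <- max(abs(g)) < 0.1
  }
  if (is.null(res)) {
    out <- start
    out$converged <- FALSE
    out$stage_history <- c(out$stage_history,
                           list(list(stage = stage, error = "optim failure")))
    return(out)
  }
  up <- unpack_params(res$par, start)
  full <- obj$eval_full(res$par)
  if (!isTRUE(full$valid))
    stop("minimizer diverged into an invalid cell")
  v_est <- start$group$multiplicity * molecular_volume(start$molecule)
  if (full$volume < 0.15 * v_est || full$volume > 25 * v_est)
    stop(sprintf("minimizer divergence: cell volume %.1f A^3 outside [%.1f, %.1f]",
                 full$volume, 0.15 * v_est, 25 * v_est))
  out <- start
  out$cell <- constrain_cell(start$group,
                             cell(up$cellpar[1], up$cellpar[2], up$cellpar[3],
                                  up$cellpar[4], up$cellpar[5], up$cellpar[6]))
  out$placement <- placement(up$centroid, up$quat)
  out$energy <- structure(list(E_repdisp = full$repdisp, E_elec = full$elec,
                               E_qq = full$e_qq, E_multi = full$e_multi,
                               E_latt = full$e_latt,
                               min_contact = full$min_r,
                               converged = res$convergence == 0 || grad_certified,
                               settings = stage),
                          class = "energy_breakdown")
  out$density <- crystal_density(out)
  out$converged <- (res$convergence == 0 || grad_certified) &&
    !isTRUE(full$clash)
  out$n_steps <- trace_env$n
  out$stage_history <- c(start$stage_history,
                         list(list(stage = stage, E = full$e_latt,
                                   n_eval = trace_env$n,
                                   accepted_trace = trace_env$accepted,
                                   convergence = res$convergence)))
  out
}

#' Run a full minimisation schedule
#'
#' Chains [minimize_stage()] over the stages; the final energy is the
#' last stage's. Divergence in any stage propagates as an error (the
#' structure is discarded by batch drivers); non-convergence within
#' `maxit` is kept but flagged.
#'
#' @param start a `crystal`.
#' @param ff a `force_field`.
#' @param schedule a [stage_schedule()]; default [default_schedule()].
#' @return a minimised `crystal`.
#' @export
run_schedule <- function(start, ff, schedule = default_schedule()) {
  cur <- start
  for (stage in schedule) cur <- minimize_stage(cur, ff, stage)
  cur
}

#' Minimise a batch of trial structures
#'
#' Applies [run_schedule()] to each trial, dropping structures that
#' diverge (cell collapse/explosion or unresolvable clashes). Only
#' converged structures count towards landscape targets.
#'
#' @param trials list of `crystal` objects.
#' @param ff a `force_field`.
#' @param schedule a [stage_schedule()].
#' @param keep_unconverged keep structures flagged unconverged?
#' @return list of minimised `crystal` objects.
#' @export
minimize_batch <- function(trials, ff, schedule = default_schedule(),
                           keep_unconverged = FALSE) {
  out <- list()
  for (tr in trials) {
    m <- tryCatch(run_schedule(tr, ff, schedule), error = function(e) NULL)
    if (is.null(m)) next
    if (isTRUE(m$converged) || keep_unconverged) out <- c(out, list(m))
  }
  out
}

#' Numerical gradient certificate at a minimised structure
#'
#' Central finite-difference gradient of the final-stage objective over
#' the free packing variables.
#' @param cr a minimised `crystal`.
#' @param ff a `force_field`.
#' @param stage stage settings; default final stage of
#'   [default_schedule()].
#' @param step finite-difference step.
#' @return numeric gradient vector.
#' @export
energy_gradient <- function(cr, ff, stage = NULL, step = 1e-4) {
  if (is.null(stage)) stage <- default_schedule()[[3]]
  obj <- make_objective(cr, ff, stage)
  p <- pack_params(cr)
  g <- numeric(length(p))
  for (i in seq_along(p)) {
    ph <- p; pl <- p
    ph[i] <- p[i] + step; pl[i] <- p[i] - step
    g[i] <- (obj$fn(ph) - obj$fn(pl)) / (2 * step)
  }
  g
}
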