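## delta_ml: committee lattice-energy correction on atom-centred
## symmetry-function descriptors, with query-by-committee active learning.

#' Atom-centred symmetry-function descriptor configuration
#'
#' Radial G2 functions `sum_j exp(-eta (r - Rs)^2) fc(r)` per neighbour
#' element channel, and angular G4 functions over neighbour pairs per
#' unordered element-pair channel, with the cosine cutoff function.
#' Descriptors are invariant to rigid motions and to permutations of
#' identical atoms; periodic images are included.
#'
#' @param cutoff neighbour cutoff, Angstrom.
#' @param radial_centers G2 centres Rs, Angstrom.
#' @param radial_eta G2 width parameter, 1/A^2.
#' @param ang_eta G4 width parameter, 1/A^2.
#' @param ang_zeta G4 sharpness exponents.
#' @param ang_lambda G4 lambda signs.
#' @param elements element channels (fixed order).
#' @export
descriptor_config <- function(cutoff = 6, radial_centers = seq(1, 5.5, 0.75),
                              radial_eta = 4, ang_eta = 0.25,
                              ang_zeta = c(1, 4), ang_lambda = c(-1, 1),
                              elements = STANDARD_ELEMENTS) {
  stopifnot(cutoff > 0, length(radial_centers) > 0)
  structure(list(cutoff = cutoff, radial_centers = radial_centers,
                 radial_eta = radial_eta, ang_eta = ang_eta,
                 ang_zeta = ang_zeta, ang_lambda = ang_lambda,
                 elements = elements),
            class = "descriptor_config")
}

descriptor_length <- function(config) {
  ne <- length(config$elements)
  ne * length(config$radial_centers) +
    ne * (ne + 1) / 2 * length(config$ang_zeta) * length(config$ang_lambda)
}

#' Per-atom descriptors of the asymmetric unit of a crystal
#'
#' @param cr a `crystal`.
#' @param config a [descriptor_config()].
#' @return n_atoms x D numeric matrix (rows follow the molecule's atom
#'   order).
#' @export
featurize <- function(cr, config = descriptor_config()) {
  contents <- cell_contents(cr)
  elem_idx <- match(contents$elements, config$elements)
  if (anyNA(elem_idx)) stop("element outside the descriptor channels")
  cpp_acsf(contents$coords, as.integer(elem_idx),
           length(config$elements), cell_matrix(cr$cell),
           as.integer(seq_len(contents$n)), # asymmetric unit = image 1
           config$cutoff, config$radial_centers, config$radial_eta,
           config$ang_eta, config$ang_zeta, config$ang_lambda)
}

## per-atom regression inputs: the descriptor row plus an element one-hot
## block (the member networks carry per-element behaviour through it)
atom_features <- function(cr, config) {
  d <- featurize(cr, config)
  ne <- length(config$elements)
  onehot <- matrix(0, nrow(d), ne)
  el <- match(cr$molecule$elements, config$elements)
  onehot[cbind(seq_len(nrow(d)), el)] <- 1
  cbind(d, onehot)
}

## per-structure feature vector of one committee member: hidden-layer
## tanh activations summed over atoms, plus a linear skip connection
## (the summed standardised atom features themselves). The skip keeps
## corrections that are linear in the descriptors exactly representable;
## the hidden units supply curvature and off-manifold disagreement.
## Both blocks are per-atom quantities summed over the molecule.
member_z <- function(af_std, W, b) {
  act <- tanh(af_std %*% W + rep(b, each = nrow(af_std)))
  c(colSums(act), colSums(af_std))
}

#' Build a correction dataset from landscapes and an oracle
#'
#' Samples up to `per_compound_n` unique structures per landscape,
#' uniformly within `window` kJ/mol of each landscape's minimum, and
#' labels them with `dE_target = E_highlevel - E_latt(FF)` per molecule.
#' Compounds are split ~85% train / rest extrapolation (floor rule, at
#' least one extrapolation compound); one structure per training
#' compound is withheld as an in-domain test set.
#'
#' @param landscapes list of `landscape` objects (distinct compounds).
#' @param oracle a [synthetic_oracle()] (or any function
#'   `(crystal) -> kJ/mol`).
#' @param per_compound_n max structures per compound.
#' @param window energy window, kJ/mol.
#' @param seed selection seed.
#' @return list of class `correction_dataset` with `records` (list of
#'   crystal/target/compound/split) and a `summary` data frame.
#' @export
build_dataset <- function(landscapes, oracle, per_compound_n = 10L,
                          window = 8.0, seed = 1L) {
  records <- list()
  compounds <- character(0)
  eval_oracle <- if (inherits(oracle, "synthetic_oracle"))
    function(cr) oracle_energy(oracle, cr) else oracle
  for (li in seq_along(landscapes)) {
    ls <- landscapes[[li]]
    s <- ls$summary
    if (!nrow(s)) next
    sel <- which(s$E_latt - min(s$E_latt) <= window)
    if (!length(sel)) next
    if (length(sel) > per_compound_n) {
      ord <- sample_with_seed(length(sel), per_compound_n,
                              seed + 31L * li)
      sel <- sel[ord]
    }
    comp <- ls$molecule$name
    compounds <- union(compounds, comp)
    for (i in sel) {
      cr <- ls$structures[[i]]
      records[[length(records) + 1]] <-
        list(crystal = cr, compound = comp,
             e_ff = s$E_latt[i],
             target = eval_oracle(cr) - s$E_latt[i],
             split = NA_character_)
    }
  }
  if (!length(records))
    return(structure(list(records = list(),
                          summary = data.frame()), class = "correction_dataset"))
  ## compound split: ~85% train, >= 1 extrapolation
  ncomp <- length(compounds)
  n_train <- max(1L, min(ncomp - 1L, floor(0.85 * ncomp)))
  ord <- sample_with_seed(ncomp, ncomp, seed + 7L)
  train_comp <- compounds[ord[seq_len(n_train)]]
  for (k in seq_along(records)) {
    records[[k]]$split <-
      if (records[[k]]$compound %in% train_comp) "train" else "extrapolation"
  }
  ## withhold one in-domain test structure per training compound
  for (comp in train_comp) {
    idx <- which(vapply(records, function(r)
      r$compound == comp && r$split == "train", logical(1)))
    if (length(idx) >= 2) {
      pick <- idx[sample_with_seed(length(idx), 1L,
                                   seed + 101L + id_seed(1L, comp) %% 1000L)]
      records[[pick]]$split <- "test"
    }
  }
  summary <- data.frame(
    compound = vapply(records, `[[`, character(1), "compound"),
    split = vapply(records, `[[`, character(1), "split"),
    e_ff = vapply(records, `[[`, numeric(1), "e_ff"),
    target = vapply(records, `[[`, numeric(1), "target"))
  structure(list(records = records, summary = summary),
            class = "correction_dataset")
}

sample_with_seed <- function(n, k, seed) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(n, k)
}

#' Train a committee correction model
#'
#' A committee of `M` small feed-forward regressors on per-atom
#' descriptors: each member applies its own seeded random hidden layer
#' (tanh units over the atom descriptor plus an element one-hot block)
#' to every atom, sums the per-atom activations over the molecule, and
#' fits the output weights by closed-form ridge regression — so each
#' member assigns per-atom energy contributions that sum to the
#' per-molecule correction, and training is exactly deterministic given
#' the seed. Members differ by their hidden layers and by bootstrap
#' resampling of the training records; with `bootstrap = FALSE` all
#' members share one hidden layer and the full training set, giving a
#' committee of identical members (zero predictive spread). Degenerate
#' (zero-variance) targets are handled exactly — the model predicts the
#' constant.
#'
#' @param dataset a [build_dataset()] result (>= 10 training records).
#' @param M committee size.
#' @param lambda ridge penalty for the output weights; `NULL` (default)
#'   selects it per member by generalised cross-validation on that
#'   member's training rows.
#' @param n_hidden hidden units per member.
#' @param descriptor a [descriptor_config()] (must match the oracle's if
#'   recovery is expected).
#' @param seed training seed.
#' @param bootstrap resample training rows (and draw distinct hidden
#'   layers) per member?
#' @return object of class `correction_model` with committee weights,
#'   normalisation constants and train/test/extrapolation MAEs.
#' @export
train_committee <- function(dataset, M = 8L, lambda = NULL,
                            n_hidden = 64L,
                            descriptor = descriptor_config(), seed = 1L,
                            bootstrap = TRUE) {
  recs <- dataset$records
  tr <- which(vapply(recs, function(r) r$split == "train", logical(1)))
  if (length(tr) < 10) stop("need at least 10 training records")
  af <- lapply(recs, function(r) atom_features(r$crystal, descriptor))
  y <- vapply(recs, `[[`, numeric(1), "target")
  mu_y <- mean(y[tr])
  ## atom-level standardisation from the training structures
  all_tr <- do.call(rbind, af[tr])
  mu_a <- colMeans(all_tr)
  sd_a <- apply(all_tr, 2, sd)
  sd_a[sd_a < 1e-12] <- 1
  af_std <- lapply(af, function(a)
    sweep(sweep(a, 2, mu_a), 2, sd_a, "/"))
  din <- ncol(all_tr)
  H <- as.integer(n_hidden)
  members <- vector("list", M)
  for (m in seq_len(M)) {
    mseed <- if (bootstrap) seed + 1000L * m else seed
    W <- matrix(local_rnorm(mseed + 1L, din * H) / sqrt(din), din, H)
    b <- local_rnorm(mseed + 2L, H) * 0.5
    rows <- if (bootstrap)
      tr[sample_with_seed(length(tr), length(tr), seed + 3000L * m)]
    else tr
    Z <- t(vapply(af_std, function(a) member_z(a, W, b),
                  numeric(H + din)))
    mu_z <- colMeans(Z[rows, , drop = FALSE])
    sd_z <- apply(Z[rows, , drop = FALSE], 2, sd)
    sd_z[sd_z < 1e-12] <- 1
    Zs <- sweep(sweep(Z, 2, mu_z), 2, sd_z, "/")
    lam <- if (is.null(lambda))
      gcv_ridge_lambda(Zs[rows, , drop = FALSE], y[rows] - mu_y)
    else lambda
    Zm <- Zs[rows, , drop = FALSE]
    A <- crossprod(Zm) + diag(lam * nrow(Zm), ncol(Zm))
    members[[m]] <- list(W = W, b = b, mu_z = mu_z, sd_z = sd_z,
                         lambda = lam,
                         v = as.numeric(solve(A, crossprod(Zm,
                                                           y[rows] - mu_y))))
  }
  model <- structure(list(members = members, mu_a = mu_a, sd_a = sd_a,
                          mu_y = mu_y, descriptor = descriptor,
                          M = as.integer(M), n_hidden = H,
                          seed = as.integer(seed), bootstrap = bootstrap),
                     class = "correction_model")
  pred <- predict_matrix_af(model, af)
  mae <- function(idx) if (length(idx))
    mean(abs(rowMeans(pred[idx, , drop = FALSE]) - y[idx])) else NA_real_
  splits <- vapply(recs, `[[`, character(1), "split")
  model$mae <- c(train = mae(which(splits == "train")),
                 test = mae(which(splits == "test")),
                 extrapolation = mae(which(splits == "extrapolation")))
  model
}

## generalised cross-validation for the ridge penalty: one SVD of the
## (standardised, centred-response) training block, then
## GCV(lambda) = n ||y - yhat||^2 / (n - tr(H))^2 over a log grid
gcv_ridge_lambda <- function(X, y, grid = 10^seq(-5, 2, by = 0.5)) {
  n <- nrow(X)
  sv <- svd(X)
  d2 <- sv$d^2
  uty <- as.numeric(crossprod(sv$u, y))
  best <- max(grid); best_gcv <- Inf
  for (lg in grid) {
    lam <- lg * n
    shrink <- d2 / (d2 + lam)
    edf <- sum(shrink)
    ## with more features than rows a tiny penalty interpolates
    ## (edf -> n, rss -> 0) and GCV degenerates to 0/0; such penalties
    ## are never admissible
    if (edf > 0.9 * n) next
    fit <- sv$u %*% (shrink * uty)
    rss <- sum((y - fit)^2)
    gcv <- n * rss / (n - edf)^2
    if (gcv < best_gcv) { best_gcv <- gcv; best <- lg }
  }
  best
}

## committee predictions for a list of atom-feature matrices: n x M
predict_matrix_af <- function(model, af_list) {
  af_std <- lapply(af_list, function(a)
    sweep(sweep(a, 2, model$mu_a), 2, model$sd_a, "/"))
  vapply(model$members, function(mem) {
    vapply(af_std, function(a) {
      z <- (member_z(a, mem$W, mem$b) - mem$mu_z) / mem$sd_z
      sum(z * mem$v) + model$mu_y
    }, numeric(1))
  }, numeric(length(af_list)))
}

#' Predict the lattice-energy correction for a crystal
#'
#' @param model a [train_committee()] model.
#' @param cr a `crystal`.
#' @return list of class `correction_prediction` with `dE_pred`
#'   (committee mean, kJ/mol) and `sigma` (committee standard
#'   deviation).
#' @export
predict_correction <- function(model, cr) {
  af <- atom_features(cr, model$descriptor)
  p <- as.numeric(predict_matrix_af(model, list(af)))
  structure(list(dE_pred = mean(p), sigma = stats::sd(p)),
            class = "correction_prediction")
}

#' Query-by-committee selection
#'
#' Returns the `budget` pool structures with the highest committee
#' standard deviation; ties break deterministically by structure id.
#'
#' @param model a `correction_model`.
#' @param pool list of `crystal` objects.
#' @param budget number of structures to select.
#' @return indices into `pool`, ordered by decreasing uncertainty.
#' @export
active_learning_round <- function(model, pool, budget) {
  stopifnot(budget >= 0)
  if (budget == 0 || !length(pool)) return(integer(0))
  sig <- vapply(pool, function(cr) predict_correction(model, cr)$sigma,
                numeric(1))
  ids <- vapply(seq_along(pool), function(i)
    if (is.null(pool[[i]]$id)) sprintf("pool-%06d", i) else pool[[i]]$id,
    character(1))
  ord <- order(-sig, ids)
  ord[seq_len(min(budget, length(pool)))]
}

#' Apply a correction model to a landscape and re-rank
#'
#' `E_corr = E_latt + dE_pred` per structure; structures with committee
#' uncertainty above `sigma_cap` are excluded from the ranking.
#'
#' @param ls a `landscape`.
#' @param model a `correction_model`.
#' @param sigma_cap exclusion threshold on sigma, kJ/mol.
#' @return a new `landscape`-like object re-sorted by `E_corr`; its
#'   summary gains `E_corr` and `sigma` columns, and `E_latt` is replaced
#'   by `E_corr` for ranking/`delta_e` purposes (original FF energy kept
#'   as `E_ff`).
#' @export
corrected_landscape <- function(ls, model, sigma_cap = 25) {
  if (!length(ls$structures)) stop("empty landscape")
  preds <- lapply(ls$structures, function(cr) predict_correction(model, cr))
  sig <- vapply(preds, `[[`, numeric(1), "sigma")
  keep <- sig <= sigma_cap
  if (!any(keep)) stop("all structures excluded by the sigma cap")
  structures <- ls$structures[keep]
  de <- vapply(preds, `[[`, numeric(1), "dE_pred")[keep]
  sig <- sig[keep]
  for (i in seq_along(structures)) {
    eb <- structures[[i]]$energy
    eb$E_ff <- eb$E_latt
    eb$E_latt <- eb$E_latt + de[i]
    eb$sigma <- sig[i]
    structures[[i]]$energy <- eb
  }
  out <- landscape(structures, molecule = ls$molecule)
  out$summary$E_ff <- vapply(out$structures, function(s) s$energy$E_ff,
                             numeric(1))
  out$summary$sigma <- vapply(out$structures, function(s) s$energy$sigma,
                              numeric(1))
  out
}
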