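## Train/test masking over adjacency cells and attribute rows, and k-fold
## cross-validation with grid search over (C, gamma).
##
## A mask holds out a set of off-diagonal (i, j, layer) cells and a set of
## attribute node rows. Held-out cells are treated as missing during
## training: they are excluded from both terms of the network likelihood
## and from every update denominator, which is what makes them scoreable
## as link-prediction candidates afterwards.

# decode 1-based flat indices over the N*(N-1)*L off-diagonal cells
.decode_cells <- function(idx, N, L) {
  p <- idx - 1
  layer <- p %/% (N * (N - 1))
  r <- p %% (N * (N - 1))
  i <- r %/% (N - 1)
  jr <- r %% (N - 1)
  j <- jr + (jr >= i)
  data.frame(i = as.integer(i + 1), j = as.integer(j + 1),
             layer = as.integer(layer + 1))
}

.cell_key <- function(i, j, layer, N) {
  (as.numeric(layer) - 1) * N * N + (as.numeric(i) - 1) * N + as.numeric(j)
}

.drop_held_edges <- function(edges, mask) {
  if (is.null(mask) || nrow(mask$cells) == 0L || nrow(edges) == 0L) return(edges)
  N <- mask$N
  held <- .cell_key(mask$cells$i, mask$cells$j, mask$cells$layer, N)
  keys <- .cell_key(edges$source, edges$target, edges$layer, N)
  edges[!(keys %in% held), , drop = FALSE]
}

.new_mask <- function(cells, nodes, N, L, fraction, tpe, seed) {
  structure(list(cells = cells, nodes = nodes, N = N, L = L,
                 fraction = fraction, tpe = tpe, seed = seed),
            class = "mask_spec")
}

#' @export
print.mask_spec <- function(x, ...) {
  cat(sprintf("mask_spec: %d held-out cells (%.1f%% of %d), %d held-out attribute rows%s\n",
              nrow(x$cells), 100 * nrow(x$cells) / (x$N * (x$N - 1) * x$L),
              x$N * (x$N - 1) * x$L, length(x$nodes),
              if (is.null(x$tpe)) "" else sprintf(", tpe=%g", x$tpe)))
  invisible(x)
}

#' Uniform train/test mask
#'
#' Samples the requested fraction of off-diagonal (i, j, layer) cells and
#' the requested fraction of attribute rows uniformly without replacement.
#' Train and test cells partition the off-diagonal cells.
#'
#' @param N,L network dimensions.
#' @param fraction held-out fraction in (0, 1) (default 0.2, the standard
#'   80-20 split).
#' @param seed integer RNG seed.
#' @param attr_fraction held-out fraction of attribute rows (default
#'   `fraction`; 0 keeps all attributes observed).
#' @return a `mask_spec`: list with `cells` (data.frame `i`, `j`,
#'   `layer`), `nodes` (held-out attribute rows), and sampling metadata.
#' @export
make_uniform_mask <- function(N, L, fraction = 0.2, seed = NULL,
                              attr_fraction = fraction) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  total <- N * (N - 1) * L
  m <- round(fraction * total)
  cells <- .decode_cells(sample(total, m), N, L)
  nodes <- if (attr_fraction > 0) sort(sample.int(N, round(attr_fraction * N))) else integer(0)
  .new_mask(cells, nodes, N, L, fraction, NULL, seed)
}

#' Class-biased train/test mask
#'
#' Holds out `fraction` of the off-diagonal cells with a controlled class
#' composition: a share `tpe` of the held-out cells are positives
#' (existing edges) and `1 - tpe` are zeros, each class sampled uniformly
#' without replacement. `tpe` equal to the empirical edge density
#' reproduces the uniform mask's composition in expectation; larger
#' values over-represent edges in the test set (leaving fewer for
#' training), smaller values under-represent them.
#'
#' @param A a [multilayer_network].
#' @param fraction held-out fraction of the `N*(N-1)*L` cells.
#' @param tpe target probability that a held-out cell is a positive.
#' @param seed integer RNG seed.
#' @param attr_fraction held-out fraction of attribute rows (default 0:
#'   biased hold-out experiments give the full design matrix as input).
#' @return a `mask_spec` (see [make_uniform_mask()]).
#' @export
make_biased_mask <- function(A, fraction, tpe, seed = NULL,
                             attr_fraction = 0) {
  stopifnot(inherits(A, "multilayer_network"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (tpe <= 0 || tpe >= 1) stop("tpe must be in (0, 1)")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  N <- A$N; L <- A$L
  total <- N * (N - 1) * L
  m <- round(fraction * total)
  n_pos <- round(tpe * m)
  n_zero <- m - n_pos
  e <- A$edges
  if (n_pos > nrow(e)) {
    stop(sprintf("requested %d positive held-out cells but only %d positive cells exist (feasible maximum tpe = %.4g at this fraction)",
                 n_pos, nrow(e), nrow(e) / m))
  }
  pos_idx <- sample.int(nrow(e), n_pos)
  pos <- data.frame(i = e$source[pos_idx], j = e$target[pos_idx],
                    layer = e$layer[pos_idx])
  pos_keys <- .cell_key(e$source, e$target, e$layer, N)
  zero <- data.frame(i = integer(0), j = integer(0), layer = integer(0))
  seen <- numeric(0)
  while (nrow(zero) < n_zero) {
    draw <- .decode_cells(sample(total, min(total, ceiling((n_zero - nrow(zero)) * 1.2) + 16L)), N, L)
    keys <- .cell_key(draw$i, draw$j, draw$layer, N)
    ok <- !(keys %in% pos_keys) & !(keys %in% seen) & !duplicated(keys)
    draw <- draw[ok, , drop = FALSE]
    seen <- c(seen, keys[ok])
    zero <- rbind(zero, draw)
  }
  zero <- zero[seq_len(n_zero), , drop = FALSE]
  cells <- rbind(pos, zero)
  rownames(cells) <- NULL
  nodes <- if (attr_fraction > 0) sort(sample.int(N, round(attr_fraction * N))) else integer(0)
  .new_mask(cells, nodes, N, L, fraction, tpe, seed)
}

#' Evaluate link and attribute prediction on held-out data
#'
#' Scores the held-out network cells with the fitted Poisson means
#' ([predict_edges()]) against the observed adjacency, and the held-out
#' attribute rows with the fitted category probabilities.
#'
#' @param fit an [mtcov_fit()] result (or bare [mtcov_params]).
#' @param A the full (unmasked) [multilayer_network].
#' @param X the full `design_matrix` (or `NULL` to skip accuracy).
#' @param mask the `mask_spec` used for training.
#' @return list with `auc` (NA if the mask holds no network cells or only
#'   one class) and `accuracy` (NA if no attribute rows are held out).
#' @export
evaluate_heldout <- function(fit, A, X, mask) {
  params <- if (inherits(fit, "mtcov_fit")) fit$params else fit
  auc <- NA_real_
  if (nrow(mask$cells) > 0L) {
    scores <- predict_edges(params, mask$cells)
    e <- A$edges
    pos_keys <- .cell_key(e$source, e$target, e$layer, A$N)
    positive <- .cell_key(mask$cells$i, mask$cells$j, mask$cells$layer,
                          A$N) %in% pos_keys
    if (any(positive) && !all(positive)) {
      auc <- auc_link_prediction(scores, positive)
    }
  }
  accuracy <- NA_real_
  if (!is.null(X) && length(mask$nodes) > 0L) {
    pii <- attribute_probs(params)
    accuracy <- attribute_accuracy(X$z[mask$nodes],
                                   pii[mask$nodes, , drop = FALSE])
  }
  list(auc = auc, accuracy = accuracy)
}

#' Cross-validated grid search over (C, gamma)
#'
#' Partitions the off-diagonal cells (and the attribute rows) into
#' `folds` folds; for each grid point, trains on all but one fold and
#' measures link-prediction AUC and attribute accuracy on the held-out
#' fold. The selected pair is the grid point whose (mean AUC, mean
#' accuracy) is jointly closest to the best of each: both metrics are
#' min-max normalized across the grid and the point minimizing the
#' Euclidean distance to (1, 1) wins.
#'
#' @param A a [multilayer_network].
#' @param X a `design_matrix`.
#' @param C_grid,gamma_grid candidate values.
#' @param folds number of folds (default 5).
#' @param seed integer RNG seed (fold assembly and fits).
#' @param ... forwarded to [mtcov_fit()] (e.g. `n_restarts`, `max_iter`).
#' @return list with `grid` (data.frame of C, gamma, mean auc, mean
#'   accuracy), `selected` (list with `C`, `gamma`) and `folds`.
#' @export
cross_validate_grid <- function(A, X, C_grid, gamma_grid, folds = 5,
                                seed = NULL, ...) {
  if (length(C_grid) == 0L || length(gamma_grid) == 0L) stop("empty grid")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  N <- A$N; L <- A$L
  total <- N * (N - 1) * L
  cell_fold <- sample(rep_len(seq_len(folds), total))
  node_fold <- sample(rep_len(seq_len(folds), N))
  fit_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 folds * length(C_grid) * length(gamma_grid)),
                      nrow = folds)
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  grid$auc <- NA_real_; grid$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(0); accs <- numeric(0)
    for (f in seq_len(folds)) {
      cells <- .decode_cells(which(cell_fold == f), N, L)
      mask <- .new_mask(cells, which(node_fold == f), N, L,
                        nrow(cells) / total, NULL, seed)
      fit <- mtcov_fit(A, X, C = grid$C[g], gamma = grid$gamma[g],
                       mask = mask, seed = fit_seeds[f, g], ...)
      ev <- evaluate_heldout(fit, A, X, mask)
      if (is.na(ev$auc)) {
        warning(sprintf("fold %d has no scoreable held-out network cells; skipped", f))
      } else {
        aucs <- c(aucs, ev$auc)
      }
      if (!is.na(ev$accuracy)) accs <- c(accs, ev$accuracy)
    }
    grid$auc[g] <- mean(aucs)
    grid$accuracy[g] <- mean(accs)
  }
  nrm <- function(x) {
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) rep(1, length(x)) else (x - rng[1L]) / diff(rng)
  }
  dist2 <- (1 - nrm(grid$auc)) ^ 2 + (1 - nrm(grid$accuracy)) ^ 2
  best <- which.min(dist2)
  list(grid = grid,
       selected = list(C = grid$C[best], gamma = grid$gamma[best]),
       folds = folds, seed = seed)
}
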