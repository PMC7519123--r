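#' Model parameter set
#'
#' Bundles the latent parameters of the joint network/attribute model:
#' out-going memberships `U` (N x C), incoming memberships `V` (N x C),
#' per-layer affinity matrices `W` (C x C x L), the community-to-category
#' matrix `beta` (C x Z) and the scaling parameter `gamma`. Rows of `U`,
#' `V` and `beta` are probability vectors; `W` entries are non-negative
#' expected edge densities between community pairs.
#'
#' @param U,V numeric N x C matrices, rows summing to 1.
#' @param W numeric C x C x L array (a C x C matrix is promoted to L = 1).
#' @param beta numeric C x Z matrix, rows summing to 1.
#' @param gamma scalar in `[0, 1]`: 0 uses only the network likelihood,
#'   1 only the attribute likelihood.
#' @return an object of class `mtcov_params`.
#' @export
mtcov_params <- function(U, V, W, beta, gamma) {
  if (is.matrix(W)) W <- array(W, c(dim(W), 1L))
  p <- structure(list(U = U, V = V, W = W, beta = beta, gamma = gamma),
                 class = "mtcov_params")
  validate_params(p)
  p
}

.param_dims <- function(p) {
  list(N = nrow(p$U), C = ncol(p$U), Z = ncol(p$beta), L = dim(p$W)[3L])
}

#' Validate model parameter invariants
#'
#' Checks non-negativity, shape consistency and the row normalizations of
#' `U`, `V` and `beta` (tolerance 1e-8), and `gamma` in `[0, 1]`.
#'
#' @param p an [mtcov_params] object.
#' @param tol tolerance on row sums.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_params <- function(p, tol = 1e-8) {
  stopifnot(inherits(p, "mtcov_params"))
  C <- ncol(p$U)
  if (!is.matrix(p$U) || !is.matrix(p$V) || !is.matrix(p$beta)) {
    stop("U, V, beta must be matrices")
  }
  if (ncol(p$V) != C || nrow(p$V) != nrow(p$U) || nrow(p$beta) != C) {
    stop("inconsistent parameter shapes")
  }
  if (length(dim(p$W)) != 3L || any(dim(p$W)[1:2] != C)) {
    stop("W must be a C x C x L array")
  }
  if (min(p$U, p$V, p$W, p$beta) < 0) stop("parameters must be non-negative")
  if (!is.numeric(p$gamma) || length(p$gamma) != 1L ||
      p$gamma < 0 || p$gamma > 1) {
    stop("gamma must be a scalar in [0, 1]")
  }
  if (max(abs(rowSums(p$U) - 1)) > tol) stop("rows of U must sum to 1")
  if (max(abs(rowSums(p$V) - 1)) > tol) stop("rows of V must sum to 1")
  if (max(abs(rowSums(p$beta) - 1)) > tol) stop("rows of beta must sum to 1")
  invisible(p)
}

#' @export
print.mtcov_params <- function(x, ...) {
  d <- .param_dims(x)
  cat(sprintf("mtcov_params: N=%d, C=%d, Z=%d, L=%d, gamma=%g\n",
              d$N, d$C, d$Z, d$L, x$gamma))
  invisible(x)
}

#' Expected-edge tensor
#'
#' The Poisson means \eqn{M_{ij}^{(\alpha)} = \sum_{k,l} u_{ik} v_{jl}
#' w_{kl}^{(\alpha)}}, materialized densely. Use [predict_edges()] to
#' evaluate the means lazily on a set of cells instead.
#'
#' @param params an [mtcov_params] object.
#' @return numeric N x N x L array.
#' @export
expected_edges <- function(params) {
  validate_params(params)
  d <- .param_dims(params)
  out <- array(0, c(d$N, d$N, d$L))
  for (al in seq_len(d$L)) {
    out[, , al] <- params$U %*% params$W[, , al] %*% t(params$V)
  }
  out
}

#' Poisson means on selected cells
#'
#' Evaluates \eqn{M_{ij}^{(\alpha)}} only at the requested (i, j, layer)
#' triples, without materializing the dense tensor. This is the score used
#' for link prediction on held-out cells.
#'
#' @param params an [mtcov_params] object.
#' @param cells data.frame with integer columns `i`, `j`, `layer`.
#' @return numeric vector of means, one per row of `cells`.
#' @export
predict_edges <- function(params, cells) {
  validate_params(params)
  stopifnot(all(c("i", "j", "layer") %in% names(cells)))
  out <- numeric(nrow(cells))
  for (al in unique(cells$layer)) {
    sel <- cells$layer == al
    P <- params$U %*% params$W[, , al]               # N x C
    out[sel] <- rowSums(P[cells$i[sel], , drop = FALSE] *
                        params$V[cells$j[sel], , drop = FALSE])
  }
  out
}

#' Attribute category probabilities
#'
#' \eqn{\pi_{iz} = \frac{1}{2} \sum_k \beta_{kz} (u_{ik} + v_{ik})}. Each
#' row is a probability vector over the Z categories because the
#' membership and beta rows are normalized.
#'
#' @param params an [mtcov_params] object.
#' @return numeric N x Z matrix of probabilities.
#' @export
attribute_probs <- function(params) {
  validate_params(params)
  0.5 * (params$U + params$V) %*% params$beta
}

# log with a hard floor; degenerate zeros are reported by the callers
.LOG_FLOOR <- 1e-300

# -sum(M) over all ordered pairs via the factorized identity
# sum_ij M_ij = (colSums U) W (colSums V) per layer; never a dense pass.
# `held` optionally subtracts cells excluded from the likelihood.
.sum_expected <- function(params, held = NULL) {
  d <- .param_dims(params)
  su <- colSums(params$U); sv <- colSums(params$V)
  tot <- 0
  for (al in seq_len(d$L)) {
    tot <- tot + as.numeric(su %*% params$W[, , al] %*% sv)
  }
  if (!is.null(held) && nrow(held) > 0L) {
    tot <- tot - sum(predict_edges(params, held))
  }
  tot
}

#' Network log-likelihood
#'
#' The Poisson log-likelihood of the adjacency tensor up to constants:
#' \eqn{\sum_{ij\alpha} [A_{ij}^{(\alpha)} \log M_{ij}^{(\alpha)} -
#' M_{ij}^{(\alpha)}]}. The log term is accumulated only over observed
#' edges; the \eqn{-\sum M} term uses the factorized identity
#' \eqn{\sum_{ij} M_{ij} = (\sum_i u_i)^\top W (\sum_j v_j)} per layer, so
#' the cost is linear in the number of edges. An edge with zero expected
#' mean yields `-Inf` with attribute `degenerate = TRUE` rather than an
#' error, so restart loops can discard pathological initializations.
#'
#' @param A a [multilayer_network].
#' @param params an [mtcov_params] object.
#' @param mask optional [make_uniform_mask()]/[make_biased_mask()] result;
#'   held-out cells are excluded from both terms.
#' @return scalar log-likelihood (possibly `-Inf`, flagged).
#' @export
loglik_network <- function(A, params, mask = NULL) {
  stopifnot(inherits(A, "multilayer_network"))
  validate_params(params)
  e <- A$edges
  held <- if (is.null(mask)) NULL else mask$cells
  if (!is.null(mask)) e <- .drop_held_edges(e, mask)
  degenerate <- FALSE
  edge_term <- 0
  if (nrow(e) > 0L) {
    m <- predict_edges(params, data.frame(i = e$source, j = e$target,
                                          layer = e$layer))
    if (any(m <= 0)) degenerate <- TRUE
    edge_term <- sum(e$weight * log(pmax(m, .LOG_FLOOR)))
  }
  val <- if (degenerate) -Inf else edge_term - .sum_expected(params, held)
  if (degenerate) attr(val, "degenerate") <- TRUE
  val
}

#' Attribute log-likelihood
#'
#' \eqn{\sum_{i,z} x_{iz} \log \pi_{iz}}: the multinomial log-likelihood
#' of the observed one-hot categories. A node whose observed category has
#' zero probability yields `-Inf` with attribute `degenerate = TRUE`.
#'
#' @param X a `design_matrix` (see [encode_attributes()]).
#' @param params an [mtcov_params] object.
#' @param mask optional mask; held-out attribute nodes are excluded.
#' @return scalar log-likelihood (possibly `-Inf`, flagged).
#' @export
loglik_attributes <- function(X, params, mask = NULL) {
  stopifnot(inherits(X, "design_matrix"))
  validate_params(params)
  keep <- seq_along(X$z)
  if (!is.null(mask) && length(mask$nodes) > 0L) keep <- setdiff(keep, mask$nodes)
  if (length(keep) == 0L) return(0)
  pii <- attribute_probs(params)[cbind(keep, X$z[keep])]
  if (any(pii <= 0)) {
    val <- -Inf
    attr(val, "degenerate") <- TRUE
    return(val)
  }
  sum(log(pii))
}

#' Joint log-likelihood
#'
#' \eqn{(1-\gamma) L_G + \gamma L_X}: at `gamma = 0` the attribute data are
#' ignored entirely (X may be `NULL`), at `gamma = 1` the network
#' likelihood is ignored. The optional `rescale` pair multiplies the two
#' terms before the convex mix, for datasets whose two likelihoods sit on
#' very different scales; the default `c(1, 1)` leaves them untouched.
#'
#' @param A a [multilayer_network] (may be `NULL` when `gamma = 1`).
#' @param X a `design_matrix` (may be `NULL` when `gamma = 0`).
#' @param params an [mtcov_params] object.
#' @param mask optional mask, forwarded to both terms.
#' @param rescale positive length-2 numeric: multipliers for the network
#'   and attribute terms.
#' @return scalar; `-Inf` flags propagate from either term.
#' @export
total_loglik <- function(A, X, params, mask = NULL, rescale = c(1, 1)) {
  g <- params$gamma
  lg <- if (g < 1) loglik_network(A, params, mask) else 0
  lx <- if (g > 0) loglik_attributes(X, params, mask) else 0
  val <- (1 - g) * rescale[1L] * lg + g * rescale[2L] * lx
  if (isTRUE(attr(lg, "degenerate")) || isTRUE(attr(lx, "degenerate"))) {
    attr(val, "degenerate") <- TRUE
  }
  val
}
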