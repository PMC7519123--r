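## EM engine: random initialization, E-step responsibilities, closed-form
## M-step updates and the restart loop.
##
## Internally the adjacency is kept as parallel edge vectors and the C x C
## affinity of layer `al` as row `al` of an L x C^2 matrix whose column
## cc encodes the (k, l) pair with k = (cc-1) %/% C + 1, l = (cc-1) %% C + 1.
## All per-iteration work is O(E C^2 + N C Z).

.kl_index <- function(C) {
  list(k = rep(seq_len(C), each = C), l = rep(seq_len(C), times = C))
}

.W_to_mat <- function(W) {
  C <- dim(W)[1L]; L <- dim(W)[3L]
  t(vapply(seq_len(L), function(al) as.numeric(t(W[, , al])), numeric(C * C)))
}

.W_from_mat <- function(W2, C) {
  L <- nrow(W2)
  W <- array(0, c(C, C, L))
  for (al in seq_len(L)) W[, , al] <- matrix(W2[al, ], C, C, byrow = TRUE)
  W
}

# training-view of the data shared by all updates
.em_data <- function(A, X = NULL, mask = NULL) {
  stopifnot(inherits(A, "multilayer_network"))
  e <- A$edges
  if (!is.null(mask)) e <- .drop_held_edges(e, mask)
  N <- A$N; L <- A$L
  xw <- numeric(N)
  z <- NULL
  if (!is.null(X)) {
    stopifnot(inherits(X, "design_matrix"))
    if (length(X$z) != N) stop("attribute table and network disagree on N")
    z <- X$z
    xw[] <- 1
    if (!is.null(mask) && length(mask$nodes) > 0L) xw[mask$nodes] <- 0
  }
  outd <- numeric(N); ind <- numeric(N)
  if (nrow(e) > 0L) {
    so <- rowsum(e$weight, e$source); outd[as.integer(rownames(so))] <- so
    si <- rowsum(e$weight, e$target); ind[as.integer(rownames(si))] <- si
  }
  list(src = e$source, dst = e$target, lay = e$layer, w = e$weight,
       N = N, L = L, z = z, Z = if (is.null(X)) NULL else length(X$categories),
       xw = xw, outdeg = outd, indeg = ind,
       held = if (is.null(mask)) NULL else mask$cells)
}

#' Random parameter initialization
#'
#' Membership and beta rows are drawn i.i.d. uniform on (0, 1) and
#' normalized; affinity entries are uniform on (0, 1). The scale of `W` is
#' immaterial: the first affinity update rescales it to match the data.
#' Fully determined by `seed`.
#'
#' @param N,C,Z,L dimensions (`Z` is ignored and set to 1 when
#'   `gamma = 0`, where beta never enters the objective).
#' @param gamma scaling parameter stored in the result.
#' @param seed integer RNG seed.
#' @return an [mtcov_params] object.
#' @export
init_params <- function(N, C, Z, L, gamma, seed) {
  if (C > N) stop("C > N: more communities than nodes")
  if (C < 1) stop("C must be >= 1")
  if (is.null(Z)) Z <- 1L
  set.seed(seed)
  nrm <- function(M) M / rowSums(M)
  mtcov_params(U = nrm(matrix(runif(N * C), N, C)),
               V = nrm(matrix(runif(N * C), N, C)),
               W = array(runif(C * C * L), c(C, C, L)),
               beta = nrm(matrix(runif(C * Z), C, Z)),
               gamma = gamma)
}

# E-step on the prepared data; returns h (N x C), rho (E x C^2) and the
# number of zero-normalizer rows replaced by the uniform distribution.
.estep <- function(dat, U, V, W2, B, need_rho = TRUE) {
  C <- ncol(U)
  flagged <- 0L
  h <- NULL
  if (!is.null(dat$z)) {
    numh <- t(B)[dat$z, , drop = FALSE] * (U + V)
    rs <- rowSums(numh)
    bad <- rs <= 0
    if (any(bad)) {
      flagged <- flagged + sum(bad)
      numh[bad, ] <- 1
      rs[bad] <- C
    }
    h <- numh / rs
  }
  rho <- NULL
  if (need_rho && length(dat$src) > 0L) {
    kl <- .kl_index(C)
    numr <- vapply(seq_len(C * C), function(cc) {
      U[dat$src, kl$k[cc]] * V[dat$dst, kl$l[cc]] * W2[dat$lay, cc]
    }, numeric(length(dat$src)))
    if (!is.matrix(numr)) numr <- matrix(numr, nrow = 1L)
    rs <- rowSums(numr)
    bad <- rs <= 0
    if (any(bad)) {
      flagged <- flagged + sum(bad)
      numr[bad, ] <- 1
      rs[bad] <- C * C
    }
    rho <- numr / rs
  }
  list(h = h, rho = rho, flagged = flagged)
}

# membership update; gamma and the attribute-observation weights fold the
# attribute responsibilities into the edge responsibilities
.mstep_UV <- function(dat, h, rho, gamma) {
  N <- dat$N
  C <- as.integer(round(if (!is.null(h)) ncol(h) else sqrt(ncol(rho))))
  kl <- .kl_index(C)
  numU <- matrix(0, N, C); numV <- matrix(0, N, C)
  if (gamma > 0 && !is.null(h)) {
    numU <- numU + gamma * dat$xw * h
    numV <- numV + gamma * dat$xw * h
  }
  if (gamma < 1 && length(dat$src) > 0L) {
    rk <- vapply(seq_len(C), function(k)
      rowSums(rho[, which(kl$k == k), drop = FALSE]), numeric(nrow(rho)))
    rl <- vapply(seq_len(C), function(l)
      rowSums(rho[, which(kl$l == l), drop = FALSE]), numeric(nrow(rho)))
    if (!is.matrix(rk)) { rk <- matrix(rk, nrow = 1L); rl <- matrix(rl, nrow = 1L) }
    sU <- rowsum(dat$w * rk, dat$src)
    numU[as.integer(rownames(sU)), ] <-
      numU[as.integer(rownames(sU)), , drop = FALSE] + (1 - gamma) * sU
    sV <- rowsum(dat$w * rl, dat$dst)
    numV[as.integer(rownames(sV)), ] <-
      numV[as.integer(rownames(sV)), , drop = FALSE] + (1 - gamma) * sV
  }
  denU <- gamma * dat$xw + (1 - gamma) * dat$outdeg
  denV <- gamma * dat$xw + (1 - gamma) * dat$indeg
  badU <- denU <= 0; badV <- denV <= 0
  U <- numU / ifelse(badU, 1, denU)
  V <- numV / ifelse(badV, 1, denV)
  if (any(badU)) U[badU, ] <- 1 / C
  if (any(badV)) V[badV, ] <- 1 / C
  list(U = U, V = V, flagged = sum(badU) + sum(badV))
}

# affinity update w_kl = sum_ij A rho / (sum_i u_ik sum_j v_jl); when cells
# are held out, the denominator excludes them
.mstep_W <- function(dat, rho, U, V) {
  C <- ncol(U)
  kl <- .kl_index(C)
  num <- matrix(0, dat$L, C * C)
  if (length(dat$src) > 0L) {
    sw <- rowsum(dat$w * rho, dat$lay)
    num[as.integer(rownames(sw)), ] <- sw
  }
  den <- matrix(rep(colSums(U)[kl$k] * colSums(V)[kl$l], each = dat$L),
                dat$L, C * C)
  if (!is.null(dat$held) && nrow(dat$held) > 0L) {
    hc <- dat$held
    for (cc in seq_len(C * C)) {
      corr <- rowsum(U[hc$i, kl$k[cc]] * V[hc$j, kl$l[cc]], hc$layer)
      den[as.integer(rownames(corr)), cc] <-
        den[as.integer(rownames(corr)), cc] - corr
    }
  }
  bad <- den <= 0
  W2 <- num / ifelse(bad, 1, den)
  W2[bad] <- 0
  list(W2 = W2, flagged = sum(bad & num > 0))
}

# beta update over nodes with observed attributes
.mstep_B <- function(dat, h, C) {
  Bn <- matrix(0, dat$Z, C)
  obs <- dat$xw > 0
  if (any(obs)) {
    s <- rowsum(h[obs, , drop = FALSE], dat$z[obs])
    Bn[as.integer(rownames(s)), ] <- s
  }
  B <- t(Bn)
  rs <- rowSums(B)
  bad <- rs <= 0
  B <- B / ifelse(bad, 1, rs)
  if (any(bad)) B[bad, ] <- 1 / dat$Z
  list(B = B, flagged = sum(bad))
}

# joint log-likelihood on the training view (fast path used inside the loop)
.loglik_internal <- function(dat, U, V, W2, B, gamma, rescale = c(1, 1)) {
  C <- ncol(U)
  kl <- .kl_index(C)
  degenerate <- FALSE
  lg <- 0
  if (gamma < 1) {
    if (length(dat$src) > 0L) {
      me <- numeric(length(dat$src))
      for (cc in seq_len(C * C)) {
        me <- me + U[dat$src, kl$k[cc]] * V[dat$dst, kl$l[cc]] * W2[dat$lay, cc]
      }
      if (any(me <= 0)) degenerate <- TRUE
      lg <- sum(dat$w * log(pmax(me, .LOG_FLOOR)))
    }
    su <- colSums(U); sv <- colSums(V)
    tot <- sum(vapply(seq_len(dat$L), function(al)
      as.numeric(su %*% matrix(W2[al, ], C, C, byrow = TRUE) %*% sv),
      numeric(1L)))
    if (!is.null(dat$held) && nrow(dat$held) > 0L) {
      hc <- dat$held
      hm <- numeric(nrow(hc))
      for (cc in seq_len(C * C)) {
        hm <- hm + U[hc$i, kl$k[cc]] * V[hc$j, kl$l[cc]] * W2[hc$layer, cc]
      }
      tot <- tot - sum(hm)
    }
    lg <- lg - tot
  }
  lx <- 0
  if (gamma > 0 && !is.null(dat$z)) {
    obs <- dat$xw > 0
    if (any(obs)) {
      pii <- 0.5 * rowSums((t(B)[dat$z, , drop = FALSE] * (U + V))[obs, , drop = FALSE])
      if (any(pii <= 0)) degenerate <- TRUE
      lx <- sum(log(pmax(pii, .LOG_FLOOR)))
    }
  }
  val <- (1 - gamma) * rescale[1L] * lg + gamma * rescale[2L] * lx
  attr(val, "degenerate") <- degenerate
  val
}

.fit_single <- function(dat, C, gamma, seed, max_iter, tol, check_every,
                        undirected, rescale) {
  Z <- if (is.null(dat$Z)) 1L else dat$Z
  p0 <- init_params(dat$N, C, Z, dat$L, gamma, seed)
  U <- p0$U; V <- p0$V; B <- p0$beta
  W2 <- .W_to_mat(p0$W)
  if (undirected) U <- V <- 0.5 * (U + V)
  flagged <- 0L
  traj_it <- integer(0); traj_ll <- numeric(0)
  ll_old <- NA_real_; hits <- 0L; converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    es <- .estep(dat, U, V, W2, B, need_rho = gamma < 1)
    flagged <- flagged + es$flagged
    up <- .mstep_UV(dat, es$h, es$rho, gamma)
    U <- up$U; V <- up$V
    if (undirected) U <- V <- 0.5 * (U + V)
    flagged <- flagged + up$flagged
    if (gamma < 1 && !is.null(es$rho)) {
      uw <- .mstep_W(dat, es$rho, U, V)
      W2 <- uw$W2
      flagged <- flagged + uw$flagged
    }
    if (gamma > 0 && !is.null(es$h)) {
      ub <- .mstep_B(dat, es$h, C)
      B <- ub$B
      flagged <- flagged + ub$flagged
    }
    if (it %% check_every == 0L || it == max_iter) {
      ll <- .loglik_internal(dat, U, V, W2, B, gamma, rescale)
      traj_it <- c(traj_it, it); traj_ll <- c(traj_ll, as.numeric(ll))
      if (!is.na(ll_old) && is.finite(ll) && abs(ll - ll_old) < tol) {
        hits <- hits + 1L
      } else {
        hits <- 0L
      }
      ll_old <- as.numeric(ll)
      if (hits >= 2L) { converged <- TRUE; break }
    }
  }
  params <- mtcov_params(U = U, V = V, W = .W_from_mat(W2, C), beta = B,
                         gamma = gamma)
  list(params = params, loglik = ll_old, converged = converged,
       n_iter = it, seed = seed, flagged = flagged,
       trajectory = data.frame(iteration = traj_it, loglik = traj_ll),
       degenerate = !is.finite(ll_old))
}

#' Fit the model by EM with random restarts
#'
#' Alternates the E-step (responsibility distributions over communities
#' for each observed attribute and over community pairs for each observed
#' edge) with the closed-form parameter updates, from `n_restarts` random
#' initializations, and keeps the run with the largest final joint
#' log-likelihood.
#'
#' The objective is checked every `check_every` iterations; a restart
#' stops when its absolute change is below `tol` on two consecutive
#' checks, or at `max_iter`. Degenerate situations (a node with no
#' training evidence for a membership row, an empty community in an
#' affinity denominator, a zero responsibility normalizer) substitute a
#' uniform row or zero entry and are counted in `flags` instead of
#' aborting the restart.
#'
#' @param A a [multilayer_network].
#' @param X a `design_matrix` from [encode_attributes()]; may be `NULL`
#'   when `gamma = 0` (the attribute data are never touched there).
#' @param C number of communities.
#' @param gamma scaling parameter in `[0, 1]`; at 0 the beta update is
#'   skipped (it is undefined there) and at 1 the affinity update is
#'   skipped, each block retaining its initialization with zero weight in
#'   the objective.
#' @param n_restarts number of random initializations (default 10).
#' @param max_iter,tol,check_every convergence control (defaults 500, 0.1,
#'   10).
#' @param seed master seed; per-restart seeds are drawn from it, so the
#'   whole fit is reproducible.
#' @param undirected force `U = V` by averaging the two updates each
#'   iteration; defaults to the directedness of `A`.
#' @param mask optional [make_uniform_mask()]/[make_biased_mask()] result;
#'   held-out network cells and attribute rows are excluded from every
#'   likelihood term and update (treated as missing, not as zeros).
#' @param rescale optional positive pair multiplying the network and
#'   attribute log-likelihoods before the convex mix (default `c(1, 1)`).
#' @param verbose print per-restart summaries.
#' @return an object of class `mtcov_fit`: list with `params`, `loglik`,
#'   `trajectory` (checkpointed objective of the best restart),
#'   `converged`, `n_iter`, `seed`, `restarts` (per-restart summary
#'   data.frame), `flags` (count of degeneracy substitutions in the best
#'   restart), plus the node/category/layer codebooks.
#' @examples
#' bench <- make_benchmark("G1", seed = 1, N = 60)
#' X <- generate_attributes(bench$truth, match_ratio = 0.9, seed = 2)
#' fit <- mtcov_fit(bench$network, X, C = 2, gamma = 0.5, n_restarts = 2,
#'                  seed = 3)
#' head(hard_memberships(fit$params$U))
#' @export
mtcov_fit <- function(A, X = NULL, C, gamma, n_restarts = 10, max_iter = 500,
                      tol = 0.1, check_every = 10, seed = NULL,
                      undirected = NULL, mask = NULL, rescale = c(1, 1),
                      verbose = FALSE) {
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1) {
    stop("gamma must be in [0, 1]")
  }
  if (gamma > 0 && is.null(X)) stop("gamma > 0 requires attribute data X")
  if (is.null(undirected)) undirected <- !A$directed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  dat <- .em_data(A, if (gamma > 0) X else NULL, mask)
  if (C > dat$N) stop("C > N: more communities than nodes")
  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)
  runs <- lapply(seq_len(n_restarts), function(r) {
    res <- .fit_single(dat, C, gamma, restart_seeds[r], max_iter, tol,
                       check_every, undirected, rescale)
    if (verbose) {
      message(sprintf("restart %d/%d: loglik %.4f after %d iterations%s",
                      r, n_restarts, res$loglik, res$n_iter,
                      if (res$converged) "" else " (no convergence)"))
    }
    res
  })
  summary_df <- data.frame(
    restart = seq_len(n_restarts),
    seed = restart_seeds,
    loglik = vapply(runs, `[[`, numeric(1L), "loglik"),
    converged = vapply(runs, `[[`, logical(1L), "converged"),
    n_iter = vapply(runs, `[[`, integer(1L), "n_iter"),
    flags = vapply(runs, function(r) as.integer(r$flagged), integer(1L))
  )
  ok <- is.finite(summary_df$loglik)
  if (!any(ok)) {
    stop("all restarts ended degenerate (non-finite log-likelihood); ",
         "restart summary: ",
         paste(sprintf("#%d ll=%g flags=%d", summary_df$restart,
                       summary_df$loglik, summary_df$flags), collapse = "; "))
  }
  best <- which(summary_df$loglik == max(summary_df$loglik[ok]))[1L]
  res <- runs[[best]]
  structure(list(
    params = res$params,
    loglik = res$loglik,
    trajectory = res$trajectory,
    converged = res$converged,
    n_iter = res$n_iter,
    seed = seed,
    best_restart = best,
    restarts = summary_df,
    flags = res$flagged,
    nodes = A$nodes,
    layers = A$layers,
    categories = if (!is.null(X)) X$categories else NULL
  ), class = "mtcov_fit")
}

#' @export
print.mtcov_fit <- function(x, ...) {
  d <- .param_dims(x$params)
  cat(sprintf("mtcov_fit: N=%d, C=%d, L=%d, gamma=%g\n", d$N, d$C, d$L,
              x$params$gamma))
  cat(sprintf("  best of %d restarts: loglik %.4f after %d iterations (%s)\n",
              nrow(x$restarts), x$loglik, x$n_iter,
              if (x$converged) "converged" else "hit max_iter"))
  if (x$flags > 0) cat(sprintf("  %d degeneracy substitutions flagged\n", x$flags))
  invisible(x)
}

#' E-step responsibility distributions
#'
#' Computes, at the current parameters, the distribution over communities
#' for each node's observed category,
#' \eqn{h_{izk} \propto \beta_{kz}(u_{ik}+v_{ik})}, and the distribution
#' over community pairs for each observed edge,
#' \eqn{\rho_{ijkl}^{(\alpha)} \propto u_{ik} v_{jl} w_{kl}^{(\alpha)}}.
#' Both are stored only on the support of X and A. Zero normalizers are
#' replaced by uniform distributions and counted in `flagged`.
#'
#' @param A a [multilayer_network].
#' @param X a `design_matrix` or `NULL`.
#' @param params an [mtcov_params] object.
#' @return list with `h` (N x C; row i is the distribution for node i's
#'   observed category), `rho` (E x C^2 matrix aligned with `A$edges`;
#'   column (k-1)C+l holds \eqn{\rho_{ijkl}}), `edges` (the support) and
#'   `flagged`.
#' @export
e_step <- function(A, X, params) {
  validate_params(params)
  dat <- .em_data(A, X)
  es <- .estep(dat, params$U, params$V, .W_to_mat(params$W), params$beta)
  list(h = es$h, rho = es$rho, edges = A$edges, flagged = es$flagged)
}

#' Closed-form update of the community-to-category matrix
#'
#' \eqn{\beta_{kz} = \sum_i x_{iz} h_{izk} / \sum_{i,z} x_{iz} h_{izk}};
#' rows sum to 1. Only defined for `gamma != 0` (at `gamma = 0` beta never
#' enters the objective and is left at its current value by [mtcov_fit()]).
#'
#' @param X a `design_matrix`.
#' @param aux an [e_step()] result.
#' @return C x Z matrix with rows summing to 1; communities with zero
#'   total responsibility get a uniform row (flagged via attribute).
#' @export
update_beta <- function(X, aux) {
  stopifnot(inherits(X, "design_matrix"), !is.null(aux$h))
  dat <- list(Z = length(X$categories), z = X$z, xw = rep(1, length(X$z)))
  res <- .mstep_B(dat, aux$h, ncol(aux$h))
  out <- res$B
  if (res$flagged > 0) attr(out, "flagged") <- res$flagged
  out
}

#' Closed-form membership updates
#'
#' \eqn{u_{ik} = [\gamma \sum_z x_{iz} h_{izk} + (1-\gamma) \sum_{jl\alpha}
#' A_{ij}^{(\alpha)} \rho_{ijkl}^{(\alpha)}] / [\gamma + (1-\gamma)
#' \sum_{j\alpha} A_{ij}^{(\alpha)}]} and the symmetric expression for
#' \eqn{v_{ik}} with the adjacency transposed and the pair indices of
#' \eqn{\rho} swapped. Rows sum to 1 by construction. A node with zero
#' denominator (e.g. zero out-degree at `gamma = 0`) gets a uniform row.
#'
#' @param A a [multilayer_network].
#' @param X a `design_matrix` or `NULL` (required when `gamma > 0`).
#' @param aux an [e_step()] result.
#' @param gamma scaling parameter.
#' @return list with `U`, `V` and the degeneracy count `flagged`.
#' @export
update_memberships <- function(A, X, aux, gamma) {
  dat <- .em_data(A, if (gamma > 0) X else NULL)
  res <- .mstep_UV(dat, aux$h, aux$rho, gamma)
  res
}

#' Closed-form affinity update
#'
#' \eqn{w_{kl}^{(\alpha)} = \sum_{ij} A_{ij}^{(\alpha)}
#' \rho_{ijkl}^{(\alpha)} / (\sum_i u_{ik} \sum_j v_{jl})}. Only defined
#' for `gamma != 1` (at `gamma = 1` the affinities never enter the
#' objective). Entries with an empty-group denominator are set to 0.
#'
#' @param A a [multilayer_network].
#' @param aux an [e_step()] result.
#' @param U,V membership matrices entering the denominator.
#' @return C x C x L array.
#' @export
update_affinity <- function(A, aux, U, V) {
  dat <- .em_data(A)
  res <- .mstep_W(dat, aux$rho, U, V)
  out <- .W_from_mat(res$W2, ncol(U))
  if (res$flagged > 0) attr(out, "flagged") <- res$flagged
  out
}
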