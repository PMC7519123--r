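# Fixture builders and independent oracles used across the suite.
# Oracles deliberately use dense triple loops / generic optimizers so they
# share no code path with the implementation they check.

# random valid parameter set (row-normalized memberships and beta)
rand_params <- function(N, C, Z, L, gamma = 0.5, seed = 1) {
  set.seed(seed)
  nrm <- function(M) M / rowSums(M)
  mtcov_params(U = nrm(matrix(runif(N * C), N, C)),
               V = nrm(matrix(runif(N * C), N, C)),
               W = array(runif(C * C * L), c(C, C, L)),
               beta = nrm(matrix(runif(C * Z), C, Z)),
               gamma = gamma)
}

# small random network + attributes on explicit node ids
rand_instance <- function(N, C, Z, L, seed = 1, rate = 0.8) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(N))
  rows <- expand.grid(i = seq_len(N), j = seq_len(N), layer = seq_len(L))
  rows <- rows[rows$i != rows$j, ]
  w <- rpois(nrow(rows), rate)
  keep <- w > 0
  edges <- data.frame(source = nodes[rows$i[keep]],
                      target = nodes[rows$j[keep]],
                      layer = sprintf("L%d", rows$layer[keep]),
                      weight = w[keep])
  A <- multilayer_network(edges, nodes = nodes)
  z <- sample.int(Z, N, replace = TRUE)
  z[seq_len(min(Z, N))] <- seq_len(min(Z, N))   # every category observed
  tab <- data.frame(node = nodes, attr = sprintf("z%d", z))
  X <- encode_attributes(tab, nodes = nodes)
  list(A = A, X = X, nodes = nodes)
}

# dense Poisson-mean tensor by an explicit triple loop over (k, l)
oracle_M <- function(params) {
  N <- nrow(params$U); C <- ncol(params$U); L <- dim(params$W)[3]
  M <- array(0, c(N, N, L))
  for (al in seq_len(L)) for (i in seq_len(N)) for (j in seq_len(N)) {
    s <- 0
    for (k in seq_len(C)) for (l in seq_len(C)) {
      s <- s + params$U[i, k] * params$V[j, l] * params$W[k, l, al]
    }
    M[i, j, al] <- s
  }
  M
}

# dense elementwise network log-likelihood (log term on edges only; the
# -sum(M) term runs over all ordered pairs, diagonal included)
oracle_loglik_network <- function(A, params) {
  M <- oracle_M(params)
  Aarr <- adjacency_tensor(A)
  s <- 0
  for (al in seq_len(dim(M)[3])) for (i in seq_len(dim(M)[1])) {
    for (j in seq_len(dim(M)[2])) {
      if (Aarr[i, j, al] > 0) s <- s + Aarr[i, j, al] * log(M[i, j, al])
      s <- s - M[i, j, al]
    }
  }
  s
}

oracle_loglik_attributes <- function(X, params) {
  s <- 0
  for (i in seq_along(X$z)) {
    p <- 0
    for (k in seq_len(ncol(params$U))) {
      p <- p + 0.5 * params$beta[k, X$z[i]] * (params$U[i, k] + params$V[i, k])
    }
    s <- s + log(p)
  }
  s
}

# maximize f over the probability simplex via softmax reparametrization
simplex_argmax <- function(f, C, n_starts = 8, seed = 1) {
  set.seed(seed)
  best <- NULL; best_val <- -Inf
  for (s in seq_len(n_starts)) {
    th0 <- rnorm(C)
    opt <- optim(th0, function(th) {
      p <- exp(th - max(th)); p <- p / sum(p)
      -f(p)
    }, method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
    p <- exp(opt$par - max(opt$par)); p <- p / sum(p)
    if (-opt$value > best_val) { best_val <- -opt$value; best <- p }
  }
  best
}

# all-pairs AUC with half-credit for ties
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# exhaustive matched set score from the full pairwise similarity table
oracle_set_score <- function(truth, detected, delta) {
  sim <- function(a, b) {
    I <- length(intersect(a, b))
    if (delta == "f1") {
      if (I == 0) 0 else 2 * (I / length(b)) * (I / length(a)) /
        (I / length(b) + I / length(a))
    } else {
      I / length(union(a, b))
    }
  }
  tab <- outer(seq_along(truth), seq_along(detected),
               Vectorize(function(i, j) sim(truth[[i]], detected[[j]])))
  0.5 * mean(apply(tab, 1, max)) + 0.5 * mean(apply(tab, 2, max))
}

# apply one permutation of community labels to a parameter set
permute_params <- function(params, perm) {
  mtcov_params(U = params$U[, perm, drop = FALSE],
               V = params$V[, perm, drop = FALSE],
               W = array(params$W[perm, perm, , drop = FALSE],
                         dim(params$W)),
               beta = params$beta[perm, , drop = FALSE],
               gamma = params$gamma)
}

# write a TSV edge list to a temp file
write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
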