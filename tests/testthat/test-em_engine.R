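test_that("initialization is seed-deterministic and valid", {
  p1 <- init_params(N = 10, C = 3, Z = 2, L = 2, gamma = 0.5, seed = 42)
  p2 <- init_params(N = 10, C = 3, Z = 2, L = 2, gamma = 0.5, seed = 42)
  expect_identical(p1, p2)
  expect_silent(validate_params(p1))
  p3 <- init_params(N = 10, C = 3, Z = 2, L = 2, gamma = 0.5, seed = 43)
  expect_false(identical(p1$U, p3$U))
  expect_error(init_params(N = 2, C = 3, Z = 2, L = 1, gamma = 0, seed = 1),
               "C > N")
})

test_that("E-step responsibilities match the product-then-normalize oracle", {
  inst <- rand_instance(N = 4, C = 2, Z = 2, L = 2, seed = 21)
  p <- rand_params(N = 4, C = 2, Z = 2, L = 2, seed = 22)
  aux <- e_step(inst$A, inst$X, p)

  # h oracle
  for (i in 1:4) {
    z <- inst$X$z[i]
    num <- vapply(1:2, function(k)
      p$beta[k, z] * (p$U[i, k] + p$V[i, k]), numeric(1))
    expect_equal(aux$h[i, ], num / sum(num), tolerance = 1e-12)
  }
  expect_lt(max(abs(rowSums(aux$h) - 1)), 1e-12)

  # rho oracle, column layout (k-1)*C + l
  e <- inst$A$edges
  for (r in seq_len(nrow(e))) {
    num <- outer(p$U[e$source[r], ], p$V[e$target[r], ]) * p$W[, , e$layer[r]]
    expect_equal(aux$rho[r, ], as.numeric(t(num / sum(num))),
                 tolerance = 1e-12)
  }
  expect_lt(max(abs(rowSums(aux$rho) - 1)), 1e-12)
})

test_that("E-step with a single community is trivially concentrated", {
  inst <- rand_instance(N = 3, C = 1, Z = 2, L = 1, seed = 23)
  p <- mtcov_params(U = matrix(1, 3, 1), V = matrix(1, 3, 1),
                    W = array(0.4, c(1, 1, 1)),
                    beta = matrix(c(0.3, 0.7), 1, 2), gamma = 0.5)
  aux <- e_step(inst$A, inst$X, p)
  expect_true(all(aux$h == 1))
  expect_true(all(aux$rho == 1))
})

test_that("E-step normalization example: equal memberships, beta column (0.2, 0.6)", {
  nodes <- c("a", "b")
  A <- multilayer_network(data.frame(source = "a", target = "b",
                                     layer = "L1", weight = 1), nodes = nodes)
  X <- encode_attributes(data.frame(node = nodes, attr = c("z1", "z2")),
                         nodes = nodes)
  U <- matrix(0.5, 2, 2)
  beta <- cbind(c(0.2, 0.6), c(0.8, 0.4))   # column for category 1: (0.2, 0.6)
  p <- mtcov_params(U = U, V = U, W = array(0.1, c(2, 2, 1)),
                    beta = beta, gamma = 0.5)
  aux <- e_step(A, X, p)
  expect_equal(aux$h[1, ], c(0.25, 0.75))   # u+v = (1,1): 0.2/0.8, 0.6/0.8
})

test_that("beta update maximizes its surrogate term over the simplex rows", {
  inst <- rand_instance(N = 5, C = 2, Z = 3, L = 1, seed = 24)
  p <- rand_params(N = 5, C = 2, Z = 3, L = 1, seed = 25)
  aux <- e_step(inst$A, inst$X, p)
  beta <- update_beta(inst$X, aux)
  expect_lt(max(abs(rowSums(beta) - 1)), 1e-12)

  # independent oracle: numerically maximize sum_i,z x_iz h_izk log beta_kz
  # per community row over the simplex
  for (k in 1:2) {
    f <- function(b) {
      s <- 0
      for (i in 1:5) s <- s + aux$h[i, k] * log(b[inst$X$z[i]])
      s
    }
    num <- simplex_argmax(f, C = 3, seed = k)
    expect_equal(beta[k, ], num, tolerance = 1e-4)
  }

  # single node, single category: the observed category takes all mass
  A1 <- multilayer_network(data.frame(source = "a", target = "b",
                                      layer = "L1", weight = 1),
                           nodes = c("a", "b"))
  X1 <- encode_attributes(data.frame(node = c("a", "b"), attr = "only"),
                          nodes = c("a", "b"))
  p1 <- rand_params(N = 2, C = 2, Z = 1, L = 1, seed = 26)
  aux1 <- e_step(A1, X1, p1)
  expect_true(all(update_beta(X1, aux1) == 1))
})

test_that("membership update matches the closed form and its endpoints", {
  inst <- rand_instance(N = 5, C = 2, Z = 2, L = 2, seed = 27)
  p <- rand_params(N = 5, C = 2, Z = 2, L = 2, seed = 28)
  aux <- e_step(inst$A, inst$X, p)
  arr <- adjacency_tensor(inst$A)

  for (gamma in c(0, 0.5, 1)) {
    up <- update_memberships(inst$A, inst$X, aux, gamma)
    # dense transcription oracle for u and v
    for (i in 1:5) for (k in 1:2) {
      num <- if (gamma > 0) gamma * aux$h[i, k] else 0
      den <- gamma
      numv <- if (gamma > 0) gamma * aux$h[i, k] else 0
      denv <- gamma
      if (gamma < 1) {
        e <- inst$A$edges
        for (r in seq_len(nrow(e))) {
          rho_r <- matrix(aux$rho[r, ], 2, 2, byrow = TRUE)
          if (e$source[r] == i) {
            num <- num + (1 - gamma) * e$weight[r] * sum(rho_r[k, ])
            den <- den + (1 - gamma) * e$weight[r]
          }
          if (e$target[r] == i) {
            numv <- numv + (1 - gamma) * e$weight[r] * sum(rho_r[, k])
            denv <- denv + (1 - gamma) * e$weight[r]
          }
        }
      }
      expect_equal(up$U[i, k], num / den, tolerance = 1e-12)
      expect_equal(up$V[i, k], numv / denv, tolerance = 1e-12)
    }
    # rows sum to 1 by construction
    expect_lt(max(abs(rowSums(up$U) - 1)), 1e-12)
    expect_lt(max(abs(rowSums(up$V) - 1)), 1e-12)
  }

  # gamma = 1: pure attribute responsibility
  up1 <- update_memberships(inst$A, inst$X, aux, 1)
  expect_equal(up1$U, aux$h, tolerance = 1e-12)
  expect_equal(up1$V, aux$h, tolerance = 1e-12)
})

test_that("membership update at gamma = 0 uses edge marginals; isolated rows go uniform", {
  # one node with a single out-edge: u row is the rho source-group marginal
  nodes <- c("a", "b", "c")
  A <- multilayer_network(data.frame(source = c("a", "b"), target = c("b", "c"),
                                     layer = "L1", weight = c(1, 1)),
                          nodes = nodes)
  p <- rand_params(N = 3, C = 2, Z = 2, L = 1, seed = 29)
  aux <- e_step(A, NULL, p)
  up <- update_memberships(A, NULL, aux, gamma = 0)
  rho1 <- matrix(aux$rho[1, ], 2, 2, byrow = TRUE)
  expect_equal(up$U[1, ], rowSums(rho1), tolerance = 1e-12)
  # node c has no out-edges: zero denominator -> uniform row, flagged
  expect_equal(up$U[3, ], c(0.5, 0.5))
  expect_gte(up$flagged, 1)
})

test_that("affinity update matches its stationary point and closed forms", {
  inst <- rand_instance(N = 4, C = 2, Z = 2, L = 2, seed = 30)
  p <- rand_params(N = 4, C = 2, Z = 2, L = 2, seed = 31)
  aux <- e_step(inst$A, inst$X, p)
  up <- update_memberships(inst$A, inst$X, aux, 0.5)
  W <- update_affinity(inst$A, aux, up$U, up$V)

  # independent oracle: root of the surrogate derivative
  # d/dw [sum_e A_e rho_ekl log w - w sum_i u_ik sum_j v_jl] = 0
  e <- inst$A$edges
  for (al in 1:2) for (k in 1:2) for (l in 1:2) {
    sel <- e$layer == al
    num <- sum(e$weight[sel] * aux$rho[sel, (k - 1) * 2 + l])
    den <- sum(up$U[, k]) * sum(up$V[, l])
    if (num > 0) {
      root <- uniroot(function(w) num / w - den,
                      interval = c(1e-12, 1e6), tol = 1e-12)$root
      expect_equal(W[k, l, al], root, tolerance = 1e-4)
    }
  }

  # single community: w = total weight / N^2
  inst1 <- rand_instance(N = 3, C = 1, Z = 2, L = 1, seed = 32)
  p1 <- mtcov_params(U = matrix(1, 3, 1), V = matrix(1, 3, 1),
                     W = array(0.4, c(1, 1, 1)), beta = matrix(1, 1, 1),
                     gamma = 0)
  aux1 <- e_step(inst1$A, NULL, p1)
  W1 <- update_affinity(inst1$A, aux1, p1$U, p1$V)
  expect_equal(W1[1, 1, 1], sum(inst1$A$edges$weight) / 9, tolerance = 1e-12)

  # a layer with no edges gets a zero affinity matrix
  nodes <- c("a", "b")
  A2 <- multilayer_network(data.frame(source = "a", target = "b",
                                      layer = c("L1"), weight = 1),
                           nodes = nodes)
  A2$layers <- c("L1", "L2"); A2$L <- 2L
  p2 <- rand_params(N = 2, C = 2, Z = 2, L = 2, seed = 33)
  aux2 <- e_step(A2, NULL, p2)
  W2 <- update_affinity(A2, aux2, p2$U, p2$V)
  expect_true(all(W2[, , 2] == 0))
})

test_that("fit returns the best restart and a recorded trajectory", {
  bench <- make_benchmark("G1", seed = 60, N = 60)
  X <- bench$attributes(0.9, seed = 61)
  fit <- mtcov_fit(bench$network, X, C = 2, gamma = 0.5, n_restarts = 5,
                   seed = 62, max_iter = 200)
  expect_equal(fit$loglik, max(fit$restarts$loglik))
  expect_equal(nrow(fit$restarts), 5)
  expect_gt(nrow(fit$trajectory), 0)
  expect_silent(validate_params(fit$params))

  # reproducibility: same seed, same fit
  fit2 <- mtcov_fit(bench$network, X, C = 2, gamma = 0.5, n_restarts = 5,
                    seed = 62, max_iter = 200)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$trajectory, fit2$trajectory)
})

test_that("fitted parameters keep all invariants and relabelling symmetry", {
  bench <- make_benchmark("G1", seed = 63, N = 60)
  X <- bench$attributes(0.8, seed = 64)
  fit <- mtcov_fit(bench$network, X, C = 2, gamma = 0.6, n_restarts = 2,
                   seed = 65, max_iter = 100)
  p <- fit$params
  expect_lt(max(abs(rowSums(p$U) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(p$V) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(p$beta) - 1)), 1e-12)

  # permuting community labels leaves the objective unchanged
  q <- permute_params(p, c(2, 1))
  expect_equal(as.numeric(total_loglik(bench$network, X, q)),
               as.numeric(total_loglik(bench$network, X, p)),
               tolerance = 1e-9)
})

test_that("gamma endpoints never touch the other data source", {
  bench <- make_benchmark("G1", seed = 66, N = 60)
  X <- bench$attributes(0.9, seed = 67)

  # gamma = 0: X is ignored entirely (NULL or any X give the same fit)
  f0a <- mtcov_fit(bench$network, NULL, C = 2, gamma = 0, n_restarts = 2,
                   seed = 68, max_iter = 100)
  f0b <- mtcov_fit(bench$network, X, C = 2, gamma = 0, n_restarts = 2,
                   seed = 68, max_iter = 100)
  expect_identical(f0a$params$U, f0b$params$U)
  expect_identical(f0a$loglik, f0b$loglik)

  # gamma = 1: the adjacency entries are ignored (different edge sets,
  # same node set, identical fit)
  other <- make_benchmark("G1", seed = 99, N = 60)
  f1a <- mtcov_fit(bench$network, X, C = 2, gamma = 1, n_restarts = 2,
                   seed = 69, max_iter = 100)
  f1b <- mtcov_fit(other$network, X, C = 2, gamma = 1, n_restarts = 2,
                   seed = 69, max_iter = 100)
  expect_identical(f1a$params$U, f1b$params$U)
  expect_identical(f1a$params$beta, f1b$params$beta)
})

test_that("undirected mode ties the two membership matrices", {
  bench <- make_benchmark("G1", seed = 70, N = 40)
  X <- bench$attributes(0.9, seed = 71)
  fit <- mtcov_fit(bench$network, X, C = 2, gamma = 0.5, n_restarts = 2,
                   seed = 72, max_iter = 100, undirected = TRUE)
  expect_identical(fit$params$U, fit$params$V)
})

test_that("easy planted structure is recovered exactly", {
  bench <- make_benchmark("G1", seed = 73, N = 100)
  X <- bench$attributes(1, seed = 74)
  fit <- mtcov_fit(bench$network, X, C = 2, gamma = 0.7, n_restarts = 5,
                   seed = 75)
  lab <- hard_memberships(fit$params$U)
  truth <- bench$truth$community
  agree <- max(mean(lab == truth), mean(3 - lab == truth))
  expect_equal(agree, 1)
})
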