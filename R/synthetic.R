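## Synthetic stochastic-block-model benchmarks with planted equal-size
## communities, archetypal layer structures and community-matched
## categorical attributes.

#' Archetypal layer affinity matrix
#'
#' Builds the C x C affinity of one layer from its structural archetype.
#' With base rate \eqn{r = kC/N} (giving average degree about `k` per
#' layer):
#' * `assortative`: diagonal r, off-diagonal `off_scale * r`;
#' * `disassortative`: off-diagonal r, diagonal `off_scale * r`;
#' * `core-periphery` (C = 2): w11 = r, w12 = w21 = `off_scale * r`,
#'   w22 = `weak_scale * r`;
#' * `biased-directed` (C = 2): w12 = r, w11 = w22 = `off_scale * r`,
#'   w21 = `weak_scale * r`.
#'
#' @param archetype one of `"assortative"`, `"disassortative"`,
#'   `"core-periphery"`, `"biased-directed"`.
#' @param N,C,k nodes, communities, target average degree.
#' @param off_scale,weak_scale relative size of the secondary and weak
#'   entries (defaults 0.1 and 0.03).
#' @return C x C numeric matrix of Poisson rates per ordered node pair.
#' @export
layer_affinity <- function(archetype, N, C = 2, k = 4,
                           off_scale = 0.1, weak_scale = 0.03) {
  r <- k * C / N
  archetype <- match.arg(archetype, c("assortative", "disassortative",
                                      "core-periphery", "biased-directed"))
  if (archetype %in% c("core-periphery", "biased-directed") && C != 2) {
    stop(archetype, " layers are defined for C = 2")
  }
  W <- matrix(off_scale * r, C, C)
  switch(archetype,
    assortative = { diag(W) <- r },
    disassortative = { W[] <- r; diag(W) <- off_scale * r },
    `core-periphery` = { W[1, 1] <- r; W[2, 2] <- weak_scale * r },
    `biased-directed` = { W[1, 2] <- r; W[2, 1] <- weak_scale * r }
  )
  W
}

#' Generate a directed multilayer SBM network with planted communities
#'
#' Nodes are split into C equal-size unmixed communities; for every
#' ordered pair (i, j), i != j, and every layer, the edge count is drawn
#' Poisson with mean \eqn{w^{(\alpha)}_{c(i) c(j)}} from that layer's
#' archetypal affinity. Poisson draws match the inference model's edge
#' distribution; at these sparse rates they are nearly indistinguishable
#' from Bernoulli draws.
#'
#' @param N number of nodes (must be divisible by C).
#' @param C number of planted communities.
#' @param archetypes character vector of layer archetypes, one per layer
#'   (see [layer_affinity()]).
#' @param k target average degree per layer.
#' @param seed integer RNG seed.
#' @param off_scale,weak_scale forwarded to [layer_affinity()].
#' @return list with `network` (a [multilayer_network]), and `truth`: list
#'   with the planted hard memberships `U0` = `V0` (N x C one-hot), the
#'   label vector `community` and the node ids.
#' @export
generate_network <- function(N, C = 2, archetypes, k = 4, seed = NULL,
                             off_scale = 0.1, weak_scale = 0.03) {
  if (N %% C != 0) stop("N must be divisible by C (equal-size groups)")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  L <- length(archetypes)
  labels <- rep(seq_len(C), each = N %/% C)
  nodes <- sprintf("N%0*d", nchar(N), seq_len(N))
  src <- integer(0); dst <- integer(0); lay <- integer(0); w <- integer(0)
  for (al in seq_len(L)) {
    W <- layer_affinity(archetypes[al], N = N, C = C, k = k,
                        off_scale = off_scale, weak_scale = weak_scale)
    for (kk in seq_len(C)) for (ll in seq_len(C)) {
      ii <- which(labels == kk); jj <- which(labels == ll)
      gi <- rep(ii, times = length(jj)); gj <- rep(jj, each = length(ii))
      ok <- gi != gj
      cnt <- rpois(sum(ok), W[kk, ll])
      nz <- cnt > 0L
      src <- c(src, gi[ok][nz]); dst <- c(dst, gj[ok][nz])
      lay <- c(lay, rep(al, sum(nz))); w <- c(w, cnt[nz])
    }
  }
  edges <- data.frame(source = nodes[src], target = nodes[dst],
                      layer = sprintf("L%d", lay), weight = w)
  net <- multilayer_network(edges, directed = TRUE, nodes = nodes)
  U0 <- matrix(0, N, C)
  U0[cbind(seq_len(N), labels)] <- 1
  list(network = net,
       truth = list(U0 = U0, V0 = U0, community = labels, nodes = nodes,
                    archetypes = archetypes, k = k, seed = seed))
}

#' Generate attributes matched to planted communities
#'
#' Exactly `round(match_ratio * N)` nodes, chosen uniformly without
#' replacement, receive the category designated for their community
#' (community c maps to category c); each remaining node draws its
#' category uniformly at random. The default draw is uniform over all Z
#' categories (`mismatch = "uniform"`), which is the protocol that
#' reproduces the published benchmark accuracies; `mismatch = "other"`
#' restricts the draw to the Z - 1 non-matching categories.
#'
#' @param truth the `truth` element of [generate_network()].
#' @param match_ratio fraction of nodes deterministically matched.
#' @param Z number of categories (default C; must be >= C).
#' @param seed integer RNG seed.
#' @param mismatch `"uniform"` (over all categories) or `"other"` (over
#'   the non-matching ones).
#' @return a `design_matrix` aligned with the network's node order.
#' @export
generate_attributes <- function(truth, match_ratio, Z = NULL, seed = NULL,
                                mismatch = c("uniform", "other")) {
  mismatch <- match.arg(mismatch)
  if (match_ratio < 0 || match_ratio > 1) stop("match_ratio must be in [0, 1]")
  labels <- truth$community
  N <- length(labels)
  C <- max(labels)
  if (is.null(Z)) Z <- C
  if (Z < 2 && match_ratio < 1) stop("Z < 2 with match_ratio < 1: no non-matching value exists")
  if (Z < C) stop("Z must be >= C: each community needs a designated category")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  z <- labels
  unmatched <- sample.int(N, N - round(match_ratio * N))
  if (length(unmatched) > 0L) {
    if (mismatch == "uniform") {
      z[unmatched] <- sample.int(Z, length(unmatched), replace = TRUE)
    } else {
      z[unmatched] <- vapply(unmatched, function(i) {
        pool <- setdiff(seq_len(Z), labels[i])
        pool[sample.int(length(pool), 1L)]
      }, integer(1L))
    }
  }
  categories <- sprintf("Z%d", seq_len(Z))
  tab <- data.frame(node = truth$nodes, attribute = categories[z])
  encode_attributes(tab, attributes = "attribute", nodes = truth$nodes)
}

#' Standard synthetic benchmarks
#'
#' The three benchmark families: `G1` has L = 2 layers (one assortative,
#' one disassortative), `G2` has L = 4 (two of each) and `G3` has L = 4
#' (assortative, disassortative, core-periphery, biased-directed), all
#' with N = 1000 nodes, C = 2 equal communities and average degree k = 4
#' by default. Duplicated archetypes in `G2` share the same affinity
#' matrix but draw their edges independently.
#'
#' @param name `"G1"`, `"G2"` or `"G3"`.
#' @param seed integer RNG seed for the edge draws.
#' @param N,C,k overrides for smaller test instances.
#' @return as [generate_network()], plus an `attributes` closure
#'   `function(match_ratio, Z = C, seed, mismatch = "uniform")` generating
#'   matched attributes for the planted truth.
#' @export
make_benchmark <- function(name = c("G1", "G2", "G3"), seed = NULL,
                           N = 1000, C = 2, k = 4) {
  name <- match.arg(name)
  archetypes <- switch(name,
    G1 = c("assortative", "disassortative"),
    G2 = c("assortative", "assortative", "disassortative", "disassortative"),
    G3 = c("assortative", "disassortative", "core-periphery", "biased-directed"))
  out <- generate_network(N = N, C = C, archetypes = archetypes, k = k,
                          seed = seed)
  truth <- out$truth
  out$attributes <- function(match_ratio, Z = NULL, seed = NULL,
                             mismatch = "uniform") {
    generate_attributes(truth, match_ratio, Z = Z, seed = seed,
                        mismatch = mismatch)
  }
  out$name <- name
  out
}
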