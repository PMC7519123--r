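## Evaluation machinery: set-matched scores for hard partitions,
## permutation-matched scores for soft memberships, link-prediction AUC,
## attribute accuracy with baselines and community attribute entropy.

#' Hard community labels from a membership matrix
#'
#' Argmax per row; exact ties go to the lowest community index.
#'
#' @param U numeric N x C membership matrix.
#' @return integer vector of labels in `1..C`.
#' @export
hard_memberships <- function(U) {
  max.col(U, ties.method = "first")
}

#' Community cover (list of node sets) from memberships
#'
#' `type = "hard"` builds one set per community from the argmax labels;
#' `type = "soft"` applies the non-zero-entry rule, treating entries below
#' `threshold` as zero (EM leaves all entries strictly positive, so a
#' literal non-zero rule would put every node in every set).
#'
#' @param U membership matrix.
#' @param type `"hard"` or `"soft"`.
#' @param threshold soft-membership cutoff (default 1e-2).
#' @return list of integer vectors, one per community (empty sets kept).
#' @export
community_cover <- function(U, type = c("hard", "soft"), threshold = 1e-2) {
  type <- match.arg(type)
  C <- ncol(U)
  if (type == "hard") {
    lab <- hard_memberships(U)
    lapply(seq_len(C), function(k) which(lab == k))
  } else {
    lapply(seq_len(C), function(k) which(U[, k] > threshold))
  }
}

.set_similarity <- function(a, b, delta) {
  inter <- length(intersect(a, b))
  if (delta == "f1") {
    if (inter == 0L) return(0)
    prec <- inter / length(b)
    rec <- inter / length(a)
    2 * prec * rec / (prec + rec)
  } else {
    inter / length(union(a, b))
  }
}

#' Matched set similarity between two community covers
#'
#' Every ground-truth community is matched with its most similar detected
#' community and vice versa; the final score is the average of the two
#' directions:
#' \deqn{\frac{1}{2|C^*|} \sum_i \max_j \delta(C^*_i, C_j) +
#'       \frac{1}{2|C|} \sum_j \max_i \delta(C^*_i, C_j)}
#' with \eqn{\delta} the set F1-score (harmonic mean of precision and
#' recall) or the Jaccard similarity. 1 means a perfect matching.
#'
#' @param truth,detected community covers: lists of node-index vectors.
#' @param delta `"f1"` or `"jaccard"`.
#' @return scalar in `[0, 1]`.
#' @export
matched_set_score <- function(truth, detected, delta = c("f1", "jaccard")) {
  delta <- match.arg(delta)
  if (length(truth) == 0L || length(detected) == 0L) {
    stop("both covers must contain at least one community")
  }
  if (any(lengths(truth) == 0L) || any(lengths(detected) == 0L)) {
    stop("empty community set in a cover")
  }
  fwd <- vapply(truth, function(a)
    max(vapply(detected, .set_similarity, numeric(1L), a = a, delta = delta)),
    numeric(1L))
  bwd <- vapply(detected, function(b)
    max(vapply(truth, .set_similarity, numeric(1L), b = b, delta = delta)),
    numeric(1L))
  0.5 * mean(fwd) + 0.5 * mean(bwd)
}

.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(.all_perms(n - 1L), function(p) c(i, p + (p >= i)))
  }))
}

# per-column-pair score matrix S[k, k'] for U0 column k vs U column k'
.column_scores <- function(U0, U, metric) {
  N <- nrow(U0)
  if (metric == "cs") {
    n0 <- sqrt(rowSums(U0 ^ 2)); n1 <- sqrt(rowSums(U ^ 2))
    A <- U0 / pmax(n0, .LOG_FLOOR); B <- U / pmax(n1, .LOG_FLOOR)
    crossprod(A, B) / N                     # mean over nodes of cosine terms
  } else {
    C <- ncol(U0)
    S <- matrix(0, C, C)
    for (k in seq_len(C)) for (kk in seq_len(C)) {
      S[k, kk] <- sum(abs(U0[, k] - U[, kk])) / (2 * N)
    }
    S
  }
}

#' Permutation-matched membership score
#'
#' Compares a detected soft membership matrix with the ground truth under
#' the best relabelling of communities. `metric = "cs"` is the mean over
#' nodes of the cosine similarity between membership rows (1 = identical
#' directions); `metric = "l1"` is the mean L1 distance with a 1/2 factor,
#' ranging from 0 for identical rows to 1 for rows with disjoint support.
#' Both decompose over matched column pairs, so the optimal relabelling is
#' an assignment problem: all C! permutations are searched exhaustively
#' for C <= 8, and a maximum-weight bipartite matching is used above that.
#'
#' @param U0 ground-truth N x C membership matrix.
#' @param U detected N x C membership matrix.
#' @param metric `"cs"` (maximized) or `"l1"` (minimized).
#' @return scalar score under the best column permutation.
#' @export
matched_vector_score <- function(U0, U, metric = c("cs", "l1")) {
  metric <- match.arg(metric)
  stopifnot(all(dim(U0) == dim(U)))
  C <- ncol(U0)
  S <- .column_scores(U0, U, metric)
  if (C <= 8L) {
    vals <- vapply(.all_perms(C), function(p)
      sum(S[cbind(seq_len(C), p)]), numeric(1L))
    if (metric == "cs") max(vals) else min(vals)
  } else {
    Wt <- if (metric == "cs") S else max(S) - S
    g <- igraph::make_bipartite_graph(rep(c(TRUE, FALSE), each = C),
                                      edges = integer(0))
    g <- igraph::add_edges(g, as.vector(rbind(rep(seq_len(C), each = C),
                                              C + rep(seq_len(C), times = C))))
    igraph::E(g)$weight <- as.vector(t(Wt)) + 1e-12
    m <- igraph::max_bipartite_match(g)$matching[seq_len(C)] - C
    sum(S[cbind(seq_len(C), m)])
  }
}

#' Link-prediction AUC
#'
#' Probability that a randomly chosen held-out positive cell (an existing
#' edge) receives a higher score than a randomly chosen held-out negative
#' cell, ties counting 1/2 — the area under the ROC curve, computed by
#' the rank statistic (average ranks handle ties exactly).
#'
#' @param scores numeric scores (e.g. [predict_edges()] on held-out cells).
#' @param positive logical vector: is the cell an observed edge?
#' @return scalar in `[0, 1]`.
#' @export
auc_link_prediction <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: need at least one positive and one negative cell")
  }
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Attribute-prediction accuracy
#'
#' Fraction of nodes whose most probable category under `pi` equals the
#' observed one; probability ties go to the lowest category index.
#'
#' @param z_true integer vector of true category indices.
#' @param pi N x Z probability matrix (e.g. [attribute_probs()] rows for
#'   the held-out nodes).
#' @return scalar in `[0, 1]`.
#' @export
attribute_accuracy <- function(z_true, pi) {
  if (length(z_true) == 0L) stop("empty held-out set")
  stopifnot(length(z_true) == nrow(pi))
  mean(max.col(pi, ties.method = "first") == z_true)
}

#' Attribute-prediction baselines
#'
#' Random probability (RP): accuracy of a uniform guess over the Z
#' categories, 1/Z. Maximum relative frequency (MRF): the relative
#' frequency of the most common category in the training set.
#'
#' @param z_train integer vector of training category indices.
#' @param Z number of categories.
#' @return list with `rp` and `mrf`.
#' @export
prediction_baselines <- function(z_train, Z) {
  if (Z < 1) stop("Z must be >= 1")
  if (length(z_train) == 0L) stop("empty training attribute set")
  list(rp = 1 / Z, mrf = max(tabulate(z_train, nbins = Z)) / length(z_train))
}

#' Normalized attribute entropy per community
#'
#' \eqn{H_k = -\sum_z f_z \log f_z / \log Z}, with \eqn{f_z} the relative
#' frequency of category z inside community k. 1 means the attribute is
#' uniformly mixed inside the community, 0 that the community carries a
#' single category.
#'
#' @param counts K x Z matrix (or vector for one community) of
#'   within-community category counts.
#' @param Z number of categories (default `ncol(counts)`); must exceed 1.
#' @return numeric vector of per-community entropies.
#' @export
community_entropy <- function(counts, Z = NULL) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1L)
  if (is.null(Z)) Z <- ncol(counts)
  if (Z <= 1) stop("entropy undefined for Z <= 1 (log Z = 0)")
  if (any(rowSums(counts) == 0)) stop("each community must be nonempty")
  apply(counts, 1L, function(ct) {
    f <- ct / sum(ct)
    f <- f[f > 0]
    -sum(f * log(f)) / log(Z)
  })
}

#' Direction-averaged benchmark score report
#'
#' Scores a fitted model against a planted truth with the four standard
#' metrics (matched F1, matched Jaccard, permutation-matched cosine
#' similarity and L1 error), each reported as the average of the score
#' computed on the outgoing (`U`) and incoming (`V`) memberships.
#'
#' @param truth the `truth` element of [generate_network()].
#' @param params fitted [mtcov_params].
#' @return named list: `f1`, `jaccard`, `cs`, `l1`.
#' @export
score_against_truth <- function(truth, params) {
  truth_cover <- community_cover(truth$U0, "hard")
  both <- function(fn) mean(c(fn(params$U), fn(params$V)))
  list(
    f1 = both(function(M) matched_set_score(truth_cover,
                                            community_cover(M, "hard"), "f1")),
    jaccard = both(function(M) matched_set_score(truth_cover,
                                                 community_cover(M, "hard"),
                                                 "jaccard")),
    cs = both(function(M) matched_vector_score(truth$U0, M, "cs")),
    l1 = both(function(M) matched_vector_score(truth$U0, M, "l1"))
  )
}
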