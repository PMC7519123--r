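#' Construct a multilayer network from a long-format edge table
#'
#' Builds the sparse adjacency representation used throughout the package
#' from records of (source, target, layer, weight). Node and layer
#' identifiers are mapped to indices by lexicographic sort of their string
#' form, so the mapping is reproducible across runs and platforms.
#'
#' Preprocessing applied on construction:
#' * zero-weight records are dropped;
#' * self-loops are removed;
#' * duplicate (source, target, layer) records are summed (weights are
#'   interpreted as counts);
#' * in undirected mode each edge is stored in both directions and the
#'   membership matrices are tied (`U = V`) during fitting.
#'
#' @param edges data.frame with columns `source`, `target`, `layer` and
#'   optionally `weight` (default 1). Weights must be non-negative integers.
#' @param directed logical; if `FALSE` the adjacency is symmetrized.
#' @param nodes optional character vector of node ids fixing the node set
#'   (isolated nodes are kept); defaults to the ids observed in `edges`.
#' @return an object of class `multilayer_network`: a list with elements
#'   `edges` (data.frame of integer-indexed `source`, `target`, `layer`,
#'   `weight`), `nodes`, `layers`, `N`, `L`, `directed`.
#' @seealso [read_multilayer_edgelist()]
#' @export
multilayer_network <- function(edges, directed = TRUE, nodes = NULL) {
  required <- c("source", "target", "layer")
  if (!all(required %in% names(edges))) {
    stop("edge table must have columns source, target, layer")
  }
  if (is.null(edges$weight)) edges$weight <- 1L
  w <- edges$weight
  if (any(!is.finite(w)) || any(w < 0) || any(w != floor(w))) {
    bad <- which(!is.finite(w) | w < 0 | w != floor(w))[1L]
    stop(sprintf("invalid weight '%s' in edge record %d: weights must be non-negative integers",
                 as.character(w[bad]), bad))
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$layer <- as.character(edges$layer)

  edges <- edges[edges$weight > 0, , drop = FALSE]          # zero counts carry no record
  edges <- edges[edges$source != edges$target, , drop = FALSE]  # self-loops removed

  node_ids <- sort(unique(c(edges$source, edges$target, nodes)))
  layer_ids <- sort(unique(edges$layer))
  if (length(node_ids) == 0L) stop("network has no nodes")
  if (length(layer_ids) == 0L) layer_ids <- "L1"

  i <- match(edges$source, node_ids)
  j <- match(edges$target, node_ids)
  a <- match(edges$layer, layer_ids)
  w <- as.numeric(edges$weight)

  if (!directed && nrow(edges) > 0L) {
    i2 <- c(i, j); j2 <- c(j, i); a2 <- c(a, a); w2 <- c(w, w)
    i <- i2; j <- j2; a <- a2; w <- w2
  }

  if (length(i) > 0L) {
    key <- paste(i, j, a)
    agg <- rowsum(w, key)
    parts <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
    tab <- data.frame(
      source = as.integer(parts[, 1]),
      target = as.integer(parts[, 2]),
      layer = as.integer(parts[, 3]),
      weight = as.numeric(agg)
    )
    tab <- tab[order(tab$layer, tab$source, tab$target), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(source = integer(), target = integer(),
                      layer = integer(), weight = numeric())
  }

  structure(list(
    edges = tab,
    nodes = node_ids,
    layers = layer_ids,
    N = length(node_ids),
    L = length(layer_ids),
    directed = directed
  ), class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("multilayer_network: %d nodes, %d layer%s, %d non-zero entries (total weight %g), %s\n",
              x$N, x$L, if (x$L == 1) "" else "s", nrow(x$edges),
              sum(x$edges$weight), if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Dense adjacency tensor of a multilayer network
#'
#' Materializes the N x N x L count tensor. Intended for small networks
#' (oracles, toy examples); the fitting code never builds it.
#'
#' @param A a `multilayer_network`.
#' @return numeric array of dimension `c(N, N, L)`.
#' @export
adjacency_tensor <- function(A) {
  stopifnot(inherits(A, "multilayer_network"))
  out <- array(0, c(A$N, A$N, A$L),
               dimnames = list(A$nodes, A$nodes, A$layers))
  e <- A$edges
  out[cbind(e$source, e$target, e$layer)] <- e$weight
  out
}

# weighted out/in strength per node (training adjacency)
.degrees <- function(A) {
  outd <- numeric(A$N); ind <- numeric(A$N)
  e <- A$edges
  if (nrow(e) > 0L) {
    so <- rowsum(e$weight, e$source)
    outd[as.integer(rownames(so))] <- so
    si <- rowsum(e$weight, e$target)
    ind[as.integer(rownames(si))] <- si
  }
  list(out = outd, `in` = ind)
}
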