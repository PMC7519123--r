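#' Read a multilayer edge list from a TSV file
#'
#' The dialect is long-format TSV with a header naming the columns
#' `source`, `target`, `layer` and optionally `weight` (missing weights
#' default to 1). One record corresponds to one (edge, layer) pair;
#' duplicate records are summed. Self-loops and zero-weight records are
#' dropped, matching the preprocessing applied to the networks this model
#' is built for.
#'
#' @param path path to the TSV file.
#' @param directed logical; `FALSE` symmetrizes and ties `U = V` at fit time.
#' @return a [multilayer_network]. Node and layer index maps are available
#'   as the `nodes` and `layers` elements (lexicographically sorted, hence
#'   deterministic given the file).
#' @export
read_multilayer_edgelist <- function(path, directed = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
               check.names = FALSE, quote = ""),
    error = function(e) stop("malformed edge list ", path, ": ", conditionMessage(e))
  )
  if (nrow(raw) == 0L) stop("empty edge list: ", path)
  required <- c("source", "target", "layer")
  if (!all(required %in% names(raw))) {
    stop("edge list must have header columns source, target, layer (got: ",
         paste(names(raw), collapse = ", "), ")")
  }
  if (is.null(raw$weight)) {
    raw$weight <- 1
  } else {
    wnum <- suppressWarnings(as.numeric(raw$weight))
    bad <- which(is.na(wnum) | wnum < 0 | wnum != floor(wnum))
    if (length(bad) > 0L) {
      stop(sprintf("format error at line %d of %s: weight '%s' is not a non-negative integer",
                   bad[1L] + 1L, path, raw$weight[bad[1L]]))
    }
    raw$weight <- wnum
  }
  blank <- which(raw$source == "" | raw$target == "" | raw$layer == "")
  if (length(blank) > 0L) {
    stop(sprintf("format error at line %d of %s: empty field", blank[1L] + 1L, path))
  }
  multilayer_network(raw, directed = directed)
}

#' Write a multilayer network as a TSV edge list
#'
#' Inverse of [read_multilayer_edgelist()]: writes original node/layer ids.
#'
#' @param A a [multilayer_network].
#' @param path output file.
#' @export
write_multilayer_edgelist <- function(A, path) {
  stopifnot(inherits(A, "multilayer_network"))
  e <- A$edges
  out <- data.frame(source = A$nodes[e$source], target = A$nodes[e$target],
                    layer = A$layers[e$layer], weight = e$weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' One-hot encode categorical node attributes
#'
#' Encodes one attribute per node into the N x Z design matrix expected by
#' the model. Several attributes can be combined into a single
#' "super-attribute" whose categories are the observed combinations
#' (e.g. gender x religion). Bounded continuous attributes are binned into
#' equal-width bins anchored at the observed minimum
#' (`floor((x - min) / bin_width)`).
#'
#' Missing values are an error: the model defines no missing-data
#' mechanism for attributes outside the cross-validation masks.
#'
#' @param table data.frame with a node-id column and one or more attribute
#'   columns.
#' @param attributes character vector of attribute column names to use; if
#'   more than one, their observed combinations form the categories.
#' @param node_col name of the node-id column (default first column).
#' @param bin_width optional bin width for a single numeric attribute.
#' @param nodes optional character vector giving the node set and row order
#'   (typically `A$nodes`); every listed node must appear exactly once in
#'   `table`, and nodes unknown to `nodes` are rejected.
#' @return an object of class `design_matrix`: list with `X` (N x Z binary
#'   matrix, one 1 per row), `z` (integer category per node), `categories`
#'   (codebook: category value per column) and `nodes`.
#' @export
encode_attributes <- function(table, attributes = NULL,
                              node_col = names(table)[1L],
                              bin_width = NULL, nodes = NULL) {
  stopifnot(is.data.frame(table), node_col %in% names(table))
  if (is.null(attributes)) attributes <- setdiff(names(table), node_col)
  if (length(attributes) == 0L) stop("no attribute columns given")
  missing_cols <- setdiff(attributes, names(table))
  if (length(missing_cols) > 0L) {
    stop("attribute column(s) not in table: ", paste(missing_cols, collapse = ", "))
  }
  ids <- as.character(table[[node_col]])
  if (anyDuplicated(ids)) stop("duplicate node id in attribute table: ",
                               ids[duplicated(ids)][1L])
  if (!is.null(nodes)) {
    unknown <- setdiff(ids, nodes)
    if (length(unknown) > 0L) stop("attribute table has unknown node(s): ",
                                   paste(utils::head(unknown, 3L), collapse = ", "))
    absent <- setdiff(nodes, ids)
    if (length(absent) > 0L) stop("attribute value missing for node(s): ",
                                  paste(utils::head(absent, 3L), collapse = ", "))
    table <- table[match(nodes, ids), , drop = FALSE]
    ids <- nodes
  } else {
    ord <- order(ids)
    table <- table[ord, , drop = FALSE]
    ids <- ids[ord]
  }

  cols <- lapply(attributes, function(a) {
    v <- table[[a]]
    if (anyNA(v)) stop("missing value for attribute '", a, "' (node ",
                       ids[which(is.na(v))[1L]], "); imputation is out of scope")
    if (!is.null(bin_width) && is.numeric(v)) {
      if (any(!is.finite(v))) stop("attribute '", a, "' has non-finite values; binning needs a finite range")
      as.character(floor((v - min(v)) / bin_width))
    } else {
      as.character(v)
    }
  })
  combo <- if (length(cols) == 1L) cols[[1L]] else do.call(paste, c(cols, sep = "/"))

  categories <- sort(unique(combo))
  z <- match(combo, categories)
  Z <- length(categories)
  X <- matrix(0L, length(ids), Z, dimnames = list(ids, categories))
  X[cbind(seq_along(ids), z)] <- 1L
  structure(list(X = X, z = z, categories = categories, nodes = ids),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d nodes, %d categories (%s)\n",
              length(x$nodes), length(x$categories),
              paste(utils::head(x$categories, 5L), collapse = ", ")))
  invisible(x)
}

.fmt <- function(x) sprintf("%.17g", x)

#' Serialize fitted model parameters
#'
#' Writes `U.csv`, `V.csv` (rows keyed by node id), `beta.csv` (rows keyed
#' by community, columns by category), one `W_<layer>.csv` per layer, a
#' hard-membership export `hard_memberships.csv` (argmax per row, ties to
#' the lowest community index) and a `metadata.yaml` run record. Numeric
#' values are written with 17 significant digits, so a write/read
#' round-trip reproduces the doubles exactly.
#'
#' @param params an [mtcov_params] object.
#' @param outdir output directory (created if needed).
#' @param nodes,categories,layers identifier vectors; defaults are
#'   positional names.
#' @param metadata named list merged into `metadata.yaml` (e.g. seed,
#'   final log-likelihood).
#' @return invisibly, the vector of files written.
#' @export
write_params <- function(params, outdir, nodes = NULL, categories = NULL,
                         layers = NULL, metadata = list()) {
  validate_params(params)
  dims <- .param_dims(params)
  if (is.null(nodes)) nodes <- sprintf("N%04d", seq_len(dims$N))
  if (is.null(categories)) categories <- sprintf("Z%d", seq_len(dims$Z))
  if (is.null(layers)) layers <- sprintf("L%d", seq_len(dims$L))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)

  comm <- sprintf("C%d", seq_len(dims$C))
  wr <- function(M, rows, cols, file, key) {
    df <- data.frame(rows, apply(M, 2L, .fmt), check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c(key, cols)
    write.csv(df, file.path(outdir, file), row.names = FALSE, quote = FALSE)
    file
  }
  files <- c(
    wr(params$U, nodes, comm, "U.csv", "node"),
    wr(params$V, nodes, comm, "V.csv", "node"),
    wr(params$beta, comm, categories, "beta.csv", "community")
  )
  for (al in seq_len(dims$L)) {
    files <- c(files, wr(params$W[, , al], comm, comm,
                         sprintf("W_%s.csv", layers[al]), "community"))
  }
  hard <- data.frame(node = nodes,
                     out_community = comm[hard_memberships(params$U)],
                     in_community = comm[hard_memberships(params$V)])
  write.csv(hard, file.path(outdir, "hard_memberships.csv"),
            row.names = FALSE, quote = FALSE)
  meta <- c(list(C = dims$C, Z = dims$Z, L = dims$L, N = dims$N,
                 gamma = params$gamma, layers = as.list(layers)), metadata)
  yaml::write_yaml(meta, file.path(outdir, "metadata.yaml"))
  invisible(c(files, "hard_memberships.csv", "metadata.yaml"))
}

#' Read parameters written by [write_params()]
#'
#' @param dir directory written by [write_params()].
#' @return an [mtcov_params] object with `nodes`, `categories`, `layers`
#'   and `metadata` attached as attributes.
#' @export
read_params <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  rd <- function(file) {
    df <- read.csv(file.path(dir, file), check.names = FALSE,
                   colClasses = "character")
    M <- apply(as.matrix(df[, -1L, drop = FALSE]), c(1L, 2L), as.numeric)
    rownames(M) <- df[[1L]]
    M
  }
  U <- rd("U.csv"); V <- rd("V.csv"); beta <- rd("beta.csv")
  layers <- unlist(meta$layers)
  W <- array(0, c(meta$C, meta$C, meta$L))
  for (al in seq_len(meta$L)) W[, , al] <- rd(sprintf("W_%s.csv", layers[al]))
  p <- mtcov_params(U = unname(U), V = unname(V), W = W,
                    beta = unname(beta), gamma = meta$gamma)
  attr(p, "nodes") <- rownames(U)
  attr(p, "categories") <- colnames(beta)
  attr(p, "layers") <- layers
  attr(p, "metadata") <- meta
  p
}
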