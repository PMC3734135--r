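#' All-pairs voxel correlation matrix
#'
#' Dense Pearson correlation between every pair of columns. The diagonal
#' is 1 by definition but is excluded from all downstream edge logic;
#' zero-variance columns get correlation 0 with everything (with a
#' warning). For node counts where a dense matrix is unwanted, use
#' [build_network()], which computes and consumes correlations
#' blockwise.
#'
#' @param matrix a `voxel_matrix` (or plain time x node numeric matrix)
#'   with at least 3 time points.
#' @return symmetric N x N correlation matrix.
#' @export
correlation_matrix <- function(matrix) {
  values <- if (inherits(matrix, "voxel_matrix")) matrix$values else matrix
  if (nrow(values) < 3L)
    stop("need at least 3 time points to correlate (got ", nrow(values), ")")
  s <- apply(values, 2, stats::sd)
  zv <- s == 0 | !is.finite(s)
  if (any(zv)) {
    warning(sum(zv), " zero-variance column(s): correlation set to 0")
    values[, zv] <- 0
    values[1, zv] <- 1  # placeholder variance; rows/cols zeroed below
  }
  r <- stats::cor(values)
  if (any(zv)) {
    r[zv, ] <- 0
    r[, zv] <- 0
  }
  diag(r) <- 1
  r
}

# Standardize columns so that crossprod() yields Pearson correlations;
# zero-variance columns become all-zero (correlation 0 with everything).
.std_columns <- function(values) {
  n <- nrow(values)
  ctr <- sweep(values, 2, colMeans(values), `-`)
  ss <- sqrt(colSums(ctr^2))
  zv <- ss == 0 | !is.finite(ss)
  ss[zv] <- 1
  out <- sweep(ctr, 2, ss, `/`)
  out[, zv] <- 0
  attr(out, "n_zero_variance") <- sum(zv)
  out
}

#' Correlation threshold for a target N = K^S connection density
#'
#' Finds the smallest correlation `r_th` such that keeping edges with
#' `r(i,j) >= r_th` gives a mean degree K as close to `N^(1/S)` as the
#' discrete edge set allows: the target edge count is
#' `floor(N * N^(1/S) / 2)` and `r_th` is the value of the target-th
#' largest off-diagonal upper-triangle correlation (equivalently the
#' `1 - d*` quantile at density `d* = N^(1/S) / (N - 1)`). Thresholding
#' is inclusive, so ties at `r_th` can push the realized K above the
#' target by the size of the tie block.
#'
#' @param correlations symmetric correlation matrix, or the vector of
#'   upper-triangle correlation values (then `n_nodes` is required).
#' @param S density exponent (> 1).
#' @param n_nodes node count N when `correlations` is a vector.
#' @return the correlation threshold `r_th`.
#' @export
solve_threshold <- function(correlations, S, n_nodes = NULL) {
  if (S <= 1) stop("'S' must be > 1")
  if (is.matrix(correlations)) {
    n_nodes <- ncol(correlations)
    vals <- correlations[upper.tri(correlations)]
  } else {
    if (is.null(n_nodes)) stop("'n_nodes' is required when passing a value vector")
    vals <- correlations
    if (length(vals) != n_nodes * (n_nodes - 1) / 2)
      stop("value vector length does not match n_nodes")
  }
  if (n_nodes < 2L) stop("need at least 2 nodes")
  m_target <- .target_edges(n_nodes, S)
  pos <- length(vals) - m_target + 1L   # m-th largest value
  sort(vals, partial = pos)[pos]
}

.target_edges <- function(n_nodes, S) {
  # guard against floating-point dips just below integer targets
  # (e.g. 1000^(1/3) evaluates slightly under 10)
  m <- floor(n_nodes * n_nodes^(1 / S) / 2 + 1e-8)
  if (m < 1) stop("network would be empty: target edge count < 1 for N = ",
                  n_nodes, ", S = ", S)
  m
}

#' Binarize a correlation matrix at a threshold
#'
#' Creates an undirected binary network with an edge (i, j), i != j,
#' wherever `r(i, j) >= r_threshold` (signed lower bound: strong
#' negative correlations are excluded; set `absolute = TRUE` to
#' threshold `|r|` instead). Edges are computed on the upper triangle
#' and mirrored, so the result is symmetric with no self-edges by
#' construction.
#'
#' @param correlations symmetric correlation matrix.
#' @param r_threshold correlation lower bound in `[-1, 1]`.
#' @param S the density exponent that produced the threshold (recorded
#'   as metadata; `NA` if the threshold was chosen otherwise).
#' @param node_map optional node map (from a `voxel_matrix`) carried
#'   along for volume mapping.
#' @param absolute threshold on `|r|` instead of signed r.
#' @return an object of class `binary_network`: list with `edges`
#'   (2-column matrix of node pairs, i < j), `n_nodes`, `n_edges`,
#'   `mean_degree`, `r_threshold`, `S`, `node_map`.
#' @export
binarize <- function(correlations, r_threshold, S = NA_real_,
                     node_map = NULL, absolute = FALSE) {
  stopifnot(is.numeric(r_threshold), length(r_threshold) == 1L)
  r <- if (absolute) abs(correlations) else correlations
  hit <- which(upper.tri(r) & r >= r_threshold, arr.ind = TRUE)
  .new_network(hit, ncol(correlations), r_threshold, S, node_map)
}

.new_network <- function(edges, n_nodes, r_threshold, S, node_map) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  colnames(edges) <- c("i", "j")
  structure(list(edges = edges, n_nodes = as.integer(n_nodes),
                 n_edges = nrow(edges),
                 mean_degree = 2 * nrow(edges) / n_nodes,
                 r_threshold = r_threshold, S = S, node_map = node_map),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> N = %d, %d edges, K = %.3f (S = %s, r_th = %.4f)\n",
              x$n_nodes, x$n_edges, x$mean_degree,
              format(x$S), x$r_threshold))
  invisible(x)
}

#' Build the thresholded voxel network for one session
#'
#' Computes all-pairs Pearson correlations, solves the `N = K^S`
#' threshold, and binarizes, without ever materialising the dense
#' correlation matrix when N exceeds `dense_limit`: correlations are
#' computed in column blocks twice, once to collect the upper-triangle
#' values for the quantile and once to extract suprathreshold edges.
#'
#' @param matrix a `voxel_matrix` (>= 3 time points).
#' @param S density exponent (> 1).
#' @param dense_limit node count above which the blockwise path is used.
#' @param block_size number of columns per block in the blockwise path.
#' @param absolute threshold on `|r|` instead of signed r.
#' @return a `binary_network` (see [binarize()]).
#' @export
build_network <- function(matrix, S, dense_limit = 2048L, block_size = 512L,
                          absolute = FALSE) {
  stopifnot(inherits(matrix, "voxel_matrix"))
  values <- matrix$values
  if (nrow(values) < 3L) stop("need at least 3 time points")
  n <- ncol(values)
  if (n <= dense_limit) {
    r <- correlation_matrix(matrix)
    r_th <- solve_threshold(if (absolute) abs(r) else r, S)
    return(binarize(r, r_th, S = S, node_map = matrix$node_map,
                    absolute = absolute))
  }
  z <- .std_columns(values)
  if (attr(z, "n_zero_variance") > 0)
    warning(attr(z, "n_zero_variance"),
            " zero-variance column(s): correlation set to 0")
  blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
  vals <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    cols <- blocks[[b]]
    rb <- crossprod(z, z[, cols, drop = FALSE])   # n x |cols|
    if (absolute) rb <- abs(rb)
    keep <- outer(seq_len(n), cols, `<`)          # upper triangle only
    vals[[b]] <- rb[keep]
  }
  vals <- unlist(vals, use.names = FALSE)
  r_th <- solve_threshold(vals, S, n_nodes = n)
  edges <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    cols <- blocks[[b]]
    rb <- crossprod(z, z[, cols, drop = FALSE])
    if (absolute) rb <- abs(rb)
    hit <- which(rb >= r_th & outer(seq_len(n), cols, `<`), arr.ind = TRUE)
    hit[, 2] <- cols[hit[, 2]]
    edges[[b]] <- hit
  }
  edges <- do.call(rbind, edges)
  .new_network(edges, n, r_th, S, matrix$node_map)
}

#' Dense logical adjacency matrix of a binary network
#'
#' @param net a `binary_network`.
#' @return symmetric logical N x N matrix with a zero diagonal.
#' @export
as_adjacency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  a <- matrix(FALSE, net$n_nodes, net$n_nodes)
  if (net$n_edges > 0) {
    a[net$edges] <- TRUE
    a[net$edges[, 2:1, drop = FALSE]] <- TRUE
  }
  a
}

# Compressed sparse row adjacency (0-based, both directions) for the
# C++ graph traversals.
.as_csr <- function(net) {
  n <- net$n_nodes
  if (net$n_edges == 0)
    return(list(indptr = integer(n + 1L), indices = integer(0)))
  from <- c(net$edges[, 1], net$edges[, 2])
  to <- c(net$edges[, 2], net$edges[, 1])
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  counts <- tabulate(from, nbins = n)
  list(indptr = c(0L, cumsum(counts)), indices = to - 1L)
}

#' Persist a binary network as an edge list with metadata sidecar
#'
#' Writes a two-column TSV (`node_i`, `node_j`) and a JSON sidecar with
#' N, S, r_threshold, mean degree and edge count.
#'
#' @param net a `binary_network`.
#' @param stem output path stem; writes `<stem>_edges.tsv` and
#'   `<stem>_network.json`.
#' @return named character vector of written paths.
#' @export
write_network <- function(net, stem) {
  paths <- c(edges = paste0(stem, "_edges.tsv"),
             meta = paste0(stem, "_network.json"))
  edges <- net$edges
  colnames(edges) <- c("node_i", "node_j")
  write.table(edges, paths[["edges"]], sep = "\t", row.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(list(n_nodes = net$n_nodes, n_edges = net$n_edges,
                            mean_degree = net$mean_degree,
                            r_threshold = net$r_threshold, S = net$S),
                       paths[["meta"]], auto_unbox = TRUE, digits = NA)
  paths
}
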