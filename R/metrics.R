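.new_metric_volume <- function(metric, values, node_map) {
  structure(list(metric = metric, values = as.numeric(values),
                 node_map = node_map,
                 summary = c(mean = mean(values), sd = stats::sd(values))),
            class = "metric_volume")
}

#' @export
print.metric_volume <- function(x, ...) {
  cat(sprintf("<metric_volume> %s: %d nodes, network mean %.4f (sd %.4f)\n",
              x$metric, length(x$values), x$summary["mean"], x$summary["sd"]))
  invisible(x)
}

#' Nodal degree
#'
#' K(i) is the number of edges incident to node i; the network degree is
#' the nodal mean.
#'
#' @param net a `binary_network`.
#' @return a `metric_volume` with metric `"K"`.
#' @export
degree <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  k <- tabulate(net$edges, nbins = net$n_nodes)
  .new_metric_volume("K", k, net$node_map)
}

#' Degree distribution
#'
#' Empirical probability of each observed degree value across the
#' network's nodes.
#'
#' @param net a `binary_network`.
#' @return data frame with columns `degree` and `p` (nonnegative,
#'   summing to 1, support = observed degrees).
#' @export
degree_distribution <- function(net) {
  k <- degree(net)$values
  tab <- table(k)
  data.frame(degree = as.integer(names(tab)),
             p = as.numeric(tab) / length(k))
}

#' Nodal and network global efficiency
#'
#' `Eglob(i) = (1 / (N - 1)) * sum_{j != i} 1 / d(i, j)` with
#' unweighted shortest-path distance d computed by breadth-first
#' search; unreachable pairs contribute 0 (no largest-component
#' restriction). The network value is the mean over all nodes and
#' equals 1 exactly on a complete graph.
#'
#' @param net a `binary_network` with at least 2 nodes.
#' @return a `metric_volume` with metric `"Eglob"`.
#' @export
global_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"), net$n_nodes >= 2L)
  csr <- .as_csr(net)
  sums <- .cpp_path_sums(csr$indptr, csr$indices)
  .new_metric_volume("Eglob", sums[, 1] / (net$n_nodes - 1), net$node_map)
}

#' Nodal and network local efficiency
#'
#' `Eloc(i)` is the global efficiency of the subgraph induced on the
#' neighbors of i (node i itself excluded); nodes with fewer than 2
#' neighbors get 0. Measures locally fault-tolerant information
#' transfer; 1 on a complete graph.
#'
#' @param net a `binary_network`.
#' @return a `metric_volume` with metric `"Eloc"`.
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  csr <- .as_csr(net)
  .new_metric_volume("Eloc", .cpp_local_efficiency(csr$indptr, csr$indices),
                     net$node_map)
}

#' Clustering coefficient and characteristic path length (optional
#' metrics)
#'
#' Binary clustering coefficient `C(i) = 2 T(i) / (k(i) (k(i) - 1))`
#' with T(i) the number of triangles through i (0 for degree < 2), and
#' nodal path length `L(i)` = mean finite shortest-path distance from i
#' to the other nodes (`NaN` for isolated nodes). Provided for
#' completeness; the efficiency metrics are the primary summaries.
#'
#' @param net a `binary_network` with at least 2 nodes.
#' @return list of two `metric_volume`s, `C` and `L`.
#' @export
clustering_and_pathlength <- function(net) {
  stopifnot(inherits(net, "binary_network"), net$n_nodes >= 2L)
  csr <- .as_csr(net)
  k <- tabulate(net$edges, nbins = net$n_nodes)
  tri <- .cpp_triangles(csr$indptr, csr$indices)
  cc <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  sums <- .cpp_path_sums(csr$indptr, csr$indices)
  L <- ifelse(sums[, 3] > 0, sums[, 2] / sums[, 3], NaN)
  list(C = .new_metric_volume("C", cc, net$node_map),
       L = .new_metric_volume("L", L, net$node_map))
}

#' Map nodal metric values back to a 3D volume
#'
#' @param metric a `metric_volume` whose node map covers all nodes.
#' @param missing value for voxels outside the node map (default `NA`).
#' @return 3D array on the session grid.
#' @export
metric_to_volume <- function(metric, missing = NA_real_) {
  nm <- metric$node_map
  if (is.null(nm)) stop("metric has no node map; cannot place values on a grid")
  dim3 <- attr(nm, "grid_dim")
  if (is.null(dim3)) stop("node map carries no grid dimensions")
  if (length(metric$values) != nrow(nm))
    stop("metric length does not match node map")
  if (any(nm$i > dim3[1] | nm$j > dim3[2] | nm$k > dim3[3]))
    stop("node map indices fall outside the grid")
  vol <- array(missing, dim = dim3)
  vol[cbind(nm$i, nm$j, nm$k)] <- metric$values
  vol
}

#' Extract nodal values from a volume via a node map
#'
#' Inverse of [metric_to_volume()] on the gray-matter mask.
#'
#' @param vol 3D array.
#' @param node_map node map data frame (with grid attributes).
#' @param metric metric name to record.
#' @return a `metric_volume`.
#' @export
volume_to_metric <- function(vol, node_map, metric = "value") {
  .new_metric_volume(metric, vol[cbind(node_map$i, node_map$j, node_map$k)],
                     node_map)
}

#' Write a metric volume as NIfTI
#'
#' @param metric a `metric_volume` with a grid-aware node map.
#' @param path output `.nii` / `.nii.gz` path.
#' @param missing fill value outside the node map.
#' @return the path, invisibly.
#' @export
write_metric_volume <- function(metric, path, missing = 0) {
  nm <- metric$node_map
  vol <- metric_to_volume(metric, missing = missing)
  img <- .as_nifti(vol, attr(nm, "affine"), attr(nm, "voxel_size_mm"))
  writeNifti(img, path)
  invisible(path)
}
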