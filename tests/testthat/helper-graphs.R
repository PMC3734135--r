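# Small-graph fixtures and naive dense oracles, independent of the
# package's CSR/BFS implementation.

# binary_network from an explicit edge list (rows i, j with i < j)
net_from_edges <- function(edges, n) {
  edges <- matrix(as.integer(edges), ncol = 2)
  voxnet:::.new_network(edges, n, r_threshold = NA_real_, S = NA_real_,
                        node_map = NULL)
}

# Erdos-Renyi random network
rand_net <- function(n, p, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  net_from_edges(pairs[keep, , drop = FALSE], n)
}

oracle_adj <- function(net) {
  a <- matrix(0L, net$n_nodes, net$n_nodes)
  if (net$n_edges > 0) {
    a[net$edges] <- 1L
    a[net$edges[, 2:1, drop = FALSE]] <- 1L
  }
  a
}

# All-pairs shortest paths by Floyd-Warshall on the dense adjacency
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1L] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

oracle_eglob_nodal <- function(a) {
  n <- nrow(a)
  if (n < 2) return(rep(0, n))
  d <- oracle_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

oracle_eloc_nodal <- function(a) {
  n <- nrow(a)
  sapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1L)
    if (length(nb) < 2) return(0)
    mean(oracle_eglob_nodal(a[nb, nb, drop = FALSE]))
  })
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  sapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    sum(a[nb, nb]) / (k * (k - 1))
  })
}

# tiny named graphs
complete_net <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  net_from_edges(pairs, n)
}
star_net <- function(n) net_from_edges(cbind(1L, 2:n), n)
path3_net <- function() net_from_edges(rbind(c(1, 2), c(2, 3)), 3)

# voxel_matrix from a plain time x node matrix (for filter/regression
# contracts that need no grid)
make_vm <- function(values, tr = 2) {
  structure(list(values = values,
                 node_map = data.frame(node = seq_len(ncol(values))),
                 tr_seconds = tr, filter = NULL),
            class = "voxel_matrix")
}

# small, fast study configuration for pipeline-level tests
small_config <- function(seed = 1, n_subjects = 2,
                         n_sessions_per_condition = 2, n_volumes = 60) {
  simulation_config(n_subjects = n_subjects,
                    n_sessions_per_condition = n_sessions_per_condition,
                    n_volumes = n_volumes, grid_shape = c(10L, 10L, 8L),
                    seed = seed)
}

# random balanced subject x condition x session table
rand_anova_table <- function(n_subj = 5, n_sess = 5, effect = 0, seed = 1) {
  set.seed(seed)
  g <- expand.grid(subject = paste0("s", seq_len(n_subj)),
                   condition = c("rest", "task"),
                   session = seq_len(n_sess))
  g$value <- rnorm(nrow(g)) + effect * (g$condition == "task")
  g
}
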