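test_that("closed-form graphs give exact metric values", {
  k4 <- complete_net(4)
  expect_equal(unname(global_efficiency(k4)$summary["mean"]), 1.0)
  expect_equal(unname(local_efficiency(k4)$summary["mean"]), 1.0)
  expect_equal(local_efficiency(k4)$values, rep(1, 4))

  p3 <- path3_net()
  expect_equal(unname(global_efficiency(p3)$summary["mean"]), 5 / 6)

  two_edges <- net_from_edges(rbind(c(1, 2), c(3, 4)), 4)
  expect_equal(unname(global_efficiency(two_edges)$summary["mean"]), 1 / 3)

  s5 <- star_net(5)
  expect_equal(degree(s5)$values, c(4, 1, 1, 1, 1))
  expect_equal(local_efficiency(s5)$values, rep(0, 5))
  dd <- degree_distribution(s5)
  expect_equal(dd$p[dd$degree == 4], 0.2)
  expect_equal(dd$p[dd$degree == 1], 0.8)

  cyc4 <- net_from_edges(rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)), 4)
  ddc <- degree_distribution(cyc4)
  expect_equal(ddc, data.frame(degree = 2L, p = 1))

  tri <- complete_net(3)
  cl <- clustering_and_pathlength(tri)
  expect_equal(cl$C$values, rep(1, 3))
  expect_equal(cl$L$values, rep(1, 3))
  expect_equal(clustering_and_pathlength(s5)$C$values[1], 0)

  empty <- net_from_edges(matrix(integer(0), ncol = 2), 5)
  expect_equal(degree(empty)$values, rep(0, 5))
  expect_equal(global_efficiency(empty)$values, rep(0, 5))
})

test_that("metrics equal naive dense oracles on random graphs", {
  n_graphs <- 100
  set.seed(123)
  specs <- data.frame(n = sample(5:60, n_graphs, replace = TRUE),
                      p = runif(n_graphs, 0.02, 0.6),
                      seed = sample.int(1e6, n_graphs))
  for (g in seq_len(n_graphs)) {
    net <- rand_net(specs$n[g], specs$p[g], specs$seed[g])
    a <- oracle_adj(net)
    expect_identical(degree(net)$values, as.numeric(rowSums(a)))
    dd <- degree_distribution(net)
    expect_equal(sum(dd$p), 1)
    expect_equal(dd$p, as.numeric(table(rowSums(a))) / net$n_nodes)
    eg <- global_efficiency(net)
    expect_equal(eg$values, oracle_eglob_nodal(a), tolerance = 1e-12)
    expect_equal(unname(eg$summary["mean"]), mean(oracle_eglob_nodal(a)),
                 tolerance = 1e-12)
    el <- local_efficiency(net)
    expect_equal(el$values, oracle_eloc_nodal(a), tolerance = 1e-12)
    cl <- clustering_and_pathlength(net)
    expect_equal(cl$C$values, oracle_clustering(a), tolerance = 1e-12)
    expect_true(all(eg$values >= 0 & eg$values <= 1))
    expect_true(all(el$values >= 0 & el$values <= 1))
    expect_true(all(cl$C$values >= 0 & cl$C$values <= 1))
  }
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    net <- rand_net(40, 0.15, seed + 500)
    g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
    g <- igraph::add_vertices(g, net$n_nodes - igraph::vcount(g))
    expect_equal(unname(global_efficiency(net)$summary["mean"]),
                 igraph::global_efficiency(g), tolerance = 1e-12)
    # igraph's local_efficiency() routes paths through the full graph
    # minus the vertex; the neighborhood-subgraph convention used here
    # is reproduced with igraph via explicit induced subgraphs
    ig_eloc <- sapply(seq_len(net$n_nodes), function(v) {
      nb <- as.integer(igraph::neighbors(g, v))
      if (length(nb) < 2) return(0)
      igraph::global_efficiency(igraph::induced_subgraph(g, nb))
    })
    ig_eloc[is.nan(ig_eloc)] <- 0
    expect_equal(local_efficiency(net)$values, ig_eloc, tolerance = 1e-12)
  }
})

test_that("nodal metrics are equivariant under node relabeling", {
  set.seed(9)
  net <- rand_net(30, 0.2, 77)
  perm <- sample(30)
  e2 <- cbind(perm[net$edges[, 1]], perm[net$edges[, 2]])
  e2 <- t(apply(e2, 1, sort))
  net2 <- net_from_edges(e2, 30)
  for (f in list(degree, global_efficiency, local_efficiency)) {
    v1 <- f(net)$values
    v2 <- f(net2)$values
    expect_equal(v2[perm], v1, tolerance = 1e-12)
  }
})

test_that("metric volumes map nodal values onto the grid and back", {
  st <- generate_study(small_config(seed = 4, n_subjects = 1,
                                    n_sessions_per_condition = 1, n_volumes = 30))
  s <- st$sessions[[1]]
  vm <- extract_gray_timeseries(s$bold, s$masks)
  nm <- vm$node_map
  set.seed(10)
  mv <- voxnet:::.new_metric_volume("K", rpois(nrow(nm), 5), nm)
  vol <- metric_to_volume(mv)
  expect_equal(vol[cbind(nm$i, nm$j, nm$k)], mv$values)
  expect_true(all(is.na(vol[!s$masks$gray])))
  back <- volume_to_metric(vol, nm, "K")
  expect_equal(back$values, mv$values)
  # single-node map
  one <- voxnet:::.new_metric_volume("K", 3, nm[7, ])
  v1 <- metric_to_volume(one)
  expect_equal(sum(!is.na(v1)), 1L)
  expect_equal(v1[nm$i[7], nm$j[7], nm$k[7]], 3)
})
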