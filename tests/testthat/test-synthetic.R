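test_that("generators are pure functions of their seed", {
  expect_identical(make_bridge_clusters(seed = 7), make_bridge_clusters(seed = 7))
  expect_false(identical(make_bridge_clusters(seed = 7)$embedding$coords,
                         make_bridge_clusters(seed = 8)$embedding$coords))
  expect_identical(make_ring(seed = 3), make_ring(seed = 3))
  expect_identical(make_modular_network(seed = 2), make_modular_network(seed = 2))
  net <- make_modular_network(seed = 2)
  expect_identical(make_pluripotency_profiles(net, seed = 4),
                   make_pluripotency_profiles(net, seed = 4))
  expect_identical(make_topo_signal_classes(n_cells = 20L, seed = 5),
                   make_topo_signal_classes(n_cells = 20L, seed = 5))
  expect_identical(make_count_blob(seed = 6), make_count_blob(seed = 6))
  # generators restore the caller's RNG state
  withr::with_seed(1, {
    before <- stats::runif(1)
  })
  withr::with_seed(1, {
    invisible(make_ring(seed = 99))
    after <- stats::runif(1)
  })
  expect_identical(before, after)
})

test_that("bridge clusters plant separable cores and a connecting bridge", {
  fx <- make_bridge_clusters(seed = 0)
  expect_equal(length(fx$labels), 300L)
  expect_equal(sum(fx$is_bridge), 60L)
  # without bridge cells the kNN graph splits into the cluster components
  fx0 <- make_bridge_clusters(n_bridge = 0L, seed = 0)
  g0 <- knn_graph(fx0$embedding, k = 5)
  comp <- igraph::components(sctopo:::as_igraph(g0))$no
  expect_gte(comp, 2L)
  # with separation near zero the bridge/core curvature contrast vanishes
  fxflat <- make_bridge_clusters(n_core = 60L, n_bridge = 30L,
                                 separation = 0.2, dim = 5L, seed = 0)
  gflat <- knn_graph(fxflat$embedding, k = 10)
  res <- orc_all(gflat)
  br <- fxflat$is_bridge
  pooled_sd <- stats::sd(res$node_curvature)
  eff <- abs(mean(res$node_curvature[br]) - mean(res$node_curvature[!br])) /
    pooled_sd
  expect_lt(eff, 0.2)
})

test_that("ring fixture plants one dominant H1 loop", {
  pts <- make_ring(n = 60, seed = 0)
  D <- as.matrix(stats::dist(pts))
  dg <- sctopo:::vr_diagram(D, 1, max(D))
  h1 <- dg[dg$dim == 1, ]
  pers <- sort(pmin(h1$death, max(D)) - h1$birth, decreasing = TRUE)
  expect_gt(pers[1], 3 * max(pers[-1], 0))
  # zero noise: birth at the polygon chord, death near sqrt(3) * radius
  p0 <- make_ring(n = 60, noise_sd = 0, seed = 0)
  D0 <- as.matrix(stats::dist(p0))
  h10 <- { d <- sctopo:::vr_diagram(D0, 1, max(D0)); d[d$dim == 1, ] }
  expect_equal(h10$birth, 2 * sin(pi / 60), tolerance = 1e-10)
  expect_equal(h10$death, sqrt(3), tolerance = 1e-6)
})

test_that("modular network is connected with denser modules than cross-links", {
  net <- make_modular_network(seed = 0)
  ig <- igraph::graph_from_edgelist(as.matrix(net$edges), directed = FALSE)
  ig <- igraph::add_vertices(ig, length(net$gene_ids) - igraph::vcount(ig))
  expect_gte(max(igraph::components(ig)$csize) / length(net$gene_ids), 0.95)
  same <- net$modules[net$edges$a] == net$modules[net$edges$b]
  n_same_pairs <- sum(choose(table(net$modules), 2))
  n_cross_pairs <- choose(length(net$gene_ids), 2) - n_same_pairs
  expect_gt(sum(same) / n_same_pairs, sum(!same) / n_cross_pairs)
  expect_error(make_modular_network(p_in = 0.1, p_out = 0.2), "exceed")
})

test_that("pluripotency profiles activate modules as described", {
  net <- make_modular_network(seed = 0)
  # zero noise: a localized cell's active genes are exactly its module
  fx0 <- make_pluripotency_profiles(net, n_cells = 8L, noise = 0, seed = 0)
  v <- as.matrix(fx0$expr$values)
  loc <- which(fx0$state == "localized")
  for (i in loc[1:4]) {
    expect_equal(unname(which(v[i, ] > 0)),
                 which(net$modules == fx0$localized_module[i]))
  }
  # broad cells dominate localized ones in H0 Betti curves at mid-filtration
  fx <- make_pluripotency_profiles(net, n_cells = 15L, seed = 0)
  vv <- as.matrix(fx$expr$values)
  curves <- lapply(seq_len(nrow(vv)), function(i) {
    nw <- gene_network(net$gene_ids, net$edges, node_weight = vv[i, ])
    filt <- vertex_clique_filtration(nw)
    dgm <- persistence(filt)
    betti_curve(cap_diagram(dgm), 0,
                betti_grid(attr(filt, "delta_max"), 50))$counts
  })
  bro <- fx$state == "broad"
  mean_b <- colMeans(do.call(rbind, curves[bro]))
  mean_l <- colMeans(do.call(rbind, curves[!bro]))
  mid <- 5:45
  expect_gte(mean(mean_b[mid] <= mean_l[mid]), 0.8)
})

test_that("topo-signal classes match marginally but differ in CSN topology", {
  fx <- make_topo_signal_classes(n_cells = 100L, seed = 0)
  v <- as.matrix(fx$expr$values)
  cls <- fx$class
  pv <- vapply(seq_len(ncol(v)), function(j)
    stats::t.test(v[cls == "ring", j], v[cls == "pairs", j])$p.value,
    numeric(1))
  expect_gte(mean(stats::p.adjust(pv, "BH") > 0.01), 0.95)
  topo <- csn_features_table(fx$expr, n_perm = 200, seed = 0, n_grid = 0)
  expect_lt(stats::wilcox.test(topo$h1_total[cls == "ring"],
                               topo$h1_total[cls == "pairs"],
                               alternative = "greater")$p.value, 0.01)
})

test_that("count blob is integral, seeded, and normalizes cleanly", {
  x <- make_count_blob(seed = 0)
  expect_true(all(as.matrix(x$values) == round(as.matrix(x$values))))
  expect_equal(x$layer, "raw")
  y <- normalize_log1p(x)
  expect_equal(y$layer, "lognorm")
  tot <- rowSums(expm1(as.matrix(y$values)))
  nonzero <- rowSums(as.matrix(x$values)) > 0
  expect_equal(unname(tot[nonzero]), rep(1e4, sum(nonzero)), tolerance = 1e-6)
})
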