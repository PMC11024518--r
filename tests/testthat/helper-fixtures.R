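# Shared fixture builders (all generated in code; no stored data).

# random connected undirected graph as an sctopo_cell_graph
random_connected_graph <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- stats::runif(nrow(ut)) < p
      if (sum(keep) < n - 1) next
      edges <- data.frame(i = ut[keep, 1], j = ut[keep, 2])
      g <- cell_graph(n, edges)
      ig <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
      ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
      if (igraph::components(ig)$no == 1) return(g)
    }
  })
}

# random monotone filtration: VR of random points, sometimes truncated,
# sometimes an edge- or node-weighted clique filtration
random_filtration <- function(seed, n_max = 12) {
  withr::with_seed(seed, {
    kind <- sample(c("vr", "edge", "vertex"), 1)
    n <- sample(4:n_max, 1)
    if (kind == "vr") {
      pts <- matrix(stats::rnorm(2 * n), n, 2)
      D <- as.matrix(stats::dist(pts))
      ms <- if (stats::runif(1) < 0.5) Inf else
        stats::quantile(D[upper.tri(D)], stats::runif(1, 0.3, 0.9))
      vr_filtration(D, max_dim = 1, max_scale = ms)
    } else {
      ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- stats::runif(nrow(ut)) < 0.5
      edges <- data.frame(a = ut[keep, 1], b = ut[keep, 2])
      if (kind == "edge") {
        net <- gene_network(paste0("g", 1:n), edges,
                            edge_weight = stats::runif(sum(keep), 0, 3))
        edge_weighted_vr_filtration(net, max_dim = 1)
      } else {
        net <- gene_network(paste0("g", 1:n), edges,
                            node_weight = stats::runif(n, 0, 3))
        vertex_clique_filtration(net, max_dim = 1)
      }
    }
  })
}

diagrams_equal <- function(a, b, tol = 0) {
  a <- as.data.frame(a)[order(a$dim, a$birth, a$death), ]
  b <- as.data.frame(b)[order(b$dim, b$birth, b$death), ]
  rownames(a) <- rownames(b) <- NULL
  if (nrow(a) != nrow(b)) return(FALSE)
  if (!nrow(a)) return(TRUE)
  fin_ok <- all(is.infinite(a$death) == is.infinite(b$death))
  av <- unlist(a[, c("dim", "birth")]); bv <- unlist(b[, c("dim", "birth")])
  dv <- a$death[is.finite(a$death)]; ev <- b$death[is.finite(b$death)]
  fin_ok && all(abs(av - bv) <= tol) && all(abs(dv - ev) <= tol)
}

unit_square_dist <- function() {
  as.matrix(stats::dist(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
}

small_raw_expr <- function(vals, ...) {
  expression_matrix(vals,
                    cell_ids = paste0("c", seq_len(nrow(vals))),
                    gene_ids = paste0("g", seq_len(ncol(vals))),
                    layer = "raw")
}
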