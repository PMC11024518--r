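#' Neighborhood measure of a node
#'
#' Probability measure describing a node's local neighborhood: mass `alpha`
#' on the node itself and `(1 - alpha) / |N(v)|` on each of its neighbors.
#'
#' @param g an `sctopo_cell_graph`.
#' @param v node index (1-based).
#' @param alpha mass retained on the center node, in `[0, 1]` (default 0.5).
#' @return list with `support` (node indices) and `mass` (summing to 1).
#' @export
node_measure <- function(g, v, alpha = 0.5) {
  stopifnot(inherits(g, "sctopo_cell_graph"))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  nb <- c(g$edges$j[g$edges$i == v], g$edges$i[g$edges$j == v])
  if (!length(nb)) stop("node ", v, " is isolated; curvature is undefined")
  nb <- sort(nb)
  list(support = c(v, nb),
       mass = c(alpha, rep((1 - alpha) / length(nb), length(nb))),
       alpha = alpha)
}

orc_edge_impl <- function(g, i, j, alpha, distmat, solver = "ssp") {
  mi <- node_measure(g, i, alpha)
  mj <- node_measure(g, j, alpha)
  S <- sort(union(mi$support, mj$support))
  a <- b <- numeric(length(S))
  a[match(mi$support, S)] <- mi$mass
  b[match(mj$support, S)] <- mj$mass
  C <- distmat[S, S, drop = FALSE]
  if (any(!is.finite(C[a > 0, b > 0, drop = FALSE])))
    stop("measure supports lie in different components")
  d_edge <- distmat[i, j]
  dW <- if (solver == "lp") transport_lp_oracle(a, b, C) else
    transport_exact(a, b, C)$cost
  1 - dW / d_edge
}

ground_distances <- function(g, ground) {
  ig <- as_igraph(g, weighted = (ground == "length"))
  igraph::distances(ig, weights = if (ground == "hop") NA else NULL)
}

#' Ollivier-Ricci curvature of one edge
#'
#' `kappa = 1 - W1(m_i, m_j) / d(i, j)` where `W1` is the exact Wasserstein
#' distance between the endpoint neighborhood measures with shortest-path
#' ground cost, and `d` the shortest-path distance between the endpoints.
#'
#' @param g an `sctopo_cell_graph`.
#' @param e length-2 vector of node indices; must be an edge of `g`.
#' @param alpha center mass (default 0.5).
#' @param ground `"hop"` for unit edge costs (default) or `"length"` for
#'   edge-length-weighted shortest paths.
#' @param solver `"ssp"` (exact successive-shortest-path solver, default) or
#'   `"lp"` (dense LP oracle; for cross-checking).
#' @return the edge curvature, always `<= 1`.
#' @export
orc_edge <- function(g, e, alpha = 0.5, ground = c("hop", "length"),
                     solver = c("ssp", "lp")) {
  ground <- match.arg(ground); solver <- match.arg(solver)
  i <- min(e); j <- max(e)
  if (!any(g$edges$i == i & g$edges$j == j))
    stop("(", i, ", ", j, ") is not an edge of the graph")
  distmat <- ground_distances(g, ground)
  orc_edge_impl(g, i, j, alpha, distmat, solver)
}

#' Ollivier-Ricci curvature of all edges and nodes
#'
#' Edge curvatures by [orc_edge()] for every edge; node curvature is the sum
#' of the curvatures of incident edges (mean available via `aggregate`).
#'
#' @inheritParams orc_edge
#' @param aggregate `"sum"` (default) or `"mean"` over incident edges.
#' @return list with `edge_curvature` (data frame `i`, `j`, `kappa`),
#'   `node_curvature` (numeric per node, `NA` for isolated nodes), `alpha`.
#' @export
orc_all <- function(g, alpha = 0.5, ground = c("hop", "length"),
                    aggregate = c("sum", "mean"), solver = c("ssp", "lp")) {
  ground <- match.arg(ground); aggregate <- match.arg(aggregate)
  solver <- match.arg(solver)
  stopifnot(inherits(g, "sctopo_cell_graph"))
  distmat <- ground_distances(g, ground)
  ne <- nrow(g$edges)
  kappa <- numeric(ne)
  for (r in seq_len(ne))
    kappa[r] <- orc_edge_impl(g, g$edges$i[r], g$edges$j[r], alpha, distmat,
                              solver)
  node_sum <- rep(0, g$n_nodes); deg <- rep(0L, g$n_nodes)
  for (r in seq_len(ne)) {
    node_sum[g$edges$i[r]] <- node_sum[g$edges$i[r]] + kappa[r]
    node_sum[g$edges$j[r]] <- node_sum[g$edges$j[r]] + kappa[r]
    deg[g$edges$i[r]] <- deg[g$edges$i[r]] + 1L
    deg[g$edges$j[r]] <- deg[g$edges$j[r]] + 1L
  }
  node <- if (aggregate == "mean") node_sum / deg else node_sum
  node[deg == 0L] <- NA_real_
  list(edge_curvature = data.frame(i = g$edges$i, j = g$edges$j,
                                   kappa = kappa),
       node_curvature = stats::setNames(node, g$cell_ids),
       alpha = alpha)
}
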