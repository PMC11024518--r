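#' Construct a weighted gene network
#'
#' @param gene_ids character vector of gene identifiers.
#' @param edges data frame with columns `a`, `b`: 1-based gene indices (or
#'   gene ids, which are matched against `gene_ids`).
#' @param edge_weight numeric per-edge weights (edge-weighted kind).
#' @param node_weight numeric per-gene weights (node-weighted kind).
#' @return an `sctopo_gene_network` with `kind` set from which weight type
#'   was supplied (exactly one must be).
#' @export
gene_network <- function(gene_ids, edges, edge_weight = NULL,
                         node_weight = NULL) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (is.null(edges)) edges <- data.frame(a = integer(0), b = integer(0))
  if (is.character(edges$a)) edges$a <- match(edges$a, gene_ids)
  if (is.character(edges$b)) edges$b <- match(edges$b, gene_ids)
  if (anyNA(edges$a) || anyNA(edges$b)) stop("edge gene not in gene_ids")
  a <- pmin(edges$a, edges$b); b <- pmax(edges$a, edges$b)
  if (any(a == b)) stop("self-loops are not allowed")
  edges <- data.frame(a = as.integer(a), b = as.integer(b))
  if (is.null(edge_weight) == is.null(node_weight))
    stop("exactly one of edge_weight / node_weight must be supplied")
  kind <- if (!is.null(edge_weight)) "edge_weighted" else "node_weighted"
  if (kind == "edge_weighted") {
    if (length(edge_weight) != nrow(edges))
      stop("one edge weight per edge required")
    if (any(edge_weight < 0)) stop("weights must be non-negative")
  } else {
    if (length(node_weight) != length(gene_ids))
      stop("one node weight per gene required")
    if (any(node_weight < 0)) stop("weights must be non-negative")
  }
  structure(list(gene_ids = gene_ids, edges = edges,
                 edge_weight = edge_weight, node_weight = node_weight,
                 kind = kind),
            class = "sctopo_gene_network")
}

#' @export
print.sctopo_gene_network <- function(x, ...) {
  cat(sprintf("GeneNetwork (%s): %d genes, %d edges\n", x$kind,
              length(x$gene_ids), nrow(x$edges)))
  invisible(x)
}

# Symmetric rank-window interval: the n_box cells whose expression *rank*
# is closest to cell k's (rank ties and window ties broken by cell index).
# Rank-locality makes the statistic invariant under strictly monotone
# transforms of the expression values.
csn_interval <- function(xv, k, n_box) {
  n <- length(xv)
  ord <- order(xv, seq_len(n))
  rk <- integer(n); rk[ord] <- seq_len(n)
  sel <- order(abs(rk - rk[k]), seq_len(n))[seq_len(n_box)]
  range(xv[sel])
}

#' Cell-specific network association statistic
#'
#' Local association between two genes around one cell:
#' `rho = n_xy/n - (n_x/n)(n_y/n)` where `n_x = n_y = round(box_fraction*n)`
#' cells define an expression interval per gene around the cell's own value,
#' and `n_xy` counts cells falling inside both intervals.
#'
#' @param x a lognorm-layer [expression_matrix()] (any layer is accepted;
#'   the statistic is rank-local).
#' @param cell cell index.
#' @param gene_x,gene_y gene ids or column indices.
#' @param box_fraction fraction of cells defining each interval (default
#'   0.1).
#' @return the statistic `rho`; 0 with a warning for a constant gene.
#' @export
csn_statistic <- function(x, cell, gene_x, gene_y, box_fraction = 0.1) {
  stopifnot(inherits(x, "sctopo_expr"))
  if (box_fraction <= 0 || box_fraction >= 1)
    stop("box_fraction must be in (0, 1)")
  v <- as.matrix(x$values)
  n <- nrow(v)
  if (n < 3L) stop("need at least 3 cells")
  xv <- v[, gene_x]; yv <- v[, gene_y]
  if (stats::var(xv) == 0 || stats::var(yv) == 0) {
    warning("constant gene; interval degenerate, rho set to 0")
    return(0)
  }
  n_box <- max(1L, round(box_fraction * n))
  Ix <- csn_interval(xv, cell, n_box)
  Iy <- csn_interval(yv, cell, n_box)
  n_xy <- sum(xv >= Ix[1] & xv <= Ix[2] & yv >= Iy[1] & yv <= Iy[2])
  n_xy / n - (n_box / n)^2
}

# Interval membership around every anchor cell for one gene:
# M[c, i] = TRUE iff cell i's value falls in the interval of the n_box
# values closest to cell c's value.
csn_membership_all <- function(col, n_box) {
  n <- length(col)
  M <- matrix(FALSE, n, n)
  for (c in seq_len(n)) {
    I <- csn_interval(col, c, n_box)
    M[c, ] <- col >= I[1] & col <= I[2]
  }
  M
}

#' Build the cell-specific gene network of one cell
#'
#' Evaluates the association statistic for every gene pair at the given
#' cell and keeps edges whose statistic exceeds the `1 - sig_level` quantile
#' of a permutation null obtained by shuffling one gene's values across
#' cells (seeded; the interval is recomputed around the cell's permuted
#' value each time). Retained edges are weighted by the statistic.
#'
#' @inheritParams csn_statistic
#' @param sig_level edge retention level (default 0.01).
#' @param n_perm permutations for the null (default 1000); must be at least
#'   `1 / sig_level` to resolve the quantile.
#' @param seed RNG seed for the permutations.
#' @return an edge-weighted `sctopo_gene_network`.
#' @export
build_csn <- function(x, cell, box_fraction = 0.1, sig_level = 0.01,
                      n_perm = 1000L, seed = 0L) {
  stopifnot(inherits(x, "sctopo_expr"))
  if (n_perm < 1 / sig_level)
    stop("n_perm must be at least 1/sig_level to resolve the null quantile")
  v <- as.matrix(x$values)
  n <- nrow(v)
  n_box <- max(1L, round(box_fraction * n))
  Ms <- lapply(seq_len(ncol(v)), function(gidx)
    csn_membership_all(v[, gidx], n_box))
  csn_from_membership(x$gene_ids, Ms, cell, n, n_box, sig_level, n_perm,
                      seed)
}

# Shared worker: per-cell CSN given precomputed membership matrices.
# Shuffling gene y's values by a permutation pi makes the membership of
# cell i equal M_y[pi(cell), pi(i)], so one permutation serves all x genes
# via a single cross product.
csn_from_membership <- function(gene_ids, Ms, cell, n, n_box, sig_level,
                                n_perm, seed) {
  g <- length(Ms)
  if (g < 2L)
    return(gene_network(gene_ids, NULL, edge_weight = numeric(0)))
  inmat <- matrix(0, n, g)
  for (y in seq_len(g)) inmat[, y] <- Ms[[y]][cell, ]
  rho <- crossprod(inmat) / n - (n_box / n)^2
  # one permutation of cell identities per draw serves every shuffled gene
  null_counts <- matrix(0, g * g, n_perm)  # [x * shuffled y, perm]
  withr::with_seed(seed, {
    Yp <- matrix(0, n, g)
    for (p in seq_len(n_perm)) {
      pi <- sample.int(n)
      for (y in seq_len(g)) Yp[, y] <- Ms[[y]][pi[cell], pi]
      null_counts[, p] <- crossprod(inmat, Yp)
    }
  })
  # per-pair upper quantile of the permutation null (type-7, partial sort)
  h <- (n_perm - 1) * (1 - sig_level) + 1
  lo <- floor(h); hi <- min(lo + 1L, n_perm)
  qs <- apply(null_counts, 1L, function(x) {
    s <- sort.int(x, partial = c(lo, hi))
    s[lo] + (h - lo) * (s[hi] - s[lo])
  })
  thresh <- matrix(qs / n - (n_box / n)^2, g, g)
  keep <- which(upper.tri(rho) & rho > pmin(thresh, t(thresh)),
                arr.ind = TRUE)
  gene_network(gene_ids,
               data.frame(a = keep[, 1L], b = keep[, 2L]),
               edge_weight = rho[cbind(keep[, 1L], keep[, 2L])])
}

#' Per-cell CSN topology feature table
#'
#' Builds the cell-specific gene network of every cell (sharing the
#' expensive interval precomputation across cells) and summarizes each
#' network's persistence via [gene_network_features()]. Betti curves are
#' evaluated on one grid shared across the dataset (spanning `[0, delta]`
#' with `delta` the largest edge weight over all cells), so curves are
#' comparable and averageable between cells.
#'
#' @inheritParams build_csn
#' @param max_dim maximal homology dimension (default 1).
#' @param n_grid number of shared Betti-curve grid values (default 100;
#'   `0` disables curve features).
#' @return data frame: `cell_id` plus the feature columns.
#' @export
csn_features_table <- function(x, box_fraction = 0.1, sig_level = 0.01,
                               n_perm = 1000L, seed = 0L, max_dim = 1L,
                               n_grid = 100L) {
  stopifnot(inherits(x, "sctopo_expr"))
  v <- as.matrix(x$values)
  n <- nrow(v)
  n_box <- max(1L, round(box_fraction * n))
  Ms <- lapply(seq_len(ncol(v)), function(gidx)
    csn_membership_all(v[, gidx], n_box))
  nets <- lapply(seq_len(n), function(k)
    csn_from_membership(x$gene_ids, Ms, k, n, n_box, sig_level,
                        n_perm, seed + k))
  grid <- NULL
  if (n_grid > 0L) {
    wmax <- max(c(0, unlist(lapply(nets, `[[`, "edge_weight"))))
    grid <- betti_grid(wmax, n_grid)
  }
  rows <- lapply(nets, gene_network_features, max_dim = max_dim,
                 grid = grid)
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(cell_id = x$cell_ids, out, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Assign per-cell node weights to a prior gene network
#'
#' Intersects a prior network with the genes of an expression matrix and
#' sets each gene's node weight to its log-normalized expression in the
#' given cell; network genes absent from the matrix get weight 0.
#'
#' @param net an `sctopo_gene_network` (weights ignored) or a data frame
#'   edge list with two gene-id columns.
#' @param x a lognorm-layer [expression_matrix()].
#' @param cell cell index.
#' @return a node-weighted `sctopo_gene_network` over the prior network's
#'   genes.
#' @export
attach_node_weights <- function(net, x, cell) {
  stopifnot(inherits(x, "sctopo_expr"))
  if (x$layer != "lognorm")
    stop("attach_node_weights expects a lognorm-layer matrix")
  if (is.data.frame(net)) {
    gid <- sort(unique(c(net[[1L]], net[[2L]])))
    net <- gene_network(gid, data.frame(a = net[[1L]], b = net[[2L]]),
                        node_weight = rep(0, length(gid)))
  }
  common <- intersect(net$gene_ids, x$gene_ids)
  if (!length(common))
    stop("prior network and expression matrix share no genes")
  w <- rep(0, length(net$gene_ids))
  idx <- match(common, net$gene_ids)
  w[idx] <- as.matrix(x$values)[cell, common]
  gene_network(net$gene_ids, net$edges, node_weight = w)
}

#' Topological features of a gene network
#'
#' Routes the network to the filtration matching its kind (edge-weighted
#' Vietoris-Rips or vertex-based clique complex), computes persistence, and
#' summarizes H0/H1 total persistence and entropy, optionally with Betti
#' curves on a shared grid.
#'
#' @param net an `sctopo_gene_network`.
#' @param max_dim maximal homology dimension (default 1).
#' @param grid optional Betti grid (see [betti_grid()]).
#' @return named numeric feature vector (see [diagram_features()]); all
#'   zeros for an empty network.
#' @export
gene_network_features <- function(net, max_dim = 1L, grid = NULL) {
  stopifnot(inherits(net, "sctopo_gene_network"))
  if (!length(net$gene_ids)) {
    empty <- new_diagram(integer(0), numeric(0), numeric(0), delta_max = 0)
    return(suppressWarnings(diagram_features(empty, max_dim = max_dim,
                                             grid = grid)))
  }
  filt <- if (net$kind == "edge_weighted")
    edge_weighted_vr_filtration(net, max_dim) else
    vertex_clique_filtration(net, max_dim)
  dgm <- persistence(filt)
  suppressWarnings(diagram_features(dgm, max_dim = max_dim, grid = grid))
}

#' Read a prior gene network from a TSV edge list
#'
#' Two gene-symbol columns; an optional third weight column is ignored
#' (node weights come from expression).
#'
#' @param path TSV file.
#' @param header whether the file has a header row.
#' @return a data frame edge list suitable for [attach_node_weights()].
#' @export
read_network_tsv <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  d[, 1:2]
}

#' Write a gene network edge list to TSV
#'
#' @param net an `sctopo_gene_network`.
#' @param path output TSV with gene symbols and, for edge-weighted
#'   networks, the weight.
#' @export
write_network_tsv <- function(net, path) {
  out <- data.frame(gene_a = net$gene_ids[net$edges$a],
                    gene_b = net$gene_ids[net$edges$b])
  if (net$kind == "edge_weighted") out$weight <- net$edge_weight
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
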