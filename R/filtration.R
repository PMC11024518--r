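#' Build a filtration object
#'
#' A filtration is an ordered sequence of simplices with real entry values,
#' sorted by (value, dimension, vertex tuple). Simplices are integer vectors
#' of 1-based vertex indices with strictly increasing entries.
#'
#' @param simplices list of sorted integer vectors.
#' @param values numeric vector of filtration values, one per simplex.
#' @param max_dim maximal homology dimension this filtration is intended for
#'   (the complex itself contains simplices up to `max_dim + 1`).
#' @param delta_max optional scale anchor stored as an attribute; used to cap
#'   infinite deaths during featurization.
#' @param check if `TRUE`, verify filtration monotonicity (every face present
#'   with a value not exceeding the coface's value).
#' @return an object of class `sctopo_filtration`.
#' @export
new_filtration <- function(simplices, values, max_dim, delta_max = NULL,
                           check = FALSE) {
  stopifnot(length(simplices) == length(values))
  if (length(simplices)) {
    dims <- lengths(simplices) - 1L
    keys <- vapply(simplices, paste, "", collapse = ",")
    ord <- order(values, dims, keys, method = "radix")
    simplices <- simplices[ord]
    values <- values[ord]
    dims <- dims[ord]
  } else {
    dims <- integer(0)
  }
  f <- structure(
    list(simplices = simplices, values = values, dims = dims,
         max_dim = as.integer(max_dim)),
    class = "sctopo_filtration")
  if (!is.null(delta_max)) attr(f, "delta_max") <- delta_max
  if (check) validate_filtration(f)
  f
}

#' @export
print.sctopo_filtration <- function(x, ...) {
  cat(sprintf("Filtration: %d simplices, dims 0..%d, values [%g, %g]\n",
              length(x$simplices),
              if (length(x$dims)) max(x$dims) else -1L,
              if (length(x$values)) min(x$values) else NA,
              if (length(x$values)) max(x$values) else NA))
  invisible(x)
}

#' Check filtration monotonicity
#'
#' Every face of every simplex must be present with a filtration value not
#' exceeding the simplex's own value.
#'
#' @param filt an `sctopo_filtration`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_filtration <- function(filt) {
  keys <- vapply(filt$simplices, paste, "", collapse = ",")
  val_of <- stats::setNames(filt$values, keys)
  if (anyDuplicated(keys)) stop("duplicate simplices in filtration")
  for (p in seq_along(filt$simplices)) {
    s <- filt$simplices[[p]]
    if (is.unsorted(s, strictly = TRUE)) stop("simplex vertices must be strictly increasing")
    if (length(s) < 2L) next
    for (i in seq_along(s)) {
      fk <- paste(s[-i], collapse = ",")
      fv <- val_of[fk]
      if (is.na(fv)) stop("face ", fk, " of simplex ", paste(s, collapse = ","),
                          " missing from filtration")
      if (fv > filt$values[p] + 1e-12)
        stop("filtration not monotone at simplex ", paste(s, collapse = ","))
    }
  }
  invisible(TRUE)
}

# Enumerate cliques of an adjacency matrix by dimension, up to `max_dim`
# vertices - 1. Returns list: [[d+1]] = matrix with d+1 columns, one clique
# per row (vertex indices increasing). Grows (d)-cliques to (d+1)-cliques by
# appending common neighbors with larger index.
clique_list <- function(adj, top_dim) {
  n <- nrow(adj)
  out <- vector("list", top_dim + 1L)
  out[[1L]] <- matrix(seq_len(n), ncol = 1L)
  if (top_dim == 0L || n < 2L) return(out)
  ep <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(ep) == 0L) return(out)
  out[[2L]] <- unname(ep[order(ep[, 1L], ep[, 2L]), , drop = FALSE])
  d <- 2L
  while (d <= top_dim && !is.null(out[[d]]) && nrow(out[[d]])) {
    prev <- out[[d]]
    grown <- vector("list", nrow(prev))
    for (r in seq_len(nrow(prev))) {
      v <- prev[r, ]
      common <- which(colSums(adj[v, , drop = FALSE]) == length(v))
      common <- common[common > v[length(v)]]
      if (length(common))
        grown[[r]] <- cbind(matrix(v, nrow = length(common), ncol = length(v),
                                   byrow = TRUE), common)
    }
    grown <- grown[!vapply(grown, is.null, TRUE)]
    if (length(grown)) out[d + 1L] <- list(do.call(rbind, grown))
    d <- d + 1L
  }
  out
}

rows_to_list <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(list())
  lapply(seq_len(nrow(m)), function(r) as.integer(m[r, ]))
}

# max over all pairwise entries of D for each row-clique of `m`
max_pair_value <- function(m, D) {
  k <- ncol(m)
  v <- rep(-Inf, nrow(m))
  for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k))
    v <- pmax(v, D[cbind(m[, a], m[, b])])
  v
}

#' Vietoris-Rips filtration of a finite metric space
#'
#' A simplex enters at the largest pairwise distance among its vertices;
#' simplices whose entry value exceeds `max_scale` are omitted. The complex
#' is built up to dimension `max_dim + 1` so that homology in dimension
#' `max_dim` is computed correctly.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param max_dim maximal homology dimension of interest.
#' @param max_scale truncation scale (default `Inf`: full complex).
#' @return an `sctopo_filtration`.
#' @export
vr_filtration <- function(D, max_dim = 1L, max_scale = Inf) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-9))
    stop("D must be a symmetric distance matrix")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")
  if (any(D < 0)) stop("D must be non-negative")
  n <- nrow(D)
  top_dim <- max_dim + 1L
  adj <- D <= max_scale & upper.tri(D)
  adj <- adj | t(adj)
  cl <- clique_list(adj, top_dim)
  simplices <- list()
  values <- numeric(0)
  for (d in 0:top_dim) {
    m <- cl[[d + 1L]]
    if (is.null(m) || nrow(m) == 0L) next
    v <- if (d == 0L) rep(0, nrow(m)) else max_pair_value(m, D)
    keep <- v <= max_scale
    simplices <- c(simplices, rows_to_list(m[keep, , drop = FALSE]))
    values <- c(values, v[keep])
  }
  new_filtration(simplices, values, max_dim,
                 delta_max = if (is.finite(max_scale)) max_scale else
                   max(values, 0))
}

#' Edge-weighted Vietoris-Rips filtration of a gene network
#'
#' Implements a descending-threshold complex on an edge-weighted network,
#' re-expressed as an ascending filtration: with `delta_max` the maximum edge
#' weight, a simplex (a clique of the network) enters at
#' `delta_max - min(edge weights within it)`, so that heavy edges appear
#' first. Vertices enter at the entry value of their heaviest incident edge;
#' isolated vertices enter at `delta_max`.
#'
#' @param net a `gene_network` of kind `edge_weighted`.
#' @param max_dim maximal homology dimension of interest.
#' @return an `sctopo_filtration` with attribute `delta_max`.
#' @export
edge_weighted_vr_filtration <- function(net, max_dim = 1L) {
  stopifnot(inherits(net, "sctopo_gene_network"), net$kind == "edge_weighted")
  w <- net$edge_weight
  if (any(w < 0)) stop("edge weights must be non-negative")
  n <- length(net$gene_ids)
  delta_max <- if (length(w)) max(w) else 0
  adj <- matrix(FALSE, n, n)
  wmat <- matrix(Inf, n, n)
  if (nrow(net$edges)) {
    ij <- cbind(net$edges$a, net$edges$b)
    adj[ij] <- TRUE; adj[ij[, 2:1, drop = FALSE]] <- TRUE
    wmat[ij] <- w; wmat[ij[, 2:1, drop = FALSE]] <- w
  }
  top_dim <- max_dim + 1L
  cl <- clique_list(adj, top_dim)
  # vertex entry: delta_max - heaviest incident edge; isolated: delta_max
  vert_val <- rep(delta_max, n)
  if (nrow(net$edges)) {
    for (r in seq_len(nrow(net$edges))) {
      a <- net$edges$a[r]; b <- net$edges$b[r]
      vert_val[a] <- min(vert_val[a], delta_max - w[r])
      vert_val[b] <- min(vert_val[b], delta_max - w[r])
    }
  }
  simplices <- rows_to_list(cl[[1L]])
  values <- vert_val
  for (d in seq_len(top_dim)) {
    m <- cl[[d + 1L]]
    if (is.null(m) || nrow(m) == 0L) next
    # entry value: delta_max - min edge weight = max over edges of (dmax - w)
    v <- max_pair_value(m, delta_max - wmat)
    simplices <- c(simplices, rows_to_list(m))
    values <- c(values, v)
  }
  new_filtration(simplices, values, max_dim, delta_max = delta_max)
}

#' Vertex-based clique complex filtration of a node-weighted gene network
#'
#' Descending node-weight activation re-expressed as an ascending filtration:
#' with `delta_max` the maximum node weight, vertex `i` enters at
#' `delta_max - w_i`, an edge at `delta_max - min(w_i, w_j)`, and a higher
#' simplex (a clique of the network) at the maximum of its faces' values, so
#' that heavily weighted (highly expressed) genes activate first.
#'
#' @param net a `gene_network` of kind `node_weighted`.
#' @param max_dim maximal homology dimension of interest.
#' @return an `sctopo_filtration` with attribute `delta_max`.
#' @export
vertex_clique_filtration <- function(net, max_dim = 1L) {
  stopifnot(inherits(net, "sctopo_gene_network"), net$kind == "node_weighted")
  w <- net$node_weight
  if (any(w < 0)) stop("node weights must be non-negative")
  n <- length(net$gene_ids)
  if (length(w) != n) stop("node weight missing for some gene")
  delta_max <- if (n) max(w) else 0
  adj <- matrix(FALSE, n, n)
  if (nrow(net$edges)) {
    ij <- cbind(net$edges$a, net$edges$b)
    adj[ij] <- TRUE; adj[ij[, 2:1, drop = FALSE]] <- TRUE
  }
  top_dim <- max_dim + 1L
  cl <- clique_list(adj, top_dim)
  tv <- delta_max - w  # transformed vertex values
  simplices <- rows_to_list(cl[[1L]])
  values <- tv
  for (d in seq_len(top_dim)) {
    m <- cl[[d + 1L]]
    if (is.null(m) || nrow(m) == 0L) next
    v <- tv[m[, 1L]]
    for (cidx in 2:ncol(m)) v <- pmax(v, tv[m[, cidx]])
    simplices <- c(simplices, rows_to_list(m))
    values <- c(values, v)
  }
  new_filtration(simplices, values, max_dim, delta_max = delta_max)
}
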