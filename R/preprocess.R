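#' Construct an expression matrix
#'
#' @param values cells x genes matrix (dense or `Matrix` sparse) of
#'   non-negative expression values.
#' @param cell_ids,gene_ids unique identifier vectors matching the rows and
#'   columns of `values`.
#' @param layer `"raw"` for counts, `"lognorm"` for normalized log1p values.
#' @return an `sctopo_expr` object.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              layer = c("raw", "lognorm")) {
  layer <- match.arg(layer)
  if (is.null(cell_ids) || is.null(gene_ids))
    stop("cell_ids and gene_ids are required")
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("length(cell_ids) must equal nrow(values)")
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) must equal ncol(values)")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (min(values) < 0) stop("expression values must be non-negative")
  rownames(values) <- cell_ids; colnames(values) <- gene_ids
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 layer = layer),
            class = "sctopo_expr")
}

#' @export
print.sctopo_expr <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s]\n",
              length(x$cell_ids), length(x$gene_ids), x$layer))
  invisible(x)
}

#' Read a count matrix from disk
#'
#' Supports Matrix Market triplets with sibling `barcodes.tsv` / `genes.tsv`
#' (the common genes-by-cells orientation is transposed to cells-by-rows),
#' and CSV with cells as rows, a header of gene names, and cell barcodes in
#' the first column.
#'
#' @param path path to the `.mtx` or `.csv` file.
#' @param format `"mtx"` or `"csv"`; guessed from the extension by default.
#' @param barcodes,genes overrides for the sibling id files in mtx mode.
#' @return a raw-layer [expression_matrix()].
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv"),
                        barcodes = NULL, genes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  if (format == "mtx") {
    if (is.null(barcodes)) barcodes <- file.path(dirname(path), "barcodes.tsv")
    if (is.null(genes)) genes <- file.path(dirname(path), "genes.tsv")
    for (f in c(barcodes, genes))
      if (!file.exists(f)) stop("sidecar file not found: ", f)
    m <- Matrix::readMM(path)
    bc <- readLines(barcodes)
    gn_tab <- utils::read.delim(genes, header = FALSE,
                                stringsAsFactors = FALSE)
    gn <- as.character(gn_tab[[1L]])
    # genes x cells triplet convention -> transpose to cells x genes
    if (nrow(m) != length(gn) || ncol(m) != length(bc))
      stop(sprintf(paste0("dimension mismatch: matrix is %d x %d but genes ",
                          "file has %d rows and barcodes file has %d rows"),
                   nrow(m), ncol(m), length(gn), length(bc)))
    expression_matrix(as.matrix(Matrix::t(m)), bc, gn, layer = "raw")
  } else {
    d <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    expression_matrix(as.matrix(d), rownames(d), colnames(d), layer = "raw")
  }
}

#' Total-count normalization and log1p transform
#'
#' Scales each cell's counts to sum `target_sum`, then applies
#' `log(1 + x)` elementwise. Cells with zero total count are left as zeros
#' with a warning.
#'
#' @param x a raw-layer [expression_matrix()].
#' @param target_sum per-cell total after scaling (default `1e4`).
#' @return a lognorm-layer [expression_matrix()].
#' @export
normalize_log1p <- function(x, target_sum = 1e4) {
  stopifnot(inherits(x, "sctopo_expr"))
  if (x$layer != "raw") stop("normalize_log1p expects a raw-layer matrix")
  v <- as.matrix(x$values)
  tot <- rowSums(v)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total count left as all zeros")
    tot[zero] <- 1
  }
  v <- log1p(v * (target_sum / tot))
  expression_matrix(v, x$cell_ids, x$gene_ids, layer = "lognorm")
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log-normalized expression and
#' returns the top `n_top` gene ids; deterministic (ties broken by column
#' order).
#'
#' @param x a lognorm-layer [expression_matrix()].
#' @param n_top number of genes to keep.
#' @return character vector of `n_top` gene ids, most variable first.
#' @export
select_hvg <- function(x, n_top) {
  stopifnot(inherits(x, "sctopo_expr"))
  if (x$layer != "lognorm") stop("select_hvg expects a lognorm-layer matrix")
  if (n_top > length(x$gene_ids))
    stop("n_top exceeds the number of genes")
  v <- apply(as.matrix(x$values), 2L, stats::var)
  ord <- order(-v, seq_along(v))
  x$gene_ids[ord[seq_len(n_top)]]
}

#' PCA embedding of expression profiles
#'
#' Mean-centered principal component scores. Each component's sign is fixed
#' so that its largest-absolute loading is positive, making the output
#' stable across runs and platforms.
#'
#' @param x a lognorm-layer [expression_matrix()].
#' @param n_comps number of components (default 30, truncated to the rank
#'   bound `min(cells, genes)`).
#' @param gene_subset optional gene ids to restrict to (e.g. from
#'   [select_hvg()]).
#' @return an `sctopo_embedding`: list with `coords` (cells x `n_comps`
#'   score matrix, rownames = cell ids) and `cell_ids`.
#' @export
pca_embed <- function(x, n_comps = 30L, gene_subset = NULL) {
  stopifnot(inherits(x, "sctopo_expr"))
  if (x$layer != "lognorm") stop("pca_embed expects a lognorm-layer matrix")
  v <- as.matrix(x$values)
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, x$gene_ids)
    if (length(missing)) stop("unknown genes in gene_subset: ",
                              paste(missing, collapse = ", "))
    v <- v[, gene_subset, drop = FALSE]
  }
  if (n_comps > min(dim(v)))
    stop("n_comps exceeds min(cells, genes)")
  p <- stats::prcomp(v, center = TRUE, scale. = FALSE, rank. = n_comps)
  flip <- apply(p$rotation, 2L, function(w) sign(w[which.max(abs(w))]))
  flip[flip == 0] <- 1
  coords <- sweep(p$x, 2L, flip, `*`)
  structure(list(coords = coords, cell_ids = x$cell_ids,
                 n_comps = as.integer(n_comps)),
            class = "sctopo_embedding")
}

#' @export
print.sctopo_embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d cells x %d components\n",
              nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

embedding_from_coords <- function(coords, cell_ids = NULL) {
  coords <- as.matrix(coords)
  if (is.null(cell_ids))
    cell_ids <- if (!is.null(rownames(coords))) rownames(coords) else
      paste0("cell", seq_len(nrow(coords)))
  rownames(coords) <- cell_ids
  structure(list(coords = coords, cell_ids = as.character(cell_ids),
                 n_comps = ncol(coords)),
            class = "sctopo_embedding")
}

pairwise_dissimilarity <- function(coords, metric) {
  switch(metric,
    euclidean = as.matrix(stats::dist(coords)),
    cosine = {
      nrm <- sqrt(rowSums(coords^2))
      nrm[nrm == 0] <- 1
      s <- tcrossprod(coords / nrm)
      d <- 1 - pmin(pmax(s, -1), 1)
      diag(d) <- 0
      d
    },
    correlation = {
      s <- stats::cor(t(coords))
      d <- 1 - pmin(pmax(s, -1), 1)
      diag(d) <- 0
      d
    })
}

#' k-nearest-neighbor cell graph
#'
#' Connects each cell to its `k` nearest neighbors (self excluded; exact
#' distance ties broken by lower cell index) and symmetrizes by union, so
#' every node has degree at least `k`. Edge lengths store the metric
#' distance.
#'
#' @param emb an `sctopo_embedding` (or a coordinate matrix).
#' @param k neighbor count (default 15), must be `< n`.
#' @param metric `"euclidean"` (default), `"cosine"` or `"correlation"`.
#' @return an `sctopo_cell_graph`: list with `n_nodes`, `edges` (data frame
#'   `i`, `j`, `length` with `i < j`, 1-based), `k`, `metric`, `cell_ids`.
#' @export
knn_graph <- function(emb, k = 15L,
                      metric = c("euclidean", "cosine", "correlation")) {
  metric <- match.arg(metric)
  if (!inherits(emb, "sctopo_embedding")) emb <- embedding_from_coords(emb)
  n <- nrow(emb$coords)
  if (k >= n) stop("k must be smaller than the number of cells")
  if (k < 1L) stop("k must be positive")
  D <- pairwise_dissimilarity(emb$coords, metric)
  pair_i <- integer(0); pair_j <- integer(0)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(k)]
    pair_i <- c(pair_i, rep.int(i, k)); pair_j <- c(pair_j, ord)
  }
  a <- pmin(pair_i, pair_j); b <- pmax(pair_i, pair_j)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  ord <- order(a, b)
  edges <- data.frame(i = a[ord], j = b[ord],
                      length = D[cbind(a[ord], b[ord])])
  cell_graph(n, edges, k = k, metric = metric, cell_ids = emb$cell_ids)
}

#' Construct a cell graph
#'
#' @param n_nodes number of cells.
#' @param edges data frame with integer columns `i`, `j` (1-based, no
#'   self-loops) and optionally `length`.
#' @param k neighbor count used to build the graph, if any.
#' @param metric dissimilarity used for the edge lengths, if any.
#' @param cell_ids optional cell identifiers.
#' @return an `sctopo_cell_graph`.
#' @export
cell_graph <- function(n_nodes, edges, k = NA_integer_, metric = NA_character_,
                       cell_ids = NULL) {
  edges$i <- as.integer(edges$i); edges$j <- as.integer(edges$j)
  if (any(edges$i == edges$j)) stop("self-loops are not allowed")
  if (any(edges$i < 1L | edges$j < 1L | edges$i > n_nodes | edges$j > n_nodes))
    stop("edge endpoints out of range")
  sw <- edges$i > edges$j
  if (any(sw)) { tmp <- edges$i[sw]; edges$i[sw] <- edges$j[sw]; edges$j[sw] <- tmp }
  if (anyDuplicated(edges[, c("i", "j")])) stop("duplicate edges")
  if (!is.null(edges$length) && any(edges$length < 0))
    stop("edge lengths must be non-negative")
  structure(list(n_nodes = as.integer(n_nodes), edges = edges,
                 k = k, metric = metric,
                 cell_ids = if (is.null(cell_ids))
                   paste0("cell", seq_len(n_nodes)) else as.character(cell_ids)),
            class = "sctopo_cell_graph")
}

#' @export
print.sctopo_cell_graph <- function(x, ...) {
  cat(sprintf("CellGraph: %d nodes, %d edges (k = %s, metric = %s)\n",
              x$n_nodes, nrow(x$edges), x$k, x$metric))
  invisible(x)
}

as_igraph <- function(g, weighted = FALSE) {
  ig <- igraph::graph_from_edgelist(as.matrix(g$edges[, c("i", "j")]),
                                    directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, g$n_nodes - igraph::vcount(ig)))
  if (weighted) igraph::E(ig)$weight <- g$edges$length
  ig
}

#' Write / read a cell graph as a TSV edge list
#'
#' Columns `i`, `j`, `length` with 0-based node indices; node index to cell
#' id mapping written to a sidecar `<path>.nodes.tsv`.
#'
#' @param g an `sctopo_cell_graph`.
#' @param path output TSV.
#' @export
write_graph_tsv <- function(g, path) {
  out <- data.frame(i = g$edges$i - 1L, j = g$edges$j - 1L,
                    length = if (is.null(g$edges$length)) NA else
                      g$edges$length)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  nodes <- data.frame(index = seq_len(g$n_nodes) - 1L, cell_id = g$cell_ids)
  utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  e <- utils::read.delim(path)
  nodes_path <- paste0(path, ".nodes.tsv")
  cell_ids <- NULL; n <- max(e$i, e$j) + 1L
  if (file.exists(nodes_path)) {
    nd <- utils::read.delim(nodes_path)
    cell_ids <- as.character(nd$cell_id); n <- nrow(nd)
  }
  edges <- data.frame(i = e$i + 1L, j = e$j + 1L)
  if (!is.null(e$length) && !all(is.na(e$length))) edges$length <- e$length
  cell_graph(n, edges, cell_ids = cell_ids)
}

#' Write an embedding to CSV
#'
#' @param emb an `sctopo_embedding`.
#' @param path output CSV with columns `cell_id`, `pc1`..`pcN`.
#' @export
write_embedding_csv <- function(emb, path) {
  out <- data.frame(cell_id = emb$cell_ids, emb$coords)
  colnames(out) <- c("cell_id", paste0("pc", seq_len(ncol(emb$coords))))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_embedding_csv
#' @export
read_embedding_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  embedding_from_coords(as.matrix(d[, -1L, drop = FALSE]), d[[1L]])
}
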