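local_neighborhood <- function(coords, cell, k_local = NULL, radius = NULL) {
  n <- nrow(coords)
  d <- sqrt(colSums((t(coords) - coords[cell, ])^2))
  if (!is.null(radius)) {
    idx <- which(d <= radius)
  } else {
    if (is.null(k_local)) stop("supply k_local or radius")
    if (k_local >= n) k_local <- n - 1L
    ord <- order(d, seq_len(n))
    ord <- ord[ord != cell]
    idx <- c(cell, ord[seq_len(k_local)])
  }
  sort(idx)
}

#' Local persistent homology around one cell
#'
#' Vietoris-Rips persistence of the Euclidean point cloud formed by a cell
#' and its neighborhood (the top `k_local` nearest neighbors, or all cells
#' within `radius`). The filtration runs to the neighborhood diameter, so no
#' finite structure is truncated.
#'
#' @param emb an `sctopo_embedding` or coordinate matrix.
#' @param cell cell index (1-based).
#' @param k_local neighborhood size excluding the center (default 30).
#' @param radius alternative distance-cutoff neighborhood.
#' @param max_dim maximal homology dimension (default 1).
#' @param include_center keep the center cell in the point cloud (default).
#' @return an `sctopo_diagram` with `delta_max` = neighborhood diameter.
#' @export
local_ph <- function(emb, cell, k_local = 30L, radius = NULL, max_dim = 1L,
                     include_center = TRUE) {
  if (!inherits(emb, "sctopo_embedding")) emb <- embedding_from_coords(emb)
  idx <- local_neighborhood(emb$coords, cell, k_local, radius)
  if (!include_center) idx <- setdiff(idx, cell)
  if (length(idx) < 2L) {
    warning("neighborhood of cell ", cell, " has fewer than 2 points")
    return(new_diagram(integer(0), numeric(0), numeric(0), delta_max = 0))
  }
  D <- as.matrix(stats::dist(emb$coords[idx, , drop = FALSE]))
  vr_diagram(D, max_dim = max_dim, max_scale = max(D))
}

# Relative persistence via coning: H_*(K, L) is the reduced homology of
# K with a cone over L attached. The apex enters at the minimum filtration
# value; each cone simplex over sigma in L enters at sigma's value, so L is
# quotiented out as soon as it appears. One infinite H0 bar (the apex
# component) is removed to pass from homology to reduced homology.
cone_filtration <- function(filt, l_vertices, n_points) {
  apex <- n_points + 1L
  in_L <- vapply(filt$simplices, function(s) all(s %in% l_vertices), TRUE)
  base_min <- if (length(filt$values)) min(filt$values) else 0
  cone_simplices <- lapply(filt$simplices[in_L], function(s) c(s, apex))
  cone_values <- filt$values[in_L]
  new_filtration(
    c(filt$simplices, list(apex), cone_simplices),
    c(filt$values, base_min, cone_values),
    filt$max_dim, delta_max = attr(filt, "delta_max"))
}

drop_one_infinite_h0 <- function(diag) {
  inf0 <- which(diag$dim == 0L & is.infinite(diag$death))
  if (length(inf0)) {
    drop <- inf0[which.min(diag$birth[inf0])]
    diag <- new_diagram(diag$dim[-drop], diag$birth[-drop],
                        diag$death[-drop], delta_max = attr(diag, "delta_max"))
  }
  diag
}

#' Relative persistent homology with respect to a cell neighborhood
#'
#' Persistence of the global Vietoris-Rips filtration relative to the
#' subcomplex spanned by a cell and its `l_size - 1` nearest neighbors (the
#' full subcomplex on those vertices at every filtration step). Realized by
#' coning the subcomplex to a virtual apex, which is homotopy-equivalent to
#' the quotient; validated against a direct relative reduction.
#'
#' @inheritParams local_ph
#' @param l_size number of vertices spanning the subcomplex (cell included);
#'   `l_size = 0` gives ordinary (absolute) persistence.
#' @param max_scale filtration truncation; default the 90th percentile of
#'   pairwise distances, which bounds the complex size while retaining the
#'   dominant structure.
#' @return an `sctopo_diagram`.
#' @export
relative_ph <- function(emb, cell, l_size = 10L, max_dim = 1L,
                        max_scale = NULL) {
  if (!inherits(emb, "sctopo_embedding")) emb <- embedding_from_coords(emb)
  n <- nrow(emb$coords)
  if (l_size > n) stop("l_size exceeds the number of cells")
  D <- as.matrix(stats::dist(emb$coords))
  if (is.null(max_scale))
    max_scale <- stats::quantile(D[upper.tri(D)], 0.9, names = FALSE)
  filt <- vr_filtration(D, max_dim = max_dim, max_scale = max_scale)
  if (l_size == 0L) return(persistence(filt))
  l_vertices <- local_neighborhood(emb$coords, cell, k_local = l_size - 1L)
  drop_one_infinite_h0(persistence(cone_filtration(filt, l_vertices, n)))
}

# Direct oracle: reduce the boundary matrix of the quotient complex K/L
# (columns of simplices not contained in L, faces inside L dropped).
relative_ph_oracle <- function(filt, l_vertices) {
  in_L <- vapply(filt$simplices, function(s) all(s %in% l_vertices), TRUE)
  keep <- which(!in_L)
  if (!length(keep))
    return(new_diagram(integer(0), numeric(0), numeric(0),
                       delta_max = attr(filt, "delta_max")))
  sub <- list(simplices = filt$simplices[keep], values = filt$values[keep],
              dims = filt$dims[keep], max_dim = filt$max_dim)
  class(sub) <- "sctopo_filtration"
  attr(sub, "delta_max") <- attr(filt, "delta_max")
  keys <- vapply(sub$simplices, paste, "", collapse = ",")
  pos_of <- stats::setNames(seq_along(keys), keys)
  m <- length(sub$simplices)
  B <- matrix(FALSE, m, m)
  for (p in seq_len(m)) {
    s <- sub$simplices[[p]]
    if (length(s) < 2L) next
    for (i in seq_along(s)) {
      face <- s[-i]
      if (all(face %in% l_vertices)) next  # face lies in L: zero in C(K)/C(L)
      fp <- pos_of[paste(face, collapse = ",")]
      B[fp, p] <- TRUE
    }
  }
  low <- function(j) { w <- which(B[, j]); if (length(w)) max(w) else 0L }
  lows <- integer(m)
  for (j in seq_len(m)) {
    repeat {
      lj <- low(j)
      if (lj == 0L) break
      k <- 0L
      for (jj in seq_len(j - 1L)) if (lows[jj] == lj) { k <- jj; break }
      if (k == 0L) break
      B[, j] <- xor(B[, j], B[, k])
    }
    lows[j] <- low(j)
  }
  deaths <- which(lows > 0L)
  births <- lows[deaths]
  pairs_to_diagram(sub, births, deaths)
}

#' Structural importance of a cell by relative persistence
#'
#' Wasserstein distance between the relative persistence diagram (global
#' structure modulo the cell's neighborhood) and the ordinary persistence
#' diagram of the whole dataset, summed over homology dimensions up to
#' `max_dim`. Deaths are capped at the filtration scale before matching.
#'
#' @inheritParams relative_ph
#' @param q Wasserstein order (default 1).
#' @return non-negative importance score.
#' @export
relative_importance <- function(emb, cell, l_size = 10L, max_dim = 1L,
                                max_scale = NULL, q = 1) {
  if (!inherits(emb, "sctopo_embedding")) emb <- embedding_from_coords(emb)
  D <- as.matrix(stats::dist(emb$coords))
  if (is.null(max_scale))
    max_scale <- stats::quantile(D[upper.tri(D)], 0.9, names = FALSE)
  rel <- relative_ph(emb, cell, l_size, max_dim, max_scale)
  reg <- persistence(vr_filtration(D, max_dim = max_dim,
                                   max_scale = max_scale))
  sum(vapply(0:max_dim, function(k)
    diagram_wasserstein(rel, reg, dim = k, q = q, cap = max_scale),
    numeric(1)))
}

#' Per-cell local topology feature table
#'
#' Applies [local_ph()] to every cell and summarizes each diagram as H0/H1
#' total persistence and persistence entropy (capped at the neighborhood
#' diameter); optionally adds the relative-persistence importance score.
#'
#' @inheritParams local_ph
#' @param with_relative also compute [relative_importance()] per cell
#'   (quadratic cost in cell number; off by default).
#' @param l_size,q passed to [relative_importance()].
#' @return data frame with one row per cell: `cell_id`, `h0_total`,
#'   `h1_total`, `h0_entropy`, `h1_entropy`, and optionally
#'   `relative_importance`.
#' @export
cell_features_table <- function(emb, k_local = 30L, max_dim = 1L,
                                with_relative = FALSE, l_size = 10L, q = 1) {
  if (!inherits(emb, "sctopo_embedding")) emb <- embedding_from_coords(emb)
  n <- nrow(emb$coords)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dgm <- suppressWarnings(local_ph(emb, i, k_local = k_local,
                                     max_dim = max_dim))
    f <- suppressWarnings(diagram_features(dgm, max_dim = max_dim))
    rows[[i]] <- f
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("h0_total", "h0_entropy", "h1_total", "h1_entropy")[
    seq_len(ncol(out))]
  out <- data.frame(cell_id = emb$cell_ids, out,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (with_relative) {
    out$relative_importance <- vapply(seq_len(n), function(i)
      relative_importance(emb, i, l_size = l_size, max_dim = max_dim, q = q),
      numeric(1))
  }
  out
}
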