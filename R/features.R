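diagram_persistences <- function(diag, dim, delta_max) {
  p <- diag[diag$dim == dim, , drop = FALSE]
  if (!nrow(p)) return(numeric(0))
  if (any(p$birth > delta_max + 1e-12))
    stop("pair born after delta_max; increase delta_max")
  l <- pmin(p$death, delta_max) - p$birth
  l[l > 0]
}

#' Total persistence of a diagram
#'
#' Sum of capped bar lengths `min(death, delta_max) - birth` over pairs of
#' one homology dimension.
#'
#' @param diag an `sctopo_diagram`.
#' @param dim homology dimension.
#' @param delta_max cap for infinite (or longer) deaths; defaults to the
#'   diagram's stored `delta_max`.
#' @return non-negative total persistence.
#' @export
total_persistence <- function(diag, dim = 0L,
                              delta_max = attr(diag, "delta_max")) {
  if (is.null(delta_max)) stop("delta_max required to cap deaths")
  sum(diagram_persistences(diag, dim, delta_max))
}

#' Persistence entropy of a diagram
#'
#' Shannon entropy (base 2) of the normalized capped bar lengths within one
#' homology dimension: `-sum (l_i/L) log2(l_i/L)`. A single-bar diagram has
#' entropy 0; an empty diagram returns 0 with a warning.
#'
#' @inheritParams total_persistence
#' @return entropy in bits, in `[0, log2(n_bars)]`.
#' @export
persistence_entropy <- function(diag, dim = 0L,
                                delta_max = attr(diag, "delta_max")) {
  if (is.null(delta_max)) stop("delta_max required to cap deaths")
  l <- diagram_persistences(diag, dim, delta_max)
  if (!length(l)) {
    warning("empty diagram in dimension ", dim, "; entropy set to 0")
    return(0)
  }
  p <- l / sum(l)
  -sum(p * log2(p))
}

#' Betti curve of a diagram
#'
#' Counts, at each grid value, the bars `[birth, death)` containing it
#' (half-open: a bar is not counted at its death value).
#'
#' @param diag an `sctopo_diagram`.
#' @param dim homology dimension.
#' @param grid ascending filtration values at which to evaluate the curve.
#' @return list with `grid`, integer `counts`, and `dim`.
#' @export
betti_curve <- function(diag, dim = 0L, grid) {
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  p <- diag[diag$dim == dim, , drop = FALSE]
  counts <- vapply(grid, function(x)
    sum(p$birth <= x & x < p$death), integer(1))
  list(grid = grid, counts = counts, dim = as.integer(dim))
}

#' Evenly spaced Betti grid on `[0, delta_max]`
#'
#' @param delta_max upper end of the filtration interval.
#' @param n number of grid values (default 100).
#' @return numeric vector of length `n`.
#' @export
betti_grid <- function(delta_max, n = 100L) {
  seq(0, delta_max, length.out = n)
}

#' Scalar and curve features of a diagram
#'
#' H0/H1 total persistence and persistence entropy (and optionally Betti
#' curves on a shared grid), as one named numeric vector.
#'
#' @param diag an `sctopo_diagram`.
#' @param delta_max death cap; defaults to the diagram's stored value.
#' @param max_dim highest homology dimension summarized (default 1).
#' @param grid optional Betti grid; if supplied, `bc_h<k>_<j>` entries are
#'   appended.
#' @return named numeric vector `h<k>_total`, `h<k>_entropy`, ... .
#' @export
diagram_features <- function(diag, delta_max = attr(diag, "delta_max"),
                             max_dim = 1L, grid = NULL) {
  out <- numeric(0)
  for (k in 0:max_dim) {
    tp <- total_persistence(diag, k, delta_max)
    en <- suppressWarnings(persistence_entropy(diag, k, delta_max))
    out <- c(out, stats::setNames(c(tp, en),
                                  paste0("h", k, c("_total", "_entropy"))))
  }
  if (!is.null(grid)) {
    for (k in 0:max_dim) {
      bc <- betti_curve(diag, k, grid)$counts
      out <- c(out, stats::setNames(bc, sprintf("bc_h%d_%03d", k,
                                                seq_along(grid) - 1L)))
    }
  }
  out
}
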