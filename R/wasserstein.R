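#' Wasserstein distance between persistence diagrams
#'
#' Order-`q` Wasserstein distance in one homology dimension, with the
#' L-infinity ground metric on birth-death points and orthogonal projection
#' to the diagonal as the partial-matching slack (a bar `[b, d)` may be
#' matched to the diagonal at cost `(d - b) / 2`). Computed as an exact
#' assignment problem via [transport_exact()].
#'
#' Infinite deaths must be capped before matching; pass `cap` (or store a
#' `delta_max` attribute on the diagrams) if any death is infinite.
#'
#' @param d1,d2 `sctopo_diagram` objects.
#' @param dim homology dimension compared.
#' @param q matching order (default 1).
#' @param cap optional finite value replacing infinite deaths before
#'   matching.
#' @return the non-negative distance; zero iff the dimension-`dim` parts of
#'   the diagrams are equal as multisets.
#' @export
diagram_wasserstein <- function(d1, d2, dim = 0L, q = 1, cap = NULL) {
  p1 <- d1[d1$dim == dim, c("birth", "death")]
  p2 <- d2[d2$dim == dim, c("birth", "death")]
  fixup <- function(p) {
    if (any(is.infinite(p$death))) {
      if (is.null(cap))
        stop("diagram has infinite deaths; supply `cap` (e.g. delta_max) ",
             "before computing the Wasserstein distance")
      p$death <- pmin(p$death, cap)
    }
    p[p$death > p$birth, , drop = FALSE]
  }
  p1 <- fixup(p1); p2 <- fixup(p2)
  k1 <- nrow(p1); k2 <- nrow(p2)
  if (k1 == 0L && k2 == 0L) return(0)
  diag_cost1 <- (p1$death - p1$birth) / 2
  diag_cost2 <- (p2$death - p2$birth) / 2
  # (k1 + k2) square assignment: rows = points of d1 then diagonal slots for
  # d2's points; columns = points of d2 then diagonal slots for d1's points.
  nn <- k1 + k2
  C <- matrix(0, nn, nn)
  if (k1 && k2) {
    for (i in seq_len(k1))
      C[i, seq_len(k2)] <- pmax(abs(p1$birth[i] - p2$birth),
                                abs(p1$death[i] - p2$death))
  }
  if (k1) C[seq_len(k1), k2 + seq_len(k1)] <- matrix(diag_cost1, k1, k1)
  if (k2) C[k1 + seq_len(k2), seq_len(k2)] <-
      matrix(diag_cost2, k2, k2, byrow = TRUE)
  res <- transport_exact(rep(1, nn), rep(1, nn), C^q)
  res$cost^(1 / q)
}
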