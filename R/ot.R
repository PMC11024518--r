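#' Exact optimal transport between discrete measures
#'
#' Solves the transportation problem min <pi, C> over couplings of `a` and
#' `b` exactly, by successive shortest augmenting paths with node potentials
#' (Dijkstra on reduced costs). Deterministic; intended for the small
#' supports arising in graph-curvature and diagram-matching problems.
#'
#' @param a,b non-negative supply/demand vectors with equal sums.
#' @param costs `length(a)` x `length(b)` non-negative cost matrix.
#' @param tol mass tolerance below which a supply is considered exhausted.
#' @return list with elements `cost` (the optimal value) and `plan` (an
#'   optimal coupling matrix).
#' @export
transport_exact <- function(a, b, costs, tol = 1e-12) {
  costs <- as.matrix(costs)
  m <- length(a); n <- length(b)
  stopifnot(nrow(costs) == m, ncol(costs) == n)
  if (any(a < 0) || any(b < 0)) stop("negative mass")
  if (any(costs < 0)) stop("negative cost")
  if (abs(sum(a) - sum(b)) > 1e-9) stop("supplies and demands must balance")
  res <- transport_ssp_cpp(as.numeric(a), as.numeric(b), costs, tol)
  list(cost = res$cost, plan = res$plan)
}

#' Dense LP oracle for optimal transport
#'
#' Independent check for [transport_exact()]: solves the same transportation
#' problem as an explicit equality-constrained linear program with a dense
#' simplex solver.
#'
#' @inheritParams transport_exact
#' @return the optimal transport cost.
#' @export
transport_lp_oracle <- function(a, b, costs) {
  costs <- as.matrix(costs)
  # zero-mass rows/columns make the equality system degenerate for the
  # dense simplex; they carry no transport and are dropped up front
  ia <- which(a > 0); ib <- which(b > 0)
  a <- a[ia]; b <- b[ib]
  costs <- costs[ia, ib, drop = FALSE]
  m <- length(a); n <- length(b)
  if (m == 1L || n == 1L) return(sum(outer(a, b) / sum(a) * costs))
  cc <- as.vector(costs)  # column-major: x[i + (j-1)m] = pi_ij
  Aeq <- matrix(0, m + n, m * n)
  for (i in seq_len(m)) Aeq[i, i + (seq_len(n) - 1L) * m] <- 1
  for (j in seq_len(n)) Aeq[m + j, (j - 1L) * m + seq_len(m)] <- 1
  # the last balance row is implied by the others; keeping it makes the
  # constraint matrix rank-deficient, which the dense simplex cannot handle
  Aeq <- Aeq[-(m + n), , drop = FALSE]
  res <- pracma::linprog(cc, Aeq = Aeq, beq = c(a, b)[-(m + n)],
                         maxiter = 10000)
  res$fval
}
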