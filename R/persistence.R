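new_diagram <- function(dim, birth, death, delta_max = NULL) {
  d <- data.frame(dim = as.integer(dim), birth = as.numeric(birth),
                  death = as.numeric(death))
  d <- d[order(d$dim, d$birth, d$death), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("sctopo_diagram", "data.frame")
  if (!is.null(delta_max)) attr(d, "delta_max") <- delta_max
  d
}

#' @export
print.sctopo_diagram <- function(x, ...) {
  cat(sprintf("Persistence diagram: %d pairs (%s)\n", nrow(x),
              paste(sprintf("H%d: %d", sort(unique(x$dim)),
                            table(factor(x$dim, sort(unique(x$dim))))),
                    collapse = ", ")))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

# Boundary columns of a filtration: for each simplex of dim >= 1, the
# positions (in filtration order) of its facets, sorted increasing.
boundary_columns <- function(filt) {
  keys <- vapply(filt$simplices, paste, "", collapse = ",")
  pos_of <- stats::setNames(seq_along(keys), keys)
  lapply(seq_along(filt$simplices), function(p) {
    s <- filt$simplices[[p]]
    if (length(s) < 2L) return(integer(0))
    fk <- vapply(seq_along(s), function(i) paste(s[-i], collapse = ","), "")
    fp <- unname(pos_of[fk])
    if (anyNA(fp)) stop("filtration is missing a face of simplex ",
                        paste(s, collapse = ","))
    sort.int(as.integer(fp))
  })
}

pairs_to_diagram <- function(filt, births, deaths, drop_zero = TRUE) {
  m <- length(filt$simplices)
  finite_dim <- filt$dims[births]
  finite_b <- filt$values[births]
  finite_d <- filt$values[deaths]
  death_set <- deaths
  positive <- setdiff(seq_len(m), death_set)     # columns creating a class
  inf_births <- setdiff(positive, births)        # never killed
  inf_dim <- filt$dims[inf_births]
  keep_inf <- inf_dim <= filt$max_dim
  dims <- c(finite_dim, inf_dim[keep_inf])
  bs <- c(finite_b, filt$values[inf_births][keep_inf])
  ds <- c(finite_d, rep(Inf, sum(keep_inf)))
  keep <- dims <= filt$max_dim
  if (drop_zero) keep <- keep & (ds > bs)
  new_diagram(dims[keep], bs[keep], ds[keep],
              delta_max = attr(filt, "delta_max"))
}

#' Persistent homology of a filtration
#'
#' Standard persistence pairing by boundary-matrix column reduction over the
#' field with two elements (compiled kernel). Zero-persistence pairs are
#' dropped from the reported diagram; bars alive in the final complex are
#' reported with infinite death.
#'
#' @param filt an `sctopo_filtration`.
#' @param check verify filtration monotonicity before reducing.
#' @return an `sctopo_diagram`: data frame with columns `dim`, `birth`,
#'   `death` (possibly `Inf`), carrying the filtration's `delta_max`
#'   attribute.
#' @export
persistence <- function(filt, check = FALSE) {
  stopifnot(inherits(filt, "sctopo_filtration"))
  if (check) validate_filtration(filt)
  if (!length(filt$simplices))
    return(new_diagram(integer(0), numeric(0), numeric(0),
                       delta_max = attr(filt, "delta_max")))
  cols <- boundary_columns(filt)
  cols0 <- lapply(cols, function(x) x - 1L)  # 0-based for the C++ kernel
  prs <- reduce_boundary_cpp(cols0)
  births <- prs[1L, ] + 1L
  deaths <- prs[2L, ] + 1L
  pairs_to_diagram(filt, births, deaths)
}

#' Naive persistence oracle
#'
#' Independent, unoptimized left-to-right column reduction over a dense
#' logical boundary matrix, scanning linearly for pivot collisions. Used as
#' a correctness oracle for [persistence()]; identical output contract.
#'
#' @param filt an `sctopo_filtration` with at most a few hundred simplices.
#' @return an `sctopo_diagram`.
#' @export
persistence_oracle <- function(filt) {
  stopifnot(inherits(filt, "sctopo_filtration"))
  m <- length(filt$simplices)
  if (!m)
    return(new_diagram(integer(0), numeric(0), numeric(0),
                       delta_max = attr(filt, "delta_max")))
  cols <- boundary_columns(filt)
  B <- matrix(FALSE, m, m)
  for (j in seq_len(m)) B[cols[[j]], j] <- TRUE
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
  pairs_to_diagram(filt, births, deaths)
}

#' Cap infinite deaths in a diagram
#'
#' @param diag an `sctopo_diagram`.
#' @param delta_max cap value; defaults to the diagram's stored `delta_max`.
#' @param drop_zero drop pairs whose capped persistence is zero.
#' @return an `sctopo_diagram` with all deaths finite.
#' @export
cap_diagram <- function(diag, delta_max = attr(diag, "delta_max"),
                        drop_zero = TRUE) {
  if (is.null(delta_max))
    stop("no delta_max available to cap infinite deaths; supply one")
  d <- pmin(diag$death, delta_max)
  keep <- if (drop_zero) d > diag$birth else rep(TRUE, nrow(diag))
  new_diagram(diag$dim[keep], diag$birth[keep], d[keep],
              delta_max = delta_max)
}

#' Write a persistence diagram to CSV
#'
#' Columns `dim`, `birth`, `death`; infinite deaths written as `"inf"`.
#'
#' @param diag an `sctopo_diagram`.
#' @param path output file.
#' @export
write_diagram <- function(diag, path) {
  out <- data.frame(dim = diag$dim, birth = diag$birth,
                    death = ifelse(is.finite(diag$death),
                                   as.character(diag$death), "inf"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a persistence diagram from CSV
#'
#' @param path CSV written by [write_diagram()].
#' @return an `sctopo_diagram`.
#' @export
read_diagram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  death <- suppressWarnings(as.numeric(d$death))
  death[d$death %in% c("inf", "Inf")] <- Inf
  new_diagram(d$dim, d$birth, death)
}
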