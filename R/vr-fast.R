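# Vectorized Vietoris-Rips persistence for point clouds, homology up to
# dimension 1 (vertices / edges / triangles). Avoids materializing
# per-simplex R vectors: boundary facet positions are assembled as flat
# arrays and reduced by the compiled kernel. Falls back to the generic
# filtration path for max_dim >= 2.
vr_diagram <- function(D, max_dim = 1L, max_scale = Inf) {
  if (max_dim >= 2L)
    return(persistence(vr_filtration(D, max_dim, max_scale)))
  D <- as.matrix(D)
  n <- nrow(D)
  delta_max <- if (is.finite(max_scale)) max_scale else max(D)
  ut <- which(upper.tri(D) & D <= max_scale, arr.ind = TRUE)
  ne <- nrow(ut)
  ei <- ut[, 1L]; ej <- ut[, 2L]
  val_e <- D[ut]
  # triangles i < j < k with all three edges present
  ti <- tj <- tk <- integer(0)
  if (max_dim >= 1L && ne) {
    adj <- matrix(FALSE, n, n)
    adj[ut] <- TRUE; adj[ut[, 2:1, drop = FALSE]] <- TRUE
    tl <- vector("list", ne)
    for (r in seq_len(ne)) {
      ks <- which(adj[ei[r], ] & adj[ej[r], ])
      ks <- ks[ks > ej[r]]
      if (length(ks)) tl[[r]] <- cbind(ei[r], ej[r], ks)
    }
    tl <- tl[!vapply(tl, is.null, TRUE)]
    if (length(tl)) {
      tm <- do.call(rbind, tl)
      ti <- tm[, 1L]; tj <- tm[, 2L]; tk <- tm[, 3L]
    }
  }
  nt <- length(ti)
  val_t <- if (nt) pmax(D[cbind(ti, tj)], D[cbind(ti, tk)],
                        D[cbind(tj, tk)]) else numeric(0)
  N <- n + ne + nt
  values <- c(rep(0, n), val_e, val_t)
  dims <- c(rep(0L, n), rep(1L, ne), rep(2L, nt))
  v1 <- c(seq_len(n), ei, ti)
  v2 <- c(rep(0L, n), ej, tj)
  v3 <- c(rep(0L, n), rep(0L, ne), tk)
  ord <- order(values, dims, v1, v2, v3, method = "radix")
  pos <- integer(N); pos[ord] <- seq_len(N)
  pos_v <- pos[seq_len(n)]
  pos_e <- pos[n + seq_len(ne)]
  pos_t <- pos[n + ne + seq_len(nt)]
  # facet positions per column, sorted within column
  fe1 <- pmin(pos_v[ei], pos_v[ej]); fe2 <- pmax(pos_v[ei], pos_v[ej])
  if (nt) {
    elook <- integer(n * n)
    elook[(ei - 1L) * n + ej] <- pos_e
    fa <- elook[(ti - 1L) * n + tj]
    fb <- elook[(ti - 1L) * n + tk]
    fc <- elook[(tj - 1L) * n + tk]
    lo <- pmin(fa, fb, fc); hi <- pmax(fa, fb, fc); mid <- fa + fb + fc - lo - hi
  }
  nf <- integer(N)
  nf[pos_e] <- 2L
  if (nt) nf[pos_t] <- 3L
  colptr <- c(0L, cumsum(nf))
  entries <- integer(2L * ne + 3L * nt)
  off <- colptr[seq_len(N)]
  entries[off[pos_e] + 1L] <- fe1; entries[off[pos_e] + 2L] <- fe2
  if (nt) {
    entries[off[pos_t] + 1L] <- lo
    entries[off[pos_t] + 2L] <- mid
    entries[off[pos_t] + 3L] <- hi
  }
  prs <- reduce_boundary_flat_cpp(entries - 1L, colptr)
  births <- prs[1L, ] + 1L
  deaths <- prs[2L, ] + 1L
  vs <- values[ord]; dsrt <- dims[ord]
  positive <- setdiff(seq_len(N), deaths)
  inf_births <- setdiff(positive, births)
  keep_inf <- dsrt[inf_births] <= max_dim
  dms <- c(dsrt[births], dsrt[inf_births][keep_inf])
  bs <- c(vs[births], vs[inf_births][keep_inf])
  ds <- c(vs[deaths], rep(Inf, sum(keep_inf)))
  keep <- dms <= max_dim & ds > bs
  new_diagram(dms[keep], bs[keep], ds[keep], delta_max = delta_max)
}
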