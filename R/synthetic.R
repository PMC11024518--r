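#' Gaussian clusters connected by sparse bridges
#'
#' Emulates stable cell states linked by transition cells: dense Gaussian
#' cores at separated centers (placed along a line, `separation` apart) and
#' bridge cells spread uniformly along each inter-center segment with the
#' same noise. Ground-truth labels mark cores (`core<i>`) and bridges
#' (`bridge<i>_<i+1>`).
#'
#' @param n_core cells per cluster core (default 120).
#' @param n_bridge total bridge cells, split evenly over adjacent center
#'   pairs (default 60).
#' @param n_clusters number of cores (default 2).
#' @param separation distance between adjacent centers, in noise SD units
#'   (default 11: with the default 12-dimensional noise the core clouds
#'   have radius about `sqrt(12)`, so states are clearly resolved while the
#'   bridge remains a sparse bottleneck between them, the regime this
#'   fixture is meant to plant).
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @param dim embedding dimension (default 12, mimicking the effective
#'   dimensionality of a PCA embedding of real single-cell data).
#' @param seed RNG seed.
#' @return list with `embedding` (an `sctopo_embedding`), `labels`
#'   (character), and `is_bridge` (logical).
#' @export
make_bridge_clusters <- function(n_core = 120L, n_bridge = 60L,
                                 n_clusters = 2L, separation = 11,
                                 noise_sd = 1, dim = 12L, seed = 0L) {
  if (n_clusters < 2L) stop("need at least 2 clusters")
  withr::with_seed(seed, {
    centers <- matrix(0, n_clusters, dim)
    centers[, 1L] <- (seq_len(n_clusters) - 1L) * separation
    pts <- list(); labels <- character(0)
    for (c in seq_len(n_clusters)) {
      pts[[length(pts) + 1L]] <-
        sweep(matrix(rnorm(n_core * dim, sd = noise_sd), n_core, dim),
              2L, centers[c, ], `+`)
      labels <- c(labels, rep(paste0("core", c), n_core))
    }
    n_seg <- n_clusters - 1L
    per_seg <- rep(n_bridge %/% n_seg, n_seg)
    if (n_bridge %% n_seg) per_seg[seq_len(n_bridge %% n_seg)] <-
      per_seg[seq_len(n_bridge %% n_seg)] + 1L
    for (s in seq_len(n_seg)) {
      nb <- per_seg[s]
      if (!nb) next
      t <- runif(nb, 0.12, 0.88)
      base <- outer(1 - t, centers[s, ]) + outer(t, centers[s + 1L, ])
      pts[[length(pts) + 1L]] <-
        base + matrix(rnorm(nb * dim, sd = noise_sd), nb, dim)
      labels <- c(labels, rep(paste0("bridge", s, "_", s + 1L), nb))
    }
    coords <- do.call(rbind, pts)
  })
  list(embedding = embedding_from_coords(coords),
       labels = labels,
       is_bridge = grepl("^bridge", labels))
}

#' Noisy circle point set
#'
#' `n` points at evenly spaced angles on a circle of the given radius, with
#' isotropic Gaussian noise; plants one dominant H1 loop.
#'
#' @param n number of points (at least 8; default 60).
#' @param radius circle radius (default 1).
#' @param noise_sd coordinate noise (default `0.05 * radius`).
#' @param seed RNG seed.
#' @return 2-column coordinate matrix.
#' @export
make_ring <- function(n = 60L, radius = 1, noise_sd = 0.05 * radius,
                      seed = 0L) {
  if (n < 8L) stop("need at least 8 points")
  withr::with_seed(seed, {
    theta <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
    cbind(radius * cos(theta), radius * sin(theta)) +
      matrix(rnorm(2L * n, sd = noise_sd), n, 2L)
  })
}

#' Uniform Gaussian blob point set
#'
#' Structureless counterpart of [make_ring()].
#'
#' @param n number of points.
#' @param sd spread (default 1).
#' @param dim dimension (default 2).
#' @param seed RNG seed.
#' @return coordinate matrix.
#' @export
make_blob <- function(n = 60L, sd = 1, dim = 2L, seed = 0L) {
  withr::with_seed(seed, matrix(rnorm(n * dim, sd = sd), n, dim))
}

#' Modular (planted-partition) gene network
#'
#' Genes split into modules; gene pairs connect with probability `p_in`
#' within a module and `p_out` across modules.
#'
#' @param n_genes number of genes (default 60).
#' @param n_modules number of modules (default 4).
#' @param p_in,p_out intra-/inter-module edge probabilities (defaults 0.6 /
#'   0.05; `p_in > p_out` required).
#' @param seed RNG seed.
#' @return list with `gene_ids`, `edges` (data frame `a`, `b` of gene
#'   indices), and `modules` (integer per gene).
#' @export
make_modular_network <- function(n_genes = 60L, n_modules = 4L, p_in = 0.6,
                                 p_out = 0.05, seed = 0L) {
  if (p_in <= p_out) stop("p_in must exceed p_out")
  withr::with_seed(seed, {
    modules <- rep(seq_len(n_modules), length.out = n_genes)
    modules <- sort(modules)
    pr <- ifelse(outer(modules, modules, `==`), p_in, p_out)
    up <- which(upper.tri(pr), arr.ind = TRUE)
    keep <- runif(nrow(up)) < pr[up]
    edges <- data.frame(a = up[keep, 1L], b = up[keep, 2L])
  })
  list(gene_ids = paste0("g", seq_len(n_genes)), edges = edges,
       modules = modules)
}

#' Broad versus module-localized expression profiles
#'
#' Emulates pluripotent versus differentiated activation patterns over a
#' modular gene network: "broad" cells express all modules at a moderate
#' level, "localized" cells express one module highly and the rest near
#' zero (modules assigned round-robin). Values are on a log-normalized-like
#' scale with multiplicative-free Gaussian noise, truncated at zero.
#'
#' @param net a network from [make_modular_network()].
#' @param n_cells cells per state (default 50).
#' @param broad_level expression level of broad cells (default 2).
#' @param localized_level active-module level of localized cells (default
#'   `2 * broad_level`: under total-count normalization a cell expressing
#'   only one module concentrates its counts there, so its active genes sit
#'   higher on the log-normalized scale than a broadly expressing cell's).
#' @param noise additive noise standard deviation (default 0.1).
#' @param seed RNG seed.
#' @return list with `expr` (lognorm-layer [expression_matrix()]) and
#'   `state` (`"broad"` / `"localized"`) plus `localized_module` per cell.
#' @export
make_pluripotency_profiles <- function(net, n_cells = 50L, broad_level = 2,
                                       localized_level = 2 * broad_level,
                                       noise = 0.1, seed = 0L) {
  g <- length(net$gene_ids)
  withr::with_seed(seed, {
    broad <- matrix(broad_level, n_cells, g) +
      matrix(rnorm(n_cells * g, sd = noise), n_cells, g)
    loc_mod <- rep(seq_len(max(net$modules)), length.out = n_cells)
    localized <- matrix(0, n_cells, g)
    for (i in seq_len(n_cells))
      localized[i, net$modules == loc_mod[i]] <- localized_level
    localized <- localized + matrix(rnorm(n_cells * g, sd = noise),
                                    n_cells, g)
    vals <- pmax(rbind(broad, localized), 0)
  })
  ids <- paste0("cell", seq_len(2L * n_cells))
  list(expr = expression_matrix(vals, ids, net$gene_ids, layer = "lognorm"),
       state = rep(c("broad", "localized"), each = n_cells),
       localized_module = c(rep(NA_integer_, n_cells), loc_mod))
}

#' Two classes separated by co-activation topology, not by means
#'
#' Every gene has the same standard-normal marginal (shifted to a positive
#' expression-like scale) in both classes; the classes differ only in the
#' dependence structure. Class "ring" draws two latent factors `u`, `v`
#' per cell and sets `gene_j = cos(theta_j) u + sin(theta_j) v` with
#' `theta_j` evenly spaced over a half circle: phase-adjacent genes are
#' strongly correlated (`cos(pi/n_genes)`), quarter-circle pairs are
#' exactly independent, and the two ends are strongly anti-correlated
#' (which local co-occurrence statistics also detect), so each cell's
#' gene network is a circular band carrying one loop. Class "pairs" couples
#' genes in independent pairs at the same adjacent-gene correlation, so
#' the network splits into disjoint edges with no loop. Expression-level
#' features thus carry no per-gene class signal while cell-specific
#' network topology does.
#'
#' @param n_cells cells per class (default 200; local co-occurrence
#'   statistics need a few hundred cells for stable edge calls).
#' @param n_genes number of structured genes (even; default 16, giving
#'   adjacent-gene correlation 0.98).
#' @param n_noise number of additional independent genes with the same
#'   marginal and no class structure (default 48), mimicking the bulk of
#'   class-irrelevant genes in real expression data.
#' @param level,scale location and scale mapping the latent normals onto a
#'   log-normalized-like expression scale (defaults 2 and 0.7; values are
#'   truncated at zero).
#' @param seed RNG seed.
#' @return list with `expr` (lognorm-layer [expression_matrix()]) and
#'   `class` labels.
#' @export
make_topo_signal_classes <- function(n_cells = 200L, n_genes = 16L,
                                     n_noise = 48L, level = 2, scale = 0.7,
                                     seed = 0L) {
  if (n_genes %% 2L || n_genes < 6L) stop("n_genes must be even, >= 6")
  theta <- pi * (seq_len(n_genes) - 1L) / n_genes
  withr::with_seed(seed, {
    u <- rnorm(n_cells); v <- rnorm(n_cells)
    ring <- outer(u, cos(theta)) + outer(v, sin(theta))
    pairs <- matrix(0, n_cells, n_genes)
    rho <- cos(pi / n_genes)
    for (pr in seq_len(n_genes / 2L)) {
      a <- rnorm(n_cells); b <- rnorm(n_cells)
      pairs[, 2L * pr - 1L] <- a
      pairs[, 2L * pr] <- rho * a + sqrt(1 - rho^2) * b
    }
    z <- rbind(ring, pairs)
    if (n_noise > 0L)
      z <- cbind(z, matrix(rnorm(2L * n_cells * n_noise), 2L * n_cells,
                           n_noise))
    vals <- pmax(level + scale * z, 0)
  })
  ids <- paste0("cell", seq_len(2L * n_cells))
  list(expr = expression_matrix(vals, ids,
                                paste0("g", seq_len(n_genes + n_noise)),
                                layer = "lognorm"),
       class = rep(c("ring", "pairs"), each = n_cells))
}

#' Negative-binomial raw counts for a blob of cells
#'
#' Count-layer fixture exercising [normalize_log1p()]: per-cell size
#' factors spread about threefold, negative-binomial sampling around
#' gene-specific means.
#'
#' @param n_cells,n_genes dimensions (defaults 50, 20).
#' @param mean_counts average counts per gene (default 5).
#' @param dispersion NB size parameter (default 2).
#' @param seed RNG seed.
#' @return a raw-layer [expression_matrix()].
#' @export
make_count_blob <- function(n_cells = 50L, n_genes = 20L, mean_counts = 5,
                            dispersion = 2, seed = 0L) {
  withr::with_seed(seed, {
    sf <- exp(runif(n_cells, -log(3) / 2, log(3) / 2))
    mu <- rexp(n_genes, 1 / mean_counts)
    lam <- outer(sf, mu)
    vals <- matrix(rnbinom(n_cells * n_genes, mu = lam, size = dispersion),
                   n_cells, n_genes)
  })
  expression_matrix(vals, paste0("cell", seq_len(n_cells)),
                    paste0("g", seq_len(n_genes)), layer = "raw")
}
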