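test_that("vr_filtration assigns max-pairwise-distance entry values", {
  D <- unit_square_dist()
  f <- vr_filtration(D, max_dim = 1)
  key <- vapply(f$simplices, paste, "", collapse = ",")
  val <- stats::setNames(f$values, key)
  expect_equal(unname(val[c("1", "2", "3", "4")]), rep(0, 4))
  expect_equal(unname(val["1,2"]), 1)
  expect_equal(unname(val["1,3"]), sqrt(2))
  expect_equal(unname(val["1,2,3"]), sqrt(2))
  # truncation below the side length leaves vertices only
  f0 <- vr_filtration(D, max_dim = 1, max_scale = 0.5)
  expect_equal(length(f0$simplices), 4L)
  # two points, max_dim 0: vertices at 0, edge at distance
  f2 <- vr_filtration(matrix(c(0, 1, 1, 0), 2, 2), max_dim = 0)
  expect_equal(sort(f2$values), c(0, 0, 1))
  expect_error(vr_filtration(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("edge-weighted VR filtration implements the descending transform", {
  # single edge of weight 3: everything enters at transformed value 0
  n1 <- gene_network(c("a", "b"), data.frame(a = 1, b = 2), edge_weight = 3)
  f1 <- edge_weighted_vr_filtration(n1)
  expect_equal(f1$values, c(0, 0, 0))
  # triangle with weights 3, 2, 1: edges at 0, 1, 2; 2-simplex at 2
  n2 <- gene_network(c("a", "b", "c"), data.frame(a = c(1, 1, 2), b = c(2, 3, 3)),
                     edge_weight = c(3, 2, 1))
  f2 <- edge_weighted_vr_filtration(n2)
  dims <- lengths(f2$simplices) - 1L
  expect_equal(sort(f2$values[dims == 1L]), c(0, 1, 2))
  expect_equal(f2$values[dims == 2L], 2)
  # no edges: vertices only, all at delta_max
  n3 <- gene_network(c("a", "b"), NULL, edge_weight = numeric(0))
  f3 <- edge_weighted_vr_filtration(n3)
  expect_equal(f3$values, c(0, 0))  # delta_max of an empty weight set is 0
  expect_error(gene_network("a", NULL, edge_weight = -1), "per edge|non-negative")
  # shifting all weights by a constant leaves the transformed diagram fixed
  withr::with_seed(11, {
    for (r in 1:10) {
      filt <- random_filtration(100 + r)
      n <- 7
      ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- stats::runif(nrow(ut)) < 0.6
      w <- stats::runif(sum(keep), 0, 2)
      net <- gene_network(paste0("g", 1:n),
                          data.frame(a = ut[keep, 1], b = ut[keep, 2]),
                          edge_weight = w)
      netc <- gene_network(paste0("g", 1:n),
                           data.frame(a = ut[keep, 1], b = ut[keep, 2]),
                           edge_weight = w + 1.7)
      d1 <- persistence(edge_weighted_vr_filtration(net))
      d2 <- persistence(edge_weighted_vr_filtration(netc))
      expect_true(diagrams_equal(d1, d2, tol = 1e-12))
    }
  })
})

test_that("vertex-based clique filtration follows the min-of-endpoints rule", {
  # path a-b-c with weights 3, 1, 2 (delta_max 3)
  net <- gene_network(c("a", "b", "c"), data.frame(a = c(1, 2), b = c(2, 3)),
                      node_weight = c(3, 1, 2))
  f <- vertex_clique_filtration(net)
  key <- vapply(f$simplices, paste, "", collapse = ",")
  val <- stats::setNames(f$values, key)
  expect_equal(unname(val[c("1", "2", "3")]), c(0, 2, 1))
  expect_equal(unname(val["1,2"]), 2)
  expect_equal(unname(val["2,3"]), 2)
  # equal weights: a single entry value
  neq <- gene_network(c("a", "b", "c"), data.frame(a = c(1, 2), b = c(2, 3)),
                      node_weight = rep(1.5, 3))
  feq <- vertex_clique_filtration(neq)
  expect_equal(unique(feq$values), 0)
  # isolated vertex of weight w: an extra H0 bar born at delta_max - w
  niso <- gene_network(c("a", "b", "z"), data.frame(a = 1, b = 2),
                       node_weight = c(5, 5, 2))
  dg <- persistence(vertex_clique_filtration(niso))
  h0 <- dg[dg$dim == 0, ]
  expect_equal(nrow(h0), 2L)
  expect_true(any(h0$birth == 3))
  expect_error(gene_network(c("a", "b"), NULL, node_weight = 1), "per gene")
})

test_that("persistence reproduces analytic diagrams", {
  # single point
  f <- new_filtration(list(1L), 0, max_dim = 0L)
  d <- persistence(f)
  expect_equal(nrow(d), 1L)
  expect_equal(d$death, Inf)
  # two points joined at value 1
  f2 <- new_filtration(list(1L, 2L, c(1L, 2L)), c(0, 0, 1), max_dim = 0L)
  d2 <- persistence(f2)
  expect_equal(d2$death[is.finite(d2$death)], 1)
  expect_equal(sum(is.infinite(d2$death)), 1L)
  # unit square: H1 = [1, sqrt(2))
  ds <- persistence(vr_filtration(unit_square_dist(), max_dim = 1))
  h1 <- ds[ds$dim == 1, ]
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))
  # H0 bars born at 0 equal the number of points; one infinite per component
  withr::with_seed(9, pts <- matrix(stats::rnorm(16), 8, 2))
  df <- persistence(vr_filtration(as.matrix(stats::dist(pts)), max_dim = 1))
  h0 <- df[df$dim == 0, ]
  expect_equal(nrow(h0), 8L)  # zero-length pairs dropped; none coincide here
  expect_equal(sum(is.infinite(h0$death)), 1L)
  # non-monotone filtration rejected
  bad <- new_filtration(list(1L, 2L, c(1L, 2L)), c(0.5, 0.5, 0.2),
                        max_dim = 0L)
  expect_error(validate_filtration(bad), "monotone")
})

test_that("optimized reduction matches the naive oracle on random filtrations", {
  for (r in 1:50) {
    filt <- random_filtration(r)
    expect_true(diagrams_equal(persistence(filt), persistence_oracle(filt)))
  }
  expect_equal(nrow(persistence_oracle(
    new_filtration(list(), numeric(0), 0L))), 0L)
})

test_that("fast point-cloud path agrees with the generic filtration path", {
  withr::with_seed(21, {
    for (r in 1:20) {
      n <- sample(4:14, 1)
      pts <- matrix(stats::rnorm(2 * n), n, 2)
      D <- as.matrix(stats::dist(pts))
      ms <- if (r %% 2) Inf else stats::quantile(D[upper.tri(D)], 0.7)
      expect_true(diagrams_equal(
        sctopo:::vr_diagram(D, 1, ms),
        persistence(vr_filtration(D, 1, ms))))
    }
  })
})

test_that("diagram Wasserstein distance matches exhaustive matchings", {
  d1 <- sctopo:::new_diagram(0L, 0, 1)
  d2 <- sctopo:::new_diagram(0L, 0, 2)
  empty <- sctopo:::new_diagram(integer(0), numeric(0), numeric(0))
  expect_equal(diagram_wasserstein(d1, d1, 0), 0)
  expect_equal(diagram_wasserstein(d1, empty, 0), 0.5)
  expect_equal(diagram_wasserstein(empty, d1, 0), 0.5)
  expect_equal(diagram_wasserstein(d2, d1, 0), 1)
  dinf <- sctopo:::new_diagram(0L, 0, Inf)
  expect_error(diagram_wasserstein(dinf, d1, 0), "cap")
  expect_equal(diagram_wasserstein(dinf, d1, 0, cap = 2), 1)
  # symmetry and triangle inequality on random diagrams
  rand_diag <- function(seed) withr::with_seed(seed, {
    k <- sample(0:5, 1)
    b <- stats::runif(k, 0, 2)
    sctopo:::new_diagram(rep(0L, k), b, b + stats::runif(k, 0, 2))
  })
  for (r in 1:25) {
    a <- rand_diag(3 * r); b <- rand_diag(3 * r + 1); c <- rand_diag(3 * r + 2)
    dab <- diagram_wasserstein(a, b, 0)
    dba <- diagram_wasserstein(b, a, 0)
    dac <- diagram_wasserstein(a, c, 0)
    dcb <- diagram_wasserstein(c, b, 0)
    expect_equal(dab, dba, tolerance = 1e-10)
    expect_lte(dab, dac + dcb + 1e-8)
  }
})

test_that("diagram CSV round-trips including infinite deaths", {
  d <- sctopo:::new_diagram(c(0L, 0L, 1L), c(0, 0, 1), c(2, Inf, 1.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_diagram(d, path)
  d2 <- read_diagram(path)
  expect_true(diagrams_equal(d, d2, tol = 1e-12))
})
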