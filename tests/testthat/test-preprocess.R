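test_that("read_counts handles CSV and MTX orientations and mismatches", {
  dir <- withr::local_tempdir()
  # CSV: 3 cells x 2 genes
  csv <- file.path(dir, "counts.csv")
  writeLines(c("barcode,gA,gB", "c1,1,2", "c2,0,3", "c3,4,0"), csv)
  x <- read_counts(csv, "csv")
  expect_equal(dim(x$values), c(3L, 2L))
  expect_equal(x$gene_ids, c("gA", "gB"))
  expect_equal(x$layer, "raw")
  # MTX: genes x cells triplets (2 genes, 3 cells) -> transposed
  mtx <- file.path(dir, "counts.mtx")
  m <- Matrix::Matrix(matrix(c(1, 0, 2, 3, 0, 4), 2, 3), sparse = TRUE)
  Matrix::writeMM(m, mtx)
  writeLines(c("c1", "c2", "c3"), file.path(dir, "barcodes.tsv"))
  writeLines(c("gA", "gB"), file.path(dir, "genes.tsv"))
  xm <- read_counts(mtx, "mtx")
  expect_equal(dim(xm$values), c(3L, 2L))
  expect_equal(unname(xm$values[1, ]), c(1, 0))
  # gene file with wrong number of rows -> format error
  writeLines(c("gA", "gB", "gC"), file.path(dir, "genes.tsv"))
  expect_error(read_counts(mtx, "mtx"), "dimension mismatch")
  expect_error(read_counts(file.path(dir, "absent.csv")), "not found")
})

test_that("normalize_log1p scales cells and handles zero cells", {
  x <- small_raw_expr(rbind(c(2, 2), c(1, 3)))
  y <- normalize_log1p(x, target_sum = 4)
  expect_equal(unname(y$values[1, ]), c(log(3), log(3)))
  expect_equal(unname(y$values[2, ]), c(log(2), log(4)))
  expect_equal(y$layer, "lognorm")
  x0 <- small_raw_expr(rbind(c(0, 0), c(1, 1)))
  expect_warning(y0 <- normalize_log1p(x0), "zero total count")
  expect_equal(unname(y0$values[1, ]), c(0, 0))
  # roundtrip: expm1 then rescaling recovers raw proportions
  x2 <- make_count_blob(20, 10, seed = 3)
  y2 <- normalize_log1p(x2, 1e4)
  back <- expm1(as.matrix(y2$values))
  props <- back / rowSums(back)
  raw <- as.matrix(x2$values)
  expect_equal(props, raw / rowSums(raw), tolerance = 1e-10)
})

test_that("select_hvg ranks by variance deterministically", {
  v <- cbind(rep(1, 6), c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 0, 0, 10))
  x <- expression_matrix(v, paste0("c", 1:6), c("flat", "mid", "spiky"),
                         layer = "lognorm")
  expect_equal(select_hvg(x, 3), c("spiky", "mid", "flat"))
  expect_equal(select_hvg(x, 2), select_hvg(x, 2))
  expect_true(which(select_hvg(x, 3) == "flat") == 3)  # zero variance last
  expect_error(select_hvg(x, 4), "exceeds")
})

test_that("pca_embed centers, fixes signs, and preserves geometry", {
  withr::with_seed(5, {
    t <- stats::runif(10)
    line <- cbind(t, 2 * t, -t) + 1  # rank-1 in gene space
  })
  x <- expression_matrix(line, paste0("c", 1:10), paste0("g", 1:3),
                         layer = "lognorm")
  e <- pca_embed(x, 2)
  expect_lt(max(abs(e$coords[, 2])), 1e-8)
  # full-rank distances preserved
  withr::with_seed(6, v <- matrix(stats::rnorm(8 * 5), 8, 5))
  xf <- expression_matrix(v - min(v), paste0("c", 1:8), paste0("g", 1:5),
                          layer = "lognorm")
  ef <- pca_embed(xf, 5)
  expect_equal(as.matrix(stats::dist(ef$coords)),
               as.matrix(stats::dist(scale(v, scale = FALSE))),
               tolerance = 1e-8, ignore_attr = TRUE)
  # duplicated cells embed identically
  xd <- expression_matrix(rbind(v, v[1, ]) - min(v), paste0("c", 1:9),
                          paste0("g", 1:5), layer = "lognorm")
  ed <- pca_embed(xd, 3)
  expect_equal(ed$coords[9, ], ed$coords[1, ], ignore_attr = TRUE)
  expect_error(pca_embed(xf, 9), "exceeds")
})

test_that("knn_graph follows the nearest-neighbor contract", {
  # collinear points at 0, 1, 3 with k = 1
  g <- knn_graph(matrix(c(0, 1, 3), 3, 1), k = 1)
  expect_equal(g$edges[, c("i", "j")], data.frame(i = c(1L, 2L), j = c(2L, 3L)))
  # k = n - 1 gives the complete graph
  withr::with_seed(2, pts <- matrix(stats::rnorm(12), 6, 2))
  gc <- knn_graph(pts, k = 5)
  expect_equal(nrow(gc$edges), choose(6, 2))
  # a duplicated point's twin is always its first neighbor (distance 0)
  gd <- knn_graph(rbind(pts, pts[1, ]), k = 1)
  expect_true(any(gd$edges$i == 1 & gd$edges$j == 7 & gd$edges$length == 0))
  expect_error(knn_graph(pts, k = 6), "smaller")
  # degree >= k under union symmetrization
  fx <- make_bridge_clusters(n_core = 30L, n_bridge = 10L, seed = 1)
  gk <- knn_graph(fx$embedding, k = 4)
  deg <- tabulate(c(gk$edges$i, gk$edges$j), nbins = gk$n_nodes)
  expect_true(all(deg >= 4))
  # permutation of input rows relabels but preserves the edge set
  perm <- withr::with_seed(3, sample(nrow(pts)))
  gp <- knn_graph(pts[perm, ], k = 2)
  g0 <- knn_graph(pts, k = 2)
  inv <- order(perm)
  remapped <- data.frame(i = pmin(inv[g0$edges$i], inv[g0$edges$j]),
                         j = pmax(inv[g0$edges$i], inv[g0$edges$j]))
  remapped <- remapped[order(remapped$i, remapped$j), ]
  expect_equal(gp$edges[, c("i", "j")], remapped, ignore_attr = TRUE)
})

test_that("graph and embedding files round-trip", {
  dir <- withr::local_tempdir()
  fx <- make_bridge_clusters(n_core = 10L, n_bridge = 5L, dim = 3L, seed = 2)
  g <- knn_graph(fx$embedding, k = 3)
  write_graph_tsv(g, file.path(dir, "g.tsv"))
  g2 <- read_graph_tsv(file.path(dir, "g.tsv"))
  expect_equal(g2$edges$i, g$edges$i)
  expect_equal(g2$edges$length, g$edges$length, tolerance = 1e-6)
  expect_equal(g2$cell_ids, g$cell_ids)
  write_embedding_csv(fx$embedding, file.path(dir, "e.csv"))
  e2 <- read_embedding_csv(file.path(dir, "e.csv"))
  expect_equal(unname(e2$coords), unname(fx$embedding$coords),
               tolerance = 1e-6)
})
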