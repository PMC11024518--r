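test_that("call_transitions flags the upper score quantile", {
  calls <- call_transitions(1:100, q = 0.1)
  expect_equal(which(calls$is_transition), 91:100)
  expect_equal(sum(call_transitions(1:100, q = 0.01)$is_transition), 1L)
  expect_error(call_transitions(1:10, q = 0), "q must be")
  expect_warning(c0 <- call_transitions(rep(2, 10), q = 0.2), "constant")
  expect_false(any(c0$is_transition))
  # invariant under strictly increasing transforms of the score
  withr::with_seed(61, s <- stats::rnorm(200))
  expect_equal(call_transitions(s, 0.15)$is_transition,
               call_transitions(exp(s), 0.15)$is_transition)
})

test_that("transition groups associate with their flanking clusters", {
  # explicit chain: cluster A (1-6), bridge1 (13-14), cluster B (7-12),
  # bridge2 (15-16), cluster C (17-22)
  ring6 <- function(off) data.frame(i = off + c(1:5, 1), j = off + c(2:6, 6))
  edges <- rbind(ring6(0), ring6(6), ring6(16),
                 data.frame(i = c(1, 13, 14, 7, 15, 16),
                            j = c(13, 14, 7, 15, 16, 17)))
  g <- cell_graph(22, edges)
  score <- rep(0, 22); score[13:16] <- 1
  calls <- call_transitions(score + seq_len(22) / 100, q = 4 / 22)
  expect_equal(which(calls$is_transition), 13:16)
  clusters <- rep(c("A", "B", "bridge", "C"), c(6, 6, 4, 6))
  res <- associate_transition_groups(calls, clusters, g)
  # two bridges -> two groups; each group's top non-self clusters are its
  # flanking clusters
  expect_equal(length(res$association), 2L)
  flanks <- lapply(res$association, function(tab)
    sort(setdiff(names(tab), "bridge")))
  expect_true(any(vapply(flanks, identical, TRUE, c("A", "B"))))
  expect_true(any(vapply(flanks, identical, TRUE, c("B", "C"))))
  # modified clustering partitions all cells exactly once
  expect_equal(length(res$modified_clustering), 22L)
  expect_true(all(grepl("^transition_", res$modified_clustering[13:16])))
  expect_equal(res$modified_clustering[-(13:16)], clusters[-(13:16)])
  # all flagged cells inside one cluster: that cluster ranks first with
  # overlap at least the group size
  withr::with_seed(66, blob <- matrix(stats::rnorm(60), 30, 2))
  g1 <- knn_graph(blob, k = 4)
  score1 <- c(rep(1, 5), rep(0, 25))
  calls1 <- call_transitions(score1 + seq(0.01, 0.3, length.out = 30),
                             q = 5 / 30)
  res1 <- associate_transition_groups(calls1, rep("X", 30), g1)
  expect_equal(names(res1$association[[1]])[1], "X")
  expect_gte(unname(res1$association[[1]][1]), sum(calls1$is_transition))
})

test_that("classification metrics implement the printed formulas", {
  y <- rep(c("a", "b", "c", "d"), each = 5)
  m <- classification_metrics(y, y)
  expect_equal(m$accuracy, 1)
  expect_equal(m$balanced_accuracy_adjusted, 1 - 1 / 4)
  expect_equal(m$balanced_accuracy_conventional, 1)
  expect_equal(m$precision_macro, 1)
  m0 <- classification_metrics(y, rep("a", 20))
  expect_equal(m0$balanced_accuracy_adjusted, 0)
  # hand-computed 3x3 confusion table:
  # truth a: 3 a, 1 b; truth b: 2 b, 2 c; truth c: 1 a, 3 c
  yt <- c(rep("a", 4), rep("b", 4), rep("c", 4))
  yp <- c("a", "a", "a", "b", "b", "b", "c", "c", "a", "c", "c", "c")
  mh <- classification_metrics(yt, yp)
  expect_equal(mh$accuracy, 8 / 12)
  rec <- c(3 / 4, 2 / 4, 3 / 4)
  expect_equal(mh$recall_macro, mean(rec))
  expect_equal(mh$balanced_accuracy_adjusted, mean(rec) - 1 / 3)
  expect_equal(mh$precision_macro, mean(c(3 / 4, 2 / 3, 3 / 5)))
  # the printed adjusted form relates to the conventional normalization
  expect_equal(mh$balanced_accuracy_adjusted,
               mh$balanced_accuracy_conventional * (1 - 1 / 3))
})

test_that("metrics agree with an independent confusion-matrix oracle", {
  oracle <- function(yt, yp) {
    cls <- sort(unique(yt))
    cm <- table(factor(yt, cls), factor(yp, union(cls, unique(yp))))
    rec <- diag(cm[, cls, drop = FALSE]) / rowSums(cm)
    colsums <- colSums(cm)[cls]
    prec <- ifelse(colsums == 0, 0, diag(cm[, cls, drop = FALSE]) / colsums)
    list(acc = sum(yt == yp) / length(yt), bal = mean(rec) - 1 / length(cls),
         prec = mean(prec), rec = mean(rec))
  }
  withr::with_seed(63, {
    for (r in 1:40) {
      C <- sample(2:5, 1)
      yt <- sample(letters[1:C], 30, replace = TRUE)
      while (length(unique(yt)) < C) yt <- sample(letters[1:C], 30, TRUE)
      yp <- sample(letters[1:C], 30, replace = TRUE)
      m <- classification_metrics(yt, yp)
      o <- oracle(yt, yp)
      expect_equal(m$accuracy, o$acc)
      expect_equal(m$balanced_accuracy_adjusted, o$bal)
      expect_equal(m$precision_macro, o$prec)
      expect_equal(m$recall_macro, o$rec)
    }
  })
})

test_that("classify_cells separates separable classes and stays at chance
           on shuffled labels", {
  withr::with_seed(64, {
    x <- rbind(matrix(stats::rnorm(200, 0), 50, 4),
               matrix(stats::rnorm(200, 6), 50, 4))
  })
  labs <- rep(c("lo", "hi"), each = 50)
  r <- classify_cells(x, labels = labs, model = "rf", seed = 1,
                      ntree = 300)
  expect_equal(r$accuracy, 1)
  rs <- classify_cells(x, labels = labs, model = "svm", seed = 1)
  expect_gt(rs$accuracy, 0.9)
  shuf <- withr::with_seed(65, sample(labs))
  r0 <- classify_cells(x, labels = shuf, model = "rf", seed = 1,
                       ntree = 300)
  expect_lt(abs(r0$balanced_accuracy_adjusted), 0.3)
  expect_error(classify_cells(x, labels = c(rep("a", 99), "b"),
                              model = "rf", seed = 1, ntree = 50),
               "absent")
})
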