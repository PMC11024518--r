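#' Flag transition cells by an upper-quantile score rule
#'
#' Cells whose score strictly exceeds the `1 - q` quantile are flagged.
#' Typical scores: local H0 total persistence (high in transition regions),
#' negated node curvature, H1 total persistence, or relative importance.
#'
#' @param score numeric per-cell score.
#' @param q upper fraction flagged (default 0.1), in (0, 1).
#' @param cell_ids optional identifiers.
#' @return an `sctopo_transitions`: list with `cell_ids`, logical
#'   `is_transition`, `score`, and `threshold`.
#' @export
call_transitions <- function(score, q = 0.1, cell_ids = NULL) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_along(score))
  if (length(unique(score)) == 1L) {
    warning("constant scores: no transition cells called")
    flag <- rep(FALSE, length(score))
    thr <- score[1]
  } else {
    thr <- stats::quantile(score, 1 - q, names = FALSE)
    flag <- score > thr
  }
  structure(list(cell_ids = as.character(cell_ids), is_transition = flag,
                 score = score, threshold = thr, q = q),
            class = "sctopo_transitions")
}

#' @export
print.sctopo_transitions <- function(x, ...) {
  cat(sprintf("TransitionCalls: %d / %d cells flagged (q = %g)\n",
              sum(x$is_transition), length(x$is_transition), x$q))
  invisible(x)
}

#' Group transition cells and associate them with clusters
#'
#' Splits flagged cells into groups by connected components of the cell
#' graph restricted to flagged cells; ranks, for each group, the original
#' clusters by overlap count with the group's neighborhood (the clusters of
#' the group's members' graph neighbors). Also returns the modified
#' clustering in which flagged cells are reassigned to their transition
#' group.
#'
#' @param calls an `sctopo_transitions`.
#' @param clusters per-cell cluster labels covering all cells.
#' @param g the `sctopo_cell_graph` over the same cells.
#' @return list with `groups` (integer per cell, `NA` if not flagged),
#'   `association` (named list: per group, a ranked table of overlapping
#'   clusters), and `modified_clustering` (character per cell).
#' @export
associate_transition_groups <- function(calls, clusters, g) {
  stopifnot(inherits(calls, "sctopo_transitions"),
            inherits(g, "sctopo_cell_graph"))
  n <- length(calls$is_transition)
  if (length(clusters) != n) stop("clusters must cover all cells")
  clusters <- as.character(clusters)
  flagged <- which(calls$is_transition)
  groups <- rep(NA_integer_, n)
  association <- list()
  if (length(flagged)) {
    ig <- as_igraph(g)
    sub <- igraph::induced_subgraph(ig, flagged)
    comp <- igraph::components(sub)$membership
    groups[flagged] <- comp
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (r in seq_len(nrow(g$edges))) {
      adj[[g$edges$i[r]]] <- c(adj[[g$edges$i[r]]], g$edges$j[r])
      adj[[g$edges$j[r]]] <- c(adj[[g$edges$j[r]]], g$edges$i[r])
    }
    for (gr in sort(unique(comp))) {
      members <- flagged[comp == gr]
      nbhd <- unique(c(members, unlist(adj[members])))
      tab <- sort(table(clusters[nbhd]), decreasing = TRUE)
      association[[as.character(gr)]] <- tab
    }
  }
  modified <- clusters
  modified[flagged] <- paste0("transition_", groups[flagged])
  list(groups = groups, association = association,
       modified_clustering = modified)
}

#' Classification metrics
#'
#' Accuracy, adjusted balanced accuracy (mean per-class recall minus `1/C`,
#' as printed; the conventional normalized form
#' `(mean recall - 1/C) / (1 - 1/C)` is also returned), macro-averaged
#' precision and macro-averaged recall. A predicted class absent from the
#' predictions contributes 0 to macro precision.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @return list with `accuracy`, `balanced_accuracy_adjusted`,
#'   `balanced_accuracy_conventional`, `precision_macro`, `recall_macro`,
#'   and `n_classes`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!length(y_true)) stop("need at least one sample")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(y_true))
  C <- length(classes)
  acc <- mean(y_pred == y_true)
  recall_c <- vapply(classes, function(cl) {
    idx <- y_true == cl
    mean(y_pred[idx] == cl)
  }, numeric(1))
  prec_c <- vapply(classes, function(cl) {
    idx <- y_pred == cl
    if (!any(idx)) 0 else mean(y_true[idx] == cl)
  }, numeric(1))
  bal <- mean(recall_c)
  list(accuracy = acc,
       balanced_accuracy_adjusted = bal - 1 / C,
       balanced_accuracy_conventional = (bal - 1 / C) / (1 - 1 / C),
       precision_macro = mean(prec_c),
       recall_macro = mean(recall_c),
       n_classes = C)
}

balanced_class_weights <- function(labels) {
  tab <- table(labels)
  w <- length(labels) / (length(tab) * as.numeric(tab))
  stats::setNames(w, names(tab))
}

#' Train and evaluate a cell-type classifier
#'
#' Fits a random forest (5000 trees) or an SVM (radial kernel, cost 0.5),
#' both with class-balanced weights, on the chosen feature block(s) and
#' reports [classification_metrics()] on the test split.
#'
#' @param gene_features cells x features matrix/data frame of expression
#'   features.
#' @param topo_features cells x features matrix/data frame of topological
#'   features (required for feature sets involving `topo`).
#' @param labels per-cell class labels.
#' @param feature_set `"gene"`, `"topo"` or `"gene+topo"`.
#' @param model `"rf"` (default) or `"svm"`.
#' @param train integer indices of training cells, or a fraction in (0, 1)
#'   drawn stratified by class (default 0.5).
#' @param seed RNG seed for the split and the forest.
#' @param ntree,cost model settings (defaults 5000 trees, SVM cost 0.5).
#' @return list: the metrics plus `model`, `feature_set`, `n_train`,
#'   `n_test`.
#' @export
classify_cells <- function(gene_features, topo_features = NULL, labels,
                           feature_set = c("gene", "topo", "gene+topo"),
                           model = c("rf", "svm"), train = 0.5, seed = 0L,
                           ntree = 5000L, cost = 0.5) {
  feature_set <- match.arg(feature_set)
  model <- match.arg(model)
  labels <- factor(labels)
  X <- switch(feature_set,
    gene = as.matrix(gene_features),
    topo = { stopifnot(!is.null(topo_features)); as.matrix(topo_features) },
    `gene+topo` = {
      stopifnot(!is.null(topo_features))
      cbind(as.matrix(gene_features), as.matrix(topo_features))
    })
  colnames(X) <- make.names(colnames(X), unique = TRUE)
  n <- nrow(X)
  if (length(labels) != n) stop("labels must match feature rows")
  if (length(train) == 1L && train > 0 && train < 1) {
    train_idx <- withr::with_seed(seed, {
      unlist(lapply(levels(labels), function(cl) {
        idx <- which(labels == cl)
        sample(idx, max(1L, round(train * length(idx))))
      }))
    })
  } else {
    train_idx <- as.integer(train)
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  ytr <- droplevels(labels[train_idx])
  if (nlevels(ytr) < nlevels(labels))
    stop("a class is absent from the training split")
  w <- balanced_class_weights(ytr)
  fit <- if (model == "rf") {
    withr::with_seed(seed, randomForest::randomForest(
      x = X[train_idx, , drop = FALSE], y = ytr,
      ntree = ntree, classwt = w))
  } else {
    e1071::svm(x = X[train_idx, , drop = FALSE], y = ytr,
               kernel = "radial", cost = cost, class.weights = w,
               scale = apply(X[train_idx, , drop = FALSE], 2, var) > 0)
  }
  pred <- stats::predict(fit, X[test_idx, , drop = FALSE])
  mets <- classification_metrics(as.character(labels[test_idx]),
                                 as.character(pred))
  c(mets, list(model = model, feature_set = feature_set,
               n_train = length(train_idx), n_test = length(test_idx)))
}
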