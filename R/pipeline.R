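run_config_defaults <- function() {
  list(
    counts = NULL, format = "auto", clusters = NULL, network = NULL,
    out_dir = "sctopo_out",
    target_sum = 1e4, n_hvg = 1000L, n_comps = 30L, k = 15L,
    metric = "euclidean",
    alpha = 0.5, ground = "hop",
    k_local = 30L, l_size = 10L, max_dim = 1L, q_wasserstein = 1,
    with_relative = FALSE,
    box_fraction = 0.1, sig_level = 0.01, n_perm = 1000L,
    transition_score = "h0_total", transition_q = 0.1,
    seed = 0L)
}

#' Build a run configuration
#'
#' All pipeline parameters with their defaults (center mass `alpha` 0.5,
#' `k` 15 neighbors, 30 components, 1000 highly variable genes, CSN box
#' fraction 0.1 at level 0.01, local neighborhood 30, relative subcomplex
#' 10, homology up to dimension 1). Unknown keys are rejected.
#'
#' @param ... overrides of the default keys.
#' @return a named list of class `sctopo_config`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "sctopo_config")
}

#' Read / write a YAML run configuration
#'
#' @param path YAML file with a subset of the keys of [run_config()];
#'   unknown keys are rejected.
#' @return an `sctopo_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param config an `sctopo_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on the configured
#' inputs, writing per-stage artifacts and a JSON manifest (config echo,
#' config hash, package version, per-stage timings) into `config$out_dir`.
#'
#' Stages: `preprocess` (normalize, HVG, PCA, kNN graph -> embedding.csv,
#' graph.tsv), `curvature` (-> curvature.csv, edge_curvature.csv),
#' `cell_topology` (-> cell_features.csv), `transitions` (requires
#' cell_topology; -> calls.csv).
#'
#' @param config an `sctopo_config`.
#' @param stages character subset of the stages above (default all).
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("preprocess", "curvature",
                                    "cell_topology", "transitions")) {
  stopifnot(inherits(config, "sctopo_config"))
  known <- c("preprocess", "curvature", "cell_topology", "transitions")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  artifacts <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[sctopo] stage %s done in %.2fs", stage,
                    timings[[stage]]))
    res
  }
  emb <- NULL; graph <- NULL; feats <- NULL
  need <- function(stage, artifact, value) {
    if (is.null(value))
      stop("stage '", stage, "' needs the output of stage '", artifact,
           "'; include it in `stages` or provide its files")
    value
  }
  if ("preprocess" %in% stages) {
    emb_graph <- tick("preprocess", {
      if (is.null(config$counts)) stop("config$counts is required")
      x <- read_counts(config$counts, config$format)
      xl <- normalize_log1p(x, config$target_sum)
      hvg <- select_hvg(xl, min(config$n_hvg, length(xl$gene_ids)))
      e <- pca_embed(xl, min(config$n_comps, length(hvg),
                             length(xl$cell_ids) - 1L), gene_subset = hvg)
      g <- knn_graph(e, config$k, config$metric)
      write_embedding_csv(e, file.path(config$out_dir, "embedding.csv"))
      write_graph_tsv(g, file.path(config$out_dir, "graph.tsv"))
      list(e = e, g = g)
    })
    emb <- emb_graph$e; graph <- emb_graph$g
    artifacts$embedding <- "embedding.csv"; artifacts$graph <- "graph.tsv"
  } else {
    ep <- file.path(config$out_dir, "embedding.csv")
    gp <- file.path(config$out_dir, "graph.tsv")
    if (file.exists(ep)) emb <- read_embedding_csv(ep)
    if (file.exists(gp)) graph <- read_graph_tsv(gp)
  }
  if ("curvature" %in% stages) {
    tick("curvature", {
      g <- need("curvature", "preprocess", graph)
      res <- orc_all(g, alpha = config$alpha, ground = config$ground)
      utils::write.csv(data.frame(cell_id = g$cell_ids,
                                  node_curvature = res$node_curvature),
                       file.path(config$out_dir, "curvature.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(res$edge_curvature,
                       file.path(config$out_dir, "edge_curvature.csv"),
                       row.names = FALSE, quote = FALSE)
    })
    artifacts$curvature <- "curvature.csv"
  }
  if ("cell_topology" %in% stages) {
    feats <- tick("cell_topology", {
      e <- need("cell_topology", "preprocess", emb)
      f <- cell_features_table(e, k_local = config$k_local,
                               max_dim = config$max_dim,
                               with_relative = isTRUE(config$with_relative),
                               l_size = config$l_size,
                               q = config$q_wasserstein)
      utils::write.csv(f, file.path(config$out_dir, "cell_features.csv"),
                       row.names = FALSE, quote = FALSE)
      f
    })
    artifacts$cell_features <- "cell_features.csv"
  } else {
    fp <- file.path(config$out_dir, "cell_features.csv")
    if (file.exists(fp)) feats <- utils::read.csv(fp)
  }
  if ("transitions" %in% stages) {
    tick("transitions", {
      f <- need("transitions", "cell_topology", feats)
      score <- f[[config$transition_score]]
      if (is.null(score))
        stop("transition score column not found: ", config$transition_score)
      calls <- call_transitions(score, q = config$transition_q,
                                cell_ids = f$cell_id)
      out <- data.frame(cell_id = calls$cell_ids,
                        score = calls$score,
                        is_transition = calls$is_transition)
      if (!is.null(graph) && !is.null(config$clusters)) {
        cl <- utils::read.csv(config$clusters, stringsAsFactors = FALSE)
        assoc <- associate_transition_groups(
          calls, cl[[2L]][match(calls$cell_ids, cl[[1L]])], graph)
        out$group <- assoc$groups
        out$modified_cluster <- assoc$modified_clustering
      }
      utils::write.csv(out, file.path(config$out_dir, "calls.csv"),
                       row.names = FALSE, quote = FALSE)
    })
    artifacts$calls <- "calls.csv"
  }
  manifest <- list(package = "sctopo",
                   version = as.character(utils::packageVersion("sctopo")),
                   config = unclass(config),
                   config_hash = config_hash(config),
                   stages = stages, timings = timings,
                   artifacts = artifacts)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(config$out_dir, "manifest.json"))
  invisible(config$out_dir)
}
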