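#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_all()]: input location/format,
#' preprocessing switches, geometry parameters, autoencoder / classifier /
#' explainer configurations, the graph size `k` and the explanation size
#' `n_top`. The global `seed` is propagated to every stage configuration
#' that does not set its own.
#'
#' @param input a [count_matrix()], an MTX directory or a dense-matrix file
#'   path (see `format`).
#' @param format `"object"`, `"mtx"` or `"dense"`.
#' @param modality assay modality for file inputs.
#' @param out_dir output directory (created when missing).
#' @param do_qc apply the quantile QC stage.
#' @param select_features apply HVG / HV-peak selection.
#' @param target_sum library-size target, see [normalize_library_size()].
#' @param n_top explanation / differential set size (default 50).
#' @param k graph neighbourhood size (default 15).
#' @param seed global seed.
#' @param train a [train_config()].
#' @param gat a [gat_config()].
#' @param explainer an [explainer_config()].
#' @param geometry named list of [phate_embed()] arguments.
#' @param max_nodes_per_class explainer subsampling cap.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, format = c("object", "mtx", "dense"),
                            modality = "GEX", out_dir = tempfile("gm_run_"),
                            do_qc = TRUE, select_features = TRUE,
                            target_sum = "median", n_top = 50, k = 15,
                            seed = 1L,
                            train = NULL, gat = NULL, explainer = NULL,
                            geometry = list(), max_nodes_per_class = 50) {
  format <- match.arg(format)
  if (format != "object")
    .assert(file.exists(input), "input path '%s' does not exist", input)
  structure(list(input = input, format = format, modality = modality,
                 out_dir = out_dir, do_qc = do_qc,
                 select_features = select_features, target_sum = target_sum,
                 n_top = n_top, k = as.integer(k), seed = as.integer(seed),
                 train = train %||% train_config(seed = seed),
                 gat = gat %||% gat_config(seed = seed),
                 explainer = explainer %||% explainer_config(seed = seed),
                 geometry = geometry,
                 max_nodes_per_class = max_nodes_per_class),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' File-based configurations round-trip exactly (in-memory `input` objects
#' cannot be serialised and are rejected).
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return the configuration (read) or `path`, invisibly (write).
#' @export
write_pipeline_config <- function(cfg, path) {
  .assert(cfg$format != "object",
          "only file-based configurations can be serialised")
  lst <- unclass(cfg)
  lst$train <- unclass(lst$train)
  lst$gat <- c(unclass(lst$gat)[setdiff(names(lst$gat), "split")],
               list(split = as.list(lst$gat$split)))
  lst$explainer <- unclass(lst$explainer)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  pipeline_config(
    input = lst$input, format = lst$format, modality = lst$modality,
    out_dir = lst$out_dir, do_qc = lst$do_qc,
    select_features = lst$select_features, target_sum = lst$target_sum,
    n_top = lst$n_top, k = lst$k, seed = lst$seed,
    train = do.call(train_config, lst$train),
    gat = do.call(gat_config, c(lst$gat[setdiff(names(lst$gat), "split")],
                                list(split = unlist(lst$gat$split)))),
    explainer = do.call(explainer_config, lst$explainer),
    geometry = lst$geometry %||% list(),
    max_nodes_per_class = lst$max_nodes_per_class)
}

.load_input <- function(cfg) {
  switch(cfg$format,
         object = { stopifnot(inherits(cfg$input, "count_matrix")); cfg$input },
         mtx = read_mtx_dir(cfg$input, modality = cfg$modality),
         dense = read_dense_matrix(cfg$input, modality = cfg$modality))
}

#' Run the full pipeline
#'
#' Executes the four stages in order — preprocess, geometry + autoencoder
#' embedding, graph construction, classification + explanation — followed
#' by the evaluation metrics, writing every stage's outputs (processed
#' matrix, embedding coordinates, latent matrix, edge list, classification
#' report, per-class explanations, metrics report) under `cfg$out_dir`
#' together with a run manifest. Identical configurations reproduce
#' identical results.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list `(manifest, results)`; `results` holds the
#'   in-memory stage objects (`processed`, `geometry`, `grae`, `graph`,
#'   `classifier`, `report`, `explanations`, `da`, `metrics`).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("graphmarkers")),
                   seed = cfg$seed, stages = list(), outputs = character())
  results <- list()
  t_all <- proc.time()[3]
  run_stage <- function(name, fn) {
    t0 <- proc.time()[3]
    out <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      .write_json(manifest, file.path(cfg$out_dir, "manifest.json"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(proc.time()[3] - t0, 2))
    out
  }
  add_output <- function(path) manifest$outputs <<- c(manifest$outputs, path)

  results$processed <- run_stage("preprocess", function() {
    m <- .load_input(cfg)
    if (cfg$do_qc) {
      flt <- if (m$modality == "GEX") qc_filter_gex(m) else qc_filter_peaks(m)
      m <- flt$matrix
      write_qc_report(flt$report, file.path(cfg$out_dir, "qc_report.json"))
      add_output("qc_report.json")
    }
    m <- normalize_library_size(m, cfg$target_sum)
    if (cfg$select_features) {
      m <- if (m$modality == "GEX") select_hvg_gex(m) else select_hv_peaks(m)
    }
    m <- log_transform(m)
    write_dense_matrix(m, file.path(cfg$out_dir, "processed_matrix.tsv"))
    add_output("processed_matrix.tsv")
    m
  })

  results$geometry <- run_stage("geometry", function() {
    args <- c(list(m = results$processed), cfg$geometry)
    if (is.null(args$seed)) args$seed <- cfg$seed
    xi <- do.call(phate_embed, args)
    write_embedding_tsv(xi, file.path(cfg$out_dir, "geometry_embedding.tsv"))
    add_output("geometry_embedding.tsv")
    xi
  })

  results$grae <- run_stage("embed", function() {
    fit <- train_grae(results$processed, results$geometry, cfg$train)
    write_latent_tsv(fit, file.path(cfg$out_dir, "latent.tsv"))
    add_output("latent.tsv")
    fit
  })

  results$graph <- run_stage("graph", function() {
    g <- knn_graph(results$grae, k = cfg$k, source = "GRAE")
    write_edges_tsv(g, file.path(cfg$out_dir, "edges.tsv"))
    add_output("edges.tsv")
    g
  })

  cls <- run_stage("classify", function() {
    .assert(!is.null(results$processed$labels),
            "cell labels are required for the classifier stage")
    out <- train_classifier(results$graph, results$processed, cfg$gat, "GAT")
    write_classification_report(out$report,
                                file.path(cfg$out_dir, "classification_report.json"))
    write_predictions_tsv(out$model, results$processed,
                          file.path(cfg$out_dir, "predictions.tsv"),
                          report = out$report,
                          cell_ids = results$processed$cell_ids)
    add_output("classification_report.json"); add_output("predictions.tsv")
    out
  })
  results$classifier <- cls$model
  results$report <- cls$report

  results$explanations <- run_stage("explain", function() {
    ex <- explain_class(results$classifier, results$graph,
                        results$processed, results$processed$labels,
                        cfg$explainer, n_top = cfg$n_top,
                        max_nodes_per_class = cfg$max_nodes_per_class)
    write_class_explanations(ex, file.path(cfg$out_dir, "explanations"),
                             cfg$explainer)
    add_output("explanations/")
    ex
  })

  results$metrics <- run_stage("evaluate", function() {
    m <- results$processed
    ex <- results$explanations
    met <- list(homogeneity = homogeneity(results$graph, m$labels),
                accuracy = results$report$accuracy,
                macro_f1 = results$report$f1,
                specificity = if (length(ex) >= 2) specificity(ex, cfg$n_top) else NA)
    if (nlevels(m$labels) >= 2 && min(table(m$labels)) >= 2) {
      results$da <<- wilcoxon_da(m, cfg$n_top)
      met$xai_da_similarity <- mean(vapply(names(ex), function(cl)
        xai_da_similarity(top_features(ex[[cl]], cfg$n_top),
                          results$da$top[[cl]], cfg$n_top), numeric(1)))
    }
    .write_json(met, file.path(cfg$out_dir, "metrics.json"))
    long <- data.frame(metric = names(met), value = unlist(met),
                       context = "run_all")
    utils::write.table(long, file.path(cfg$out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_output("metrics.json"); add_output("metrics.tsv")
    met
  })

  manifest$total_seconds <- round(proc.time()[3] - t_all, 2)
  manifest$config <- list(format = cfg$format, modality = cfg$modality,
                          n_top = cfg$n_top, k = cfg$k, seed = cfg$seed,
                          do_qc = cfg$do_qc, select_features = cfg$select_features)
  .write_json(manifest, file.path(cfg$out_dir, "manifest.json"))
  invisible(list(manifest = manifest, results = results))
}

.fit_embedder <- function(kind, m, cfg_train, geometry = list(), seed = 1L) {
  cfg <- train_config(lambda_geo = cfg_train$lambda_geo, lr = cfg_train$lr,
                      weight_decay = cfg_train$weight_decay,
                      max_epochs = cfg_train$max_epochs,
                      patience = cfg_train$patience,
                      val_frac = cfg_train$val_frac, seed = seed,
                      input_dropout = cfg_train$input_dropout)
  switch(kind,
         GRAE = {
           args <- c(list(m = m), geometry)
           if (is.null(args$seed)) args$seed <- seed
           train_grae(m, do.call(phate_embed, args), cfg)
         },
         AE = train_ae(m, cfg),
         VAE = train_vae(m, cfg),
         PCA = pca_embed(m),
         stop("unknown embedder: ", kind))
}

#' Ablation harness: embedders x architectures x corruption levels
#'
#' Replicates the evaluation battery on one matrix: for every embedder and
#' dropout level and repeat, corrupts the matrix (seeded, the dropped
#' features varying with the repeat), trains the embedder on the corrupted
#' data and scores the reconstruction against the original (MSE, top-1%
#' covered MSE on both bases, NB loss, Spearman); for every embedder, the
#' homogeneity of its uncorrupted-latent k-NN graph; and, when `arches` is
#' non-empty and labels exist, classification reports plus explanation
#' specificity per embedder/architecture and stability across repeats.
#'
#' Aggregated means carry `3 * standard error` as their uncertainty.
#'
#' @param m a processed, labelled [count_matrix()].
#' @param embedders subset of `c("GRAE", "AE", "VAE", "PCA")`.
#' @param arches subset of `c("GAT", "GCN")` (empty vector skips the
#'   classification block).
#' @param dropout_levels corruption fractions (e.g. `seq(0.1, 0.5, 0.1)`).
#' @param n_repeats repeats per combination (seeds vary per repeat).
#' @param k graph neighbourhood size.
#' @param train,gat,explainer stage configurations (templates; seeds are
#'   derived per repeat).
#' @param geometry [phate_embed()] argument list for the GRAE.
#' @param n_top explanation set size.
#' @param explain_nodes_per_class explainer subsampling cap in the
#'   stability/specificity block.
#' @param seed base seed.
#' @return an object of class `ablation_result`: `raw` (long data.frame:
#'   embedder, arch, dropout, repeat, metric, value) and `summary` (means
#'   with `uncertainty = 3 * se` over repeats).
#' @export
run_ablation <- function(m, embedders = c("GRAE", "AE", "VAE", "PCA"),
                         arches = c("GAT", "GCN"),
                         dropout_levels = seq(0.1, 0.5, 0.1),
                         n_repeats = 5, k = 15,
                         train = train_config(), gat = gat_config(),
                         explainer = explainer_config(),
                         geometry = list(), n_top = 50,
                         explain_nodes_per_class = 10, seed = 1L) {
  stopifnot(inherits(m, "count_matrix"))
  .assert(length(embedders) > 0, "embedders must be non-empty")
  rows <- list()
  add <- function(embedder, arch, dropout, rep, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      embedder = embedder, arch = arch, dropout = dropout, rep = rep,
      metric = metric, value = value, stringsAsFactors = FALSE)
  }
  X0 <- m$counts

  # reconstruction under corruption
  for (emb in embedders) {
    for (li in seq_along(dropout_levels)) {
      frac <- dropout_levels[li]
      for (r in seq_len(n_repeats)) {
        sd_r <- seed + 1009L * li + 97L * r
        crp <- corrupt_dropout(m, frac, seed = sd_r)
        fit <- .fit_embedder(emb, crp$matrix, train, geometry, seed = sd_r)
        Xhat <- reconstruct(fit, crp$matrix)
        add(emb, NA, frac, r, "mse", mse(X0, Xhat))
        add(emb, NA, frac, r, "mse1obs", mse_top_covered(X0, Xhat, "observed"))
        add(emb, NA, frac, r, "mse1imp", mse_top_covered(X0, Xhat, "imputed"))
        add(emb, NA, frac, r, "nb_loss", nb_loss(X0, pmax(Xhat, 0)))
        sp <- tryCatch(spearman(X0, Xhat), error = function(e) NA_real_)
        add(emb, NA, frac, r, "spearman", sp)
      }
    }
  }

  # homogeneity of the uncorrupted latent graph
  if (!is.null(m$labels)) {
    for (emb in embedders) {
      for (r in seq_len(n_repeats)) {
        sd_r <- seed + 7919L * r
        fit <- .fit_embedder(emb, m, train, geometry, seed = sd_r)
        g <- knn_graph(fit, k = k, source = emb)
        add(emb, NA, NA, r, "homogeneity", homogeneity(g, m$labels))
      }
    }
  }

  # classification + explanations
  if (length(arches) > 0 && !is.null(m$labels)) {
    for (emb in embedders) {
      for (arch in arches) {
        run_sets <- list()
        for (r in seq_len(n_repeats)) {
          sd_r <- seed + 104729L * r
          fit <- .fit_embedder(emb, m, train, geometry, seed = sd_r)
          g <- knn_graph(fit, k = k, source = emb)
          gcfg <- gat_config(hidden_dim = gat$hidden_dim, n_heads = gat$n_heads,
                             lr = gat$lr, weight_decay = gat$weight_decay,
                             max_epochs = gat$max_epochs, patience = gat$patience,
                             split = gat$split, seed = sd_r,
                             dropout = gat$dropout, leaky_slope = gat$leaky_slope)
          cls <- train_classifier(g, m, gcfg, arch)
          add(emb, arch, NA, r, "accuracy", cls$report$accuracy)
          add(emb, arch, NA, r, "f1", cls$report$f1)
          add(emb, arch, NA, r, "precision", cls$report$precision)
          add(emb, arch, NA, r, "recall", cls$report$recall)
          if (arch == "GAT") {
            ecfg <- explainer_config(epochs = explainer$epochs, lr = explainer$lr,
                                     feat_size_weight = explainer$feat_size_weight,
                                     feat_entropy_weight = explainer$feat_entropy_weight,
                                     edge_size_weight = explainer$edge_size_weight,
                                     edge_entropy_weight = explainer$edge_entropy_weight,
                                     seed = sd_r)
            ex <- explain_class(cls$model, g, m, m$labels, ecfg, n_top = n_top,
                                max_nodes_per_class = explain_nodes_per_class)
            run_sets[[r]] <- lapply(ex, top_features, n = n_top)
            add(emb, arch, NA, r, "explainer_specificity", specificity(ex, n_top))
          }
        }
        if (length(run_sets) >= 2)
          add(emb, arch, NA, NA, "explainer_stability", stability(run_sets, n_top))
      }
    }
  }

  raw <- do.call(rbind, rows)
  grp <- paste(raw$embedder, raw$arch, raw$dropout, raw$metric, sep = "|")
  summary <- do.call(rbind, lapply(split(raw, grp), function(d) {
    v <- d$value[!is.na(d$value)]
    data.frame(embedder = d$embedder[1], arch = d$arch[1], dropout = d$dropout[1],
               metric = d$metric[1], mean = mean(v),
               uncertainty = if (length(v) > 1) 3 * stats::sd(v) / sqrt(length(v)) else 0,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(raw = raw, summary = summary), class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf("<ablation_result> %d measurements, %d aggregated rows\n",
              nrow(x$raw), nrow(x$summary)))
  invisible(x)
}

#' Write ablation results as a long-format TSV
#' @param res an `ablation_result`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_ablation_tsv <- function(res, path) {
  utils::write.table(res$summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
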