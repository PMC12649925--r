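# Configuration, validation and the end-to-end pipeline runner tying
# the stages together: differential screens, temporal clustering, and
# hierarchical network inference, with a machine-readable manifest and
# an audit log of every threshold applied.

#' Assemble a pipeline configuration
#'
#' @param expression,metadata Paths to the expression TSV (log-scale
#'   abundances, features x samples) and its sample metadata CSV.
#' @param counts Optional counts TSV sharing `metadata`; when given, a
#'   per-timepoint differential-expression screen against the earliest
#'   timepoint is run.
#' @param metabolome,metab_metadata,metab_classes Paths to the
#'   metabolite intensity TSV, its metadata CSV (with `is_qc`), and an
#'   optional class CSV.
#' @param tf_list,pathway_genes Paths to plain-text id lists.
#' @param lfc_min,alpha,vip_min,fc_up,fc_down,cv_max,r_min Screening
#'   thresholds (defaults: |log2FC| >= 1 with FDR < 0.05 for genes;
#'   VIP > 1 with FC >= 2 or <= 0.5 for metabolites; QC CV < 0.5;
#'   |r| >= 0.8 for gene-metabolite links).
#' @param k_impute,k_clusters,restarts,n_trees,drop_fraction,n_layers,edges_per_target,max_layer_size
#'   Algorithm parameters (see the stage functions).
#' @param seed Integer seed driving every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, metadata,
                            metabolome, metab_metadata,
                            tf_list, pathway_genes,
                            counts = NULL, metab_classes = NULL,
                            lfc_min = 1, alpha = 0.05, vip_min = 1,
                            fc_up = 2, fc_down = 0.5, cv_max = 0.5,
                            r_min = 0.8,
                            k_impute = 10L, k_clusters = 8L,
                            restarts = 50L, n_trees = 1000L,
                            drop_fraction = 0.1, n_layers = 2L,
                            edges_per_target = 3L, max_layer_size = NULL,
                            seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config` list.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Validate pipeline inputs
#'
#' Report-only checks: referenced files exist, feature ids are unique,
#' sample metadata covers every matrix column, values are non-negative,
#' and at least 3 QC injections are present.
#'
#' @param config A [pipeline_config()].
#' @return Data frame with `severity` (`"error"`/`"warning"`) and
#'   `message`; zero rows when everything is clean.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- list()
  note <- function(severity, msg) {
    bad[[length(bad) + 1L]] <<- data.frame(severity = severity, message = msg,
                                           stringsAsFactors = FALSE)
  }
  required <- c("expression", "metadata", "metabolome", "metab_metadata",
                "tf_list", "pathway_genes")
  for (key in required) {
    p <- config[[key]]
    if (is.null(p) || !file.exists(p)) {
      note("error", sprintf("missing input file `%s`: %s", key,
                            if (is.null(p)) "(not set)" else p))
    }
  }
  if (length(bad)) return(do.call(rbind, bad))

  check_matrix <- function(path, meta_path, label) {
    mat <- read_matrix_tsv(path)
    if (anyDuplicated(rownames(mat))) {
      dup <- rownames(mat)[duplicated(rownames(mat))]
      note("error", sprintf("%s: duplicated feature id(s): %s", label,
                            paste(unique(dup), collapse = ", ")))
    }
    neg <- which(mat < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      note("error", sprintf("%s: negative value at [%s, %s]", label,
                            rownames(mat)[neg[1, 1]], colnames(mat)[neg[1, 2]]))
    }
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    uncovered <- setdiff(colnames(mat), meta$sample_id)
    if (length(uncovered)) {
      note("error", sprintf("%s: metadata missing sample(s): %s", label,
                            paste(uncovered, collapse = ", ")))
    }
    meta
  }
  check_matrix(config$expression, config$metadata, "expression")
  mmeta <- check_matrix(config$metabolome, config$metab_metadata, "metabolome")
  if (!is.null(mmeta$is_qc) && sum(as.logical(mmeta$is_qc)) < 3) {
    note("warning", "metabolome: fewer than 3 QC samples")
  }
  if (length(bad)) do.call(rbind, bad) else {
    data.frame(severity = character(), message = character(),
               stringsAsFactors = FALSE)
  }
}

#' Run the full drought multi-omics pipeline
#'
#' Executes the differential screens, temporal clustering, and
#' hierarchical GRN stages in order, writing per-stage TSV/SIF/GraphML
#' artifacts, a JSON run manifest and a plain-text log into `out_dir`.
#' Re-running with the same configuration reproduces byte-identical
#' tables.  On a stage failure, partial outputs are moved under
#' `out_dir/failed/` and the error names the stage.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; must not already contain a
#'   manifest).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- validate_inputs(config)
  if (any(report$severity == "error")) {
    stop("input validation failed:\n  ",
         paste(report$message[report$severity == "error"], collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    writeLines(log_lines, log_path)
  }
  manifest <- list(
    inputs = config[c("expression", "metadata", "counts", "metabolome",
                      "metab_metadata", "metab_classes", "tf_list",
                      "pathway_genes")],
    parameters = config[c("lfc_min", "alpha", "vip_min", "fc_up", "fc_down",
                          "cv_max", "r_min", "k_impute", "k_clusters",
                          "restarts", "n_trees", "drop_fraction", "n_layers",
                          "edges_per_target", "max_layer_size")],
    seed = config$seed,
    stages = list(),
    outputs = character()
  )
  current_stage <- "setup"
  run_stage <- function(name, fun) {
    current_stage <<- name
    say(sprintf("[stage %s] start", name))
    fun()
    manifest$stages[[name]] <<- "ok"
    say(sprintf("[stage %s] done", name))
  }

  result <- tryCatch({
    expr <- read_expression(config$expression, config$metadata, unit = "log2au")
    metab <- read_metabolome(config$metabolome, config$metab_metadata,
                             config$metab_classes)
    tfs <- read_id_list(config$tf_list)
    pathway <- read_id_list(config$pathway_genes)
    metab_imp <- NULL
    dam_ids <- character()

    run_stage("screen", function() {
      say(sprintf("thresholds: |log2FC| >= %g with FDR < %g (genes); ",
                  config$lfc_min, config$alpha),
          sprintf("VIP > %g with FC >= %g or <= %g, QC CV < %g (metabolites)",
                  config$vip_min, config$fc_up, config$fc_down, config$cv_max))
      if (!is.null(config$counts)) {
        counts <- read_matrix_tsv(config$counts)
        meta <- expr$samples
        tps <- sort(unique(meta$timepoint))
        ref <- meta$sample_id[meta$timepoint == tps[1]]
        deg_sets <- list()
        for (tp in tps[-1]) {
          trt <- meta$sample_id[meta$timepoint == tp]
          res <- screen_degs(nb_wald_test(counts, ref, trt),
                             lfc_min = config$lfc_min, alpha = config$alpha)
          f <- file.path(out_dir, sprintf("deg_t%s.tsv", tp))
          utils::write.table(res, f, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          manifest$outputs <<- c(manifest$outputs, f)
          deg_sets[[paste0("t", tp)]] <-
            res$feature_id[res$status != "ns"]
          say(sprintf("DEGs at t=%s: %d", tp, sum(res$status != "ns")))
        }
        if (length(deg_sets) >= 2) {
          sets <- shared_exclusive_sets(deg_sets)
          write_id_list(sets$shared, file.path(out_dir, "deg_shared.txt"))
          manifest$outputs <<- c(manifest$outputs,
                                 file.path(out_dir, "deg_shared.txt"))
          say(sprintf("shared DEGs across contrasts: %d", length(sets$shared)))
        }
      }
      metab_imp <<- knn_impute(metab, k = config$k_impute)
      groups <- setdiff(unique(metab$samples$group[!metab$samples$is_qc]),
                        "control")
      dam_union <- character()
      for (g in groups) {
        scr <- screen_metabolome(metab, "control", g,
                                 k_impute = config$k_impute,
                                 cv_max = config$cv_max,
                                 vip_min = config$vip_min,
                                 fc_up = config$fc_up,
                                 fc_down = config$fc_down)
        f <- file.path(out_dir, sprintf("dam_%s.tsv", g))
        utils::write.table(scr$table, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        manifest$outputs <<- c(manifest$outputs, f)
        dam_union <- union(dam_union,
                           scr$table$metabolite_id[scr$table$status != "ns"])
        say(sprintf("DAMs control vs %s: %d (dropped by QC CV: %d)",
                    g, sum(scr$table$status != "ns"),
                    length(scr$dropped_ids)))
      }
      dam_ids <<- dam_union
      write_id_list(dam_union, file.path(out_dir, "dam_union.txt"))
      manifest$outputs <<- c(manifest$outputs,
                             file.path(out_dir, "dam_union.txt"))
    })

    run_stage("cluster", function() {
      prof <- profile_matrix(metab_imp)
      k <- min(config$k_clusters, nrow(prof))
      cl <- kmeans_cluster(prof, k = k, restarts = config$restarts,
                           seed = config$seed)
      utils::write.table(
        data.frame(metabolite_id = names(cl$assignments),
                   cluster = unname(cl$assignments)),
        file.path(out_dir, "clusters.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(cluster = seq_len(cl$k), cl$centroids,
                   check.names = FALSE),
        file.path(out_dir, "cluster_centroids.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$outputs <<- c(manifest$outputs,
                             file.path(out_dir, "clusters.tsv"),
                             file.path(out_dir, "cluster_centroids.tsv"))
      say(sprintf("clustered %d profiles into %d clusters (inertia %.4f)",
                  length(cl$assignments), cl$k, cl$inertia))
    })

    run_stage("grn", function() {
      net <- build_hierarchy(expr, tfs, pathway,
                             n_layers = config$n_layers,
                             drop_fraction = config$drop_fraction,
                             n_trees = config$n_trees,
                             edges_per_target = config$edges_per_target,
                             max_layer_size = config$max_layer_size,
                             seed = config$seed)
      pg_expr <- expr
      pg_expr$values <- expr$values[pathway, , drop = FALSE]
      metab_link <- metab_imp
      if (length(dam_ids) >= 1) {
        metab_link$intensities <-
          metab_imp$intensities[rownames(metab_imp$intensities) %in% dam_ids, ,
                                drop = FALSE]
      }
      links <- tryCatch(
        link_metabolites(pg_expr, metab_link, r_min = config$r_min,
                         alpha = config$alpha),
        error = function(e) {
          say("gene-metabolite linking skipped: ", conditionMessage(e))
          NULL
        })
      if (!is.null(links)) net <- add_metabolite_edges(net, links)
      say(sprintf("gene-metabolite links at |r| >= %g, FDR < %g: %d",
                  config$r_min, config$alpha,
                  nrow(net$gene_metabolite_edges)))
      write_sif(net, file.path(out_dir, "network.sif"))
      write_graphml(net, file.path(out_dir, "network.graphml"))
      utils::write.table(node_attributes(net),
                         file.path(out_dir, "node_attributes.csv"),
                         sep = ",", quote = FALSE, row.names = FALSE)
      manifest$outputs <<- c(manifest$outputs,
                             file.path(out_dir, "network.sif"),
                             file.path(out_dir, "network.graphml"),
                             file.path(out_dir, "node_attributes.csv"))
      s <- network_summary(net)
      say(sprintf("network: %s TFs per layer, %d TF edges",
                  paste(s$tfs_per_layer, collapse = "/"), s$n_tf_edges))
    })

    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest
  }, error = function(e) {
    failed <- file.path(out_dir, "failed")
    dir.create(failed, showWarnings = FALSE)
    arts <- setdiff(list.files(out_dir, full.names = TRUE), failed)
    file.copy(arts, failed, overwrite = TRUE)
    file.remove(arts[!dir.exists(arts)])
    stop(sprintf("pipeline stage `%s` failed: %s", current_stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
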