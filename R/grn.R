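# Bottom-up weighted random-forest (BWERF) construction of a
# multi-layer hierarchical gene regulatory network: recursive
# random-forest importance ranking with iterative elimination of the
# least important TFs, Gaussian-mixture selection of each regulatory
# layer, and correlation-based gene-metabolite linking.

#' Random-forest importance of candidate regulators for one target
#'
#' Regresses the target profile on the TF profiles with a random forest
#' and returns impurity-decrease importances normalised to sum to 1.
#' TFs are ordered canonically (by id) before fitting, so the result is
#' invariant to the input column order.
#'
#' @param target_profile Numeric vector, expression of the target across
#'   samples (>= 6).
#' @param tf_profiles Numeric matrix, TFs in rows (>= 2), samples in
#'   columns matching `target_profile`.
#' @param n_trees Number of trees (default 1000).
#' @param seed Integer seed; fixed seed gives identical importances.
#' @param mode `"impurity"` (default) or `"permutation"` importance;
#'   permutation importance is slower but less biased when TFs are
#'   strongly correlated.
#' @return Named non-negative vector over TFs summing to 1.
#' @export
rf_importance <- function(target_profile, tf_profiles, n_trees = 1000L,
                          seed = 1L, mode = c("impurity", "permutation")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(tf_profiles))
  if (nrow(tf_profiles) < 2) stop("need at least 2 TFs", call. = FALSE)
  if (length(target_profile) < 6) stop("need at least 6 samples", call. = FALSE)
  if (length(target_profile) != ncol(tf_profiles)) {
    stop("sample dimensions of target and TF profiles differ", call. = FALSE)
  }
  tf_ids <- rownames(tf_profiles) %||% sprintf("tf%03d", seq_len(nrow(tf_profiles)))
  ord <- order(tf_ids)
  if (stats::sd(target_profile) < 1e-12) {
    warning("constant target profile; returning uniform importances")
    return(stats::setNames(rep(1 / length(tf_ids), length(tf_ids)), tf_ids))
  }
  x <- as.data.frame(t(tf_profiles[ord, , drop = FALSE]))
  names(x) <- tf_ids[ord]
  fit <- ranger::ranger(
    x = x, y = target_profile,
    num.trees = n_trees,
    mtry = ceiling(sqrt(ncol(x))),
    importance = mode,
    seed = as.integer(seed),
    num.threads = 1L
  )
  imp <- pmax(fit$variable.importance, 0)
  tot <- sum(imp)
  imp <- if (tot > 0) imp / tot else rep(1 / length(imp), length(imp))
  imp[tf_ids]
}

#' Recursive random-forest importance ranking with elimination (BWERF)
#'
#' For every pathway gene, the surviving candidate TFs are re-scored by
#' [rf_importance()] and, after each iteration, the lowest-importance
#' `ceiling(drop_fraction * survivors)` TFs (at least one) are removed
#' until a single TF remains.  Each TF's importance for a gene is
#' aggregated as the mean over the iterations it survived; the per-TF
#' pathway score is the sum of these aggregates over all pathway genes.
#'
#' @param expr An [expr_set] or numeric matrix (features x samples)
#'   containing both TFs and pathway genes.
#' @param candidate_tfs Character vector of >= 2 TF ids.
#' @param pathway_genes Character vector of target gene ids.
#' @param drop_fraction Fraction of survivors eliminated per iteration
#'   (default 0.1; small steps stabilise the ranking at extra cost).
#' @param n_trees Trees per forest.
#' @param seed Integer seed; every (gene, iteration) forest uses a
#'   deterministic sub-seed.
#' @param mode Importance mode passed to [rf_importance()].
#' @return Object of class `importance_table`: `table` (data frame
#'   `tf`, `gene`, `importance`, `iterations_survived`) and `scores`
#'   (named per-TF pathway score).
#' @export
bwerf_rank <- function(expr, candidate_tfs, pathway_genes,
                       drop_fraction = 0.1, n_trees = 1000L, seed = 1L,
                       mode = "impurity") {
  values <- if (inherits(expr, "expr_set")) expr$values else expr
  stopifnot(is.matrix(values))
  stop_if_not_fraction(drop_fraction, "drop_fraction", lo = 1e-12, hi = 1)
  if (length(candidate_tfs) < 2) stop("need at least 2 candidate TFs", call. = FALSE)
  missing_g <- setdiff(pathway_genes, rownames(values))
  if (length(missing_g)) {
    stop("pathway gene(s) absent from expression matrix: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  missing_tf <- setdiff(candidate_tfs, rownames(values))
  if (length(missing_tf)) {
    stop("candidate TF(s) absent from expression matrix: ",
         paste(missing_tf, collapse = ", "), call. = FALSE)
  }

  rows <- list()
  for (gi in seq_along(pathway_genes)) {
    g <- pathway_genes[gi]
    survivors <- setdiff(candidate_tfs, g)
    imp_sum <- stats::setNames(rep(0, length(survivors)), survivors)
    n_seen <- stats::setNames(rep(0L, length(survivors)), survivors)
    iter <- 0L
    while (length(survivors) >= 2L) {
      iter <- iter + 1L
      imp <- rf_importance(values[g, ], values[survivors, , drop = FALSE],
                           n_trees = n_trees,
                           seed = sub_seed(seed, gi * 1000L + iter),
                           mode = mode)
      imp_sum[survivors] <- imp_sum[survivors] + imp[survivors]
      n_seen[survivors] <- n_seen[survivors] + 1L
      n_drop <- max(1L, ceiling(drop_fraction * length(survivors)))
      drop <- survivors[order(imp[survivors])][seq_len(n_drop)]
      survivors <- setdiff(survivors, drop)
    }
    rows[[gi]] <- data.frame(
      tf = names(imp_sum), gene = g,
      importance = as.numeric(imp_sum / pmax(n_seen, 1L)),
      iterations_survived = as.integer(n_seen),
      stringsAsFactors = FALSE
    )
  }
  table <- do.call(rbind, rows)
  scores <- tapply(table$importance, table$tf, sum)
  scores <- stats::setNames(as.numeric(scores), names(scores))
  structure(list(table = table,
                 scores = scores[candidate_tfs[candidate_tfs %in% names(scores)]]),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("importance_table: %d TFs x %d pathway genes\n",
              length(unique(x$table$tf)), length(unique(x$table$gene))))
  cat("top pathway scores:\n")
  print(utils::head(sort(x$scores, decreasing = TRUE), 5))
  invisible(x)
}

#' Select the TFs forming a regulatory layer
#'
#' Retains TFs whose posterior responsibility for the higher-mean
#' component of a two-component Gaussian mixture over pathway scores is
#' at least 0.5.  When the two component means are indistinguishable
#' (difference < 1e-6) the mixture carries no layer information and the
#' top half of TFs by score is retained with a warning.
#'
#' @param scores Named per-TF pathway scores (from [bwerf_rank()]).
#' @param gmm A two-component [gmm_fit_1d()] fitted on `scores`.
#' @return Character vector of retained TF ids.
#' @export
select_layer_tfs <- function(scores, gmm) {
  if (length(scores) == 0) stop("`scores` is empty", call. = FALSE)
  stopifnot(inherits(gmm, "gmm_fit"), gmm$n_components == 2L)
  if (abs(diff(gmm$means)) < 1e-6) {
    warning("mixture components indistinguishable; retaining top half by score")
    keep_n <- ceiling(length(scores) / 2)
    return(names(sort(scores, decreasing = TRUE))[seq_len(keep_n)])
  }
  hi <- which.max(gmm$means)
  post <- gmm_posterior(gmm, as.numeric(scores))[, hi]
  names(scores)[post >= 0.5]
}

#' Build a multi-layer hierarchical gene regulatory network
#'
#' Bottom-up construction: layer 1 is the [select_layer_tfs()] output of
#' a [bwerf_rank()] run with the pathway genes as targets and all TFs as
#' candidates; each further layer repeats the procedure with the
#' previous layer's TFs as targets and the not-yet-placed TFs as
#' candidates.  Edges between adjacent layers connect each target to its
#' `edges_per_target` highest-importance selected regulators, weighted
#' by aggregated importance.
#'
#' @inheritParams bwerf_rank
#' @param n_layers Number of TF layers above the pathway genes
#'   (default 2).
#' @param edges_per_target Regulators kept per target when materialising
#'   edges (default 3).
#' @param max_layer_size Optional cap on a layer's size (top TFs by
#'   score); `NULL` (default) leaves layers uncapped.
#' @param gmm_n_init Random restarts for the layer-selection mixture.
#' @return Object of class `hgrn`: `layers` (list of TF id vectors,
#'   layer 1 adjacent to the pathway genes), `tf_edges` (data frame
#'   `regulator`, `target`, `weight`, `regulator_layer`),
#'   `gene_metabolite_edges` (empty until [link_metabolites()]),
#'   `pathway_genes`, and per-layer `scores`.
#' @export
build_hierarchy <- function(expr, candidate_tfs, pathway_genes,
                            n_layers = 2L, drop_fraction = 0.1,
                            n_trees = 1000L, edges_per_target = 3L,
                            max_layer_size = NULL, gmm_n_init = 10L,
                            seed = 1L, mode = "impurity") {
  stop_if_not_count(n_layers, "n_layers")
  layers <- list()
  layer_scores <- list()
  edges <- list()
  placed <- character()
  targets <- pathway_genes
  for (l in seq_len(n_layers)) {
    cands <- setdiff(candidate_tfs, placed)
    if (length(cands) < 2) {
      warning("candidate pool exhausted; returning ", l - 1L, " layer(s)")
      break
    }
    bw <- bwerf_rank(expr, cands, targets,
                     drop_fraction = drop_fraction, n_trees = n_trees,
                     seed = sub_seed(seed, l), mode = mode)
    sel <- if (length(bw$scores) >= 4) {
      gmm <- gmm_fit_1d(as.numeric(bw$scores), n_components = 2L,
                        n_init = gmm_n_init, seed = sub_seed(seed, 100L + l))
      select_layer_tfs(bw$scores, gmm)
    } else {
      warning("too few candidates for mixture selection; retaining top half")
      names(sort(bw$scores, decreasing = TRUE))[
        seq_len(ceiling(length(bw$scores) / 2))]
    }
    if (!is.null(max_layer_size) && length(sel) > max_layer_size) {
      sel <- names(sort(bw$scores[sel], decreasing = TRUE))[seq_len(max_layer_size)]
    }
    tab <- bw$table[bw$table$tf %in% sel, , drop = FALSE]
    e <- do.call(rbind, lapply(split(tab, tab$gene), function(d) {
      d <- d[order(-d$importance), , drop = FALSE]
      d[seq_len(min(edges_per_target, nrow(d))), , drop = FALSE]
    }))
    if (!is.null(e) && nrow(e)) {
      edges[[l]] <- data.frame(regulator = e$tf, target = e$gene,
                               weight = e$importance, regulator_layer = l,
                               stringsAsFactors = FALSE)
    }
    layers[[l]] <- sel
    layer_scores[[l]] <- bw$scores
    placed <- c(placed, sel)
    targets <- sel
  }
  structure(list(
    layers = layers,
    tf_edges = if (length(edges)) {
      do.call(rbind, c(edges, list(make.row.names = FALSE)))
    } else {
      data.frame(regulator = character(), target = character(),
                 weight = numeric(), regulator_layer = integer())
    },
    gene_metabolite_edges = data.frame(gene = character(),
                                       metabolite = character(),
                                       r = numeric(), p = numeric(),
                                       fdr = numeric()),
    pathway_genes = pathway_genes,
    scores = layer_scores
  ), class = "hgrn")
}

#' @export
print.hgrn <- function(x, ...) {
  cat(sprintf("hgrn: %d pathway genes, %d TF layer(s)\n",
              length(x$pathway_genes), length(x$layers)))
  for (l in seq_along(x$layers)) {
    cat(sprintf("  layer %d: %d TFs\n", l, length(x$layers[[l]])))
  }
  cat(sprintf("  %d TF edges, %d gene-metabolite edges\n",
              nrow(x$tf_edges), nrow(x$gene_metabolite_edges)))
  invisible(x)
}

#' Link pathway genes to metabolites by correlation
#'
#' Pearson correlation between each gene and metabolite over matched
#' observations — either per-timepoint means (default; robust when the
#' two assays were run on different aliquots) or directly matched sample
#' columns.  Pairs with `|r| >= r_min` and BH-adjusted p < `alpha` are
#' kept.
#'
#' @param gene_expr An [expr_set] (typically restricted to pathway
#'   genes).
#' @param metab A [metab_set] without missing values.
#' @param r_min Minimum absolute correlation (default 0.8).
#' @param alpha FDR threshold (default 0.05).
#' @param match One of `"timepoint_means"` or `"samples"`.
#' @return Data frame `gene`, `metabolite`, `r`, `p`, `fdr`.
#' @export
link_metabolites <- function(gene_expr, metab, r_min = 0.8, alpha = 0.05,
                             match = c("timepoint_means", "samples")) {
  match <- match.arg(match)
  stopifnot(inherits(gene_expr, "expr_set"), inherits(metab, "metab_set"))
  if (match == "timepoint_means") {
    tps <- intersect(unique(gene_expr$samples$timepoint),
                     unique(metab$samples$timepoint[!metab$samples$is_qc]))
    tps <- sort(tps[!is.na(tps)])
    if (length(tps) < 3) stop("need at least 3 matched observations", call. = FALSE)
    g <- vapply(tps, function(tp) {
      rowMeans(gene_expr$values[, gene_expr$samples$timepoint == tp, drop = FALSE])
    }, numeric(nrow(gene_expr$values)))
    m <- vapply(tps, function(tp) {
      sel <- !metab$samples$is_qc & !is.na(metab$samples$timepoint) &
        metab$samples$timepoint == tp
      rowMeans(metab$intensities[, sel, drop = FALSE])
    }, numeric(nrow(metab$intensities)))
    n_obs <- length(tps)
  } else {
    common <- intersect(gene_expr$samples$sample_id,
                        metab$samples$sample_id[!metab$samples$is_qc])
    if (length(common) < 3) stop("need at least 3 matched observations", call. = FALSE)
    g <- gene_expr$values[, common, drop = FALSE]
    m <- metab$intensities[, common, drop = FALSE]
    n_obs <- length(common)
  }
  r <- stats::cor(t(g), t(m))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n_obs - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(-abs(tstat), df = n_obs - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  out <- data.frame(
    gene = rep(rownames(g), times = ncol(r)),
    metabolite = rep(colnames(r), each = nrow(r)),
    r = as.numeric(r), p = as.numeric(p),
    stringsAsFactors = FALSE
  )
  out$fdr <- bh_fdr(out$p)
  out[abs(out$r) >= r_min & out$fdr < alpha, , drop = FALSE]
}

#' Attach gene-metabolite edges to a network
#'
#' @param net An [build_hierarchy()] network.
#' @param edges Data frame from [link_metabolites()].
#' @return The network with `gene_metabolite_edges` set.
#' @export
add_metabolite_edges <- function(net, edges) {
  stopifnot(inherits(net, "hgrn"))
  net$gene_metabolite_edges <- edges
  net
}

#' Summarise a hierarchical network
#'
#' @param net An `hgrn` object.
#' @param status Optional named regulation-status vector (`"up"`,
#'   `"down"`, `"ns"`) over node ids to tally.
#' @return List of counts: TFs per layer, total TFs, pathway
#'   (functional) genes, TF edges, metabolite edges, and status tallies
#'   when supplied.
#' @export
network_summary <- function(net, status = NULL) {
  stopifnot(inherits(net, "hgrn"))
  out <- list(
    n_layers = length(net$layers),
    tfs_per_layer = vapply(net$layers, length, integer(1)),
    n_tfs = length(unlist(net$layers)),
    n_pathway_genes = length(net$pathway_genes),
    n_tf_edges = nrow(net$tf_edges),
    n_metabolite_edges = nrow(net$gene_metabolite_edges)
  )
  if (!is.null(status)) {
    ids <- c(unlist(net$layers), net$pathway_genes)
    st <- status[ids]
    st[is.na(st)] <- "ns"
    out$status_tally <- table(factor(st, levels = c("up", "down", "ns")))
  }
  out
}

#' Permutation test for retained-vs-dropped score separation
#'
#' Guards against the mixture model inventing structure: under a null
#' with no planted regulation, pathway scores recomputed in an
#' independent run should not separate a previously retained TF set
#' from the dropped set.  Tests the mean score difference by label
#' permutation.
#'
#' @param scores Named per-TF scores from an evaluation run.
#' @param retained_ids TF ids retained by a selection made independently
#'   of `scores`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `observed` mean difference and one-sided
#'   permutation `p`.
#' @export
score_separation_test <- function(scores, retained_ids, n_perm = 1000L,
                                  seed = 1L) {
  lab <- names(scores) %in% retained_ids
  if (!any(lab) || all(lab)) {
    stop("need both retained and dropped TFs among `scores`", call. = FALSE)
  }
  obs <- mean(scores[lab]) - mean(scores[!lab])
  with_seed(seed, {
    perm <- replicate(n_perm, {
      pl <- sample(lab)
      mean(scores[pl]) - mean(scores[!pl])
    })
    list(observed = obs, p = (sum(perm >= obs) + 1) / (n_perm + 1))
  })
}
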