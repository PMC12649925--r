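# Small problem sizes keep the forest-based tests fast; the full-scale
# recovery experiment lives in the acceptance suite.

test_that("rf_importance finds a planted single regulator", {
  hits <- vapply(1:20, function(seed) {
    with_seed_test(seed, {
      n <- 30
      tfs <- matrix(rnorm(6 * n), 6, n,
                    dimnames = list(sprintf("TF%02d", 1:6), NULL))
      target <- tfs["TF01", ]
      imp <- rf_importance(target, tfs, n_trees = 500, seed = seed)
      names(which.max(imp)) == "TF01"
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("rf_importance normalises, validates, and is order-invariant", {
  set.seed(8)
  tfs <- matrix(rnorm(5 * 24), 5, 24,
                dimnames = list(sprintf("TF%02d", 1:5), NULL))
  target <- tfs["TF02", ] + rnorm(24, sd = 0.3)
  imp <- rf_importance(target, tfs, n_trees = 300, seed = 4)
  expect_equal(sum(imp), 1, tolerance = 1e-8)
  expect_true(all(imp >= 0))
  perm <- c(4, 1, 5, 2, 3)
  imp_perm <- rf_importance(target, tfs[perm, ], n_trees = 300, seed = 4)
  expect_identical(imp_perm[names(imp)], imp)
  expect_warning(u <- rf_importance(rep(1, 24), tfs, n_trees = 50, seed = 1),
                 "constant")
  expect_equal(unname(u), rep(0.2, 5))
  expect_error(rf_importance(target[1:4], tfs[, 1:4], 100, 1), "6 samples")
  expect_error(rf_importance(target, tfs[1, , drop = FALSE], 100, 1),
               "2 TFs")
})

test_that("BWERF on the smallest instance reduces to one forest", {
  set.seed(9)
  vals <- matrix(rnorm(3 * 12), 3, 12,
                 dimnames = list(c("G1", "TFa", "TFb"), sprintf("s%d", 1:12)))
  bw <- bwerf_rank(vals, c("TFa", "TFb"), "G1", drop_fraction = 0.5,
                   n_trees = 200, seed = 5)
  expect_equal(sort(bw$table$iterations_survived), c(1L, 1L))
  single <- rf_importance(vals["G1", ], vals[c("TFa", "TFb"), ],
                          n_trees = 200, seed = sub_seed_test(5, 1001))
  expect_equal(sort(bw$scores), sort(single), tolerance = 1e-12)
})

test_that("elimination follows the ceiling-drop recurrence", {
  # iteration count for m TFs equals the recurrence n -> n - ceil(f n)
  recurrence_iters <- function(m, f) {
    it <- 0
    while (m >= 2) {
      it <- it + 1
      m <- m - max(1, ceiling(f * m))
    }
    it
  }
  set.seed(10)
  for (m in c(2, 4, 8, 16, 5, 11)) {
    vals <- matrix(rnorm((m + 1) * 12), m + 1, 12)
    rownames(vals) <- c("G1", sprintf("TF%02d", 1:m))
    bw <- bwerf_rank(vals, sprintf("TF%02d", 1:m), "G1",
                     drop_fraction = 0.5, n_trees = 50, seed = 2)
    expect_equal(max(bw$table$iterations_survived),
                 recurrence_iters(m, 0.5))
    if (log2(m) == round(log2(m))) {
      expect_equal(max(bw$table$iterations_survived), log2(m))
    }
  }
})

test_that("BWERF importances sum to at most one per gene per iteration", {
  set.seed(11)
  vals <- matrix(rnorm(8 * 12), 8, 12)
  rownames(vals) <- c("G1", "G2", sprintf("TF%02d", 1:6))
  bw <- bwerf_rank(vals, sprintf("TF%02d", 1:6), c("G1", "G2"),
                   drop_fraction = 0.34, n_trees = 100, seed = 3)
  # each snapshot is normalised to 1, so no mean-over-survived aggregate
  # can exceed 1, and none is negative
  expect_true(all(bw$table$importance <= 1 + 1e-8))
  expect_true(all(bw$table$importance >= 0))
  expect_error(bwerf_rank(vals, sprintf("TF%02d", 1:6), "nope", seed = 1),
               "nope")
  expect_error(bwerf_rank(vals, "TF01", "G1", seed = 1), "at least 2")
})

test_that("true regulators out-rank decoys on a planted hierarchy", {
  sim <- simulate_hierarchy_expression(12, 4, 3, 12, timepoints = 6,
                                       replicates = 3, seed = 17)
  truth <- sim$truth
  bw <- bwerf_rank(sim$expr, names(truth$layer_assignments),
                   truth$pathway_genes, drop_fraction = 0.2,
                   n_trees = 300, seed = 17)
  l1 <- names(which(truth$layer_assignments == 1))
  wt <- stats::wilcox.test(bw$scores[l1],
                           bw$scores[truth$decoy_tfs],
                           alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("layer selection retains the high-score component", {
  scores <- setNames(c(rep(0.01, 20), rep(0.9, 5)),
                     sprintf("TF%02d", 1:25))
  gmm <- gmm_fit_1d(as.numeric(scores), 2, n_init = 5, seed = 1)
  sel <- select_layer_tfs(scores, gmm)
  expect_setequal(sel, sprintf("TF%02d", 21:25))
  # raising a retained TF's score keeps it retained under the same fit
  shifted <- scores
  shifted["TF21"] <- shifted["TF21"] + 0.5
  expect_true("TF21" %in% select_layer_tfs(shifted, gmm))
  expect_error(select_layer_tfs(setNames(numeric(), character()), gmm),
               "empty")
})

test_that("identical scores trigger the degenerate fallback", {
  scores <- setNames(rep(0.5, 10), sprintf("TF%02d", 1:10))
  gmm <- suppressWarnings(gmm_fit_1d(as.numeric(scores), 2, n_init = 2,
                                     seed = 1))
  expect_warning(sel <- select_layer_tfs(scores, gmm), "top half")
  expect_length(sel, 5)
})

test_that("build_hierarchy respects layering invariants end to end", {
  sim <- simulate_hierarchy_expression(10, 4, 3, 8, seed = 23)
  tfs <- names(sim$truth$layer_assignments)
  net <- build_hierarchy(sim$expr, tfs, sim$truth$pathway_genes,
                         n_layers = 2, drop_fraction = 0.2, n_trees = 200,
                         seed = 23)
  expect_s3_class(net, "hgrn")
  # layers disjoint, edges span exactly adjacent layers
  expect_length(intersect(net$layers[[1]], net$layers[[2]]), 0)
  e <- net$tf_edges
  for (i in seq_len(nrow(e))) {
    l <- e$regulator_layer[i]
    expect_true(e$regulator[i] %in% net$layers[[l]])
    expect_true(e$target[i] %in%
                  (if (l == 1) net$pathway_genes else net$layers[[l - 1]]))
  }
  # every target keeps at most edges_per_target regulators
  expect_true(all(table(e$target) <= 3))
  # determinism: identical seed reproduces the whole network
  net2 <- build_hierarchy(sim$expr, tfs, sim$truth$pathway_genes,
                          n_layers = 2, drop_fraction = 0.2, n_trees = 200,
                          seed = 23)
  expect_identical(net, net2)
})

test_that("a single-layer build is the recursion base", {
  sim <- simulate_hierarchy_expression(8, 3, 2, 6, seed = 29)
  tfs <- names(sim$truth$layer_assignments)
  net <- build_hierarchy(sim$expr, tfs, sim$truth$pathway_genes,
                         n_layers = 1, drop_fraction = 0.3, n_trees = 150,
                         seed = 29)
  expect_length(net$layers, 1)
  bw <- bwerf_rank(sim$expr, tfs, sim$truth$pathway_genes,
                   drop_fraction = 0.3, n_trees = 150,
                   seed = sub_seed_test(29, 1))
  gmm <- gmm_fit_1d(as.numeric(bw$scores), 2, seed = sub_seed_test(29, 101))
  expect_setequal(net$layers[[1]], select_layer_tfs(bw$scores, gmm))
})

test_that("an exhausted candidate pool shortens the hierarchy with a warning", {
  sim <- simulate_hierarchy_expression(6, 2, 2, 1, seed = 31)
  tfs <- names(sim$truth$layer_assignments)
  w <- capture_warnings(
    net <- build_hierarchy(sim$expr, tfs[1:3], sim$truth$pathway_genes,
                           n_layers = 4, drop_fraction = 0.5, n_trees = 100,
                           seed = 31))
  expect_true(any(grepl("exhausted", w)))
  expect_lt(length(net$layers), 4)
})

test_that("metabolite linking keeps exactly the strong correlated pairs", {
  # toy fixture with known correlations over 6 timepoints
  tp <- c(0, 2, 4, 6, 8, 10)
  g <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
             g2 = c(6, 5, 4, 3, 2, 1),
             g3 = c(1, 5, 2, 6, 3, 4),
             g4 = c(2, 2, 3, 3, 4, 4))
  samples <- data.frame(sample_id = sprintf("s%d", 1:6), timepoint = tp,
                        replicate = 1, group = "drought")
  colnames(g) <- samples$sample_id
  expr <- expr_set(g, samples)
  m <- rbind(m1 = 10 * g["g1", ] + 3,       # r = 1 with g1, -1 with g2
             m2 = c(5, 1, 6, 2, 6, 3),
             m3 = g["g4", ] + c(0.1, -0.1, 0.1, -0.1, 0.1, -0.1))
  msamples <- samples
  msamples$is_qc <- FALSE
  metab <- metab_set(m, msamples)
  got <- link_metabolites(expr, metab, r_min = 0.99, alpha = 0.05)
  expect_setequal(paste(got$gene, got$metabolite),
                  c("g1 m1", "g2 m1", "g4 m3"))
  expect_equal(got$r[got$gene == "g1"], 1, tolerance = 1e-12)
  # brute-force enumeration at a looser threshold
  all_r <- cor(t(g), t(m))
  keep_oracle <- c()
  pvals <- c()
  for (gi in rownames(g)) for (mi in rownames(m)) {
    ct <- cor.test(g[gi, ], m[mi, ])
    pvals <- c(pvals, ct$p.value)
    keep_oracle <- c(keep_oracle, paste(gi, mi))
  }
  fdr_o <- oracle_bh(pvals)
  sel_o <- keep_oracle[abs(as.numeric(t(all_r))) >= 0.8 & fdr_o < 0.05]
  loose <- link_metabolites(expr, metab, r_min = 0.8, alpha = 0.05)
  expect_setequal(paste(loose$gene, loose$metabolite), sel_o)
})

test_that("null correlation pairs are kept at the expected tail rate", {
  set.seed(55)
  n_tp <- 6
  g <- matrix(10 + rnorm(40 * n_tp), 40, n_tp,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:n_tp)))
  samples <- data.frame(sample_id = sprintf("s%d", 1:n_tp),
                        timepoint = seq_len(n_tp), replicate = 1,
                        group = "x")
  expr <- expr_set(g, samples)
  m <- matrix(10 + rnorm(50 * n_tp), 50, n_tp,
              dimnames = list(sprintf("m%02d", 1:50), sprintf("s%d", 1:n_tp)))
  ms <- samples; ms$is_qc <- FALSE
  metab <- metab_set(m, ms)
  # keep by |r| only (alpha = 1): tail probability of |r| >= 0.8 at n = 6
  got <- link_metabolites(expr, metab, r_min = 0.8, alpha = 1.0000001)
  r_null <- function() abs(cor(rnorm(n_tp), rnorm(n_tp)))
  tail_p <- mean(replicate(4000, r_null()) >= 0.8)
  expect_lt(abs(nrow(got) / 2000 - tail_p), 0.02)
})

test_that("network summaries count what the construction planted", {
  sim <- simulate_hierarchy_expression(8, 3, 2, 6, seed = 37)
  tfs <- names(sim$truth$layer_assignments)
  net <- build_hierarchy(sim$expr, tfs, sim$truth$pathway_genes,
                         n_layers = 1, drop_fraction = 0.3, n_trees = 100,
                         seed = 37)
  s <- network_summary(net)
  expect_equal(s$n_layers, 1)
  expect_equal(s$tfs_per_layer, length(net$layers[[1]]))
  expect_equal(s$n_tf_edges, nrow(net$tf_edges))
  expect_equal(s$n_tf_edges,
               sum(table(net$tf_edges$target)))
  empty <- structure(list(layers = list(), tf_edges = net$tf_edges[0, ],
                          gene_metabolite_edges = net$gene_metabolite_edges,
                          pathway_genes = character()), class = "hgrn")
  se <- network_summary(empty)
  expect_equal(se$n_tfs + se$n_pathway_genes + se$n_tf_edges, 0)
  st <- network_summary(net, status = setNames("up", net$pathway_genes[1]))
  expect_equal(unname(st$status_tally["up"]), 1L)
})
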