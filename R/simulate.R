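# Seeded simulators with planted ground truth.  These define the study
# conditions every downstream stage is tested against: a two-layer
# TF -> TF -> pathway-gene expression hierarchy sampled over a drought
# time course, negative-binomial read counts, and a metabolome with
# planted fold changes, QC replicates and missing values.

#' Construct an expression set
#'
#' Light container pairing a features x samples abundance matrix with
#' per-sample metadata.
#'
#' @param values Numeric matrix, features in rows, samples in columns;
#'   no negative values.
#' @param samples Data frame with one row per column of `values`; must
#'   contain `sample_id`, `timepoint`, `replicate`, `group`.
#' @param unit Unit tag, e.g. `"log2au"`, `"counts"`, `"FPKM"`.
#' @return An object of class `expr_set`.
#' @export
expr_set <- function(values, samples, unit = "au") {
  stopifnot(is.matrix(values), is.data.frame(samples))
  if (ncol(values) != nrow(samples)) {
    stop("`samples` must have one row per column of `values`", call. = FALSE)
  }
  need <- c("sample_id", "timepoint", "replicate", "group")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("feature ids must be unique", call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be non-negative", call. = FALSE)
  colnames(values) <- samples$sample_id
  structure(list(values = values, samples = samples, unit = unit),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat(sprintf("  timepoints: %s; groups: %s\n",
              paste(sort(unique(x$samples$timepoint)), collapse = ", "),
              paste(unique(x$samples$group), collapse = ", ")))
  invisible(x)
}

# random natural cubic spline over `timepoints` support points, scaled to
# zero mean / unit sd across timepoints -- a smooth temporal signal whose
# variance is comparable across genes so noise_sd alone sets R^2
random_spline_signal <- function(timepoints, n_knots = 4L) {
  kx <- seq(1, timepoints, length.out = n_knots)
  ky <- stats::rnorm(n_knots)
  y <- stats::spline(kx, ky, xout = seq_len(timepoints), method = "natural")$y
  s <- stats::sd(y)
  if (s < 1e-12) y <- y + stats::rnorm(timepoints, sd = 1) else y <- y / s
  y - mean(y)
}

#' Simulate a two-layer regulatory hierarchy over a drought time course
#'
#' Generates an expression matrix with a planted hierarchy: layer-2 TFs
#' carry independent smooth temporal signals (random cubic splines over
#' timepoints), each layer-1 TF is a linear combination of the observed
#' per-sample profiles of 1-3 layer-2 TFs, each pathway gene a linear
#' combination of 1-3 layer-1 TF profiles, and decoy TFs are
#' independent noise.  Regulation acts on observed regulator levels, as
#' in a real cascade, so a direct parent is strictly more informative
#' about its target than a grandparent.  Each combination is
#' standardised to unit variance before `noise_sd` Gaussian noise is
#' added, so the attainable per-gene R^2 is `1 / (1 + noise_sd^2)`.
#'
#' @param n_pathway_genes,n_layer1_tfs,n_layer2_tfs,n_decoys Counts (>= 1).
#' @param timepoints Number of timepoints (days are spaced 2 apart,
#'   starting at 0, mirroring a progressive-drought sampling design).
#' @param replicates Biological replicates per timepoint.
#' @param noise_sd Standard deviation of per-sample Gaussian noise added
#'   to every profile, in units of signal sd; must be > 0 (pass a tiny
#'   value for a near-noiseless check).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `expr` (an [expr_set], log2-scale abundances offset
#'   to be non-negative) and `truth` (class `grn_truth`: `layer_assignments`
#'   named vector TF -> layer, `edges` data frame
#'   (`regulator`, `target`, `effect`), `pathway_genes`, `decoy_tfs`).
#' @export
simulate_hierarchy_expression <- function(n_pathway_genes = 40L,
                                          n_layer1_tfs = 10L,
                                          n_layer2_tfs = 8L,
                                          n_decoys = 32L,
                                          timepoints = 6L,
                                          replicates = 3L,
                                          noise_sd = 1,
                                          seed = 1L) {
  for (nm in c("n_pathway_genes", "n_layer1_tfs", "n_layer2_tfs", "n_decoys",
               "timepoints", "replicates")) {
    stop_if_not_count(get(nm), nm)
  }
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    stop("`noise_sd` must be > 0", call. = FALSE)
  }
  with_seed(seed, {
    tp <- as.integer(timepoints); rep_n <- as.integer(replicates)
    n_samp <- tp * rep_n
    tp_of_sample <- rep(seq_len(tp), each = rep_n)

    n_tf <- n_layer1_tfs + n_layer2_tfs + n_decoys
    tf_ids <- sprintf("TF%03d", seq_len(n_tf))
    roles <- sample(rep(c("l1", "l2", "decoy"),
                        c(n_layer1_tfs, n_layer2_tfs, n_decoys)))
    l1_ids <- tf_ids[roles == "l1"]
    l2_ids <- tf_ids[roles == "l2"]
    decoy_ids <- tf_ids[roles == "decoy"]
    gene_ids <- sprintf("G%03d", seq_len(n_pathway_genes))

    # layer-2 profiles: independent smooth temporal signals (shared by
    # replicates) plus per-sample noise
    l2_prof <- vapply(l2_ids, function(id) {
      random_spline_signal(tp)[tp_of_sample] +
        stats::rnorm(n_samp, sd = noise_sd)
    }, numeric(n_samp))

    # child = unit-variance linear combination of observed parent
    # profiles + fresh noise; effect sizes recorded on the standardised
    # scale so the zero-noise limit is an exact identity
    combine_parents <- function(parent_prof, n_parents_max = 3L) {
      k <- sample.int(min(n_parents_max, ncol(parent_prof)), 1L)
      idx <- sample.int(ncol(parent_prof), k)
      a <- stats::runif(k, 0.5, 1.5) * sample(c(-1, 1), k, replace = TRUE)
      raw <- parent_prof[, idx, drop = FALSE] %*% a
      s <- stats::sd(raw)
      if (s < 1e-12) s <- 1
      list(profile = as.numeric(raw / s) + stats::rnorm(n_samp, sd = noise_sd),
           parents = colnames(parent_prof)[idx],
           effect = a / s)
    }

    l1_prof <- matrix(0, n_samp, length(l1_ids), dimnames = list(NULL, l1_ids))
    edges <- list()
    for (id in l1_ids) {
      cmb <- combine_parents(l2_prof)
      l1_prof[, id] <- cmb$profile
      edges[[length(edges) + 1L]] <-
        data.frame(regulator = cmb$parents, target = id, effect = cmb$effect)
    }
    gene_prof <- matrix(0, n_samp, n_pathway_genes,
                        dimnames = list(NULL, gene_ids))
    for (id in gene_ids) {
      cmb <- combine_parents(l1_prof)
      gene_prof[, id] <- cmb$profile
      edges[[length(edges) + 1L]] <-
        data.frame(regulator = cmb$parents, target = id, effect = cmb$effect)
    }
    edges <- do.call(rbind, edges)

    feature_ids <- c(gene_ids, tf_ids)
    signal <- matrix(0, length(feature_ids), n_samp,
                     dimnames = list(feature_ids, NULL))
    signal[gene_ids, ] <- t(gene_prof)
    signal[l1_ids, ] <- t(l1_prof)
    signal[l2_ids, ] <- t(l2_prof)
    # decoys: independent noise with comparable total variance, no
    # regulatory structure
    signal[decoy_ids, ] <- matrix(
      stats::rnorm(length(decoy_ids) * n_samp, sd = sqrt(1 + noise_sd^2)),
      length(decoy_ids), n_samp)

    values <- pmax(8 + signal, 0)

    samples <- data.frame(
      sample_id = sprintf("S_t%02d_r%d", tp_of_sample, rep(seq_len(rep_n), tp)),
      timepoint = 2 * (tp_of_sample - 1L),
      replicate = rep(seq_len(rep_n), tp),
      group = "drought",
      stringsAsFactors = FALSE
    )
    rownames(values) <- feature_ids

    truth <- structure(list(
      layer_assignments = stats::setNames(
        ifelse(tf_ids %in% l1_ids, 1L, ifelse(tf_ids %in% l2_ids, 2L, NA_integer_)),
        tf_ids),
      edges = edges,
      pathway_genes = gene_ids,
      decoy_tfs = decoy_ids
    ), class = "grn_truth")

    list(expr = expr_set(values, samples, unit = "log2au"), truth = truth)
  })
}

#' Simulate negative-binomial read counts from an expression matrix
#'
#' Count means are proportional to expression x gene length x library
#' size (the FPKM relation inverted), with a shared negative-binomial
#' dispersion.
#'
#' @param expression Numeric matrix (features x samples) of non-negative
#'   abundances, or an [expr_set].
#' @param gene_lengths Positive integer vector (bp), recycled per gene.
#' @param dispersion Shared NB dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`, so small values approach Poisson.
#' @param library_sizes Positive per-sample library sizes (fragments).
#' @param seed Integer seed.
#' @return Integer count matrix with the input dimnames.
#' @export
simulate_counts <- function(expression, gene_lengths = 1000L,
                            dispersion = 0.05,
                            library_sizes = 1e7, seed = 1L) {
  if (inherits(expression, "expr_set")) expression <- expression$values
  stopifnot(is.matrix(expression))
  if (!is.finite(dispersion) || dispersion <= 0) {
    stop("`dispersion` must be > 0", call. = FALSE)
  }
  gene_lengths <- rep_len(gene_lengths, nrow(expression))
  library_sizes <- rep_len(library_sizes, ncol(expression))
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(library_sizes <= 0)) stop("library sizes must be positive", call. = FALSE)
  with_seed(seed, {
    mu <- expression * outer(gene_lengths, library_sizes) * 1e-9
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow(mu), ncol(mu), dimnames = dimnames(expression))
    counts[mu == 0] <- 0L
    counts
  })
}

#' Construct a metabolite set
#'
#' @param intensities Numeric matrix, metabolites x samples; `NA` marks a
#'   missing measurement (the missing-value mask).
#' @param samples Data frame with `sample_id`, `group`, `replicate`,
#'   `timepoint`, `is_qc` per column of `intensities`.
#' @param classes Named character vector mapping metabolite id to
#'   compound class; ids absent from it are treated as class `"other"`.
#' @return An object of class `metab_set`.
#' @export
metab_set <- function(intensities, samples, classes = character()) {
  stopifnot(is.matrix(intensities), is.data.frame(samples))
  if (ncol(intensities) != nrow(samples)) {
    stop("`samples` must have one row per column of `intensities`", call. = FALSE)
  }
  need <- c("sample_id", "group", "is_qc")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  colnames(intensities) <- samples$sample_id
  structure(list(intensities = intensities, samples = samples,
                 classes = classes),
            class = "metab_set")
}

#' @export
print.metab_set <- function(x, ...) {
  cat(sprintf("metab_set: %d metabolites x %d samples (%d QC), %d missing values\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$samples$is_qc), sum(is.na(x$intensities))))
  invisible(x)
}

#' Simulate a widely-targeted metabolome with planted fold changes
#'
#' Log-normal peak areas with group structure: a fraction of metabolites
#' is shifted by `log2fc` in every non-control group, pooled QC samples
#' are drawn with a controlled coefficient of variation, and values go
#' missing completely at random.  Compound classes are assigned with
#' flavonoids most frequent, mirroring a leaf metabolome.
#'
#' @param n_metabolites Number of metabolites.
#' @param n_groups Number of biological groups; group 1 is the untreated
#'   control, all later groups carry the planted shift.
#' @param replicates Biological replicates per group (>= 3 for the
#'   downstream OPLS-DA screen).
#' @param n_qc Number of pooled QC injections (>= 3).
#' @param frac_differential Fraction of metabolites with a planted shift.
#' @param log2fc Planted log2 fold change (treated vs control); may be
#'   negative for depleted metabolites.
#' @param missing_rate Probability a measurement is missing, in [0, 0.5).
#' @param qc_cv Target coefficient of variation among QC injections;
#'   scalar or per-metabolite vector (recycled).
#' @param bio_sd Between-replicate biological standard deviation on the
#'   log2 scale; 0.3 (about 23% CV) is typical for targeted LC-MS leaf
#'   profiles.
#' @param seed Integer seed.
#' @return List with `metab` (a [metab_set]) and `truth` (class
#'   `metab_truth`: `differential_ids`, `planted_log2fc` named vector,
#'   `missing_mask` logical matrix, `qc_cv_true` per-metabolite vector).
#' @export
simulate_metabolome <- function(n_metabolites = 1000L, n_groups = 2L,
                                replicates = 3L, n_qc = 3L,
                                frac_differential = 0.1, log2fc = 2,
                                missing_rate = 0.02, qc_cv = 0.2,
                                bio_sd = 0.3, seed = 1L) {
  stop_if_not_count(n_metabolites, "n_metabolites")
  stop_if_not_count(n_groups, "n_groups", min = 2L)
  stop_if_not_count(replicates, "replicates")
  stop_if_not_count(n_qc, "n_qc", min = 3L)
  stop_if_not_fraction(frac_differential, "frac_differential")
  if (!is.finite(missing_rate) || missing_rate < 0 || missing_rate >= 0.5) {
    stop("`missing_rate` must be in [0, 0.5)", call. = FALSE)
  }
  with_seed(seed, {
    ids <- sprintf("M%04d", seq_len(n_metabolites))
    groups <- c("control", sprintf("treat%d", seq_len(n_groups - 1L)))
    n_bio <- n_groups * replicates
    samples <- data.frame(
      sample_id = c(sprintf("%s_r%d", rep(groups, each = replicates),
                            rep(seq_len(replicates), n_groups)),
                    sprintf("QC_%d", seq_len(n_qc))),
      group = c(rep(groups, each = replicates), rep("QC", n_qc)),
      replicate = c(rep(seq_len(replicates), n_groups), seq_len(n_qc)),
      timepoint = c(rep(2 * (seq_len(n_groups) - 1L), each = replicates),
                    rep(NA_real_, n_qc)),
      is_qc = c(rep(FALSE, n_bio), rep(TRUE, n_qc)),
      stringsAsFactors = FALSE
    )

    n_diff <- round(frac_differential * n_metabolites)
    diff_ids <- if (n_diff > 0) sort(sample(ids, n_diff)) else character()
    shift <- stats::setNames(rep(0, n_metabolites), ids)
    shift[diff_ids] <- log2fc

    base_log2 <- stats::rnorm(n_metabolites, mean = 17, sd = 2)
    # per-group log2 means: control at baseline, treated groups shifted
    grp_shift <- outer(shift, c(0, rep(1, n_groups - 1L)))  # metab x group
    bio_log2 <- grp_shift[, rep(seq_len(n_groups), each = replicates)] +
      base_log2 + matrix(stats::rnorm(n_metabolites * n_bio, sd = bio_sd),
                         n_metabolites, n_bio)

    # QC: pooled across groups, multiplicative noise with target CV
    qc_cv <- rep_len(qc_cv, n_metabolites)
    sdlog <- sqrt(log1p(qc_cv^2))
    qc_center <- base_log2 + rowMeans(grp_shift)
    qc_log <- qc_center * log(2) +
      matrix(stats::rnorm(n_metabolites * n_qc, sd = rep(sdlog, n_qc)),
             n_metabolites, n_qc)
    intens <- cbind(2^bio_log2, exp(qc_log))
    dimnames(intens) <- list(ids, samples$sample_id)

    mask <- matrix(stats::runif(length(intens)) < missing_rate,
                   n_metabolites, ncol(intens), dimnames = dimnames(intens))
    # keep at least one observed value per metabolite
    all_miss <- rowSums(!mask) == 0
    if (any(all_miss)) mask[all_miss, 1L] <- FALSE
    intens[mask] <- NA_real_

    classes <- stats::setNames(
      sample(c("flavonoid", "lipid", "phenolic acid", "amino acid",
               "alkaloid", "other"),
             n_metabolites, replace = TRUE,
             prob = c(0.22, 0.18, 0.15, 0.15, 0.1, 0.2)),
      ids)

    truth <- structure(list(
      differential_ids = diff_ids,
      planted_log2fc = shift[diff_ids],
      missing_mask = mask,
      qc_cv_true = stats::setNames(qc_cv, ids)
    ), class = "metab_truth")

    list(metab = metab_set(intens, samples, classes), truth = truth)
  })
}
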