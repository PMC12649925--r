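# Differential expression screening for time-course contrasts:
# FPKM computation, median-of-ratios normalisation, a simplified
# negative-binomial Wald test, BH FDR, and the |log2FC| >= 1 with
# FDR < 0.05 screening rule, plus shared/exclusive DEG set logic and
# qPCR 2^-ddCt relative expression.

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = counts * 1e9 / (gene_length * library_size)`.
#'
#' @param counts Count matrix (genes x samples).
#' @param gene_lengths Positive gene lengths in bp, one per row.
#' @param library_sizes Positive per-sample totals; defaults to column
#'   sums of `counts`.
#' @return Numeric FPKM matrix with attribute `unit = "FPKM"`.
#' @export
compute_fpkm <- function(counts, gene_lengths,
                         library_sizes = colSums(counts)) {
  stopifnot(is.matrix(counts))
  if (length(gene_lengths) != nrow(counts)) {
    stop("`gene_lengths` must have one entry per gene", call. = FALSE)
  }
  if (length(library_sizes) != ncol(counts)) {
    stop("`library_sizes` must have one entry per sample", call. = FALSE)
  }
  if (any(gene_lengths <= 0) || any(library_sizes <= 0)) {
    stop("gene lengths and library sizes must be positive", call. = FALSE)
  }
  fpkm <- counts * 1e9 / outer(gene_lengths, library_sizes)
  attr(fpkm, "unit") <- "FPKM"
  fpkm
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed against the per-gene geometric
#' mean reference (genes with a zero count in any sample are excluded
#' from the reference), then rescaled to geometric mean 1.
#'
#' @param counts Count matrix (genes x samples).
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts))
  ok <- rowSums(counts <= 0) == 0
  if (!any(ok)) {
    stop("no gene has nonzero counts in all samples; add a pseudo-count ",
         "before normalisation", call. = FALSE)
  }
  logc <- log(counts[ok, , drop = FALSE])
  logref <- rowMeans(logc)
  sf <- exp(apply(logc - logref, 2L, stats::median))
  sf / geom_mean(sf)
}

#' Simplified negative-binomial Wald test for two groups
#'
#' Per-gene NB model with median-of-ratios size factors as offsets and a
#' moment-based dispersion estimate.  The fold change is computed on
#' normalised group means with a pseudo-count of 0.5, its standard error
#' by the delta method from the NB variance `mu + dispersion * mu^2`,
#' and the Wald statistic `z = log2FC / SE` is referred to the standard
#' normal.  By default the dispersion is a single moment estimate shared
#' across genes (the median of per-gene moment estimates), which keeps
#' the test calibrated at small n; `dispersion = "per-gene"` uses each
#' gene's own estimate.  Either way the estimate is floored at 1e-8.
#'
#' @param counts Count matrix (genes x samples) with column names.
#' @param group_a,group_b Disjoint character vectors of sample ids (>= 2
#'   each); the fold change is `group_b` over `group_a`.
#' @param dispersion `"shared"` (default) or `"per-gene"`.
#' @return Data frame with `feature_id`, `log2fc`, `stat`, `p`, `fdr`
#'   (BH-adjusted), and `status` set to `"ns"` pending [screen_degs()].
#' @export
nb_wald_test <- function(counts, group_a, group_b,
                         dispersion = c("shared", "per-gene")) {
  stopifnot(is.matrix(counts))
  dispersion <- match.arg(dispersion)
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "),
         call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(missing)) {
    stop("sample id(s) not in count matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  sf <- tryCatch(size_factors(sub),
                 error = function(e) rep(1, ncol(sub)))
  q <- sweep(sub, 2L, sf, "/")
  qa <- q[, group_a, drop = FALSE]
  qb <- q[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  ma <- rowMeans(qa); mb <- rowMeans(qb)
  va <- apply(qa, 1L, stats::var); vb <- apply(qb, 1L, stats::var)

  # moment estimator of NB dispersion: Var = mu + a * mu^2.  The shared
  # estimate pools numerator and denominator across genes, which is far
  # more stable than per-gene moments at n = 3 and keeps the Wald test
  # calibrated.
  vp <- (va * (na - 1) + vb * (nb - 1)) / (na + nb - 2)
  mp <- (ma * na + mb * nb) / (na + nb)
  alpha <- if (dispersion == "shared") {
    rep(max(sum(vp - mp, na.rm = TRUE) /
              max(sum(mp^2, na.rm = TRUE), 1e-8), 1e-8), nrow(sub))
  } else {
    pmax((vp - mp) / pmax(mp, 1e-8)^2, 1e-8)
  }

  log2fc <- log2((mb + 0.5) / (ma + 0.5))
  # delta method on log2 of the (pseudo-counted) group means
  v_log2 <- function(m, a, n) (m + a * m^2) / (n * (m + 0.5)^2 * log(2)^2)
  se <- sqrt(v_log2(ma, alpha, na) + v_log2(mb, alpha, nb))
  stat <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  zero <- ma == 0 & mb == 0
  log2fc[zero] <- 0; stat[zero] <- 0; p[zero] <- 1

  data.frame(
    feature_id = rownames(sub) %||% as.character(seq_len(nrow(sub))),
    log2fc = log2fc, stat = stat, p = p,
    fdr = bh_fdr(p), status = "ns",
    row.names = NULL, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; output order
#' matches input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1]; `NA`/`NaN`
#'   values are rejected.
#' @return Adjusted p-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values)) stop("p-values contain NA/NaN", call. = FALSE)
  if (any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Apply the differential-expression screening rule
#'
#' A gene is called `up` when `log2fc >= lfc_min` and `fdr < alpha`,
#' `down` when `log2fc <= -lfc_min` and `fdr < alpha`, otherwise `ns`.
#' The fold-change boundary is inclusive, the FDR boundary strict.
#'
#' @param results Data frame with `log2fc` and `fdr` columns (as from
#'   [nb_wald_test()], or an externally computed table).
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @param alpha FDR significance level (default 0.05).
#' @return `results` with `status` filled in.
#' @export
screen_degs <- function(results, lfc_min = 1, alpha = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("log2fc", "fdr") %in% names(results)))
  if (anyNA(results$fdr)) stop("`fdr` column must be populated", call. = FALSE)
  status <- rep("ns", nrow(results))
  sig <- results$fdr < alpha
  status[sig & results$log2fc >= lfc_min] <- "up"
  status[sig & results$log2fc <= -lfc_min] <- "down"
  results$status <- status
  results
}

#' Shared and exclusive members across feature sets
#'
#' @param deg_sets Named list of >= 2 character vectors (for instance
#'   DEG ids per timepoint contrast).
#' @return List with `shared` (ids in every set) and `exclusive` (named
#'   list of ids unique to each set).
#' @export
shared_exclusive_sets <- function(deg_sets) {
  if (!is.list(deg_sets) || length(deg_sets) < 2 || is.null(names(deg_sets))) {
    stop("`deg_sets` must be a named list of at least 2 sets", call. = FALSE)
  }
  sets <- lapply(deg_sets, unique)
  shared <- Reduce(intersect, sets)
  exclusive <- lapply(seq_along(sets), function(i) {
    setdiff(sets[[i]], unique(unlist(sets[-i])))
  })
  names(exclusive) <- names(sets)
  list(shared = shared, exclusive = exclusive)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2 ^ -((ct_target - ct_ref) - (ct_target_ctrl - ct_ref_ctrl))`,
#' the fold change of a target gene relative to a reference gene and a
#' control condition in qRT-PCR.
#'
#' @param ct_target,ct_ref Treatment Ct values for target and reference
#'   gene (cycles).
#' @param ct_target_ctrl,ct_ref_ctrl Control-condition Ct values.
#' @return Fold change(s), vectorised over inputs.
#' @export
ddct_relative_expression <- function(ct_target, ct_ref,
                                     ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target, ct_ref, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  2^-((ct_target - ct_ref) - (ct_target_ctrl - ct_ref_ctrl))
}
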