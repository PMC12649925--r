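# Metabolomics statistics: KNN missing-value imputation, QC
# coefficient-of-variation filtering, PCA, OPLS-DA with VIP scoring, and
# the VIP > 1 with fold change >= 2 or <= 0.5 differential screen.

#' K-nearest-neighbour imputation of missing intensities
#'
#' Each missing cell is replaced by the inverse-distance-weighted average
#' of the `k` nearest metabolites' values in that sample.  Nearness is
#' Euclidean distance over the samples both metabolites have observed;
#' neighbours at zero distance share equal weights.  Metabolites with no
#' observed value at all are an error.
#'
#' @param x A [metab_set] or a numeric matrix with `NA` for missing
#'   values (metabolites in rows).
#' @param k Number of neighbours (default 10).
#' @return Object of the same type with every `NA` imputed.
#' @export
knn_impute <- function(x, k = 10L) {
  stop_if_not_count(k, "k")
  mat <- if (inherits(x, "metab_set")) x$intensities else x
  stopifnot(is.matrix(mat))
  obs <- !is.na(mat)
  none <- rowSums(obs) == 0
  if (any(none)) {
    stop("metabolite(s) with no observed values: ",
         paste(rownames(mat)[none], collapse = ", "), call. = FALSE)
  }
  need <- which(rowSums(!obs) > 0)
  out <- mat
  for (i in need) {
    common <- obs & matrix(obs[i, ], nrow(mat), ncol(mat), byrow = TRUE)
    n_common <- rowSums(common)
    diffs <- sweep(mat, 2L, mat[i, ], "-")
    diffs[!common] <- 0
    d <- sqrt(rowSums(diffs^2))
    for (j in which(!obs[i, ])) {
      cand <- which(obs[, j] & n_common > 0)
      cand <- cand[cand != i]
      if (length(cand) == 0) {
        out[i, j] <- mean(mat[i, obs[i, ]])
        next
      }
      dc <- d[cand]
      sel <- cand[order(dc)][seq_len(min(k, length(cand)))]
      ds <- d[sel]
      w <- if (any(ds < 1e-12)) {
        as.numeric(ds < 1e-12)
      } else {
        1 / ds
      }
      out[i, j] <- sum(w * mat[sel, j]) / sum(w)
    }
  }
  if (inherits(x, "metab_set")) {
    x$intensities <- out
    x
  } else {
    out
  }
}

#' Filter metabolites by QC coefficient of variation
#'
#' CV is the sample standard deviation over the QC injections divided by
#' their mean; metabolites with CV strictly below `cv_max` are retained.
#' A metabolite with zero mean and zero spread gets CV 0.
#'
#' @param metab A [metab_set] with at least 2 QC samples.
#' @param cv_max Retention threshold (default 0.5; retention is strict
#'   `CV < cv_max`).
#' @return List with `retained` (subset [metab_set]), `dropped_ids`, and
#'   the per-metabolite `cv` vector.
#' @export
qc_cv_filter <- function(metab, cv_max = 0.5) {
  stopifnot(inherits(metab, "metab_set"))
  qc <- metab$intensities[, metab$samples$is_qc, drop = FALSE]
  if (ncol(qc) < 2) stop("need at least 2 QC samples", call. = FALSE)
  m <- rowMeans(qc, na.rm = TRUE)
  s <- apply(qc, 1L, stats::sd, na.rm = TRUE)
  cv <- ifelse(s == 0, 0, s / m)
  cv[is.na(cv)] <- 0
  keep <- cv < cv_max
  retained <- metab
  retained$intensities <- metab$intensities[keep, , drop = FALSE]
  retained$classes <- metab$classes[intersect(names(metab$classes),
                                              rownames(retained$intensities))]
  list(retained = retained,
       dropped_ids = rownames(metab$intensities)[!keep],
       cv = stats::setNames(cv, rownames(metab$intensities)))
}

#' Principal component analysis by singular value decomposition
#'
#' @param x Numeric matrix, observations (samples) in rows.
#' @param n_components Number of components to return.
#' @param center,scale. Passed to the underlying decomposition;
#'   defaults centre only.
#' @return List with `scores`, `loadings` (orthonormal columns), and
#'   `explained` (variance fractions).
#' @export
pca_decomp <- function(x, n_components = 2L, center = TRUE, scale. = FALSE) {
  stopifnot(is.matrix(x))
  stop_if_not_count(n_components, "n_components")
  if (n_components > min(dim(x))) {
    stop("`n_components` exceeds min(samples, variables)", call. = FALSE)
  }
  if (all(apply(x, 2L, stats::sd) < 1e-12)) {
    stop("matrix is constant; PCA undefined", call. = FALSE)
  }
  fit <- stats::prcomp(x, center = center, scale. = scale.)
  keep <- seq_len(n_components)
  list(scores = fit$x[, keep, drop = FALSE],
       loadings = fit$rotation[, keep, drop = FALSE],
       explained = (fit$sdev^2 / sum(fit$sdev^2))[keep])
}

#' Fit an orthogonal PLS discriminant model (O-PLS, NIPALS)
#'
#' Components orthogonal to the class labels are estimated and removed
#' one at a time, then a single predictive component is fitted on the
#' deflated matrix.  Variables are unit-variance scaled by default, the
#' metabolomics convention.  With `n_orthogonal = 0` the model reduces
#' to one-component PLS-DA.
#'
#' @param x Numeric matrix, samples in rows, metabolites in columns.
#' @param y Binary group labels (two levels; each group needs >= 3
#'   samples).
#' @param n_orthogonal Number of orthogonal components (default 1).
#' @param center,scale. Column centring/scaling (defaults TRUE/TRUE =
#'   unit variance).
#' @return An object of class `opls_model` with predictive scores `t`,
#'   weights `w` (unit norm), loadings `p`, regression coefficient `c`,
#'   orthogonal score/loading/weight matrices, `y_variance_explained`,
#'   and the scaling parameters.
#' @export
oplsda_fit <- function(x, y, n_orthogonal = 1L, center = TRUE, scale. = TRUE) {
  stopifnot(is.matrix(x))
  if (n_orthogonal < 0 || n_orthogonal != round(n_orthogonal)) {
    stop("`n_orthogonal` must be a non-negative integer", call. = FALSE)
  }
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("`y` must have exactly two groups", call. = FALSE)
  if (min(table(y)) < 3) {
    stop("each group needs at least 3 biological replicates", call. = FALSE)
  }
  if (length(y) != nrow(x)) stop("length(y) != nrow(x)", call. = FALSE)

  ctr <- if (center) colMeans(x) else rep(0, ncol(x))
  scl <- if (scale.) apply(x, 2L, stats::sd) else rep(1, ncol(x))
  zero_var <- scl < 1e-12
  if (any(zero_var)) {
    warning(sum(zero_var), " constant variable(s) left unscaled")
    scl[zero_var] <- 1
  }
  Xs <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  yc <- as.numeric(y) - mean(as.numeric(y))

  Xd <- Xs
  t_o <- p_o <- w_o <- NULL
  n_fit <- 0L
  for (h in seq_len(n_orthogonal)) {
    w <- crossprod(Xd, yc); w <- w / sqrt(sum(w^2))
    tt <- Xd %*% w
    p <- crossprod(Xd, tt) / sum(tt^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break
    wo <- wo / nwo
    to <- Xd %*% wo
    po <- crossprod(Xd, to) / sum(to^2)
    Xd <- Xd - to %*% t(po)
    t_o <- cbind(t_o, to); p_o <- cbind(p_o, po); w_o <- cbind(w_o, wo)
    n_fit <- n_fit + 1L
  }
  w <- crossprod(Xd, yc); w <- w / sqrt(sum(w^2))
  tt <- as.numeric(Xd %*% w)
  p <- as.numeric(crossprod(Xd, tt) / sum(tt^2))
  cc <- sum(yc * tt) / sum(tt^2)
  structure(list(
    t = tt,
    w = stats::setNames(as.numeric(w), colnames(x)),
    p = stats::setNames(p, colnames(x)),
    c = cc,
    t_orth = t_o, p_orth = p_o, w_orth = w_o,
    n_orthogonal = n_fit,
    y = yc, y_levels = levels(y),
    y_variance_explained = cc^2 * sum(tt^2) / sum(yc^2),
    center = ctr, scale = scl
  ), class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "opls_model: 1 predictive + %d orthogonal component(s), %d variables\n",
    x$n_orthogonal, length(x$w)))
  cat(sprintf("  R2Y (predictive) = %.3f\n", x$y_variance_explained))
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP over the predictive component:
#' `VIP_j = sqrt(p * w_j^2 / sum(w^2))` with `p` the number of
#' variables, so the mean squared VIP is exactly 1.
#'
#' @param model A fitted [oplsda_fit()] model.
#' @return Data frame with `metabolite_id` and `vip`.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "opls_model")) {
    stop("`model` must be a fitted opls_model", call. = FALSE)
  }
  p_vars <- length(model$w)
  vip <- sqrt(p_vars * model$w^2 / sum(model$w^2))
  data.frame(metabolite_id = names(model$w) %||% as.character(seq_len(p_vars)),
             vip = as.numeric(vip),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold change of group means
#'
#' Ratio of arithmetic means of (imputed) intensities, treated over
#' control, per metabolite.
#'
#' @param metab A [metab_set] without missing values (impute first).
#' @param group_control,group_treated Group labels in the sample
#'   metadata.
#' @return Named positive numeric vector of fold changes.
#' @export
group_fold_change <- function(metab, group_control, group_treated) {
  stopifnot(inherits(metab, "metab_set"))
  a <- metab$intensities[, metab$samples$group == group_control & !metab$samples$is_qc,
                         drop = FALSE]
  b <- metab$intensities[, metab$samples$group == group_treated & !metab$samples$is_qc,
                         drop = FALSE]
  if (ncol(a) == 0 || ncol(b) == 0) stop("unknown group label", call. = FALSE)
  rowMeans(b) / rowMeans(a)
}

#' Screen differentially accumulated metabolites
#'
#' A metabolite is `up` when `vip > vip_min` (strict) and
#' `fc >= fc_up`, `down` when `vip > vip_min` and `fc <= fc_down`,
#' otherwise `ns`.
#'
#' @param vip_results Data frame from [vip_scores()].
#' @param fc Named vector of fold changes covering every metabolite id.
#' @param vip_min,fc_up,fc_down Screening thresholds (defaults 1, 2,
#'   0.5).
#' @return `vip_results` with `fc`, `log2fc`, and `status` columns.
#' @export
screen_dams <- function(vip_results, fc, vip_min = 1, fc_up = 2,
                        fc_down = 0.5) {
  stopifnot(is.data.frame(vip_results), "vip" %in% names(vip_results))
  miss <- setdiff(vip_results$metabolite_id, names(fc))
  if (length(miss)) {
    stop("no fold change for: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  fcv <- as.numeric(fc[vip_results$metabolite_id])
  if (any(fcv <= 0)) stop("fold changes must be positive", call. = FALSE)
  status <- rep("ns", nrow(vip_results))
  hit <- vip_results$vip > vip_min
  status[hit & fcv >= fc_up] <- "up"
  status[hit & fcv <= fc_down] <- "down"
  vip_results$fc <- fcv
  vip_results$log2fc <- log2(fcv)
  vip_results$status <- status
  vip_results
}

#' Welch's t-test on log2 intensities
#'
#' The univariate companion to the multivariate screen: per-metabolite
#' Welch t-test on log2 intensities with BH FDR.  Reported alongside the
#' VIP/fold-change screen but not part of its decision rule.
#'
#' @inheritParams group_fold_change
#' @return Data frame with `metabolite_id`, `stat`, `p`, `fdr`.
#' @export
metab_welch_test <- function(metab, group_control, group_treated) {
  stopifnot(inherits(metab, "metab_set"))
  a <- log2(metab$intensities[, metab$samples$group == group_control &
                                !metab$samples$is_qc, drop = FALSE])
  b <- log2(metab$intensities[, metab$samples$group == group_treated &
                                !metab$samples$is_qc, drop = FALSE])
  res <- vapply(seq_len(nrow(a)), function(i) {
    ht <- stats::t.test(b[i, ], a[i, ])
    c(ht$statistic, ht$p.value)
  }, numeric(2))
  data.frame(metabolite_id = rownames(metab$intensities),
             stat = res[1, ], p = res[2, ], fdr = bh_fdr(res[2, ]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count compound classes within an id set
#'
#' @param ids Character vector of metabolite ids.
#' @param class_labels Named character vector id -> class; ids without a
#'   label count as `"other"`.
#' @return Named integer vector of class counts (partitioning `ids`).
#' @export
class_summary <- function(ids, class_labels) {
  ids <- unique(ids)
  if (length(ids) == 0) return(stats::setNames(integer(), character()))
  cls <- unname(class_labels[ids])
  cls[is.na(cls)] <- "other"
  tab <- table(cls)
  stats::setNames(as.integer(tab), names(tab))
}

#' Full differential-metabolite screen for one contrast
#'
#' Convenience wrapper: impute, filter by QC CV, fit OPLS-DA on the two
#' biological groups, score VIP, and apply the VIP/fold-change screen.
#'
#' @param metab A [metab_set].
#' @param group_control,group_treated Group labels to contrast.
#' @param k_impute Neighbours for [knn_impute()].
#' @param cv_max QC CV retention threshold.
#' @param n_orthogonal Orthogonal components for [oplsda_fit()].
#' @param vip_min,fc_up,fc_down Screen thresholds.
#' @return List with the screened `table` (plus Welch `p`/`fdr` merged
#'   in), the fitted `model`, and `dropped_ids` from the CV filter.
#' @export
screen_metabolome <- function(metab, group_control, group_treated,
                              k_impute = 10L, cv_max = 0.5,
                              n_orthogonal = 1L, vip_min = 1,
                              fc_up = 2, fc_down = 0.5) {
  imp <- knn_impute(metab, k = k_impute)
  flt <- qc_cv_filter(imp, cv_max = cv_max)
  kept <- flt$retained
  sel <- !kept$samples$is_qc &
    kept$samples$group %in% c(group_control, group_treated)
  x <- t(kept$intensities[, sel, drop = FALSE])
  y <- kept$samples$group[sel]
  model <- oplsda_fit(x, y, n_orthogonal = n_orthogonal)
  fc <- group_fold_change(kept, group_control, group_treated)
  tab <- screen_dams(vip_scores(model), fc,
                     vip_min = vip_min, fc_up = fc_up, fc_down = fc_down)
  welch <- metab_welch_test(kept, group_control, group_treated)
  tab$p <- welch$p[match(tab$metabolite_id, welch$metabolite_id)]
  tab$fdr <- welch$fdr[match(tab$metabolite_id, welch$metabolite_id)]
  list(table = tab, model = model, dropped_ids = flt$dropped_ids)
}
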