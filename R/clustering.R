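# K-means clustering of metabolite temporal profiles: replicate means
# per timepoint, per-row z-scoring, k-means++ initialisation with Lloyd
# iterations and multiple restarts.

#' Z-scored temporal profile matrix
#'
#' Collapses replicates to per-timepoint means (QC samples excluded) and
#' z-scores each metabolite across timepoints (mean 0, sample sd 1).
#' Rows constant across timepoints carry no profile shape and are
#' dropped with a warning.
#'
#' @param metab A [metab_set] whose biological samples carry numeric
#'   `timepoint` metadata covering >= 2 timepoints; impute missing
#'   values first.
#' @return Numeric matrix, metabolites x timepoints (columns named by
#'   timepoint, ascending).
#' @export
profile_matrix <- function(metab) {
  stopifnot(inherits(metab, "metab_set"))
  bio <- !metab$samples$is_qc & !is.na(metab$samples$timepoint)
  tps <- sort(unique(metab$samples$timepoint[bio]))
  if (length(tps) < 2) stop("need at least 2 timepoints", call. = FALSE)
  means <- matrix(vapply(tps, function(tp) {
    rowMeans(metab$intensities[, bio & metab$samples$timepoint == tp,
                               drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(metab$intensities))), nrow = nrow(metab$intensities))
  dimnames(means) <- list(rownames(metab$intensities), as.character(tps))
  sds <- apply(means, 1L, stats::sd)
  constant <- sds < 1e-12
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant profile(s)")
    means <- means[!constant, , drop = FALSE]
    sds <- sds[!constant]
  }
  (means - rowMeans(means)) / sds
}

# k-means++ seeding: first centre uniform, later centres with probability
# proportional to squared distance to the nearest chosen centre
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ], "-")^2)
  for (i in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      centers[i, ] <- x[sample.int(n, 1L), ]
    } else {
      centers[i, ] <- x[sample.int(n, 1L, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[i, ], "-")^2))
  }
  centers
}

lloyd_run <- function(x, centers, max_iter = 300L, tol = 1e-8) {
  k <- nrow(centers)
  inertia_trace <- numeric()
  assign <- integer(nrow(x))
  for (iter in seq_len(max_iter)) {
    # squared distances to every centroid
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, nrow(x)), rowSums(centers^2))
    assign <- max.col(-d2, ties.method = "first")
    inertia_trace <- c(inertia_trace,
                       sum(d2[cbind(seq_len(nrow(x)), assign)]))
    new_centers <- centers
    for (c_ in seq_len(k)) {
      members <- assign == c_
      if (any(members)) {
        new_centers[c_, ] <- colMeans(x[members, , drop = FALSE])
      } else {
        # re-seed an empty cluster at the worst-fitted point
        new_centers[c_, ] <- x[which.max(d2[cbind(seq_len(nrow(x)), assign)]), ]
      }
    }
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  assign <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(x)), assign)])
  list(assign = assign, centers = centers,
       inertia = inertia, inertia_trace = inertia_trace)
}

#' Cluster temporal profiles with restarted k-means
#'
#' K-means++ initialisation followed by Lloyd iterations (centroid shift
#' < 1e-8 or 300 iterations); the best of `restarts` runs by total
#' within-cluster sum of squares is kept.  Deterministic for a given
#' seed.
#'
#' @param profiles Numeric matrix, profiles in rows (e.g. from
#'   [profile_matrix()]).
#' @param k Number of clusters (default 8, the conventional cluster
#'   count for drought time-course metabolite profiles).
#' @param restarts Independent restarts (default 50).
#' @param seed Integer seed.
#' @return Object of class `profile_clustering`: `k`, `assignments`
#'   (named integer vector), `centroids` (k x timepoints), `inertia`,
#'   and the winning run's `inertia_trace`.
#' @export
kmeans_cluster <- function(profiles, k = 8L, restarts = 50L, seed = 1L) {
  stopifnot(is.matrix(profiles))
  stop_if_not_count(k, "k")
  stop_if_not_count(restarts, "restarts")
  if (k > nrow(profiles)) {
    stop("`k` exceeds the number of profiles", call. = FALSE)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      run <- lloyd_run(profiles, kmeanspp_init(profiles, k))
      if (is.null(best) || run$inertia < best$inertia) best <- run
    }
  })
  structure(list(
    k = as.integer(k),
    assignments = stats::setNames(best$assign, rownames(profiles)),
    centroids = best$centers,
    inertia = best$inertia,
    inertia_trace = best$inertia_trace
  ), class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("profile_clustering: %d profiles in %d clusters, inertia %.3f\n",
              length(x$assignments), x$k, x$inertia))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Compound-class composition per cluster
#'
#' @param clustering A [kmeans_cluster()] result.
#' @param class_labels Named character vector id -> class.
#' @return Named list, one [class_summary()] per cluster.
#' @export
cluster_class_counts <- function(clustering, class_labels) {
  stopifnot(inherits(clustering, "profile_clustering"))
  lapply(stats::setNames(seq_len(clustering$k),
                         paste0("cluster", seq_len(clustering$k))),
         function(c_) {
           ids <- names(clustering$assignments)[clustering$assignments == c_]
           class_summary(ids, class_labels)
         })
}
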