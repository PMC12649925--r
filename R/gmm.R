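# One-dimensional Gaussian mixture fitting by EM, used to separate
# high-importance transcription factors (signal component) from the
# background when deciding layer membership.

#' Fit a one-dimensional Gaussian mixture by expectation-maximisation
#'
#' Best of `n_init` random initialisations (component means drawn from
#' the data, common variance, uniform weights) by final log-likelihood.
#' Component variances are floored at 1e-10 to keep the likelihood
#' bounded when a component collapses onto duplicated points.
#'
#' @param values Numeric vector with at least `2 * n_components` points.
#' @param n_components Number of components (default 2: signal vs
#'   background).
#' @param n_init Random restarts (default 10).
#' @param seed Integer seed.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum EM iterations per start.
#' @param init Optional explicit start: a list with `means`,
#'   `variances`, `weights`; when given, the single EM run starts there
#'   and `n_init`/`seed` are ignored.
#' @return Object of class `gmm_fit`: `means`, `variances`, `weights`
#'   (sum 1), `responsibilities` (points x components, rows sum 1),
#'   `log_likelihood_trace` (non-decreasing), `log_likelihood`.
#' @export
gmm_fit_1d <- function(values, n_components = 2L, n_init = 10L, seed = 1L,
                       tol = 1e-8, max_iter = 500L, init = NULL) {
  values <- as.numeric(values)
  stop_if_not_count(n_components, "n_components")
  stop_if_not_count(n_init, "n_init")
  n <- length(values)
  if (n < 2L * n_components) {
    stop("need at least 2 * n_components data points", call. = FALSE)
  }
  best <- NULL
  if (!is.null(init)) n_init <- 1L
  with_seed(seed, {
    for (start in seq_len(n_init)) {
      if (!is.null(init)) {
        mu <- init$means; var_ <- init$variances; w <- init$weights
      } else {
        mu <- sample(values, n_components, replace = n < n_components)
        mu <- mu +
          stats::rnorm(n_components, sd = 1e-6 * (stats::sd(values) + 1e-12))
        var_ <- rep(max(stats::var(values), 1e-10), n_components)
        w <- rep(1 / n_components, n_components)
      }
      trace <- numeric()
      ll_old <- -Inf
      resp <- NULL
      for (iter in seq_len(max_iter)) {
        logd <- vapply(seq_len(n_components), function(c_) {
          stats::dnorm(values, mu[c_], sqrt(var_[c_]), log = TRUE) + log(w[c_])
        }, numeric(n))
        m <- apply(logd, 1L, max)
        lse <- m + log(rowSums(exp(logd - m)))
        ll <- sum(lse)
        trace <- c(trace, ll)
        resp <- exp(logd - lse)
        if (is.finite(ll_old) && ll - ll_old < tol) break
        ll_old <- ll
        nk <- colSums(resp)
        w <- nk / n
        mu <- colSums(resp * values) / nk
        var_ <- pmax(colSums(resp * (outer(values, mu, "-"))^2) / nk, 1e-10)
      }
      if (is.null(best) || trace[length(trace)] > best$log_likelihood) {
        best <- list(means = mu, variances = var_, weights = w,
                     responsibilities = resp,
                     log_likelihood_trace = trace,
                     log_likelihood = trace[length(trace)])
      }
    }
  })
  structure(c(list(n_components = as.integer(n_components),
                   values = values), best),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: %d components on %d points, logLik %.4f\n",
              x$n_components, length(x$values), x$log_likelihood))
  print(data.frame(mean = x$means, variance = x$variances,
                   weight = x$weights))
  invisible(x)
}

#' Posterior component responsibilities under a fitted mixture
#'
#' @param fit A [gmm_fit_1d()] result.
#' @param values Points to evaluate (defaults to the fitted data).
#' @return Matrix, points x components, rows summing to 1.
#' @export
gmm_posterior <- function(fit, values = fit$values) {
  stopifnot(inherits(fit, "gmm_fit"))
  logd <- vapply(seq_len(fit$n_components), function(c_) {
    stats::dnorm(values, fit$means[c_], sqrt(fit$variances[c_]), log = TRUE) +
      log(fit$weights[c_])
  }, numeric(length(values)))
  if (length(values) == 1L) logd <- matrix(logd, 1L)
  m <- apply(logd, 1L, max)
  exp(logd - (m + log(rowSums(exp(logd - m)))))
}
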