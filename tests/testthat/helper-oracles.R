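# Independent brute-force oracles, deliberately written from the
# definitions rather than sharing code with the package.

# BH step-up from the definition: find the largest k with
# p_(k) <= k/m * alpha; the adjusted value is the running minimum of
# m * p_(k) / k from the largest p downward.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in seq(m, 1)) {
    running <- min(running, m * p[ord[i]] / i)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# KNN imputation by exhaustive search over every candidate neighbour,
# recomputing distances cell by cell.
oracle_knn_impute <- function(mat, k) {
  out <- mat
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      if (!is.na(mat[i, j])) next
      cand <- c()
      dist <- c()
      for (o in seq_len(nrow(mat))) {
        if (o == i || is.na(mat[o, j])) next
        common <- which(!is.na(mat[i, ]) & !is.na(mat[o, ]))
        if (length(common) == 0) next
        cand <- c(cand, o)
        dist <- c(dist, sqrt(sum((mat[i, common] - mat[o, common])^2)))
      }
      if (length(cand) == 0) {
        out[i, j] <- mean(mat[i, ], na.rm = TRUE)
        next
      }
      sel <- order(dist)[seq_len(min(k, length(cand)))]
      ds <- dist[sel]
      w <- if (any(ds < 1e-12)) as.numeric(ds < 1e-12) else 1 / ds
      out[i, j] <- sum(w * mat[cand[sel], j]) / sum(w)
    }
  }
  out
}

# One-component NIPALS PLS regression of centred/UV-scaled X on centred
# y, from the textbook update equations.
oracle_pls1 <- function(x, y01) {
  xs <- scale(x, center = TRUE, scale = TRUE)
  yc <- y01 - mean(y01)
  w <- t(xs) %*% yc
  w <- w / sqrt(sum(w^2))
  t_ <- xs %*% w
  p <- t(xs) %*% t_ / sum(t_^2)
  list(w = as.numeric(w), t = as.numeric(t_), p = as.numeric(p))
}

# Straightforward 1-D Gaussian-mixture EM with the same variance floor,
# run from a given starting point (no restarts, no vectorisation
# tricks).
oracle_gmm_em <- function(x, mu, var_, w, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  k <- length(mu)
  ll_old <- -Inf
  trace <- c()
  for (iter in seq_len(max_iter)) {
    dens <- matrix(0, n, k)
    for (c_ in seq_len(k)) {
      dens[, c_] <- w[c_] * stats::dnorm(x, mu[c_], sqrt(var_[c_]))
    }
    tot <- rowSums(dens)
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    resp <- dens / tot
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    for (c_ in seq_len(k)) {
      nk <- sum(resp[, c_])
      w[c_] <- nk / n
      mu[c_] <- sum(resp[, c_] * x) / nk
      var_[c_] <- max(sum(resp[, c_] * (x - mu[c_])^2) / nk, 1e-10)
    }
  }
  list(means = mu, variances = var_, weights = w,
       log_likelihood = trace[length(trace)], trace = trace)
}

# adjusted Rand index from the contingency table definition
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ <- sum_a * sum_b / n2
  (sum_ij - exp_) / ((sum_a + sum_b) / 2 - exp_)
}
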