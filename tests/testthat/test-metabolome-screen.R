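make_metab <- function(mat, n_qc = 0, groups = NULL, classes = character()) {
  n <- ncol(mat)
  if (is.null(groups)) groups <- rep("g1", n - n_qc)
  samples <- data.frame(
    sample_id = colnames(mat) %||% sprintf("s%d", seq_len(n)),
    group = c(groups, rep("QC", n_qc)),
    replicate = seq_len(n),
    timepoint = c(as.numeric(factor(groups)) - 1, rep(NA, n_qc)),
    is_qc = c(rep(FALSE, n - n_qc), rep(TRUE, n_qc))
  )
  colnames(mat) <- samples$sample_id
  metab_set(mat, samples, classes)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("KNN imputation is exact on hand-checkable cases", {
  m <- matrix(c(1, 2, 3,
                1.1, 2.1, NA,
                10, 20, 30), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  got <- knn_impute(m, k = 2)
  # neighbours of b at distances sqrt(0.02) (a) and sqrt(399.62) (c)
  d_a <- sqrt(0.1^2 + 0.1^2); d_c <- sqrt(8.9^2 + 17.9^2)
  expect_equal(got["b", 3], (3 / d_a + 30 / d_c) / (1 / d_a + 1 / d_c),
               ignore_attr = TRUE)
  # complete matrix unchanged
  full <- matrix(rnorm(12), 3, 4)
  expect_identical(knn_impute(full, 2), full)
  # identical twin at zero distance dominates
  twin <- matrix(c(5, 6, 7,
                   5, 6, NA,
                   50, 1, 2), 3, 3, byrow = TRUE)
  expect_equal(knn_impute(twin, 2)[2, 3], 7)
  # all-missing row is an error naming the metabolite
  bad <- matrix(c(1, 2, NA, NA), 2, 2, byrow = TRUE,
                dimnames = list(c("ok", "void"), NULL))
  expect_error(knn_impute(bad, 1), "void")
})

test_that("KNN imputation equals the exhaustive-search oracle on small matrices", {
  set.seed(11)
  for (trial in 1:60) {
    nr <- sample(3:5, 1); nc <- sample(3:5, 1)
    m <- matrix(round(runif(nr * nc, 1, 100), 2), nr, nc)
    holes <- sample(length(m), sample(1:2, 1))
    m[holes] <- NA
    if (any(rowSums(!is.na(m)) == 0)) next
    k <- sample(1:4, 1)
    expect_equal(knn_impute(m, k), oracle_knn_impute(m, k), tolerance = 1e-12)
  }
})

test_that("QC CV filter uses sample sd and a strict threshold", {
  m <- matrix(c(5, 5, 5, 5, 5,    # constant QC -> CV 0, kept
                1, 1, 10, 20, 30, # QC CV exactly 0.5 -> dropped
                1, 1, 10, 11, 12), 3, 5, byrow = TRUE,
              dimnames = list(c("flat", "edge", "tight"), NULL))
  ms <- make_metab(m, n_qc = 3, groups = c("g1", "g1"))
  out <- qc_cv_filter(ms, cv_max = 0.5)
  expect_equal(unname(out$cv["edge"]), 0.5)
  expect_equal(out$dropped_ids, "edge")
  expect_setequal(rownames(out$retained$intensities), c("flat", "tight"))
  expect_error(qc_cv_filter(make_metab(m, n_qc = 1,
                                       groups = rep("g1", 4))), "QC")
})

test_that("QC CV filter separates planted high- and low-CV halves", {
  sim <- simulate_metabolome(400, n_qc = 20, missing_rate = 0,
                             qc_cv = c(0.2, 0.8), seed = 13)
  out <- qc_cv_filter(sim$metab, cv_max = 0.5)
  high <- names(which(sim$truth$qc_cv_true == 0.8))
  low <- names(which(sim$truth$qc_cv_true == 0.2))
  expect_gte(mean(high %in% out$dropped_ids), 0.85)
  expect_lte(mean(low %in% out$dropped_ids), 0.05)
})

test_that("PCA is an exact orthogonal decomposition", {
  set.seed(5)
  x <- matrix(rnorm(60), 10, 6)
  out <- pca_decomp(x, n_components = 6)
  expect_equal(crossprod(out$loadings), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full reconstruction reproduces the centred matrix
  xc <- scale(x, scale = FALSE)
  expect_equal(out$scores %*% t(out$loadings), xc, tolerance = 1e-6,
               ignore_attr = TRUE)
  # rank-1 data: first component explains everything
  r1 <- outer(rnorm(8), rnorm(5))
  out1 <- pca_decomp(r1, 2)
  expect_equal(out1$explained[1], 1, tolerance = 1e-10)
  expect_error(pca_decomp(matrix(3, 4, 4), 2), "constant")
  expect_error(pca_decomp(x, 20), "exceeds")
})

test_that("OPLS-DA orthogonal scores are orthogonal to the class vector", {
  set.seed(21)
  x <- matrix(rnorm(8 * 40), 8, 40)
  y <- rep(c("a", "b"), each = 4)
  fit <- oplsda_fit(x, y, n_orthogonal = 2)
  yc <- fit$y
  for (h in seq_len(fit$n_orthogonal)) {
    expect_lt(abs(sum(fit$t_orth[, h] * yc)), 1e-8)
  }
  expect_equal(sum(fit$w^2), 1, tolerance = 1e-10)
})

test_that("a single separating variable dominates the predictive weights", {
  set.seed(22)
  x <- matrix(rnorm(12 * 30, sd = 1), 12, 30)
  y <- rep(c("a", "b"), each = 6)
  x[, 17] <- ifelse(y == "b", 8, 0) + rnorm(12, sd = 0.1)
  colnames(x) <- sprintf("m%02d", 1:30)
  fit <- oplsda_fit(x, y, n_orthogonal = 1)
  expect_equal(names(which.max(abs(fit$w))), "m17")
  vip <- vip_scores(fit)
  expect_equal(vip$metabolite_id[which.max(vip$vip)], "m17")
})

test_that("zero orthogonal components reduce to one-component PLS", {
  set.seed(23)
  x <- matrix(rnorm(10 * 25), 10, 25)
  y <- rep(c(0, 1), each = 5)
  fit <- oplsda_fit(x, y, n_orthogonal = 0)
  oracle <- oracle_pls1(x, y)
  expect_equal(unname(fit$w), oracle$w, tolerance = 1e-8)
  expect_equal(fit$t, oracle$t, tolerance = 1e-8)
  expect_equal(unname(fit$p), oracle$p, tolerance = 1e-8)
  expect_error(oplsda_fit(x, rep("a", 10)), "two groups")
  expect_error(oplsda_fit(x[1:5, ], c("a", "a", "b", "b", "b")), "3 biological")
})

test_that("VIP normalisation holds on every fit and for one variable", {
  set.seed(24)
  for (trial in 1:5) {
    x <- matrix(rnorm(12 * sample(5:50, 1)), 12)
    fit <- oplsda_fit(x, rep(c("a", "b"), each = 6))
    expect_equal(mean(vip_scores(fit)$vip^2), 1, tolerance = 1e-6)
  }
  x1 <- matrix(rnorm(12), 12, 1, dimnames = list(NULL, "only"))
  fit1 <- oplsda_fit(x1, rep(c("a", "b"), each = 6), scale. = TRUE)
  expect_equal(vip_scores(fit1)$vip, 1, tolerance = 1e-10)
  expect_error(vip_scores(list()), "opls_model")
})

test_that("leave-one-out prediction beats permuted labels on planted data", {
  sim <- simulate_metabolome(150, replicates = 6, frac_differential = 0.2,
                             log2fc = 2, missing_rate = 0, seed = 31)
  sel <- !sim$metab$samples$is_qc
  x <- t(log2(sim$metab$intensities[, sel]))
  y <- sim$metab$samples$group[sel]
  q2 <- function(x, y) {
    yn <- as.numeric(factor(y)) - 1
    press <- 0
    for (i in seq_len(nrow(x))) {
      fit <- oplsda_fit(x[-i, ], y[-i], n_orthogonal = 0)
      xs <- (x[i, ] - fit$center) / fit$scale
      pred <- sum(xs * fit$w) * fit$c + mean(yn[-i])
      press <- press + (yn[i] - pred)^2
    }
    1 - press / sum((yn - mean(yn))^2)
  }
  real <- q2(x, y)
  set.seed(99)
  perm <- q2(x, sample(y))  # scrambled group structure
  expect_gt(real, perm)
  expect_gt(real, 0.5)
})

test_that("DAM screening applies strict VIP and inclusive FC boundaries", {
  vips <- data.frame(metabolite_id = c("a", "b", "c", "d", "e"),
                     vip = c(1.0, 1.5, 1.5, 1.5, 0.2))
  fc <- c(a = 4, b = 2, c = 0.5, d = 1.2, e = 9)
  res <- screen_dams(vips, fc)
  expect_equal(res$status, c("ns", "up", "down", "ns", "ns"))
  expect_error(screen_dams(vips, fc[-1]), "no fold change")

  set.seed(77)
  toy <- data.frame(metabolite_id = sprintf("m%02d", 1:30),
                    vip = round(runif(30, 0, 3), 2))
  fc30 <- setNames(round(2^runif(30, -3, 3), 3), toy$metabolite_id)
  res <- screen_dams(toy, fc30)
  hand <- vapply(seq_len(30), function(i) {
    v <- toy$vip[i]; f <- fc30[[toy$metabolite_id[i]]]
    if (v > 1 && f >= 2) "up" else if (v > 1 && f <= 0.5) "down" else "ns"
  }, character(1))
  expect_equal(res$status, hand)
})

test_that("the full metabolome screen recovers planted differentials", {
  sens <- fpr <- numeric(3)
  for (i in 1:3) {
    sim <- simulate_metabolome(400, frac_differential = 0.1, log2fc = 2,
                               seed = 40 + i)
    out <- screen_metabolome(sim$metab, "control", "treat1")
    hit <- out$table$metabolite_id[out$table$status != "ns"]
    truth <- sim$truth$differential_ids
    sens[i] <- mean(truth %in% hit)
    fpr[i] <- mean(setdiff(out$table$metabolite_id, truth) %in% hit)
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fpr), 0.1)
})

test_that("class summaries partition the id set", {
  labels <- c(a = "flavonoid", b = "flavonoid", c = "alkaloid")
  expect_equal(class_summary(c("a", "b", "c"), labels),
               c(alkaloid = 1L, flavonoid = 2L))
  expect_equal(class_summary(c("a", "z"), labels),
               c(flavonoid = 1L, other = 1L))
  expect_length(class_summary(character(), labels), 0)
  ids <- c("a", "b", "c", "q", "r")
  expect_equal(sum(class_summary(ids, labels)), length(ids))
})
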