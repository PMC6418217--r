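test_that("Hellinger rows have unit sum of squares", {
  expect_equal(hellinger(matrix(c(1, 1, 1, 1), 1)), matrix(0.5, 1, 4))
  expect_equal(hellinger(matrix(c(4, 0, 0), 1)), matrix(c(1, 0, 0), 1))
  expect_equal(round(hellinger(matrix(c(1, 3), 1)), 4),
               matrix(c(0.5, 0.8660), 1))
  set.seed(1)
  x <- matrix(rpois(15 * 6, 5) + 1, 15, 6)
  h <- hellinger(x)
  expect_equal(rowSums(h^2), rep(1, 15))
  if (requireNamespace("vegan", quietly = TRUE))
    expect_equal(h, unclass(vegan::decostand(x, "hellinger")),
                 ignore_attr = TRUE)
  expect_error(hellinger(rbind(c(0, 0), c(1, 2))), "zero row sum")
  expect_error(hellinger(matrix(c(-1, 2), 1)), "non-negative")
})

test_that("PCA separates constructed clusters and conserves variance", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40, 0, 0.1), 10, 4),
             matrix(rnorm(40, 3, 0.1), 10, 4))
  p <- pca(x)
  expect_gt(p$proportion[1], 0.9)
  expect_lt(max(p$scores[1:10, 1]), min(p$scores[11:20, 1]))
  expect_equal(sum(p$eigenvalues), p$total_variance, tolerance = 1e-10)
  expect_equal(p$eigenvalues,
               prcomp(x)$sdev[seq_along(p$eigenvalues)]^2, tolerance = 1e-10)
  iso <- matrix(rnorm(600 * 3), 600, 3)
  pe <- pca(iso)$eigenvalues
  expect_lt(max(pe) / min(pe), 1.5)  # isotropic noise: comparable eigenvalues
  expect_error(pca(matrix(1, 3, 3)), "rank 0")
})

test_that("RDA equals PCA of the fitted responses and matches vegan", {
  set.seed(5)
  n <- 24
  X <- standardize_env(matrix(rnorm(n * 2), n, 2))
  Y <- matrix(rnorm(n * 6), n, 6)
  m <- rda(Y, X)
  p_fit <- pca(m$fitted)
  expect_equal(m$eigenvalues, p_fit$eigenvalues, tolerance = 1e-10)
  if (requireNamespace("vegan", quietly = TRUE)) {
    mv <- vegan::rda(Y ~ X)
    expect_equal(unname(m$eigenvalues),
                 unname(mv$CCA$eig[seq_along(m$eigenvalues)]),
                 tolerance = 1e-8)
  }
  # noiseless single-gradient response: the constrained axis captures all
  x1 <- standardize_env(matrix(seq_len(n), n, 1))
  Y1 <- outer(drop(x1), c(1, -2, 0.5)) + 3
  m1 <- rda(Y1, x1)
  expect_equal(m1$constrained_proportion, 1, tolerance = 1e-10)
  expect_error(rda(Y, cbind(X, X[, 1])), "collinear")
})

test_that("unrelated predictors explain no more than their permutation null", {
  set.seed(6)
  n <- 50
  Y <- matrix(rnorm(n * 5), n, 5)
  X <- standardize_env(matrix(rnorm(n), n, 1))
  obs <- rda(Y, X)$constrained_proportion
  null <- vapply(1:199, function(i) {
    rda(Y, X[sample(n), , drop = FALSE])$constrained_proportion
  }, numeric(1))
  expect_lt(obs, quantile(null, 0.99))
  expect_lt(obs, 0.2)
})

test_that("variance inflation factors follow their closed form", {
  n <- 40
  q <- unclass(poly(seq_len(n), 3))   # zero-mean, exactly orthogonal columns
  v <- vif(q)
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-10)
  dup <- cbind(a = q[, 1], b = q[, 1])
  expect_equal(unname(vif(dup)), c(Inf, Inf))
  # empirical correlation exactly 0.9 by construction
  z1 <- q[, 1]; z2 <- q[, 2]          # orthonormal, mean zero
  x2 <- 0.9 * z1 + sqrt(1 - 0.81) * z2
  expect_equal(cor(z1, x2), 0.9, tolerance = 1e-12)
  v2 <- vif(cbind(z1, x2))
  expect_equal(unname(v2), rep(1 / (1 - 0.81), 2), tolerance = 1e-8)
})

test_that("forward selection finds the active gradient and respects AIC", {
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    n <- 60
    X <- standardize_env(matrix(rnorm(n * 6), n, 6))
    colnames(X) <- paste0("x", 1:6)
    signal <- outer(drop(X[, 3]), c(1, -1, 0.5, 0.2))
    Y <- signal + matrix(rnorm(n * 4, 0, sd(signal) / 3), n, 4)
    f <- forward_select_rda(Y, X)
    hits <- hits + (length(f$selected_variables) > 0 &&
                      f$selected_variables[1] == "x3")
    expect_true(all(diff(f$aic_path$aic) < 0))  # AIC never increases
  }
  expect_gte(hits, 45)
})

test_that("forward selection on noise stays at or near the null model", {
  lens <- integer(30)
  for (s in 1:30) {
    set.seed(1000 + s)
    Y <- matrix(rnorm(40 * 6), 40, 6)
    X <- standardize_env(matrix(rnorm(40 * 5), 40, 5))
    f <- forward_select_rda(Y, X)
    lens[s] <- length(f$selected_variables)
  }
  expect_gte(mean(lens <= 1), 0.8)   # AIC is liberal; spurious picks are rare
  expect_gt(sum(lens == 0), 12)
})

test_that("greedy first steps match exhaustive best subsets", {
  set.seed(12)
  n <- 30
  X <- standardize_env(matrix(rnorm(n * 4), n, 4))
  colnames(X) <- paste0("x", 1:4)
  Y <- outer(drop(X[, 2]), c(2, -1)) + 0.5 * outer(drop(X[, 4]), c(1, 1)) +
    matrix(rnorm(n * 2, 0, 0.3), n, 2)
  f <- forward_select_rda(Y, X)
  aic1 <- vapply(colnames(X), function(v)
    glacierLOAC:::rda_aic(Y, X[, v, drop = FALSE]), numeric(1))
  expect_equal(f$selected_variables[1], names(which.min(aic1)))
  pairs <- t(combn(colnames(X), 2))
  aic2 <- apply(pairs, 1, function(vv)
    glacierLOAC:::rda_aic(Y, X[, vv, drop = FALSE]))
  best_pair <- sort(pairs[which.min(aic2), ])
  expect_equal(sort(f$selected_variables[1:2]), best_pair)
})

test_that("first-axis regression equals squared correlation algebraically", {
  x <- seq(0, 10, length.out = 20)
  perfect <- pc1_env_regression(2 * x - 3, x)
  expect_equal(perfect$r2, 1, tolerance = 1e-12)
  expect_equal(perfect$slope, 2, tolerance = 1e-12)
  set.seed(9)
  s <- rnorm(100); e <- rnorm(100)
  fit <- pc1_env_regression(s, e)
  expect_equal(fit$r2, cor(s, e)^2, tolerance = 1e-12)
  expect_lt(fit$r2, 0.1)
  expect_error(pc1_env_regression(s, rep(1, 100)), "zero variance")
})

test_that("richness counts per season and season-unique taxa are exact", {
  m <- rbind(c(1, 0, 2, 0, 0),
             c(0, 0, 3, 0, 0),
             c(0, 4, 0, 1, 0),
             c(0, 1, 0, 0, 5))
  colnames(m) <- paste0("t", 1:5)
  season <- c("spring", "spring", "summer", "summer")
  out <- richness_summary(m, season)
  expect_equal(out$n_taxa[out$season == "spring"], 2)   # t1, t3
  expect_equal(out$n_taxa[out$season == "summer"], 3)   # t2, t4, t5
  expect_equal(out$n_unique[out$season == "spring"], 2)
  expect_equal(out$n_unique[out$season == "summer"], 3)
  ident <- richness_summary(rbind(m[1, ], m[1, ]), c("a", "b"))
  expect_equal(ident$n_unique, c(0, 0))
})
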