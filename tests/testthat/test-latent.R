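centered <- function(n, J, seed = 42) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * J), n, J, dimnames = list(NULL, paste0("v", 1:J)))
  sweep(X, 2, colMeans(X))
}

test_that("PCA of collinear points explains everything with one component", {
  t <- c(-2, -1, 0, 1, 2)
  X <- cbind(v1 = 3 * t, v2 = -4 * t)
  pc <- fit_pca(X, 1)
  expect_equal(pc$explained, 1, tolerance = 1e-12)
})

test_that("PCA agrees with the eigendecomposition oracle", {
  X <- centered(12, 20)
  pc <- fit_pca(X, 3)
  ev <- eigen(crossprod(X), symmetric = TRUE)
  expect_equal(abs(pc$loadings), abs(ev$vectors[, 1:3]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(pc$explained, ev$values[1:3] / sum(ev$values), tolerance = 1e-8)
  # definitional contract and sign convention
  expect_equal(pc$scores, X %*% pc$loadings, tolerance = 1e-12)
  for (j in 1:3) {
    v <- pc$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(fit_pca(X, 15), "exceeds")
})

test_that("PCA explained fractions are invariant to sample order", {
  X <- centered(10, 8, seed = 9)
  expect_equal(fit_pca(X, 3)$explained,
               fit_pca(X[sample(10), ], 3)$explained, tolerance = 1e-10)
})

test_that("OPLS-DA with no orthogonal components equals a one-component PLS", {
  skip_if_not_installed("mixOmics")
  X <- centered(12, 20)
  y <- rep(c("A", "B"), each = 6)
  m <- fit_oplsda(X, y, n_orth = 0, class_labels = c("A", "B"))
  ynum <- ifelse(y == "A", 1, -1)
  pls <- mixOmics::pls(X, ynum, ncomp = 1, scale = FALSE, mode = "regression")
  oracle <- predict(pls, X)$predict[, 1, 1] - mean(ynum)
  expect_equal(predict(m, X)$score, oracle, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("on noiseless rank-2 data one orthogonal component matches 2-component PLS", {
  skip_if_not_installed("mixOmics")
  set.seed(21)
  n <- 12; J <- 20
  t1 <- stats::rnorm(n); t2 <- stats::rnorm(n)
  yc <- t1 - mean(t1)
  t2 <- t2 - sum(t2 * yc) / sum(yc^2) * yc   # class-orthogonal variation
  p1 <- stats::rnorm(J); p2 <- stats::rnorm(J)
  y <- ifelse(yc > stats::median(yc), "A", "B")
  ynum <- ifelse(y == "A", 1, -1)
  build <- function(scale_o) {
    X <- outer(t1, p1) + outer(scale_o * t2, p2)
    X <- sweep(X, 2, colMeans(X)); colnames(X) <- paste0("v", 1:J)
    X
  }
  X <- build(1)
  m <- fit_oplsda(X, y, n_orth = 1, class_labels = c("A", "B"))
  pls2 <- mixOmics::pls(X, ynum, ncomp = 2, scale = FALSE, mode = "regression")
  oracle <- predict(pls2, X)$predict[, 1, 2] - mean(ynum)
  expect_equal(predict(m, X)$score, oracle, tolerance = 1e-6, ignore_attr = TRUE)
  # predictions invariant to inflating the orthogonal loading tenfold
  X10 <- build(10)
  m10 <- fit_oplsda(X10, y, n_orth = 1, class_labels = c("A", "B"))
  expect_equal(predict(m10, X10)$score, predict(m, X)$score, tolerance = 1e-6)
})

test_that("model invariants hold: unit weights, orthogonality, VIP identity", {
  X <- centered(14, 25, seed = 4)
  y <- rep(c("A", "B"), 7)
  m <- fit_oplsda(X, y, n_orth = 2, class_labels = c("A", "B"))
  expect_equal(sum(m$w_pred^2), 1, tolerance = 1e-10)
  for (wo in m$w_orth) {
    expect_equal(sum(wo^2), 1, tolerance = 1e-10)
    expect_lt(abs(sum(m$w_pred * wo)), 1e-8)
  }
  v <- vip(m)
  expect_true(all(v >= 0))
  expect_equal(sum(v^2), ncol(X), tolerance = 1e-8)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)
})

test_that("VIP closed forms: unit vector and uniform weights", {
  X <- centered(8, 4, seed = 5)
  y <- rep(c("A", "B"), 4)
  m <- fit_oplsda(X, y, n_orth = 0, class_labels = c("A", "B"))
  m$w_pred <- c(1, 0, 0, 0)
  expect_equal(vip(m), c(2, 0, 0, 0))
  m$w_pred <- rep(0.5, 4)
  expect_equal(vip(m), rep(1, 4))
})

test_that("perfect single-bin separation classifies training data exactly", {
  X <- centered(14, 10, seed = 6)
  y <- rep(c("A", "B"), each = 7)
  X[, 3] <- ifelse(y == "A", 5, -5) + stats::rnorm(14, 0, 0.1)
  X <- sweep(X, 2, colMeans(X))
  m <- fit_oplsda(X, y, n_orth = 1, class_labels = c("A", "B"))
  pr <- predict(m, X)
  expect_identical(pr$class, y)
  # a row at a class mean goes to that class; an all-zero row follows the tie rule
  pr_mean <- predict(m, rbind(colMeans(X[y == "A", ])))
  expect_identical(pr_mean$class, "A")
  thr0 <- m; thr0$decision_threshold <- 0
  expect_identical(predict(thr0, rbind(rep(0, 10)))$class, "A")
})

test_that("degenerate inputs are rejected and bin mismatch caught", {
  X <- centered(8, 5)
  expect_error(fit_oplsda(X, rep("A", 8)), "two classes")
  expect_error(fit_oplsda(X, rep(c("A", "B"), 4), n_orth = 20), "rank")
  m <- fit_oplsda(X, rep(c("A", "B"), 4), n_orth = 0)
  expect_error(predict(m, matrix(0, 2, 7)), "bin mismatch")
})

test_that("adding a pure-noise bin barely moves predictions", {
  X <- centered(14, 10, seed = 8)
  y <- rep(c("A", "B"), each = 7)
  X[, 1] <- ifelse(y == "A", 2, -2)
  X <- sweep(X, 2, colMeans(X))
  m <- fit_oplsda(X, y, n_orth = 0, class_labels = c("A", "B"))
  eps <- 1e-3
  Xn <- cbind(X, noise = stats::rnorm(14, 0, eps))
  Xn <- sweep(Xn, 2, colMeans(Xn))
  mn <- fit_oplsda(Xn, y, n_orth = 0, class_labels = c("A", "B"))
  expect_lt(max(abs(predict(mn, Xn)$score - predict(m, X)$score)), 10 * eps)
})
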