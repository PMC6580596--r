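lin_data <- function(n = 60, p = 8, sd = 0.1, seed = 21) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- as.vector(X %*% c(2, -1, rep(0, p - 2))) + rnorm(n, sd = sd)
  list(X = X, y = y)
}

test_that("monte_carlo_cv honours the passthrough and tie-break contracts", {
  d <- lin_data()
  fp <- function(Xf, yf, Xv) matrix(mean(yf), nrow(Xv), 2)
  expect_equal(monte_carlo_cv(list("only"), fp, d$X, d$y)$params, "only")
  # identical candidates: the first wins
  res <- monte_carlo_cv(list("a", "b"), fp, d$X, d$y, k = 4, seed = 2)
  expect_equal(res$index, 1L)
  expect_error(monte_carlo_cv(list(1, 2), fp, d$X[1:5, ], d$y[1:5]),
               class = "pancanrx_too_few_cells")
})

test_that("monte_carlo_cv picks the generating component count", {
  # selection-consistency: the design has two dominant factors and the
  # response lives on them, so the generating component count is 2
  wins <- vapply(1:20, function(s) {
    set.seed(300 + s)
    n <- 60; p <- 30
    Z <- matrix(rnorm(n * 2), n, 2)
    L <- matrix(rnorm(p * 2, sd = 3), p, 2)
    X <- Z %*% t(L) + matrix(rnorm(n * p, sd = 0.5), n, p)
    colnames(X) <- sprintf("f%02d", 1:p)
    y <- as.vector(Z %*% c(2, -1)) + rnorm(n, sd = 0.1)
    cands <- c(2L, 22L)
    res <- monte_carlo_cv(as.list(cands),
                          function(Xf, yf, Xv)
                            pancanrx:::pcr_path_predict(Xf, yf, Xv, cands, FALSE),
                          X, y, k = 10, seed = s)
    res$params == 2L
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("PCR at full rank equals ordinary least squares", {
  d <- lin_data(n = 50, p = 6, sd = 0.5)
  m <- fit_pcr(d$X, d$y, n_components = 6)
  ols <- stats::lm(d$y ~ d$X)
  expect_equal(predict(m, d$X), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("PCR scores match an independent eigendecomposition oracle", {
  d <- lin_data(n = 40, p = 12, sd = 0.3)
  m <- fit_pcr(d$X, d$y, n_components = 5)
  Xc <- sweep(d$X, 2, colMeans(d$X))
  ev <- eigen(crossprod(Xc), symmetric = TRUE)
  scores_pkg <- Xc %*% m$rotation
  scores_ora <- Xc %*% ev$vectors[, 1:5]
  # columns may differ in sign only
  for (j in 1:5)
    expect_lt(min(sum(abs(scores_pkg[, j] - scores_ora[, j])),
                  sum(abs(scores_pkg[, j] + scores_ora[, j]))) /
                sum(abs(scores_ora[, j])), 1e-8)
  # the wide-matrix Gram path agrees with the direct SVD
  d2 <- lin_data(n = 25, p = 60, sd = 0.3)
  m_wide <- fit_pcr(d2$X, d2$y, n_components = 4)
  sv <- svd(sweep(d2$X, 2, colMeans(d2$X)))
  g <- crossprod(sv$u[, 1:4], d2$y - mean(d2$y)) / sv$d[1:4]
  pred_ora <- mean(d2$y) +
    (sweep(d2$X, 2, colMeans(d2$X)) %*% sv$v[, 1:4]) %*% g
  expect_equal(predict(m_wide, d2$X), as.vector(pred_ora), tolerance = 1e-8)
})

test_that("PCR training MSE is non-increasing in the component count", {
  d <- lin_data(n = 45, p = 10, sd = 1)
  mse <- vapply(1:8, function(c) {
    m <- fit_pcr(d$X, d$y, n_components = c)
    mean((predict(m, d$X) - d$y)^2)
  }, numeric(1))
  expect_true(all(diff(mse) <= 1e-10))
})

test_that("SVR solves a realizable linear problem", {
  set.seed(5)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 2 * X[, 1]
  m <- fit_svr(X, y, "linear", grid = data.frame(C = 100, epsilon = 0.01),
               seed = 1)
  expect_gte(cor(rank(predict(m, X)), rank(y)), 0.99)
})

test_that("SVR dual matches the quadprog oracle on small instances", {
  skip_if_not_installed("quadprog")
  dual_obj <- function(K, y, eps, beta)
    0.5 * sum(beta * (K %*% beta)) - sum(beta * y) + eps * sum(abs(beta))
  set.seed(3)
  for (trial in 1:4) {
    n <- 14 + trial
    X <- matrix(rnorm(n * 3), n, 3)
    y <- X[, 1] - 0.5 * X[, 2] + rnorm(n, sd = 0.2)
    K <- if (trial %% 2 == 0) tcrossprod(X) / 3 else
      exp(-0.4 * as.matrix(dist(X))^2)
    C <- c(1, 10, 0.5, 50)[trial]; eps <- 0.1
    sol <- pancanrx:::.svr_smo(K, y, C, eps, tol = 1e-6)
    expect_true(sol$converged)

    # independent KKT certificate, recomputed from scratch in R on the
    # box-constrained beta formulation
    beta <- sol$beta
    g1 <- as.vector(K %*% beta) + eps - y     # alpha-side gradient
    g2 <- -as.vector(K %*% beta) + eps + y    # alpha*-side gradient
    a1 <- pmax(beta, 0); a2 <- pmax(-beta, 0)
    up <- c(a1 < C - 1e-12, a2 > 1e-12)
    lo <- c(a1 > 1e-12, a2 < C - 1e-12)
    v <- c(-g1, g2)
    expect_lt(max(v[up]) - min(v[lo]), 1e-5)

    # quadprog on a mildly ridged (hence solvable) copy of the dual; the
    # SMO objective must be at least as good
    ridge <- 1e-4
    Q <- rbind(cbind(K, -K), cbind(-K, K)) + diag(ridge, 2 * n)
    p <- c(eps - y, eps + y)
    A <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
    qp <- quadprog::solve.QP(Q, -p, A, c(0, rep(0, 2 * n), rep(-C, 2 * n)),
                             meq = 1)
    beta_qp <- qp$solution[1:n] - qp$solution[(n + 1):(2 * n)]
    expect_lte(dual_obj(K, y, eps, beta),
               dual_obj(K, y, eps, beta_qp) + 1e-5)
  }
})

test_that("RBF beats the linear kernel on a smooth nonlinear response", {
  wins <- vapply(1:10, function(s) {
    set.seed(600 + s)
    X <- matrix(runif(120, -2, 2), 60, 2,
                dimnames = list(NULL, c("x1", "x2")))
    y <- sin(2 * X[, 1]) + rnorm(60, sd = 0.1)
    tr <- 1:45; te <- 46:60
    small_lin <- default_svr_grid("linear")[c(5, 15, 25), ]
    small_rbf <- expand.grid(C = c(1, 10), epsilon = 0.1,
                             gamma = c(0.1, 1))
    ml <- fit_svr(X[tr, ], y[tr], "linear", grid = small_lin, cv_folds = 4,
                  seed = s)
    mr <- fit_svr(X[tr, ], y[tr], "rbf", grid = small_rbf, cv_folds = 4,
                  seed = s)
    rl <- cor(rank(predict(ml, X[te, ])), rank(y[te]))
    rr <- cor(rank(predict(mr, X[te, ])), rank(y[te]))
    rr > rl
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})

test_that("SVR on shuffled features has no test association", {
  rhos <- vapply(1:15, function(s) {
    set.seed(700 + s)
    X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, sprintf("f%d", 1:5)))
    y <- as.vector(X %*% rnorm(5)) + rnorm(50, sd = 0.2)
    Xs <- shuffle_matrix(X, seed = s)
    m <- fit_svr(Xs[1:35, ], y[1:35], "linear",
                 grid = data.frame(C = 1, epsilon = 0.1), seed = s)
    suppressWarnings(cor(rank(predict(m, Xs[36:50, ])), rank(y[36:50])))
  }, numeric(1))
  expect_lt(abs(mean(rhos, na.rm = TRUE)), 0.15)
})

test_that("grid validation rejects non-positive C and gamma", {
  d <- lin_data(n = 20, p = 3)
  expect_error(fit_svr(d$X, d$y, "linear",
                       grid = data.frame(C = -1, epsilon = 0.1)),
               class = "pancanrx_invalid_arg")
  expect_error(fit_svr(d$X, d$y, "rbf",
                       grid = data.frame(C = 1, epsilon = 0.1, gamma = 0)),
               class = "pancanrx_invalid_arg")
  g <- default_svr_grid("rbf")
  expect_equal(nrow(g), 210L)
  expect_equal(nrow(default_svr_grid("linear")), 30L)
})

test_that("ANN learns a linear signal and is seed-reproducible", {
  d <- lin_data(n = 80, p = 5, sd = 0.2, seed = 44)
  m <- fit_ann(d$X, d$y, dropout = 0, epochs = 60, seed = 9)
  expect_gt(cor(rank(predict(m, d$X)), rank(d$y)), 0.8)
  m2 <- fit_ann(d$X, d$y, dropout = 0, epochs = 60, seed = 9)
  expect_identical(predict(m, d$X), predict(m2, d$X))
  expect_false(m$warning_flag)
})

test_that("histotype-mean model is exactly the group-mean oracle", {
  ann <- data.frame(cell_id = sprintf("c%d", 1:6),
                    histotype = rep(c("a", "b"), each = 3))
  y <- c(1, 1, 1, 3, 3, 3)
  m <- fit_histotype_mean(ann, y)
  expect_equal(predict(m, ann, c("c1", "c4")), c(1, 3))
  # unseen histotype falls back to the global mean with a warning
  ann2 <- data.frame(cell_id = "zz", histotype = "new")
  expect_warning(p <- predict(m, ann2, "zz"), "unseen")
  expect_equal(p, 2)
  # equal group means: predictions collapse to a constant
  m2 <- fit_histotype_mean(ann, rep(5, 6))
  expect_equal(predict(m2, ann), rep(5, 6))
  # random cohorts: equivalence with direct group means
  for (s in 1:10) {
    set.seed(s)
    lab <- sample(letters[1:4], 30, replace = TRUE)
    ann3 <- data.frame(cell_id = sprintf("c%02d", 1:30), histotype = lab)
    yy <- rnorm(30)
    m3 <- fit_histotype_mean(ann3, yy)
    expect_equal(predict(m3, ann3),
                 as.vector(tapply(yy, lab, mean)[lab]))
  }
})

test_that("prediction respects name-based alignment and flags missing features", {
  d <- lin_data(n = 30, p = 6)
  m <- fit_pcr(d$X, d$y, n_components = 3)
  perm <- d$X[, sample(ncol(d$X))]
  expect_equal(predict(m, perm), predict(m, d$X))
  expect_error(predict(m, d$X[, 1:4]), class = "pancanrx_missing_feature")
  # in-sample prediction reproduces fitted values deterministically
  expect_equal(predict(m, d$X), predict(m, d$X))
})

test_that("information hygiene: tuning ignores test cells entirely", {
  co <- tiny_cohort(seed = 13L)
  tt <- train_test(co)
  deg <- spearman_screen(tt$X_train, tt$y_train)$features$probe_ids[1:10]
  m1 <- fit_pcr(tt$X_train[, deg], tt$y_train, max_components = 6, seed = 2)
  # retrain after perturbing the held-out data: identical model
  tt$X_test[] <- tt$X_test + 100
  tt$y_test <- rev(tt$y_test)
  m2 <- fit_pcr(tt$X_train[, deg], tt$y_train, max_components = 6, seed = 2)
  expect_identical(m1$score_coef, m2$score_coef)
  expect_identical(m1$n_components, m2$n_components)
})
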