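#' Monte Carlo cross-validation over a candidate grid
#'
#' Repeatedly splits the training data into a random fit/validation pair
#' (`k` times, the same folds for every candidate), obtains validation
#' predictions for all candidates, and returns the candidate with the
#' lowest mean validation MSE. Exact ties go to the earliest candidate, so
#' grids should be ordered simple-to-complex (fewest components / largest
#' regularization first).
#'
#' @param candidates list (or data.frame rows) of hyperparameter settings.
#' @param fit_predict `function(X_fit, y_fit, X_val)` returning an
#'   `n_val x length(candidates)` matrix of validation predictions.
#' @param X,y training data.
#' @param k number of random subsamples (default 10).
#' @param val_frac validation fraction per subsample (default 0.25).
#' @param seed RNG seed for the folds.
#' @return list: `index` of the chosen candidate, `params`, and the
#'   `k x n_candidates` matrix of validation MSEs.
#' @export
monte_carlo_cv <- function(candidates, fit_predict, X, y, k = 10L,
                           val_frac = 0.25, seed = 1L) {
  n_cand <- if (is.data.frame(candidates)) nrow(candidates) else length(candidates)
  if (n_cand == 1L)
    return(list(index = 1L, params = cv_candidate(candidates, 1L), mse = NULL))
  n <- nrow(X)
  if (n < 8L) stop_pancanrx("Monte Carlo CV needs >= 8 training cells",
                            "pancanrx_too_few_cells")
  n_val <- floor(val_frac * n)
  if (n_val < 2L) {
    warning("validation sets degenerate; using 2-cell validation sets",
            call. = FALSE)
    n_val <- 2L
  }
  mse <- with_seed(seed, {
    out <- matrix(NA_real_, k, n_cand)
    for (fold in seq_len(k)) {
      val <- sample(n, n_val)
      P <- fit_predict(X[-val, , drop = FALSE], y[-val], X[val, , drop = FALSE])
      out[fold, ] <- colMeans((P - y[val])^2)
    }
    out
  })
  idx <- which.min(colMeans(mse))
  list(index = idx, params = cv_candidate(candidates, idx), mse = mse)
}

cv_candidate <- function(candidates, i) {
  if (is.data.frame(candidates)) as.list(candidates[i, , drop = FALSE])
  else candidates[[i]]
}

# column-name-based alignment; missing features are a hard error
align_features <- function(X, features) {
  missing <- setdiff(features, colnames(X))
  if (length(missing) > 0L)
    stop_pancanrx(paste0("missing feature(s) in new data: ",
                         paste(head(missing, 5L), collapse = ", "),
                         if (length(missing) > 5L) " ..."),
                  "pancanrx_missing_feature")
  X[, features, drop = FALSE]
}

# ---------------------------------------------------------------------------
# Principal components regression

#' Fit principal-components regression
#'
#' Centers the training features (unit scaling optional), projects onto the
#' leading principal components of the training matrix, and runs ordinary
#' least squares in component space. The component count is chosen by
#' [monte_carlo_cv()] over `1..max_components`, computed efficiently from a
#' single SVD per fold.
#'
#' @param X_train training cells x features matrix.
#' @param y_train training response.
#' @param max_components largest component count considered (capped at the
#'   matrix rank; default 30).
#' @param n_components fix the component count, skipping CV.
#' @param scale. unit-scale features (default `FALSE`: centering only).
#' @param cv_folds,cv_val_frac,seed Monte Carlo CV controls.
#' @return a `pcr_model` (also `tuned_model`).
#' @export
fit_pcr <- function(X_train, y_train, max_components = 30L,
                    n_components = NULL, scale. = FALSE, cv_folds = 10L,
                    cv_val_frac = 0.25, seed = 1L) {
  if (nrow(X_train) < 2L || ncol(X_train) < 1L)
    stop_pancanrx("PCR needs >= 2 cells and >= 1 feature", "pancanrx_too_few_cells")
  if (all(apply(X_train, 2L, sd) == 0))
    stop_pancanrx("all features have zero variance", "pancanrx_degenerate")

  if (is.null(n_components)) {
    cmax <- min(max_components, nrow(X_train) - 2L, ncol(X_train))
    cands <- seq_len(max(cmax, 1L))
    chosen <- if (length(cands) == 1L) cands else
      monte_carlo_cv(as.list(cands),
                     function(Xf, yf, Xv) pcr_path_predict(Xf, yf, Xv, cands, scale.),
                     X_train, y_train, k = cv_folds, val_frac = cv_val_frac,
                     seed = seed)$params
    n_components <- as.integer(chosen)
  }

  fit <- pcr_core(X_train, y_train, n_components, scale.)
  structure(c(fit, list(features = colnames(X_train), family = "PCR",
                        chosen_params = list(n_components = fit$n_components))),
            class = c("pcr_model", "tuned_model"))
}

# thin SVD; for wide matrices (p > n) via the eigendecomposition of the
# n x n Gram matrix, which is much cheaper than a direct SVD
thin_svd <- function(Xc) {
  if (ncol(Xc) <= nrow(Xc)) return(svd(Xc))
  e <- eigen(tcrossprod(Xc), symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  pos <- d > 0
  v <- crossprod(Xc, sweep(e$vectors[, pos, drop = FALSE], 2L, d[pos], "/"))
  list(d = d[pos], u = e$vectors[, pos, drop = FALSE], v = v)
}

# single fit at component count c
pcr_core <- function(X, y, c, scale.) {
  mu <- colMeans(X)
  sc <- if (scale.) pmax(apply(X, 2L, sd), .Machine$double.eps) else
    rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2L, mu), 2L, sc, "/")
  sv <- thin_svd(Xc)
  r <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1L])
  c <- min(c, r)
  yc <- y - mean(y)
  g <- crossprod(sv$u[, seq_len(c), drop = FALSE], yc) / sv$d[seq_len(c)]
  list(center = mu, scaling = sc, rotation = sv$v[, seq_len(c), drop = FALSE],
       score_coef = as.vector(g), intercept = mean(y), n_components = c,
       singular_values = sv$d)
}

# validation predictions for every component count in one SVD
pcr_path_predict <- function(Xf, yf, Xv, cs, scale.) {
  mu <- colMeans(Xf)
  sc <- if (scale.) pmax(apply(Xf, 2L, sd), .Machine$double.eps) else
    rep(1, ncol(Xf))
  Xc <- sweep(sweep(Xf, 2L, mu), 2L, sc, "/")
  sv <- thin_svd(Xc)
  r <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1L])
  g <- numeric(length(sv$d))
  use <- seq_len(r)
  g[use] <- crossprod(sv$u[, use, drop = FALSE], yf - mean(yf)) / sv$d[use]
  S <- sweep(sweep(Xv, 2L, mu), 2L, sc, "/") %*% sv$v
  contrib <- sweep(S, 2L, g, "*")
  cum <- t(apply(contrib, 1L, cumsum))
  if (nrow(Xv) == 1L) cum <- matrix(cum, nrow = 1L)
  mean(yf) + cum[, pmin(cs, r), drop = FALSE]
}

#' @export
predict.pcr_model <- function(object, newdata, ...) {
  X <- align_features(newdata, object$features)
  Xc <- sweep(sweep(X, 2L, object$center), 2L, object$scaling, "/")
  as.vector(object$intercept + (Xc %*% object$rotation) %*% object$score_coef)
}

# ---------------------------------------------------------------------------
# Support vector regression

#' Default SVR hyperparameter grids
#'
#' 30 combinations for the linear kernel (10 costs x 3 tube widths) and
#' 210 for the RBF kernel (10 costs x 3 tube widths x 7 kernel widths),
#' ordered from most to least regularized so CV ties resolve to the
#' simpler model.
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @return data.frame of candidate rows (`C`, `epsilon`, and `gamma` for
#'   the RBF kernel).
#' @export
default_svr_grid <- function(kernel = c("linear", "rbf")) {
  kernel <- match.arg(kernel)
  Cs <- 10^seq(-2, 3, length.out = 10)
  eps <- c(0.01, 0.1, 0.5)
  if (kernel == "linear") {
    g <- expand.grid(epsilon = eps, C = Cs)[, c("C", "epsilon")]
  } else {
    g <- expand.grid(epsilon = eps, gamma = 10^seq(-4, 1, length.out = 7),
                     C = Cs)[, c("C", "epsilon", "gamma")]
  }
  g[order(g$C), , drop = FALSE]
}

#' Fit epsilon-insensitive support vector regression
#'
#' Solves the SVR dual with a native SMO solver; the hyperparameter grid is
#' resolved by [monte_carlo_cv()] with the kernel matrix shared across
#' candidates within each fold. Features are z-scored by training
#' statistics.
#'
#' @param X_train,y_train training data.
#' @param kernel `"linear"` or `"rbf"`.
#' @param grid candidate data.frame (`C`, `epsilon`[, `gamma`]); defaults
#'   to [default_svr_grid()].
#' @param standardize z-score features by training statistics (default TRUE).
#' @param cv_folds,cv_val_frac,seed Monte Carlo CV controls.
#' @param tol,max_iter SMO stopping controls.
#' @return an `svr_model` (also `tuned_model`).
#' @export
fit_svr <- function(X_train, y_train, kernel = c("linear", "rbf"),
                    grid = NULL, standardize = TRUE, cv_folds = 10L,
                    cv_val_frac = 0.25, seed = 1L, tol = 1e-3,
                    max_iter = 200000L) {
  kernel <- match.arg(kernel)
  grid <- grid %||% default_svr_grid(kernel)
  if (any(grid$C <= 0) || (kernel == "rbf" && any(grid$gamma <= 0)))
    stop_pancanrx("C and gamma must be positive", "pancanrx_invalid_arg")
  if (any(grid$epsilon < 0))
    stop_pancanrx("epsilon must be non-negative", "pancanrx_invalid_arg")

  std <- standardize_stats(X_train, standardize)
  Z <- apply_standardize(X_train, std)

  chosen <- if (nrow(grid) == 1L) as.list(grid[1L, , drop = FALSE]) else
    monte_carlo_cv(grid,
                   function(Xf, yf, Xv) svr_grid_predict(Xf, yf, Xv, grid,
                                                         kernel, tol, max_iter),
                   Z, y_train, k = cv_folds, val_frac = cv_val_frac,
                   seed = seed)$params

  K <- svr_kernel(Z, Z, kernel, chosen$gamma)
  sol <- .svr_smo(K, y_train, chosen$C, chosen$epsilon, tol, max_iter)
  if (!sol$converged)
    warning("SVR solver hit the iteration cap before convergence", call. = FALSE)
  structure(list(family = if (kernel == "rbf") "SVR_RBF" else "SVR_LINEAR",
                 kernel = kernel, chosen_params = chosen,
                 beta = sol$beta, b = sol$b, converged = sol$converged,
                 support_points = Z, std = std, features = colnames(X_train)),
            class = c("svr_model", "tuned_model"))
}

standardize_stats <- function(X, standardize) {
  if (!standardize) return(list(center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  list(center = colMeans(X), scale = pmax(apply(X, 2L, sd), .Machine$double.eps))
}

apply_standardize <- function(X, std) {
  sweep(sweep(X, 2L, std$center), 2L, std$scale, "/")
}

svr_kernel <- function(A, B, kernel, gamma = NULL) {
  # linear kernel = mean inner product, so the cost grid is comparable
  # across feature counts and the solver is well-conditioned
  if (kernel == "linear") return(tcrossprod(A, B) / ncol(A))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# validation predictions for every grid row; kernel shared per gamma
svr_grid_predict <- function(Xf, yf, Xv, grid, kernel, tol, max_iter) {
  P <- matrix(NA_real_, nrow(Xv), nrow(grid))
  gammas <- if (kernel == "rbf") unique(grid$gamma) else NA_real_
  for (gm in gammas) {
    rows <- if (kernel == "rbf") which(grid$gamma == gm) else seq_len(nrow(grid))
    Kf <- svr_kernel(Xf, Xf, kernel, gm)
    Kv <- svr_kernel(Xv, Xf, kernel, gm)
    for (r in rows) {
      sol <- .svr_smo(Kf, yf, grid$C[r], grid$epsilon[r], tol, max_iter)
      P[, r] <- as.vector(Kv %*% sol$beta) + sol$b
    }
  }
  P
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  X <- align_features(newdata, object$features)
  Z <- apply_standardize(X, object$std)
  K <- svr_kernel(Z, object$support_points, object$kernel,
                  object$chosen_params$gamma)
  as.vector(K %*% object$beta) + object$b
}

# ---------------------------------------------------------------------------
# Single-hidden-layer neural network (optional family)

#' Fit a single-hidden-layer neural network with dropout
#'
#' A 20-unit tanh hidden layer with a linear output, trained by Adam on
#' mini-batches with inverted dropout on the hidden activations; the
#' dropout rate is chosen from `dropout_grid` by [monte_carlo_cv()]. This
#' family is a pluggable extra: nothing downstream depends on it.
#'
#' @param X_train,y_train training data.
#' @param hidden hidden units (default 20).
#' @param dropout_grid candidate dropout rates (default 0, 0.10, 0.25, 0.50).
#' @param dropout fix the rate, skipping CV.
#' @param epochs,learning_rate,batch_size optimizer controls.
#' @param cv_folds,cv_val_frac,seed CV and initialization controls.
#' @return an `ann_model` (also `tuned_model`); `warning_flag` is TRUE if
#'   training failed to reduce the loss.
#' @export
fit_ann <- function(X_train, y_train, hidden = 20L,
                    dropout_grid = c(0, 0.10, 0.25, 0.50), dropout = NULL,
                    epochs = 100L, learning_rate = 0.01, batch_size = 32L,
                    cv_folds = 10L, cv_val_frac = 0.25, seed = 1L) {
  std <- standardize_stats(X_train, TRUE)
  Z <- apply_standardize(X_train, std)
  y_mu <- mean(y_train); y_sd <- max(sd(y_train), .Machine$double.eps)
  ys <- (y_train - y_mu) / y_sd

  if (is.null(dropout)) {
    dropout <- if (length(dropout_grid) == 1L) dropout_grid else
      monte_carlo_cv(as.list(dropout_grid),
                     function(Xf, yf, Xv) {
                       vapply(dropout_grid, function(dr) {
                         net <- ann_train(Xf, yf, hidden, dr, epochs,
                                          learning_rate, batch_size,
                                          derive_seed(seed, "cv", dr))
                         ann_forward(net, Xv)
                       }, numeric(nrow(Xv)))
                     },
                     Z, ys, k = cv_folds, val_frac = cv_val_frac,
                     seed = seed)$params
  }
  net <- ann_train(Z, ys, hidden, dropout, epochs, learning_rate, batch_size,
                   derive_seed(seed, "final"))
  if (net$warning_flag)
    warning("ANN training did not reduce the loss; model flagged", call. = FALSE)
  structure(list(family = "ANN", net = net, std = std, y_mu = y_mu, y_sd = y_sd,
                 chosen_params = list(dropout = dropout, hidden = hidden),
                 warning_flag = net$warning_flag, features = colnames(X_train)),
            class = c("ann_model", "tuned_model"))
}

ann_train <- function(X, y, hidden, dropout, epochs, lr, batch_size, seed) {
  with_seed(seed, {
    p <- ncol(X); n <- nrow(X)
    W1 <- matrix(rnorm(p * hidden, sd = 1 / sqrt(p)), p, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(rnorm(hidden, sd = 1 / sqrt(hidden)), hidden, 1L)
    b2 <- 0
    pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    mom <- lapply(pars, function(x) x * 0)
    vel <- lapply(pars, function(x) x * 0)
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; step <- 0
    first_loss <- mean((y - mean(y))^2); last_loss <- first_loss
    for (ep in seq_len(epochs)) {
      idx <- sample(n)
      for (start in seq(1L, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1L, n)]
        Xb <- X[bi, , drop = FALSE]; yb <- y[bi]
        A <- tanh(sweep(Xb %*% pars$W1, 2L, pars$b1, "+"))
        if (dropout > 0) {
          mask <- matrix(runif(length(A)) >= dropout, nrow(A), ncol(A)) /
            (1 - dropout)
          H <- A * mask
        } else { mask <- NULL; H <- A }
        pred <- as.vector(H %*% pars$W2) + pars$b2
        err <- pred - yb
        dH <- err %o% as.vector(pars$W2)
        if (!is.null(mask)) dH <- dH * mask
        dA <- dH * (1 - A^2)
        grads <- list(
          W1 = crossprod(Xb, dA) / length(bi),
          b1 = colMeans(dA),
          W2 = crossprod(H, err) / length(bi),
          b2 = mean(err))
        step <- step + 1
        for (nm in names(pars)) {
          mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
          vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
          m_hat <- mom[[nm]] / (1 - beta1^step)
          v_hat <- vel[[nm]] / (1 - beta2^step)
          pars[[nm]] <- pars[[nm]] - lr * m_hat / (sqrt(v_hat) + adam_eps)
        }
      }
      H <- tanh(sweep(X %*% pars$W1, 2L, pars$b1, "+"))
      last_loss <- mean((as.vector(H %*% pars$W2) + pars$b2 - y)^2)
    }
    c(pars, list(warning_flag = !is.finite(last_loss) || last_loss > first_loss))
  })
}

ann_forward <- function(net, X) {
  H <- tanh(sweep(X %*% net$W1, 2L, net$b1, "+"))
  as.vector(H %*% net$W2) + net$b2
}

#' @export
predict.ann_model <- function(object, newdata, ...) {
  X <- align_features(newdata, object$features)
  Z <- apply_standardize(X, object$std)
  ann_forward(object$net, Z) * object$y_sd + object$y_mu
}

# ---------------------------------------------------------------------------
# Histotype-mean baseline

#' Fit the histotype-mean baseline
#'
#' Least squares on the one-hot histotype encoding, which is exactly the
#' per-histotype training mean of the response. At prediction time an
#' unseen histotype falls back to the global training mean with a warning.
#'
#' @param annotation_train data.frame `cell_id`, `histotype` covering the
#'   training cells.
#' @param y_train training response, aligned with `cells`.
#' @param cells training cell IDs (default: annotation order).
#' @return a `histmean_model` (also `tuned_model`).
#' @export
fit_histotype_mean <- function(annotation_train, y_train,
                               cells = annotation_train$cell_id) {
  lab <- annotation_train$histotype[match(cells, annotation_train$cell_id)]
  if (anyNA(lab))
    stop_pancanrx("unlabeled training cell(s)", "pancanrx_invalid_arg")
  means <- tapply(y_train, lab, mean)
  structure(list(family = "HIST_MEAN",
                 group_means = setNames(as.vector(means), names(means)),
                 global_mean = mean(y_train),
                 chosen_params = list(), features = NULL),
            class = c("histmean_model", "tuned_model"))
}

#' @export
#' @param annotation data.frame `cell_id`, `histotype` for the new cells.
#' @param cells cell IDs to predict.
#' @rdname fit_histotype_mean
predict.histmean_model <- function(object, annotation, cells = annotation$cell_id,
                                   ...) {
  lab <- annotation$histotype[match(cells, annotation$cell_id)]
  pred <- object$group_means[lab]
  unseen <- is.na(pred)
  if (any(unseen)) {
    warning(sprintf("%d cell(s) from unseen histotype(s); using global mean",
                    sum(unseen)), call. = FALSE)
    pred[unseen] <- object$global_mean
  }
  unname(pred)
}

# ---------------------------------------------------------------------------

#' Construct a prediction set
#'
#' Pairs measured and predicted held-out responses with their provenance.
#'
#' @param cell_ids test-cell IDs.
#' @param y_measured,y_predicted log IC50 vectors of matching length.
#' @param drug,split,family,feature_method provenance labels.
#' @return data.frame of class `prediction_set`.
#' @export
prediction_set <- function(cell_ids, y_measured, y_predicted, drug = NA,
                           split = NA, family = NA, feature_method = NA) {
  stopifnot(length(y_measured) == length(y_predicted),
            length(cell_ids) == length(y_measured))
  structure(data.frame(cell_id = cell_ids, y_measured = y_measured,
                       y_predicted = y_predicted,
                       drug = drug, split = split, family = family,
                       feature_method = feature_method,
                       stringsAsFactors = FALSE),
            class = c("prediction_set", "data.frame"))
}
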