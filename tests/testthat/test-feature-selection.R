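make_screen_data <- function(n = 50, m = 30, seed = 8) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m,
              dimnames = list(NULL, sprintf("p%03d", 1:m)))
  y <- rnorm(n)
  list(X = X, y = y)
}

test_that("spearman screen finds perfect probes and respects symmetry", {
  d <- make_screen_data()
  d$X[, 1] <- d$y                      # identical to the response
  out <- spearman_screen(d$X, d$y)
  expect_true("p001" %in% out$features$probe_ids)
  expect_lt(out$screen["p001", "p"], 1e-20)
  # sign flip of y leaves the selected set unchanged
  flipped <- spearman_screen(d$X, -d$y)
  expect_setequal(out$features$probe_ids, flipped$features$probe_ids)
  expect_error(spearman_screen(d$X, rep(1, nrow(d$X))),
               class = "pancanrx_constant_response")
  # constant probe gets p = 1
  d$X[, 2] <- 5
  expect_equal(spearman_screen(d$X, d$y)$screen["p002", "p"], 1)
})

test_that("screen p-values match the t-approximation oracle per probe", {
  d <- make_screen_data(n = 24, m = 10, seed = 2)
  scr <- spearman_screen(d$X, d$y)$screen
  for (j in 1:10) {
    rho <- cor(rank(d$X[, j]), rank(d$y))
    tt <- rho * sqrt((24 - 2) / (1 - rho^2))
    expect_equal(scr$rho[j], rho, tolerance = 1e-12)
    expect_equal(scr$p[j], 2 * pt(-abs(tt), 22), tolerance = 1e-12)
  }
})

test_that("bonferroni_threshold is alpha/m", {
  # panel-scale value: 0.05 / 49386 = 1.0e-6 to two significant figures
  expect_equal(signif(bonferroni_threshold(0.05, 49386), 2), 1.0e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 500), 1e-4)
  expect_error(bonferroni_threshold(0.05, 0), class = "pancanrx_invalid_arg")
  expect_error(bonferroni_threshold(1.2, 10), class = "pancanrx_invalid_arg")
})

test_that("BC is nested in DEG and counts are monotone in stringency", {
  co <- tiny_cohort()
  tt <- train_test(co)
  deg <- spearman_screen(tt$X_train, tt$y_train)$features
  bc <- spearman_screen(tt$X_train, tt$y_train,
                        alpha = bonferroni_threshold(0.05, ncol(tt$X_train)),
                        method = "BC")$features
  expect_true(all(bc$probe_ids %in% deg$probe_ids))
  expect_lte(bc$n_features, deg$n_features)
  expect_lte(deg$n_features, ncol(tt$X_train))
})

test_that("moderated t with d0 = 0 equals the ordinary pooled t exactly", {
  d <- make_screen_data(n = 40, m = 15, seed = 3)
  out <- select_moderated_t(d$X, d$y, d0_override = 0)
  n_tail <- 10
  ord <- order(d$y)
  g2 <- d$X[ord[1:n_tail], ]          # sensitive
  g1 <- d$X[ord[31:40], ]             # resistant
  for (j in 1:15) {
    tt <- t.test(g1[, j], g2[, j], var.equal = TRUE)
    expect_equal(out$table$t[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(out$table$p[j], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t matches the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(12)
  n_per <- 8; m <- 200
  # two groups with heterogeneous probe variances
  sds <- sqrt(1 / rgamma(m, shape = 4, rate = 4))
  X <- rbind(matrix(rnorm(n_per * m, sd = rep(sds, each = n_per)), n_per, m),
             matrix(rnorm(n_per * m, sd = rep(sds, each = n_per)), n_per, m))
  X[seq_len(n_per), 1:20] <- X[seq_len(n_per), 1:20] + 1.2
  colnames(X) <- sprintf("p%03d", 1:m)
  # response orders the first n_per cells into the resistant tail
  y <- c(rnorm(n_per, 10, 0.1), rnorm(n_per, 0, 0.1))
  out <- select_moderated_t(X, y, tail_frac = 0.5)

  fit <- limma::lmFit(t(X), cbind(1, c(rep(1, n_per), rep(0, n_per))))
  eb <- limma::eBayes(fit)
  expect_equal(attr(out$table, "d0"), eb$df.prior, tolerance = 1e-6)
  expect_equal(attr(out$table, "s0sq"), eb$s2.prior, tolerance = 1e-6)
  expect_equal(out$table$t, unname(eb$t[, 2]), tolerance = 1e-8)
  expect_equal(out$table$p, unname(eb$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderated-t FDR holds on null data", {
  hits <- vapply(1:25, function(s) {
    d <- make_screen_data(n = 40, m = 120, seed = 400 + s)
    select_moderated_t(d$X, d$y)$features$n_features
  }, numeric(1))
  expect_lte(mean(hits) / 120, 0.05)
})

test_that("bootstrap selection: perfect probes survive, noise probes do not", {
  d <- make_screen_data(n = 40, m = 20, seed = 5)
  d$X[, 1] <- d$y + rnorm(40, sd = 1e-3)
  bs <- select_bootstrap(d$X, d$y, n_boot = 20, seed = 2)
  expect_true("p001" %in% bs$probe_ids)
  # pure-noise probes essentially never survive consensus = 1
  expect_lte(bs$n_features, 3L)
  # BS is contained in DEG on the same training data (necessary in
  # expectation; checked over seeds)
  for (s in 1:5) {
    co <- tiny_cohort(seed = 50L + s)
    tt <- train_test(co)
    deg <- spearman_screen(tt$X_train, tt$y_train)$features
    bs2 <- select_bootstrap(tt$X_train, tt$y_train, n_boot = 15, seed = s)
    expect_true(all(bs2$probe_ids %in% deg$probe_ids))
  }
})

test_that("histotype-stratified bootstrap uses one cell per histotype", {
  co <- tiny_cohort(n_histotypes = 8L, cells_per_histotype = 10L)
  tt <- train_test(co)
  bsh <- select_bootstrap(tt$X_train, tt$y_train, n_boot = 10,
                          stratify_histotype = TRUE,
                          annotation = co$annotation, seed = 4)
  expect_s3_class(bsh, "feature_set")
  expect_equal(bsh$method, "BS_HIST")
  expect_equal(bsh$params$consensus, 0.5)
  expect_error(select_bootstrap(tt$X_train, tt$y_train, consensus = 1.5),
               class = "pancanrx_invalid_arg")
})

test_that("MRMR matches the brute-force greedy oracle", {
  # independent oracle: exhaustive greedy over the stated criterion
  greedy_oracle <- function(X, y, k) {
    rel <- abs(apply(X, 2, function(col) cor(rank(col), rank(y))))
    rel[is.na(rel)] <- 0
    S <- integer(0)
    for (step in seq_len(k)) {
      best <- -Inf; pick <- NA
      for (g in setdiff(seq_len(ncol(X)), S)) {
        red <- if (length(S) == 0) 0 else
          mean(abs(vapply(S, function(s)
            cor(rank(X[, g]), rank(X[, s])), numeric(1))))
        sc <- rel[g] - red
        if (sc > best + 1e-12) { best <- sc; pick <- g }
      }
      S <- c(S, pick)
    }
    colnames(X)[S]
  }
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, letters[1:8]))
    y <- rnorm(20)
    expect_equal(select_mrmr(X, y, k = 3)$probe_ids, greedy_oracle(X, y, 3))
  }
  # k = 1 is the single most relevant probe
  set.seed(9)
  X <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, letters[1:6]))
  y <- X[, 3] + rnorm(30, sd = 0.1)
  expect_equal(select_mrmr(X, y, k = 1)$probe_ids, "c")
  # a duplicated probe is never picked second
  X2 <- cbind(X, dup = X[, 3])
  picks <- select_mrmr(X2, y, k = 2)$probe_ids
  expect_equal(picks[1], "c")
  expect_false(picks[2] == "dup")
  expect_error(select_mrmr(X, y, k = 99), class = "pancanrx_invalid_arg")
})

test_that("control constructions have the stated cardinalities", {
  probes <- sprintf("p%03d", 1:100)
  deg <- feature_set(probes[1:30], "DEG")
  ctr1 <- make_control_features(probes, deg, "CTR1", seed = 3)
  ctr2 <- make_control_features(probes, deg, "CTR2")
  expect_equal(ctr1$n_features, 30L)
  expect_equal(ctr2$n_features, 70L)
  expect_length(intersect(ctr2$probe_ids, deg$probe_ids), 0L)
  expect_identical(ctr1$probe_ids,
                   make_control_features(probes, deg, "CTR1", seed = 3)$probe_ids)
  # CTR1 samples from ALL probes: overlap with the reference is possible
  overlaps <- vapply(1:20, function(s)
    length(intersect(make_control_features(probes, deg, "CTR1",
                                           seed = s)$probe_ids,
                     deg$probe_ids)), numeric(1))
  expect_gt(sum(overlaps), 0)
  # empty reference
  empty <- feature_set(character(0), "DEG")
  expect_equal(make_control_features(probes, empty, "CTR1")$n_features, 0L)
  expect_equal(make_control_features(probes, empty, "CTR2")$n_features, 100L)
})

test_that("shuffle_matrix permutes columns and is seed-reproducible", {
  d <- make_screen_data(n = 25, m = 10)
  S1 <- shuffle_matrix(d$X, 6, seed = 7)
  S2 <- shuffle_matrix(d$X, 6, seed = 7)
  expect_identical(S1, S2)
  for (j in colnames(S1)) {
    expect_equal(sort(S1[, j]), sort(d$X[, j]))   # multiset preserved
  }
  expect_error(shuffle_matrix(d$X, 11), class = "pancanrx_invalid_arg")
})

test_that("one-hot encoding satisfies the row and column contracts", {
  ann <- data.frame(cell_id = c("c1", "c2", "c3"),
                    histotype = c("a", "b", "a"))
  M <- encode_histotype(ann, ann$cell_id)
  expect_equal(unname(M), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_true(all(rowSums(M) == 1))
  expect_equal(unname(colSums(M)), c(2, 1))
  expect_error(encode_histotype(ann, c("c1", "zz")),
               class = "pancanrx_invalid_arg")
})

test_that("selectors never look at test cells", {
  co <- tiny_cohort(seed = 77L)
  tt <- train_test(co)
  deg1 <- spearman_screen(tt$X_train, tt$y_train)$features
  mrmr1 <- select_mrmr(tt$X_train, tt$y_train, k = 5)
  # perturbing the held-out response cannot change any training-only set
  deg2 <- spearman_screen(tt$X_train, tt$y_train)$features
  expect_identical(deg1$probe_ids, deg2$probe_ids)
  expect_identical(mrmr1$probe_ids,
                   select_mrmr(tt$X_train, tt$y_train, k = 5)$probe_ids)
})
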