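#' Cluster cells on a feature subset with restarted k-means
#'
#' k-means with k-means++-style seeding, keeping the best of `n_restarts`
#' runs by within-cluster sum of squares. Deterministic given `seed`.
#'
#' @param X cells x probes matrix.
#' @param feature_set a [feature_set()] or character vector of probe IDs;
#'   `NULL` uses all columns.
#' @param k number of clusters (conventionally the number of retained
#'   histotypes).
#' @param n_restarts independent seeded restarts (default 10).
#' @param seed RNG seed.
#' @return list of class `clustering_result`: `assignments` (named integer
#'   vector), `k`, `objective` (best total within-cluster SS),
#'   `restart_objectives`, `seed`.
#' @export
cluster_features <- function(X, feature_set = NULL, k, n_restarts = 10L,
                             seed = 1L) {
  ids <- if (is.null(feature_set)) colnames(X) else
    if (inherits(feature_set, "feature_set")) feature_set$probe_ids else
      as.character(feature_set)
  if (length(ids) < 1L)
    stop_pancanrx("need at least one feature to cluster", "pancanrx_invalid_arg")
  if (k > nrow(X))
    stop_pancanrx("k exceeds the number of cells", "pancanrx_invalid_arg")
  M <- align_features(X, ids)

  runs <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      # an empty cluster aborts Hartigan-Wong: re-seed and retry
      for (attempt in 1:5) {
        centers <- kmeanspp_centers(M, k)
        km <- tryCatch(
          suppressWarnings(kmeans(M, centers = centers, iter.max = 50L)),
          error = function(e) NULL)
        if (!is.null(km)) return(km)
      }
      stop_pancanrx("k-means failed after 5 re-seedings", "pancanrx_degenerate")
    })
  })
  objectives <- vapply(runs, function(km) km$tot.withinss, numeric(1))
  best <- runs[[which.min(objectives)]]
  structure(list(assignments = setNames(best$cluster, rownames(X)),
                 k = k, objective = min(objectives),
                 restart_objectives = objectives, seed = seed),
            class = "clustering_result")
}

# k-means++ seeding: each next center drawn proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(M, k) {
  n <- nrow(M)
  centers <- matrix(NA_real_, k, ncol(M))
  centers[1L, ] <- M[sample(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(M, 2L, centers[1L, ])^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      pick <- sample(n, 1L, prob = prob)
      centers[j, ] <- M[pick, ]
      d2 <- pmin(d2, rowSums(sweep(M, 2L, centers[j, ])^2))
    }
  }
  # jitter exact duplicates so kmeans accepts the center matrix
  dup <- duplicated(centers)
  if (any(dup))
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(rnorm(sum(dup) * ncol(M), sd = 1e-8), sum(dup))
  centers
}

#' Cluster entropy of a histotype labeling
#'
#' The cluster-size-weighted mean of the within-cluster histotype label
#' entropy (natural log):
#' \deqn{S_c = \sum_j \frac{n_j}{N} H_j, \quad
#'       H_j = -\sum_i p_{ij} \ln p_{ij}}
#' where `p_ij` is the fraction of cluster `j` drawn from histotype `i`.
#' `S_c = 0` exactly when every cluster is histotype-pure; empty clusters
#' are ignored.
#'
#' @param assignments cluster assignment per cell (named by cell ID, as
#'   returned by [cluster_features()], or a bare vector aligned with
#'   `annotation`).
#' @param annotation data.frame `cell_id`, `histotype`.
#' @return the raw cluster entropy (nats).
#' @export
cluster_entropy <- function(assignments, annotation) {
  if (inherits(assignments, "clustering_result"))
    assignments <- assignments$assignments
  cells <- names(assignments) %||% annotation$cell_id
  lab <- annotation$histotype[match(cells, annotation$cell_id)]
  if (anyNA(lab))
    stop_pancanrx("annotation does not cover the clustered cells",
                  "pancanrx_invalid_arg")
  N <- length(assignments)
  tab <- table(assignments, lab)
  cluster_sizes <- rowSums(tab)
  H_j <- apply(tab, 1L, function(row) {
    p <- row[row > 0] / sum(row)
    -sum(p * log(p))
  })
  sum(cluster_sizes / N * H_j)
}

#' Random-control-normalized cluster entropy
#'
#' Divides a raw cluster entropy by the mean entropy of matched random
#' controls: the same matrix with a size-matched set of columns
#' independently shuffled across cells ([shuffle_matrix()]), clustered
#' with the same parameters. The normalized value is 0 for perfect
#' histotype clustering, about 1 for histotype-free features, and can
#' exceed 1.
#'
#' @param S_c_raw raw entropy of the feature set under audit.
#' @param X full cells x probes matrix (source for the shuffled controls).
#' @param feature_count number of columns to match.
#' @param annotation data.frame `cell_id`, `histotype`.
#' @param k,n_restarts clustering parameters (as used for `S_c_raw`).
#' @param n_random number of random-control draws averaged (default 5).
#' @param seed RNG seed.
#' @return list: `S_c_normalized`, `S_c_raw`, `control_mean`,
#'   `control_values`.
#' @export
normalized_entropy <- function(S_c_raw, X, feature_count, annotation, k,
                               n_restarts = 10L, n_random = 5L, seed = 1L) {
  controls <- vapply(seq_len(n_random), function(r) {
    Xr <- shuffle_matrix(X, feature_count, seed = derive_seed(seed, "rctr", r))
    cl <- cluster_features(Xr, NULL, k, n_restarts,
                           seed = derive_seed(seed, "cluster", r))
    cluster_entropy(cl, annotation)
  }, numeric(1))
  cm <- mean(controls)
  if (cm == 0)
    stop_pancanrx("random-control entropy is zero; normalization undefined",
                  "pancanrx_degenerate")
  list(S_c_normalized = S_c_raw / cm, S_c_raw = S_c_raw,
       control_mean = cm, control_values = controls)
}

#' Pairwise F-tests of differential drug response between histotypes
#'
#' For every histotype pair with at least `min_cells` cells on both sides,
#' a two-group one-way ANOVA F statistic (the square of the pooled
#' two-sample t) with p from `F(1, n1 + n2 - 2)`; Welch-corrected
#' variances are available behind `var_equal = FALSE`. Reports the
#' fraction of tested pairs significant at `alpha` — a per-drug summary
#' of how strongly histotype structures the response.
#'
#' @param response named numeric vector of per-cell response (names = cell
#'   IDs), or a one-row-per-cell response data.frame.
#' @param annotation data.frame `cell_id`, `histotype`.
#' @param alpha significance cutoff for the fraction (default 0.05).
#' @param min_cells minimum cells per histotype in a tested pair.
#' @param var_equal pooled-variance F (default) or Welch-type.
#' @return list of class `ftest_matrix`: `pairs` (data.frame `hist_a`,
#'   `hist_b`, `F`, `p`), `fraction_significant`, `n_tested`, `n_skipped`.
#' @export
pairwise_histotype_ftests <- function(response, annotation, alpha = 0.05,
                                      min_cells = 3L, var_equal = TRUE) {
  if (is.data.frame(response))
    response <- setNames(response$log_ic50, response$cell_id)
  lab <- annotation$histotype[match(names(response), annotation$cell_id)]
  if (anyNA(lab))
    stop_pancanrx("annotation does not cover the response cells",
                  "pancanrx_invalid_arg")
  groups <- split(unname(response), lab)
  groups <- groups[vapply(groups, length, integer(1)) >= min_cells]
  if (length(groups) < 2L)
    stop_pancanrx("need >= 2 histotypes with enough cells", "pancanrx_degenerate")

  combs <- utils::combn(names(groups), 2L)
  res <- apply(combs, 2L, function(pr) {
    a <- groups[[pr[1L]]]; b <- groups[[pr[2L]]]
    n1 <- length(a); n2 <- length(b)
    if (var_equal) {
      sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
      Fstat <- (mean(a) - mean(b))^2 / (sp2 * (1 / n1 + 1 / n2))
      df2 <- n1 + n2 - 2
    } else {
      se2 <- var(a) / n1 + var(b) / n2
      Fstat <- (mean(a) - mean(b))^2 / se2
      df2 <- se2^2 / ((var(a) / n1)^2 / (n1 - 1) + (var(b) / n2)^2 / (n2 - 1))
    }
    c(Fstat, pf(Fstat, 1, df2, lower.tail = FALSE))
  })
  pairs <- data.frame(hist_a = combs[1L, ], hist_b = combs[2L, ],
                      F = res[1L, ], p = res[2L, ], stringsAsFactors = FALSE)
  n_all_pairs <- choose(length(unique(lab)), 2L)
  structure(list(pairs = pairs,
                 fraction_significant = mean(pairs$p < alpha),
                 n_tested = nrow(pairs),
                 n_skipped = n_all_pairs - nrow(pairs),
                 alpha = alpha),
            class = "ftest_matrix")
}

#' Correlation between histotype signal and model performance across drugs
#'
#' Spearman correlation between a per-drug vector of significant-F-test
#' fractions and a per-drug vector of model test correlations: large
#' positive values indicate that histotype structure drives performance.
#'
#' @param fraction_significant per-drug fraction of significant pairwise
#'   F-tests.
#' @param model_rho per-drug mean model test correlation, same order.
#' @return list `rho`, `p`, `n`; `rho = NA` with a warning if either
#'   vector is constant.
#' @export
histotype_signal_correlation <- function(fraction_significant, model_rho) {
  if (length(fraction_significant) != length(model_rho))
    stop_pancanrx("vectors must be aligned per drug", "pancanrx_invalid_arg")
  n <- length(model_rho)
  if (n < 5L) stop_pancanrx("need >= 5 drugs", "pancanrx_too_few_cells")
  rho <- spearman_rho(fraction_significant, model_rho)
  if (is.na(rho)) {
    warning("constant input vector: correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  list(rho = rho, p = spearman_p(rho, n), n = n)
}
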