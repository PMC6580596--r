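#' Spearman evaluation of a prediction set
#'
#' Spearman correlation between predicted and measured held-out responses;
#' the p-value uses the Student-t approximation on `n - 2` df.
#'
#' @param pred a [prediction_set()] (or any data.frame with `y_measured`
#'   and `y_predicted`).
#' @return list `rho`, `p`, `n`. Constant predictions give `rho = NA` with
#'   a warning (undefined, never silently zero).
#' @export
spearman_eval <- function(pred) {
  n <- nrow(pred)
  if (n < 5L) stop_pancanrx("need >= 5 test cells", "pancanrx_too_few_cells")
  if (sd(pred$y_measured) == 0)
    stop_pancanrx("measured values all tied", "pancanrx_degenerate")
  if (sd(pred$y_predicted) == 0) {
    warning("constant predictions: Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- spearman_rho(pred$y_predicted, pred$y_measured)
  list(rho = rho, p = spearman_p(rho, n), n = n)
}

#' Mean absolute difference between predicted and measured response
#'
#' @param pred a [prediction_set()].
#' @return mean of `|y_predicted - y_measured|` (log IC50 units).
#' @export
mad_eval <- function(pred) {
  if (nrow(pred) < 1L) stop_pancanrx("empty prediction set", "pancanrx_degenerate")
  mean(abs(pred$y_predicted - pred$y_measured))
}

#' Weighted-probability concordance index
#'
#' A noise-weighted pairwise ranking-agreement score. Over all test-cell
#' pairs with distinct measured responses, each pair is weighted by the
#' probability that its measured ordering is real under a Gaussian
#' replicate-noise model, `w_ij = Phi(|dy_meas| / (noise_sd * sqrt(2)))`,
#' and scores 1 if the predicted ordering agrees, 0.5 on a predicted tie,
#' 0 otherwise:
#' \deqn{wpc = \sum_{i<j} w_{ij} c_{ij} / \sum_{i<j} w_{ij}.}
#' Under random permutation of the predictions the expected value is 0.5;
#' for constant predictions every pair is a predicted tie and the index
#' degenerates, so a condition of class `pancanrx_wpc_undefined` is raised
#' instead (zero prediction variance).
#'
#' @param pred a [prediction_set()].
#' @param noise_sd replicate-noise SD in log IC50 units; if `NULL`,
#'   estimated as `noise_frac` of the SD of the measured values.
#' @param noise_frac fallback fraction of the response SD (default 0.25).
#' @return the wpc index, in `[0, 1]`.
#' @export
wpc_index <- function(pred, noise_sd = NULL, noise_frac = 0.25) {
  if (nrow(pred) < 2L) stop_pancanrx("need >= 2 test cells", "pancanrx_degenerate")
  if (sd(pred$y_predicted) == 0)
    stop_pancanrx(paste("predictions have a variance of 0, which results in",
                        "division by 0 in the wpc index"),
                  "pancanrx_wpc_undefined")
  pairs <- wpc_pairs(pred$y_measured, noise_sd, noise_frac)
  wpc_from_pairs(pairs, pred$y_predicted)
}

# precompute pair indices and weights from the measured vector
wpc_pairs <- function(y_meas, noise_sd = NULL, noise_frac = 0.25) {
  noise_sd <- noise_sd %||% (noise_frac * sd(y_meas))
  idx <- which(upper.tri(diag(length(y_meas))), arr.ind = TRUE)
  dmeas <- y_meas[idx[, 2L]] - y_meas[idx[, 1L]]
  keep <- dmeas != 0
  idx <- idx[keep, , drop = FALSE]
  dmeas <- dmeas[keep]
  w <- if (noise_sd > 0) pnorm(abs(dmeas) / (noise_sd * sqrt(2))) else
    rep(1, length(dmeas))
  list(i = idx[, 1L], j = idx[, 2L], sign_meas = sign(dmeas), w = w)
}

wpc_from_pairs <- function(pairs, y_pred) {
  if (length(pairs$w) == 0L || sum(pairs$w) == 0)
    stop_pancanrx("no informative measured pairs for the wpc index",
                  "pancanrx_wpc_undefined")
  dpred <- y_pred[pairs$j] - y_pred[pairs$i]
  c_ij <- ifelse(dpred == 0, 0.5, (sign(dpred) == pairs$sign_meas) * 1)
  sum(pairs$w * c_ij) / sum(pairs$w)
}

#' Permutation null distribution for the wpc index
#'
#' Permutes the predicted values across cells `n_perm` times, recomputes
#' the wpc index each time, and reports the empirical one-sided p-value
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams wpc_index
#' @param n_perm number of permutations (default 3000).
#' @param seed RNG seed.
#' @return list of class `wpc_null`: `observed`, `null` (length `n_perm`),
#'   `p`, `null_mean`.
#' @export
wpc_null_test <- function(pred, noise_sd = NULL, noise_frac = 0.25,
                          n_perm = 3000L, seed = 1L) {
  if (sd(pred$y_predicted) == 0)
    stop_pancanrx("wpc undefined for constant predictions",
                  "pancanrx_wpc_undefined")
  pairs <- wpc_pairs(pred$y_measured, noise_sd, noise_frac)
  observed <- wpc_from_pairs(pairs, pred$y_predicted)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b)
      wpc_from_pairs(pairs, sample(pred$y_predicted)), numeric(1))
  })
  structure(list(observed = observed, null = null,
                 p = (1 + sum(null >= observed)) / (n_perm + 1),
                 null_mean = mean(null)),
            class = "wpc_null")
}

#' Paired nonparametric comparison of two methods
#'
#' Wilcoxon matched-pairs signed-rank test on per-dataset score differences
#' (two-sided); zero differences are dropped. If every pair is tied the
#' result is flagged rather than given a p-value.
#'
#' @param scores_a,scores_b equal-length paired score vectors (one entry
#'   per drug/split dataset).
#' @return list `statistic`, `p`, `n_effective`, `all_tied`.
#' @export
paired_method_comparison <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop_pancanrx("paired score vectors must have equal length",
                  "pancanrx_invalid_arg")
  if (length(scores_a) < 5L)
    stop_pancanrx("need >= 5 paired datasets", "pancanrx_too_few_cells")
  d <- scores_a - scores_b
  d <- d[d != 0]
  if (length(d) == 0L)
    return(list(statistic = NA_real_, p = NA_real_, n_effective = 0L,
                all_tied = TRUE))
  wt <- suppressWarnings(wilcox.test(d, exact = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_effective = length(d), all_tied = FALSE)
}
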