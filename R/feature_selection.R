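#' Construct a feature set
#'
#' An ordered probe subset together with the selection method and
#' parameters that produced it. The `HIST` method is special: it carries
#' histotype labels rather than probe IDs.
#'
#' @param probe_ids ordered character vector of probe IDs (or histotype
#'   labels for method `"HIST"`).
#' @param method one of `"NOFS"`, `"DEG"`, `"MODT"`, `"BC"`, `"BS"`,
#'   `"BS_HIST"`, `"MRMR"`, `"CTR1"`, `"CTR2"`, `"RCTR"`, `"HIST"`.
#' @param params list of method parameters, kept for provenance.
#' @return object of class `feature_set`.
#' @export
feature_set <- function(probe_ids, method, params = list()) {
  method <- match.arg(method, c("NOFS", "DEG", "MODT", "BC", "BS", "BS_HIST",
                                "MRMR", "CTR1", "CTR2", "RCTR", "HIST"))
  probe_ids <- as.character(probe_ids)
  if (anyDuplicated(probe_ids))
    stop_pancanrx("feature set contains duplicate probe IDs",
                  "pancanrx_invalid_features")
  structure(list(probe_ids = probe_ids, method = method, params = params,
                 n_features = length(probe_ids)), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set [%s]: %d features\n", x$method, x$n_features))
  invisible(x)
}

#' Spearman screen for response-correlated probes (the DEG set)
#'
#' Correlates every training probe with the training response using
#' Spearman's rho (p from the Student-t approximation) and selects probes
#' with `p < alpha`. This is the primary correlation-based filter; with
#' `alpha = bonferroni_threshold(0.05, m)` it becomes the
#' Bonferroni-corrected (BC) variant.
#'
#' @param X_train training cells x probes matrix.
#' @param y_train training response (log IC50), aligned with rows.
#' @param alpha per-probe significance cutoff (default 0.05).
#' @param method label stored on the returned feature set.
#' @return list with `screen` (data.frame `rho`, `p` per probe) and
#'   `features` (a `feature_set`).
#' @export
spearman_screen <- function(X_train, y_train, alpha = 0.05, method = "DEG") {
  screen <- spearman_screen_stats(X_train, y_train)
  sel <- which(screen$p < alpha)
  list(screen = screen,
       features = feature_set(colnames(X_train)[sel], method,
                              params = list(alpha = alpha)))
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` for `m` simultaneous probe-level tests; with the panel-scale
#' defaults (alpha 0.05, 49,386 probes) this is 1.0e-6 to two significant
#' figures.
#'
#' @param alpha family-wise significance level, in (0, 1).
#' @param m number of features tested, >= 1.
#' @return the per-test p-value cutoff `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1L || m < 1) stop_pancanrx("m must be >= 1", "pancanrx_invalid_arg")
  if (alpha <= 0 || alpha >= 1)
    stop_pancanrx("alpha must lie in (0, 1)", "pancanrx_invalid_arg")
  alpha / m
}

#' Moderated-t selection on response tails (empirical Bayes)
#'
#' Forms a resistant group (top `tail_frac` of the training response) and a
#' sensitive group (bottom `tail_frac`), computes a per-probe two-sample
#' moderated t-statistic with empirical-Bayes variance shrinkage, and
#' selects probes at Benjamini-Hochberg FDR `fdr`.
#'
#' The shrinkage follows the standard hierarchical model for gene-wise
#' variances: the prior df `d0` and prior variance `s0^2` are estimated by
#' moment-matching the log sample variances against a scaled log-F
#' distribution (trigamma inversion for `d0`); the posterior variance is
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)` and `t~` is referred to a t
#' distribution on `d + d0` df.
#'
#' @param X_train training cells x probes matrix.
#' @param y_train training response.
#' @param tail_frac fraction of cells in each tail (default 0.25).
#' @param fdr Benjamini-Hochberg cutoff (default 0.05).
#' @param d0_override force the prior df (0 recovers the ordinary pooled
#'   two-sample t exactly); mainly for testing.
#' @return list with `table` (per-probe `t`, `p`, `q`, `df`, plus the
#'   estimated `d0`, `s0sq` as attributes) and `features`
#'   (a `feature_set` of method `"MODT"`).
#' @export
select_moderated_t <- function(X_train, y_train, tail_frac = 0.25, fdr = 0.05,
                               d0_override = NULL) {
  n <- nrow(X_train)
  n_tail <- floor(tail_frac * n)
  if (n_tail < 3L)
    stop_pancanrx("each response tail needs >= 3 cells", "pancanrx_too_few_cells")
  ord <- order(y_train)
  sens <- ord[seq_len(n_tail)]                 # lowest IC50: sensitive
  res <- ord[seq(n - n_tail + 1L, n)]          # highest IC50: resistant

  X1 <- X_train[res, , drop = FALSE]
  X2 <- X_train[sens, , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  d <- n1 + n2 - 2L
  mean_diff <- colMeans(X1) - colMeans(X2)
  s2 <- (colSums(sweep(X1, 2L, colMeans(X1))^2) +
           colSums(sweep(X2, 2L, colMeans(X2))^2)) / d
  if (all(s2 == 0))
    stop_pancanrx("zero within-group variance for every probe",
                  "pancanrx_degenerate")

  if (is.null(d0_override)) {
    prior <- fit_variance_prior(s2[s2 > 0], d)
    d0 <- prior$d0; s0sq <- prior$s0sq
  } else {
    d0 <- d0_override
    s0sq <- if (d0 > 0) mean(s2) else 0
  }
  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2)) else
    (d0 * s0sq + d * s2) / (d0 + d)
  tstat <- mean_diff / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- d + d0
  p <- 2 * pt(-abs(tstat), df = if (is.infinite(df_total)) 1e6 else df_total)
  p[s2_post == 0] <- ifelse(mean_diff[s2_post == 0] == 0, 1, 0)
  q <- p.adjust(p, method = "BH")

  tab <- data.frame(t = tstat, p = p, q = q, row.names = colnames(X_train))
  attr(tab, "d0") <- d0
  attr(tab, "s0sq") <- s0sq
  attr(tab, "df") <- df_total
  list(table = tab,
       features = feature_set(colnames(X_train)[q < fdr], "MODT",
                              params = list(tail_frac = tail_frac, fdr = fdr,
                                            d0 = d0, s0sq = s0sq)))
}

# Moment-match log sample variances to log(s0^2 * F(d, d0)):
#   E[log s^2] = log s0^2 + psi(d/2) - log(d/2) - psi(d0/2) + log(d0/2)
#   Var[log s^2] = psi'(d/2) + psi'(d0/2)
fit_variance_prior <- function(s2, d) {
  z <- log(s2)
  evar <- var(z) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0sq <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0sq = s0sq)
}

# Newton solve of trigamma(y) = x on y > 0 (monotone decreasing)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Bootstrap-consensus Spearman selection (BS and BS-Hist)
#'
#' Repeats the Spearman screen over `n_boot` random subsets of the
#' training data and keeps probes significant in at least a `consensus`
#' fraction of subsets. Two modes:
#' \itemize{
#'   \item plain bootstrap (`stratify_histotype = FALSE`): each subset is
#'     a random `subset_frac` of the training cells; the default
#'     `consensus = 1` requires significance in every subset.
#'   \item histotype-stratified (`stratify_histotype = TRUE`): each subset
#'     holds exactly one randomly chosen cell per histotype; the
#'     conventional consensus is 0.5.
#' }
#'
#' @param X_train,y_train training data.
#' @param n_boot number of subsets (default 50).
#' @param subset_frac fraction of training cells per subset (plain mode).
#' @param alpha per-screen significance cutoff.
#' @param consensus required fraction of subsets, in (0, 1];
#'   default 1 in plain mode, 0.5 in stratified mode.
#' @param stratify_histotype switch to the one-cell-per-histotype mode.
#' @param annotation required when `stratify_histotype = TRUE`.
#' @param seed RNG seed for the subset draws.
#' @return a `feature_set` of method `"BS"` or `"BS_HIST"`; the per-probe
#'   significance frequency is attached as attribute `support`.
#' @export
select_bootstrap <- function(X_train, y_train, n_boot = 50L,
                             subset_frac = 0.75, alpha = 0.05,
                             consensus = NULL, stratify_histotype = FALSE,
                             annotation = NULL, seed = 1L) {
  consensus <- consensus %||% if (stratify_histotype) 0.5 else 1
  if (consensus <= 0 || consensus > 1)
    stop_pancanrx("consensus must lie in (0, 1]", "pancanrx_invalid_arg")
  n <- nrow(X_train)
  if (stratify_histotype) {
    if (is.null(annotation))
      stop_pancanrx("stratified bootstrap needs a histotype annotation",
                    "pancanrx_invalid_arg")
    lab <- annotation$histotype[match(rownames(X_train), annotation$cell_id)]
    if (anyNA(lab))
      stop_pancanrx("annotation does not cover the training cells",
                    "pancanrx_invalid_arg")
    groups <- split(seq_len(n), lab)
    if (length(groups) < 5L)
      stop_pancanrx("stratified subsets need >= 5 histotypes for the screen",
                    "pancanrx_too_few_cells")
  } else if (floor(subset_frac * n) < 5L) {
    stop_pancanrx("subsets too small for the Spearman screen (< 5 cells)",
                  "pancanrx_too_few_cells")
  }

  hits <- with_seed(seed, {
    acc <- numeric(ncol(X_train))
    for (b in seq_len(n_boot)) {
      idx <- if (stratify_histotype)
        vapply(groups, function(g) if (length(g) == 1L) g else sample(g, 1L),
               integer(1))
      else sample(n, floor(subset_frac * n))
      scr <- spearman_screen_stats(X_train[idx, , drop = FALSE], y_train[idx])
      acc <- acc + (scr$p < alpha)
    }
    acc / n_boot
  })
  method <- if (stratify_histotype) "BS_HIST" else "BS"
  fs <- feature_set(colnames(X_train)[hits >= consensus], method,
                    params = list(n_boot = n_boot, alpha = alpha,
                                  consensus = consensus,
                                  subset_frac = subset_frac, seed = seed))
  attr(fs, "support") <- hits
  fs
}

#' Greedy maximum-relevance minimum-redundancy selection
#'
#' Selects `k` probes greedily: the first maximizes `|rho(x_g, y)|`; each
#' subsequent probe maximizes
#' `|rho(x_g, y)| - mean_{s in S} |rho(x_g, x_s)|`, with Spearman
#' correlations throughout and ties broken by probe index for determinism.
#'
#' @param X_train,y_train training data.
#' @param k number of probes to select (default 1000).
#' @return a `feature_set` of method `"MRMR"`, in selection order.
#' @export
select_mrmr <- function(X_train, y_train, k = 1000L) {
  m <- ncol(X_train)
  if (k > m) stop_pancanrx("k exceeds the number of probes", "pancanrx_invalid_arg")
  if (k < 1L) stop_pancanrx("k must be >= 1", "pancanrx_invalid_arg")
  n <- nrow(X_train)
  # standardized ranks: Spearman correlations become crossproducts
  Z <- apply(X_train, 2L, rank)
  Z <- scale(Z)
  Z[is.na(Z)] <- 0   # constant probes: zero correlation with everything
  zy <- as.vector(scale(rank(y_train)))
  relevance <- abs(as.vector(crossprod(Z, zy)) / (n - 1))

  selected <- integer(k)
  red_sum <- numeric(m)
  in_set <- logical(m)
  for (step in seq_len(k)) {
    score <- if (step == 1L) relevance else relevance - red_sum / (step - 1L)
    score[in_set] <- -Inf
    pick <- which.max(score)   # first maximum = lowest probe index on ties
    selected[step] <- pick
    in_set[pick] <- TRUE
    if (step < k)
      red_sum <- red_sum + abs(as.vector(crossprod(Z, Z[, pick])) / (n - 1))
  }
  feature_set(colnames(X_train)[selected], "MRMR", params = list(k = k))
}

#' Size-matched and complement control feature sets (CTR1 / CTR2)
#'
#' CTR1 draws, uniformly without replacement from the full probe universe,
#' a random set the same size as the reference selection (overlap with the
#' reference is allowed). CTR2 is the set-theoretic complement of the
#' reference.
#'
#' @param all_probes character vector: the probe universe.
#' @param reference a `feature_set` (typically the DEG set) computed on the
#'   same universe.
#' @param mode `"CTR1"` or `"CTR2"`.
#' @param seed RNG seed (CTR1 only).
#' @return a `feature_set`.
#' @export
make_control_features <- function(all_probes, reference, mode = c("CTR1", "CTR2"),
                                  seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(reference$probe_ids) <= length(all_probes))
  if (mode == "CTR1") {
    ids <- with_seed(seed, sample(all_probes, reference$n_features))
    feature_set(ids, "CTR1", params = list(seed = seed,
                                           matched_to = reference$method))
  } else {
    feature_set(setdiff(all_probes, reference$probe_ids), "CTR2",
                params = list(matched_to = reference$method))
  }
}

#' Cell-shuffled random-control feature matrix (RCTR)
#'
#' Samples `n_features` probes and independently permutes each selected
#' column across cells, destroying any cell-feature association while
#' preserving every column's marginal distribution. The response is left
#' untouched by construction.
#'
#' @param X_train training cells x probes matrix.
#' @param n_features number of probes to sample (defaults to all).
#' @param seed RNG seed.
#' @return a cells x `n_features` matrix with shuffled columns; the probe
#'   IDs sampled are kept as column names.
#' @export
shuffle_matrix <- function(X_train, n_features = ncol(X_train), seed = 1L) {
  if (n_features > ncol(X_train))
    stop_pancanrx("n_features exceeds the number of probes", "pancanrx_invalid_arg")
  with_seed(seed, {
    cols <- sample(ncol(X_train), n_features)
    out <- X_train[, cols, drop = FALSE]
    for (j in seq_len(ncol(out))) out[, j] <- out[sample(nrow(out)), j]
    out
  })
}

#' One-hot histotype encoding (HIST features)
#'
#' Encodes each cell as a binary vector over the retained histotypes
#' (column order = sorted labels); exactly one entry per row is 1.
#'
#' @param annotation data.frame `cell_id`, `histotype`.
#' @param cells cell IDs to encode, in row order.
#' @return cells x histotypes 0/1 matrix with dimnames.
#' @export
encode_histotype <- function(annotation, cells) {
  lab <- annotation$histotype[match(cells, annotation$cell_id)]
  if (anyNA(lab))
    stop_pancanrx("unlabeled cell(s) in one-hot encoding", "pancanrx_invalid_arg")
  levels <- sort(unique(lab))
  M <- matrix(0L, length(cells), length(levels),
              dimnames = list(cells, levels))
  M[cbind(seq_along(cells), match(lab, levels))] <- 1L
  M
}
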