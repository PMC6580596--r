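#' Specify a synthetic pharmacogenomic cohort
#'
#' Describes the generative model used by [generate_cohort()]: a cell-line
#' log2-expression matrix with histotype-structured probes, and a per-drug
#' log IC50 response decomposed into a histotype mean effect, a gene-driven
#' cell-specific effect and measurement noise. The knob that matters for the
#' histotype-confounding analysis is `hist_var_share` (lambda): the fraction
#' of *signal* variance (before measurement noise) contributed by the
#' histotype means.
#'
#' Defaults emulate, at desk scale, a pan-cancer panel: 20 histotypes of 30
#' cell lines, 3000 probes of which 2000 carry histotype centroids (tissue
#' signature diffuse across most of the array, so that size-matched random
#' probe subsets also encode histotype) and 300 carry response effects (150
#' of them inside the tissue-informative set), IC50s measured in 3
#' replicates with 5% of cells censored above the maximum tested
#' concentration.
#'
#' @param n_histotypes number of tissue-of-origin groups.
#' @param cells_per_histotype scalar or per-histotype vector of cell counts.
#' @param n_probes total number of expression probes.
#' @param n_hist_probes probes carrying per-histotype centroids.
#' @param n_resp_probes probes whose expression feeds the response.
#' @param n_overlap_probes probes in both sets.
#' @param hist_var_share lambda in `[0,1]`: share of signal variance from
#'   histotype means (0 = response unrelated to histotype, 1 = pure
#'   histotype effect).
#' @param noise_sd_expr SD of probe-level expression noise (log2 units).
#' @param noise_sd_resp SD of per-replicate response measurement noise
#'   (log IC50 units), relative to unit signal SD.
#' @param hist_centroid_sd SD of the per-histotype expression centroids.
#' @param censor_fraction fraction of cells flagged as IC50 above the
#'   maximum tested concentration (the most resistant cells).
#' @param replicates IC50 measurements per cell.
#' @param seed integer RNG seed; the cohort is a pure function of the spec.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_histotypes = 20L, cells_per_histotype = 30L,
                        n_probes = 3000L, n_hist_probes = 2000L,
                        n_resp_probes = 300L, n_overlap_probes = 150L,
                        hist_var_share = 0.5, noise_sd_expr = 1,
                        noise_sd_resp = 0.2, hist_centroid_sd = 1,
                        censor_fraction = 0.05, replicates = 3L,
                        seed = 1L) {
  spec <- list(n_histotypes = as.integer(n_histotypes),
               cells_per_histotype = as.integer(cells_per_histotype),
               n_probes = as.integer(n_probes),
               n_hist_probes = as.integer(n_hist_probes),
               n_resp_probes = as.integer(n_resp_probes),
               n_overlap_probes = as.integer(n_overlap_probes),
               hist_var_share = hist_var_share,
               noise_sd_expr = noise_sd_expr,
               noise_sd_resp = noise_sd_resp,
               hist_centroid_sd = hist_centroid_sd,
               censor_fraction = censor_fraction,
               replicates = as.integer(replicates),
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    counts <- c(n_histotypes, cells_per_histotype, n_probes, n_hist_probes,
                n_resp_probes, n_overlap_probes, replicates)
    if (any(counts < 0L))
      stop_pancanrx("all counts must be non-negative", "pancanrx_invalid_spec")
    if (hist_var_share < 0 || hist_var_share > 1)
      stop_pancanrx("hist_var_share (lambda) must lie in [0, 1]",
                    "pancanrx_invalid_spec")
    if (n_overlap_probes > min(n_hist_probes, n_resp_probes))
      stop_pancanrx("n_overlap_probes cannot exceed either probe set",
                    "pancanrx_invalid_spec")
    if (n_hist_probes + n_resp_probes - n_overlap_probes > n_probes)
      stop_pancanrx("infeasible probe partition: hist + resp - overlap exceeds n_probes",
                    "pancanrx_invalid_spec")
    if (censor_fraction < 0 || censor_fraction >= 1)
      stop_pancanrx("censor_fraction must lie in [0, 1)", "pancanrx_invalid_spec")
    if (length(cells_per_histotype) != 1L &&
        length(cells_per_histotype) != n_histotypes)
      stop_pancanrx("cells_per_histotype must be scalar or one per histotype",
                    "pancanrx_invalid_spec")
  })
  invisible(spec)
}

#' Generate a synthetic expression/response cohort
#'
#' Draws a cohort from the model described in [cohort_spec()]:
#' \deqn{x_{ig} = m_g + a_{h(i),g} 1[g \in hist] + e_{ig}}
#' \deqn{y_i = s_h \mu_{h(i)} + s_g \sum_g \beta_g x_{ig} + \epsilon_i}
#' where the histotype-mean and gene components are rescaled (empirically,
#' on the generated cells) so the histotype share of the signal variance is
#' `hist_var_share` and the total signal variance is 1. Replicate
#' measurements add independent noise per replicate; the most resistant
#' `censor_fraction` of cells are flagged censored, not dropped.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `drug_cohort` with elements `expression`
#'   (cells x probes matrix), `response` (data.frame `cell_id`,
#'   `log_ic50`, `censored`, `replicate`; one row per replicate),
#'   `annotation` (data.frame `cell_id`, `histotype`) and `truth`
#'   (histotype means, beta, probe id lists, true per-cell response).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, generate_cohort_impl(spec, null_response = FALSE))
}

#' Generate a null cohort (response independent of everything)
#'
#' Identical expression/annotation model to [generate_cohort()], but the
#' response is drawn independently of expression and histotype — a
#' type-I-error fixture for selection and F-test calibration.
#'
#' @inheritParams generate_cohort
#' @return as [generate_cohort()]; `truth$beta` and `truth$histotype_means`
#'   are all zero.
#' @export
generate_null_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, generate_cohort_impl(spec, null_response = TRUE))
}

generate_cohort_impl <- function(spec, null_response) {
  H <- spec$n_histotypes
  nh <- if (length(spec$cells_per_histotype) == 1L)
    rep(spec$cells_per_histotype, H) else spec$cells_per_histotype
  n <- sum(nh)
  m <- spec$n_probes
  if (n == 0L || m == 0L)
    stop_pancanrx("cohort must contain at least one cell and one probe",
                  "pancanrx_invalid_spec")

  hist_labels <- sprintf("hist%02d", seq_len(H))
  histotype <- rep(hist_labels, times = nh)
  cell_ids <- sprintf("cell%04d", seq_len(n))
  probe_ids <- sprintf("probe%05d", seq_len(m))

  hist_idx <- seq_len(spec$n_hist_probes)
  n_new_resp <- spec$n_resp_probes - spec$n_overlap_probes
  resp_idx <- c(head(hist_idx, spec$n_overlap_probes),
                if (n_new_resp > 0L)
                  spec$n_hist_probes + seq_len(n_new_resp) else integer(0))

  # expression: baseline + histotype centroids on hist probes + noise
  m_g <- rnorm(m, mean = 7, sd = 1)
  X <- matrix(rnorm(n * m, sd = spec$noise_sd_expr), n, m,
              dimnames = list(cell_ids, probe_ids))
  X <- sweep(X, 2L, m_g, "+")
  if (length(hist_idx) > 0L) {
    A <- matrix(rnorm(H * length(hist_idx), sd = spec$hist_centroid_sd),
                H, length(hist_idx))
    X[, hist_idx] <- X[, hist_idx] + A[match(histotype, hist_labels), ]
  }

  lambda <- spec$hist_var_share
  mu_h <- rnorm(H)
  beta <- numeric(m)
  if (length(resp_idx) > 0L) beta[resp_idx] <- rnorm(length(resp_idx))

  hist_comp <- mu_h[match(histotype, hist_labels)]
  gene_comp <- if (length(resp_idx) > 0L)
    as.vector(X[, resp_idx, drop = FALSE] %*% beta[resp_idx]) else numeric(n)

  # empirical rescaling: histotype share lambda, gene share 1 - lambda,
  # total signal variance 1 (exact analytic scaling is intractable once X
  # is random)
  s_h <- if (lambda > 0 && sd(hist_comp) > 0) sqrt(lambda) / sd(hist_comp) else 0
  s_g <- if (lambda < 1 && sd(gene_comp) > 0) sqrt(1 - lambda) / sd(gene_comp) else 0
  mu_h <- mu_h * s_h
  beta <- beta * s_g
  y_true <- s_h * hist_comp + s_g * (gene_comp - mean(gene_comp))

  if (null_response) {
    y_true <- rnorm(n)
    mu_h <- rep(0, H)
    beta <- numeric(m)
  }

  reps <- max(1L, spec$replicates)
  response <- data.frame(
    cell_id = rep(cell_ids, each = reps),
    log_ic50 = rep(y_true, each = reps) + rnorm(n * reps, sd = spec$noise_sd_resp),
    replicate = rep(seq_len(reps), times = n),
    stringsAsFactors = FALSE)

  # censoring: the most resistant cells sit above the max tested concentration
  censored_cells <- character(0)
  if (spec$censor_fraction > 0) {
    y_bar <- tapply(response$log_ic50, response$cell_id, mean)[cell_ids]
    n_cens <- floor(spec$censor_fraction * n)
    if (n_cens > 0L)
      censored_cells <- cell_ids[order(y_bar, decreasing = TRUE)[seq_len(n_cens)]]
  }
  response$censored <- response$cell_id %in% censored_cells

  structure(list(
    expression = X,
    response = response,
    annotation = data.frame(cell_id = cell_ids, histotype = histotype,
                            stringsAsFactors = FALSE),
    truth = list(histotype_means = setNames(mu_h, hist_labels),
                 beta = setNames(beta, probe_ids),
                 hist_probe_ids = probe_ids[hist_idx],
                 resp_probe_ids = probe_ids[resp_idx],
                 y_true = setNames(y_true, cell_ids),
                 hist_var_share = lambda),
    spec = spec), class = "drug_cohort")
}

#' @export
print.drug_cohort <- function(x, ...) {
  cat(sprintf("drug_cohort: %d cells x %d probes, %d histotypes, %d response rows\n",
              nrow(x$expression), ncol(x$expression),
              length(unique(x$annotation$histotype)), nrow(x$response)))
  invisible(x)
}

#' Write a cohort to the standard on-disk layout
#'
#' Emits `expression.tsv` (cells x probes, first column `cell_id`),
#' `response.csv` (`cell_id,log_ic50,censored[,replicate]`),
#' `annotation.csv` (`cell_id,histotype`) and, when ground truth is
#' present, `truth.json`.
#'
#' @param cohort a `drug_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- data.table::as.data.table(cohort$expression, keep.rownames = "cell_id")
  data.table::fwrite(expr, file.path(dir, "expression.tsv"), sep = "\t")
  data.table::fwrite(cohort$response, file.path(dir, "response.csv"))
  data.table::fwrite(cohort$annotation, file.path(dir, "annotation.csv"))
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
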