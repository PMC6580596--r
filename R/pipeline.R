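#' Define an experiment grid
#'
#' The full benchmarking grid: drugs x splits x feature-selection methods
#' x model families. Per-cell RNG seeds are derived deterministically from
#' the master seed and the cell's labels, so results are reproducible
#' regardless of execution order.
#'
#' @param drugs character vector of drug labels (a cohort per drug).
#' @param n_splits number of stratified splits (default 6).
#' @param feature_methods subset of `"NOFS"`, `"DEG"`, `"MODT"`, `"BC"`,
#'   `"BS"`, `"BS_HIST"`, `"MRMR"`, `"CTR1"`, `"CTR2"`, `"RCTR"`, `"HIST"`.
#' @param families subset of `"PCR"`, `"SVR_LINEAR"`, `"SVR_RBF"`, `"ANN"`,
#'   `"HIST_MEAN"`.
#' @param sweep_counts feature-count sweep levels (default 10, 55, 250,
#'   500, 1000).
#' @param seed master seed.
#' @param alpha DEG screen significance level.
#' @param mrmr_k MRMR selection size.
#' @param train_frac,min_cells_per_histotype split controls.
#' @param model_args named list of extra per-family arguments passed to
#'   the fitting functions (e.g. `list(PCR = list(max_components = 20))`).
#' @return list of class `experiment_grid`.
#' @export
experiment_grid <- function(drugs = "drug1", n_splits = 6L,
                            feature_methods = c("DEG", "CTR1", "CTR2"),
                            families = c("PCR", "SVR_LINEAR"),
                            sweep_counts = c(10L, 55L, 250L, 500L, 1000L),
                            seed = 1L, alpha = 0.05, mrmr_k = 1000L,
                            train_frac = 0.75, min_cells_per_histotype = 4L,
                            model_args = list()) {
  structure(list(drugs = drugs, n_splits = as.integer(n_splits),
                 feature_methods = feature_methods, families = families,
                 sweep_counts = as.integer(sweep_counts), seed = as.integer(seed),
                 alpha = alpha, mrmr_k = as.integer(mrmr_k),
                 train_frac = train_frac,
                 min_cells_per_histotype = as.integer(min_cells_per_histotype),
                 model_args = model_args),
            class = "experiment_grid")
}

# resolve the feature matrix + feature list for one method on one split
resolve_features <- function(method, X_train, y_train, annotation, grid,
                             cell_seed) {
  switch(method,
    NOFS = list(ids = colnames(X_train), X = NULL),
    DEG = list(ids = spearman_screen(X_train, y_train,
                                     grid$alpha)$features$probe_ids, X = NULL),
    BC = list(ids = spearman_screen(
      X_train, y_train,
      bonferroni_threshold(grid$alpha, ncol(X_train)),
      method = "BC")$features$probe_ids, X = NULL),
    MODT = list(ids = select_moderated_t(X_train, y_train)$features$probe_ids,
                X = NULL),
    BS = list(ids = select_bootstrap(X_train, y_train,
                                     seed = cell_seed)$probe_ids, X = NULL),
    BS_HIST = list(ids = select_bootstrap(X_train, y_train,
                                          stratify_histotype = TRUE,
                                          annotation = annotation,
                                          seed = cell_seed)$probe_ids, X = NULL),
    MRMR = list(ids = select_mrmr(X_train, y_train,
                                  k = min(grid$mrmr_k,
                                          ncol(X_train)))$probe_ids, X = NULL),
    CTR1 = {
      deg <- spearman_screen(X_train, y_train, grid$alpha)$features
      list(ids = make_control_features(colnames(X_train), deg, "CTR1",
                                       seed = cell_seed)$probe_ids, X = NULL)
    },
    CTR2 = {
      deg <- spearman_screen(X_train, y_train, grid$alpha)$features
      list(ids = make_control_features(colnames(X_train), deg,
                                       "CTR2")$probe_ids, X = NULL)
    },
    RCTR = {
      deg <- spearman_screen(X_train, y_train, grid$alpha)$features
      Xs <- shuffle_matrix(X_train, max(deg$n_features, 1L), seed = cell_seed)
      list(ids = colnames(Xs), X = Xs)
    },
    HIST = list(ids = NULL, X = NULL),
    stop_pancanrx(paste0("unknown feature method: ", method),
                  "pancanrx_invalid_arg"))
}

fit_family <- function(family, X_train, y_train, annotation, train_ids,
                       cell_seed, extra = list()) {
  args_of <- function(defaults) utils::modifyList(defaults, extra)
  switch(family,
    PCR = do.call(fit_pcr, args_of(list(X_train = X_train, y_train = y_train,
                                        seed = cell_seed))),
    SVR_LINEAR = do.call(fit_svr, args_of(list(X_train = X_train,
                                               y_train = y_train,
                                               kernel = "linear",
                                               seed = cell_seed))),
    SVR_RBF = do.call(fit_svr, args_of(list(X_train = X_train,
                                            y_train = y_train,
                                            kernel = "rbf",
                                            seed = cell_seed))),
    ANN = do.call(fit_ann, args_of(list(X_train = X_train, y_train = y_train,
                                        seed = cell_seed))),
    HIST_MEAN = fit_histotype_mean(annotation, y_train, cells = train_ids),
    stop_pancanrx(paste0("unknown model family: ", family),
                  "pancanrx_invalid_arg"))
}

#' Run the full benchmark grid on a cohort
#'
#' For every (drug, split, feature method, family) cell: select features on
#' the training cells only, tune and fit on training, predict the held-out
#' test cells, and score with Spearman, MAD and wpc. Replicates are
#' averaged and censored cells excluded up front. Individual cell failures
#' are recorded (`status` column) and never abort the run.
#'
#' When `out_dir` is given, each completed cell is checkpointed as a CSV
#' under `out_dir/cells/`; a restarted run recomputes only the missing
#' cells.
#'
#' @param grid an [experiment_grid()].
#' @param cohorts a named list of `drug_cohort` objects (one per drug in
#'   the grid), or a single cohort used for every drug.
#' @param out_dir optional checkpoint/output directory.
#' @param quiet suppress progress messages.
#' @return long-format results data.frame: one row per grid cell with
#'   provenance (`drug`, `split`, `feature_method`, `family`, `n_features`,
#'   `seed`), metrics (`rho`, `p`, `mad`, `wpc`) and `status`.
#' @export
run_benchmark <- function(grid, cohorts, out_dir = NULL, quiet = TRUE) {
  if (inherits(cohorts, "drug_cohort"))
    cohorts <- setNames(rep(list(cohorts), length(grid$drugs)), grid$drugs)
  if (!is.null(out_dir))
    dir.create(file.path(out_dir, "cells"), showWarnings = FALSE,
               recursive = TRUE)
  rows <- list()
  for (drug in grid$drugs) {
    cohort <- cohorts[[drug]]
    prep <- prepare_cohort(cohort, grid)
    for (split in prep$splits) {
      parts <- split_matrices(prep, split)
      for (fm in grid$feature_methods) {
        feat <- tryCatch(
          resolve_features(fm, parts$X_train, parts$y_train, prep$annotation,
                           grid, derive_seed(grid$seed, drug, split$split_index,
                                             fm, "features")),
          error = function(e) e)
        for (family in grid$families) {
          cell_id <- paste(drug, split$split_index, fm, family, sep = "_")
          cache <- if (!is.null(out_dir))
            file.path(out_dir, "cells", paste0(cell_id, ".csv")) else NULL
          if (!is.null(cache) && file.exists(cache)) {
            rows[[cell_id]] <- as.data.frame(data.table::fread(cache))
            next
          }
          if (!quiet) message("cell: ", cell_id)
          row <- run_cell(grid, prep, parts, split, drug, fm, family, feat)
          rows[[cell_id]] <- row
          if (!is.null(cache)) data.table::fwrite(row, cache)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir))
    data.table::fwrite(out, file.path(out_dir, "results.csv"))
  out
}

prepare_cohort <- function(cohort, grid) {
  resp <- filter_censored(average_replicates(cohort$response), quiet = TRUE)
  cells <- intersect(rownames(cohort$expression), resp$cell_id)
  splits <- suppressWarnings(make_stratified_splits(
    cells, cohort$annotation, n_splits = grid$n_splits,
    train_frac = grid$train_frac,
    min_cells_per_histotype = grid$min_cells_per_histotype,
    seed = derive_seed(grid$seed, "splits")))
  list(expression = cohort$expression,
       response = setNames(resp$log_ic50, resp$cell_id),
       annotation = cohort$annotation, splits = splits)
}

split_matrices <- function(prep, split) {
  list(X_train = prep$expression[split$train_ids, , drop = FALSE],
       y_train = unname(prep$response[split$train_ids]),
       X_test = prep$expression[split$test_ids, , drop = FALSE],
       y_test = unname(prep$response[split$test_ids]))
}

run_cell <- function(grid, prep, parts, split, drug, fm, family, feat) {
  base <- data.frame(drug = drug, split = split$split_index,
                     feature_method = fm, family = family,
                     n_features = NA_integer_, seed = grid$seed,
                     rho = NA_real_, p = NA_real_, mad = NA_real_,
                     wpc = NA_real_, status = "ok",
                     stringsAsFactors = FALSE)
  result <- tryCatch({
    if (inherits(feat, "error")) stop(feat)
    cell_seed <- derive_seed(grid$seed, drug, split$split_index, fm, family)
    if (family == "HIST_MEAN" || fm == "HIST") {
      model <- fit_histotype_mean(prep$annotation, parts$y_train,
                                  cells = split$train_ids)
      pred <- predict(model, prep$annotation, cells = split$test_ids)
      n_feat <- length(model$group_means)
    } else {
      if (length(feat$ids) == 0L) stop("empty feature set")
      if (is.null(feat$X)) {
        Xtr <- parts$X_train[, feat$ids, drop = FALSE]
        Xte <- parts$X_test[, feat$ids, drop = FALSE]
      } else {
        # RCTR: shuffled training features; test features equally arbitrary
        Xtr <- feat$X
        Xte <- shuffle_matrix(parts$X_test[, colnames(feat$X), drop = FALSE],
                              seed = cell_seed)
      }
      model <- fit_family(family, Xtr, parts$y_train, prep$annotation,
                          split$train_ids, cell_seed,
                          extra = grid$model_args[[family]] %||% list())
      pred <- predict(model, Xte)
      n_feat <- length(feat$ids)
    }
    ps <- prediction_set(split$test_ids, parts$y_test, pred, drug = drug,
                         split = split$split_index, family = family,
                         feature_method = fm)
    ev <- suppressWarnings(spearman_eval(ps))
    wpc <- tryCatch(wpc_index(ps), pancanrx_wpc_undefined = function(e) NA_real_)
    base$n_features <- n_feat
    base$rho <- ev$rho; base$p <- ev$p
    base$mad <- mad_eval(ps); base$wpc <- wpc
    base
  }, error = function(e) {
    base$status <- paste0("failed: ", conditionMessage(e))
    base
  })
  result
}

#' Feature-count sweep
#'
#' Subsamples a source feature pool (DEG, CTR1 or CTR2, computed per
#' split) down to each requested count, runs the benchmark per count, and
#' audits the normalized cluster entropy of each subsample. The subsets
#' are nested — one random ordering of the pool is drawn per split and
#' each count takes its prefix — a common-random-numbers design that
#' isolates the effect of the count from subsampling noise. Counts
#' exceeding the available pool are skipped with a warning.
#'
#' @param grid an [experiment_grid()] (`families` and `drugs` are
#'   honoured; `feature_methods` is ignored).
#' @param cohorts as in [run_benchmark()].
#' @param counts feature counts (default `grid$sweep_counts`).
#' @param source `"DEG"`, `"CTR1"` or `"CTR2"`.
#' @param audit_entropy also compute normalized S_c per count (default
#'   TRUE).
#' @param n_restarts,n_random entropy-audit clustering controls.
#' @return long-format results data.frame with columns as in
#'   [run_benchmark()] plus `count`, `S_c_raw`, `S_c_normalized`.
#' @export
feature_count_sweep <- function(grid, cohorts, counts = grid$sweep_counts,
                                source = c("DEG", "CTR1", "CTR2"),
                                audit_entropy = TRUE, n_restarts = 5L,
                                n_random = 3L) {
  source <- match.arg(source)
  if (inherits(cohorts, "drug_cohort"))
    cohorts <- setNames(rep(list(cohorts), length(grid$drugs)), grid$drugs)
  rows <- list()
  for (drug in grid$drugs) {
    cohort <- cohorts[[drug]]
    prep <- prepare_cohort(cohort, grid)
    k_hist <- length(unique(prep$annotation$histotype[
      prep$annotation$cell_id %in% names(prep$response)]))
    for (split in prep$splits) {
      parts <- split_matrices(prep, split)
      pool <- resolve_features(source, parts$X_train, parts$y_train,
                               prep$annotation, grid,
                               derive_seed(grid$seed, drug, split$split_index,
                                           source, "pool"))$ids
      pool_order <- with_seed(derive_seed(grid$seed, drug, split$split_index,
                                          source, "order"),
                              sample(pool))
      for (count in counts) {
        if (count > length(pool)) {
          warning(sprintf("count %d exceeds the %s pool (%d); skipped",
                          count, source, length(pool)), call. = FALSE)
          next
        }
        sub_seed <- derive_seed(grid$seed, drug, split$split_index, source,
                                count)
        ids <- pool_order[seq_len(count)]
        ent <- if (audit_entropy) {
          cl <- cluster_features(prep$expression, ids, k = k_hist,
                                 n_restarts = n_restarts, seed = sub_seed)
          raw <- cluster_entropy(cl, prep$annotation)
          norm <- normalized_entropy(raw, prep$expression, count,
                                     prep$annotation, k = k_hist,
                                     n_restarts = n_restarts,
                                     n_random = n_random, seed = sub_seed)
          list(raw = raw, norm = norm$S_c_normalized)
        } else list(raw = NA_real_, norm = NA_real_)
        for (family in grid$families) {
          feat <- list(ids = ids, X = NULL)
          row <- run_cell(grid, prep, parts, split, drug, source, family, feat)
          row$count <- count
          row$S_c_raw <- ent$raw
          row$S_c_normalized <- ent$norm
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
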