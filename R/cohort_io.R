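#' Read a cohort from disk
#'
#' Loads the expression matrix (TSV, probes as columns, first column
#' `cell_id`), per-drug response table (CSV: `cell_id`, `log_ic50`,
#' optional `censored`, optional `replicate`) and histotype annotation
#' (CSV: `cell_id`, `histotype`), then aligns all three on the
#' intersection of cell IDs. IDs are case-sensitive exact strings; cells
#' missing from any table are dropped and reported in the load report.
#'
#' @param expr_path path to the expression TSV.
#' @param response_path path to the response CSV.
#' @param annotation_path path to the annotation CSV.
#' @param quiet suppress the load-report message.
#' @return a `drug_cohort` (without ground truth); the load report is
#'   attached as attribute `load_report`.
#' @export
read_cohort <- function(expr_path, response_path, annotation_path,
                        quiet = FALSE) {
  for (p in c(expr_path, response_path, annotation_path))
    if (!file.exists(p))
      stop_pancanrx(paste0("file not found: ", p), "pancanrx_io_error")

  expr_dt <- data.table::fread(expr_path, header = TRUE)
  if (ncol(expr_dt) < 2L)
    stop_pancanrx("expression table needs a cell_id column plus >=1 probe",
                  "pancanrx_io_error")
  cell_ids <- as.character(expr_dt[[1L]])
  probe_cols <- names(expr_dt)[-1L]
  for (j in probe_cols) {
    if (!is.numeric(expr_dt[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(expr_dt[[j]]))) &
                     !is.na(expr_dt[[j]]))[1L]
      stop_pancanrx(sprintf("non-numeric expression value in column '%s', row %d",
                            j, bad %||% NA_integer_), "pancanrx_io_error")
    }
  }
  X <- as.matrix(expr_dt[, -1L, drop = FALSE])
  rownames(X) <- cell_ids
  if (anyNA(X))
    stop_pancanrx("expression matrix contains missing values", "pancanrx_io_error")
  if (anyDuplicated(cell_ids)) {
    # duplicate cell lines are averaged before modeling
    X <- apply(X, 2L, function(col) tapply(col, cell_ids, mean))
    X <- X[unique(cell_ids), , drop = FALSE]
  }

  response <- as.data.frame(data.table::fread(response_path, header = TRUE))
  if (!all(c("cell_id", "log_ic50") %in% names(response)))
    stop_pancanrx("response table needs cell_id and log_ic50 columns",
                  "pancanrx_io_error")
  response$cell_id <- as.character(response$cell_id)
  if (is.null(response$censored)) response$censored <- FALSE
  response$censored <- as.logical(response$censored)

  annotation <- as.data.frame(data.table::fread(annotation_path, header = TRUE))
  if (!all(c("cell_id", "histotype") %in% names(annotation)))
    stop_pancanrx("annotation table needs cell_id and histotype columns",
                  "pancanrx_io_error")
  annotation$cell_id <- as.character(annotation$cell_id)
  annotation <- annotation[!duplicated(annotation$cell_id), , drop = FALSE]

  keep <- sort(Reduce(intersect, list(rownames(X), response$cell_id,
                                      annotation$cell_id)))
  if (length(keep) == 0L)
    stop_pancanrx("no cell IDs shared by expression, response and annotation",
                  "pancanrx_io_error")
  report <- list(
    n_loaded = length(keep),
    dropped_from_expression = setdiff(rownames(X), keep),
    dropped_from_response = setdiff(unique(response$cell_id), keep),
    dropped_from_annotation = setdiff(annotation$cell_id, keep))
  n_dropped <- sum(lengths(report[-1L]))
  if (!quiet && n_dropped > 0L)
    message(sprintf("read_cohort: aligned %d cells; dropped %d unmatched IDs",
                    length(keep), n_dropped))

  response <- response[response$cell_id %in% keep, , drop = FALSE]
  annotation <- annotation[match(keep, annotation$cell_id), , drop = FALSE]
  rownames(response) <- NULL
  rownames(annotation) <- NULL
  cohort <- structure(list(
    expression = X[keep, , drop = FALSE],
    response = response,
    annotation = annotation,
    truth = NULL, spec = NULL), class = "drug_cohort")
  attr(cohort, "load_report") <- report
  cohort
}

#' Average replicate IC50 measurements per cell
#'
#' Collapses a response table with repeated `cell_id` rows to one row per
#' cell by the arithmetic mean of `log_ic50` (the final IC50 is an
#' average over all measurements). A cell is censored if any replicate is
#' flagged.
#'
#' @param response data.frame with columns `cell_id`, `log_ic50` and
#'   optionally `censored`.
#' @return data.frame `cell_id`, `log_ic50`, `censored`, one row per cell,
#'   in first-appearance order.
#' @export
average_replicates <- function(response) {
  if (nrow(response) == 0L)
    stop_pancanrx("empty response table", "pancanrx_io_error")
  if (is.null(response$censored)) response$censored <- FALSE
  ids <- unique(response$cell_id)
  f <- factor(response$cell_id, levels = ids)
  data.frame(
    cell_id = ids,
    log_ic50 = as.vector(tapply(response$log_ic50, f, mean)),
    censored = as.vector(tapply(response$censored, f, any)),
    stringsAsFactors = FALSE)
}

#' Drop cells whose IC50 exceeded the maximum tested concentration
#'
#' Censored measurements carry no usable IC50 and are excluded from every
#' modeling set (they are flagged upstream, never silently removed by the
#' generator).
#'
#' @param response one-row-per-cell response table with a `censored` column.
#' @param quiet suppress the removal count message.
#' @return the response table without censored rows.
#' @export
filter_censored <- function(response, quiet = FALSE) {
  if (is.null(response$censored)) response$censored <- FALSE
  n_cens <- sum(response$censored)
  out <- response[!response$censored, , drop = FALSE]
  if (nrow(out) == 0L)
    stop_pancanrx("all cells are censored; nothing to model",
                  "pancanrx_all_censored")
  if (!quiet && n_cens > 0L)
    message(sprintf("filter_censored: removed %d of %d cells", n_cens,
                    nrow(response)))
  out
}

#' Histotype-stratified train/test splits
#'
#' Builds `n_splits` independent random splits in which
#' `ceiling(train_frac * n_h)` cells of every retained histotype go to
#' training and the remainder to test, so each histotype is represented on
#' both sides. Histotypes with fewer than `min_cells_per_histotype` cells
#' are excluded from modeling (as sparsely measured tissues are dropped
#' from pan-cancer panels) and reported via a warning.
#'
#' With `disjoint_tests = TRUE` the function instead partitions each
#' histotype into `floor(1 / (1 - train_frac))` folds and returns that many
#' splits with pairwise-disjoint test sets.
#'
#' @param cells character vector of modelable cell IDs.
#' @param annotation data.frame `cell_id`, `histotype` covering `cells`.
#' @param n_splits number of independent splits (default 6).
#' @param train_frac fraction of each histotype reserved for
#'   training/validation (default 0.75).
#' @param min_cells_per_histotype histotypes below this size are excluded.
#' @param seed integer seed; split `i` uses a child stream derived from it.
#' @param disjoint_tests use the disjoint-test-fold variant.
#' @return list of `data_split` objects: `split_index`, `train_ids`,
#'   `test_ids`; excluded histotypes in attribute `excluded_histotypes`.
#' @export
make_stratified_splits <- function(cells, annotation, n_splits = 6L,
                                   train_frac = 0.75,
                                   min_cells_per_histotype = 4L, seed = 1L,
                                   disjoint_tests = FALSE) {
  if (train_frac <= 0 || train_frac >= 1)
    stop_pancanrx("train_frac must lie strictly between 0 and 1",
                  "pancanrx_invalid_split")
  lab <- annotation$histotype[match(cells, annotation$cell_id)]
  if (anyNA(lab))
    stop_pancanrx("annotation does not cover every cell", "pancanrx_invalid_split")
  counts <- table(lab)
  small <- names(counts)[counts < min_cells_per_histotype]
  if (length(small) > 0L)
    warning(sprintf("excluding %d histotype(s) with < %d cells: %s",
                    length(small), min_cells_per_histotype,
                    paste(small, collapse = ", ")), call. = FALSE)
  keep <- !(lab %in% small)
  cells <- cells[keep]; lab <- lab[keep]
  if (length(cells) == 0L)
    stop_pancanrx("no histotype passes min_cells_per_histotype",
                  "pancanrx_invalid_split")

  by_hist <- split(cells, lab)
  if (disjoint_tests) {
    n_folds <- max(2L, floor(1 / (1 - train_frac)))
    folds <- with_seed(derive_seed(seed, "disjoint"), {
      lapply(by_hist, function(ids) {
        ids <- sample(ids)
        split(ids, rep_len(seq_len(n_folds), length(ids)))
      })
    })
    splits <- lapply(seq_len(n_folds), function(i) {
      test <- unlist(lapply(folds, function(f) f[[as.character(i)]] %||% character(0)),
                     use.names = FALSE)
      new_data_split(i, setdiff(cells, test), test)
    })
  } else {
    splits <- lapply(seq_len(n_splits), function(i) {
      with_seed(derive_seed(seed, "split", i), {
        train <- unlist(lapply(by_hist, function(ids) {
          n_tr <- ceiling(train_frac * length(ids))
          sample(ids, n_tr)
        }), use.names = FALSE)
        new_data_split(i, train, setdiff(cells, train))
      })
    })
  }
  attr(splits, "excluded_histotypes") <- small
  splits
}

new_data_split <- function(index, train, test) {
  structure(list(split_index = index,
                 train_ids = sort(train),
                 test_ids = sort(test)),
            class = "data_split")
}

#' Serialize splits to JSON
#' @param splits list of `data_split` objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_splits <- function(splits, path) {
  jsonlite::write_json(lapply(splits, unclass), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read splits written by [write_splits()]
#' @param path JSON path.
#' @return list of `data_split` objects.
#' @export
read_splits <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) {
    new_data_split(as.integer(s$split_index),
                   as.character(unlist(s$train_ids)),
                   as.character(unlist(s$test_ids)))
  })
}
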