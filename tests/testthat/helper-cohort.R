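# small cohort factories shared across test files

tiny_spec <- function(...) {
  defaults <- list(n_histotypes = 6L, cells_per_histotype = 12L,
                   n_probes = 120L, n_hist_probes = 40L, n_resp_probes = 20L,
                   n_overlap_probes = 5L, hist_var_share = 0.6,
                   censor_fraction = 0, replicates = 1L, seed = 11L)
  do.call(cohort_spec, utils::modifyList(defaults, list(...)))
}

tiny_cohort <- function(...) generate_cohort(tiny_spec(...))

# averaged, censor-filtered response as a named vector
modelable_response <- function(cohort) {
  resp <- filter_censored(average_replicates(cohort$response), quiet = TRUE)
  setNames(resp$log_ic50, resp$cell_id)
}

train_test <- function(cohort, seed = 3L, train_frac = 0.75) {
  y <- modelable_response(cohort)
  s <- make_stratified_splits(names(y), cohort$annotation, n_splits = 1L,
                              train_frac = train_frac, seed = seed)[[1L]]
  list(X_train = cohort$expression[s$train_ids, , drop = FALSE],
       y_train = unname(y[s$train_ids]),
       X_test = cohort$expression[s$test_ids, , drop = FALSE],
       y_test = unname(y[s$test_ids]),
       split = s)
}
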