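# Shared synthetic datasets, generated once per test run and cached.
# Sizes: the cross-validation benchmarks use the full 200-record, 4:1 study
# condition; auxiliary training tests reuse subsets so the suite stays
# within a desk-scale runtime.

.ctg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ctg_cache)) {
    assign(key, force(expr), envir = .ctg_cache)
  }
  get(key, envir = .ctg_cache)
}

# generate, preprocess and featurize a class-conditional dataset
make_study_data <- function(level, n, seed) {
  sched <- difficulty_schedule(level)
  d <- generate_fhr_dataset(n, params_normal = sched$normal,
                            params_pathological = sched$pathological,
                            seed = seed)
  sigs <- suppressWarnings(lapply(d$signals, preprocess_fhr))
  X <- vapply(sigs, function(s) s$samples, numeric(4800))
  feats <- fhr_feature_table(sigs)
  list(X = X, features = feats, labels = d$labels, truths = d$truths,
       raw = d$signals)
}

study_data <- function(level) {
  switch(level,
    easy = cached("easy200", make_study_data("easy", 200, 101)),
    hard = cached("hard200", make_study_data("hard", 200, 101)),
    medium = cached("medium100", make_study_data("medium", 100, 202)),
    hard100 = cached("hard100", make_study_data("hard", 100, 202)),
    stop("unknown level")
  )
}

# stratified subset of the cached easy data
easy_subset <- function(n_normal, n_path) {
  d <- study_data("easy")
  idx <- c(which(d$labels == "normal")[seq_len(n_normal)],
           which(d$labels == "pathological")[seq_len(n_path)])
  list(X = d$X[, idx, drop = FALSE],
       features = d$features[idx, , drop = FALSE],
       labels = d$labels[idx])
}

# small backbone used by gradient / determinism tests
tiny_spec <- function(dropout = 0) {
  backbone_spec(input_length = 48, branch_kernels = c(3, 5),
                branch_filters = 2, trunk_kernel = 5, trunk_filters = 6,
                pool_windows = c(2, 2, 2), dropout_conv = dropout,
                lstm_units = 3, fc_units = 4, dropout_fc = dropout,
                n_engineered = 16)
}
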