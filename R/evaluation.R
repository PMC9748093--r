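#' Confusion matrix with pathological as the positive class
#'
#' @param labels Observed labels (factor/character/0-1; 1 or
#'   `"pathological"` = positive).
#' @param predictions Predicted labels, same encodings.
#' @return Named list with counts `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_matrix <- function(labels, predictions) {
  y <- label_to_int(labels)
  p <- label_to_int(predictions)
  if (!length(y)) stop("empty input", call. = FALSE)
  if (length(y) != length(p)) stop("length mismatch", call. = FALSE)
  list(TP = sum(y == 1 & p == 1), FP = sum(y == 0 & p == 1),
       FN = sum(y == 1 & p == 0), TN = sum(y == 0 & p == 0))
}

#' Sensitivity, specificity and quality index
#'
#' `SE = TP / (TP + FN)` (recall of pathological records), `SP = TN /
#' (TN + FP)` (recall of normal records), and their geometric mean
#' `QI = sqrt(SE * SP)` — the headline metric under class imbalance.
#'
#' @param cm A confusion matrix from [confusion_matrix()].
#' @return Named numeric vector `SE`, `SP`, `QI`.
#' @export
se_sp_qi <- function(cm) {
  if (cm$TP + cm$FN == 0 || cm$TN + cm$FP == 0) {
    stop("metrics undefined: one class is absent from the evaluation set",
         call. = FALSE)
  }
  se <- cm$TP / (cm$TP + cm$FN)
  sp <- cm$TN / (cm$TN + cm$FP)
  c(SE = se, SP = sp, QI = sqrt(se * sp))
}

#' Stratified k-fold assignment
#'
#' Partitions records into `k` folds preserving class proportions: within
#' each class the (shuffled) records are dealt round-robin, so per-fold class
#' counts deviate from exact proportionality by at most one record.
#'
#' @param labels Class labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per record.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1) {
  y <- label_to_int(labels)
  fold <- integer(length(y))
  rng <- local({ set.seed(seed); NULL })
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop(sprintf("class %d has %d records, fewer than k = %d folds",
                   cls, length(idx), k), call. = FALSE)
    }
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified cross-validation of the DFFN
#'
#' Trains a fresh model per fold on the remaining records and evaluates it on
#' the held-out fold. Per-fold SE/SP/QI are aggregated as mean and standard
#' deviation across folds (not from a pooled confusion matrix). A failing
#' fold is recorded and skipped; the report flags incompleteness.
#'
#' @param signals,features,labels The dataset (see [dffn()]).
#' @param config A [dffn_config()]; `config$seed` also seeds the fold split.
#' @param k Number of folds (default 10).
#' @param stage1_epochs,stage2_epochs Per-stage epoch overrides.
#' @param threshold Decision threshold for [predict.dffn()].
#' @return A `dffn_cv` object: per-fold metrics, confusion matrices,
#'   probabilities, and `mean`/`sd` aggregates.
#' @export
cross_validate <- function(signals, features, labels, config = dffn_config(),
                           k = 10, stage1_epochs = config$epochs,
                           stage2_epochs = config$epochs, threshold = 0.5) {
  features <- as.matrix(features)
  y <- label_to_int(labels)
  X <- as_signal_matrix(signals, config$backbone$input_length)
  fold <- stratified_kfold(y, k = k, seed = config$seed)
  per_fold <- matrix(NA_real_, k, 3L, dimnames = list(NULL, c("SE", "SP", "QI")))
  cms <- vector("list", k)
  probs <- vector("list", k)
  failed <- character(0)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    res <- tryCatch({
      fit <- dffn(X[, tr, drop = FALSE], features[tr, , drop = FALSE], y[tr],
                  cfg_f, stage1_epochs = stage1_epochs,
                  stage2_epochs = stage2_epochs)
      p <- predict(fit, X[, te, drop = FALSE], features[te, , drop = FALSE])
      cm <- confusion_matrix(y[te], as.integer(p >= threshold))
      list(metrics = se_sp_qi(cm), cm = cm, prob = p)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("fold %d: %s", f, conditionMessage(res)))
    } else {
      per_fold[f, ] <- res$metrics
      cms[[f]] <- res$cm
      probs[[f]] <- res$prob
    }
  }
  ok <- stats::complete.cases(per_fold)
  structure(list(
    folds = per_fold,
    confusion = cms,
    probabilities = probs,
    mean = colMeans(per_fold[ok, , drop = FALSE]),
    sd = apply(per_fold[ok, , drop = FALSE], 2L, stats::sd),
    k = k, failed = failed, complete = all(ok),
    class_weights = config$class_weights
  ), class = "dffn_cv")
}

#' @export
print.dffn_cv <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (class weights %.2f : %.2f)\n",
              x$k, x$class_weights[1L], x$class_weights[2L]))
  m <- x$mean * 100; s <- x$sd * 100
  cat(sprintf("  SE %.2f%% +/- %.2f   SP %.2f%% +/- %.2f   QI %.2f%% +/- %.2f\n",
              m["SE"], s["SE"], m["SP"], s["SP"], m["QI"], s["QI"]))
  if (!x$complete) {
    cat("  INCOMPLETE:", length(x$failed), "fold(s) failed\n")
    for (msg in x$failed) cat("   -", msg, "\n")
  }
  invisible(x)
}

#' Class-weight sweep
#'
#' Runs one cross-validation per class-weight pair and tabulates mean SE, SP
#' and QI. The default grid spans 0.22:0.78 down to 0.16:0.84. The returned
#' table is sorted by mean QI (descending); ties break toward the pair with
#' higher SP (preserving normal-sample detection).
#'
#' @param signals,features,labels The dataset.
#' @param weight_grid Two-column matrix (normal, pathological) or list of
#'   length-2 vectors.
#' @param config Base [dffn_config()]; class weights are overridden per run.
#' @param ... Passed to [cross_validate()] (e.g. `k`, `stage1_epochs`).
#' @return A `dffn_sweep` data frame of per-pair aggregates with the selected
#'   best pair in `attr(, "best")` and the full CV objects in
#'   `attr(, "runs")`.
#' @export
class_weight_sweep <- function(signals, features, labels,
                               weight_grid = default_weight_grid(),
                               config = dffn_config(), ...) {
  if (is.matrix(weight_grid)) {
    weight_grid <- lapply(seq_len(nrow(weight_grid)),
                          function(i) weight_grid[i, ])
  }
  runs <- vector("list", length(weight_grid))
  rows <- vector("list", length(weight_grid))
  for (i in seq_along(weight_grid)) {
    wp <- as.numeric(weight_grid[[i]])
    stopifnot(length(wp) == 2L, all(wp > 0))
    cfg <- config
    cfg$class_weights <- stats::setNames(wp, c("normal", "pathological"))
    cv <- cross_validate(signals, features, labels, cfg, ...)
    runs[[i]] <- cv
    rows[[i]] <- data.frame(w_normal = wp[1L], w_pathological = wp[2L],
                            SE = cv$mean["SE"], SP = cv$mean["SP"],
                            QI = cv$mean["QI"], SE_sd = cv$sd["SE"],
                            SP_sd = cv$sd["SP"], QI_sd = cv$sd["QI"],
                            row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$QI, -tab$SP)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "best") <- c(tab$w_normal[1L], tab$w_pathological[1L])
  attr(tab, "runs") <- runs[ord]
  class(tab) <- c("dffn_sweep", "data.frame")
  tab
}

#' Default class-weight grid
#'
#' Normal:pathological weight pairs from 0.22:0.78 to 0.16:0.84 in steps of
#' 0.01, spanning the useful range for a roughly 4:1 class imbalance.
#'
#' @return A 7 x 2 matrix with columns (normal, pathological).
#' @export
default_weight_grid <- function() {
  w_n <- seq(0.22, 0.16, by = -0.01)
  cbind(normal = w_n, pathological = 1 - w_n)
}

#' Precision-recall curve and average precision
#'
#' Precision and recall of the pathological class at every distinct score
#' threshold, plus average precision by the step-wise sum
#' `AP = sum((R_i - R_{i-1}) * P_i)` over thresholds in decreasing score
#' order.
#'
#' @param labels Observed labels (1/`"pathological"` = positive).
#' @param probabilities Predicted scores in `[0, 1]`.
#' @return List with `curve` (data frame `threshold`, `precision`, `recall`)
#'   and `average_precision`.
#' @export
precision_recall <- function(labels, probabilities) {
  y <- label_to_int(labels)
  s <- as.numeric(probabilities)
  stopifnot(length(y) == length(s))
  if (length(unique(y)) < 2L) {
    stop("precision-recall undefined: labels contain a single class",
         call. = FALSE)
  }
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # collapse tied scores: evaluate at the last index of each distinct score
  keep <- c(diff(s) != 0, TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  ap <- sum(diff(c(0, rec)) * prec)
  list(curve = data.frame(threshold = s[keep], precision = prec, recall = rec),
       average_precision = ap)
}
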