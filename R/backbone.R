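#' Multiscale CNN-BiLSTM backbone specification
#'
#' The layer table of the backbone as data. Defaults reproduce the reference
#' architecture: a 4800-sample input, two parallel convolution branches
#' (kernel sizes 32 and 64, 8 filters each, stride 1, SAME padding)
#' concatenated to 16 channels; three trunk convolution stages (kernel 32, 24
#' filters, SAME), each followed by batch normalisation, ELU, valid-padding
#' average pooling (windows 4, 8, 16) and dropout 0.25; a bidirectional LSTM
#' (12 units per direction, concatenated width 24) over the final 9-step
#' sequence; a parameter-free residual add of the convolutional path and the
#' BiLSTM output; flatten (216); a 32-unit fully connected layer with ELU and
#' dropout 0.5; and a 1-unit sigmoid head for stage-1 training.
#'
#' @param input_length Samples per input signal (4800 = 20 min at 4 Hz).
#' @param branch_kernels Kernel sizes of the parallel branches.
#' @param branch_filters Filters per branch.
#' @param trunk_kernel,trunk_filters Trunk convolution kernel size and filter
#'   count.
#' @param pool_windows Average-pooling window (= stride) per trunk stage.
#' @param dropout_conv Dropout rate after each pooled trunk stage.
#' @param lstm_units Hidden units per LSTM direction; the concatenated width
#'   `2 * lstm_units` must equal `trunk_filters` for the residual add.
#' @param fc_units Width of the deep-feature fully connected layer.
#' @param dropout_fc Dropout rate after the fully connected layer.
#' @param n_engineered Width of the engineered feature vector fused in
#'   stage 2.
#' @param dropout_fuse Dropout rate on the fused 48-dimensional vector.
#' @return A `backbone_spec` list.
#' @export
backbone_spec <- function(input_length = 4800, branch_kernels = c(32, 64),
                          branch_filters = 8, trunk_kernel = 32,
                          trunk_filters = 24, pool_windows = c(4, 8, 16),
                          dropout_conv = 0.25, lstm_units = 12, fc_units = 32,
                          dropout_fc = 0.5, n_engineered = 16,
                          dropout_fuse = 0.25) {
  if (2 * lstm_units != trunk_filters) {
    stop("residual add requires 2 * lstm_units == trunk_filters", call. = FALSE)
  }
  len <- input_length
  for (w in pool_windows) len <- len %/% w
  if (len < 1) stop("pooling reduces the sequence below length 1", call. = FALSE)
  structure(list(
    input_length = as.integer(input_length),
    branch_kernels = as.integer(branch_kernels),
    branch_filters = as.integer(branch_filters),
    trunk_kernel = as.integer(trunk_kernel),
    trunk_filters = as.integer(trunk_filters),
    pool_windows = as.integer(pool_windows),
    dropout_conv = dropout_conv,
    lstm_units = as.integer(lstm_units),
    fc_units = as.integer(fc_units),
    dropout_fc = dropout_fc,
    n_engineered = as.integer(n_engineered),
    dropout_fuse = dropout_fuse,
    final_steps = as.integer(len),
    flatten = as.integer(len * trunk_filters)
  ), class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf(
    "<backbone_spec> input %d, branches k=%s (%d filters), trunk k=%d f=%d, pools %s,\n  BiLSTM %dx2, flatten %d, fc %d, fused %d\n",
    x$input_length, paste(x$branch_kernels, collapse = "/"), x$branch_filters,
    x$trunk_kernel, x$trunk_filters, paste(x$pool_windows, collapse = "/"),
    x$lstm_units, x$flatten, x$fc_units, x$fc_units + x$n_engineered))
  invisible(x)
}

#' Training configuration
#'
#' Stage-1 (backbone) and stage-2 (fusion head) optimisation settings:
#' SGD with momentum 0.9, initial learning rate 0.01 divided by 10 after
#' epochs 15 and 90, 130 epochs, and class-weighted cross-entropy with
#' weights 0.21 (normal) : 0.79 (pathological) chosen for the roughly 4:1
#' class imbalance of intrapartum archives.
#'
#' @param epochs Training epochs.
#' @param lr0 Initial learning rate.
#' @param lr_drop_epochs Epochs after which the rate divides by
#'   `lr_drop_factor`.
#' @param lr_drop_factor Division factor at each drop.
#' @param momentum SGD momentum.
#' @param class_weights Length-2 numeric `(normal, pathological)` loss
#'   weights.
#' @param batch_size Minibatch size (unspecified in the reference setting;
#'   default 32).
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @param backbone A [backbone_spec()].
#' @return A `dffn_config` list.
#' @export
dffn_config <- function(epochs = 130, lr0 = 0.01, lr_drop_epochs = c(15, 90),
                        lr_drop_factor = 10, momentum = 0.9,
                        class_weights = c(normal = 0.21, pathological = 0.79),
                        batch_size = 32, seed = 1,
                        backbone = backbone_spec()) {
  stopifnot(length(class_weights) == 2L, all(class_weights > 0),
            epochs >= 1, batch_size >= 1)
  structure(list(
    epochs = as.integer(epochs), lr0 = lr0,
    lr_drop_epochs = as.integer(lr_drop_epochs),
    lr_drop_factor = lr_drop_factor, momentum = momentum,
    class_weights = stats::setNames(as.numeric(class_weights),
                                    c("normal", "pathological")),
    batch_size = as.integer(batch_size), seed = as.integer(seed),
    backbone = backbone
  ), class = "dffn_config")
}

#' Learning-rate schedule
#'
#' Step schedule: the rate starts at `lr0` and divides by `lr_drop_factor`
#' after each epoch listed in `lr_drop_epochs` (so with drops at 15 and 90,
#' epoch 16 runs at `lr0/10` and epoch 91 at `lr0/100`).
#'
#' @param cfg A [dffn_config()].
#' @param epochs Number of epochs to produce (defaults to `cfg$epochs`).
#' @return Numeric vector of per-epoch learning rates.
#' @export
lr_schedule <- function(cfg, epochs = cfg$epochs) {
  e <- seq_len(epochs)
  drops <- vapply(e, function(ep) sum(ep > cfg$lr_drop_epochs), 0L)
  cfg$lr0 / cfg$lr_drop_factor^drops
}

#' Build (initialise) a backbone
#'
#' Draws Glorot-uniform weights for every layer of the specification and
#' verifies by a real forward pass that the layer output shapes match the
#' specification row for row (any mismatch is a construction error naming the
#' layer).
#'
#' @param spec A [backbone_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return A `dffn_backbone` object (list of weight matrices plus the spec).
#' @export
build_backbone <- function(spec = backbone_spec(), seed = 1) {
  par <- cpp_dffn_init(spec, as.integer(seed))
  bb <- structure(list(par = par, spec = spec), class = "dffn_backbone")
  sh <- backbone_shapes(bb)
  expected <- expected_shapes(spec)
  got <- sh$output_shape[match(names(expected), sh$layer)]
  bad <- which(got != unlist(expected))
  if (length(bad)) {
    stop(sprintf("backbone construction: layer %s produced %s, expected %s",
                 names(expected)[bad[1L]], got[bad[1L]],
                 expected[[bad[1L]]]), call. = FALSE)
  }
  bb
}

# analytic shape table used to cross-check the real forward pass
expected_shapes <- function(spec) {
  out <- list(signal_input = sprintf("%dx1", spec$input_length))
  for (i in seq_along(spec$branch_kernels)) {
    out[[paste0("branch_conv", i)]] <-
      sprintf("%dx%d", spec$input_length, spec$branch_filters)
  }
  out$branch_concat <- sprintf("%dx%d", spec$input_length,
                               length(spec$branch_kernels) * spec$branch_filters)
  len <- spec$input_length
  for (s in seq_along(spec$pool_windows)) {
    out[[paste0("trunk_conv", s)]] <- sprintf("%dx%d", len, spec$trunk_filters)
    len <- len %/% spec$pool_windows[s]
    out[[paste0("avg_pool", s)]] <- sprintf("%dx%d", len, spec$trunk_filters)
    out[[paste0("dropout", s)]] <- sprintf("%dx%d", len, spec$trunk_filters)
  }
  out$bilstm <- sprintf("%dx%d", len, 2L * spec$lstm_units)
  out$add <- sprintf("%dx%d", len, spec$trunk_filters)
  out$flatten <- sprintf("1x%d", len * spec$trunk_filters)
  out$fully_connected <- sprintf("1x%d", spec$fc_units)
  out$fc_dropout <- sprintf("1x%d", spec$fc_units)
  out$head_fc <- "1x1"
  out$sigmoid <- "1x1"
  out
}

#' Layer-by-layer output shapes of a backbone forward pass
#'
#' Runs one real forward pass on a zero input and records the output shape of
#' every layer, appending the stage-2 fusion rows (engineered feature input,
#' concatenation, fused dropout, fusion head).
#'
#' @param backbone A `dffn_backbone` (from [build_backbone()]) or a fitted
#'   [dffn()] model.
#' @return Data frame with columns `layer` and `output_shape`.
#' @export
backbone_shapes <- function(backbone) {
  if (inherits(backbone, "dffn")) backbone <- backbone$backbone
  stopifnot(inherits(backbone, "dffn_backbone"))
  sh <- cpp_dffn_shapes(backbone$par, backbone$spec)
  spec <- backbone$spec
  fuse <- data.frame(
    layer = c("feature_input", "fuse_concat", "fuse_dropout", "fusion_head",
              "fusion_sigmoid"),
    output_shape = c(sprintf("1x%d", spec$n_engineered),
                     sprintf("1x%d", spec$fc_units + spec$n_engineered),
                     sprintf("1x%d", spec$fc_units + spec$n_engineered),
                     "1x1", "1x1"),
    stringsAsFactors = FALSE
  )
  rbind(sh, fuse)
}

as_signal_matrix <- function(signals, input_length) {
  if (is.matrix(signals)) {
    X <- signals
  } else if (is.list(signals)) {
    X <- vapply(signals, as_samples, numeric(input_length))
  } else {
    X <- matrix(as.numeric(signals), ncol = 1L)
  }
  if (nrow(X) != input_length) {
    stop(sprintf("signals have %d samples; the backbone expects %d",
                 nrow(X), input_length), call. = FALSE)
  }
  X
}

label_to_int <- function(labels) {
  if (is.factor(labels)) {
    as.integer(labels == "pathological")
  } else if (is.character(labels)) {
    as.integer(labels == "pathological")
  } else {
    as.integer(labels != 0)
  }
}

#' Stage-1 training of the backbone
#'
#' Trains the full backbone (sigmoid head included) end to end with
#' class-weighted cross-entropy and SGD momentum under the configured
#' learning-rate schedule. Deterministic given `cfg$seed`.
#'
#' @param signals Preprocessed signals: a list of [fhr_signal()] or a numeric
#'   matrix (`input_length` rows, one column per record).
#' @param labels Class labels (factor/character with level `"pathological"`,
#'   or 0/1 numeric with 1 = pathological).
#' @param cfg A [dffn_config()].
#' @param backbone Optional pre-built `dffn_backbone` to continue training.
#' @param epochs Override of `cfg$epochs`.
#' @return A `dffn_backbone` with a `loss` attribute (per-epoch mean training
#'   loss).
#' @export
train_stage1 <- function(signals, labels, cfg = dffn_config(),
                         backbone = NULL, epochs = cfg$epochs) {
  spec <- if (is.null(backbone)) cfg$backbone else backbone$spec
  X <- as_signal_matrix(signals, spec$input_length)
  y <- label_to_int(labels)
  stopifnot(length(y) == ncol(X))
  if (is.null(backbone)) backbone <- build_backbone(spec, cfg$seed)
  lr <- lr_schedule(cfg, epochs)
  fit <- cpp_dffn_train(backbone$par, spec, X, y,
                        unname(cfg$class_weights), lr, cfg$momentum,
                        cfg$batch_size, cfg$seed)
  out <- structure(list(par = fit$par, spec = spec), class = "dffn_backbone")
  attr(out, "loss") <- as.numeric(fit$loss)
  out
}

#' Extract deep features
#'
#' Evaluation-mode activations of the fully connected layer (pre-dropout),
#' the 32-dimensional deep representation fused with the engineered features
#' in stage 2.
#'
#' @param backbone A `dffn_backbone` or fitted [dffn()] model.
#' @param signals Signals as in [train_stage1()].
#' @return Numeric matrix, one row per record, `fc_units` columns.
#' @export
extract_deep_features <- function(backbone, signals) {
  if (inherits(backbone, "dffn")) backbone <- backbone$backbone
  stopifnot(inherits(backbone, "dffn_backbone"))
  X <- as_signal_matrix(signals, backbone$spec$input_length)
  cpp_dffn_forward(backbone$par, backbone$spec, X)$deep
}

backbone_prob <- function(backbone, signals) {
  X <- as_signal_matrix(signals, backbone$spec$input_length)
  as.numeric(cpp_dffn_forward(backbone$par, backbone$spec, X)$prob)
}

#' Class-weighted binary cross-entropy
#'
#' Per-sample cross-entropy multiplied by the weight of the sample's class
#' and averaged over the batch. Predicted probabilities at exactly 0 or 1 are
#' clamped to `[eps, 1 - eps]`.
#'
#' @param y Observed labels in `{0, 1}` (1 = pathological).
#' @param y_hat Predicted probabilities.
#' @param class_weights Length-2 weights `(normal, pathological)`.
#' @param eps Clamp bound (default 1e-7).
#' @return Mean weighted loss (scalar).
#' @export
weighted_bce <- function(y, y_hat, class_weights = c(1, 1), eps = 1e-7) {
  stopifnot(length(y) == length(y_hat), all(y %in% c(0, 1)))
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  w <- ifelse(y == 1, class_weights[2L], class_weights[1L])
  mean(-w * (y * log(p) + (1 - y) * log(1 - p)))
}
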