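#' Fit a deep feature fusion network (DFFN)
#'
#' Two-stage training of the fetal-state classifier. Stage 1 trains the
#' multiscale CNN-BiLSTM backbone end to end on the raw 20-minute signals
#' with class-weighted cross-entropy. Stage 2 freezes the backbone (by
#' default), extracts its 32-dimensional deep representation, concatenates it
#' with the 16 engineered features (z-scored with training statistics) into a
#' 48-dimensional fused vector, and trains a dropout-regularised sigmoid head
#' on the fused features with the same optimiser settings.
#'
#' @param signals Preprocessed signals: list of [fhr_signal()] or numeric
#'   matrix (`input_length` rows, one column per record).
#' @param features Engineered feature matrix, one row per record (see
#'   [fhr_feature_table()]).
#' @param labels Class labels (factor/character with level `"pathological"`,
#'   or 0/1 with 1 = pathological).
#' @param config A [dffn_config()].
#' @param stage1_epochs,stage2_epochs Epoch overrides per stage (both default
#'   to `config$epochs`).
#' @param finetune Reserved for backbone updates during stage 2; only
#'   `FALSE` (frozen backbone) is implemented.
#' @return An object of class `dffn` with components `backbone`, `head`
#'   (weights `W`, bias `b`), `scaler` (`center`, `scale`), `config`,
#'   `feature_names`, and per-stage training `loss` curves.
#' @seealso [predict.dffn()], [cross_validate()]
#' @examples
#' \donttest{
#' sched <- difficulty_schedule("easy")
#' d <- generate_fhr_dataset(40, params_normal = sched$normal,
#'                           params_pathological = sched$pathological, seed = 1)
#' feats <- fhr_feature_table(d$signals)
#' cfg <- dffn_config(epochs = 5, seed = 1)
#' fit <- dffn(d$signals, feats, d$labels, cfg)
#' predict(fit, d$signals[1:2], feats[1:2, , drop = FALSE])
#' }
#' @export
dffn <- function(signals, features, labels, config = dffn_config(),
                 stage1_epochs = config$epochs, stage2_epochs = config$epochs,
                 finetune = FALSE) {
  if (finetune) stop("finetuning the backbone in stage 2 is not implemented",
                     call. = FALSE)
  features <- as.matrix(features)
  y <- label_to_int(labels)
  spec <- config$backbone
  if (ncol(features) != spec$n_engineered) {
    stop(sprintf("engineered features have %d columns; the spec expects %d",
                 ncol(features), spec$n_engineered), call. = FALSE)
  }
  if (nrow(features) != length(y)) {
    stop("features and labels disagree in length", call. = FALSE)
  }

  backbone <- train_stage1(signals, y, config, epochs = stage1_epochs)
  deep <- extract_deep_features(backbone, signals)

  # divergent entropy estimates surface as NA; impute with the column mean
  # so one degenerate record cannot poison the scaler
  features[!is.finite(features)] <- NA
  scaler <- list(center = colMeans(features, na.rm = TRUE),
                 scale = apply(features, 2L, stats::sd, na.rm = TRUE))
  scaler$center[!is.finite(scaler$center)] <- 0
  scaler$scale[!is.finite(scaler$scale) | scaler$scale == 0] <- 1
  for (j in seq_len(ncol(features))) {
    features[is.na(features[, j]), j] <- scaler$center[j]
  }
  fused <- cbind(deep, scale(features, scaler$center, scaler$scale))

  head <- train_fusion_head(fused, y, config, stage2_epochs,
                            dropout = spec$dropout_fuse)

  structure(list(
    backbone = backbone,
    head = head[c("W", "b")],
    scaler = scaler,
    config = config,
    feature_names = colnames(features),
    loss = list(stage1 = attr(backbone, "loss"), stage2 = head$loss),
    n_train = length(y),
    class_counts = c(normal = sum(y == 0), pathological = sum(y == 1))
  ), class = "dffn")
}

# SGD-momentum logistic head on fused features with input dropout
train_fusion_head <- function(fused, y, cfg, epochs, dropout = 0.25) {
  n <- nrow(fused); d <- ncol(fused)
  lr <- lr_schedule(cfg, epochs)
  w <- cfg$class_weights
  set.seed(cfg$seed + 1L)
  W <- matrix(stats::runif(d, -sqrt(6 / (d + 1)), sqrt(6 / (d + 1))), ncol = 1L)
  b <- 0
  vW <- W * 0; vb <- 0
  keep <- 1 - dropout
  losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0; nb <- 0
    for (s0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[s0:min(n, s0 + cfg$batch_size - 1L)]
      Xb <- fused[idx, , drop = FALSE]
      if (dropout > 0) {
        mask <- matrix(stats::rbinom(length(Xb), 1L, keep) / keep, nrow(Xb), d)
        Xb <- Xb * mask
      }
      yb <- y[idx]
      z <- drop(Xb %*% W) + b
      p <- 1 / (1 + exp(-z))
      wt <- ifelse(yb == 1, w[2L], w[1L])
      pcl <- pmin(pmax(p, 1e-7), 1 - 1e-7)
      tot <- tot + mean(-wt * (yb * log(pcl) + (1 - yb) * log(1 - pcl)))
      nb <- nb + 1L
      dz <- wt * (p - yb) / length(yb)
      gW <- crossprod(Xb, dz)
      gb <- sum(dz)
      vW <- cfg$momentum * vW - lr[e] * gW
      vb <- cfg$momentum * vb - lr[e] * gb
      W <- W + vW
      b <- b + vb
    }
    losses[e] <- tot / nb
  }
  list(W = W, b = b, loss = losses)
}

#' Predict fetal state from a fitted DFFN
#'
#' @param object A fitted [dffn()] model.
#' @param signals New preprocessed signals (list or matrix).
#' @param features Matching engineered feature matrix (raw scale; the
#'   training z-scoring is applied internally).
#' @param type `"prob"` for probabilities, `"class"` for labels, `"both"`
#'   for a data frame with both.
#' @param threshold Decision threshold; a probability greater than or equal
#'   to it is called pathological (ties go to pathological).
#' @param ... Unused.
#' @return Probabilities, a factor of labels, or a data frame.
#' @export
predict.dffn <- function(object, signals, features,
                         type = c("prob", "class", "both"), threshold = 0.5,
                         ...) {
  type <- match.arg(type)
  features <- matrix(as.numeric(features), ncol = length(object$scaler$center))
  for (j in seq_len(ncol(features))) {
    bad <- !is.finite(features[, j])
    features[bad, j] <- object$scaler$center[j]
  }
  deep <- extract_deep_features(object$backbone, signals)
  if (nrow(deep) != nrow(features)) {
    stop("signals and features disagree in record count", call. = FALSE)
  }
  fused <- cbind(deep, scale(features, object$scaler$center,
                             object$scaler$scale))
  z <- drop(fused %*% object$head$W) + object$head$b
  prob <- 1 / (1 + exp(-z))
  if (type == "prob") return(prob)
  lab <- factor(ifelse(prob >= threshold, "pathological", "normal"),
                levels = c("normal", "pathological"))
  if (type == "class") lab else data.frame(prob = prob, class = lab)
}

#' @export
print.dffn <- function(x, ...) {
  cat("Deep feature fusion network (multiscale CNN-BiLSTM + engineered features)\n")
  cat(sprintf("  trained on %d records (%d normal, %d pathological)\n",
              x$n_train, x$class_counts["normal"], x$class_counts["pathological"]))
  cat(sprintf("  deep features: %d, engineered: %d, fused: %d\n",
              x$config$backbone$fc_units, x$config$backbone$n_engineered,
              x$config$backbone$fc_units + x$config$backbone$n_engineered))
  cat(sprintf("  class weights %.2f : %.2f, final stage-1 loss %.4f\n",
              x$config$class_weights[1L], x$config$class_weights[2L],
              utils::tail(x$loss$stage1, 1L)))
  invisible(x)
}

#' @export
summary.dffn <- function(object, ...) {
  out <- list(
    shapes = backbone_shapes(object$backbone),
    loss = object$loss,
    config = object$config,
    head_coef = coef(object)
  )
  class(out) <- "summary.dffn"
  out
}

#' @export
print.summary.dffn <- function(x, ...) {
  cat("Layer shapes:\n")
  print(x$shapes, row.names = FALSE)
  cat(sprintf("\nStage-1 loss: %.4f -> %.4f over %d epochs\n",
              x$loss$stage1[1L], utils::tail(x$loss$stage1, 1L),
              length(x$loss$stage1)))
  cat(sprintf("Stage-2 loss: %.4f -> %.4f over %d epochs\n",
              x$loss$stage2[1L], utils::tail(x$loss$stage2, 1L),
              length(x$loss$stage2)))
  cat("\nLargest-magnitude fusion-head coefficients:\n")
  co <- sort(abs(x$head_coef), decreasing = TRUE)
  print(round(utils::head(co, 8L), 4L))
  invisible(x)
}

#' @export
coef.dffn <- function(object, ...) {
  nm <- c(paste0("deep", seq_len(object$config$backbone$fc_units)),
          if (!is.null(object$feature_names)) object$feature_names
          else paste0("feat", seq_len(object$config$backbone$n_engineered)),
          "(bias)")
  stats::setNames(c(drop(object$head$W), object$head$b), nm)
}

#' @export
plot.dffn <- function(x, ...) {
  graphics::plot(x$loss$stage1, type = "l", xlab = "epoch",
                 ylab = "mean weighted BCE", main = "DFFN training loss", ...)
  graphics::lines(seq_along(x$loss$stage2), x$loss$stage2, lty = 2)
  graphics::legend("topright", legend = c("stage 1 (backbone)",
                                          "stage 2 (fusion head)"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
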