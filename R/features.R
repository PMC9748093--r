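#' Default engineered-feature layout
#'
#' The fusion classifier consumes a 16-dimensional engineered feature vector:
#' 4 morphological features (baseline, acceleration count, deceleration
#' count, variability), 8 time-domain/FHRV statistics (mean, sd, mean
#' absolute deviation, median absolute deviation, LTV, STV, LTI, II) and 4
#' entropy features (ApEn and SampEn at r = 0.15 and r = 0.2). The exact
#' membership of the bank is configurable; an alternate layout swaps one
#' entropy column for the Lempel-Ziv complexity (`"lzc"`).
#'
#' @param include_lzc Replace `"sampen_r20"` by `"lzc"`.
#' @return Character vector of 16 feature names.
#' @export
feature_layout <- function(include_lzc = FALSE) {
  base <- c("baseline", "accel_count", "decel_count", "variability",
            "mean", "std", "mean_ad", "median_ad",
            "ltv", "stv", "lti", "ii",
            "apen_r15", "apen_r20", "sampen_r15", "sampen_r20")
  if (include_lzc) base[base == "sampen_r20"] <- "lzc"
  base
}

#' Compute the engineered feature bank of one FHR segment
#'
#' Computes all linear, morphological and nonlinear features of a
#' preprocessed segment and returns the named vector selected by `layout`.
#'
#' @param x A preprocessed [fhr_signal()] or numeric vector (assumed 4 Hz).
#' @param layout Character vector of feature names (see [feature_layout()]).
#' @param m,r_values Entropy parameters: embedding dimension and tolerance
#'   levels (relative to the series SD).
#' @param metric Entropy distance metric.
#' @param lti_variant Convention for [fhr_lti()].
#' @return Named numeric vector, one entry per `layout` element.
#' @export
fhr_features <- function(x, layout = feature_layout(), m = 4,
                         r_values = c(0.15, 0.2),
                         metric = c("euclidean", "chebyshev"),
                         lti_variant = c("literal", "modulus")) {
  metric <- match.arg(metric)
  lti_variant <- match.arg(lti_variant)
  xs <- as_samples(x)
  fs <- if (inherits(x, "fhr_signal")) x$fs else 4

  bs <- fhr_basic_stats(xs)
  blocks <- fhr_block_means(xs, fs = fs)
  baseline <- fhr_baseline(xs)
  acc <- detect_events(xs, baseline, "accel", fs = fs)
  dec <- detect_events(xs, baseline, "decel", fs = fs)
  met <- match(metric, c("euclidean", "chebyshev")) - 1L
  sdx <- stats::sd(xs)
  if (sdx > 0) {
    ent <- cpp_entropy_counts(xs, m, r_values * sdx, met)
    apen <- ent$apen
    sampen <- ent$sampen
    sampen[!is.finite(sampen)] <- NA_real_
  } else {
    apen <- sampen <- rep(0, length(r_values))
  }

  vals <- c(
    baseline = baseline,
    accel_count = nrow(acc),
    decel_count = nrow(dec),
    variability = variability_bandwidth(xs, baseline,
                                        events = rbind(acc, dec), fs = fs),
    mean = unname(bs["mean"]),
    std = unname(bs["std"]),
    mean_ad = unname(bs["mean_ad"]),
    median_ad = unname(bs["median_ad"]),
    ltv = fhr_ltv(blocks),
    stv = fhr_stv(blocks),
    lti = fhr_lti(blocks, lti_variant),
    ii = if (stats::sd(blocks$block_means) > 0) fhr_interval_index(xs) else NA_real_,
    apen_r15 = apen[1L],
    apen_r20 = apen[2L],
    sampen_r15 = sampen[1L],
    sampen_r20 = sampen[2L],
    lzc = fhr_lzc(xs)
  )
  assemble_feature_vector(vals, layout)
}

#' Assemble a named feature vector in a fixed layout
#'
#' Selects and orders computed feature values according to `layout`,
#' validating that the result matches the width the fusion network expects.
#'
#' @param values Named numeric vector of computed features (a superset of
#'   `layout` is allowed).
#' @param layout Character vector of names to select, in order.
#' @param expected_length Required length (default 16, the fusion input
#'   width); set `NULL` to skip the check.
#' @return Named numeric vector `values[layout]`.
#' @export
assemble_feature_vector <- function(values, layout = feature_layout(),
                                    expected_length = 16L) {
  missing <- setdiff(layout, names(values))
  if (length(missing)) {
    stop("features not computed: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(expected_length) && length(layout) != expected_length) {
    stop(sprintf("feature layout has %d entries; the fusion input expects %d",
                 length(layout), expected_length), call. = FALSE)
  }
  out <- values[layout]
  names(out) <- layout
  out
}

#' Engineered feature table for a set of records
#'
#' @param signals List of preprocessed [fhr_signal()] objects (or a numeric
#'   matrix with one column per record).
#' @inheritParams fhr_features
#' @return Numeric matrix, one row per record, columns named by `layout`.
#' @export
fhr_feature_table <- function(signals, layout = feature_layout(), ...) {
  if (is.matrix(signals)) {
    signals <- lapply(seq_len(ncol(signals)), function(i) signals[, i])
  }
  out <- t(vapply(signals, function(s) fhr_features(s, layout = layout, ...),
                  numeric(length(layout))))
  colnames(out) <- layout
  rownames(out) <- NULL
  out
}
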