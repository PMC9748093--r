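as_samples <- function(x) {
  if (inherits(x, "fhr_signal")) x$samples else as.numeric(x)
}

#' Time-domain summary statistics of an FHR segment
#'
#' Returns the four classical time-domain descriptors: the mean, the sample
#' standard deviation (1/(N-1) normalisation), the mean absolute deviation
#' from the mean, and the median absolute deviation from the median
#' (unscaled).
#'
#' @param x An [fhr_signal()] or numeric vector.
#' @return Named numeric vector `mean`, `std`, `mean_ad`, `median_ad`.
#' @export
fhr_basic_stats <- function(x) {
  x <- as_samples(x)
  n <- length(x)
  if (n < 2L) stop("standard deviation undefined for N < 2", call. = FALSE)
  m <- mean(x)
  c(mean = m,
    std = stats::sd(x),
    mean_ad = mean(abs(x - m)),
    median_ad = stats::median(abs(x - stats::median(x))))
}

#' Block decomposition of an FHR segment
#'
#' Splits the signal into consecutive 2.5-s fragment blocks (10 samples at
#' 4 Hz) whose means drive the short-term variability statistics, and into
#' whole 60-s minutes whose min/max drive the long-term variability. Trailing
#' partial blocks and partial minutes are discarded.
#'
#' @param x An [fhr_signal()] or numeric vector.
#' @param fs Sampling frequency in Hz (default 4).
#' @param block_s Fragment-block duration in seconds (default 2.5).
#' @return A `fhr_blocks` list: `block_means` (one per fragment block),
#'   `blocks_per_min`, `M` (whole minutes), `minute_ranges` (per-minute
#'   max - min of the raw signal), `fs`, `block_s`.
#' @export
fhr_block_means <- function(x, fs = 4, block_s = 2.5) {
  if (inherits(x, "fhr_signal")) { fs <- x$fs; x <- x$samples }
  x <- as.numeric(x)
  bl <- as.integer(round(block_s * fs))
  if (length(x) < bl) stop("signal shorter than one fragment block", call. = FALSE)
  nb <- length(x) %/% bl
  bm <- colMeans(matrix(x[seq_len(nb * bl)], nrow = bl))
  spm <- as.integer(round(60 * fs))
  M <- length(x) %/% spm
  mr <- if (M >= 1L) {
    xm <- matrix(x[seq_len(M * spm)], nrow = spm)
    apply(xm, 2L, max) - apply(xm, 2L, min)
  } else numeric(0)
  structure(list(block_means = bm, blocks_per_min = as.integer(round(60 / block_s)),
                 M = M, minute_ranges = mr, fs = fs, block_s = block_s),
            class = "fhr_blocks")
}

blocks_of <- function(x) if (inherits(x, "fhr_blocks")) x else fhr_block_means(x)

#' Short-term variability (STV)
#'
#' Mean absolute difference between consecutive 2.5-s block means, averaged
#' over the `24 * M` consecutive-block differences available in the `M` whole
#' minutes of the segment.
#'
#' @param x An [fhr_signal()], numeric vector, or [fhr_block_means()] result.
#' @return STV in bpm.
#' @export
fhr_stv <- function(x) {
  b <- blocks_of(x)
  if (b$M < 1L) stop("STV needs at least one whole minute of signal", call. = FALSE)
  nd <- b$blocks_per_min * b$M
  sm <- b$block_means
  if (length(sm) < nd + 1L) nd <- length(sm) - 1L
  sum(abs(diff(sm[seq_len(nd + 1L)]))) / (b$blocks_per_min * b$M)
}

#' Long-term variability (LTV)
#'
#' Mean over whole minutes of the per-minute range (max - min) of the raw
#' signal.
#'
#' @inheritParams fhr_stv
#' @return LTV in bpm.
#' @export
fhr_ltv <- function(x) {
  b <- blocks_of(x)
  if (b$M < 1L) stop("LTV needs at least one whole minute of signal", call. = FALSE)
  mean(b$minute_ranges)
}

#' Long-term irregularity (LTI)
#'
#' Summary of consecutive 2.5-s block-mean pairs. Two conventions are
#' provided: `"literal"` (default) averages `sqrt(sm(i+1) + sm(i))`
#' (the literal reading of the printed formula, whose radical grouping is
#' typographically ambiguous); `"modulus"` averages the classical modulus
#' `sqrt(sm(i)^2 + sm(i+1)^2)`. Both divide by `24 * M`.
#'
#' @inheritParams fhr_stv
#' @param variant `"literal"` or `"modulus"`.
#' @return LTI in bpm (modulus) or sqrt-bpm (literal).
#' @export
fhr_lti <- function(x, variant = c("literal", "modulus")) {
  variant <- match.arg(variant)
  b <- blocks_of(x)
  if (b$M < 1L) stop("LTI needs at least one whole minute of signal", call. = FALSE)
  nd <- b$blocks_per_min * b$M
  sm <- b$block_means
  if (length(sm) < nd + 1L) nd <- length(sm) - 1L
  s1 <- sm[seq_len(nd)]; s2 <- sm[seq_len(nd) + 1L]
  if (variant == "literal") {
    if (any(s1 + s2 < 0)) stop("negative radicand under literal LTI", call. = FALSE)
    sum(sqrt(s2 + s1)) / (b$blocks_per_min * b$M)
  } else {
    sum(sqrt(s1^2 + s2^2)) / (b$blocks_per_min * b$M)
  }
}

#' Interval index (II)
#'
#' Ratio of the overall FHR standard deviation to the standard deviation of
#' the 2.5-s block means (both sample SDs). Dimensionless; invariant to
#' scaling the signal.
#'
#' @param x An [fhr_signal()] or numeric vector (the raw samples are needed;
#'   a bare `fhr_blocks` object is not accepted).
#' @return II (dimensionless).
#' @export
fhr_interval_index <- function(x) {
  xs <- as_samples(x)
  b <- fhr_block_means(x)
  s_blocks <- stats::sd(b$block_means)
  if (!is.finite(s_blocks) || s_blocks == 0) {
    stop("interval index undefined: block means have zero variance", call. = FALSE)
  }
  stats::sd(xs) / s_blocks
}

#' Baseline estimation by iterative trimmed mean
#'
#' The baseline is the slowly varying FHR level excluding accelerations and
#' decelerations. It is estimated by iterating: compute the mean of the
#' currently retained samples, drop samples further than `trim_bpm` from it,
#' and repeat until the retained set is stable or `max_iter` iterations have
#' run (non-convergence returns the last iterate with a warning).
#'
#' @param x An [fhr_signal()] or numeric vector.
#' @param trim_bpm Trim band around the running mean (default 10 bpm).
#' @param max_iter Iteration cap (default 20).
#' @return Baseline in bpm.
#' @export
fhr_baseline <- function(x, trim_bpm = 10, max_iter = 20) {
  x <- as_samples(x)
  keep <- rep(TRUE, length(x))
  b <- mean(x)
  for (i in seq_len(max_iter)) {
    new_keep <- abs(x - b) <= trim_bpm
    if (!any(new_keep)) new_keep <- keep  # degenerate: keep last set
    b_new <- mean(x[new_keep])
    if (identical(new_keep, keep) && isTRUE(all.equal(b_new, b))) {
      return(b_new)
    }
    keep <- new_keep
    b <- b_new
  }
  warning("baseline trimming did not converge; returning last iterate",
          call. = FALSE)
  b
}

# centered moving average with shrinking windows at the edges
moving_avg <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect accelerations or decelerations
#'
#' FIGO-style event rule: a maximal interval where the (lightly smoothed)
#' signal deviates at least `min_magnitude_bpm` from the baseline (above for
#' accelerations, below for decelerations) for at least `min_duration_s`
#' seconds. Beat-to-beat variability momentarily crossing the threshold
#' should not split one clinical event into fragments, so the trace is
#' smoothed with a short moving average before thresholding and
#' sub-threshold gaps shorter than `merge_gap_s` between excursions are
#' bridged.
#'
#' @param x An [fhr_signal()] or numeric vector.
#' @param baseline Baseline in bpm; defaults to [fhr_baseline()].
#' @param kind `"accel"` or `"decel"`.
#' @param min_magnitude_bpm Excursion threshold (default 15 bpm).
#' @param min_duration_s Duration gate (default 15 s).
#' @param smooth_s Moving-average window in seconds (default 2.5).
#' @param merge_gap_s Maximum sub-threshold gap bridged between excursions
#'   (default 5 s).
#' @param fs Sampling frequency (taken from the signal when available).
#' @return A data frame with columns `start_s`, `end_s`,
#'   `peak_excursion_bpm`, one row per detected event (zero rows when none).
#' @export
detect_events <- function(x, baseline = NULL, kind = c("accel", "decel"),
                          min_magnitude_bpm = 15, min_duration_s = 15,
                          smooth_s = 2.5, merge_gap_s = 5, fs = 4) {
  kind <- match.arg(kind)
  if (inherits(x, "fhr_signal")) { fs <- x$fs; x <- x$samples }
  x <- as.numeric(x)
  if (is.null(baseline)) baseline <- fhr_baseline(x)
  xs <- moving_avg(x, as.integer(round(smooth_s * fs)))
  dev <- if (kind == "accel") xs - baseline else baseline - xs
  above <- dev >= min_magnitude_bpm
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s <- starts[r$values]
  e <- ends[r$values]
  if (length(s) > 1L) {  # bridge short sub-threshold gaps
    merged_s <- s[1L]; merged_e <- e[1L]
    for (i in 2L:length(s)) {
      if (s[i] - merged_e[length(merged_e)] - 1L <= merge_gap_s * fs) {
        merged_e[length(merged_e)] <- e[i]
      } else {
        merged_s <- c(merged_s, s[i])
        merged_e <- c(merged_e, e[i])
      }
    }
    s <- merged_s; e <- merged_e
  }
  keep <- (e - s + 1L) >= min_duration_s * fs
  if (!any(keep)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_excursion_bpm = numeric(0)))
  }
  s <- s[keep]; e <- e[keep]
  data.frame(
    start_s = (s - 1L) / fs,
    end_s = e / fs,
    peak_excursion_bpm = mapply(function(a, b) max(dev[a:b]), s, e)
  )
}

#' Variability bandwidth outside events
#'
#' Mean per-minute peak-to-peak range of the signal after removing baseline
#' drift and masking out detected accelerations/decelerations. With no events
#' and a constant baseline this coincides with [fhr_ltv()].
#'
#' @inheritParams detect_events
#' @param events Optional data frame of event intervals (rows with `start_s`,
#'   `end_s`) to exclude; defaults to accelerations plus decelerations
#'   detected at the standard 15 bpm / 15 s rule.
#' @return Variability in bpm.
#' @export
variability_bandwidth <- function(x, baseline = NULL, events = NULL, fs = 4) {
  if (inherits(x, "fhr_signal")) { fs <- x$fs; x <- x$samples }
  x <- as.numeric(x)
  if (is.null(baseline)) baseline <- fhr_baseline(x)
  if (is.null(events)) {
    events <- rbind(detect_events(x, baseline, "accel", fs = fs),
                    detect_events(x, baseline, "decel", fs = fs))
  }
  inc <- rep(TRUE, length(x))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      a <- max(1L, floor(events$start_s[i] * fs) + 1L)
      b <- min(length(x), ceiling(events$end_s[i] * fs))
      inc[a:b] <- FALSE
    }
  }
  spm <- as.integer(round(60 * fs))
  M <- length(x) %/% spm
  if (M < 1L) stop("variability needs at least one whole minute", call. = FALSE)
  rng <- vapply(seq_len(M), function(m) {
    idx <- ((m - 1L) * spm + 1L):(m * spm)
    v <- x[idx][inc[idx]]
    if (length(v) < 2L) NA_real_ else max(v) - min(v)
  }, 0)
  mean(rng, na.rm = TRUE)
}
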