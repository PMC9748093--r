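#' Select the analysis segment of a recording
#'
#' Clinical practice assesses the fetus on the window closest to delivery, so
#' the default takes the trailing 20 minutes of the recording (4800 samples at
#' 4 Hz).
#'
#' @param sig An [fhr_signal()].
#' @param duration_min Window length in minutes (default 20).
#' @param anchor Where to anchor the window; only `"end"` (trailing window) is
#'   supported.
#' @return An `fhr_signal` containing the selected window.
#' @export
select_segment <- function(sig, duration_min = 20, anchor = "end") {
  stopifnot(inherits(sig, "fhr_signal"))
  anchor <- match.arg(anchor, "end")
  n <- as.integer(round(duration_min * 60 * sig$fs))
  N <- length(sig$samples)
  if (N < n) {
    stop(sprintf("signal too short: %d samples, need %d (%g min at %g Hz)",
                 N, n, duration_min, sig$fs), call. = FALSE)
  }
  idx <- (N - n + 1L):N
  fhr_signal(sig$samples[idx], fs = sig$fs, valid_mask = sig$valid_mask[idx],
             record_id = sig$record_id, ph = sig$ph)
}

#' Flag physiologically invalid samples
#'
#' Two rules mark a sample invalid: (a) its value lies outside the acceptable
#' fetal range of 50-220 bpm; (b) it jumps by more than 25 bpm in absolute
#' value relative to the most recent sample still considered valid. Rule (b)
#' uses the last *retained* sample (not the raw predecessor) as reference so
#' that an isolated spike invalidates only itself rather than cascading down
#' the remainder of the trace.
#'
#' A long genuine level shift should not be rejected forever, so when the
#' jump rule alone has vetoed more than `reanchor_s` seconds in a row, the
#' reference re-anchors to the current in-range sample (a true artifact run
#' is orders of magnitude shorter than this guard).
#'
#' @param sig An [fhr_signal()] or numeric vector.
#' @param range Acceptable bpm range, default `c(50, 220)`.
#' @param max_jump Maximum allowed adjacent change in bpm, default 25.
#' @param reanchor_s Cascade guard in seconds (default 60).
#' @param fs Sampling frequency used for the guard when `sig` is a bare
#'   vector.
#' @return Logical validity mask (`TRUE` = valid), same length as the signal.
#' @export
flag_invalid_samples <- function(sig, range = c(50, 220), max_jump = 25,
                                 reanchor_s = 60, fs = 4) {
  if (inherits(sig, "fhr_signal")) { fs <- sig$fs; x <- sig$samples }
  else x <- as.numeric(sig)
  if (!length(x)) stop("empty signal", call. = FALSE)
  mask <- x >= range[1L] & x <= range[2L] & is.finite(x)
  last_valid <- NA_real_
  streak <- 0L
  hold <- as.integer(reanchor_s * fs)
  for (i in seq_along(x)) {
    if (!mask[i]) next  # range rule; does not advance the jump streak
    if (!is.na(last_valid) && abs(x[i] - last_valid) > max_jump) {
      streak <- streak + 1L
      if (streak >= hold) {
        last_valid <- x[i]  # re-anchor: the new level is persistent
        streak <- 0L
      } else {
        mask[i] <- FALSE
      }
    } else {
      last_valid <- x[i]
      streak <- 0L
    }
  }
  mask
}

#' Repair invalid samples by linear interpolation
#'
#' Each invalid run is replaced by the straight line between its flanking
#' valid samples; runs touching the start or end of the record (which have
#' only one flank) are filled with the nearest valid value. Since valid
#' samples lie in 50-220 bpm, interpolated output does too.
#'
#' @param sig An [fhr_signal()] or numeric vector.
#' @param mask Logical validity mask; defaults to [flag_invalid_samples()].
#' @param gap_warn_s Warn when a repaired gap exceeds this many seconds
#'   (default 30); set `Inf` to silence.
#' @return An `fhr_signal` with all samples valid.
#' @export
interpolate_invalid <- function(sig, mask = NULL, gap_warn_s = 30) {
  is_sig <- inherits(sig, "fhr_signal")
  x <- if (is_sig) sig$samples else as.numeric(sig)
  fs <- if (is_sig) sig$fs else 4
  if (is.null(mask)) mask <- flag_invalid_samples(sig)
  stopifnot(length(mask) == length(x))
  nv <- sum(mask)
  if (nv < 2L) {
    stop("unrecoverable signal: fewer than 2 valid samples", call. = FALSE)
  }
  if (any(!mask)) {
    runs <- rle(!mask)
    gap <- max(runs$lengths[runs$values]) / fs
    if (gap > gap_warn_s) {
      warning(sprintf("interpolating a gap of %.1f s (> %g s)", gap, gap_warn_s),
              call. = FALSE)
    }
    idx <- which(mask)
    y <- stats::approx(idx, x[idx], xout = seq_along(x), method = "linear",
                       rule = 2)$y  # rule 2: constant fill at edges
    x <- y
  }
  fhr_signal(x, fs = fs,
             record_id = if (is_sig) sig$record_id else "",
             ph = if (is_sig) sig$ph else NA_real_)
}

#' Preprocess a raw FHR recording
#'
#' Convenience composition: select the trailing window, flag invalid samples
#' (range and jump rules), and repair them by linear interpolation.
#'
#' @inheritParams select_segment
#' @inheritParams flag_invalid_samples
#' @return A repaired `fhr_signal` of `duration_min` minutes.
#' @export
preprocess_fhr <- function(sig, duration_min = 20, range = c(50, 220),
                           max_jump = 25) {
  seg <- select_segment(sig, duration_min)
  interpolate_invalid(seg, flag_invalid_samples(seg, range, max_jump))
}

#' Record-inclusion quality criteria
#'
#' @param min_duration_min Minimum recording duration in minutes (default 60).
#' @param max_loss_per_30min Maximum fraction of invalid samples allowed in
#'   any 30-minute window (default 0.15).
#' @param require_ph Must the record carry an umbilical-artery pH? Default
#'   `TRUE` (the pH supplies the class label).
#' @return A `quality_criteria` list.
#' @export
quality_criteria <- function(min_duration_min = 60, max_loss_per_30min = 0.15,
                             require_ph = TRUE) {
  stopifnot(max_loss_per_30min >= 0, max_loss_per_30min <= 1)
  structure(list(min_duration_min = min_duration_min,
                 max_loss_per_30min = max_loss_per_30min,
                 require_ph = require_ph),
            class = "quality_criteria")
}

#' Apply the record-inclusion quality gates
#'
#' A record passes when it is long enough, no 30-minute window loses more
#' than the allowed fraction of samples (loss = invalid under
#' [flag_invalid_samples()]), and a pH is present when required. Windows are
#' consecutive non-overlapping 30-minute blocks; a shorter trailing remainder
#' is judged against the same fraction.
#'
#' @param sig An [fhr_signal()].
#' @param qc A [quality_criteria()].
#' @return List with `pass` (logical) and `reason` (`""` when passing, else
#'   the first violated criterion: `"duration"`, `"loss"` or `"ph"`).
#' @export
record_passes_quality <- function(sig, qc = quality_criteria()) {
  stopifnot(inherits(sig, "fhr_signal"))
  if (fhr_duration_min(sig) < qc$min_duration_min) {
    return(list(pass = FALSE, reason = "duration"))
  }
  mask <- flag_invalid_samples(sig)
  w <- as.integer(30 * 60 * sig$fs)
  starts <- seq(1L, length(mask), by = w)
  for (s in starts) {
    win <- mask[s:min(s + w - 1L, length(mask))]
    if (mean(!win) > qc$max_loss_per_30min) {
      return(list(pass = FALSE, reason = "loss"))
    }
  }
  if (qc$require_ph && is.na(sig$ph)) {
    return(list(pass = FALSE, reason = "ph"))
  }
  list(pass = TRUE, reason = "")
}

#' Class label from umbilical-artery pH
#'
#' A record is pathological (fetal acidemia) when pH is strictly below the
#' threshold; a pH exactly at the threshold is normal.
#'
#' @param ph Umbilical-artery pH value(s).
#' @param threshold Decision threshold, default 7.15.
#' @return Factor with levels `normal`, `pathological`.
#' @export
label_from_ph <- function(ph, threshold = 7.15) {
  if (any(is.na(ph))) stop("cannot label a record without pH", call. = FALSE)
  out_of_range <- ph < 6.5 | ph > 7.7
  if (any(out_of_range)) {
    warning(sprintf("%d pH value(s) outside the physiological range [6.5, 7.7]",
                    sum(out_of_range)), call. = FALSE)
  }
  factor(ifelse(ph < threshold, "pathological", "normal"),
         levels = c("normal", "pathological"))
}
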