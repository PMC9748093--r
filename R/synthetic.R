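#' Generator parameters for synthetic FHR signals
#'
#' A synthetic record is baseline + band-limited variability (Gaussian noise
#' low-pass/band-pass filtered to 0.03-0.5 Hz) + Hann-shaped accelerations
#' and decelerations + white measurement noise, followed by artifact
#' injection mimicking the two invalid-sample classes the preprocessing
#' removes (out-of-range spikes/dropouts and >25 bpm step offsets). The
#' record-level baseline and variability are jittered across records so the
#' class-conditional feature distributions have realistic within-class
#' spread.
#'
#' @param baseline_bpm Mean baseline level of the class (bpm).
#' @param baseline_sd Between-record SD of the baseline (bpm).
#' @param variability_bpm Target oscillation bandwidth (typical per-minute
#'   peak-to-peak range of the variability component, bpm).
#' @param variability_rel_sd Between-record relative SD of the variability.
#' @param accel_rate,decel_rate Expected accelerations/decelerations per
#'   20-minute segment (Poisson).
#' @param event_magnitude_bpm,event_magnitude_sd Peak event excursion (bpm);
#'   draws are truncated at the 15 bpm detection threshold.
#' @param event_duration_s,event_duration_sd Event duration (s), truncated at
#'   the 15 s gate.
#' @param noise_sd_bpm White measurement-noise SD (bpm).
#' @param artifact_spike_rate Isolated out-of-range spikes per minute.
#' @param artifact_dropout_rate Short runs dropped to 0 bpm, per minute.
#' @param artifact_jump_rate Short >25 bpm step offsets per minute.
#' @param ph_range Range of the umbilical-artery pH drawn for the record.
#' @param class_label `"normal"` or `"pathological"`.
#' @param n_samples,fs Segment length and sampling rate (4800 at 4 Hz).
#' @return An `fhr_gen_params` list.
#' @export
fhr_gen_params <- function(baseline_bpm = 140, baseline_sd = 4,
                           variability_bpm = 10, variability_rel_sd = 0.15,
                           accel_rate = 4, decel_rate = 0.5,
                           event_magnitude_bpm = 20, event_magnitude_sd = 3,
                           event_duration_s = 35, event_duration_sd = 8,
                           noise_sd_bpm = 1.5,
                           artifact_spike_rate = 0.5,
                           artifact_dropout_rate = 0.2,
                           artifact_jump_rate = 0.2,
                           ph_range = c(7.16, 7.42),
                           class_label = "normal",
                           n_samples = 4800, fs = 4) {
  stopifnot(accel_rate >= 0, decel_rate >= 0, event_magnitude_bpm >= 15,
            event_duration_s >= 15, noise_sd_bpm >= 0)
  structure(as.list(environment()), class = "fhr_gen_params")
}

# band-limited variability component with unit peak-to-peak calibration:
# white Gaussian noise filtered to [0.03, 0.5] Hz, scaled so the typical
# per-minute peak-to-peak range is ~1, then multiplied by variability_bpm
band_limited_noise <- function(n, fs, lo = 0.03, hi = 0.5) {
  z <- stats::rnorm(n)
  f <- stats::fft(z)
  freq <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  freq <- pmin(freq, fs - freq)  # two-sided
  keep <- freq >= lo & freq <= hi
  f[!keep] <- 0+0i
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic FHR record with ground truth
#'
#' @param params An [fhr_gen_params()].
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return List with `signal` (an [fhr_signal()]) and `truth` (baseline
#'   track, event table, artifact indices, class label, pH).
#' @export
generate_fhr <- function(params = fhr_gen_params(), seed = 1) {
  stopifnot(inherits(params, "fhr_gen_params"))
  set.seed(seed)
  n <- params$n_samples; fs <- params$fs
  dur_s <- n / fs

  baseline <- params$baseline_bpm + params$baseline_sd * stats::rnorm(1L)
  baseline_track <- rep(baseline, n)

  vb <- params$variability_bpm *
    max(0.1, 1 + params$variability_rel_sd * stats::rnorm(1L))
  # sd -> typical per-minute peak-to-peak is about 4 sd for this bandwidth
  variability <- if (vb > 0) band_limited_noise(n, fs) * vb / 4 else numeric(n)

  # events: Poisson counts, non-overlapping placement (up to 40 attempts each)
  ev <- data.frame(kind = character(0), start_s = numeric(0),
                   end_s = numeric(0), magnitude_bpm = numeric(0))
  event_sig <- numeric(n)
  place <- function(kind, rate) {
    n_ev <- stats::rpois(1L, rate)
    for (i in seq_len(n_ev)) {
      for (try in seq_len(40L)) {
        # truncated at 20 s: with the tapered pulse shape, shorter events
        # cannot hold the 15 bpm excursion for the full 15 s gate
        d <- stats::rnorm(1L, params$event_duration_s, params$event_duration_sd)
        d <- max(20, min(d, dur_s / 2))
        s <- stats::runif(1L, 0, dur_s - d)
        if (!nrow(ev) || all(s > ev$end_s + 10 | s + d < ev$start_s - 10)) {
          m <- max(15, stats::rnorm(1L, params$event_magnitude_bpm,
                                    params$event_magnitude_sd))
          i0 <- floor(s * fs) + 1L
          i1 <- min(n, floor((s + d) * fs))
          len <- i1 - i0 + 1L
          # Tukey (tapered-cosine) pulse: smooth onset/offset with a flat
          # plateau at full magnitude, so an event of stated magnitude and
          # duration actually satisfies the 15 bpm / 15 s detection gates
          ramp <- max(1L, floor(0.25 * len))
          up <- sin(pi / 2 * seq(0, 1, length.out = ramp))^2
          win <- c(up, rep(1, len - 2L * ramp), rev(up))
          sgn <- if (kind == "accel") 1 else -1
          event_sig[i0:i1] <<- event_sig[i0:i1] + sgn * m * win
          ev <<- rbind(ev, data.frame(kind = kind, start_s = s, end_s = s + d,
                                      magnitude_bpm = m))
          break
        }
      }
    }
  }
  place("accel", params$accel_rate)
  place("decel", params$decel_rate)

  x <- baseline_track + variability + event_sig +
    params$noise_sd_bpm * stats::rnorm(n)

  # artifact injection
  artifact_idx <- integer(0)
  mins <- dur_s / 60
  n_spike <- stats::rpois(1L, params$artifact_spike_rate * mins)
  n_drop <- stats::rpois(1L, params$artifact_dropout_rate * mins)
  n_jump <- stats::rpois(1L, params$artifact_jump_rate * mins)
  if (n_spike > 0) {
    at <- sample.int(n, n_spike)
    hi <- stats::runif(n_spike) < 0.5
    x[at] <- ifelse(hi, stats::runif(n_spike, 225, 245),
                    stats::runif(n_spike, 5, 45))
    artifact_idx <- c(artifact_idx, at)
  }
  for (i in seq_len(n_drop)) {
    len <- sample(2:8, 1L)
    at <- sample.int(n - len, 1L)
    idx <- at:(at + len - 1L)
    x[idx] <- 0
    artifact_idx <- c(artifact_idx, idx)
  }
  for (i in seq_len(n_jump)) {
    len <- sample(4:12, 1L)
    at <- sample.int(n - len, 1L)
    idx <- at:(at + len - 1L)
    # well above the 25 bpm jump rule so the step cannot hide inside
    # ordinary variability excursions
    off <- sample(c(-1, 1), 1L) * stats::runif(1L, 45, 60)
    # keep the offset run inside the 50-220 band so only the jump rule fires
    if (any(x[idx] + off < 52) || any(x[idx] + off > 218)) off <- -off
    x[idx] <- x[idx] + off
    artifact_idx <- c(artifact_idx, idx)
  }
  artifact_idx <- sort(unique(artifact_idx))

  ph <- stats::runif(1L, params$ph_range[1L], params$ph_range[2L])
  sig <- fhr_signal(x, fs = fs, record_id = sprintf("syn-%08d", seed), ph = ph)
  truth <- list(baseline_track = baseline_track, events = ev,
                artifact_indices = artifact_idx,
                class_label = params$class_label, ph = ph,
                variability_bpm = vb)
  list(signal = sig, truth = truth)
}

#' Generate a labelled synthetic dataset
#'
#' @param n Number of records (>= 10).
#' @param class_ratio Normal:pathological ratio (default 4, i.e. 4:1).
#' @param params_normal,params_pathological Class-conditional
#'   [fhr_gen_params()].
#' @param seed Integer seed; per-record seeds are derived reproducibly.
#' @return List with `signals` (list of [fhr_signal()]), `labels` (factor),
#'   `truths`, `ph` (numeric vector).
#' @export
generate_fhr_dataset <- function(n, class_ratio = 4,
                                 params_normal = fhr_gen_params(),
                                 params_pathological = fhr_gen_params(
                                   baseline_bpm = 125, variability_bpm = 3,
                                   accel_rate = 0.5, decel_rate = 4,
                                   ph_range = c(6.85, 7.14),
                                   class_label = "pathological"),
                                 seed = 1) {
  stopifnot(n >= 10)
  n_path <- max(1L, round(n / (class_ratio + 1)))
  n_norm <- n - n_path
  set.seed(seed)
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n)
  labels <- rep(c("normal", "pathological"), c(n_norm, n_path))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- if (labels[i] == "normal") params_normal else params_pathological
    out[[i]] <- generate_fhr(p, rec_seeds[i])
  }
  list(signals = lapply(out, `[[`, "signal"),
       labels = factor(labels, levels = c("normal", "pathological")),
       truths = lapply(out, `[[`, "truth"),
       ph = vapply(out, function(o) o$truth$ph, 0))
}

#' Difficulty schedules for the synthetic benchmark
#'
#' Three fixed class-contrast levels: `easy` has large, clinically plausible
#' contrasts (tachycardia-free normal traces with high variability and
#' accelerations versus low-variability decelerating pathological traces) and
#' should be almost perfectly separable; `hard` makes the two classes nearly
#' identical so a classifier can only reach chance-level quality index; and
#' `medium` lies componentwise between the two.
#'
#' @param level `"easy"`, `"medium"` or `"hard"`.
#' @return List with elements `normal` and `pathological` (both
#'   [fhr_gen_params()]) and `level`.
#' @export
difficulty_schedule <- function(level = c("easy", "medium", "hard")) {
  level <- match.arg(level)
  base_norm <- list(easy = fhr_gen_params(
    baseline_bpm = 140, baseline_sd = 4, variability_bpm = 10,
    accel_rate = 4, decel_rate = 0.5, class_label = "normal"),
    medium = fhr_gen_params(
      baseline_bpm = 140, baseline_sd = 5, variability_bpm = 10,
      accel_rate = 3, decel_rate = 1, class_label = "normal"),
    hard = fhr_gen_params(
      baseline_bpm = 140, baseline_sd = 6, variability_bpm = 10,
      variability_rel_sd = 0.2, accel_rate = 2, decel_rate = 1.5,
      class_label = "normal"))
  base_path <- list(easy = fhr_gen_params(
    baseline_bpm = 125, baseline_sd = 4, variability_bpm = 3,
    accel_rate = 0.5, decel_rate = 4, ph_range = c(6.85, 7.14),
    class_label = "pathological"),
    medium = fhr_gen_params(
      baseline_bpm = 132, baseline_sd = 5, variability_bpm = 6,
      accel_rate = 1.5, decel_rate = 2.5, ph_range = c(6.85, 7.14),
      class_label = "pathological"),
    hard = fhr_gen_params(
      baseline_bpm = 139.5, baseline_sd = 6, variability_bpm = 9.6,
      variability_rel_sd = 0.2, accel_rate = 1.9, decel_rate = 1.6,
      ph_range = c(6.85, 7.14), class_label = "pathological"))
  list(normal = base_norm[[level]], pathological = base_path[[level]],
       level = level)
}
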