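#' Construct an FHR signal object
#'
#' An `fhr_signal` bundles a beats-per-minute series sampled at a fixed rate
#' (4 Hz for cardiotocography recordings) with a per-sample validity mask and
#' record-level metadata (record id, umbilical-artery pH at delivery).
#'
#' @param samples Numeric vector of FHR values in beats per minute.
#' @param fs Sampling frequency in Hz. All pipeline defaults assume 4 Hz.
#' @param valid_mask Logical vector, one entry per sample; `TRUE` marks a
#'   sample considered physiologically valid. Defaults to all-`TRUE`.
#' @param record_id Opaque record identifier string.
#' @param ph Umbilical-artery pH associated with the record, or `NA` when the
#'   outcome is unknown.
#' @return An object of class `fhr_signal`.
#' @examples
#' sig <- fhr_signal(rep(140, 4800))
#' sig
#' @export
fhr_signal <- function(samples, fs = 4, valid_mask = NULL, record_id = "",
                       ph = NA_real_) {
  samples <- as.numeric(samples)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, length(samples))
  valid_mask <- as.logical(valid_mask)
  if (length(samples) != length(valid_mask)) {
    stop("`samples` and `valid_mask` must have equal length", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = fs, valid_mask = valid_mask,
         record_id = as.character(record_id), ph = as.numeric(ph)[1L]),
    class = "fhr_signal"
  )
}

#' @export
print.fhr_signal <- function(x, ...) {
  mins <- length(x$samples) / x$fs / 60
  cat(sprintf("<fhr_signal> %s: %d samples @ %g Hz (%.1f min), %d invalid, pH %s\n",
              if (nzchar(x$record_id)) x$record_id else "(unnamed)",
              length(x$samples), x$fs, mins, sum(!x$valid_mask),
              ifelse(is.na(x$ph), "NA", format(x$ph))))
  invisible(x)
}

#' @export
length.fhr_signal <- function(x) length(x$samples)

#' Duration of a signal in minutes
#' @param sig An `fhr_signal`.
#' @return Duration in minutes.
#' @export
fhr_duration_min <- function(sig) length(sig$samples) / sig$fs / 60

#' Read an FHR record from disk
#'
#' Supports two dialects: `"csv"` — a two-column (time in seconds, bpm) text
#' file, header optional; and `"physionet"` — a PhysioNet-style waveform
#' record (a `.hea` header next to a format-16 binary `.dat`, the layout used
#' by the public intrapartum cardiotocography archives). For multi-signal
#' PhysioNet records the FHR channel is taken from the signal whose
#' description contains "FHR" (case-insensitive), else the first signal. pH
#' is read from a `#pH <value>` header comment when present.
#'
#' The reader never resamples: a record whose declared sampling frequency
#' differs from `expect_fs` raises an error.
#'
#' @param path Path to the `.csv` file or to the record (with or without the
#'   `.hea` extension).
#' @param format `"csv"` or `"physionet"`.
#' @param expect_fs Required sampling frequency in Hz (default 4).
#' @param ph Optional pH overriding anything found in the file.
#' @return An [fhr_signal()] with an all-`TRUE` validity mask.
#' @seealso [write_fhr_csv()]
#' @examples
#' demo <- system.file("extdata", "synthetic_fhr_demo.csv", package = "ctgdffn")
#' sig <- read_fhr_record(demo, "csv")
#' sig
#' @export
read_fhr_record <- function(path, format = c("csv", "physionet"),
                            expect_fs = 4, ph = NULL) {
  format <- match.arg(format)
  out <- switch(format,
    csv = read_fhr_csv(path, expect_fs),
    physionet = read_fhr_physionet(path, expect_fs)
  )
  if (!is.null(ph)) out$ph <- as.numeric(ph)
  out
}

read_fhr_csv <- function(path, expect_fs) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", sub("^#", "", first))
  dat <- utils::read.csv(path, header = header,
                         comment.char = "#", strip.white = TRUE)
  if (ncol(dat) < 2L) {
    stop("CSV dialect requires two columns (seconds, bpm): ", path,
         call. = FALSE)
  }
  tt <- as.numeric(dat[[1L]]); bpm <- as.numeric(dat[[2L]])
  if (anyNA(tt) || anyNA(bpm)) {
    bad <- which(is.na(tt) | is.na(bpm))[1L]
    stop(sprintf("could not parse row %d of %s as numeric", bad + header, path),
         call. = FALSE)
  }
  if (length(tt) >= 2L) {
    dt <- diff(tt)
    fs <- 1 / stats::median(dt)
    if (abs(fs - expect_fs) > 1e-6 * expect_fs) {
      stop(sprintf(
        "sampling-rate mismatch in %s: declared spacing implies %.6g Hz, expected %g Hz (no silent resampling)",
        path, fs, expect_fs), call. = FALSE)
    }
  }
  ph <- NA_real_
  # optional '#pH 7.23' comment line anywhere in the file
  cm <- grep("^#\\s*pH\\b", readLines(path), value = TRUE, ignore.case = TRUE)
  if (length(cm)) ph <- suppressWarnings(as.numeric(sub("^#\\s*pH\\s*", "", cm[1L],
                                                        ignore.case = TRUE)))
  fhr_signal(bpm, fs = expect_fs,
             record_id = sub("\\.[^.]*$", "", basename(path)), ph = ph)
}

# Minimal PhysioNet (WFDB) reader: header + format-16 little-endian int16.
read_fhr_physionet <- function(path, expect_fs) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("header file not found: ", hea, call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(body[1L]), "\\s+")[[1L]]
  if (length(rec) < 3L) stop("malformed record line in ", hea, call. = FALSE)
  record_id <- rec[1L]
  nsig <- as.integer(rec[2L])
  fs <- as.numeric(sub("/.*$", "", rec[3L]))
  nsamp <- if (length(rec) >= 4L) as.integer(rec[4L]) else NA_integer_
  if (abs(fs - expect_fs) > 1e-9) {
    stop(sprintf("sampling-rate mismatch in %s: header declares %g Hz, expected %g Hz (no silent resampling)",
                 hea, fs, expect_fs), call. = FALSE)
  }
  sig_lines <- body[seq_len(nsig) + 1L]
  sig <- lapply(sig_lines, function(l) strsplit(trimws(l), "\\s+")[[1L]])
  descr <- vapply(sig, function(f) paste(f[-seq_len(min(8L, length(f)))],
                                         collapse = " "), "")
  chan <- grep("fhr", descr, ignore.case = TRUE)
  chan <- if (length(chan)) chan[1L] else 1L
  f <- sig[[chan]]
  datfile <- f[1L]
  fmt <- sub("x.*$", "", f[2L])
  if (fmt != "16") {
    stop(sprintf("unsupported WFDB signal format '%s' in %s (only format 16 is read)",
                 f[2L], hea), call. = FALSE)
  }
  gainfield <- if (length(f) >= 3L) f[3L] else "200"
  gain <- as.numeric(sub("^\\(?([-0-9.]+).*$", "\\1", gainfield))
  if (!is.finite(gain) || gain == 0) gain <- 200
  baselinefld <- regmatches(gainfield, regexec("\\(([-0-9]+)\\)", gainfield))[[1L]]
  baseline <- if (length(baselinefld) == 2L) as.numeric(baselinefld[2L]) else 0
  dat <- file.path(dirname(hea), datfile)
  if (!file.exists(dat)) stop("signal file not found: ", dat, call. = FALSE)
  raw <- readBin(dat, "integer", n = file.size(dat) / 2L, size = 2L,
                 signed = TRUE, endian = "little")
  # format 16 interleaves samples across signals
  x <- raw[seq(chan, length(raw), by = nsig)]
  if (!is.na(nsamp) && length(x) > nsamp) x <- x[seq_len(nsamp)]
  bpm <- (x - baseline) / gain
  ph <- NA_real_
  cm <- grep("^\\s*#\\s*pH\\b", lines, value = TRUE, ignore.case = TRUE)
  if (length(cm)) ph <- suppressWarnings(as.numeric(strsplit(trimws(cm[1L]),
                                                             "\\s+")[[1L]][2L]))
  fhr_signal(bpm, fs = fs, record_id = record_id, ph = ph)
}

#' Write an FHR signal as a two-column CSV
#'
#' The inverse of the `"csv"` dialect of [read_fhr_record()]: column 1 is time
#' in seconds, column 2 the bpm value. The pH, when present, is stored as a
#' `#pH` comment line so a round trip preserves it.
#'
#' @param sig An [fhr_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fhr_csv <- function(sig, path) {
  stopifnot(inherits(sig, "fhr_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(sig$ph)) writeLines(sprintf("#pH %.15g", sig$ph), con)
  writeLines("seconds,bpm", con)
  tt <- (seq_along(sig$samples) - 1L) / sig$fs
  writeLines(sprintf("%.15g,%.15g", tt, sig$samples), con)
  invisible(path)
}
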