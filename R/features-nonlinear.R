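resolve_r <- function(x, r, r_mode) {
  if (r_mode == "relative_to_sd") r * stats::sd(x) else r
}

#' Approximate entropy (ApEn)
#'
#' Regularity statistic over `m`-length embedded template vectors with
#' tolerance `r`: `ApEn = Phi^m(r) - Phi^(m+1)(r)` where
#' `Phi^m = mean_i log(C_i^m)` and `C_i^m` is the fraction of templates within
#' distance `r` of template `i`, self-match included. By convention in the
#' FHR literature a bare `r` is interpreted relative to the sample standard
#' deviation of the series.
#'
#' @param x Numeric series or [fhr_signal()].
#' @param m Embedding dimension (default 4).
#' @param r Tolerance (default 0.2).
#' @param r_mode `"relative_to_sd"` (default; `r` is multiplied by `sd(x)`)
#'   or `"absolute"`.
#' @param metric Distance between templates: `"euclidean"` (default) or
#'   `"chebyshev"`.
#' @return ApEn in nats.
#' @export
fhr_apen <- function(x, m = 4, r = 0.2, r_mode = c("relative_to_sd", "absolute"),
                     metric = c("euclidean", "chebyshev")) {
  x <- as_samples(x)
  r_mode <- match.arg(r_mode)
  metric <- match.arg(metric)
  if (length(x) <= m + 1) stop("series too short: need N > m + 1", call. = FALSE)
  r_abs <- resolve_r(x, r, r_mode)
  if (r_abs <= 0) {
    # constant series under relative r: all templates coincide, zero entropy
    if (stats::sd(x) == 0) return(0)
    stop("tolerance r must resolve to a positive value", call. = FALSE)
  }
  cpp_entropy_counts(x, m, r_abs, match(metric, c("euclidean", "chebyshev")) - 1L)$apen
}

#' Sample entropy (SampEn)
#'
#' Like [fhr_apen()] but excluding self-matches: `SampEn = -log(A/B)` where
#' `B` and `A` count template pairs within tolerance at dimensions `m` and
#' `m + 1`. When no `(m+1)`-dimensional pair matches, the statistic diverges
#' and `Inf` is returned with a warning.
#'
#' @inheritParams fhr_apen
#' @return SampEn in nats.
#' @export
fhr_sampen <- function(x, m = 4, r = 0.2, r_mode = c("relative_to_sd", "absolute"),
                       metric = c("euclidean", "chebyshev")) {
  x <- as_samples(x)
  r_mode <- match.arg(r_mode)
  metric <- match.arg(metric)
  if (length(x) <= m + 1) stop("series too short: need N > m + 1", call. = FALSE)
  r_abs <- resolve_r(x, r, r_mode)
  if (r_abs <= 0) {
    if (stats::sd(x) == 0) return(0)
    stop("tolerance r must resolve to a positive value", call. = FALSE)
  }
  res <- cpp_entropy_counts(x, m, r_abs, match(metric, c("euclidean", "chebyshev")) - 1L)
  if (!is.finite(res$sampen)) {
    warning("no template matches at dimension m + 1; SampEn is infinite",
            call. = FALSE)
  }
  res$sampen
}

#' Binarize a series for complexity analysis
#'
#' Symbol 1 where the value is greater than or equal to the threshold (the
#' series mean or median), else 0. Ties therefore map to symbol 1; a constant
#' series becomes all ones.
#'
#' @param x Numeric series or [fhr_signal()].
#' @param rule Threshold rule: `"mean"` (default) or `"median"`.
#' @return Integer vector of 0/1 symbols with attributes `alphabet = 2` and
#'   `rule`.
#' @export
binarize <- function(x, rule = c("mean", "median")) {
  x <- as_samples(x)
  if (!length(x)) stop("empty series", call. = FALSE)
  rule <- match.arg(rule)
  thr <- if (rule == "mean") mean(x) else stats::median(x)
  s <- as.integer(x >= thr)
  attr(s, "alphabet") <- 2L
  attr(s, "rule") <- rule
  s
}

#' Lempel-Ziv 1976 pattern count
#'
#' Number of words in the exhaustive-history parsing of a symbol sequence:
#' scanning left to right, the current word grows while it can still be
#' copied from the already-seen text, and the counter increments each time a
#' genuinely new pattern completes (including the final word).
#'
#' @param seq Integer symbol sequence (e.g. from [binarize()]).
#' @return The complexity count `c(n)`.
#' @export
lz76_count <- function(seq) {
  cpp_lz76_count(as.integer(seq))
}

#' Normalized Lempel-Ziv complexity (LZC)
#'
#' `LZC = c(N) / b(N)` with `b(N) = N / log_a(N)`, where `c(N)` is the
#' [lz76_count()] of the binarized series and `a` the alphabet size (2).
#' Values near 1 indicate a sequence as complex as random coin flips.
#'
#' @param x Numeric series or [fhr_signal()].
#' @param rule Binarization rule passed to [binarize()].
#' @return LZC (dimensionless).
#' @export
fhr_lzc <- function(x, rule = c("mean", "median")) {
  s <- binarize(x, match.arg(rule))
  n <- length(s)
  if (n < 2L) stop("series too short for LZC", call. = FALSE)
  a <- attr(s, "alphabet")
  lz76_count(s) * log(n, base = a) / n
}
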