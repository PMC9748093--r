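# Independent reference implementations: direct transcriptions of the
# defining formulas, written before the package versions and kept free of
# any shared code with them.

# block means by explicit loop
naive_block_means <- function(x, fs = 4, block_s = 2.5) {
  bl <- round(block_s * fs)
  nb <- length(x) %/% bl
  sm <- numeric(nb)
  for (i in seq_len(nb)) sm[i] <- mean(x[((i - 1) * bl + 1):(i * bl)])
  sm
}

# STV = (1 / 24M) * sum_{i=1}^{24M} |sm(i+1) - sm(i)|; when the segment is
# exactly M minutes, sm(24M + 1) does not exist and the sum truncates at the
# available differences (the denominator keeps the printed 24M)
naive_stv <- function(x, fs = 4) {
  sm <- naive_block_means(x, fs)
  M <- length(x) %/% (60 * fs)
  acc <- 0
  for (i in seq_len(min(24 * M, length(sm) - 1))) {
    acc <- acc + abs(sm[i + 1] - sm[i])
  }
  acc / (24 * M)
}

# LTV = (1/M) * sum over whole minutes of (max - min) within the minute
naive_ltv <- function(x, fs = 4) {
  spm <- 60 * fs
  M <- length(x) %/% spm
  acc <- 0
  for (i in seq_len(M)) {
    v <- x[((i - 1) * spm + 1):(i * spm)]
    acc <- acc + (max(v) - min(v))
  }
  acc / M
}

naive_lti <- function(x, fs = 4, variant = "literal") {
  sm <- naive_block_means(x, fs)
  M <- length(x) %/% (60 * fs)
  acc <- 0
  for (i in seq_len(min(24 * M, length(sm) - 1))) {
    acc <- acc + if (variant == "literal") sqrt(sm[i + 1] + sm[i])
                 else sqrt(sm[i]^2 + sm[i + 1]^2)
  }
  acc / (24 * M)
}

naive_ii <- function(x, fs = 4) {
  sd(x) / sd(naive_block_means(x, fs))
}

# ApEn: Phi^m - Phi^(m+1), template counts include the self-match,
# templates i = 1..N-m+1 at dimension m
naive_phi <- function(x, m, r, metric) {
  N <- length(x)
  n_t <- N - m + 1
  E <- sapply(seq_len(m), function(k) x[k:(k + n_t - 1)])
  if (n_t == 1) E <- matrix(E, nrow = 1)
  cnt <- numeric(n_t)
  for (i in seq_len(n_t)) {
    if (metric == "euclidean") {
      d <- sqrt(rowSums((E - matrix(E[i, ], n_t, m, byrow = TRUE))^2))
    } else {
      d <- apply(abs(E - matrix(E[i, ], n_t, m, byrow = TRUE)), 1, max)
    }
    cnt[i] <- sum(d <= r)
  }
  mean(log(cnt / n_t))
}

naive_apen <- function(x, m, r, metric = "euclidean") {
  naive_phi(x, m, r, metric) - naive_phi(x, m + 1, r, metric)
}

# SampEn: -log(A/B), self-matches excluded, both template sets i = 1..N-m
naive_sampen <- function(x, m, r, metric = "euclidean") {
  N <- length(x)
  n_t <- N - m
  count_pairs <- function(mm) {
    E <- sapply(seq_len(mm), function(k) x[k:(k + n_t - 1)])
    acc <- 0
    for (i in seq_len(n_t - 1)) {
      for (j in (i + 1):n_t) {
        d <- if (metric == "euclidean") sqrt(sum((E[i, ] - E[j, ])^2))
             else max(abs(E[i, ] - E[j, ]))
        if (d <= r) acc <- acc + 1
      }
    }
    acc
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1)
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}

# precision-recall by explicit thresholding at every distinct score
naive_pr <- function(y, s) {
  th <- sort(unique(s), decreasing = TRUE)
  prec <- rec <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- as.integer(s >= th[i])
    tp <- sum(y == 1 & pred == 1)
    fp <- sum(y == 0 & pred == 1)
    prec[i] <- tp / (tp + fp)
    rec[i] <- tp / sum(y == 1)
  }
  ap <- sum(diff(c(0, rec)) * prec)
  list(precision = prec, recall = rec, average_precision = ap)
}
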