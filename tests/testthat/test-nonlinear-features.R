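test_that("entropies are zero for constant series and shift-invariant", {
  expect_equal(fhr_apen(rep(5, 100)), 0)
  expect_equal(fhr_sampen(rep(5, 100)), 0)

  set.seed(1)
  x <- rnorm(300)
  expect_equal(fhr_apen(x + 100, m = 2, r = 0.2), fhr_apen(x, m = 2, r = 0.2),
               tolerance = 1e-9)
  expect_equal(fhr_sampen(x + 100, m = 2, r = 0.2), fhr_sampen(x, m = 2, r = 0.2),
               tolerance = 1e-9)
})

test_that("entropies match the naive reference on random series", {
  set.seed(2)
  for (metric in c("euclidean", "chebyshev")) {
    for (i in 1:4) {
      x <- rnorm(150)
      for (m in c(2, 4)) {
        r_abs <- 0.2 * sd(x)
        expect_equal(fhr_apen(x, m, 0.2, metric = metric),
                     naive_apen(x, m, r_abs, metric), tolerance = 1e-10)
        # at m = 4 on a short white-noise series SampEn may diverge; the
        # oracle must diverge identically
        expect_equal(suppressWarnings(fhr_sampen(x, m, 0.2, metric = metric)),
                     naive_sampen(x, m, r_abs, metric), tolerance = 1e-10)
      }
    }
  }
})

test_that("regularity ordering: noise is more entropic than a sine", {
  set.seed(4)
  noise <- rnorm(1000)
  sine <- sin(2 * pi * (1:1000) / 50)
  expect_gt(fhr_apen(noise, m = 2, r = 0.2), fhr_apen(sine, m = 2, r = 0.2))
  expect_gt(fhr_sampen(noise, m = 2, r = 0.2), fhr_sampen(sine, m = 2, r = 0.2))
})

test_that("SampEn exceeds the self-match-included statistic (bias direction)", {
  # with self-matches the ratio A/B is inflated, so -log(A/B) shrinks
  set.seed(9)
  x <- rnorm(200)
  r_abs <- 0.2 * sd(x)
  n_t <- length(x) - 4
  with_self <- local({
    pairs <- function(mm) {
      E <- sapply(seq_len(mm), function(k) x[k:(k + n_t - 1)])
      acc <- 0
      for (i in seq_len(n_t)) {
        for (j in seq_len(n_t)) {
          if (sqrt(sum((E[i, ] - E[j, ])^2)) <= r_abs) acc <- acc + 1
        }
      }
      acc
    }
    -log(pairs(5) / pairs(4))
  })
  expect_gte(suppressWarnings(fhr_sampen(x, 4, 0.2)), with_self - 1e-9)
})

test_that("divergent SampEn returns an infinite sentinel with warning", {
  set.seed(10)
  x <- rnorm(30)
  expect_warning(v <- fhr_sampen(x, m = 4, r = 0.01), "infinite")
  expect_true(is.infinite(v))
})

test_that("binarization follows the >= threshold convention", {
  expect_equal(as.integer(binarize(c(1, 2, 3, 4), "mean")), c(0L, 0L, 1L, 1L))
  expect_true(all(binarize(rep(3, 10)) == 1L))  # ties map to 1
  med <- binarize(c(-3, -2, -1, 1, 2, 3), "median")
  expect_lte(abs(sum(med == 1) - sum(med == 0)), 1)
})

test_that("LZ76 parsing reproduces hand-parsed counts", {
  expect_equal(lz76_count(rep(0L, 10)), 2)
  classic <- as.integer(strsplit("0001101001000101", "")[[1]])
  expect_equal(lz76_count(classic), 6)
  expect_equal(lz76_count(0L), 1)
})

test_that("LZ76 count is monotone under sequence extension", {
  set.seed(12)
  s <- sample(0:1, 400, replace = TRUE)
  counts <- vapply(seq(50, 400, by = 50), function(n) lz76_count(s[1:n]), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("normalized LZC behaves as expected", {
  expect_equal(fhr_lzc(rep(7, 4800)), 2 * log2(4800) / 4800, tolerance = 1e-12)
  set.seed(13)
  coin <- rnorm(4800)
  lzc_coin <- fhr_lzc(coin)
  expect_gt(lzc_coin, 0.8)
  expect_lt(lzc_coin, 1.2)
  expect_lt(fhr_lzc(sort(coin)), lzc_coin)  # sorting destroys complexity
  expect_equal(fhr_lzc(coin + 50), lzc_coin)  # mean rule shifts with signal
})

test_that("the 16-feature vector assembles in a stable named layout", {
  layout <- feature_layout()
  expect_length(layout, 16)
  sched <- difficulty_schedule("easy")
  sig <- suppressWarnings(preprocess_fhr(generate_fhr(sched$normal, 3)$signal))
  f <- fhr_features(sig)
  expect_named(f, layout)
  expect_true(all(is.finite(f)))

  alt <- feature_layout(include_lzc = TRUE)
  expect_length(alt, 16)
  expect_true("lzc" %in% alt)
  f2 <- fhr_features(sig, layout = alt)
  expect_named(f2, alt)

  expect_error(assemble_feature_vector(f, layout[1:10]), "16")
  expect_error(assemble_feature_vector(f[1:4], layout), "not computed")

  # serialization round trip keeps names aligned with values
  tmp <- tempfile(fileext = ".csv")
  write.csv(t(f), tmp, row.names = FALSE)
  back <- read.csv(tmp)
  expect_equal(unlist(back[1, ]), f, tolerance = 1e-9,
               ignore_attr = FALSE)
})
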