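test_that("time-domain statistics match hand-computed values", {
  s <- fhr_basic_stats(rep(140, 100))
  expect_equal(unname(s), c(140, 0, 0, 0))

  s2 <- fhr_basic_stats(c(118, 122))
  expect_equal(unname(s2), c(120, sqrt(8), 2, 2))

  s3 <- fhr_basic_stats(c(100, 100, 100, 200))
  expect_equal(unname(s3["median_ad"]), 0)

  expect_error(fhr_basic_stats(140), "N < 2")
})

test_that("block decomposition counts fragments and minutes", {
  b <- fhr_block_means(rep(130, 4800))
  expect_length(b$block_means, 480)
  expect_equal(b$M, 20)
  expect_true(all(b$block_means == 130))

  expect_length(fhr_block_means(seq_len(25))$block_means, 2)
})

test_that("STV, LTV, LTI and II match small hand examples", {
  expect_equal(fhr_stv(rep(120, 240)), 0)
  # block means alternating 120/121 over one minute: 24 diffs of 1
  x <- rep(rep(c(120, 121), each = 10), length.out = 250)
  expect_equal(fhr_stv(x), 1)

  expect_equal(fhr_ltv(rep(120, 240)), 0)
  one_min <- seq(120, 140, length.out = 240)
  expect_equal(fhr_ltv(one_min), 20)
  ramp <- c(seq(120, 124, length.out = 240), seq(124, 128, length.out = 240))
  expect_equal(fhr_ltv(ramp), 4, tolerance = 1e-2)

  # 250 samples give one whole minute plus a spare block, so all 24
  # consecutive-block pairs of the minute exist
  expect_equal(fhr_lti(rep(128, 250)), 16)
  expect_equal(fhr_lti(rep(100, 250), "modulus"), 100 * sqrt(2))

  expect_error(fhr_interval_index(rep(120, 240)), "undefined")
  set.seed(7)
  wn <- rnorm(48000, 140, 5)
  expect_equal(fhr_interval_index(wn), sqrt(10), tolerance = 0.05)
})

test_that("FHRV statistics agree with direct-loop evaluation", {
  set.seed(11)
  for (i in 1:5) {
    x <- 135 + 5 * sin(2 * pi * (1:4800) / (40 * i)) + rnorm(4800, 0, 2)
    expect_equal(fhr_stv(x), naive_stv(x), tolerance = 1e-11)
    expect_equal(fhr_ltv(x), naive_ltv(x), tolerance = 1e-11)
    expect_equal(fhr_lti(x), naive_lti(x), tolerance = 1e-11)
    expect_equal(fhr_lti(x, "modulus"), naive_lti(x, variant = "modulus"),
                 tolerance = 1e-11)
    expect_equal(fhr_interval_index(x), naive_ii(x), tolerance = 1e-11)
  }
})

test_that("statistics transform correctly under shift and scale", {
  set.seed(3)
  x <- 140 + 6 * sin(2 * pi * (1:2400) / 120) + rnorm(2400)
  shift <- x + 7
  scl <- x * 1.5
  expect_equal(fhr_stv(shift), fhr_stv(x))
  expect_equal(fhr_ltv(shift), fhr_ltv(x))
  expect_equal(fhr_interval_index(shift), fhr_interval_index(x))
  expect_equal(fhr_baseline(shift), fhr_baseline(x) + 7, tolerance = 1e-6)
  expect_equal(unname(fhr_basic_stats(shift)["std"]),
               unname(fhr_basic_stats(x)["std"]))
  expect_equal(fhr_stv(scl), 1.5 * fhr_stv(x))
  expect_equal(fhr_ltv(scl), 1.5 * fhr_ltv(x))
  expect_equal(unname(fhr_basic_stats(scl)[c("std", "mean_ad", "median_ad")]),
               1.5 * unname(fhr_basic_stats(x)[c("std", "mean_ad", "median_ad")]))
  expect_equal(fhr_interval_index(scl), fhr_interval_index(x))
})

test_that("trimmed-mean baseline ignores transient events", {
  expect_equal(fhr_baseline(rep(140, 4800)), 140)
  # one 15-s acceleration to +25 bpm on a 140 baseline
  x <- rep(140, 4800)
  x[1000:1060] <- 140 + 25 * sin(pi * seq(0, 1, length.out = 61))
  expect_equal(fhr_baseline(x), 140, tolerance = 0.5)
})

test_that("baseline is recovered on generated records with known truth", {
  sched <- difficulty_schedule("easy")
  for (seed in 1:6) {
    g <- generate_fhr(sched$normal, seed = seed)
    sig <- suppressWarnings(preprocess_fhr(g$signal))
    expect_equal(fhr_baseline(sig), g$truth$baseline_track[1L],
                 tolerance = 2, label = paste("baseline seed", seed))
  }
})

test_that("event detection applies the 15 bpm / 15 s gates", {
  flat <- rep(140, 4800)
  expect_equal(nrow(detect_events(flat, 140, "accel")), 0)

  x <- rep(140, 4800)
  x[2001:2080] <- 160  # 20 bpm excursion lasting 20 s
  acc <- detect_events(x, 140, "accel")
  expect_equal(nrow(acc), 1)
  expect_true(acc$peak_excursion_bpm >= 15)
  expect_equal(nrow(detect_events(x, 140, "decel")), 0)

  y <- rep(140, 4800)
  y[2001:2040] <- 160  # 20 bpm but only 10 s
  expect_equal(nrow(detect_events(y, 140, "accel")), 0)
})

test_that("variability bandwidth matches its definition", {
  expect_equal(variability_bandwidth(rep(140, 4800), 140), 0)
  osc <- 140 + 5 * sin(2 * pi * (1:4800) * 0.2 / 4)  # 5 bpm amplitude
  expect_equal(variability_bandwidth(osc, 140), 10, tolerance = 0.05)
  # with no events and a constant baseline it coincides with LTV
  set.seed(5)
  z <- 140 + 3 * sin(2 * pi * (1:4800) / 160) + rnorm(4800, 0, 0.5)
  expect_equal(variability_bandwidth(z, 140), fhr_ltv(z), tolerance = 1e-9)
})
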