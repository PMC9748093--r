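test_that("degenerate parameters give a constant baseline trace", {
  p <- fhr_gen_params(baseline_sd = 0, variability_bpm = 0, accel_rate = 0,
                      decel_rate = 0, noise_sd_bpm = 0,
                      artifact_spike_rate = 0, artifact_dropout_rate = 0,
                      artifact_jump_rate = 0)
  g <- generate_fhr(p, seed = 4)
  expect_true(all(g$signal$samples == 140))
  expect_equal(g$truth$baseline_track, rep(140, 4800))
  expect_equal(nrow(g$truth$events), 0)
  expect_length(g$truth$artifact_indices, 0)
})

test_that("a fixed seed reproduces the record bit for bit", {
  p <- fhr_gen_params()
  a <- generate_fhr(p, seed = 99)
  b <- generate_fhr(p, seed = 99)
  expect_identical(a$signal$samples, b$signal$samples)
  expect_identical(a$truth, b$truth)
  c <- generate_fhr(p, seed = 100)
  expect_false(identical(a$signal$samples, c$signal$samples))
})

test_that("injected artifacts are the samples the preprocessing flags", {
  p <- fhr_gen_params()
  tp <- 0L; fn <- 0L
  for (seed in 1:20) {
    g <- generate_fhr(p, seed = seed)
    m <- flag_invalid_samples(g$signal)
    idx <- g$truth$artifact_indices
    tp <- tp + sum(!m[idx])
    fn <- fn + sum(m[idx])
  }
  expect_gte(tp / (tp + fn), 0.95)
})

test_that("clean generated signals pass preprocessing unchanged", {
  p <- fhr_gen_params(artifact_spike_rate = 0, artifact_dropout_rate = 0,
                      artifact_jump_rate = 0)
  for (seed in 1:5) {
    g <- generate_fhr(p, seed = seed)
    expect_true(all(flag_invalid_samples(g$signal)))
    out <- preprocess_fhr(g$signal)
    expect_identical(out$samples, g$signal$samples)
  }
})

test_that("ground-truth events are recovered at easy settings", {
  sched <- difficulty_schedule("easy")
  p <- sched$normal
  p$accel_rate <- 4; p$decel_rate <- 2
  p$event_magnitude_bpm <- 22; p$event_magnitude_sd <- 1
  p$noise_sd_bpm <- 1.5
  p$artifact_spike_rate <- 0; p$artifact_dropout_rate <- 0
  p$artifact_jump_rate <- 0
  hits <- 0L; total <- 0L
  for (seed in 21:30) {
    g <- generate_fhr(p, seed = seed)
    bl <- fhr_baseline(g$signal)
    det <- rbind(detect_events(g$signal, bl, "accel"),
                 detect_events(g$signal, bl, "decel"))
    ev <- g$truth$events
    # an event counts as recovered if a detection overlaps its interval
    for (i in seq_len(nrow(ev))) {
      total <- total + 1L
      ok <- any(det$start_s < ev$end_s[i] & det$end_s > ev$start_s[i])
      if (ok) hits <- hits + 1L
    }
  }
  expect_gt(total, 20L)  # enough events for the rate to be meaningful
  expect_gte(hits / total, 0.9)
})

test_that("class-conditional features shift in the designed directions", {
  d <- study_data("easy")
  f <- as.data.frame(d$features)
  n <- d$labels == "normal"
  wt <- function(col) wilcox.test(f[[col]][n], f[[col]][!n])$p.value
  expect_gt(mean(f$stv[n]), mean(f$stv[!n]))
  expect_lt(wt("stv"), 0.01)
  expect_gt(mean(f$ltv[n]), mean(f$ltv[!n]))
  expect_lt(wt("ltv"), 0.01)
  expect_gt(mean(f$variability[n]), mean(f$variability[!n]))
  expect_gt(mean(f$decel_count[!n]), mean(f$decel_count[n]))
  expect_lt(wt("decel_count"), 0.01)
})

test_that("dataset generation honours the class ratio and pH labelling", {
  sched <- difficulty_schedule("easy")
  d <- generate_fhr_dataset(100, class_ratio = 4,
                            params_normal = sched$normal,
                            params_pathological = sched$pathological, seed = 55)
  expect_equal(sum(d$labels == "normal"), 80)
  expect_equal(sum(d$labels == "pathological"), 20)
  # the drawn pH reproduces the label through the 7.15 rule
  expect_equal(label_from_ph(d$ph), d$labels)
  # disjoint seeds give sample-distinct datasets
  d2 <- generate_fhr_dataset(100, class_ratio = 4,
                             params_normal = sched$normal,
                             params_pathological = sched$pathological,
                             seed = 56)
  expect_false(identical(d$signals[[1]]$samples, d2$signals[[1]]$samples))
})

test_that("medium difficulty lies componentwise between easy and hard", {
  e <- difficulty_schedule("easy")
  m <- difficulty_schedule("medium")
  h <- difficulty_schedule("hard")
  between <- function(field) {
    gap <- function(s) abs(s$normal[[field]] - s$pathological[[field]])
    expect_lte(gap(m), gap(e))
    expect_gte(gap(m), gap(h))
  }
  for (fd in c("baseline_bpm", "variability_bpm", "accel_rate", "decel_rate")) {
    between(fd)
  }
})
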