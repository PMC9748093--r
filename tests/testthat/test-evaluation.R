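test_that("confusion counts treat pathological as positive", {
  cm <- confusion_matrix(rep("pathological", 10), rep("pathological", 10))
  expect_equal(cm$TP, 10)
  expect_equal(cm$FP + cm$FN + cm$TN, 0)

  cm2 <- confusion_matrix(c("pathological", "pathological", "normal", "normal"),
                          c("pathological", "normal", "normal", "pathological"))
  expect_equal(unlist(cm2), c(TP = 1L, FP = 1L, FN = 1L, TN = 1L))

  expect_error(confusion_matrix(integer(0), integer(0)), "empty")
  expect_error(confusion_matrix(c(1, 0), 1), "mismatch")
})

test_that("SE, SP and QI follow their definitions", {
  m <- se_sp_qi(list(TP = 8, FN = 2, TN = 9, FP = 1))
  expect_equal(unname(m), c(0.8, 0.9, sqrt(0.72)))
  m2 <- se_sp_qi(list(TP = 3, FN = 1, TN = 6, FP = 2))
  expect_equal(unname(m2["QI"]), unname(sqrt(m2["SE"] * m2["SP"])))
  expect_equal(unname(se_sp_qi(list(TP = 5, FN = 0, TN = 0, FP = 5))["QI"]), 0)
  expect_error(se_sp_qi(list(TP = 0, FN = 0, TN = 5, FP = 0)), "undefined")
  # fixed point: SE == SP == x implies QI == x
  m3 <- se_sp_qi(list(TP = 6, FN = 2, TN = 9, FP = 3))
  expect_equal(unname(m3["SE"]), unname(m3["SP"]))
  expect_equal(unname(m3["QI"]), unname(m3["SE"]))
})

test_that("QI^2 equals SE x SP on random confusion matrices", {
  set.seed(8)
  for (i in 1:50) {
    cm <- list(TP = sample(1:50, 1), FN = sample(1:50, 1),
               TN = sample(1:50, 1), FP = sample(1:50, 1))
    m <- se_sp_qi(cm)
    expect_equal(unname(m["QI"]^2), unname(m["SE"] * m["SP"]),
                 tolerance = 1e-12)
  }
})

test_that("stratified folds are proportional within one record", {
  y <- rep(c(0, 1), c(440, 110))
  f <- stratified_kfold(y, k = 10, seed = 1)
  tab <- table(f, y)
  expect_true(all(tab[, "0"] == 44))
  expect_true(all(tab[, "1"] == 11))

  # 496-train / 56-test style split: 44 normal + 12 pathological per fold
  y2 <- rep(c(0, 1), c(440, 112))
  f2 <- stratified_kfold(y2, k = 10, seed = 2)
  tab2 <- table(f2, y2)
  expect_true(all(tab2[, "0"] == 44))
  expect_true(all(abs(tab2[, "1"] - 11.2) <= 1))

  expect_error(stratified_kfold(rep(c(0, 1), c(30, 5)), k = 10), "fewer")
  expect_identical(stratified_kfold(y, 10, 7), stratified_kfold(y, 10, 7))
})

test_that("stratification holds within one record across 100 seeds", {
  y <- rep(c(0, 1), c(83, 21))
  for (seed in 1:100) {
    f <- stratified_kfold(y, k = 5, seed = seed)
    expect_equal(sort(unique(f)), 1:5)
    tab <- table(factor(f, 1:5), y)
    for (cls in c("0", "1")) {
      prop <- sum(y == as.integer(cls)) / 5
      expect_true(all(abs(tab[, cls] - prop) <= 1))
    }
  }
})

test_that("raising the threshold never raises SE nor lowers SP", {
  set.seed(14)
  y <- rbinom(200, 1, 0.3)
  p <- runif(200)
  prev <- NULL
  for (th in seq(0.05, 0.95, by = 0.05)) {
    cm <- confusion_matrix(y, as.integer(p >= th))
    m <- se_sp_qi(cm)
    if (!is.null(prev)) {
      expect_lte(m["SE"], prev["SE"] + 1e-12)
      expect_gte(m["SP"], prev["SP"] - 1e-12)
    }
    prev <- m
  }
})

test_that("precision-recall agrees with all-thresholds enumeration", {
  y <- c(1, 1, 0, 0)
  expect_equal(precision_recall(y, c(0.9, 0.8, 0.2, 0.1))$average_precision, 1)

  set.seed(15)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    y <- rbinom(n, 1, 0.35)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # rounded scores exercise tie handling
    got <- precision_recall(y, s)
    ref <- naive_pr(y, s)
    expect_equal(got$curve$precision, ref$precision, tolerance = 1e-12)
    expect_equal(got$curve$recall, ref$recall, tolerance = 1e-12)
    expect_equal(got$average_precision, ref$average_precision,
                 tolerance = 1e-12)
  }

  # worst-case ranking: on a balanced set every positive scores below every
  # negative, so average precision cannot exceed prevalence plus tolerance
  yb <- rep(c(1, 0), each = 25)
  srev <- c(seq(0.01, 0.25, length.out = 25), seq(0.51, 0.75, length.out = 25))
  expect_lte(precision_recall(yb, srev)$average_precision, 0.5 + 0.1)
  expect_error(precision_recall(rep(1, 5), runif(5)), "single class")
})

test_that("cross-validation is reproducible and reports every fold", {
  d <- easy_subset(24, 6)
  cfg <- dffn_config(epochs = 2, seed = 42)
  cv1 <- cross_validate(d$X, d$features, d$labels, cfg, k = 2,
                        stage2_epochs = 20)
  cv2 <- cross_validate(d$X, d$features, d$labels, cfg, k = 2,
                        stage2_epochs = 20)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(nrow(cv1$folds), 2)
  expect_true(cv1$complete)
  expect_equal(unname(cv1$mean), unname(colMeans(cv1$folds)))
  expect_equal(unname(cv1$sd), unname(apply(cv1$folds, 2, sd)))
  expect_output(print(cv1), "cross-validation")
})

test_that("a degenerate single-pair sweep yields one sorted row", {
  d <- easy_subset(24, 6)
  cfg <- dffn_config(epochs = 2, seed = 42)
  sw <- class_weight_sweep(d$X, d$features, d$labels,
                           weight_grid = list(c(0.21, 0.79)),
                           config = cfg, k = 2, stage2_epochs = 20)
  expect_equal(nrow(sw), 1)
  expect_equal(attr(sw, "best"), c(0.21, 0.79))
  expect_equal(dim(default_weight_grid()), c(7L, 2L))
})
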