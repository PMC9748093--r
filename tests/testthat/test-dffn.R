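fit_small <- function(n_normal = 32, n_path = 8, epochs = 3, seed = 31) {
  d <- easy_subset(n_normal, n_path)
  cfg <- dffn_config(epochs = epochs, seed = seed)
  list(fit = dffn(d$X, d$features, d$labels, cfg), data = d)
}

test_that("the fusion head consumes a 48-dimensional fused vector", {
  r <- cached("fit_small", fit_small())
  expect_length(r$fit$head$W, 48)
  expect_named(coef(r$fit)[1:32], paste0("deep", 1:32))
  expect_equal(names(coef(r$fit))[33:48], feature_layout())
  # wrong engineered width is a dimension error
  expect_error(dffn(r$data$X, r$data$features[, 1:10], r$data$labels,
                    dffn_config(epochs = 1)), "16")
})

test_that("zero fusion weights give probability one half; ties go pathological", {
  r <- cached("fit_small", fit_small())
  fit <- r$fit
  fit$head$W[] <- 0
  fit$head$b <- 0
  p <- predict(fit, r$data$X[, 1:3], r$data$features[1:3, ])
  expect_equal(p, rep(0.5, 3))
  lab <- predict(fit, r$data$X[, 1:3], r$data$features[1:3, ], type = "class")
  expect_true(all(lab == "pathological"))  # P = 0.5 boundary
})

test_that("predicted probabilities lie strictly inside (0, 1)", {
  r <- cached("fit_small", fit_small())
  p <- predict(r$fit, r$data$X, r$data$features)
  expect_true(all(p > 0 & p < 1))
  both <- predict(r$fit, r$data$X[, 1:2], r$data$features[1:2, ], type = "both")
  expect_named(both, c("prob", "class"))
})

test_that("identical seeds give identical fitted models", {
  a <- fit_small(20, 5, epochs = 2, seed = 77)$fit
  b <- fit_small(20, 5, epochs = 2, seed = 77)$fit
  expect_identical(a$backbone$par, b$backbone$par)
  expect_identical(a$head, b$head)
})

test_that("raising the pathological weight raises predicted probabilities", {
  d <- easy_subset(32, 8)
  mean_p <- function(w) {
    cfg <- dffn_config(epochs = 6, seed = 13,
                       class_weights = c(normal = 1 - w, pathological = w))
    fit <- dffn(d$X, d$features, d$labels, cfg)
    mean(predict(fit, d$X, d$features))
  }
  expect_gt(mean_p(0.85), mean_p(0.15))
})

test_that("repeated restarts reliably fit the training data", {
  d <- easy_subset(64, 16)
  hits <- 0L
  for (s in 1:10) {
    cfg <- dffn_config(epochs = 6, seed = 1000 + s)
    fit <- dffn(d$X, d$features, d$labels, cfg, stage2_epochs = 60)
    p <- predict(fit, d$X, d$features)
    qi <- se_sp_qi(confusion_matrix(d$labels, as.integer(p >= 0.5)))["QI"]
    if (qi >= 0.85) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("print, summary and plot methods run", {
  r <- cached("fit_small", fit_small())
  expect_output(print(r$fit), "fusion")
  expect_output(print(summary(r$fit)), "Layer shapes")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(r$fit))
})
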