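test_that("backbone layer shapes reproduce the reference table row for row", {
  bb <- build_backbone(backbone_spec(), seed = 1)
  sh <- backbone_shapes(bb)
  expected <- c(
    signal_input = "4800x1", branch_conv1 = "4800x8", branch_conv2 = "4800x8",
    branch_concat = "4800x16",
    trunk_conv1 = "4800x24", avg_pool1 = "1200x24", dropout1 = "1200x24",
    trunk_conv2 = "1200x24", avg_pool2 = "150x24", dropout2 = "150x24",
    trunk_conv3 = "150x24", avg_pool3 = "9x24", dropout3 = "9x24",
    bilstm = "9x24", add = "9x24", flatten = "1x216",
    fully_connected = "1x32", fc_dropout = "1x32",
    head_fc = "1x1", sigmoid = "1x1",
    feature_input = "1x16", fuse_concat = "1x48", fuse_dropout = "1x48",
    fusion_head = "1x1", fusion_sigmoid = "1x1")
  got <- setNames(sh$output_shape, sh$layer)
  expect_equal(got[names(expected)], expected)
})

test_that("inconsistent specs are rejected at construction", {
  expect_error(backbone_spec(lstm_units = 10), "residual add")
  expect_error(backbone_spec(input_length = 100, pool_windows = c(64, 64, 64)),
               "below length 1")
})

test_that("weighted cross-entropy matches hand evaluation and scales linearly", {
  expect_lt(weighted_bce(1, 1 - 1e-12), 1e-6)          # clamped near zero
  expect_equal(weighted_bce(1, 0.5), log(2))
  expect_equal(weighted_bce(1, 0.5, c(0.21, 0.79)), 0.79 * log(2))
  expect_equal(weighted_bce(0, 0.5, c(0.21, 0.79)), 0.21 * log(2))
  y <- c(0, 1, 1, 0); p <- c(0.2, 0.9, 0.4, 0.6)
  expect_equal(weighted_bce(y, p, c(0.6, 1.4)) * 3,
               weighted_bce(y, p, 3 * c(0.6, 1.4)))
  expect_true(is.finite(weighted_bce(c(0, 1), c(1, 0))))  # clamp at the rails
})

test_that("the learning rate drops by 10 after epochs 15 and 90", {
  lr <- lr_schedule(dffn_config(epochs = 130))
  expect_equal(lr[15], 0.01)
  expect_equal(lr[16], 0.001)
  expect_equal(lr[90], 0.001)
  expect_equal(lr[91], 0.0001)
  expect_equal(lr[130], 0.0001)
})

test_that("analytic gradients match finite differences (double path)", {
  spec <- tiny_spec(dropout = 0)
  par <- ctgdffn:::cpp_dffn_init(spec, 7)
  set.seed(2)
  X <- matrix(rnorm(48 * 5, 120, 10), 48, 5)
  y <- c(0L, 1L, 1L, 0L, 1L)
  cw <- c(0.3, 0.7)
  res <- ctgdffn:::cpp_dffn_loss_grad(par, spec, X, y, cw)
  eps <- 1e-5
  worst <- 0
  for (nm in names(par)) {
    g <- res$grad[[nm]]
    th <- par[[nm]]
    if (!length(th) || grepl("rmean|rvar", nm)) next
    idx <- order(-abs(g))[seq_len(min(length(th), 4L))]
    for (i in idx) {
      if (abs(g[i]) < 1e-6) next
      p1 <- par; p1[[nm]][i] <- th[i] + eps
      p2 <- par; p2[[nm]][i] <- th[i] - eps
      num <- (ctgdffn:::cpp_dffn_loss(p1, spec, X, y, cw) -
              ctgdffn:::cpp_dffn_loss(p2, spec, X, y, cw)) / (2 * eps)
      worst <- max(worst, abs(num - g[i]) / max(abs(num), abs(g[i])))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("training is deterministic given the seed", {
  spec <- tiny_spec(dropout = 0.25)
  set.seed(3)
  X <- matrix(rnorm(48 * 12, 120, 10), 48, 12)
  y <- rep(c(0L, 1L), 6)
  run <- function() {
    bb <- build_backbone(spec, seed = 5)
    cfg <- dffn_config(epochs = 4, seed = 5, backbone = spec, batch_size = 4)
    train_stage1(X, y, cfg, backbone = bb)
  }
  a <- run(); b <- run()
  expect_identical(a$par, b$par)
  expect_identical(attr(a, "loss"), attr(b, "loss"))
})

test_that("deep features are 32-wide, batched and inference-deterministic", {
  bb <- build_backbone(backbone_spec(), seed = 2)
  set.seed(6)
  X <- matrix(rnorm(4800 * 3, 140, 8), 4800, 3)
  d1 <- extract_deep_features(bb, X)
  expect_equal(dim(d1), c(3L, 32L))
  expect_identical(d1, extract_deep_features(bb, X))
  expect_error(extract_deep_features(bb, X[1:100, ]), "expects")
})

test_that("stage-1 training separates strongly contrasting classes", {
  d <- study_data("easy")
  cfg <- dffn_config(epochs = 30, seed = 21)
  bb <- train_stage1(d$X, d$labels, cfg)
  p <- ctgdffn:::backbone_prob(bb, d$X)
  m <- se_sp_qi(confusion_matrix(d$labels, as.integer(p >= 0.5)))
  expect_gte(m["QI"], 0.9)
  loss <- attr(bb, "loss")
  expect_lt(tail(loss, 1), head(loss, 1))
})
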