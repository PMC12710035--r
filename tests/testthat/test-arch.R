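test_that("closed-form layer accounting matches hand examples", {
  b <- podkit:::newGraphBuilder(8L)
  cv <- podkit:::addNode(b, "conv", 1L, cout = 8L, k = 3L, name = "c")
  g1 <- podkit:::finishGraph(b)
  expect_equal(countParameters(g1), 3 * 8 * 9 + 8)  # biased 3x3, 3 -> 8

  b <- podkit:::newGraphBuilder(8L)
  podkit:::addNode(b, "conv", 1L, cout = 4L, k = 1L, cin = 4L,
                   biased = FALSE, name = "c1x1")
  g2 <- podkit:::finishGraph(b)
  expect_equal(countFlops(g2), 2 * 4 * 4 * 64)      # 8,192 FLOPs on 8x8

  b <- podkit:::newGraphBuilder(8L)
  podkit:::addNode(b, "nearest_upsample", 1L, stride = 2L, name = "up")
  g3 <- podkit:::finishGraph(b)
  expect_equal(countFlops(g3), 0)
})

test_that("baseline parameter totals match the published table rows", {
  expect_equal(round(countParameters(buildBaseline(1, 32, 640)) / 1e6, 3), 3.258)
  expect_equal(countParameters(buildBaseline(1, 32, 640)), 3258259L)
  # printed precision is one unit in the third decimal
  expect_lt(abs(countParameters(buildBaseline(1, 16, 640)) / 1e6 - 3.110), 1e-3 + 1e-9)
  expect_equal(round(countParameters(buildBaseline(1, 128, 640)) / 1e6, 3), 4.113)
  expect_equal(round(countParameters(buildBaseline(1, 32, 640, p3p4_only = TRUE)) / 1e6, 3),
               2.161)
})

test_that("parameters are independent of input size and monotone in k", {
  expect_equal(countParameters(buildBaseline(1, 32, 320)),
               countParameters(buildBaseline(1, 32, 640)))
  ks <- c(16, 32, 64, 128)
  ps <- vapply(ks, function(k) countParameters(buildBaseline(1, k, 640)), numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("HPA variant reproduces the printed total and validates its config", {
  g <- applyHPA(buildBaseline(), hpaConfig("parallel_convT", 24, 6, 2))
  expect_equal(round(countParameters(g) / 1e6, 3), 3.586)
  expect_error(hpaConfig("parallel_convT", 24, 6, 1, k = 32),
               class = "podkitConstraintViolation")
  # zero-channel paths are dropped: P3-only fused pathway remains
  g0 <- applyHPA(buildBaseline(), hpaConfig("parallel_convT", 32, 0, 0))
  expect_false(any(grepl("hpa.p4|hpa.p5", g0@layers$name)))
  expect_true(any(grepl("hpa.p3", g0@layers$name)))
  # requesting P5 channels without a P5 tap fails
  expect_error(applyHPA(buildBaseline(p3p4_only = TRUE),
                        hpaConfig("parallel_convT", 24, 6, 2)),
               class = "podkitMissingTap")
})

test_that("U-decoder variants land on the printed totals", {
  un <- applyUEMA(buildBaseline(), protonetConfig("nearest", use_ema = FALSE))
  uc <- applyUEMA(buildBaseline(), protonetConfig("transposed_conv", use_ema = FALSE))
  expect_equal(round(countParameters(un) / 1e6, 3), 3.242)
  expect_lt(abs(countParameters(uc) / 1e6 - 3.274), 1e-3 + 1e-9)
  # nearest upsampling is parameter-free, so it is strictly lighter
  expect_lt(countParameters(un), countParameters(uc))
  # proto_out at input/4 for U-decoder variants
  sh <- inferShapes(un)
  po <- sh[taps(un)[["proto_out"]], ]
  expect_equal(c(po$out_h, po$out_w), c(160, 160))
})

test_that("composed model matches the printed total for every HPA variant", {
  p <- buildPodNet()
  expect_equal(countParameters(p), 3537043L)
  expect_equal(round(countParameters(p) / 1e6, 3), 3.537)
  for (v in c("cascaded_convT", "parallel_interp"))
    expect_equal(countParameters(buildPodNet(hpa_variant = v)),
                 countParameters(p))
  expect_gte(sum(p@layers$kind == "ema"), 1)
  po <- p@layers[taps(p)[["proto_out"]], ]
  expect_equal(c(po$out_c, po$out_h, po$out_w), c(32, 160, 160))
})

test_that("symbolic counts equal the materialised-weight oracle", {
  graphs <- list(
    buildBaseline(),
    buildBaseline(1, 64, 640),
    buildBaseline(p3p4_only = TRUE),
    applyHPA(buildBaseline(), hpaConfig("parallel_convT", 24, 6, 2)),
    applyUEMA(buildBaseline(), protonetConfig("nearest", use_ema = FALSE)),
    applyUEMA(buildBaseline(), protonetConfig("transposed_conv", use_ema = FALSE)),
    buildPodNet())
  for (g in graphs)
    expect_equal(countParameters(g), materializedParamCount(g))
})

test_that("shape inference honours the pyramid and fusion contracts", {
  g <- applyHPA(buildBaseline(), hpaConfig("parallel_convT", 24, 6, 2))
  sh <- inferShapes(g)
  tp <- taps(g)
  expect_equal(sh$out_h[tp[["P3"]]], 80)
  expect_equal(sh$out_h[tp[["P4"]]], 40)
  expect_equal(sh$out_h[tp[["P5"]]], 20)
  cat_row <- sh[g@layers$name == "hpa.cat", ]
  expect_equal(c(cat_row$out_c, cat_row$out_h, cat_row$out_w), c(32, 80, 80))
  # resolution-independent strides
  sh320 <- inferShapes(g, input_size = 320)
  expect_equal(sh320$out_h[tp[["P3"]]], 40)
})

test_that("invalid configurations are rejected with typed errors", {
  expect_error(buildBaseline(input_size = 600), class = "podkitInvalidConfig")
  expect_error(applyUEMA(buildBaseline(),
                         protonetConfig("nearest", use_ema = TRUE, ema_groups = 7)),
               class = "podkitInvalidConfig")
})

test_that("FLOP accounting follows the 2xMAC convention", {
  g <- buildBaseline()
  # convolutional cost scales with spatial area
  expect_equal(countFlops(g, input_size = 320) * 4, countFlops(g, input_size = 640),
               tolerance = 1e-6)
  # the stock-width class-head profile reproduces the published 12.0 GFLOPs
  pr <- profileModel(g)
  expect_equal(pr$gflops_stock_head, 12.0)
})

test_that("YAML config round trip rebuilds the same architecture", {
  p <- buildPodNet()
  f <- tempfile(fileext = ".yaml")
  writeModelConfig(p, f)
  g2 <- buildFromConfig(f)
  expect_equal(countParameters(g2), countParameters(p))
  expect_equal(nLayers(g2), nLayers(p))
})
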