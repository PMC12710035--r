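test_that("mask assembly equals the per-pixel brute-force oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(1:4, 1)
    h <- sample(4:8, 1); w <- sample(4:8, 1)
    pl <- array(rnorm(k * h * w), c(k, h, w))
    co <- rnorm(k)
    box <- c(sample(0:(w - 2), 1), sample(0:(h - 2), 1))
    box <- c(box, sample((box[1] + 1):w, 1), sample((box[2] + 1):h, 1))
    preds <- instancePredictions(matrix(box, 1), 0.9, matrix(co, 1), c(h, w))
    got <- assembleInstanceMasks(prototypeBundle(pl), preds)
    expect_identical(got@masks[[1]], assembleOracle(pl, co, box))
  }
})

test_that("assembly edge cases: zero plane, crop contract, length check", {
  pl <- array(0, c(1, 6, 6))
  preds <- instancePredictions(matrix(c(1, 1, 5, 5), 1), 0.9,
                               matrix(3.7, 1), c(6, 6))
  got <- assembleInstanceMasks(prototypeBundle(pl), preds)
  expect_equal(sum(got@masks[[1]]), 0)   # logistic(0) = 0.5, strict >
  # no foreground outside the box, ever
  set.seed(42)
  pl <- array(rnorm(2 * 8 * 8, sd = 3), c(2, 8, 8))
  preds <- instancePredictions(matrix(c(2, 3, 6, 7), 1), 0.5,
                               matrix(c(2, -1), 1), c(8, 8))
  m <- assembleInstanceMasks(prototypeBundle(pl), preds)@masks[[1]]
  outside <- m
  outside[(3 + 1):7, (2 + 1):6] <- FALSE
  expect_equal(sum(outside), 0)
  bad <- instancePredictions(matrix(c(0, 0, 4, 4), 1), 0.5,
                             matrix(c(1, 2, 3), 1), c(8, 8))
  expect_error(assembleInstanceMasks(prototypeBundle(pl), bad),
               class = "podkitConstraintViolation")
})

test_that("postprocess thresholds and greedy NMS behave as specified", {
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  p <- instancePredictions(b, c(0.9, 0.8), matrix(0, 2, 1), c(20, 20))
  expect_equal(nInstances(postprocess(p)), 1L)

  p2 <- instancePredictions(b, c(0.2, 0.1), matrix(0, 2, 1), c(20, 20))
  expect_equal(nInstances(postprocess(p2)), 0L)

  # pairwise IoUs {0.6, 0.1, 0.1}: the 0.6 pair collapses, two remain
  b3 <- rbind(c(0, 0, 10, 10), c(0, 2.5, 10, 12.5), c(30, 30, 36, 36))
  expect_equal(podkit:::boxIoU(b3[1, ], b3[2, ]), 0.6, tolerance = 1e-9)
  p3 <- instancePredictions(b3, c(0.9, 0.8, 0.7), matrix(0, 3, 1), c(40, 40))
  expect_equal(nInstances(postprocess(p3)), 2L)
})

test_that("mask IoU handles identity, disjointness and partial overlap", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(maskIoU(a, a), 1.0)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(maskIoU(a, b), 0.0)
  # 2x2 masks overlapping in 1 of 3 set pixels
  m1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  m2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(maskIoU(m1, m2), 1 / 3)
  expect_equal(maskIoU(a & FALSE, b & FALSE), 1.0)  # empty vs empty
  expect_error(maskIoU(a, matrix(FALSE, 3, 3)), class = "podkitShapeMismatch")
})

test_that("greedy matching conserves counts and follows confidence order", {
  t1 <- matrix(FALSE, 6, 6); t1[1:3, 1:3] <- TRUE
  mr <- matchInstances(list(t1), 1.0, list(t1), 0.5)
  expect_equal(c(mr@tp, mr@fp, mr@fn), c(1L, 0L, 0L))
  mr0 <- matchInstances(list(), numeric(0), list(t1, t1), 0.5)
  expect_equal(c(mr0@tp, mr0@fn), c(0L, 2L))
  # 1 truth; preds with IoU 0.6 (conf 0.9) and 0.55 (conf 0.95):
  # the conf-0.95 prediction is visited first and takes the match
  tr <- matrix(FALSE, 10, 10); tr[1:4, 1:5] <- TRUE           # 20 px
  pA <- matrix(FALSE, 10, 10); pA[1:4, 1:4] <- TRUE           # IoU 16/24
  pB <- matrix(FALSE, 10, 10); pB[1:5, 1:5] <- TRUE           # IoU 20/25
  expect_equal(maskIoU(pB, tr), 0.8)
  mr2 <- matchInstances(list(pA, pB), c(0.9, 0.95), list(tr), 0.5)
  expect_equal(c(mr2@tp, mr2@fp, mr2@fn), c(1L, 1L, 0L))
  expect_equal(mr2@pairs$pred, 2L)
  # conservation on random cases
  set.seed(7)
  for (i in 1:5) {
    np <- sample(0:4, 1); nt <- sample(1:4, 1)
    pm <- lapply(seq_len(np), function(i) matrix(runif(36) > 0.5, 6, 6))
    tm <- lapply(seq_len(nt), function(i) matrix(runif(36) > 0.5, 6, 6))
    mr <- matchInstances(pm, runif(np), tm, 0.5)
    expect_equal(mr@tp + mr@fn, nt)
    expect_equal(mr@tp + mr@fp, np)
  }
})

test_that("average precision reproduces hand-enumerated PR curves", {
  t1 <- matrix(FALSE, 4, 4); t1[1:2, 1:2] <- TRUE
  t2 <- matrix(FALSE, 4, 4); t2[3:4, 3:4] <- TRUE
  fpm <- matrix(FALSE, 4, 4); fpm[1:2, 3:4] <- TRUE
  truths <- list(list(t1, t2))
  # perfect ranked predictions -> AP 1
  perfect <- list(list(masks = list(t1, t2), confidence = c(0.9, 0.8)))
  expect_equal(averagePrecision(perfect, truths, 0.5), 1.0)
  # no predictions -> AP 0
  none <- list(list(masks = list(), confidence = numeric(0)))
  expect_equal(averagePrecision(none, truths, 0.5), 0.0)
  # ranked (TP, FP, TP): precision 1, 1/2, 2/3 at recall 1/2, 1/2, 1;
  # 101-point interpolation = (51 * 1 + 50 * 2/3) / 101
  mixed <- list(list(masks = list(t1, fpm, t2), confidence = c(0.9, 0.8, 0.7)))
  expect_equal(averagePrecision(mixed, truths, 0.5), (51 + 50 * 2 / 3) / 101,
               tolerance = 1e-12)
  # zero ground truth is signalled
  expect_error(averagePrecision(mixed, list(list()), 0.5),
               class = "podkitUndefinedMetric")
})

test_that("AP invariants: order, bounds, FP monotonicity, map ordering", {
  t1 <- matrix(FALSE, 4, 4); t1[1:2, 1:2] <- TRUE
  t2 <- matrix(FALSE, 4, 4); t2[3:4, 3:4] <- TRUE
  fpm <- matrix(FALSE, 4, 4); fpm[1:2, 3:4] <- TRUE
  truths <- list(list(t1, t2))
  a <- list(list(masks = list(t1, t2), confidence = c(0.8, 0.8)))
  b <- list(list(masks = list(t2, t1), confidence = c(0.8, 0.8)))
  expect_equal(averagePrecision(a, truths, 0.5), averagePrecision(b, truths, 0.5))
  # appending an FP at the lowest rank never increases AP
  withfp <- list(list(masks = list(t1, t2, fpm), confidence = c(0.8, 0.7, 0.1)))
  expect_lte(averagePrecision(withfp, truths, 0.5),
             averagePrecision(a, truths, 0.5))
  # bounds and the map50_95 <= map50 ordering on random mask sets
  set.seed(11)
  for (i in 1:4) {
    preds <- list(list(masks = lapply(1:3, function(j) matrix(runif(16) > 0.4, 4, 4)),
                       confidence = runif(3)))
    ap <- averagePrecision(preds, truths, 0.5)
    expect_gte(ap, 0); expect_lte(ap, 1)
    r <- evaluateInstances(preds, truths)
    expect_lte(r@map50_95, r@map50 + 1e-12)
  }
})

test_that("all-point interpolation computes the exact PR envelope area", {
  t1 <- matrix(FALSE, 4, 4); t1[1:2, 1:2] <- TRUE
  t2 <- matrix(FALSE, 4, 4); t2[3:4, 3:4] <- TRUE
  fpm <- matrix(FALSE, 4, 4); fpm[1:2, 3:4] <- TRUE
  truths <- list(list(t1, t2))
  mixed <- list(list(masks = list(t1, fpm, t2), confidence = c(0.9, 0.8, 0.7)))
  # envelope: precision 1 up to recall 0.5, then 2/3 up to recall 1
  expect_equal(averagePrecision(mixed, truths, 0.5, interpolation = "all"),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
})
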