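# loop oracles for the detail indicators (valid interior, same kernels)
clarityOracle <- function(g) {
  h <- nrow(g); w <- ncol(g)
  vals <- c()
  for (i in 2:(h - 1)) for (j in 2:(w - 1))
    vals <- c(vals, g[i - 1, j] + g[i + 1, j] + g[i, j - 1] + g[i, j + 1] - 4 * g[i, j])
  mean((vals - mean(vals))^2)
}
tenengradOracle <- function(g) {
  h <- nrow(g); w <- ncol(g)
  vals <- c()
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    gx <- -g[i - 1, j - 1] + g[i - 1, j + 1] - 2 * g[i, j - 1] + 2 * g[i, j + 1] -
      g[i + 1, j - 1] + g[i + 1, j + 1]
    gy <- -g[i - 1, j - 1] - 2 * g[i - 1, j] - g[i - 1, j + 1] +
      g[i + 1, j - 1] + 2 * g[i + 1, j] + g[i + 1, j + 1]
    vals <- c(vals, gx^2 + gy^2)
  }
  mean(vals)
}

test_that("constant images score the degenerate indicator values", {
  const <- matrix(0.47, 12, 12)
  expect_equal(clarity(const), 0)
  expect_equal(edgeSharpness(const), 0)
  expect_equal(imageEntropy(const), 0)
  expect_equal(glcmEnergy(const), 1.0)
})

test_that("clarity and sharpness match hand-computed oracles", {
  spot <- matrix(0, 8, 8); spot[4, 5] <- 1
  expect_gt(clarity(spot), 0)
  expect_equal(clarity(spot), clarityOracle(spot), tolerance = 1e-12)
  hand <- matrix(c(0, 0, 1, 1,
                   0, 0, 1, 1,
                   0, 0, 1, 1,
                   0, 0, 1, 1), 4, 4, byrow = TRUE)
  expect_equal(edgeSharpness(hand), tenengradOracle(hand), tolerance = 1e-12)
  # a step edge outscores its blurred version
  step <- matrix(rep(c(rep(0, 8), rep(1, 8)), each = 16), 16, 16)
  expect_gt(edgeSharpness(step), edgeSharpness(gaussianBlur(step, 2)))
})

test_that("entropy hits its closed-form anchors and bounds", {
  cb <- outer(1:16, 1:16, function(i, j) ((i + j) %% 2)) * 0.999
  expect_equal(imageEntropy(cb), 1.0)                      # 50/50 two-level
  allv <- matrix(rep(0:255, each = 4) / 256, 32, 32)
  expect_equal(imageEntropy(allv), 8.0)                    # uniform 256 levels
  card <- testCard()
  e <- imageEntropy(card)
  expect_gte(e, 0); expect_lte(e, 8)
})

test_that("co-occurrence energy: checkerboard anchor and noise ordering", {
  cb <- outer(1:16, 1:16, function(i, j) ((i + j) %% 2)) * 0.999
  expect_equal(glcmEnergy(cb), 0.5)                 # two off-diagonal cells of 1/2
  set.seed(3)
  noisy <- matrix(runif(32 * 32), 32, 32)
  expect_lt(glcmEnergy(noisy), glcmEnergy(matrix(0.5, 32, 32)))
  expect_gt(glcmEnergy(noisy), 0)
  expect_lte(glcmEnergy(noisy), 1)
})

test_that("indicators are invariant to flips and monotone under blur", {
  card <- testCard()
  for (f in list(clarity, edgeSharpness, imageEntropy, glcmEnergy)) {
    expect_equal(f(card), f(card[nrow(card):1, ]), tolerance = 1e-12)
    expect_equal(f(card), f(card[, ncol(card):1]), tolerance = 1e-12)
  }
  sig <- c(0, 1, 2, 4)
  cl <- vapply(sig, function(s) clarity(gaussianBlur(card, s)), numeric(1))
  sh <- vapply(sig, function(s) edgeSharpness(gaussianBlur(card, s)), numeric(1))
  expect_true(all(diff(cl) < 0))
  expect_true(all(diff(sh) < 0))
})

test_that("frame extraction follows the interval and boundary rule", {
  img <- matrix(0.5, 4, 4)
  clip <- function(n, fps) list(fps = fps, frames = rep(list(img), n), id = "c")
  expect_equal(nrow(extractFrames(clip(120, 60))$meta), 2L)  # t = 0, 1
  expect_equal(nrow(extractFrames(clip(121, 60))$meta), 3L)  # final frame exists
  expect_equal(nrow(extractFrames(clip(0, 60))$meta), 0L)    # empty video
  # 5 s at 30 fps: manual index oracle floor(k * fps) + 1 while <= n
  got <- extractFrames(clip(150, 30))
  manual <- c()
  k <- 0
  repeat { i <- floor(k * 30) + 1; if (i > 150) break; manual <- c(manual, i); k <- k + 1 }
  expect_equal(got$meta$index, manual)
  expect_equal(got$meta$t, 0:(length(manual) - 1))
  expect_error(extractFrames(list(frames = list(img))), class = "podkitIOError")
})

test_that("two-stage filtering keeps, drops and audits as specified", {
  sc <- data.frame(clip = "a", t = 0:3,
                   clarity = c(10, 1, 10, 10), sharpness = c(5, 5, 5, 5),
                   entropy = c(4, 4, 4, 0.1), energy = c(0.2, 0.2, 0.2, 0.2))
  prof <- thresholdProfile(list(clarity = c(min = 2), entropy = c(min = 1)))
  out <- twoStageFilter(sc, prof)
  expect_equal(out$kept, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$reason[2], "clarity")
  expect_equal(out$stage[2], 1L)
  # stage 2 tightening per subset
  prof2 <- thresholdProfile(list(clarity = c(min = 2)),
                            list(s1 = list(clarity = c(min = 8))))
  out2 <- twoStageFilter(sc, prof2, subset = "s1")
  expect_equal(out2$kept, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(out2$stage[2], 1L)
  sc2 <- sc; sc2$clarity <- c(10, 5, 10, 10)
  out3 <- twoStageFilter(sc2, prof2, subset = "s1")
  expect_equal(out3$stage[2], 2L)
  expect_error(twoStageFilter(sc, prof2, subset = "nope"),
               class = "podkitInvalidConfig")
  expect_error(thresholdProfile(list(clarity = c(min = 2)),
                                list(s1 = list(clarity = c(min = 1)))),
               class = "podkitInvalidConfig")
  # order independence
  perm <- c(3, 1, 4, 2)
  outp <- twoStageFilter(sc[perm, ], prof)
  expect_equal(outp$kept, out$kept[perm])
})

test_that("sharp and blurred fixtures separate perfectly", {
  card <- testCard(n = 40)
  sharp <- lapply(1:10, function(i) podkit:::clamp(card + matrix(rnorm(1600, 0, 0.01), 40, 40), 0, 1))
  blurred <- lapply(sharp, gaussianBlur, sigma = 4)
  sc <- scoreFrames(c(sharp, blurred))
  cut <- mean(c(max(sc$clarity[11:20]), min(sc$clarity[1:10])))
  prof <- thresholdProfile(list(clarity = c(min = cut)))
  out <- twoStageFilter(sc, prof)
  expect_equal(out$kept, rep(c(TRUE, FALSE), each = 10))
})
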