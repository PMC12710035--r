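test_that("label parsing handles valid lines and reports malformed ones", {
  f <- tempfile(fileext = ".txt")
  writeLines("0 0.1 0.1 0.5 0.1 0.3 0.6", f)
  anns <- readLabels(f, c(100, 100))
  expect_length(anns, 1)
  expect_equal(anns[[1]]$class_id, 0L)
  expect_equal(nrow(anns[[1]]$polygon), 3)
  expect_gt(sum(anns[[1]]$mask), 0)
  # derived box is the mask's minimal bounding rectangle
  expect_equal(anns[[1]]$box, podkit:::maskBox(anns[[1]]$mask))

  writeLines("0 0.1 0.1 0.5 0.1 0.3", f)         # odd coordinate count
  expect_error(readLabels(f, c(100, 100)), "line 1", class = "podkitParseError")
  writeLines(c("0 0.1 0.1 0.5 0.1 0.3 0.6",
               "0 0.1 0.1 1.2 0.1 0.3 0.6"), f)  # out of range on line 2
  expect_error(readLabels(f, c(100, 100)), "line 2", class = "podkitParseError")
})

test_that("write/read round trip is lossless up to float formatting", {
  sc <- easyScene(4)
  f <- tempfile(fileext = ".txt")
  writeLabels(sc@annotations, f)
  back <- readLabels(f, dim(sc@image)[1:2])
  expect_length(back, length(sc@annotations))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$polygon, sc@annotations[[i]]$polygon, tolerance = 1e-5)
    expect_gte(maskIoU(back[[i]]$mask, sc@annotations[[i]]$mask), 0.99)
  }
  # writing the re-read labels reproduces the file exactly
  f2 <- tempfile(fileext = ".txt")
  writeLabels(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("rasterisation and vectorisation agree with pixel conventions", {
  p <- cbind(c(2, 5, 5, 2), c(3, 3, 7, 7))
  m <- polygonToMask(p, c(10, 10), normalized = FALSE)
  expect_equal(sum(m), 12)                        # [2,5) x [3,7)
  expect_true(all(which(m, arr.ind = TRUE)[, 1] %in% 4:7))
  expect_error(polygonToMask(p[1:2, ], c(10, 10), normalized = FALSE),
               class = "podkitInvalidConfig")
  expect_identical(maskToPolygon(matrix(FALSE, 5, 5)), list())
  # convex blob round trip (lattice tracing is exact)
  blob <- podkit:::ellipseMask(24, 24, 12, 11, 8, 5, 0.4, wobble = 0)
  polys <- maskToPolygon(blob)
  expect_length(polys, 1)
  expect_gte(maskIoU(polygonToMask(polys[[1]], c(24, 24)), blob), 0.99)
  # multi-part masks come back as multiple polygons
  two <- matrix(FALSE, 8, 8); two[2:3, 2:3] <- TRUE; two[6:7, 6:7] <- TRUE
  expect_length(maskToPolygon(two), 2)
})

test_that("splits are sized, disjoint, exhaustive and seed-stable", {
  ids <- sprintf("img%03d", 1:488)
  sp <- splitDataset(ids, c(406, 47, 35), seed = 9)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 406L, val = 47L, test = 35L))
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_identical(sp, splitDataset(ids, c(406, 47, 35), seed = 9))
  expect_false(identical(sp$train, splitDataset(ids, c(406, 47, 35), seed = 10)$train))
  expect_error(splitDataset(ids, c(406, 47, 36), seed = 0),
               class = "podkitInvalidConfig")
})

test_that("dataset statistics conserve counts and bin centres as stated", {
  mk <- function(n, seed) {
    sc <- generateScene(sceneConfig(image_size = c(64, 64), n_pods = n,
                                    n_occluders = 0, allow_overlap = FALSE,
                                    axis_range = c(3, 5, 6, 9), seed = seed))
    list(size = c(64, 64), annotations = sc@annotations)
  }
  ds <- list(mk(3, 1), mk(5, 2))
  st <- computeStats(ds, grid = 8)
  expect_equal(st$per_image_counts, c(3L, 5L))
  expect_equal(st$mean_instances, 4.0)
  expect_equal(st$total, 8)
  expect_equal(sum(st$density), 8)
  expect_equal(lengths(st$areas), c(3L, 5L))
  # hand binning: a box centred at (x, y) = (0.5, 0.25) on a 4x4 grid falls
  # in 0-based (row 1, col 2)
  one <- list(list(size = c(16, 16), annotations = list(list(
    class_id = 0L, box = c(6, 2, 10, 6),
    mask = polygonToMask(cbind(c(6, 10, 10, 6), c(2, 2, 6, 6)), c(16, 16),
                         normalized = FALSE)))))
  d <- computeStats(one, grid = 4)$density
  expect_equal(d[2, 3], 1)
  expect_equal(sum(d), 1)
})

test_that("augmentations transform masks with the image", {
  sc <- easyScene(6)
  # horizontal flip is an involution
  a1 <- augment(sc@image, sc@annotations, ops = "flip-h")
  a2 <- augment(a1$image, a1$annotations, ops = "flip-h")
  expect_equal(a2$image, sc@image)
  for (i in seq_along(sc@annotations))
    expect_identical(a2$annotations[[i]]$mask, sc@annotations[[i]]$mask)
  # right-angle rotation preserves pixel areas
  r <- augment(sc@image, sc@annotations, ops = "rotate", rotate_k = 1)
  expect_equal(vapply(r$annotations, function(a) sum(a$mask), numeric(1)),
               vapply(sc@annotations, function(a) sum(a$mask), numeric(1)))
  expect_equal(dim(r$image)[1:2], rev(dim(sc@image)[1:2]))
  # deterministic per seed
  b1 <- augment(sc@image, sc@annotations, ops = c("crop", "rotate"), seed = 3)
  b2 <- augment(sc@image, sc@annotations, ops = c("crop", "rotate"), seed = 3)
  expect_equal(b1$image, b2$image)
})

test_that("cropping removes excluded instances and matches the oracle crop", {
  sc <- easyScene(2, size = 96, n_pods = 3)
  boxes <- t(vapply(sc@annotations, function(a) a$box, numeric(4)))
  # crop window that fully excludes the rightmost instance
  drop_i <- which.max(boxes[, 1])
  kept <- setdiff(seq_len(nrow(boxes)), drop_i)
  win <- c(0, 0, max(boxes[kept, 3]), 96)
  stopifnot(boxes[drop_i, 1] >= win[3])     # fixture sanity
  cr <- augment(sc@image, sc@annotations, ops = "crop", crop = win)
  expect_length(cr$annotations, length(kept))
  for (j in seq_along(kept)) {
    oracle <- sc@annotations[[kept[j]]]$mask[(win[2] + 1):win[4],
                                             (win[1] + 1):win[3]]
    expect_identical(cr$annotations[[j]]$mask, oracle)
  }
  expect_error(augment(sc@image, sc@annotations, ops = "crop",
                       crop = c(-2, 0, 50, 50)),
               class = "podkitInvalidConfig")
})

test_that("COCO JSON round trip preserves instances and scores", {
  sc <- easyScene(12, size = 64, n_pods = 2)
  ds <- list(list(id = 1L, size = c(64, 64), annotations = lapply(
    sc@annotations, function(a) c(a, list(score = 0.7)))))
  f <- tempfile(fileext = ".json")
  writeCoco(ds, f)
  back <- readCoco(f)
  expect_length(back, 1)
  expect_length(back[[1]]$annotations, 2)
  for (i in 1:2) {
    expect_gte(maskIoU(back[[1]]$annotations[[i]]$mask,
                       sc@annotations[[i]]$mask), 0.99)
    expect_equal(back[[1]]$annotations[[i]]$score, 0.7)
  }
})
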