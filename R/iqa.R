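# No-reference image-quality indicators and the two-stage frame filter used
# to harvest static frames from field video.

validRegionConv <- function(gray, kern) {
  # 'valid' 2-D convolution (no padding), so constant images give exact zeros
  kh <- nrow(kern); kw <- ncol(kern)
  h <- nrow(gray); w <- ncol(gray)
  if (h < kh || w < kw) pkStop("image smaller than kernel", "podkitInvalidConfig")
  out <- matrix(0, h - kh + 1L, w - kw + 1L)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    if (kern[i, j] == 0) next
    out <- out + kern[i, j] * gray[i:(i + nrow(out) - 1L), j:(j + ncol(out) - 1L)]
  }
  out
}

#' Image clarity (variance of the Laplacian)
#'
#' Variance of the 4-neighbour Laplacian response of the grayscale image
#' over the valid interior.  Zero for constant images; decreases
#' monotonically under increasing Gaussian blur of a fixed scene.
#'
#' @param image numeric matrix (grayscale, any scale) or `h x w x 3` RGB
#'   array in `[0, 1]`.
#' @return non-negative real.
#' @export
clarity <- function(image) {
  g <- toGray(image)
  if (length(g) == 0L) pkStop("empty image", "podkitInvalidConfig")
  lap <- validRegionConv(g, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
  mean((lap - mean(lap))^2)
}

#' Edge sharpness (mean Tenengrad)
#'
#' Mean squared Sobel gradient magnitude over the valid interior.
#'
#' @inheritParams clarity
#' @return non-negative real; 0 for constant images.
#' @export
edgeSharpness <- function(image) {
  g <- toGray(image)
  if (length(g) == 0L) pkStop("empty image", "podkitInvalidConfig")
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- validRegionConv(g, sx)
  gy <- validRegionConv(g, t(sx))
  mean(gx^2 + gy^2)
}

#' Shannon entropy of the intensity histogram
#'
#' Entropy in bits of the 256-bin histogram of the image quantised to
#' 8-bit grayscale; lies in `[0, 8]`.
#'
#' @inheritParams clarity
#' @return entropy in bits.
#' @export
imageEntropy <- function(image) {
  g <- toGray(image)
  q <- clamp(floor(g * 256), 0, 255)
  p <- tabulate(q + 1L, nbins = 256L) / length(q)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Energy (angular second moment) of the gray-level co-occurrence matrix
#'
#' The image is quantised to `levels` gray levels; for each offset the
#' symmetric co-occurrence matrix is accumulated and normalised, the
#' matrices are averaged over offsets, and the energy is the sum of
#' squared entries.  Lies in `(0, 1]`, equal to 1 for constant images.
#'
#' @inheritParams clarity
#' @param levels quantisation level count (default 32).
#' @param offsets list of integer `c(dy, dx)` neighbour offsets.
#' @return energy in `(0, 1]`.
#' @export
glcmEnergy <- function(image, levels = 32,
                       offsets = list(c(0L, 1L), c(1L, 0L))) {
  g <- toGray(image)
  q <- clamp(floor(g * levels), 0, levels - 1L)
  h <- nrow(q); w <- ncol(q)
  acc <- matrix(0, levels, levels)
  for (off in offsets) {
    dy <- off[1]; dx <- off[2]
    r1 <- seq_len(h - abs(dy)); c1 <- seq_len(w - abs(dx))
    a <- q[r1 + max(0, dy), c1 + max(0, dx)]
    bmat <- q[r1 + max(0, -dy), c1 + max(0, -dx)]
    co <- matrix(0, levels, levels)
    tab <- table(factor(a, levels = 0:(levels - 1L)),
                 factor(bmat, levels = 0:(levels - 1L)))
    co <- co + tab + t(tab)          # symmetric
    acc <- acc + co / sum(co)
  }
  acc <- acc / length(offsets)
  sum(acc^2)
}

#' Score frames with the four quality indicators
#'
#' @param images list of images (matrices or RGB arrays).
#' @param clip clip identifier(s), recycled.
#' @param t frame timestamps in seconds (defaults to the frame index - 1).
#' @return data.frame with `clip`, `t`, `clarity`, `sharpness`, `entropy`,
#'   `energy`.
#' @export
scoreFrames <- function(images, clip = "clip", t = seq_along(images) - 1) {
  data.frame(
    clip = rep_len(clip, length(images)), t = t,
    clarity = vapply(images, clarity, numeric(1)),
    sharpness = vapply(images, edgeSharpness, numeric(1)),
    entropy = vapply(images, imageEntropy, numeric(1)),
    energy = vapply(images, glcmEnergy, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Extract frames from a clip at a fixed time interval
#'
#' Takes one frame per `interval` seconds starting at t = 0; the number of
#' extracted frames is `floor(duration / interval) + 1`, capped by frame
#' availability.  A clip is a list with elements `fps`, `frames` (a list of
#' images or a character vector of image file paths) and optionally `id`.
#'
#' @param clip list with `fps`, `frames`, and optional `id`.
#' @param interval sampling interval in seconds (default 1).
#' @return list with `meta` (data.frame `clip`, `t`, `index`) and `images`
#'   (list of frames; paths are loaded with [png::readPNG()]).
#' @export
extractFrames <- function(clip, interval = 1.0) {
  if (is.null(clip$fps) || clip$fps <= 0)
    pkStop(sprintf("clip '%s': unreadable stream (unknown frame rate)",
                   if (is.null(clip$id)) "?" else clip$id), "podkitIOError")
  n <- length(clip$frames)
  id <- if (is.null(clip$id)) "clip" else clip$id
  idx <- integer(); ts <- numeric(); k <- 0
  repeat {
    i <- floor(k * interval * clip$fps) + 1
    if (i > n) break
    idx <- c(idx, as.integer(i)); ts <- c(ts, k * interval); k <- k + 1
  }
  imgs <- lapply(idx, function(i) {
    f <- clip$frames[[i]]
    if (is.character(f)) png::readPNG(f) else f
  })
  list(meta = data.frame(clip = rep_len(id, length(idx)), t = ts, index = idx,
                         stringsAsFactors = FALSE),
       images = imgs)
}

#' Build a two-stage threshold profile
#'
#' Stage 1 holds loose bounds applied to every frame; stage 2 holds
#' per-subset bounds that must be at least as strict as stage 1 for shared
#' indicators.  Each bound set is a named list of `c(min = ..)` and/or
#' `c(max = ..)` entries keyed by indicator (`clarity`, `sharpness`,
#' `entropy`, `energy`).
#'
#' @param stage1 loose bounds.
#' @param stage2 named list of per-subset bound sets.
#' @return classed list.
#' @export
thresholdProfile <- function(stage1, stage2 = list()) {
  for (sub in names(stage2)) {
    for (ind in intersect(names(stage2[[sub]]), names(stage1))) {
      b1 <- stage1[[ind]]; b2 <- stage2[[sub]][[ind]]
      if (!is.na(b1["min"]) && !is.na(b2["min"]) && b2["min"] < b1["min"])
        pkStop(sprintf("stage-2 '%s' bound for subset '%s' looser than stage 1",
                       ind, sub), "podkitInvalidConfig")
      if (!is.na(b1["max"]) && !is.na(b2["max"]) && b2["max"] > b1["max"])
        pkStop(sprintf("stage-2 '%s' bound for subset '%s' looser than stage 1",
                       ind, sub), "podkitInvalidConfig")
    }
  }
  structure(list(stage1 = stage1, stage2 = stage2), class = "thresholdProfile")
}

#' Loose dataset-relative threshold profile
#'
#' Builds a stage-1 profile keeping frames above the `pct` quantile of each
#' detail indicator (clarity, sharpness, entropy) and below the
#' `1 - pct` quantile of co-occurrence energy (near-constant frames score
#' maximal energy).
#'
#' @param scores data.frame from [scoreFrames()].
#' @param pct loose quantile (default 0.05).
#' @return a [thresholdProfile()].
#' @export
looseProfile <- function(scores, pct = 0.05) {
  q <- function(v, p) as.numeric(stats::quantile(v, p, names = FALSE))
  thresholdProfile(list(
    clarity = c(min = q(scores$clarity, pct)),
    sharpness = c(min = q(scores$sharpness, pct)),
    entropy = c(min = q(scores$entropy, pct)),
    energy = c(max = q(scores$energy, 1 - pct))))
}

failedBounds <- function(row, bounds) {
  bad <- character()
  for (ind in names(bounds)) {
    v <- row[[ind]]
    b <- bounds[[ind]]
    if (!is.na(b["min"]) && v < b["min"]) bad <- c(bad, ind)
    else if (!is.na(b["max"]) && v > b["max"]) bad <- c(bad, ind)
  }
  bad
}

#' Two-stage quality filtering of scored frames
#'
#' Stage 1 drops frames failing any loose bound; stage 2 applies the
#' frame's subset-specific bounds.  The returned audit table records, for
#' every dropped frame, the rejection stage and the failing indicator(s).
#'
#' @param scores data.frame from [scoreFrames()]; column `sharpness` is
#'   matched against the `sharpness` bound, and so on.
#' @param profile a [thresholdProfile()].
#' @param subset character vector (recycled) naming each frame's subset
#'   for stage 2; subsets without stage-2 bounds fall back to stage 1 only.
#' @return `scores` with added columns `kept`, `stage`, `reason`.
#' @export
twoStageFilter <- function(scores, profile, subset = "default") {
  stopifnot(inherits(profile, "thresholdProfile"))
  subset <- rep_len(subset, nrow(scores))
  unknown <- setdiff(unique(subset),
                     c("default", names(profile$stage2)))
  if (length(profile$stage2) && length(unknown))
    pkStop(paste("unknown subset id:", paste(unknown, collapse = ", ")),
           "podkitInvalidConfig")
  kept <- logical(nrow(scores)); stage <- integer(nrow(scores))
  reason <- character(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    row <- scores[i, ]
    bad <- failedBounds(row, profile$stage1)
    if (length(bad)) {
      kept[i] <- FALSE; stage[i] <- 1L; reason[i] <- paste(bad, collapse = "+")
      next
    }
    b2 <- profile$stage2[[subset[i]]]
    if (!is.null(b2)) {
      bad <- failedBounds(row, b2)
      if (length(bad)) {
        kept[i] <- FALSE; stage[i] <- 2L; reason[i] <- paste(bad, collapse = "+")
        next
      }
    }
    kept[i] <- TRUE; stage[i] <- 0L; reason[i] <- ""
  }
  scores$kept <- kept; scores$stage <- stage; scores$reason <- reason
  scores
}
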