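# Prototype-coefficient mask assembly, postprocessing at the inference
# settings, and instance-segmentation evaluation.

#' Create a prototype bundle
#' @param planes numeric array `k x h x w` (or a single `h x w` matrix).
#' @return a [PrototypeBundle-class].
#' @export
prototypeBundle <- function(planes) {
  if (is.matrix(planes)) planes <- array(planes, c(1L, dim(planes)))
  new("PrototypeBundle", planes = planes)
}

#' @rdname planes
#' @export
setMethod("planes", "PrototypeBundle", function(object) object@planes)

#' Create an instance prediction set
#'
#' @param boxes numeric `n x 4` matrix of half-open, 0-based pixel boxes
#'   (`x1`, `y1`, `x2`, `y2`).
#' @param confidence numeric vector in `[0, 1]`.
#' @param coefficients numeric `n x k` prototype coefficient matrix.
#' @param image_size integer `c(h, w)`.
#' @param masks optional list of logical matrices.
#' @return an [InstancePredictionSet-class].
#' @export
instancePredictions <- function(boxes, confidence, coefficients, image_size,
                                masks = list()) {
  boxes <- matrix(as.numeric(boxes), ncol = 4L,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  if (!is.matrix(coefficients)) coefficients <- matrix(coefficients, nrow = nrow(boxes))
  new("InstancePredictionSet", boxes = boxes, confidence = as.numeric(confidence),
      coefficients = coefficients, masks = masks,
      image_size = as.integer(image_size))
}

#' @rdname nInstances
#' @export
setMethod("nInstances", "InstancePredictionSet", function(object) nrow(object@boxes))

setMethod("show", "InstancePredictionSet", function(object) {
  cat(sprintf("InstancePredictionSet: %d instances on %dx%d image (%s masks)\n",
              nInstances(object), object@image_size[1], object@image_size[2],
              if (length(object@masks)) "with" else "no"))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: precision %.3f  recall %.3f  mAP@50 %.3f  mAP@50-95 %.3f\n",
              object@precision, object@recall, object@map50, object@map50_95))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: TP %d  FP %d  FN %d\n", object@tp, object@fp, object@fn))
})

#' Coerce an evaluation report to a one-row data frame
#'
#' Convenient for CSV or JSON export of [evaluateInstances()] results.
#'
#' @param x an [EvalReport-class].
#' @param row.names,optional,... passed through for generic compatibility.
#' @return one-row data.frame with `precision`, `recall`, `map50`, `map50_95`.
#' @export
as.data.frame.EvalReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(precision = x@precision, recall = x@recall,
             map50 = x@map50, map50_95 = x@map50_95)
}

#' Postprocessing configuration for raw predictions
#'
#' Defaults follow the inference settings used throughout: confidence 0.3,
#' IoU 0.5 and mask binarisation at 0.5 (strictly greater-than).
#'
#' @param conf_threshold minimum retained confidence, in `(0, 1)`.
#' @param iou_threshold non-maximum-suppression box IoU threshold.
#' @param mask_binarize_threshold logistic-mask binarisation threshold.
#' @return a named list of class `postprocessConfig`.
#' @export
postprocessConfig <- function(conf_threshold = 0.3, iou_threshold = 0.5,
                              mask_binarize_threshold = 0.5) {
  v <- c(conf_threshold, iou_threshold, mask_binarize_threshold)
  if (any(v <= 0) || any(v >= 1))
    pkStop("postprocess thresholds must lie in (0, 1)", "podkitInvalidConfig")
  structure(list(conf_threshold = conf_threshold, iou_threshold = iou_threshold,
                 mask_binarize_threshold = mask_binarize_threshold),
            class = "postprocessConfig")
}

#' Assemble instance masks from prototypes and coefficients
#'
#' For each instance the per-pixel mask logit is the linear combination of
#' the prototype planes weighted by the instance's coefficients; the
#' logistic transform of the logit map is cropped to the instance box
#' (pixels outside are zeroed) and binarised strictly above
#' `cfg$mask_binarize_threshold`.
#'
#' @param protos a [PrototypeBundle-class] whose planes match the image size.
#' @param preds an [InstancePredictionSet-class] with `k` coefficients per
#'   instance.
#' @param cfg a [postprocessConfig()].
#' @return the prediction set with the `masks` slot filled (logical
#'   matrices).
#' @export
assembleInstanceMasks <- function(protos, preds, cfg = postprocessConfig()) {
  pl <- planes(protos)
  k <- dim(pl)[1]; h <- dim(pl)[2]; w <- dim(pl)[3]
  if (ncol(preds@coefficients) != k)
    pkStop(sprintf("coefficient length (%d) does not match prototype count (%d)",
                   ncol(preds@coefficients), k), "podkitConstraintViolation")
  pm <- matrix(pl, nrow = k)          # k x (h*w)
  masks <- vector("list", nInstances(preds))
  for (i in seq_len(nInstances(preds))) {
    logit <- matrix(as.numeric(preds@coefficients[i, ] %*% pm), h, w)
    prob <- logistic(logit)
    bx <- preds@boxes[i, ]
    keep <- matrix(FALSE, h, w)
    rows <- seq_len(h) - 1L   # 0-based pixel indices (y)
    cols <- seq_len(w) - 1L   # (x)
    rsel <- rows >= bx[2] & rows < bx[4]
    csel <- cols >= bx[1] & cols < bx[3]
    keep[rsel, csel] <- TRUE
    masks[[i]] <- keep & (prob > cfg$mask_binarize_threshold)
  }
  preds@masks <- masks
  validObject(preds)
  preds
}

boxIoU <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}

#' Filter raw predictions by confidence and non-maximum suppression
#'
#' Drops predictions below the confidence threshold, then applies greedy
#' non-maximum suppression on boxes in order of descending confidence
#' (ties broken by input index).
#'
#' @param preds an [InstancePredictionSet-class].
#' @param cfg a [postprocessConfig()].
#' @return the retained subset, ordered by descending confidence.
#' @export
postprocess <- function(preds, cfg = postprocessConfig()) {
  keep <- which(preds@confidence >= cfg$conf_threshold)
  ord <- keep[order(-preds@confidence[keep], keep)]
  retained <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in retained) {
      if (boxIoU(preds@boxes[i, ], preds@boxes[j, ]) > cfg$iou_threshold) {
        ok <- FALSE; break
      }
    }
    if (ok) retained <- c(retained, i)
  }
  subsetPredictions(preds, retained)
}

subsetPredictions <- function(preds, idx) {
  instancePredictions(preds@boxes[idx, , drop = FALSE],
                      preds@confidence[idx],
                      preds@coefficients[idx, , drop = FALSE],
                      preds@image_size,
                      if (length(preds@masks)) preds@masks[idx] else list())
}

#' Mask intersection-over-union
#'
#' @param a,b logical (or 0/1) matrices of identical shape.
#' @return `|a & b| / |a | b|`; defined as 1 when both masks are empty.
#' @examples
#' maskIoU(diag(3) > 0, diag(3) > 0)
#' @export
maskIoU <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    pkStop("mask shapes differ", "podkitShapeMismatch")
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1.0)
  sum(a & b) / u
}

#' Greedy one-to-one matching of predictions against ground truth
#'
#' Predictions are visited in order of descending confidence (ties by
#' input index); each claims the unmatched ground-truth instance of
#' highest mask IoU at or above the threshold (IoU ties by truth index).
#' Unmatched predictions are false positives, unmatched truths false
#' negatives.
#'
#' @param pred_masks list of logical matrices (predicted masks).
#' @param confidence numeric vector parallel to `pred_masks`.
#' @param truth_masks list of logical matrices (ground truth).
#' @param iou_threshold minimum IoU for a match.
#' @return a [MatchResult-class].
#' @export
matchInstances <- function(pred_masks, confidence, truth_masks,
                           iou_threshold = 0.5) {
  np <- length(pred_masks); nt <- length(truth_masks)
  ord <- order(-confidence, seq_len(np))
  matched <- rep(FALSE, nt)
  pairs <- data.frame(pred = integer(), truth = integer(), iou = numeric())
  for (i in ord) {
    best <- 0; bestj <- 0L
    for (j in seq_len(nt)) {
      if (matched[j]) next
      v <- maskIoU(pred_masks[[i]], truth_masks[[j]])
      if (v >= iou_threshold && v > best) { best <- v; bestj <- j }
    }
    if (bestj > 0L) {
      matched[bestj] <- TRUE
      pairs <- rbind(pairs, data.frame(pred = i, truth = bestj, iou = best))
    }
  }
  tp <- nrow(pairs)
  new("MatchResult", tp = as.integer(tp), fp = as.integer(np - tp),
      fn = as.integer(nt - tp), pairs = pairs)
}

# Flags TP/FP for every prediction across a dataset at one IoU threshold,
# in global descending-confidence order.
apFlags <- function(preds, truths, iou_threshold) {
  recs <- data.frame(img = integer(), conf = numeric(), idx = integer())
  for (m in seq_along(preds)) {
    p <- preds[[m]]
    if (length(p$masks))
      recs <- rbind(recs, data.frame(img = m, conf = p$confidence,
                                     idx = seq_along(p$masks)))
  }
  ngt <- sum(vapply(truths, length, integer(1)))
  if (nrow(recs) == 0L)
    return(list(tp = logical(0), ngt = ngt))
  recs <- recs[order(-recs$conf, recs$img, recs$idx), ]
  matched <- lapply(truths, function(t) rep(FALSE, length(t)))
  tp <- logical(nrow(recs))
  for (r in seq_len(nrow(recs))) {
    m <- recs$img[r]
    pm <- preds[[m]]$masks[[recs$idx[r]]]
    best <- 0; bestj <- 0L
    tm <- truths[[m]]
    for (j in seq_along(tm)) {
      if (matched[[m]][j]) next
      v <- maskIoU(pm, tm[[j]])
      if (v >= iou_threshold && v > best) { best <- v; bestj <- j }
    }
    if (bestj > 0L) { matched[[m]][bestj] <- TRUE; tp[r] <- TRUE }
  }
  list(tp = tp, ngt = ngt)
}

#' Average precision over a dataset at one IoU threshold
#'
#' Computes the 101-point interpolated area under the confidence-ranked
#' precision-recall curve (`interpolation = "101"`), or the all-point
#' envelope area (`"all"`).
#'
#' @param preds list (one element per image) of `list(masks =, confidence =)`.
#' @param truths list (one element per image) of lists of logical masks.
#' @param iou_threshold mask IoU required for a true positive.
#' @param interpolation `"101"` (default) or `"all"`.
#' @return AP in `[0, 1]`.
#' @export
averagePrecision <- function(preds, truths, iou_threshold = 0.5,
                             interpolation = c("101", "all")) {
  interpolation <- match.arg(interpolation)
  fl <- apFlags(preds, truths, iou_threshold)
  if (fl$ngt == 0L)
    pkStop("average precision is undefined with zero ground-truth instances",
           "podkitUndefinedMetric")
  if (!length(fl$tp)) return(0.0)
  ctp <- cumsum(fl$tp); cfp <- cumsum(!fl$tp)
  prec <- ctp / (ctp + cfp)
  rec <- ctp / fl$ngt
  if (interpolation == "101") {
    grid <- seq(0, 1, by = 0.01)
    ap <- mean(vapply(grid, function(r) {
      sel <- rec >= r
      if (any(sel)) max(prec[sel]) else 0
    }, numeric(1)))
  } else {
    # precision envelope, exact area
    mrec <- c(0, rec, 1)
    mpre <- c(1, prec, 0)
    for (i in rev(seq_len(length(mpre) - 1))) mpre[i] <- max(mpre[i], mpre[i + 1])
    ii <- which(diff(mrec) > 0)
    ap <- sum((mrec[ii + 1] - mrec[ii]) * mpre[ii + 1])
  }
  ap
}

#' Evaluate instance segmentation over a dataset
#'
#' Precision and recall are computed from greedy matching at
#' `iou_threshold`; `map50` is the average precision at IoU 0.5 and
#' `map50_95` the mean over IoU 0.50 to 0.95 in steps of 0.05.
#'
#' @inheritParams averagePrecision
#' @param iou_threshold IoU used for the precision/recall counts.
#' @return an [EvalReport-class].
#' @export
evaluateInstances <- function(preds, truths, iou_threshold = 0.5) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (m in seq_along(preds)) {
    mr <- matchInstances(preds[[m]]$masks, preds[[m]]$confidence,
                         truths[[m]], iou_threshold)
    tp <- tp + mr@tp; fp <- fp + mr@fp; fn <- fn + mr@fn
  }
  map50 <- averagePrecision(preds, truths, 0.5)
  maps <- vapply(seq(0.5, 0.95, by = 0.05), function(t)
    averagePrecision(preds, truths, t), numeric(1))
  new("EvalReport",
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      map50 = map50, map50_95 = mean(maps))
}
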