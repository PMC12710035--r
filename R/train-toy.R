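# A deliberately small, pure-R trainable stand-in for the full network:
# fixed per-pixel features feed trainable linear heads for objectness, box
# geometry, prototype planes and mask coefficients.  It exists so the
# prototype-coefficient mask pathway and the evaluator can be exercised
# end to end on synthetic scenes; it makes no claim of replicating any
# full-scale training recipe.

sameConv3 <- function(m, kern) {
  h <- nrow(m); w <- ncol(m)
  pad <- m[c(1L, seq_len(h), h), c(1L, seq_len(w), w)]
  out <- matrix(0, h, w)
  for (i in 1:3) for (j in 1:3) {
    if (kern[i, j] == 0) next
    out <- out + kern[i, j] * pad[(i - 1L) + seq_len(h), (j - 1L) + seq_len(w)]
  }
  out
}

# fixed feature stack: colour channels, grayscale, blurred grayscale,
# gradient magnitude, bias
toyFeatures <- function(image) {
  g <- toGray(image)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- sameConv3(g, sx); gy <- sameConv3(g, t(sx))
  cbind(as.numeric(image[, , 1]), as.numeric(image[, , 2]),
        as.numeric(image[, , 3]), as.numeric(g),
        as.numeric(gaussianBlur(g, 2)),
        as.numeric(sqrt(gx^2 + gy^2)), 1)
}

poolCells <- function(Fm, h, w, stride) {
  ch <- h %/% stride; cw <- w %/% stride
  D <- ncol(Fm)
  Fc <- matrix(0, ch * cw, D)
  pix <- matrix(seq_len(h * w), h, w)
  for (cy in seq_len(ch)) for (cx in seq_len(cw)) {
    rows <- ((cy - 1L) * stride + 1L):(cy * stride)
    cols <- ((cx - 1L) * stride + 1L):(cx * stride)
    Fc[(cx - 1L) * ch + cy, ] <- colMeans(Fm[as.numeric(pix[rows, cols]), , drop = FALSE])
  }
  Fc
}

cellOf <- function(cx, cy, h, w, stride) {
  ch <- h %/% stride
  icx <- clamp(floor(cx / stride), 0, (w %/% stride) - 1L)
  icy <- clamp(floor(cy / stride), 0, ch - 1L)
  icx * ch + icy + 1L
}

cellCenter <- function(idx, h, stride) {
  ch <- h %/% stride
  icx <- (idx - 1L) %/% ch; icy <- (idx - 1L) %% ch
  c((icx + 0.5) * stride, (icy + 0.5) * stride)  # (x, y)
}

toySceneTargets <- function(anns, h, w, stride) {
  nc_ <- (h %/% stride) * (w %/% stride)
  obj <- rep(0, nc_)
  assign <- rep(NA_integer_, nc_)
  tb <- matrix(0, nc_, 4)
  for (i in seq_along(anns)) {
    bx <- anns[[i]]$box
    cx <- (bx[1] + bx[3]) / 2; cy <- (bx[2] + bx[4]) / 2
    cell <- cellOf(cx, cy, h, w, stride)
    if (!is.na(assign[cell])) next
    obj[cell] <- 1
    assign[cell] <- i
    cc <- cellCenter(cell, h, stride)
    tb[cell, ] <- c((cx - cc[1]) / stride, (cy - cc[2]) / stride,
                    log(max(bx[3] - bx[1], 1) / stride),
                    log(max(bx[4] - bx[2], 1) / stride))
  }
  list(obj = obj, assign = assign, tb = tb)
}

#' Train the toy prototype-coefficient segmenter
#'
#' Stochastic gradient descent on a composite loss: binary cross-entropy on
#' cell objectness, squared error on box geometry at positive cells
#' (centre-based assignment), and per-instance binary cross-entropy between
#' the assembled logistic mask and the ground-truth mask.  Each step draws
#' one scene and applies a random augmentation (flip / rotation / crop
#' combinations).  Deterministic given `seed`.
#'
#' @param scenes list of [SyntheticScene-class] objects (each with at least
#'   one instance).
#' @param steps gradient steps (>= 1).
#' @param seed integer seed.
#' @param k number of toy prototype planes.
#' @param stride candidate grid stride in pixels.
#' @param lr learning rate.
#' @param augment_prob probability of augmenting the drawn scene.
#' @return an object of class `toyModel`: weights, config and `loss_trace`
#'   (one composite loss per step).
#' @export
trainToy <- function(scenes, steps = 300, seed = 0, k = 6, stride = 8,
                     lr = 1.0, augment_prob = 0.5) {
  if (!length(scenes)) pkStop("empty scene set", "podkitInvalidConfig")
  if (steps < 1) pkStop("steps must be >= 1", "podkitInvalidConfig")
  for (s in scenes) if (!length(s@annotations))
    pkStop("every training scene needs at least one instance", "podkitInvalidConfig")
  D <- 7L
  withSeed(seed, {
    Wp <- matrix(stats::rnorm(D * k, sd = 0.05), D, k)
    Wc <- matrix(stats::rnorm(D * k, sd = 0.05), D, k)
    wo <- stats::rnorm(D, sd = 0.05)
    Wb <- matrix(0, D, 4)
    loss_trace <- numeric(steps)
    order_ <- sample(rep_len(seq_along(scenes), steps))
    for (step in seq_len(steps)) {
      sc <- scenes[[order_[step]]]
      img <- sc@image; anns <- sc@annotations
      if (stats::runif(1) < augment_prob) {
        ops <- sample(c("flip-h", "flip-v", "rotate"),
                      size = sample(1:2, 1))
        aug <- augment(img, anns, ops = ops, seed = stats::runif(1, 0, 1e6))
        if (length(aug$annotations)) { img <- aug$image; anns <- aug$annotations }
      }
      h <- dim(img)[1]; w <- dim(img)[2]
      Fm <- toyFeatures(img)
      Fc <- poolCells(Fm, h, w, stride)
      tg <- toySceneTargets(anns, h, w, stride)
      npos <- max(1, sum(tg$obj))
      ## objectness (class-balanced: positive cells are rare)
      po <- logistic(as.numeric(Fc %*% wo))
      wts <- ifelse(tg$obj > 0, nrow(Fc) / (2 * npos),
                    nrow(Fc) / (2 * max(1, nrow(Fc) - npos)))
      eo <- wts * (po - tg$obj)
      lobj <- -mean(wts * (tg$obj * log(po + 1e-9) +
                           (1 - tg$obj) * log(1 - po + 1e-9)))
      gwo <- as.numeric(t(Fc) %*% eo) / nrow(Fc)
      ## box regression at positive cells
      pos <- which(tg$obj > 0)
      pb <- Fc %*% Wb
      eb <- matrix(0, nrow(Fc), 4)
      eb[pos, ] <- pb[pos, , drop = FALSE] - tg$tb[pos, , drop = FALSE]
      lbox <- sum(eb^2) / (2 * npos)
      gWb <- t(Fc) %*% eb / npos
      ## prototype masks + coefficients at positive cells; the per-instance
      ## loss is cropped to the (slightly dilated) instance box so that
      ## other instances outside it do not supply conflicting supervision
      P <- Fm %*% Wp                      # pixels x k
      gWp <- matrix(0, D, k); gWc <- matrix(0, D, k)
      lmask <- 0
      for (cell in pos) {
        i <- tg$assign[cell]
        bx <- anns[[i]]$box
        r0 <- clamp(floor(bx[2]) - 2, 0, h - 1); r1 <- clamp(ceiling(bx[4]) + 1, 1, h)
        c0 <- clamp(floor(bx[1]) - 2, 0, w - 1); c1 <- clamp(ceiling(bx[3]) + 1, 1, w)
        idx <- as.numeric(outer((r0 + 1):r1, (c0:(c1 - 1)) * h, `+`))
        y <- as.numeric(anns[[i]]$mask)[idx]
        cc <- as.numeric(Fc[cell, ] %*% Wc)
        Pi <- P[idx, , drop = FALSE]
        pm <- logistic(as.numeric(Pi %*% cc))
        lmask <- lmask + -mean(y * log(pm + 1e-9) + (1 - y) * log(1 - pm + 1e-9))
        e <- (pm - y) / length(y)
        gWp <- gWp + t(Fm[idx, , drop = FALSE]) %*% (e %o% cc)
        gWc <- gWc + Fc[cell, ] %o% as.numeric(t(Pi) %*% e)
      }
      lmask <- lmask / npos
      gWp <- gWp / npos; gWc <- gWc / npos
      loss_trace[step] <- lobj + lbox + lmask
      clip <- function(g, lim = 3) {
        nrm <- sqrt(sum(g^2))
        if (is.finite(nrm) && nrm > lim) g * (lim / nrm) else g
      }
      wo <- wo - lr * 4 * clip(gwo)
      Wb <- Wb - lr * 0.5 * clip(gWb)
      Wp <- Wp - lr * 2 * clip(gWp)
      Wc <- Wc - lr * 2 * clip(gWc)
    }
    structure(list(Wp = Wp, Wc = Wc, wo = wo, Wb = Wb, k = k,
                   stride = stride, loss_trace = loss_trace, seed = seed),
              class = "toyModel")
  })
}

#' Predict instances with the toy segmenter
#'
#' @param model a `toyModel` from [trainToy()].
#' @param image numeric `h x w x 3` array.
#' @param cfg a [postprocessConfig()] (confidence and NMS thresholds).
#' @return an [InstancePredictionSet-class] with assembled masks.
#' @export
predictToy <- function(model, image, cfg = postprocessConfig()) {
  h <- dim(image)[1]; w <- dim(image)[2]
  Fm <- toyFeatures(image)
  Fc <- poolCells(Fm, h, w, model$stride)
  conf <- logistic(as.numeric(Fc %*% model$wo))
  keep <- which(conf >= cfg$conf_threshold)
  if (!length(keep)) {
    return(instancePredictions(matrix(numeric(0), 0, 4), numeric(0),
                               matrix(numeric(0), 0, model$k), c(h, w)))
  }
  tb <- Fc[keep, , drop = FALSE] %*% model$Wb
  tb[, 1:2] <- clamp(tb[, 1:2], -2, 2)
  tb[, 3:4] <- clamp(tb[, 3:4], -2, 4)
  boxes <- t(vapply(seq_along(keep), function(ii) {
    cc <- cellCenter(keep[ii], h, model$stride)
    cx <- cc[1] + tb[ii, 1] * model$stride
    cy <- cc[2] + tb[ii, 2] * model$stride
    bw <- exp(tb[ii, 3]) * model$stride
    bh <- exp(tb[ii, 4]) * model$stride
    c(clamp(cx - bw / 2, 0, w - 1), clamp(cy - bh / 2, 0, h - 1),
      clamp(cx + bw / 2, 1, w), clamp(cy + bh / 2, 1, h))
  }, numeric(4)))
  boxes[, 3] <- pmax(boxes[, 3], boxes[, 1] + 1)
  boxes[, 4] <- pmax(boxes[, 4], boxes[, 2] + 1)
  coef <- Fc[keep, , drop = FALSE] %*% model$Wc
  protos <- prototypeBundle(array(t(Fm %*% model$Wp), c(model$k, h, w)))
  ## assemble inside dilated boxes, tighten each box to its mask extent
  ## (duplicate candidates then collapse onto the same box), then suppress
  bw <- boxes[, 3] - boxes[, 1]; bh <- boxes[, 4] - boxes[, 2]
  dil <- cbind(clamp(boxes[, 1] - 0.3 * bw, 0, w - 1),
               clamp(boxes[, 2] - 0.3 * bh, 0, h - 1),
               clamp(boxes[, 3] + 0.3 * bw, 1, w),
               clamp(boxes[, 4] + 0.3 * bh, 1, h))
  tmp <- assembleInstanceMasks(
    protos, instancePredictions(dil, conf[keep], coef, c(h, w)), cfg)
  refined <- t(vapply(seq_along(tmp@masks), function(i) {
    bb <- maskBox(tmp@masks[[i]])
    if (bb[3] > bb[1] && bb[4] > bb[2]) bb else boxes[i, ]
  }, numeric(4)))
  preds <- instancePredictions(refined, conf[keep], coef, c(h, w),
                               masks = tmp@masks)
  postprocess(preds, cfg)
}

#' Evaluate the toy segmenter on held-out scenes
#'
#' @param model a `toyModel`.
#' @param scenes list of [SyntheticScene-class] objects.
#' @param cfg a [postprocessConfig()].
#' @return an [EvalReport-class].
#' @export
evalToy <- function(model, scenes, cfg = postprocessConfig()) {
  preds <- list(); truths <- list()
  for (i in seq_along(scenes)) {
    p <- predictToy(model, scenes[[i]]@image, cfg)
    preds[[i]] <- list(masks = p@masks, confidence = p@confidence)
    truths[[i]] <- lapply(scenes[[i]]@annotations, `[[`, "mask")
  }
  evaluateInstances(preds, truths, cfg$iou_threshold)
}

#' @export
print.toyModel <- function(x, ...) {
  cat(sprintf("toyModel: k=%d prototypes, stride %d, %d training steps, final loss %.4f\n",
              x$k, x$stride, length(x$loss_trace),
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}
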