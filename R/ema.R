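# Efficient multiscale attention (EMA): channel-to-batch grouped attention
# with parallel 1x1 and 3x3 branches and cross-spatial weighting, applied
# without channel dimensionality reduction.

sigmoidv <- function(x) 1 / (1 + exp(-x))
softmaxv <- function(x) { e <- exp(x - max(x)); e / sum(e) }

#' Initialise EMA block weights
#'
#' Deterministic Gaussian initialisation of the per-group 1x1 and 3x3
#' convolution kernels and the group-norm affine parameters.
#'
#' @param channels input channel count.
#' @param groups channel-to-batch group count; must divide `channels`.
#' @param seed integer seed.
#' @return list of weights (`w1`, `b1`, `w3`, `b3`, `gamma`, `beta`).
#' @export
emaInit <- function(channels, groups = 32, seed = 0) {
  if (channels %% groups != 0)
    pkStop(sprintf("channels (%d) not divisible by groups (%d)", channels, groups),
           "podkitInvalidConfig")
  cg <- channels %/% groups
  r <- withSeed(seed, {
    list(w1 = matrix(rnorm(cg * cg, sd = 0.3), cg, cg),
         b1 = rnorm(cg, sd = 0.1),
         w3 = array(rnorm(cg * cg * 9, sd = 0.2), c(cg, cg, 3, 3)),
         b3 = rnorm(cg, sd = 0.1),
         gamma = rep(1, cg), beta = rep(0, cg))
  })
  r
}

conv3x3same <- function(x, w, b) {
  # x: (c_in, h, w); w: (c_out, c_in, 3, 3); 'same' replicate padding, so a
  # constant input yields a constant response (spatial-uniformity contract)
  d <- dim(x); ci <- d[1]; h <- d[2]; wd <- d[3]
  co <- dim(w)[1]
  out <- matrix(rep(b, h * wd), co, h * wd)
  for (di in -1:1) for (dj in -1:1) {
    ri <- clamp(seq_len(h) + di, 1, h)     # cross-correlation orientation
    rj <- clamp(seq_len(wd) + dj, 1, wd)
    xs <- x[, ri, rj, drop = FALSE]
    out <- out + w[, , di + 2, dj + 2, drop = FALSE][, , 1, 1] %*%
      matrix(xs, ci, h * wd)
  }
  array(out, c(co, h, wd))
}

groupNormPerChannel <- function(x, gamma, beta, eps = 1e-5) {
  # group-norm with one group per channel (instance normalisation + affine)
  d <- dim(x)
  for (c in seq_len(d[1])) {
    v <- x[c, , ]
    mu <- mean(v); va <- mean((v - mu)^2)
    x[c, , ] <- gamma[c] * (v - mu) / sqrt(va + eps) + beta[c]
  }
  x
}

#' EMA attention forward pass
#'
#' Applies the efficient multiscale attention block to a `c x h x w`
#' feature map: channels are reshaped into groups, a 1x1 branch acts on
#' pooled height/width profiles, a 3x3 branch acts spatially, and the two
#' are fused by cross-spatial weighting.  Output shape equals input shape;
#' no channel dimensionality reduction occurs.
#'
#' @param x numeric array `c x h x w`.
#' @param groups group count; must divide `c`.
#' @param weights optional weight list from [emaInit()]; created from
#'   `seed` when missing.
#' @param seed seed for default weights.
#' @return numeric array of the same dimensions as `x`.
#' @examples
#' x <- array(rnorm(8 * 16 * 16), c(8, 16, 16))
#' dim(emaLayer(x, groups = 4))
#' @export
emaLayer <- function(x, groups, weights = NULL, seed = 0) {
  d <- dim(x)
  if (length(d) != 3L) pkStop("x must be a c x h x w array", "podkitInvalidConfig")
  ch <- d[1]; h <- d[2]; w <- d[3]
  if (ch %% groups != 0)
    pkStop(sprintf("channels (%d) not divisible by groups (%d)", ch, groups),
           "podkitInvalidConfig")
  cg <- ch %/% groups
  if (is.null(weights)) weights <- emaInit(ch, groups, seed)
  out <- array(0, d)
  for (g in seq_len(groups)) {
    idx <- ((g - 1) * cg + 1):(g * cg)
    xg <- x[idx, , , drop = FALSE]
    dim(xg) <- c(cg, h, w)
    ## 1x1 branch on pooled height/width profiles
    ph <- apply(xg, c(1, 2), mean)                  # (cg, h)
    pw <- apply(xg, c(1, 3), mean)                  # (cg, w)
    hw <- weights$w1 %*% cbind(ph, pw) + weights$b1 # (cg, h + w)
    ah <- sigmoidv(hw[, seq_len(h), drop = FALSE])
    aw <- sigmoidv(hw[, h + seq_len(w), drop = FALSE])
    x1 <- xg
    for (c in seq_len(cg))
      x1[c, , ] <- xg[c, , ] * outer(ah[c, ], aw[c, ])
    x1 <- groupNormPerChannel(x1, weights$gamma, weights$beta)
    ## 3x3 branch
    x2 <- conv3x3same(xg, weights$w3, weights$b3)
    ## cross-spatial fusion
    s1 <- softmaxv(apply(x1, 1, mean))              # (cg)
    s2 <- softmaxv(apply(x2, 1, mean))
    m1 <- as.numeric(s1 %*% matrix(x2, cg, h * w))
    m2 <- as.numeric(s2 %*% matrix(x1, cg, h * w))
    wmap <- sigmoidv(matrix(m1 + m2, h, w))
    for (c in seq_len(cg))
      out[idx[c], , ] <- xg[c, , ] * wmap
  }
  out
}
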