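# Straight-loop re-implementation of the EMA block, kept deliberately
# naive (explicit per-group, per-channel, per-pixel loops) as an
# independent oracle for the vectorised implementation.
emaOracle <- function(x, groups, wts) {
  d <- dim(x); ch <- d[1]; h <- d[2]; w <- d[3]
  cg <- ch %/% groups
  sig <- function(v) 1 / (1 + exp(-v))
  out <- array(0, d)
  for (g in seq_len(groups)) {
    xg <- array(0, c(cg, h, w))
    for (c in seq_len(cg)) xg[c, , ] <- x[(g - 1) * cg + c, , ]
    ph <- matrix(0, cg, h); pw <- matrix(0, cg, w)
    for (c in seq_len(cg)) {
      for (i in seq_len(h)) ph[c, i] <- mean(xg[c, i, ])
      for (j in seq_len(w)) pw[c, j] <- mean(xg[c, , j])
    }
    # 1x1 conv over the concatenated (h + w) profile
    hw <- matrix(0, cg, h + w)
    for (co in seq_len(cg)) for (p in seq_len(h + w)) {
      acc <- wts$b1[co]
      for (ci in seq_len(cg))
        acc <- acc + wts$w1[co, ci] * (if (p <= h) ph[ci, p] else pw[ci, p - h])
      hw[co, p] <- acc
    }
    x1 <- array(0, c(cg, h, w))
    for (c in seq_len(cg)) for (i in seq_len(h)) for (j in seq_len(w))
      x1[c, i, j] <- xg[c, i, j] * sig(hw[c, i]) * sig(hw[c, h + j])
    for (c in seq_len(cg)) {
      v <- as.numeric(x1[c, , ])
      mu <- mean(v); va <- mean((v - mu)^2)
      x1[c, , ] <- wts$gamma[c] * (x1[c, , ] - mu) / sqrt(va + 1e-5) + wts$beta[c]
    }
    # 3x3 conv, replicate padded
    x2 <- array(0, c(cg, h, w))
    for (co in seq_len(cg)) for (i in seq_len(h)) for (j in seq_len(w)) {
      acc <- wts$b3[co]
      for (ci in seq_len(cg)) for (di in -1:1) for (dj in -1:1) {
        ii <- min(max(i + di, 1), h); jj <- min(max(j + dj, 1), w)
        acc <- acc + wts$w3[co, ci, di + 2, dj + 2] * xg[ci, ii, jj]
      }
      x2[co, i, j] <- acc
    }
    sm <- function(m) { a <- numeric(cg)
      for (c in seq_len(cg)) a[c] <- mean(m[c, , ])
      e <- exp(a - max(a)); e / sum(e) }
    s1 <- sm(x1); s2 <- sm(x2)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      m1 <- 0; m2 <- 0
      for (c in seq_len(cg)) {
        m1 <- m1 + s1[c] * x2[c, i, j]
        m2 <- m2 + s2[c] * x1[c, i, j]
      }
      wm <- sig(m1 + m2)
      for (c in seq_len(cg)) out[(g - 1) * cg + c, i, j] <- xg[c, i, j] * wm
    }
  }
  out
}


# brute-force oracle: per-pixel double loop over the assembly definition
assembleOracle <- function(planes, coefs, box, thr = 0.5) {
  k <- dim(planes)[1]; h <- dim(planes)[2]; w <- dim(planes)[3]
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    s <- 0
    for (j in seq_len(k)) s <- s + coefs[j] * planes[j, r, c]
    p <- 1 / (1 + exp(-s))
    x <- c - 1; y <- r - 1
    inside <- x >= box[1] && x < box[3] && y >= box[2] && y < box[4]
    out[r, c] <- inside && p > thr
  }
  out
}

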