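# Synthetic backdrop scenes: dense rotated-ellipse "pods" with occluding
# stems/leaves against a bright solid backdrop, plus degraded frame
# sequences for the harvesting pipeline.  A deliberate cartoon of side-view
# field imagery: geometry, occlusion, blur and noise are emulated; real
# plant texture and lighting are not.

#' Separable Gaussian blur
#'
#' @param image numeric matrix or `h x w x 3` array.
#' @param sigma Gaussian sigma in pixels; `sigma = 0` returns the input.
#' @return blurred image of the same shape (replicate-padded borders).
#' @export
gaussianBlur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  blur1 <- function(m) {
    h <- nrow(m); w <- ncol(m)
    pad <- m[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
    out <- matrix(0, h, w)
    for (i in seq_along(k)) out <- out + k[i] * pad[(i - 1L) + seq_len(h), , drop = FALSE]
    pad <- out[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
    out2 <- matrix(0, h, w)
    for (i in seq_along(k)) out2 <- out2 + k[i] * pad[, (i - 1L) + seq_len(w), drop = FALSE]
    out2
  }
  if (length(dim(image)) == 3L) {
    for (ch in seq_len(dim(image)[3])) image[, , ch] <- blur1(image[, , ch])
    image
  } else blur1(image)
}

#' Create a synthetic scene configuration
#'
#' @param image_size `c(h, w)` pixels.
#' @param n_pods number of pod instances.
#' @param axis_range `c(min_minor, max_minor, min_major, max_major)`
#'   semi-axes in pixels.
#' @param cluster_sd centre spread as a fraction of the image side.
#' @param n_occluders number of stems/leaves drawn over the pods.
#' @param allow_overlap allow pods to overlap each other.
#' @param backdrop backdrop intensity.
#' @param noise_sd additive Gaussian noise sd.
#' @param blur_sigma Gaussian blur sigma.
#' @param seed integer seed.
#' @return a [SceneConfig-class].
#' @export
sceneConfig <- function(image_size = c(160, 160), n_pods = 8,
                        axis_range = c(4, 7, 9, 16), cluster_sd = 0.22,
                        n_occluders = 3, allow_overlap = TRUE,
                        backdrop = 0.92, noise_sd = 0.01, blur_sigma = 0,
                        seed = 0) {
  new("SceneConfig", image_size = as.integer(image_size),
      n_pods = as.integer(n_pods), axis_range = as.numeric(axis_range),
      cluster_sd = as.numeric(cluster_sd), n_occluders = as.integer(n_occluders),
      allow_overlap = isTRUE(allow_overlap), backdrop = as.numeric(backdrop),
      noise_sd = as.numeric(noise_sd), blur_sigma = as.numeric(blur_sigma),
      seed = as.integer(seed))
}

# rotated ellipse with a mild low-frequency boundary wobble
ellipseMask <- function(h, w, cx, cy, a, b, theta, wobble = 0.06, phase = 0) {
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  ang <- atan2(v, u)
  lim <- 1 + wobble * sin(3 * ang + phase)
  (u / a)^2 + (v / b)^2 <= lim^2
}

paintMask <- function(img, mask, col, shade) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- clamp(col[ch] + shade[mask], 0, 1)
    img[, , ch] <- plane
  }
  img
}

#' Generate a synthetic backdrop scene
#'
#' Renders exactly `n_pods` elliptical pod instances (placement retried on
#' degenerate results), draws occluders over them, and stores the visible
#' (post-occlusion) masks as ground truth.  Bitwise deterministic for a
#' given configuration.
#'
#' @param cfg a [SceneConfig-class] from [sceneConfig()].
#' @param max_retries placement retries per pod before giving up.
#' @return a [SyntheticScene-class].
#' @examples
#' sc <- generateScene(sceneConfig(n_pods = 3, seed = 1))
#' length(sc@annotations)
#' @export
generateScene <- function(cfg, max_retries = 60) {
  validObject(cfg)
  h <- cfg@image_size[1]; w <- cfg@image_size[2]
  withSeed(cfg@seed, {
    img <- array(cfg@backdrop, c(h, w, 3))
    img[, , 1] <- img[, , 1] * 0.98   # slightly warm white board
    pods <- list()
    occupied <- matrix(FALSE, h, w)
    for (i in seq_len(cfg@n_pods)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        cx <- clamp(stats::rnorm(1, w / 2, cfg@cluster_sd * w), 2, w - 2)
        cy <- clamp(stats::rnorm(1, h / 2, cfg@cluster_sd * h), 2, h - 2)
        b <- stats::runif(1, cfg@axis_range[1], cfg@axis_range[2])
        a <- stats::runif(1, cfg@axis_range[3], cfg@axis_range[4])
        th <- stats::runif(1, 0, pi)
        m <- ellipseMask(h, w, cx, cy, a, b, th, phase = stats::runif(1, 0, 2 * pi))
        if (sum(m) < 6) next
        if (!cfg@allow_overlap && any(m & occupied)) next
        pods[[i]] <- m
        occupied <- occupied | m
        placed <- TRUE
        break
      }
      if (!placed)
        pkStop(sprintf("could not place pod %d after %d retries", i, max_retries),
               "podkitPlacementError")
    }
    # paint pods (green with per-pod tone variation and gentle shading)
    for (i in seq_along(pods)) {
      tone <- stats::runif(1, -0.08, 0.08)
      shade <- matrix(stats::rnorm(h * w, 0, 0.02), h, w)
      col <- clamp(c(0.32 + tone, 0.45 + tone, 0.16 + tone / 2), 0, 1)
      img <- paintMask(img, pods[[i]], col, shade)
    }
    # occluders: thin elongated "stems" and broad "leaves", drawn over pods
    occl <- matrix(FALSE, h, w)
    oc <- 0L
    for (j in seq_len(cfg@n_occluders)) {
      for (try in seq_len(max_retries)) {
        if (stats::runif(1) < 0.6) {  # stem: long thin ellipse
          m <- ellipseMask(h, w, stats::runif(1, 0, w), stats::runif(1, 0, h),
                           stats::runif(1, 0.3, 0.6) * max(h, w),
                           stats::runif(1, 1, 2.2),
                           stats::runif(1, 0, pi), wobble = 0)
          col <- c(0.35, 0.3, 0.12)
        } else {                      # leaf: broad blob
          m <- ellipseMask(h, w, stats::runif(1, 0, w), stats::runif(1, 0, h),
                           stats::runif(1, 8, 16), stats::runif(1, 6, 12),
                           stats::runif(1, 0, pi), wobble = 0.2,
                           phase = stats::runif(1, 0, 2 * pi))
          col <- c(0.2, 0.5, 0.18)
        }
        # an occluder may not fully hide any pod
        hides <- any(vapply(pods, function(p) !any(p & !(occl | m)), logical(1)))
        if (length(pods) && hides) next
        shade <- matrix(stats::rnorm(h * w, 0, 0.015), h, w)
        img <- paintMask(img, m, col, shade)
        occl <- occl | m
        break
      }
    }
    visible <- lapply(pods, function(p) p & !occl)
    if (cfg@blur_sigma > 0) img <- gaussianBlur(img, cfg@blur_sigma)
    if (cfg@noise_sd > 0)
      img <- clamp(img + array(stats::rnorm(length(img), 0, cfg@noise_sd), dim(img)), 0, 1)
    anns <- lapply(visible, function(m) {
      polys <- maskToPolygon(m)
      list(class_id = 0L, polygon = polys[[1]], polygons = polys,
           mask = m, box = maskBox(m))
    })
    new("SyntheticScene", image = img, annotations = anns, config = cfg)
  })
}

#' Generate a synthetic handheld-scan clip
#'
#' Renders a wide scene and pans a window across it, with per-frame
#' lateral jitter and an optional per-frame blur schedule, emulating a
#' handheld scanning video.
#'
#' @param cfg a [SceneConfig-class]; `image_size` gives the frame size.
#' @param duration clip duration in seconds.
#' @param fps frames per second.
#' @param jitter per-frame jitter sd in pixels.
#' @param speed pan speed in pixels per second.
#' @param blur_schedule optional function `sigma(t_seconds)` applied per
#'   frame.
#' @param id clip identifier.
#' @return a clip `list(fps, frames, id)` consumable by [extractFrames()].
#' @export
generateClip <- function(cfg, duration, fps, jitter = 0, speed = 8,
                         blur_schedule = NULL, id = "clip") {
  stopifnot(duration > 0, fps > 0)
  n <- floor(duration * fps)
  h <- cfg@image_size[1]; w <- cfg@image_size[2]
  span <- ceiling(speed * duration) + ceiling(3 * jitter) + 1
  wide <- sceneConfig(image_size = c(h, w + span), n_pods = cfg@n_pods,
                      axis_range = cfg@axis_range, cluster_sd = cfg@cluster_sd,
                      n_occluders = cfg@n_occluders,
                      allow_overlap = cfg@allow_overlap,
                      backdrop = cfg@backdrop, noise_sd = 0,
                      blur_sigma = 0, seed = cfg@seed)
  sc <- generateScene(wide)
  jit <- withSeed(cfg@seed + 1L, round(stats::rnorm(n, 0, jitter)))
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    t <- (i - 1) / fps
    x0 <- clamp(round(speed * t) + jit[i], 0, span - 1)
    fr <- sc@image[, (x0 + 1):(x0 + w), , drop = FALSE]
    if (!is.null(blur_schedule)) {
      s <- blur_schedule(t)
      if (s > 0) fr <- gaussianBlur(fr, s)
    }
    if (cfg@noise_sd > 0) {
      fr <- withSeed(cfg@seed + 100L + i,
        clamp(fr + array(stats::rnorm(length(fr), 0, cfg@noise_sd), dim(fr)), 0, 1))
    }
    frames[[i]] <- fr
  }
  list(fps = fps, frames = frames, id = id)
}
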