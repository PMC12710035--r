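# Polygon instance-label I/O, polygon/mask conversion, dataset splitting,
# statistics and training augmentations.
#
# Geometric convention used throughout: pixel (r, c) is 0-based and occupies
# the half-open square [c, c+1) x [r, r+1); x grows rightwards, y downwards.
# A pixel belongs to a polygon iff its centre (c + 0.5, r + 0.5) is inside
# under the even-odd rule.

#' Rasterise a polygon to a binary mask
#'
#' Even-odd scanline fill sampling pixel centres under the half-open pixel
#' convention.
#'
#' @param polygon numeric `n x 2` matrix of `(x, y)` vertices; normalized
#'   to `[0, 1]` unless `normalized = FALSE` (then pixels).
#' @param image_size integer `c(h, w)`.
#' @param normalized are the vertices normalized coordinates?
#' @return logical `h x w` matrix.
#' @examples
#' # rectangle covering exactly pixels [2,5) x [3,7): 12 pixels
#' p <- cbind(c(2, 5, 5, 2), c(3, 3, 7, 7))
#' sum(polygonToMask(p, c(10, 10), normalized = FALSE))
#' @export
polygonToMask <- function(polygon, image_size, normalized = TRUE) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L)
    pkStop("degenerate polygon (fewer than 3 vertices)", "podkitInvalidConfig")
  h <- image_size[1]; w <- image_size[2]
  px <- if (normalized) polygon[, 1] * w else polygon[, 1]
  py <- if (normalized) polygon[, 2] * h else polygon[, 2]
  n <- length(px)
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  mask <- matrix(FALSE, h, w)
  for (r in seq_len(h) - 1L) {
    y <- r + 0.5
    crosses <- (py <= y & y < y2) | (y2 <= y & y < py)
    if (!any(crosses)) next
    xs <- px[crosses] + (y - py[crosses]) *
      (x2[crosses] - px[crosses]) / (y2[crosses] - py[crosses])
    xs <- sort(xs)
    for (i in seq(1, length(xs) - 1, by = 2)) {
      a <- xs[i]; bnd <- xs[i + 1]
      c0 <- ceiling(a - 0.5); c1 <- ceiling(bnd - 0.5) - 1
      c0 <- max(c0, 0); c1 <- min(c1, w - 1L)
      if (c0 <= c1) mask[r + 1L, (c0:c1) + 1L] <- TRUE
    }
  }
  mask
}

# 4-connected component labelling
labelComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% h + 1L; c <- (p - 1L) %/% h + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] < 1L || d[1] > h || d[2] < 1L || d[2] > w) next
        q <- (d[2] - 1L) * h + d[1]
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# Trace the outer boundary of a 4-connected pixel region as a lattice
# polygon (crack following, region kept on the right of the walk).
traceBoundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  filled <- function(r, c) r >= 0L && r < h && c >= 0L && c < w && mask[r + 1L, c + 1L]
  idx <- which(mask)[1]
  r0 <- (idx - 1L) %% h; c0 <- (idx - 1L) %/% h
  # start at the top-left corner of the first pixel, moving right
  start <- c(c0, r0); dir <- c(1L, 0L)  # (dx, dy)
  pos <- start
  verts <- list(start)
  repeat {
    dx <- dir[1]; dy <- dir[2]
    # squares ahead-left / ahead-right of corner (x, y) for direction (dx, dy)
    x <- pos[1]; y <- pos[2]
    if (dx == 1L) { fl <- c(y - 1L, x); fr <- c(y, x) }
    else if (dx == -1L) { fl <- c(y, x - 1L); fr <- c(y - 1L, x - 1L) }
    else if (dy == 1L) { fl <- c(y, x); fr <- c(y, x - 1L) }
    else { fl <- c(y - 1L, x - 1L); fr <- c(y - 1L, x) }
    if (!filled(fr[1], fr[2])) {            # turn right
      dir <- c(-dy, dx)
      verts[[length(verts) + 1L]] <- pos
    } else if (filled(fl[1], fl[2])) {      # turn left
      dir <- c(dy, -dx)
      verts[[length(verts) + 1L]] <- pos
    }
    pos <- pos + dir
    if (all(pos == start) ) break
  }
  v <- do.call(rbind, verts)
  if (all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  v
}

#' Vectorise a binary mask into polygon(s)
#'
#' Each 4-connected component's outer boundary is traced along the pixel
#' lattice, giving polygons whose rasterisation reproduces the component
#' exactly (holes are not represented).
#'
#' @param mask logical matrix.
#' @param normalized return normalized coordinates (default) or pixels.
#' @return list of `n x 2` `(x, y)` vertex matrices; empty list for an
#'   empty mask.
#' @export
maskToPolygon <- function(mask, normalized = TRUE) {
  if (!any(mask)) return(list())
  lab <- labelComponents(mask)
  out <- list()
  for (i in seq_len(max(lab))) {
    poly <- traceBoundary(lab == i)
    if (normalized) {
      poly <- cbind(poly[, 1] / ncol(mask), poly[, 2] / nrow(mask))
    }
    out[[i]] <- poly
  }
  out
}

maskBox <- function(mask) {
  if (!any(mask)) return(c(0, 0, 0, 0))
  rows <- range(which(rowSums(mask) > 0)) - 1L
  cols <- range(which(colSums(mask) > 0)) - 1L
  c(cols[1], rows[1], cols[2] + 1L, rows[2] + 1L)  # half-open pixel box
}

makeAnnotation <- function(class_id, polygon, image_size) {
  mask <- polygonToMask(polygon, image_size)
  list(class_id = as.integer(class_id), polygon = polygon, mask = mask,
       box = maskBox(mask))
}

#' Read polygon-per-line instance labels
#'
#' Each line holds a class id followed by an even number (>= 6) of
#' normalized polygon coordinates `x1 y1 x2 y2 ...`.  Malformed lines are
#' reported with their line numbers.
#'
#' @param path label file path.
#' @param image_size integer `c(h, w)` of the labelled image.
#' @return list of annotations; each has `class_id`, `polygon`
#'   (normalized `n x 2`), derived `mask` (logical) and `box`
#'   (pixel, half-open).
#' @export
readLabels <- function(path, image_size) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(v) || length(v) < 7L)
      pkStop(sprintf("line %d: expected class id and >= 3 vertices", i),
             "podkitParseError")
    coords <- v[-1]
    if (length(coords) %% 2L != 0L)
      pkStop(sprintf("line %d: odd coordinate count (%d)", i, length(coords)),
             "podkitParseError")
    if (any(coords < 0) || any(coords > 1))
      pkStop(sprintf("line %d: coordinate outside [0, 1]", i), "podkitParseError")
    poly <- matrix(coords, ncol = 2L, byrow = TRUE)
    out[[i]] <- makeAnnotation(v[1], poly, image_size)
  }
  out
}

#' Write polygon-per-line instance labels
#'
#' Inverse of [readLabels()]; the round trip is lossless up to float
#' formatting (`%.6f`).
#'
#' @param annotations list of annotations (`class_id`, `polygon`).
#' @param path output path.
#' @export
writeLabels <- function(annotations, path) {
  lines <- vapply(annotations, function(a) {
    paste(c(a$class_id, sprintf("%.6f", as.numeric(t(a$polygon)))),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
}

#' Split image ids into train/validation/test sets
#'
#' Uniformly random, seed-reproducible, disjoint partition.
#'
#' @param ids character or integer vector of image ids.
#' @param sizes integer vector `c(train, val, test)` summing to
#'   `length(ids)`; defaults to the 406/47/35 split of a 488-image set.
#' @param seed integer seed.
#' @return list with `train`, `val`, `test` and `seed`.
#' @export
splitDataset <- function(ids, sizes = c(406, 47, 35), seed = 0) {
  if (sum(sizes) != length(ids))
    pkStop(sprintf("split sizes sum to %d but there are %d ids",
                   sum(sizes), length(ids)), "podkitInvalidConfig")
  perm <- withSeed(seed, sample(ids))
  list(train = perm[seq_len(sizes[1])],
       val = perm[sizes[1] + seq_len(sizes[2])],
       test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])],
       seed = as.integer(seed))
}

#' Dataset-level annotation statistics
#'
#' Per-image instance counts, instance pixel areas, and the normalized
#' bounding-box-centre density grid.
#'
#' @param dataset list with one element per image:
#'   `list(size = c(h, w), annotations = <list>)`.
#' @param grid density grid resolution (default 64).
#' @return list with `per_image_counts`, `mean_instances`, `total`,
#'   `areas` (list of per-instance pixel areas) and `density`
#'   (`grid x grid` matrix summing to `total`).
#' @export
computeStats <- function(dataset, grid = 64) {
  counts <- vapply(dataset, function(d) length(d$annotations), integer(1))
  areas <- lapply(dataset, function(d)
    vapply(d$annotations, function(a) sum(a$mask), numeric(1)))
  dens <- matrix(0, grid, grid)
  for (d in dataset) {
    h <- d$size[1]; w <- d$size[2]
    for (a in d$annotations) {
      cx <- (a$box[1] + a$box[3]) / 2 / w
      cy <- (a$box[2] + a$box[4]) / 2 / h
      col <- clamp(floor(cx * grid), 0, grid - 1L) + 1L
      row <- clamp(floor(cy * grid), 0, grid - 1L) + 1L
      dens[row, col] <- dens[row, col] + 1
    }
  }
  list(per_image_counts = counts,
       mean_instances = if (length(counts)) mean(counts) else NA_real_,
       total = sum(counts), areas = areas, density = dens)
}

flipImage <- function(img, horizontal) {
  if (length(dim(img)) == 3L) {
    if (horizontal) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    else img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  } else {
    if (horizontal) img[, rev(seq_len(ncol(img))), drop = FALSE]
    else img[rev(seq_len(nrow(img))), , drop = FALSE]
  }
}

rot90Image <- function(img, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  for (i in seq_len(k)) {
    if (length(dim(img)) == 3L) {
      img <- aperm(img, c(2, 1, 3))
      img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
    } else {
      img <- t(img)
      img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    }
  }
  img
}

#' Augment an image with its instance annotations
#'
#' Applies the requested operations (in the order crop, rotate, flips);
#' masks are transformed with the image, instances fully cropped out (or
#' reduced below `min_pixels`) are removed, and polygons are re-derived
#' from the transformed masks.  Deterministic given `seed`.
#'
#' @param image numeric image array.
#' @param annotations annotation list as from [readLabels()].
#' @param ops subset of `c("crop", "rotate", "flip-h", "flip-v")`.
#' @param seed integer seed driving the random crop window and rotation.
#' @param crop optional explicit pixel crop window `c(x1, y1, x2, y2)`
#'   (half-open); must lie inside the image.
#' @param rotate_k optional explicit number of 90-degree counter-clockwise
#'   rotations.
#' @param min_pixels minimum surviving mask area (default 3).
#' @return list with transformed `image` and `annotations`.
#' @export
augment <- function(image, annotations, ops = c("flip-h"), seed = 0,
                    crop = NULL, rotate_k = NULL, min_pixels = 3) {
  bad <- setdiff(ops, c("crop", "rotate", "flip-h", "flip-v"))
  if (length(bad))
    pkStop(paste("unknown augmentation op:", paste(bad, collapse = ", ")),
           "podkitInvalidConfig")
  h <- dim(image)[1]; w <- dim(image)[2]
  masks <- lapply(annotations, `[[`, "mask")
  img <- image
  rnd <- withSeed(seed, list(cropfrac = runif(4), k = sample(0:3, 1)))
  if ("crop" %in% ops) {
    if (is.null(crop)) {
      cw <- floor(w * (0.5 + 0.4 * rnd$cropfrac[1]))
      ch <- floor(h * (0.5 + 0.4 * rnd$cropfrac[2]))
      x1 <- floor((w - cw) * rnd$cropfrac[3])
      y1 <- floor((h - ch) * rnd$cropfrac[4])
      crop <- c(x1, y1, x1 + cw, y1 + ch)
    }
    if (crop[1] < 0 || crop[2] < 0 || crop[3] > w || crop[4] > h ||
        crop[1] >= crop[3] || crop[2] >= crop[4])
      pkStop("crop window outside image", "podkitInvalidConfig")
    rows <- (crop[2] + 1):crop[4]; cols <- (crop[1] + 1):crop[3]
    img <- if (length(dim(img)) == 3L) img[rows, cols, , drop = FALSE]
           else img[rows, cols, drop = FALSE]
    masks <- lapply(masks, function(m) m[rows, cols, drop = FALSE])
  }
  if ("rotate" %in% ops) {
    k <- if (is.null(rotate_k)) rnd$k else rotate_k
    img <- rot90Image(img, k)
    masks <- lapply(masks, rot90Image, k = k)
  }
  if ("flip-h" %in% ops) {
    img <- flipImage(img, TRUE)
    masks <- lapply(masks, flipImage, horizontal = TRUE)
  }
  if ("flip-v" %in% ops) {
    img <- flipImage(img, FALSE)
    masks <- lapply(masks, flipImage, horizontal = FALSE)
  }
  keep <- vapply(masks, function(m) sum(m) >= min_pixels, logical(1))
  anns <- mapply(function(a, m) {
    polys <- maskToPolygon(m)
    list(class_id = a$class_id, polygon = polys[[1]], polygons = polys,
         mask = m, box = maskBox(m))
  }, annotations[keep], masks[keep], SIMPLIFY = FALSE)
  list(image = img, annotations = anns)
}

#' Write annotations (or predictions) as COCO-style JSON
#'
#' Polygon segmentations in absolute pixel coordinates, one annotation per
#' instance; predictions additionally carry a `score`.
#'
#' @param dataset list per image: `list(id =, size =, annotations =)`;
#'   prediction sets may give `score` per annotation.
#' @param path output JSON path.
#' @export
writeCoco <- function(dataset, path) {
  images <- lapply(seq_along(dataset), function(i) {
    d <- dataset[[i]]
    list(id = if (is.null(d$id)) i else d$id,
         height = d$size[1], width = d$size[2])
  })
  anns <- list(); aid <- 0L
  for (i in seq_along(dataset)) {
    d <- dataset[[i]]
    for (a in d$annotations) {
      aid <- aid + 1L
      poly <- a$polygon
      seg <- as.numeric(t(cbind(poly[, 1] * d$size[2], poly[, 2] * d$size[1])))
      rec <- list(id = aid, image_id = if (is.null(d$id)) i else d$id,
                  category_id = a$class_id + 1L,
                  segmentation = list(seg),
                  bbox = c(a$box[1], a$box[2], a$box[3] - a$box[1],
                           a$box[4] - a$box[2]),
                  area = sum(a$mask))
      if (!is.null(a$score)) rec$score <- a$score
      anns[[aid]] <- rec
    }
  }
  jsonlite::write_json(
    list(images = images, annotations = anns,
         categories = list(list(id = 1L, name = "pod"))),
    path, auto_unbox = TRUE, digits = NA)
}

#' Read COCO-style polygon annotations
#'
#' @param path JSON path written by [writeCoco()] or compatible.
#' @return list per image: `list(id =, size =, annotations =)` with derived
#'   masks and boxes.
#' @export
readCoco <- function(path) {
  j <- jsonlite::read_json(path)
  imgs <- list()
  for (im in j$images) {
    imgs[[as.character(im$id)]] <-
      list(id = im$id, size = c(im$height, im$width), annotations = list())
  }
  for (a in j$annotations) {
    key <- as.character(a$image_id)
    d <- imgs[[key]]
    seg <- unlist(a$segmentation[[1]])
    poly <- cbind(seg[seq(1, length(seg), 2)] / d$size[2],
                  seg[seq(2, length(seg), 2)] / d$size[1])
    ann <- makeAnnotation(as.integer(a$category_id) - 1L, poly, d$size)
    if (!is.null(a$score)) ann$score <- a$score
    imgs[[key]]$annotations <- c(imgs[[key]]$annotations, list(ann))
  }
  unname(imgs)
}
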