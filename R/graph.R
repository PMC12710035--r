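# Graph-builder machinery: an append-only node accumulator from which a
# ModelGraph is assembled.  Nodes are appended in topological order, so the
# DAG property holds by construction and is re-checked by the class validity.

newGraphBuilder <- function(input_size, meta = list()) {
  b <- new.env(parent = emptyenv())
  b$rows <- list()
  b$inputs <- list()
  b$taps <- integer()
  b$meta <- c(list(input_size = as.integer(input_size)), meta)
  id <- addNode(b, "input", from = integer(), cout = 3L,
                out_h = input_size, out_w = input_size, name = "images")
  b
}

addNode <- function(b, kind, from, cout = NA_integer_, k = NA_integer_,
                    stride = 1L, groups = 1L, biased = NA, cin = NA_integer_,
                    out_h = NA_integer_, out_w = NA_integer_,
                    name = kind, module = "") {
  from <- as.integer(from)
  id <- length(b$rows) + 1L
  shapeOf <- function(i) {
    r <- b$rows[[i]]
    c(r$out_c, r$out_h, r$out_w)
  }
  if (length(from)) {
    s1 <- shapeOf(from[1])
    if (is.na(cin)) cin <- s1[1]
    h <- s1[2]; w <- s1[3]
  } else {
    h <- out_h; w <- out_w
  }
  out_c <- cout
  if (kind == "conv") {
    h <- h %/% stride; w <- w %/% stride
    if (is.na(biased)) biased <- TRUE
  } else if (kind == "transposed_conv") {
    h <- h * stride; w <- w * stride
    if (is.na(biased)) biased <- TRUE
  } else if (kind == "nearest_upsample") {
    h <- h * stride; w <- w * stride
    out_c <- cin
  } else if (kind == "maxpool") {
    h <- h %/% stride; w <- w %/% stride
    out_c <- cin
  } else if (kind == "concat") {
    ss <- lapply(from, shapeOf)
    hw <- vapply(ss, function(s) s[2:3], numeric(2))
    if (any(hw[1, ] != hw[1, 1]) || any(hw[2, ] != hw[2, 1])) {
      who <- vapply(from, function(i) sprintf("'%s' (%dx%d)", b$rows[[i]]$name,
                    b$rows[[i]]$out_h, b$rows[[i]]$out_w), character(1))
      stop("shape mismatch at concat between ", paste(who, collapse = " and "))
    }
    out_c <- sum(vapply(ss, `[`, numeric(1), 1))
  } else if (kind == "slice") {
    # channel slice: cout given, spatial unchanged
  } else if (kind == "add") {
    out_c <- cin
  } else if (kind == "ema") {
    out_c <- cin
    if (cin %% groups != 0L)
      stop(sprintf("ema groups (%d) must divide channels (%d)", groups, cin))
  } else if (kind == "dfl") {
    out_c <- cout
    if (is.na(biased)) biased <- FALSE
  } else if (kind == "activation" || kind == "batchnorm") {
    out_c <- cin
  } else if (kind != "input") {
    stop("unknown layer kind: ", kind)
  }
  if (is.na(biased)) biased <- FALSE
  b$rows[[id]] <- list(id = id, name = name, module = module, kind = kind,
                       cin = as.integer(cin), cout = as.integer(out_c),
                       k = as.integer(k), stride = as.integer(stride),
                       groups = as.integer(groups), biased = isTRUE(biased),
                       out_c = as.integer(out_c), out_h = as.integer(h),
                       out_w = as.integer(w))
  b$inputs[[id]] <- from
  id
}

setTap <- function(b, name, id) b$taps[[name]] <- as.integer(id)

finishGraph <- function(b) {
  layers <- do.call(rbind, lapply(b$rows, function(r)
    data.frame(r[c("id", "name", "module", "kind", "cin", "cout", "k",
                   "stride", "groups", "biased", "out_c", "out_h", "out_w")],
               stringsAsFactors = FALSE)))
  g <- new("ModelGraph", layers = layers, inputs = b$inputs,
           taps = b$taps, meta = b$meta)
  validObject(g)
  g
}

# Composite blocks ----------------------------------------------------------

# Conv block of the family (conv + BN + SiLU), counted fused: biased conv.
addConvBlock <- function(b, from, cout, k = 1L, stride = 1L, name = "conv",
                         module = "") {
  addNode(b, "conv", from, cout = cout, k = k, stride = stride,
          name = name, module = module)
}

# C2f block: 1x1 expand, split, n residual bottlenecks (two 3x3 convs each),
# concat of all intermediate chunks, 1x1 project.
addC2f <- function(b, from, cout, n = 1L, shortcut = FALSE, name = "c2f",
                   module = "") {
  c_ <- cout %/% 2L
  cv1 <- addConvBlock(b, from, 2L * c_, 1L, name = paste0(name, ".cv1"),
                      module = module)
  y2 <- addNode(b, "slice", cv1, cout = c_, name = paste0(name, ".split"),
                module = module)
  chunks <- c(cv1)  # concat takes cv1's two chunks via its full output
  prev <- y2
  for (i in seq_len(n)) {
    h1 <- addConvBlock(b, prev, c_, 3L, name = sprintf("%s.m%d.cv1", name, i),
                       module = module)
    h2 <- addConvBlock(b, h1, c_, 3L, name = sprintf("%s.m%d.cv2", name, i),
                       module = module)
    prev <- if (shortcut) addNode(b, "add", c(prev, h2), name =
                sprintf("%s.m%d.add", name, i), module = module) else h2
    chunks <- c(chunks, prev)
  }
  cat_ <- addNode(b, "concat", chunks, name = paste0(name, ".cat"),
                  module = module)
  addConvBlock(b, cat_, cout, 1L, name = paste0(name, ".cv2"), module = module)
}

addSPPF <- function(b, from, cout, name = "sppf", module = "") {
  cin <- b$rows[[from]]$out_c
  c_ <- cin %/% 2L
  cv1 <- addConvBlock(b, from, c_, 1L, name = paste0(name, ".cv1"), module = module)
  p1 <- addNode(b, "maxpool", cv1, k = 5L, stride = 1L, name = paste0(name, ".p1"), module = module)
  p2 <- addNode(b, "maxpool", p1, k = 5L, stride = 1L, name = paste0(name, ".p2"), module = module)
  p3 <- addNode(b, "maxpool", p2, k = 5L, stride = 1L, name = paste0(name, ".p3"), module = module)
  cat_ <- addNode(b, "concat", c(cv1, p1, p2, p3), name = paste0(name, ".cat"), module = module)
  addConvBlock(b, cat_, cout, 1L, name = paste0(name, ".cv2"), module = module)
}

addEMABlock <- function(b, from, groups, name = "ema", module = "") {
  addNode(b, "ema", from, groups = groups, name = name, module = module)
}

# Accounting ----------------------------------------------------------------

layerParams <- function(kind, cin, cout, k, groups, biased) {
  if (kind %in% c("conv", "transposed_conv")) {
    cin * cout * k * k / groups + if (biased) cout else 0
  } else if (kind == "ema") {
    cg <- cin / groups
    # per-group group-norm (2cg) + biased 1x1 (cg^2+cg) + biased 3x3 (9cg^2+cg)
    10 * cg^2 + 4 * cg
  } else if (kind == "dfl") {
    cin * cout
  } else 0
}

layerFlops <- function(kind, cin, cout, k, stride, groups, out_h, out_w) {
  if (kind == "conv") {
    2 * (cin / groups) * k * k * cout * out_h * out_w
  } else if (kind == "transposed_conv") {
    # kernel = stride geometry: every input pixel scatters into k^2 outputs
    2 * (cin / groups) * k * k * cout * (out_h / stride) * (out_w / stride)
  } else if (kind == "ema") {
    cg <- cin / groups
    2 * groups * (cg * cg + 9 * cg * cg) * out_h * out_w
  } else if (kind == "dfl") {
    2 * cin * cout * out_h * out_w
  } else 0
}

#' @rdname countParameters
#' @export
setMethod("countParameters", "ModelGraph", function(object, ...) {
  L <- object@layers
  total <- sum(mapply(layerParams, L$kind, L$cin, L$cout, L$k, L$groups, L$biased))
  as.integer(round(total))
})

#' @rdname countFlops
#' @export
setMethod("countFlops", "ModelGraph", function(object, input_size = NULL, ...) {
  L <- object@layers
  if (!is.null(input_size) && input_size != object@meta$input_size) {
    sh <- inferShapes(object, input_size = input_size)
    L$out_h <- sh$out_h; L$out_w <- sh$out_w
  }
  sum(mapply(layerFlops, L$kind, L$cin, L$cout, L$k, L$stride, L$groups,
             L$out_h, L$out_w))
})

#' @rdname inferShapes
#' @export
setMethod("inferShapes", "ModelGraph", function(object, input_size = NULL, ...) {
  L <- object@layers
  if (is.null(input_size)) input_size <- object@meta$input_size
  n <- nrow(L)
  oc <- integer(n); oh <- integer(n); ow <- integer(n)
  for (i in seq_len(n)) {
    kind <- L$kind[i]; from <- object@inputs[[i]]
    if (kind == "input") {
      oc[i] <- L$out_c[i]; oh[i] <- input_size; ow[i] <- input_size
      next
    }
    h <- oh[from[1]]; w <- ow[from[1]]
    oc[i] <- L$out_c[i]
    if (kind %in% c("conv", "maxpool")) {
      oh[i] <- h %/% L$stride[i]; ow[i] <- w %/% L$stride[i]
    } else if (kind %in% c("transposed_conv", "nearest_upsample")) {
      oh[i] <- h * L$stride[i]; ow[i] <- w * L$stride[i]
    } else if (kind == "concat") {
      hs <- oh[from]; ws <- ow[from]
      if (any(hs != hs[1]) || any(ws != ws[1])) {
        who <- sprintf("'%s' (%dx%d)", L$name[from], hs, ws)
        stop("shape mismatch at concat '", L$name[i], "' between ",
             paste(who, collapse = " and "))
      }
      oh[i] <- h; ow[i] <- w
      oc[i] <- sum(oc[from])
    } else {
      oh[i] <- h; ow[i] <- w
    }
  }
  data.frame(id = L$id, name = L$name, out_c = oc, out_h = oh, out_w = ow,
             stringsAsFactors = FALSE)
})

#' @rdname taps
#' @export
setMethod("taps", "ModelGraph", function(object) object@taps)

#' @rdname nLayers
#' @export
setMethod("nLayers", "ModelGraph", function(object) nrow(object@layers))

setMethod("show", "ModelGraph", function(object) {
  m <- object@meta
  cat(sprintf("ModelGraph '%s': %d nodes, input %dx%d, nc=%d, k=%d\n",
              if (is.null(m$label)) "model" else m$label, nrow(object@layers),
              m$input_size, m$input_size,
              if (is.null(m$nc)) NA_integer_ else m$nc,
              if (is.null(m$k)) NA_integer_ else m$k))
  cat(sprintf("  parameters: %s (%.3f M)   GFLOPs(%d): %.1f\n",
              format(countParameters(object), big.mark = ","),
              countParameters(object) / 1e6, m$input_size,
              countFlops(object) / 1e9))
  tp <- object@taps
  if (length(tp)) {
    sh <- object@layers[tp, ]
    cat("  taps: ", paste(sprintf("%s=%dx%dx%d", names(tp), sh$out_c, sh$out_h,
                                  sh$out_w), collapse = ", "), "\n", sep = "")
  }
})
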