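# Builders for the baseline prototype-mask segmentation network and its
# HPA / U-EMA variants.  All counting follows the fused (deployment)
# convention documented in ?countParameters.

pkStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "podkitError")))
}

#' Create a hierarchical prototype aggregation configuration
#'
#' @param variant `"cascaded_convT"`, `"parallel_convT"` or
#'   `"parallel_interp"`: how P4/P5 are brought to P3 resolution (two
#'   chained x2 transposed convolutions; independent x2/x4 transposed
#'   convolutions; nearest-neighbour interpolation).
#' @param c3,c4,c5 channels contributed by P3/P4/P5 to the fused prototype
#'   input; must satisfy `c3 + c4 + c5 = k`.
#' @param k total fused channel count (defaults to the sum).
#' @return an [HPAConfig-class].
#' @examples
#' hpaConfig("parallel_convT", 24, 6, 2)
#' @export
hpaConfig <- function(variant = c("parallel_convT", "cascaded_convT", "parallel_interp"),
                      c3, c4, c5, k = c3 + c4 + c5) {
  variant <- match.arg(variant)
  cfg <- try(new("HPAConfig", variant = variant, c3 = as.integer(c3),
                 c4 = as.integer(c4), c5 = as.integer(c5), k = as.integer(k)),
             silent = TRUE)
  if (inherits(cfg, "try-error"))
    pkStop(sprintf("invalid HPA configuration: %s", attr(cfg, "condition")$message),
           "podkitConstraintViolation")
  cfg
}

#' Create a prototype-decoder configuration
#'
#' @param upsample_mode `"nearest"` (parameter-free) or `"transposed_conv"`.
#' @param use_ema insert an EMA attention block after each convolution of
#'   the prototype branch.
#' @param k prototype count.
#' @param ema_groups channel-to-batch group count of the EMA blocks; the
#'   published module's default of 32 is kept (its parameter cost is then
#'   a few dozen weights per block).
#' @return a [ProtonetConfig-class].
#' @export
protonetConfig <- function(upsample_mode = c("nearest", "transposed_conv"),
                           use_ema = TRUE, k = 32, ema_groups = 32) {
  upsample_mode <- match.arg(upsample_mode)
  new("ProtonetConfig", upsample_mode = upsample_mode, use_ema = use_ema,
      k = as.integer(k), ema_groups = as.integer(ema_groups))
}

# width rules of the architecture family (nano scale)
protoStemWidth <- function(k) as.integer(min(2L * k, 64L))
coefHeadWidth <- function(k) as.integer(max(16L, k))
classHeadWidth <- function(nc) as.integer(max(64L, min(nc, 100L)))

# -- internal: full model assembly ------------------------------------------

buildModel <- function(nc, k, input_size, hpa = NULL, protonet = NULL,
                       p3p4_only = FALSE, label = "model") {
  nc <- as.integer(nc); k <- as.integer(k); input_size <- as.integer(input_size)
  if (nc < 1L) pkStop("nc must be >= 1", "podkitInvalidConfig")
  if (k < 1L) pkStop("k must be >= 1", "podkitInvalidConfig")
  if (input_size %% 32L != 0L)
    pkStop(sprintf("input_size (%d) must be divisible by 32", input_size),
           "podkitInvalidConfig")
  npr <- protoStemWidth(k)
  b <- newGraphBuilder(input_size,
                       meta = list(nc = nc, k = k, npr = npr, label = label,
                                   hpa = hpa, protonet = protonet,
                                   p3p4_only = p3p4_only))
  ## backbone
  x <- addConvBlock(b, 1L, 16L, 3L, 2L, "stem0", "backbone")
  x <- addConvBlock(b, x, 32L, 3L, 2L, "stem1", "backbone")
  x <- addC2f(b, x, 32L, 1L, TRUE, "b2", "backbone")
  x <- addConvBlock(b, x, 64L, 3L, 2L, "down3", "backbone")
  c4b <- addC2f(b, x, 64L, 2L, TRUE, "b4", "backbone")      # stride 8
  x <- addConvBlock(b, c4b, 128L, 3L, 2L, "down5", "backbone")
  c6b <- addC2f(b, x, 128L, 2L, TRUE, "b6", "backbone")     # stride 16
  x <- addConvBlock(b, c6b, 256L, 3L, 2L, "down7", "backbone")
  x <- addC2f(b, x, 256L, 1L, TRUE, "b8", "backbone")
  sppf <- addSPPF(b, x, 256L, "sppf", "backbone")           # stride 32
  ## neck (feature pyramid)
  u1 <- addNode(b, "nearest_upsample", sppf, stride = 2L, name = "up.p4", module = "neck")
  x <- addNode(b, "concat", c(u1, c6b), name = "cat.p4", module = "neck")
  n12 <- addC2f(b, x, 128L, 1L, FALSE, "n12", "neck")
  u2 <- addNode(b, "nearest_upsample", n12, stride = 2L, name = "up.p3", module = "neck")
  x <- addNode(b, "concat", c(u2, c4b), name = "cat.p3", module = "neck")
  p3 <- addC2f(b, x, 64L, 1L, FALSE, "n15.P3", "neck")      # P3: 64 ch, stride 8
  x <- addConvBlock(b, p3, 64L, 3L, 2L, "down16", "neck")
  x <- addNode(b, "concat", c(x, n12), name = "cat17", module = "neck")
  p4 <- addC2f(b, x, 128L, 1L, FALSE, "n18.P4", "neck")     # P4: 128 ch, stride 16
  setTap(b, "P3", p3); setTap(b, "P4", p4)
  scales <- list(P3 = p3, P4 = p4)
  if (!p3p4_only) {
    x <- addConvBlock(b, p4, 128L, 3L, 2L, "down19", "neck")
    x <- addNode(b, "concat", c(x, sppf), name = "cat20", module = "neck")
    p5 <- addC2f(b, x, 256L, 1L, FALSE, "n21.P5", "neck")   # P5: 256 ch, stride 32
    setTap(b, "P5", p5)
    scales$P5 <- p5
  }
  ## decoupled prediction heads (box regression / class / mask coefficients)
  chw <- classHeadWidth(nc)
  cw <- coefHeadWidth(k)
  for (nm in names(scales)) {
    src <- scales[[nm]]
    x <- addConvBlock(b, src, 64L, 3L, name = sprintf("box.%s.0", nm), module = "head_box")
    x <- addConvBlock(b, x, 64L, 3L, name = sprintf("box.%s.1", nm), module = "head_box")
    bx <- addConvBlock(b, x, 64L, 1L, name = sprintf("box.%s.out", nm), module = "head_box")
    setTap(b, paste0("box_", nm), bx)
    x <- addConvBlock(b, src, chw, 3L, name = sprintf("cls.%s.0", nm), module = "head_cls")
    x <- addConvBlock(b, x, chw, 3L, name = sprintf("cls.%s.1", nm), module = "head_cls")
    cl <- addConvBlock(b, x, nc, 1L, name = sprintf("cls.%s.out", nm), module = "head_cls")
    setTap(b, paste0("cls_", nm), cl)
    x <- addConvBlock(b, src, cw, 3L, name = sprintf("coef.%s.0", nm), module = "head_coef")
    x <- addConvBlock(b, x, cw, 3L, name = sprintf("coef.%s.1", nm), module = "head_coef")
    co <- addConvBlock(b, x, k, 1L, name = sprintf("coef.%s.out", nm), module = "head_coef")
    setTap(b, paste0("coef_", nm), co)
  }
  # distribution-focal-loss projection (frozen 1x1, 16 bins -> expectation)
  dfl <- addNode(b, "dfl", b$taps[["box_P3"]], cin = 16L, cout = 1L, k = 1L,
                 name = "dfl", module = "head_box")
  setTap(b, "dfl", dfl)
  ## prototype branch
  buildProtoBranch(b, scales, hpa, protonet, k, npr)
  finishGraph(b)
}

buildProtoBranch <- function(b, scales, hpa, protonet, k, npr) {
  ema <- !is.null(protonet) && protonet@use_ema
  eg <- if (ema) protonet@ema_groups else 32L
  upMode <- if (is.null(protonet)) "transposed_conv" else protonet@upsample_mode
  addUp <- function(from, ch, name) {
    if (upMode == "nearest")
      addNode(b, "nearest_upsample", from, stride = 2L, name = name, module = "proto")
    else
      addNode(b, "transposed_conv", from, cout = ch, k = 2L, stride = 2L,
              name = name, module = "proto")
  }
  maybeEMA <- function(from, name) {
    if (ema) addEMABlock(b, from, eg, name, "proto") else from
  }
  if (!is.null(hpa) && !is.null(protonet)) {
    ## composed model: the U-decoder spans the pyramid and subsumes the
    ## aggregation pathway (P5 -> +P4 -> +P3 -> full x2 chain).
    if (is.null(scales$P5))
      pkStop("U-decoder over an aggregating graph needs the P5 tap",
             "podkitMissingTap")
    x <- addConvBlock(b, scales$P5, npr, 3L, name = "proto.d5", module = "proto")
    x <- maybeEMA(x, "proto.d5.ema")
    x <- addUp(x, npr, "proto.up5")
    x <- addNode(b, "concat", c(x, scales$P4), name = "proto.cat4", module = "proto")
    x <- addConvBlock(b, x, npr, 3L, name = "proto.d4", module = "proto")
    x <- maybeEMA(x, "proto.d4.ema")
    x <- addUp(x, npr, "proto.up4")
    x <- addNode(b, "concat", c(x, scales$P3), name = "proto.cat3", module = "proto")
    x <- addConvBlock(b, x, npr, 3L, name = "proto.d3", module = "proto")
    x <- maybeEMA(x, "proto.d3.ema")
    x <- addUp(x, npr, "proto.up3")
    x <- addConvBlock(b, x, npr, 3L, name = "proto.refine", module = "proto")
    x <- maybeEMA(x, "proto.refine.ema")
    out <- addConvBlock(b, x, k, 1L, name = "proto.out", module = "proto")
    setTap(b, "proto_out", out)
    return(invisible(out))
  }
  src <- if (is.null(hpa)) scales$P3 else addHPAPathway(b, scales, hpa)
  if (is.null(protonet)) {
    ## classic prototype stem: conv - convT x2 - conv - 1x1
    x <- addConvBlock(b, src, npr, 3L, name = "proto.cv1", module = "proto")
    x <- addNode(b, "transposed_conv", x, cout = npr, k = 2L, stride = 2L,
                 name = "proto.up", module = "proto")
    x <- addConvBlock(b, x, npr, 3L, name = "proto.cv2", module = "proto")
    out <- addConvBlock(b, x, k, 1L, name = "proto.cv3", module = "proto")
  } else {
    ## P3-only U-decoder: local trough (x2 pooled) and two x2 upsamplings
    x <- addConvBlock(b, src, npr, 3L, name = "proto.cv1", module = "proto")
    x <- maybeEMA(x, "proto.cv1.ema")
    x <- addNode(b, "maxpool", x, k = 2L, stride = 2L, name = "proto.down",
                 module = "proto")
    x <- addUp(x, npr, "proto.up1")
    x <- addUp(x, npr, "proto.up2")
    x <- addConvBlock(b, x, npr, 3L, name = "proto.cv2", module = "proto")
    x <- maybeEMA(x, "proto.cv2.ema")
    out <- addConvBlock(b, x, k, 1L, name = "proto.cv3", module = "proto")
  }
  setTap(b, "proto_out", out)
  invisible(out)
}

# HPA input pathway: channel-projected pyramid levels, upsampled to P3
# resolution, concatenated to k channels and fused back to the prototype
# stem width by a C2f block; the prototype stem itself is untouched.
addHPAPathway <- function(b, scales, hpa) {
  wUp <- 64L  # working width of the learnable upsampling stages
  parts <- integer()
  if (hpa@c3 > 0L) {
    parts <- c(parts, addConvBlock(b, scales$P3, hpa@c3, 1L,
                                   name = "hpa.p3", module = "hpa"))
  }
  needP4 <- hpa@c4 > 0L; needP5 <- hpa@c5 > 0L
  if ((needP4 && is.null(scales$P4)) || (needP5 && is.null(scales$P5)))
    pkStop("HPA requests channels from a pyramid level whose tap is missing",
           "podkitMissingTap")
  if (hpa@variant == "parallel_convT") {
    if (needP4) {
      x <- addNode(b, "transposed_conv", scales$P4, cout = wUp, k = 2L,
                   stride = 2L, name = "hpa.p4.up", module = "hpa")
      parts <- c(parts, addConvBlock(b, x, hpa@c4, 3L, name = "hpa.p4.proj",
                                     module = "hpa"))
    }
    if (needP5) {
      x <- addNode(b, "transposed_conv", scales$P5, cout = wUp, k = 4L,
                   stride = 4L, name = "hpa.p5.up", module = "hpa")
      parts <- c(parts, addConvBlock(b, x, hpa@c5, 3L, name = "hpa.p5.proj",
                                     module = "hpa"))
    }
  } else if (hpa@variant == "cascaded_convT") {
    if (needP4 || needP5) {
      if (is.null(scales$P5))
        pkStop("cascaded HPA needs the P5 tap", "podkitMissingTap")
      x <- addNode(b, "transposed_conv", scales$P5, cout = wUp, k = 2L,
                   stride = 2L, name = "hpa.p5.up", module = "hpa")
      x <- addNode(b, "concat", c(x, scales$P4), name = "hpa.cat45", module = "hpa")
      x <- addNode(b, "transposed_conv", x, cout = wUp, k = 2L, stride = 2L,
                   name = "hpa.p45.up", module = "hpa")
      parts <- c(parts, addConvBlock(b, x, hpa@c4 + hpa@c5, 3L,
                                     name = "hpa.p45.proj", module = "hpa"))
    }
  } else {  # parallel_interp
    if (needP4) {
      x <- addNode(b, "nearest_upsample", scales$P4, stride = 2L,
                   name = "hpa.p4.up", module = "hpa")
      parts <- c(parts, addConvBlock(b, x, hpa@c4, 3L, name = "hpa.p4.proj",
                                     module = "hpa"))
    }
    if (needP5) {
      x <- addNode(b, "nearest_upsample", scales$P5, stride = 4L,
                   name = "hpa.p5.up", module = "hpa")
      parts <- c(parts, addConvBlock(b, x, hpa@c5, 3L, name = "hpa.p5.proj",
                                     module = "hpa"))
    }
  }
  x <- if (length(parts) > 1L)
    addNode(b, "concat", parts, name = "hpa.cat", module = "hpa") else parts[1]
  addC2f(b, x, 64L, 1L, FALSE, "hpa.fuse", "hpa")
}

#' Build the baseline single-class prototype segmentation network
#'
#' Assembles the symbolic graph of the nano-scale one-stage
#' segmentation baseline: CSP backbone, feature pyramid with taps P3/P4/P5
#' at strides 8/16/32, decoupled box/class heads, per-scale mask-coefficient
#' heads emitting `k` coefficients per candidate, and a prototype branch
#' consuming only P3.
#'
#' @param nc number of object classes (1 for the single pod class).
#' @param k number of prototype masks (coefficients per candidate).
#' @param input_size input resolution in pixels; must be divisible by 32.
#' @param p3p4_only drop the P5 pyramid level and its prediction heads.
#' @return a [ModelGraph-class].
#' @examples
#' g <- buildBaseline(nc = 1, k = 32, input_size = 640)
#' round(countParameters(g) / 1e6, 3)  # 3.258
#' @export
buildBaseline <- function(nc = 1, k = 32, input_size = 640, p3p4_only = FALSE) {
  buildModel(nc, k, input_size, p3p4_only = p3p4_only,
             label = if (p3p4_only) "baseline-P34" else "baseline")
}

#' Apply hierarchical prototype aggregation to a model graph
#'
#' Rebuilds the prototype-branch input pipeline so that it consumes a
#' channel-concatenation of a `c3`-channel projection of P3, a `c4`-channel
#' path from P4 upsampled x2 and a `c5`-channel path from P5 upsampled x4,
#' all at P3 resolution, fused back to the prototype stem width.
#' Zero-channel paths are dropped.
#'
#' @param graph a [ModelGraph-class] with P3/P4/P5 taps.
#' @param cfg an [HPAConfig-class]; see [hpaConfig()].
#' @return a new [ModelGraph-class].
#' @examples
#' g <- applyHPA(buildBaseline(), hpaConfig("parallel_convT", 24, 6, 2))
#' round(countParameters(g) / 1e6, 3)  # 3.586
#' @export
applyHPA <- function(graph, cfg) {
  stopifnot(is(graph, "ModelGraph"), is(cfg, "HPAConfig"))
  validObject(cfg)
  m <- graph@meta
  if (cfg@k != m$k)
    pkStop(sprintf("HPA k (%d) must equal the graph's prototype count (%d)",
                   cfg@k, m$k), "podkitConstraintViolation")
  buildModel(m$nc, m$k, m$input_size, hpa = cfg, protonet = m$protonet,
             p3p4_only = isTRUE(m$p3p4_only),
             label = paste0(m$label, "+HPA(", cfg@variant, ")"))
}

#' Rebuild the prototype branch as a U-shaped decoder with EMA attention
#'
#' The prototype branch is rebuilt as a U-shaped decoder whose output
#' resolution is one quarter of the input image.  On a P3-only graph the U
#' is local (a pooled trough followed by two x2 upsampling stages); on a
#' graph carrying hierarchical prototype aggregation the decoder spans the
#' pyramid itself, ascending from P5 through P4 and P3 to quarter
#' resolution and subsuming the aggregation upsampling pathway (which is
#' why the composed model's parameter count no longer depends on the HPA
#' upsampling variant).  With `upsample_mode = "nearest"` the upsampling
#' stages add no parameters; with `use_ema` an EMA block follows each
#' convolution of the branch.
#'
#' @param graph a [ModelGraph-class] with a prototype branch.
#' @param cfg a [ProtonetConfig-class]; see [protonetConfig()].
#' @return a new [ModelGraph-class].
#' @examples
#' g <- applyUEMA(buildBaseline(), protonetConfig("nearest", use_ema = FALSE))
#' round(countParameters(g) / 1e6, 3)  # 3.242
#' @export
applyUEMA <- function(graph, cfg) {
  stopifnot(is(graph, "ModelGraph"), is(cfg, "ProtonetConfig"))
  validObject(cfg)
  m <- graph@meta
  if (cfg@use_ema && (m$npr %% cfg@ema_groups != 0L))
    pkStop(sprintf("ema_groups (%d) must divide the prototype width (%d)",
                   cfg@ema_groups, m$npr), "podkitInvalidConfig")
  buildModel(m$nc, m$k, m$input_size, hpa = m$hpa, protonet = cfg,
             p3p4_only = isTRUE(m$p3p4_only),
             label = paste0(m$label, "+U-", cfg@upsample_mode,
                            if (cfg@use_ema) "+EMA" else ""))
}

#' Build the full composed pod-segmentation model
#'
#' Composition of hierarchical prototype aggregation (parallel transposed
#' convolution, channel split 24/6/2) and the U-shaped prototype decoder
#' with nearest-neighbour upsampling and EMA attention; identical to
#' `applyUEMA(applyHPA(buildBaseline(nc, 32, input_size), ...), ...)`.
#'
#' @param nc number of classes.
#' @param input_size input resolution, divisible by 32.
#' @param hpa_variant HPA upsampling variant; the composed decoder subsumes
#'   the aggregation pathway, so the parameter count is variant-independent.
#' @return a [ModelGraph-class].
#' @examples
#' round(countParameters(buildPodNet()) / 1e6, 3)  # 3.537
#' @export
buildPodNet <- function(nc = 1, input_size = 640,
                        hpa_variant = "parallel_convT") {
  g <- applyHPA(buildBaseline(nc = nc, k = 32, input_size = input_size),
                hpaConfig(hpa_variant, 24, 6, 2))
  g <- applyUEMA(g, protonetConfig("nearest", use_ema = TRUE, k = 32,
                                   ema_groups = 32))
  g@meta$label <- "podnet"
  g
}

#' Profile a model graph
#'
#' One summary row per graph: node count, parameters (absolute and in
#' millions, 3 decimals) and GFLOPs at the build resolution.  `stock_head`
#' additionally reports the FLOP profile of the same architecture with the
#' family's stock 80-class prediction-head widths, which is the profile
#' convention under which these architectures are usually quoted.
#'
#' @param graph a [ModelGraph-class].
#' @param stock_head also report the stock-class-head GFLOPs.
#' @return a one-row data.frame.
#' @export
profileModel <- function(graph, stock_head = TRUE) {
  m <- graph@meta
  out <- data.frame(
    model = if (is.null(m$label)) "model" else m$label,
    layers = nLayers(graph),
    params = countParameters(graph),
    params_M = round(countParameters(graph) / 1e6, 3),
    gflops = round(countFlops(graph) / 1e9, 1))
  if (stock_head) {
    gs <- buildModel(80L, m$k, m$input_size, hpa = m$hpa,
                     protonet = m$protonet, p3p4_only = isTRUE(m$p3p4_only),
                     label = m$label)
    out$gflops_stock_head <- round(countFlops(gs) / 1e9, 1)
  }
  out
}
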