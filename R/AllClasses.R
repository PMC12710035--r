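#' @import methods
NULL

#' Symbolic model graph
#'
#' A `ModelGraph` is a topologically ordered DAG of primitive layers
#' (convolutions, transposed convolutions, poolings, upsamplings, concats,
#' attention blocks, ...) with inferred tensor shapes.  It is the object that
#' parameter and FLOP accounting operate on; no weights are attached.
#'
#' @slot layers a `data.frame` with one row per node: `id`, `name`, `module`,
#'   `kind`, `cin`, `cout`, `k`, `stride`, `groups`, `biased`, `out_c`,
#'   `out_h`, `out_w`.
#' @slot inputs a list, parallel to `layers`, of integer vectors of
#'   predecessor node ids (empty for the input node).
#' @slot taps named integer vector resolving the pyramid taps `P3`, `P4`,
#'   `P5`, the prototype output `proto_out` and the prediction-head outputs
#'   to node ids.
#' @slot meta list of build metadata: `nc` (class count), `k` (prototype
#'   count), `npr` (prototype stem width), `input_size` (pixels), and the
#'   variant configurations used to build the graph.
#'
#' @seealso [buildBaseline()], [applyHPA()], [applyUEMA()], [buildPodNet()]
#' @export
setClass("ModelGraph",
  representation(layers = "data.frame", inputs = "list",
                 taps = "integer", meta = "list"))

setValidity("ModelGraph", function(object) {
  msgs <- character()
  n <- nrow(object@layers)
  if (length(object@inputs) != n)
    msgs <- c(msgs, "inputs list and layer table lengths differ")
  for (i in seq_len(n)) {
    pre <- object@inputs[[i]]
    if (length(pre) && any(pre >= i))
      msgs <- c(msgs, sprintf("node %d has a non-causal input (graph not a DAG)", i))
  }
  if (length(object@taps) && any(object@taps < 1L | object@taps > n))
    msgs <- c(msgs, "tap does not resolve to a node")
  need <- c("id", "kind", "cin", "cout", "k", "stride", "groups", "biased",
            "out_c", "out_h", "out_w")
  if (!all(need %in% names(object@layers)))
    msgs <- c(msgs, "layer table misses required columns")
  if (length(msgs)) msgs else TRUE
})

#' Hierarchical prototype aggregation configuration
#'
#' Channel allocation and upsampling variant for feeding the prototype
#' branch a fusion of the P3/P4/P5 pyramid levels.  The allocation
#' `c3 + c4 + c5 = k` states how many of the `k` fused channels each scale
#' contributes.
#'
#' @slot variant one of `"cascaded_convT"`, `"parallel_convT"`,
#'   `"parallel_interp"`.
#' @slot c3,c4,c5 non-negative integer channel counts contributed by
#'   P3, P4 and P5.
#' @slot k positive integer; total fused (prototype) channel count.
#' @export
setClass("HPAConfig",
  representation(variant = "character", c3 = "integer", c4 = "integer",
                 c5 = "integer", k = "integer"))

setValidity("HPAConfig", function(object) {
  msgs <- character()
  if (!object@variant %in% c("cascaded_convT", "parallel_convT", "parallel_interp"))
    msgs <- c(msgs, sprintf("unknown HPA variant '%s'", object@variant))
  if (any(c(object@c3, object@c4, object@c5) < 0L))
    msgs <- c(msgs, "channel counts must be non-negative")
  if (object@k < 1L) msgs <- c(msgs, "k must be >= 1")
  if (object@c3 + object@c4 + object@c5 != object@k)
    msgs <- c(msgs, sprintf("channel split violates c3 + c4 + c5 = k (%d + %d + %d != %d)",
                            object@c3, object@c4, object@c5, object@k))
  if (length(msgs)) msgs else TRUE
})

#' Prototype-branch (Protonet) configuration
#'
#' Upsampling operator and attention choice for the U-shaped prototype
#' decoder.
#'
#' @slot upsample_mode `"transposed_conv"` or `"nearest"`.
#' @slot use_ema logical; insert an efficient multiscale attention (EMA)
#'   block after each convolution of the prototype branch.
#' @slot k positive integer prototype count.
#' @slot ema_groups positive integer; EMA channel-to-batch group count
#'   (must divide every channel width at the insertion points).
#' @export
setClass("ProtonetConfig",
  representation(upsample_mode = "character", use_ema = "logical",
                 k = "integer", ema_groups = "integer"))

setValidity("ProtonetConfig", function(object) {
  msgs <- character()
  if (!object@upsample_mode %in% c("transposed_conv", "nearest"))
    msgs <- c(msgs, sprintf("unknown upsample mode '%s'", object@upsample_mode))
  if (object@k < 1L) msgs <- c(msgs, "k must be >= 1")
  if (object@ema_groups < 1L) msgs <- c(msgs, "ema_groups must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Bundle of prototype planes
#'
#' The `k` full-image basis planes produced by the prototype branch.
#' Instance masks are logistic-transformed linear combinations of these
#' planes.
#'
#' @slot planes numeric array `k x h x w`.
#' @export
setClass("PrototypeBundle", representation(planes = "array"))

setValidity("PrototypeBundle", function(object) {
  d <- dim(object@planes)
  if (length(d) != 3L) return("planes must be a k x h x w array")
  if (d[1] < 1L) return("need at least one prototype plane")
  TRUE
})

#' A set of instance predictions
#'
#' Boxes are pixel coordinates in the half-open, 0-based convention
#' `[x1, x2) x [y1, y2)` with x growing rightwards and y downwards.
#'
#' @slot boxes numeric matrix `n x 4` (`x1`, `y1`, `x2`, `y2`).
#' @slot confidence numeric vector in `[0, 1]`.
#' @slot coefficients numeric matrix `n x k` of prototype coefficients.
#' @slot masks list of `n` binary (logical) matrices, filled by
#'   [assembleInstanceMasks()]; empty list before assembly.
#' @slot image_size integer `c(h, w)`.
#' @export
setClass("InstancePredictionSet",
  representation(boxes = "matrix", confidence = "numeric",
                 coefficients = "matrix", masks = "list",
                 image_size = "integer"))

setValidity("InstancePredictionSet", function(object) {
  n <- nrow(object@boxes)
  msgs <- character()
  if (ncol(object@boxes) != 4L) msgs <- c(msgs, "boxes must have 4 columns")
  if (length(object@confidence) != n) msgs <- c(msgs, "confidence length mismatch")
  if (n && nrow(object@coefficients) != n) msgs <- c(msgs, "coefficient rows mismatch")
  if (length(object@confidence) &&
      (any(object@confidence < 0) || any(object@confidence > 1)))
    msgs <- c(msgs, "confidences must lie in [0, 1]")
  if (n && any(object@boxes[, 1] >= object@boxes[, 3]))
    msgs <- c(msgs, "boxes must satisfy x1 < x2")
  if (n && any(object@boxes[, 2] >= object@boxes[, 4]))
    msgs <- c(msgs, "boxes must satisfy y1 < y2")
  if (length(object@masks) && length(object@masks) != n)
    msgs <- c(msgs, "mask list length mismatch")
  if (length(msgs)) msgs else TRUE
})

#' Greedy matching result between predictions and ground truth
#'
#' @slot tp,fp,fn non-negative integer counts.  `tp + fn` equals the number
#'   of ground-truth instances and `tp + fp` the number of retained
#'   predictions.
#' @slot pairs data.frame of matched pairs (`pred`, `truth`, `iou`).
#' @export
setClass("MatchResult",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 pairs = "data.frame"))

#' Instance-segmentation evaluation report
#'
#' @slot precision,recall,map50,map50_95 reals in `[0, 1]`.
#' @export
setClass("EvalReport",
  representation(precision = "numeric", recall = "numeric",
                 map50 = "numeric", map50_95 = "numeric"))

setValidity("EvalReport", function(object) {
  v <- c(object@precision, object@recall, object@map50, object@map50_95)
  if (any(!is.na(v) & (v < 0 | v > 1))) "metrics must lie in [0, 1]" else TRUE
})

#' Synthetic backdrop scene configuration
#'
#' Parameters of the synthetic side-view "pod" scene generator: dense rotated
#' ellipses against a bright solid-colour backdrop, with optional elongated
#' occluders ("stems"/"leaves"), additive noise and Gaussian blur.
#'
#' @slot image_size integer `c(h, w)` pixels.
#' @slot n_pods number of pod instances.
#' @slot axis_range numeric `c(min_minor, max_minor, min_major, max_major)`
#'   semi-axis lengths in pixels (each >= 2 pixel diameter).
#' @slot cluster_sd spatial spread of pod centres, as a fraction of the
#'   image side (small = tight cluster along the plant axis).
#' @slot n_occluders number of occluding stems/leaves drawn over the pods.
#' @slot allow_overlap logical; if `FALSE`, pods are placed disjointly.
#' @slot backdrop backdrop intensity in `[0, 1]`.
#' @slot noise_sd additive Gaussian pixel noise standard deviation.
#' @slot blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @slot seed integer random seed.
#' @export
setClass("SceneConfig",
  representation(image_size = "integer", n_pods = "integer",
                 axis_range = "numeric", cluster_sd = "numeric",
                 n_occluders = "integer", allow_overlap = "logical",
                 backdrop = "numeric", noise_sd = "numeric",
                 blur_sigma = "numeric", seed = "integer"))

setValidity("SceneConfig", function(object) {
  msgs <- character()
  if (object@n_pods < 0L) msgs <- c(msgs, "n_pods must be >= 0")
  if (length(object@axis_range) != 4L || any(object@axis_range < 1))
    msgs <- c(msgs, "axis_range must give four semi-axes >= 1 pixel")
  if (object@blur_sigma < 0) msgs <- c(msgs, "blur_sigma must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' A rendered synthetic scene with its ground truth
#'
#' @slot image numeric array `h x w x 3` in `[0, 1]`.
#' @slot annotations list of instance annotations as returned by
#'   [readLabels()]: each has `class_id`, `polygon` (normalized n x 2),
#'   `mask` (logical h x w) and `box` (pixel, half-open).
#' @slot config the [SceneConfig-class] that produced the scene.
#' @export
setClass("SyntheticScene",
  representation(image = "array", annotations = "list", config = "SceneConfig"))

setValidity("SyntheticScene", function(object) {
  for (a in object@annotations) {
    if (!any(a$mask)) return("every annotation mask must be non-empty")
  }
  TRUE
})
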