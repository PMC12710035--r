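#' Count trainable parameters of a model graph
#'
#' Sums the closed-form parameter count of every layer.  The convention is
#' the deployment ("fused") form of the network: a convolution followed by
#' batch normalization is counted as a single biased convolution, which is
#' what the folded inference-time network actually carries.
#'
#' @param object a [ModelGraph-class].
#' @param ... unused.
#' @return integer total parameter count.
#' @examples
#' g <- buildBaseline(nc = 1, k = 32, input_size = 640)
#' countParameters(g) / 1e6
#' @export
setGeneric("countParameters", function(object, ...) standardGeneric("countParameters"))

#' Count floating-point operations of a model graph
#'
#' FLOPs are fixed at 2 x multiply-accumulates of convolution,
#' transposed-convolution and linear layers at the given input size.
#' Nearest-neighbour upsampling, pooling and concatenation contribute
#' nothing (index/copy operations), matching the convention under which the
#' architecture family's profiles are usually quoted.
#'
#' @param object a [ModelGraph-class].
#' @param input_size optional input resolution in pixels; defaults to the
#'   size the graph was built for.
#' @param ... unused.
#' @return numeric FLOP count (multiply by `1e-9` for GFLOPs).
#' @examples
#' g <- buildBaseline(nc = 1, k = 32, input_size = 640)
#' countFlops(g) / 1e9
#' @export
setGeneric("countFlops", function(object, input_size = NULL, ...) standardGeneric("countFlops"))

#' Infer tensor shapes for every node of a model graph
#'
#' Walks the DAG in topological order and derives each node's output shape
#' from its inputs, validating the spatial contracts (concatenated operands
#' must agree in resolution; mismatches raise a diagnostic naming both
#' operands).
#'
#' @param object a [ModelGraph-class].
#' @param input_size optional input resolution overriding the built one.
#' @param ... unused.
#' @return data.frame with `id`, `name`, `out_c`, `out_h`, `out_w`.
#' @export
setGeneric("inferShapes", function(object, input_size = NULL, ...) standardGeneric("inferShapes"))

#' Pyramid and head taps of a model graph
#' @param object a [ModelGraph-class].
#' @return named integer vector of node ids.
#' @export
setGeneric("taps", function(object) standardGeneric("taps"))

#' Number of nodes in a model graph
#' @param object a [ModelGraph-class].
#' @export
setGeneric("nLayers", function(object) standardGeneric("nLayers"))

#' Prototype planes of a bundle
#' @param object a [PrototypeBundle-class].
#' @export
setGeneric("planes", function(object) standardGeneric("planes"))

#' Number of instances in a prediction set
#' @param object an [InstancePredictionSet-class].
#' @export
setGeneric("nInstances", function(object) standardGeneric("nInstances"))
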