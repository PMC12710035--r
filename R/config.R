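# YAML model configuration

#' Build a model graph from a YAML configuration
#'
#' The configuration holds `nc`, `input_size`, `k`, and optional `hpa`
#' (`variant`, `c3`, `c4`, `c5`) and `protonet` (`upsample`, `ema`,
#' `groups`) blocks.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return a [ModelGraph-class].
#' @examples
#' cfg <- list(nc = 1, input_size = 640, k = 32,
#'             hpa = list(variant = "parallel_convT", c3 = 24, c4 = 6, c5 = 2),
#'             protonet = list(upsample = "nearest", ema = TRUE, groups = 32))
#' g <- buildFromConfig(cfg)
#' @export
buildFromConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  nc <- if (is.null(cfg$nc)) 1L else cfg$nc
  k <- if (is.null(cfg$k)) 32L else cfg$k
  input_size <- if (is.null(cfg$input_size)) 640L else cfg$input_size
  g <- buildBaseline(nc = nc, k = k, input_size = input_size,
                     p3p4_only = isTRUE(cfg$p3p4_only))
  if (!is.null(cfg$hpa)) {
    h <- cfg$hpa
    g <- applyHPA(g, hpaConfig(h$variant, h$c3, h$c4, h$c5))
  }
  if (!is.null(cfg$protonet)) {
    p <- cfg$protonet
    g <- applyUEMA(g, protonetConfig(
      upsample_mode = if (is.null(p$upsample)) "nearest" else p$upsample,
      use_ema = isTRUE(p$ema), k = k,
      ema_groups = if (is.null(p$groups)) 32L else p$groups))
  }
  g
}

#' Write a model configuration to YAML
#'
#' @param graph a [ModelGraph-class].
#' @param path output path.
#' @export
writeModelConfig <- function(graph, path) {
  m <- graph@meta
  cfg <- list(nc = m$nc, input_size = m$input_size, k = m$k)
  if (isTRUE(m$p3p4_only)) cfg$p3p4_only <- TRUE
  if (!is.null(m$hpa))
    cfg$hpa <- list(variant = m$hpa@variant, c3 = m$hpa@c3, c4 = m$hpa@c4,
                    c5 = m$hpa@c5)
  if (!is.null(m$protonet))
    cfg$protonet <- list(upsample = m$protonet@upsample_mode,
                         ema = m$protonet@use_ema,
                         groups = m$protonet@ema_groups)
  yaml::write_yaml(cfg, path)
  invisible(cfg)
}
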