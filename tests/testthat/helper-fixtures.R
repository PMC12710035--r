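# shared fixtures built in code

# an easy scene: a few large, disjoint, unoccluded pods
easyScene <- function(seed, size = 96, n_pods = 3) {
  generateScene(sceneConfig(image_size = c(size, size), n_pods = n_pods,
                            axis_range = c(7, 10, 12, 18), cluster_sd = 0.3,
                            n_occluders = 0, allow_overlap = FALSE,
                            noise_sd = 0.005, seed = seed))
}

# deterministic textured grayscale test card (values in [0, 1])
testCard <- function(n = 48, seed = 5) {
  set.seed(seed)
  base <- outer(seq_len(n), seq_len(n), function(i, j)
    0.5 + 0.3 * sin(i / 3) * cos(j / 5))
  podkit:::clamp(base + matrix(rnorm(n * n, 0, 0.05), n, n), 0, 1)
}

# independent parameter oracle: materialise every layer's weight arrays and
# count their lengths (no closed-form formulas involved)
materializedParamCount <- function(graph) {
  L <- graph@layers
  total <- 0
  for (i in seq_len(nrow(L))) {
    kind <- L$kind[i]
    if (kind %in% c("conv", "transposed_conv")) {
      w <- array(0, c(L$cout[i], L$cin[i] %/% L$groups[i], L$k[i], L$k[i]))
      total <- total + length(w)
      if (L$biased[i]) total <- total + length(numeric(L$cout[i]))
    } else if (kind == "ema") {
      cg <- L$cin[i] %/% L$groups[i]
      parts <- list(gamma = numeric(cg), beta = numeric(cg),
                    w1 = array(0, c(cg, cg, 1, 1)), b1 = numeric(cg),
                    w3 = array(0, c(cg, cg, 3, 3)), b3 = numeric(cg))
      total <- total + sum(vapply(parts, length, numeric(1)))
    } else if (kind == "dfl") {
      total <- total + length(array(0, c(L$cout[i], L$cin[i], 1, 1)))
    }
  }
  total
}
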