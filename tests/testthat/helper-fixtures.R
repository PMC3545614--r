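# Shared fixtures, all generated in code.

# uniform-color image
flatImage <- function(rgb, h = 4L, w = 4L) {
  RGBImage(array(rep(rgb, each = h * w), dim = c(h, w, 3)))
}

# image made of vertical flat-color stripes (one per color row)
stripeImage <- function(colors) {
  w <- nrow(colors)
  px <- array(0, dim = c(4L, w, 3L))
  for (j in seq_len(w)) px[, j, ] <- matrix(colors[j, ], 4L, 3L, byrow = TRUE)
  RGBImage(px)
}

# small, fast generator setup used by unit tests
smallGenerator <- function(...) {
  generatorConfig(imageSize = c(48L, 64L), fruitBlobCount = 20L,
                  fruitRadiusRange = c(3, 6), spikeCount = 12L, ...)
}

# quick end-to-end experiment config for structural tests
smallExperiment <- function(method = "MA", pcCounts = NULL, seed = 0,
                            generator = smallGenerator(), ...) {
  experimentConfig(method, combinations = c("CC"), pcCounts = pcCounts,
                   nPerClass = 6L, splitSizes = c(12L, 4L, 8L),
                   generator = generator, restarts = 2L,
                   maxEpochs = 400L, seed = seed, ...)
}
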