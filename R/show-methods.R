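setMethod("show", "RGBImage", function(object) {
  d <- dim(object@pixels)
  cat("RGBImage:", d[1], "x", d[2], "pixels, 3 channels in [0,1]\n")
})

setMethod("show", "LabImage", function(object) {
  cat("LabImage:", nrow(object@L), "x", ncol(object@L),
      sprintf("| L in [%.1f, %.1f], a* in [%.1f, %.1f], b* in [%.1f, %.1f]\n",
              min(object@L), max(object@L), min(object@a), max(object@a),
              min(object@b), max(object@b)))
})

setMethod("show", "MarkerSet", function(object) {
  cat("MarkerSet:", nrow(object@coords), "color markers (k =",
      object@kPerImage, "per image, merge radius", object@mergeRadius, ")\n")
  df <- data.frame(a = round(object@coords[, 1], 2),
                   b = round(object@coords[, 2], 2),
                   label = object@labels, pixels = object@weights)
  print(df, row.names = FALSE)
})

setMethod("show", "PCAModel", function(object) {
  lam <- object@eigenvalues
  cat("PCAModel:", length(lam), "components (",
      length(object@dropped), "zero-variance column(s) dropped )\n")
  cum <- cumsum(lam) / sum(lam)
  k <- min(5L, length(lam))
  cat("  leading eigenvalues:", paste(round(lam[seq_len(k)], 3), collapse = ", "),
      "| cumulative variance:", paste(round(cum[seq_len(k)], 3), collapse = ", "), "\n")
})

setMethod("show", "MLPModel", function(object) {
  cat(sprintf("MLPModel: %d-%d-%d (%s hidden, %s output, bias %s)\n",
              nrow(object@W1), ncol(object@W1), ncol(object@W2),
              object@hiddenTF, object@outputTF,
              if (object@useBias) "on" else "off"))
})

setMethod("show", "OutputCoding", function(object) {
  cat("OutputCoding", object@label, "->", object@nOutputs, "output neuron(s)\n")
  print(object@codewords)
})

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:", object@imageSize[1], "x", object@imageSize[2],
      "| fruit hue means:",
      paste(sprintf("%s=%g", names(object@classHueMean), object@classHueMean),
            collapse = ", "),
      "(sd", object@classHueSD, ")\n")
})

setMethod("show", "ResultGrid", function(object) {
  cat("ResultGrid, method", object@method, "- test h.c.a. (%):\n")
  print(round(object@accuracy, 2))
  bc <- bestCell(object)
  cat(sprintf("best: %s at %g feature(s) -> %.2f%%\n",
              bc$combination, bc$nFeatures, bc$accuracy))
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult:", sum(object@mask == 1L), "fruit /",
      sum(object@mask == 0L), "non-fruit pixels\n")
})

setMethod("show", "HueHistogram", function(object) {
  nz <- which(object@bins > 0)
  cat("HueHistogram: 100 bins,", object@pixelCount, "pixels,",
      length(nz), "occupied bins\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@X), "images x",
      ncol(object@X), "selected hue bins\n")
})
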