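#' Hue histogram of the fruit region
#'
#' Computes the hue of every masked-in pixel via \code{\link{rgbToHue}},
#' drops achromatic pixels (their hue is undefined), and bins the rest into
#' 100 equal-width bins of 3.6 degrees over [0, 360), normalized to relative
#' frequencies so that bunches of different fruit-region area are comparable.
#'
#' @param img an \linkS4class{RGBImage}.
#' @param mask binary matrix of the image's dimensions; 1 selects fruit pixels.
#' @return A \linkS4class{HueHistogram}.
#' @export
hueHistogram <- function(img, mask) {
  if (!identical(dim(mask), dim(img@pixels)[1:2]))
    stop("mask and image dimensions differ")
  hm <- rgbToHue(img)
  sel <- mask == 1L & hm@valid
  h <- hm@hue[sel]
  if (length(h) == 0L)
    stop("empty-region error: no valid fruit pixels under the mask")
  bin <- pmin(floor(h / 3.6), 99) + 1L
  new("HueHistogram", bins = tabulate(bin, 100L) / length(h),
      pixelCount = length(h))
}

#' Select informative hue bins from training histograms
#'
#' A bin is informative when its relative frequency exceeds \code{threshold}
#' in at least one training histogram; only those bins become features. The
#' selection is fitted on the training set alone and reused unchanged for
#' validation and test data.
#'
#' @param histograms nonempty list of training \linkS4class{HueHistogram}s.
#' @param threshold occupancy threshold (default 0: any strictly positive
#'   count marks the bin informative).
#' @return Ascending integer vector of 1-based bin indices.
#' @export
selectBins <- function(histograms, threshold = 0) {
  if (length(histograms) == 0L) stop("no training histograms supplied")
  occ <- Reduce(`|`, lapply(histograms, function(hh) hh@bins > threshold))
  which(occ)
}

#' Assemble the feature matrix
#'
#' Row i is histogram i restricted to the selected bins, preserving input
#' order, giving the N x q matrix fed to PCA and the classifier.
#'
#' @param histograms list of \linkS4class{HueHistogram}s.
#' @param selectedBins ascending 1-based bin indices from
#'   \code{\link{selectBins}}.
#' @return A \linkS4class{FeatureMatrix}.
#' @export
buildFeatureMatrix <- function(histograms, selectedBins) {
  X <- t(vapply(histograms, function(hh) hh@bins[selectedBins],
                numeric(length(selectedBins))))
  if (length(selectedBins) == 1L) X <- matrix(X, ncol = 1L)
  colnames(X) <- sprintf("bin%03d", selectedBins)
  new("FeatureMatrix", X = X, selectedBins = as.integer(selectedBins))
}
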