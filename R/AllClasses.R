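#' @import methods
NULL

#' Ripeness class labels
#'
#' The four bunch ripeness categories used throughout the package, in
#' canonical order: deep-violet unripe bunches, reddish-black underripe,
#' red ripe, and reddish-orange overripe. The order defines class indices
#' (1--4) used by output codings and tie-breaking rules.
#'
#' @return Character vector of the four class labels.
#' @export
#' @examples
#' ripenessClasses()
ripenessClasses <- function() c("unripe", "underripe", "ripe", "overripe")

#' RGBImage: a 24-bit color raster normalized to [0, 1]
#'
#' Pixel raster with three channels (red, green, blue). 8-bit images are
#' divided by 255 on load so that all color math is scale-explicit.
#'
#' @slot pixels numeric array, height x width x 3, values in [0, 1].
#' @export
setClass("RGBImage", representation(pixels = "array"), validity = function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be a height x width x 3 array")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    return("all channel values must be finite and in [0, 1]")
  TRUE
})

#' Construct an RGBImage
#'
#' @param pixels height x width x 3 numeric array in [0, 1], or an integer
#'   array in 0..255 which is divided by 255.
#' @return An \linkS4class{RGBImage}.
#' @export
RGBImage <- function(pixels) {
  if (length(dim(pixels)) == 2L)
    stop("RGBImage requires 3 channels, got a single-channel raster")
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("RGBImage requires a height x width x 3 array")
  if (max(pixels) > 1) pixels <- pixels / 255
  new("RGBImage", pixels = pixels)
}

#' LabImage: CIE L*a*b* rasters
#'
#' @slot L lightness raster in [0, 100].
#' @slot a a* (green-red) raster.
#' @slot b b* (blue-yellow) raster.
#' @export
setClass("LabImage",
  representation(L = "matrix", a = "matrix", b = "matrix"),
  validity = function(object) {
    d <- dim(object@L)
    if (!identical(d, dim(object@a)) || !identical(d, dim(object@b)))
      return("L, a and b rasters must share dimensions")
    TRUE
  })

#' HueMap: per-pixel hue angles with a validity mask
#'
#' Hue in degrees in [0, 360); achromatic pixels (R = G = B), where the
#' hue angle is undefined, carry NA and valid = FALSE.
#'
#' @slot hue numeric matrix of degrees, NA where undefined.
#' @slot valid logical matrix, FALSE exactly where the pixel is achromatic.
#' @export
setClass("HueMap",
  representation(hue = "matrix", valid = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@hue), dim(object@valid)))
      return("hue and valid must share dimensions")
    h <- object@hue[object@valid]
    if (length(h) && (anyNA(h) || any(h < 0) || any(h >= 360)))
      return("valid hues must lie in [0, 360)")
    if (!all(is.na(object@hue[!object@valid])))
      return("invalid pixels must carry NA hue")
    TRUE
  })

#' MarkerSet: labeled a*b* color prototypes for pixel classification
#'
#' Color markers are representative (a*, b*) means derived by clustering
#' training images; each carries a region label (fruit or spike) and drives
#' nearest-distance pixel classification. Fruit markers are ordered first.
#'
#' @slot coords numeric matrix, one row per marker, columns a and b.
#' @slot labels character, "fruit" or "spike" per marker.
#' @slot weights numeric, pixel count behind each marker.
#' @slot kPerImage integer, clusters used per training image.
#' @slot mergeRadius numeric, minimum a*b* separation between markers.
#' @export
setClass("MarkerSet",
  representation(coords = "matrix", labels = "character", weights = "numeric",
                 kPerImage = "integer", mergeRadius = "numeric"),
  validity = function(object) {
    n <- nrow(object@coords)
    if (ncol(object@coords) != 2L) return("coords must have two columns (a*, b*)")
    if (length(object@labels) != n) return("one label per marker required")
    if (!all(object@labels %in% c("fruit", "spike")))
      return("marker labels must be 'fruit' or 'spike'")
    if (!any(object@labels == "fruit") || !any(object@labels == "spike"))
      return("need at least one fruit and one spike marker")
    if (anyNA(object@coords) || any(!is.finite(object@coords)))
      return("marker coordinates must be finite")
    if (n > 1L) {
      d <- as.matrix(stats::dist(object@coords))
      diag(d) <- Inf
      if (min(d) < object@mergeRadius - 1e-9)
        return("two markers are closer than mergeRadius")
    }
    TRUE
  })

#' SegmentationResult: binary fruit mask plus masked image
#'
#' @slot mask integer matrix; 1 = fruit, 0 = spike/other.
#' @slot segmented \linkS4class{RGBImage}; original pixels where mask = 1,
#'   black elsewhere.
#' @export
setClass("SegmentationResult",
  representation(mask = "matrix", segmented = "RGBImage"),
  validity = function(object) {
    if (!all(object@mask %in% c(0L, 1L))) return("mask must be 0/1")
    if (!identical(dim(object@mask), dim(object@segmented@pixels)[1:2]))
      return("mask and image dimensions differ")
    TRUE
  })

#' HueHistogram: 100-bin relative-frequency hue distribution
#'
#' Bin j (1-based) covers hue degrees [3.6 (j-1), 3.6 j).
#'
#' @slot bins numeric(100) of relative frequencies, summing to 1.
#' @slot pixelCount integer, number of valid fruit pixels binned.
#' @export
setClass("HueHistogram",
  representation(bins = "numeric", pixelCount = "integer"),
  validity = function(object) {
    if (length(object@bins) != 100L) return("exactly 100 bins required")
    if (any(object@bins < 0)) return("bin frequencies must be non-negative")
    if (object@pixelCount > 0L && abs(sum(object@bins) - 1) > 1e-9)
      return("bins must sum to 1")
    TRUE
  })

#' FeatureMatrix: images x selected hue bins
#'
#' Row i is image i's hue histogram restricted to the selected bins, so the
#' matrix is N x q with q <= 100.
#'
#' @slot X numeric matrix, N x q.
#' @slot selectedBins integer, ascending 1-based indices into the 100 bins.
#' @export
setClass("FeatureMatrix",
  representation(X = "matrix", selectedBins = "integer"),
  validity = function(object) {
    if (ncol(object@X) != length(object@selectedBins))
      return("one column per selected bin required")
    if (is.unsorted(object@selectedBins, strictly = TRUE))
      return("selectedBins must be strictly ascending")
    if (length(object@selectedBins) &&
        (min(object@selectedBins) < 1L || max(object@selectedBins) > 100L))
      return("selectedBins must index the 100 hue bins")
    TRUE
  })

#' PCAModel: standardization statistics plus eigenstructure
#'
#' Fitted on training features only. Columns are standardized to zero mean
#' and unit variance, so the covariance of the standardized data is the
#' correlation matrix and its eigenvalues sum to the number of retained
#' columns. Eigenvectors are stored in descending-eigenvalue order.
#'
#' @slot center,scale numeric, training column means and standard deviations.
#' @slot rotation numeric matrix of orthonormal eigenvector columns.
#' @slot eigenvalues numeric, non-increasing, >= 0.
#' @slot dropped integer, indices of zero-variance columns removed before
#'   standardization.
#' @slot q integer, column count of the original feature matrix.
#' @export
setClass("PCAModel",
  representation(center = "numeric", scale = "numeric", rotation = "matrix",
                 eigenvalues = "numeric", dropped = "integer", q = "integer"),
  validity = function(object) {
    p <- length(object@eigenvalues)
    if (!identical(dim(object@rotation), c(p, p)))
      return("rotation must be square, one column per eigenvalue")
    if (is.unsorted(rev(object@eigenvalues))) return("eigenvalues must be non-increasing")
    if (any(object@eigenvalues < -1e-8)) return("eigenvalues must be non-negative")
    g <- crossprod(object@rotation)
    if (max(abs(g - diag(p))) > 1e-8) return("eigenvector columns must be orthonormal")
    TRUE
  })

#' OutputCoding: class-to-codeword mapping for the MLP output layer
#'
#' Combinations CA/CB use 4 one-hot output neurons, CC/CD a 2-bit binary
#' code, and CE/CF a single neuron carrying the class index 1--4.
#'
#' @slot label one of CA, CB, CC, CD, CE, CF.
#' @slot nOutputs integer output-neuron count (4, 2 or 1).
#' @slot codewords numeric matrix, 4 rows (classes in canonical order) x
#'   nOutputs columns.
#' @slot hiddenTF,outputTF transfer-function names for the combination.
#' @export
setClass("OutputCoding",
  representation(label = "character", nOutputs = "integer",
                 codewords = "matrix", hiddenTF = "character",
                 outputTF = "character"),
  validity = function(object) {
    if (nrow(object@codewords) != 4L) return("four codewords required")
    if (ncol(object@codewords) != object@nOutputs)
      return("codeword width must equal nOutputs")
    if (anyDuplicated(apply(object@codewords, 1L, paste, collapse = ",")))
      return("codewords must be pairwise distinct")
    TRUE
  })

#' MLPModel: single-hidden-layer perceptron weights
#'
#' @slot W1 input-to-hidden weight matrix (nInputs x nHidden).
#' @slot b1 hidden bias vector.
#' @slot W2 hidden-to-output weight matrix (nHidden x nOutputs).
#' @slot b2 output bias vector.
#' @slot hiddenTF,outputTF transfer-function names (logsig/tansig/purelin).
#' @slot useBias logical; FALSE drops both bias terms from the forward pass.
#' @export
setClass("MLPModel",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 hiddenTF = "character", outputTF = "character",
                 useBias = "logical"),
  validity = function(object) {
    if (ncol(object@W1) != nrow(object@W2))
      return("hidden layer sizes of W1 and W2 differ")
    if (length(object@b1) != ncol(object@W1) || length(object@b2) != ncol(object@W2))
      return("bias lengths must match layer widths")
    if (!all(is.finite(object@W1)) || !all(is.finite(object@W2)))
      return("weights must be finite")
    TRUE
  })

#' GeneratorConfig: parameters of the synthetic bunch-image generator
#'
#' Defaults emulate the four MPOB color stages of oil-palm fresh fruit
#' bunches photographed outdoors: fruit disks on an elliptical bunch with
#' spiky stalk structure, class-dependent fruit hue distributions and a
#' per-image multiplicative lighting gain.
#'
#' @slot imageSize integer(2), height and width in pixels.
#' @slot classHueMean named numeric, circular-mean fruit hue (degrees) per class.
#' @slot classHueSD numeric, circular standard deviation of fruit hue (degrees).
#' @slot classValueMean named numeric, mean fruit brightness (HSV value) per class.
#' @slot classValueSD numeric, brightness standard deviation.
#' @slot fruitSaturation numeric, HSV saturation of fruit pixels.
#' @slot spikeColorMean,spikeColorSD numeric(3)/numeric, spike RGB mean and noise.
#' @slot backgroundColor,backgroundSD numeric(3)/numeric, background RGB mean and noise.
#' @slot fruitBlobCount integer, fruit disks rendered per bunch.
#' @slot fruitRadiusRange numeric(2), disk radius range in pixels.
#' @slot spikeCount integer, protruding radial spike strokes.
#' @slot lightingGainRange numeric(2), per-image multiplicative gain bounds.
#' @export
setClass("GeneratorConfig",
  representation(imageSize = "integer", classHueMean = "numeric",
                 classHueSD = "numeric", classValueMean = "numeric",
                 classValueSD = "numeric", fruitSaturation = "numeric",
                 spikeColorMean = "numeric", spikeColorSD = "numeric",
                 backgroundColor = "numeric", backgroundSD = "numeric",
                 fruitBlobCount = "integer", fruitRadiusRange = "numeric",
                 spikeCount = "integer", lightingGainRange = "numeric"),
  validity = function(object) {
    cls <- ripenessClasses()
    if (any(object@imageSize < 8L)) return("image size too small")
    if (!identical(names(object@classHueMean), cls) ||
        !identical(names(object@classValueMean), cls))
      return("class parameters must be named by the four ripeness classes")
    if (anyDuplicated(round(object@classHueMean %% 360, 6)))
      return("class hue means must be pairwise distinct")
    if (object@fruitBlobCount < 1L) return("need at least one fruit blob")
    if (diff(object@lightingGainRange) < 0 || any(object@lightingGainRange <= 0))
      return("lightingGainRange must be positive and non-decreasing")
    TRUE
  })

#' LabeledImage: a synthetic image with its class and ground-truth mask
#'
#' @slot image \linkS4class{RGBImage}.
#' @slot label one of the four ripeness classes.
#' @slot truthMask integer matrix: 0 = background, 1 = fruit, 2 = spike.
#' @export
setClass("LabeledImage",
  representation(image = "RGBImage", label = "character", truthMask = "matrix"),
  validity = function(object) {
    if (!object@label %in% ripenessClasses()) return("unknown ripeness label")
    if (!identical(dim(object@truthMask), dim(object@image@pixels)[1:2]))
      return("truth mask and image dimensions differ")
    if (!all(object@truthMask %in% 0:2))
      return("truth mask values must be 0 (background), 1 (fruit) or 2 (spike)")
    TRUE
  })

#' ResultGrid: test accuracies across combinations and feature counts
#'
#' Rows are transfer-function/output-coding combinations, columns feature
#' counts (a single column for the full-feature method MA, one per retained
#' principal-component count for MB). Cells hold test-set classification
#' accuracy percentages.
#'
#' @slot accuracy numeric matrix of h.c.a. percentages in [0, 100] (NA where
#'   a cell failed).
#' @slot method "MA" or "MB".
#' @slot featureCounts numeric, input-feature count per column.
#' @export
setClass("ResultGrid",
  representation(accuracy = "matrix", method = "character",
                 featureCounts = "numeric"),
  validity = function(object) {
    a <- object@accuracy[!is.na(object@accuracy)]
    if (length(a) && (any(a < 0) || any(a > 100)))
      return("accuracies must lie in [0, 100]")
    if (length(object@featureCounts) != ncol(object@accuracy))
      return("one feature count per grid column required")
    TRUE
  })
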