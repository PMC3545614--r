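#' Convert an RGB image to CIE L*a*b*
#'
#' Standard sRGB companding followed by the XYZ (D65 white point) to L*a*b*
#' transform. Chromatic information lives in the a* (green-red) and b*
#' (blue-yellow) planes, which downstream segmentation clusters.
#'
#' @param img an \linkS4class{RGBImage}.
#' @return A \linkS4class{LabImage} with the same dimensions.
#' @export
setGeneric("rgbToLab", function(img) standardGeneric("rgbToLab"))

#' Per-pixel hue from RGB
#'
#' Computes the HSI hue angle with the arccosine formula
#' \deqn{H = \cos^{-1}\frac{\frac12[(R-G)+(R-B)]}{[(R-G)^2+(R-B)(G-B)]^{1/2}}}
#' taking \eqn{H \leftarrow 360 - H} when \eqn{B > G}, so the result is in
#' degrees in [0, 360). Achromatic pixels (R = G = B) have a zero denominator
#' and are flagged invalid rather than assigned an arbitrary angle, which
#' would bias the first histogram bin. Wherever defined, the angle agrees
#' with the familiar max/min hexcone hue.
#'
#' @param img an \linkS4class{RGBImage}.
#' @return A \linkS4class{HueMap}.
#' @export
setGeneric("rgbToHue", function(img) standardGeneric("rgbToHue"))

#' Nearest-marker pixel classification
#'
#' Assigns every pixel to the closest color marker by Euclidean distance in
#' the a*b* plane (ties broken toward the lowest marker index) and returns
#' the binary fruit mask together with the mask-multiplied image.
#'
#' @param img a \linkS4class{LabImage}.
#' @param markers a \linkS4class{MarkerSet}.
#' @param rgb optional \linkS4class{RGBImage} used to render the segmented
#'   image; when missing, the segmented raster is reconstructed as zeros.
#' @return A \linkS4class{SegmentationResult}.
#' @export
setGeneric("classifyPixels", function(img, markers, rgb = NULL)
  standardGeneric("classifyPixels"))

#' Marker coordinates and labels
#' @param x a \linkS4class{MarkerSet}.
#' @return \code{markerCoords}: numeric matrix of (a*, b*) rows;
#'   \code{markerLabels}: character vector of region labels.
#' @export
setGeneric("markerCoords", function(x) standardGeneric("markerCoords"))

#' @rdname markerCoords
#' @export
setGeneric("markerLabels", function(x) standardGeneric("markerLabels"))

#' Number of principal components retained at a residual-variance threshold
#'
#' Returns the smallest m such that the trailing eigenvalues (components
#' m+1..q) carry at most \code{threshold} of the total variance. Smaller
#' thresholds therefore retain more components.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param threshold residual variance fraction in (0, 1).
#' @param m optional explicit override; returned unchanged after validation.
#' @return Integer component count in 1..q.
#' @export
setGeneric("chooseM", function(model, threshold, m = NULL)
  standardGeneric("chooseM"))

#' Project features onto leading principal components
#'
#' Standardizes columns with the training mean and standard deviation stored
#' in the model, then multiplies by the first m eigenvector columns.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param X numeric matrix or \linkS4class{FeatureMatrix} with the same
#'   column layout the model was fitted on.
#' @param m number of components; defaults to all.
#' @return N x m score matrix.
#' @export
setGeneric("projectPCA", function(model, X, m = NULL)
  standardGeneric("projectPCA"))

#' Forward pass of the multilayer perceptron
#'
#' Each hidden processing element sums its weighted inputs
#' (\eqn{net_j = \sum_i W_{ji} x_i}, plus a bias when enabled) and applies
#' the layer transfer function; the output layer repeats the same scheme.
#'
#' @param model an \linkS4class{MLPModel}.
#' @param x numeric vector of length nInputs, or an N x nInputs matrix.
#' @return Output vector (or N x nOutputs matrix for matrix input).
#' @export
setGeneric("mlpForward", function(model, x) standardGeneric("mlpForward"))

#' Grid accuracies
#' @param x a \linkS4class{ResultGrid}.
#' @return \code{gridAccuracy}: the numeric accuracy matrix;
#'   \code{bestAccuracy}: the grid maximum;
#'   \code{bestCell}: named list with combination, feature count and accuracy
#'   of the best cell.
#' @export
setGeneric("gridAccuracy", function(x) standardGeneric("gridAccuracy"))

#' @rdname gridAccuracy
#' @export
setGeneric("bestAccuracy", function(x) standardGeneric("bestAccuracy"))

#' @rdname gridAccuracy
#' @export
setGeneric("bestCell", function(x) standardGeneric("bestCell"))
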