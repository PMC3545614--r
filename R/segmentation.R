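#' K-means clustering in the a*b* chromaticity plane
#'
#' Lloyd's algorithm on the 2-D point set of (a*, b*) pixel values.
#' Initialization is farthest-point: the first centroid is a distinct pixel
#' color sampled under the seed and each further centroid is the point
#' maximizing its distance to those already chosen, which keeps well
#' separated color groups from sharing a centroid; iteration alternates
#' nearest-centroid
#' assignment (ties to the lowest centroid index) and centroid means until
#' assignments stop changing or \code{maxIter} is reached. A cluster left
#' empty is re-seeded to the point farthest from its centroid. The
#' within-cluster sum of squares is recorded per iteration and is
#' non-increasing.
#'
#' @param img a \linkS4class{LabImage}, or an n x 2 numeric matrix of
#'   (a*, b*) points.
#' @param k number of clusters, >= 2.
#' @param seed integer RNG seed for the initial sample.
#' @param maxIter iteration cap.
#' @param include optional logical matrix/vector selecting the pixels to
#'   cluster (e.g. the bunch region of a synthetic truth mask).
#' @return List with \code{centers} (k x 2), \code{cluster} (assignment per
#'   included pixel), \code{size} (pixels per cluster), \code{wcss}
#'   (objective per iteration), \code{iterations}.
#' @export
kmeansAB <- function(img, k, seed = 0, maxIter = 300L, include = NULL) {
  pts <- if (is(img, "LabImage")) cbind(a = as.vector(img@a), b = as.vector(img@b))
         else as.matrix(img)
  if (!is.null(include)) pts <- pts[as.vector(include), , drop = FALSE]
  if (k < 2) stop("k must be >= 2")
  uniq <- unique(pts)
  if (nrow(uniq) < k)
    stop("clustering error: only ", nrow(uniq), " distinct colors for k = ", k)
  withSeed(seed, {
    centers <- uniq[sample.int(nrow(uniq), 1L), , drop = FALSE]
    while (nrow(centers) < k) {
      minD <- apply(.pairDist2(uniq, centers), 1L, min)
      centers <- rbind(centers, uniq[which.max(minD), ])
    }
    assign <- rep(0L, nrow(pts))
    wcss <- numeric(0)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      d2 <- .pairDist2(pts, centers)
      newAssign <- as.integer(max.col(-d2, ties.method = "first"))
      # re-seed empty clusters to the point farthest from its centroid
      for (j in which(tabulate(newAssign, k) == 0L)) {
        far <- which.max(d2[cbind(seq_len(nrow(pts)), newAssign)])
        centers[j, ] <- pts[far, ]
        d2 <- .pairDist2(pts, centers)
        newAssign <- as.integer(max.col(-d2, ties.method = "first"))
      }
      wcss <- c(wcss, sum(d2[cbind(seq_len(nrow(pts)), newAssign)]))
      converged <- identical(newAssign, assign)
      assign <- newAssign
      for (j in seq_len(k))
        centers[j, ] <- colMeans(pts[assign == j, , drop = FALSE])
      if (converged || iter >= maxIter) break
    }
    finalD2 <- .pairDist2(pts, centers)
    list(centers = centers, cluster = assign,
         size = tabulate(assign, k),
         wcss = c(wcss, sum(finalD2[cbind(seq_len(nrow(pts)), assign)])),
         iterations = iter)
  })
}

# squared Euclidean distances between n x 2 points and k x 2 centers
.pairDist2 <- function(pts, centers) {
  outer(pts[, 1], centers[, 1], "-")^2 + outer(pts[, 2], centers[, 2], "-")^2
}

#' Derive labeled color markers from training images
#'
#' Runs per-image K-means in a*b* (k clusters each), pools all centroids,
#' and agglomeratively merges the closest pair (replacing it with the
#' pixel-count-weighted mean) until no two centroids are closer than
#' \code{mergeRadius}. The number of surviving markers is therefore emergent
#' from the data. Each marker is labeled fruit or spike either by the
#' majority ground-truth region of the pixels it attracts (when truth masks
#' are supplied) or by an explicit \code{labeling} vector.
#'
#' @param labImages list of \linkS4class{LabImage} training images.
#' @param truthMasks optional list of ternary truth masks (0 background,
#'   1 fruit, 2 spike); background pixels are excluded from clustering and
#'   labels follow majority overlap.
#' @param labeling optional character vector of fruit/spike labels applied to
#'   the merged markers (ordered by ascending a*, then b*); required when no
#'   truth masks are given.
#' @param k clusters per image (default 3).
#' @param mergeRadius minimum marker separation in a*b* units (default 8).
#' @param seed integer RNG seed.
#' @return A \linkS4class{MarkerSet} with fruit markers first, each group
#'   ordered by (a*, b*).
#' @export
deriveMarkers <- function(labImages, truthMasks = NULL, labeling = NULL,
                          k = 3L, mergeRadius = 8, seed = 0) {
  stopifnot(length(labImages) >= 1L)
  cents <- list(); wts <- numeric(0)
  for (i in seq_along(labImages)) {
    inc <- if (!is.null(truthMasks)) truthMasks[[i]] > 0L else NULL
    # one shared sub-seed: centroids then depend on image content only,
    # keeping the pooled marker set invariant to training-image order
    km <- kmeansAB(labImages[[i]], k = k, seed = subSeed(seed, 1), include = inc)
    cents[[i]] <- km$centers
    wts <- c(wts, km$size)
  }
  centers <- do.call(rbind, cents)
  # canonical ordering makes the greedy merge independent of image order
  ord <- order(centers[, 1], centers[, 2])
  centers <- centers[ord, , drop = FALSE]
  wts <- wts[ord]
  repeat {
    if (nrow(centers) == 1L) break
    d <- as.matrix(stats::dist(centers))
    diag(d) <- Inf
    if (min(d) >= mergeRadius) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    wsum <- wts[i] + wts[j]
    merged <- (centers[i, ] * wts[i] + centers[j, ] * wts[j]) / wsum
    centers <- centers[-j, , drop = FALSE]
    centers[i, ] <- merged
    wts[i] <- wsum
    wts <- wts[-j]
    ord <- order(centers[, 1], centers[, 2])
    centers <- centers[ord, , drop = FALSE]
    wts <- wts[ord]
  }
  if (nrow(centers) < 2L)
    stop("degenerate marker set: all centroids merged into one; ",
         "reduce mergeRadius")
  labels <- if (!is.null(truthMasks)) {
    .labelMarkersByTruth(centers, labImages, truthMasks)
  } else {
    if (is.null(labeling))
      stop("labeling error: supply truth masks or an explicit labeling")
    labeling
  }
  if (length(labels) != nrow(centers))
    stop("labeling error: ", length(labels), " labels for ",
         nrow(centers), " markers")
  if (!any(labels == "fruit") || !any(labels == "spike"))
    stop("labeling error: need at least one fruit and one spike marker")
  ord <- order(labels != "fruit", centers[, 1], centers[, 2])
  new("MarkerSet", coords = centers[ord, , drop = FALSE],
      labels = labels[ord], weights = wts[ord],
      kPerImage = as.integer(k), mergeRadius = mergeRadius)
}

# majority fruit/spike overlap of each marker's attracted (non-background)
# pixels with the ground-truth region mask
.labelMarkersByTruth <- function(centers, labImages, truthMasks) {
  votes <- matrix(0, nrow(centers), 2)  # cols: fruit, spike
  for (i in seq_along(labImages)) {
    inc <- truthMasks[[i]] > 0L
    pts <- cbind(as.vector(labImages[[i]]@a)[inc],
                 as.vector(labImages[[i]]@b)[inc])
    nearest <- max.col(-.pairDist2(pts, centers), ties.method = "first")
    truth <- truthMasks[[i]][inc]
    votes[, 1] <- votes[, 1] + vapply(seq_len(nrow(centers)), function(m)
      sum(nearest == m & truth == 1L), 0)
    votes[, 2] <- votes[, 2] + vapply(seq_len(nrow(centers)), function(m)
      sum(nearest == m & truth == 2L), 0)
  }
  ifelse(votes[, 1] >= votes[, 2], "fruit", "spike")
}

#' @rdname classifyPixels
setMethod("classifyPixels", "LabImage", function(img, markers, rgb = NULL) {
  if (nrow(markers@coords) == 0L) stop("empty marker set")
  pts <- cbind(as.vector(img@a), as.vector(img@b))
  nearest <- max.col(-.pairDist2(pts, markers@coords), ties.method = "first")
  mask <- matrix(as.integer(markers@labels[nearest] == "fruit"),
                 nrow(img@a), ncol(img@a))
  seg <- if (is.null(rgb)) array(0, dim = c(dim(mask), 3L)) else rgb@pixels
  seg <- seg * array(mask, dim = c(dim(mask), 3L))
  new("SegmentationResult", mask = mask, segmented = RGBImage(seg))
})

#' @rdname markerCoords
setMethod("markerCoords", "MarkerSet", function(x) x@coords)

#' @rdname markerCoords
setMethod("markerLabels", "MarkerSet", function(x) x@labels)
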