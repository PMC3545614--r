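#' Experiment configuration for the MA / MB comparison
#'
#' Method MA trains the classifier on the full selected-bin hue features
#' (standardized with training statistics); method MB first reduces them to
#' principal-component scores. Every stage that learns anything — color
#' markers, bin selection, standardization, PCA, early stopping — consumes
#' only the training and validation splits; the test split is touched once,
#' for the reported accuracy.
#'
#' @param method "MA" (full features) or "MB" (PCA-reduced).
#' @param combinations subset of CA..CF transfer/coding combinations.
#' @param pcCounts integer vector of retained principal-component counts
#'   (MB only; ignored for MA).
#' @param nPerClass synthetic images generated per class (default 52, i.e.
#'   208 images).
#' @param splitSizes integer(3) train/validation/test sizes (default
#'   120/28/60).
#' @param generator a \linkS4class{GeneratorConfig}.
#' @param k clusters per image for marker derivation.
#' @param mergeRadius marker merge radius in a*b* units.
#' @param nHidden hidden-layer width.
#' @param restarts seeded restarts per grid cell.
#' @param maxEpochs,patience training-loop controls.
#' @param binThreshold occupancy threshold for bin selection.
#' @param seed master seed; all stage seeds derive from it.
#' @return A named list of class \code{palmgradeConfig}.
#' @export
experimentConfig <- function(method = c("MA", "MB"),
                             combinations = c("CA", "CB", "CC", "CD", "CE", "CF"),
                             pcCounts = NULL,
                             nPerClass = 52L,
                             splitSizes = c(120L, 28L, 60L),
                             generator = generatorConfig(),
                             k = 3L, mergeRadius = 8,
                             nHidden = 15L, restarts = 5L,
                             maxEpochs = 1000L, patience = 6L,
                             binThreshold = 0, seed = 0) {
  method <- match.arg(method)
  if (method == "MB" && length(pcCounts) == 0L)
    stop("method MB requires nonempty pcCounts")
  stopifnot(all(combinations %in% c("CA", "CB", "CC", "CD", "CE", "CF")))
  structure(list(method = method, combinations = combinations,
                 pcCounts = pcCounts, nPerClass = as.integer(nPerClass),
                 splitSizes = as.integer(splitSizes), generator = generator,
                 k = as.integer(k), mergeRadius = mergeRadius,
                 nHidden = as.integer(nHidden), restarts = as.integer(restarts),
                 maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
                 binThreshold = binThreshold, seed = seed),
            class = "palmgradeConfig")
}

# shared pipeline front end: generate, split, derive markers, segment,
# histogram, select bins, assemble per-split feature matrices
.preparePipeline <- function(cfg) {
  ds <- generateDataset(cfg$generator, cfg$nPerClass, seed = subSeed(cfg$seed, 1))
  labels <- ds$manifest$label
  split <- splitDataset(labels, sizes = cfg$splitSizes, seed = subSeed(cfg$seed, 2))
  labImgs <- lapply(ds$images, function(li) rgbToLab(li@image))
  markers <- deriveMarkers(labImgs[split$train],
                           truthMasks = lapply(ds$images[split$train],
                                               function(li) li@truthMask),
                           k = cfg$k, mergeRadius = cfg$mergeRadius,
                           seed = subSeed(cfg$seed, 3))
  segs <- lapply(seq_along(ds$images), function(i)
    classifyPixels(labImgs[[i]], markers, rgb = ds$images[[i]]@image))
  hists <- lapply(seq_along(ds$images), function(i)
    hueHistogram(ds$images[[i]]@image, segs[[i]]@mask))
  bins <- selectBins(hists[split$train], threshold = cfg$binThreshold)
  fm <- buildFeatureMatrix(hists, bins)
  list(dataset = ds, labels = labels, split = split, markers = markers,
       segmentations = segs, histograms = hists, selectedBins = bins,
       X = fm@X,
       Xtrain = fm@X[split$train, , drop = FALSE],
       Xval = fm@X[split$val, , drop = FALSE],
       Xtest = fm@X[split$test, , drop = FALSE],
       yTrain = labels[split$train], yVal = labels[split$val],
       yTest = labels[split$test])
}

#' Run a full grading experiment
#'
#' Executes the whole pipeline — synthetic dataset, stratified split, marker
#' derivation, segmentation, hue histograms, training-set bin selection,
#' optional PCA — then trains one classifier per grid cell (combination x
#' feature count) with seeded restarts and reports the test-set
#' classification accuracy of each cell. Deterministic for a fixed
#' configuration. A failed cell is recorded as NA with its reason; an
#' experiment in which every cell fails is an error.
#'
#' @param cfg configuration from \code{\link{experimentConfig}}.
#' @param outDir optional directory; when given, the grid (CSV), marker set
#'   (JSON) and a provenance record (JSON: config, seeds, package version)
#'   are written there.
#' @return List with \code{grid} (a \linkS4class{ResultGrid}), \code{markers},
#'   \code{selectedBins}, \code{pca} (MB only), \code{failures} (named list
#'   of per-cell error messages), and \code{pipeline} internals.
#' @export
runExperiment <- function(cfg, outDir = NULL) {
  pp <- .preparePipeline(cfg)
  combos <- cfg$combinations
  pcaModel <- NULL
  if (cfg$method == "MA") {
    ctr <- colMeans(pp$Xtrain)
    sc <- apply(pp$Xtrain, 2L, stats::sd)
    sc[sc < 1e-12] <- 1
    std <- function(M) sweep(sweep(M, 2L, ctr), 2L, sc, "/")
    inputs <- list(list(train = std(pp$Xtrain), val = std(pp$Xval),
                        test = std(pp$Xtest), nFeatures = ncol(pp$Xtrain)))
  } else {
    pcaModel <- fitPCA(pp$Xtrain)
    pcs <- pmin(as.integer(cfg$pcCounts), length(pcaModel@eigenvalues))
    inputs <- lapply(pcs, function(m)
      list(train = projectPCA(pcaModel, pp$Xtrain, m),
           val = projectPCA(pcaModel, pp$Xval, m),
           test = projectPCA(pcaModel, pp$Xtest, m),
           nFeatures = m))
  }
  acc <- matrix(NA_real_, length(combos), length(inputs),
                dimnames = list(combos,
                                vapply(inputs, function(x) as.character(x$nFeatures), "")))
  failures <- list()
  for (ci in seq_along(combos)) {
    coding <- outputCoding(combos[ci])
    for (fi in seq_along(inputs)) {
      cellSeed <- subSeed(cfg$seed, 1000 + ci * 100 + fi)
      res <- tryCatch({
        fit <- trainClassifier(inputs[[fi]]$train, pp$yTrain,
                               inputs[[fi]]$val, pp$yVal, coding,
                               nHidden = cfg$nHidden, restarts = cfg$restarts,
                               seed = cellSeed, maxEpochs = cfg$maxEpochs,
                               patience = cfg$patience)
        pred <- decodeOutputs(mlpForward(fit$model, inputs[[fi]]$test), coding)
        hca(pred, pp$yTest)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[paste0(combos[ci], "@", inputs[[fi]]$nFeatures)]] <-
          conditionMessage(res)
      } else acc[ci, fi] <- res
    }
  }
  if (all(is.na(acc)))
    stop("experiment failed: every grid cell errored (first: ",
         failures[[1]], ")")
  grid <- new("ResultGrid", accuracy = acc, method = cfg$method,
              featureCounts = vapply(inputs, function(x) as.numeric(x$nFeatures), 0))
  out <- list(grid = grid, markers = pp$markers,
              selectedBins = pp$selectedBins, pca = pcaModel,
              failures = failures,
              pipeline = pp[c("split", "labels")])
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(acc, file.path(outDir, paste0("grid_", cfg$method, ".csv")))
    writeMarkers(pp$markers, file.path(outDir, "markers.json"))
    prov <- list(method = cfg$method, combinations = combos,
                 pc_counts = cfg$pcCounts, n_per_class = cfg$nPerClass,
                 split_sizes = cfg$splitSizes, seed = cfg$seed,
                 k = cfg$k, merge_radius = cfg$mergeRadius,
                 n_hidden = cfg$nHidden, restarts = cfg$restarts,
                 selected_bins = pp$selectedBins,
                 package_version = as.character(utils::packageVersion("palmgrade")))
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Compare the best accuracies of two methods
#'
#' Reports each grid's maximum test accuracy and their signed difference
#' (second minus first), the summary used to state how much PCA-reduced
#' inputs improve over full features.
#'
#' @param gridMA,gridMB \linkS4class{ResultGrid}s (any two grids).
#' @return List with \code{bestMA}, \code{bestMB}, \code{difference}.
#' @export
compareMethods <- function(gridMA, gridMB) {
  a <- bestAccuracy(gridMA)
  b <- bestAccuracy(gridMB)
  list(bestMA = a, bestMB = b, difference = round(b - a, 2))
}

#' @rdname gridAccuracy
setMethod("gridAccuracy", "ResultGrid", function(x) x@accuracy)

#' @rdname gridAccuracy
setMethod("bestAccuracy", "ResultGrid", function(x)
  max(x@accuracy, na.rm = TRUE))

#' @rdname gridAccuracy
setMethod("bestCell", "ResultGrid", function(x) {
  ij <- which(x@accuracy == max(x@accuracy, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(combination = rownames(x@accuracy)[ij[1]],
       nFeatures = x@featureCounts[ij[2]],
       accuracy = x@accuracy[ij[1], ij[2]])
})
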