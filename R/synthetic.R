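#' Construct a synthetic-generator configuration
#'
#' The generator emulates outdoor photographs of oil-palm fresh fruit
#' bunches: overlapping fruit disks on an elliptical bunch, thin radial
#' spike strokes, a low-chroma background, and a per-image multiplicative
#' lighting gain. Fruit hue follows the MPOB color progression — deep
#' violet (unripe) through reddish black (underripe) and red (ripe) to
#' reddish orange (overripe).
#'
#' @param imageSize integer(2) height, width; default 120 x 160.
#' @param classHueMean named circular-mean fruit hue per class, degrees.
#' @param classHueSD circular standard deviation of fruit hue, degrees.
#' @param classValueMean named mean fruit brightness (HSV value) per class;
#'   ripening fruit brightens as the dark anthocyanin surface gives way to red.
#' @param classValueSD brightness standard deviation.
#' @param fruitSaturation HSV saturation of fruit pixels.
#' @param spikeColorMean,spikeColorSD spike RGB mean and per-channel noise.
#' @param backgroundColor,backgroundSD background RGB mean and noise.
#' @param fruitBlobCount fruit disks per bunch.
#' @param fruitRadiusRange disk radius range, pixels.
#' @param spikeCount protruding radial spike strokes.
#' @param lightingGainRange per-image multiplicative gain bounds.
#' @return A \linkS4class{GeneratorConfig}.
#' @export
generatorConfig <- function(imageSize = c(120L, 160L),
                            classHueMean = c(unripe = 280, underripe = 350,
                                             ripe = 10, overripe = 30),
                            classHueSD = 8,
                            classValueMean = c(unripe = 0.30, underripe = 0.40,
                                               ripe = 0.55, overripe = 0.65),
                            classValueSD = 0.05,
                            fruitSaturation = 0.85,
                            spikeColorMean = c(0.24, 0.16, 0.09),
                            spikeColorSD = 0.03,
                            backgroundColor = c(0.45, 0.47, 0.52),
                            backgroundSD = 0.01,
                            fruitBlobCount = 60L,
                            fruitRadiusRange = c(5, 10),
                            spikeCount = 24L,
                            lightingGainRange = c(0.85, 1.15)) {
  new("GeneratorConfig",
      imageSize = as.integer(imageSize),
      classHueMean = classHueMean, classHueSD = classHueSD,
      classValueMean = classValueMean, classValueSD = classValueSD,
      fruitSaturation = fruitSaturation,
      spikeColorMean = spikeColorMean, spikeColorSD = spikeColorSD,
      backgroundColor = backgroundColor, backgroundSD = backgroundSD,
      fruitBlobCount = as.integer(fruitBlobCount),
      fruitRadiusRange = fruitRadiusRange,
      spikeCount = as.integer(spikeCount),
      lightingGainRange = lightingGainRange)
}

# Render the ternary region mask (0 background, 1 fruit, 2 spike): elliptical
# bunch filled with spike matrix, fruit disks drawn on top, radial spike
# strokes protruding past the bunch outline. Consumes the current RNG stream.
.renderMask <- function(cfg) {
  h <- cfg@imageSize[1]; w <- cfg@imageSize[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ay <- 0.42 * h; ax <- 0.42 * w
  y <- matrix(seq_len(h), h, w)
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- matrix(0L, h, w)
  mask[((y - cy) / ay)^2 + ((x - cx) / ax)^2 <= 1] <- 2L
  # protruding spikes
  theta <- 2 * pi * (seq_len(cfg@spikeCount) - 1) / cfg@spikeCount +
    stats::runif(cfg@spikeCount, -0.1, 0.1)
  tt <- seq(0.9, 1.15, by = 0.01)
  for (th in theta) {
    py <- round(cy + tt * ay * sin(th))
    px <- round(cx + tt * ax * cos(th))
    ok <- py >= 1 & py <= h & px >= 1 & px <= w
    idx <- cbind(py[ok], px[ok])
    mask[idx][mask[idx] == 0L] <- 2L
  }
  # fruit disks inside the bunch
  nb <- cfg@fruitBlobCount
  bth <- stats::runif(nb, 0, 2 * pi)
  br <- sqrt(stats::runif(nb)) * 0.88
  bcy <- cy + br * ay * sin(bth)
  bcx <- cx + br * ax * cos(bth)
  rad <- stats::runif(nb, cfg@fruitRadiusRange[1], cfg@fruitRadiusRange[2])
  for (i in seq_len(nb)) {
    y0 <- max(1L, floor(bcy[i] - rad[i])); y1 <- min(h, ceiling(bcy[i] + rad[i]))
    x0 <- max(1L, floor(bcx[i] - rad[i])); x1 <- min(w, ceiling(bcx[i] + rad[i]))
    if (y0 > y1 || x0 > x1) next
    yy <- y0:y1; xx <- x0:x1
    sub <- outer((yy - bcy[i])^2, (xx - bcx[i])^2, "+") <= rad[i]^2
    blk <- mask[yy, xx, drop = FALSE]
    blk[sub] <- 1L
    mask[yy, xx] <- blk
  }
  mask
}

# Render one image for a given class label on top of a region mask.
.renderImage <- function(cfg, label, mask) {
  h <- cfg@imageSize[1]; w <- cfg@imageSize[2]
  npx <- h * w
  R <- matrix(0, h, w); G <- matrix(0, h, w); B <- matrix(0, h, w)
  bg <- mask == 0L; fr <- mask == 1L; sp <- mask == 2L
  nbg <- sum(bg); nfr <- sum(fr); nsp <- sum(sp)
  if (nbg) {
    R[bg] <- stats::rnorm(nbg, cfg@backgroundColor[1], cfg@backgroundSD)
    G[bg] <- stats::rnorm(nbg, cfg@backgroundColor[2], cfg@backgroundSD)
    B[bg] <- stats::rnorm(nbg, cfg@backgroundColor[3], cfg@backgroundSD)
  }
  if (nsp) {
    R[sp] <- stats::rnorm(nsp, cfg@spikeColorMean[1], cfg@spikeColorSD)
    G[sp] <- stats::rnorm(nsp, cfg@spikeColorMean[2], cfg@spikeColorSD)
    B[sp] <- stats::rnorm(nsp, cfg@spikeColorMean[3], cfg@spikeColorSD)
  }
  if (nfr) {
    hue <- (cfg@classHueMean[[label]] + stats::rnorm(nfr, 0, cfg@classHueSD)) %% 360
    val <- pmin(0.85, pmax(0.05,
      stats::rnorm(nfr, cfg@classValueMean[[label]], cfg@classValueSD)))
    rgb <- hsvToRGB(hue, cfg@fruitSaturation, val)
    R[fr] <- rgb[, 1]; G[fr] <- rgb[, 2]; B[fr] <- rgb[, 3]
  }
  gain <- stats::runif(1, cfg@lightingGainRange[1], cfg@lightingGainRange[2])
  px <- array(c(R, G, B) * gain, dim = c(h, w, 3))
  px[px < 0] <- 0
  px[px > 1] <- 1
  RGBImage(px)
}

#' Generate a balanced, labeled synthetic dataset
#'
#' Produces \code{4 * nPerClass} images (equal numbers per ripeness class,
#' class-major order), each with its ground-truth region mask, plus a
#' manifest. Deterministic for a given seed: repeating the call reproduces
#' byte-identical rasters.
#'
#' @param cfg a \linkS4class{GeneratorConfig}.
#' @param nPerClass images per ripeness class, >= 1.
#' @param seed integer RNG seed.
#' @return List with \code{images} (list of \linkS4class{LabeledImage}) and
#'   \code{manifest} (data frame with columns id, label).
#' @export
#' @examples
#' ds <- generateDataset(generatorConfig(imageSize = c(40L, 50L),
#'                                       fruitBlobCount = 12L,
#'                                       fruitRadiusRange = c(3, 5)),
#'                       nPerClass = 1, seed = 1)
#' table(ds$manifest$label)
generateDataset <- function(cfg, nPerClass, seed = 0) {
  if (nPerClass < 1) stop("nPerClass must be >= 1")
  withSeed(seed, {
    labels <- rep(ripenessClasses(), each = nPerClass)
    images <- lapply(labels, function(lb) {
      mask <- .renderMask(cfg)
      new("LabeledImage", image = .renderImage(cfg, lb, mask),
          label = lb, truthMask = mask)
    })
    list(images = images,
         manifest = data.frame(id = seq_along(labels), label = labels,
                               stringsAsFactors = FALSE))
  })
}

#' Stratified train/validation/test split
#'
#' Randomly partitions a labeled manifest into disjoint training, validation
#' and test index sets, stratified by class so that each split's class
#' proportions deviate from the global ones by at most one image per class.
#' The default sizes follow the 120/28/60 split of a 208-image study.
#'
#' @param labels character vector of class labels, one per image.
#' @param sizes integer(3): train, validation, test counts; must sum to at
#'   most \code{length(labels)}.
#' @param seed integer RNG seed; the same seed reproduces the same split.
#' @return List of integer index vectors \code{train}, \code{val}, \code{test}.
#' @export
splitDataset <- function(labels, sizes = c(120L, 28L, 60L), seed = 0) {
  n <- length(labels)
  if (sum(sizes) > n)
    stop("split sizes (", sum(sizes), ") exceed available images (", n, ")")
  if (length(sizes) != 3L || any(sizes < 0))
    stop("sizes must be three non-negative counts")
  withSeed(seed, {
    classes <- unique(labels)
    pools <- lapply(classes, function(cl) {
      idx <- which(labels == cl)
      idx[sample.int(length(idx))]
    })
    names(pools) <- classes
    counts <- vapply(pools, length, 0L)
    out <- list(train = integer(0), val = integer(0), test = integer(0))
    remaining <- counts
    for (s in 1:3) {
      target <- sizes[s]
      if (target == 0) next
      # largest-remainder allocation proportional to remaining class sizes
      exact <- target * remaining / sum(remaining)
      base <- floor(exact)
      room <- target - sum(base)
      if (room > 0) {
        ord <- order(exact - base, decreasing = TRUE)
        base[ord[seq_len(room)]] <- base[ord[seq_len(room)]] + 1
      }
      take <- pmin(base, remaining)
      for (cl in classes) {
        k <- take[[cl]]
        if (k > 0) {
          used <- counts[[cl]] - remaining[[cl]]
          out[[s]] <- c(out[[s]], pools[[cl]][(used + 1):(used + k)])
          remaining[[cl]] <- remaining[[cl]] - k
        }
      }
      out[[s]] <- sort(out[[s]])
    }
    out
  })
}
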