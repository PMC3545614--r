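test_that("k-means recovers flat color patches exactly", {
  img <- rgbToLab(stripeImage(rbind(c(0.9, 0.1, 0.1), c(0.9, 0.1, 0.1),
                                    c(0.1, 0.1, 0.9), c(0.1, 0.1, 0.9))))
  km <- kmeansAB(img, k = 2, seed = 0)
  got <- km$centers[order(km$centers[, 1]), ]
  ab <- unique(cbind(as.vector(img@a), as.vector(img@b)))
  want <- ab[order(ab[, 1]), ]
  expect_equal(unname(got), unname(want), tolerance = 1e-9)
})

test_that("k-means is deterministic and validates its inputs", {
  set.seed(1)
  pts <- matrix(rnorm(400), ncol = 2)
  a <- kmeansAB(pts, k = 3, seed = 4)
  b <- kmeansAB(pts, k = 3, seed = 4)
  expect_identical(a$centers, b$centers)
  expect_identical(a$cluster, b$cluster)
  flat <- rgbToLab(flatImage(c(0.5, 0.2, 0.2)))
  expect_error(kmeansAB(flat, k = 3, seed = 0), "distinct colors")
  expect_error(kmeansAB(pts, k = 1, seed = 0), ">= 2")
})

test_that("k-means objective is non-increasing and matches the exhaustive optimum", {
  # three tight color groups, 8 distinct points, small weights
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1),
               c(20, 20), c(21, 20), c(20, 21),
               c(-15, 25), c(-16, 25))
  counts <- c(3, 2, 1, 4, 1, 1, 2, 2)
  img <- pts[rep(seq_len(nrow(pts)), counts), ]
  oracle <- bruteForceWCSS(pts, counts, k = 3)
  for (s in 1:5) {
    km <- kmeansAB(img, k = 3, seed = s)
    expect_true(all(diff(km$wcss) <= 1e-9))
    expect_equal(km$wcss[length(km$wcss)], oracle, tolerance = 1e-9)
  }
})

test_that("pixel classification follows nearest marker with index tie-break", {
  mk <- new("MarkerSet",
            coords = rbind(c(10, 0), c(-10, 0)),
            labels = c("fruit", "spike"), weights = c(1, 1),
            kPerImage = 3L, mergeRadius = 8)
  img <- new("LabImage",
             L = matrix(50, 1, 3),
             a = matrix(c(10, -10, 0), 1, 3),   # at fruit, at spike, equidistant
             b = matrix(0, 1, 3))
  seg <- classifyPixels(img, mk)
  expect_identical(seg@mask[1, ], c(1L, 0L, 1L))  # tie goes to index 1 = fruit
})

test_that("segmented image is the mask-multiplied original", {
  ds <- generateDataset(smallGenerator(), nPerClass = 1, seed = 3)
  li <- ds$images[[2]]
  lab <- rgbToLab(li@image)
  mk <- deriveMarkers(list(lab), truthMasks = list(li@truthMask), seed = 0)
  seg <- classifyPixels(lab, mk, rgb = li@image)
  expect_true(all(seg@mask %in% c(0L, 1L)))
  m3 <- array(seg@mask, dim = dim(li@image@pixels))
  expect_identical(seg@segmented@pixels, li@image@pixels * m3)
})

test_that("marker derivation finds well-separated group colors with labels", {
  # two fruit colors and two spike colors, far apart in a*b*
  mkImg <- function(cols, regions) {
    w <- length(regions)
    px <- array(0, dim = c(6L, w, 3L))
    for (j in seq_len(w)) px[, j, ] <- matrix(cols[j, ], 6L, 3L, byrow = TRUE)
    list(lab = rgbToLab(RGBImage(px)),
         mask = matrix(rep(regions, each = 6L), 6L, w))
  }
  cols <- rbind(c(0.9, 0.1, 0.1), c(0.2, 0.1, 0.7),
                c(0.1, 0.6, 0.1), c(0.8, 0.7, 0.1))
  fx <- mkImg(cols, c(1L, 1L, 2L, 2L))
  mk <- deriveMarkers(list(fx$lab), truthMasks = list(fx$mask),
                      k = 4, mergeRadius = 5, seed = 0)
  expect_equal(nrow(markerCoords(mk)), 4L)
  expect_equal(sum(markerLabels(mk) == "fruit"), 2L)
  expect_equal(sum(markerLabels(mk) == "spike"), 2L)
  # each marker sits on one of the four true patch colors
  truth <- cbind(as.vector(fx$lab@a[1, ]), as.vector(fx$lab@b[1, ]))
  d <- sqrt(palmgrade:::.pairDist2(markerCoords(mk), truth))
  expect_lt(max(apply(d, 1, min)), 1e-6)
})

test_that("an infinite merge radius collapses markers into a degenerate set", {
  ds <- generateDataset(smallGenerator(), nPerClass = 1, seed = 1)
  labs <- lapply(ds$images[1:2], function(li) rgbToLab(li@image))
  masks <- lapply(ds$images[1:2], function(li) li@truthMask)
  expect_error(deriveMarkers(labs, truthMasks = masks, mergeRadius = 1e9),
               "degenerate")
  expect_error(deriveMarkers(labs, labeling = NULL), "labeling")
})

test_that("marker derivation is invariant to training-image order", {
  ds <- generateDataset(smallGenerator(), nPerClass = 1, seed = 8)
  labs <- lapply(ds$images, function(li) rgbToLab(li@image))
  masks <- lapply(ds$images, function(li) li@truthMask)
  m1 <- deriveMarkers(labs, truthMasks = masks, seed = 0)
  perm <- c(3, 1, 4, 2)
  m2 <- deriveMarkers(labs[perm], truthMasks = masks[perm], seed = 0)
  expect_equal(markerLabels(m1), markerLabels(m2))
  expect_lt(max(abs(markerCoords(m1) - markerCoords(m2))), 1e-9)
})
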