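test_that("generator produces balanced labeled images with partition masks", {
  ds <- generateDataset(smallGenerator(), nPerClass = 3, seed = 5)
  expect_length(ds$images, 12L)
  expect_equal(as.vector(table(ds$manifest$label)), rep(3L, 4))
  for (li in ds$images) {
    expect_true(all(li@truthMask %in% 0:2))      # regions partition the frame
    expect_true(all(li@image@pixels >= 0 & li@image@pixels <= 1))
    expect_gt(sum(li@truthMask == 1L), 0)        # some fruit
    expect_gt(sum(li@truthMask == 2L), 0)        # some spike
  }
})

test_that("generation is byte-identical under a repeated seed", {
  a <- generateDataset(smallGenerator(), nPerClass = 2, seed = 9)
  b <- generateDataset(smallGenerator(), nPerClass = 2, seed = 9)
  for (i in seq_along(a$images)) {
    expect_identical(a$images[[i]]@image@pixels, b$images[[i]]@image@pixels)
    expect_identical(a$images[[i]]@truthMask, b$images[[i]]@truthMask)
  }
  c <- generateDataset(smallGenerator(), nPerClass = 2, seed = 10)
  expect_false(identical(a$images[[1]]@image@pixels, c$images[[1]]@image@pixels))
})

test_that("noise-free limit yields a single fruit hue per image", {
  cfg <- smallGenerator(classHueSD = 0, classValueSD = 0,
                        lightingGainRange = c(1, 1))
  ds <- generateDataset(cfg, nPerClass = 1, seed = 2)
  for (li in ds$images) {
    hm <- rgbToHue(li@image)
    hues <- hm@hue[li@truthMask == 1L & hm@valid]
    expect_lt(max(circDiff(hues, hues[1])), 1e-6)
    # fruit colors are emitted through the hexcone map while the feature path
    # measures the chromaticity angle; the two differ by at most ~1.15 degrees
    expect_lt(circDiff(hues[1], cfg@classHueMean[[li@label]]), 1.2)
  }
})

test_that("degenerate generator configs are rejected", {
  expect_error(generatorConfig(fruitBlobCount = 0L), "blob")
  expect_error(generatorConfig(imageSize = c(0L, 10L)), "size")
  expect_error(generatorConfig(classHueMean = c(unripe = 10, underripe = 10,
                                                ripe = 20, overripe = 30)),
               "distinct")
  expect_error(generateDataset(smallGenerator(), nPerClass = 0), ">= 1")
})

test_that("stratified split reproduces the 120/28/60 design exactly", {
  labels <- rep(ripenessClasses(), each = 52)
  sp <- splitDataset(labels, c(120L, 28L, 60L), seed = 0)
  expect_length(sp$train, 120L)
  expect_length(sp$val, 28L)
  expect_length(sp$test, 60L)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$val, sp$test), 0L)
  # per-class proportions deviate from global (1/4) by at most one image
  for (s in sp) {
    tab <- table(factor(labels[s], levels = ripenessClasses()))
    expect_lte(max(abs(tab - length(s) / 4)), 1)
  }
})

test_that("split handles boundary sizes and is seed-deterministic", {
  labels <- rep(c("ripe", "unripe"), 2)
  sp <- splitDataset(labels, c(4L, 0L, 0L), seed = 1)
  expect_equal(sort(sp$train), 1:4)
  expect_length(sp$val, 0L)
  expect_length(sp$test, 0L)
  labels208 <- rep(ripenessClasses(), each = 52)
  s1 <- splitDataset(labels208, seed = 3)
  s2 <- splitDataset(labels208, seed = 3)
  expect_identical(s1, s2)
  expect_error(splitDataset(labels, c(3L, 1L, 1L)), "exceed")
})

test_that("wider class hue separation never hurts end-to-end accuracy", {
  # compress the class hue centers around their midpoint by three factors
  base <- c(unripe = 280, underripe = 350, ripe = 10, overripe = 30)
  offs <- c(-60, 10, 30, 50)  # degrees from the 340-degree midpoint
  accAt <- function(f, seed = 0) {
    hm <- (340 + offs * f) %% 360
    names(hm) <- ripenessClasses()
    cfg <- smallExperiment(generator = smallGenerator(classHueMean = hm))
    bestAccuracy(runExperiment(cfg)$grid)
  }
  acc <- vapply(c(0.12, 0.5, 1), accAt, 0)
  expect_true(all(diff(acc) >= 0))
})
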