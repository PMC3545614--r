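test_that("transfer functions have the right ranges and derivatives", {
  s <- seq(-5, 5, by = 0.25)
  for (name in c("logsig", "tansig", "purelin")) {
    tf <- transferFunction(name)
    fd <- (tf$f(s + 1e-6) - tf$f(s - 1e-6)) / 2e-6
    expect_lt(max(abs(tf$df(s) - fd)), 1e-6)
  }
  lg <- transferFunction("logsig")$f
  tg <- transferFunction("tansig")$f
  expect_true(all(lg(s) > 0 & lg(s) < 1))
  expect_true(all(tg(s) > -1 & tg(s) < 1))
  expect_identical(transferFunction("purelin")$f(s), s)
  # the two sigmoids are linked: logsig(s) = (tansig(s/2) + 1) / 2
  expect_lt(max(abs(lg(s) - (tg(s / 2) + 1) / 2)), 1e-12)
  expect_error(transferFunction("relu"), "unknown")
})

test_that("output codings reproduce the published class codewords", {
  expect_equal(unname(encodeTargets("ripe", outputCoding("CA"))[1, ]),
               c(0, 0, 1, 0))
  expect_equal(unname(encodeTargets("overripe", outputCoding("CC"))[1, ]),
               c(1, 1))
  expect_equal(unname(encodeTargets("underripe", outputCoding("CE"))[1, ]), 2)
  expect_equal(outputCoding("CB")@nOutputs, 4L)
  expect_equal(outputCoding("CD")@nOutputs, 2L)
  expect_equal(outputCoding("CF")@nOutputs, 1L)
  # hidden/output transfer pairs per combination
  expect_equal(outputCoding("CC")@hiddenTF, "logsig")
  expect_equal(outputCoding("CD")@hiddenTF, "tansig")
  expect_equal(outputCoding("CE")@outputTF, "purelin")
  expect_error(outputCoding("CZ"), "unknown")
})

test_that("decoding picks the nearest codeword with clamping and tie rules", {
  expect_equal(decodeOutputs(c(0.9, 0.1, 0.2, 0.05), outputCoding("CA")),
               "unripe")
  expect_equal(decodeOutputs(0.4, outputCoding("CE")), "unripe")   # clamps to 1
  expect_equal(decodeOutputs(7.2, outputCoding("CE")), "overripe") # clamps to 4
  expect_equal(decodeOutputs(2.49, outputCoding("CE")), "underripe")
  # equidistant CC output (0.5, 0) between 00 and 10 -> lowest class index
  expect_equal(decodeOutputs(c(0.5, 0), outputCoding("CC")), "unripe")
  # decode(encode(class)) identity across all 24 class x coding cases
  for (label in c("CA", "CB", "CC", "CD", "CE", "CF")) {
    coding <- outputCoding(label)
    for (cls in ripenessClasses())
      expect_identical(decodeOutputs(encodeTargets(cls, coding), coding), cls)
  }
})

test_that("forward pass equals a per-neuron loop oracle", {
  model <- mlpInit(3, 4, 2, hiddenTF = "tansig", outputTF = "logsig", seed = 17)
  set.seed(18)
  for (i in 1:5) {
    x <- rnorm(3)
    expect_equal(mlpForward(model, x), naiveForward(model, x),
                 tolerance = 1e-12)
  }
  expect_error(mlpForward(model, rnorm(5)), "shape")
})

test_that("zero weights with logsig output produce 0.5 everywhere", {
  model <- mlpInit(3, 4, 2, seed = 0)
  model@W1[] <- 0; model@W2[] <- 0
  expect_equal(unname(mlpForward(model, c(1, 2, 3))), c(0.5, 0.5))
})

test_that("purelin/purelin network is the composed affine map", {
  model <- mlpInit(3, 4, 2, hiddenTF = "purelin", outputTF = "purelin",
                   seed = 23)
  model@b1 <- rnorm(4); model@b2 <- rnorm(2)
  X <- matrix(rnorm(15), 5, 3)
  direct <- sweep(sweep(X %*% model@W1, 2, model@b1, "+") %*% model@W2,
                  2, model@b2, "+")
  expect_equal(mlpForward(model, X), direct, tolerance = 1e-12)
})

test_that("analytic gradients match centered finite differences", {
  model <- mlpInit(3, 4, 2, hiddenTF = "tansig", outputTF = "logsig", seed = 29)
  set.seed(30)
  X <- matrix(rnorm(18), 6, 3)
  T <- encodeTargets(sample(ripenessClasses()[1:4], 6, replace = TRUE),
                     outputCoding("CC"))
  g <- palmgrade:::.mlpGrad(model, X, T)
  ng <- numericalGradient(model, X, T)
  relErr <- function(a, b) max(abs(a - b)) / max(abs(b), 1e-8)
  expect_lt(relErr(g$gW1, ng$gW1), 1e-6)
  expect_lt(relErr(g$gb1, ng$gb1), 1e-6)
  expect_lt(relErr(g$gW2, ng$gW2), 1e-6)
  expect_lt(relErr(g$gb2, ng$gb2), 1e-6)
})

test_that("training solves a linearly separable toy and records monotone loss", {
  X <- rbind(c(0, 0), c(0, 1), c(5, 5), c(5, 6))
  y <- c("unripe", "unripe", "ripe", "ripe")
  fit <- mlpTrain(X, y, X, y, outputCoding("CC"), nHidden = 3, seed = 1,
                  maxEpochs = 500L, patience = 100L)
  pred <- decodeOutputs(mlpForward(fit$model, X), outputCoding("CC"))
  expect_identical(pred, y)
  expect_true(all(diff(fit$history$trainLoss) <= 1e-12))
})

test_that("early stopping honors the patience boundary", {
  X <- rbind(c(0, 0), c(0, 1), c(5, 5), c(5, 6))
  y <- c("unripe", "unripe", "ripe", "ripe")
  fit <- mlpTrain(X, y, X, y, outputCoding("CC"), nHidden = 2, seed = 2,
                  maxEpochs = 1000L, patience = 0L)
  # patience 0: the run ends at the first epoch that fails to improve
  last <- nrow(fit$history)
  expect_lt(last, 1000L)
  expect_true(fit$history$valAccuracy[last] <= fit$valAccuracy + 1e-12)
})

test_that("divergent training reports the failing epoch", {
  # an absurd learning rate blows the purelin output layer past the floating
  # point range, so the candidate loss overflows on the first step
  X <- rbind(c(1, 0), c(0, 1))
  y <- c("unripe", "ripe")
  expect_error(
    mlpTrain(X, y, X, y, outputCoding("CE"), nHidden = 2, seed = 3,
             maxEpochs = 10L, lr0 = 1e160),
    "epoch")
})

test_that("network growing needs two hidden units for an XOR-like problem", {
  base <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  X <- base[rep(1:4, each = 6), ]
  y <- rep(c("unripe", "ripe", "ripe", "unripe"), each = 6)
  grown <- growHidden(X, y, X, y, outputCoding("CC"), hMax = 6,
                      stallLimit = 3, restarts = 3, seed = 5,
                      maxEpochs = 2000L, patience = 200L, lr0 = 0.5)
  expect_gte(grown$h, 2L)
  expect_gte(grown$valAccuracy, 0.99)
  degenerate <- growHidden(X, y, X, y, outputCoding("CC"), hMax = 6,
                           stallLimit = 0, seed = 5, maxEpochs = 50L)
  expect_identical(degenerate$h, 1L)
})

test_that("multi-restart selection is deterministic", {
  set.seed(44)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c("ripe", "unripe"), 10)
  f1 <- trainClassifier(X, y, X, y, outputCoding("CA"), nHidden = 3,
                        restarts = 3, seed = 7, maxEpochs = 100L)
  f2 <- trainClassifier(X, y, X, y, outputCoding("CA"), nHidden = 3,
                        restarts = 3, seed = 7, maxEpochs = 100L)
  expect_identical(f1$model@W1, f2$model@W1)
  expect_identical(f1$valAccuracy, f2$valAccuracy)
})

test_that("accuracy percentages follow the two-decimal convention", {
  pred <- c(rep("ripe", 56), rep("unripe", 4))
  truth <- rep("ripe", 60)
  expect_identical(hca(pred, truth), 93.33)
  expect_identical(hca(rep("ripe", 55), truth[1:55]), 100)
  truth2 <- rep("ripe", 60)
  pred2 <- c(rep("ripe", 55), rep("unripe", 5))
  expect_identical(hca(pred2, truth2), 91.67)
  expect_identical(hca(rep("unripe", 3), rep("ripe", 3)), 0)
  expect_error(hca(character(0), character(0)), "nonempty")
  expect_error(hca("ripe", c("ripe", "ripe")), "equal length")
})

test_that("MLP model JSON serialization round-trips", {
  model <- mlpInit(4, 3, 2, hiddenTF = "tansig", seed = 31)
  path <- tempfile(fileext = ".json")
  writeMLPModel(model, path)
  back <- readMLPModel(path)
  expect_equal(back@W1, model@W1)
  expect_equal(back@W2, model@W2)
  expect_identical(back@hiddenTF, "tansig")
})
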