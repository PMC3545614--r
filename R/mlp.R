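#' Transfer functions for MLP processing elements
#'
#' The three activations used by the classifier combinations: the logistic
#' sigmoid \eqn{f(s)=1/(1+e^{-s})} (range (0,1)), the hyperbolic tangent
#' sigmoid \eqn{f(s)=(e^s-e^{-s})/(e^s+e^{-s})} (range (-1,1)) and the
#' identity (purelin).
#'
#' @param name one of "logsig", "tansig", "purelin".
#' @return List with elements \code{name}, \code{f} (forward map) and
#'   \code{df} (derivative, as a function of s).
#' @export
#' @examples
#' tf <- transferFunction("logsig")
#' tf$f(0)   # 0.5
transferFunction <- function(name) {
  switch(name,
    logsig = list(name = "logsig",
                  f = function(s) 1 / (1 + exp(-s)),
                  df = function(s) { y <- 1 / (1 + exp(-s)); y * (1 - y) }),
    tansig = list(name = "tansig",
                  f = tanh,
                  df = function(s) 1 - tanh(s)^2),
    purelin = list(name = "purelin",
                   f = identity,
                   df = function(s) rep(1, length(s))),
    stop("unknown transfer function: ", name))
}

#' Output-coding / transfer-function combinations
#'
#' The six investigated classifier heads: CA and CB use four one-hot output
#' neurons, CC and CD a two-bit binary code (unripe 00, underripe 01,
#' ripe 10, overripe 11), CE and CF a single neuron carrying the class
#' index 1--4. Hidden transfer is logsig for CA/CC/CE and tansig for
#' CB/CD/CF; the output transfer is logsig except for the scalar codings,
#' which use purelin.
#'
#' @param label one of "CA", "CB", "CC", "CD", "CE", "CF".
#' @return An \linkS4class{OutputCoding}.
#' @export
outputCoding <- function(label) {
  spec <- list(
    CA = list(h = "logsig", o = "logsig", code = diag(4)),
    CB = list(h = "tansig", o = "logsig", code = diag(4)),
    CC = list(h = "logsig", o = "logsig",
              code = matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)),
    CD = list(h = "tansig", o = "logsig",
              code = matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)),
    CE = list(h = "logsig", o = "purelin", code = matrix(1:4, 4, 1)),
    CF = list(h = "tansig", o = "purelin", code = matrix(1:4, 4, 1))
  )[[label]]
  if (is.null(spec)) stop("unknown combination label: ", label)
  cw <- spec$code
  rownames(cw) <- ripenessClasses()
  new("OutputCoding", label = label, nOutputs = ncol(cw), codewords = cw,
      hiddenTF = spec$h, outputTF = spec$o)
}

#' Encode class labels as target vectors
#'
#' @param labels character vector of ripeness classes.
#' @param coding an \linkS4class{OutputCoding}.
#' @return N x nOutputs numeric target matrix.
#' @export
encodeTargets <- function(labels, coding) {
  idx <- match(labels, ripenessClasses())
  if (anyNA(idx)) stop("unknown ripeness label")
  coding@codewords[idx, , drop = FALSE]
}

#' Decode network outputs to class labels
#'
#' Each output row is mapped to the nearest codeword in Euclidean distance;
#' ties go to the lowest class index (unripe < underripe < ripe < overripe).
#' For the scalar codings this is equivalent to rounding and clamping to 1..4.
#'
#' @param y numeric vector (one sample) or N x nOutputs matrix.
#' @param coding an \linkS4class{OutputCoding}.
#' @return Character vector of class labels.
#' @export
decodeOutputs <- function(y, coding) {
  if (is.null(dim(y))) y <- matrix(y, ncol = coding@nOutputs)
  if (ncol(y) != coding@nOutputs)
    stop("output width ", ncol(y), " does not match coding ", coding@label)
  cw <- coding@codewords
  d2 <- outer(rowSums(y^2), rowSums(cw^2), "+") - 2 * y %*% t(cw)
  ripenessClasses()[max.col(-d2, ties.method = "first")]
}

#' Initialize an MLP with small random weights
#'
#' Weights are drawn uniformly from \eqn{\pm 1/\sqrt{fan_{in}}} under the
#' seed; biases start at zero.
#'
#' @param nInputs,nHidden,nOutputs layer widths.
#' @param hiddenTF,outputTF transfer-function names.
#' @param seed integer RNG seed.
#' @param useBias include bias terms (default TRUE); FALSE restores the
#'   literal bias-free weighted sum.
#' @return An \linkS4class{MLPModel}.
#' @export
mlpInit <- function(nInputs, nHidden, nOutputs, hiddenTF = "logsig",
                    outputTF = "logsig", seed = 0, useBias = TRUE) {
  withSeed(seed, {
    r1 <- 1 / sqrt(nInputs)
    r2 <- 1 / sqrt(nHidden)
    new("MLPModel",
        W1 = matrix(stats::runif(nInputs * nHidden, -r1, r1), nInputs, nHidden),
        b1 = numeric(nHidden),
        W2 = matrix(stats::runif(nHidden * nOutputs, -r2, r2), nHidden, nOutputs),
        b2 = numeric(nOutputs),
        hiddenTF = hiddenTF, outputTF = outputTF, useBias = useBias)
  })
}

# forward pass returning intermediate sums for backprop
.mlpForwardFull <- function(model, X) {
  fh <- transferFunction(model@hiddenTF)
  fo <- transferFunction(model@outputTF)
  net1 <- X %*% model@W1
  if (model@useBias) net1 <- sweep(net1, 2L, model@b1, "+")
  H <- fh$f(net1)
  net2 <- H %*% model@W2
  if (model@useBias) net2 <- sweep(net2, 2L, model@b2, "+")
  list(net1 = net1, H = H, net2 = net2, Y = fo$f(net2))
}

#' @rdname mlpForward
setMethod("mlpForward", "MLPModel", function(model, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != nrow(model@W1))
    stop("shape error: model expects ", nrow(model@W1), " inputs, got ", ncol(X))
  Y <- .mlpForwardFull(model, X)$Y
  if (vec) drop(Y) else Y
})

# mean-squared-error loss and analytic gradients (batch)
.mlpGrad <- function(model, X, T) {
  fh <- transferFunction(model@hiddenTF)
  fo <- transferFunction(model@outputTF)
  fw <- .mlpForwardFull(model, X)
  N <- nrow(X)
  E <- fw$Y - T
  loss <- mean(E^2)
  dY <- 2 * E / length(E) * fo$df(fw$net2)
  gW2 <- crossprod(fw$H, dY)
  gb2 <- colSums(dY)
  dH <- (dY %*% t(model@W2)) * fh$df(fw$net1)
  gW1 <- crossprod(X, dH)
  gb1 <- colSums(dH)
  list(loss = loss, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2)
}

#' Train an MLP by batch backpropagation with early stopping
#'
#' Minimizes the mean squared error between network outputs and encoded
#' class targets by full-batch gradient descent with an adaptive learning
#' rate: a step that increases the training loss is undone and the rate
#' halved, otherwise the rate grows by 5\%. Training stops at
#' \code{maxEpochs} or when the validation performance fails to improve for
#' \code{patience} consecutive epochs; the best-validation weights are
#' restored. Validation performance is classification accuracy of the
#' decoded outputs, with validation MSE breaking ties, so an epoch counts as
#' improving while either quantity advances.
#'
#' @param X,labels training features (N x nInputs) and class labels.
#' @param Xval,labelsVal validation features and labels.
#' @param coding an \linkS4class{OutputCoding}; fixes target codewords and
#'   both transfer functions.
#' @param nHidden hidden-layer width (default 15).
#' @param seed integer RNG seed for weight initialization.
#' @param maxEpochs epoch cap (default 1000).
#' @param patience stop once this many consecutive epochs fail to improve
#'   validation performance (default 6, minimum 1); 0 stops at the first
#'   non-improving epoch.
#' @param lr0 initial learning rate.
#' @param useBias include bias terms.
#' @return List with \code{model} (best-validation \linkS4class{MLPModel}),
#'   \code{history} (data frame: epoch, trainLoss, valAccuracy, valMSE, lr),
#'   \code{valAccuracy}, \code{valMSE}, \code{epochs}.
#' @export
mlpTrain <- function(X, labels, Xval, labelsVal, coding, nHidden = 15L,
                     seed = 0, maxEpochs = 1000L, patience = 6L, lr0 = 0.2,
                     useBias = TRUE) {
  X <- as.matrix(X); Xval <- as.matrix(Xval)
  if (nrow(X) < 1L) stop("empty training set")
  T <- encodeTargets(labels, coding)
  model <- mlpInit(ncol(X), nHidden, coding@nOutputs,
                   hiddenTF = coding@hiddenTF, outputTF = coding@outputTF,
                   seed = seed, useBias = useBias)
  lr <- lr0
  g <- .mlpGrad(model, X, T)
  prevLoss <- g$loss
  evalVal <- function(mod) {
    Y <- .mlpForwardFull(mod, Xval)$Y
    pred <- decodeOutputs(Y, coding)
    list(acc = mean(pred == labelsVal),
         mse = mean((Y - encodeTargets(labelsVal, coding))^2))
  }
  v <- evalVal(model)
  best <- list(model = model, acc = v$acc, mse = v$mse)
  stall <- 0L
  hist <- vector("list", maxEpochs)
  for (epoch in seq_len(maxEpochs)) {
    cand <- model
    cand@W1 <- model@W1 - lr * g$gW1
    cand@W2 <- model@W2 - lr * g$gW2
    if (model@useBias) {
      cand@b1 <- model@b1 - lr * g$gb1
      cand@b2 <- model@b2 - lr * g$gb2
    }
    gNew <- .mlpGrad(cand, X, T)
    if (!is.finite(gNew$loss))
      stop("divergence error: non-finite loss at epoch ", epoch)
    if (gNew$loss > prevLoss) {
      lr <- lr / 2           # undo the step, retry smaller
    } else {
      model <- cand
      g <- gNew
      prevLoss <- gNew$loss
      lr <- lr * 1.05
    }
    v <- evalVal(model)
    improved <- v$acc > best$acc + 1e-12 ||
      (abs(v$acc - best$acc) <= 1e-12 && v$mse < best$mse - 1e-15)
    if (improved) {
      best <- list(model = model, acc = v$acc, mse = v$mse)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    hist[[epoch]] <- c(epoch = epoch, trainLoss = prevLoss,
                       valAccuracy = v$acc, valMSE = v$mse, lr = lr)
    if (stall >= max(1L, patience)) break
  }
  history <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  list(model = best$model, history = history,
       valAccuracy = best$acc, valMSE = best$mse, epochs = nrow(history))
}

#' Train with multiple restarts, keeping the best validation model
#'
#' Realizes the maximum in the highest-classification-accuracy rule
#' reproducibly: the configuration is trained from \code{restarts} seeded
#' initializations and the model with the best validation accuracy
#' (validation MSE breaking ties) is kept.
#'
#' @inheritParams mlpTrain
#' @param restarts number of seeded restarts (default 5).
#' @param ... passed to \code{\link{mlpTrain}}.
#' @return As \code{\link{mlpTrain}}, plus \code{restartSeeds}.
#' @export
trainClassifier <- function(X, labels, Xval, labelsVal, coding,
                            nHidden = 15L, restarts = 5L, seed = 0, ...) {
  seeds <- vapply(seq_len(restarts), function(r) subSeed(seed, r), 0)
  best <- NULL
  for (s in seeds) {
    fit <- mlpTrain(X, labels, Xval, labelsVal, coding, nHidden = nHidden,
                    seed = s, ...)
    if (is.null(best) || fit$valAccuracy > best$valAccuracy + 1e-12 ||
        (abs(fit$valAccuracy - best$valAccuracy) <= 1e-12 &&
         fit$valMSE < best$valMSE))
      best <- fit
  }
  best$restartSeeds <- seeds
  best
}

#' Network growing: choose the hidden-layer width
#'
#' Trains networks with 1, 2, ... hidden neurons and returns the width with
#' the highest validation accuracy, stopping after \code{stallLimit}
#' consecutive non-improving increments or at \code{hMax}.
#'
#' @inheritParams mlpTrain
#' @param hMax maximum width tried (default 30).
#' @param stallLimit consecutive non-improving increments tolerated
#'   (default 3); 0 returns the single-neuron network's width.
#' @param restarts restarts per width.
#' @param ... passed to \code{\link{mlpTrain}}.
#' @return List with \code{h} (chosen width), \code{valAccuracy}, and
#'   \code{trace} (data frame of width vs validation accuracy).
#' @export
growHidden <- function(X, labels, Xval, labelsVal, coding, hMax = 30L,
                       stallLimit = 3L, restarts = 1L, seed = 0, ...) {
  stopifnot(hMax >= 1L)
  bestH <- 1L; bestAcc <- -Inf; stall <- 0L
  trace <- list()
  for (h in seq_len(hMax)) {
    fit <- trainClassifier(X, labels, Xval, labelsVal, coding, nHidden = h,
                           restarts = restarts, seed = subSeed(seed, 97 + h), ...)
    trace[[h]] <- c(h = h, valAccuracy = fit$valAccuracy)
    if (fit$valAccuracy > bestAcc + 1e-12) {
      bestAcc <- fit$valAccuracy
      bestH <- h
      stall <- 0L
    } else if (h > 1L) {
      stall <- stall + 1L
      if (stall >= stallLimit) break
    }
    if (h == 1L && stallLimit == 0L) break
  }
  list(h = bestH, valAccuracy = bestAcc,
       trace = as.data.frame(do.call(rbind, trace[!vapply(trace, is.null, TRUE)])))
}

#' Classification accuracy percentage (h.c.a. convention)
#'
#' The percentage of correct classifications, \eqn{100 n / N}, reported to
#' two decimals as accuracy tables conventionally print it (56 of 60
#' correct gives 93.33).
#'
#' @param predictions,truth equal-length nonempty class vectors.
#' @return Numeric percentage rounded to 2 decimals.
#' @export
hca <- function(predictions, truth) {
  if (length(predictions) == 0L || length(predictions) != length(truth))
    stop("predictions and truth must be nonempty and of equal length")
  round(100 * sum(predictions == truth) / length(truth), 2)
}

#' Serialize / restore an MLP model as JSON
#' @param model an \linkS4class{MLPModel}.
#' @param path file path.
#' @export
writeMLPModel <- function(model, path) {
  jsonlite::write_json(list(
    W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2,
    hidden_tf = model@hiddenTF, output_tf = model@outputTF,
    use_bias = model@useBias
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMLPModel
#' @export
readMLPModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("MLPModel", W1 = as.matrix(x$W1), b1 = as.numeric(x$b1),
      W2 = as.matrix(x$W2), b2 = as.numeric(x$b2),
      hiddenTF = x$hidden_tf, outputTF = x$output_tf, useBias = x$use_bias)
}
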