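#' Fit a PCA model on training features
#'
#' Columns are standardized to zero mean and unit variance using the
#' training statistics, so the sample covariance of the standardized data is
#' the correlation matrix and its eigenvalues sum to the number of columns.
#' A symmetric eigendecomposition yields eigenvector columns sorted by
#' descending eigenvalue; each eigenvector is sign-fixed so its
#' largest-magnitude entry is positive. Zero-variance columns (a selected
#' hue bin that happens to be constant) are dropped with a warning since
#' unit-variance scaling is undefined for them.
#'
#' @param X numeric matrix or \linkS4class{FeatureMatrix}, N x q with N >= 2.
#' @return A \linkS4class{PCAModel}.
#' @export
fitPCA <- function(X) {
  if (is(X, "FeatureMatrix")) X <- X@X
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("insufficient data: PCA needs at least 2 rows")
  ctr <- colMeans(X)
  sc <- apply(X, 2L, stats::sd)
  dropped <- which(sc < 1e-12)
  if (length(dropped)) {
    warning(length(dropped), " zero-variance column(s) dropped before PCA")
    Xk <- X[, -dropped, drop = FALSE]
    ctrK <- ctr[-dropped]; scK <- sc[-dropped]
  } else {
    Xk <- X; ctrK <- ctr; scK <- sc
  }
  Z <- sweep(sweep(Xk, 2L, ctrK), 2L, scK, "/")
  C <- stats::cov(Z)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  new("PCAModel", center = ctrK, scale = scK, rotation = vecs,
      eigenvalues = vals, dropped = as.integer(dropped),
      q = ncol(X))
}

#' @rdname chooseM
setMethod("chooseM", "PCAModel", function(model, threshold, m = NULL) {
  p <- length(model@eigenvalues)
  if (!is.null(m)) {
    m <- as.integer(m)
    if (m < 1L || m > p) stop("m override must lie in 1..", p)
    return(m)
  }
  if (threshold <= 0 || threshold >= 1)
    stop("config error: variation threshold must lie in (0, 1)")
  tot <- sum(model@eigenvalues)
  residual <- rev(cumsum(rev(model@eigenvalues)))  # residual[m+1] = tail sum from m+1
  for (mm in seq_len(p)) {
    tail <- if (mm < p) residual[mm + 1L] else 0
    if (tail / tot <= threshold) return(mm)
  }
  p
})

#' @rdname projectPCA
setMethod("projectPCA", "PCAModel", function(model, X, m = NULL) {
  if (is(X, "FeatureMatrix")) X <- X@X
  X <- as.matrix(X)
  if (ncol(X) != model@q)
    stop("shape error: model fitted on ", model@q, " columns, got ", ncol(X))
  if (length(model@dropped)) X <- X[, -model@dropped, drop = FALSE]
  if (is.null(m)) m <- length(model@eigenvalues)
  m <- as.integer(m)
  if (m < 1L || m > length(model@eigenvalues))
    stop("m must lie in 1..", length(model@eigenvalues))
  Z <- sweep(sweep(X, 2L, model@center), 2L, model@scale, "/")
  scores <- Z %*% model@rotation[, seq_len(m), drop = FALSE]
  colnames(scores) <- sprintf("PC%d", seq_len(m))
  scores
})

#' Serialize / restore a PCA model as JSON
#' @param model a \linkS4class{PCAModel}.
#' @param path file path.
#' @export
writePCAModel <- function(model, path) {
  jsonlite::write_json(list(
    center = model@center, scale = model@scale,
    rotation = model@rotation, eigenvalues = model@eigenvalues,
    dropped = model@dropped, q = model@q
  ), path, digits = NA)
  invisible(path)
}

#' @rdname writePCAModel
#' @export
readPCAModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PCAModel", center = as.numeric(x$center), scale = as.numeric(x$scale),
      rotation = as.matrix(x$rotation), eigenvalues = as.numeric(x$eigenvalues),
      dropped = as.integer(x$dropped), q = as.integer(x$q))
}
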