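# Independent oracles, deliberately implemented along different algebraic
# routes than the package code they check.

# Hexcone (max/min) hue in degrees [0, 360); NA on the gray axis.
hexconeHue <- function(R, G, B) {
  mx <- pmax(R, G, B)
  mn <- pmin(R, G, B)
  d <- mx - mn
  h <- ifelse(d == 0, NA_real_,
       ifelse(mx == R, ((G - B) / d) %% 6,
       ifelse(mx == G, (B - R) / d + 2, (R - G) / d + 4))) * 60
  h %% 360
}

# Chromaticity-plane hue via atan2 (no arccos, no explicit branch rule):
# the exact angle of the color's projection orthogonal to the gray axis.
chromaHue <- function(R, G, B) {
  (atan2(sqrt(3) * (G - B), 2 * R - G - B) * 180 / pi) %% 360
}

# Pixel with an exact chromaticity-plane hue h (degrees): invert the
# projection at a given chroma and mean level.
rgbWithHue <- function(h, chroma = 0.3, level = 0.4) {
  u <- chroma * cos(h * pi / 180)
  v <- chroma * sin(h * pi / 180) / sqrt(3)
  c(level + u / 3, level - u / 6 + v / 2, level - u / 6 - v / 2)
}

# smallest angular distance between two hue angles in degrees
circDiff <- function(h1, h2) {
  d <- abs(h1 - h2) %% 360
  pmin(d, 360 - d)
}

# Exhaustive k-partition within-cluster sum of squares for weighted 2-D
# points: enumerates every assignment of the m distinct points to k
# nonempty clusters.
bruteForceWCSS <- function(pts, weights, k) {
  m <- nrow(pts)
  grids <- do.call(expand.grid, rep(list(seq_len(k)), m))
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    a <- as.integer(grids[r, ])
    if (length(unique(a)) < k) next
    w <- 0
    for (j in seq_len(k)) {
      sel <- a == j
      cw <- weights[sel]
      cen <- colSums(pts[sel, , drop = FALSE] * cw) / sum(cw)
      w <- w + sum(cw * ((pts[sel, 1] - cen[1])^2 + (pts[sel, 2] - cen[2])^2))
    }
    best <- min(best, w)
  }
  best
}

# Closed-form eigenvalues of a symmetric 3x3 matrix via the trigonometric
# solution of its characteristic cubic (no LAPACK involved). Descending.
eig3x3Oracle <- function(C) {
  stopifnot(identical(dim(C), c(3L, 3L)))
  p1 <- C[1, 2]^2 + C[1, 3]^2 + C[2, 3]^2
  q <- sum(diag(C)) / 3
  if (p1 < 1e-300) return(sort(diag(C), decreasing = TRUE))
  p2 <- (C[1, 1] - q)^2 + (C[2, 2] - q)^2 + (C[3, 3] - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  B <- (C - q * diag(3)) / p
  detB <- B[1, 1] * (B[2, 2] * B[3, 3] - B[2, 3] * B[3, 2]) -
          B[1, 2] * (B[2, 1] * B[3, 3] - B[2, 3] * B[3, 1]) +
          B[1, 3] * (B[2, 1] * B[3, 2] - B[2, 2] * B[3, 1])
  r <- max(-1, min(1, detB / 2))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  sort(c(e1, 3 * q - e1 - e3, e3), decreasing = TRUE)
}

# Naive per-neuron forward pass with explicit loops (vs the matrix code).
naiveForward <- function(model, x) {
  tfEval <- function(name, s) switch(name,
    logsig = 1 / (1 + exp(-s)), tansig = tanh(s), purelin = s)
  nH <- ncol(model@W1)
  nO <- ncol(model@W2)
  h <- numeric(nH)
  for (j in seq_len(nH)) {
    s <- if (model@useBias) model@b1[j] else 0
    for (i in seq_along(x)) s <- s + model@W1[i, j] * x[i]
    h[j] <- tfEval(model@hiddenTF, s)
  }
  y <- numeric(nO)
  for (j in seq_len(nO)) {
    s <- if (model@useBias) model@b2[j] else 0
    for (i in seq_len(nH)) s <- s + model@W2[i, j] * h[i]
    y[j] <- tfEval(model@outputTF, s)
  }
  y
}

# Centered finite-difference gradient of the MLP mean-squared-error loss
# with respect to every weight and bias.
numericalGradient <- function(model, X, T, eps = 1e-6) {
  loss <- function(m) mean((palmgrade:::.mlpForwardFull(m, X)$Y - T)^2)
  gradOf <- function(slot) {
    v <- slot(model, slot)
    g <- v
    for (i in seq_along(v)) {
      mp <- model; mm <- model
      vp <- v; vm <- v
      vp[i] <- v[i] + eps; vm[i] <- v[i] - eps
      slot(mp, slot) <- vp; slot(mm, slot) <- vm
      g[i] <- (loss(mp) - loss(mm)) / (2 * eps)
    }
    g
  }
  list(gW1 = gradOf("W1"), gb1 = gradOf("b1"),
       gW2 = gradOf("W2"), gb2 = gradOf("b2"))
}
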