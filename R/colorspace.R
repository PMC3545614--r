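## sRGB (D65) constants
.srgb2xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                      0.2126729, 0.7151522, 0.0721750,
                      0.0193339, 0.1191920, 0.9503041),
                    nrow = 3, byrow = TRUE)
.whiteD65 <- c(0.95047, 1.00000, 1.08883)

.srgbToLinear <- function(u) ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)

.labF <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

#' @rdname rgbToLab
setMethod("rgbToLab", "RGBImage", function(img) {
  p <- img@pixels
  d <- dim(p)[1:2]
  rgbLin <- .srgbToLinear(matrix(p, ncol = 3L))
  xyz <- rgbLin %*% t(.srgb2xyz)
  fx <- .labF(xyz[, 1] / .whiteD65[1])
  fy <- .labF(xyz[, 2] / .whiteD65[2])
  fz <- .labF(xyz[, 3] / .whiteD65[3])
  new("LabImage",
      L = matrix(116 * fy - 16, d[1], d[2]),
      a = matrix(500 * (fx - fy), d[1], d[2]),
      b = matrix(200 * (fy - fz), d[1], d[2]))
})

#' @rdname rgbToHue
setMethod("rgbToHue", "RGBImage", function(img) {
  p <- img@pixels
  d <- dim(p)[1:2]
  R <- p[, , 1]; G <- p[, , 2]; B <- p[, , 3]
  num <- 0.5 * ((R - G) + (R - B))
  # den^2 = (R-G)^2 - (R-G)(R-B) + (R-B)^2 is a positive-definite form:
  # it vanishes exactly on the gray axis R = G = B.
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  valid <- den > 0
  ratio <- pmin(1, pmax(-1, num / ifelse(valid, den, 1)))
  h <- acos(ratio) * 180 / pi
  flip <- valid & (B > G)
  h[flip] <- 360 - h[flip]
  h[h >= 360] <- 0
  h[!valid] <- NA_real_
  new("HueMap", hue = matrix(h, d[1], d[2]), valid = matrix(valid, d[1], d[2]))
})

# HSV hue/saturation/value -> RGB, vectorized; used by the synthetic
# generator so that the emitted fruit pixels carry a prescribed hue.
hsvToRGB <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  R <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  G <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  B <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(R, G, B)
}
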