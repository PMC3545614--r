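#' Read and write RGB images and truth masks as PNG
#'
#' Images are stored as 24-bit PNG; load-normalization divides 8-bit values
#' by 255 so every pixel is in [0, 1]. Truth masks are single-channel PNGs
#' with gray levels 0 (background), 1/255 (fruit) and 2/255 (spike).
#'
#' @param path file path.
#' @return \code{readRGBImage}: an \linkS4class{RGBImage};
#'   \code{readTruthMask}: an integer matrix with values 0, 1, 2.
#' @export
readRGBImage <- function(path) {
  p <- png::readPNG(path)
  if (length(dim(p)) == 3L && dim(p)[3] == 4L) p <- p[, , 1:3, drop = FALSE]
  RGBImage(p)
}

#' @rdname readRGBImage
#' @param img an \linkS4class{RGBImage}.
#' @export
writeRGBImage <- function(img, path) {
  png::writePNG(img@pixels, path)
  invisible(path)
}

#' @rdname readRGBImage
#' @export
readTruthMask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' @rdname readRGBImage
#' @param mask integer matrix with values 0 (background), 1 (fruit), 2 (spike).
#' @export
writeTruthMask <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Serialize a marker set to JSON
#'
#' @param markers a \linkS4class{MarkerSet}.
#' @param path output file.
#' @export
writeMarkers <- function(markers, path) {
  jsonlite::write_json(list(
    a = markers@coords[, 1], b = markers@coords[, 2],
    labels = markers@labels, weights = markers@weights,
    k_per_image = markers@kPerImage, merge_radius = markers@mergeRadius
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMarkers
#' @return A \linkS4class{MarkerSet}.
#' @export
readMarkers <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("MarkerSet", coords = cbind(a = x$a, b = x$b),
      labels = x$labels, weights = as.numeric(x$weights),
      kPerImage = as.integer(x$k_per_image), mergeRadius = x$merge_radius)
}

#' Write a generated dataset to disk
#'
#' Writes each image and its ground-truth mask as PNG plus a CSV manifest
#' with columns \code{path}, \code{label}, \code{mask_path}.
#'
#' @param dataset list of \linkS4class{LabeledImage} from
#'   \code{\link{generateDataset}}.
#' @param dir output directory (created if missing).
#' @return The manifest data frame, invisibly written to
#'   \code{file.path(dir, "manifest.csv")}.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset)
  manifest <- data.frame(
    path = file.path(dir, sprintf("img_%03d.png", seq_len(n))),
    label = vapply(dataset, function(d) d@label, ""),
    mask_path = file.path(dir, sprintf("mask_%03d.png", seq_len(n))),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    writeRGBImage(dataset[[i]]@image, manifest$path[i])
    writeTruthMask(dataset[[i]]@truthMask, manifest$mask_path[i])
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i)
    new("LabeledImage", image = readRGBImage(manifest$path[i]),
        label = manifest$label[i],
        truthMask = readTruthMask(manifest$mask_path[i])))
}
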