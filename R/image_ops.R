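# Low-level raster helpers. Images are plain numeric arrays (rows, cols, 3)
# with values in [0, 1]; masks are logical matrices of the same spatial shape.

#' Read a slide raster from PNG or TIFF
#'
#' Returns an RGB array (rows x cols x 3) in \[0, 1\]. Grayscale rasters are
#' replicated across channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric array of dimension `c(rows, cols, 3)`.
#' @export
read_slide_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("Reading TIFF rasters requires the 'tiff' package.")
      }
      tiff::readTIFF(path)
    },
    abort(sprintf("Unsupported raster format '%s' (use PNG or TIFF).", ext))
  )
  as_rgb_array(img)
}

as_rgb_array <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) != 3L) abort("Raster must be 2- or 3-dimensional.")
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L) abort("Raster must have 3 colour channels.")
  storage.mode(img) <- "double"
  img
}

#' Write an RGB array to PNG
#'
#' @param img Array `(rows, cols, 3)` in \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slide_png <- function(img, path) {
  png::writePNG(clamp(img), target = path)
  invisible(path)
}

# Bilinear resize to (rows, cols). EBImage operates on the first two array
# dimensions symmetrically, so the row/col-major convention is preserved.
resize_bilinear <- function(img, rows, cols) {
  if (all(dim(img)[1:2] == c(rows, cols))) return(img)
  out <- EBImage::resize(img, w = rows, h = cols, filter = "bilinear")
  as_rgb_array(as.array(out))
}

# Mirror-pad an image by `pad` pixels on every side (reflection without
# repeating the edge row), used as rotation fill so no artificial background
# colour enters augmented tiles.
mirror_pad <- function(img, pad) {
  d <- dim(img)
  ridx <- reflect_index(seq_len(d[1] + 2 * pad) - pad, d[1])
  cidx <- reflect_index(seq_len(d[2] + 2 * pad) - pad, d[2])
  img[ridx, cidx, , drop = FALSE]
}

reflect_index <- function(i, n) {
  # map arbitrary integer positions onto 1..n by mirror reflection
  period <- 2L * n
  j <- ((i - 1L) %% period + period) %% period
  ifelse(j < n, j + 1L, period - j)
}

# Rotate about the tile centre by `angle` degrees with mirrored borders,
# preserving the tile size.
rotate_reflect <- function(img, angle) {
  d <- dim(img)
  pad <- ceiling(max(d[1:2]) * (sqrt(2) - 1) / 2) + 2L
  padded <- mirror_pad(img, pad)
  rot <- EBImage::rotate(padded, angle,
    filter = "bilinear",
    output.dim = dim(padded)[1:2], bg.col = "white"
  )
  rot <- as_rgb_array(as.array(rot))
  clamp(rot[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE])
}

# 3x3 Gaussian blur (kernel [1,2,1] x [1,2,1] / 16) with replicated borders.
gaussian_blur3 <- function(img) {
  k <- outer(c(1, 2, 1), c(1, 2, 1)) / 16
  out <- EBImage::filter2(img, k, boundary = "replicate")
  clamp(as_rgb_array(as.array(out)))
}

# Zoom in by factor `s` >= 1: crop the central 1/s field and resize back.
scale_zoom <- function(img, s) {
  if (abs(s - 1) < 1e-12) return(img)
  d <- dim(img)
  ch <- max(2L, round(d[1] / s))
  cw <- max(2L, round(d[2] / s))
  r0 <- floor((d[1] - ch) / 2)
  c0 <- floor((d[2] - cw) / 2)
  crop <- img[r0 + seq_len(ch), c0 + seq_len(cw), , drop = FALSE]
  resize_bilinear(crop, d[1], d[2])
}

# RGB (rows, cols, 3) -> HSV channels as a list of matrices, all in [0, 1].
rgb_array_to_hsv <- function(img) {
  d <- dim(img)
  m <- rbind(
    as.vector(img[, , 1]),
    as.vector(img[, , 2]),
    as.vector(img[, , 3])
  )
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  lapply(1:3, function(i) matrix(hsv[i, ], d[1], d[2]))
}

# Inverse of rgb_array_to_hsv, vectorised (h, s, v in [0, 1]).
hsv_to_rgb_array <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
    ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
    ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
    ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, dim = c(dim(h), 3L))
  out[, , 1] <- r
  out[, , 2] <- g
  out[, , 3] <- b
  clamp(out)
}
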