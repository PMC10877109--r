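#' Construct a slide image object
#'
#' Bundles a slide raster with its identifier, physical pixel size and
#' pathology diagnosis. The raster is an RGB array `(rows, cols, 3)` in
#' \[0, 1\]; `microns_per_pixel` ties the raster to physical scale so that
#' tiling can be requested in microns.
#'
#' @param slide_id Character scalar identifier.
#' @param pixels RGB array `(rows, cols, 3)` in \[0, 1\].
#' @param microns_per_pixel Positive finite scalar, microns per raster pixel.
#' @param diagnosis One of `"HCC"`, `"iCCA"`, `"cHCC-CCA"`, `"unknown"`.
#' @return A `histo_slide` object (list with the validated fields).
#' @export
slide_image <- function(slide_id, pixels, microns_per_pixel,
                        diagnosis = c("unknown", "HCC", "iCCA", "cHCC-CCA")) {
  if (!is.character(slide_id) || length(slide_id) != 1L || !nzchar(slide_id)) {
    abort("`slide_id` must be a non-empty string.")
  }
  pixels <- as_rgb_array(pixels)
  stopifnot_scalar_number(microns_per_pixel, "microns_per_pixel", positive = TRUE)
  diagnosis <- match.arg(diagnosis)
  structure(
    list(
      slide_id = slide_id, pixels = pixels,
      microns_per_pixel = microns_per_pixel, diagnosis = diagnosis
    ),
    class = "histo_slide"
  )
}

#' @export
print.histo_slide <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<histo_slide> %s: %d x %d px @ %.3g um/px, diagnosis %s\n",
    x$slide_id, d[1], d[2], x$microns_per_pixel, x$diagnosis
  ))
  invisible(x)
}

#' Read a slide manifest
#'
#' A slide manifest is a CSV with columns `slide_id`, `path`,
#' `microns_per_pixel`, `diagnosis` and `split`; extra columns are kept.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_slide_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("slide_id", "path", "microns_per_pixel", "diagnosis", "split")
  missing <- setdiff(needed, names(m))
  if (length(missing) > 0) {
    abort(sprintf("Slide manifest lacks columns: %s.", paste(missing, collapse = ", ")))
  }
  m
}
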