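#' Compute a tissue mask for a slide
#'
#' Separates stained tissue from the near-white scanner background by
#' thresholding HSV saturation: background pixels are bright and essentially
#' unsaturated, eosin-stained tissue is not. With `method = "otsu"` the
#' threshold is derived from the saturation histogram instead of being fixed.
#'
#' @param slide A `histo_slide`.
#' @param saturation_threshold Saturation cut-off in \[0, 1\]; pixels strictly
#'   above it count as tissue. Default 0.07.
#' @param method `"threshold"` (fixed cut-off) or `"otsu"` (data-driven).
#' @return Logical matrix `(rows, cols)`, `TRUE` on tissue. An all-background
#'   slide yields an all-`FALSE` mask with a warning.
#' @export
compute_tissue_mask <- function(slide, saturation_threshold = 0.07,
                                method = c("threshold", "otsu")) {
  method <- match.arg(method)
  if (length(slide$pixels) == 0) abort("Slide raster is empty.")
  s <- rgb_array_to_hsv(slide$pixels)[[2]]
  thr <- if (method == "otsu") EBImage::otsu(s, range = c(0, 1)) else saturation_threshold
  mask <- s > thr
  if (!any(mask)) {
    warn(sprintf("Slide '%s' appears to contain no tissue.", slide$slide_id))
  }
  mask
}

#' Extract labelled patches from a slide
#'
#' Tiles the slide on a non-overlapping grid of square windows of physical
#' edge `patch_microns` (converted to source pixels through the slide's
#' `microns_per_pixel` and rounded to the nearest pixel; windows are
#' half-open `[r, r+s) x [c, c+s)`, 0-based, origin top-left). Windows whose
#' tissue fraction exceeds `tissue_threshold` are kept and resampled
#' bilinearly to `patch_pixels` square tiles. A window's weak label is
#' `"tumour"` exactly when more than half of its pixels fall in the tumour
#' mask — border windows are labelled by this majority rule.
#'
#' @param slide A `histo_slide`.
#' @param tissue_mask Logical matrix from [compute_tissue_mask()].
#' @param tumour_mask Logical matrix from [rasterise_annotations()], or `NULL`
#'   for a slide with no tumour annotation (all labels `"non_tumour"`).
#' @param patch_microns Physical window edge in microns (default 125).
#' @param patch_pixels Output tile edge in pixels (default 256).
#' @param tissue_threshold Minimum tissue fraction, exclusive (default 0.5).
#' @return A tibble with one row per retained patch: `slide_id`, `grid_row`,
#'   `grid_col` (0-based), `tissue_fraction`, `tumour_fraction`, `weak_label`
#'   and a `pixels` list-column of `patch_pixels` square RGB tiles.
#' @export
extract_patches <- function(slide, tissue_mask, tumour_mask = NULL,
                            patch_microns = 125, patch_pixels = 256,
                            tissue_threshold = 0.5) {
  stopifnot_scalar_number(patch_microns, "patch_microns", positive = TRUE)
  d <- dim(slide$pixels)
  win <- round(patch_microns / slide$microns_per_pixel)
  if (win < 1) {
    abort(sprintf(
      "patch_microns = %g maps to %.2f source pixels; it must cover at least one pixel.",
      patch_microns, patch_microns / slide$microns_per_pixel
    ))
  }
  if (!all(dim(tissue_mask) == d[1:2])) abort("tissue_mask shape does not match the slide.")
  if (!is.null(tumour_mask) && !all(dim(tumour_mask) == d[1:2])) {
    abort("tumour_mask shape does not match the slide.")
  }
  n_rows <- d[1] %/% win
  n_cols <- d[2] %/% win
  if (n_rows < 1 || n_cols < 1) {
    warn(sprintf("Slide '%s' is smaller than one %d-pixel window; no patches.", slide$slide_id, win))
    return(empty_patch_tibble())
  }
  grid <- expand.grid(grid_row = seq_len(n_rows) - 1L, grid_col = seq_len(n_cols) - 1L)
  grid <- grid[order(grid$grid_row, grid$grid_col), ]
  rows <- purrr::pmap(grid, function(grid_row, grid_col) {
    ri <- grid_row * win + seq_len(win)
    ci <- grid_col * win + seq_len(win)
    tf <- mean(tissue_mask[ri, ci])
    if (tf <= tissue_threshold) return(NULL)
    uf <- if (is.null(tumour_mask)) 0 else mean(tumour_mask[ri, ci])
    tile <- resize_bilinear(slide$pixels[ri, ci, , drop = FALSE], patch_pixels, patch_pixels)
    tibble(
      slide_id = slide$slide_id,
      grid_row = as.integer(grid_row), grid_col = as.integer(grid_col),
      tissue_fraction = tf, tumour_fraction = uf,
      weak_label = if (uf > 0.5) "tumour" else "non_tumour",
      pixels = list(tile)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty_patch_tibble() else out
}

empty_patch_tibble <- function() {
  tibble(
    slide_id = character(), grid_row = integer(), grid_col = integer(),
    tissue_fraction = double(), tumour_fraction = double(),
    weak_label = character(), pixels = list()
  )
}

#' Write a patch manifest (and optionally the tiles) to disk
#'
#' @param patches Patch tibble from [extract_patches()].
#' @param path Manifest CSV path.
#' @param tile_dir If non-`NULL`, tiles are written there as
#'   `<slide_id>_r<row>_c<col>.png` and the manifest gains a `patch_path`
#'   column.
#' @return The manifest tibble (without the `pixels` column), invisibly.
#' @export
write_patch_manifest <- function(patches, path, tile_dir = NULL) {
  man <- dplyr::select(patches, -"pixels")
  if (!is.null(tile_dir)) {
    dir.create(tile_dir, recursive = TRUE, showWarnings = FALSE)
    man$patch_path <- purrr::pmap_chr(
      list(patches$slide_id, patches$grid_row, patches$grid_col, patches$pixels),
      function(sid, r, c, px) {
        p <- file.path(tile_dir, sprintf("%s_r%03d_c%03d.png", sid, r, c))
        write_slide_png(px, p)
        p
      }
    )
  }
  readr::write_csv(man, path)
  invisible(man)
}
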