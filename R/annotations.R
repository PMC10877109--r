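# Tumour outlines are closed polygons in pixel coordinates: 0-based, origin
# at the top-left corner, x along columns and y along rows. A pixel (r, c)
# is covered when its centre (c + 0.5, r + 0.5) falls inside a polygon under
# the even-odd rule; coverage is the union over polygons.

#' Construct an annotation set
#'
#' @param slide_id Character scalar.
#' @param polygons List of numeric matrices with columns `x`, `y` (pixel
#'   coordinates, one row per vertex, not necessarily closed — the closing
#'   edge is implicit). Each polygon needs at least 3 vertices and non-zero
#'   area.
#' @return A `histo_annotations` object.
#' @export
annotation_set <- function(slide_id, polygons) {
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    # drop an explicit closing vertex
    if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    p
  })
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    if (nrow(p) < 3L) abort(sprintf("Polygon %d has fewer than 3 vertices.", i))
    if (abs(polygon_area(p)) < .Machine$double.eps) {
      abort(sprintf("Polygon %d has zero area.", i))
    }
  }
  structure(list(slide_id = slide_id, polygons = polygons),
    class = "histo_annotations"
  )
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# TRUE when any two non-adjacent edges properly cross.
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  ax <- p[, 1]; ay <- p[, 2]
  bx <- p[j, 1]; by <- p[j, 2]
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (e in seq_len(n - 2L)) {
    # candidate partner edges, skipping adjacent ones
    f <- setdiff((e + 2L):n, if (e == 1L) n else integer(0))
    if (length(f) == 0) next
    d1 <- cross(ax[e], ay[e], bx[e], by[e], ax[f], ay[f])
    d2 <- cross(ax[e], ay[e], bx[e], by[e], bx[f], by[f])
    d3 <- cross(ax[f], ay[f], bx[f], by[f], rep(ax[e], length(f)), rep(ay[e], length(f)))
    d4 <- cross(ax[f], ay[f], bx[f], by[f], rep(bx[e], length(f)), rep(by[e], length(f)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Rasterise tumour annotations to a binary mask
#'
#' A pixel is marked tumour when its centre lies inside at least one
#' annotation polygon (even-odd rule per polygon, union across polygons).
#'
#' @param slide A `histo_slide`, or an integer vector `c(rows, cols)`.
#' @param ann A `histo_annotations` object.
#' @return Logical matrix `(rows, cols)`, `TRUE` on tumour.
#' @export
rasterise_annotations <- function(slide, ann) {
  d <- if (inherits(slide, "histo_slide")) dim(slide$pixels)[1:2] else as.integer(slide)
  H <- d[1]; W <- d[2]
  mask <- matrix(FALSE, H, W)
  py <- seq_len(H) - 0.5  # pixel-centre y per row
  px <- seq_len(W) - 0.5  # pixel-centre x per column
  for (k in seq_along(ann$polygons)) {
    p <- ann$polygons[[k]]
    if (polygon_self_intersects(p)) {
      abort(sprintf("Polygon %d is self-intersecting; fix the annotation.", k))
    }
    inside <- matrix(FALSE, H, W)
    n <- nrow(p)
    j <- c(n, seq_len(n - 1L))
    for (e in seq_len(n)) {
      yi <- p[e, 2]; yj <- p[j[e], 2]
      xi <- p[e, 1]; xj <- p[j[e], 1]
      rows <- which((yi > py) != (yj > py))
      if (length(rows) == 0) next
      xcross <- xi + (xj - xi) * (py[rows] - yi) / (yj - yi)
      hit <- outer(xcross, px, `>`)  # centre strictly left of the crossing
      inside[rows, ] <- xor(inside[rows, , drop = FALSE], hit)
    }
    mask <- mask | inside
  }
  mask
}

#' Read polygon annotations from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with coordinates in pixel
#' units (x along columns, y along rows, origin top-left). Only the outer
#' ring of each polygon is used.
#'
#' @param path GeoJSON file, conventionally named `<slide_id>.geojson`.
#' @param slide_id Identifier; defaults to the file stem.
#' @return A `histo_annotations` object.
#' @export
read_annotations_geojson <- function(path, slide_id = NULL) {
  slide_id <- slide_id %||% tools::file_path_sans_ext(basename(path))
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% abort("GeoJSON file has no 'features' array.")
  polygons <- lapply(feats, function(f) {
    geom <- f$geometry
    if (!identical(geom$type, "Polygon")) {
      abort(sprintf("Feature geometry '%s' is not a Polygon.", geom$type %||% "NULL"))
    }
    ring <- geom$coordinates[[1]]
    do.call(rbind, lapply(ring, function(v) c(x = v[[1]], y = v[[2]])))
  })
  annotation_set(slide_id, polygons)
}

#' Write an annotation set to GeoJSON
#'
#' @param ann A `histo_annotations` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_geojson <- function(ann, path) {
  feats <- lapply(ann$polygons, function(p) {
    ring <- rbind(p, p[1, , drop = FALSE])  # close the ring
    list(
      type = "Feature",
      properties = list(classification = "tumour"),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
          c(ring[i, 1], ring[i, 2])
        }))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path,
    auto_unbox = TRUE, digits = 8
  )
  invisible(path)
}
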