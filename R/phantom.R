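# Phantom biopsy slides: an elongated, gently curved tissue strip on a
# near-white background, carrying up to two procedurally textured tumour
# contingents with exact per-pixel ground truth. Texture A mimics sheets of
# large eosinophilic cells (hepatocellular-like): a pink cytoplasm field
# packed with small dark nuclei and no stroma. Texture B mimics glandular
# structures in fibrous stroma (cholangiocellular-like): dark ring/gland
# motifs with pale lumina embedded in saffron-orange stroma bands. Textures
# are deliberately minimal-but-sufficient so ground truth stays exact and
# generation stays cheap.

#' Specify a phantom biopsy slide
#'
#' @param slide_id Character scalar.
#' @param canvas `c(rows, cols)` canvas size in pixels.
#' @param microns_per_pixel Physical pixel size (default 0.5 um/px).
#' @param strip_width Width of the biopsy strip in pixels.
#' @param strip_margin Blank margin at both strip ends, pixels.
#' @param curvature Amplitude (pixels) of the strip's sinusoidal centreline.
#' @param tumour_fraction_of_tissue Fraction of tissue pixels that are
#'   tumour, in \[0, 1\].
#' @param contingent_fraction_A Fraction of tumour pixels carrying texture A
#'   (hepatocellular-like), in \[0, 1\]; the remainder carries texture B.
#' @param interleaved If `TRUE`, the two contingents alternate in short
#'   blocks along the strip instead of forming two contiguous regions
#'   (a stress-test layout; real combined tumours are contiguous).
#' @param noise_sd Gaussian pixel noise added to tissue, linear \[0,1\] units.
#' @param seed Integer seed; identical spec + seed gives identical slides.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(slide_id, canvas = c(768, 768), microns_per_pixel = 0.5,
                         strip_width = 256, strip_margin = 32, curvature = 24,
                         tumour_fraction_of_tissue = 0.6,
                         contingent_fraction_A = 1, interleaved = FALSE,
                         noise_sd = 0.015, seed = 1L) {
  stopifnot_scalar_number(tumour_fraction_of_tissue, "tumour_fraction_of_tissue")
  stopifnot_scalar_number(contingent_fraction_A, "contingent_fraction_A")
  if (tumour_fraction_of_tissue < 0 || tumour_fraction_of_tissue > 1 ||
    contingent_fraction_A < 0 || contingent_fraction_A > 1) {
    abort("Fractions must lie in [0, 1].")
  }
  if (strip_width + 2 >= canvas[1] || 2 * strip_margin >= canvas[2]) {
    abort("Strip geometry does not fit the canvas.")
  }
  structure(
    list(
      slide_id = slide_id, canvas = as.integer(canvas),
      microns_per_pixel = microns_per_pixel,
      strip_width = strip_width, strip_margin = strip_margin,
      curvature = curvature,
      tumour_fraction_of_tissue = tumour_fraction_of_tissue,
      contingent_fraction_A = contingent_fraction_A,
      interleaved = interleaved,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Generate one phantom slide with ground truth
#'
#' @param spec A [phantom_spec()].
#' @param diagnosis Diagnosis label recorded on the slide.
#' @return A list with elements `slide` (a `histo_slide`), `annotations`
#'   (a `histo_annotations` tracing the tumour region) and `truth` (a
#'   `phantom_truth` list: `tissue_mask`, `tumour_mask`, `class_map` with
#'   codes 0 background / 1 non-tumour tissue / 2 texture A / 3 texture B,
#'   `fraction_A`, `tumour_fraction`).
#' @export
generate_slide <- function(spec, diagnosis = "unknown") {
  with_seed(spec$seed, generate_slide_impl(spec, diagnosis))
}

generate_slide_impl <- function(spec, diagnosis) {
  H <- spec$canvas[1]; W <- spec$canvas[2]
  ycent <- seq_len(H) - 0.5
  xcent <- seq_len(W) - 0.5
  span <- W - 2 * spec$strip_margin
  cy_fun <- function(x) H / 2 + spec$curvature * sin(2 * pi * (x - spec$strip_margin) / span)
  cy <- cy_fun(xcent)
  half <- spec$strip_width / 2

  in_cols <- xcent >= spec$strip_margin & xcent < (W - spec$strip_margin)
  # |y - centreline(x)| <= width/2, evaluated at pixel centres
  dy <- outer(ycent, cy, `-`)
  tissue <- sweep(abs(dy) <= half, 2, in_cols, `&`)

  col_counts <- colSums(tissue)
  total <- sum(col_counts)
  if (total == 0) abort("Infeasible geometry: no tissue pixels.")
  cum <- cumsum(col_counts)
  ft <- spec$tumour_fraction_of_tissue
  if (ft > 0) {
    a <- which(cum >= (1 - ft) / 2 * total)[1]
    b <- which(cum >= (1 + ft) / 2 * total)[1]
    tum_cols <- seq(a, b)
  } else {
    tum_cols <- integer(0)
  }
  tumour <- matrix(FALSE, H, W)
  tumour[, tum_cols] <- tissue[, tum_cols]

  # split the tumour span into contingents by cumulative pixel count, so the
  # realised area fraction matches the requested one to within one column
  class_map <- matrix(0L, H, W)
  class_map[tissue] <- 1L
  if (length(tum_cols) > 0) {
    tcounts <- col_counts[tum_cols]
    fA <- spec$contingent_fraction_A
    if (spec$interleaved && fA > 0 && fA < 1) {
      block <- max(8L, round(length(tum_cols) / 8))
      phase <- ((seq_along(tum_cols) - 1L) %/% block) %% 2L
      # alternate blocks, trimmed to hit the requested fraction
      ord <- order(phase, seq_along(tum_cols))
      take <- ord[cumsum(tcounts[ord]) <= fA * sum(tcounts)]
      is_A <- seq_along(tum_cols) %in% take
    } else {
      cumt <- cumsum(tcounts)
      is_A <- cumt <= fA * sum(tcounts) + 1e-9
      if (fA >= 1) is_A[] <- TRUE
      if (fA <= 0) is_A[] <- FALSE
    }
    for (k in seq_along(tum_cols)) {
      cc <- tum_cols[k]
      class_map[tissue[, cc], cc] <- if (is_A[k]) 2L else 3L
    }
  }

  img <- render_phantom(class_map, cy, spec)

  polygons <- if (length(tum_cols) > 0) {
    list(strip_polygon(tum_cols, cy_fun, half))
  } else {
    list()
  }
  ann <- structure(list(slide_id = spec$slide_id, polygons = polygons),
    class = "histo_annotations"
  )
  n_tum <- sum(class_map >= 2L)
  truth <- structure(
    list(
      tissue_mask = tissue, tumour_mask = class_map >= 2L, class_map = class_map,
      fraction_A = if (n_tum > 0) sum(class_map == 2L) / n_tum else NA_real_,
      tumour_fraction = n_tum / total
    ),
    class = "phantom_truth"
  )
  list(
    slide = slide_image(spec$slide_id, img, spec$microns_per_pixel, diagnosis),
    annotations = ann,
    truth = truth
  )
}

# Closed polygon tracing the tumour sub-strip: along the top edge
# y = centreline - width/2 and back along the bottom edge, sampled every
# column so the chord error against the sinusoidal boundary is negligible.
strip_polygon <- function(tum_cols, cy_fun, half) {
  x0 <- min(tum_cols) - 1
  x1 <- max(tum_cols)
  xs <- seq(x0, x1, by = 1)
  if (xs[length(xs)] != x1) xs <- c(xs, x1)
  eps <- 1e-6
  top <- cbind(x = xs, y = cy_fun(xs) - half - eps)
  bot <- cbind(x = rev(xs), y = cy_fun(rev(xs)) + half + eps)
  rbind(top, bot)
}

PALETTE <- list(
  background = c(0.970, 0.962, 0.955),
  non_tumour = c(0.820, 0.680, 0.750),
  a_cytoplasm = c(0.910, 0.540, 0.620),
  a_nucleus = c(0.450, 0.250, 0.450),
  b_stroma = c(0.880, 0.630, 0.330),
  b_ring = c(0.480, 0.320, 0.500),
  b_lumen = c(0.950, 0.900, 0.820)
)

render_phantom <- function(class_map, cy, spec) {
  H <- nrow(class_map); W <- ncol(class_map)
  img <- array(0, dim = c(H, W, 3L))
  set_colour <- function(img, sel, col) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- col[ch]
      img[, , ch] <- plane
    }
    img
  }
  img <- set_colour(img, class_map == 0L, PALETTE$background)
  img <- set_colour(img, class_map == 1L, PALETTE$non_tumour)
  img <- set_colour(img, class_map == 2L, PALETTE$a_cytoplasm)
  img <- set_colour(img, class_map == 3L, PALETTE$b_stroma)

  ycent <- seq_len(H) - 0.5
  dy <- outer(ycent, cy, `-`)  # signed distance to the strip centreline

  # fine fibre shading along the non-tumour strip
  fib <- 0.035 * sin(dy / 5)
  sel <- class_map == 1L
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[sel] <- plane[sel] + fib[sel]
    img[, , ch] <- plane
  }

  # saffron stroma bands across texture B
  band <- 0.06 * sin(2 * pi * dy / 14)
  sel <- class_map == 3L
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[sel] <- plane[sel] * (1 + band[sel])
    img[, , ch] <- plane
  }

  img <- stamp_discs(img, class_map, class = 2L,
    density = 0.012, radius = 2.2, colour = PALETTE$a_nucleus
  )
  img <- stamp_rings(img, class_map, class = 3L,
    density = 0.004, radius = 6, ring_width = 2,
    ring_colour = PALETTE$b_ring, lumen_colour = PALETTE$b_lumen
  )

  noise <- array(rnorm(H * W * 3, sd = spec$noise_sd), dim = c(H, W, 3L))
  bg <- array(rep(class_map == 0L, 3L), dim = c(H, W, 3L))
  noise[bg] <- rnorm(sum(bg), sd = 0.004)
  clamp(img + noise)
}

# Stamp filled discs (nuclei) at random positions inside a class region,
# painting only pixels of that region so motifs never bleed across truth
# boundaries.
stamp_discs <- function(img, class_map, class, density, radius, colour) {
  sel <- which(class_map == class)
  if (length(sel) == 0) return(img)
  n <- round(length(sel) * density)
  if (n == 0) return(img)
  centres <- sel[sample.int(length(sel), n, replace = TRUE)]
  H <- nrow(class_map)
  r0 <- (centres - 1L) %% H + 1L
  c0 <- (centres - 1L) %/% H + 1L
  paint_stamps(img, class_map, class, r0, c0, function(d2) {
    list(list(mask = d2 <= radius^2, colour = colour))
  }, reach = ceiling(radius))
}

# Stamp ring/gland motifs: a dark ring with a pale lumen.
stamp_rings <- function(img, class_map, class, density, radius, ring_width,
                        ring_colour, lumen_colour) {
  sel <- which(class_map == class)
  if (length(sel) == 0) return(img)
  n <- round(length(sel) * density)
  if (n == 0) return(img)
  centres <- sel[sample.int(length(sel), n, replace = TRUE)]
  H <- nrow(class_map)
  r0 <- (centres - 1L) %% H + 1L
  c0 <- (centres - 1L) %/% H + 1L
  inner <- radius - ring_width
  paint_stamps(img, class_map, class, r0, c0, function(d2) {
    list(
      list(mask = d2 <= radius^2 & d2 > inner^2, colour = ring_colour),
      list(mask = d2 <= inner^2, colour = lumen_colour)
    )
  }, reach = ceiling(radius))
}

paint_stamps <- function(img, class_map, class, r0, c0, layers_fun, reach) {
  H <- nrow(class_map); W <- ncol(class_map)
  off <- seq(-reach, reach)
  d2_grid <- outer(off^2, off^2, `+`)
  for (i in seq_along(r0)) {
    rr <- r0[i] + off
    cc <- c0[i] + off
    rok <- rr >= 1 & rr <= H
    cok <- cc >= 1 & cc <= W
    rr <- rr[rok]; cc <- cc[cok]
    d2 <- d2_grid[rok, cok, drop = FALSE]
    region <- class_map[rr, cc, drop = FALSE] == class
    for (layer in layers_fun(d2)) {
      m <- layer$mask & region
      if (!any(m)) next
      idx <- which(m, arr.ind = TRUE)
      lin <- cbind(rr[idx[, 1]], cc[idx[, 2]])
      for (ch in 1:3) {
        img[cbind(lin, ch)] <- layer$colour[ch]
      }
    }
  }
  img
}

#' Generate a phantom cohort with manifest, truth and synthetic IHC counts
#'
#' Pure texture-A slides are labelled HCC, pure texture-B slides iCCA, and
#' mixed slides cHCC-CCA with their true contingent fraction recorded.
#' Slides are split patient-wise into training and validation partitions,
#' stratified by diagnosis. Synthetic immunohistochemistry cell counts are
#' drawn binomially so marker positive-ratios track the true contingent
#' fractions up to a bounded (±5%) systematic jitter.
#'
#' @param n_A_pure,n_B_pure,n_mixed Slide counts per group.
#' @param mixed_fraction_range Range of true texture-A fractions for mixed
#'   slides (default `c(0.2, 0.8)`).
#' @param split_ratio Training share of each diagnosis group (default 0.7).
#' @param seed Integer master seed; every slide derives its own stream.
#' @param dir If non-`NULL`, slide PNGs, GeoJSON annotations, the manifest,
#'   IHC counts and truth files are written beneath this directory.
#' @param ... Passed on to [phantom_spec()] (canvas, strip geometry, noise).
#' @return A list: `manifest` (tibble: slide_id, diagnosis, split,
#'   true_fraction_A, tumour fraction, path columns when written), `slides`
#'   (named list of [generate_slide()] outputs), `ihc` (tibble of synthetic
#'   cell counts).
#' @export
generate_cohort <- function(n_A_pure = 10, n_B_pure = 10, n_mixed = 10,
                            mixed_fraction_range = c(0.2, 0.8),
                            split_ratio = 0.7, seed = 1L, dir = NULL, ...) {
  groups <- list(
    HCC = if (n_A_pure > 0) sprintf("hcc_%02d", seq_len(n_A_pure)) else character(),
    iCCA = if (n_B_pure > 0) sprintf("icca_%02d", seq_len(n_B_pure)) else character(),
    `cHCC-CCA` = if (n_mixed > 0) sprintf("mixed_%02d", seq_len(n_mixed)) else character()
  )
  manifest <- purrr::imap(groups, function(ids, diag) {
    if (length(ids) == 0) return(NULL)
    tibble(slide_id = ids, diagnosis = diag)
  })
  manifest <- dplyr::bind_rows(manifest)

  manifest <- with_seed(derive_seed(seed, "cohort"), {
    manifest$true_fraction_A <- dplyr::case_when(
      manifest$diagnosis == "HCC" ~ 1,
      manifest$diagnosis == "iCCA" ~ 0,
      TRUE ~ runif(nrow(manifest), mixed_fraction_range[1], mixed_fraction_range[2])
    )
    manifest$tumour_fraction_of_tissue <- runif(nrow(manifest), 0.5, 0.7)
    manifest$split <- assign_split(manifest$diagnosis, split_ratio)
    manifest
  })

  slides <- purrr::pmap(manifest, function(slide_id, diagnosis, true_fraction_A,
                                           tumour_fraction_of_tissue, split) {
    spec <- phantom_spec(
      slide_id,
      tumour_fraction_of_tissue = tumour_fraction_of_tissue,
      contingent_fraction_A = true_fraction_A,
      seed = derive_seed(seed, slide_id), ...
    )
    generate_slide(spec, diagnosis = diagnosis)
  })
  names(slides) <- manifest$slide_id

  realised <- purrr::map_dbl(slides, function(s) {
    f <- s$truth$fraction_A
    if (is.na(f)) 0 else f
  })
  ihc <- synthesise_ihc_counts(manifest$slide_id, realised[manifest$slide_id],
    seed = derive_seed(seed, "ihc")
  )

  mpp <- slides[[1]]$slide$microns_per_pixel
  manifest$microns_per_pixel <- mpp

  if (!is.null(dir)) {
    for (sub in c("slides", "annotations", "truth")) {
      dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
    }
    manifest$path <- file.path(dir, "slides", paste0(manifest$slide_id, ".png"))
    ann_paths <- file.path(dir, "annotations", paste0(manifest$slide_id, ".geojson"))
    for (i in seq_len(nrow(manifest))) {
      s <- slides[[manifest$slide_id[i]]]
      write_slide_png(s$slide$pixels, manifest$path[i])
      write_annotations_geojson(s$annotations, ann_paths[i])
      write_slide_png(
        array(rep(s$truth$class_map / 3, 3), dim = c(dim(s$truth$class_map), 3)),
        file.path(dir, "truth", paste0(manifest$slide_id, "_classmap.png"))
      )
    }
    truth_tbl <- tibble(
      slide_id = manifest$slide_id,
      true_fraction_A = manifest$true_fraction_A,
      realised_fraction_A = unname(realised[manifest$slide_id]),
      tumour_fraction = purrr::map_dbl(slides[manifest$slide_id], ~ .x$truth$tumour_fraction)
    )
    readr::write_csv(truth_tbl, file.path(dir, "truth", "truth.csv"))
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
    readr::write_csv(ihc, file.path(dir, "ihc_counts.csv"))
  }

  list(manifest = manifest, slides = slides, ihc = ihc)
}

assign_split <- function(diagnosis, split_ratio) {
  split <- character(length(diagnosis))
  for (g in unique(diagnosis)) {
    idx <- which(diagnosis == g)
    n <- length(idx)
    if (n < 2) {
      abort(sprintf(
        "Diagnosis group '%s' has %d slide(s); at least 2 are needed to appear in both partitions.",
        g, n
      ))
    }
    n_train <- min(max(round(split_ratio * n), 1L), n - 1L)
    train_idx <- idx[sample.int(n, n_train)]
    split[train_idx] <- "train"
    split[setdiff(idx, train_idx)] <- "validation"
  }
  split
}

#' Synthesise immunohistochemistry cell counts for phantom slides
#'
#' Positive-cell counts are binomial draws whose success probabilities track
#' the slide's true hepatocellular contingent fraction `p`: glypican-3 around
#' `0.75 p`, anti-hepatocyte around `0.92 p`, CK7 around `0.92 (1 - p)`, each
#' offset by an independent systematic jitter bounded by ±0.05.
#'
#' @param slide_ids Character vector.
#' @param fraction_A True hepatocellular fractions, same length.
#' @param n_cells_range Range of tumour-cell counts per slide.
#' @param seed Integer seed.
#' @return A tibble with columns `slide_id`, `n_tumour_cells`,
#'   `n_positive_glypican3`, `n_positive_hepatocyte`, `n_positive_ck7`.
#' @export
synthesise_ihc_counts <- function(slide_ids, fraction_A,
                                  n_cells_range = c(600, 1400), seed = 1L) {
  with_seed(seed, {
    n <- length(slide_ids)
    cells <- round(runif(n, n_cells_range[1], n_cells_range[2]))
    jit <- function() runif(n, -0.05, 0.05)
    p_gly <- clamp(0.75 * fraction_A + jit())
    p_hep <- clamp(0.92 * fraction_A + jit())
    p_ck7 <- clamp(0.92 * (1 - fraction_A) + jit())
    tibble(
      slide_id = slide_ids,
      n_tumour_cells = as.integer(cells),
      n_positive_glypican3 = rbinom(n, cells, p_gly),
      n_positive_hepatocyte = rbinom(n, cells, p_hep),
      n_positive_ck7 = rbinom(n, cells, p_ck7)
    )
  })
}
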