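test_that("phantom slides honour requested contingent fractions", {
  for (fA in c(0, 0.3, 0.5, 1)) {
    g <- generate_slide(small_phantom_spec(seed = 5, contingent_fraction_A = fA))
    truth <- g$truth
    expect_true(all(truth$tumour_mask[truth$tumour_mask] & truth$tissue_mask[truth$tumour_mask]))
    if (fA == 1) expect_identical(sum(truth$class_map == 3L), 0L)
    if (fA == 0) expect_identical(sum(truth$class_map == 2L), 0L)
    expect_equal(truth$fraction_A, fA, tolerance = 0.02)
  }
  g <- generate_slide(small_phantom_spec(seed = 5, tumour_fraction_of_tissue = 0.55))
  expect_equal(g$truth$tumour_fraction, 0.55, tolerance = 0.02)
})

test_that("identical spec and seed give byte-identical slides", {
  spec <- small_phantom_spec(seed = 9, contingent_fraction_A = 0.4)
  g1 <- generate_slide(spec)
  g2 <- generate_slide(spec)
  expect_identical(g1$slide$pixels, g2$slide$pixels)
  expect_identical(g1$truth$class_map, g2$truth$class_map)
  f1 <- tempfile(fileext = ".png")
  f2 <- tempfile(fileext = ".png")
  write_slide_png(g1$slide$pixels, f1)
  write_slide_png(g2$slide$pixels, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  # a different seed changes the rendering
  g3 <- generate_slide(small_phantom_spec(seed = 10, contingent_fraction_A = 0.4))
  expect_false(identical(g1$slide$pixels, g3$slide$pixels))
})

test_that("annotation polygons rasterise back to the truth tumour mask", {
  g <- generate_slide(small_phantom_spec(seed = 13, contingent_fraction_A = 0.5))
  mask <- rasterise_annotations(g$slide, g$annotations)
  expect_gt(mean(mask == g$truth$tumour_mask), 0.999)
})

test_that("the two tumour textures are separable by plain pixel statistics", {
  ga <- generate_slide(small_phantom_spec("a", seed = 31, contingent_fraction_A = 1))
  gb <- generate_slide(small_phantom_spec("b", seed = 32, contingent_fraction_A = 0))
  tile_stats <- function(g) {
    tissue <- g$truth$tissue_mask
    tumour <- g$truth$tumour_mask
    p <- extract_patches(g$slide, tissue, tumour, patch_microns = 16, patch_pixels = 32)
    p <- dplyr::filter(p, .data$weak_label == "tumour")
    t(vapply(p$pixels, function(px) apply(px, 3, mean), numeric(3)))
  }
  sa <- tile_stats(ga)
  sb <- tile_stats(gb)
  # nearest-class-centroid classifier on mean RGB
  ca <- colMeans(sa)
  cb <- colMeans(sb)
  pred <- function(m) apply(m, 1, function(v) {
    if (sum((v - ca)^2) < sum((v - cb)^2)) "A" else "B"
  })
  acc <- mean(c(pred(sa) == "A", pred(sb) == "B"))
  expect_gte(acc, 0.95)
})

test_that("cohorts have clean manifests, partitions and truth bookkeeping", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(2, 2, 2,
    seed = 3, dir = dir,
    canvas = c(192, 192), strip_width = 96, strip_margin = 12, curvature = 8
  )
  m <- coh$manifest
  expect_identical(nrow(m), 6L)
  expect_setequal(m$diagnosis, c("HCC", "iCCA", "cHCC-CCA"))
  # every diagnosis group appears in both partitions
  tab <- table(m$diagnosis, m$split)
  expect_true(all(tab > 0))
  expect_identical(anyDuplicated(m$slide_id), 0L)
  expect_true(all(file.exists(m$path)))
  expect_true(all(file.exists(file.path(dir, "annotations", paste0(m$slide_id, ".geojson")))))
  expect_true(file.exists(file.path(dir, "truth", "truth.csv")))
  # GeoJSON roundtrip reproduces the rasterised tumour mask
  sid <- m$slide_id[1]
  ann <- read_annotations_geojson(file.path(dir, "annotations", paste0(sid, ".geojson")))
  m1 <- rasterise_annotations(coh$slides[[sid]]$slide, ann)
  m2 <- rasterise_annotations(coh$slides[[sid]]$slide, coh$slides[[sid]]$annotations)
  expect_gt(mean(m1 == m2), 0.9999)
  # pure slides record exact fractions; mixed in the requested range
  expect_true(all(m$true_fraction_A[m$diagnosis == "HCC"] == 1))
  expect_true(all(m$true_fraction_A[m$diagnosis == "iCCA"] == 0))
  mixed <- m$true_fraction_A[m$diagnosis == "cHCC-CCA"]
  expect_true(all(mixed >= 0.2 & mixed <= 0.8))
  # determinism of the whole cohort
  coh2 <- generate_cohort(2, 2, 2,
    seed = 3,
    canvas = c(192, 192), strip_width = 96, strip_margin = 12, curvature = 8
  )
  expect_identical(
    rlang::hash(dplyr::select(m, -"path")),
    rlang::hash(coh2$manifest)
  )
  expect_identical(coh$slides[[sid]]$slide$pixels, coh2$slides[[sid]]$slide$pixels)
})

test_that("a diagnosis group too small to split raises an error", {
  expect_error(
    generate_cohort(1, 2, 2, seed = 1, canvas = c(192, 192), strip_width = 96,
      strip_margin = 12, curvature = 8),
    "at least 2"
  )
})

test_that("synthetic IHC counts track true contingents within noise bounds", {
  ids <- sprintf("s%02d", 1:20)
  frac <- rep(c(1, 0, 0.5, 0.8), 5)
  counts <- synthesise_ihc_counts(ids, frac, seed = 8)
  expect_true(all(counts$n_tumour_cells > 0))
  expect_true(all(counts$n_positive_glypican3 <= counts$n_tumour_cells))
  expect_true(all(counts$n_positive_ck7 <= counts$n_tumour_cells))
  cc <- ihc_contingents(counts)
  # pure hepatocellular slides: strong HCC-marker staining, minimal CK7
  expect_true(all(cc$ihc_hcc_contingent_pct[frac == 1] >= 80))
  expect_true(all(cc$ihc_icca_contingent_pct[frac == 1] <= 10))
  # pure cholangiocellular slides: the converse
  expect_true(all(cc$ihc_hcc_contingent_pct[frac == 0] <= 10))
  expect_true(all(cc$ihc_icca_contingent_pct[frac == 0] >= 80))
  # ratios track the underlying fraction
  expect_gt(cor(cc$ihc_hcc_contingent_pct, frac), 0.95)
})

test_that("interleaved mixing still hits the requested fraction", {
  g <- generate_slide(small_phantom_spec(seed = 17, contingent_fraction_A = 0.5, interleaved = TRUE))
  expect_equal(g$truth$fraction_A, 0.5, tolerance = 0.05)
  # contiguous layout: texture-A columns form one run; interleaved: several
  runs_of <- function(cm) {
    colsA <- which(apply(cm == 2L, 2, any))
    sum(diff(colsA) > 1) + 1
  }
  expect_gt(runs_of(g$truth$class_map), 1)
  gc_ <- generate_slide(small_phantom_spec(seed = 17, contingent_fraction_A = 0.5))
  expect_identical(runs_of(gc_$truth$class_map), 1)
})
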