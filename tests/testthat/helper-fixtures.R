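# Small in-code fixtures shared across tests.

# A compact phantom spec that keeps per-test generation fast.
small_phantom_spec <- function(slide_id = "p1", seed = 1L, ...) {
  phantom_spec(
    slide_id,
    canvas = c(192, 192), strip_width = 96, strip_margin = 12,
    curvature = 8, seed = seed, ...
  )
}

# Uniform-colour slide helper.
flat_slide <- function(col, dims = c(64, 64), slide_id = "flat", mpp = 1) {
  img <- array(0, dim = c(dims, 3L))
  for (ch in 1:3) img[, , ch] <- col[ch]
  slide_image(slide_id, img, mpp)
}

# Trivially separable tile set (red-ish "tumour" vs blue-ish "non_tumour")
# for fast classifier tests.
toy_tiles <- function(n_per_class, slide_ids, size = 32, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(channel, n, sid, label) {
      tibble::tibble(
        slide_id = sid,
        grid_row = seq_len(n) - 1L, grid_col = 0L,
        tissue_fraction = 1, tumour_fraction = as.numeric(label == "tumour"),
        weak_label = label,
        pixels = lapply(seq_len(n), function(i) {
          a <- array(runif(size * size * 3, 0, 0.25), dim = c(size, size, 3))
          a[, , channel] <- a[, , channel] + 0.6
          a
        })
      )
    }
    dplyr::bind_rows(
      mk(1, n_per_class, slide_ids[1], "tumour"),
      mk(3, n_per_class, slide_ids[2], "non_tumour")
    )
  })
}

expect_monotone_trace <- function(fit, tol = 1e-7) {
  expect_true(all(diff(fit$log_likelihood_trace) >= -tol))
}
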