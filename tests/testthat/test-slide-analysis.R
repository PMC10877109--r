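mk_assignments <- function(counts_by_cluster, slide_id = "s1") {
  # counts_by_cluster: named vector cluster_id -> n tiles
  dplyr::bind_rows(purrr::imap(counts_by_cluster, function(n, cl) {
    if (n == 0) return(NULL)
    tibble::tibble(
      slide_id = slide_id,
      grid_row = seq_len(n) - 1L, grid_col = as.integer(cl),
      cluster_id = as.integer(cl)
    )
  }))
}

test_that("slide proportions are exact tile-count ratios", {
  a <- mk_assignments(c(`0` = 10, `1` = 0))
  r <- compute_slide_proportions(a, K = 2)
  expect_identical(r$n_tumour_tiles, 10L)
  expect_equal(unname(r$proportion[1, ]), c(1, 0))

  a <- mk_assignments(c(`0` = 3, `1` = 1))
  r <- compute_slide_proportions(a, K = 2)
  expect_equal(unname(r$proportion[1, ]), c(0.75, 0.25))

  # multi-slide fixture matches brute-force counting, sums conserve
  withr::with_seed(11, {
    many <- dplyr::bind_rows(lapply(sprintf("s%d", 1:6), function(sid) {
      mk_assignments(setNames(sample(0:9, 3), 0:2), slide_id = sid)
    }))
  })
  r <- compute_slide_proportions(many, K = 3)
  for (i in seq_len(nrow(r))) {
    sub <- many[many$slide_id == r$slide_id[i], ]
    expect_identical(r$n_tumour_tiles[i], nrow(sub))
    for (k in 0:2) {
      expect_equal(unname(r$proportion[i, as.character(k)]), sum(sub$cluster_id == k) / nrow(sub))
    }
  }
  expect_equal(unname(rowSums(r$proportion)), rep(1, nrow(r)), tolerance = 1e-9)
  expect_error(
    compute_slide_proportions(many, K = 3, slide_ids = c("s1", "missing")),
    "missing"
  )
})

test_that("major contingents follow the argmax through the cluster map", {
  map2 <- c(`0` = "HCC", `1` = "iCCA")
  r <- compute_slide_proportions(mk_assignments(c(`0` = 97, `1` = 3)), K = 2) |>
    predict_major_contingent(map2)
  expect_identical(r$predicted_major_contingent, "HCC")
  r <- compute_slide_proportions(mk_assignments(c(`0` = 5, `1` = 95)), K = 2) |>
    predict_major_contingent(map2)
  expect_identical(r$predicted_major_contingent, "iCCA")
  # exact tie: flagged indeterminate, never silently broken
  r <- compute_slide_proportions(mk_assignments(c(`0` = 50, `1` = 50)), K = 2) |>
    predict_major_contingent(map2)
  expect_identical(r$predicted_major_contingent, "indeterminate")
  # K = 3 with two clusters of one type: same-type proportions sum first
  map3 <- c(`0` = "HCC", `1` = "HCC", `2` = "iCCA")
  r <- compute_slide_proportions(mk_assignments(c(`0` = 30, `1` = 25, `2` = 45)), K = 3) |>
    predict_major_contingent(map3)
  expect_identical(r$predicted_major_contingent, "HCC")
  expect_equal(unname(r$type_proportion[1, c("HCC", "iCCA")]), c(0.55, 0.45))
  # missing map entry errors
  r0 <- compute_slide_proportions(mk_assignments(c(`0` = 1, `1` = 1)), K = 2)
  expect_error(predict_major_contingent(r0, c(`0` = "HCC")), "lacks entries")
})

test_that("IHC contingents apply the max-of-two-antibodies rule exactly", {
  counts <- tibble::tibble(
    slide_id = "s1", n_tumour_cells = 1000L,
    n_positive_glypican3 = 520L, n_positive_hepatocyte = 930L, n_positive_ck7 = 20L
  )
  cc <- ihc_contingents(counts)
  expect_equal(cc$ihc_hcc_contingent_pct, 93)
  expect_equal(cc$ihc_icca_contingent_pct, 2)

  zero <- dplyr::mutate(counts,
    n_positive_glypican3 = 0L, n_positive_hepatocyte = 0L, n_positive_ck7 = 0L
  )
  cc <- ihc_contingents(zero)
  expect_equal(cc$ihc_hcc_contingent_pct, 0)
  expect_equal(cc$ihc_icca_contingent_pct, 0)

  tie <- dplyr::mutate(counts, n_positive_glypican3 = 930L)
  expect_equal(ihc_contingents(tie)$ihc_hcc_contingent_pct, 93)

  # random fixtures against direct arithmetic
  withr::with_seed(12, {
    n <- 50
    cells <- sample(100:2000, n)
    rnd <- tibble::tibble(
      slide_id = sprintf("r%02d", seq_len(n)),
      n_tumour_cells = cells,
      n_positive_glypican3 = vapply(cells, function(m) sample(0:m, 1), integer(1)),
      n_positive_hepatocyte = vapply(cells, function(m) sample(0:m, 1), integer(1)),
      n_positive_ck7 = vapply(cells, function(m) sample(0:m, 1), integer(1))
    )
  })
  cc <- ihc_contingents(rnd)
  expect_identical(
    cc$ihc_hcc_contingent_pct,
    100 * pmax(rnd$n_positive_glypican3, rnd$n_positive_hepatocyte) / rnd$n_tumour_cells
  )
  expect_identical(cc$ihc_icca_contingent_pct, 100 * rnd$n_positive_ck7 / rnd$n_tumour_cells)

  expect_error(ihc_contingents(dplyr::mutate(counts, n_tumour_cells = 0L)), "no tumour cells")
  expect_error(ihc_contingents(dplyr::mutate(counts, n_positive_ck7 = 2000L)), "exceed")
})

test_that("diagnostic agreement counts, groups and rounds as reported tables do", {
  cases_of <- function(diag, n, k, major = diag) tibble::tibble(
    pathology_diagnosis = diag,
    predicted_major_contingent = rep(c(major, if (diag == "cHCC-CCA") "other" else "other"), c(k, n - k)),
    pathology_major_contingent = major
  )
  cases <- dplyr::bind_rows(
    cases_of("HCC", 11, 11),
    cases_of("iCCA", 9, 7),
    cases_of("cHCC-CCA", 9, 8, major = "iCCA")
  )
  tab <- diagnostic_agreement(cases)
  expect_identical(tab$agreement_pct[tab$pathology_diagnosis == "HCC"], 100)
  expect_identical(tab$agreement_pct[tab$pathology_diagnosis == "iCCA"], 78)
  expect_identical(tab$agreement_pct[tab$pathology_diagnosis == "cHCC-CCA"], 89)
  expect_identical(tab$n_concordant[tab$pathology_diagnosis == "iCCA"], 7L)
  expect_equal(tab$agreement_fraction[tab$pathology_diagnosis == "iCCA"], 7 / 9)

  # zero concordant and half-up rounding behaviour
  none <- cases_of("HCC", 4, 0)
  expect_identical(diagnostic_agreement(none)$agreement_pct, 0)
  expect_identical(round_half_up(100 * 13 / 15), 87)
  expect_identical(round_half_up(100 * 7 / 9), 78)
  expect_identical(round_half_up(0.5), 1)

  # empty factor level warns and is omitted
  fac <- dplyr::mutate(cases_of("HCC", 3, 3),
    pathology_diagnosis = factor(pathology_diagnosis, levels = c("HCC", "iCCA"))
  )
  expect_warning(tab <- diagnostic_agreement(fac), "omitted")
  expect_identical(nrow(tab), 1L)

  # combined cases need the pathologist's major contingent
  bad <- tibble::tibble(
    pathology_diagnosis = "cHCC-CCA",
    predicted_major_contingent = "HCC"
  )
  expect_error(diagnostic_agreement(bad), "pathology_major_contingent")
})

test_that("model/IHC correlations reproduce the textbook formula", {
  mk_reports <- function(model_hcc, ihc_hcc, ihc_icca) {
    tp <- cbind(HCC = model_hcc, iCCA = 1 - model_hcc)
    tibble::tibble(
      slide_id = sprintf("s%d", seq_along(model_hcc)),
      type_proportion = tp,
      ihc_hcc_contingent_pct = ihc_hcc,
      ihc_icca_contingent_pct = ihc_icca
    )
  }
  r <- proportion_ihc_correlation(mk_reports(c(0.1, 0.5, 0.9), c(10, 50, 90), c(90, 50, 10)))
  expect_equal(r$pearson_r, c(1, 1), tolerance = 1e-12)
  r <- proportion_ihc_correlation(mk_reports(c(0.1, 0.5, 0.9), c(90, 50, 10), c(10, 50, 90)))
  expect_equal(r$pearson_r, c(-1, -1), tolerance = 1e-12)

  withr::with_seed(13, {
    mh <- runif(12)
    ih <- runif(12, 0, 100)
    ii <- runif(12, 0, 100)
  })
  r <- proportion_ihc_correlation(mk_reports(mh, ih, ii))
  brute <- function(a, b) {
    mean((a - mean(a)) * (b - mean(b))) /
      sqrt(mean((a - mean(a))^2) * mean((b - mean(b))^2))
  }
  expect_equal(r$pearson_r[1], brute(mh * 100, ih), tolerance = 1e-12)
  expect_equal(r$pearson_r[2], brute((1 - mh) * 100, ii), tolerance = 1e-12)

  expect_error(proportion_ihc_correlation(mk_reports(c(0.1, 0.9), c(1, 2), c(3, 4))), "at least 3")
  expect_warning(
    expect_warning(
      r0 <- proportion_ihc_correlation(mk_reports(c(0.5, 0.5, 0.5), c(1, 2, 3), c(4, 5, 6))),
      "Zero variance"
    ),
    "Zero variance"
  )
  expect_true(is.na(r0$pearson_r[1]))
})
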