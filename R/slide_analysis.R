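# Slide-level aggregation: tile clusters -> per-slide contingent
# proportions -> major-contingent diagnosis -> agreement with pathology and
# correlation with quantitative immunohistochemistry. All printed
# percentages use round-half-up so reported tables are exactly reproducible.

#' Per-slide cluster proportions
#'
#' @param assignments Assignment tibble from [assign_clusters()] with
#'   `slide_id` and `cluster_id`.
#' @param K Number of clusters; defaults to `max(cluster_id) + 1` over all
#'   assignments, so slides missing a cluster still report a 0 proportion
#'   for it.
#' @param slide_ids Optional vector of slides that must be present; a listed
#'   slide with no tumour tile is an error naming the slide.
#' @return A tibble with one row per slide: `slide_id`, `n_tumour_tiles`,
#'   and a `proportion` matrix column (columns = clusters 0..K-1, rows sum
#'   to 1).
#' @export
compute_slide_proportions <- function(assignments, K = NULL, slide_ids = NULL) {
  if (nrow(assignments) == 0) abort("No assignments supplied.")
  K <- K %||% (max(assignments$cluster_id) + 1L)
  if (!is.null(slide_ids)) {
    absent <- setdiff(slide_ids, assignments$slide_id)
    if (length(absent) > 0) {
      abort(sprintf(
        "Slide(s) %s have zero tumour tiles.", paste(absent, collapse = ", ")
      ))
    }
  }
  counts <- assignments |>
    dplyr::count(.data$slide_id, .data$cluster_id) |>
    tidyr::pivot_wider(
      names_from = "cluster_id", values_from = "n",
      names_sort = TRUE, values_fill = 0L
    )
  mat <- matrix(0L, nrow(counts), K,
    dimnames = list(NULL, as.character(seq_len(K) - 1L))
  )
  present <- intersect(colnames(mat), names(counts))
  mat[, present] <- as.matrix(counts[, present])
  n_tiles <- rowSums(mat)
  if (any(n_tiles == 0)) {
    abort(sprintf(
      "Slide(s) %s have zero tumour tiles.",
      paste(counts$slide_id[n_tiles == 0], collapse = ", ")
    ))
  }
  tibble(
    slide_id = counts$slide_id,
    n_tumour_tiles = as.integer(n_tiles),
    proportion = mat / n_tiles
  )
}

#' Predict the major tumour contingent of each slide
#'
#' The predicted contingent is the tumour type of the cluster holding the
#' largest share of the slide's tumour tiles. When several clusters map to
#' the same type (the K = 3 case), same-type proportions are summed before
#' the argmax. An exact tie between types is flagged `"indeterminate"`
#' rather than silently broken.
#'
#' @param reports Tibble from [compute_slide_proportions()].
#' @param cluster_map A `histo_cluster_map` from [map_clusters_to_types()],
#'   or a named character vector cluster id -> type.
#' @return `reports` with columns `predicted_major_contingent` and
#'   `type_proportion` (matrix column of per-type summed proportions).
#' @export
predict_major_contingent <- function(reports, cluster_map) {
  map <- if (inherits(cluster_map, "histo_cluster_map")) cluster_map$map else cluster_map
  clusters <- colnames(reports$proportion)
  missing <- setdiff(clusters, names(map))
  if (length(missing) > 0) {
    abort(sprintf("Cluster map lacks entries for cluster(s) %s.", paste(missing, collapse = ", ")))
  }
  types <- unique(unname(map[clusters]))
  type_prop <- vapply(types, function(tp) {
    rowSums(reports$proportion[, clusters[map[clusters] == tp], drop = FALSE])
  }, numeric(nrow(reports)))
  type_prop <- matrix(type_prop, nrow = nrow(reports), dimnames = list(NULL, types))
  best <- apply(type_prop, 1, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1) "indeterminate" else types[top]
  })
  reports$predicted_major_contingent <- unname(best)
  reports$type_proportion <- type_prop
  reports
}

#' Immunohistochemistry contingent percentages
#'
#' The hepatocellular contingent is the larger of the glypican-3 and
#' anti-hepatocyte positive-cell ratios (the two HCC markers; the highest
#' ratio between the two antibodies is retained); the cholangiocellular
#' contingent is the CK7 positive-cell ratio. Both are expressed in percent
#' of tumour cells.
#'
#' @param counts Tibble with columns `slide_id`, `n_tumour_cells`,
#'   `n_positive_glypican3`, `n_positive_hepatocyte`, `n_positive_ck7`.
#' @return `counts` with `ihc_hcc_contingent_pct` and
#'   `ihc_icca_contingent_pct` appended.
#' @export
ihc_contingents <- function(counts) {
  if (any(counts$n_tumour_cells <= 0)) {
    abort(sprintf(
      "Slide(s) %s have no tumour cells counted.",
      paste(counts$slide_id[counts$n_tumour_cells <= 0], collapse = ", ")
    ))
  }
  bad <- with(counts, pmax(n_positive_glypican3, n_positive_hepatocyte, n_positive_ck7) > n_tumour_cells)
  if (any(bad)) {
    abort(sprintf(
      "Positive counts exceed tumour-cell counts for slide(s) %s.",
      paste(counts$slide_id[bad], collapse = ", ")
    ))
  }
  counts |>
    mutate(
      ihc_hcc_contingent_pct = 100 * pmax(
        .data$n_positive_glypican3, .data$n_positive_hepatocyte
      ) / .data$n_tumour_cells,
      ihc_icca_contingent_pct = 100 * .data$n_positive_ck7 / .data$n_tumour_cells
    )
}

#' Diagnostic agreement between pathology and model predictions
#'
#' Counts concordant cases per pathology diagnosis group. HCC and iCCA cases
#' are concordant when the predicted major contingent equals the diagnosis;
#' combined (cHCC-CCA) cases are concordant when the predicted major
#' contingent matches the pathologist's reported major contingent (supplied
#' in `pathology_major_contingent`). Percentages are rounded half-up; raw
#' fractions are retained.
#'
#' @param cases Tibble with `pathology_diagnosis`,
#'   `predicted_major_contingent` and, for combined cases,
#'   `pathology_major_contingent`.
#' @return A tibble with one row per diagnosis group: `pathology_diagnosis`,
#'   `n_cases`, `n_concordant`, `agreement_pct` (integer-valued) and
#'   `agreement_fraction`.
#' @export
diagnostic_agreement <- function(cases) {
  needed <- c("pathology_diagnosis", "predicted_major_contingent")
  missing <- setdiff(needed, names(cases))
  if (length(missing) > 0) {
    abort(sprintf("`cases` lacks column(s) %s.", paste(missing, collapse = ", ")))
  }
  if (any(is.na(cases$pathology_diagnosis)) || any(is.na(cases$predicted_major_contingent))) {
    abort("Every case needs both a pathology diagnosis and a model prediction.")
  }
  reference <- ifelse(
    cases$pathology_diagnosis == "cHCC-CCA",
    cases[["pathology_major_contingent"]] %||% rep(NA_character_, nrow(cases)),
    cases$pathology_diagnosis
  )
  if (any(is.na(reference))) {
    abort("Combined (cHCC-CCA) cases need a `pathology_major_contingent` reference.")
  }
  cases$concordant <- cases$predicted_major_contingent == reference
  out <- cases |>
    dplyr::group_by(.data$pathology_diagnosis) |>
    dplyr::summarise(
      n_cases = dplyr::n(),
      n_concordant = sum(.data$concordant),
      .groups = "drop"
    ) |>
    mutate(
      agreement_fraction = .data$n_concordant / .data$n_cases,
      agreement_pct = round_half_up(100 * .data$agreement_fraction)
    )
  all_groups <- if (is.factor(cases$pathology_diagnosis)) {
    levels(cases$pathology_diagnosis)
  } else {
    unique(cases$pathology_diagnosis)
  }
  empty <- setdiff(all_groups, out$pathology_diagnosis)
  if (length(empty) > 0) {
    warn(sprintf("Empty diagnosis group(s) omitted: %s.", paste(empty, collapse = ", ")))
  }
  out
}

#' Correlation between model proportions and IHC contingents
#'
#' Pearson product-moment correlation between (i) the slide proportion of
#' the hepatocellular-mapped cluster and the IHC hepatocellular contingent,
#' and (ii) the cholangiocellular-mapped cluster proportion and the CK7
#' contingent.
#'
#' @param reports Tibble from [predict_major_contingent()] joined with
#'   [ihc_contingents()] output (columns `type_proportion`,
#'   `ihc_hcc_contingent_pct`, `ihc_icca_contingent_pct`).
#' @return A tibble with rows `HCC` and `iCCA`: `n_slides`, `pearson_r`.
#' @export
proportion_ihc_correlation <- function(reports) {
  needed <- c("type_proportion", "ihc_hcc_contingent_pct", "ihc_icca_contingent_pct")
  missing <- setdiff(needed, names(reports))
  if (length(missing) > 0) {
    abort(sprintf("`reports` lacks column(s) %s.", paste(missing, collapse = ", ")))
  }
  if (nrow(reports) < 3) abort("Need at least 3 slides with both measurements.")
  type_share <- function(tp) {
    if (tp %in% colnames(reports$type_proportion)) {
      reports$type_proportion[, tp] * 100
    } else {
      warn(sprintf("No cluster maps to '%s'; its model proportion is 0 everywhere.", tp))
      rep(0, nrow(reports))
    }
  }
  pairs <- list(
    HCC = list(model = type_share("HCC"), ihc = reports$ihc_hcc_contingent_pct),
    iCCA = list(model = type_share("iCCA"), ihc = reports$ihc_icca_contingent_pct)
  )
  purrr::imap(pairs, function(p, nm) {
    r <- if (sd(p$model) == 0 || sd(p$ihc) == 0) {
      warn(sprintf("Zero variance in the %s pair; correlation undefined.", nm))
      NA_real_
    } else {
      stats::cor(p$model, p$ihc)
    }
    tibble(contingent = nm, n_slides = length(p$model), pearson_r = r)
  }) |> dplyr::bind_rows()
}
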