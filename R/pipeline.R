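# End-to-end phantom study: simulate an annotated cohort, tile it, train
# the weak tumour/non-tumour classifier on the training partition, pool
# last-conv-layer features for tumour tiles, halve them with PCA, cluster
# with a K-component Gaussian mixture, map clusters to tumour types on
# pure-type slides, and score slide-level predictions against the
# generator's ground truth and synthetic immunohistochemistry.

#' Run the full pipeline on a phantom cohort
#'
#' @param n_A_pure,n_B_pure,n_mixed Cohort composition (defaults 10/10/10).
#' @param seed Master seed for simulation, training and clustering.
#' @param K Number of mixture components (default 2).
#' @param patch_microns,patch_pixels Tile scale; defaults 32 um / 64 px, the
#'   desk-scale counterpart of 125 um / 256 px tiles.
#' @param epochs Training epochs for the weak classifier (default 10).
#' @param n_augments_per_patch Augmented copies per training tile (default 1).
#' @param cluster_purity Minimum tumour fraction for a tile to enter feature
#'   extraction and clustering (default 1: fully tumoural windows). On
#'   gigapixel slides the share of annotation-boundary tiles among tumour
#'   tiles is negligible, so clustering "tumoural tiles" effectively means
#'   fully tumoural ones; a small phantom has proportionally far more
#'   boundary tiles, and without this filter their mixed content dominates
#'   the leading feature axis.
#' @param cluster_cohort `"all"` (default): PCA and the mixture are fitted
#'   on the pure tumour tiles of the whole cohort, which is also the cohort
#'   scored slide-wise; `"validation"` fits them on the validation partition
#'   only and projects the rest through the persisted transform.
#' @param cohort_args Extra arguments for [generate_cohort()].
#' @param config Optional [backbone_config()] override.
#' @param verbose Print stage progress.
#' @return A `phantom_study` list: the cohort, tiles, model, features,
#'   mixture fit, cluster map, per-slide reports and a `metrics` list
#'   (validation accuracy, cluster compositions, pure-slide agreement,
#'   mixed-slide truth correlation, IHC correlations).
#' @export
run_phantom_study <- function(n_A_pure = 10, n_B_pure = 10, n_mixed = 10,
                              seed = 1L, K = 2L,
                              patch_microns = 32, patch_pixels = 64,
                              epochs = 10L, n_augments_per_patch = 1L,
                              cluster_purity = 1,
                              cluster_cohort = c("all", "validation"),
                              cohort_args = list(), config = NULL,
                              verbose = FALSE) {
  cluster_cohort <- match.arg(cluster_cohort)
  say <- function(...) if (verbose) inform(sprintf(...))

  say("Simulating %d + %d + %d phantom slides", n_A_pure, n_B_pure, n_mixed)
  cohort <- do.call(generate_cohort, c(
    list(
      n_A_pure = n_A_pure, n_B_pure = n_B_pure, n_mixed = n_mixed,
      seed = seed
    ),
    cohort_args
  ))
  manifest <- cohort$manifest

  say("Tiling %d slides", nrow(manifest))
  patches <- purrr::map(cohort$slides, function(s) {
    tissue <- compute_tissue_mask(s$slide)
    tumour <- rasterise_annotations(s$slide, s$annotations)
    extract_patches(s$slide, tissue, tumour,
      patch_microns = patch_microns, patch_pixels = patch_pixels
    )
  }) |> dplyr::bind_rows()

  say("Augmenting the training partition")
  policy <- augmentation_policy(
    n_augments_per_patch = n_augments_per_patch,
    seed = derive_seed(seed, "augment")
  )
  split <- dplyr::select(manifest, "slide_id", "split")
  tiles <- build_training_set(patches, policy, split)

  # Desk-scale schedule for the from-scratch backbone: small batches give
  # the optimiser enough steps on a few hundred tiles, and a 0.7 decay keeps
  # the late epochs useful (the 0.03 / 0.5 defaults suit fine-tuning).
  config <- config %||% backbone_config(
    input_size = patch_pixels, epochs = epochs,
    learning_rate = 0.01, lr_decay_factor = 0.7, batch_size = 16L,
    seed = derive_seed(seed, "train")
  )
  train_tiles <- dplyr::filter(tiles, .data$split == "train")
  val_tiles <- dplyr::filter(tiles, .data$split == "validation")
  say(
    "Training the weak classifier on %d tiles (validating on %d)",
    nrow(train_tiles), nrow(val_tiles)
  )
  model <- train_weak_classifier(train_tiles, val_tiles, config)
  say("Validation accuracy %.3f", model$final_val_accuracy)

  say("Extracting pooled features for tumour tiles")
  tumour_patches <- patches |>
    dplyr::filter(
      .data$weak_label == "tumour",
      .data$tumour_fraction >= cluster_purity
    ) |>
    dplyr::left_join(dplyr::distinct(split), by = "slide_id")
  features <- extract_features(model, tumour_patches)

  # The whole phantom cohort is the clustering cohort (slide-level scoring
  # covers every pure and mixed slide); the train/validation partition
  # governs classifier training only. With `cluster_cohort = "validation"`
  # PCA and the mixture are instead fitted on the validation partition alone
  # and the persisted transform/model applied to the remaining slides.
  fit_features <- if (cluster_cohort == "validation") {
    dplyr::filter(features, .data$split == "validation")
  } else {
    features
  }
  pca <- reduce_pca(fit_features)
  reduced_all <- predict(pca, features)
  say(
    "Fitting the K = %d Gaussian mixture on %d tumour tiles",
    K, nrow(fit_features)
  )
  gmm <- fit_gmm(pca$reduced, K = K, seed = derive_seed(seed, "gmm"))
  assignments <- assign_clusters(gmm, reduced_all)
  assignments$split <- features$split

  reference <- manifest |>
    dplyr::filter(.data$diagnosis %in% c("HCC", "iCCA")) |>
    dplyr::select("slide_id", tumour_type = "diagnosis") |>
    dplyr::inner_join(
      dplyr::select(tumour_patches, "slide_id", "grid_row", "grid_col"),
      by = "slide_id"
    )
  cluster_map <- map_clusters_to_types(assignments, reference)

  reports <- compute_slide_proportions(assignments, K = K) |>
    predict_major_contingent(cluster_map) |>
    dplyr::left_join(
      dplyr::select(
        manifest, "slide_id", "diagnosis", "split", "true_fraction_A"
      ),
      by = "slide_id"
    )

  pure <- dplyr::filter(reports, .data$diagnosis %in% c("HCC", "iCCA"))
  mixed <- dplyr::filter(reports, .data$diagnosis == "cHCC-CCA")
  agreement <- diagnostic_agreement(tibble(
    pathology_diagnosis = reports$diagnosis,
    predicted_major_contingent = reports$predicted_major_contingent,
    pathology_major_contingent = ifelse(
      reports$true_fraction_A > 0.5, "HCC", "iCCA"
    )
  ))

  ihc <- ihc_contingents(cohort$ihc)
  reports <- dplyr::left_join(
    reports,
    dplyr::select(
      ihc, "slide_id", "ihc_hcc_contingent_pct", "ihc_icca_contingent_pct"
    ),
    by = "slide_id"
  )
  ihc_cor <- proportion_ihc_correlation(reports)

  comp <- cluster_map$composition |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::filter(.data$n == max(.data$n)) |>
    dplyr::ungroup()
  metrics <- list(
    val_accuracy = model$final_val_accuracy,
    cluster_composition = comp,
    pure_agreement = mean(pure$predicted_major_contingent == pure$diagnosis),
    agreement_table = agreement,
    mixed_truth_correlation = if (nrow(mixed) >= 3) {
      stats::cor(mixed$type_proportion[, "HCC"], mixed$true_fraction_A)
    } else {
      NA_real_
    },
    ihc_correlation = ihc_cor
  )

  structure(
    list(
      cohort = cohort, patches = patches, tiles = tiles, model = model,
      features = features, pca = pca, gmm = gmm,
      assignments = assignments, cluster_map = cluster_map,
      reports = reports, metrics = metrics, seed = seed
    ),
    class = "phantom_study"
  )
}

#' @export
print.phantom_study <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    paste0(
      "<phantom_study> %d slides, %d tumour tiles, K = %d\n",
      "  weak classifier validation accuracy: %.3f\n",
      "  pure-slide major-contingent accuracy: %.2f\n",
      "  mixed-slide correlation with true contingent: %.3f\n"
    ),
    nrow(x$cohort$manifest), nrow(x$features), x$gmm$K,
    m$val_accuracy, m$pure_agreement, m$mixed_truth_correlation
  ))
  invisible(x)
}
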