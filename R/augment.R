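# Plausibility-restricted augmentation for histology tiles. The canonical
# family: colour jitter of at most ±2% hue, -80%..+60% saturation and ±20%
# brightness; horizontal/vertical flips; rotations within ±90 degrees with
# mirrored borders; 3x3 Gaussian blur applied with a given probability; and
# a mild zoom between 1.0 and 1.2 emulating jitter of the physical tile
# scale. Transforms compose in a fixed order (zoom -> rotation -> flips ->
# colour -> blur) so a logged parameter draw fully determines the output.

CANONICAL_BOUNDS <- list(
  hue_delta = 0.02,
  saturation_scale = c(0.2, 1.6),
  brightness_delta = 0.2,
  rotation_deg = c(-90, 90),
  scale_jitter = c(1, 1.2)
)

#' Define an augmentation policy
#'
#' Defaults are the full canonical transform family. Ranges wider than the
#' canonical bounds are rejected unless `allow_custom_ranges = TRUE`,
#' because wider jitter produces implausible histology.
#'
#' @param hue_delta Maximum absolute hue shift, as a fraction of the hue
#'   circle (default 0.02, i.e. ±2%).
#' @param saturation_scale Multiplicative saturation range (default
#'   `c(0.2, 1.6)`, i.e. −80% to +60%).
#' @param brightness_delta Maximum absolute brightness (value) shift
#'   (default 0.2).
#' @param rotation_deg Rotation range in degrees (default `c(-90, 90)`).
#' @param hflip,vflip Whether the respective flip may be sampled (each with
#'   probability 0.5 when enabled).
#' @param blur_prob Probability of applying the 3x3 Gaussian blur
#'   (default 0.25).
#' @param scale_jitter Zoom factor range (default `c(1, 1.2)`).
#' @param n_augments_per_patch Augmented copies generated per training patch
#'   by [build_training_set()] (default 1).
#' @param seed Integer seed governing all parameter draws.
#' @param allow_custom_ranges Permit ranges outside the canonical bounds.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(hue_delta = 0.02,
                                saturation_scale = c(0.2, 1.6),
                                brightness_delta = 0.2,
                                rotation_deg = c(-90, 90),
                                hflip = TRUE, vflip = TRUE,
                                blur_prob = 0.25,
                                scale_jitter = c(1, 1.2),
                                n_augments_per_patch = 1L,
                                seed = 1L,
                                allow_custom_ranges = FALSE) {
  policy <- list(
    hue_delta = hue_delta, saturation_scale = sort(saturation_scale),
    brightness_delta = brightness_delta, rotation_deg = sort(rotation_deg),
    hflip = isTRUE(hflip), vflip = isTRUE(vflip),
    blur_prob = blur_prob, scale_jitter = sort(scale_jitter),
    n_augments_per_patch = as.integer(n_augments_per_patch),
    seed = as.integer(seed)
  )
  if (policy$n_augments_per_patch < 0) abort("`n_augments_per_patch` must be >= 0.")
  if (blur_prob < 0 || blur_prob > 1) abort("`blur_prob` must be in [0, 1].")
  if (!allow_custom_ranges) {
    b <- CANONICAL_BOUNDS
    ok <- policy$hue_delta <= b$hue_delta &&
      policy$saturation_scale[1] >= b$saturation_scale[1] &&
      policy$saturation_scale[2] <= b$saturation_scale[2] &&
      policy$brightness_delta <= b$brightness_delta &&
      policy$rotation_deg[1] >= b$rotation_deg[1] &&
      policy$rotation_deg[2] <= b$rotation_deg[2] &&
      policy$scale_jitter[1] >= b$scale_jitter[1] &&
      policy$scale_jitter[2] <= b$scale_jitter[2]
    if (!ok) {
      abort(paste(
        "Policy ranges exceed the canonical plausibility bounds",
        "(set `allow_custom_ranges = TRUE` to override)."
      ))
    }
  }
  structure(policy, class = "augmentation_policy")
}

#' Sample one set of augmentation parameters
#'
#' Draws from the ambient R random stream.
#'
#' @param policy An [augmentation_policy()].
#' @return A one-row tibble of sampled parameters.
#' @export
sample_augment_params <- function(policy) {
  tibble(
    scale = runif(1, policy$scale_jitter[1], policy$scale_jitter[2]),
    rotation = runif(1, policy$rotation_deg[1], policy$rotation_deg[2]),
    hflip = policy$hflip && runif(1) < 0.5,
    vflip = policy$vflip && runif(1) < 0.5,
    hue = runif(1, -policy$hue_delta, policy$hue_delta),
    saturation = runif(1, policy$saturation_scale[1], policy$saturation_scale[2]),
    brightness = runif(1, -policy$brightness_delta, policy$brightness_delta),
    blur = runif(1) < policy$blur_prob
  )
}

#' Augment a single patch
#'
#' Applies one sampled draw of the policy's transform family. Labels,
#' identifiers and tile size are preserved; the sampled parameters are
#' recorded in a `params` list-column of the result. If `params` is omitted
#' it is drawn from the ambient random stream (seed it, or use
#' [build_training_set()], for reproducibility).
#'
#' @param patch A one-row patch tibble (as produced by [extract_patches()]).
#' @param policy An [augmentation_policy()].
#' @param params Optional pre-sampled parameter row from
#'   [sample_augment_params()].
#' @return A one-row patch tibble with transformed `pixels` and a `params`
#'   list-column.
#' @export
augment_patch <- function(patch, policy, params = NULL) {
  if (nrow(patch) != 1L) abort("`augment_patch()` takes a single patch row.")
  params <- params %||% sample_augment_params(policy)
  out <- patch
  out$pixels <- list(apply_augment(patch$pixels[[1]], params))
  out$params <- list(params)
  out
}

apply_augment <- function(img, p) {
  if (p$scale != 1) img <- scale_zoom(img, p$scale)
  if (p$rotation != 0) img <- rotate_reflect(img, p$rotation)
  if (p$hflip) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  if (p$vflip) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  if (p$hue != 0 || p$saturation != 1 || p$brightness != 0) {
    hsv <- rgb_array_to_hsv(img)
    img <- hsv_to_rgb_array(
      hsv[[1]] + p$hue,
      clamp(hsv[[2]] * p$saturation),
      clamp(hsv[[3]] + p$brightness)
    )
  }
  if (p$blur) img <- gaussian_blur3(img)
  img
}

#' Build a training/validation tile set with patient-level separation
#'
#' Training tiles are the original patches from training slides plus
#' `n_augments_per_patch` augmented copies of each; validation tiles are the
#' untouched originals from validation slides. Every output row records its
#' provenance (origin patch, augment index, sampled parameters). Slides
#' present in both partitions are a patient-leakage error.
#'
#' @param patches Patch tibble (possibly several slides).
#' @param policy An [augmentation_policy()]; its `seed` drives all draws.
#' @param split A data frame with columns `slide_id` and `split`
#'   (`"train"` / `"validation"`), one row per slide.
#' @return A tibble of tiles with columns of `patches` plus `split`,
#'   `origin` (`"original"`/`"augmented"`), `augment_index` and `params`.
#' @export
build_training_set <- function(patches, policy, split) {
  split <- as_tibble(split)
  if (!all(c("slide_id", "split") %in% names(split))) {
    abort("`split` needs columns slide_id and split.")
  }
  dup <- split |>
    dplyr::distinct(.data$slide_id, .data$split) |>
    dplyr::count(.data$slide_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Patient leakage: slide(s) %s assigned to both partitions.",
      paste(dup$slide_id, collapse = ", ")
    ))
  }
  bad <- setdiff(split$split, c("train", "validation"))
  if (length(bad) > 0) abort("`split` values must be 'train' or 'validation'.")
  unassigned <- setdiff(unique(patches$slide_id), split$slide_id)
  if (length(unassigned) > 0) {
    abort(sprintf(
      "Slide(s) %s have no partition assignment.",
      paste(unassigned, collapse = ", ")
    ))
  }
  tiles <- dplyr::left_join(patches, dplyr::distinct(split), by = "slide_id")
  tiles$origin <- "original"
  tiles$augment_index <- 0L
  tiles$params <- rep(list(NULL), nrow(tiles))

  train <- dplyr::filter(tiles, .data$split == "train")
  n_aug <- policy$n_augments_per_patch
  aug <- NULL
  if (n_aug > 0 && nrow(train) > 0) {
    aug <- with_seed(policy$seed, {
      purrr::map(seq_len(nrow(train)), function(i) {
        purrr::map(seq_len(n_aug), function(k) {
          a <- augment_patch(train[i, ], policy)
          a$origin <- "augmented"
          a$augment_index <- as.integer(k)
          a
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
    })
  }
  dplyr::bind_rows(tiles, aug)
}
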