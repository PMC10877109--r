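#' Halve feature dimension with principal component analysis
#'
#' Projects mean-centred features onto their top `target_dim` principal
#' components; by default the feature dimension is halved (rounded down).
#' The fitted transform (centre + rotation) is returned so new cohorts can
#' be projected into the same space with [predict()].
#'
#' @param features Numeric matrix (rows = patches) or a feature tibble from
#'   [extract_features()] (its `feature` matrix column is used).
#' @param target_dim Number of components to keep; default `floor(D / 2)`.
#' @param rank_tol Relative tolerance defining the usable rank: components
#'   with a standard deviation below `rank_tol` times the leading one are
#'   treated as rank deficiency, dropped with a warning. Such directions
#'   carry no signal (relative variance below `rank_tol^2`) but would
#'   destabilise a full-covariance mixture downstream. Default `1e-4`.
#' @return A `histo_pca` object with elements `reduced` (the projected
#'   matrix, or the input tibble with `feature` replaced by its projection),
#'   `center`, `rotation`, `sdev` and `explained_variance`.
#' @export
reduce_pca <- function(features, target_dim = NULL, rank_tol = 1e-4) {
  tbl <- NULL
  if (is.data.frame(features)) {
    tbl <- features
    features <- features$feature
  }
  if (!is.matrix(features)) abort("`features` must be a matrix or a tibble with a `feature` column.")
  if (any(!is.finite(features))) abort("Features must be finite.")
  D <- ncol(features)
  target_dim <- target_dim %||% (D %/% 2L)
  if (nrow(features) <= target_dim) {
    abort(sprintf("Need more than %d rows to keep %d components.", target_dim, target_dim))
  }
  fit <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  rank <- sum(fit$sdev > fit$sdev[1] * rank_tol)
  keep <- target_dim
  if (rank < target_dim) {
    warn(sprintf(
      "Feature rank %d is below the requested %d components; keeping %d.",
      rank, target_dim, rank
    ))
    keep <- rank
  }
  reduced_mat <- fit$x[, seq_len(keep), drop = FALSE]
  reduced <- if (is.null(tbl)) {
    reduced_mat
  } else {
    tbl$feature <- reduced_mat
    tbl
  }
  structure(
    list(
      reduced = reduced,
      center = fit$center,
      rotation = fit$rotation[, seq_len(keep), drop = FALSE],
      sdev = fit$sdev,
      explained_variance = fit$sdev[seq_len(keep)]^2 / sum(fit$sdev^2),
      target_dim = keep
    ),
    class = "histo_pca"
  )
}

#' Project new features with a fitted PCA transform
#'
#' @param object A `histo_pca` from [reduce_pca()].
#' @param newdata Matrix or feature tibble in the original feature space.
#' @param ... Unused.
#' @return Projected matrix, or tibble with projected `feature` column.
#' @export
predict.histo_pca <- function(object, newdata, ...) {
  tbl <- NULL
  if (is.data.frame(newdata)) {
    tbl <- newdata
    newdata <- newdata$feature
  }
  proj <- sweep(newdata, 2, object$center) %*% object$rotation
  if (is.null(tbl)) {
    proj
  } else {
    tbl$feature <- proj
    tbl
  }
}

#' @export
print.histo_pca <- function(x, ...) {
  cat(sprintf(
    "<histo_pca> %d -> %d dims; %.1f%% variance kept\n",
    length(x$center), x$target_dim, 100 * sum(x$explained_variance)
  ))
  invisible(x)
}
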