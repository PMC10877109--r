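# Gaussian mixture modelling of reduced tumour-tile features, fitted by
# expectation-maximization: seeded k-means initialisation, best of n_init
# restarts, full (default) or diagonal covariances with ridge regularisation
# when a covariance turns singular. Components are re-indexed by descending
# mixture weight after fitting so "Cluster 0", "Cluster 1", ... are stable
# across runs; cluster identifiers are 0-based throughout.

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# log N(x | mean, cov) for all rows of x, via Cholesky; returns the factor
# too so callers can detect regularisation needs.
log_dmvnorm <- function(x, mean, cov) {
  R <- chol(cov)  # upper triangular, cov = R'R
  z <- backsolve(R, t(sweep(x, 2, mean)), transpose = TRUE)
  -0.5 * (ncol(x) * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(z^2))
}

chol_ok <- function(cov) {
  tryCatch(
    {
      chol(cov)
      TRUE
    },
    error = function(e) FALSE
  )
}

#' Fit a Gaussian mixture model by expectation-maximization
#'
#' @param reduced Numeric matrix (rows = patches, columns = reduced feature
#'   dimensions) or a feature tibble whose `feature` column holds it.
#' @param K Number of mixture components (the study uses 2 or 3).
#' @param seed Integer seed for initialisation.
#' @param n_init Number of k-means-seeded EM restarts; the solution with the
#'   best final log-likelihood is kept (default 5).
#' @param max_iter Maximum EM iterations per restart (default 200).
#' @param tol Absolute log-likelihood change declaring convergence
#'   (default 1e-4).
#' @param covariance `"full"` (default) or `"diagonal"`.
#' @param ridge Ridge added to a covariance diagonal when it turns singular
#'   (default 1e-6).
#' @param init_params Optional explicit initialisation bypassing k-means and
#'   `n_init`: a list with `weights` (length K), `means` (K x d matrix) and
#'   `covariances` (list of K d x d matrices).
#' @return A `histo_gmm` object: `weights`, `means`, `covariances`,
#'   `log_likelihood_trace`, `n_iter`, `converged`, plus the fitting
#'   configuration.
#' @export
fit_gmm <- function(reduced, K, seed = 1L, n_init = 5L, max_iter = 200L,
                    tol = 1e-4, covariance = c("full", "diagonal"),
                    ridge = 1e-6, init_params = NULL) {
  covariance <- match.arg(covariance)
  if (is.data.frame(reduced)) reduced <- reduced$feature
  x <- as.matrix(reduced)
  n <- nrow(x)
  d <- ncol(x)
  if (K < 1) abort("`K` must be at least 1.")
  if (n < K) abort(sprintf("Need at least K = %d observations, got %d.", K, n))

  runs <- if (is.null(init_params)) seq_len(n_init) else 1L
  best <- NULL
  for (r in runs) {
    init <- init_params %||% kmeans_init(x, K, seed + r - 1L, ridge)
    # a plain maximum-likelihood run first; if any covariance turns
    # singular, restart the same run with the ridge applied in every M-step
    # so the optimised objective (and the monotone trace) stays consistent
    fit <- em_run(x, init, max_iter, tol, covariance, ridge = 0)
    if (is.null(fit)) {
      warn(sprintf(
        "Singular covariance in EM restart %d; refitting with ridge %g.", r, ridge
      ))
      fit <- em_run(x, init, max_iter, tol, covariance, ridge = ridge)
      if (is.null(fit)) {
        abort("Covariance stayed singular even with the ridge; increase `ridge`.")
      }
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ord <- order(best$weights, decreasing = TRUE)
  structure(
    list(
      K = as.integer(K),
      weights = best$weights[ord],
      means = best$means[ord, , drop = FALSE],
      covariances = best$covariances[ord],
      log_likelihood_trace = best$trace,
      n_iter = best$n_iter,
      converged = best$converged,
      seed = as.integer(seed), n_init = as.integer(n_init),
      max_iter = as.integer(max_iter), tol = tol,
      covariance = covariance, ridge = ridge,
      n = n, d = d
    ),
    class = "histo_gmm"
  )
}

kmeans_init <- function(x, K, seed, ridge) {
  km <- with_seed(seed, {
    if (K == 1L) {
      list(cluster = rep(1L, nrow(x)), centers = matrix(colMeans(x), 1))
    } else {
      stats::kmeans(x, centers = K, nstart = 1, iter.max = 50)
    }
  })
  d <- ncol(x)
  pooled <- crossprod(sweep(x, 2, colMeans(x))) / nrow(x)
  covs <- lapply(seq_len(K), function(k) {
    xk <- x[km$cluster == k, , drop = FALSE]
    cv <- if (nrow(xk) > d) {
      crossprod(sweep(xk, 2, colMeans(xk))) / nrow(xk)
    } else {
      pooled
    }
    if (!chol_ok(cv)) cv <- pooled
    if (!chol_ok(cv)) cv <- cv + diag(max(ridge, 1e-6), d)
    cv
  })
  list(
    weights = tabulate(km$cluster, K) / nrow(x),
    means = matrix(km$centers, nrow = K),
    covariances = covs
  )
}

# One EM run. With ridge = 0 a singular covariance aborts the run (returns
# NULL) so the caller can restart with consistent regularisation.
em_run <- function(x, init, max_iter, tol, covariance, ridge) {
  n <- nrow(x)
  d <- ncol(x)
  K <- length(init$weights)
  w <- init$weights
  mu <- init$means
  regularise <- function(cv) {
    if (covariance == "diagonal") cv <- diag(diag(cv), d)
    cv <- cv + diag(ridge, d)
    if (!chol_ok(cv)) return(NULL)
    cv
  }
  covs <- lapply(init$covariances, regularise)
  if (any(vapply(covs, is.null, logical(1)))) return(NULL)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    # E-step
    logp <- vapply(
      seq_len(K),
      function(k) log(w[k]) + log_dmvnorm(x, mu[k, ], covs[[k]]),
      numeric(n)
    )
    logp <- matrix(logp, nrow = n)
    lse <- logsumexp_rows(logp)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (it > 0 && abs(ll - trace[it]) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    it <- it + 1L
    resp <- exp(logp - lse)
    # M-step
    Nk <- colSums(resp)
    w <- Nk / n
    mu <- t(vapply(seq_len(K), function(k) colSums(resp[, k] * x) / Nk[k], numeric(d)))
    mu <- matrix(mu, nrow = K)
    covs <- lapply(seq_len(K), function(k) {
      xc <- sweep(x, 2, mu[k, ])
      regularise(crossprod(xc * sqrt(resp[, k])) / Nk[k])
    })
    if (any(vapply(covs, is.null, logical(1)))) return(NULL)
  }
  list(
    weights = w, means = mu, covariances = covs,
    loglik = trace[length(trace)], trace = trace,
    n_iter = it, converged = converged
  )
}

#' @export
print.histo_gmm <- function(x, ...) {
  cat(sprintf(
    "<histo_gmm> K = %d, d = %d, n = %d; log-likelihood %.4f after %d iterations%s\n",
    x$K, x$d, x$n, x$log_likelihood_trace[length(x$log_likelihood_trace)],
    x$n_iter, if (x$converged) "" else " (not converged)"
  ))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Per-component parameters of a fitted mixture
#'
#' @param x A `histo_gmm`.
#' @param ... Unused.
#' @return A tibble with one row per component: `cluster_id` (0-based,
#'   ordered by descending weight), `weight`, and list-columns `mean` and
#'   `covariance`.
#' @export
tidy.histo_gmm <- function(x, ...) {
  tibble(
    cluster_id = seq_len(x$K) - 1L,
    weight = x$weights,
    mean = lapply(seq_len(x$K), function(k) x$means[k, ]),
    covariance = x$covariances
  )
}

#' One-row summary of a fitted mixture
#'
#' @param x A `histo_gmm`.
#' @param ... Unused.
#' @return A one-row tibble including the BIC.
#' @export
glance.histo_gmm <- function(x, ...) {
  ll <- x$log_likelihood_trace[length(x$log_likelihood_trace)]
  p_cov <- if (x$covariance == "full") x$d * (x$d + 1) / 2 else x$d
  n_par <- (x$K - 1) + x$K * x$d + x$K * p_cov
  tibble(
    K = x$K, n = x$n, d = x$d, log_likelihood = ll,
    n_iter = x$n_iter, converged = x$converged,
    BIC = -2 * ll + n_par * log(x$n)
  )
}

#' Posterior cluster assignments for reduced features
#'
#' @param model A `histo_gmm`.
#' @param reduced Matrix of reduced features, or a feature tibble (its key
#'   columns are carried through).
#' @return A tibble with `cluster_id` (0-based argmax of the posterior) and
#'   a `responsibility` matrix column of posterior component probabilities
#'   (rows sum to 1).
#' @export
assign_clusters <- function(model, reduced) {
  tbl <- NULL
  if (is.data.frame(reduced)) {
    tbl <- dplyr::select(
      reduced,
      dplyr::any_of(c("slide_id", "grid_row", "grid_col", "weak_label"))
    )
    reduced <- reduced$feature
  }
  x <- as.matrix(reduced)
  if (ncol(x) != model$d) {
    abort(sprintf("Feature dimension %d does not match the model's %d.", ncol(x), model$d))
  }
  logp <- vapply(
    seq_len(model$K),
    function(k) log(model$weights[k]) + log_dmvnorm(x, model$means[k, ], model$covariances[[k]]),
    numeric(nrow(x))
  )
  logp <- matrix(logp, nrow = nrow(x))
  resp <- exp(logp - logsumexp_rows(logp))
  out <- tbl %||% tibble(.rows = nrow(x))
  out$cluster_id <- as.integer(max.col(resp, ties.method = "first") - 1L)
  out$responsibility <- resp
  out
}

#' Map clusters to tumour types using pure-type reference slides
#'
#' Each cluster is assigned the majority tumour type among its reference
#' tiles (tiles from slides with an unambiguous HCC or iCCA diagnosis), and
#' the composition percentage of the majority type is reported. An exact
#' 50/50 split is refused unless a `tie_break` type is supplied. Under
#' K = 2 a warning is raised if both clusters map to the same type (with
#' K = 3 two hepatocellular-dominant clusters are expected).
#'
#' @param assignments Assignment tibble from [assign_clusters()] including
#'   `slide_id`, `grid_row`, `grid_col`.
#' @param reference Tibble with `slide_id`, `grid_row`, `grid_col` and
#'   `tumour_type` for reference tiles.
#' @param tie_break `NULL` (refuse ties) or a type name to prefer on a tie.
#' @return A `histo_cluster_map` list: `map` (named character vector,
#'   cluster id -> type) and `composition` (tibble with per-cluster,
#'   per-type counts and percentages).
#' @export
map_clusters_to_types <- function(assignments, reference, tie_break = NULL) {
  keyed <- dplyr::inner_join(
    dplyr::select(assignments, "slide_id", "grid_row", "grid_col", "cluster_id"),
    reference,
    by = c("slide_id", "grid_row", "grid_col")
  )
  if (nrow(keyed) == 0) abort("No assignment matches any reference tile.")
  composition <- keyed |>
    dplyr::count(.data$cluster_id, .data$tumour_type) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cluster_id, dplyr::desc(.data$n))
  map <- vapply(split(composition, composition$cluster_id), function(g) {
    top <- g[g$n == max(g$n), ]
    if (nrow(top) > 1) {
      if (is.null(tie_break) || !tie_break %in% top$tumour_type) {
        abort(sprintf(
          "Cluster %d reference tiles split evenly between %s; supply `tie_break`.",
          g$cluster_id[1], paste(top$tumour_type, collapse = " and ")
        ))
      }
      return(tie_break)
    }
    top$tumour_type
  }, character(1))
  if (anyDuplicated(map) && length(map) == 2) {
    warn(sprintf("Both clusters map to '%s'; inspect the composition table.", map[1]))
  }
  structure(list(map = map, composition = composition), class = "histo_cluster_map")
}

#' @export
print.histo_cluster_map <- function(x, ...) {
  for (cl in names(x$map)) {
    comp <- x$composition[x$composition$cluster_id == as.integer(cl), ]
    maj <- comp$pct[comp$tumour_type == x$map[[cl]]]
    cat(sprintf("Cluster %s -> %s (%d%% of reference tiles)\n",
      cl, x$map[[cl]], round_half_up(maj)))
  }
  invisible(x)
}

#' Paint tile cluster assignments back onto the slide grid
#'
#' Reconstructs the spatial distribution of cluster labels: every assigned
#' tile window is painted in its cluster's colour on a copy of the slide
#' raster; background and non-tumour tissue are left untouched.
#'
#' @param slide A `histo_slide`.
#' @param assignments Assignment tibble (rows for this slide are used).
#' @param patch_microns Tile edge in microns used at extraction (default 125).
#' @param colours Vector of colours indexed by `cluster_id + 1`; defaults to
#'   green/blue then a qualitative tail.
#' @return RGB array of the painted slide.
#' @export
reconstruct_label_map <- function(slide, assignments, patch_microns = 125,
                                  colours = c("#2e9e4f", "#2b6fb3", "#e8a33d", "#8c4fb0")) {
  rows <- dplyr::filter(assignments, .data$slide_id == slide$slide_id)
  if (nrow(rows) == 0) {
    warn(sprintf("No assignments reference slide '%s'.", slide$slide_id))
  }
  win <- round(patch_microns / slide$microns_per_pixel)
  img <- slide$pixels
  d <- dim(img)
  for (i in seq_len(nrow(rows))) {
    rgbcol <- grDevices::col2rgb(colours[rows$cluster_id[i] + 1L]) / 255
    ri <- rows$grid_row[i] * win + seq_len(win)
    ci <- rows$grid_col[i] * win + seq_len(win)
    if (max(ri) > d[1] || max(ci) > d[2]) {
      abort(sprintf(
        "Tile (%d, %d) of slide '%s' falls outside the raster; check patch_microns.",
        rows$grid_row[i], rows$grid_col[i], slide$slide_id
      ))
    }
    for (ch in 1:3) img[ri, ci, ch] <- rgbcol[ch]
  }
  img
}

#' Save / load a fitted mixture model as JSON
#'
#' @param model A `histo_gmm`.
#' @param path JSON path.
#' @return `path` (write) or the restored `histo_gmm` (read).
#' @export
write_gmm_json <- function(model, path) {
  obj <- unclass(model)
  obj$means <- apply(model$means, 1, identity, simplify = FALSE)
  obj$covariances <- lapply(model$covariances, function(m) apply(m, 1, identity, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gmm_json
#' @export
read_gmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m, nrow_) {
    if (is.matrix(m)) unname(m) else matrix(unlist(m), nrow = nrow_, byrow = TRUE)
  }
  obj$means <- as_mat(obj$means, obj$K)
  cv <- obj$covariances
  obj$covariances <- if (is.array(cv) && length(dim(cv)) == 3) {
    # list of matrices simplified to a (K, d, d) array
    lapply(seq_len(dim(cv)[1]), function(k) {
      matrix(cv[k, , ], obj$d, obj$d)
    })
  } else if (is.list(cv)) {
    lapply(cv, function(m) as_mat(m, obj$d))
  } else {
    list(as_mat(cv, obj$d))
  }
  obj$weights <- as.numeric(obj$weights)
  structure(obj, class = "histo_gmm")
}
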