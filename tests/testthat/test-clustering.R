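test_that("PCA recovers exact low-dimensional structure", {
  withr::with_seed(1, {
    basis <- qr.Q(qr(matrix(rnorm(16), 4, 4)))[, 1:2]
    scores <- matrix(rnorm(100 * 2, sd = c(3, 1)), 100, 2, byrow = TRUE)
    x <- scores %*% t(basis) + matrix(rnorm(4), 100, 4, byrow = TRUE)
  })
  suppressWarnings(fit <- reduce_pca(x, target_dim = 2))
  # data lie exactly in a 2-D affine subspace: reconstruction is exact
  recon <- sweep(fit$reduced %*% t(fit$rotation), 2, fit$center, `+`)
  expect_equal(recon, x, tolerance = 1e-10)
  # projecting the same data again gives identical output
  expect_equal(predict(fit, x), fit$reduced, tolerance = 1e-12)
})

test_that("explained variance matches a dense eigendecomposition oracle", {
  withr::with_seed(2, {
    x <- matrix(rnorm(80 * 6), 80, 6) %*% diag(c(4, 3, 2, 1, 0.5, 0.2))
  })
  fit <- reduce_pca(x, target_dim = 3)
  cov_oracle <- crossprod(sweep(x, 2, colMeans(x))) / (nrow(x) - 1)
  ev <- eigen(cov_oracle, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fit$sdev^2, ev, tolerance = 1e-10)
  expect_equal(fit$explained_variance, (ev / sum(ev))[1:3], tolerance = 1e-10)
  # default target is half the dimension
  expect_identical(reduce_pca(x)$target_dim, 3L)
})

test_that("rank-deficient features are truncated with a warning", {
  withr::with_seed(3, {
    base <- matrix(rnorm(40 * 2), 40, 2)
  })
  x <- cbind(base, base %*% matrix(c(1, 2, -1, 0.5), 2, 2))  # rank 2 in 4-D
  expect_warning(fit <- reduce_pca(x, target_dim = 3), "rank")
  expect_identical(fit$target_dim, 2L)
  expect_identical(ncol(fit$reduced), 2L)
})

test_that("a single-component fit has the closed-form solution", {
  withr::with_seed(4, {
    x <- matrix(rnorm(60 * 3), 60, 3)
  })
  fit <- fit_gmm(x, K = 1)
  expect_equal(fit$weights, 1)
  expect_equal(as.vector(fit$means), colMeans(x), tolerance = 1e-12)
  ml_cov <- crossprod(sweep(x, 2, colMeans(x))) / nrow(x)  # denominator N
  expect_equal(fit$covariances[[1]], ml_cov, tolerance = 1e-9)
})

test_that("EM matches the brute-force oracle from identical initialisation", {
  # tiny instance: N = 6, d = 1, K = 2
  x <- matrix(c(-2.1, -1.9, -2.0, 1.8, 2.2, 2.0), ncol = 1)
  labels <- c(1, 1, 1, 2, 2, 2)
  init <- init_from_labels(x, labels)
  fit <- fit_gmm(x, K = 2, init_params = init, tol = 1e-12, max_iter = 500)
  orc <- oracle_em(x, init$weights, init$means, init$covariances)
  expect_equal(tail(fit$log_likelihood_trace, 1), orc$loglik, tolerance = 1e-6)
  ord <- order(fit$weights, decreasing = TRUE)
  oord <- order(orc$weights, decreasing = TRUE)
  expect_equal(fit$weights, orc$weights[oord], tolerance = 1e-6)
  expect_equal(unname(fit$means), unname(orc$means[oord, , drop = FALSE]), tolerance = 1e-6)
  expect_equal(fit$covariances[[1]], orc$covs[[oord[1]]], tolerance = 1e-6)
})

test_that("well-separated components are recovered with correct assignments", {
  withr::with_seed(5, {
    x <- rbind(
      matrix(rnorm(200 * 2, mean = -5), ncol = 2),
      matrix(rnorm(200 * 2, mean = 5), ncol = 2)
    )
  })
  truth <- rep(1:2, each = 200)
  fit <- fit_gmm(x, K = 2, seed = 1)
  expect_monotone_trace(fit)
  a <- assign_clusters(fit, x)
  tab <- table(a$cluster_id, truth)
  acc <- max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1]) / sum(tab)
  expect_gte(acc, 0.99)
  centres <- fit$means[order(fit$means[, 1]), ]
  expect_lt(max(abs(centres - rbind(c(-5, -5), c(5, 5)))), 0.2)
  # responsibilities are proper posteriors
  expect_equal(unname(rowSums(a$responsibility)), rep(1, nrow(x)), tolerance = 1e-9)
  expect_identical(a$cluster_id, as.integer(max.col(a$responsibility) - 1L))
  # components are reported in descending weight order
  expect_true(all(diff(fit$weights) <= 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
})

test_that("the log-likelihood trace is non-decreasing across random problems", {
  withr::with_seed(6, {
    for (rep in 1:8) {
      n <- sample(30:80, 1)
      d <- sample(1:3, 1)
      x <- matrix(rnorm(n * d, mean = sample(c(-1, 1), 1)), n, d)
      fit <- suppressWarnings(fit_gmm(x, K = 2, seed = rep, n_init = 2))
      expect_monotone_trace(fit)
    }
  })
})

test_that("relabelling components leaves the data log-likelihood unchanged", {
  withr::with_seed(7, {
    x <- rbind(
      matrix(rnorm(60 * 2, -2), ncol = 2),
      matrix(rnorm(40 * 2, 2), ncol = 2)
    )
  })
  fit <- fit_gmm(x, K = 2, seed = 1)
  ll <- oracle_mixture_loglik(x, fit$weights, fit$means, fit$covariances)
  ll_perm <- oracle_mixture_loglik(
    x, fit$weights[2:1], fit$means[2:1, , drop = FALSE], fit$covariances[2:1]
  )
  expect_equal(ll, ll_perm, tolerance = 1e-10)
  # and the trace's final value matches the oracle likelihood evaluation
  expect_equal(tail(fit$log_likelihood_trace, 1), ll, tolerance = 1e-6)
})

test_that("EM agrees with mclust from the same initialisation", {
  skip_if_not_installed("mclust")
  withr::with_seed(8, {
    x <- rbind(
      matrix(rnorm(50 * 2, -3), ncol = 2),
      matrix(rnorm(50 * 2, 3), ncol = 2)
    )
  })
  init <- init_from_labels(x, rep(1:2, each = 50))
  fit <- fit_gmm(x, K = 2, init_params = init, tol = 1e-10, max_iter = 500)
  sigma <- array(0, dim = c(2, 2, 2))
  chsig <- array(0, dim = c(2, 2, 2))
  for (k in 1:2) {
    sigma[, , k] <- init$covariances[[k]]
    chsig[, , k] <- chol(init$covariances[[k]])
  }
  mc <- mclust::emVVV(
    data = x,
    parameters = list(
      pro = init$weights, mean = t(init$means),
      variance = list(
        modelName = "VVV", d = 2, G = 2,
        sigma = sigma, cholsigma = chsig
      )
    ),
    control = mclust::emControl(tol = 1e-10)
  )
  expect_equal(tail(fit$log_likelihood_trace, 1), mc$loglik, tolerance = 1e-5)
  ord <- order(fit$weights, decreasing = TRUE)
  mord <- order(mc$parameters$pro, decreasing = TRUE)
  expect_equal(fit$weights[ord], mc$parameters$pro[mord], tolerance = 1e-4)
  expect_equal(
    unname(fit$means[ord, , drop = FALSE]),
    unname(t(mc$parameters$mean)[mord, , drop = FALSE]),
    tolerance = 1e-4
  )
})

test_that("assignments at component means are dominated by that component", {
  fit <- structure(
    list(
      K = 2L, weights = c(0.5, 0.5),
      means = rbind(c(-4, 0), c(4, 0)),
      covariances = list(diag(2), diag(2)),
      d = 2L, covariance = "full"
    ),
    class = "histo_gmm"
  )
  a <- assign_clusters(fit, fit$means)
  expect_gt(a$responsibility[1, 1], 0.99)
  expect_gt(a$responsibility[2, 2], 0.99)
  # hard labels equal the brute-force weighted-density argmax
  withr::with_seed(9, {
    pts <- matrix(rnorm(40 * 2, sd = 3), ncol = 2)
  })
  a2 <- assign_clusters(fit, pts)
  for (i in seq_len(nrow(pts))) {
    dens <- vapply(1:2, function(k) {
      fit$weights[k] * oracle_dmvnorm(pts[i, ], fit$means[k, ], fit$covariances[[k]])
    }, numeric(1))
    expect_identical(a2$cluster_id[i], as.integer(which.max(dens) - 1L))
  }
  expect_error(assign_clusters(fit, matrix(0, 2, 3)), "dimension")
})

test_that("cluster-to-type mapping reports majority compositions and ties", {
  mk_keys <- function(n, cluster, sid) tibble::tibble(
    slide_id = sid, grid_row = seq_len(n) - 1L, grid_col = 0L, cluster_id = cluster
  )
  assignments <- dplyr::bind_rows(
    mk_keys(100, 0L, "ref1"),
    mk_keys(100, 1L, "ref2")
  )
  reference <- dplyr::bind_rows(
    dplyr::mutate(mk_keys(100, 0L, "ref1"), tumour_type = rep(c("HCC", "iCCA"), c(76, 24))),
    dplyr::mutate(mk_keys(100, 1L, "ref2"), tumour_type = rep(c("iCCA", "HCC"), c(92, 8)))
  )
  reference$cluster_id <- NULL
  map <- map_clusters_to_types(assignments, reference)
  expect_identical(unname(map$map["0"]), "HCC")
  expect_identical(unname(map$map["1"]), "iCCA")
  comp <- map$composition
  expect_equal(comp$pct[comp$cluster_id == 0 & comp$tumour_type == "HCC"], 76)
  expect_equal(comp$pct[comp$cluster_id == 1 & comp$tumour_type == "iCCA"], 92)

  # an exact 50/50 split is refused without a tie-break policy
  tied_ref <- dplyr::mutate(mk_keys(100, 0L, "ref1"), tumour_type = rep(c("HCC", "iCCA"), 50))
  tied_ref$cluster_id <- NULL
  expect_error(map_clusters_to_types(mk_keys(100, 0L, "ref1"), tied_ref), "tie_break")
  tb <- map_clusters_to_types(mk_keys(100, 0L, "ref1"), tied_ref, tie_break = "HCC")
  expect_identical(unname(tb$map["0"]), "HCC")

  # two clusters mapping to one type warns under K = 2
  ref_same <- dplyr::bind_rows(
    dplyr::mutate(mk_keys(10, 0L, "ref1"), tumour_type = "HCC"),
    dplyr::mutate(mk_keys(10, 1L, "ref2"), tumour_type = "HCC")
  )
  ref_same$cluster_id <- NULL
  both <- dplyr::bind_rows(mk_keys(10, 0L, "ref1"), mk_keys(10, 1L, "ref2"))
  expect_warning(map_clusters_to_types(both, ref_same), "Both clusters")
})

test_that("label maps paint exactly the assigned windows", {
  g <- generate_slide(small_phantom_spec(seed = 41, contingent_fraction_A = 1))
  tissue <- g$truth$tissue_mask
  tumour <- g$truth$tumour_mask
  p <- extract_patches(g$slide, tissue, tumour, patch_microns = 16, patch_pixels = 32)
  tum <- dplyr::filter(p, .data$weak_label == "tumour")
  assignments <- dplyr::mutate(
    dplyr::select(tum, "slide_id", "grid_row", "grid_col"),
    cluster_id = 0L
  )
  img <- reconstruct_label_map(g$slide, assignments, patch_microns = 16)
  col0 <- grDevices::col2rgb("#2e9e4f") / 255
  painted <- matrix(FALSE, 192, 192)
  for (i in seq_len(nrow(assignments))) {
    ri <- assignments$grid_row[i] * 32 + 1:32
    ci <- assignments$grid_col[i] * 32 + 1:32
    painted[ri, ci] <- TRUE
    expect_true(all(img[ri, ci, 1] == col0[1] & img[ri, ci, 2] == col0[2]))
  }
  # everything outside assigned windows is untouched
  for (ch in 1:3) {
    orig <- g$slide$pixels[, , ch]
    new <- img[, , ch]
    expect_identical(new[!painted], orig[!painted])
  }
})

test_that("mixture models roundtrip through JSON", {
  withr::with_seed(10, {
    x <- rbind(matrix(rnorm(30 * 2, -3), ncol = 2), matrix(rnorm(30 * 2, 3), ncol = 2))
  })
  fit <- fit_gmm(x, K = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_gmm_json(fit, path)
  back <- read_gmm_json(path)
  expect_equal(back$weights, fit$weights, tolerance = 1e-12)
  expect_equal(back$means, unname(fit$means), tolerance = 1e-12)
  expect_equal(back$covariances[[1]], unname(fit$covariances[[1]]), tolerance = 1e-12)
  a1 <- assign_clusters(fit, x)
  a2 <- assign_clusters(back, x)
  expect_identical(a1$cluster_id, a2$cluster_id)
  # tidy/glance views
  td <- tidy(fit)
  expect_identical(td$cluster_id, 0:1)
  expect_equal(sum(td$weight), 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_identical(gl$K, 2L)
  expect_true(is.finite(gl$BIC))
})
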