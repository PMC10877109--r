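# Independent brute-force oracles. These deliberately use naive scalar
# loops and textbook formulas, sharing no code with the package internals.

# Ray-casting point-in-polygon, one point at a time.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- (xj - xi) * (py - yi) / (yj - yi) + xi
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# Rasterise polygons by testing every pixel centre.
oracle_rasterise <- function(dims, polygons) {
  mask <- matrix(FALSE, dims[1], dims[2])
  for (r in seq_len(dims[1])) {
    for (c in seq_len(dims[2])) {
      for (p in polygons) {
        if (oracle_point_in_polygon(c - 0.5, r - 0.5, p)) {
          mask[r, c] <- TRUE
          break
        }
      }
    }
  }
  mask
}

# Per-window fractions by explicit pixel counting.
oracle_window_fraction <- function(mask, grid_row, grid_col, win) {
  total <- 0
  hits <- 0
  for (r in seq_len(win)) {
    for (c in seq_len(win)) {
      total <- total + 1
      if (mask[grid_row * win + r, grid_col * win + c]) hits <- hits + 1
    }
  }
  hits / total
}

# Textbook multivariate normal density.
oracle_dmvnorm <- function(x, mean, cov) {
  d <- length(mean)
  diff <- x - mean
  exp(-0.5 * t(diff) %*% solve(cov) %*% diff)[1, 1] /
    sqrt((2 * pi)^d * det(cov))
}

# Plain-loop EM for a K-component Gaussian mixture, ML covariances
# (denominator N_k), log-likelihood recorded before each M-step.
oracle_em <- function(x, weights, means, covs, max_iter = 500, tol = 1e-10) {
  n <- nrow(x)
  K <- length(weights)
  trace <- numeric(0)
  for (iter in seq_len(max_iter + 1)) {
    dens <- matrix(0, n, K)
    for (i in seq_len(n)) {
      for (k in seq_len(K)) {
        dens[i, k] <- weights[k] * oracle_dmvnorm(x[i, ], means[k, ], covs[[k]])
      }
    }
    ll <- sum(log(rowSums(dens)))
    trace <- c(trace, ll)
    if (iter > 1 && abs(ll - trace[iter - 1]) < tol) break
    if (iter > max_iter) break
    resp <- dens / rowSums(dens)
    for (k in seq_len(K)) {
      nk <- sum(resp[, k])
      weights[k] <- nk / n
      means[k, ] <- colSums(resp[, k] * x) / nk
      s <- matrix(0, ncol(x), ncol(x))
      for (i in seq_len(n)) {
        diff <- x[i, ] - means[k, ]
        s <- s + resp[i, k] * (diff %*% t(diff))
      }
      covs[[k]] <- s / nk
    }
  }
  list(
    weights = weights, means = means, covs = covs,
    loglik = trace[length(trace)], trace = trace
  )
}

# Data log-likelihood under a fitted mixture, via the density oracle.
oracle_mixture_loglik <- function(x, weights, means, covs) {
  n <- nrow(x)
  ll <- 0
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_along(weights)) {
      s <- s + weights[k] * oracle_dmvnorm(x[i, ], means[k, ], covs[[k]])
    }
    ll <- ll + log(s)
  }
  ll
}

# Moment initialisation from a hard labelling, shared by oracle tests.
init_from_labels <- function(x, labels) {
  ks <- sort(unique(labels))
  list(
    weights = as.vector(table(labels)) / length(labels),
    means = do.call(rbind, lapply(ks, function(k) colMeans(x[labels == k, , drop = FALSE]))),
    covariances = lapply(ks, function(k) {
      xk <- x[labels == k, , drop = FALSE]
      crossprod(sweep(xk, 2, colMeans(xk))) / nrow(xk)
    })
  )
}
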