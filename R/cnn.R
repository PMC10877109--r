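# Weakly supervised feature learning: a small convolutional tumour /
# non-tumour classifier whose last convolutional layer doubles as the
# feature extractor for tumour tiles. Convolutions are stride-1 "same" with
# 3x3 kernels; each conv layer except the last is followed by 2x2
# max-pooling; a global average pool and a single logistic unit close the
# network. Training is Adam on binary cross-entropy with a per-epoch
# exponential learning-rate decay, everything seeded.

#' Configure the weak tumour/non-tumour backbone
#'
#' The implemented backbone is `small_cnn`: a randomly initialised stack of
#' 3x3 convolutions sized for desk-scale tiles (64 px), CPU-trainable in
#' minutes. Training runs Adam (learning rate 0.03 by default) under an
#' exponential schedule that halves the rate after every epoch; the first
#' `n_frozen_conv_layers` convolution layers receive no updates, mirroring
#' partial fine-tuning of a pretrained network.
#'
#' @param architecture `"small_cnn"`. (`"resnet18"` — a pretrained deep
#'   backbone fine-tuned on its last eight convolutional layers with the
#'   first nine frozen — is recognised but not provided here; constructing
#'   it errors with guidance.)
#' @param pretrained Must be `FALSE` for `small_cnn`.
#' @param channels Output channels per conv layer (default `c(8, 16, 32, 32)`).
#' @param n_frozen_conv_layers Leading conv layers excluded from updates
#'   (default 0; freezing randomly initialised layers is only useful for
#'   audits).
#' @param learning_rate Initial Adam learning rate (default 0.03).
#' @param lr_decay_factor Multiplicative per-epoch decay in (0, 1\]
#'   (default 0.5).
#' @param epochs,batch_size Training schedule (defaults 10 and 64).
#' @param input_size Tile edge in pixels expected by the network
#'   (default 64).
#' @param seed Integer seed for initialisation and batch order.
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(architecture = c("small_cnn", "resnet18"),
                            pretrained = FALSE,
                            channels = c(8L, 16L, 32L, 32L),
                            n_frozen_conv_layers = 0L,
                            learning_rate = 0.03,
                            lr_decay_factor = 0.5,
                            epochs = 10L, batch_size = 64L,
                            input_size = 64L, seed = 1L) {
  architecture <- match.arg(architecture)
  if (architecture == "resnet18") {
    abort(paste(
      "The 'resnet18' backbone (ImageNet weights, first nine conv layers",
      "frozen, last eight fine-tuned) needs a pretrained deep-learning",
      "backbone that this package does not ship. Use 'small_cnn'."
    ))
  }
  if (isTRUE(pretrained)) abort("No pretrained weights are available for 'small_cnn'.")
  stopifnot_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  stopifnot_scalar_number(lr_decay_factor, "lr_decay_factor", positive = TRUE)
  if (lr_decay_factor > 1) abort("`lr_decay_factor` must be in (0, 1].")
  channels <- as.integer(channels)
  if (length(channels) < 1 || any(channels < 1)) abort("`channels` must be positive integers.")
  n_frozen_conv_layers <- as.integer(n_frozen_conv_layers)
  if (n_frozen_conv_layers < 0 || n_frozen_conv_layers > length(channels)) {
    abort("`n_frozen_conv_layers` must lie between 0 and the number of conv layers.")
  }
  if (log2(input_size) < length(channels) - 1) {
    abort("`input_size` is too small for the pooling depth of `channels`.")
  }
  structure(
    list(
      architecture = architecture, pretrained = FALSE, channels = channels,
      n_frozen_conv_layers = n_frozen_conv_layers,
      n_finetuned_conv_layers = length(channels) - n_frozen_conv_layers,
      learning_rate = learning_rate, lr_decay_factor = lr_decay_factor,
      optimiser = "adam", epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), input_size = as.integer(input_size),
      seed = as.integer(seed)
    ),
    class = "backbone_config"
  )
}

# He-initialised parameters: conv weights are (F x C*3*3) matrices matching
# the im2col row layout; the dense head maps the pooled features to 1 logit.
init_small_cnn <- function(config) {
  k <- 3L
  with_seed(config$seed, {
    in_ch <- c(3L, config$channels[-length(config$channels)])
    conv <- purrr::map2(config$channels, in_ch, function(f, cin) {
      fan_in <- cin * k * k
      list(
        W = matrix(rnorm(f * fan_in, sd = sqrt(2 / fan_in)), nrow = f),
        b = rep(0, f)
      )
    })
    f_last <- config$channels[length(config$channels)]
    dense <- list(
      W = matrix(rnorm(f_last, sd = sqrt(1 / f_last)), nrow = 1),
      b = 0
    )
    list(conv = conv, dense = dense)
  })
}

# Forward pass on a batch array (H, W, 3, N). Returns logits plus the
# activations needed for backprop; `featmap` is the post-ReLU output of the
# last convolutional layer, `pooled` its spatial mean.
cnn_forward <- function(params, x, keep_acts = FALSE) {
  L <- length(params$conv)
  acts <- if (keep_acts) vector("list", L) else NULL
  a <- x
  for (l in seq_len(L)) {
    z <- conv_fwd_cpp(a, params$conv[[l]]$W, params$conv[[l]]$b, 3L)
    r <- pmax(z, 0)
    dim(r) <- dim(z)
    if (l < L) {
      mp <- maxpool_fwd_cpp(r)
      if (keep_acts) acts[[l]] <- list(input = a, z = z, arg = mp$arg, in_dim = dim(r))
      a <- mp$out
    } else {
      if (keep_acts) acts[[l]] <- list(input = a, z = z)
      a <- r
    }
  }
  d <- dim(a)
  # channel means per image: flatten to (H*W) x (C*N), then fold back to N x C
  pooled <- t(matrix(colMeans(matrix(a, nrow = d[1] * d[2])), nrow = d[3], ncol = d[4]))
  logits <- as.vector(params$dense$W %*% t(pooled)) + params$dense$b
  list(logits = logits, featmap = a, pooled = pooled, acts = acts)
}

# Numerically stable binary cross-entropy with logits.
bce_loss <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

cnn_backward <- function(params, fwd, y) {
  L <- length(params$conv)
  n <- length(y)
  d <- dim(fwd$featmap)
  p <- 1 / (1 + exp(-fwd$logits))
  dlogit <- (p - y) / n                                  # dL/dz of the head
  gdense <- list(
    W = matrix(dlogit, nrow = 1) %*% fwd$pooled,
    b = sum(dlogit)
  )
  dpooled <- t(params$dense$W) %*% matrix(dlogit, nrow = 1)  # C x N
  # spread the pooled gradient uniformly over spatial positions
  da <- array(0, dim = d)
  per_pos <- dpooled / (d[1] * d[2])
  da[] <- rep(as.vector(per_pos), each = d[1] * d[2])
  gconv <- vector("list", L)
  for (l in rev(seq_len(L))) {
    act <- fwd$acts[[l]]
    dz <- da * (act$z > 0)
    dim(dz) <- dim(act$z)
    bw <- conv_bwd_cpp(act$input, params$conv[[l]]$W, dz, 3L)
    gconv[[l]] <- list(W = bw$dW, b = as.vector(bw$db))
    da <- bw$dx
    if (l > 1) {
      prev <- fwd$acts[[l - 1]]
      da <- maxpool_bwd_cpp(da, prev$arg, prev$in_dim)
    }
  }
  list(conv = gconv, dense = gdense)
}

adam_init <- function(param) {
  list(m = param * 0, v = param * 0)
}

adam_step <- function(param, grad, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  param <- param - lr * mhat / (sqrt(vhat) + eps)
  list(param = param, state = state)
}

tiles_to_batch <- function(tiles, input_size) {
  n <- nrow(tiles)
  x <- array(0, dim = c(input_size, input_size, 3L, n))
  for (i in seq_len(n)) {
    px <- tiles$pixels[[i]]
    if (!all(dim(px)[1:2] == input_size)) {
      px <- resize_bilinear(px, input_size, input_size)
    }
    x[, , , i] <- px
  }
  x
}

#' Train the weak tumour/non-tumour classifier
#'
#' Fits the configured backbone to tiles labelled only `"tumour"` /
#' `"non_tumour"` (the weak labels inherited from region annotations).
#' Training and validation tiles must come from disjoint slides.
#'
#' @param train_tiles,val_tiles Tile tibbles with `pixels`, `weak_label` and
#'   `slide_id` columns (from [extract_patches()] / [build_training_set()]).
#' @param config A [backbone_config()].
#' @return A `histo_cnn` model: parameters, config, learning-rate trace and
#'   a `report` tibble of per-epoch train/validation loss and accuracy.
#' @export
train_weak_classifier <- function(train_tiles, val_tiles, config = backbone_config()) {
  y_train <- as.numeric(train_tiles$weak_label == "tumour")
  y_val <- as.numeric(val_tiles$weak_label == "tumour")
  if (length(unique(y_train)) < 2) {
    abort("Training tiles contain a single weak-label class; both are required.")
  }
  leak <- intersect(unique(train_tiles$slide_id), unique(val_tiles$slide_id))
  if (length(leak) > 0) {
    abort(sprintf(
      "Patient leakage: slide(s) %s occur in both training and validation tiles.",
      paste(leak, collapse = ", ")
    ))
  }
  x_train <- tiles_to_batch(train_tiles, config$input_size)
  x_val <- tiles_to_batch(val_tiles, config$input_size)

  params <- init_small_cnn(config)
  opt <- list(
    conv = purrr::map(params$conv, ~ list(W = adam_init(.x$W), b = adam_init(.x$b))),
    dense = list(W = adam_init(params$dense$W), b = adam_init(params$dense$b))
  )
  n <- length(y_train)
  L <- length(params$conv)
  frozen <- seq_len(config$n_frozen_conv_layers)
  report <- vector("list", config$epochs)
  lr_trace <- numeric(config$epochs)
  t_step <- 0L

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate * config$lr_decay_factor^(epoch - 1)
      lr_trace[epoch] <- lr
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      ep_correct <- 0
      for (b in batches) {
        xb <- x_train[, , , b, drop = FALSE]
        yb <- y_train[b]
        fwd <- cnn_forward(params, xb, keep_acts = TRUE)
        loss <- bce_loss(fwd$logits, yb)
        if (!is.finite(loss)) {
          abort(sprintf(
            "Non-finite loss at epoch %d (lr = %g); lower the learning rate.",
            epoch, lr
          ))
        }
        ep_loss <- ep_loss + loss * length(b)
        ep_correct <- ep_correct + sum((fwd$logits > 0) == (yb == 1))
        grads <- cnn_backward(params, fwd, yb)
        t_step <- t_step + 1L
        for (l in setdiff(seq_len(L), frozen)) {
          for (nm in c("W", "b")) {
            up <- adam_step(
              params$conv[[l]][[nm]], grads$conv[[l]][[nm]],
              opt$conv[[l]][[nm]], lr, t_step
            )
            params$conv[[l]][[nm]] <- up$param
            opt$conv[[l]][[nm]] <- up$state
          }
        }
        for (nm in c("W", "b")) {
          up <- adam_step(
            params$dense[[nm]], grads$dense[[nm]],
            opt$dense[[nm]], lr, t_step
          )
          params$dense[[nm]] <- up$param
          opt$dense[[nm]] <- up$state
        }
      }
      val <- cnn_evaluate(params, x_val, y_val, config$batch_size)
      report[[epoch]] <- tibble(
        epoch = epoch, learning_rate = lr,
        train_loss = ep_loss / n, train_accuracy = ep_correct / n,
        val_loss = val$loss, val_accuracy = val$accuracy
      )
    }
  })
  report <- dplyr::bind_rows(report)
  structure(
    list(
      params = params, config = config, report = report, lr_trace = lr_trace,
      final_train_accuracy = report$train_accuracy[config$epochs],
      final_val_accuracy = report$val_accuracy[config$epochs]
    ),
    class = "histo_cnn"
  )
}

cnn_evaluate <- function(params, x, y, batch_size) {
  n <- dim(x)[4]
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  loss <- 0
  correct <- 0
  for (b in idx) {
    fwd <- cnn_forward(params, x[, , , b, drop = FALSE])
    loss <- loss + bce_loss(fwd$logits, y[b]) * length(b)
    correct <- correct + sum((fwd$logits > 0) == (y[b] == 1))
  }
  list(loss = loss / n, accuracy = correct / n)
}

#' @export
print.histo_cnn <- function(x, ...) {
  cat(sprintf(
    "<histo_cnn> %d conv layers (%s), %d epochs; train acc %.3f, val acc %.3f\n",
    length(x$params$conv), paste(x$config$channels, collapse = "-"),
    x$config$epochs, x$final_train_accuracy, x$final_val_accuracy
  ))
  invisible(x)
}

#' Per-epoch training metrics of a fitted weak classifier
#'
#' @param x A `histo_cnn` model.
#' @param ... Unused.
#' @return A tibble with one row per epoch.
#' @export
tidy.histo_cnn <- function(x, ...) x$report

#' One-row summary of a fitted weak classifier
#'
#' @param x A `histo_cnn` model.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.histo_cnn <- function(x, ...) {
  tibble(
    n_conv_layers = length(x$params$conv),
    n_frozen = x$config$n_frozen_conv_layers,
    epochs = x$config$epochs,
    train_accuracy = x$final_train_accuracy,
    val_accuracy = x$final_val_accuracy
  )
}

#' Extract pooled deep features for tumour tiles
#'
#' Runs tiles through the trained network, keeps the post-ReLU output of the
#' last convolutional layer and pools it to one vector per tile by global
#' spatial averaging. Following the weak-supervision design, only
#' tumour-labelled tiles are meant to be transformed: non-tumour tiles are
#' dropped with a warning unless `allow_non_tumour = TRUE`.
#'
#' @param model A `histo_cnn` from [train_weak_classifier()].
#' @param tiles Tile tibble with `pixels` and `weak_label`.
#' @param pool `TRUE` (default) returns pooled vectors in a `feature` matrix
#'   column; `FALSE` returns the full spatial maps in a `feature_map`
#'   list-column (the per-pixel pathway).
#' @param allow_non_tumour Keep non-tumour tiles instead of dropping them.
#' @return The tile tibble (minus `pixels`) with the feature column added,
#'   rows in input order.
#' @export
extract_features <- function(model, tiles, pool = TRUE, allow_non_tumour = FALSE) {
  if (!allow_non_tumour && any(tiles$weak_label != "tumour")) {
    n_bad <- sum(tiles$weak_label != "tumour")
    warn(sprintf(
      "Dropping %d non-tumour tile(s); set `allow_non_tumour = TRUE` to keep them.",
      n_bad
    ))
    tiles <- dplyr::filter(tiles, .data$weak_label == "tumour")
  }
  if (nrow(tiles) == 0) abort("No tiles left to transform.")
  x <- tiles_to_batch(tiles, model$config$input_size)
  n <- dim(x)[4]
  idx <- split(seq_len(n), ceiling(seq_len(n) / model$config$batch_size))
  out <- dplyr::select(tiles, -"pixels")
  if (pool) {
    feats <- matrix(
      0, n, model$config$channels[length(model$config$channels)]
    )
    for (b in idx) {
      fwd <- cnn_forward(model$params, x[, , , b, drop = FALSE])
      feats[b, ] <- fwd$pooled
    }
    out$feature <- feats
  } else {
    maps <- vector("list", n)
    for (b in idx) {
      fwd <- cnn_forward(model$params, x[, , , b, drop = FALSE])
      for (j in seq_along(b)) maps[[b[j]]] <- fwd$featmap[, , , j]
    }
    out$feature_map <- maps
  }
  out
}

#' Save / load a trained weak classifier
#'
#' The checkpoint is a single serialised weights file with a JSON sidecar
#' describing the configuration.
#'
#' @param model A `histo_cnn`.
#' @param path Checkpoint path (the sidecar is `<path>.json`).
#' @return `path` (write) or the restored `histo_cnn` (read).
#' @export
write_cnn_checkpoint <- function(model, path) {
  saveRDS(model, path)
  cfg <- model$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cnn_checkpoint
#' @export
read_cnn_checkpoint <- function(path) {
  readRDS(path)
}
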