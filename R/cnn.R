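#' Six-layer convolutional tile classifier
#'
#' Small binary CNN deciding whether a temperature-difference tile contains
#' at least one hot node: conv(3x3, 8) + ReLU, 2x2 max-pool, conv(3x3, 16)
#' + ReLU, 2x2 max-pool, dense(32) + ReLU, dense(1) + sigmoid. Implemented
#' directly on BLAS matrix products (im2col), trained with Adam on a
#' class-weighted binary cross-entropy.
#'
#' @name tile_classifier
#' @keywords internal
NULL

cnn_dims <- function(input_width, conv_channels = c(8L, 16L)) {
  c1 <- input_width - 2L
  p1 <- c1 %/% 2L
  c2 <- p1 - 2L
  p2 <- c2 %/% 2L
  stop_if_not(p2 >= 1L, "input tiles too small for the 6-layer architecture")
  list(w = input_width, c1 = c1, p1 = p1, c2 = c2, p2 = p2,
       ch = conv_channels, flat = p2 * p2 * conv_channels[2], dense = 32L)
}

cnn_init <- function(dims, seed = 1L) {
  he <- function(fan_in, n) rnorm(n, 0, sqrt(2 / fan_in))
  with_seed(seed, {
    list(
      W1 = matrix(he(9, dims$ch[1] * 9), nrow = dims$ch[1]),          # 8 x 9
      b1 = numeric(dims$ch[1]),
      W2 = matrix(he(9 * dims$ch[1], dims$ch[2] * 9 * dims$ch[1]),
                  nrow = dims$ch[2]),                                  # 16 x 72
      b2 = numeric(dims$ch[2]),
      W3 = matrix(he(dims$flat, dims$dense * dims$flat), nrow = dims$dense),
      b3 = numeric(dims$dense),
      W4 = matrix(rnorm(dims$dense, 0, sqrt(1 / dims$dense)), nrow = 1),
      b4 = 0
    )
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Tile sources: either a dense (DT^2 x n) matrix of flattened tiles, or a
# "tile_store" that materializes tile columns on demand from packed map
# rasters (halves memory for large corpora, since tiles overlap).
ts_npix <- function(tiles) {
  if (inherits(tiles, "tile_store")) tiles$tile_npix else nrow(tiles)
}
ts_n <- function(tiles) {
  if (inherits(tiles, "tile_store")) length(tiles$pair_map) else ncol(tiles)
}
ts_fetch <- function(tiles, cols) {
  if (!inherits(tiles, "tile_store")) return(tiles[, cols, drop = FALSE])
  out <- matrix(0, nrow = tiles$tile_npix, ncol = length(cols))
  for (q in seq_along(cols)) {
    j <- cols[q]
    out[, q] <- tiles$maps[tiles$tile_pixel_idx[[tiles$pair_tile[j]]],
                           tiles$pair_map[j]]
  }
  out
}

#' Lazy tile corpus backed by packed map rasters
#'
#' @param maps Matrix (resolution^2 x n_maps) of flattened (already
#'   normalized) map pixels.
#' @param grid A [tile_grid()].
#' @param resolution Raster width in pixels.
#' @return A `tile_store` usable wherever a dense tile matrix is accepted
#'   by the classifier trainer; pairs are ordered map-major (all tiles of
#'   map 1, then map 2, ...).
#' @export
tile_store <- function(maps, grid, resolution) {
  nt <- nrow(grid$windows)
  idx <- lapply(seq_len(nt), function(k) {
    win <- grid$windows[k, ]
    as.vector(outer(win[1]:win[3], (win[2]:win[4]) - 1L,
                    function(r, cm1) r + cm1 * resolution))
  })
  nm <- ncol(maps)
  structure(list(maps = maps, tile_pixel_idx = idx,
                 pair_map = rep(seq_len(nm), each = nt),
                 pair_tile = rep(seq_len(nt), times = nm),
                 tile_npix = grid$tile_width^2),
            class = "tile_store")
}

# Forward pass (compiled kernel); returns the sigmoid probabilities.
cnn_forward <- function(params, dims, tiles) {
  as.numeric(cnn_forward_cpp(params, dims, tiles))
}

cnn_loss <- function(prob, y, w) {
  eps <- 1e-12
  sum(w * (-y * log(prob + eps) - (1 - y) * log(1 - prob + eps))) / sum(w)
}

adam_step <- function(state, params, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

#' Train the tile classifier
#'
#' @param tiles Matrix of flattened tile pixels (DT^2 x n_tiles).
#' @param labels Binary vector (1 = tile contains a hot node).
#' @param split Fraction of tiles used for training; the rest validates.
#' @param stop_accuracy Training stops once validation accuracy exceeds
#'   this (checked per epoch, after `min_epochs`).
#' @param seed Integer seed (initialization, split and batch shuffling).
#' @param max_epochs Epoch cap.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param min_epochs Minimum epochs before the stop rule may fire.
#' @return A `tile_classifier` with trained parameters and a per-epoch
#'   training log (loss, validation accuracy).
#' @export
train_tile_classifier <- function(tiles, labels, split = 0.75,
                                  stop_accuracy = 0.9, seed = 1L,
                                  max_epochs = 200L, batch_size = 128L,
                                  lr = 1e-3, min_epochs = 2L) {
  stop_if_not(split > 0 && split < 1, "split must lie in (0,1)")
  stop_if_not(length(unique(labels)) == 2,
              "both classes must be present in the training data")
  w_in <- as.integer(round(sqrt(ts_npix(tiles))))
  stop_if_not(w_in^2 == ts_npix(tiles), "tiles must be square images")
  dims <- cnn_dims(w_in)
  n <- ts_n(tiles)
  seeds <- derive_seeds(seed, 3L)
  idx <- with_seed(seeds[1], sample.int(n))
  ntr <- max(2L, floor(split * n))
  tr <- idx[seq_len(ntr)]; va <- idx[(ntr + 1L):n]
  if (length(unique(labels[tr])) < 2) {
    stop("training split contains a single class", call. = FALSE)
  }
  y_tr <- labels[tr]; y_va <- labels[va]
  # inverse-frequency class weights (most tiles are negative)
  n_pos <- sum(y_tr == 1); n_neg <- sum(y_tr == 0)
  w_pos <- length(y_tr) / (2 * n_pos); w_neg <- length(y_tr) / (2 * n_neg)
  params <- cnn_init(dims, seed = seeds[2])
  state <- list(t = 0,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    val_accuracy = numeric(0))
  reached <- FALSE
  with_seed(seeds[3], {
    for (ep in seq_len(max_epochs)) {
      ord <- sample(length(tr))
      ep_loss <- 0; nb <- 0
      for (b0 in seq(1, length(ord), by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
        xb <- ts_fetch(tiles, tr[bi])
        yb <- y_tr[bi]
        wb <- ifelse(yb == 1, w_pos, w_neg)
        st <- cnn_train_step_cpp(params, dims, xb, yb, wb)
        upd <- adam_step(state, params, st$grads, lr = lr)
        state <- upd$state; params <- upd$params
        ep_loss <- ep_loss + st$loss; nb <- nb + 1
      }
      pv <- predict_tiles_src(params, dims, tiles, va)
      acc <- mean((pv > 0.5) == (y_va == 1))
      log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / nb,
                                   val_accuracy = acc))
      if (ep >= min_epochs && acc >= stop_accuracy) { reached <- TRUE; break }
    }
  })
  if (!reached) {
    warning(sprintf("validation accuracy %.3f did not reach %.3f in %d epochs",
                    utils::tail(log$val_accuracy, 1), stop_accuracy,
                    max_epochs))
  }
  structure(list(params = params, dims = dims, log = log,
                 threshold = 0.5,
                 architecture = paste(
                   "conv(3x3,8)+ReLU -> maxpool(2) -> conv(3x3,16)+ReLU ->",
                   "maxpool(2) -> dense(32)+ReLU -> dense(1)+sigmoid")),
            class = "tile_classifier")
}

predict_in_batches <- function(params, dims, tiles, batch = 512L) {
  predict_tiles_src(params, dims, tiles, seq_len(ts_n(tiles)), batch = batch)
}

predict_tiles_src <- function(params, dims, tiles, cols, batch = 512L) {
  out <- numeric(length(cols))
  for (b0 in seq(1, length(cols), by = batch)) {
    bi <- b0:min(b0 + batch - 1L, length(cols))
    out[bi] <- cnn_forward(params, dims, ts_fetch(tiles, cols[bi]))
  }
  out
}

#' Classifier probabilities for a set of tiles
#' @param classifier A `tile_classifier`.
#' @param tiles Matrix (DT^2 x n) of flattened tiles.
#' @return Numeric vector of sigmoid outputs in (0,1).
#' @export
tile_probabilities <- function(classifier, tiles) {
  stop_if_not(nrow(tiles) == classifier$dims$w^2,
              "tile size does not match the classifier's training size")
  predict_in_batches(classifier$params, classifier$dims, tiles)
}

#' Classify tiles as positive/negative
#' @param classifier A `tile_classifier`.
#' @param tiles Matrix (DT^2 x n) of flattened tiles.
#' @return Integer indices of tiles whose probability exceeds the 0.5
#'   decision threshold.
#' @export
classify_tiles <- function(classifier, tiles) {
  which(tile_probabilities(classifier, tiles) > classifier$threshold)
}

#' @export
print.tile_classifier <- function(x, ...) {
  cat("tile_classifier:", x$architecture, "\n")
  if (nrow(x$log)) {
    cat(sprintf("  trained %d epochs, final validation accuracy %.3f\n",
                nrow(x$log), utils::tail(x$log$val_accuracy, 1)))
  }
  invisible(x)
}
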