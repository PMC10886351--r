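#' Per-tile multi-linear regression of hot-node scores
#'
#' Each tile that can be positive carries a linear model mapping its raw
#' pixels (plus an intercept) to one score per member node; scores above
#' 0.5 vote the node hot. Models are fit by least squares — the minimum-norm
#' solution when the system is underdetermined (more pixels than training
#' pairs, the usual regime).
#'
#' @name tile_regressor
#' @keywords internal
NULL

# Minimum-norm least-squares solve: X (n x p), Y (n x m) -> W (p x m).
# Underdetermined (n <= p): W = X^T (X X^T)^+ Y via eigendecomposition;
# overdetermined: W = (X^T X)^+ X^T Y.
lsq_min_norm <- function(X, Y, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p) {
    Gm <- tcrossprod(X)            # n x n
    eg <- eigen(Gm, symmetric = TRUE)
    keep <- eg$values > tol * max(eg$values, 0)
    if (!any(keep)) return(matrix(0, p, ncol(Y)))
    Ginv_Y <- eg$vectors[, keep, drop = FALSE] %*%
      ((t(eg$vectors[, keep, drop = FALSE]) %*% Y) / eg$values[keep])
    crossprod(X, Ginv_Y)
  } else {
    Gm <- crossprod(X)
    eg <- eigen(Gm, symmetric = TRUE)
    keep <- eg$values > tol * max(eg$values, 0)
    XtY <- crossprod(X, Y)
    eg$vectors[, keep, drop = FALSE] %*%
      ((t(eg$vectors[, keep, drop = FALSE]) %*% XtY) / eg$values[keep])
  }
}

#' Train the per-tile regressors
#'
#' @param tile_data List over tiles; element i holds `X` (n_i x DT^2 matrix
#'   of flattened tile pixels from the corpus maps where tile i is positive)
#'   and `Y` (n_i x M_i binary hot/cold matrix over the tile's member
#'   nodes). Tiles never positive in the corpus may be `NULL`.
#' @param member_nodes List of member node index vectors per tile.
#' @return List of `tile_regressor` (or `NULL`) per tile; each has
#'   `weights` ((DT^2+1) x M_i, intercept first row), `node_ids`, and
#'   `tile_index`.
#' @export
train_tile_regressors <- function(tile_data, member_nodes) {
  lapply(seq_along(tile_data), function(i) {
    td <- tile_data[[i]]
    if (is.null(td) || is.null(td$X) || nrow(td$X) == 0) return(NULL)
    M <- length(member_nodes[[i]])
    stop_if_not(ncol(td$Y) == M,
                "node vector length inconsistent with tile membership")
    Xa <- cbind(1, td$X)
    W <- lsq_min_norm(Xa, td$Y)
    structure(list(tile_index = i, node_ids = member_nodes[[i]],
                   weights = W),
              class = "tile_regressor")
  })
}

#' Evaluate one tile regressor
#' @param reg A `tile_regressor`.
#' @param tile_pixels Flattened tile (length DT^2).
#' @return Numeric scores, one per member node.
#' @export
predict_tile_scores <- function(reg, tile_pixels) {
  as.numeric(c(1, tile_pixels) %*% reg$weights)
}

#' Predict hot nodes from a temperature-difference map
#'
#' Two-stage detection: the CNN flags positive tiles; each positive tile's
#' regressor scores its member nodes; overlapping votes are fused. With the
#' default `"vote-ratio"` rule a candidate node is hot iff at least half of
#' the positive tiles covering it vote hot (an intersection-over-union of
#' the per-tile hot sets); `"union"` and `"intersection"` are the two
#' degenerate alternatives.
#'
#' @param classifier A `tile_classifier`.
#' @param regressors Output of [train_tile_regressors()].
#' @param map A `temperature_map` (difference map, same normalization as
#'   training — see [train_detector()]).
#' @param mesh The training `pmi_mesh`.
#' @param grid_shape Tiles per axis used in training.
#' @param fusion One of "vote-ratio", "union", "intersection".
#' @param score_threshold Per-node regression score cut (default 0.5).
#' @param normalize Divide the map by its max before tiling (must match
#'   training preprocessing).
#' @return A `hot_node_prediction`: `predicted_hot` (sorted node indices),
#'   `score` (per-node fused vote fraction), `positive_tiles`, and
#'   `provenance` (per predicted node, the tiles that voted hot).
#' @export
predict_hot_nodes <- function(classifier, regressors, map, mesh,
                              grid_shape = 7L, fusion = "vote-ratio",
                              score_threshold = 0.5, normalize = TRUE) {
  fusion <- match.arg(fusion, c("vote-ratio", "union", "intersection"))
  pix_max <- max(abs(map$pixels))
  if (normalize && pix_max > 0) {
    map <- new_temperature_map(map$pixels / pix_max, map$extent, map$mask)
  }
  ex <- extract_tiles(map, grid_shape)
  pos <- classify_tiles(classifier, ex$tiles)
  n <- mesh$n_nodes
  votes_hot <- numeric(n); votes_all <- numeric(n)
  voters <- vector("list", n)
  for (k in pos) {
    reg <- regressors[[k]]
    if (is.null(reg)) next
    sc <- predict_tile_scores(reg, ex$tiles[, k])
    ids <- reg$node_ids
    votes_all[ids] <- votes_all[ids] + 1
    hot <- sc > score_threshold
    votes_hot[ids[hot]] <- votes_hot[ids[hot]] + 1
    for (v in ids[hot]) voters[[v]] <- c(voters[[v]], k)
  }
  covered <- votes_all > 0
  frac <- numeric(n)
  frac[covered] <- votes_hot[covered] / votes_all[covered]
  hot_set <- switch(fusion,
    "vote-ratio" = which(covered & frac >= 0.5),
    "union" = which(votes_hot > 0),
    "intersection" = which(covered & votes_hot == votes_all & votes_hot > 0))
  structure(list(predicted_hot = hot_set, score = frac,
                 positive_tiles = pos,
                 provenance = voters[hot_set]),
            class = "hot_node_prediction")
}

#' @export
print.hot_node_prediction <- function(x, ...) {
  cat(sprintf("hot_node_prediction: %d hot nodes from %d positive tiles\n",
              length(x$predicted_hot), length(x$positive_tiles)))
  invisible(x)
}
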