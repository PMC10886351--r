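#' Half-overlapping tile decomposition of a temperature map
#'
#' Divides a W x W raster into a g x g grid of square tiles of width DT
#' where each tile overlaps its neighbor by exactly half its width:
#' W = DT (g + 1) / 2. For the 256 x 256 maps and the 7 x 7 grid this gives
#' the 64 x 64-pixel tiles used throughout.
#'
#' @param width Raster width in pixels (square maps).
#' @param grid_shape Tiles per axis.
#' @return A `tile_grid`: `tile_width` (DT), `stride` (DT/2), `grid_shape`,
#'   and `windows`, a (g^2) x 4 matrix of (row0, col0, row1, col1) closed
#'   pixel windows in row-major tile order (tile 1 top-left).
#' @export
tile_grid <- function(width, grid_shape) {
  dt_num <- 2 * width / (grid_shape + 1)
  if (abs(dt_num - round(dt_num)) > 1e-9 || round(dt_num) %% 2 != 0) {
    feas <- Filter(function(g) {
      d <- 2 * width / (g + 1); abs(d - round(d)) < 1e-9 && round(d) %% 2 == 0
    }, 1:63)
    stop(sprintf(
      "no integer half-overlap tile width for width %d and grid %d; feasible grid shapes: %s",
      width, grid_shape, paste(feas, collapse = ", ")), call. = FALSE)
  }
  DT <- as.integer(round(dt_num))
  stride <- DT %/% 2L
  wins <- matrix(0L, nrow = grid_shape^2, ncol = 4)
  k <- 0L
  for (tr in seq_len(grid_shape)) {
    for (tc in seq_len(grid_shape)) {
      k <- k + 1L
      r0 <- (tr - 1L) * stride + 1L
      c0 <- (tc - 1L) * stride + 1L
      wins[k, ] <- c(r0, c0, r0 + DT - 1L, c0 + DT - 1L)
    }
  }
  colnames(wins) <- c("row0", "col0", "row1", "col1")
  structure(list(tile_width = DT, stride = stride, grid_shape = grid_shape,
                 windows = wins),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid: %dx%d tiles of %dpx, stride %dpx\n",
              x$grid_shape, x$grid_shape, x$tile_width, x$stride))
  invisible(x)
}

#' Extract tile sub-images from a temperature map
#'
#' @param map A `temperature_map` (square).
#' @param grid_shape Tiles per axis.
#' @return List with the `grid` (a [tile_grid()]) and `tiles`, a matrix of
#'   flattened tile pixels (DT^2 x g^2, one column per tile, column-major
#'   within each tile).
#' @export
extract_tiles <- function(map, grid_shape) {
  w <- nrow(map$pixels)
  stop_if_not(w == ncol(map$pixels), "tile extraction requires square maps")
  g <- tile_grid(w, grid_shape)
  nt <- nrow(g$windows)
  tiles <- matrix(0, nrow = g$tile_width^2, ncol = nt)
  for (k in seq_len(nt)) {
    win <- g$windows[k, ]
    tiles[, k] <- as.vector(map$pixels[win[1]:win[3], win[2]:win[4]])
  }
  list(grid = g, tiles = tiles)
}

#' Map mesh nodes to tile membership
#'
#' @param grid A [tile_grid()].
#' @param mesh A `pmi_mesh`.
#' @param extent Raster extent used for the node-to-pixel mapping.
#' @param resolution Raster width in pixels.
#' @return List of integer vectors: member node indices per tile.
#' @export
tile_member_nodes <- function(grid, mesh, extent, resolution) {
  pc <- pixel_centers(extent, resolution)
  x <- mesh$node_coords[, 1]; y <- mesh$node_coords[, 2]
  col <- floor((x - extent[1]) / pc$px) + 1
  row <- floor((extent[4] - y) / pc$py) + 1
  if (any(col < 1 | col > resolution | row < 1 | row > resolution)) {
    stop("node maps outside the raster extent", call. = FALSE)
  }
  lapply(seq_len(nrow(grid$windows)), function(k) {
    win <- grid$windows[k, ]
    which(row >= win[1] & row <= win[3] & col >= win[2] & col <= win[4])
  })
}

#' Label tiles against a hot-node set
#'
#' A tile is positive iff at least one of its member nodes is hot.
#'
#' @param grid A [tile_grid()].
#' @param mesh A `pmi_mesh`.
#' @param hot_nodes Integer node indices inside inclusions.
#' @param extent Raster extent (mm box).
#' @param resolution Raster width in pixels.
#' @return List with `labels` (0/1 per tile), `member_nodes` (per tile) and
#'   `node_hot` (per-tile 0/1 vectors over member nodes).
#' @export
label_tiles <- function(grid, mesh, hot_nodes, extent, resolution) {
  members <- tile_member_nodes(grid, mesh, extent, resolution)
  hot <- logical(mesh$n_nodes); hot[hot_nodes] <- TRUE
  labels <- vapply(members, function(mn) as.integer(any(hot[mn])), integer(1))
  node_hot <- lapply(members, function(mn) as.integer(hot[mn]))
  list(labels = labels, member_nodes = members, node_hot = node_hot)
}
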