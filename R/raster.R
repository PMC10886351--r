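#' Temperature maps: nodal fields rasterized to pixel grids
#'
#' A `temperature_map` mirrors what MR thermometry delivers: a square raster
#' of temperature increase covering the phantom cross-section, with a mask
#' of in-disk pixels and an extent mapping pixels to mesh coordinates.
#'
#' @name temperature_map
#' @keywords internal
NULL

new_temperature_map <- function(pixels, extent, mask) {
  structure(list(pixels = pixels, extent = extent, mask = mask),
            class = "temperature_map")
}

#' @export
print.temperature_map <- function(x, ...) {
  cat(sprintf("temperature_map: %dx%d px, extent [%.3g,%.3g]x[%.3g,%.3g] mm, max %.4g C\n",
              nrow(x$pixels), ncol(x$pixels), x$extent[1], x$extent[2],
              x$extent[3], x$extent[4], max(x$pixels)))
  invisible(x)
}

# Default symmetric extent: the 25-mm disk sits in a 25.6-mm field of view,
# giving an exact 0.1-mm pixel pitch at 256x256.
default_extent <- function(radius, resolution) {
  half <- radius * 1.024
  c(xmin = -half, xmax = half, ymin = -half, ymax = half)
}

# Pixel-center coordinates. Row 1 is the TOP of the image (max y), matching
# image conventions; columns run left (min x) to right.
pixel_centers <- function(extent, resolution) {
  px <- (extent[2] - extent[1]) / resolution
  py <- (extent[4] - extent[3]) / resolution
  xs <- extent[1] + (seq_len(resolution) - 0.5) * px
  ys <- extent[4] - (seq_len(resolution) - 0.5) * py
  list(x = xs, y = ys, px = px, py = py)
}

#' Sparse rasterization operator for a mesh
#'
#' Barycentric (P1) interpolation matrix from nodal values to the pixels of
#' a square raster; cached on the mesh. Pixels outside every element get no
#' support and rasterize to 0.
#'
#' @param mesh A `pmi_mesh`.
#' @param resolution Pixels per axis (>= 8).
#' @param extent Optional extent `c(xmin, xmax, ymin, ymax)` (mm).
#' @return List with sparse `R` (resolution^2 x N, row-major over the
#'   transposed image: entry (p, n) weights node n in pixel p), logical
#'   `mask`, and the `extent`.
#' @export
raster_interp_matrix <- function(mesh, resolution = 256, extent = NULL) {
  stop_if_not(resolution >= 8, "resolution must be at least 8 pixels")
  if (is.null(extent)) extent <- default_extent(mesh$radius, resolution)
  key <- sprintf("raster_%d_%.6g_%.6g", resolution, extent[1], extent[4])
  if (!is.null(mesh$cache[[key]])) return(mesh$cache[[key]])
  pc <- pixel_centers(extent, resolution)
  # pixel p = (row r, col c) linearized as (c-1)*resolution + r (column-major
  # of the pixels matrix with rows = image rows)
  el <- mesh$elements
  coords <- mesh$node_coords
  geo <- element_geometry(mesh)
  acc_i <- vector("list", nrow(el)); acc_j <- vector("list", nrow(el))
  acc_x <- vector("list", nrow(el))
  npx <- resolution * resolution
  assigned <- logical(npx)
  colx <- pc$x; rowy <- pc$y
  for (e in seq_len(nrow(el))) {
    tx <- coords[el[e, ], 1]; ty <- coords[el[e, ], 2]
    cr <- range(tx); rr <- range(ty)
    cols <- which(colx >= cr[1] - pc$px & colx <= cr[2] + pc$px)
    rows <- which(rowy >= rr[1] - pc$py & rowy <= rr[2] + pc$py)
    if (!length(cols) || !length(rows)) next
    gx <- rep(colx[cols], each = length(rows))
    gy <- rep(rowy[rows], times = length(cols))
    pid <- rep((cols - 1L) * resolution, each = length(rows)) + rows
    # barycentric coordinates via the P1 basis-function representation
    l2 <- geo$b[e, 2] * (gx - tx[1]) + geo$c[e, 2] * (gy - ty[1])
    l3 <- geo$b[e, 3] * (gx - tx[1]) + geo$c[e, 3] * (gy - ty[1])
    l1 <- 1 - l2 - l3
    tol <- -1e-9
    inside <- l1 >= tol & l2 >= tol & l3 >= tol & !assigned[pid]
    if (!any(inside)) next
    pid <- pid[inside]
    assigned[pid] <- TRUE
    acc_i[[e]] <- c(pid, pid, pid)
    acc_j[[e]] <- rep(el[e, ], each = length(pid))
    acc_x[[e]] <- c(l1[inside], l2[inside], l3[inside])
  }
  R <- Matrix::sparseMatrix(i = unlist(acc_i), j = unlist(acc_j),
                            x = unlist(acc_x), dims = c(npx, mesh$n_nodes))
  # mask: supported pixels that are also inside the disk
  gx_all <- rep(colx, each = resolution)
  gy_all <- rep(rowy, times = resolution)
  in_disk <- (gx_all^2 + gy_all^2) <= mesh$radius^2
  mask <- matrix(assigned & in_disk, nrow = resolution)  # rows = image rows
  out <- list(R = R, mask = mask, extent = extent, resolution = resolution)
  mesh$cache[[key]] <- out
  out
}

#' Rasterize a nodal field to a temperature map
#'
#' @param values Per-node values (e.g. the final frame of a
#'   `temperature_series`).
#' @param mesh A `pmi_mesh`.
#' @param resolution Pixels per axis (default 256).
#' @param extent Optional extent (mm).
#' @return A `temperature_map`.
#' @export
rasterize <- function(values, mesh, resolution = 256, extent = NULL) {
  stop_if_not(length(values) == mesh$n_nodes,
              "values must have one entry per mesh node")
  op <- raster_interp_matrix(mesh, resolution, extent)
  v <- as.numeric(op$R %*% values)
  pixels <- matrix(v, nrow = resolution)
  pixels[!op$mask] <- 0
  new_temperature_map(pixels, op$extent, op$mask)
}

#' Sample a temperature map back at mesh node coordinates
#'
#' Bilinear interpolation of the raster at each node position; the inverse
#' bridge of [rasterize()] used to express raster measurements on the FEM
#' detector nodes.
#'
#' @param map A `temperature_map`.
#' @param mesh A `pmi_mesh`.
#' @return Numeric vector of length N.
#' @export
sample_map_at_nodes <- function(map, mesh) {
  res <- nrow(map$pixels)
  pc <- pixel_centers(map$extent, res)
  x <- mesh$node_coords[, 1]; y <- mesh$node_coords[, 2]
  # fractional column/row positions (row 1 = top)
  fc <- (x - pc$x[1]) / pc$px + 1
  fr <- (pc$y[1] - y) / pc$py + 1
  c0 <- pmin(pmax(floor(fc), 1), res - 1); r0 <- pmin(pmax(floor(fr), 1), res - 1)
  wc <- pmin(pmax(fc - c0, 0), 1); wr <- pmin(pmax(fr - r0, 0), 1)
  p <- map$pixels
  v00 <- p[cbind(r0, c0)];     v01 <- p[cbind(r0, c0 + 1)]
  v10 <- p[cbind(r0 + 1, c0)]; v11 <- p[cbind(r0 + 1, c0 + 1)]
  # mask-aware bilinear: off-mask neighbors (outside the imaged disk) carry
  # no information, so their weights are dropped and the rest renormalized;
  # otherwise boundary nodes would be biased toward zero.
  m00 <- map$mask[cbind(r0, c0)];     m01 <- map$mask[cbind(r0, c0 + 1)]
  m10 <- map$mask[cbind(r0 + 1, c0)]; m11 <- map$mask[cbind(r0 + 1, c0 + 1)]
  w00 <- (1 - wr) * (1 - wc) * m00; w01 <- (1 - wr) * wc * m01
  w10 <- wr * (1 - wc) * m10;       w11 <- wr * wc * m11
  tot <- w00 + w01 + w10 + w11
  out <- numeric(length(tot))
  ok <- tot > 0
  out[ok] <- (w00 * v00 + w01 * v01 + w10 * v10 + w11 * v11)[ok] / tot[ok]
  if (any(!ok)) {
    # all four neighbors off-mask: take the nearest in-mask pixel value
    for (i in which(!ok)) {
      rr <- max(1, r0[i] - 2):min(res, r0[i] + 3)
      cc <- max(1, c0[i] - 2):min(res, c0[i] + 3)
      sub <- map$mask[rr, cc, drop = FALSE]
      if (any(sub)) {
        idx <- which(sub, arr.ind = TRUE)[1, ]
        out[i] <- p[rr[idx[1]], cc[idx[2]]]
      }
    }
  }
  out
}

#' Subtract the homogeneous reference from a measured map
#'
#' Removes the strong surface heating below the laser spots so that the
#' residual emphasizes the extra heating at absorbing inclusions; this is
#' the detector's input and equals the data misfit at the first
#' reconstruction iteration.
#'
#' @param measured,homogeneous `temperature_map`s on identical grids.
#' @return A `temperature_map` of the pixelwise difference.
#' @export
homogeneous_difference <- function(measured, homogeneous) {
  stop_if_not(all(dim(measured$pixels) == dim(homogeneous$pixels)),
              "maps must share the same resolution")
  stop_if_not(isTRUE(all.equal(measured$extent, homogeneous$extent)),
              "maps must share the same extent")
  d <- measured$pixels - homogeneous$pixels
  d[!measured$mask] <- 0
  new_temperature_map(d, measured$extent, measured$mask)
}

#' Add i.i.d. Gaussian measurement noise to in-mask pixels
#'
#' @param map A `temperature_map`.
#' @param sigma Noise standard deviation (C); 0 is the identity.
#' @param seed Integer seed (deterministic per seed).
#' @return A noisy `temperature_map`.
#' @export
add_measurement_noise <- function(map, sigma, seed = 1L) {
  stop_if_not(sigma >= 0, "sigma must be nonnegative")
  if (sigma == 0) return(map)
  p <- map$pixels
  nmask <- sum(map$mask)
  noise <- with_seed(seed, rnorm(nmask, 0, sigma))
  p[map$mask] <- p[map$mask] + noise
  new_temperature_map(p, map$extent, map$mask)
}

# ---- temperature map I/O --------------------------------------------------

#' Write a temperature map as 16-bit TIFF plus a JSON sidecar
#'
#' The TIFF stores pixels linearly scaled to [0,1] over `[lo, hi]`; the
#' sidecar records the extent, scaling and mask-defining radius so the map
#' can be restored losslessly up to 16-bit quantization.
#'
#' @param map A `temperature_map`.
#' @param path Output `.tif` path; the sidecar is `path` + `.json`.
#' @export
write_temperature_map_tiff <- function(map, path) {
  lo <- min(map$pixels); hi <- max(map$pixels)
  scale <- if (hi > lo) hi - lo else 1
  img <- (map$pixels - lo) / scale
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  jsonlite::write_json(list(extent = unname(map$extent), lo = lo, hi = hi,
                            mask_packed = as.integer(map$mask)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a temperature map written by [write_temperature_map_tiff()]
#' @param path `.tif` path with accompanying `.json` sidecar.
#' @return A `temperature_map`.
#' @export
read_temperature_map_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pixels <- img * (side$hi - side$lo) + side$lo
  mask <- matrix(as.logical(side$mask_packed), nrow = nrow(pixels))
  pixels[!mask] <- 0
  new_temperature_map(pixels, side$extent, mask)
}

#' Write a temperature map as plain CSV (no sidecar; mask where nonzero)
#' @param map A `temperature_map`.
#' @param path Output CSV path.
#' @export
write_temperature_map_csv <- function(map, path) {
  write.csv(map$pixels, path, row.names = FALSE)
  invisible(path)
}
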