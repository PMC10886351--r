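#' Simulate the temperature-difference map of a phantom
#'
#' Runs the coupled photon/bioheat forward model for the phantom and for the
#' homogeneous background, rasterizes both final frames, and subtracts the
#' homogeneous reference — the preprocessing that suppresses the surface
#' heating under the laser spots and emphasizes inclusions.
#'
#' @param phantom A `pmi_phantom`.
#' @param source A [source_spec()].
#' @param thermal A [thermal_params()].
#' @param duration Heating time (s).
#' @param resolution Raster width in pixels.
#' @param dt Time step (s).
#' @param homogeneous_map Optional precomputed homogeneous reference
#'   `temperature_map` (recomputed when `NULL`).
#' @return A `temperature_map` of the difference (C).
#' @export
simulate_difference_map <- function(phantom, source, thermal, duration,
                                    resolution = 256, dt = 0.2,
                                    homogeneous_map = NULL) {
  mesh <- phantom$mesh
  if (is.null(homogeneous_map)) {
    homogeneous_map <- homogeneous_reference_map(
      mesh, phantom$background_mua, phantom$background_musp, source, thermal,
      duration, resolution, dt)
  }
  optics <- phantom_optics(phantom)
  Tn <- final_temperature(mesh, optics, source, thermal, duration, dt)
  measured <- rasterize(Tn, mesh, resolution)
  homogeneous_difference(measured, homogeneous_map)
}

#' Homogeneous-background reference temperature map
#' @inheritParams simulate_difference_map
#' @param mesh A `pmi_mesh`.
#' @param background_mua,background_musp Homogeneous optics (mm^-1).
#' @return A `temperature_map`.
#' @export
homogeneous_reference_map <- function(mesh, background_mua, background_musp,
                                      source, thermal, duration,
                                      resolution = 256, dt = 0.2) {
  n <- mesh$n_nodes
  optics <- optical_map(rep(background_mua, n), rep(background_musp, n))
  Tn <- final_temperature(mesh, optics, source, thermal, duration, dt)
  rasterize(Tn, mesh, resolution)
}

#' Build the detector training corpus from phantoms
#'
#' Simulates each phantom's difference map, normalizes it by its maximum,
#' and labels every tile against the phantom's hot nodes.
#'
#' @param phantoms List of `pmi_phantom` sharing one mesh.
#' @param source,thermal,duration Acquisition conditions.
#' @param grid_shape Tiles per axis.
#' @param resolution Raster width in pixels.
#' @param dt Time step (s).
#' @param noise_sigma Optional Gaussian pixel noise (C) added to each
#'   difference map before normalization; 0 disables.
#' @param seed Seed for the noise draws.
#' @return A `detector_corpus`: `maps` (resolution^2 x n matrix of
#'   normalized difference maps), `tile_labels` (n_tiles x n 0/1 matrix),
#'   `node_hot` (list over maps of per-tile binary member vectors), the
#'   shared `grid`, `member_nodes`, `extent` and `hot_nodes` per map.
#' @export
build_detector_corpus <- function(phantoms, source, thermal, duration,
                                  grid_shape = 7L, resolution = 256,
                                  dt = 0.2, noise_sigma = 0, seed = 1L) {
  mesh <- phantoms[[1]]$mesh
  homog <- homogeneous_reference_map(mesh, phantoms[[1]]$background_mua,
                                     phantoms[[1]]$background_musp,
                                     source, thermal, duration, resolution, dt)
  grid <- tile_grid(resolution, grid_shape)
  members <- tile_member_nodes(grid, mesh, homog$extent, resolution)
  nmap <- length(phantoms)
  nt <- nrow(grid$windows)
  maps <- matrix(0, nrow = resolution^2, ncol = nmap)
  tile_labels <- matrix(0L, nrow = nt, ncol = nmap)
  node_hot <- vector("list", nmap)
  hot_sets <- vector("list", nmap)
  noise_seeds <- if (noise_sigma > 0) derive_seeds(seed, nmap) else NULL
  for (i in seq_len(nmap)) {
    dm <- simulate_difference_map(phantoms[[i]], source, thermal, duration,
                                  resolution, dt, homogeneous_map = homog)
    if (noise_sigma > 0) {
      dm <- add_measurement_noise(dm, noise_sigma, noise_seeds[i])
    }
    mx <- max(abs(dm$pixels))
    maps[, i] <- as.vector(dm$pixels) / if (mx > 0) mx else 1
    lab <- label_tiles(grid, mesh, phantoms[[i]]$hot_nodes, homog$extent,
                       resolution)
    tile_labels[, i] <- lab$labels
    node_hot[[i]] <- lab$node_hot
    hot_sets[[i]] <- phantoms[[i]]$hot_nodes
  }
  structure(list(maps = maps, tile_labels = tile_labels,
                 node_hot = node_hot, grid = grid, member_nodes = members,
                 extent = homog$extent, resolution = resolution,
                 hot_nodes = hot_sets, homogeneous_map = homog),
            class = "detector_corpus")
}

#' Train the two-stage hot-node detector
#'
#' Stage 1: the six-layer CNN tile classifier, trained on all (map, tile)
#' pairs. Stage 2: per-tile multi-linear regressors trained on the maps
#' where that tile is truly positive.
#'
#' @param corpus A [build_detector_corpus()] result.
#' @param seed Integer seed.
#' @param stop_accuracy Validation-accuracy stopping threshold (stage 1).
#' @param split Train/validation split fraction (stage 1).
#' @param ... Further arguments to [train_tile_classifier()].
#' @return A `pmi_detector` bundling both stages and the tiling geometry.
#' @export
train_detector <- function(corpus, seed = 1L, stop_accuracy = 0.9,
                           split = 0.75, ...) {
  store <- tile_store(corpus$maps, corpus$grid, corpus$resolution)
  labels <- as.integer(corpus$tile_labels)  # column-major: tile fast, map slow
  # tile_store pairs are map-major with tile fast index: pair j ->
  # map pair_map[j], tile pair_tile[j]; tile_labels is (tile, map) so the
  # column-major flattening matches pair ordering exactly.
  classifier <- train_tile_classifier(store, labels, split = split,
                                      stop_accuracy = stop_accuracy,
                                      seed = seed, ...)
  nt <- nrow(corpus$grid$windows)
  tile_data <- vector("list", nt)
  idx_tile <- tile_store(corpus$maps, corpus$grid, corpus$resolution)$tile_pixel_idx
  for (k in seq_len(nt)) {
    pos_maps <- which(corpus$tile_labels[k, ] == 1L)
    if (!length(pos_maps)) next
    X <- t(corpus$maps[idx_tile[[k]], pos_maps, drop = FALSE])
    Y <- do.call(rbind, lapply(pos_maps, function(i) corpus$node_hot[[i]][[k]]))
    tile_data[[k]] <- list(X = X, Y = Y)
  }
  regressors <- train_tile_regressors(tile_data, corpus$member_nodes)
  structure(list(classifier = classifier, regressors = regressors,
                 grid_shape = corpus$grid$grid_shape,
                 resolution = corpus$resolution, extent = corpus$extent,
                 member_nodes = corpus$member_nodes),
            class = "pmi_detector")
}

#' @export
print.pmi_detector <- function(x, ...) {
  cat(sprintf("pmi_detector: %dx%d grid at %dpx, %d trained regressors\n",
              x$grid_shape, x$grid_shape, x$resolution,
              sum(!vapply(x$regressors, is.null, logical(1)))))
  invisible(x)
}

#' Detect hot nodes on a difference map
#'
#' @param detector A `pmi_detector`.
#' @param map A `temperature_map` difference map (raw scale; normalization
#'   is applied internally to match training).
#' @param mesh The mesh the detector was trained on.
#' @param fusion Vote-fusion rule (see [predict_hot_nodes()]).
#' @return A `hot_node_prediction`.
#' @export
detect_hot_nodes <- function(detector, map, mesh, fusion = "vote-ratio") {
  predict_hot_nodes(detector$classifier, detector$regressors, map, mesh,
                    grid_shape = detector$grid_shape, fusion = fusion)
}

# ---- detector serialization (plain text bundle) ---------------------------

#' Save a detector to a directory of JSON/CSV files
#' @param detector A `pmi_detector`.
#' @param dir Bundle directory (created).
#' @export
save_detector <- function(detector, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- detector$classifier
  meta <- list(grid_shape = detector$grid_shape,
               resolution = detector$resolution,
               extent = unname(detector$extent),
               architecture = cl$architecture,
               dims = cl$dims, threshold = cl$threshold,
               member_nodes = detector$member_nodes,
               regressor_tiles = which(!vapply(detector$regressors, is.null,
                                               logical(1))))
  jsonlite::write_json(meta, file.path(dir, "detector.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(cl$params)) {
    write.csv(as.matrix(cl$params[[nm]]),
              file.path(dir, paste0("cnn_", nm, ".csv")), row.names = FALSE)
  }
  write.csv(cl$log, file.path(dir, "training_log.csv"), row.names = FALSE)
  for (k in meta$regressor_tiles) {
    write.csv(detector$regressors[[k]]$weights,
              file.path(dir, sprintf("mlr_%03d.csv", k)), row.names = FALSE)
  }
  invisible(dir)
}

#' Load a detector bundle written by [save_detector()]
#' @param dir Bundle directory.
#' @return A `pmi_detector`.
#' @export
load_detector <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "detector.json"),
                              simplifyVector = TRUE)
  params <- list()
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")) {
    m <- as.matrix(read.csv(file.path(dir, paste0("cnn_", nm, ".csv"))))
    dimnames(m) <- NULL
    params[[nm]] <- if (ncol(m) == 1 && !startsWith(nm, "W")) as.numeric(m) else m
  }
  params$b4 <- as.numeric(params$b4)
  dims <- meta$dims
  dims$ch <- as.integer(dims$ch)
  classifier <- structure(list(params = params, dims = dims,
                               log = read.csv(file.path(dir, "training_log.csv")),
                               threshold = meta$threshold,
                               architecture = meta$architecture),
                          class = "tile_classifier")
  member_nodes <- lapply(meta$member_nodes, as.integer)
  nt <- meta$grid_shape^2
  regressors <- vector("list", nt)
  for (k in meta$regressor_tiles) {
    w <- as.matrix(read.csv(file.path(dir, sprintf("mlr_%03d.csv", k))))
    dimnames(w) <- NULL
    regressors[[k]] <- structure(list(tile_index = k,
                                      node_ids = member_nodes[[k]],
                                      weights = w),
                                 class = "tile_regressor")
  }
  structure(list(classifier = classifier, regressors = regressors,
                 grid_shape = meta$grid_shape, resolution = meta$resolution,
                 extent = meta$extent, member_nodes = member_nodes),
            class = "pmi_detector")
}
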