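test_that("minimum-norm least squares matches the pseudoinverse oracle", {
  set.seed(2)
  # underdetermined 5-pair toy problem
  X <- matrix(rnorm(5 * 20), 5, 20)
  Y <- matrix(rbinom(5 * 3, 1, 0.5), 5, 3)
  W <- pmir:::lsq_min_norm(X, Y)
  W_orac <- apply(Y, 2, function(y) {
    sv <- svd(X)
    keep <- sv$d > 1e-10 * max(sv$d)
    sv$v[, keep, drop = FALSE] %*% ((t(sv$u[, keep, drop = FALSE]) %*% y) /
                                      sv$d[keep])
  })
  expect_equal(W, W_orac, tolerance = 1e-9)
  # exact interpolation of the training data
  expect_equal(X %*% W, Y, tolerance = 1e-8)
  # overdetermined branch agrees with lm.fit
  X2 <- cbind(1, matrix(rnorm(40 * 3), 40, 3))
  y2 <- rnorm(40)
  W2 <- pmir:::lsq_min_norm(X2, matrix(y2))
  expect_equal(as.numeric(W2), unname(coef(lm.fit(X2, y2))), tolerance = 1e-9)
})

test_that("a single training pair is reproduced exactly by its regressor", {
  set.seed(3)
  member_nodes <- list(1:4)
  X <- matrix(rnorm(16), 1, 16)
  Y <- matrix(c(1, 0, 1, 0), 1, 4)
  regs <- train_tile_regressors(list(list(X = X, Y = Y)), member_nodes)
  sc <- predict_tile_scores(regs[[1]], X[1, ])
  expect_equal(sc, c(1, 0, 1, 0), tolerance = 1e-8)
})

test_that("regressor training validates node-vector consistency", {
  member_nodes <- list(1:3)
  bad <- list(list(X = matrix(rnorm(8), 2, 4), Y = matrix(0, 2, 2)))
  expect_error(train_tile_regressors(bad, member_nodes), "inconsistent|length")
  # tiles with no positive training maps give NULL regressors
  regs <- train_tile_regressors(list(NULL), list(1:3))
  expect_null(regs[[1]])
})

test_that("single-voter fusion equals direct regressor evaluation", {
  # build a 1-tile universe: classifier always positive via a trained toy
  toy <- toy_tiles(n = 60, w = 16, seed = 9)
  clf <- suppressWarnings(train_tile_classifier(toy$X, toy$labels, seed = 2,
                                                max_epochs = 20,
                                                stop_accuracy = 0.9))
  m <- small_mesh()
  map <- rasterize(rep(1, m$n_nodes), m, 16)
  # single tile grid (16 px, 1x1)
  members <- tile_member_nodes(tile_grid(16, 1), m, map$extent, 16)
  set.seed(4)
  W <- matrix(rnorm(257 * length(members[[1]]), 0, 0.2), 257)
  reg <- structure(list(tile_index = 1L, node_ids = members[[1]],
                        weights = W), class = "tile_regressor")
  pred <- predict_hot_nodes(clf, list(reg), map, m, grid_shape = 1L,
                            normalize = FALSE)
  if (length(pred$positive_tiles)) {
    sc <- predict_tile_scores(reg, as.vector(map$pixels))
    expect_setequal(pred$predicted_hot, reg$node_ids[sc > 0.5])
  } else {
    expect_length(pred$predicted_hot, 0)
  }
})

test_that("fusion rules order as intersection <= vote-ratio <= union", {
  m <- std_mesh()
  ph <- representative_cases(m)$case2
  dm <- simulate_difference_map(ph, source_spec(), thermal_params(), 8)
  corpus <- build_detector_corpus(
    generate_corpus(m, 40, corpus_ranges(), seed = 77), source_spec(),
    thermal_params(), 8)
  det <- train_detector(corpus, seed = 1, max_epochs = 6)
  p_int <- detect_hot_nodes(det, dm, m, fusion = "intersection")
  p_vr <- detect_hot_nodes(det, dm, m, fusion = "vote-ratio")
  p_un <- detect_hot_nodes(det, dm, m, fusion = "union")
  expect_true(all(p_int$predicted_hot %in% p_vr$predicted_hot))
  expect_true(all(p_vr$predicted_hot %in% p_un$predicted_hot))
  # predictions confined to member nodes of positive tiles
  cand <- sort(unique(unlist(det$member_nodes[p_un$positive_tiles])))
  expect_true(all(p_un$predicted_hot %in% cand))
})

test_that("a homogeneous (all-zero) difference map yields an empty prediction", {
  m <- std_mesh()
  corpus <- build_detector_corpus(
    generate_corpus(m, 40, corpus_ranges(), seed = 78), source_spec(),
    thermal_params(), 8)
  det <- train_detector(corpus, seed = 2, max_epochs = 6)
  zero_map <- rasterize(numeric(m$n_nodes), m, 256)
  pred <- detect_hot_nodes(det, zero_map, m)
  expect_length(pred$predicted_hot, 0)
})

test_that("detector serialization round-trips predictions exactly", {
  m <- small_mesh()
  corpus <- build_detector_corpus(
    generate_corpus(m, 25, corpus_ranges(), seed = 5), source_spec(),
    thermal_params(), 8, grid_shape = 3L, resolution = 64)
  det <- suppressWarnings(train_detector(corpus, seed = 3, max_epochs = 4))
  dir <- withr::local_tempdir()
  save_detector(det, dir)
  det2 <- load_detector(dir)
  ph <- generate_corpus(m, 1, corpus_ranges(), seed = 99)[[1]]
  dm <- simulate_difference_map(ph, source_spec(), thermal_params(), 8,
                                resolution = 64)
  p1 <- detect_hot_nodes(det, dm, m)
  p2 <- detect_hot_nodes(det2, dm, m)
  expect_equal(p1$predicted_hot, p2$predicted_hot)
  expect_equal(p1$score, p2$score, tolerance = 1e-10)
})
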