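test_that("hot nodes equal the brute-force point-in-shape scan", {
  m <- std_mesh()
  ph <- make_phantom(m, inclusions = list(
    list(shape = "circle", center = c(0, 0), radii = 2, mua = 0.02)))
  oracle <- which(vapply(seq_len(m$n_nodes), function(i) {
    sqrt(sum(m$node_coords[i, ]^2)) <= 2
  }, logical(1)))
  expect_setequal(ph$hot_nodes, oracle)
  # ellipse membership
  phe <- make_phantom(m, inclusions = list(
    list(shape = "ellipse", center = c(0, 6), radii = c(4.5, 2), mua = 0.02)))
  oracle_e <- which(vapply(seq_len(m$n_nodes), function(i) {
    p <- m$node_coords[i, ]
    (p[1] / 4.5)^2 + ((p[2] - 6) / 2)^2 <= 1
  }, logical(1)))
  expect_setequal(phe$hot_nodes, oracle_e)
})

test_that("the representative case phantoms have the printed geometry", {
  m <- std_mesh()
  cases <- representative_cases(m)
  expect_length(cases$case2$inclusions, 3)
  comps <- node_components(m, cases$case2$hot_nodes)
  expect_length(comps, 3)
  # case 3: two inclusions with a 1.5-mm edge-to-edge gap along y
  inc <- cases$case3$inclusions
  gap <- (inc[[2]]$center[2] - inc[[2]]$radii[1]) -
         (inc[[1]]$center[2] + inc[[1]]$radii[1])
  expect_equal(gap, 1.5)
})

test_that("phantom invariants are enforced", {
  m <- small_mesh()
  expect_error(make_phantom(m, inclusions = list(
    list(shape = "circle", center = c(12, 0), radii = 2, mua = 0.02))),
    "outside")
  expect_error(make_phantom(m, inclusions = list(
    list(shape = "circle", center = c(0, 0), radii = 2, mua = 0.005))),
    "exceed")
  ph0 <- make_phantom(m)
  expect_length(ph0$hot_nodes, 0)
  expect_equal(unique(ph0$mua), 0.01)
})

test_that("corpus generation is deterministic, seed-sensitive and valid", {
  m <- small_mesh()
  a <- generate_corpus(m, 25, corpus_ranges(), seed = 9)
  b <- generate_corpus(m, 25, corpus_ranges(), seed = 9)
  c <- generate_corpus(m, 25, corpus_ranges(), seed = 10)
  expect_identical(lapply(a, `[[`, "inclusions"),
                   lapply(b, `[[`, "inclusions"))
  expect_false(identical(lapply(a, `[[`, "inclusions"),
                         lapply(c, `[[`, "inclusions")))
  for (ph in a) {
    expect_gte(length(ph$inclusions), 1)
    expect_lte(length(ph$inclusions), 3)
    for (inc in ph$inclusions) {
      expect_gt(inc$mua, ph$background_mua)
      expect_lte(sqrt(sum(inc$center^2)) + max(inc$radii), m$radius)
    }
  }
  # degenerate single-inclusion ranges reproduce that exact phantom
  rg <- corpus_ranges()
  rg$radius <- c(2, 2); rg$mua <- c(0.03, 0.03); rg$n_inclusions <- 1L
  rg$p_ellipse <- 0
  d <- generate_corpus(m, 1, rg, seed = 1)
  expect_equal(d[[1]]$inclusions[[1]]$radii, 2)
  expect_equal(d[[1]]$inclusions[[1]]$mua, 0.03)
  # infeasible ranges rejected
  rg$radius <- c(20, 30)
  rg$ellipse_a <- c(1, 1); rg$ellipse_b <- c(1, 1)
  expect_error(generate_corpus(m, 1, rg, seed = 1), "infeasible")
})

test_that("rasterization is exact for constant and linear nodal fields", {
  m <- std_mesh()
  cmap <- rasterize(rep(2.5, m$n_nodes), m, 128)
  expect_equal(range(cmap$pixels[cmap$mask]), c(2.5, 2.5), tolerance = 1e-12)
  expect_true(all(cmap$pixels[!cmap$mask] == 0))
  # f(x, y) = x is reproduced exactly by P1 interpolation
  fx <- m$node_coords[, 1]
  xmap <- rasterize(fx, m, 128)
  pc <- pmir:::pixel_centers(xmap$extent, 128)
  xs <- matrix(rep(pc$x, each = 128), nrow = 128)
  expect_lt(max(abs(xmap$pixels[xmap$mask] - xs[xmap$mask])), 1e-9)
})

test_that("raster round-trip: linear fields exact at nodes, smooth fields close", {
  m <- std_mesh()
  lin <- 1 + 0.3 * m$node_coords[, 1] - 0.2 * m$node_coords[, 2]
  map <- rasterize(lin, m, 256)
  back <- sample_map_at_nodes(map, m)
  interior <- sqrt(rowSums(m$node_coords^2)) < m$radius - 1
  expect_lt(max(abs(back[interior] - lin[interior])), 1e-9)
  smooth <- exp(-rowSums(m$node_coords^2) / 20)
  map2 <- rasterize(smooth, m, 256)
  back2 <- sample_map_at_nodes(map2, m)
  expect_lt(max(abs(back2[interior] - smooth[interior])), 0.01 * max(smooth))
})

test_that("rasterization keeps the nodal maximum within one pixel diagonal", {
  m <- std_mesh()
  set.seed(8)
  v <- exp(-rowSums((m$node_coords - matrix(c(3, -2), m$n_nodes, 2,
                                            byrow = TRUE))^2) / 6)
  map <- rasterize(v, m, 256)
  pk <- which(map$pixels == max(map$pixels), arr.ind = TRUE)[1, ]
  pc <- pmir:::pixel_centers(map$extent, 256)
  peak_xy <- c(pc$x[pk[2]], pc$y[pk[1]])
  node_xy <- m$node_coords[which.max(v), ]
  expect_lt(sqrt(sum((peak_xy - node_xy)^2)), sqrt(2) * pc$px + 1e-9)
})

test_that("homogeneous difference is exact pixel arithmetic", {
  m <- small_mesh()
  a <- rasterize(runif(m$n_nodes), m, 64)
  b <- rasterize(runif(m$n_nodes), m, 64)
  d <- homogeneous_difference(a, b)
  expect_equal(d$pixels[d$mask], (a$pixels - b$pixels)[d$mask])
  expect_equal(max(abs(homogeneous_difference(a, a)$pixels)), 0)
  shifted <- pmir:::new_temperature_map(a$pixels + 0.3, a$extent, a$mask)
  d2 <- homogeneous_difference(shifted, b)
  expect_equal(d2$pixels[d$mask], d$pixels[d$mask] + 0.3, tolerance = 1e-12)
  bad <- rasterize(runif(m$n_nodes), m, 32)
  expect_error(homogeneous_difference(a, bad), "resolution")
})

test_that("measurement noise is seeded, masked and correctly scaled", {
  m <- std_mesh()
  map <- rasterize(rep(1, m$n_nodes), m, 128)
  expect_identical(add_measurement_noise(map, 0), map)
  n1 <- add_measurement_noise(map, 0.01, seed = 4)
  n2 <- add_measurement_noise(map, 0.01, seed = 4)
  expect_identical(n1$pixels, n2$pixels)
  expect_true(all(n1$pixels[!map$mask] == 0))
  s <- sd(n1$pixels[map$mask] - map$pixels[map$mask])
  expect_lt(abs(s - 0.01) / 0.01, 0.05)
  expect_error(add_measurement_noise(map, -1), "nonnegative")
})

test_that("temperature map TIFF round-trip preserves values to 16-bit depth", {
  m <- small_mesh()
  map <- rasterize(exp(-rowSums(m$node_coords^2) / 30), m, 64)
  f <- file.path(withr::local_tempdir(), "map.tif")
  write_temperature_map_tiff(map, f)
  map2 <- read_temperature_map_tiff(f)
  expect_equal(map2$extent, unname(map$extent), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(map2$pixels - map$pixels)), diff(range(map$pixels)) / 2^15)
})
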