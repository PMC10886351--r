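test_that("penalty matrix entries follow the region rule exactly", {
  # one region {a, b}: diagonal 1, off-diagonal -1/2
  pm <- build_penalty_matrix(list(c(2, 5)), 6)
  L <- as.matrix(pm$L)
  expect_equal(L[2, 2], 1); expect_equal(L[5, 5], 1)
  expect_equal(L[2, 5], -0.5); expect_equal(L[5, 2], -0.5)
  # unassigned nodes are singleton (identity) rows
  expect_equal(L[1, ], c(1, 0, 0, 0, 0, 0))
  # no regions: identity
  expect_equal(as.matrix(build_penalty_matrix(list(), 4)$L), diag(4),
               ignore_attr = TRUE)
  # exhaustive-entry oracle for a size-4 region + a size-2 region
  pm2 <- build_penalty_matrix(list(c(1, 3, 4, 7), c(2, 8)), 9)
  L2 <- as.matrix(pm2$L)
  reg_of <- function(i) {
    if (i %in% c(1, 3, 4, 7)) 1 else if (i %in% c(2, 8)) 2 else 0
  }
  for (i in 1:9) for (j in 1:9) {
    expected <- if (i == j) 1
    else if (reg_of(i) != 0 && reg_of(i) == reg_of(j)) {
      -1 / c(4, 2)[reg_of(i)]
    } else 0
    expect_equal(L2[i, j], expected)
  }
  # row sums over a region of size Nr equal 1/Nr
  expect_equal(sum(L2[1, ]), 1 - 3 / 4)
  expect_true(Matrix::isSymmetric(pm2$L))
  expect_error(build_penalty_matrix(list(c(1, 2), c(2, 3)), 5), "disjoint")
})

test_that("LM update equals the dense normal-equations oracle to 1e-12", {
  set.seed(6)
  J <- matrix(rnorm(9), 3, 3)
  r <- rnorm(3)
  alpha <- 1
  d <- lm_update(J, r, alpha)
  oracle <- solve(t(J) %*% J + alpha * diag(3), t(J) %*% r)
  expect_equal(d, as.numeric(oracle), tolerance = 1e-12)
  # with a penalty matrix
  pm <- build_penalty_matrix(list(c(1, 2)), 3)
  dp <- lm_update(J, r, alpha, pm)
  Ld <- as.matrix(pm$L)
  oracle_p <- solve(t(J) %*% J + alpha * t(Ld) %*% Ld, t(J) %*% r)
  expect_equal(dp, as.numeric(oracle_p), tolerance = 1e-12)
  # larger random systems
  for (n in c(10, 40)) {
    Jn <- matrix(rnorm(n * n), n); rn <- rnorm(n)
    dn <- lm_update(Jn, rn, 0.5)
    expect_equal(dn, as.numeric(solve(crossprod(Jn) + 0.5 * diag(n),
                                      crossprod(Jn, rn))), tolerance = 1e-10)
  }
})

test_that("the identity penalty reduces the soft-prior update to standard LM", {
  set.seed(7)
  J <- matrix(rnorm(64), 8, 8)
  r <- rnorm(8)
  pm_ident <- build_penalty_matrix(list(), 8)     # L = I
  expect_equal(lm_update(J, r, 2.5, pm_ident), lm_update(J, r, 2.5),
               tolerance = 1e-12)
})

test_that("regularization shrinkage: large alpha drives the update to zero", {
  set.seed(8)
  J <- matrix(rnorm(100), 10, 10)
  r <- rnorm(10)
  norms <- vapply(c(1, 10, 100, 1e4), function(a) {
    sqrt(sum(lm_update(J, r, a)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("perturbation Jacobian matches central differences at sampled nodes", {
  m <- tiny_mesh()
  n <- m$n_nodes
  opt <- uniform_optics(m, 0.012, 0.8)
  th <- thermal_params()
  src <- source_spec()
  J <- compute_jacobian(m, opt, src, th, duration = 4, perturbation = 0.01,
                        dt = 0.5)
  set.seed(5)
  for (j in sample(n, 5)) {
    h <- 0.005 * opt$mua[j]
    up <- opt$mua; up[j] <- up[j] + h
    dn <- opt$mua; dn[j] <- dn[j] - h
    Tu <- pmir:::final_temperature(m, optical_map(up, opt$musp), src, th, 4,
                                   dt = 0.5)
    Td <- pmir:::final_temperature(m, optical_map(dn, opt$musp), src, th, 4,
                                   dt = 0.5)
    central <- (Tu - Td) / (2 * h)
    expect_lt(max(abs(J[, j] - central)) / max(abs(central)), 0.01)
  }
  # first-order consistency: halving the perturbation changes J by O(h)
  J2 <- compute_jacobian(m, opt, src, th, duration = 4,
                         perturbation = 0.005, dt = 0.5)
  expect_lt(max(abs(J - J2)) / max(abs(J)), 0.01)
})

test_that("zero residual yields a (near) zero update and immediate convergence", {
  m <- tiny_mesh()
  opt <- uniform_optics(m)
  th <- thermal_params()
  src <- source_spec()
  Tm <- pmir:::final_temperature(m, opt, src, th, 4, dt = 0.5)
  J <- compute_jacobian(m, opt, src, th, 4, dt = 0.5)
  d <- lm_update(J, Tm - Tm, 1e-3 * max(diag(crossprod(J))))
  expect_equal(max(abs(d)), 0)
  rec <- reconstruct(Tm, m, src, th, 4, initial_mua = 0.01, max_iter = 2,
                     dt = 0.5)
  expect_lt(rec$objective_history$objective[1], 1e-20)
})

test_that("objective history is non-increasing over accepted iterations", {
  m <- small_mesh()
  th <- thermal_params()
  src <- source_spec()
  ph <- make_phantom(m, inclusions = list(
    list(shape = "circle", center = c(4, 2), radii = 2.5, mua = 0.02)))
  Tm <- pmir:::final_temperature(m, phantom_optics(ph), src, th, 6)
  rec <- reconstruct(Tm, m, src, th, 6, initial_mua = 0.01,
                     prior = ph$hot_nodes, max_iter = 4)
  expect_true(all(diff(rec$objective_history$objective) <= 0))
  expect_true(all(rec$mua > 0))
})

test_that("soft prior with true regions beats no-prior recovery (paired phantoms)", {
  m <- small_mesh()
  th <- thermal_params()
  src <- source_spec()
  errs <- matrix(NA_real_, 5, 2)
  for (s in 1:5) {
    ph <- generate_corpus(m, 1, corpus_ranges(), seed = 40 + s)[[1]]
    Tm <- pmir:::final_temperature(m, phantom_optics(ph), src, th, 6)
    with_p <- reconstruct(Tm, m, src, th, 6, initial_mua = 0.01,
                          prior = ph$hot_nodes, max_iter = 3)
    no_p <- reconstruct(Tm, m, src, th, 6, initial_mua = 0.01,
                        max_iter = 3)
    truth <- ph$mua
    errs[s, 1] <- sqrt(mean((with_p$mua - truth)^2))
    errs[s, 2] <- sqrt(mean((no_p$mua - truth)^2))
  }
  expect_true(all(errs[, 1] < errs[, 2]))
})

test_that("homogeneous absorption fitting recovers the truth and responds monotonely", {
  m <- small_mesh()
  th <- thermal_params()
  src <- source_spec(angles_deg = 90, width_mm = 8)
  opt <- uniform_optics(m, 0.01, 0.8)
  Tm <- pmir:::final_temperature(m, opt, src, th, 8)
  measured <- rasterize(Tm, m, 128)
  fit <- fit_homogeneous_mua(measured, m, src, th, 8)
  expect_lt(abs(fit - 0.01) / 0.01, 0.01)
  # doubling the measured temperatures raises the recovered absorption
  measured2 <- pmir:::new_temperature_map(measured$pixels * 2,
                                          measured$extent, measured$mask)
  fit2 <- fit_homogeneous_mua(measured2, m, src, th, 8)
  expect_gt(fit2, fit)
  expect_error(fit_homogeneous_mua(measured, m, src, th, 8,
                                   near_spot_nodes = integer(0)), "empty")
})

test_that("pixel-domain linearization reproduces the dense data-space normal equations", {
  m <- small_mesh()
  map <- rasterize(pmir:::final_temperature(m, uniform_optics(m),
                                            source_spec(), thermal_params(),
                                            4), m, 64)
  obs <- pmir:::pixel_observation(map, m)
  set.seed(12)
  n <- m$n_nodes
  J <- matrix(rnorm(n * n, sd = 0.1), n, n)
  Tsim <- runif(n)
  lin <- obs$linearize(J, Tsim)
  # dense oracle straight from R and the selected pixels
  op <- pmir:::raster_interp_matrix(m, 64, map$extent)
  sel <- as.vector(op$mask & map$mask)
  Rd <- as.matrix(op$R[sel, , drop = FALSE])
  y <- as.vector(map$pixels)[sel]
  a <- 0.5
  d_pkg <- lm_update(lin$J, lin$residual, a)
  d_orac <- solve(t(J) %*% crossprod(Rd) %*% J + a * diag(n),
                  t(J) %*% t(Rd) %*% (y - Rd %*% Tsim))
  expect_equal(d_pkg, as.numeric(d_orac), tolerance = 1e-8)
  # objective equals the plain pixel sum of squares
  expect_equal(obs$objective(Tsim), sum((y - Rd %*% Tsim)^2), tolerance = 1e-10)
})

test_that("raster measurements reconstruct as accurately as nodal ones", {
  m <- small_mesh()
  th <- thermal_params()
  src <- source_spec()
  ph <- make_phantom(m, inclusions = list(
    list(shape = "circle", center = c(0, 4), radii = 2.5, mua = 0.02)))
  Tn <- pmir:::final_temperature(m, phantom_optics(ph), src, th, 6)
  map <- rasterize(Tn, m, 128)
  rec_map <- reconstruct(map, m, src, th, 6, initial_mua = 0.01,
                         prior = ph$hot_nodes, max_iter = 4)
  rec_vec <- reconstruct(Tn, m, src, th, 6, initial_mua = 0.01,
                         prior = ph$hot_nodes, max_iter = 4)
  # fitting in the pixel domain must not inherit raster resampling error:
  # both reconstructions recover the phantom to a small nodal RMS
  rms <- function(x) sqrt(mean((x - ph$mua)^2))
  expect_lt(rms(rec_map$mua), 0.1 * 0.01)
  expect_lt(abs(rms(rec_map$mua) - rms(rec_vec$mua)), 0.02 * 0.01)
})
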