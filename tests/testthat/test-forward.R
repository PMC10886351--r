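# Dense brute-force forward oracles on small meshes: direct dense solves of
# the same weak forms, built independently from the assembled matrices.
dense_photon_solve <- function(mesh, optics, source) {
  mats <- assemble_fem_matrices(mesh, optics$D, optics$mua)
  B <- pmir:::boundary_mass_matrix(mesh)
  A <- as.matrix(mats$stiffness + mats$mass + source$boundary_mismatch_A * B)
  f <- pmir:::boundary_load_vector(mesh, pmir:::edge_source_flux(mesh, source))
  solve(A, f)
}

test_that("zero source yields an identically zero photon field", {
  m <- small_mesh()
  opt <- uniform_optics(m)
  src <- source_spec(angles_deg = 0, power_density = 0)
  phi <- solve_photon_density(m, opt, src)
  expect_equal(max(abs(phi$phi)), 0)
})

test_that("photon solver matches a dense solve on a small mesh", {
  m <- tiny_mesh()
  opt <- uniform_optics(m, 0.02, 1.1)
  src <- source_spec()
  phi <- solve_photon_density(m, opt, src)
  expect_equal(phi$phi, as.numeric(dense_photon_solve(m, opt, src)),
               tolerance = 1e-8)
})

test_that("interior point source tracks the 2-D infinite-medium Green's function", {
  # unit point load at the center node (node 1 by construction)
  point_source_phi <- function(mesh, mua = 0.01, musp = 0.8) {
    opt <- uniform_optics(mesh, mua, musp)
    mats <- assemble_fem_matrices(mesh, opt$D, opt$mua)
    A <- mats$stiffness + mats$mass + 0.2 * pmir:::boundary_mass_matrix(mesh)
    f <- numeric(mesh$n_nodes); f[1] <- 1
    as.numeric(Matrix::solve(A, f))
  }
  # large disk so the Robin boundary barely perturbs the interior band
  m <- generate_disk_mesh(25, 1200, seed = 1)
  phi <- point_source_phi(m)
  r <- sqrt(rowSums(m$node_coords^2))
  sel <- r > 3 & r < 8
  D <- 1 / (3 * (0.01 + 0.8)); mueff <- sqrt(0.01 / D)
  green <- besselK(mueff * r[sel], 0) / (2 * pi * D)
  expect_lt(max(abs(phi[sel] / green - 1)), 0.1)
  # boundary-effect bound: enlarging the disk barely moves the band values,
  # so the agreement above reflects the solver, not truncation
  m2 <- generate_disk_mesh(32, 1900, seed = 1)
  phi2 <- point_source_phi(m2)
  r2 <- sqrt(rowSums(m2$node_coords^2))
  band <- function(rr, ff) stats::approx(rr[order(rr)], ff[order(rr)],
                                         xout = 5.5)$y
  s2 <- r2 > 3 & r2 < 8
  expect_lt(abs(band(r[sel], phi[sel]) / band(r2[s2], phi2[s2]) - 1), 0.05)
})

test_that("discrete maximum principle holds for boundary illumination", {
  m <- small_mesh()
  opt <- uniform_optics(m)
  src <- source_spec()
  phi <- solve_photon_density(m, opt, src)$phi
  bnd <- unique(as.vector(m$boundary_edges))
  expect_lte(max(phi[-bnd]), max(phi[bnd]))
  expect_gte(min(phi), 0)
})

test_that("bioheat: zero source stays at equilibrium, insulated uniform source matches the ODE", {
  m <- small_mesh()
  n <- m$n_nodes
  opt <- uniform_optics(m, 0.02, 0.8)
  th <- thermal_params()
  ts0 <- solve_bioheat(m, numeric(n), opt, th, duration = 4, dt = 0.5)
  expect_equal(max(abs(ts0$T)), 0)
  # h = 0, uniform volumetric source Q = phi * mua: T(t) = Q t / (rho c)
  th_ins <- thermal_params(h = 0)
  ts <- solve_bioheat(m, rep(1, n), opt, th_ins, duration = 8, dt = 0.2)
  expected <- 1 * 0.02 * 8 / (th_ins$rho * th_ins$c)
  expect_lt(max(abs(ts$T[, ncol(ts$T)] - expected) / expected), 0.005)
  expect_equal(ts$T[, 1], numeric(n))
})

test_that("bioheat agrees with a dense brute-force stepping oracle", {
  m <- tiny_mesh()
  n <- m$n_nodes
  opt <- uniform_optics(m, 0.05, 0.9)
  th <- thermal_params()
  phi <- runif(n, 0, 2)
  ts <- solve_bioheat(m, phi, opt, th, duration = 2, dt = 0.25)
  # dense backward Euler
  mats <- assemble_fem_matrices(m, rep(th$k, n), rep(th$rho * th$c, n))
  Mu <- assemble_fem_matrices(m, rep(0, n), rep(1, n))$mass
  B <- pmir:::boundary_mass_matrix(m)
  S <- as.matrix(mats$mass / 0.25 + mats$stiffness + th$h * B)
  src <- as.numeric(as.matrix(Mu) %*% (phi * opt$mua))
  Tc <- numeric(n)
  for (s in 1:8) Tc <- solve(S, as.matrix(mats$mass) %*% Tc / 0.25 + src)
  expect_equal(ts$T[, ncol(ts$T)], as.numeric(Tc), tolerance = 1e-8)
})

test_that("halving dt changes the final field by less than 1%", {
  m <- small_mesh()
  opt <- uniform_optics(m)
  th <- thermal_params()
  phi <- solve_photon_density(m, opt, source_spec())
  t1 <- solve_bioheat(m, phi, opt, th, duration = 8, dt = 0.2)
  t2 <- solve_bioheat(m, phi, opt, th, duration = 8, dt = 0.1)
  f1 <- t1$T[, ncol(t1$T)]; f2 <- t2$T[, ncol(t2$T)]
  expect_lt(max(abs(f1 - f2)) / max(f2), 0.01)
})

test_that("the cached propagator reproduces explicit time stepping", {
  m <- small_mesh()
  opt <- uniform_optics(m, 0.015, 0.8)
  th <- thermal_params()
  src <- source_spec()
  phi <- solve_photon_density(m, opt, src)
  ts <- solve_bioheat(m, phi, opt, th, duration = 8, dt = 0.2)
  G <- bioheat_propagator(m, th, 8, 0.2)
  expect_equal(as.numeric(G %*% (phi$phi * opt$mua)), ts$T[, ncol(ts$T)],
               tolerance = 1e-12)
})

test_that("heating increases monotonically with inclusion absorption", {
  m <- small_mesh()
  th <- thermal_params()
  src <- source_spec()
  inc <- function(mua) make_phantom(m, inclusions = list(
    list(shape = "circle", center = c(5, 0), radii = 2, mua = mua)))
  ph1 <- inc(0.02); ph2 <- inc(0.04)
  t1 <- pmir:::final_temperature(m, phantom_optics(ph1), src, th, 8)
  t2 <- pmir:::final_temperature(m, phantom_optics(ph2), src, th, 8)
  center_node <- ph1$hot_nodes[which.min(rowSums(
    (m$node_coords[ph1$hot_nodes, , drop = FALSE] -
       matrix(c(5, 0), length(ph1$hot_nodes), 2, byrow = TRUE))^2))]
  expect_gt(t2[center_node], t1[center_node])
})

test_that("four-spot heating peaks under the spots and inclusions appear after subtraction", {
  m <- std_mesh()
  th <- thermal_params()
  src <- source_spec()
  ph <- representative_cases(m)$case2
  dm <- simulate_difference_map(ph, src, th, 8)
  # the difference map peaks locally at each inclusion site: the value at
  # the center beats everything on a ring just outside the inclusion
  for (inc in ph$inclusions) {
    v_at <- pmir:::sample_map_xy(dm, matrix(inc$center, 1))
    th_ang <- seq(0, 2 * pi, length.out = 36)
    ring <- cbind(inc$center[1] + (inc$radii[1] + 1.5) * cos(th_ang),
                  inc$center[2] + (inc$radii[1] + 1.5) * sin(th_ang))
    v_ring <- pmir:::sample_map_xy(dm, ring)
    expect_gt(v_at, max(v_ring, na.rm = TRUE))
  }
  # homogeneous phantom difference is identically zero
  ph0 <- make_phantom(m)
  dm0 <- simulate_difference_map(ph0, src, th, 8)
  expect_lt(max(abs(dm0$pixels)), 1e-12)
})

test_that("invalid forward arguments are rejected", {
  m <- tiny_mesh()
  opt <- uniform_optics(m)
  expect_error(solve_bioheat(m, numeric(m$n_nodes), opt, thermal_params(),
                             duration = 4, dt = -1), "dt")
  expect_error(optical_map(c(-0.01, 0.01), c(0.8, 0.8)), "positive")
})
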