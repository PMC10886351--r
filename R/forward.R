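#' Optical property map
#'
#' Per-node absorption and reduced scattering; the diffusion coefficient
#' D = 1/(3(mua + musp)) is always recomputed from the stored fields.
#'
#' @param mua Per-node absorption coefficient (mm^-1), positive.
#' @param musp Per-node reduced scattering coefficient (mm^-1), positive.
#' @return An `optical_map` with fields `mua`, `musp` and derived `D` (mm).
#' @export
optical_map <- function(mua, musp) {
  stop_if_not(all(mua > 0), "mua must be positive at every node")
  stop_if_not(all(musp > 0), "musp must be positive at every node")
  stop_if_not(length(mua) == length(musp) || length(musp) == 1,
              "mua and musp lengths must agree")
  if (length(musp) == 1) musp <- rep(musp, length(mua))
  structure(list(mua = as.numeric(mua), musp = as.numeric(musp),
                 D = 1 / (3 * (mua + musp))),
            class = "optical_map")
}

#' Laser illumination specification
#'
#' Boundary-arc illumination: each spot is an arc on the phantom surface
#' carrying a constant inward flux. The default power density is the ANSI
#' skin limit 0.32 W/cm^2 = 3.2e-3 W/mm^2 used by the PMI instrument.
#'
#' @param angles_deg Arc center angles in degrees (CCW from +x axis); 1 to 4
#'   spots (four-sided or top-only illumination).
#' @param width_mm Arc length of each spot along the boundary (mm).
#' @param power_density Inward flux per spot (W mm^-2), recycled.
#' @param boundary_mismatch_A Dimensionless Robin coefficient modeling the
#'   refractive-index mismatch at the surface.
#' @return A `source_spec`.
#' @export
source_spec <- function(angles_deg = c(0, 90, 180, 270), width_mm = 4,
                        power_density = 3.2e-3, boundary_mismatch_A = 0.2) {
  stop_if_not(length(angles_deg) >= 1 && length(angles_deg) <= 4,
              "between 1 and 4 illumination spots are supported")
  stop_if_not(all(power_density >= 0), "power densities must be >= 0")
  structure(list(angles_deg = angles_deg, width_mm = width_mm,
                 power_density = rep_len(power_density, length(angles_deg)),
                 boundary_mismatch_A = boundary_mismatch_A),
            class = "source_spec")
}

#' Thermal properties of the medium
#'
#' Defaults emulate water, appropriate for high-water-content agarose
#' phantoms: k = 6.0e-4 W/(mm C), rho = 1.0e-3 g/mm^3, c = 4.184 J/(g C),
#' with a still-air surface heat-transfer coefficient.
#'
#' @param rho Density (g mm^-3).
#' @param c Specific heat (J g^-1 C^-1).
#' @param k Thermal conductivity (W mm^-1 C^-1).
#' @param h Surface heat-transfer coefficient (W mm^-2 C^-1).
#' @param Tf Ambient temperature (C); the solvers work on the temperature
#'   increase above baseline, so `Tf` only enters the boundary term when the
#'   ambient differs from the baseline (default: equal, i.e. 0 increase).
#' @return A `thermal_params`.
#' @export
thermal_params <- function(rho = 1.0e-3, c = 4.184, k = 6.0e-4,
                           h = 1.0e-5, Tf = 0) {
  stop_if_not(rho > 0 && c > 0 && k > 0 && h >= 0,
              "rho, c, k must be positive and h nonnegative")
  structure(list(rho = rho, c = c, k = k, h = h, Tf = Tf),
            class = "thermal_params")
}

# Per-boundary-edge source flux for a source_spec (W mm^-2; constant on
# edges whose midpoint angle falls inside a spot arc).
edge_source_flux <- function(mesh, source) {
  be <- mesh$boundary_edges
  mids <- (mesh$node_coords[be[, 1], , drop = FALSE] +
           mesh$node_coords[be[, 2], , drop = FALSE]) / 2
  ang <- atan2(mids[, 2], mids[, 1])
  flux <- numeric(nrow(be))
  half_arc <- (source$width_mm / 2) / mesh$radius  # radians
  for (s in seq_along(source$angles_deg)) {
    a0 <- source$angles_deg[s] * pi / 180
    d <- atan2(sin(ang - a0), cos(ang - a0))  # wrapped angular distance
    flux[abs(d) <= half_arc] <- flux[abs(d) <= half_arc] +
      source$power_density[s]
  }
  flux
}

# Assemble the photon-diffusion system matrix K(D) + M(mua) + A*B and the
# boundary source load for the weak form of
#   -div(D grad Phi) + mua Phi = q0,  n.(D grad Phi) + A Phi = 0 on dOmega
# with the laser entering as an inhomogeneous boundary flux.
photon_system <- function(mesh, optics, source) {
  mats <- assemble_fem_matrices(mesh, optics$D, optics$mua)
  B <- boundary_mass_matrix(mesh)
  A_sys <- mats$stiffness + mats$mass + source$boundary_mismatch_A * B
  f <- boundary_load_vector(mesh, edge_source_flux(mesh, source))
  list(A = Matrix::forceSymmetric(A_sys), f = f, mass_unit = NULL)
}

#' Solve the steady-state photon-diffusion problem
#'
#' Computes the photon density field on the mesh for the given optical
#' properties and laser illumination, using the diffusion approximation with
#' a Robin (mismatch) boundary condition.
#'
#' @param mesh A `pmi_mesh`.
#' @param optics An [optical_map()].
#' @param source A [source_spec()], or a numeric per-node volumetric source
#'   `q0` (W mm^-3) for interior sources (then a zero-flux Robin boundary
#'   with the default mismatch A = 0.2 is applied).
#' @param interior_q0 Optional per-node volumetric source added to the
#'   boundary illumination.
#' @return A `photon_field` list with `phi` (per-node W mm^-2).
#' @export
solve_photon_density <- function(mesh, optics, source, interior_q0 = NULL) {
  stop_if_not(inherits(optics, "optical_map"), "optics must be an optical_map")
  if (is.numeric(source)) {
    interior_q0 <- source
    source <- source_spec(angles_deg = 0, power_density = 0)
  }
  sys <- photon_system(mesh, optics, source)
  f <- sys$f
  if (!is.null(interior_q0)) {
    stop_if_not(length(interior_q0) == mesh$n_nodes,
                "interior_q0 must have one value per node")
    Mu <- assemble_fem_matrices(mesh, rep(0, mesh$n_nodes),
                                rep(1, mesh$n_nodes))$mass
    f <- f + as.numeric(Mu %*% interior_q0)
  }
  if (max(abs(optics$mua)) == 0 && source$boundary_mismatch_A == 0) {
    stop("singular photon system: zero absorption and zero boundary mismatch",
         call. = FALSE)
  }
  phi <- as.numeric(Matrix::solve(sys$A, f))
  res <- as.numeric(sys$A %*% phi) - f
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(f^2)), .Machine$double.eps)
  if (rel > 1e-10 && sqrt(sum(f^2)) > 0) {
    warning(sprintf("photon solve relative residual %.2e", rel))
  }
  structure(list(phi = phi), class = "photon_field")
}

#' Solve the transient Pennes bioheat problem
#'
#' Backward-Euler time integration of the temperature-increase form of the
#' bioheat equation: rho c dT/dt - div(k grad T) = Phi mua inside the disk,
#' with convective surface loss -k dT/dn = h (T - Tf_increase) on the
#' boundary. The initial increase is zero.
#'
#' @param mesh A `pmi_mesh`.
#' @param phi A `photon_field` (or per-node numeric photon density).
#' @param optics An [optical_map()] supplying `mua` for the heat source.
#' @param thermal A [thermal_params()].
#' @param duration Total heating time (s).
#' @param dt Time step (s), default 0.2.
#' @return A `temperature_series`: `times` (including 0) and `T`, an
#'   N x length(times) matrix of temperature increases (C).
#' @export
solve_bioheat <- function(mesh, phi, optics, thermal, duration, dt = 0.2) {
  stop_if_not(duration > 0, "duration must be positive")
  stop_if_not(dt > 0 && dt <= duration, "dt must lie in (0, duration]")
  if (inherits(phi, "photon_field")) phi <- phi$phi
  n <- mesh$n_nodes
  mats <- assemble_fem_matrices(mesh, rep(thermal$k, n), rep(thermal$rho * thermal$c, n))
  Mu <- assemble_fem_matrices(mesh, rep(0, n), rep(1, n))$mass
  B <- boundary_mass_matrix(mesh)
  Kh <- mats$stiffness + thermal$h * B
  Mrc <- mats$mass
  src <- as.numeric(Mu %*% (phi * optics$mua)) +
         thermal$h * as.numeric(B %*% rep(thermal$Tf, n))
  nt <- ceiling(duration / dt - 1e-9)
  times <- c(0, pmin(seq_len(nt) * dt, duration))
  S <- Matrix::forceSymmetric(Mrc / dt + Kh)
  ch <- Matrix::Cholesky(S, LDL = FALSE)
  Tm <- matrix(0, nrow = n, ncol = nt + 1)
  Tcur <- numeric(n)
  for (s in seq_len(nt)) {
    step <- times[s + 1] - times[s]
    if (abs(step - dt) > 1e-12) {
      Ss <- Matrix::forceSymmetric(Mrc / step + Kh)
      Tcur <- as.numeric(Matrix::solve(Ss, Mrc %*% Tcur / step + src))
    } else {
      Tcur <- as.numeric(Matrix::solve(ch, Mrc %*% Tcur / dt + src,
                                       system = "A"))
    }
    Tm[, s + 1] <- Tcur
  }
  structure(list(times = times, T = Tm), class = "temperature_series")
}

#' Final-time bioheat propagator
#'
#' Precomputes the dense linear map G with T_final = G (phi * mua), the
#' end-of-heating temperature increase as a function of the volumetric heat
#' source, for fixed mesh, thermal properties and time grid. Reused by the
#' Jacobian builder so that each perturbed forward solve costs one sparse
#' photon solve plus a dense mat-vec.
#'
#' @param mesh A `pmi_mesh`.
#' @param thermal A [thermal_params()].
#' @param duration Heating time (s).
#' @param dt Time step (s).
#' @return N x N dense matrix G (C per W mm^-3).
#' @export
bioheat_propagator <- function(mesh, thermal, duration, dt = 0.2) {
  key <- sprintf("prop_%g_%g_%g_%g_%g", thermal$rho, thermal$c, thermal$k,
                 thermal$h, duration)
  key <- paste0(key, "_", dt)
  if (!is.null(mesh$cache[[key]])) return(mesh$cache[[key]])
  n <- mesh$n_nodes
  mats <- assemble_fem_matrices(mesh, rep(thermal$k, n),
                                rep(thermal$rho * thermal$c, n))
  Mu <- assemble_fem_matrices(mesh, rep(0, n), rep(1, n))$mass
  B <- boundary_mass_matrix(mesh)
  Kh <- mats$stiffness + thermal$h * B
  Mrc <- mats$mass
  nt <- ceiling(duration / dt - 1e-9)
  times <- c(0, pmin(seq_len(nt) * dt, duration))
  S <- Matrix::forceSymmetric(Mrc / dt + Kh)
  ch <- Matrix::Cholesky(S, LDL = FALSE)
  G <- matrix(0, n, n)
  Mu_d <- as.matrix(Mu)
  for (s in seq_len(nt)) {
    step <- times[s + 1] - times[s]
    rhs <- as.matrix(Mrc %*% G) / step + Mu_d
    if (abs(step - dt) > 1e-12) {
      Ss <- Matrix::forceSymmetric(Mrc / step + Kh)
      G <- as.matrix(Matrix::solve(Ss, rhs))
    } else {
      G <- as.matrix(Matrix::solve(ch, rhs, system = "A"))
    }
  }
  mesh$cache[[key]] <- G
  G
}

#' Simulate a full PMI measurement on a phantom
#'
#' Composes the photon-diffusion and bioheat solvers with the phantom's
#' per-node optical properties: deterministic forward model of the heating
#' experiment.
#'
#' @param phantom A [make_phantom()] object.
#' @param source A [source_spec()].
#' @param thermal A [thermal_params()].
#' @param duration Heating time (s).
#' @param dt Time step (s).
#' @return A `temperature_series`.
#' @export
simulate_pmi_measurement <- function(phantom, source, thermal, duration,
                                     dt = 0.2) {
  optics <- phantom_optics(phantom)
  phi <- solve_photon_density(phantom$mesh, optics, source)
  solve_bioheat(phantom$mesh, phi, optics, thermal, duration, dt = dt)
}

# Fast path: final-frame temperature for given optics, using the cached
# propagator. Returns per-node temperature increase at end of heating.
final_temperature <- function(mesh, optics, source, thermal, duration,
                              dt = 0.2) {
  G <- bioheat_propagator(mesh, thermal, duration, dt)
  phi <- solve_photon_density(mesh, optics, source)$phi
  as.numeric(G %*% (phi * optics$mua))
}

# ---- temperature series I/O ----------------------------------------------

#' Write a temperature series as CSV (times row + node x time matrix)
#' @param series A `temperature_series`.
#' @param path Output CSV path.
#' @export
write_temperature_series_csv <- function(series, path) {
  df <- as.data.frame(series$T)
  names(df) <- sprintf("t_%g", series$times)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a temperature series written by [write_temperature_series_csv()]
#' @param path CSV path.
#' @return A `temperature_series`.
#' @export
read_temperature_series_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  times <- as.numeric(sub("^t_", "", names(df)))
  structure(list(times = times, T = as.matrix(df)),
            class = "temperature_series")
}
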