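#' Region-based soft-prior penalty matrix
#'
#' L has 1 on the diagonal, -1/Nr between distinct nodes sharing a region
#' of size Nr, and 0 elsewhere; nodes outside every region act as
#' singletons (identity rows). Used as alpha * L'L in the regularized
#' normal equations, which softly drives each region toward a common value
#' without hard-fixing it.
#'
#' @param regions List of disjoint integer node-index sets.
#' @param n_nodes Total node count N.
#' @return A `penalty_matrix`: sparse `L` (N x N) plus the `regions`.
#' @export
build_penalty_matrix <- function(regions, n_nodes) {
  all_idx <- unlist(regions)
  stop_if_not(!anyDuplicated(all_idx), "regions must be disjoint")
  stop_if_not(all(all_idx >= 1 & all_idx <= n_nodes),
              "region indices out of range")
  ii <- seq_len(n_nodes); jj <- seq_len(n_nodes); xx <- rep(1, n_nodes)
  for (r in regions) {
    nr <- length(r)
    if (nr < 2) next
    off <- expand.grid(i = r, j = r)
    off <- off[off$i != off$j, ]
    ii <- c(ii, off$i); jj <- c(jj, off$j); xx <- c(xx, rep(-1 / nr, nrow(off)))
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n_nodes, n_nodes))
  structure(list(L = L, regions = regions), class = "penalty_matrix")
}

#' Sensitivity (Jacobian) matrix by nodal perturbation
#'
#' Column j holds the change of the end-of-heating temperature at every
#' detector node per unit change of absorption at node j, estimated by a
#' relative forward-difference perturbation: each column costs one photon
#' solve (with a reused symbolic factorization) plus a dense propagator
#' product.
#'
#' @param mesh A `pmi_mesh`.
#' @param optics Current [optical_map()] iterate.
#' @param source A [source_spec()].
#' @param thermal A [thermal_params()].
#' @param duration Heating time (s).
#' @param perturbation Relative perturbation of each nodal mua (default 1%).
#' @param dt Time step (s).
#' @return Dense N x N matrix J (C per mm^-1); rows = detector nodes.
#' @export
compute_jacobian <- function(mesh, optics, source, thermal, duration,
                             perturbation = 0.01, dt = 0.2) {
  stop_if_not(perturbation > 0, "perturbation must be positive")
  n <- mesh$n_nodes
  G <- bioheat_propagator(mesh, thermal, duration, dt)
  B <- boundary_mass_matrix(mesh)
  base <- photon_assembled(mesh, optics, source, B)
  phi0 <- as.numeric(Matrix::solve(base$ch, base$f, system = "A"))
  T0 <- as.numeric(G %*% (phi0 * optics$mua))
  J <- matrix(0, n, n)
  mua <- optics$mua; musp <- optics$musp
  for (j in seq_len(n)) {
    mua_j <- mua
    dmu <- mua[j] * perturbation
    mua_j[j] <- mua[j] + dmu
    opt_j <- optical_map(mua_j, musp)
    sys_j <- photon_assembled(mesh, opt_j, source, B, symbolic = base$ch)
    phi_j <- as.numeric(Matrix::solve(sys_j$ch, base$f, system = "A"))
    T_j <- as.numeric(G %*% (phi_j * mua_j))
    J[, j] <- (T_j - T0) / dmu
  }
  J
}

# Assemble the photon system and (optionally reusing a symbolic analysis)
# factorize it.
photon_assembled <- function(mesh, optics, source, B, symbolic = NULL) {
  mats <- assemble_fem_matrices(mesh, optics$D, optics$mua)
  A <- Matrix::forceSymmetric(mats$stiffness + mats$mass +
                              source$boundary_mismatch_A * B)
  f <- boundary_load_vector(mesh, edge_source_flux(mesh, source))
  ch <- if (is.null(symbolic)) {
    Matrix::Cholesky(A, LDL = FALSE)
  } else {
    Matrix::update(symbolic, A)
  }
  list(A = A, f = f, ch = ch)
}

#' One Levenberg-Marquardt update
#'
#' Solves (J'J + alpha I) d = J' r without a prior, or
#' (J'J + alpha L'L) d = J' r with the soft-prior penalty, as a symmetric
#' positive-definite system.
#'
#' @param J Jacobian (detectors x N).
#' @param residual Tm - T(mua) at the detector nodes.
#' @param alpha Regularization scalar.
#' @param prior Optional [build_penalty_matrix()] result.
#' @return Numeric update vector (mm^-1).
#' @export
lm_update <- function(J, residual, alpha, prior = NULL) {
  JtJ <- crossprod(J)
  reg <- if (is.null(prior)) {
    Matrix::Diagonal(ncol(J)) * alpha
  } else {
    alpha * Matrix::crossprod(prior$L)
  }
  A <- as.matrix(JtJ + reg)
  rhs <- as.numeric(crossprod(J, residual))
  sol <- tryCatch(
    chol2inv_solve(A, rhs),
    error = function(e) stop(
      "singular regularized normal matrix; increase alpha", call. = FALSE))
  sol
}

chol2inv_solve <- function(A, b) {
  R <- chol(A)
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

# Observation models for reconstruct(): each provides
#   objective(Tsim)       -- squared data misfit of a nodal simulation
#   linearize(J, Tsim)    -- an equivalent nodal-size (J, residual) pair
#                            whose normal equations J'J d = J'r match the
#                            data-space Gauss-Newton system exactly.

# Per-node measurement: the identity observation.
nodal_observation <- function(Tm) {
  list(objective = function(Tsim) sum((Tm - Tsim)^2),
       linearize = function(J, Tsim) list(J = J, residual = Tm - Tsim))
}

# Raster measurement: data live on the in-mask pixels y = R mua-field
# temperatures. Minimizing ||y - R T(mua)||^2 needs J' R'R J and
# J' R' (y - R Tsim) only, so with M = R'R = C'C (Cholesky) the pair
# (C J, C^-T R'(y - R Tsim)) reproduces the pixel-domain normal equations
# at nodal size.
pixel_observation <- function(map, mesh) {
  res <- nrow(map$pixels)
  op <- raster_interp_matrix(mesh, res, map$extent)
  sel <- as.vector(op$mask & map$mask)
  stop_if_not(any(sel), "measured map shares no supported pixels with the mesh")
  Rsel <- op$R[sel, , drop = FALSE]
  y <- as.vector(map$pixels)[sel]
  M <- as.matrix(Matrix::crossprod(Rsel))
  C <- tryCatch(chol(M), error = function(e) {
    # guard against nodes with (numerically) empty pixel support
    chol(M + diag(1e-10 * mean(diag(M)), nrow(M)))
  })
  list(
    objective = function(Tsim) {
      r <- y - as.numeric(Rsel %*% Tsim)
      sum(r^2)
    },
    linearize = function(J, Tsim) {
      rhs <- as.numeric(Matrix::crossprod(Rsel, y)) -
             as.numeric(M %*% Tsim)
      list(J = C %*% J,
           residual = backsolve(C, rhs, transpose = TRUE))
    })
}

#' Iterative PMI absorption reconstruction
#'
#' Levenberg-Marquardt minimization of the squared temperature misfit.
#' When the measurement is a raster `temperature_map`, the misfit is
#' evaluated in the measurement (pixel) domain through the same P1
#' interpolation operator that [rasterize()] uses, so the model is
#' projected onto the data rather than the data being resampled onto the
#' mesh; resampling a piecewise-linear raster back to the nodes carries an
#' interpolation error that the iteration would otherwise fit into
#' spurious near-surface absorption. A per-node measurement vector is
#' fitted directly at the nodes. Iterates while the objective decreases;
#' when an update increases the objective, it is recomputed with a 10x
#' larger damping up to three times before the algorithm stops, returning
#' the best iterate.
#'
#' @param measured A `temperature_map` (measured/simulated final-frame
#'   heating) or a per-node numeric vector.
#' @param mesh A `pmi_mesh`.
#' @param source A [source_spec()].
#' @param thermal A [thermal_params()].
#' @param duration Heating time (s).
#' @param initial_mua Positive scalar starting absorption (homogeneous), or
#'   per-node vector.
#' @param musp Reduced scattering (scalar or per-node, held fixed).
#' @param prior Optional node set (integer indices) used to build the
#'   soft-prior penalty: one region per mesh-connected component plus one
#'   background region covering the remaining nodes.
#' @param alpha Initial damping/regularization scalar, updated by the
#'   standard Marquardt schedule: divided by 10 after each accepted step
#'   (floored at 1e-6 of the initial value) and multiplied by 10 when an
#'   update is rejected; `NULL` sets 1e-2 * max diag(J'J) at
#'   the first iteration.
#' @param max_iter Iteration cap.
#' @param max_retries Damping escalations allowed after an objective
#'   increase (default 3).
#' @param dt Time step (s).
#' @param perturbation Jacobian perturbation fraction.
#' @param mua_floor Positivity clip applied after each update.
#' @return A `pmi_recon`: final `mua`, `objective_history`, `alpha`,
#'   iterate history, the prior regions used and `retries_used`.
#' @export
reconstruct <- function(measured, mesh, source, thermal, duration,
                        initial_mua, musp = 0.8, prior = NULL, alpha = NULL,
                        max_iter = 12L, max_retries = 3L, dt = 0.2,
                        perturbation = 0.01, mua_floor = 1e-4) {
  stop_if_not(all(initial_mua > 0), "initial_mua must be positive")
  n <- mesh$n_nodes
  if (inherits(measured, "temperature_map")) {
    obs <- pixel_observation(measured, mesh)
  } else {
    stop_if_not(length(measured) == n, "measured vector must have N entries")
    obs <- nodal_observation(as.numeric(measured))
  }
  mua <- rep_len(initial_mua, n)
  musp <- rep_len(musp, n)
  penalty <- NULL
  if (!is.null(prior) && length(prior)) {
    comps <- node_components(mesh, prior)
    background <- setdiff(seq_len(n), unlist(comps))
    penalty <- build_penalty_matrix(c(comps, list(background)), n)
  }
  objective <- function(mu) {
    Tsim <- final_temperature(mesh, optical_map(mu, musp), source, thermal,
                              duration, dt)
    obs$objective(Tsim)
  }
  obj <- objective(mua)
  alpha0 <- alpha
  history <- data.frame(iteration = 0L, objective = obj, alpha = NA_real_)
  best <- list(mua = mua, obj = obj)
  retries_used <- 0L
  mua_path <- list(mua)
  for (it in seq_len(max_iter)) {
    optics <- optical_map(mua, musp)
    J <- compute_jacobian(mesh, optics, source, thermal, duration,
                          perturbation, dt)
    Tsim <- final_temperature(mesh, optics, source, thermal, duration, dt)
    lin <- obs$linearize(J, Tsim)
    if (is.null(alpha)) {
      alpha <- 1e-2 * max(diag(crossprod(lin$J)))
      alpha0 <- alpha
    }
    a_try <- alpha
    accepted <- FALSE
    for (retry in 0:max_retries) {
      d <- tryCatch(lm_update(lin$J, lin$residual, a_try, penalty),
                    error = function(e) NULL)
      obj_c <- if (is.null(d)) Inf else {
        cand <- pmax(mua + d, mua_floor)
        objective(cand)
      }
      if (obj_c < obj) {
        accepted <- TRUE
        mua <- cand; obj <- obj_c
        history <- rbind(history, data.frame(iteration = it,
                                             objective = obj, alpha = a_try))
        mua_path[[length(mua_path) + 1L]] <- mua
        if (obj < best$obj) best <- list(mua = mua, obj = obj)
        # standard Marquardt schedule: relax the damping after success so
        # the data term progressively dominates the prior/damping
        alpha <- max(a_try / 10, 1e-6 * alpha0)
        break
      }
      if (retry < max_retries) {
        retries_used <- retries_used + 1L
        a_try <- a_try * 10
      }
    }
    if (!accepted) break
    if (obj > 10 * history$objective[1]) {
      warning("reconstruction diverging; stopped")
      break
    }
  }
  structure(list(mua = best$mua, objective_history = history,
                 alpha = alpha0, retries_used = retries_used,
                 prior_regions = if (is.null(penalty)) NULL else penalty$regions,
                 mua_path = mua_path,
                 iterations = max(history$iteration)),
            class = "pmi_recon")
}

#' @export
print.pmi_recon <- function(x, ...) {
  cat(sprintf("pmi_recon: %d iterations, objective %.4g -> %.4g, %s prior\n",
              x$iterations, x$objective_history$objective[1],
              min(x$objective_history$objective),
              if (is.null(x$prior_regions)) "no" else "soft"))
  invisible(x)
}

#' Fit the homogeneous background absorption near the laser area
#'
#' Recovers a single scalar absorption by matching the simulated
#' homogeneous temperature to the measurement over a region near the
#' illumination spots (where the background dominates the signal); used to
#' initialize reconstruction and to generate the homogeneous reference for
#' the difference map.
#'
#' @param measured A `temperature_map` or per-node vector.
#' @param mesh A `pmi_mesh`.
#' @param source A [source_spec()].
#' @param thermal A [thermal_params()].
#' @param duration Heating time (s).
#' @param near_spot_nodes Node indices of the fitting region; `NULL`
#'   selects the region within `near_depth_mm` of an illuminated arc. With
#'   a raster measurement and the default region, the fit is evaluated
#'   directly on the near-spot pixels (no raster-to-node resampling);
#'   an explicit node set forces the nodal fit.
#' @param near_depth_mm Depth band under the spots used by the default
#'   region (mm). The default keeps the band superficial (2 mm): the
#'   temperature there is set by the background absorption, while deeper
#'   bands are contaminated by inclusion heating and bias the fit upward.
#' @param musp Fixed reduced scattering.
#' @param interval Search interval for the absorption (mm^-1).
#' @param dt Time step (s).
#' @return Fitted scalar absorption (mm^-1).
#' @export
fit_homogeneous_mua <- function(measured, mesh, source, thermal, duration,
                                near_spot_nodes = NULL, near_depth_mm = 2,
                                musp = 0.8, interval = c(1e-3, 0.1),
                                dt = 0.2) {
  n <- mesh$n_nodes
  is_map <- inherits(measured, "temperature_map")
  if (is_map && is.null(near_spot_nodes)) {
    # fit on the near-spot pixels themselves (no raster-to-node resampling)
    res <- nrow(measured$pixels)
    op <- raster_interp_matrix(mesh, res, measured$extent)
    pc <- pixel_centers(measured$extent, res)
    xy <- cbind(rep(pc$x, each = res), rep(pc$y, times = res))
    sel <- as.vector(op$mask & measured$mask) &
           near_spot_xy(xy, mesh$radius, source, near_depth_mm)
    stop_if_not(any(sel), "fitting region is empty")
    y <- as.vector(measured$pixels)[sel]
    if (max(abs(y)) <= 0) stop("fitting region carries no signal",
                               call. = FALSE)
    Rsel <- op$R[sel, , drop = FALSE]
    misfit <- function(mua) {
      Tsim <- final_temperature(mesh, optical_map(rep(mua, n), rep(musp, n)),
                                source, thermal, duration, dt)
      sum((y - as.numeric(Rsel %*% Tsim))^2)
    }
    return(stats::optimize(misfit, interval = interval, tol = 1e-6)$minimum)
  }
  Tm <- if (is_map) sample_map_at_nodes(measured, mesh) else as.numeric(measured)
  if (is.null(near_spot_nodes)) {
    near_spot_nodes <- which(near_spot_mask(mesh, source, near_depth_mm))
  }
  stop_if_not(length(near_spot_nodes) > 0, "fitting region is empty")
  if (max(abs(Tm[near_spot_nodes])) <= 0) {
    stop("fitting region carries no signal", call. = FALSE)
  }
  misfit <- function(mua) {
    Tsim <- final_temperature(mesh, optical_map(rep(mua, n), rep(musp, n)),
                              source, thermal, duration, dt)
    sum((Tm[near_spot_nodes] - Tsim[near_spot_nodes])^2)
  }
  stats::optimize(misfit, interval = interval, tol = 1e-6)$minimum
}

# Points within depth_mm of an illuminated boundary arc.
near_spot_xy <- function(xy, radius, source, depth_mm) {
  mask <- rep(FALSE, nrow(xy))
  half_arc <- (source$width_mm / 2) / radius
  r <- sqrt(rowSums(xy^2))
  ang <- atan2(xy[, 2], xy[, 1])
  for (s in seq_along(source$angles_deg)) {
    if (source$power_density[s] <= 0) next
    a0 <- source$angles_deg[s] * pi / 180
    d <- atan2(sin(ang - a0), cos(ang - a0))
    mask <- mask | (abs(d) <= half_arc * 1.5 & r >= radius - depth_mm)
  }
  mask
}

# Nodes within depth_mm of an illuminated boundary arc.
near_spot_mask <- function(mesh, source, depth_mm) {
  near_spot_xy(mesh$node_coords, mesh$radius, source, depth_mm)
}
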