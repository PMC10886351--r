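#' Construct a phantom with absorbing inclusions
#'
#' A phantom is a disk-shaped homogeneous background carrying circular or
#' elliptical inclusions of elevated absorption that mimic tumors (higher
#' hemoglobin, hence higher NIR absorption). Hot nodes are the mesh nodes
#' that fall inside any inclusion.
#'
#' @param mesh A `pmi_mesh`.
#' @param background_mua Background absorption (mm^-1), default 0.01
#'   (mouse-muscle-like).
#' @param background_musp Background reduced scattering (mm^-1), default 0.8.
#' @param inclusions List of inclusion specs; each a list with `shape`
#'   ("circle" or "ellipse"), `center` (xy, mm), `radii` (one value for a
#'   circle, two semi-axes for an ellipse, mm) and `mua` (mm^-1, must exceed
#'   the background).
#' @return A `pmi_phantom` with per-node optics and the `hot_nodes` index set.
#' @export
make_phantom <- function(mesh, background_mua = 0.01, background_musp = 0.8,
                         inclusions = list()) {
  for (inc in inclusions) {
    stop_if_not(inc$mua > background_mua,
                "inclusion mua must exceed the background mua")
    rmax <- max(inc$radii)
    stop_if_not(sqrt(sum(inc$center^2)) + rmax <= mesh$radius + 1e-9,
                "inclusion extends outside the disk")
  }
  n <- mesh$n_nodes
  mua <- rep(background_mua, n)
  hot <- logical(n)
  for (inc in inclusions) {
    inside <- nodes_in_inclusion(mesh$node_coords, inc)
    mua[inside] <- inc$mua
    hot[inside] <- TRUE
  }
  structure(list(mesh = mesh, background_mua = background_mua,
                 background_musp = background_musp, inclusions = inclusions,
                 mua = mua, hot_nodes = which(hot)),
            class = "pmi_phantom")
}

nodes_in_inclusion <- function(coords, inc) {
  dx <- coords[, 1] - inc$center[1]
  dy <- coords[, 2] - inc$center[2]
  if (identical(inc$shape, "ellipse")) {
    (dx / inc$radii[1])^2 + (dy / inc$radii[2])^2 <= 1
  } else {
    dx^2 + dy^2 <= inc$radii[1]^2
  }
}

#' Per-node optical map of a phantom
#' @param phantom A `pmi_phantom`.
#' @return An [optical_map()].
#' @export
phantom_optics <- function(phantom) {
  optical_map(phantom$mua, rep(phantom$background_musp,
                               length(phantom$mua)))
}

#' @export
print.pmi_phantom <- function(x, ...) {
  cat(sprintf("pmi_phantom: %d inclusions, %d hot nodes / %d, bg mua %.3g\n",
              length(x$inclusions), length(x$hot_nodes), x$mesh$n_nodes,
              x$background_mua))
  invisible(x)
}

#' Generate a seeded corpus of random phantoms
#'
#' Draws `n_cases` phantoms with 1 to 3 non-overlapping inclusions whose
#' size, position and absorption are sampled uniformly from the given
#' ranges; all inclusions keep a margin from the boundary. Deterministic
#' for a fixed seed.
#'
#' @param mesh A `pmi_mesh` shared by all cases.
#' @param n_cases Number of phantoms.
#' @param ranges List of sampling ranges: `radius` (circle radius, mm),
#'   `ellipse_a` / `ellipse_b` (semi-axes, mm), `mua` (inclusion absorption,
#'   mm^-1), `n_inclusions` (integer candidates), `p_ellipse` (probability an
#'   inclusion is elliptical), `margin` (clearance from the boundary, mm).
#' @param seed Integer seed.
#' @param background_mua,background_musp Background optics.
#' @return List of `pmi_phantom`.
#' @export
generate_corpus <- function(mesh, n_cases, ranges = corpus_ranges(),
                            seed = 1L, background_mua = 0.01,
                            background_musp = 0.8) {
  stop_if_not(n_cases >= 1, "n_cases must be >= 1")
  stop_if_not(length(ranges$radius) == 2 && ranges$radius[1] <= ranges$radius[2],
              "ranges$radius must be an increasing pair")
  max_half <- max(ranges$radius[2], ranges$ellipse_a[2], ranges$ellipse_b[2])
  if (max_half + ranges$margin >= mesh$radius) {
    stop("infeasible ranges: largest inclusion cannot fit inside the disk",
         call. = FALSE)
  }
  with_seed(seed, {
    lapply(seq_len(n_cases), function(case) {
      k <- if (length(ranges$n_inclusions) == 1) ranges$n_inclusions
           else sample(ranges$n_inclusions, 1)
      incs <- list()
      for (j in seq_len(k)) {
        for (try in 1:200) {
          if (runif(1) < ranges$p_ellipse) {
            radii <- c(runif(1, ranges$ellipse_a[1], ranges$ellipse_a[2]),
                       runif(1, ranges$ellipse_b[1], ranges$ellipse_b[2]))
            shape <- "ellipse"
          } else {
            radii <- runif(1, ranges$radius[1], ranges$radius[2])
            shape <- "circle"
          }
          rmax <- max(radii)
          rcmax <- mesh$radius - ranges$margin - rmax
          if (rcmax <= 0) next
          # uniform position over the admissible disk
          rc <- sqrt(runif(1)) * rcmax
          th <- runif(1, 0, 2 * pi)
          center <- c(rc * cos(th), rc * sin(th))
          cand <- list(shape = shape, center = center, radii = radii,
                       mua = runif(1, ranges$mua[1], ranges$mua[2]))
          overlap <- any(vapply(incs, function(o) {
            sum((o$center - center)^2) < (max(o$radii) + rmax)^2
          }, logical(1)))
          if (!overlap) { incs[[j]] <- cand; break }
        }
        if (length(incs) < j) stop("could not place inclusion within ranges",
                                   call. = FALSE)
      }
      make_phantom(mesh, background_mua, background_musp, incs)
    })
  })
}

#' Default corpus sampling ranges
#'
#' Spans the concrete cases used in the evaluation studies: circle radii
#' 0.75-3 mm, ellipse semi-axes up to 4.5 mm, inclusion absorption
#' 0.015-0.04 mm^-1, 1-3 inclusions, 1 mm boundary margin.
#' @return Named list of ranges for [generate_corpus()].
#' @export
corpus_ranges <- function() {
  list(radius = c(0.75, 3), ellipse_a = c(2, 4.5), ellipse_b = c(1, 3),
       mua = c(0.015, 0.04), n_inclusions = 1:3, p_ellipse = 0.25,
       margin = 1)
}

#' The three representative evaluation phantoms
#'
#' Case 1: one ellipse (semi-axes 4.5 x 2 mm) centered at (0,6).
#' Case 2: three circles of diameter 2.5, 2 and 1.5 mm at (6,0), (-3,-5)
#' and (-5,5). Case 3: circles of radius 1.5 mm at the center and radius
#' 2 mm at (0,5), separated by a 1.5-mm edge-to-edge gap to probe the
#' closest resolvable separation.
#'
#' @param mesh A `pmi_mesh`.
#' @param inclusion_mua Absorption inside inclusions (mm^-1).
#' @return Named list of three `pmi_phantom`s.
#' @export
representative_cases <- function(mesh, inclusion_mua = 0.023) {
  list(
    case1 = make_phantom(mesh, inclusions = list(
      list(shape = "ellipse", center = c(0, 6), radii = c(4.5, 2),
           mua = inclusion_mua))),
    case2 = make_phantom(mesh, inclusions = list(
      list(shape = "circle", center = c(6, 0), radii = 1.25,
           mua = inclusion_mua),
      list(shape = "circle", center = c(-3, -5), radii = 1.0,
           mua = inclusion_mua),
      list(shape = "circle", center = c(-5, 5), radii = 0.75,
           mua = inclusion_mua))),
    case3 = make_phantom(mesh, inclusions = list(
      list(shape = "circle", center = c(0, 0), radii = 1.5,
           mua = inclusion_mua),
      list(shape = "circle", center = c(0, 5), radii = 2.0,
           mua = inclusion_mua)))
  )
}

#' The experimental-phantom twin
#'
#' Synthetic duplicate of the physical agarose phantom used for the
#' reconstruction study: 25-mm disk, background mua 0.01 / musp 0.8 mm^-1,
#' two 4-mm-diameter inclusions of mua 0.023 mm^-1 at (-4, 5.25) and
#' (3.1, 7.5), heated from the top surface only for 12 s.
#'
#' @param mesh A `pmi_mesh`.
#' @return List with the `phantom`, its `source` (top-only illumination),
#'   the heating `duration` (s) and per-inclusion node sets.
#' @export
experiment_twin_phantom <- function(mesh) {
  incs <- list(
    list(shape = "circle", center = c(-4, 5.25), radii = 2, mua = 0.023),
    list(shape = "circle", center = c(3.1, 7.5), radii = 2, mua = 0.023))
  ph <- make_phantom(mesh, inclusions = incs)
  inc_nodes <- lapply(incs, function(inc)
    which(nodes_in_inclusion(mesh$node_coords, inc)))
  list(phantom = ph,
       source = source_spec(angles_deg = 90, width_mm = 8),
       duration = 12,
       inclusion_nodes = inc_nodes)
}
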