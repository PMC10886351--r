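#' Triangular FEM meshes of the circular imaging domain
#'
#' A `pmi_mesh` is a linear (P1) triangle discretization of the disk-shaped
#' cross-section imaged by PMI. Coordinates are in mm with the origin at the
#' disk center and y increasing upward, matching the convention used for
#' inclusion positions throughout the package.
#'
#' @name pmi_mesh
#' @keywords internal
NULL

new_mesh <- function(node_coords, elements, boundary_edges, boundary_normals,
                     radius) {
  dimnames(node_coords) <- NULL
  dimnames(elements) <- NULL
  dimnames(boundary_edges) <- NULL
  dimnames(boundary_normals) <- NULL
  storage.mode(elements) <- "integer"
  storage.mode(boundary_edges) <- "integer"
  m <- list(
    node_coords = node_coords,        # N x 2 (mm)
    elements = elements,              # E x 3 node indices, CCW
    boundary_edges = boundary_edges,  # B x 2 node indices, ordered loop
    boundary_normals = boundary_normals, # B x 2 unit outward vectors
    radius = radius,
    n_nodes = nrow(node_coords),
    n_elements = nrow(elements),
    cache = new.env(parent = emptyenv())
  )
  class(m) <- "pmi_mesh"
  m
}

#' @export
print.pmi_mesh <- function(x, ...) {
  cat(sprintf("pmi_mesh: %d nodes, %d elements, radius %.3g mm\n",
              x$n_nodes, x$n_elements, x$radius))
  invisible(x)
}

#' Generate a triangular mesh of a disk
#'
#' Builds a deterministic, seeded triangulation of a circular domain from
#' concentric rings of nodes with jittered angular/radial placement, joined
#' by a two-pointer ring triangulation. The boundary ring lies exactly on
#' the circle so that Robin boundary terms see the true geometry.
#'
#' @param radius Disk radius in mm (default 12.5, a 25-mm diameter phantom).
#' @param target_node_count Desired number of nodes; the realized count is
#'   within 10 percent of this.
#' @param seed Integer seed controlling the jitter; same inputs give
#'   bit-identical meshes.
#' @return A `pmi_mesh`.
#' @export
generate_disk_mesh <- function(radius = 12.5, target_node_count = 852,
                               seed = 1L) {
  stop_if_not(is.numeric(radius) && length(radius) == 1 && radius > 0,
              "radius must be a positive scalar")
  stop_if_not(target_node_count >= 3,
              "target_node_count must be at least 3")

  if (target_node_count < 6) {
    # minimal mesh: center node + 3-node boundary ring
    n_rings <- 1L
    ring_counts <- 3L
  } else {
    # ring k holds ~c*k nodes; pick n_rings ~ sqrt(target/pi) and solve for c
    n_rings <- max(1L, round(sqrt(target_node_count / pi)))
    best <- NULL
    for (nr in unique(pmax(1L, n_rings + (-2:2)))) {
      # total(c) = 1 + sum round(c*k); monotone in c, solve by bisection
      total_for <- function(cc) 1 + sum(pmax(3, round(cc * seq_len(nr))))
      lo <- 0.5; hi <- 20
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (total_for(mid) < target_node_count) lo <- mid else hi <- mid
      }
      cc <- (lo + hi) / 2
      tot <- total_for(cc)
      if (is.null(best) || abs(tot - target_node_count) < best$err) {
        best <- list(nr = nr, cc = cc, err = abs(tot - target_node_count))
      }
    }
    n_rings <- best$nr
    ring_counts <- pmax(3, round(best$cc * seq_len(n_rings)))
  }

  h <- radius / n_rings
  coords <- matrix(0, nrow = 1, ncol = 2)  # center node first
  ring_idx <- vector("list", n_rings)
  nxt <- 2L
  with_seed(seed, {
    for (k in seq_len(n_rings)) {
      m <- ring_counts[k]
      phase <- runif(1, 0, 2 * pi / m)
      ang <- phase + 2 * pi * (seq_len(m) - 1) / m
      # angular jitter < 30% of spacing keeps in-ring ordering intact
      ang <- ang + runif(m, -0.3, 0.3) * (2 * pi / m)
      r <- rep(h * k, m)
      if (k < n_rings) r <- r + runif(m, -0.25, 0.25) * h
      pts <- cbind(r * cos(ang), r * sin(ang))
      ring_idx[[k]] <- nxt:(nxt + m - 1L)
      coords <- rbind(coords, pts)
      nxt <- nxt + m
    }
  })

  # triangulate: center fan + ring-to-ring strips
  elems <- list()
  ang_of <- function(idx) atan2(coords[idx, 2], coords[idx, 1]) %% (2 * pi)
  ord1 <- ring_idx[[1]][order(ang_of(ring_idx[[1]]))]
  m1 <- length(ord1)
  elems[[1]] <- cbind(1L, ord1, ord1[c(2:m1, 1)])
  if (n_rings > 1) {
    for (k in 2:n_rings) {
      inner <- ring_idx[[k - 1L]]
      outer <- ring_idx[[k]]
      inner <- inner[order(ang_of(inner))]
      outer <- outer[order(ang_of(outer))]
      elems[[k]] <- triangulate_ring_strip(inner, ang_of(inner),
                                           outer, ang_of(outer))
    }
  }
  elements <- do.call(rbind, elems)

  # enforce positive (CCW) orientation
  a <- signed_areas(coords, elements)
  flip <- which(a < 0)
  if (length(flip)) {
    tmp <- elements[flip, 2]
    elements[flip, 2] <- elements[flip, 3]
    elements[flip, 3] <- tmp
    a <- signed_areas(coords, elements)
  }
  if (any(a <= 0)) stop("degenerate triangulation: non-positive element area",
                        call. = FALSE)

  bnd <- ring_idx[[n_rings]]
  bnd <- bnd[order(ang_of(bnd))]
  nb <- length(bnd)
  boundary_edges <- cbind(bnd, bnd[c(2:nb, 1)])
  mids <- (coords[boundary_edges[, 1], , drop = FALSE] +
           coords[boundary_edges[, 2], , drop = FALSE]) / 2
  boundary_normals <- mids / sqrt(rowSums(mids^2))

  m <- new_mesh(coords, elements, boundary_edges, boundary_normals, radius)
  realized <- m$n_nodes
  if (target_node_count >= 50 &&
      abs(realized - target_node_count) / target_node_count > 0.1) {
    warning(sprintf("realized node count %d deviates >10%% from target %d",
                    realized, target_node_count))
  }
  m
}

# Merge two concentric rings of node indices into a triangle strip.
# Both rings are re-sorted by angle relative to the first inner node; the
# walk advances whichever ring has the smaller next (unrolled) angle, a
# two-pointer merge on circular lists producing mi+mo triangles.
triangulate_ring_strip <- function(inner, ang_in, outer, ang_out) {
  mi <- length(inner); mo <- length(outer)
  base <- ang_in[1]
  ua_in <- (ang_in - base) %% (2 * pi)
  ua_out <- (ang_out - base) %% (2 * pi)
  oi <- order(ua_in); inner <- inner[oi]; ua_in <- ua_in[oi]
  oo <- order(ua_out); outer <- outer[oo]; ua_out <- ua_out[oo]
  unrolled <- function(ua, p, m) ua[(p - 1L) %% m + 1L] + 2 * pi * ((p - 1L) %/% m)
  pi_ <- 1L; po <- 1L  # advancing pointers (1-based, unbounded)
  tris <- matrix(0L, nrow = mi + mo, ncol = 3)
  t <- 0L
  while ((pi_ - 1L) < mi || (po - 1L) < mo) {
    i_cur <- (pi_ - 1L) %% mi + 1L
    o_cur <- (po - 1L) %% mo + 1L
    a_i_next <- unrolled(ua_in, pi_ + 1L, mi)
    a_o_next <- unrolled(ua_out, po + 1L, mo)
    take_inner <- if ((pi_ - 1L) >= mi) FALSE
                  else if ((po - 1L) >= mo) TRUE
                  else a_i_next <= a_o_next
    t <- t + 1L
    if (take_inner) {
      i_nxt <- pi_ %% mi + 1L
      tris[t, ] <- c(inner[i_cur], outer[o_cur], inner[i_nxt])
      pi_ <- pi_ + 1L
    } else {
      o_nxt <- po %% mo + 1L
      tris[t, ] <- c(inner[i_cur], outer[o_cur], outer[o_nxt])
      po <- po + 1L
    }
  }
  tris[seq_len(t), , drop = FALSE]
}

signed_areas <- function(coords, elements) {
  p1 <- coords[elements[, 1], , drop = FALSE]
  p2 <- coords[elements[, 2], , drop = FALSE]
  p3 <- coords[elements[, 3], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

#' Element areas of a mesh
#' @param mesh A `pmi_mesh`.
#' @return Numeric vector of positive element areas (mm^2).
#' @export
element_areas <- function(mesh) {
  abs(signed_areas(mesh$node_coords, mesh$elements))
}

#' Validate mesh invariants
#'
#' Checks that all nodes lie inside the disk (with tolerance), all elements
#' have positive signed area, the boundary edges form one closed loop, and
#' boundary normals are unit outward vectors.
#'
#' @param mesh A `pmi_mesh`.
#' @param tol Geometric tolerance in mm.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_mesh <- function(mesh, tol = 1e-8) {
  r <- sqrt(rowSums(mesh$node_coords^2))
  stop_if_not(all(r <= mesh$radius + tol),
              "mesh invariant violated: node outside disk")
  stop_if_not(all(signed_areas(mesh$node_coords, mesh$elements) > 0),
              "mesh invariant violated: non-positive element area")
  be <- mesh$boundary_edges
  stop_if_not(all(be[, 2] == be[c(2:nrow(be), 1), 1]),
              "mesh invariant violated: boundary edges not a closed loop")
  nlen <- sqrt(rowSums(mesh$boundary_normals^2))
  stop_if_not(all(abs(nlen - 1) < 1e-9),
              "mesh invariant violated: non-unit boundary normal")
  mids <- (mesh$node_coords[be[, 1], , drop = FALSE] +
           mesh$node_coords[be[, 2], , drop = FALSE]) / 2
  outward <- rowSums(mids * mesh$boundary_normals)
  stop_if_not(all(outward > 0),
              "mesh invariant violated: boundary normal points inward")
  invisible(TRUE)
}

#' Node adjacency of a mesh
#'
#' @param mesh A `pmi_mesh`.
#' @return A list mapping each node index to the sorted indices of nodes
#'   sharing an element with it.
#' @export
mesh_adjacency <- function(mesh) {
  if (!is.null(mesh$cache$adj)) return(mesh$cache$adj)
  el <- mesh$elements
  pairs <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)])
  pairs <- rbind(pairs, pairs[, c(2, 1)])
  adj <- split(pairs[, 2], pairs[, 1])
  adj <- lapply(adj, function(v) sort(unique(v)))
  out <- vector("list", mesh$n_nodes)
  out[as.integer(names(adj))] <- adj
  mesh$cache$adj <- out
  out
}

#' Connected components of a node subset on the mesh graph
#'
#' Used to split a predicted hot-node set into distinct regions of interest
#' (one per inclusion) for the soft-prior penalty matrix.
#'
#' @param mesh A `pmi_mesh`.
#' @param nodes Integer vector of node indices.
#' @return A list of integer vectors, one per connected component.
#' @export
node_components <- function(mesh, nodes) {
  nodes <- sort(unique(as.integer(nodes)))
  if (!length(nodes)) return(list())
  adj <- mesh_adjacency(mesh)
  inset <- logical(mesh$n_nodes); inset[nodes] <- TRUE
  seen <- logical(mesh$n_nodes)
  comps <- list()
  for (s in nodes) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adj[[v]]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Mean edge length of a mesh
#' @param mesh A `pmi_mesh`.
#' @return Mean over unique element edges, in mm.
#' @export
mean_edge_length <- function(mesh) {
  el <- mesh$elements
  e <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  d <- mesh$node_coords[e[, 1], , drop = FALSE] -
       mesh$node_coords[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

# ---- mesh I/O -------------------------------------------------------------

#' Write a mesh as Gmsh MSH v2 ASCII
#' @param mesh A `pmi_mesh`.
#' @param path Output file path.
#' @export
write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(mesh$n_nodes)), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(mesh$n_nodes),
                     mesh$node_coords[, 1], mesh$node_coords[, 2]), con)
  writeLines(c("$EndNodes", "$Elements",
               as.character(mesh$n_elements + nrow(mesh$boundary_edges))), con)
  nb <- nrow(mesh$boundary_edges)
  writeLines(sprintf("%d 1 2 0 1 %d %d", seq_len(nb),
                     mesh$boundary_edges[, 1], mesh$boundary_edges[, 2]), con)
  writeLines(sprintf("%d 2 2 0 1 %d %d %d", nb + seq_len(mesh$n_elements),
                     mesh$elements[, 1], mesh$elements[, 2],
                     mesh$elements[, 3]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a mesh from Gmsh MSH v2 ASCII
#' @param path File written by [write_mesh_msh()] (2-node line elements mark
#'   the boundary loop, 3-node triangles the interior).
#' @param radius Disk radius; if `NULL`, the max node norm is used.
#' @return A `pmi_mesh`.
#' @export
read_mesh_msh <- function(path, radius = NULL) {
  lines <- readLines(path)
  i_nodes <- which(lines == "$Nodes")
  n <- as.integer(lines[i_nodes + 1L])
  node_rows <- lines[(i_nodes + 2L):(i_nodes + 1L + n)]
  nm <- matrix(as.numeric(unlist(strsplit(node_rows, " "))), ncol = 4,
               byrow = TRUE)
  coords <- nm[order(nm[, 1]), 2:3, drop = FALSE]
  i_el <- which(lines == "$Elements")
  ne <- as.integer(lines[i_el + 1L])
  el_rows <- strsplit(lines[(i_el + 2L):(i_el + 1L + ne)], " ")
  tris <- list(); edges <- list()
  for (row in el_rows) {
    v <- as.integer(row)
    if (v[2] == 2L) tris[[length(tris) + 1L]] <- v[(length(v) - 2):length(v)]
    if (v[2] == 1L) edges[[length(edges) + 1L]] <- v[(length(v) - 1):length(v)]
  }
  elements <- do.call(rbind, tris)
  boundary_edges <- do.call(rbind, edges)
  if (is.null(radius)) radius <- max(sqrt(rowSums(coords^2)))
  mids <- (coords[boundary_edges[, 1], , drop = FALSE] +
           coords[boundary_edges[, 2], , drop = FALSE]) / 2
  normals <- mids / sqrt(rowSums(mids^2))
  m <- new_mesh(coords, elements, boundary_edges, normals, radius)
  validate_mesh(m)
  m
}

#' Write a mesh as a two-file plain-text pair (nodes.csv, elements.csv)
#' @param mesh A `pmi_mesh`.
#' @param dir Output directory (created if missing).
#' @export
write_mesh_csv <- function(mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(x = mesh$node_coords[, 1], y = mesh$node_coords[, 2]),
            file.path(dir, "nodes.csv"), row.names = FALSE)
  write.csv(data.frame(n1 = mesh$elements[, 1], n2 = mesh$elements[, 2],
                       n3 = mesh$elements[, 3]),
            file.path(dir, "elements.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a mesh from a nodes.csv / elements.csv pair
#' @param dir Directory holding `nodes.csv` and `elements.csv`.
#' @param radius Disk radius; if `NULL`, the max node norm is used.
#' @return A `pmi_mesh` (boundary recovered as the edges owned by a single
#'   triangle).
#' @export
read_mesh_csv <- function(dir, radius = NULL) {
  coords <- as.matrix(read.csv(file.path(dir, "nodes.csv")))
  elements <- as.matrix(read.csv(file.path(dir, "elements.csv")))
  storage.mode(elements) <- "integer"
  if (is.null(radius)) radius <- max(sqrt(rowSums(coords^2)))
  # boundary edges: appear in exactly one triangle
  e <- rbind(elements[, c(1, 2)], elements[, c(2, 3)], elements[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  bnd <- e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  # order into a loop
  loop <- integer(0); cur <- bnd[1, 1]; nxt <- bnd[1, 2]
  used <- rep(FALSE, nrow(bnd)); used[1] <- TRUE
  ordered <- list(bnd[1, ])
  while (sum(used) < nrow(bnd)) {
    k <- which(!used & (bnd[, 1] == nxt | bnd[, 2] == nxt))[1]
    if (is.na(k)) break
    edge <- bnd[k, ]
    if (edge[1] != nxt) edge <- rev(edge)
    ordered[[length(ordered) + 1L]] <- edge
    nxt <- edge[2]; used[k] <- TRUE
  }
  boundary_edges <- do.call(rbind, ordered)
  mids <- (coords[boundary_edges[, 1], , drop = FALSE] +
           coords[boundary_edges[, 2], , drop = FALSE]) / 2
  normals <- mids / sqrt(rowSums(mids^2))
  m <- new_mesh(coords, elements, boundary_edges, normals, radius)
  validate_mesh(m)
  m
}
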