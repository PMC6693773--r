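#' Idealized ventricle geometry as a short-axis slice stack plus hex mesh
#'
#' Builds a truncated half-ellipsoid thick-walled shell, open at the base
#' (top slice, largest z) and truncated just short of the apex pole so every
#' hexahedron is non-degenerate, the way a short-axis CMR contour stack never
#' reaches the apical tip. Slices are planar: each carries an inner
#' (endocardial) and outer (epicardial) closed contour at the same z, stored
#' counter-clockwise viewed from the base. Slice positions are uniform in the
#' meridional angle of the endocardial ellipsoid, which keeps element aspect
#' ratios tame near the apex.
#'
#' @param long_axis_len apex-to-base length of the endocardial ellipsoid (mm).
#' @param endo_radius endocardial equatorial (base) radius (mm).
#' @param wall_thickness wall thickness at the base (mm), must be < endo_radius.
#' @param n_slices number of slice rings (>= 3).
#' @param n_circ contour vertices per slice (>= 8).
#' @param n_layers transmural element layers (default 2: endo + epi).
#' @param apex_angle meridional truncation angle at the apex (radians).
#' @return list with `stack` (a `slice_stack`) and `mesh` (a `ventricle_mesh`).
#' @export
make_idealized_ventricle <- function(long_axis_len = 50, endo_radius = 22,
                                     wall_thickness = 4, n_slices = 7,
                                     n_circ = 12, n_layers = 2,
                                     apex_angle = 0.35) {
  if (long_axis_len <= 0 || endo_radius <= 0 || wall_thickness <= 0) {
    stop("geometry error: all dimensions must be positive")
  }
  if (wall_thickness >= endo_radius) {
    stop("geometry error: wall thickness must be smaller than the endocardial radius")
  }
  if (n_slices < 3) stop("geometry error: need at least 3 slices")
  if (n_circ < 8) stop("geometry error: need at least 8 contour vertices")

  L <- long_axis_len; r <- endo_radius; t <- wall_thickness
  phis <- seq(apex_angle, pi / 2, length.out = n_slices)
  theta <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  ct <- cos(theta); st <- sin(theta)

  slices <- lapply(phis, function(phi) {
    z <- L * (1 - cos(phi))
    rin <- r * sin(phi)
    # outer ellipsoid shares the base plane: semi-axes (r + t, L + t), same center
    zc <- (z - L) / (L + t)
    rout <- (r + t) * sqrt(pmax(1 - zc^2, 0))
    list(z = z,
         inner = cbind(rin * ct, rin * st),
         outer = cbind(rout * ct, rout * st))
  })
  stack <- new_slice_stack(slices)
  list(stack = stack, mesh = mesh_from_slices(stack, n_layers = n_layers))
}

new_slice_stack <- function(slices, long_axis = c(0, 0, 1)) {
  z <- vapply(slices, `[[`, numeric(1), "z")
  if (is.unsorted(z, strictly = TRUE)) stop("slice stack: slices must be ordered in z")
  for (s in slices) {
    if (polygon_area(s$outer) - polygon_area(s$inner) <= 0) {
      stop("slice stack: wall area must be positive on every slice")
    }
  }
  structure(list(slices = slices, long_axis = long_axis), class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  z <- vapply(x$slices, `[[`, numeric(1), "z")
  cat(sprintf("Slice stack: %d slices, z in [%.2f, %.2f] mm\n",
              length(x$slices), min(z), max(z)))
  cat(sprintf("  cavity volume %.2f cm^3, wall volume %.2f cm^3\n",
              stack_cavity_volume(x), stack_wall_volume(x)))
  invisible(x)
}

polygon_area <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  0.5 * abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2]))
}

polygon_centroid <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  cr <- xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2]
  a <- sum(cr) / 2
  c(sum((xy[, 1] + xy[i2, 1]) * cr), sum((xy[, 2] + xy[i2, 2]) * cr)) / (6 * a)
}

#' Wall volume of a slice stack (cm^3), trapezoidal rule over slices
#' @param stack a `slice_stack`.
#' @export
stack_wall_volume <- function(stack) {
  z <- vapply(stack$slices, `[[`, numeric(1), "z")
  a <- vapply(stack$slices, function(s) {
    polygon_area(s$outer) - polygon_area(s$inner)
  }, numeric(1))
  sum((a[-1] + a[-length(a)]) / 2 * diff(z)) / 1000
}

#' Cavity volume of a slice stack (cm^3), trapezoidal rule over inner contours
#' @param stack a `slice_stack`.
#' @export
stack_cavity_volume <- function(stack) {
  z <- vapply(stack$slices, `[[`, numeric(1), "z")
  a <- vapply(stack$slices, function(s) polygon_area(s$inner), numeric(1))
  sum((a[-1] + a[-length(a)]) / 2 * diff(z)) / 1000
}

#' Pre-shrink a slice stack toward a zero-load geometry
#'
#' Shrinks each inner contour about its centroid by `inner_rate`, scales the
#' outer contour by the factor that conserves the slice's wall-volume
#' contribution, and compresses the slice spacing by `long_axis_rate` about the
#' base plane (top slice). Because the myocardium is (nearly) incompressible,
#' the muscle volume must not change while the cavity shrinks: with the slice
#' spacing reduced by (1 - long_axis_rate) each slice's wall area is enlarged
#' by 1/(1 - long_axis_rate), so the total wall volume is conserved exactly
#' under the trapezoidal slice-stack quadrature.
#'
#' @param stack a `slice_stack`.
#' @param inner_rate inner-contour shrink fraction in [0, 1).
#' @param long_axis_rate slice-spacing shrink fraction in [0, 1), default equal
#'   to `inner_rate`.
#' @return the shrunk `slice_stack`.
#' @export
preshrink <- function(stack, inner_rate, long_axis_rate = inner_rate) {
  stopifnot(inner_rate >= 0, inner_rate < 1,
            long_axis_rate >= 0, long_axis_rate < 1)
  z <- vapply(stack$slices, `[[`, numeric(1), "z")
  z_base <- z[length(z)]
  z_new <- z_base + (z - z_base) * (1 - long_axis_rate)

  slices <- Map(function(s, zn) {
    a_in <- polygon_area(s$inner)
    a_out <- polygon_area(s$outer)
    c_in <- polygon_centroid(s$inner)
    c_out <- polygon_centroid(s$outer)
    s_in <- 1 - inner_rate
    inner <- sweep(sweep(s$inner, 2, c_in) * s_in, 2, c_in, "+")
    # outer scale: a_out s^2 - a_in s_in^2 = (a_out - a_in)/(1 - long_axis_rate)
    s_out2 <- ((a_out - a_in) / (1 - long_axis_rate) + a_in * s_in^2) / a_out
    if (s_out2 <= 0) stop("geometry error: wall inversion during pre-shrink")
    outer <- sweep(sweep(s$outer, 2, c_out) * sqrt(s_out2), 2, c_out, "+")
    rin <- sqrt(rowSums(sweep(inner, 2, c_in)^2))
    rout <- sqrt(rowSums(sweep(outer, 2, c_in)^2))
    if (any(rout <= rin)) {
      stop("geometry error: wall inversion during pre-shrink (outer inside inner)")
    }
    list(z = zn, inner = inner, outer = outer)
  }, stack$slices, z_new)
  new_slice_stack(slices, stack$long_axis)
}

#' Hexahedral two-layer mesh from a slice stack
#'
#' Nodes are placed on each slice by transmural interpolation between the inner
#' and outer contour vertices; consecutive slices are joined into 8-node
#' hexahedra. Elements in the inner half of the wall are tagged `endo`, the
#' rest `epi`. Endocardial/epicardial face lists, base node set, default
#' boundary conditions (base fixed along the long axis plus two tangential
#' pins killing the in-plane rigid motions) and the ordered endocardial rings
#' used to close the cavity surface are attached.
#'
#' @param stack a `slice_stack`.
#' @param n_layers number of transmural element layers.
#' @return a `ventricle_mesh`.
#' @export
mesh_from_slices <- function(stack, n_layers = 2) {
  ns <- length(stack$slices)
  nc <- nrow(stack$slices[[1]]$inner)
  nk <- n_layers + 1L
  idx <- function(i, j, k) {
    jj <- ((j - 1L) %% nc) + 1L
    (i - 1L) * nc * nk + (k - 1L) * nc + jj
  }
  nodes <- matrix(0, ns * nc * nk, 3)
  for (i in seq_len(ns)) {
    s <- stack$slices[[i]]
    for (k in seq_len(nk)) {
      w <- (k - 1) / (nk - 1)
      xy <- (1 - w) * s$inner + w * s$outer
      nodes[idx(i, seq_len(nc), k), ] <- cbind(xy, s$z)
    }
  }
  nel <- (ns - 1L) * nc * n_layers
  elems <- matrix(0L, nel, 8)
  layer_tag <- character(nel)
  e <- 0L
  for (i in seq_len(ns - 1L)) {
    for (k in seq_len(n_layers)) {
      for (j in seq_len(nc)) {
        e <- e + 1L
        elems[e, ] <- c(idx(i, j, k), idx(i, j + 1L, k),
                        idx(i + 1L, j + 1L, k), idx(i + 1L, j, k),
                        idx(i, j, k + 1L), idx(i, j + 1L, k + 1L),
                        idx(i + 1L, j + 1L, k + 1L), idx(i + 1L, j, k + 1L))
        layer_tag[e] <- if ((k - 0.5) / n_layers <= 0.5) "endo" else "epi"
      }
    }
  }
  endo_faces <- matrix(0L, (ns - 1L) * nc, 4)
  epi_faces <- matrix(0L, (ns - 1L) * nc, 4)
  f <- 0L
  for (i in seq_len(ns - 1L)) {
    for (j in seq_len(nc)) {
      f <- f + 1L
      # ordered so the bilinear normal points out of the cavity (into the wall)
      endo_faces[f, ] <- c(idx(i, j, 1L), idx(i, j + 1L, 1L),
                           idx(i + 1L, j + 1L, 1L), idx(i + 1L, j, 1L))
      epi_faces[f, ] <- c(idx(i, j, nk), idx(i + 1L, j, nk),
                          idx(i + 1L, j + 1L, nk), idx(i, j + 1L, nk))
    }
  }
  base_nodes <- as.integer(idx(ns, rep(seq_len(nc), nk), rep(seq_len(nk), each = nc)))
  endo_base_ring <- as.integer(idx(ns, seq_len(nc), 1L))
  endo_apex_ring <- as.integer(idx(1L, seq_len(nc), 1L))

  # rigid-motion pins: tangential dofs of two base-ring nodes a quarter turn apart
  pin1 <- endo_base_ring[1L]
  pin2 <- endo_base_ring[1L + (nc %/% 4L)]
  fixed <- rbind(cbind(base_nodes, 3L),
                 cbind(pin1, 2L), cbind(pin2, 1L))

  mesh <- structure(list(
    nodes = nodes, elems = elems, layer_tag = layer_tag,
    region_tag = rep("RV", nel),
    endo_faces = endo_faces, epi_faces = epi_faces,
    base_nodes = base_nodes,
    endo_base_ring = endo_base_ring, endo_apex_ring = endo_apex_ring,
    fixed_dofs = fixed, closed = FALSE,
    n_slices = ns, n_circ = nc, n_layers = n_layers),
    class = "ventricle_mesh")
  mesh$elem_circ <- element_direction(mesh, c(1, 2, 4, 3, 5, 6, 8, 7))
  mesh$elem_merid <- element_direction(mesh, c(1, 4, 2, 3, 5, 8, 6, 7))
  jac <- hex_min_jacobians(mesh)
  if (any(jac <= 0)) {
    stop("geometry error: non-positive Jacobian in element(s) ",
         paste(utils::head(which(jac <= 0)), collapse = ", "))
  }
  mesh
}

# mean edge vector over the four parallel element edges given as (from,to) pairs
element_direction <- function(mesh, pairs) {
  p <- matrix(pairs, ncol = 2, byrow = TRUE)
  out <- matrix(0, nrow(mesh$elems), 3)
  for (q in seq_len(nrow(p))) {
    out <- out + (mesh$nodes[mesh$elems[, p[q, 2]], , drop = FALSE] -
                    mesh$nodes[mesh$elems[, p[q, 1]], , drop = FALSE])
  }
  out / nrow(p)
}

#' @export
print.ventricle_mesh <- function(x, ...) {
  cat(sprintf("Ventricle mesh: %d nodes, %d hexahedra (%d endo / %d epi layer)\n",
              nrow(x$nodes), nrow(x$elems),
              sum(x$layer_tag == "endo"), sum(x$layer_tag == "epi")))
  cat(sprintf("  %d endocardial faces, cavity volume %.2f cm^3\n",
              nrow(x$endo_faces), cavity_volume(x)))
  invisible(x)
}

# trilinear hex shape-function derivatives at a local point
hex_dN <- function(xi, eta, zeta) {
  sx <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  sy <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  sz <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  cbind(sx * (1 + sy * eta) * (1 + sz * zeta),
        sy * (1 + sx * xi) * (1 + sz * zeta),
        sz * (1 + sx * xi) * (1 + sy * eta)) / 8
}

hex_gauss <- local({
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  lapply(seq_len(8), function(q) hex_dN(pts[q, 1], pts[q, 2], pts[q, 3]))
})

# minimum reference Jacobian determinant per element over the 8 Gauss points
hex_min_jacobians <- function(mesh) {
  vapply(seq_len(nrow(mesh$elems)), function(e) {
    Xe <- mesh$nodes[mesh$elems[e, ], ]
    min(vapply(hex_gauss, function(dN) det(crossprod(dN, Xe)), numeric(1)))
  }, numeric(1))
}

#' Closed spherical-shell verification mesh (cubed-sphere)
#'
#' Hexahedral mesh of a full thick spherical shell built by projecting the six
#' faces of a cube onto the sphere, giving a closed, degeneracy-free mesh used
#' to verify the inflation solver against the semi-analytic thick-sphere
#' solution. Boundary conditions pin the six rigid-body motions through three
#' nodes (3-2-1 scheme); the pressurized shell is self-equilibrated.
#'
#' @param r_in,r_out inner and outer radii (mm).
#' @param n_face cells per cube-face edge.
#' @param n_layers radial element layers.
#' @return a `ventricle_mesh` with `closed = TRUE` (cavity surface needs no caps).
#' @export
sphere_shell_mesh <- function(r_in = 25, r_out = 30, n_face = 6, n_layers = 2) {
  stopifnot(r_out > r_in, r_in > 0, n_face >= 2, n_layers >= 1)
  faces <- list(
    list(c = c(1, 0, 0), u = c(0, 1, 0), v = c(0, 0, 1)),
    list(c = c(-1, 0, 0), u = c(0, 0, 1), v = c(0, 1, 0)),
    list(c = c(0, 1, 0), u = c(0, 0, 1), v = c(1, 0, 0)),
    list(c = c(0, -1, 0), u = c(1, 0, 0), v = c(0, 0, 1)),
    list(c = c(0, 0, 1), u = c(1, 0, 0), v = c(0, 1, 0)),
    list(c = c(0, 0, -1), u = c(0, 1, 0), v = c(1, 0, 0)))
  key_env <- new.env(hash = TRUE, size = 10000L)
  dirs <- list(); ndir <- 0L
  dir_id <- function(d) {
    key <- paste(sprintf("%.8f", round(d, 8)), collapse = ",")
    id <- key_env[[key]]
    if (is.null(id)) {
      ndir <<- ndir + 1L
      dirs[[ndir]] <<- d
      key_env[[key]] <- ndir
      id <- ndir
    }
    id
  }
  uv <- seq(-1, 1, length.out = n_face + 1L)
  face_grids <- lapply(faces, function(fc) {
    ids <- matrix(0L, n_face + 1L, n_face + 1L)
    for (a in seq_along(uv)) for (b in seq_along(uv)) {
      d <- fc$c + uv[a] * fc$u + uv[b] * fc$v
      ids[a, b] <- dir_id(d / sqrt(sum(d^2)))
    }
    ids
  })
  dirs <- do.call(rbind, dirs)
  radii <- seq(r_in, r_out, length.out = n_layers + 1L)
  nsurf <- nrow(dirs)
  nodes <- do.call(rbind, lapply(radii, function(rr) dirs * rr))
  gid <- function(surf_id, k) (k - 1L) * nsurf + surf_id

  elems <- list(); endo <- list()
  for (fi in seq_along(face_grids)) {
    ids <- face_grids[[fi]]
    for (a in seq_len(n_face)) for (b in seq_len(n_face)) {
      quad <- c(ids[a, b], ids[a + 1L, b], ids[a + 1L, b + 1L], ids[a, b + 1L])
      # orient so (t1 x t2) points radially outward
      t1 <- dirs[quad[2], ] - dirs[quad[1], ]
      t2 <- dirs[quad[4], ] - dirs[quad[1], ]
      nrm <- c(t1[2] * t2[3] - t1[3] * t2[2], t1[3] * t2[1] - t1[1] * t2[3],
               t1[1] * t2[2] - t1[2] * t2[1])
      if (sum(nrm * dirs[quad[1], ]) < 0) quad <- quad[c(1, 4, 3, 2)]
      endo[[length(endo) + 1L]] <- gid(quad, 1L)
      for (k in seq_len(n_layers)) {
        elems[[length(elems) + 1L]] <- c(gid(quad, k), gid(quad, k + 1L))
      }
    }
  }
  elems <- do.call(rbind, elems)
  nel <- nrow(elems)
  # rigid-body pins: tangential constraints at the three axis nodes of the
  # inner surface. Each constrained dof is orthogonal to the node's radial
  # direction, so a purely radial (spherically symmetric) field satisfies all
  # six constraints with zero reaction, while all 6 rigid modes are blocked.
  n1 <- which.max(nodes[seq_len(nsurf), 1])   # near (+r, 0, 0)
  n2 <- which.max(nodes[seq_len(nsurf), 2])   # near (0, +r, 0)
  n3 <- which.max(nodes[seq_len(nsurf), 3])   # near (0, 0, +r)
  fixed <- rbind(cbind(n1, 2L), cbind(n1, 3L),
                 cbind(n2, 1L), cbind(n2, 3L),
                 cbind(n3, 1L), cbind(n3, 2L))

  mesh <- structure(list(
    nodes = nodes, elems = elems,
    layer_tag = rep("endo", nel), region_tag = rep("RV", nel),
    endo_faces = do.call(rbind, endo),
    epi_faces = NULL, base_nodes = integer(0),
    endo_base_ring = NULL, endo_apex_ring = NULL,
    fixed_dofs = fixed, closed = TRUE,
    n_slices = NA, n_circ = NA, n_layers = n_layers),
    class = "ventricle_mesh")
  mesh$elem_circ <- element_direction(mesh, c(1, 2, 4, 3, 5, 6, 8, 7))
  mesh$elem_merid <- element_direction(mesh, c(1, 4, 2, 3, 5, 8, 6, 7))
  jac <- hex_min_jacobians(mesh)
  if (any(jac <= 0)) stop("sphere_shell_mesh: negative Jacobian (internal error)")
  mesh
}

#' Assign per-element fiber directions from layer-wise helix angles
#'
#' Fibers lie in the local wall tangent plane, rotated from the circumferential
#' direction toward the longitudinal (apex-to-base) direction by the helix
#' angle of the element's layer: `endo_angle` in the inner half of the wall,
#' `epi_angle` in the outer half. The local frame is computed from the
#' element's own edge vectors, so the field is equivariant under rigid
#' rotations of the mesh. The published two-layer settings are +40deg
#' endocardial / -45deg epicardial for the RV and +80deg / -60deg for the LV.
#'
#' @param mesh a `ventricle_mesh` with layer tags.
#' @param endo_angle,epi_angle helix angles in degrees, within [-90, 90].
#' @return a `fiber_field`: matrix (n_elements x 3) of unit fiber vectors.
#' @export
assign_fibers <- function(mesh, endo_angle = 40, epi_angle = -45) {
  stopifnot(abs(endo_angle) <= 90, abs(epi_angle) <= 90)
  ang <- ifelse(mesh$layer_tag == "endo", endo_angle, epi_angle) * pi / 180
  circ <- mesh$elem_circ
  merid <- mesh$elem_merid
  cn <- sqrt(rowSums(circ^2))
  if (any(cn < 1e-12)) {
    warning("assign_fibers: degenerate circumferential frame; using slice-plane tangent")
    bad <- cn < 1e-12
    circ[bad, ] <- matrix(rep(c(1, 0, 0), sum(bad)), ncol = 3, byrow = TRUE)
    cn[bad] <- 1
  }
  e_c <- circ / cn
  proj <- rowSums(merid * e_c)
  lon <- merid - proj * e_c
  ln <- sqrt(rowSums(lon^2))
  if (any(ln < 1e-12)) stop("assign_fibers: degenerate longitudinal frame")
  e_l <- lon / ln
  f <- cos(ang) * e_c + sin(ang) * e_l
  f <- f / sqrt(rowSums(f^2))
  structure(f, class = c("fiber_field", "matrix"))
}

#' Piecewise-linear cardiac pressure profile through the four key states
#'
#' Key points: begin-filling (minimum pressure, minimum volume), end-filling
#' (end-diastolic pressure, maximum volume), begin-ejection (maximum pressure,
#' maximum volume) and end-ejection (end-systolic pressure, minimum volume).
#' Key times place filling at 55\% of the period and ejection at 35\%, with
#' the isovolumic transitions in between.
#'
#' @param p_max maximum (begin-ejection) pressure, mmHg.
#' @param p_min minimum (begin-filling) pressure, mmHg.
#' @param p_ed end-diastolic (end-filling) pressure, mmHg.
#' @param p_es end-systolic (end-ejection) pressure, mmHg. The default 40\%
#'   of the peak reflects right-ventricular physiology: ejection ends when RV
#'   pressure falls to the pulmonary-artery diastolic level, a considerably
#'   smaller fraction of peak pressure than on the systemic (aortic) side.
#' @param period cycle length in seconds.
#' @return a `pressure_profile` with `key_points` (time s, pressure mmHg) and `period`.
#' @export
make_pressure_profile <- function(p_max, p_min = 0.1 * p_max,
                                  p_ed = 0.25 * p_max, p_es = 0.4 * p_max,
                                  period = 0.8) {
  if (any(c(p_max, p_min, p_ed, p_es) < 0)) {
    stop("pressure profile validation error: pressures must be non-negative")
  }
  if (!(p_min <= p_es && p_es < p_max && p_min <= p_ed && p_ed < p_max)) {
    stop("pressure profile validation error: need p_min <= p_es < p_max and ",
         "p_min <= p_ed < p_max")
  }
  kp <- data.frame(
    timepoint = c("BF", "EF", "BE", "EE"),
    time = period * c(0, 0.55, 0.60, 0.95),
    pressure = c(p_min, p_ed, p_max, p_es),
    stringsAsFactors = FALSE)
  structure(list(key_points = kp, period = period), class = "pressure_profile")
}

#' @export
print.pressure_profile <- function(x, ...) {
  cat(sprintf("Pressure profile, period %.2f s\n", x$period))
  print(x$key_points, row.names = FALSE)
  invisible(x)
}

#' Export a mesh (optionally with fields) as legacy ASCII VTK
#'
#' @param mesh a `ventricle_mesh`.
#' @param file output path.
#' @param point_data named list of per-node scalars/vectors.
#' @export
write_mesh_vtk <- function(mesh, file, point_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  writeLines(c("# vtk DataFile Version 3.0", "ventmech2g mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  m <- nrow(mesh$elems)
  writeLines(sprintf("CELLS %d %d", m, 9 * m), con)
  utils::write.table(cbind(8L, mesh$elems - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(12L, m)), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(as.character(v), con)
      }
    }
  }
  invisible(file)
}
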