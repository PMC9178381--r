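# Parametric mesh pieces for the synthetic-limb generator. Every labelled
# vertex lies *exactly* on its generating primitive (sphere, cylinder or
# plane) so that fits can be validated against known ground truth; bones are
# unions of primitive-capped pieces, not anatomical scans.

# Grid-triangulated cylinder band: axis through `centre` along unit `axis`,
# radius r, axial extent `len` centred on `centre`, angular range
# `arc_deg` centred about `arc_centre` (a direction perpendicular to the
# axis toward which the band faces).
cylinder_band_mesh <- function(centre, axis, radius, len, n_circ = 16,
                               n_len = 4, arc_deg = 360, arc_centre = NULL) {
  a <- unit3(axis)
  basis <- axis_plane_basis(a)
  u <- basis$u; v <- basis$v
  if (!is.null(arc_centre)) {
    w <- as.numeric(arc_centre)
    w <- w - sum(w * a) * a
    if (vnorm(w) > 1e-12) {
      u <- unit3(w)
      v <- cross3(a, u)
    }
  }
  closed <- arc_deg >= 360 - 1e-9
  half <- arc_deg / 2 * DEG2RAD
  theta <- if (closed) seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
           else seq(-half, half, length.out = n_circ + 1)
  zs <- seq(-len / 2, len / 2, length.out = n_len + 1)
  nt <- length(theta)
  verts <- matrix(0, nt * length(zs), 3)
  k <- 0L
  for (z in zs) for (th in theta) {
    k <- k + 1L
    verts[k, ] <- centre + z * a + radius * (cos(th) * u + sin(th) * v)
  }
  faces <- list()
  idx <- function(i, jr) (jr - 1L) * nt + i  # i: angular, jr: axial ring
  for (jr in seq_len(length(zs) - 1)) {
    for (i in seq_len(if (closed) nt else nt - 1)) {
      i2 <- if (closed && i == nt) 1L else i + 1L
      faces[[length(faces) + 1L]] <- c(idx(i, jr), idx(i2, jr), idx(i2, jr + 1))
      faces[[length(faces) + 1L]] <- c(idx(i, jr), idx(i2, jr + 1), idx(i, jr + 1))
    }
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

# Spherical cap: sphere of `radius` about `centre`, cap pole along unit
# `direction`, opening `half_angle_deg`.
sphere_cap_mesh <- function(centre, radius, direction, half_angle_deg = 60,
                            n_phi = 6, n_theta = 16) {
  d <- unit3(direction)
  basis <- axis_plane_basis(d)
  u <- basis$u; v <- basis$v
  phis <- seq(0, half_angle_deg * DEG2RAD, length.out = n_phi + 1)[-1]
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  verts <- matrix(0, 1 + length(phis) * n_theta, 3)
  verts[1, ] <- centre + radius * d  # pole
  k <- 1L
  for (phi in phis) for (th in thetas) {
    k <- k + 1L
    verts[k, ] <- centre + radius *
      (cos(phi) * d + sin(phi) * (cos(th) * u + sin(th) * v))
  }
  faces <- list()
  ring <- function(jr, i) 1L + (jr - 1L) * n_theta + i  # jr-th ring, i in 1..n_theta
  for (i in seq_len(n_theta)) {
    i2 <- if (i == n_theta) 1L else i + 1L
    faces[[length(faces) + 1L]] <- c(1L, ring(1, i), ring(1, i2))
  }
  if (length(phis) > 1) {
    for (jr in seq_len(length(phis) - 1)) {
      for (i in seq_len(n_theta)) {
        i2 <- if (i == n_theta) 1L else i + 1L
        faces[[length(faces) + 1L]] <- c(ring(jr, i), ring(jr + 1, i), ring(jr + 1, i2))
        faces[[length(faces) + 1L]] <- c(ring(jr, i), ring(jr + 1, i2), ring(jr, i2))
      }
    }
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

# Flat disk in the plane through `centre` with unit `normal`.
disk_mesh <- function(centre, normal, radius, n_ring = 3, n_theta = 16) {
  nrm <- unit3(normal)
  basis <- axis_plane_basis(nrm)
  u <- basis$u; v <- basis$v
  rads <- seq(0, radius, length.out = n_ring + 1)[-1]
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  verts <- matrix(0, 1 + length(rads) * n_theta, 3)
  verts[1, ] <- centre
  k <- 1L
  for (r in rads) for (th in thetas) {
    k <- k + 1L
    verts[k, ] <- centre + r * (cos(th) * u + sin(th) * v)
  }
  faces <- list()
  ring <- function(jr, i) 1L + (jr - 1L) * n_theta + i
  for (i in seq_len(n_theta)) {
    i2 <- if (i == n_theta) 1L else i + 1L
    faces[[length(faces) + 1L]] <- c(1L, ring(1, i), ring(1, i2))
  }
  if (length(rads) > 1) {
    for (jr in seq_len(length(rads) - 1)) {
      for (i in seq_len(n_theta)) {
        i2 <- if (i == n_theta) 1L else i + 1L
        faces[[length(faces) + 1L]] <- c(ring(jr, i), ring(jr + 1, i), ring(jr + 1, i2))
        faces[[length(faces) + 1L]] <- c(ring(jr, i), ring(jr + 1, i2), ring(jr, i2))
      }
    }
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

# Accumulate labelled parts into one mesh, recording the face-index range of
# each labelled part (label NA = unlabelled filler geometry like shafts).
new_mesh_builder <- function() {
  list(vertices = list(), faces = list(), labels = list())
}

builder_add <- function(builder, part, label = NA_character_) {
  offset <- sum(vapply(builder$vertices, nrow, 0L))
  nface0 <- sum(vapply(builder$faces, nrow, 0L))
  builder$vertices[[length(builder$vertices) + 1L]] <- part$vertices
  builder$faces[[length(builder$faces) + 1L]] <- part$faces + offset
  if (!is.na(label)) {
    builder$labels[[label]] <- seq.int(nface0 + 1L, nface0 + nrow(part$faces))
  }
  builder
}

builder_mesh <- function(builder) {
  trimesh(do.call(rbind, builder$vertices), do.call(rbind, builder$faces))
}

# Mirror a mesh across the sagittal (xz) plane: negate y and flip face
# winding so outward normals stay outward.
mirror_mesh_xz <- function(mesh) {
  v <- mesh$vertices
  v[, 2] <- -v[, 2]
  trimesh(v, mesh$faces[, c(1L, 3L, 2L), drop = FALSE])
}

mirror_point_xz <- function(p) c(p[1], -p[2], p[3])
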