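#' Triangle surface meshes
#'
#' Meshes are lists with `vertices` (n x 3 numeric, mm) and `faces` (m x 3
#' integer, 1-based, counter-clockwise when viewed from outside). All
#' structures of a heart model must be watertight and outward-oriented so
#' that parity-based containment is well defined.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @export
mesh <- function(vertices, faces) {
  vertices <- rbind_points(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face index out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "vf_mesh")
}

#' @export
print.vf_mesh <- function(x, ...) {
  cat(sprintf("<vf_mesh: %d vertices, %d faces, volume %.3f mm^3>\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for
#' outward-oriented closed surfaces.
#'
#' @param m a mesh.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(m) {
  V <- m$vertices; F <- m$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Surface area of a mesh
#'
#' @param m a mesh.
#' @return area in mm^2.
#' @export
mesh_area <- function(m) {
  V <- m$vertices; F <- m$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Watertightness and orientation checks
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' triangles; it is consistently oriented when each such edge is traversed
#' once in each direction. `mesh_is_watertight()` requires both plus positive
#' signed volume (outward orientation).
#'
#' @param m a mesh.
#' @export
mesh_is_watertight <- function(m) {
  F <- m$faces
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L)) return(FALSE)
  dkey <- paste(he[, 1], he[, 2])
  if (any(table(dkey) != 1L)) return(FALSE)   # opposite directions required
  mesh_volume(m) > 0
}

#' @rdname mesh_is_watertight
#' @export
mesh_boundary_edge_count <- function(m) {
  F <- m$faces
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  sum(table(key) == 1L)
}

#' Transform a mesh by a pose or affine map
#'
#' @param m a mesh.
#' @param pose 4x4 pose matrix.
#' @export
mesh_transform <- function(m, pose) {
  assert_pose(pose)
  mesh(pose_apply(pose, m$vertices), m$faces)
}

#' Scale a mesh about a center
#'
#' @param m a mesh.
#' @param factor positive scalar.
#' @param center length-3 point.
#' @export
mesh_scale <- function(m, factor, center = c(0, 0, 0)) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("scale factor must be a positive scalar", call. = FALSE)
  center <- as.numeric(center)
  V <- sweep(m$vertices, 2, center)
  mesh(sweep(V * factor, 2, center, `+`), m$faces)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron with all vertices on the sphere of radius `radius`.
#' Subdivision 3 (the package default tessellation) gives 642 vertices.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 triangle subdivisions.
#' @param center sphere center.
#' @export
mesh_icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_id <- new.env(hash = TRUE)
    nv <- nrow(V)
    extra <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_id[[key]]
      if (!is.null(id)) return(id)
      p <- (V[a, ] + V[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      extra[[length(extra) + 1L]] <<- p
      id <- nv + length(extra)
      edge_id[[key]] <- id
      id
    }
    Fn <- matrix(0L, nrow(F) * 4L, 3L)
    for (i in seq_len(nrow(F))) {
      a <- F[i, 1]; b <- F[i, 2]; c <- F[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      Fn[(i - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    V <- rbind(V, do.call(rbind, extra))
    F <- Fn
  }
  mesh(sweep(V * radius, 2, as.numeric(center), `+`), F)
}

#' Ellipsoid mesh (optionally radially deformed)
#'
#' An icosphere scaled anisotropically by `semi_axes`, then optionally
#' perturbed radially by a smooth low-order harmonic field. Radial
#' deformation of a star-shaped surface preserves watertightness.
#'
#' @param semi_axes length-3 semi-axes (mm).
#' @param center center (mm).
#' @param subdivisions icosphere subdivisions.
#' @param deform_amp relative amplitude of the radial deformation (0 = exact
#'   ellipsoid).
#' @param deform_coef optional length-6 coefficient vector in [-1, 1]; when
#'   `NULL` no deformation is applied even if `deform_amp > 0`.
#' @export
mesh_ellipsoid <- function(semi_axes, center = c(0, 0, 0), subdivisions = 3,
                           deform_amp = 0, deform_coef = NULL) {
  m <- mesh_icosphere(1, subdivisions)
  U <- m$vertices   # unit directions
  if (deform_amp > 0 && !is.null(deform_coef)) {
    cf <- deform_coef
    f <- 1 + deform_amp * (
      cf[1] * U[, 1] * U[, 2] + cf[2] * U[, 2] * U[, 3] +
      cf[3] * U[, 1] * U[, 3] + cf[4] * (U[, 1]^2 - U[, 2]^2) +
      cf[5] * (3 * U[, 3]^2 - 1) / 2 + cf[6] * U[, 1] * U[, 2] * U[, 3])
    U <- U * f
  }
  V <- sweep(U, 2, as.numeric(semi_axes), `*`)
  mesh(sweep(V, 2, as.numeric(center), `+`), m$faces)
}

# Chaikin corner-cutting; endpoints kept fixed.
chaikin <- function(P, iters = 2) {
  for (it in seq_len(iters)) {
    n <- nrow(P)
    if (n < 3) return(P)
    Q <- matrix(0, 2 * (n - 1), 3)
    for (i in seq_len(n - 1)) {
      Q[2 * i - 1, ] <- 0.75 * P[i, ] + 0.25 * P[i + 1, ]
      Q[2 * i, ] <- 0.25 * P[i, ] + 0.75 * P[i + 1, ]
    }
    P <- rbind(P[1, ], Q, P[n, ])
  }
  P
}

#' Swept-tube mesh along a polyline
#'
#' Sweeps a circular cross-section along a Chaikin-smoothed polyline using
#' parallel-transport frames, closing both ends with triangle fans (flat
#' caps). The result is watertight and outward-oriented.
#'
#' @param waypoints k x 3 matrix of path points (mm), k >= 2.
#' @param radius tube radius (mm); scalar or one value per waypoint
#'   (interpolated along the smoothed path).
#' @param n_around vertices per cross-section ring.
#' @param smooth_iters Chaikin smoothing iterations for the path.
#' @export
mesh_tube <- function(waypoints, radius, n_around = 16, smooth_iters = 2) {
  P <- rbind_points(waypoints)
  if (nrow(P) < 2) stop("tube needs at least 2 waypoints", call. = FALSE)
  if (length(radius) == 1) {
    r_at <- function(s) rep(radius, length(s))
  } else {
    if (length(radius) != nrow(P))
      stop("radius must be scalar or one per waypoint", call. = FALSE)
    s0 <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
    r_at <- function(s) approx(s0 / max(s0), radius, xout = s, rule = 2)$y
  }
  P <- chaikin(P, smooth_iters)
  # drop duplicate consecutive points
  keep <- c(TRUE, rowSums(diff(P)^2) > 1e-16)
  P <- P[keep, , drop = FALSE]
  n <- nrow(P)
  seg <- sqrt(rowSums(diff(P)^2))
  s <- c(0, cumsum(seg)) / sum(seg)
  rr <- r_at(s)
  # tangents and parallel-transport frames
  tang <- matrix(0, n, 3)
  tang[1, ] <- P[2, ] - P[1, ]
  tang[n, ] <- P[n, ] - P[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- P[3:n, ] - P[1:(n - 2), ]
  tang <- tang / sqrt(rowSums(tang^2))
  u <- if (abs(tang[1, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- u - sum(u * tang[1, ]) * tang[1, ]
  e1 <- e1 / sqrt(sum(e1^2))
  ang <- 2 * pi * (seq_len(n_around) - 1) / n_around
  rings <- vector("list", n)
  for (i in seq_len(n)) {
    if (i > 1) {
      # transport e1 to the new tangent
      tprev <- tang[i - 1, ]; tcur <- tang[i, ]
      ax <- c(tprev[2] * tcur[3] - tprev[3] * tcur[2],
              tprev[3] * tcur[1] - tprev[1] * tcur[3],
              tprev[1] * tcur[2] - tprev[2] * tcur[1])
      na <- sqrt(sum(ax^2))
      if (na > 1e-12) {
        ax <- ax / na
        th <- atan2(na, sum(tprev * tcur))
        e1 <- e1 * cos(th) + c(ax[2] * e1[3] - ax[3] * e1[2],
                               ax[3] * e1[1] - ax[1] * e1[3],
                               ax[1] * e1[2] - ax[2] * e1[1]) * sin(th) +
          ax * sum(ax * e1) * (1 - cos(th))
      }
      e1 <- e1 - sum(e1 * tcur) * tcur
      e1 <- e1 / sqrt(sum(e1^2))
    }
    tcur <- tang[i, ]
    e2 <- c(tcur[2] * e1[3] - tcur[3] * e1[2],
            tcur[3] * e1[1] - tcur[1] * e1[3],
            tcur[1] * e1[2] - tcur[2] * e1[1])
    rings[[i]] <- sweep(outer(cos(ang), e1) + outer(sin(ang), e2), 1,
                        rr[i], `*`)
    rings[[i]] <- sweep(rings[[i]], 2, P[i, ], `+`)
  }
  V <- do.call(rbind, rings)
  V <- rbind(V, P[1, ], P[n, ])   # cap centers
  c0 <- n * n_around + 1L
  c1 <- n * n_around + 2L
  F <- list()
  for (i in seq_len(n - 1)) {
    a <- (i - 1L) * n_around + seq_len(n_around)
    b <- i * n_around + seq_len(n_around)
    an <- c(a[-1], a[1]); bn <- c(b[-1], b[1])
    F[[length(F) + 1L]] <- cbind(a, b, bn)
    F[[length(F) + 1L]] <- cbind(a, bn, an)
  }
  a <- seq_len(n_around); an <- c(a[-1], a[1])
  F[[length(F) + 1L]] <- cbind(a, an, c0)       # start cap
  b <- (n - 1L) * n_around + seq_len(n_around); bn <- c(b[-1], b[1])
  F[[length(F) + 1L]] <- cbind(bn, b, c1)       # end cap
  m <- mesh(V, do.call(rbind, F))
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Taubin mesh smoothing
#'
#' Alternating positive/negative Laplacian steps (lambda/mu) that smooth the
#' surface while approximately preserving enclosed volume. Connectivity is
#' unchanged, so watertightness is preserved.
#'
#' @param m a mesh.
#' @param iters number of lambda+mu iteration pairs.
#' @param lambda positive smoothing step.
#' @param mu negative (inflation) step; must satisfy `mu < -lambda` in the
#'   usual Taubin band-pass sense.
#' @export
mesh_smooth <- function(m, iters = 10, lambda = 0.5, mu = -0.53) {
  if (iters <= 0) return(m)
  V <- cpp_taubin_smooth(m$vertices, m$faces, as.integer(iters), lambda, mu)
  mesh(V, m$faces)
}
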