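#' Spatial index over a posed heart model
#'
#' Builds an axis-aligned bounding-volume hierarchy over every triangle of
#' the model, tagged by structure. The defining contract is oracle
#' equivalence: crossover queries return exactly the set a brute-force test
#' over all triangles returns (same epsilon policy), the tree only
#' accelerates the search.
#'
#' @param model a [heart_model()].
#' @return a `spatial_index` object.
#' @export
build_index <- function(model) {
  if (!length(model$structures)) stop("empty model", call. = FALSE)
  nm <- structure_names(model)
  Vs <- lapply(model$structures, function(s) s$mesh$vertices)
  offs <- cumsum(c(0L, vapply(Vs, nrow, 1L)))
  V <- do.call(rbind, Vs)
  F <- do.call(rbind, lapply(seq_along(nm), function(i)
    model$structures[[i]]$mesh$faces + offs[i]))
  tag <- unlist(lapply(seq_along(nm), function(i)
    rep(i, nrow(model$structures[[i]]$mesh$faces))))
  structure(list(ptr = cpp_bvh_build(V, F, as.integer(tag)),
                 structure_names = nm,
                 priorities = vapply(model$structures,
                                     function(s) s$priority, 1L),
                 material_ids = vapply(model$structures,
                                       function(s) s$material_id, "")),
            class = "spatial_index")
}

#' @export
print.spatial_index <- function(x, ...) {
  cat(sprintf("<spatial_index over %d structures>\n",
              length(x$structure_names)))
  invisible(x)
}

#' Scan-line / mesh crossings
#'
#' Returns all surface crossings along one or more rays, sorted by distance.
#' `entering` is derived from triangle orientation (TRUE when the ray runs
#' against the outward normal). Crossings of one closed structure alternate
#' entering/exiting along the ray.
#'
#' @param index a [build_index()] result.
#' @param origins n x 3 matrix (or length-3 vector) of ray origins (mm).
#' @param dirs n x 3 matrix (or length-3 vector) of unit directions.
#' @param lengths maximal distance per ray (mm); recycled.
#' @return data frame: `ray`, `distance`, `structure`, `entering`.
#' @export
intersect_scanlines <- function(index, origins, dirs, lengths = Inf) {
  origins <- rbind_points(origins)
  dirs <- rbind_points(dirs)
  nd <- sqrt(rowSums(dirs^2))
  if (any(abs(nd - 1) > 1e-9)) stop("directions must be unit", call. = FALSE)
  res <- cpp_bvh_query(index$ptr, origins, dirs, as.numeric(lengths))
  data.frame(ray = res$ray, distance = res$distance,
             structure = index$structure_names[res$tag],
             entering = res$entering == 1L)
}

#' Brute-force crossing oracle
#'
#' Independent all-triangle reference for the spatial index: a vectorized
#' Moller-Trumbore test over every triangle of the model with the same
#' epsilon policy as the compiled path. Used to certify the index, never for
#' production rendering.
#'
#' @param model a [heart_model()].
#' @param origin length-3 ray origin.
#' @param dir length-3 unit direction.
#' @param length maximal distance (mm).
#' @return data frame sorted like [intersect_scanlines()] (single ray).
#' @export
intersect_brute <- function(model, origin, dir, length = Inf) {
  BARY_EPS <- 1e-9
  DET_EPS <- 1e-12
  origin <- as.numeric(origin)
  dir <- as.numeric(dir)
  out <- list()
  for (nm in structure_names(model)) {
    m <- model$structures[[nm]]$mesh
    V <- m$vertices; F <- m$faces
    p0 <- V[F[, 1], , drop = FALSE]
    e1 <- V[F[, 2], , drop = FALSE] - p0
    e2 <- V[F[, 3], , drop = FALSE] - p0
    hx <- dir[2] * e2[, 3] - dir[3] * e2[, 2]
    hy <- dir[3] * e2[, 1] - dir[1] * e2[, 3]
    hz <- dir[1] * e2[, 2] - dir[2] * e2[, 1]
    a <- e1[, 1] * hx + e1[, 2] * hy + e1[, 3] * hz
    ok <- abs(a) >= DET_EPS
    f <- ifelse(ok, 1 / a, NA)
    sx <- origin[1] - p0[, 1]; sy <- origin[2] - p0[, 2]; sz <- origin[3] - p0[, 3]
    u <- f * (sx * hx + sy * hy + sz * hz)
    ok <- ok & !is.na(u) & u >= -BARY_EPS & u <= 1 + BARY_EPS
    qx <- sy * e1[, 3] - sz * e1[, 2]
    qy <- sz * e1[, 1] - sx * e1[, 3]
    qz <- sx * e1[, 2] - sy * e1[, 1]
    v <- f * (dir[1] * qx + dir[2] * qy + dir[3] * qz)
    ok <- ok & !is.na(v) & v >= -BARY_EPS & (u + v) <= 1 + BARY_EPS
    t <- f * (e2[, 1] * qx + e2[, 2] * qy + e2[, 3] * qz)
    ok <- ok & !is.na(t) & t >= -BARY_EPS & t <= length + BARY_EPS
    if (any(ok))
      out[[length(out) + 1L]] <- data.frame(
        distance = t[ok], structure = nm, entering = a[ok] > 0)
  }
  if (!length(out))
    return(data.frame(ray = integer(0), distance = numeric(0),
                      structure = character(0), entering = logical(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$distance, res$structure), , drop = FALSE]
  rownames(res) <- NULL
  cbind(ray = 1L, res)
}

#' Point-in-structure test
#'
#' Ray-parity containment for each structure of the model at the given
#' points (closed outward-oriented meshes assumed).
#'
#' @param model a [heart_model()] or a single [mesh()].
#' @param points n x 3 matrix.
#' @return if `model` is a mesh, a logical vector; otherwise a logical
#'   matrix (points x structures).
#' @export
point_in_mesh <- function(model, points) {
  points <- rbind_points(points)
  if (inherits(model, "vf_mesh")) {
    ptr <- cpp_bvh_build(model$vertices, model$faces, integer(0))
    return(cpp_point_in_mesh(ptr, points))
  }
  res <- vapply(model$structures, function(s) {
    ptr <- cpp_bvh_build(s$mesh$vertices, s$mesh$faces, integer(0))
    cpp_point_in_mesh(ptr, points)
  }, logical(nrow(points)))
  matrix(res, nrow = nrow(points),
         dimnames = list(NULL, structure_names(model)))
}
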