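#' Rigid probe poses
#'
#' A pose is a 4x4 homogeneous transform (rotation + translation, millimetres)
#' mapping probe/image coordinates into heart coordinates. The rotation block
#' must be orthonormal with determinant +1 and the bottom row (0, 0, 0, 1).
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation in mm.
#' @return A 4x4 pose matrix.
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4] <- translation
  assert_pose(m)
  m
}

#' @rdname pose
#' @export
pose_identity <- function() diag(4)

#' @rdname pose
#' @param offset length-3 translation in mm.
#' @export
pose_translate <- function(offset) pose(diag(3), offset)

#' Rotation pose about a coordinate axis
#'
#' @param axis one of "x", "y", "z".
#' @param angle_deg rotation angle in degrees (right-handed).
#' @param center optional point the rotation pivots about (default origin).
#' @export
pose_rotate <- function(axis = c("x", "y", "z"), angle_deg, center = c(0, 0, 0)) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  R <- switch(axis,
    x = rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca)),
    y = rbind(c(ca, 0, sa), c(0, 1, 0), c(-sa, 0, ca)),
    z = rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1)))
  pose(R, as.numeric(center) - R %*% as.numeric(center))
}

#' Validate a pose matrix
#'
#' @param m candidate 4x4 matrix.
#' @param tol orthonormality tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_pose <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || !all(dim(m) == c(4, 4)) || !is.numeric(m)) return(FALSE)
  if (any(abs(m[4, ] - c(0, 0, 0, 1)) > tol)) return(FALSE)
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol) return(FALSE)
  abs(det(R) - 1) <= tol
}

assert_pose <- function(m) {
  if (!is_valid_pose(m)) stop("invalid pose matrix", call. = FALSE)
  invisible(m)
}

#' Compose two poses
#'
#' `pose_compose(a, b)` applies `b` first, then `a` (matrix product `a %*% b`).
#'
#' @param a,b valid pose matrices.
#' @export
pose_compose <- function(a, b) {
  assert_pose(a); assert_pose(b)
  a %*% b
}

#' Invert a pose
#'
#' @param m valid pose matrix.
#' @export
pose_invert <- function(m) {
  assert_pose(m)
  R <- t(m[1:3, 1:3])
  pose(R, -R %*% m[1:3, 4])
}

#' Apply a pose to points
#'
#' @param m valid pose matrix.
#' @param pts n x 3 matrix of points (mm).
#' @return n x 3 matrix of transformed points.
#' @export
pose_apply <- function(m, pts) {
  pts <- rbind_points(pts)
  t(m[1:3, 1:3] %*% t(pts) + m[1:3, 4])
}

rbind_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3, byrow = TRUE)
  storage.mode(pts) <- "double"
  pts
}

#' Build a pose from an image plane definition
#'
#' Constructs the pose of a probe whose image plane passes through `center`
#' with lateral (image-x) direction `xdir` and depth (image-y) direction
#' `ydir`; the probe contact point sits `standoff` mm before `center` along
#' the depth direction. `xdir`/`ydir` are orthonormalized (Gram-Schmidt, depth
#' direction kept exact).
#'
#' @param center point on the image plane, heart frame (mm).
#' @param xdir lateral direction of the image.
#' @param ydir depth direction (from transducer into tissue).
#' @param standoff distance (mm) from the probe contact point to `center`.
#' @export
pose_from_plane <- function(center, xdir, ydir, standoff = 30) {
  v <- ydir / sqrt(sum(ydir^2))
  u <- xdir - sum(xdir * v) * v
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("xdir parallel to ydir", call. = FALSE)
  u <- u / nu
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  pose(cbind(u, v, w, deparse.level = 0), as.numeric(center) - standoff * v)
}

#' Read or write a pose file
#'
#' Accepts JSON (`{"matrix": [...16 numbers row-major...]}`) or plain text
#' (16 whitespace-separated numbers, row-major). The writer emits JSON.
#'
#' @param path file path.
#' @export
read_pose <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  vals <- if (grepl("\\{", txt)) {
    as.numeric(unlist(jsonlite::fromJSON(txt)$matrix))
  } else {
    as.numeric(strsplit(trimws(txt), "[[:space:],]+")[[1]])
  }
  if (length(vals) != 16) stop("pose file must contain 16 numbers", call. = FALSE)
  m <- matrix(vals, 4, 4, byrow = TRUE)
  assert_pose(m)
  m
}

#' @rdname read_pose
#' @param m valid pose matrix.
#' @export
write_pose <- function(m, path) {
  assert_pose(m)
  jsonlite::write_json(list(matrix = as.vector(t(m))), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Interpolate between two poses
#'
#' Linear interpolation of translation with spherical linear interpolation of
#' the rotation (quaternion slerp), used by probe sweeps.
#'
#' @param a,b valid poses.
#' @param t interpolation parameter in [0, 1].
#' @export
pose_interpolate <- function(a, b, t) {
  assert_pose(a); assert_pose(b)
  qa <- rot_to_quat(a[1:3, 1:3]); qb <- rot_to_quat(b[1:3, 1:3])
  if (sum(qa * qb) < 0) qb <- -qb
  d <- max(-1, min(1, sum(qa * qb)))
  th <- acos(d)
  q <- if (th < 1e-9) qa else
    (sin((1 - t) * th) * qa + sin(t * th) * qb) / sin(th)
  q <- q / sqrt(sum(q^2))
  pose(quat_to_rot(q), (1 - t) * a[1:3, 4] + t * b[1:3, 4])
}

rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}
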