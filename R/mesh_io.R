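#' Read a surface mesh file
#'
#' Supports STL (binary and ASCII), OBJ and ASCII PLY. STL files carry no
#' shared vertex indices, so identical vertex positions are merged on read to
#' restore connectivity.
#'
#' @param path mesh file; format inferred from the extension.
#' @return a [mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = read_stl(path),
    obj = read_obj(path),
    ply = read_ply(path),
    stop("unsupported mesh format: ", ext, call. = FALSE))
}

#' Write a surface mesh file
#'
#' @param m a [mesh()].
#' @param path output path; format from extension (`.stl` binary by default,
#'   `.obj`, `.ply` ASCII).
#' @param ascii write ASCII STL instead of binary.
#' @export
write_mesh <- function(m, path, ascii = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = if (ascii) write_stl_ascii(m, path) else write_stl_binary(m, path),
    obj = write_obj(m, path),
    ply = write_ply(m, path),
    stop("unsupported mesh format: ", ext, call. = FALSE))
  invisible(path)
}

merge_vertices <- function(tri_pts) {
  key <- paste(tri_pts[, 1], tri_pts[, 2], tri_pts[, 3])
  ids <- match(key, unique(key))
  V <- tri_pts[!duplicated(key), , drop = FALSE]
  F <- matrix(ids, ncol = 3, byrow = TRUE)
  mesh(V, F)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  sz <- file.size(path)
  if (length(n) == 1 && !is.na(n) && sz == 84 + 50 * as.numeric(n) && n > 0) {
    tri <- matrix(0, n * 3L, 3L)
    for (i in seq_len(n)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      tri[(i - 1L) * 3L + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", 2)
    }
    return(merge_vertices(tri))
  }
  close(con)
  on.exit(NULL)
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("not a valid STL file: ", path, call. = FALSE)
  pts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(x) as.numeric(x[2:4])))
  merge_vertices(pts)
}

write_stl_binary <- function(m, path) {
  V <- m$vertices; F <- m$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  for (i in seq_len(nrow(F))) {
    writeBin(as.numeric(c(nrm[i, ], t(V[F[i, ], ]))), con, size = 4,
             endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

write_stl_ascii <- function(m, path) {
  V <- m$vertices; F <- m$faces
  out <- c("solid vfecho")
  for (i in seq_len(nrow(F))) {
    tri <- V[F[i, ], , drop = FALSE]
    out <- c(out, "  facet normal 0 0 0", "    outer loop",
             sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
             "    endloop", "  endfacet")
  }
  writeLines(c(out, "endsolid vfecho"), path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vt <- strsplit(trimws(grep("^v\\s", lines, value = TRUE)), "\\s+")
  V <- do.call(rbind, lapply(vt, function(x) as.numeric(x[2:4])))
  ft <- strsplit(trimws(grep("^f\\s", lines, value = TRUE)), "\\s+")
  F <- do.call(rbind, lapply(ft, function(x) {
    idx <- as.integer(vapply(strsplit(x[-1], "/"), `[[`, "", 1))
    if (length(idx) != 3) stop("only triangle OBJ faces supported", call. = FALSE)
    idx
  }))
  mesh(V, F)
}

write_obj <- function(m, path) {
  V <- m$vertices; F <- m$faces
  writeLines(c(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
               sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])), path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("not an ASCII PLY file: ", path, call. = FALSE)
  head <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", head)))
    stop("only ASCII PLY supported", call. = FALSE)
  nv <- as.integer(sub("element vertex\\s+", "", grep("^element vertex", head,
                                                      value = TRUE)))
  nf <- as.integer(sub("element face\\s+", "", grep("^element face", head,
                                                    value = TRUE)))
  body <- lines[(endh + 1):length(lines)]
  vt <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- do.call(rbind, lapply(vt, function(x) as.numeric(x[1:3])))
  ft <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  F <- do.call(rbind, lapply(ft, function(x) as.integer(x[2:4]) + 1L))
  mesh(V, F)
}

write_ply <- function(m, path) {
  V <- m$vertices; F <- m$faces
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices", "end_header",
               sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
               sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)),
             path)
}
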