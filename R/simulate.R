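#' Simulate a B-mode image and its label slice
#'
#' The core rendering pipeline: the model is transformed into the image
#' frame (inverse of the probe pose), scan lines are laid out per the probe
#' config, the spatial index yields all scan-line/mesh crossings, segments
#' between crossings are filled with material grey values, and the filled
#' lines are scan-converted into a Cartesian B-mode image. A companion label
#' slice is rendered with the same sampling but stores structure ids
#' (nearest-neighbor always), for ground-truth verification.
#'
#' @param model a [heart_model()] in the heart frame.
#' @param pose probe pose: image frame -> heart frame.
#' @param probe a [probe_config()].
#' @param materials a [material_table()].
#' @param speckle_sd multiplicative speckle noise sd (0 = off).
#' @param seed speckle seed.
#' @return list with `bmode` (a `bmode_image`) and `label` (a `label_slice`).
#' @export
simulate_bmode <- function(model, pose, probe, materials = default_materials(),
                           speckle_sd = 0, seed = 1L) {
  assert_pose(pose)
  check_materials(model, materials)
  posed <- apply_pose(model, pose_invert(pose))
  index <- build_index(posed)
  lines <- compute_scanlines(probe)
  origins <- as.matrix(lines[, c("ox", "oy", "oz")])
  dirs <- as.matrix(lines[, c("dx", "dy", "dz")])
  cross <- intersect_scanlines(index, origins, dirs, probe$scanline_depth_mm)
  nm <- structure_names(posed)
  # start-inside states for every line origin (bounding-box prefiltered)
  start_in <- matrix(FALSE, nrow(lines), length(nm),
                     dimnames = list(NULL, nm))
  for (s in nm) {
    b <- apply(posed$structures[[s]]$mesh$vertices, 2, range)
    cand <- which(origins[, 1] >= b[1, 1] & origins[, 1] <= b[2, 1] &
                  origins[, 2] >= b[1, 2] & origins[, 2] <= b[2, 2] &
                  origins[, 3] >= b[1, 3] & origins[, 3] <= b[2, 3])
    if (length(cand))
      start_in[cand, s] <- point_in_mesh(posed$structures[[s]]$mesh,
                                         origins[cand, , drop = FALSE])
  }
  depths <- scanline_sample_depths(probe)
  S <- length(depths)
  intens <- matrix(0, S, nrow(lines))
  labs <- matrix(0L, S, nrow(lines))
  cross_by_ray <- split(cross[, c("distance", "structure", "entering")],
                        factor(cross$ray, levels = seq_len(nrow(lines))))
  for (i in seq_len(nrow(lines))) {
    filled <- fill_scanline(cross_by_ray[[i]], lines[i, ], posed, materials,
                            depths = depths, start_inside = start_in[i, ])
    intens[, i] <- filled$intensity
    labs[, i] <- filled$label
  }
  img <- scan_convert(intens, probe)
  img <- round(pmin(pmax(img, 0), 255))
  lab <- scan_convert(labs, probe, labels = TRUE)
  bm <- structure(img, class = "bmode_image", pixel_spacing_mm =
                    probe$pixel_spacing_mm, pose = pose, probe = probe)
  ls <- structure(array(as.integer(lab), dim(lab)), class = "label_slice",
                  pixel_spacing_mm = probe$pixel_spacing_mm,
                  structure_names = nm)
  if (speckle_sd > 0) bm <- add_speckle(bm, seed = seed, sd = speckle_sd)
  list(bmode = bm, label = ls)
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image %dx%d px @ %g mm, grey %d..%d>\n", nrow(x),
              ncol(x), attr(x, "pixel_spacing_mm"), min(x), max(x)))
  invisible(x)
}

#' @export
print.label_slice <- function(x, ...) {
  ids <- setdiff(sort(unique(as.vector(x))), 0L)
  cat(sprintf("<label_slice %dx%d px: %s>\n", nrow(x), ncol(x),
              paste(attr(x, "structure_names")[ids], collapse = ", ")))
  invisible(x)
}

#' @export
plot.bmode_image <- function(x, ...) {
  graphics::image(t(unclass(x))[, nrow(x):1], col = grey.colors(256, 0, 1),
                  zlim = c(0, 255), asp = nrow(x) / ncol(x), axes = FALSE, ...)
  invisible(x)
}

#' Add multiplicative speckle noise
#'
#' Cosmetic post-processing: each pixel is multiplied by `1 + sd * N(0,1)`
#' (seeded) and clipped to [0, 255]. `sd = 0` is the identity.
#'
#' @param image a `bmode_image`.
#' @param seed RNG seed.
#' @param sd relative noise standard deviation.
#' @export
add_speckle <- function(image, seed = 1L, sd = 0.1) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) return(image)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  noisy <- unclass(image) * (1 + sd * stats::rnorm(length(image)))
  out <- round(pmin(pmax(noisy, 0), 255))
  attributes(out) <- attributes(image)
  out
}

#' Per-structure pixel counts of a label slice
#'
#' @param slice a `label_slice`.
#' @return named integer vector over the model's structures.
#' @export
slice_pixel_counts <- function(slice) {
  nm <- attr(slice, "structure_names")
  counts <- tabulate(as.vector(slice), nbins = length(nm))
  stats::setNames(counts, nm)
}

#' Write a B-mode image as PNG with a JSON sidecar
#'
#' The sidecar records pose, probe and pixel spacing so a render can be
#' reproduced; label slices go to NRRD alongside.
#'
#' @param image a `bmode_image`.
#' @param path output PNG path.
#' @param label optional companion `label_slice`, written as NRRD with the
#'   structure-id map in the header.
#' @export
write_bmode <- function(image, path, label = NULL) {
  png::writePNG(unclass(image) / 255, path)
  probe <- attr(image, "probe")
  sidecar <- list(pixel_spacing_mm = attr(image, "pixel_spacing_mm"),
                  pose = as.vector(t(attr(image, "pose"))),
                  probe = unclass(probe))
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path),
                                       ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(label)) {
    nm <- attr(label, "structure_names")
    lv <- label_volume(array(as.integer(label), c(dim(label), 1L)),
                       c(attr(label, "pixel_spacing_mm"),
                         attr(label, "pixel_spacing_mm"), 1),
                       c(0, 0, 0), stats::setNames(seq_along(nm), nm))
    write_volume(lv, paste0(tools::file_path_sans_ext(path), "_label.nrrd"))
  }
  invisible(path)
}
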