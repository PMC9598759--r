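#' Threshold a cast-CT grey volume
#'
#' The cast volume is two-phase (resin versus air), so a global threshold is
#' a faithful stand-in for interactive segmentation: a voxel is foreground
#' iff its intensity is at least `threshold`.
#'
#' @param grey a `grey_volume` (see [add_acquisition_noise()]).
#' @param threshold intensity cutoff.
#' @return logical 3D array with the grid geometry attached.
#' @export
threshold_cast <- function(grey, threshold) {
  structure(list(array = grey$array >= threshold, spacing = grey$spacing,
                 origin = grey$origin), class = "binary_volume")
}

#' Connected-component labeling of a binary volume
#'
#' Components are enumerated deterministically: labels are assigned by
#' descending voxel count, ties broken by the first voxel in scan order.
#' Components smaller than `min_voxels` are discarded.
#'
#' @param binary a binary volume from [threshold_cast()] (or a logical array
#'   with `spacing`/`origin`).
#' @param connectivity 6 or 26.
#' @param min_voxels minimum component size kept.
#' @return a [label_volume()] with numeric component names.
#' @export
label_components <- function(binary, connectivity = 6, min_voxels = 1) {
  if (!connectivity %in% c(6, 26))
    stop("connectivity must be 6 or 26", call. = FALSE)
  if (!any(binary$array)) stop("empty foreground", call. = FALSE)
  dims <- dim(binary$array)
  lab <- cpp_connected_components(as.vector(binary$array), dims,
                                  as.integer(connectivity))
  sizes <- tabulate(lab)
  drop <- which(sizes < min_voxels)
  if (length(drop)) {
    lab[lab %in% drop] <- 0L
    keep <- which(sizes >= min_voxels)
    lab <- match(lab, keep, nomatch = 0L)  # keep is sorted: order preserved
  }
  nlab <- max(lab)
  label_volume(array(lab, dims), binary$spacing, binary$origin,
               stats::setNames(seq_len(nlab), paste0("component_", seq_len(nlab))))
}

#' Dice coefficient between two masks
#'
#' @param a,b logical arrays of identical shape.
#' @export
dice <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(NA_real_)
  2 * sum(a & b) / s
}

#' Rename components by maximal overlap with a reference
#'
#' Each component takes the name of the reference label with which it has
#' the largest Dice coefficient; components overlapping no reference label
#' keep their numeric component names. The automated surrogate for manual
#' anatomical naming.
#'
#' @param components a [label_volume()] of components.
#' @param reference a [label_volume()] of ground-truth structure labels on
#'   the same grid.
#' @return `components` with renamed `label_map`; the matching table is in
#'   attribute `"matching"` (component, matched name, Dice).
#' @export
match_labels <- function(components, reference) {
  if (!identical(dim(components$array), dim(reference$array)))
    stop("component and reference grids differ", call. = FALSE)
  comp_names <- names(components$label_map)
  out_names <- comp_names
  rows <- list()
  for (i in seq_along(components$label_map)) {
    cl <- components$label_map[[i]]
    cmask <- components$array == cl
    best <- NA_character_; best_d <- 0
    for (nm in names(reference$label_map)) {
      d <- dice(cmask, reference$array == reference$label_map[[nm]])
      if (!is.na(d) && d > best_d) {
        best_d <- d
        best <- nm
      }
    }
    if (!is.na(best)) out_names[i] <- best
    rows[[i]] <- data.frame(component = comp_names[i],
                            matched = if (is.na(best)) NA_character_ else best,
                            dice = best_d)
  }
  names(components$label_map) <- out_names
  attr(components, "matching") <- do.call(rbind, rows)
  components
}

#' Reference-guided delineation of a thresholded cast volume
#'
#' The synthetic heart's lumens are connected at their junctions, so plain
#' connected components collapse them into one object; anatomical naming
#' needs a reference. This surrogate for manual delineation assigns each
#' thresholded foreground voxel the reference label at that voxel; foreground
#' with no reference label keeps its connected-component number (offset past
#' the reference labels).
#'
#' @param binary thresholded volume from [threshold_cast()].
#' @param reference ground-truth [label_volume()] on the same grid.
#' @return a [label_volume()] with the reference's structure names.
#' @export
segment_volume <- function(binary, reference) {
  if (!identical(dim(binary$array), dim(reference$array)))
    stop("grids differ", call. = FALSE)
  lab <- ifelse(binary$array, reference$array, 0L)
  lm <- reference$label_map
  orphan <- binary$array & reference$array == 0L
  if (any(orphan)) {
    comp <- cpp_connected_components(as.vector(orphan), dim(binary$array), 6L)
    nref <- max(lm, 0L)
    extra <- max(comp)
    lab[orphan] <- comp[as.vector(orphan)] + nref
    lm <- c(lm, stats::setNames(nref + seq_len(extra),
                                paste0("component_", seq_len(extra))))
  }
  label_volume(array(as.integer(lab), dim(binary$array)), binary$spacing,
               binary$origin, lm)
}

#' Extract per-structure surfaces from a label volume
#'
#' Runs marching tetrahedra at the 0.5 level on each per-label mask (padded
#' by one voxel so surfaces touching the volume border still close), then
#' optionally applies Taubin smoothing. Extracted surfaces are watertight
#' and feed the ultrasound simulator directly.
#'
#' @param vol a [label_volume()].
#' @param smoothing_iters Taubin lambda/mu iteration pairs (0 = raw
#'   marching-tetrahedra surface).
#' @param material_for optional function(name) returning a material id.
#' @return a [heart_model()].
#' @export
extract_surfaces <- function(vol, smoothing_iters = 25, material_for = NULL) {
  labs <- vol$label_map
  if (!length(labs)) stop("label volume has no nonzero labels", call. = FALSE)
  dims <- dim(vol$array)
  structures <- list()
  for (nm in names(labs)) {
    mask <- vol$array == labs[[nm]]
    if (!any(mask)) next
    padded <- array(0, dims + 2L)
    padded[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- mask
    res <- cpp_marching_tets(as.vector(padded), dims + 2L,
                             vol$origin - vol$spacing, vol$spacing, 0.5)
    m <- mesh(res$vertices, res$faces)
    if (smoothing_iters > 0) m <- mesh_smooth(m, smoothing_iters)
    mat <- if (is.null(material_for)) "blood_pool" else material_for(nm)
    structures[[length(structures) + 1L]] <-
      heart_structure(nm, m, material_id = mat)
  }
  heart_model(structures)
}

#' Per-label voxel volumes
#'
#' @param vol a [label_volume()].
#' @return named numeric vector of voxel-count volumes in mm^3.
#' @export
label_volumes <- function(vol) {
  vv <- prod(vol$spacing)
  counts <- tabulate(as.vector(vol$array), nbins = max(vol$label_map))
  stats::setNames(counts[vol$label_map] * vv, names(vol$label_map))
}
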