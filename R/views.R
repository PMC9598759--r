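#' View specifications
#'
#' A view spec names a probe pose (relative to the canonical heart frame)
#' together with the structures a correctly acquired plane must show (and,
#' optionally, must not show). The eight standard fetal echocardiography
#' views ship as a YAML data file with poses as 16 row-major numbers.
#'
#' @param name view name.
#' @param pose 4x4 probe pose in the heart frame.
#' @param required character vector of structure names that must appear.
#' @param forbidden optional structure names that must not appear.
#' @export
view_spec <- function(name, pose, required, forbidden = character(0)) {
  assert_pose(pose)
  if (!length(required)) stop("required_structures must be nonempty",
                              call. = FALSE)
  structure(list(name = name, pose = pose, required = required,
                 forbidden = forbidden), class = "view_spec")
}

#' @export
print.view_spec <- function(x, ...) {
  cat(sprintf("<view_spec '%s': requires %s%s>\n", x$name,
              paste(x$required, collapse = ", "),
              if (length(x$forbidden))
                paste0("; forbids ", paste(x$forbidden, collapse = ", "))
              else ""))
  invisible(x)
}

load_view_library <- function(file) {
  y <- yaml::read_yaml(file)
  specs <- lapply(y, function(e)
    view_spec(e$name, matrix(as.numeric(e$pose), 4, 4, byrow = TRUE),
              unlist(e$required),
              if (is.null(e$forbidden)) character(0) else unlist(e$forbidden)))
  stats::setNames(specs, vapply(specs, function(s) s$name, ""))
}

#' The eight standard fetal echocardiography views
#'
#' Preset poses and required-structure sets for the four-chamber, left and
#' right ventricular outflow tract, three-vessel, three-vessels-and-trachea,
#' aortic arch, ductal and bicaval views, defined against the canonical
#' heart frame of the synthetic models.
#'
#' @return named list of 8 [view_spec()] objects.
#' @export
standard_views <- function() {
  load_view_library(system.file("extdata", "views.yaml", package = "vfecho",
                                mustWork = TRUE))
}

#' Lesion-sensitive views for the pathology cases
#'
#' For the double aortic arch: a transverse plane cephalad of the
#' three-vessel-trachea level showing the two arch cross-sections, and a
#' coronal plane showing both arches joining the descending aorta. For the
#' hypoplastic right heart case: the four-chamber plane (RV smaller than
#' LV), a plane along the septal channel, and a plane at the blind origin of
#' the pulmonary trunk.
#'
#' @param case_kind "double_aortic_arch" or "hrh_vsd_mga_pa"; the normal
#'   case has no lesion views (empty list).
#' @return named list of [view_spec()] objects.
#' @export
lesion_views <- function(case_kind) {
  if (case_kind == "normal") return(list())
  if (!case_kind %in% c("double_aortic_arch", "hrh_vsd_mga_pa"))
    stop("unknown case: ", case_kind, call. = FALSE)
  lib <- load_view_library(system.file("extdata", "lesion_views.yaml",
                                       package = "vfecho", mustWork = TRUE))
  pref <- if (case_kind == "double_aortic_arch") "darch_" else "hrh_"
  lib[startsWith(names(lib), pref)]
}

#' Default probe used for view verification
#'
#' Linear array fully covering the mid-gestation heart: 60 mm footprint and
#' depth, 128 scan lines, 200 samples, 200 x 200 px at 0.3 mm.
#'
#' @export
default_view_probe <- function() {
  probe_config(kind = "linear", n_scanlines = 128, scanline_depth_mm = 60,
               samples_per_line = 200, image_width_px = 200,
               image_height_px = 200, pixel_spacing_mm = 0.3,
               footprint_mm = 60, interpolation = "nearest")
}

#' Verify that a slice shows a view's required structures
#'
#' Passes iff every required structure covers at least `min_pixels` pixels
#' of the label slice and every forbidden structure covers fewer. Counts
#' come from the ground-truth label slice, never the grey image.
#'
#' @param slice a `label_slice` from [simulate_bmode()].
#' @param spec a [view_spec()].
#' @param min_pixels pixel threshold.
#' @return a `view_report`: list with `pass`, `counts`, `required`,
#'   `forbidden`, `min_pixels`.
#' @export
verify_view <- function(slice, spec, min_pixels = 30) {
  counts <- slice_pixel_counts(slice)
  unknown <- setdiff(c(spec$required, spec$forbidden), names(counts))
  if (length(unknown))
    stop("unknown structure name(s) in view spec: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  pass <- all(counts[spec$required] >= min_pixels) &&
    (!length(spec$forbidden) || all(counts[spec$forbidden] < min_pixels))
  structure(list(view = spec$name, pass = pass, counts = counts,
                 required = spec$required, forbidden = spec$forbidden,
                 min_pixels = min_pixels), class = "view_report")
}

#' @export
print.view_report <- function(x, ...) {
  cat(sprintf("<view_report '%s': %s; %s>\n", x$view,
              if (x$pass) "PASS" else "FAIL",
              paste(sprintf("%s=%d", x$required, x$counts[x$required]),
                    collapse = " ")))
  invisible(x)
}

view_score <- function(slice, spec, min_pixels) {
  counts <- slice_pixel_counts(slice)
  sum(pmin(counts[spec$required], min_pixels)) -
    sum(pmin(counts[spec$forbidden], min_pixels))
}

#' Local search for a passing probe pose
#'
#' Seeded stochastic hill climbing around the spec's preset pose: random
#' rigid perturbations are accepted when they improve the verification
#' score (required-structure coverage capped at `min_pixels`, forbidden
#' coverage penalized). Returns a passing pose as soon as one is found, or
#' the best pose seen within the budget.
#'
#' @param model a [heart_model()].
#' @param spec a [view_spec()].
#' @param probe probe config (default [default_view_probe()]).
#' @param materials material table.
#' @param search_budget number of pose evaluations (>= 1).
#' @param min_pixels verification threshold.
#' @param step_mm translation perturbation scale.
#' @param step_deg rotation perturbation scale (degrees).
#' @param seed RNG seed.
#' @return the selected pose with the final `view_report` in attribute
#'   `"report"`.
#' @export
find_view <- function(model, spec, probe = default_view_probe(),
                      materials = default_materials(), search_budget = 200,
                      min_pixels = 30, step_mm = 1, step_deg = 3, seed = 1L) {
  if (search_budget < 1) stop("search_budget must be >= 1", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  evaluate <- function(pose) {
    sl <- simulate_bmode(model, pose, probe, materials)$label
    list(report = verify_view(sl, spec, min_pixels),
         score = view_score(sl, spec, min_pixels))
  }
  best_pose <- spec$pose
  best <- evaluate(best_pose)
  k <- 1
  while (k < search_budget && !best$report$pass) {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::rnorm(1, 0, step_deg) * pi / 180
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
                byrow = TRUE)
    Rp <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    cand <- best_pose
    cand[1:3, 1:3] <- Rp %*% cand[1:3, 1:3]
    cand[1:3, 4] <- cand[1:3, 4] + stats::rnorm(3, 0, step_mm)
    ev <- evaluate(cand)
    k <- k + 1
    if (ev$score > best$score) {
      best <- ev
      best_pose <- cand
    }
  }
  attr(best_pose, "report") <- best$report
  best_pose
}

# 2D connected components of a structure mask on a label slice
# (4-connectivity via the 3D labeller on a single-slice volume).
slice_components <- function(slice, structures) {
  nm <- attr(slice, "structure_names")
  ids <- match(structures, nm)
  if (anyNA(ids)) stop("unknown structure name(s): ",
                       paste(structures[is.na(ids)], collapse = ", "),
                       call. = FALSE)
  mask <- matrix(as.vector(slice) %in% ids, nrow(slice), ncol(slice))
  comp <- cpp_connected_components(as.vector(mask),
                                   c(dim(slice), 1L), 6L)
  matrix(comp, nrow(slice), ncol(slice))
}

#' Count disjoint regions of a set of structures in a slice
#'
#' 4-connected component count of the pixels labeled with any of the given
#' structures (e.g. the two arch cross-sections of a double aortic arch in
#' a transverse plane).
#'
#' @param slice a `label_slice`.
#' @param structures structure names forming the mask.
#' @export
count_slice_regions <- function(slice, structures) {
  max(slice_components(slice, structures), 0L)
}

#' Are two structures connected through a channel in a slice?
#'
#' TRUE when pixels of `a` and pixels of `b` fall in one 4-connected
#' component of the union mask `a + b + via` (e.g. LV and RV joined through
#' a ventricular septal defect).
#'
#' @param slice a `label_slice`.
#' @param a,b structure names.
#' @param via additional bridging structures included in the mask.
#' @export
slice_connected <- function(slice, a, b, via = character(0)) {
  comp <- slice_components(slice, c(a, b, via))
  nm <- attr(slice, "structure_names")
  ca <- unique(comp[as.vector(slice) == match(a, nm)])
  cb <- unique(comp[as.vector(slice) == match(b, nm)])
  length(intersect(setdiff(ca, 0L), setdiff(cb, 0L))) > 0
}

#' Are two structures' pixel regions 4-adjacent in a slice?
#'
#' TRUE when some pixel of `a` touches a pixel of `b` horizontally or
#' vertically (used to show the atretic pulmonary trunk is not connected to
#' the ventricle).
#'
#' @param slice a `label_slice`.
#' @param a,b structure names.
#' @export
slice_adjacent <- function(slice, a, b) {
  nm <- attr(slice, "structure_names")
  ia <- match(a, nm); ib <- match(b, nm)
  if (is.na(ia) || is.na(ib))
    stop("unknown structure name", call. = FALSE)
  M <- unclass(slice)
  H <- nrow(M); W <- ncol(M)
  horiz <- (M[, -W] == ia & M[, -1] == ib) | (M[, -W] == ib & M[, -1] == ia)
  vert <- (M[-H, ] == ia & M[-1, ] == ib) | (M[-H, ] == ib & M[-1, ] == ia)
  any(horiz) || any(vert)
}
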