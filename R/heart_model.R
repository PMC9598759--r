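#' Multi-structure heart models
#'
#' A heart model is an ordered collection of named cardiovascular structures,
#' each a watertight outward-oriented triangle mesh with a material id and an
#' integer priority used to resolve overlaps (higher priority wins; ties go
#' to the earlier structure). All meshes share one anatomical frame:
#' x = fetal left, y = fetal posterior, z = fetal cephalad, origin at the
#' crux of the four-chamber plane, units mm.
#'
#' @param structures list of [heart_structure()] objects.
#' @param frame_note free-text description of the axes convention.
#' @export
heart_model <- function(structures,
                        frame_note = "x=left, y=posterior, z=cephalad, mm") {
  if (!length(structures)) stop("heart model needs >= 1 structure", call. = FALSE)
  nm <- vapply(structures, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("duplicate structure name: ",
                              nm[duplicated(nm)][1], call. = FALSE)
  names(structures) <- nm
  structure(list(structures = structures, frame_note = frame_note),
            class = "heart_model")
}

#' @rdname heart_model
#' @param name anatomical label (LA, LV, AO, ... or user-defined).
#' @param mesh a watertight [mesh()].
#' @param material_id key into the material table.
#' @param priority integer overlap rank.
#' @param check validate watertightness/orientation (set `FALSE` only for
#'   deliberately broken fixtures).
#' @export
heart_structure <- function(name, mesh, material_id = "blood_pool",
                            priority = 1L, check = TRUE) {
  if (check && !mesh_is_watertight(mesh))
    stop("mesh for '", name, "' is not watertight/outward-oriented",
         call. = FALSE)
  structure(list(name = name, mesh = mesh, material_id = material_id,
                 priority = as.integer(priority)), class = "heart_structure")
}

#' @export
print.heart_model <- function(x, ...) {
  cat(sprintf("<heart_model: %d structures [%s]>\n", length(x$structures),
              paste(names(x$structures), collapse = ", ")))
  invisible(x)
}

#' @export
summary.heart_model <- function(object, ...) {
  df <- data.frame(
    name = names(object$structures),
    material = vapply(object$structures, function(s) s$material_id, ""),
    priority = vapply(object$structures, function(s) s$priority, 1L),
    vertices = vapply(object$structures, function(s) nrow(s$mesh$vertices), 1L),
    faces = vapply(object$structures, function(s) nrow(s$mesh$faces), 1L),
    volume_mm3 = vapply(object$structures, function(s) mesh_volume(s$mesh), 1),
    row.names = NULL)
  class(df) <- c("summary.heart_model", "data.frame")
  df
}

#' Names of structures in a model
#' @param model a heart model.
#' @export
structure_names <- function(model) names(model$structures)

#' Load a heart model from mesh files and a manifest
#'
#' The manifest maps structure names to mesh files, material ids and
#' priorities; as a file it is YAML of the form
#' `name: {file: ..., material_id: ..., priority: ...}`. Non-watertight
#' meshes are rejected unless `repair = TRUE`, which fills simple boundary
#' loops of at most 100 edges with a triangle fan.
#'
#' @param manifest path to a manifest YAML file, or an equivalent named list.
#' @param dir directory that mesh file paths are relative to (defaults to the
#'   manifest's directory).
#' @param repair attempt hole filling for small boundary loops.
#' @return a [heart_model()].
#' @export
load_model <- function(manifest, dir = NULL, repair = FALSE) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- yaml::read_yaml(manifest)
  }
  if (is.null(dir)) dir <- "."
  if (anyDuplicated(names(manifest)))
    stop("duplicate structure name in manifest", call. = FALSE)
  structures <- lapply(names(manifest), function(nm) {
    entry <- manifest[[nm]]
    path <- entry$file
    if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(dir, path)
    m <- read_mesh(path)
    if (!mesh_is_watertight(m)) {
      if (repair) m <- mesh_repair(m)
      if (!mesh_is_watertight(m))
        stop("mesh for '", nm, "' is not watertight (", path, ")",
             call. = FALSE)
    }
    heart_structure(nm, m,
                    material_id = entry$material_id %||% "blood_pool",
                    priority = entry$priority %||% 1L)
  })
  heart_model(structures)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a heart model as mesh files plus a manifest
#'
#' @param model a heart model.
#' @param dir output directory (created if needed).
#' @param format mesh format extension.
#' @return path of the manifest file.
#' @export
write_model <- function(model, dir, format = "stl") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (s in model$structures) {
    fn <- paste0(s$name, ".", format)
    write_mesh(s$mesh, file.path(dir, fn))
    manifest[[s$name]] <- list(file = fn, material_id = s$material_id,
                               priority = s$priority)
  }
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Repair small mesh holes
#'
#' Fills each boundary loop of at most `max_edges` edges with a triangle fan
#' around the loop centroid, then flips orientation if the repaired surface
#' has negative volume.
#'
#' @param m a mesh.
#' @param max_edges largest boundary loop that will be filled.
#' @export
mesh_repair <- function(m, max_edges = 100) {
  F <- m$faces
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  boundary <- he[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  V <- m$vertices
  while (nrow(boundary) > 0) {
    # walk one loop; boundary half-edges run opposite to face winding
    loop <- boundary[1, ]
    used <- 1L
    repeat {
      nxt <- which(boundary[, 1] == loop[length(loop)])
      nxt <- setdiff(nxt, used)[1]
      if (is.na(nxt)) break
      used <- c(used, nxt)
      if (boundary[nxt, 2] == loop[1]) break
      loop <- c(loop, boundary[nxt, 2])
    }
    if (length(loop) > max_edges)
      stop("boundary loop with ", length(loop), " edges exceeds repair limit",
           call. = FALSE)
    centroid <- colMeans(V[loop, , drop = FALSE])
    V <- rbind(V, centroid)
    cid <- nrow(V)
    lp <- c(loop, loop[1])
    newF <- cbind(lp[-length(lp)], cid, lp[-1])
    F <- rbind(F, newF)
    boundary <- boundary[-used, , drop = FALSE]
  }
  out <- mesh(V, F)
  if (mesh_volume(out) < 0) out$faces <- out$faces[, c(1, 3, 2)]
  out
}

#' Apply a rigid pose to every structure of a model
#'
#' @param model a heart model.
#' @param pose valid 4x4 pose.
#' @export
apply_pose <- function(model, pose) {
  assert_pose(pose)
  structures <- lapply(model$structures, function(s) {
    s$mesh <- mesh_transform(s$mesh, pose)
    s
  })
  heart_model(structures, model$frame_note)
}

#' Scale one structure about a center
#'
#' Calibration hook for cast perfusion-pressure distortion: chambers or
#' vessels inflated or shrunken by the casting process can be rescaled
#' individually (enclosed volume scales by `factor^3`).
#'
#' @param model a heart model.
#' @param name structure to scale.
#' @param factor positive scale factor.
#' @param center point the scaling pivots about (default: structure centroid).
#' @export
scale_structure <- function(model, name, factor, center = NULL) {
  if (!name %in% names(model$structures))
    stop("unknown structure: ", name, call. = FALSE)
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("scale factor must be a positive scalar", call. = FALSE)
  s <- model$structures[[name]]
  if (is.null(center)) center <- colMeans(s$mesh$vertices)
  model$structures[[name]]$mesh <- mesh_scale(s$mesh, factor, center)
  model
}

#' Material tables
#'
#' Materials drive the grey value of scan-line segments: each structure's
#' material has a display echogenicity `grey_value` (0-255) and an optional
#' exponential depth attenuation coefficient per mm of insonified tissue.
#' The `background` material fills samples outside every structure.
#'
#' @param materials named list; each element a list with `grey_value` and
#'   optionally `attenuation_per_mm`.
#' @param background background material (defaults to anechoic grey 0,
#'   matching the black surroundings of a blood-pool cast).
#' @export
material_table <- function(materials, background = list(grey_value = 0)) {
  norm <- function(m, id) {
    g <- m$grey_value
    if (is.null(g) || g < 0 || g > 255)
      stop("grey_value for '", id, "' must be in [0,255]", call. = FALSE)
    a <- m$attenuation_per_mm %||% 0
    if (a < 0) stop("attenuation_per_mm must be >= 0", call. = FALSE)
    list(grey_value = as.numeric(g), attenuation_per_mm = as.numeric(a))
  }
  materials <- mapply(norm, materials, names(materials), SIMPLIFY = FALSE)
  structure(list(materials = materials,
                 background = norm(background, "background")),
            class = "material_table")
}

#' Default material table for generated hearts
#'
#' Blood-pool structures render bright (the cast is the echogenic object);
#' the airway placeholder is darker; background is anechoic.
#'
#' @export
default_materials <- function() {
  material_table(list(
    chamber = list(grey_value = 210),
    appendage = list(grey_value = 190),
    great_vessel = list(grey_value = 170),
    vein = list(grey_value = 140),
    shunt = list(grey_value = 230),
    airway = list(grey_value = 60)))
}

#' Check that every material referenced by a model resolves
#'
#' @param model a heart model.
#' @param materials a [material_table()].
#' @export
check_materials <- function(model, materials) {
  ids <- unique(vapply(model$structures, function(s) s$material_id, ""))
  missing <- setdiff(ids, names(materials$materials))
  if (length(missing))
    stop("material id(s) not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
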