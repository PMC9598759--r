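#' Specification for a synthetic fetal heart
#'
#' Defines the procedural anatomy for one of three cases: a normal
#' mid-gestation heart, a double aortic arch (the ascending aorta splits into
#' left and right arches that both rejoin the descending aorta, encircling
#' the trachea), or hypoplastic right heart with ventricular septal defect,
#' malposed great arteries and pulmonary atresia. Absolute sizes default to
#' mid-gestation scale (ventricular long axis about 15 mm, great-vessel
#' diameters about 4 mm), consistent with 25-26 week anatomy.
#'
#' @param case_kind one of "normal", "double_aortic_arch", "hrh_vsd_mga_pa",
#'   "custom".
#' @param chamber_radii named equivalent-sphere radii (mm) for LA, RA, LV, RV.
#' @param vessel_radii named tube radii (mm).
#' @param rv_lv_ratio target RV/LV enclosed-volume ratio (hypoplasia control;
#'   used by the hrh case).
#' @param vsd_radius septal-channel radius in mm (0 = intact septum).
#' @param pa_atretic initial pulmonary-trunk segment disconnected from the
#'   ventricle (fed only via the ductus arteriosus).
#' @param aorta_from_rv aorta arises anteriorly from the right ventricle.
#' @param seed integer controlling the deterministic chamber deformation.
#' @param subdivisions icosphere subdivisions for chambers (tessellation
#'   resolution).
#' @param deform_amp relative amplitude of chamber surface deformation.
#' @export
synthetic_heart_spec <- function(case_kind = c("normal", "double_aortic_arch",
                                               "hrh_vsd_mga_pa", "custom"),
                                 chamber_radii = c(LA = 3.7, RA = 3.6,
                                                   LV = 5.5, RV = 5.3),
                                 vessel_radii = c(AO = 2.2, PA = 2.3,
                                                  Arch = 1.8, DAO = 2.0,
                                                  AoBs = 1.0, lPA = 1.2,
                                                  rPA = 1.2, DA = 1.6,
                                                  SVC = 1.7, IVC = 1.8,
                                                  Trachea = 1.0),
                                 rv_lv_ratio = 1.0, vsd_radius = 0,
                                 pa_atretic = FALSE, aorta_from_rv = FALSE,
                                 seed = 1L, subdivisions = 3,
                                 deform_amp = 0.05) {
  case_kind <- match.arg(case_kind)
  # case presets imply the malformation flags
  if (case_kind == "hrh_vsd_mga_pa") {
    if (rv_lv_ratio >= 1) rv_lv_ratio <- 0.4
    if (vsd_radius <= 0) vsd_radius <- 1.5
    pa_atretic <- TRUE
    aorta_from_rv <- TRUE
  }
  if (case_kind %in% c("normal", "double_aortic_arch")) {
    pa_atretic <- FALSE
    aorta_from_rv <- FALSE
    vsd_radius <- 0
  }
  defaults <- formals(synthetic_heart_spec)
  cr <- eval(defaults$chamber_radii); cr[names(chamber_radii)] <- chamber_radii
  vr <- eval(defaults$vessel_radii); vr[names(vessel_radii)] <- vessel_radii
  if (any(cr <= 0) || any(vr <= 0))
    stop("all radii must be > 0", call. = FALSE)
  if (vsd_radius < 0) stop("vsd_radius must be >= 0", call. = FALSE)
  if (rv_lv_ratio <= 0) stop("rv_lv_ratio must be > 0", call. = FALSE)
  if (vsd_radius > 0.6 * min(cr["LV"], cr["RV"] * rv_lv_ratio^(1 / 3)))
    stop("vsd_radius too large for the ventricles", call. = FALSE)
  structure(list(case_kind = case_kind, chamber_radii = cr, vessel_radii = vr,
                 rv_lv_ratio = rv_lv_ratio, vsd_radius = vsd_radius,
                 pa_atretic = pa_atretic, aorta_from_rv = aorta_from_rv,
                 seed = as.integer(seed), subdivisions = subdivisions,
                 deform_amp = deform_amp),
            class = "synthetic_heart_spec")
}

# Fixed chamber shape ratios (relative semi-axes, unit geometric mean).
chamber_shapes <- list(
  LA = c(1.10, 0.96, 0.96), RA = c(1.10, 0.94, 0.97),
  LV = c(0.826, 0.826, 1.468), RV = c(0.83, 0.83, 1.452))
chamber_centers <- list(
  LA = c(4, 5.5, 1), RA = c(-4, 5.5, 1),
  LV = c(5, -2, -2), RV = c(-4.5, -4, -2))

#' Generate a synthetic heart model
#'
#' Chambers are deformed ellipsoids; vessels are swept tubes whose endpoints
#' are embedded in the structures they connect to, so anatomical continuity
#' (e.g. the ductus joining pulmonary trunk to descending aorta) is
#' detectable as mesh overlap. Deterministic for a fixed spec and seed.
#'
#' @param spec a [synthetic_heart_spec()].
#' @return a [heart_model()] carrying the spec as attribute `"spec"`.
#' @export
generate_heart <- function(spec = synthetic_heart_spec()) {
  if (!inherits(spec, "synthetic_heart_spec"))
    stop("spec must be a synthetic_heart_spec", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  cr <- spec$chamber_radii
  vr <- spec$vessel_radii
  sub <- spec$subdivisions
  n_around <- 16L
  st <- list()
  add <- function(name, mesh, material, priority) {
    st[[length(st) + 1L]] <<- heart_structure(name, mesh, material, priority)
  }
  chamber <- function(name) {
    coef <- stats::runif(6, -1, 1)
    mesh_ellipsoid(chamber_shapes[[name]] * cr[[name]],
                   chamber_centers[[name]], sub,
                   deform_amp = spec$deform_amp, deform_coef = coef)
  }
  tube <- function(wp, r) mesh_tube(wp, r, n_around = n_around)

  # -- chambers -------------------------------------------------------
  lv <- chamber("LV")
  rv <- chamber("RV")
  if (spec$case_kind == "hrh_vsd_mga_pa" || spec$rv_lv_ratio != 1) {
    target <- spec$rv_lv_ratio * mesh_volume(lv)
    rv <- mesh_scale(rv, (target / mesh_volume(rv))^(1 / 3),
                     chamber_centers$RV)
  }
  add("LA", chamber("LA"), "chamber", 15L)
  add("LAA", mesh_ellipsoid(c(2.0, 1.5, 1.5) * cr[["LA"]] / 3.7,
                            c(7.5, 3.0, 3.0), sub), "appendage", 12L)
  add("RA", chamber("RA"), "chamber", 15L)
  add("RAA", mesh_ellipsoid(c(2.0, 1.5, 1.5) * cr[["RA"]] / 3.6,
                            c(-7.5, 3.0, 3.0), sub), "appendage", 12L)
  add("LV", lv, "chamber", 15L)
  add("RV", rv, "chamber", 15L)

  # -- great arteries -------------------------------------------------
  ao_wp <- if (spec$aorta_from_rv) {
    rbind(c(-4, -4.3, 0.5), c(-3, -4, 5), c(-1, -1.8, 8.5), c(1, 0, 10))
  } else {
    rbind(c(4, -1, 2), c(3.2, -1, 5.5), c(1, 0, 10))
  }
  add("AO", tube(ao_wp, vr[["AO"]]), "great_vessel", 22L)

  if (spec$case_kind == "double_aortic_arch") {
    add("Arch", tube(rbind(c(1.4, 0.2, 9.0), c(2.6, 1.2, 11.5),
                           c(2.6, 3.8, 11.5), c(1.6, 5.0, 10.6)),
                     vr[["Arch"]] * 0.85), "great_vessel", 25L)
    add("RArch", tube(rbind(c(0.0, 0.2, 9.0), c(-2.8, 1.2, 11.5),
                            c(-2.8, 3.8, 11.5), c(-1.6, 5.0, 10.6)),
                      vr[["Arch"]] * 0.85), "great_vessel", 25L)
  } else {
    add("Arch", tube(rbind(c(1.2, 0.2, 9.8), c(2.0, 1.5, 11.3),
                           c(1.6, 3.5, 11.3), c(0.5, 5.0, 10.6)),
                     vr[["Arch"]]), "great_vessel", 25L)
  }
  add("DAO", tube(rbind(c(0, 5.2, 11.0), c(0, 6.2, 6), c(0, 6.8, 0),
                        c(0, 6.8, -12)), vr[["DAO"]]), "great_vessel", 22L)
  add("AoBs", tube(rbind(c(1.6, 1.8, 11.2), c(1.6, 1.5, 16)), vr[["AoBs"]]),
      "great_vessel", 32L)

  pa_wp <- if (spec$pa_atretic) {
    rbind(c(-2.0, -0.8, 6.5), c(-1.5, -1, 9))
  } else {
    rbind(c(-3, -3, 2), c(-2.5, -2.2, 5.5), c(-1.5, -1, 9))
  }
  add("PA", tube(pa_wp, vr[["PA"]]), "great_vessel", 23L)
  add("lPA", tube(rbind(c(-1.8, -0.9, 8.8), c(-4, 0.5, 8.4),
                        c(-6.5, 1.5, 8.2)), vr[["lPA"]]), "great_vessel", 32L)
  add("rPA", tube(rbind(c(-1.5, -0.8, 8.7), c(0.5, 0.6, 8.2),
                        c(4.5, 1.8, 8.0)), vr[["rPA"]]), "great_vessel", 32L)
  add("DA", tube(rbind(c(-1.5, -0.8, 9.0), c(-0.8, 2.0, 9.5),
                       c(0, 4.8, 9.8)), vr[["DA"]]), "great_vessel", 32L)

  # -- veins and airway ----------------------------------------------
  add("SVC", tube(rbind(c(-4, 4.3, 12.5), c(-4, 4.8, 8), c(-4, 5.2, 3)),
                  vr[["SVC"]]), "vein", 30L)
  add("IVC", tube(rbind(c(-4, 5.8, -2), c(-3.5, 6.2, -7), c(-3, 6.5, -12)),
                  vr[["IVC"]]), "vein", 30L)
  add("Trachea", tube(rbind(c(-1.2, 2.8, 5.5), c(-1.2, 2.8, 16)),
                      vr[["Trachea"]]), "airway", 35L)

  # -- septal defect --------------------------------------------------
  if (spec$vsd_radius > 0)
    add("VSD", tube(rbind(c(3.5, -2.4, -2), c(-2.5, -3.6, -2)),
                    spec$vsd_radius), "shunt", 60L)

  model <- heart_model(st)
  attr(model, "spec") <- spec
  model
}

#' Structure adjacency graph
#'
#' Two structures are adjacent when their meshes overlap (a vertex of one
#' lies inside the other). Vessel continuity in the generator is modeled by
#' embedding tube endpoints inside their partner structures, so e.g. the
#' ductus arteriosus is adjacent to both the pulmonary trunk and the
#' descending aorta.
#'
#' @param model a heart model.
#' @return an [igraph::graph] with one vertex per structure.
#' @export
structure_adjacency <- function(model) {
  nm <- structure_names(model)
  n <- length(nm)
  boxes <- lapply(model$structures, function(s)
    rbind(apply(s$mesh$vertices, 2, min), apply(s$mesh$vertices, 2, max)))
  bvhs <- lapply(model$structures, function(s)
    cpp_bvh_build(s$mesh$vertices, s$mesh$faces, integer(0)))
  inside_any <- function(i, j) {
    # any vertex of i inside mesh j
    V <- model$structures[[i]]$mesh$vertices
    b <- boxes[[j]]
    sel <- V[, 1] >= b[1, 1] & V[, 1] <= b[2, 1] &
           V[, 2] >= b[1, 2] & V[, 2] <= b[2, 2] &
           V[, 3] >= b[1, 3] & V[, 3] <= b[2, 3]
    if (!any(sel)) return(FALSE)
    any(cpp_point_in_mesh(bvhs[[j]], V[sel, , drop = FALSE]))
  }
  edges <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    bi <- boxes[[i]]; bj <- boxes[[j]]
    if (any(bi[1, ] > bj[2, ]) || any(bj[1, ] > bi[2, ])) next
    if (inside_any(i, j) || inside_any(j, i))
      edges <- c(edges, nm[i], nm[j])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nm)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

#' Detect a vascular ring in the arch system
#'
#' Restricted to the arch structures (ascending/descending aorta and any
#' arch segments), reports whether the adjacency graph contains a cycle,
#' i.e. two vertex-disjoint arch paths from the ascending to the descending
#' aorta as in a double aortic arch.
#'
#' @param model a heart model (or a precomputed adjacency graph).
#' @export
has_vascular_ring <- function(model) {
  g <- if (inherits(model, "igraph")) model else structure_adjacency(model)
  keep <- intersect(c("AO", "Arch", "RArch", "DAO"), igraph::V(g)$name)
  sg <- igraph::induced_subgraph(g, keep)
  igraph::gsize(sg) >= igraph::gorder(sg) &&
    all(c("AO", "DAO") %in% keep) &&
    igraph::vertex_disjoint_paths(sg, which(igraph::V(sg)$name == "AO"),
                                  which(igraph::V(sg)$name == "DAO")) >= 2
}

#' Label volumes
#'
#' A 3D integer label grid emulating a segmented cast-CT scan: 0 is
#' background, positive labels index structures via `label_map`. `origin` is
#' the center of the first voxel; `spacing` is per-axis voxel size in mm.
#'
#' @param array 3D integer array.
#' @param spacing length-3 voxel spacing (mm).
#' @param origin length-3 position of the first voxel center (mm).
#' @param label_map named integer vector: `label_map[name] = label`.
#' @export
label_volume <- function(array, spacing, origin, label_map = integer(0)) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive values", call. = FALSE)
  labs <- sort(unique(as.vector(array)))
  labs <- labs[labs != 0]
  if (length(setdiff(labs, label_map)))
    stop("labels present in array but missing from label_map", call. = FALSE)
  structure(list(array = array, spacing = spacing,
                 origin = as.numeric(origin), label_map = label_map),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume: %s voxels @ (%s) mm, %d labels>\n",
              paste(dim(x$array), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              length(x$label_map)))
  invisible(x)
}

#' Rasterize a heart model into a label volume
#'
#' Emulates the CT digitization of a cardiovascular cast: each voxel takes
#' the label of the structure containing its center, with overlaps resolved
#' by structure priority (ties by declaration order). The grid covers the
#' model bounding box plus `margin` on every side.
#'
#' @param model a heart model.
#' @param spacing voxel spacing in mm; the cast-CT emulation default follows
#'   in-plane 0.4 mm with 0.6 mm slice thickness.
#' @param margin empty border in mm.
#' @return a [label_volume()].
#' @export
rasterize <- function(model, spacing = c(0.4, 0.4, 0.6), margin = 2) {
  if (!length(model$structures)) stop("empty model", call. = FALSE)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  allV <- do.call(rbind, lapply(model$structures, function(s) s$mesh$vertices))
  lo <- apply(allV, 2, min) - margin
  hi <- apply(allV, 2, max) + margin
  dims <- as.integer(floor((hi - lo) / spacing)) + 1L
  origin <- lo
  lab <- integer(prod(dims))
  pri <- integer(prod(dims))
  nm <- structure_names(model)
  for (i in seq_along(model$structures)) {
    s <- model$structures[[i]]
    m <- cpp_voxelize_mask(s$mesh$vertices, s$mesh$faces, origin, spacing, dims)
    win <- m & (lab == 0L | s$priority > pri)
    lab[win] <- i
    pri[win] <- s$priority
  }
  label_volume(array(lab, dims), spacing, origin,
               stats::setNames(seq_along(nm), nm))
}

#' Simulate CT acquisition intensities over a label volume
#'
#' Maps each label to a mean intensity and adds seeded Gaussian noise,
#' producing the grey volume that the segmentation module consumes.
#'
#' @param vol a [label_volume()].
#' @param intensity_map named intensities per structure name; the `air` entry
#'   is used for background (label 0).
#' @param noise_sd Gaussian noise standard deviation (same units).
#' @param seed RNG seed.
#' @return a `grey_volume`: list with `array`, `spacing`, `origin`.
#' @export
add_acquisition_noise <- function(vol, intensity_map = NULL, noise_sd = 0,
                                  seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(intensity_map))
    intensity_map <- c(air = -1000,
                       stats::setNames(rep(800, length(vol$label_map)),
                                       names(vol$label_map)))
  lut <- numeric(length(vol$label_map) + 1L)
  lut[1] <- intensity_map[["air"]]
  for (nm in names(vol$label_map))
    lut[vol$label_map[[nm]] + 1L] <- intensity_map[[nm]]
  g <- lut[as.vector(vol$array) + 1L]
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    g <- g + stats::rnorm(length(g), 0, noise_sd)
  }
  structure(list(array = array(g, dim(vol$array)), spacing = vol$spacing,
                 origin = vol$origin), class = "grey_volume")
}
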