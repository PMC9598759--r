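#' Transducer and image geometry
#'
#' Defines the scan-line layout and the output pixel grid. The probe contact
#' point is at the top-center of the image; image x is lateral, image y is
#' depth; pixel (1,1) has its center at the top-left, pixel indices map to mm
#' via `pixel_spacing_mm`. For a linear array, `n_scanlines` parallel lines
#' span `footprint_mm`; for a curvilinear array, line origins sit on the
#' transducer arc of radius `transducer_radius_mm` and directions fan evenly
#' over `fov_deg` centered on the probe axis.
#'
#' @param kind "linear" or "curvilinear".
#' @param n_scanlines number of scan lines (>= 1).
#' @param scanline_depth_mm imaging depth along each line.
#' @param samples_per_line intensity samples per line.
#' @param image_width_px,image_height_px output image size.
#' @param pixel_spacing_mm square pixel size in mm.
#' @param footprint_mm linear-array width (linear only).
#' @param fov_deg opening angle in degrees (curvilinear only).
#' @param transducer_radius_mm arc radius (curvilinear only).
#' @param interpolation "nearest" or "bilinear" scan conversion.
#' @export
probe_config <- function(kind = c("linear", "curvilinear"),
                         n_scanlines = 128, scanline_depth_mm = 60,
                         samples_per_line = 200,
                         image_width_px = 200, image_height_px = 200,
                         pixel_spacing_mm = 0.3,
                         footprint_mm = 60, fov_deg = 60,
                         transducer_radius_mm = 40,
                         interpolation = c("nearest", "bilinear")) {
  kind <- match.arg(kind)
  interpolation <- match.arg(interpolation)
  if (n_scanlines < 1 || samples_per_line < 1 || image_width_px < 1 ||
      image_height_px < 1)
    stop("counts must be >= 1", call. = FALSE)
  if (scanline_depth_mm <= 0 || pixel_spacing_mm <= 0)
    stop("depth and pixel spacing must be > 0", call. = FALSE)
  if (kind == "curvilinear" && (fov_deg <= 0 || fov_deg >= 180))
    stop("fov_deg must be in (0, 180)", call. = FALSE)
  if (kind == "curvilinear" && transducer_radius_mm <= 0)
    stop("transducer_radius_mm must be > 0", call. = FALSE)
  if (kind == "linear" && footprint_mm <= 0)
    stop("footprint_mm must be > 0", call. = FALSE)
  structure(list(kind = kind, n_scanlines = as.integer(n_scanlines),
                 scanline_depth_mm = scanline_depth_mm,
                 samples_per_line = as.integer(samples_per_line),
                 image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px),
                 pixel_spacing_mm = pixel_spacing_mm,
                 footprint_mm = footprint_mm, fov_deg = fov_deg,
                 transducer_radius_mm = transducer_radius_mm,
                 interpolation = interpolation),
            class = "probe_config")
}

#' @export
print.probe_config <- function(x, ...) {
  cat(sprintf("<probe_config: %s, %d lines x %d samples, depth %g mm, image %dx%d @ %g mm>\n",
              x$kind, x$n_scanlines, x$samples_per_line, x$scanline_depth_mm,
              x$image_width_px, x$image_height_px, x$pixel_spacing_mm))
  invisible(x)
}

#' Scan-line layout in the image frame
#'
#' Lines live in the image plane (z = 0 of the probe frame). Linear arrays
#' produce parallel lines with origins spanning `[-footprint/2, footprint/2]`
#' inclusive and direction (0, 1, 0); curvilinear arrays place origins on the
#' transducer arc (arc center at (0, -radius, 0)) with radial directions at
#' angles evenly spanning the field of view, ordered left to right.
#'
#' @param probe a [probe_config()].
#' @return data frame: origin (`ox,oy,oz`), direction (`dx,dy,dz`), `length`,
#'   `sample_spacing_mm`.
#' @export
compute_scanlines <- function(probe) {
  n <- probe$n_scanlines
  ss <- if (probe$samples_per_line > 1)
    probe$scanline_depth_mm / (probe$samples_per_line - 1) else
    probe$scanline_depth_mm
  if (probe$kind == "linear") {
    x <- if (n == 1) 0 else seq(-probe$footprint_mm / 2,
                                probe$footprint_mm / 2, length.out = n)
    df <- data.frame(ox = x, oy = 0, oz = 0, dx = 0, dy = 1, dz = 0)
  } else {
    half <- probe$fov_deg / 2 * pi / 180
    th <- if (n == 1) 0 else seq(-half, half, length.out = n)
    R <- probe$transducer_radius_mm
    df <- data.frame(ox = R * sin(th), oy = R * cos(th) - R, oz = 0,
                     dx = sin(th), dy = cos(th), dz = 0)
  }
  df$length <- probe$scanline_depth_mm
  df$sample_spacing_mm <- ss
  df
}

#' Sample depths along a scan line
#'
#' Depths span `[0, depth]` inclusive when there is more than one sample.
#'
#' @param probe a [probe_config()].
#' @export
scanline_sample_depths <- function(probe) {
  if (probe$samples_per_line == 1) return(0)
  seq(0, probe$scanline_depth_mm, length.out = probe$samples_per_line)
}

#' Read a simulator configuration file (XML or YAML)
#'
#' The XML layout mirrors a probe/image/material configuration file:
#' ```
#' <VfEchoConfig>
#'   <Probe kind="curvilinear" n_scanlines="128" depth_mm="60"
#'          samples_per_line="200" fov_deg="60" transducer_radius_mm="40"/>
#'   <Image width_px="200" height_px="200" pixel_spacing_mm="0.3"
#'          interpolation="nearest"/>
#'   <Materials background_grey="0">
#'     <Material id="chamber" grey="210" attenuation_per_mm="0"/>
#'   </Materials>
#' </VfEchoConfig>
#' ```
#' The YAML equivalent uses keys `probe`, `image`, `materials`,
#' `background_grey`.
#'
#' @param path configuration file (`.xml`, `.yaml`, `.yml`).
#' @return list with elements `probe` ([probe_config()]) and `materials`
#'   ([material_table()]).
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xml") read_config_xml(path)
  else if (ext %in% c("yaml", "yml")) read_config_yaml(path)
  else stop("unsupported config format: ", ext, call. = FALSE)
}

num_or <- function(x, default) if (is.null(x) || is.na(x)) default else as.numeric(x)
chr_or <- function(x, default) if (is.null(x) || is.na(x)) default else x

read_config_xml <- function(path) {
  doc <- xml2::read_xml(path)
  p <- xml2::xml_find_first(doc, ".//Probe")
  i <- xml2::xml_find_first(doc, ".//Image")
  a <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) NULL else v
  }
  probe <- probe_config(
    kind = chr_or(a(p, "kind"), "linear"),
    n_scanlines = num_or(a(p, "n_scanlines"), 128),
    scanline_depth_mm = num_or(a(p, "depth_mm"), 60),
    samples_per_line = num_or(a(p, "samples_per_line"), 200),
    image_width_px = num_or(a(i, "width_px"), 200),
    image_height_px = num_or(a(i, "height_px"), 200),
    pixel_spacing_mm = num_or(a(i, "pixel_spacing_mm"), 0.3),
    footprint_mm = num_or(a(p, "footprint_mm"), 60),
    fov_deg = num_or(a(p, "fov_deg"), 60),
    transducer_radius_mm = num_or(a(p, "transducer_radius_mm"), 40),
    interpolation = chr_or(a(i, "interpolation"), "nearest"))
  mats <- xml2::xml_find_all(doc, ".//Material")
  ml <- list()
  for (m in mats)
    ml[[xml2::xml_attr(m, "id")]] <-
      list(grey_value = as.numeric(xml2::xml_attr(m, "grey")),
           attenuation_per_mm = num_or(a(m, "attenuation_per_mm"), 0))
  bg <- num_or(a(xml2::xml_find_first(doc, ".//Materials"), "background_grey"), 0)
  materials <- if (length(ml))
    material_table(ml, background = list(grey_value = bg)) else
    default_materials()
  list(probe = probe, materials = materials)
}

read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  pr <- y$probe %||% list()
  im <- y$image %||% list()
  probe <- probe_config(
    kind = pr$kind %||% "linear",
    n_scanlines = pr$n_scanlines %||% 128,
    scanline_depth_mm = pr$depth_mm %||% 60,
    samples_per_line = pr$samples_per_line %||% 200,
    image_width_px = im$width_px %||% 200,
    image_height_px = im$height_px %||% 200,
    pixel_spacing_mm = im$pixel_spacing_mm %||% 0.3,
    footprint_mm = pr$footprint_mm %||% 60,
    fov_deg = pr$fov_deg %||% 60,
    transducer_radius_mm = pr$transducer_radius_mm %||% 40,
    interpolation = im$interpolation %||% "nearest")
  materials <- if (!is.null(y$materials))
    material_table(y$materials,
                   background = list(grey_value = y$background_grey %||% 0))
  else default_materials()
  list(probe = probe, materials = materials)
}

#' Write a simulator configuration file
#'
#' @param probe a [probe_config()].
#' @param materials a [material_table()].
#' @param path output `.xml` or `.yaml` path.
#' @export
write_config <- function(probe, materials, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(list(
      probe = list(kind = probe$kind, n_scanlines = probe$n_scanlines,
                   depth_mm = probe$scanline_depth_mm,
                   samples_per_line = probe$samples_per_line,
                   footprint_mm = probe$footprint_mm, fov_deg = probe$fov_deg,
                   transducer_radius_mm = probe$transducer_radius_mm),
      image = list(width_px = probe$image_width_px,
                   height_px = probe$image_height_px,
                   pixel_spacing_mm = probe$pixel_spacing_mm,
                   interpolation = probe$interpolation),
      background_grey = materials$background$grey_value,
      materials = materials$materials), path)
    return(invisible(path))
  }
  if (ext != "xml") stop("unsupported config format: ", ext, call. = FALSE)
  doc <- xml2::xml_new_root("VfEchoConfig")
  xml2::xml_add_child(doc, "Probe", kind = probe$kind,
                      n_scanlines = probe$n_scanlines,
                      depth_mm = probe$scanline_depth_mm,
                      samples_per_line = probe$samples_per_line,
                      footprint_mm = probe$footprint_mm,
                      fov_deg = probe$fov_deg,
                      transducer_radius_mm = probe$transducer_radius_mm)
  xml2::xml_add_child(doc, "Image", width_px = probe$image_width_px,
                      height_px = probe$image_height_px,
                      pixel_spacing_mm = probe$pixel_spacing_mm,
                      interpolation = probe$interpolation)
  mats <- xml2::xml_add_child(doc, "Materials",
                              background_grey = materials$background$grey_value)
  for (id in names(materials$materials)) {
    m <- materials$materials[[id]]
    xml2::xml_add_child(mats, "Material", id = id, grey = m$grey_value,
                        attenuation_per_mm = m$attenuation_per_mm)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
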