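#' Fill one scan line with material grey values
#'
#' The sorted crossings divide the line into segments; each sample takes the
#' material of the highest-priority structure containing it (containment by
#' crossing parity per structure, with the start-inside state resolved by a
#' point-in-mesh test at the line origin). Intensity is the material's grey
#' value, optionally multiplied by `exp(-attenuation_per_mm * cumulative
#' in-tissue path)`; samples outside all structures get the background grey.
#'
#' @param crossings data frame (`distance`, `structure`, `entering`) for this
#'   line, as one ray of [intersect_scanlines()].
#' @param line one row of [compute_scanlines()] (origin, direction, length,
#'   sample spacing), or a list with those fields.
#' @param model the posed [heart_model()] (image frame).
#' @param materials a [material_table()].
#' @param depths sample depths; defaults to even spacing over the line.
#' @param start_inside optional named logical vector: containment of the line
#'   origin per structure (computed if missing).
#' @return list: `intensity` (per sample), `label` (structure index per
#'   sample, 0 = background).
#' @export
# Collapse coincident crossings of one structure: a ray passing exactly
# through a shared vertex or edge reports one hit per incident triangle.
# Clusters (within tol) that agree in direction count once; mixed clusters
# are tangential grazes and cancel.
dedupe_crossings <- function(cr, tol = 1e-7) {
  if (!nrow(cr)) return(numeric(0))
  o <- order(cr$distance)
  ts <- cr$distance[o]
  ent <- cr$entering[o]
  cl <- cumsum(c(TRUE, diff(ts) > tol))
  out <- numeric(0)
  for (k in unique(cl)) {
    sel <- cl == k
    has_in <- any(ent[sel]); has_out <- any(!ent[sel])
    if (has_in != has_out) out <- c(out, ts[sel][1])
  }
  out
}

fill_scanline <- function(crossings, line, model, materials, depths = NULL,
                          start_inside = NULL) {
  nm <- structure_names(model)
  if (is.null(depths)) {
    ns <- max(2L, as.integer(round(line$length / line$sample_spacing_mm)) + 1L)
    depths <- seq(0, line$length, length.out = ns)
  }
  origin <- c(line$ox, line$oy, line$oz)
  dirv <- c(line$dx, line$dy, line$dz)
  if (is.null(start_inside)) {
    start_inside <- stats::setNames(rep(FALSE, length(nm)), nm)
    for (s in nm) {
      b <- apply(model$structures[[s]]$mesh$vertices, 2, range)
      if (all(origin >= b[1, ] - 1e-9) && all(origin <= b[2, ] + 1e-9))
        start_inside[s] <- point_in_mesh(model$structures[[s]]$mesh,
                                         matrix(origin, 1))
    }
  }
  pend <- origin + line$length * dirv
  nsmp <- length(depths)
  inside <- matrix(FALSE, nsmp, length(nm), dimnames = list(NULL, nm))
  intervals <- list()
  active <- unique(c(names(start_inside)[start_inside],
                     unique(crossings$structure)))
  for (s in active) {
    ts <- dedupe_crossings(crossings[crossings$structure == s, , drop = FALSE])
    s0 <- isTRUE(start_inside[[s]])
    # parity sanity: if the line exits the structure's bounding box, the
    # total crossing count must leave us outside
    b <- apply(model$structures[[s]]$mesh$vertices, 2, range)
    end_out <- any(pend < b[1, ] - 1e-6) || any(pend > b[2, ] + 1e-6)
    if (end_out && (length(ts) + s0) %% 2 == 1)
      stop("inconsistent crossing parity for structure '", s,
           "': mesh not watertight?", call. = FALSE)
    inside[, s] <- (findInterval(depths, ts) + s0) %% 2 == 1
    edges <- c(if (s0) 0, ts, if ((length(ts) + s0) %% 2 == 1) line$length)
    if (length(edges) >= 2)
      intervals[[s]] <- matrix(edges[seq_len(length(edges) %/% 2 * 2)],
                               ncol = 2, byrow = TRUE)
  }
  # priority resolution: higher priority wins, ties by declaration order
  pri <- vapply(model$structures, function(s) s$priority, 1L)
  ord <- order(-pri, seq_along(nm))
  label <- integer(nsmp)
  for (i in ord) {
    sel <- inside[, i] & label == 0L
    label[sel] <- i
  }
  # cumulative in-tissue path length (union of all structure intervals)
  cum <- numeric(nsmp)
  if (length(intervals)) {
    iv <- do.call(rbind, intervals)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    merged <- list()
    for (r in seq_len(nrow(iv))) {
      if (length(merged) && iv[r, 1] <= merged[[length(merged)]][2]) {
        merged[[length(merged)]][2] <- max(merged[[length(merged)]][2], iv[r, 2])
      } else merged[[length(merged) + 1L]] <- iv[r, ]
    }
    for (mg in merged)
      cum <- cum + pmax(0, pmin(depths, mg[2]) - mg[1])
  }
  mat_ids <- vapply(model$structures, function(s) s$material_id, "")
  grey <- numeric(nsmp) + materials$background$grey_value
  att <- numeric(nsmp) + materials$background$attenuation_per_mm
  hit <- label > 0L
  if (any(hit)) {
    mats <- materials$materials[mat_ids[label[hit]]]
    grey[hit] <- vapply(mats, function(m) m$grey_value, 1)
    att[hit] <- vapply(mats, function(m) m$attenuation_per_mm, 1)
  }
  list(intensity = grey * exp(-att * cum), label = label)
}
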