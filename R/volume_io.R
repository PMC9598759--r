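#' Read and write volumes (NRRD, NIfTI-1, MetaImage)
#'
#' Format is inferred from the extension: `.nrrd` (attached raw little-endian
#' NRRD), `.nii`/`.nii.gz` (NIfTI-1 via RNifti), `.mhd` (MetaImage header +
#' `.raw`). Label volumes carry their label map in NRRD key/value pairs or a
#' `<file>.labels.yaml` sidecar for the other formats.
#'
#' @param vol a [label_volume()] or `grey_volume`.
#' @param path output path.
#' @export
write_volume <- function(vol, path) {
  ext <- volume_ext(path)
  is_label <- inherits(vol, "label_volume")
  arr <- vol$array
  switch(ext,
    nrrd = write_nrrd(arr, vol$spacing, vol$origin, path,
                      label_map = if (is_label) vol$label_map),
    nii = {
      a <- arr * 1.0
      attr(a, "pixdim") <- vol$spacing
      RNifti::writeNifti(RNifti::asNifti(a), path)
      if (is_label) write_label_sidecar(vol, path)
    },
    mhd = {
      write_mhd(arr, vol$spacing, vol$origin, path)
      if (is_label) write_label_sidecar(vol, path)
    })
  invisible(path)
}

write_label_sidecar <- function(vol, path) {
  yaml::write_yaml(list(origin = vol$origin,
                        label_map = as.list(vol$label_map)),
                   paste0(path, ".labels.yaml"))
}

volume_ext <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) return("nii")
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("nrrd", "mhd"))
    stop("unsupported volume format: ", ext, call. = FALSE)
  ext
}

#' @rdname write_volume
#' @param as_label force interpretation as a label volume.
#' @export
read_volume <- function(path, as_label = NA) {
  ext <- volume_ext(path)
  res <- switch(ext,
    nrrd = read_nrrd(path),
    nii = {
      img <- RNifti::readNifti(path)
      info <- list(array = as.array(img),
                   spacing = RNifti::pixdim(img)[1:3], origin = c(0, 0, 0))
      sc <- paste0(path, ".labels.yaml")
      if (file.exists(sc)) {
        meta <- yaml::read_yaml(sc)
        info$origin <- as.numeric(meta$origin)
        info$label_map <- unlist(meta$label_map)
      }
      info
    },
    mhd = {
      info <- read_mhd(path)
      sc <- paste0(path, ".labels.yaml")
      if (file.exists(sc)) info$label_map <- unlist(yaml::read_yaml(sc)$label_map)
      info
    })
  labelled <- !is.null(res$label_map)
  if (isTRUE(as_label) && !labelled)
    res$label_map <- stats::setNames(seq_len(max(res$array)),
                                     paste0("label_", seq_len(max(res$array))))
  if (labelled || isTRUE(as_label)) {
    label_volume(array(as.integer(round(res$array)), dim(res$array)),
                 res$spacing, res$origin, res$label_map)
  } else {
    structure(list(array = res$array, spacing = res$spacing,
                   origin = res$origin), class = "grey_volume")
  }
}

write_nrrd <- function(arr, spacing, origin, path, label_map = NULL) {
  is_int <- is.integer(arr) || all(arr == round(arr))
  type <- if (is_int) "int" else "double"
  hdr <- c("NRRD0004",
           "# vfecho volume",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(dim(arr), collapse = " ")),
           "encoding: raw",
           "endian: little",
           "space: left-posterior-superior",
           sprintf("space directions: (%.15g,0,0) (0,%.15g,0) (0,0,%.15g)",
                   spacing[1], spacing[2], spacing[3]),
           sprintf("space origin: (%.15g,%.15g,%.15g)",
                   origin[1], origin[2], origin[3]))
  if (!is.null(label_map))
    hdr <- c(hdr, paste0("vfecho_label_map:=",
                         paste(names(label_map), label_map, sep = "=",
                               collapse = ";")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  if (is_int) writeBin(as.integer(arr), con, size = 4, endian = "little")
  else writeBin(as.numeric(arr), con, size = 8, endian = "little")
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (!length(line) || line == "") break
    hdr <- c(hdr, line)
  }
  field <- function(name) {
    x <- grep(paste0("^", name, ":"), hdr, value = TRUE)
    if (!length(x)) return(NULL)
    trimws(sub(paste0("^", name, ":\\s*"), "", x[1]))
  }
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  type <- field("type")
  if (field("encoding") != "raw") stop("only raw NRRD supported", call. = FALSE)
  n <- prod(sizes)
  arr <- if (type %in% c("int", "int32", "signed int"))
    readBin(con, "integer", n, size = 4, endian = "little")
  else if (type %in% c("double", "float64"))
    readBin(con, "numeric", n, size = 8, endian = "little")
  else if (type %in% c("float", "float32"))
    readBin(con, "numeric", n, size = 4, endian = "little")
  else if (type %in% c("uchar", "uint8", "unsigned char"))
    as.integer(readBin(con, "raw", n))
  else stop("unsupported NRRD type: ", type, call. = FALSE)
  sd <- field("space directions")
  spacing <- if (!is.null(sd)) {
    v <- regmatches(sd, gregexpr("-?[0-9.eE+]+", sd))[[1]]
    m <- matrix(as.numeric(v), 3, 3, byrow = TRUE)
    sqrt(rowSums(m^2))
  } else c(1, 1, 1)
  so <- field("space origin")
  origin <- if (!is.null(so))
    as.numeric(regmatches(so, gregexpr("-?[0-9.eE+]+", so))[[1]]) else c(0, 0, 0)
  lm_line <- grep("^vfecho_label_map:=", hdr, value = TRUE)
  label_map <- NULL
  if (length(lm_line)) {
    pairs <- strsplit(strsplit(sub("^vfecho_label_map:=", "", lm_line[1]),
                               ";")[[1]], "=")
    label_map <- stats::setNames(as.integer(vapply(pairs, `[`, "", 2)),
                                 vapply(pairs, `[`, "", 1))
  }
  list(array = array(arr, sizes), spacing = spacing, origin = origin,
       label_map = label_map)
}

write_mhd <- function(arr, spacing, origin, path) {
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  is_int <- is.integer(arr) || all(arr == round(arr))
  writeLines(c("ObjectType = Image", "NDims = 3", "BinaryData = True",
               "BinaryDataByteOrderMSB = False",
               paste0("DimSize = ", paste(dim(arr), collapse = " ")),
               paste0("ElementSpacing = ", paste(sprintf("%.15g", spacing), collapse = " ")),
               paste0("Offset = ", paste(sprintf("%.15g", origin), collapse = " ")),
               paste0("ElementType = ", if (is_int) "MET_INT" else "MET_DOUBLE"),
               paste0("ElementDataFile = ", raw_name)), path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (is_int) writeBin(as.integer(arr), con, size = 4, endian = "little")
  else writeBin(as.numeric(arr), con, size = 8, endian = "little")
}

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get <- function(key) {
    x <- grep(paste0("^", key, "\\s*="), lines, value = TRUE)
    if (!length(x)) return(NULL)
    trimws(sub("^[^=]*=\\s*", "", x[1]))
  }
  sizes <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing") %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset") %||% "0 0 0", "\\s+")[[1]])
  type <- get("ElementType")
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  n <- prod(sizes)
  arr <- switch(type,
    MET_INT = readBin(con, "integer", n, size = 4, endian = "little"),
    MET_SHORT = readBin(con, "integer", n, size = 2, endian = "little"),
    MET_UCHAR = as.integer(readBin(con, "raw", n)),
    MET_DOUBLE = readBin(con, "numeric", n, size = 8, endian = "little"),
    MET_FLOAT = readBin(con, "numeric", n, size = 4, endian = "little"),
    stop("unsupported MetaImage type: ", type, call. = FALSE))
  list(array = array(arr, sizes), spacing = spacing, origin = origin)
}
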