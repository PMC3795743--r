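#' Read a 3D volume from NRRD or NIfTI-1
#'
#' Format is chosen by extension: `.nrrd` / `.nhdr` for NRRD, `.nii` /
#' `.nii.gz` for NIfTI-1. Grid dimensions, spacing, origin and direction are
#' taken from the header; intensities are returned as double.
#'
#' @param path Path to the file.
#' @return An `image_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  low <- tolower(path)
  if (grepl("\\.(nrrd|nhdr)$", low)) {
    read_nrrd(path)
  } else if (grepl("\\.nii(\\.gz)?$", low)) {
    read_nifti_volume(path)
  } else {
    stop("unrecognised volume format (expect .nrrd, .nhdr, .nii, .nii.gz): ",
         path, call. = FALSE)
  }
}

#' Write a 3D volume or mask to NRRD or NIfTI-1
#'
#' Masks are written as unsigned 8-bit 0/1 with the grid geometry copied
#' from the object; volumes are written as double (NRRD) or float64 (NIfTI).
#'
#' @param x An `image_volume` or `binary_mask`.
#' @param path Output path; extension selects the format as in
#'   [read_volume()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "image_volume") || inherits(x, "binary_mask"))
  is_mask <- inherits(x, "binary_mask")
  low <- tolower(path)
  if (grepl("\\.nrrd$", low)) {
    write_nrrd(x, path, type = if (is_mask) "uint8" else "double")
  } else if (grepl("\\.nii(\\.gz)?$", low)) {
    write_nifti_volume(x, path, datatype = if (is_mask) "uint8" else "double")
  } else {
    stop("unrecognised volume format (expect .nrrd, .nii, .nii.gz): ", path,
         call. = FALSE)
  }
  invisible(path)
}

#' Read a mask file as a binary mask
#'
#' Any strictly positive voxel is treated as set.
#'
#' @param path Path to a NRRD or NIfTI-1 mask.
#' @return A `binary_mask`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$voxels > 0, geometry = v)
}

## ---- NIfTI-1 via RNifti ----------------------------------------------------

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  }
  m <- unclass(RNifti::xform(img))
  lin <- m[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  direction <- sweep(lin, 2L, spacing, "/")
  image_volume(array(as.double(img), dim(img)), spacing = spacing,
               origin = m[1:3, 4L], direction = direction)
}

write_nifti_volume <- function(x, path, datatype = "double") {
  arr <- if (datatype == "uint8") {
    array(as.integer(x$voxels != 0), dim(x$voxels))
  } else {
    array(as.double(x$voxels), dim(x$voxels))
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  m <- diag(4)
  m[1:3, 1:3] <- x$direction %*% diag(x$spacing)
  m[1:3, 4L] <- x$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

## ---- NRRD ------------------------------------------------------------------
## Minimal NRRD reader/writer for 3D scalar volumes: attached header, raw or
## gzip encoding, little-endian, the geometry fields used by this package.

nrrd_types <- c(
  "signed char" = "int8", "int8" = "int8", "int8_t" = "int8",
  "uchar" = "uint8", "unsigned char" = "uint8", "uint8" = "uint8",
  "uint8_t" = "uint8",
  "short" = "int16", "short int" = "int16", "signed short" = "int16",
  "int16" = "int16", "int16_t" = "int16",
  "ushort" = "uint16", "unsigned short" = "uint16", "uint16" = "uint16",
  "uint16_t" = "uint16",
  "int" = "int32", "signed int" = "int32", "int32" = "int32",
  "int32_t" = "int32",
  "uint" = "uint32", "unsigned int" = "uint32", "uint32" = "uint32",
  "uint32_t" = "uint32",
  "float" = "float", "double" = "double"
)

nrrd_type_info <- function(type) {
  switch(type,
    int8 = list(size = 1L, what = "integer", signed = TRUE),
    uint8 = list(size = 1L, what = "integer", signed = FALSE),
    int16 = list(size = 2L, what = "integer", signed = TRUE),
    uint16 = list(size = 2L, what = "integer", signed = FALSE),
    int32 = list(size = 4L, what = "integer", signed = TRUE),
    uint32 = list(size = 4L, what = "integer", signed = TRUE),  # read as int
    float = list(size = 4L, what = "double", signed = TRUE),
    double = list(size = 8L, what = "double", signed = TRUE),
    stop("unsupported NRRD type: ", type, call. = FALSE)
  )
}

parse_nrrd_vectors <- function(value) {
  # "(a,b,c) (d,e,f) ..." -> list of numeric vectors; "none" entries -> NA
  parts <- regmatches(value, gregexpr("\\(([^)]*)\\)|none", value))[[1L]]
  lapply(parts, function(p) {
    if (p == "none") return(NA)
    as.numeric(strsplit(gsub("[()]", "", p), ",")[[1L]])
  })
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic)) {
    stop("not a NRRD file (bad magic): ", path, call. = FALSE)
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) {
      stop("corrupt NRRD header (no end-of-header blank line): ", path,
           call. = FALSE)
    }
    if (line == "") break
    if (grepl("^#", line)) next
    sep <- regexpr(": ", line, fixed = TRUE)
    if (sep < 0) {
      if (grepl(":=", line, fixed = TRUE)) next  # key-value pairs ignored
      stop("corrupt NRRD header line: ", line, call. = FALSE)
    }
    key <- tolower(substr(line, 1L, sep - 1L))
    fields[[key]] <- substr(line, sep + 2L, nchar(line))
  }
  need <- c("type", "dimension", "sizes", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss)) {
    stop("NRRD header missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (as.integer(fields$dimension) != 3L) {
    stop("only 3D NRRD volumes are supported: ", path, call. = FALSE)
  }
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1L]])
  type <- nrrd_types[[tolower(fields$type)]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields$type, call. = FALSE)
  info <- nrrd_type_info(type)
  n <- prod(sizes)

  encoding <- tolower(fields$encoding)
  payload <- readBin(con, "raw", n = file.size(path))
  if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding: ", encoding, call. = FALSE)
  }
  if (length(payload) < n * info$size) {
    stop("NRRD data shorter than header promises: ", path, call. = FALSE)
  }
  endian <- if (!is.null(fields$endian) && tolower(fields$endian) == "big") {
    "big"
  } else "little"
  vals <- readBin(payload, what = info$what, n = n, size = info$size,
                  signed = if (info$size < 4L) info$signed else TRUE,
                  endian = endian)
  vals <- as.double(vals)

  spacing <- c(1, 1, 1); direction <- diag(3); origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    vecs <- parse_nrrd_vectors(fields[["space directions"]])
    vecs <- vecs[!vapply(vecs, function(v) all(is.na(v)), logical(1L))]
    if (length(vecs) == 3L) {
      lin <- do.call(cbind, vecs)
      spacing <- sqrt(colSums(lin^2))
      direction <- sweep(lin, 2L, spacing, "/")
    }
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1L]])
  }
  if (!is.null(fields[["space origin"]])) {
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1L]]
  }
  image_volume(array(vals, sizes), spacing = spacing, origin = origin,
               direction = direction)
}

write_nrrd <- function(x, path, type = c("double", "float", "uint8", "int16")) {
  type <- match.arg(type)
  info <- nrrd_type_info(type)
  d <- dim(x$voxels)
  lin <- x$direction %*% diag(x$spacing)
  fmt <- function(v) paste0("(", paste(format(v, digits = 17, trim = TRUE,
                                              scientific = FALSE),
                                       collapse = ","), ")")
  header <- c(
    "NRRD0004",
    "# raycut volume",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(d, collapse = " ")),
    paste0("space directions: ", paste(apply(lin, 2L, fmt), collapse = " ")),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    paste0("space origin: ", fmt(x$origin)),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  vals <- as.vector(x$voxels)
  if (info$what == "integer") {
    vals <- as.integer(round(vals))
  }
  writeBin(vals, con, size = info$size, endian = "little")
  invisible(path)
}

## ---- STL -------------------------------------------------------------------

#' Write a surface mesh as binary STL
#'
#' Standard little-endian binary STL: 80-byte header, triangle count, then
#' per triangle a unit normal (right-hand rule from the vertex order) and
#' three vertices as 32-bit floats, units mm, world coordinates.
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path (conventionally `.stl`).
#' @return `path`, invisibly.
#' @export
write_mesh_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  tr <- mesh$triangles
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "raycut binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(nrow(tr)), con, size = 4L, endian = "little")
  for (f in seq_len(nrow(tr))) {
    a <- v[tr[f, 1L], ]; b <- v[tr[f, 2L], ]; c3 <- v[tr[f, 3L], ]
    nrm <- c((b - a)[2L] * (c3 - a)[3L] - (b - a)[3L] * (c3 - a)[2L],
             (b - a)[3L] * (c3 - a)[1L] - (b - a)[1L] * (c3 - a)[3L],
             (b - a)[1L] * (c3 - a)[2L] - (b - a)[2L] * (c3 - a)[1L])
    len <- sqrt(sum(nrm^2))
    if (len > 0) nrm <- nrm / len
    writeBin(c(nrm, a, b, c3), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
  invisible(path)
}
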