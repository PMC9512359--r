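#' Read a volume from disk
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) or MetaImage (`.mha`, `.mhd`) files.
#' NIfTI images carrying an orientation are reoriented on load to the
#' package's canonical axis order (left-right, anterior-posterior,
#' inferior-superior); world coordinates in this package are expressed in
#' that frame, so the posterior direction is +axis 2.
#'
#' @param path path to an existing image file.
#' @return A [as_volume()] object with spacing and origin from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    ctv_stop("ctv_error_format", sprintf("cannot read '%s': no such file", path))
  ext <- tolower(sub("^.*?(\\.[a-zA-Z0-9.]+)$", "\\1", basename(path)))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    read_nifti_volume(path)
  } else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    read_metaimage(path)
  } else {
    ctv_stop("ctv_error_format",
             sprintf("unsupported image format '%s' for '%s'", ext, path))
  }
}

#' Read a binary mask from disk
#'
#' As [read_volume()], but validates that voxel values are restricted to
#' \{0, 1\} and returns a label map.
#' @inheritParams read_volume
#' @return A [as_labelmap()] object.
#' @export
read_labelmap <- function(path) {
  v <- read_volume(path)
  as_labelmap(v$data, v$spacing, v$origin)
}

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) ctv_stop("ctv_error_format",
                    sprintf("cannot read '%s': %s", path, conditionMessage(e))))
  if (length(dim(img)) != 3L)
    ctv_stop("ctv_error_format",
             sprintf("'%s' is %d-D; a 3-D image is required", path, length(dim(img))))
  x <- RNifti::xform(img)
  if (!is.null(attr(x, "code")) && attr(x, "code") > 0) {
    RNifti::orientation(img) <- "RPS"
    x <- RNifti::xform(img)
    spacing <- sqrt(colSums(x[1:3, 1:3]^2))
    origin <- c(x[1, 4], -x[2, 4], x[3, 4])
  } else {
    spacing <- RNifti::pixdim(img)
    origin <- c(0, 0, 0)
  }
  as_volume(array(as.numeric(img), dim(img)), spacing, origin)
}

#' Write a volume or label map to disk
#'
#' The output format follows the file extension (`.nii`, `.nii.gz`, `.mha`,
#' `.mhd`).  Label maps are stored as unsigned 8-bit integers; volumes as
#' 32-bit floats (NIfTI) or 64-bit doubles (MetaImage).  The header encodes
#' spacing and origin so that [read_volume()] round-trips the grid.
#'
#' @param volume a `ctv_volume` or `ctv_labelmap`.
#' @param path output path; the parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  if (!dir.exists(dirname(path)))
    ctv_stop("ctv_error_io", sprintf("cannot write '%s': directory does not exist", path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    write_nifti_volume(volume, path)
  } else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    write_metaimage(volume, path)
  } else {
    ctv_stop("ctv_error_format", sprintf("unsupported output format for '%s'", path))
  }
  invisible(path)
}

write_nifti_volume <- function(volume, path) {
  sp <- volume$spacing; org <- volume$origin
  datatype <- if (is_labelmap(volume)) "uint8" else "float"
  img <- RNifti::asNifti(volume$data, pixdim = sp, datatype = datatype)
  m <- diag(4)
  m[1, 1] <- sp[1]; m[2, 2] <- -sp[2]; m[3, 3] <- sp[3]
  m[1, 4] <- org[1]; m[2, 4] <- -org[2]; m[3, 4] <- org[3]
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
}

meta_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                MET_SHORT = "integer", MET_USHORT = "integer",
                MET_INT = "integer", MET_UINT = "integer",
                MET_FLOAT = "double", MET_DOUBLE = "double")
meta_sizes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2, MET_USHORT = 2,
                MET_INT = 4, MET_UINT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      ctv_stop("ctv_error_format", sprintf("'%s': truncated MetaImage header", path))
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "3")
  if (ndims != 3L)
    ctv_stop("ctv_error_format", sprintf("'%s' is %d-D; a 3-D image is required", path, ndims))
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||% "0 0 0", "\\s+")[[1]])
  type <- hdr$ElementType %||% "MET_FLOAT"
  if (!type %in% names(meta_types))
    ctv_stop("ctv_error_format", sprintf("'%s': unsupported ElementType %s", path, type))
  if (identical(tolower(hdr$CompressedData %||% "false"), "true"))
    ctv_stop("ctv_error_format", sprintf("'%s': compressed MetaImage not supported", path))
  n <- prod(dims)
  swap <- identical(tolower(hdr$BinaryDataByteOrderMSB %||% "false"), "true")
  endian <- if (swap) "big" else "little"
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
    data <- readBin(raw_con, meta_types[[type]], n = n, size = meta_sizes[[type]],
                    signed = if (meta_sizes[[type]] >= 4) TRUE else signed,
                    endian = endian)
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath))
      ctv_stop("ctv_error_format", sprintf("'%s': missing data file '%s'", path, rawpath))
    rcon <- file(rawpath, "rb"); on.exit(close(rcon), add = TRUE)
    data <- readBin(rcon, meta_types[[type]], n = n, size = meta_sizes[[type]],
                    signed = if (meta_sizes[[type]] >= 4) TRUE else signed,
                    endian = endian)
  }
  if (length(data) != n)
    ctv_stop("ctv_error_format", sprintf("'%s': expected %d voxels, read %d", path, n, length(data)))
  as_volume(array(as.numeric(data), dims), spacing, origin)
}

write_metaimage <- function(volume, path) {
  label <- is_labelmap(volume)
  type <- if (label) "MET_UCHAR" else "MET_DOUBLE"
  local_data <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (local_data) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                      ignore.case = TRUE), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           sprintf("Offset = %s", paste(format(volume$origin, digits = 17), collapse = " ")),
           sprintf("ElementSpacing = %s", paste(format(volume$spacing, digits = 17), collapse = " ")),
           sprintf("DimSize = %s", paste(dim(volume$data), collapse = " ")),
           sprintf("ElementType = %s", type),
           sprintf("ElementDataFile = %s", datafile))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) ctv_stop("ctv_error_io",
                    sprintf("cannot write '%s'", path)))
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  payload <- if (label) as.integer(volume$data) else as.numeric(volume$data)
  size <- if (label) 1L else 8L
  if (local_data) {
    writeBin(payload, con, size = size, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(payload, rcon, size = size, endian = "little")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
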