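#' Read and write 3-D volumes and masks
#'
#' Images and masks are exchanged as NIfTI (`.nii`, `.nii.gz`) through RNifti,
#' or as uncompressed MetaImage (`.mha`, `.mhd` + `.raw`). Only axis-aligned
#' geometries are supported: a header whose direction matrix has nonzero
#' off-diagonal terms is rejected. Axes stored with negative direction are
#' flipped to the package's positive-spacing convention on read. Masks are
#' written as unsigned 8-bit \{0, 1\} and read with a nonzero-is-member rule.
#'
#' @param path File path.
#' @return `read_volume()` returns a [scalar_image()]; `read_mask()` a
#'   [binary_mask()].
#' @name volume_io
NULL

io_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) return("metaimage")
  stop("unsupported file format (expected .nii, .nii.gz, .mha or .mhd): ", path)
}

#' @rdname volume_io
#' @export
read_volume <- function(path) {
  if (io_format(path) == "nifti") read_nifti_volume(path) else read_mha_volume(path)
}

#' @rdname volume_io
#' @param image A [scalar_image()].
#' @export
write_volume <- function(image, path) {
  if (io_format(path) == "nifti") {
    write_nifti_volume(image$values, image$grid, path)
  } else {
    write_mha_volume(image$values, image$grid, path, element_type = "MET_DOUBLE")
  }
  invisible(path)
}

#' @rdname volume_io
#' @export
read_mask <- function(path) {
  img <- read_volume(path)
  binary_mask(img$values != 0, img$grid)
}

#' @rdname volume_io
#' @param mask A [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  vals <- array(as.numeric(mask$member), mask$grid$shape)
  if (io_format(path) == "nifti") {
    write_nifti_volume(vals, mask$grid, path, datatype = "uint8")
  } else {
    write_mha_volume(vals, mask$grid, path, element_type = "MET_UCHAR")
  }
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6 * max(abs(diag(rot))))) {
    stop("grid must be axis-aligned")
  }
  vals <- as.array(img)
  if (length(dim(vals)) != 3) stop("expected a 3-D volume: ", path)
  vals <- array(as.numeric(vals), dim(vals))  # strip header attributes
  spacing <- diag(rot)
  origin <- xf[1:3, 4]
  # flip axes stored in negative direction to the positive-spacing convention
  for (a in 1:3) {
    if (spacing[a] < 0) {
      vals <- flip_axis(vals, a)
      origin[a] <- origin[a] + spacing[a] * (dim(vals)[a] - 1)
      spacing[a] <- -spacing[a]
    }
  }
  scalar_image(vals, voxel_grid(dim(vals), spacing, origin))
}

flip_axis <- function(a, axis) {
  idx <- list(seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3]))
  idx[[axis]] <- rev(idx[[axis]])
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

write_nifti_volume <- function(vals, grid, path, datatype = "double") {
  img <- RNifti::asNifti(as.array(vals))
  RNifti::pixdim(img) <- grid$spacing
  aff <- rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
}

# ---- minimal MetaImage (.mha / .mhd) support: uncompressed, axis-aligned ----

mha_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
               MET_USHORT = "integer", MET_SHORT = "integer",
               MET_UINT = "integer", MET_INT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
mha_sizes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_USHORT = 2, MET_SHORT = 2,
               MET_UINT = 4, MET_INT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)
mha_signed <- c(MET_UCHAR = FALSE, MET_CHAR = TRUE, MET_USHORT = FALSE,
                MET_SHORT = TRUE, MET_UINT = FALSE, MET_INT = TRUE,
                MET_FLOAT = TRUE, MET_DOUBLE = TRUE)

read_mha_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  # read header lines byte-wise so the connection position is exact when the
  # pixel data follow in the same file (ElementDataFile = LOCAL)
  read_line_bin <- function(con) {
    bytes <- raw()
    repeat {
      b <- readBin(con, "raw", n = 1)
      if (length(b) == 0) return(NULL)
      if (b == as.raw(10)) break
      bytes <- c(bytes, b)
    }
    sub("\r$", "", rawToChar(bytes))
  }
  repeat {
    line <- read_line_bin(con)
    if (is.null(line)) stop("unexpected end of MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr[["NDims"]] %||% "3")
  if (!identical(ndims, 3L)) stop("only 3-D MetaImage volumes are supported")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% hdr[["Position"]] %||%
                                  "0 0 0", "\\s+")[[1]])
  tm <- hdr[["TransformMatrix"]]
  if (!is.null(tm)) {
    m <- matrix(as.numeric(strsplit(tm, "\\s+")[[1]]), 3, 3, byrow = TRUE)
    if (max(abs(m - diag(3))) > 1e-6) stop("grid must be axis-aligned")
  }
  if (isTRUE(tolower(hdr[["CompressedData"]] %||% "false") == "true")) {
    stop("compressed MetaImage data are not supported")
  }
  type <- hdr[["ElementType"]]
  if (is.null(type) || !type %in% names(mha_types)) {
    stop("unsupported MetaImage element type: ", type)
  }
  datafile <- hdr[["ElementDataFile"]]
  n <- prod(dims)
  if (identical(toupper(datafile), "LOCAL")) {
    raw_con <- con
  } else {
    raw_con <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- readBin(raw_con, what = mha_types[[type]], n = n,
                  size = mha_sizes[[type]], signed = mha_signed[[type]],
                  endian = "little")
  if (length(vals) != n) stop("truncated MetaImage data: ", path)
  scalar_image(array(as.numeric(vals), dims), voxel_grid(dims, spacing, origin))
}

write_mha_volume <- function(vals, grid, path, element_type = "MET_DOUBLE") {
  is_mhd <- grepl("\\.mhd$", path, ignore.case = TRUE)
  datafile <- if (is_mhd) sub("\\.mhd$", ".raw", basename(path),
                              ignore.case = TRUE) else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(grid$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =",
          paste(format(grid$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(grid$shape, collapse = " ")),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", datafile)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  store <- if (mha_types[[element_type]] == "integer") {
    as.integer(round(vals))
  } else {
    as.numeric(vals)
  }
  raw_con <- if (is_mhd) {
    f <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(f), add = TRUE)
    f
  } else con
  writeBin(store, raw_con, size = mha_sizes[[element_type]], endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
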