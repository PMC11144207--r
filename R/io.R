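#' Read and write voxel volumes
#'
#' Scalar images, dose grids and masks are stored as 3D NIfTI volumes;
#' displacement fields as 4D volumes whose last dimension holds the (x,y,z)
#' vector components in mm. Spacing is carried in \code{pixdim} and the
#' origin in the sform translation (axis-aligned grids only). Uncompressed
#' MetaImage (\code{.mha}, local raw data) is supported as an alternative
#' interchange format.
#'
#' @param x grid object to write.
#' @param file path ending in \code{.nii}, \code{.nii.gz} or \code{.mha}.
#' @return \code{write_volume} returns \code{file} invisibly;
#'   \code{read_volume} returns an \code{image_grid} (3D file) or
#'   \code{displacement_field} (4D file with 3 components).
#' @name volume_io
NULL

#' @rdname volume_io
#' @export
write_volume <- function(x, file) {
  if (inherits(x, "structure_mask")) {
    arr <- array(as.numeric(x$inside), dim(x$inside))
  } else if (inherits(x, "displacement_field")) {
    arr <- x$vectors
  } else if (inherits(x, "image_grid")) {
    arr <- x$values
  } else stop("unsupported object of class ", class(x)[1])
  if (grepl("\\.mha$", file, ignore.case = TRUE)) {
    write_metaimage(arr, x$spacing, x$origin, file)
  } else {
    img <- RNifti::asNifti(arr)
    nd <- length(dim(arr))
    RNifti::pixdim(img) <- c(x$spacing, rep(1, nd - 3L))
    aff <- diag(4)
    diag(aff)[1:3] <- x$spacing
    aff[1:3, 4] <- x$origin
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, file)
  }
  invisible(file)
}

#' @rdname volume_io
#' @export
read_volume <- function(file) {
  if (grepl("\\.mha$", file, ignore.case = TRUE)) {
    m <- read_metaimage(file)
    arr <- m$data; spacing <- m$spacing; origin <- m$origin
  } else {
    img <- RNifti::readNifti(file)
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))
    hdr <- RNifti::niftiHeader(img)
    spacing <- abs(hdr$pixdim[2:4])
    aff <- RNifti::xform(img)
    origin <- aff[1:3, 4]
    # our writer uses a positive axis-aligned sform; undo any sign flips
    sgn <- sign(diag(aff)[1:3])
    origin <- origin * ifelse(sgn == 0, 1, sgn)
  }
  nd <- length(dim(arr))
  if (nd == 3L) {
    image_grid(arr, spacing, origin)
  } else if (nd == 4L && dim(arr)[4] == 3L) {
    displacement_field(arr, spacing, origin)
  } else stop("unsupported volume dimensionality: ", paste(dim(arr), collapse = "x"))
}

# ---- MetaImage (.mha, uncompressed, ElementDataFile = LOCAL) ----

write_metaimage <- function(arr, spacing, origin, file) {
  d <- dim(arr)
  channels <- if (length(d) == 4L) d[4] else 1L
  nd3 <- d[1:3]
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("TransformMatrix = %s", paste(c(1, 0, 0, 0, 1, 0, 0, 0, 1), collapse = " ")),
    sprintf("Offset = %s", paste(format(origin, trim = TRUE), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    sprintf("ElementSpacing = %s", paste(format(spacing, trim = TRUE), collapse = " ")),
    sprintf("DimSize = %s", paste(nd3, collapse = " ")),
    if (channels > 1L) sprintf("ElementNumberOfChannels = %d", channels),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  con <- file(file, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  # MetaImage multi-channel layout: components interleaved per voxel
  if (channels > 1L) {
    v <- aperm(arr, c(4, 1, 2, 3))
  } else v <- arr
  writeBin(as.double(v), con, size = 8, endian = "little")
  invisible(file)
}

read_metaimage <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  kv <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of MetaImage header")
    parts <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    kv[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(kv[["ElementDataFile"]], "LOCAL"))
    stop("only ElementDataFile = LOCAL MetaImage files are supported")
  if (!is.null(kv[["BinaryDataByteOrderMSB"]]) &&
      tolower(kv[["BinaryDataByteOrderMSB"]]) == "true")
    stop("big-endian MetaImage not supported")
  dims <- as.integer(strsplit(kv[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(kv[["ElementSpacing"]], "\\s+")[[1]])
  origin <- if (!is.null(kv[["Offset"]]))
    as.numeric(strsplit(kv[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  channels <- if (!is.null(kv[["ElementNumberOfChannels"]]))
    as.integer(kv[["ElementNumberOfChannels"]]) else 1L
  type <- kv[["ElementType"]]
  n <- prod(dims) * channels
  raw_read <- switch(type,
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    MET_FLOAT = readBin(con, "double", n, size = 4, endian = "little"),
    MET_SHORT = readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little"),
    MET_USHORT = readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little"),
    MET_UCHAR = readBin(con, "integer", n, size = 1, signed = FALSE, endian = "little"),
    stop("unsupported ElementType: ", type))
  if (length(raw_read) != n) stop("truncated MetaImage data block")
  if (channels > 1L) {
    data <- aperm(array(raw_read, c(channels, dims)), c(2, 3, 4, 1))
  } else {
    data <- array(raw_read, dims)
  }
  list(data = data, spacing = spacing, origin = origin)
}

#' Write a cohort table to CSV
#'
#' Columns: \code{patient_id}, \code{V5} ... \code{V60}, \code{rp_grade2plus},
#' followed by any extra covariate columns present.
#'
#' @param cohort a \code{cohort_table} (see \code{\link{simulate_cohort}}).
#' @param file output CSV path.
#' @export
write_cohort_csv <- function(cohort, file) {
  utils::write.csv(as.data.frame(cohort), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  as_cohort_table(df)
}
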