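#' Read a 3D volume from disk
#'
#' Supported formats: MetaImage (`.mha` with attached data, `.mhd` + raw
#' file), NRRD (`.nrrd`, attached raw or ascii data), and TIFF stacks (a
#' multi-page `.tif`/`.tiff` file or a directory of single-slice TIFFs, read
#' in lexicographic filename order). Slices are stacked along axis 1 so the
#' returned array is indexed `[z, y, x]` with z the axial direction.
#'
#' MetaImage/NRRD spacings are interpreted as millimetres (the convention of
#' the imaging toolkits that write them) and converted to micrometres; TIFF
#' carries no spacing, so `voxel_size_override` is required there.
#'
#' @param path File (or, for TIFF stacks, directory) to read.
#' @param voxel_size_override Voxel size in um, overriding any header value.
#' @param name Specimen/stage identifier; defaults to the file name.
#' @return A [grey_volume()].
#' @export
read_volume <- function(path, voxel_size_override = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  name <- name %||% basename(path)
  ext <- tolower(tools::file_ext(path))
  if (dir.exists(path) || ext %in% c("tif", "tiff")) {
    out <- read_tiff_stack(path)
  } else if (ext %in% c("mha", "mhd")) {
    out <- read_metaimage(path)
  } else if (ext == "nrrd") {
    out <- read_nrrd(path)
  } else {
    stop("unrecognised volume format: .", ext,
         " (expected .mha/.mhd, .nrrd, .tif/.tiff or a TIFF directory)",
         call. = FALSE)
  }
  vs <- voxel_size_override %||% out$voxel_size
  if (is.null(vs) || !is.finite(vs))
    stop("no voxel size in header and no `voxel_size_override` given",
         call. = FALSE)
  grey_volume(out$data, voxel_size = vs, name = name)
}

#' Write a 3D volume to disk
#'
#' Formats as in [read_volume()]. MetaImage and NRRD round-trip grey values
#' bit-exactly (data are written as double unless the volume is integer-valued
#' in `[0, 65535]`, in which case 16-bit unsigned is used) and store the voxel
#' size as a spacing in millimetres. TIFF output requires integer grey values
#' in `[0, 65535]` and does not store the voxel size.
#'
#' @param vol A `vertfe_volume` (grey, mask, binary or label volume).
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "vertfe_volume"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    mha = write_metaimage(vol, path, attached = TRUE),
    mhd = write_metaimage(vol, path, attached = FALSE),
    nrrd = write_nrrd(vol, path),
    tif = ,
    tiff = write_tiff_stack(vol, path),
    stop("unrecognised output format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Read per-specimen experimental force records
#'
#' Reads a comma-separated table with header columns `specimen_id`,
#' `free_height_mm` and `af_exp_N`: the specimen label, its free height
#' between the embedding pots (mm) and the experimental axial force reached
#' at the loaded step (N, the difference between the peak force at the loaded
#' step and the relaxed preload force). Additional numeric columns (for
#' example model-predicted forces) are carried through unchanged.
#'
#' @param path CSV file.
#' @return A tibble with one row per specimen.
#' @export
read_force_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("specimen_id", "free_height_mm", "af_exp_N")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("force record file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) return(tibble::as_tibble(df))
  for (col in setdiff(names(df), "specimen_id")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (col %in% required && any(!is.finite(v)))
      stop("non-numeric or non-finite value in column `", col, "`",
           call. = FALSE)
    df[[col]] <- v
  }
  if (any(df$free_height_mm <= 0))
    stop("free_height_mm must be positive", call. = FALSE)
  tibble::as_tibble(df)
}

# ---- TIFF ------------------------------------------------------------------

read_tiff_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0) stop("no TIFF files in ", path, call. = FALSE)
    slices <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else {
    slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(slices)) slices <- list(slices)
  }
  d2 <- dim(slices[[1]])
  if (length(d2) != 2)
    stop("TIFF slices must be single-channel greyscale", call. = FALSE)
  arr <- array(0, c(length(slices), d2[1], d2[2]))
  for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]
  list(data = arr, voxel_size = NULL)
}

write_tiff_stack <- function(vol, path) {
  data <- vol$data
  if (any(data != round(data)) || min(data) < 0 || max(data) > 65535)
    stop("TIFF output requires integer grey values in [0, 65535]",
         call. = FALSE)
  pages <- lapply(seq_len(dim(data)[1]),
                  function(z) matrix(data[z, , ] / 65535,
                                     nrow = dim(data)[2], ncol = dim(data)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
}

# ---- MetaImage -------------------------------------------------------------

meta_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0) stop("truncated MetaImage header", call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed MetaImage header line: ", line,
                              call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3) stop("only 3D MetaImage volumes are supported",
                              call. = FALSE)
  type <- meta_types[[hdr$ElementType %||% "MET_DOUBLE"]]
  if (is.null(type)) stop("unsupported ElementType: ", hdr$ElementType,
                          call. = FALSE)
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "", "\\s+")[[1]])
  big <- identical(hdr$BinaryDataByteOrderMSB, "True") ||
    identical(hdr$ElementByteOrderMSB, "True")
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, type$what, n = n, size = type$size,
                   signed = type$signed, endian = if (big) "big" else "little")
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, type$what, n = n, size = type$size,
                   signed = type$signed, endian = if (big) "big" else "little")
  }
  if (length(raw) != n) stop("MetaImage data shorter than DimSize",
                             call. = FALSE)
  # file order is x fastest, z slowest; repack to [z, y, x]
  arr <- aperm(array(as.double(raw), dims), c(3, 2, 1))
  vs <- if (length(spacing) >= 1 && is.finite(spacing[1])) spacing[1] * 1000
  list(data = arr, voxel_size = vs)
}

write_metaimage <- function(vol, path, attached = TRUE) {
  data <- vol$data
  int16 <- all(data == round(data)) && min(data) >= 0 && max(data) <= 65535
  type <- if (int16) "MET_USHORT" else "MET_DOUBLE"
  dims <- dim(data)
  sp <- vol$voxel_size / 1000
  datafile <- if (attached) "LOCAL" else paste0(
    tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image", "NDims = 3", "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("ElementSpacing = %.9g %.9g %.9g", sp, sp, sp),
    sprintf("DimSize = %d %d %d", dims[3], dims[2], dims[1]),
    sprintf("ElementType = %s", type),
    sprintf("ElementDataFile = %s", datafile)
  )
  payload <- aperm(data, c(3, 2, 1))  # back to x-fastest file order
  write_payload <- function(con) {
    if (int16) writeBin(as.integer(payload), con, size = 2L, endian = "little")
    else writeBin(as.double(payload), con, size = 8L, endian = "little")
  }
  if (attached) {
    con <- file(path, "wb"); on.exit(close(con), add = TRUE)
    writeLines(hdr, con)
    write_payload(con)
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con), add = TRUE)
    write_payload(con)
  }
}

# ---- NRRD ------------------------------------------------------------------

nrrd_types <- list(
  uchar = meta_types$MET_UCHAR, `unsigned char` = meta_types$MET_UCHAR,
  short = meta_types$MET_SHORT, ushort = meta_types$MET_USHORT,
  `unsigned short` = meta_types$MET_USHORT,
  int = meta_types$MET_INT, float = meta_types$MET_FLOAT,
  double = meta_types$MET_DOUBLE
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path, call. = FALSE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0) stop("truncated NRRD header", call. = FALSE)
    if (nchar(line) == 0) break  # blank line ends the header
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    hdr[[tolower(key)]] <- val
  }
  dims <- as.integer(strsplit(hdr$sizes, "\\s+")[[1]])
  if (length(dims) != 3) stop("only 3D NRRD volumes are supported",
                              call. = FALSE)
  type <- nrrd_types[[hdr$type %||% "double"]]
  if (is.null(type)) stop("unsupported NRRD type: ", hdr$type, call. = FALSE)
  n <- prod(dims)
  enc <- hdr$encoding %||% "raw"
  if (enc == "raw") {
    big <- identical(hdr$endian, "big")
    raw <- readBin(con, type$what, n = n, size = type$size,
                   signed = type$signed, endian = if (big) "big" else "little")
  } else if (enc %in% c("ascii", "text", "txt")) {
    raw <- scan(con, what = double(), n = n, quiet = TRUE)
  } else {
    stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  }
  if (length(raw) != n) stop("NRRD data shorter than sizes", call. = FALSE)
  spacing <- suppressWarnings(
    as.numeric(strsplit(gsub("[(),]", " ", hdr$spacings %||% ""),
                        "\\s+")[[1]]))
  spacing <- spacing[is.finite(spacing)]
  vs <- if (length(spacing) >= 1) spacing[1] * 1000
  arr <- aperm(array(as.double(raw), dims), c(3, 2, 1))
  list(data = arr, voxel_size = vs)
}

write_nrrd <- function(vol, path) {
  data <- vol$data
  int16 <- all(data == round(data)) && min(data) >= 0 && max(data) <= 65535
  dims <- dim(data)
  sp <- vol$voxel_size / 1000
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", if (int16) "unsigned short" else "double"),
    "dimension: 3",
    sprintf("sizes: %d %d %d", dims[3], dims[2], dims[1]),
    sprintf("spacings: %.9g %.9g %.9g", sp, sp, sp),
    "encoding: raw", "endian: little", ""
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  payload <- aperm(data, c(3, 2, 1))
  if (int16) writeBin(as.integer(payload), con, size = 2L, endian = "little")
  else writeBin(as.double(payload), con, size = 8L, endian = "little")
}
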