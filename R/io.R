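# Volume readers/writers.  Three lossless container formats are supported:
# NIfTI-1 (.nii, .nii.gz), MetaImage (.mha single-file, .mhd + .raw), and
# raw binary with a JSON sidecar (<file>.raw + <file>.raw.json).  No other
# imaging package is assumed; headers are parsed explicitly and a missing
# or ambiguous geometry field is an error, never a guess.

DTYPES <- list(
  float32 = list(what = "double", size = 4L),
  float64 = list(what = "double", size = 8L),
  int16   = list(what = "integer", size = 2L),
  int32   = list(what = "integer", size = 4L),
  uint8   = list(what = "integer", size = 1L),
  uint16  = list(what = "integer", size = 2L)
)

read_voxels <- function(con, dtype, n, endian) {
  dt <- DTYPES[[dtype]]
  if (is.null(dt)) stop("unsupported voxel dtype: ", dtype, call. = FALSE)
  signed <- !(dtype %in% c("uint8", "uint16"))
  v <- readBin(con, what = dt$what, n = n, size = dt$size,
               signed = signed, endian = endian)
  if (length(v) != n)
    stop("truncated voxel data: expected ", n, " values, got ", length(v),
         call. = FALSE)
  as.double(v)
}

format_from_path <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p) || grepl("\\.nii$", p)) return("nifti")
  if (grepl("\\.mhd$", p) || grepl("\\.mha$", p)) return("metaimage")
  if (grepl("\\.raw$", p)) return("raw")
  stop("cannot infer volume format from path: ", path, call. = FALSE)
}

#' Read a CT volume from disk
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`), MetaImage (`.mha`, `.mhd` with
#' companion raw file) and raw binary with a JSON sidecar
#' (`<file>.raw` + `<file>.raw.json`).  NIfTI and MetaImage volumes are
#' declared to be in HU unless the NIfTI `descrip` field carries a
#' `unit=REL_MU` tag written by [write_volume()]; the raw sidecar states
#' its unit explicitly.  Geometry (dimensions, spacing) is taken from the
#' header; a missing field is an error.
#'
#' @param path file path.
#' @param format_hint optional `"nifti"`, `"metaimage"` or `"raw"`;
#'   by default the format is inferred from the file extension.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- if (is.null(format_hint)) format_from_path(path) else
    match.arg(format_hint, c("nifti", "metaimage", "raw"))
  switch(fmt,
         nifti = read_nifti(path),
         metaimage = read_metaimage(path),
         raw = read_raw_sidecar(path))
}

#' Write a CT volume to disk
#'
#' The on-disk format follows the file extension (see [read_volume()]).
#' Voxels are stored as little-endian float32 for NIfTI/MetaImage and
#' float64 for raw + sidecar; both round-trip the double-precision values
#' used throughout the package exactly for float64 and to float32
#' precision otherwise.  Pass `dtype = "float64"` to force lossless
#' storage in any format.
#'
#' @param volume a [ct_volume()].
#' @param path output path.
#' @param dtype voxel storage type, `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, dtype = NULL) {
  if (!inherits(volume, "ct_volume"))
    stop("expected a `ct_volume`", call. = FALSE)
  fmt <- format_from_path(path)
  if (is.null(dtype)) dtype <- if (fmt == "raw") "float64" else "float32"
  dtype <- match.arg(dtype, c("float32", "float64"))
  switch(fmt,
         nifti = write_nifti(volume, path, dtype),
         metaimage = write_metaimage(volume, path, dtype),
         raw = write_raw_sidecar(volume, path, dtype))
  invisible(path)
}

## ---- NIfTI-1 ------------------------------------------------------------

NIFTI_DT <- c("2" = "uint8", "4" = "int16", "8" = "int32",
              "16" = "float32", "64" = "float64", "512" = "uint16")

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "rb") else
    file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("NIfTI header truncated", call. = FALSE)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L)
      stop("not a NIfTI-1 file (sizeof_hdr != 348)", call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("NIfTI magic string missing", call. = FALSE)
  dim0 <- readBin(hdr[41:56], "integer", n = 8L, size = 2L, endian = endian)
  if (dim0[1] < 3L) stop("NIfTI volume is not 3D (dim[0] < 3)", call. = FALSE)
  d <- dim0[2:4]
  datatype <- readBin(hdr[71:72], "integer", size = 2L, endian = endian)
  dtype <- NIFTI_DT[as.character(datatype)]
  if (is.na(dtype))
    stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE)
  pixdim <- readBin(hdr[77:108], "double", n = 8L, size = 4L, endian = endian)
  spacing <- pixdim[2:4]
  if (any(spacing <= 0))
    stop("NIfTI header has non-positive pixdim spacing", call. = FALSE)
  vox_offset <- readBin(hdr[109:112], "double", size = 4L, endian = endian)
  scl_slope <- readBin(hdr[113:116], "double", size = 4L, endian = endian)
  scl_inter <- readBin(hdr[117:120], "double", size = 4L, endian = endian)
  descrip <- rawToChar(hdr[149:228][hdr[149:228] != as.raw(0)])
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(d)
  v <- read_voxels(con, dtype, n, endian)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  unit <- if (grepl("unit=REL_MU", descrip, fixed = TRUE)) "REL_MU" else "HU"
  ct_volume(array(v, dim = d), unit = unit, spacing = spacing)
}

write_nifti <- function(volume, path, dtype) {
  d <- dim(volume$values)
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "wb") else
    file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(s, width) {
    r <- charToRaw(s)
    writeBin(c(r[seq_len(min(length(r), width))],
               rep(as.raw(0), max(0L, width - length(r)))), con)
  }
  dt_code <- if (dtype == "float32") 16L else 64L
  bitpix <- if (dtype == "float32") 32L else 64L
  w4(348L); wc("", 10L); wc("", 18L); w4(0L); w2(0L); writeBin(charToRaw("r"), con)
  writeBin(as.raw(0), con)
  w2(c(3L, d, 1L, 1L, 1L, 1L))              # dim
  wf(c(0, 0, 0)); w2(0L)                    # intent
  w2(dt_code); w2(bitpix); w2(0L)           # datatype, bitpix, slice_start
  wf(c(1, volume$spacing, 0, 0, 0, 0))      # pixdim
  wf(352); wf(1); wf(0)                     # vox_offset, scl_slope, scl_inter
  w2(0L); writeBin(as.raw(c(0L, 2L)), con)  # slice_end, slice_code, xyzt=mm
  wf(c(0, 0, 0, 0)); w4(0L); w4(0L)         # cal/slice_duration/toffset/gl*
  wc(paste0("cbctshade unit=", volume$unit), 80L)
  wc("", 24L)
  w2(0L); w2(1L)                            # qform=0, sform=1
  wf(c(0, 0, 0, 0, 0, 0))                   # quatern/qoffset
  wf(c(volume$spacing[1], 0, 0, 0))         # srow_x
  wf(c(0, volume$spacing[2], 0, 0))         # srow_y
  wf(c(0, 0, volume$spacing[3], 0))         # srow_z
  wc("", 16L)
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(rep(as.raw(0), 4L), con)         # no extensions
  writeBin(as.double(volume$values),
           con, size = if (dtype == "float32") 4L else 8L, endian = "little")
}

## ---- MetaImage ----------------------------------------------------------

MET_DT <- c(MET_UCHAR = "uint8", MET_SHORT = "int16", MET_USHORT = "uint16",
            MET_INT = "int32", MET_FLOAT = "float32", MET_DOUBLE = "float64")

read_metaimage <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header is the text up to and including the ElementDataFile line
  nl <- which(bytes == as.raw(10L))
  hdr_end <- NA_integer_
  hdr_lines <- character()
  prev <- 0L
  for (p in nl) {
    line <- rawToChar(bytes[(prev + 1):(p - 1)])
    line <- sub("\r$", "", line)
    hdr_lines <- c(hdr_lines, line)
    prev <- p
    if (grepl("^\\s*ElementDataFile\\s*=", line)) { hdr_end <- p; break }
  }
  if (is.na(hdr_end))
    stop("MetaImage header: missing required field ElementDataFile",
         call. = FALSE)
  kv <- strsplit(hdr_lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get <- function(key, required = TRUE) {
    i <- match(key, trimws(keys))
    if (is.na(i)) {
      if (required)
        stop("MetaImage header: missing required field ", key, call. = FALSE)
      return(NULL)
    }
    trimws(vals[i])
  }
  if (!is.null(get("CompressedData", FALSE)) &&
      tolower(get("CompressedData", FALSE)) == "true")
    stop("compressed MetaImage data is not supported", call. = FALSE)
  if (as.integer(get("NDims")) != 3L)
    stop("MetaImage volume is not 3D", call. = FALSE)
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  dtype <- MET_DT[get("ElementType")]
  if (is.na(dtype))
    stop("unsupported MetaImage ElementType: ", get("ElementType"),
         call. = FALSE)
  msb <- get("BinaryDataByteOrderMSB", FALSE)
  endian <- if (!is.null(msb) && tolower(msb) == "true") "big" else "little"
  datafile <- get("ElementDataFile")
  n <- prod(d)
  if (toupper(datafile) == "LOCAL") {
    con <- rawConnection(bytes[(hdr_end + 1):length(bytes)])
    on.exit(close(con))
    v <- read_voxels(con, dtype, n, endian)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop("MetaImage data file not found: ", rawpath, call. = FALSE)
    con <- file(rawpath, "rb")
    on.exit(close(con))
    v <- read_voxels(con, dtype, n, endian)
  }
  ct_volume(array(v, dim = d), unit = "HU", spacing = spacing)
}

write_metaimage <- function(volume, path, dtype) {
  d <- dim(volume$values)
  local <- grepl("\\.mha$", tolower(path))
  datafile <- if (local) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =",
                 paste(format(volume$spacing, scientific = FALSE),
                       collapse = " ")),
           paste("ElementType =",
                 if (dtype == "float32") "MET_FLOAT" else "MET_DOUBLE"),
           paste("ElementDataFile =", datafile))
  size <- if (dtype == "float32") 4L else 8L
  if (local) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(as.double(volume$values), con, size = size, endian = "little")
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con))
    writeBin(as.double(volume$values), con, size = size, endian = "little")
  }
}

## ---- raw + JSON sidecar -------------------------------------------------

sidecar_path <- function(path) paste0(path, ".json")

read_raw_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("raw volume is missing its sidecar file: ", sp, call. = FALSE)
  meta <- jsonlite::fromJSON(sp)
  for (field in c("dims", "dtype", "spacing", "unit"))
    if (is.null(meta[[field]]))
      stop("raw sidecar is missing required field '", field, "'",
           call. = FALSE)
  d <- as.integer(meta$dims)
  endian <- if (identical(meta$byte_order, "big")) "big" else "little"
  con <- file(path, "rb")
  on.exit(close(con))
  v <- read_voxels(con, meta$dtype, prod(d), endian)
  ct_volume(array(v, dim = d), unit = match.arg(meta$unit, c("HU", "REL_MU")),
            spacing = as.numeric(meta$spacing))
}

write_raw_sidecar <- function(volume, path, dtype) {
  meta <- list(dims = dim(volume$values), dtype = dtype,
               spacing = volume$spacing, unit = volume$unit,
               byte_order = "little")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.double(volume$values), con,
           size = if (dtype == "float32") 4L else 8L, endian = "little")
}

## ---- ROI files ----------------------------------------------------------

#' Read or write an ROI specification file
#'
#' ROI files are tab-separated text with a header line
#' `label lo_x lo_y lo_z hi_x hi_y hi_z`; indices are 0-based and
#' half-open (`hi` exclusive), matching [roi_box()].
#'
#' @param path file path.
#' @return `read_roi_file()`: a list of [roi_box()] objects.
#' @export
read_roi_file <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("label", "lo_x", "lo_y", "lo_z", "hi_x", "hi_y", "hi_z")
  if (!all(need %in% names(df)))
    stop("ROI file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    roi_box(df$label[i],
            c(df$lo_x[i], df$lo_y[i], df$lo_z[i]),
            c(df$hi_x[i], df$hi_y[i], df$hi_z[i])))
}

#' @param rois list of [roi_box()] objects.
#' @rdname read_roi_file
#' @export
write_roi_file <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(label = r$label, lo_x = r$lo[1], lo_y = r$lo[2],
               lo_z = r$lo[3], hi_x = r$hi[1], hi_y = r$hi[2],
               hi_z = r$hi[3])))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
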