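# Image and ROI input/output.
#
# Two image formats are supported:
#  * plain-text raster: a TSV matrix of stored values with a JSON sidecar
#    (same path with extension .json) carrying pixel spacing and the
#    rescale calibration;
#  * single-frame uncompressed DICOM (implicit or explicit VR, little
#    endian), honoring Rescale Slope/Intercept and Pixel Spacing.
# In both, HU = slope * stored + intercept; images without pixel spacing
# metadata are refused because every geometric feature depends on it.

sidecar_path <- function(path) paste0(sub("\\.[^.]*$", "", path), ".json")

#' Read a calibrated CT slice
#'
#' Dispatches on extension: `.dcm`/`.dicom` to the DICOM reader, anything
#' else to the TSV-with-JSON-sidecar raster reader.
#'
#' @param path Image file path.
#' @return An [hu_image].
#' @export
read_ct <- function(path) {
  if (grepl("\\.(dcm|dicom)$", path, ignore.case = TRUE))
    read_dicom(path)
  else
    read_ct_raster(path)
}

#' @rdname read_ct
#' @export
read_ct_raster <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(side))
    stopf("missing sidecar %s: images without pixel-spacing metadata are refused", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$pixel_spacing))
    stopf("sidecar %s has no pixel_spacing entry", side)
  stored <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(stored) <- NULL
  slope <- meta$rescale_slope %||% 1
  intercept <- meta$rescale_intercept %||% 0
  hu_image(slope * stored + intercept,
           pixel_spacing = as.numeric(meta$pixel_spacing))
}

#' Write a calibrated CT slice as a text raster with JSON sidecar
#'
#' Values are written at full double precision, so a read back reproduces
#' the HU grid exactly.
#'
#' @param image An [hu_image].
#' @param path Output path (the sidecar goes next to it).
#' @param rescale_slope,rescale_intercept Calibration under which the
#'   stored values are written (stored = (HU - intercept) / slope).
#' @return `path`, invisibly.
#' @export
write_ct_raster <- function(image, path, rescale_slope = 1,
                            rescale_intercept = 0) {
  stored <- (as_plain_matrix(image) - rescale_intercept) / rescale_slope
  txt <- apply(stored, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, path)
  jsonlite::write_json(list(pixel_spacing = pixel_spacing(image),
                            rescale_slope = rescale_slope,
                            rescale_intercept = rescale_intercept),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- minimal single-frame DICOM (little endian, uncompressed) ----------

dcm_uint16 <- function(raw) readBin(raw, "integer", n = length(raw) / 2,
                                    size = 2, signed = FALSE, endian = "little")
dcm_int16 <- function(raw) readBin(raw, "integer", n = length(raw) / 2,
                                   size = 2, signed = TRUE, endian = "little")
dcm_uint32 <- function(raw) {
  lo <- dcm_uint16(raw[1:2]); hi <- dcm_uint16(raw[3:4])
  hi * 65536 + lo
}

#' Read a single-frame uncompressed DICOM CT image
#'
#' Supports implicit and explicit VR little endian with 16-bit pixel data.
#' Rescale Slope/Intercept (0028,1053 / 0028,1052) and Pixel Spacing
#' (0028,0030) are honored; files without Pixel Spacing are refused.
#' Sequences and encapsulated (compressed) transfer syntaxes are not
#' supported.
#'
#' @param path DICOM file path.
#' @return An [hu_image].
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  if (length(bytes) > 132 && rawToChar(bytes[129:132]) == "DICM") pos <- 133L
  tags <- list()
  explicit <- NA  # decided from the first element
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= length(bytes)) {
    group <- dcm_uint16(bytes[pos:(pos + 1)])
    elem <- dcm_uint16(bytes[(pos + 2):(pos + 3)])
    vrb <- bytes[(pos + 4):(pos + 5)]
    looks_explicit <- all(vrb >= as.raw(0x41) & vrb <= as.raw(0x5A))
    vr_chars <- if (looks_explicit) rawToChar(vrb) else ""
    if (is.na(explicit) || group == 0x0002) {
      exp_here <- looks_explicit  # file meta group is always explicit
      if (is.na(explicit) && group != 0x0002) explicit <- looks_explicit
    } else exp_here <- explicit
    if (exp_here) {
      vr <- vr_chars
      if (vr %in% long_vrs) {
        len <- dcm_uint32(bytes[(pos + 8):(pos + 11)])
        hdr <- 12L
      } else {
        len <- dcm_uint16(bytes[(pos + 6):(pos + 7)])
        hdr <- 8L
      }
      if (vr == "SQ") stopf("DICOM sequences are not supported (tag %04x,%04x)", group, elem)
    } else {
      vr <- NA_character_
      len <- dcm_uint32(bytes[(pos + 4):(pos + 7)])
      hdr <- 8L
    }
    if (len == 4294967295) stopf("undefined-length DICOM elements are not supported")
    val_start <- pos + hdr
    if (val_start + len - 1 > length(bytes))
      stopf("truncated DICOM element (%04x,%04x)", group, elem)
    value <- if (len > 0) bytes[val_start:(val_start + len - 1)] else raw(0)
    tags[[sprintf("%04x%04x", group, elem)]] <- list(vr = vr, value = value)
    pos <- val_start + len
  }
  get_str <- function(tag) {
    t <- tags[[tag]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$value))
  }
  get_u16 <- function(tag) {
    t <- tags[[tag]]
    if (is.null(t)) return(NULL)
    dcm_uint16(t$value[1:2])
  }
  rows <- get_u16("00280010"); cols <- get_u16("00280011")
  if (is.null(rows) || is.null(cols)) stopf("DICOM file lacks Rows/Columns")
  bits <- get_u16("00280100") %||% 16
  if (bits != 16) stopf("only 16-bit DICOM pixel data is supported (got %d)", bits)
  pixrep <- get_u16("00280103") %||% 0
  spacing_str <- get_str("00280030")
  if (is.null(spacing_str))
    stopf("DICOM file has no Pixel Spacing (0028,0030); refusing an uncalibrated image")
  spacing <- as.numeric(strsplit(spacing_str, "\\\\")[[1]])
  slope <- as.numeric(get_str("00281053") %||% "1")
  intercept <- as.numeric(get_str("00281052") %||% "0")
  px <- tags[["7fe00010"]]
  if (is.null(px)) stopf("DICOM file has no pixel data")
  stored <- if (pixrep == 1) dcm_int16(px$value) else dcm_uint16(px$value)
  if (length(stored) < rows * cols) stopf("DICOM pixel data is truncated")
  stored <- matrix(stored[seq_len(rows * cols)], nrow = rows, byrow = TRUE)
  hu_image(slope * stored + intercept, pixel_spacing = spacing)
}

#' Write a single-frame explicit-VR little-endian DICOM file
#'
#' Minimal writer (CT Image Storage-like attribute set) used to exchange
#' synthetic images and to exercise the reader; stored values are 16-bit.
#'
#' @param image An [hu_image].
#' @param path Output path.
#' @param rescale_slope,rescale_intercept Calibration; stored = (HU -
#'   intercept) / slope, rounded to the nearest integer, so choose a
#'   calibration under which your values are integral if losslessness
#'   matters.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(image, path, rescale_slope = 1,
                        rescale_intercept = -1024) {
  stored <- round((as_plain_matrix(image) - rescale_intercept) / rescale_slope)
  if (any(stored < -32768 | stored > 65535))
    stopf("stored values out of 16-bit range under this calibration")
  signed <- any(stored < 0)
  if (signed && any(stored > 32767))
    stopf("stored values out of signed 16-bit range")
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  short_el <- function(group, elem, vr, value_raw) {
    if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0x20))
    c(u16(group), u16(elem), charToRaw(vr), u16(length(value_raw)), value_raw)
  }
  long_el <- function(group, elem, vr, value_raw) {
    c(u16(group), u16(elem), charToRaw(vr), as.raw(c(0, 0)),
      u32(length(value_raw)), value_raw)
  }
  str_raw <- function(s) charToRaw(s)
  sp <- pixel_spacing(image)
  ts <- str_raw("1.2.840.10008.1.2.1")  # explicit VR little endian
  body <- c(
    short_el(0x0008, 0x0060, "CS", str_raw("CT")),
    short_el(0x0028, 0x0002, "US", u16(1)),
    short_el(0x0028, 0x0004, "CS", str_raw("MONOCHROME2")),
    short_el(0x0028, 0x0010, "US", u16(nrow(image))),
    short_el(0x0028, 0x0011, "US", u16(ncol(image))),
    short_el(0x0028, 0x0030, "DS", str_raw(sprintf("%.10g\\%.10g", sp[1], sp[2]))),
    short_el(0x0028, 0x0100, "US", u16(16)),
    short_el(0x0028, 0x0101, "US", u16(16)),
    short_el(0x0028, 0x0102, "US", u16(15)),
    short_el(0x0028, 0x0103, "US", u16(if (signed) 1 else 0)),
    short_el(0x0028, 0x1052, "DS", str_raw(sprintf("%.10g", rescale_intercept))),
    short_el(0x0028, 0x1053, "DS", str_raw(sprintf("%.10g", rescale_slope))),
    long_el(0x7fe0, 0x0010, "OW",
            writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  inner <- c(long_el(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
             short_el(0x0002, 0x0010, "UI", ts))
  writeBin(c(short_el(0x0002, 0x0000, "UL", u32(length(inner))), inner, body),
           con)
  invisible(path)
}

#' Read a polygonal ROI from a vertex text file
#'
#' Whitespace- or comma-separated file with two columns (row, col) in
#' pixel coordinates (0-based, centers at integers); lines starting with
#' `#` are comments.
#'
#' @param path Vertex file path.
#' @return An [roi_polygon].
#' @export
read_roi <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  v <- do.call(rbind, lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]])))
  roi_polygon(v)
}

#' @rdname read_roi
#' @param polygon An [roi_polygon].
#' @export
write_roi <- function(polygon, path) {
  stopifnot(inherits(polygon, "roi_polygon"))
  writeLines(c("# ROI vertices: row col (pixel coordinates, 0-based)",
               apply(polygon$vertices, 1, function(r)
                 sprintf("%.10g %.10g", r[1], r[2]))), path)
  invisible(path)
}
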