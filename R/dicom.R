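# Minimal DICOM part-10 codec for single-frame CT image objects, explicit VR
# little endian only. Covers exactly the elements the Dw pipeline needs:
# pixel data, rescale slope/intercept, pixel spacing, slice location, tube
# current, series identity. Compressed transfer syntaxes and enhanced
# multi-frame CT are out of scope.

.ts_explicit_le <- "1.2.840.10008.1.2.1"
.sop_ct_image <- "1.2.840.10008.5.1.4.1.1.2"
.uid_root <- "1.2.826.0.1.3680043.9590"

# VRs using the 12-byte (long) explicit header form.
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

.pad_even <- function(raw, pad) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

.enc_string <- function(x, nul = FALSE) {
  .pad_even(charToRaw(as.character(x)), if (nul) as.raw(0L) else charToRaw(" "))
}

.enc_uint <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

# One explicit-VR element as a raw vector.
.enc_element <- function(group, elem, vr, value_raw) {
  head <- c(.enc_uint(group, 2L), .enc_uint(elem, 2L), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(head, as.raw(c(0L, 0L)), .enc_uint(length(value_raw), 4L), value_raw)
  } else {
    if (length(value_raw) > 65534L)
      stop("value too long for short-form VR ", vr)
    c(head, .enc_uint(length(value_raw), 2L), value_raw)
  }
}

.fmt_ds <- function(x) paste(vapply(x, function(v) sprintf("%.8g", v), ""),
                             collapse = "\\")

# Build the raw bytes of one CT file.
.encode_ct_file <- function(slice, series_uid, sop_uid, rescale_slope,
                            rescale_intercept) {
  px <- slice$pixels
  raw_vals <- round((px - rescale_intercept) / rescale_slope)
  if (any(raw_vals < -32768 | raw_vals > 32767))
    stop("pixel values out of int16 range after rescale encoding")
  pixel_raw <- writeBin(as.integer(t(raw_vals)), raw(), size = 2L,
                        endian = "little")

  ds <- c(
    .enc_element(0x0008, 0x0016, "UI", .enc_string(.sop_ct_image, nul = TRUE)),
    .enc_element(0x0008, 0x0018, "UI", .enc_string(sop_uid, nul = TRUE)),
    .enc_element(0x0008, 0x0060, "CS", .enc_string("CT")),
    if (!is.null(slice$tube_current) && !is.na(slice$tube_current))
      .enc_element(0x0018, 0x1151, "IS",
                   .enc_string(sprintf("%d", as.integer(round(slice$tube_current))))),
    .enc_element(0x0020, 0x000D, "UI",
                 .enc_string(paste0(series_uid, ".0"), nul = TRUE)),
    .enc_element(0x0020, 0x000E, "UI", .enc_string(series_uid, nul = TRUE)),
    .enc_element(0x0020, 0x0013, "IS",
                 .enc_string(sprintf("%d", as.integer(slice$slice_id)))),
    .enc_element(0x0020, 0x1041, "DS", .enc_string(.fmt_ds(slice$z_position))),
    .enc_element(0x0028, 0x0002, "US", .enc_uint(1L, 2L)),
    .enc_element(0x0028, 0x0004, "CS", .enc_string("MONOCHROME2")),
    .enc_element(0x0028, 0x0010, "US", .enc_uint(nrow(px), 2L)),
    .enc_element(0x0028, 0x0011, "US", .enc_uint(ncol(px), 2L)),
    .enc_element(0x0028, 0x0030, "DS",
                 .enc_string(.fmt_ds(slice$pixel_spacing))),
    .enc_element(0x0028, 0x0100, "US", .enc_uint(16L, 2L)),
    .enc_element(0x0028, 0x0101, "US", .enc_uint(16L, 2L)),
    .enc_element(0x0028, 0x0102, "US", .enc_uint(15L, 2L)),
    .enc_element(0x0028, 0x0103, "US", .enc_uint(1L, 2L)),
    .enc_element(0x0028, 0x1052, "DS", .enc_string(.fmt_ds(rescale_intercept))),
    .enc_element(0x0028, 0x1053, "DS", .enc_string(.fmt_ds(rescale_slope))),
    .enc_element(0x7FE0, 0x0010, "OW", pixel_raw)
  )

  meta_body <- c(
    .enc_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    .enc_element(0x0002, 0x0002, "UI", .enc_string(.sop_ct_image, nul = TRUE)),
    .enc_element(0x0002, 0x0003, "UI", .enc_string(sop_uid, nul = TRUE)),
    .enc_element(0x0002, 0x0010, "UI", .enc_string(.ts_explicit_le, nul = TRUE)),
    .enc_element(0x0002, 0x0012, "UI", .enc_string(.uid_root, nul = TRUE))
  )
  meta <- c(.enc_element(0x0002, 0x0000, "UL",
                         .enc_uint(length(meta_body), 4L)),
            meta_body)

  c(raw(128L), charToRaw("DICM"), meta, ds)
}

# --- decoding ---------------------------------------------------------------

.dec_uint <- function(raw, offset, size) {
  # size 4 reads as signed int; DICOM lengths here are far below 2^31
  readBin(raw[(offset + 1L):(offset + size)], "integer", size = size,
          endian = "little", signed = (size == 4L))
}

# Parse explicit-VR elements from `offset` while group matches `group_filter`
# (NULL = parse to end). Returns list(elements = named list, offset = next).
.parse_elements <- function(raw, offset, end, group_filter = NULL) {
  out <- list()
  while (offset < end) {
    group <- .dec_uint(raw, offset, 2L)
    if (!is.null(group_filter) && group != group_filter) break
    elem <- .dec_uint(raw, offset + 2L, 2L)
    vr <- rawToChar(raw[(offset + 5L):(offset + 6L)])
    if (vr %in% .long_vrs) {
      len <- .dec_uint(raw, offset + 8L, 4L)
      val_off <- offset + 12L
    } else {
      len <- .dec_uint(raw, offset + 6L, 2L)
      val_off <- offset + 8L
    }
    if (val_off + len > end)
      stop("truncated DICOM element ", .tag_key(group, elem))
    value <- raw[seq_len(len) + val_off]
    out[[.tag_key(group, elem)]] <- list(vr = vr, value = value)
    offset <- val_off + len
  }
  list(elements = out, offset = offset)
}

.dec_string <- function(el) {
  if (is.null(el)) return(NULL)
  s <- rawToChar(el$value[el$value != as.raw(0L)])
  trimws(s)
}

.dec_numbers <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(.dec_string(el), "\\\\")[[1]])
}

.dec_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", n = length(el$value) / 2L, size = 2L,
          endian = "little", signed = FALSE)
}

# Parse one CT file into slice fields plus series metadata.
.decode_ct_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  meta <- .parse_elements(raw, 132L, length(raw), group_filter = 0x0002)
  ts <- .dec_string(meta$elements[["0002,0010"]])
  if (!identical(ts, .ts_explicit_le))
    stop("unsupported transfer syntax '", ts, "' in ", path)
  ds <- .parse_elements(raw, meta$offset, length(raw))$elements

  rows <- .dec_us(ds[["0028,0010"]])
  cols <- .dec_us(ds[["0028,0011"]])
  slope <- .dec_numbers(ds[["0028,1053"]])
  intercept <- .dec_numbers(ds[["0028,1052"]])
  if (is.null(slope) || is.null(intercept))
    stop("missing rescale slope/intercept in ", path)
  spacing <- .dec_numbers(ds[["0028,0030"]])
  if (is.null(spacing) || length(spacing) != 2L || any(spacing <= 0))
    stop("missing or invalid pixel spacing in ", path)
  z <- .dec_numbers(ds[["0020,1041"]])
  if (is.null(z)) stop("missing slice location in ", path)
  signed <- identical(.dec_us(ds[["0028,0103"]]), 1L)

  px_el <- ds[["7FE0,0010"]]
  if (is.null(px_el)) stop("missing pixel data in ", path)
  vals <- readBin(px_el$value, "integer", n = rows * cols, size = 2L,
                  endian = "little", signed = signed)
  pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  list(
    pixels_raw = pixels,
    rescale_slope = slope,
    rescale_intercept = intercept,
    pixel_spacing = spacing,
    z_position = z,
    tube_current = {
      tc <- .dec_numbers(ds[["0018,1151"]])
      if (is.null(tc)) NA_real_ else tc
    },
    instance_number = {
      inn <- .dec_numbers(ds[["0020,0013"]])
      if (is.null(inn)) NA_integer_ else as.integer(inn)
    },
    series_uid = .dec_string(ds[["0020,000E"]])
  )
}

# Deterministic series UID from content, so identical series write
# byte-identical files.
.series_uid_for <- function(series) {
  z <- vapply(series$slices, function(s) s$z_position, 0)
  h <- 0
  for (v in c(length(z), round(z * 100),
              round(sum(abs(series$slices[[1]]$pixels)) %% 1e7)))
    h <- (h * 31 + (v %% 1e6)) %% 1e9
  sprintf("%s.%d.%d", .uid_root, length(z), as.integer(h))
}

#' Replace out-of-field padding sentinels with air
#'
#' CT vendors pad pixels outside the reconstruction circle with large negative
#' sentinel values (commonly -2000 or -3024 HU). Because air contributes zero
#' water-equivalent area, replacing sentinels with -1000 HU (air) leaves
#' \code{\link{slice_dw}} unchanged relative to a sentinel-free image while
#' removing the vendor dependence.
#'
#' @param pixels Numeric matrix of CT numbers in HU.
#' @param sentinel_threshold Values strictly below this threshold are treated
#'   as padding; must be \eqn{\le} -1500 HU. Default -1500.
#' @return The matrix with all padding pixels set to -1000 HU.
#' @export
#' @examples
#' mask_padding(matrix(c(-3024, -1000, 0, 50), 2, 2))
mask_padding <- function(pixels, sentinel_threshold = -1500) {
  if (sentinel_threshold > -1500)
    stop("'sentinel_threshold' must be <= -1500 HU")
  pixels[pixels < sentinel_threshold] <- -1000
  pixels
}

#' Read a CT image series
#'
#' Reads all DICOM files of one series, converts stored pixel values to
#' Hounsfield units via the per-file rescale slope/intercept, masks padding
#' sentinels, and returns slices sorted by ascending table position. The
#' result does not depend on the order of the input files.
#'
#' @param path Directory containing the files, or a character vector of file
#'   paths.
#' @param ctdi_vol Examination CTDIvol in mGy (32-cm body phantom reference).
#'   Not read from image metadata; inject it here or set it later. Default
#'   `NA`.
#' @param exam_type One of `"chest"`, `"CAP"`, `"phantom"`.
#' @param scanner_id Scanner label.
#' @param sentinel_threshold Padding threshold passed to
#'   \code{\link{mask_padding}}.
#' @return A [scan_series] object.
#' @export
read_series <- function(path, ctdi_vol = NA_real_, exam_type = "phantom",
                        scanner_id = "unknown", sentinel_threshold = -1500) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  } else {
    path
  }
  if (length(files) == 0L) stop("no DICOM files found")
  decoded <- lapply(files, .decode_ct_file)

  uids <- vapply(decoded, function(d) d$series_uid %||% "", "")
  if (length(unique(uids)) > 1L) {
    bad <- files[uids != uids[1L]][1L]
    stop("mixed series identifiers; offending file: ", bad)
  }
  spacings <- t(vapply(decoded, function(d) d$pixel_spacing, c(0, 0)))
  if (nrow(unique(round(spacings, 6))) > 1L)
    warning("nonuniform pixel spacing across slices; per-slice spacing retained")

  slices <- lapply(seq_along(decoded), function(i) {
    d <- decoded[[i]]
    hu <- d$pixels_raw * d$rescale_slope + d$rescale_intercept
    ct_slice(pixels = mask_padding(hu, sentinel_threshold),
             pixel_spacing = d$pixel_spacing,
             z_position = d$z_position,
             tube_current = d$tube_current,
             slice_id = d$instance_number %||% i)
  })
  scan_series(slices, ctdi_vol = ctdi_vol, exam_type = exam_type,
              scanner_id = scanner_id)
}

#' Write a CT image series
#'
#' Writes one DICOM file per slice (explicit VR little endian, rescale slope 1
#' and intercept -1024) such that \code{\link{read_series}} reproduces the
#' series: metadata exactly (tube current rounded to the nearest mA, the
#' stored unit) and pixels within rescale quantization (0.5 HU).
#'
#' @param series A [scan_series] object.
#' @param path Output directory (created if needed).
#' @return Invisibly, the vector of files written, in slice order.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "scan_series"))
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", path)
  uid <- .series_uid_for(series)
  files <- character(length(series$slices))
  for (i in seq_along(series$slices)) {
    sl <- series$slices[[i]]
    sop <- sprintf("%s.%d", uid, i)
    bytes <- .encode_ct_file(sl, uid, sop,
                             rescale_slope = 1, rescale_intercept = -1024)
    files[i] <- file.path(path, sprintf("slice_%04d.dcm", i))
    writeBin(bytes, files[i])
  }
  invisible(files)
}
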