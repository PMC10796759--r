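# Minimal DICOM support: uncompressed, explicit-VR little-endian, single-frame
# CT slices, one file per slice. This covers the subset of the standard that
# axial thin-slice CT exports use; anything else (implicit VR, compressed
# transfer syntaxes, oblique orientations, multi-frame objects) is rejected
# with a clear error.

.dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
.dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                 endian = "little")

.dcm_pad <- function(value, pad) {
  if (length(value) %% 2L == 1L) value <- c(value, pad)
  value
}

# Encode one data element (explicit VR little endian).
.dcm_element <- function(group, element, vr, value) {
  if (is.character(value)) value <- charToRaw(paste(value, collapse = "\\"))
  value <- .dcm_pad(value, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  tag <- c(.dcm_u16(group), .dcm_u16(element))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)), .dcm_u32(length(value)), value)
  } else {
    if (length(value) > 65534L) rlang::abort("DICOM element value too long")
    c(tag, charToRaw(vr), .dcm_u16(length(value)), value)
  }
}

.dcm_ds <- function(x) paste(sprintf("%.10g", x), collapse = "\\")

.dcm_uid_root <- "1.2.826.0.1.3680043.9.7453"

# Write one CT slice; `data_xy` is the in-plane matrix with x (column index of
# the DICOM image) as the first R dimension.
.dcm_write_slice <- function(path, data_xy, instance, position, pixel_spacing,
                             slice_thickness, series_uid, study_uid,
                             intercept, slope) {
  stored <- as.integer(round((data_xy - intercept) / slope))
  if (any(stored < -32768L) || any(stored > 32767L))
    rlang::abort("HU values out of int16 stored range for chosen rescale")
  nx <- nrow(data_xy); ny <- ncol(data_xy)
  # DICOM pixel order is row-major with rows = y; iterating our matrix
  # column-major runs x fastest within each y row, which matches.
  pix <- writeBin(stored, raw(), size = 2, endian = "little")
  sop_uid <- sprintf("%s.%s.%d", .dcm_uid_root, series_uid_suffix(series_uid),
                     instance)
  ds <- c(
    .dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    .dcm_element(0x0008, 0x0018, "UI", sop_uid),
    .dcm_element(0x0008, 0x0060, "CS", "CT"),
    .dcm_element(0x0018, 0x0050, "DS", .dcm_ds(slice_thickness)),
    .dcm_element(0x0020, 0x000D, "UI", study_uid),
    .dcm_element(0x0020, 0x000E, "UI", series_uid),
    .dcm_element(0x0020, 0x0013, "IS", sprintf("%d", instance)),
    .dcm_element(0x0020, 0x0032, "DS", .dcm_ds(position)),
    .dcm_element(0x0020, 0x0037, "DS", .dcm_ds(c(1, 0, 0, 0, 1, 0))),
    .dcm_element(0x0028, 0x0002, "US", .dcm_u16(1)),
    .dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_element(0x0028, 0x0010, "US", .dcm_u16(ny)),   # Rows (y)
    .dcm_element(0x0028, 0x0011, "US", .dcm_u16(nx)),   # Columns (x)
    .dcm_element(0x0028, 0x0030, "DS",
                 .dcm_ds(c(pixel_spacing[2], pixel_spacing[1]))),
    .dcm_element(0x0028, 0x0100, "US", .dcm_u16(16)),
    .dcm_element(0x0028, 0x0101, "US", .dcm_u16(16)),
    .dcm_element(0x0028, 0x0102, "US", .dcm_u16(15)),
    .dcm_element(0x0028, 0x0103, "US", .dcm_u16(1)),
    .dcm_element(0x0028, 0x1052, "DS", .dcm_ds(intercept)),
    .dcm_element(0x0028, 0x1053, "DS", .dcm_ds(slope)),
    .dcm_element(0x7FE0, 0x0010, "OW", pix)
  )
  meta_body <- c(
    .dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    .dcm_element(0x0002, 0x0003, "UI", sop_uid),
    .dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  meta <- c(.dcm_element(0x0002, 0x0000, "UL", .dcm_u32(length(meta_body))),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

series_uid_suffix <- function(uid) {
  parts <- strsplit(uid, ".", fixed = TRUE)[[1]]
  parts[length(parts)]
}

write_dicom_series <- function(volume, path, intercept = -1024, slope = 1) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  d <- dim(volume$data)
  series_uid <- sprintf("%s.1.%d", .dcm_uid_root,
                        abs(sum(d) + round(1000 * sum(volume$spacing))))
  study_uid <- sprintf("%s.0.1", .dcm_uid_root)
  for (k in seq_len(d[3])) {
    pos <- c(volume$origin[1], volume$origin[2],
             volume$origin[3] + (k - 1) * volume$spacing[3])
    .dcm_write_slice(file.path(path, sprintf("slice%04d.dcm", k)),
                     volume$data[, , k], k, pos, volume$spacing[1:2],
                     volume$spacing[3], series_uid, study_uid, intercept,
                     slope)
  }
  invisible(path)
}

# --- reading ----------------------------------------------------------------

.dcm_read_u16 <- function(raw, at)
  readBin(raw[at:(at + 1)], "integer", size = 2, endian = "little",
          signed = FALSE)
.dcm_read_u32 <- function(raw, at)
  readBin(raw[at:(at + 3)], "integer", size = 4, endian = "little")

# Parse all data elements of one file; returns list keyed "GGGGEEEE" with raw
# values (and the VR seen).
.dcm_parse <- function(raw_bytes) {
  n <- length(raw_bytes)
  if (n < 140 || rawToChar(raw_bytes[129:132]) != "DICM")
    rlang::abort("not a DICOM part-10 file (missing DICM marker)")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  known_vrs <- c(long_vrs, "AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL",
                 "FD", "IS", "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM",
                 "UI", "UL", "US")
  out <- list()
  at <- 133L
  while (at + 7L <= n) {
    group <- .dcm_read_u16(raw_bytes, at)
    element <- .dcm_read_u16(raw_bytes, at + 2L)
    vr <- rawToChar(raw_bytes[(at + 4L):(at + 5L)])
    if (!vr %in% known_vrs)
      rlang::abort("unsupported DICOM encoding (implicit VR or corrupt file)")
    if (vr %in% long_vrs) {
      len <- .dcm_read_u32(raw_bytes, at + 8L)
      val_at <- at + 12L
    } else {
      len <- .dcm_read_u16(raw_bytes, at + 6L)
      val_at <- at + 8L
    }
    if (len < 0 || val_at + len - 1L > n)
      rlang::abort("truncated DICOM element")
    key <- sprintf("%04X%04X", group, element)
    out[[key]] <- list(
      vr = vr,
      value = if (len > 0) raw_bytes[val_at:(val_at + len - 1L)] else raw(0))
    at <- val_at + len
  }
  out
}

.dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  v <- el$value
  v <- v[v != as.raw(0)]  # UI values are null-padded
  trimws(rawToChar(v))
}
.dcm_num <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(.dcm_str(el), "\\", fixed = TRUE)[[1]])
}
.dcm_us <- function(el)
  readBin(el$value, "integer", size = 2, endian = "little", signed = FALSE)

.dcm_read_slice <- function(path) {
  elems <- .dcm_parse(readBin(path, "raw", file.size(path)))
  ts <- .dcm_str(elems[["00020010"]])
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    rlang::abort(sprintf("unsupported transfer syntax %s in %s", ts, path))
  rows <- .dcm_us(elems[["00280010"]])
  cols <- .dcm_us(elems[["00280011"]])
  bits <- .dcm_us(elems[["00280100"]])
  if (bits != 16L)
    rlang::abort("only 16-bit DICOM pixel data is supported")
  signed <- isTRUE(.dcm_us(elems[["00280103"]]) == 1L)
  orient <- .dcm_num(elems[["00200037"]])
  if (is.null(orient) || max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    rlang::abort("oblique DICOM orientation is not supported (axis-aligned only)")
  pix <- readBin(elems[["7FE00010"]]$value, "integer", n = rows * cols,
                 size = 2, endian = "little", signed = signed)
  slope <- .dcm_num(elems[["00281053"]]); if (is.null(slope)) slope <- 1
  inter <- .dcm_num(elems[["00281052"]]); if (is.null(inter)) inter <- 0
  ps <- .dcm_num(elems[["00280030"]])   # row spacing (y), column spacing (x)
  list(data_xy = matrix(slope * pix + inter, nrow = cols, ncol = rows),
       position = .dcm_num(elems[["00200032"]]),
       spacing_xy = c(ps[2], ps[1]),
       series = .dcm_str(elems[["0020000E"]]))
}

read_dicom_series <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L)
    rlang::abort("a DICOM series directory needs >= 2 slice files")
  slices <- lapply(sort(files), .dcm_read_slice)
  series <- vapply(slices, `[[`, "", "series")
  if (length(unique(series)) != 1L)
    rlang::abort("mixed series: directory contains more than one SeriesInstanceUID")
  z <- vapply(slices, function(s) s$position[3], 0)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  gaps <- diff(z)
  med <- stats::median(gaps)
  if (med <= 0 || any(abs(gaps - med) > 1e-3 * med)) {
    bad <- which.max(abs(gaps - med))
    rlang::abort(sprintf(
      "non-uniform slice gaps: gap of %.6g mm between slices %d and %d (expected %.6g mm)",
      gaps[bad], bad, bad + 1L, med))
  }
  d1 <- slices[[1]]
  arr <- array(0, c(nrow(d1$data_xy), ncol(d1$data_xy), length(slices)))
  for (k in seq_along(slices)) {
    if (!identical(dim(slices[[k]]$data_xy), dim(d1$data_xy)))
      rlang::abort("slice matrix sizes differ within the series")
    arr[, , k] <- slices[[k]]$data_xy
  }
  ct_volume(arr, spacing = c(d1$spacing_xy, med),
            origin = c(d1$position[1], d1$position[2], z[1]))
}
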