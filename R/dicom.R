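# Minimal DICOM (CT Image Storage, explicit VR little endian) writer and
# series reader. Covers exactly what the focused-view pipeline needs: one
# single-frame 16-bit CT file per slice with geometry and HU rescale tags.
# RescaleIntercept is fixed at -1024 with slope 1 so the -1000 HU mask
# value is an exact stored integer (stored value 24).

UID_ROOT <- "1.2.826.0.1.3680043.10763"
CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# deterministic UID component derived from content (no digest dependency)
content_uid <- function(values, salt = 0) {
  v <- as.numeric(values)
  h <- (sum(v %% 9973) + salt * 7919) %% 1e8
  sprintf("%s.%d.%d", UID_ROOT, as.integer(h), length(v) %% 1e6)
}

#' DICOM series metadata template
#'
#' Describes the series-level tags used when exporting a volume as a DICOM
#' series. The rescale mapping is fixed at slope 1, intercept -1024.
#'
#' @param modality DICOM modality code, default `"CT"`.
#' @param series_uid,study_uid series/study instance UIDs; generated when
#'   `NULL`.
#' @param slice_thickness_mm optional; defaults to the volume's z spacing.
#' @return An object of class `series_meta`.
#' @export
series_meta <- function(modality = "CT", series_uid = NULL,
                        study_uid = NULL, slice_thickness_mm = NULL) {
  structure(list(modality = modality, series_uid = series_uid,
                 study_uid = study_uid,
                 slice_thickness_mm = slice_thickness_mm,
                 rescale_slope = 1, rescale_intercept = -1024),
            class = "series_meta")
}

dcm_short_vrs <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD",
                   "IS", "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM",
                   "UI", "UL", "US")

dcm_element <- function(group, element, vr, value) {
  tag <- writeBin(as.integer(c(group, element)), raw(), size = 2L,
                  endian = "little")
  if (vr %in% c("US", "UL", "SS", "SL")) {
    sz <- if (vr %in% c("US", "SS")) 2L else 4L
    val <- writeBin(as.integer(value), raw(), size = sz, endian = "little")
  } else if (vr == "OW") {
    val <- value  # already raw
  } else {
    val <- charToRaw(as.character(value))
    if (length(val) %% 2L == 1L)
      val <- c(val, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  if (vr %in% dcm_short_vrs) {
    c(tag, charToRaw(vr),
      writeBin(length(val), raw(), size = 2L, endian = "little"), val)
  } else {
    c(tag, charToRaw(vr), as.raw(c(0L, 0L)),
      writeBin(length(val), raw(), size = 4L, endian = "little"), val)
  }
}

ds_num <- function(x) paste(formatC(x, format = "g", digits = 10),
                            collapse = "\\")

write_dicom_slice <- function(path, pixels_stored, meta, sop_uid,
                              instance, position, spacing) {
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", CT_SOP_CLASS),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", meta$modality),
    dcm_element(0x0020, 0x000D, "UI", meta$study_uid),
    dcm_element(0x0020, 0x000E, "UI", meta$series_uid),
    dcm_element(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_element(0x0020, 0x0032, "DS", ds_num(position)),
    dcm_element(0x0020, 0x0037, "DS", ds_num(c(1, 0, 0, 0, 1, 0))),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", ncol(pixels_stored)),   # Rows (y)
    dcm_element(0x0028, 0x0011, "US", nrow(pixels_stored)),   # Columns (x)
    dcm_element(0x0028, 0x0030, "DS", ds_num(spacing[c(2, 1)])),
    dcm_element(0x0018, 0x0050, "DS", ds_num(meta$slice_thickness_mm)),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x0028, 0x1052, "DS", ds_num(meta$rescale_intercept)),
    dcm_element(0x0028, 0x1053, "DS", ds_num(meta$rescale_slope)),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(as.integer(pixels_stored), raw(), size = 2L,
                         endian = "little")))
  meta_grp <- c(
    dcm_element(0x0002, 0x0002, "UI", CT_SOP_CLASS),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE))
  meta_grp <- c(dcm_element(0x0002, 0x0000, "UL", length(meta_grp)),
                meta_grp)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_grp, body), con)
  invisible(path)
}

#' Export a volume as a DICOM series
#'
#' Writes one explicit-VR little-endian CT Image Storage file per axial
#' slice, with HU mapped through stored = HU - intercept (slope 1,
#' intercept -1024, so -1000 HU is exactly representable and re-reading
#' reproduces intensities within the half-unit integer quantization). The
#' series always receives a fresh series UID distinct from the template's.
#'
#' @param volume a HU-valued [cta_volume()] with at least one slice.
#' @param template a [series_meta()]; `NULL` for defaults.
#' @param path output directory (created if missing).
#' @return Character vector of written file paths, one per slice.
#' @export
write_focused_dicom <- function(volume, template = series_meta(), path) {
  if (!inherits(volume, "cta_volume")) stop("volume must be a cta_volume")
  d <- dim(volume$intensities)
  if (any(d == 0L)) stop("volume has zero slices")
  if (is.null(template)) template <- series_meta()
  meta <- template
  meta$series_uid <- content_uid(volume$intensities[seq(1, length(volume$intensities), length.out = 257)],
                                 salt = d[3])
  if (!is.null(template$series_uid) &&
      identical(meta$series_uid, template$series_uid))
    meta$series_uid <- paste0(meta$series_uid, ".1")
  if (is.null(meta$study_uid)) meta$study_uid <- paste0(UID_ROOT, ".7.1")
  if (is.null(meta$slice_thickness_mm))
    meta$slice_thickness_mm <- volume$spacing[3]
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  stored <- round(volume$intensities - meta$rescale_intercept)
  stored[stored < 0] <- 0
  stored[stored > 65535] <- 65535
  files <- character(d[3])
  for (z in seq_len(d[3])) {
    pos <- volume$origin + c(0, 0, (z - 1) * volume$spacing[3])
    f <- file.path(path, sprintf("slice_%04d.dcm", z))
    write_dicom_slice(f, stored[, , z, drop = TRUE], meta,
                      sop_uid = sprintf("%s.%d", meta$series_uid, z),
                      instance = z, position = pos,
                      spacing = volume$spacing[1:2])
    files[z] <- f
  }
  files
}

read_dicom_elements <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  if (length(bytes) < 140L ||
      rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(bytes)) {
    grp <- readBin(bytes[pos:(pos + 1L)], "integer", size = 2L,
                   signed = FALSE, endian = "little")
    ele <- readBin(bytes[(pos + 2L):(pos + 3L)], "integer", size = 2L,
                   signed = FALSE, endian = "little")
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- readBin(bytes[(pos + 8L):(pos + 11L)], "integer", size = 4L,
                     endian = "little")
      vstart <- pos + 12L
    } else {
      len <- readBin(bytes[(pos + 6L):(pos + 7L)], "integer", size = 2L,
                     signed = FALSE, endian = "little")
      vstart <- pos + 8L
    }
    key <- sprintf("%04X%04X", grp, ele)
    val_raw <- if (len > 0L) bytes[vstart:(vstart + len - 1L)] else raw(0)
    out[[key]] <- list(vr = vr, raw = val_raw)
    pos <- vstart + len
    if (key == "7FE00010") break
  }
  out
}

dcm_str <- function(el) {
  if (is.null(el)) return(NA_character_)
  trimws(rawToChar(el$raw[el$raw != as.raw(0)]))
}

dcm_nums <- function(el) as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])

dcm_us <- function(el) readBin(el$raw, "integer", size = 2L, signed = FALSE,
                               endian = "little")

#' Read a DICOM series directory as a volume
#'
#' Reads every `.dcm` file in a directory, verifies that all files belong
#' to one series with a consistent grid, sorts slices by their position
#' along the stacking axis, maps stored values through
#' RescaleSlope/Intercept to HU, and rejects interleaved series, missing
#' slices, and non-uniform slice spacing.
#'
#' @param path directory containing one DICOM series.
#' @return A [cta_volume()].
#' @export
read_dicom_series <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) stop("no DICOM files found in ", path)
  slices <- lapply(files, read_dicom_elements)
  series <- vapply(slices, function(s) dcm_str(s[["0020000E"]]), "")
  if (length(unique(series)) > 1L)
    stop("directory contains ", length(unique(series)),
         " interleaved DICOM series; expected one")
  rows <- vapply(slices, function(s) dcm_us(s[["00280010"]]), 0L)
  cols <- vapply(slices, function(s) dcm_us(s[["00280011"]]), 0L)
  if (length(unique(rows)) > 1L || length(unique(cols)) > 1L)
    stop("inconsistent slice dimensions within series")
  zpos <- vapply(slices, function(s) dcm_nums(s[["00200032"]])[3], 0)
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]
  if (length(zpos) > 1L) {
    dz <- diff(zpos)
    if (any(dz <= 0)) stop("duplicate slice positions in series")
    if (max(dz) - min(dz) > 1e-3 * max(dz))
      stop("non-uniform slice spacing (missing slices?): range ",
           signif(min(dz), 6), " to ", signif(max(dz), 6), " mm")
    sz <- mean(dz)
  } else {
    sz <- dcm_nums(slices[[1]][["00180050"]])
    if (!length(sz) || is.na(sz)) sz <- 1
  }
  ps <- dcm_nums(slices[[1]][["00280030"]])  # (row, col) = (y, x)
  nx <- cols[1]; ny <- rows[1]
  arr <- array(0, c(nx, ny, length(slices)))
  for (z in seq_along(slices)) {
    s <- slices[[z]]
    slope <- dcm_nums(s[["00281053"]]); icpt <- dcm_nums(s[["00281052"]])
    if (!length(slope) || slope == 0) stop("invalid RescaleSlope")
    px <- readBin(s[["7FE00010"]]$raw, "integer", n = nx * ny, size = 2L,
                  signed = FALSE, endian = "little")
    arr[, , z] <- px * slope + icpt
  }
  origin <- dcm_nums(slices[[1]][["00200032"]])
  cta_volume(arr, spacing = c(ps[2], ps[1], sz), origin = origin)
}
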