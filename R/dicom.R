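# Minimal single-frame DICOM I/O: uncompressed little-endian transfer
# syntaxes only (implicit 1.2.840.10008.1.2 and explicit 1.2.840.10008.1.2.1),
# one axial slice per file, 16-bit monochrome pixels. This covers the
# exported T1 series this planner consumes; enhanced multi-frame objects,
# compressed syntaxes and sequences of undefined length are rejected.

.dcm.explicit <- "1.2.840.10008.1.2.1"
.dcm.implicit <- "1.2.840.10008.1.2"
.dcm.longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.rawstr <- function(v) {
  v <- v[v != as.raw(0)]
  sub("\\s+$", "", rawToChar(v))
}

.u16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}
.u32 <- function(raw, at) {
  as.integer(raw[at]) + 256 * as.integer(raw[at + 1L]) +
    65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
}

# Parse one data element at offset `at`; returns list(tag, value_raw, next).
.dcm.element <- function(raw, at, explicit) {
  g <- .u16(raw, at); e <- .u16(raw, at + 2L)
  tag <- sprintf("%04X,%04X", g, e)
  if (explicit) {
    vr <- rawToChar(raw[(at + 4L):(at + 5L)])
    if (vr %in% .dcm.longVRs) {
      len <- .u32(raw, at + 8L)
      hdr <- 12L
    } else {
      len <- .u16(raw, at + 6L)
      hdr <- 8L
    }
  } else {
    vr <- NA_character_
    len <- .u32(raw, at + 4L)
    hdr <- 8L
  }
  if (is.na(len) || len < 0 || len == 4294967295)
    stop("unsupported undefined-length DICOM element at tag ", tag)
  val <- if (len > 0) raw[(at + hdr):(at + hdr + len - 1L)] else raw(0)
  list(tag = tag, vr = vr, value = val, nxt = at + hdr + len)
}

.dcm.parse <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  at <- 133L
  ts <- .dcm.explicit
  # file meta group (0002,xxxx) is always explicit VR little endian
  while (at + 8L <= length(raw) && .u16(raw, at) == 2L) {
    el <- .dcm.element(raw, at, explicit = TRUE)
    if (el$tag == "0002,0010") ts <- .rawstr(el$value)
    at <- el$nxt
  }
  explicit <- switch(ts,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2" = FALSE,
    stop("unsupported DICOM transfer syntax: ", ts))
  out <- list()
  while (at + 8L <= length(raw)) {
    el <- .dcm.element(raw, at, explicit)
    out[[el$tag]] <- el
    at <- el$nxt
  }
  out
}

.dcm.str <- function(els, tag) {
  el <- els[[tag]]
  if (is.null(el)) return(NA_character_)
  .rawstr(el$value)
}
.dcm.num <- function(els, tag) {
  s <- .dcm.str(els, tag)
  if (is.na(s) || !nzchar(s)) return(NA_real_)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.dcm.us <- function(els, tag) {
  el <- els[[tag]]
  if (is.null(el)) return(NA_integer_)
  .u16(el$value, 1L)
}

#' Read a DICOM series into a VoxelVolume
#'
#' Reads every single-frame DICOM file in a directory, sorts the slices
#' into a consistent stack (by image position projected on the slice
#' normal when present, else by instance number), and assembles the
#' \code{rows x cols x n_slices} volume. Spacing comes from PixelSpacing
#' and the inter-slice step.
#'
#' @param directory directory holding one DICOM file per axial slice.
#' @param pattern filename regexp (default all files).
#' @return A \linkS4class{VoxelVolume}.
#' @export
readDicomSeries <- function(directory, pattern = NULL) {
  files <- list.files(directory, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("empty directory: no DICOM files in ", directory)
  slices <- lapply(files, .dcm.parse)
  R <- vapply(slices, .dcm.us, 1L, tag = "0028,0010")
  C <- vapply(slices, .dcm.us, 1L, tag = "0028,0011")
  if (any(is.na(R)) || any(is.na(C)))
    stop("DICOM file lacks Rows/Columns")
  if (length(unique(R)) != 1L || length(unique(C)) != 1L)
    stop("inconsistent slice dimensions across the series")
  R <- R[1]; C <- C[1]
  bits <- vapply(slices, .dcm.us, 1L, tag = "0028,0100")
  if (any(!is.na(bits) & bits != 16L))
    stop("only 16-bit pixel data is supported")

  # sort key: projection of ImagePositionPatient on the slice normal
  pos <- lapply(slices, .dcm.num, tag = "0020,0032")
  orient <- .dcm.num(slices[[1]], "0020,0037")
  key <- rep(NA_real_, length(slices))
  if (all(vapply(pos, length, 1L) == 3L) && length(orient) == 6L) {
    nrm <- c(orient[2] * orient[6] - orient[3] * orient[5],
             orient[3] * orient[4] - orient[1] * orient[6],
             orient[1] * orient[5] - orient[2] * orient[4])
    key <- vapply(pos, function(p) sum(p * nrm), 0)
  }
  if (any(is.na(key))) {
    key <- vapply(slices, function(s) .dcm.num(s, "0020,0013")[1], 0)
    if (any(is.na(key))) stop("slices carry neither position nor instance number")
  }
  if (anyDuplicated(key) && length(slices) > 1L)
    stop("unsortable series: duplicated slice positions")
  ord <- order(key)
  slices <- slices[ord]

  vol <- array(0, dim = c(R, C, length(slices)))
  for (i in seq_along(slices)) {
    el <- slices[[i]][["7FE0,0010"]]
    if (is.null(el)) stop("DICOM file lacks PixelData")
    vals <- readBin(el$value, "integer", n = R * C, size = 2L,
                    signed = FALSE, endian = "little")
    if (length(vals) != R * C) stop("truncated PixelData")
    vol[, , i] <- matrix(vals, nrow = R, byrow = TRUE)
  }
  ps <- .dcm.num(slices[[1]], "0028,0030")
  if (length(ps) != 2L || any(is.na(ps))) ps <- c(1, 1)
  dz <- NA_real_
  if (length(slices) > 1L) {
    k <- sort(key)
    dz <- stats::median(diff(k))
  }
  if (is.na(dz) || dz <= 0) {
    dz <- .dcm.num(slices[[1]], "0018,0088")[1]
    if (is.na(dz)) dz <- .dcm.num(slices[[1]], "0018,0050")[1]
    if (is.na(dz) || dz <= 0) dz <- 1
  }
  VoxelVolume(vol, spacing = c(ps[1], ps[2], dz))
}

.dcm.pad <- function(s) {          # space-padded to even length
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, charToRaw(" "))
  r
}
.dcm.padn <- function(s) {         # NUL-padded (UI values)
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, as.raw(0))
  r
}
.w16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.w32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.dcm.el.short <- function(g, e, vr, val) {
  c(.w16(g), .w16(e), charToRaw(vr), .w16(length(val)), val)
}
.dcm.el.long <- function(g, e, vr, val) {
  c(.w16(g), .w16(e), charToRaw(vr), as.raw(c(0, 0)), .w32(length(val)), val)
}

#' Write a VoxelVolume as a single-frame DICOM series
#'
#' Emits one explicit-VR little-endian MR Image file per axial slice with
#' fresh instance identifiers. Intensities are stored as 16-bit integers
#' clipped to [0, 32767].
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param directory output directory (created if needed).
#' @param seriesNumber integer series number.
#' @return the directory, invisibly.
#' @export
writeDicomSeries <- function(volume, directory, seriesNumber = 1L) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume)
  sp <- spacing(volume)
  uidRoot <- "1.2.826.0.1.3680043.9999"
  stamp <- format(Sys.time(), "%Y%m%d%H%M%S")
  studyUID <- paste0(uidRoot, ".1.", stamp)
  seriesUID <- paste0(uidRoot, ".2.", stamp, ".", seriesNumber)
  sopClass <- "1.2.840.10008.5.1.4.1.1.4"  # MR Image Storage
  data <- intensities(volume)
  data <- pmin(pmax(round(data), 0), 32767)
  for (s in seq_len(d[3])) {
    sopUID <- paste0(seriesUID, ".", s)
    meta <- c(
      .dcm.el.long(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      .dcm.el.short(0x0002, 0x0002, "UI", .dcm.padn(sopClass)),
      .dcm.el.short(0x0002, 0x0003, "UI", .dcm.padn(sopUID)),
      .dcm.el.short(0x0002, 0x0010, "UI", .dcm.padn(.dcm.explicit)),
      .dcm.el.short(0x0002, 0x0012, "UI", .dcm.padn(paste0(uidRoot, ".0.1"))))
    grplen <- .dcm.el.short(0x0002, 0x0000, "UL", .w32(length(meta)))
    px <- as.vector(t(data[, , s]))  # row-major pixel order
    body <- c(
      .dcm.el.short(0x0008, 0x0016, "UI", .dcm.padn(sopClass)),
      .dcm.el.short(0x0008, 0x0018, "UI", .dcm.padn(sopUID)),
      .dcm.el.short(0x0008, 0x0060, "CS", .dcm.pad("MR")),
      .dcm.el.short(0x0020, 0x000D, "UI", .dcm.padn(studyUID)),
      .dcm.el.short(0x0020, 0x000E, "UI", .dcm.padn(seriesUID)),
      .dcm.el.short(0x0020, 0x0011, "IS", .dcm.pad(as.character(seriesNumber))),
      .dcm.el.short(0x0020, 0x0013, "IS", .dcm.pad(as.character(s))),
      .dcm.el.short(0x0020, 0x0032, "DS",
                    .dcm.pad(sprintf("0\\0\\%g", (s - 1) * sp[3]))),
      .dcm.el.short(0x0020, 0x0037, "DS", .dcm.pad("1\\0\\0\\0\\1\\0")),
      .dcm.el.short(0x0018, 0x0050, "DS", .dcm.pad(sprintf("%g", sp[3]))),
      .dcm.el.short(0x0018, 0x0088, "DS", .dcm.pad(sprintf("%g", sp[3]))),
      .dcm.el.short(0x0028, 0x0002, "US", .w16(1L)),
      .dcm.el.short(0x0028, 0x0004, "CS", .dcm.pad("MONOCHROME2")),
      .dcm.el.short(0x0028, 0x0010, "US", .w16(d[1])),
      .dcm.el.short(0x0028, 0x0011, "US", .w16(d[2])),
      .dcm.el.short(0x0028, 0x0030, "DS",
                    .dcm.pad(sprintf("%g\\%g", sp[1], sp[2]))),
      .dcm.el.short(0x0028, 0x0100, "US", .w16(16L)),
      .dcm.el.short(0x0028, 0x0101, "US", .w16(16L)),
      .dcm.el.short(0x0028, 0x0102, "US", .w16(15L)),
      .dcm.el.short(0x0028, 0x0103, "US", .w16(0L)),
      .dcm.el.long(0x7FE0, 0x0010, "OW",
                   writeBin(as.integer(px), raw(), size = 2L, endian = "little")))
    out <- c(as.raw(rep(0, 128)), charToRaw("DICM"), grplen, meta, body)
    writeBin(out, file.path(directory, sprintf("slice_%04d.dcm", s)))
  }
  invisible(directory)
}
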