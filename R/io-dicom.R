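## Minimal DICOM support: single-frame, uncompressed, explicit-VR
## little-endian series, which covers the axial T2 exports the pipeline
## consumes. No R DICOM reader is available in the dependency set, so the
## subset needed here (spatial tags + 16-bit pixel data) is parsed directly.

.DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.VR_LONG <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dicomParseFile <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  u16 <- function(p) as.integer(raw[p]) + 256L * as.integer(raw[p + 1L])
  u32 <- function(p) as.integer(raw[p]) + 256 * as.integer(raw[p + 1L]) +
    65536 * as.integer(raw[p + 2L]) + 16777216 * as.numeric(raw[p + 3L])
  pos <- 133L
  n <- length(raw)
  tags <- list()
  while (pos + 7L <= n) {
    group <- u16(pos)
    elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .VR_LONG) {
      len <- u32(pos + 8L)
      hdr <- 12L
    } else {
      len <- u16(pos + 6L)
      hdr <- 8L
    }
    if (len >= 4294967295)
      stop("undefined-length DICOM elements unsupported: ", path)
    key <- sprintf("%04X,%04X", group, elem)
    if (vr == "SQ") {
      pos <- pos + hdr + len  # skip sequences wholesale
      next
    }
    val <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    tags[[key]] <- list(vr = vr, value = val)
    pos <- pos + hdr + len
  }
  ts <- .dicomString(tags, "0002,0010")
  if (!is.na(ts) && ts != .DICOM_EXPLICIT_LE)
    stop("unsupported DICOM transfer syntax ", ts, ": ", path)
  tags
}

.dicomString <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NA_character_)
  v <- t$value[t$value != as.raw(0)]  # strip NUL padding before conversion
  if (!length(v)) return("")
  trimws(rawToChar(v))
}

.dicomNumeric <- function(tags, key) {
  s <- .dicomString(tags, key)
  if (is.na(s) || !nzchar(s)) return(NA_real_)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dicomUS <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NA_integer_)
  readBin(t$value, "integer", n = 1, size = 2, signed = FALSE,
          endian = "little")
}

.axisCode <- function(v) {
  ## patient-axis letter for an (approximately) axis-aligned direction vector
  i <- which.max(abs(v))
  if (abs(abs(v[i]) - 1) > 1e-3 || sum(abs(v[-i])) > 1e-3)
    stop("oblique DICOM series are not supported")
  codes <- rbind(c("L", "R"), c("P", "A"), c("S", "I"))
  codes[i, if (v[i] > 0) 1L else 2L]
}

.flipAxis <- function(arr, axis) {
  idx <- lapply(dim(arr), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

## reorient an array with per-axis patient codes into the canonical LPS frame
.reorientCanonical <- function(arr, codes, spacing) {
  target <- c("L", "P", "S")
  pair <- c(L = "L", R = "L", P = "P", A = "P", S = "S", I = "S")
  perm <- match(target, pair[codes])
  if (anyNA(perm)) stop("orientation codes do not span the patient axes")
  arr <- aperm(arr, perm)
  codes <- codes[perm]
  spacing <- spacing[perm]
  for (a in 1:3) if (codes[a] != target[a]) arr <- .flipAxis(arr, a)
  list(data = arr, spacing = spacing)
}

#' Read a single-frame DICOM series as a volume
#'
#' Slices are sorted by their through-plane position (so the on-disk file
#' order is irrelevant), pixel spacing is taken from the in-plane spacing
#' tags and the slice interval from the sorted positions, and the volume is
#' reoriented into the canonical patient frame using the image-orientation
#' metadata. Only uncompressed, explicit-VR little-endian, axis-aligned
#' series are supported.
#'
#' @param directory directory containing exactly one DICOM series.
#' @param series_pattern optional regular expression; only files whose
#'   SeriesDescription matches are used.
#' @return A [VolumeImage-class].
#' @export
readDicomSeries <- function(directory, series_pattern = NULL) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in DICOM directory: ", directory)
  parsed <- lapply(files, .dicomParseFile)
  if (!is.null(series_pattern)) {
    keep <- vapply(parsed, function(t) {
      sd <- .dicomString(t, "0008,103E")
      !is.na(sd) && grepl(series_pattern, sd)
    }, logical(1))
    parsed <- parsed[keep]
    if (!length(parsed)) stop("no series matches pattern: ", series_pattern)
  }
  uids <- vapply(parsed, .dicomString, character(1), key = "0020,000E")
  if (length(unique(uids)) > 1L)
    stop("directory contains more than one series: ",
         paste(unique(uids), collapse = ", "))

  first <- parsed[[1]]
  iop <- .dicomNumeric(first, "0020,0037")
  if (length(iop) != 6 || anyNA(iop))
    stop("missing image orientation metadata")
  d1 <- iop[1:3]; d2 <- iop[4:6]
  d3 <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  ps <- .dicomNumeric(first, "0028,0030")
  if (length(ps) != 2 || anyNA(ps)) stop("missing pixel spacing metadata")
  rows <- .dicomUS(first, "0028,0010")
  cols <- .dicomUS(first, "0028,0011")
  if (is.na(rows) || is.na(cols)) stop("missing image dimension metadata")

  proj <- vapply(parsed, function(t) {
    ipp <- .dicomNumeric(t, "0020,0032")
    if (length(ipp) != 3 || anyNA(ipp)) stop("missing image position metadata")
    sum(ipp * d3)
  }, numeric(1))
  ord <- order(proj)
  parsed <- parsed[ord]
  proj <- proj[ord]

  if (length(parsed) > 1L) {
    gaps <- diff(proj)
    gap <- median(gaps)
    if (any(abs(gaps - gap) > 0.01 * abs(gap)))
      warning("non-uniform slice gaps; proceeding with the median gap")
  } else {
    gap <- .dicomNumeric(first, "0018,0088")
    if (is.na(gap)) gap <- .dicomNumeric(first, "0018,0050")
    if (is.na(gap)) stop("cannot determine slice interval for a single slice")
  }

  slices <- lapply(parsed, function(t) {
    px <- t[["7FE0,0010"]]
    if (is.null(px)) stop("missing pixel data")
    bits <- .dicomUS(t, "0028,0100")
    if (!identical(bits, 16L)) stop("only 16-bit pixel data supported")
    v <- readBin(px$value, "integer", n = rows * cols, size = 2,
                 signed = FALSE, endian = "little")
    slope <- .dicomNumeric(t, "0028,1053")
    icpt <- .dicomNumeric(t, "0028,1052")
    if (!is.na(slope)) v <- v * slope
    if (!is.na(icpt)) v <- v + icpt
    ## pixel stream is row-major: the fastest-running index follows the row
    ## direction d1, so axis 1 of the matrix is the d1 axis
    matrix(v, nrow = cols, ncol = rows)
  })
  arr <- array(unlist(slices), dim = c(cols, rows, length(slices)))
  codes <- c(.axisCode(d1), .axisCode(d2), .axisCode(d3))
  spacing <- c(ps[2], ps[1], abs(gap))
  can <- .reorientCanonical(arr, codes, spacing)
  sdesc <- .dicomString(first, "0008,103E")
  VolumeImage(can$data, can$spacing,
              meta = list(series = sdesc, series_uid = uids[1],
                          plane = "axial"))
}

## ---- writer (used to exercise the reader and to export phantoms) ----------

.evenPad <- function(s, nul = FALSE) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, if (nul) as.raw(0) else charToRaw(" "))
  r
}

.u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dicomElement <- function(group, elem, vr, value) {
  out <- c(.u16le(group), .u16le(elem), charToRaw(vr))
  if (vr %in% .VR_LONG) {
    c(out, as.raw(c(0, 0)), .u32le(length(value)), value)
  } else {
    c(out, .u16le(length(value)), value)
  }
}

.dsValue <- function(x) .evenPad(paste(sprintf("%.8g", x), collapse = "\\"))

#' Write a volume as a single-frame DICOM series
#'
#' Writes one explicit-VR little-endian file per axial slice with the spatial
#' metadata (pixel spacing, slice positions, axial orientation) matching the
#' canonical in-memory frame. Intensities are stored as 16-bit integers with
#' rescale slope/intercept tags so the reader recovers them to within
#' quantization precision.
#'
#' @param vol a [VolumeImage-class].
#' @param directory output directory (created if needed).
#' @param series_description SeriesDescription tag value.
#' @param series_uid SeriesInstanceUID (generated if `NULL`).
#' @return Character vector of file paths, invisibly.
#' @export
writeDicomSeries <- function(vol, directory,
                             series_description = "AX T2 PHANTOM",
                             series_uid = NULL) {
  stopifnot(is(vol, "VolumeImage"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol@data)
  sp <- vol@spacing
  if (is.null(series_uid))
    series_uid <- paste0("2.25.", paste(sample(0:9, 12, TRUE), collapse = ""))
  study_uid <- paste0(series_uid, ".1")
  lo <- min(vol@data); hi <- max(vol@data)
  slope <- if (hi > lo) (hi - lo) / 65535 else 1
  stored <- round((vol@data - lo) / slope)
  xs <- .axisCoords(d[1], sp[1])
  ys <- .axisCoords(d[2], sp[2])
  zs <- .axisCoords(d[3], sp[3])
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    px <- writeBin(as.integer(stored[, , k]), raw(), size = 2,
                   endian = "little")
    body <- c(
      .dicomElement(0x0002, 0x0010, "UI", .evenPad(.DICOM_EXPLICIT_LE, nul = TRUE)),
      .dicomElement(0x0008, 0x0018, "UI",
                    .evenPad(sprintf("%s.%d", series_uid, k), nul = TRUE)),
      .dicomElement(0x0008, 0x103E, "LO", .evenPad(series_description)),
      .dicomElement(0x0018, 0x0050, "DS", .dsValue(sp[3])),
      .dicomElement(0x0018, 0x0088, "DS", .dsValue(sp[3])),
      .dicomElement(0x0020, 0x000D, "UI", .evenPad(study_uid, nul = TRUE)),
      .dicomElement(0x0020, 0x000E, "UI", .evenPad(series_uid, nul = TRUE)),
      .dicomElement(0x0020, 0x0013, "IS", .evenPad(as.character(k))),
      .dicomElement(0x0020, 0x0032, "DS", .dsValue(c(xs[1], ys[1], zs[k]))),
      .dicomElement(0x0020, 0x0037, "DS", .dsValue(c(1, 0, 0, 0, 1, 0))),
      .dicomElement(0x0028, 0x0002, "US", .u16le(1)),
      .dicomElement(0x0028, 0x0004, "CS", .evenPad("MONOCHROME2")),
      .dicomElement(0x0028, 0x0010, "US", .u16le(d[2])),
      .dicomElement(0x0028, 0x0011, "US", .u16le(d[1])),
      .dicomElement(0x0028, 0x0030, "DS", .dsValue(c(sp[2], sp[1]))),
      .dicomElement(0x0028, 0x0100, "US", .u16le(16)),
      .dicomElement(0x0028, 0x0101, "US", .u16le(16)),
      .dicomElement(0x0028, 0x0102, "US", .u16le(15)),
      .dicomElement(0x0028, 0x0103, "US", .u16le(0)),
      .dicomElement(0x0028, 0x1052, "DS", .dsValue(lo)),
      .dicomElement(0x0028, 0x1053, "DS", .dsValue(slope)),
      .dicomElement(0x7FE0, 0x0010, "OW", px)
    )
    paths[k] <- file.path(directory, sprintf("slice_%03d.dcm", k))
    con <- file(paths[k], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), body), con)
    close(con)
  }
  invisible(paths)
}
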