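## NIfTI IO through RNifti. Volumes are reoriented at read into the canonical
## patient frame (axis 1 right-to-left, axis 2 anterior-to-posterior, axis 3
## inferior-to-superior) so downstream midline logic never has to consult
## per-file orientation again.

.lpsAffine <- function(spacing, dims) {
  ## canonical frame expressed in NIfTI's RAS world coordinates, volume
  ## centered at the origin
  orig <- (dims - 1) / 2 * spacing
  rbind(c(-spacing[1], 0, 0, orig[1]),
        c(0, -spacing[2], 0, orig[2]),
        c(0, 0, spacing[3], -orig[3]),
        c(0, 0, 0, 1))
}

.readNiftiCanonical <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI volume: ", path)
  code <- attr(RNifti::xform(img), "code")
  if (!is.null(code) && code > 0) {
    RNifti::orientation(img) <- "LPS"
  } else {
    warning("NIfTI file has no qform/sform; assuming canonical LPS axes: ",
            path)
  }
  a <- as.array(img)
  list(data = array(as.vector(a), dim(a)),
       spacing = as.numeric(RNifti::pixdim(img)[1:3]))
}

#' Read a NIfTI intensity volume
#'
#' The volume is reoriented into the canonical patient frame at read, so
#' in-memory data are independent of the on-disk axis ordering.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param meta optional metadata list attached to the result.
#' @return A [VolumeImage-class].
#' @export
readNiftiVolume <- function(path, meta = list()) {
  x <- .readNiftiCanonical(path)
  VolumeImage(x$data, x$spacing, meta = meta)
}

#' Read a NIfTI label map
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param convention `"standard"` (organ codes 0-4 only) or `"legacy-sum"`.
#' @return A [LabelMap-class].
#' @export
readNiftiLabelMap <- function(path, convention = "standard") {
  x <- .readNiftiCanonical(path)
  vals <- unique(as.vector(x$data))
  if (any(vals != round(vals)))
    stop("non-integer voxel values; not a label map: ", path)
  allowed <- if (convention == "standard") 0:4 else 0:8
  bad <- setdiff(vals, allowed)
  if (length(bad))
    stop(sprintf("label value(s) outside the %s convention: %s",
                 convention, paste(sort(bad), collapse = ", ")))
  LabelMap(x$data, x$spacing, convention = convention)
}

#' Write a volume, label map or probability map as NIfTI
#'
#' Label maps are stored as unsigned 8-bit integers (exact, ITK-SNAP
#' compatible with the standard colour indices); intensities and
#' probabilities as 32-bit float.
#'
#' @param x a [VolumeImage-class], [LabelMap-class] or [ProbabilityMap-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
setGeneric("saveNifti", function(x, path) standardGeneric("saveNifti"))

.saveNiftiArray <- function(data, spacing, path, datatype) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  aff <- .lpsAffine(spacing, dim(data))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname saveNifti
setMethod("saveNifti", "VolumeImage", function(x, path)
  .saveNiftiArray(x@data, x@spacing, path, "float"))

#' @rdname saveNifti
setMethod("saveNifti", "LabelMap", function(x, path)
  .saveNiftiArray(x@data, x@spacing, path, "uint8"))

#' @rdname saveNifti
setMethod("saveNifti", "ProbabilityMap", function(x, path)
  .saveNiftiArray(x@data, x@spacing, path, "float"))

#' Validate a label map against the standard organ convention
#'
#' Reports per-label voxel counts, flags values outside the standard
#' convention (for example the legacy overlap code 5) and lists organs that
#' are absent. Never mutates its input.
#'
#' @param map a [LabelMap-class].
#' @return A list of class `"labelValidation"` with elements `counts`
#'   (named voxel counts), `violations` (out-of-convention values),
#'   `organs_absent` and `valid`.
#' @export
validateLabels <- function(map) {
  stopifnot(is(map, "LabelMap"))
  tab <- table(map@data)
  vals <- as.integer(names(tab))
  counts <- as.integer(tab)
  names(counts) <- names(.ORGAN_LABELS)[match(vals, .ORGAN_LABELS)]
  names(counts)[is.na(names(counts))] <- paste0("value_", vals[is.na(match(vals, .ORGAN_LABELS))])
  violations <- setdiff(vals, 0:4)
  absent <- names(.ORGAN_LABELS)[-1][!(.ORGAN_LABELS[-1] %in% vals)]
  structure(list(counts = counts, violations = violations,
                 organs_absent = absent,
                 valid = length(violations) == 0L),
            class = "labelValidation")
}

#' @export
print.labelValidation <- function(x, ...) {
  cat("Label validation:", if (x$valid) "OK" else "VIOLATIONS", "\n")
  cat("  voxel counts:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = " "), "\n")
  if (length(x$violations))
    cat("  out-of-convention values:", paste(x$violations, collapse = ", "), "\n")
  if (length(x$organs_absent))
    cat("  organs absent:", paste(x$organs_absent, collapse = ", "), "\n")
  invisible(x)
}
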