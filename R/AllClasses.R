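#' @useDynLib abdoseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rnorm runif median quantile sd var aggregate
#' @importFrom utils write.csv read.csv packageVersion
NULL

## Organ label convention: 1 = right kidney (red), 2 = left kidney (green),
## 3 = spleen (blue), 4 = liver (yellow); 0 = background. The indices match
## the ITK-SNAP default colour table so exported label maps display with the
## conventional colours.
.ORGAN_LABELS <- c(background = 0L, right_kidney = 1L, left_kidney = 2L,
                   spleen = 3L, liver = 4L)

#' Organ label convention
#'
#' Integer label indices used throughout the package: 1 = right kidney,
#' 2 = left kidney, 3 = spleen, 4 = liver, 0 = background. These match the
#' ITK-SNAP default colour table (red, green, blue, yellow).
#'
#' @return Named integer vector of label indices.
#' @export
#' @examples
#' organLabels()
organLabels <- function() .ORGAN_LABELS

## Canonical in-memory orientation: grid axis 1 increases toward the patient
## left (L), axis 2 toward posterior (P), axis 3 toward superior (S). All
## readers reorient into this frame so the mid-sagittal plane is always a
## constant-index plane along axis 1.
.CANONICAL_AXES <- c("L", "P", "S")

.validSpacing <- function(spacing) {
  is.numeric(spacing) && length(spacing) == 3L && all(is.finite(spacing)) &&
    all(spacing > 0)
}

.validOrientation <- function(orientation) {
  if (!is.character(orientation) || length(orientation) != 3L) return(FALSE)
  axis <- c(L = 1L, R = 1L, P = 2L, A = 2L, S = 3L, I = 3L)[orientation]
  !anyNA(axis) && !anyDuplicated(axis)
}

#' 3D scalar intensity volume
#'
#' An intensity volume on a regular anisotropic lattice, stored in the
#' canonical patient frame (axis 1: right-to-left, axis 2:
#' anterior-to-posterior, axis 3: inferior-to-superior).
#'
#' @slot data 3D numeric array of voxel intensities.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @slot orientation character(3), patient-axis direction of each grid axis.
#' @slot meta list of free-form metadata (subject_id, series description, ...).
#' @export
setClass("VolumeImage",
         representation(data = "array", spacing = "numeric",
                        orientation = "character", meta = "list"),
         prototype(orientation = c("L", "P", "S"), meta = list()))

setValidity("VolumeImage", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (!.validSpacing(object@spacing)) return("spacing must be 3 positive mm values")
  if (!.validOrientation(object@orientation))
    return("orientation must be a signed permutation of the patient axes")
  TRUE
})

#' 3D organ label map
#'
#' An integer label volume congruent with a [VolumeImage]. Under the
#' `"standard"` convention only the values 0 (background), 1 (right kidney),
#' 2 (left kidney), 3 (spleen) and 4 (liver) are permitted; the `"legacy-sum"`
#' convention additionally allows the diagnostic overlap codes produced by
#' [encodeOverlapsSum()].
#'
#' @slot data 3D integer array of labels.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @slot orientation character(3), patient-axis direction of each grid axis.
#' @slot convention `"standard"` or `"legacy-sum"`.
#' @export
setClass("LabelMap",
         representation(data = "array", spacing = "numeric",
                        orientation = "character", convention = "character"),
         prototype(orientation = c("L", "P", "S"), convention = "standard"))

setValidity("LabelMap", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (!.validSpacing(object@spacing)) return("spacing must be 3 positive mm values")
  if (!.validOrientation(object@orientation))
    return("orientation must be a signed permutation of the patient axes")
  if (!object@convention %in% c("standard", "legacy-sum"))
    return("convention must be 'standard' or 'legacy-sum'")
  vals <- unique(as.vector(object@data))
  if (any(vals != round(vals))) return("labels must be integer-valued")
  if (object@convention == "standard") {
    bad <- setdiff(vals, 0:4)
    if (length(bad))
      return(sprintf("out-of-convention label value(s): %s",
                     paste(sort(bad), collapse = ", ")))
  } else {
    bad <- setdiff(vals, 0:10)
    if (length(bad))
      return(sprintf("label value(s) outside legacy-sum range: %s",
                     paste(sort(bad), collapse = ", ")))
  }
  TRUE
})

#' Per-organ probability volume
#'
#' A per-voxel probability map in `[0, 1]` for one organ class, on the native
#' grid of the input volume.
#'
#' @slot data 3D numeric array of probabilities in `[0, 1]`.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @slot orientation character(3), patient-axis direction of each grid axis.
#' @slot organ organ class name ("kidney", "spleen" or "liver").
#' @export
setClass("ProbabilityMap",
         representation(data = "array", spacing = "numeric",
                        orientation = "character", organ = "character"),
         prototype(orientation = c("L", "P", "S"), organ = "kidney"))

setValidity("ProbabilityMap", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (!.validSpacing(object@spacing)) return("spacing must be 3 positive mm values")
  rng <- range(object@data)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    return("probabilities must lie in [0, 1]")
  TRUE
})

#' Trained per-organ segmentation checkpoint
#'
#' Holds the parameters of one trained binary organ network together with the
#' preprocessing configuration used at training time and the validation Dice
#' score the checkpoint achieved.
#'
#' @slot organ organ class ("kidney", "spleen" or "liver").
#' @slot arch list describing the network architecture.
#' @slot params list of parameter arrays.
#' @slot preprocess the [preprocessConfig()] used during training.
#' @slot bestDSC best validation Dice score.
#' @slot bestEpoch epoch at which `bestDSC` was reached.
#' @slot log per-epoch training log (`epoch`, `train_loss`, `val_dsc`).
#' @export
setClass("OrganCheckpoint",
         representation(organ = "character", arch = "list", params = "list",
                        preprocess = "list", bestDSC = "numeric",
                        bestEpoch = "integer", log = "data.frame"))

setValidity("OrganCheckpoint", function(object) {
  if (!object@organ %in% c("kidney", "spleen", "liver"))
    return("organ must be kidney, spleen or liver")
  if (length(object@bestDSC) == 1L &&
      (object@bestDSC < 0 || object@bestDSC > 1))
    return("bestDSC must lie in [0, 1]")
  TRUE
})

#' Phantom subject: image, truth and stratification covariates
#'
#' @slot image synthetic [VolumeImage].
#' @slot truth ground-truth [LabelMap].
#' @slot height_m subject height in metres.
#' @slot sequence_name pulse-sequence stratum tag.
#' @slot subject_id subject identifier.
#' @export
setClass("PhantomSubject",
         representation(image = "VolumeImage", truth = "LabelMap",
                        height_m = "numeric", sequence_name = "character",
                        subject_id = "character"))

setValidity("PhantomSubject", function(object) {
  if (!identical(dim(object@image@data), dim(object@truth@data)))
    return("image and truth must share a grid")
  if (!isTRUE(all.equal(object@image@spacing, object@truth@spacing)))
    return("image and truth must share voxel spacing")
  if (object@height_m <= 0) return("height must be positive")
  TRUE
})

#' Per-organ agreement report
#'
#' One row per organ with the agreement metrics between a reference and a
#' comparison measurement series: Dice score, Lin's concordance, RMSE (mL),
#' mean absolute percent error, zero-error count, Bland-Altman bias and 95%
#' limits (percent scale), and (when observer data are supplied)
#' interobserver SD (mL) and ICC.
#'
#' @slot table data.frame, one row per organ.
#' @slot n_cases number of cases the metrics were computed over.
#' @export
setClass("AgreementReport",
         representation(table = "data.frame", n_cases = "integer"))

## ---- constructors ----------------------------------------------------------

#' Create a VolumeImage
#'
#' @param data 3D numeric array in the canonical patient frame.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param meta optional metadata list.
#' @return A [VolumeImage-class] object.
#' @export
VolumeImage <- function(data, spacing = c(1, 1, 1), meta = list()) {
  storage.mode(data) <- "double"
  new("VolumeImage", data = data, spacing = as.numeric(spacing),
      orientation = .CANONICAL_AXES, meta = meta)
}

#' Create a LabelMap
#'
#' @param data 3D integer array in the canonical patient frame.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param convention `"standard"` (organ codes 0-4) or `"legacy-sum"`.
#' @return A [LabelMap-class] object.
#' @export
LabelMap <- function(data, spacing = c(1, 1, 1), convention = "standard") {
  storage.mode(data) <- "integer"
  new("LabelMap", data = data, spacing = as.numeric(spacing),
      orientation = .CANONICAL_AXES, convention = convention)
}

#' Create a ProbabilityMap
#'
#' @param data 3D numeric array of probabilities in `[0, 1]`.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param organ organ class name.
#' @return A [ProbabilityMap-class] object.
#' @export
ProbabilityMap <- function(data, spacing = c(1, 1, 1), organ = "kidney") {
  storage.mode(data) <- "double"
  new("ProbabilityMap", data = data, spacing = as.numeric(spacing),
      orientation = .CANONICAL_AXES, organ = organ)
}

## ---- accessors -------------------------------------------------------------

#' @rdname voxelData
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelSpacing
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname axisOrientation
#' @export
setGeneric("axisOrientation", function(x) standardGeneric("axisOrientation"))

#' Extract the voxel array
#' @param x a VolumeImage, LabelMap or ProbabilityMap.
#' @return The underlying 3D array.
#' @rdname voxelData
#' @export
setMethod("voxelData", "VolumeImage", function(x) x@data)
#' @rdname voxelData
setMethod("voxelData", "LabelMap", function(x) x@data)
#' @rdname voxelData
setMethod("voxelData", "ProbabilityMap", function(x) x@data)

#' Voxel spacing in mm
#' @param x a VolumeImage, LabelMap or ProbabilityMap.
#' @return numeric(3) voxel edge lengths (mm).
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "VolumeImage", function(x) x@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "LabelMap", function(x) x@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "ProbabilityMap", function(x) x@spacing)

#' Grid-axis orientation codes
#' @param x a VolumeImage, LabelMap or ProbabilityMap.
#' @return character(3) patient-axis codes, canonically `c("L","P","S")`.
#' @rdname axisOrientation
#' @export
setMethod("axisOrientation", "VolumeImage", function(x) x@orientation)
#' @rdname axisOrientation
setMethod("axisOrientation", "LabelMap", function(x) x@orientation)
#' @rdname axisOrientation
setMethod("axisOrientation", "ProbabilityMap", function(x) x@orientation)

#' Label convention of a LabelMap
#' @param x a [LabelMap-class].
#' @return `"standard"` or `"legacy-sum"`.
#' @export
labelConvention <- function(x) {
  stopifnot(is(x, "LabelMap"))
  x@convention
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeImage %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm [%s]\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], paste(object@orientation, collapse = "")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
  if (!is.null(object@meta$subject_id))
    cat("  subject:", object@meta$subject_id, "\n")
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  tab <- table(object@data)
  cat(sprintf("LabelMap %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm (%s convention)\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], object@convention))
  cat("  voxels per label:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "), "\n")
})

setMethod("show", "ProbabilityMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("ProbabilityMap (%s) %d x %d x %d voxels, range [%.3f, %.3f]\n",
              object@organ, d[1], d[2], d[3], min(object@data),
              max(object@data)))
})

setMethod("show", "OrganCheckpoint", function(object) {
  cat(sprintf("OrganCheckpoint: %s network (%s preset), best validation DSC %.4f at epoch %d\n",
              object@organ, object@arch$preset %||% "custom",
              object@bestDSC, object@bestEpoch))
})

setMethod("show", "PhantomSubject", function(object) {
  cat(sprintf("PhantomSubject %s (height %.2f m, sequence %s)\n",
              object@subject_id, object@height_m, object@sequence_name))
  show(object@image)
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport over %d case(s)\n", object@n_cases))
  print(object@table, digits = 4, row.names = FALSE)
})

#' Agreement report as a data.frame
#' @param x an [AgreementReport-class].
#' @param ... ignored.
#' @return The per-organ metric table.
#' @export
as.data.frame.AgreementReport <- function(x, ...) x@table

`%||%` <- function(a, b) if (is.null(a)) b else a
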