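## Ensemble inference: the three organ networks each produce a probability
## volume; voxels above the 50% threshold for more than one organ are
## adjudicated by fixed priority (kidney > spleen > liver), and the merged
## kidney class is split into right/left at the mid-sagittal plane.

#' Run one organ network over a volume
#'
#' Per slice: min-max normalization, crop-free resize to the model input
#' size, forward pass, and resize of the probability slice back to the
#' native grid. Slices are reassembled into a probability volume on the
#' input lattice.
#'
#' @param image a [VolumeImage-class].
#' @param ckpt an [OrganCheckpoint-class].
#' @param batch slices per forward batch.
#' @return A [ProbabilityMap-class] congruent with `image`.
#' @export
inferOrgan <- function(image, ckpt, batch = 8L) {
  stopifnot(is(image, "VolumeImage"), is(ckpt, "OrganCheckpoint"))
  if (!identical(image@orientation, .CANONICAL_AXES))
    stop("volume orientation is not canonical; re-read it through the package readers")
  pp <- ckpt@preprocess
  class(pp) <- "PreprocessConfig"
  d <- dim(image@data)
  nz <- d[3]
  size <- pp$infer_size
  xs <- array(0, c(size, size, 1L, nz))
  invs <- vector("list", nz)
  for (z in seq_len(nz)) {
    tf <- inferTransform(minmaxNormalize(image@data[, , z]), pp)
    xs[, , 1L, z] <- tf$image
    invs[[z]] <- tf$inverse
  }
  prob_model <- .forwardBatched(ckpt@params, xs, batch)
  out <- array(0, d)
  for (z in seq_len(nz))
    out[, , z] <- restoreNative(prob_model[, , 1L, z], invs[[z]])
  ProbabilityMap(out, image@spacing, organ = ckpt@organ)
}

#' Threshold per-organ probability maps into binary claims
#'
#' A voxel is positive for an organ iff its probability strictly exceeds the
#' cutoff (ties at the cutoff are negative, so 0.5 exactly is background).
#'
#' @param claims named list of congruent [ProbabilityMap-class] objects
#'   (names `kidney`, `spleen`, `liver`).
#' @param threshold probability cutoff (default 0.5).
#' @return Named list of logical 3D arrays.
#' @export
thresholdClaims <- function(claims, threshold = 0.5) {
  stopifnot(length(claims) >= 1)
  dims <- lapply(claims, function(p) dim(voxelData(p)))
  if (!all(vapply(dims, identical, logical(1), y = dims[[1]])))
    stop("claim maps are not congruent")
  lapply(claims, function(p) voxelData(p) > threshold)
}

.CLASS_INDEX <- c(kidney = 1L, right_kidney = 1L, left_kidney = 2L,
                  spleen = 3L, liver = 4L)
.PRIORITY <- c("kidney", "spleen", "liver")

#' Adjudicate overlapping organ claims by fixed priority
#'
#' Every voxel receives the single highest-priority claiming class, with
#' priority kidney > spleen > liver (kidney/liver overlaps default to the
#' kidney; spleen/liver overlaps to the spleen). Unclaimed voxels are
#' background. The kidney class carries the provisional label 1 until
#' [splitKidneysMidline()] assigns sides.
#'
#' @param masks named list of congruent logical arrays with names among
#'   `kidney`, `spleen`, `liver`.
#' @param spacing_mm voxel spacing of the output map.
#' @return A [LabelMap-class] with values in \{0, 1, 3, 4\}.
#' @export
adjudicatePriority <- function(masks, spacing_mm = c(1, 1, 1)) {
  stopifnot(all(names(masks) %in% .PRIORITY))
  d <- dim(masks[[1]])
  out <- array(0L, d)
  for (organ in rev(.PRIORITY)) {    # write low priority first; higher overwrites
    if (is.null(masks[[organ]])) next
    out[masks[[organ]]] <- .CLASS_INDEX[[organ]]
  }
  LabelMap(out, spacing_mm)
}

#' Legacy sum-based overlap encoding (diagnostic)
#'
#' The historical conflict handling: voxels claimed by a single organ keep
#' the standard index; voxels claimed by several organs receive the sum of
#' the claiming indices (e.g. right kidney 1 + liver 4 = 5, displayed pink in
#' ITK-SNAP), leaving the conflict for visual adjudication. The encoding is
#' ambiguous (2+3 and 1+4 both give 5), which is why it was replaced by
#' [adjudicatePriority()]; it is kept for audit only - see
#' [sumOverlapAudit()].
#'
#' @param masks named list of congruent logical arrays with names among
#'   `kidney`, `right_kidney`, `left_kidney`, `spleen`, `liver`.
#' @param spacing_mm voxel spacing of the output map.
#' @return A [LabelMap-class] with `"legacy-sum"` convention.
#' @export
encodeOverlapsSum <- function(masks, spacing_mm = c(1, 1, 1)) {
  stopifnot(all(names(masks) %in% names(.CLASS_INDEX)))
  d <- dim(masks[[1]])
  out <- array(0L, d)
  for (organ in names(masks))
    out <- out + masks[[organ]] * .CLASS_INDEX[[organ]]
  LabelMap(out, spacing_mm, convention = "legacy-sum")
}

#' Audit table for the legacy sum encoding
#'
#' Lists every sum code reachable from the supplied organ set together with
#' the claim combinations that produce it, flagging codes that are ambiguous
#' (more than one combination) or that collide with a standard single-organ
#' index.
#'
#' @param masks named list as in [encodeOverlapsSum()].
#' @return data.frame with columns `code`, `combinations`, `ambiguous`,
#'   `collides_with_single`.
#' @export
sumOverlapAudit <- function(masks) {
  organs <- names(masks)
  idx <- .CLASS_INDEX[organs]
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(organs)))
  names(combos) <- organs
  combos <- combos[rowSums(combos) >= 1, , drop = FALSE]
  code <- as.integer(as.matrix(combos) %*% idx)
  lab <- apply(combos, 1, function(r) paste(organs[as.logical(r)], collapse = "+"))
  multi <- rowSums(combos) > 1
  out <- do.call(rbind, lapply(sort(unique(code)), function(cd) {
    sel <- code == cd
    data.frame(code = cd,
               combinations = paste(lab[sel], collapse = " | "),
               ambiguous = sum(sel) > 1,
               collides_with_single = any(multi[sel]) && cd %in% .CLASS_INDEX,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Split the merged kidney class at the mid-sagittal plane
#'
#' Kidney voxels on the patient-left of the volume's mid-sagittal plane
#' become left kidney (2); all others, including voxels exactly on the
#' plane, stay right kidney (1). Non-kidney labels are untouched. The plane
#' is the mid-sagittal plane of the volume grid, not an anatomical landmark,
#' so a kidney crossing the midline is split geometrically (a known failure
#' mode that is accepted).
#'
#' @param map a [LabelMap-class] whose kidney voxels carry label 1 (and
#'   possibly 2, making the operation idempotent).
#' @return A standard-convention [LabelMap-class].
#' @export
splitKidneysMidline <- function(map) {
  stopifnot(is(map, "LabelMap"))
  if (!identical(map@orientation, .CANONICAL_AXES))
    stop("unknown or non-canonical orientation; cannot locate the midline")
  d <- dim(map@data)
  mid <- (d[1] + 1) / 2    # axis 1 increases toward the patient left
  kid <- map@data == 1L | map@data == 2L
  out <- map@data
  out[kid] <- 1L
  left <- slice.index(map@data, 1) > mid
  out[kid & left] <- 2L
  LabelMap(out, map@spacing)
}

#' Full multi-organ ensemble inference
#'
#' Composition of the pipeline stages: per-organ inference, 50% probability
#' thresholding, priority adjudication (kidney > spleen > liver), and the
#' midline kidney split. The output is a standard-convention label map on
#' the input grid.
#'
#' @param image a [VolumeImage-class].
#' @param checkpoints named list of [OrganCheckpoint-class] objects with
#'   names `kidney`, `spleen`, `liver`.
#' @param threshold probability cutoff (default 0.5).
#' @param batch slices per forward batch.
#' @return A standard-convention [LabelMap-class].
#' @export
runEnsemble <- function(image, checkpoints, threshold = 0.5, batch = 8L) {
  stopifnot(all(c("kidney", "spleen", "liver") %in% names(checkpoints)))
  claims <- lapply(checkpoints[c("kidney", "spleen", "liver")],
                   function(ck) inferOrgan(image, ck, batch = batch))
  masks <- thresholdClaims(claims, threshold)
  adj <- adjudicatePriority(masks, spacing_mm = image@spacing)
  splitKidneysMidline(adj)
}
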