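## Slice-level preprocessing. The spatial paths are deliberately asymmetric:
## training uses the map-to-640 / center-crop-to-512 scheme, while inference
## uses a crop-free direct resize so organs near the image border (typically
## the liver) are never truncated.

#' Preprocessing configuration
#'
#' @param train_map_size side length slices are mapped to during training
#'   (aspect-preserving, zero-padded).
#' @param train_crop_size side length of the symmetric center crop applied
#'   after mapping (training only).
#' @param infer_size side length of the crop-free resize used at inference.
#' @param augment list of augmentation toggles and magnitudes:
#'   `enabled`, `rotate_deg` (max |rotation|), `scale` (max relative scale
#'   change), `translate` (max translation as a fraction of the side),
#'   `hflip` (allow horizontal flips), `brightness`, `contrast`
#'   (max additive / multiplicative intensity jitter).
#' @param image_interp interpolation for intensities (`"bilinear"`).
#' @param label_interp interpolation for labels (`"nearest"`; labels must
#'   stay categorical).
#' @return A list of class `"PreprocessConfig"`.
#' @export
preprocessConfig <- function(train_map_size = 640L, train_crop_size = 512L,
                             infer_size = 512L,
                             augment = list(enabled = TRUE, rotate_deg = 10,
                                            scale = 0.1, translate = 0.05,
                                            hflip = TRUE, brightness = 0.1,
                                            contrast = 0.1),
                             image_interp = "bilinear",
                             label_interp = "nearest") {
  stopifnot(train_map_size > 0, train_crop_size > 0, infer_size > 0,
            train_crop_size <= train_map_size)
  structure(list(train_map_size = as.integer(train_map_size),
                 train_crop_size = as.integer(train_crop_size),
                 infer_size = as.integer(infer_size),
                 augment = augment,
                 image_interp = image_interp, label_interp = label_interp),
            class = "PreprocessConfig")
}

#' Serialize / read a preprocessing configuration
#'
#' Plain key=value text, one key per line; augmentation keys are prefixed
#' with `augment.`.
#'
#' @param cfg a [preprocessConfig()].
#' @param path file path.
#' @return `readPreprocessConfig` returns a `PreprocessConfig`.
#' @export
writePreprocessConfig <- function(cfg, path) {
  flat <- c(train_map_size = as.character(cfg$train_map_size),
            train_crop_size = as.character(cfg$train_crop_size),
            infer_size = as.character(cfg$infer_size),
            image_interp = cfg$image_interp,
            label_interp = cfg$label_interp,
            stats::setNames(vapply(cfg$augment, as.character, character(1)),
                            paste0("augment.", names(cfg$augment))))
  writeLines(paste(names(flat), flat, sep = "="), path)
  invisible(path)
}

#' @rdname writePreprocessConfig
#' @export
readPreprocessConfig <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  num <- function(k) as.numeric(vals[[k]])
  lgl <- function(k) vals[[k]] %in% c("TRUE", "true", "1")
  aug <- list(enabled = lgl("augment.enabled"),
              rotate_deg = num("augment.rotate_deg"),
              scale = num("augment.scale"),
              translate = num("augment.translate"),
              hflip = lgl("augment.hflip"),
              brightness = num("augment.brightness"),
              contrast = num("augment.contrast"))
  preprocessConfig(num("train_map_size"), num("train_crop_size"),
                   num("infer_size"), augment = aug,
                   image_interp = vals[["image_interp"]],
                   label_interp = vals[["label_interp"]])
}

#' Min-max normalize a slice
#'
#' Maps the slice minimum to 0.0 and the maximum to 1.0. A constant slice
#' maps to all zeros: such slices carry no contrast, and zeroing them marks
#' them as uninformative without a divide-by-zero.
#'
#' @param slice 2D numeric matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
minmaxNormalize <- function(slice) {
  if (!all(is.finite(slice))) stop("slice contains non-finite values")
  lo <- min(slice); hi <- max(slice)
  if (hi == lo) return(array(0, dim(slice)))
  (slice - lo) / (hi - lo)
}

.resize2d <- function(m, w, h, interp) {
  out <- EBImage::resize(m, w = w, h = h,
                         filter = if (interp == "nearest") "none" else "bilinear")
  array(EBImage::imageData(out), dim = c(w, h))
}

.padCenter <- function(m, size, fill = 0) {
  d <- dim(m)
  out <- array(fill, c(size, size))
  o1 <- floor((size - d[1]) / 2)
  o2 <- floor((size - d[2]) / 2)
  out[o1 + seq_len(d[1]), o2 + seq_len(d[2])] <- m
  out
}

.cropCenter <- function(m, size) {
  d <- dim(m)
  o1 <- floor((d[1] - size) / 2)
  o2 <- floor((d[2] - size) / 2)
  m[o1 + seq_len(size), o2 + seq_len(size)]
}

#' Training-path spatial transform
#'
#' Maps a slice to `train_map_size` squared (aspect-preserving resize of the
#' longer side, zero-padding the shorter) and center-crops to
#' `train_crop_size` squared. Image and label receive the identical geometry
#' (bilinear vs. nearest interpolation).
#'
#' @param slice normalized 2D intensity matrix.
#' @param label congruent 2D integer label matrix.
#' @param cfg a [preprocessConfig()].
#' @return list with `image` and `label`, both `train_crop_size` squared.
#' @export
trainTransform <- function(slice, label, cfg = preprocessConfig()) {
  stopifnot(identical(dim(slice), dim(label)))
  d <- dim(slice)
  s <- cfg$train_map_size / max(d)
  nd <- pmax(1L, round(d * s))
  nd[which.max(d)] <- cfg$train_map_size
  img <- .resize2d(slice, nd[1], nd[2], cfg$image_interp)
  lab <- .resize2d(label, nd[1], nd[2], "nearest")
  img <- .padCenter(img, cfg$train_map_size)
  lab <- .padCenter(lab, cfg$train_map_size)
  lab <- .cropCenter(lab, cfg$train_crop_size)
  storage.mode(lab) <- "integer"   # nearest-neighbour keeps labels categorical
  list(image = .cropCenter(img, cfg$train_crop_size), label = lab)
}

#' Inference-path spatial transform (crop-free)
#'
#' Direct resize to `infer_size` squared with no cropping, so the full field
#' of view reaches the model. Returns the inverse descriptor consumed by
#' [restoreNative()].
#'
#' @param slice normalized 2D intensity matrix.
#' @param cfg a [preprocessConfig()].
#' @return list with `image` (`infer_size` squared) and `inverse`
#'   (descriptor holding the native dimensions).
#' @export
inferTransform <- function(slice, cfg = preprocessConfig()) {
  d <- dim(slice)
  img <- if (all(d == cfg$infer_size)) slice else
    .resize2d(slice, cfg$infer_size, cfg$infer_size, cfg$image_interp)
  list(image = img, inverse = list(native_dim = d))
}

#' Map a model-resolution probability slice back to the native grid
#'
#' @param prob_slice 2D probability matrix produced at model resolution.
#' @param inverse inverse descriptor from [inferTransform()].
#' @return Probability matrix at the native resolution, values in `[0, 1]`.
#' @export
restoreNative <- function(prob_slice, inverse) {
  if (min(prob_slice) < 0 || max(prob_slice) > 1)
    stop("probabilities must lie in [0, 1]")
  d <- inverse$native_dim
  if (all(dim(prob_slice) == d)) return(prob_slice)
  out <- .resize2d(prob_slice, d[1], d[2], "bilinear")
  pmin(pmax(out, 0), 1)
}

#' Paired augmentation of a slice and its label
#'
#' Applies the identical random spatial transform (horizontal flip, rotation,
#' isotropic scaling, translation) to image and label, plus intensity jitter
#' to the image only. Labels are interpolated with nearest neighbour so they
#' stay integer-valued. Deterministic given `seed`.
#'
#' @param slice normalized 2D intensity matrix.
#' @param label congruent 2D integer label matrix.
#' @param cfg a [preprocessConfig()]; `cfg$augment` controls magnitudes.
#' @param seed integer RNG seed.
#' @return list with `image` and `label`.
#' @export
augmentPair <- function(slice, label, cfg = preprocessConfig(), seed = 1L) {
  stopifnot(identical(dim(slice), dim(label)))
  a <- cfg$augment
  if (!isTRUE(a$enabled)) return(list(image = slice, label = label))
  set.seed(seed)
  d <- dim(slice)
  img <- slice
  lab <- label

  if (isTRUE(a$hflip) && runif(1) < 0.5) {
    img <- img[rev(seq_len(d[1])), , drop = FALSE]
    lab <- lab[rev(seq_len(d[1])), , drop = FALSE]
  }

  ang <- runif(1, -a$rotate_deg, a$rotate_deg)
  if (abs(ang) > 1e-8) {
    img <- array(EBImage::imageData(
      EBImage::rotate(img, ang, filter = "bilinear", output.dim = d,
                      bg.col = 0)), d)
    lab <- array(EBImage::imageData(
      EBImage::rotate(lab, ang, filter = "none", output.dim = d,
                      bg.col = 0)), d)
  }

  sc <- 1 + runif(1, -a$scale, a$scale)
  if (abs(sc - 1) > 1e-8) {
    nd <- pmax(1L, round(d * sc))
    rimg <- .resize2d(img, nd[1], nd[2], "bilinear")
    rlab <- .resize2d(lab, nd[1], nd[2], "nearest")
    if (sc >= 1) {
      img <- .cropCenter2(rimg, d)
      lab <- .cropCenter2(rlab, d)
    } else {
      img <- .padCenter2(rimg, d)
      lab <- .padCenter2(rlab, d)
    }
  }

  tr <- round(runif(2, -a$translate, a$translate) * d)
  if (any(tr != 0)) {
    img <- .translate2(img, tr)
    lab <- .translate2(lab, tr)
  }

  img <- img + runif(1, -a$brightness, a$brightness)
  img <- img * (1 + runif(1, -a$contrast, a$contrast))
  img <- pmin(pmax(img, 0), 1)
  storage.mode(lab) <- "integer"
  list(image = img, label = lab)
}

.cropCenter2 <- function(m, d) {
  o1 <- floor((dim(m)[1] - d[1]) / 2)
  o2 <- floor((dim(m)[2] - d[2]) / 2)
  m[o1 + seq_len(d[1]), o2 + seq_len(d[2]), drop = FALSE]
}

.padCenter2 <- function(m, d, fill = 0) {
  out <- array(fill, d)
  o1 <- floor((d[1] - dim(m)[1]) / 2)
  o2 <- floor((d[2] - dim(m)[2]) / 2)
  out[o1 + seq_len(dim(m)[1]), o2 + seq_len(dim(m)[2])] <- m
  out
}

.translate2 <- function(m, tr, fill = 0) {
  d <- dim(m)
  out <- array(fill, d)
  src1 <- seq_len(d[1]) - tr[1]
  src2 <- seq_len(d[2]) - tr[2]
  ok1 <- src1 >= 1 & src1 <= d[1]
  ok2 <- src2 >= 1 & src2 <= d[2]
  out[which(ok1), which(ok2)] <- m[src1[ok1], src2[ok2]]
  out
}
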