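## Synthetic abdominal phantom: piecewise-constant ellipsoidal organs with
## bright spherical cysts on a darker background, plus additive Gaussian
## noise. Voxel membership is decided by center-point containment so that
## brute-force lattice scans are an exact oracle for organ volumes.

#' Default per-organ ellipsoid parameters
#'
#' Centers are in mm in the canonical patient frame (axis 1 increases toward
#' the patient left), relative to the volume center. Base intensities follow
#' T2-weighted contrast: liver darkest, kidney parenchyma intermediate,
#' spleen brighter, fluid-filled cysts brightest.
#'
#' @return Named list of per-organ parameter lists (center, semiaxes,
#'   intensity).
#' @export
defaultOrganParams <- function() {
  list(
    right_kidney = list(center = c(-95, 30, -30), semiaxes = c(42, 38, 65),
                        intensity = 0.45),
    left_kidney  = list(center = c(95, 30, -30), semiaxes = c(42, 38, 65),
                        intensity = 0.45),
    spleen       = list(center = c(120, -30, 55), semiaxes = c(36, 28, 45),
                        intensity = 0.65),
    liver        = list(center = c(-75, -60, 35), semiaxes = c(90, 50, 65),
                        intensity = 0.25)
  )
}

#' Default per-organ cyst parameters
#'
#' Cysts are hyperintense spheres fully contained in their parent organ; they
#' alter the image only, never the truth labels. Spleens in ADPKD are
#' typically enlarged without cysts, so the spleen gets none.
#'
#' @return Named list with `count`, `radius_mm` (range) and `intensity` per
#'   organ.
#' @export
defaultCystParams <- function() {
  list(
    right_kidney = list(count = 10L, radius_mm = c(4, 14), intensity = 1.0),
    left_kidney  = list(count = 10L, radius_mm = c(4, 14), intensity = 1.0),
    spleen       = list(count = 0L, radius_mm = c(3, 8), intensity = 1.0),
    liver        = list(count = 5L, radius_mm = c(3, 10), intensity = 1.0)
  )
}

#' Phantom specification
#'
#' Bundles everything [generatePhantom()] needs: grid geometry, per-organ
#' ellipsoids, cyst burden, noise level and RNG seed.
#'
#' @param grid_shape integer(3), voxels per axis.
#' @param spacing_mm numeric(3), voxel edge lengths in mm.
#' @param organ_params per-organ ellipsoid list, see [defaultOrganParams()].
#' @param cyst_params per-organ cyst list, see [defaultCystParams()].
#' @param background_intensity base intensity outside all organs.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed integer RNG seed.
#' @return A list of class `"PhantomSpec"`.
#' @export
#' @examples
#' spec <- phantomSpec(noise_sd = 0)
#' subj <- generatePhantom(spec)
phantomSpec <- function(grid_shape = c(64L, 64L, 24L),
                        spacing_mm = c(6, 6, 9),
                        organ_params = defaultOrganParams(),
                        cyst_params = defaultCystParams(),
                        background_intensity = 0.08,
                        noise_sd = 0.02,
                        seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            .validSpacing(spacing_mm), noise_sd >= 0)
  for (org in names(organ_params)) {
    p <- organ_params[[org]]
    if (any(p$semiaxes <= 0))
      stop("all semi-axes must be positive (organ ", org, ")")
  }
  rk <- organ_params$right_kidney$center[1]
  lk <- organ_params$left_kidney$center[1]
  sp <- organ_params$spleen$center[1]
  if (!is.null(rk) && rk >= 0)
    stop("right kidney center must lie on the patient-right of the midline")
  if ((!is.null(lk) && lk <= 0) || (!is.null(sp) && sp <= 0))
    stop("left kidney and spleen centers must lie on the patient-left of the midline")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 organ_params = organ_params,
                 cyst_params = cyst_params,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

## voxel-center coordinates (mm) along one axis, volume center at the origin
.axisCoords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

## logical mask of voxels whose centers fall inside an ellipsoid
.ellipsoidMask <- function(grid_shape, spacing, center, semiaxes) {
  cx <- (.axisCoords(grid_shape[1], spacing[1]) - center[1]) / semiaxes[1]
  cy <- (.axisCoords(grid_shape[2], spacing[2]) - center[2]) / semiaxes[2]
  cz <- (.axisCoords(grid_shape[3], spacing[3]) - center[3]) / semiaxes[3]
  q <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  q < 1
}

#' Generate one phantom subject
#'
#' Renders the organ ellipsoids of a [phantomSpec()] into a truth label map
#' and a noisy intensity volume. Truth labels are decided by voxel-center
#' containment; cysts are hyperintense spheres drawn fully inside their
#' parent organ and belong to that organ in the truth. Generation is
#' deterministic given `spec$seed`.
#'
#' @param spec a [phantomSpec()].
#' @param subject_id subject identifier.
#' @param height_m subject height (m).
#' @param sequence_name pulse-sequence stratum tag.
#' @return A [PhantomSubject-class].
#' @export
generatePhantom <- function(spec, subject_id = "phantom-001",
                            height_m = 1.70, sequence_name = "ssfse_t2") {
  stopifnot(inherits(spec, "PhantomSpec"))
  gs <- spec$grid_shape
  sp <- spec$spacing_mm
  organs <- names(spec$organ_params)
  masks <- lapply(spec$organ_params, function(p)
    .ellipsoidMask(gs, sp, p$center, p$semiaxes))

  ## reject overlapping organ ellipsoids, naming the colliding pair
  for (i in seq_along(masks)) {
    for (j in seq_len(i - 1L)) {
      if (any(masks[[i]] & masks[[j]]))
        stop(sprintf("organ ellipsoids overlap: %s / %s",
                     organs[j], organs[i]))
    }
  }

  truth <- array(0L, dim = gs)
  img <- array(spec$background_intensity, dim = gs)
  for (org in organs) {
    lab <- .ORGAN_LABELS[[org]]
    truth[masks[[org]]] <- lab
    img[masks[[org]]] <- spec$organ_params[[org]]$intensity
  }

  ## cysts: spheres fully inside the parent organ, image-only
  set.seed(spec$seed)
  xs <- .axisCoords(gs[1], sp[1]); ys <- .axisCoords(gs[2], sp[2])
  zs <- .axisCoords(gs[3], sp[3])
  for (org in organs) {
    cp <- spec$cyst_params[[org]]
    if (is.null(cp) || cp$count < 1L) next
    op <- spec$organ_params[[org]]
    amin <- min(op$semiaxes)
    for (k in seq_len(cp$count)) {
      r <- runif(1, cp$radius_mm[1], cp$radius_mm[2])
      ## rejection-sample a center so the sphere stays inside the ellipsoid
      for (try in 1:50) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        rad <- runif(1)^(1 / 3)
        c0 <- op$center + u * rad * (op$semiaxes)
        m <- sqrt(sum(((c0 - op$center) / op$semiaxes)^2))
        if (m <= 1 - r / amin) break
        c0 <- NULL
      }
      if (is.null(c0)) next
      ix <- which(abs(xs - c0[1]) <= r); iy <- which(abs(ys - c0[2]) <= r)
      iz <- which(abs(zs - c0[3]) <= r)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (xs[ix] - c0[1])^2; dy2 <- (ys[iy] - c0[2])^2
      dz2 <- (zs[iz] - c0[3])^2
      inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) < r^2
      sub <- img[ix, iy, iz, drop = FALSE]
      sub[inside] <- cp$intensity
      img[ix, iy, iz] <- sub
    }
  }

  if (spec$noise_sd > 0)
    img <- img + array(rnorm(prod(gs), 0, spec$noise_sd), dim = gs)

  new("PhantomSubject",
      image = VolumeImage(img, sp, meta = list(subject_id = subject_id,
                                               series = sequence_name,
                                               plane = "axial")),
      truth = LabelMap(truth, sp),
      height_m = height_m, sequence_name = sequence_name,
      subject_id = subject_id)
}

#' Generate a phantom cohort
#'
#' Draws `n_subjects` jittered variants of a base [phantomSpec()]:
#' per-subject global kidney scale (driving the TKV spread used for quartile
#' stratification), per-organ/axis semi-axis jitter, center jitter, subject
#' height, and a pulse-sequence tag. Reproducible given `seed`.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param base_spec base [phantomSpec()]; per-subject seeds are derived.
#' @param scale_jitter SD of the multiplicative semi-axis jitter.
#' @param position_jitter_mm SD (mm) of the organ-center jitter.
#' @param tkv_spread SD of the per-subject global kidney scale factor.
#' @param sequences pulse-sequence tags to sample from.
#' @param seed integer RNG seed.
#' @return List of [PhantomSubject-class] objects.
#' @export
generateCohort <- function(n_subjects, base_spec = phantomSpec(),
                           scale_jitter = 0.06, position_jitter_mm = 5,
                           tkv_spread = 0.15,
                           sequences = c("ssfse_t2", "haste_t2"),
                           seed = 1L) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  subject_seeds <- sample.int(2^30, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    ## jitter draws that collide two organs are redrawn (deterministically,
    ## from the subject's own seed sequence)
    for (attempt in 0:19) {
      set.seed(subject_seeds[i] + attempt)
      d <- list(kidney_scale = exp(rnorm(1, 0, tkv_spread)),
                axis = lapply(base_spec$organ_params, function(p)
                  exp(rnorm(3, 0, scale_jitter))),
                shift = lapply(base_spec$organ_params, function(p)
                  rnorm(3, 0, position_jitter_mm)),
                height = rnorm(1, 1.70, 0.10),
                sequence = sample(sequences, 1),
                seed = sample.int(2^30, 1))
      op <- base_spec$organ_params
      for (org in names(op)) {
        ks <- if (grepl("kidney", org)) d$kidney_scale else 1
        op[[org]]$semiaxes <- op[[org]]$semiaxes * d$axis[[org]] * ks
        op[[org]]$center <- op[[org]]$center + d$shift[[org]]
      }
      spec_i <- base_spec
      spec_i$organ_params <- op
      spec_i$seed <- d$seed
      class(spec_i) <- "PhantomSpec"
      subj <- tryCatch(
        generatePhantom(spec_i, subject_id = sprintf("phantom-%03d", i),
                        height_m = max(d$height, 1.2),
                        sequence_name = d$sequence),
        error = function(e) if (grepl("overlap", conditionMessage(e)) &&
                                  attempt < 19L) NULL else stop(e))
      if (!is.null(subj)) return(subj)
    }
  })
}

#' Cohort manifest
#'
#' Per-subject covariates used for stratified splitting: truth TKV (mL),
#' height, ht-TKV and the pulse-sequence tag.
#'
#' @param cohort list of [PhantomSubject-class] objects.
#' @return data.frame with one row per subject.
#' @export
cohortManifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    rk <- organVolume(s@truth, "right_kidney")
    lk <- organVolume(s@truth, "left_kidney")
    data.frame(subject_id = s@subject_id, height_m = s@height_m,
               sequence_name = s@sequence_name, TKV_truth_mL = rk + lk,
               stringsAsFactors = FALSE)
  }))
}

## shift a logical 3D mask by one voxel along an axis (zero fill)
.shift1 <- function(m, axis, dir) {
  d <- dim(m)
  out <- array(FALSE, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (n < 2L) return(out)
  if (dir > 0) {
    idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1L)
  } else {
    idx_dst[[axis]] <- 1:(n - 1L); idx_src[[axis]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

.dilate1 <- function(m) {
  out <- m
  for (axis in 1:3) for (dir in c(-1, 1)) out <- out | .shift1(m, axis, dir)
  out
}

.erode1 <- function(m) {
  out <- m
  for (axis in 1:3) for (dir in c(-1, 1)) out <- out & .shift1(m, axis, dir)
  out
}

## 2D one-voxel (4-neighbourhood) dilation / erosion on a slice
.shift2d <- function(m, axis, dir) {
  d <- dim(m)
  out <- matrix(FALSE, d[1], d[2])
  n <- d[axis]
  if (n < 2L) return(out)
  if (axis == 1L) {
    if (dir > 0) out[2:n, ] <- m[1:(n - 1L), ]
    else out[1:(n - 1L), ] <- m[2:n, ]
  } else {
    if (dir > 0) out[, 2:n] <- m[, 1:(n - 1L)]
    else out[, 1:(n - 1L)] <- m[, 2:n]
  }
  out
}

.dilate2d <- function(m) {
  m | .shift2d(m, 1L, 1) | .shift2d(m, 1L, -1) |
    .shift2d(m, 2L, 1) | .shift2d(m, 2L, -1)
}

.erode2d <- function(m) {
  m & .shift2d(m, 1L, 1) & .shift2d(m, 1L, -1) &
    .shift2d(m, 2L, 1) & .shift2d(m, 2L, -1)
}

#' Simulate an observer's contouring of a truth label map
#'
#' Emulates interobserver boundary variability at the scale observers work:
#' contour by contour. For every organ and every axial slice a signed
#' boundary offset is drawn from `N(0, boundary_noise_mm)` and applied as
#' whole-voxel 2D dilation/erosion layers, with the fractional remainder
#' applied as one further layer with matching probability. Organ identities
#' are unchanged; overlaps created by dilation are resolved with kidney
#' priority (right kidney > left kidney > spleen > liver). A scale of 0
#' returns the truth exactly.
#'
#' @param truth a standard-convention [LabelMap-class].
#' @param boundary_noise_mm spatial scale (mm) of the boundary perturbation.
#' @param seed integer RNG seed.
#' @return A perturbed [LabelMap-class].
#' @export
simulateObserver <- function(truth, boundary_noise_mm, seed = 1L) {
  stopifnot(is(truth, "LabelMap"))
  if (boundary_noise_mm < 0) stop("boundary_noise_mm must be non-negative")
  if (boundary_noise_mm == 0) return(truth)
  set.seed(seed)
  step_mm <- min(truth@spacing[1:2])
  d <- dim(truth@data)
  out <- array(0L, d)
  for (org in c("liver", "spleen", "left_kidney", "right_kidney")) {
    lab <- .ORGAN_LABELS[[org]]
    vol <- truth@data == lab
    if (!any(vol)) next
    for (z in seq_len(d[3])) {
      m <- vol[, , z]
      if (!any(m)) next
      offset <- rnorm(1, 0, boundary_noise_mm)
      layers_exact <- abs(offset) / step_mm
      k <- floor(layers_exact)
      if (runif(1) < layers_exact - k) k <- k + 1L
      if (k > 0) {
        for (i in seq_len(k))
          m <- if (offset > 0) .dilate2d(m) else .erode2d(m)
      }
      vol[, , z] <- m
    }
    out[vol] <- lab  # later organs in the loop take precedence
  }
  LabelMap(out, truth@spacing)
}
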