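## Training protocol for the per-organ binary networks: kidney labels are
## merged into one class before training (right/left are recovered later by
## the midline split), subjects are assigned to train/validation strata by
## TKV quartile x pulse sequence, and after every epoch validation Dice is
## computed to keep the best checkpoint.

#' Merge both kidney labels into one binary mask
#'
#' The kidneys are segmented as a single class (model performance is better
#' without distinguishing right from left); the left/right identity is
#' restored after inference by the midline split.
#'
#' @param map a standard-convention [LabelMap-class].
#' @return Logical 3D array: `TRUE` where the voxel is labelled 1 or 2.
#' @export
mergeKidneyLabels <- function(map) {
  stopifnot(is(map, "LabelMap"), labelConvention(map) == "standard")
  map@data == .ORGAN_LABELS[["right_kidney"]] |
    map@data == .ORGAN_LABELS[["left_kidney"]]
}

#' Binary training target for one organ class
#'
#' `"kidney"` delegates to [mergeKidneyLabels()]; `"spleen"` and `"liver"`
#' select their single label.
#'
#' @param map a standard-convention [LabelMap-class].
#' @param organ `"kidney"`, `"spleen"` or `"liver"`.
#' @return Logical 3D array.
#' @export
binaryTarget <- function(map, organ = c("kidney", "spleen", "liver")) {
  organ <- match.arg(organ)
  if (organ == "kidney") return(mergeKidneyLabels(map))
  stopifnot(is(map, "LabelMap"), labelConvention(map) == "standard")
  map@data == .ORGAN_LABELS[[organ]]
}

#' Training configuration
#'
#' @param organ organ class to train ("kidney" covers both kidneys).
#' @param preset model preset, see [buildOrganModel()].
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of epochs.
#' @param lr base learning rate of the rectified-Adam optimizer.
#' @param lookahead_k,lookahead_alpha Lookahead synchronization period and
#'   interpolation factor.
#' @param w_dice,w_ce loss weights of the soft-Dice and cross-entropy terms.
#' @param eps Dice smoothing constant.
#' @param patience epochs without validation-Dice improvement before training
#'   stops (convergence criterion).
#' @param augment apply the augmentation suite to training slices.
#' @param seed RNG seed.
#' @return A list of class `"TrainConfig"`.
#' @export
trainConfig <- function(organ = c("kidney", "spleen", "liver"),
                        preset = "tiny", batch_size = 8L, max_epochs = 30L,
                        lr = 3e-3, lookahead_k = 5L, lookahead_alpha = 0.5,
                        w_dice = 1, w_ce = 1, eps = 1, patience = 10L,
                        augment = FALSE, seed = 1L) {
  organ <- match.arg(organ)
  stopifnot(batch_size >= 1, max_epochs >= 1, eps > 0, lr > 0)
  structure(list(organ = organ, preset = preset,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 lookahead_k = as.integer(lookahead_k),
                 lookahead_alpha = lookahead_alpha, w_dice = w_dice,
                 w_ce = w_ce, eps = eps, patience = as.integer(patience),
                 augment = augment, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Stratified per-subject train/validation split
#'
#' Subjects are binned by TKV quartile crossed with pulse-sequence name, and
#' assigned to the training partition at the requested fraction within each
#' stratum. All scans of a subject stay in the same partition. Deterministic
#' given `seed`.
#'
#' @param manifest data.frame with columns `subject_id`, `TKV_truth_mL` and
#'   `sequence_name` (one row per scan; repeated subjects allowed).
#' @param fraction training fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return A list of class `"SplitSpec"` with `assignments` (subject_id,
#'   partition, stratum), `train` and `validation` subject vectors.
#' @export
stratifiedSplit <- function(manifest, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  subj <- manifest[!duplicated(manifest$subject_id),
                   c("subject_id", "TKV_truth_mL", "sequence_name")]
  if (nrow(subj) < 2) stop("need at least 2 subjects to split")
  brk <- unique(quantile(subj$TKV_truth_mL, probs = 0:4 / 4))
  bin <- if (length(brk) > 2) {
    cut(subj$TKV_truth_mL, breaks = brk, include.lowest = TRUE,
        labels = FALSE)
  } else rep(1L, nrow(subj))
  stratum <- paste(bin, subj$sequence_name, sep = ":")
  set.seed(seed)
  ## largest-remainder allocation: per-stratum quotas that honour the global
  ## training fraction even when strata are small
  strata <- unique(stratum)
  sizes <- vapply(strata, function(s) sum(stratum == s), integer(1))
  exact <- fraction * sizes
  quota <- floor(exact)
  short <- round(fraction * nrow(subj)) - sum(quota)
  if (short > 0) {
    give <- order(exact - quota, decreasing = TRUE)[seq_len(short)]
    quota[give] <- quota[give] + 1L
  }
  partition <- character(nrow(subj))
  for (k in seq_along(strata)) {
    idx <- which(stratum == strata[k])
    tr <- idx[sample.int(length(idx), min(quota[k], length(idx)))]
    partition[idx] <- "validation"
    partition[tr] <- "train"
  }
  ## guarantee both partitions are non-empty
  if (!any(partition == "train")) partition[sample(length(partition), 1)] <- "train"
  if (!any(partition == "validation")) partition[sample(length(partition), 1)] <- "validation"
  structure(list(assignments = data.frame(subject_id = subj$subject_id,
                                          partition = partition,
                                          stratum = stratum,
                                          stringsAsFactors = FALSE),
                 train = subj$subject_id[partition == "train"],
                 validation = subj$subject_id[partition == "validation"]),
            class = "SplitSpec")
}

## assemble a (H, W, 1, N) slice tensor and matching target tensor from a
## list of phantom subjects
.sliceTensor <- function(subjects, organ, augment = FALSE,
                         cfg = NULL, seed = 1L) {
  xs <- list(); ys <- list()
  k <- 0L
  for (s in subjects) {
    img <- s@image@data
    tgt <- binaryTarget(s@truth, organ)
    for (z in seq_len(dim(img)[3])) {
      k <- k + 1L
      sl <- minmaxNormalize(img[, , z])
      lb <- tgt[, , z] * 1L
      if (augment) {
        out <- augmentPair(sl, matrix(as.integer(lb), nrow(lb), ncol(lb)),
                           cfg %||% preprocessConfig(), seed = seed + k)
        sl <- out$image; lb <- out$label
      }
      xs[[k]] <- sl; ys[[k]] <- lb
    }
  }
  d <- dim(xs[[1]])
  x <- array(unlist(xs), dim = c(d[1], d[2], 1L, k))
  y <- array(as.numeric(unlist(ys)), dim = c(d[1], d[2], 1L, k))
  list(x = x, y = y)
}

## pooled Dice over a probability tensor vs. target tensor at threshold 0.5
.pooledDice <- function(prob, target, threshold = 0.5) {
  pred <- prob > threshold
  pos <- target > 0.5
  denom <- sum(pred) + sum(pos)
  if (denom == 0) return(1.0)
  2 * sum(pred & pos) / denom
}

.forwardBatched <- function(params, x, batch = 8L) {
  n <- dim(x)[4]
  out <- array(0, dim(x))
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    out[, , , idx] <- .netForward(params, x[, , , idx, drop = FALSE])$prob
  }
  out
}

#' Train a per-organ binary segmentation network
#'
#' Runs minibatch optimization (rectified Adam wrapped in Lookahead) of the
#' combined soft-Dice + cross-entropy loss on the training partition. After
#' each epoch the pooled validation Dice (threshold 0.5) is computed and the
#' best-scoring parameters are kept; training stops at `max_epochs` or when
#' validation Dice has not improved for `patience` epochs.
#'
#' @param cohort list of [PhantomSubject-class] objects (or any objects with
#'   `image`/`truth` slots and `subject_id`).
#' @param split a [stratifiedSplit()] result.
#' @param cfg a [trainConfig()].
#' @param verbose print per-epoch progress.
#' @return An [OrganCheckpoint-class] holding the best parameters, the
#'   preprocessing configuration, the best validation Dice and the full
#'   per-epoch log.
#' @export
trainOrgan <- function(cohort, split, cfg = trainConfig(), verbose = FALSE) {
  ids <- vapply(cohort, function(s) s@subject_id, character(1))
  train_subj <- cohort[ids %in% split$train]
  val_subj <- cohort[ids %in% split$validation]
  if (!length(train_subj) || !length(val_subj))
    stop("both train and validation partitions must be non-empty")

  pp <- preprocessConfig(infer_size = .presetChannels(cfg$preset)$input_size)
  tr <- .sliceTensor(train_subj, cfg$organ, augment = cfg$augment, cfg = pp,
                     seed = cfg$seed)
  va <- .sliceTensor(val_subj, cfg$organ)
  if (dim(tr$x)[1] != pp$infer_size)
    stop("slice size does not match the model preset input size")

  set.seed(cfg$seed)
  model <- buildOrganModel(cfg$organ, preset = cfg$preset, seed = cfg$seed)
  fast <- model$params
  slow <- fast
  state <- .radamInit(fast)
  n <- dim(tr$x)[4]
  best_dsc <- -Inf
  best_params <- fast
  best_epoch <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_dsc = numeric(0))
  step <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- tr$x[, , , idx, drop = FALSE]
      yb <- tr$y[, , , idx, drop = FALSE]
      fw <- .netForward(fast, xb, keep = TRUE)
      lg <- .lossGrad(fw$prob, yb, cfg$w_dice, cfg$w_ce, cfg$eps)
      grads <- .netBackward(fast, fw$cache, lg$dz)
      upd <- .radamStep(fast, grads, state, lr = cfg$lr)
      fast <- upd$params
      state <- upd$state
      step <- step + 1L
      if (step %% cfg$lookahead_k == 0L) {
        sync <- .lookaheadSync(fast, slow, cfg$lookahead_alpha)
        fast <- sync$fast
        slow <- sync$slow
      }
      losses <- c(losses, lg$loss)
    }
    prob <- .forwardBatched(fast, va$x, cfg$batch_size)
    vd <- .pooledDice(prob, va$y)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = mean(losses), val_dsc = vd))
    if (verbose)
      message(sprintf("[%s] epoch %d loss %.4f val DSC %.4f",
                      cfg$organ, epoch, mean(losses), vd))
    if (vd > best_dsc) {
      best_dsc <- vd
      best_params <- fast
      best_epoch <- epoch
    } else if (epoch - best_epoch >= cfg$patience) {
      break
    }
  }
  new("OrganCheckpoint", organ = cfg$organ, arch = model$arch,
      params = best_params, preprocess = unclass(pp),
      bestDSC = best_dsc, bestEpoch = best_epoch, log = log)
}

#' Save / load an organ checkpoint
#'
#' The checkpoint is a self-describing archive: parameters, architecture,
#' preprocessing configuration and the validation metrics, so a reloaded
#' checkpoint reproduces identical inference outputs.
#'
#' @param ckpt an [OrganCheckpoint-class].
#' @param path file path.
#' @return `loadCheckpoint` returns the [OrganCheckpoint-class].
#' @export
saveCheckpoint <- function(ckpt, path) {
  stopifnot(is(ckpt, "OrganCheckpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(is(ckpt, "OrganCheckpoint"))
  ckpt
}

#' Write a training log as CSV
#'
#' @param ckpt an [OrganCheckpoint-class].
#' @param path output CSV path.
#' @export
writeTrainingLog <- function(ckpt, path) {
  write.csv(ckpt@log, path, row.names = FALSE)
  invisible(path)
}
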